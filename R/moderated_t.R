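#' Empirical-Bayes moderated two-group test
#'
#' Per-feature two-group comparison with variance moderation: each row is
#' fit by a two-group linear model, the residual variances s^2 (on d =
#' n1 + n2 - 2 df) are shrunk towards a prior s0^2 estimated from all
#' features, and the moderated t statistic
#' \deqn{\tilde t = logFC / (\tilde s \sqrt{1/n_1 + 1/n_2}), \quad
#'       \tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)}
#' is referred to a Student t distribution on d + d0 degrees of freedom.
#' With `d0 = 0` the statistic is the ordinary pooled-variance two-sample
#' t; with `d0 = Inf` all features share the prior variance.
#'
#' The prior (d0, s0^2) is estimated by moment matching on log s^2: the
#' excess variance of log s^2 over trigamma(d/2) is inverted through the
#' trigamma function to give d0 (Smyth-style method of moments). If the
#' moment estimate is non-finite (no excess variance), d0 = Inf is used.
#'
#' @param x numeric matrix, features x samples (e.g. the normalized
#'   enrichment assay).
#' @param condition character/factor of "control"/"treated" per column.
#' @param d0 prior degrees of freedom: "estimate" (default), a number, 0
#'   (ordinary t) or Inf (fully shared variance).
#' @param s0sq prior variance; only used when `d0` is given numerically
#'   (estimated otherwise).
#' @return data.frame with columns logFC (mean treated - mean control), t,
#'   p, meanCtrl, meanTrt, s2, df, plus attributes `d0` and `s0sq`.
#'   Features with zero variance and d0 = 0 get NA statistics.
#' @export
moderatedTTest <- function(x, condition, d0 = "estimate", s0sq = NULL) {
    condition <- as.character(condition)
    stopifnot(ncol(x) == length(condition),
              all(condition %in% c("control", "treated")))
    iC <- condition == "control"
    iT <- condition == "treated"
    n1 <- sum(iC); n2 <- sum(iT)
    if (n1 < 2 || n2 < 2)
        stop("at least 2 samples per group are required")
    meanCtrl <- rowMeans(x[, iC, drop = FALSE])
    meanTrt <- rowMeans(x[, iT, drop = FALSE])
    logFC <- meanTrt - meanCtrl
    ssC <- rowSums((x[, iC, drop = FALSE] - meanCtrl)^2)
    ssT <- rowSums((x[, iT, drop = FALSE] - meanTrt)^2)
    d <- n1 + n2 - 2
    s2 <- (ssC + ssT) / d
    if (identical(d0, "estimate")) {
        fit <- estimatePriorVariance(s2, d)
        d0 <- fit$d0
        s0sq <- fit$s0sq
    } else {
        d0 <- as.numeric(d0)
        if (is.null(s0sq)) s0sq <- estimatePriorVariance(s2, d)$s0sq
    }
    if (is.infinite(d0)) {
        sTilde2 <- rep(s0sq, length(s2))
        dfTotal <- Inf
    } else {
        sTilde2 <- (d0 * s0sq + d * s2) / (d0 + d)
        dfTotal <- d + d0
    }
    se <- sqrt(sTilde2 * (1 / n1 + 1 / n2))
    t <- logFC / se
    t[se == 0] <- NA_real_
    p <- 2 * stats::pt(-abs(t), df = dfTotal)
    out <- data.frame(logFC = logFC, t = t, p = p, meanCtrl = meanCtrl,
                      meanTrt = meanTrt, s2 = s2, df = dfTotal)
    attr(out, "d0") <- d0
    attr(out, "s0sq") <- s0sq
    out
}

#' Moment-matching estimate of the variance prior
#'
#' Matches the first two moments of log s^2 to the scaled-F marginal
#' distribution implied by an inverse-chi-square prior on the true
#' variances, using digamma/trigamma inversion.
#'
#' @param s2 residual variances.
#' @param d residual degrees of freedom per feature.
#' @return list(d0, s0sq).
#' @export
estimatePriorVariance <- function(s2, d) {
    z <- log(s2)
    z <- z[is.finite(z)]
    if (length(z) < 2)
        return(list(d0 = Inf, s0sq = mean(s2[s2 > 0], na.rm = TRUE)))
    e <- z - digamma(d / 2) + log(d / 2)
    emean <- mean(e)
    evar <- stats::var(e) - trigamma(d / 2)
    if (!is.finite(evar) || evar <= 0)
        return(list(d0 = Inf, s0sq = exp(emean)))
    d0 <- 2 * trigammaInverse(evar)
    s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    list(d0 = d0, s0sq = s0sq)
}

#' Inverse of the trigamma function
#'
#' Newton iteration on 1/trigamma, which is nearly linear; converges in a
#' handful of steps for all positive arguments.
#'
#' @param y positive value(s).
#' @return x with trigamma(x) = y.
#' @export
trigammaInverse <- function(y) {
    out <- y
    hi <- y > 1e7
    lo <- y < 1e-6
    out[hi] <- 1 / sqrt(y[hi])
    out[lo] <- 1 / y[lo]
    mid <- which(!hi & !lo)
    if (length(mid)) {
        x <- 0.5 + 1 / y[mid]
        for (i in 1:50) {
            tri <- trigamma(x)
            dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2L)
            x <- x + dif
            if (max(-dif / x) < 1e-8) break
        }
        out[mid] <- x
    }
    out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; q values are monotone in p and capped at 1.
#' Missing p values (e.g. zero-variance features under d0 = 0) are excluded
#' from the adjustment and returned as NA.
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed).
#' @return numeric vector of q-values, same length and order.
#' @export
bhAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    q <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    q[ok] <- stats::p.adjust(p[ok], method = "BH")
    q
}
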