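#' Genome layout helpers
#'
#' A genome layout is simply a `Seqinfo` object giving chromosome lengths;
#' `genomeLayout()` builds one from a named vector and `totalLength()`
#' returns the summed genome size G used by the random-placement null.
#'
#' @param chromLengths named numeric vector of chromosome lengths in bp.
#' @return `genomeLayout()`: a Seqinfo; `totalLength()`: numeric(1).
#' @examples
#' gl <- genomeLayout(c(chr1 = 5e7, chr2 = 5e7))
#' totalLength(gl)
#' @export
genomeLayout <- function(chromLengths) {
    if (is.null(names(chromLengths)) || any(!nzchar(names(chromLengths))))
        stop("chromLengths must be a named vector")
    if (any(!is.finite(chromLengths)) || any(chromLengths <= 0))
        stop("all chromosome lengths must be positive")
    Seqinfo(seqnames = names(chromLengths),
            seqlengths = as.integer(chromLengths))
}

#' @param layout a Seqinfo genome layout.
#' @rdname genomeLayout
#' @export
totalLength <- function(layout) {
    sum(as.numeric(seqlengths(layout)))
}

#' Evaluate an expression with a locally-seeded RNG
#'
#' Sets the given seed for the duration of `expr` and restores the previous
#' global RNG state afterwards, so seeded operations never leak RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}
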