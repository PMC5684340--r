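#' qPCR fold change by the 2^-ddCt method
#'
#' Normalizes the target gene's threshold cycle to a reference
#' (housekeeping) gene within each condition (dCt = Ct_target - Ct_ref)
#' and reports fold change of treated over control as 2^-(dCt_trt -
#' dCt_ctrl), assuming perfect per-cycle doubling.
#'
#' @param ctTargetTrt,ctRefTrt treated-condition threshold cycles for the
#'   target and reference genes.
#' @param ctTargetCtrl,ctRefCtrl control-condition threshold cycles.
#' @return fold change (vectorized).
#' @examples
#' foldChangeDdct(24, 20, 26, 20)  # ddCt = -2 -> fold 4
#' @export
foldChangeDdct <- function(ctTargetTrt, ctRefTrt, ctTargetCtrl,
                           ctRefCtrl) {
    dctTrt <- ctTargetTrt - ctRefTrt
    dctCtrl <- ctTargetCtrl - ctRefCtrl
    2^(-(dctTrt - dctCtrl))
}

#' ChIP-qPCR percent input
#'
#' Expresses ChIP enrichment relative to the total input chromatin:
#' the measured input Ct (from the saved `inputFraction` of chromatin) is
#' first adjusted to a 100 percent-input equivalent,
#' `Ct_100 = Ct_input - log2(1/inputFraction)`, and percent input is
#' `100 * 2^-(Ct_ChIP - Ct_100)`. Strictly decreasing in Ct_ChIP; assumes
#' doubling efficiency.
#'
#' @param ctChip ChIP sample threshold cycle.
#' @param ctInput input sample threshold cycle.
#' @param inputFraction fraction of chromatin saved as input (default 0.1,
#'   i.e. 10 percent).
#' @return percent input (vectorized).
#' @examples
#' percentInput(26.678, 25)  # 5 cycles above the 100%-input Ct -> 3.125
#' @export
percentInput <- function(ctChip, ctInput, inputFraction = 0.1) {
    if (any(inputFraction <= 0) || any(inputFraction > 1))
        stop("inputFraction must lie in (0, 1]")
    ct100 <- ctInput - log2(1 / inputFraction)
    100 * 2^(-(ctChip - ct100))
}
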