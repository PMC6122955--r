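#' qRT-PCR relative quantitation
#'
#' Fold value `2^-(Ct - Cc)` for a normalized threshold-cycle difference
#' between target and calibrator.
#'
#' @param ctDiff normalized threshold cycle difference `Ct - Cc`.
#' @return fold value(s).
#' @examples
#' relativeQuantitation(0)   # 1
#' relativeQuantitation(1)   # 0.5
#' @export
relativeQuantitation <- function(ctDiff) {
    2^(-ctDiff)
}

#' ChIP-qPCR percent input
#'
#' Enrichment of immunoprecipitated DNA relative to a fixed fraction of
#' input chromatin: `inputFraction x 2^(ctInput - ctIp)`, expressed as a
#' percentage. With equal threshold cycles the result is the input
#' fraction itself (2% by default).
#'
#' @param ctInput threshold cycle of the input aliquot (> 0).
#' @param ctIp threshold cycle of the immunoprecipitated sample (> 0).
#' @param inputFraction fraction of chromatin used as input (default
#'   0.02, i.e. a 2% input aliquot).
#' @return percent input.
#' @examples
#' chipPercentInput(25, 25)  # 2
#' @export
chipPercentInput <- function(ctInput, ctIp, inputFraction = 0.02) {
    stopifnot(all(ctInput > 0), all(ctIp > 0))
    100 * inputFraction * 2^(ctInput - ctIp)
}

#' Xenograft tumor volume
#'
#' Caliper estimate `length x width^2 / 2` in cubic millimetres.
#'
#' @param length,width tumor dimensions in mm (positive; a width larger
#'   than the length warns but is computed anyway).
#' @return volume in mm^3.
#' @export
tumorVolume <- function(length, width) {
    if (any(length <= 0) || any(width <= 0))
        stop("tumor dimensions must be positive")
    if (any(width > length))
        warning("width exceeds length; check the measurement order")
    length * width^2 / 2
}
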