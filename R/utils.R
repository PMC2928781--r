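#' Round half away from zero
#'
#' Report tables round to a fixed number of decimals with halves away from
#' zero (the convention of the dissection-genetics literature), unlike base
#' [round()]'s round-half-even.
#'
#' @param x Numeric.
#' @param digits Number of decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}
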