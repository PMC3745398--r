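#' Round half away from zero
#'
#' Deterministic commercial rounding used when converting expected allele
#' counts to integers, so that reconstructed tables are identical across
#' platforms (base [round()] rounds half to even).
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Two-sided normal quantile used for all 95% confidence intervals.
Z975 <- stats::qnorm(0.975)

stop_domain <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
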