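#' Round half away from zero
#'
#' Commercial rounding (half away from zero), used wherever the package
#' reproduces table-style display values at one decimal place. Differs from
#' [base::round()], which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places (default 0).
#' @return numeric vector of the same length as `x`.
#' @examples
#' round_half_up(0.45, 1)  # 0.5
#' round(0.45, 1)          # 0.4 (banker's rounding)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Stop with a domain error unless every value in every argument is finite and
# strictly positive. Names in the message come from the call.
check_positive <- function(...) {
  args <- list(...)
  nms <- names(args)
  for (i in seq_along(args)) {
    x <- args[[i]]
    if (!is.numeric(x) || length(x) == 0L || anyNA(x) ||
        any(!is.finite(x)) || any(x <= 0)) {
      stop(sprintf("`%s` must be finite and > 0", nms[i]), call. = FALSE)
    }
  }
  invisible(TRUE)
}
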