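#' Generate synthetic erythrocyte records
#'
#' Draws a reproducible sample of plausible (diameter, thickness) pairs for
#' property-style testing. Diameters are uniform over `d_range` and
#' thicknesses follow `t = ratio * d` with the ratio uniform over
#' `ratio_range`; the default ranges span real mammalian erythrocytes
#' (diameters roughly 2–10 µm) and deliberately straddle both the
#' biconcave-validity boundary (t/d = 0.5) and the computability boundary
#' (t/d = 3/4), so generated sets exercise valid, invalid and not-computable
#' regimes. The MCV column is filled in as the cylinder volume of each pair,
#' so protocol round-trips recover `t` exactly.
#'
#' The caller's RNG state is left untouched.
#'
#' @param n number of records.
#' @param seed integer RNG seed (generation is deterministic given the seed).
#' @param d_range diameter interval, µm (default `c(2, 10)`).
#' @param ratio_range thickness:diameter interval (default `c(0.15, 0.9)`).
#' @return data frame with `species` (synthetic labels), `d_um`, `t_um`,
#'   `mcv_fl`.
#' @examples
#' generate_rbc_sample(5, seed = 1)
#' @export
generate_rbc_sample <- function(n, seed, d_range = c(2, 10),
                                ratio_range = c(0.15, 0.9)) {
  stopifnot(n >= 1, length(d_range) == 2, length(ratio_range) == 2,
            all(d_range > 0), all(ratio_range > 0),
            d_range[1] <= d_range[2], ratio_range[1] <= ratio_range[2])
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  d <- stats::runif(n, d_range[1], d_range[2])
  ratio <- stats::runif(n, ratio_range[1], ratio_range[2])
  t <- ratio * d
  data.frame(species = sprintf("synthetic_%03d", seq_len(n)),
             d_um = d, t_um = t, mcv_fl = pi / 4 * d^2 * t)
}
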