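#' @title Erythrocyte shape models: closed-form volumes and surface areas
#'
#' @description
#' Four solids approximate the mammalian red blood cell, each parameterised
#' by quantities measurable on a blood smear and a complete blood count:
#'
#' * **sphere** — diameter `d` only; adequate for truly spherical cells
#'   (spherocytes, *Tragulus javanicus*).
#' * **cylinder** — diameter `d` and thickness `t`; its volume
#'   \eqn{V_c = (\pi/4) d^2 t} is the workhorse for volume because it inverts
#'   trivially to give thickness from MCV.
#' * **biconcave spheroid** — an oblate spheroid of rotation (equatorial
#'   semi-axis `A = d/2`, polar semi-axis `B = 2t/3`) from which two small cap
#'   spheroids (`a = d/4`, `b = t/8`) are subtracted; the recommended model
#'   for surface area.
#' * **elliptical cylinder** — major/minor diameters `a`, `b` and thickness
#'   `t`; for the flattened elliptic erythrocytes of camelids.
#'
#' All lengths are in micrometres; volumes in \eqn{\mu m^3} (1 fL), areas in
#' \eqn{\mu m^2}. All functions are vectorised and recycle their arguments.
#'
#' @param d cell diameter, µm (> 0).
#' @param t cell thickness, µm (> 0).
#' @name rbc-models
NULL

#' @describeIn rbc-models volume of the sphere, \eqn{(\pi/6) d^3}.
#' @return numeric vector of volumes (µm³) or areas (µm²).
#' @examples
#' sphere_volume(7.2)            # 195.4 um^3, a human-sized cell
#' cylinder_volume(5.5, 2.1)     # 49.9 um^3, mouse
#' biconcave_surface(7.2, 2.2)   # oblate-spheroid closed form
#' @export
sphere_volume <- function(d) {
  check_positive(d = d)
  pi / 6 * d^3
}

#' @describeIn rbc-models surface of the sphere, \eqn{\pi d^2}.
#' @export
sphere_surface <- function(d) {
  check_positive(d = d)
  pi * d^2
}

#' @describeIn rbc-models volume of the cylinder, \eqn{(\pi/4) d^2 t}.
#' @export
cylinder_volume <- function(d, t) {
  check_positive(d = d, t = t)
  pi / 4 * d^2 * t
}

#' @describeIn rbc-models surface of the cylinder,
#'   \eqn{\pi d (d/2 + t)}: two circular faces plus the lateral wall.
#' @export
cylinder_surface <- function(d, t) {
  check_positive(d = d, t = t)
  pi * d * (d / 2 + t)
}

#' Spheroid parameters for the biconcave model
#'
#' Maps the measured pair (diameter, thickness) to the semi-axes of the large
#' oblate spheroid and of the small cap spheroids, using the standard
#' approximations `A = d/2`, `B = 2t/3`, `a = d/4`, `b = t/8`, and the second
#' eccentricity around the minor axis \eqn{e = \sqrt{A^2 - B^2}/B}.
#'
#' `e` is real only while `A >= B`, i.e. `t/d <= 3/4`. Beyond that boundary
#' the eccentricity is imaginary and the surface-area formula has no real
#' value; rather than leak a `NaN`, the result flags this explicitly through
#' `e_imaginary` and sets `e` to `NA`.
#'
#' @inheritParams rbc-models
#' @return A data frame with one row per input cell and columns `d`, `t`,
#'   `A`, `B`, `a`, `b`, `e` (`NA` when imaginary) and the logical flag
#'   `e_imaginary`.
#' @examples
#' spheroid_params(7.2, 2.2)  # normal discocyte, e real
#' spheroid_params(4.0, 7.2)  # spherocyte-like, e imaginary
#' @export
spheroid_params <- function(d, t) {
  check_positive(d = d, t = t)
  n <- max(length(d), length(t))
  d <- rep_len(d, n); t <- rep_len(t, n)
  A <- d / 2
  B <- 2 * t / 3
  imag <- B > A
  e <- ifelse(imag, NA_real_, sqrt(pmax(A^2 - B^2, 0)) / B)
  data.frame(d = d, t = t, A = A, B = B, a = d / 4, b = t / 8,
             e = e, e_imaginary = imag)
}

# asinh(e)/e with a series guard near e = 0: the direct quotient loses
# accuracy by cancellation, and at e = 0 it is 0/0 while the limit is 1.
asinh_over_e <- function(e) {
  small <- e < 1e-4
  out <- numeric(length(e))
  out[small] <- 1 - e[small]^2 / 6 + 3 * e[small]^4 / 40
  out[!small] <- asinh(e[!small]) / e[!small]
  out
}

#' @describeIn rbc-models volume of the spheroid with concave caps,
#'   \eqn{(4/3)\pi A^2 B - 2 (4/3)\pi a^2 b}, which under the stated
#'   substitutions simplifies to \eqn{(29/144)\pi d^2 t}. Always computable
#'   (no eccentricity involved); the ratio to the cylinder volume is exactly
#'   29/36.
#' @export
biconcave_volume <- function(d, t) {
  check_positive(d = d, t = t)
  29 / 144 * pi * d^2 * t
}

#' @describeIn rbc-models surface of the biconcave spheroid,
#'   \eqn{\pi d (d/2 + (2/3) t \sinh^{-1}(e)/e)} — the exact oblate-spheroid
#'   closed form, with the concave caps' surface approximated by the full
#'   spheroid surface. Returns `NA` (with a warning) where the eccentricity
#'   is imaginary, i.e. `t/d > 3/4`; at the boundary `t/d = 3/4` the value is
#'   continuous and equals `sphere_surface(d)`. Use [biconcave_computable()]
#'   to test the domain, or [surface_area_protocol()] for a result object
#'   that carries the reason.
#' @export
biconcave_surface <- function(d, t) {
  p <- spheroid_params(d, t)
  out <- rep(NA_real_, nrow(p))
  ok <- !p$e_imaginary
  out[ok] <- pi * p$d[ok] *
    (p$d[ok] / 2 + 2 / 3 * p$t[ok] * asinh_over_e(p$e[ok]))
  if (any(!ok)) {
    warning(sprintf(
      "surface not computable for %d cell(s): imaginary eccentricity (t/d > 3/4)",
      sum(!ok)), call. = FALSE)
  }
  out
}

#' @describeIn rbc-models `TRUE` where the biconcave surface has a real
#'   value (`t/d <= 3/4`), `FALSE` where the eccentricity is imaginary.
#' @export
biconcave_computable <- function(d, t) {
  !spheroid_params(d, t)$e_imaginary
}

#' Elliptical-cylinder model for camelid erythrocytes
#'
#' Camelids (camels, llamas, alpacas) have flattened elliptic erythrocytes
#' without a central concavity; a cylinder of elliptical cross-section fits
#' them better than any solid of revolution. `a` and `b` are the full major
#' and minor diameters (not semi-axes); with `a = b = d` both formulas reduce
#' exactly to the circular-cylinder ones.
#'
#' @param a major diameter, µm (`a >= b`).
#' @param b minor diameter, µm.
#' @param t thickness, µm.
#' @return numeric vector: volume \eqn{(\pi/4) a b t} (µm³) or surface
#'   \eqn{(\pi/2)(a + b) t + (\pi/2) a b} (µm²).
#' @examples
#' elliptical_cylinder_volume(8, 4, 1)   # 8 * pi
#' elliptical_cylinder_surface(8, 4, 1)  # 22 * pi
#' @name elliptical-cylinder
NULL

#' @rdname elliptical-cylinder
#' @export
elliptical_cylinder_volume <- function(a, b, t) {
  check_positive(a = a, b = b, t = t)
  if (any(rep_len(a, max(length(a), length(b))) <
          rep_len(b, max(length(a), length(b)))))
    stop("`a` must be the major diameter: a >= b", call. = FALSE)
  pi / 4 * a * b * t
}

#' @rdname elliptical-cylinder
#' @export
elliptical_cylinder_surface <- function(a, b, t) {
  check_positive(a = a, b = b, t = t)
  if (any(rep_len(a, max(length(a), length(b))) <
          rep_len(b, max(length(a), length(b)))))
    stop("`a` must be the major diameter: a >= b", call. = FALSE)
  pi / 2 * (a + b) * t + pi / 2 * a * b
}
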