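#' Mean corpuscular volume from hematocrit and red cell count
#'
#' MCV (fL) = hematocrit / RBC count, the standard red-cell index. With the
#' hematocrit as a percentage this is the familiar `10 * Hct% / RBC`; with a
#' volume fraction it is `1000 * Hct / RBC`. The unit of the hematocrit is
#' never guessed: pass `hct_unit` explicitly when using percentages.
#'
#' @param hct hematocrit: a volume fraction in (0, 1) when
#'   `hct_unit = "fraction"` (the default), or a percentage in (0, 100) when
#'   `hct_unit = "percent"`.
#' @param rbc_count red blood cell count, in 10^6 cells/µL (> 0).
#' @param hct_unit `"fraction"` or `"percent"`.
#' @return MCV in femtoliters (1 fL = 1 µm³).
#' @examples
#' mcv_from_count(0.45, 5.5)                       # 81.8 fL
#' mcv_from_count(45, 5.5, hct_unit = "percent")   # identical
#' @export
mcv_from_count <- function(hct, rbc_count, hct_unit = c("fraction", "percent")) {
  hct_unit <- match.arg(hct_unit)
  check_positive(hct = hct, rbc_count = rbc_count)
  if (hct_unit == "percent") {
    if (any(hct >= 100))
      stop("percent hematocrit must be in (0, 100)", call. = FALSE)
    hct <- hct / 100
  } else if (any(hct >= 1)) {
    stop("fraction hematocrit must be in (0, 1); use hct_unit = \"percent\" for percentages",
         call. = FALSE)
  }
  # fraction / (count * 1e6 cells/uL) * 1e9 fL/uL
  1000 * hct / rbc_count
}

#' Cell thickness from diameter and MCV
#'
#' Inverts the cylinder volume \eqn{V = (\pi/4) d^2 t} at `V = MCV`:
#' \eqn{t = 4\,MCV / (\pi d^2)}. The cylinder is used for this inversion
#' because its volume is nearly identical to the biconcave spheroid's over
#' the physiological range while being trivially invertible.
#'
#' @param diameter mean cell diameter, µm (> 0).
#' @param mcv mean corpuscular volume, fL (> 0).
#' @return thickness in µm; exact inverse of [cylinder_volume()].
#' @examples
#' thickness_from_mcv(7.2, 90)  # ~2.21 um, a normal discocyte
#' @export
thickness_from_mcv <- function(diameter, mcv) {
  check_positive(diameter = diameter, mcv = mcv)
  4 * mcv / (pi * diameter^2)
}

#' Validity screen for the biconcave model
#'
#' Two smear-level rules of thumb decide whether the biconcave-spheroid
#' surface formula may be applied, plus the hard eccentricity domain:
#'
#' 1. **central pallor** — if the lighter central region is absent on the
#'    smear the cells are probably spherical and the model is rejected;
#' 2. **thickness:diameter ratio** — if `t/d` is 0.5 or greater the model is
#'    invalid. By default the ratio is rounded to 1 decimal place before the
#'    comparison (so 0.496 counts as 0.5 and fails); set
#'    `ratio_rule = "unrounded"` to compare the raw ratio;
#' 3. **eccentricity domain** — for `t/d > 3/4` the eccentricity is imaginary
#'    and the surface is not computable at all.
#'
#' @param diameter cell diameter, µm.
#' @param thickness cell thickness, µm (typically from [thickness_from_mcv()]).
#' @param central_pallor logical; was a central pallor seen on the smear?
#'   Default `TRUE` (the common case for a discocyte).
#' @param ratio_rule `"rounded_1dp"` (default) or `"unrounded"`.
#' @return A list of class `"rbc_screen"`: `valid` (logical), `ratio` (raw
#'   t/d), `ratio_used` (the value actually compared), `reasons` (character
#'   vector of the rules that fired, empty when valid).
#' @examples
#' screen_validity(7.2, 2.21)             # valid, ratio 0.3
#' screen_validity(5.9, 2.926)            # invalid: ratio rounds to 0.5
#' screen_validity(7.2, 2.21, central_pallor = FALSE)
#' @export
screen_validity <- function(diameter, thickness, central_pallor = TRUE,
                            ratio_rule = c("rounded_1dp", "unrounded")) {
  ratio_rule <- match.arg(ratio_rule)
  check_positive(diameter = diameter, thickness = thickness)
  ratio <- thickness / diameter
  ratio_used <- if (ratio_rule == "rounded_1dp") round_half_up(ratio, 1) else ratio
  reasons <- character(0)
  if (!isTRUE(central_pallor))
    reasons <- c(reasons, "central pallor absent: cells probably spherical")
  if (ratio_used >= 0.5)
    reasons <- c(reasons,
                 sprintf("thickness:diameter ratio %s >= 0.5",
                         format(ratio_used, digits = 3)))
  if (ratio > 3 / 4)
    reasons <- c(reasons, "imaginary eccentricity (t/d > 3/4): surface not computable")
  structure(list(valid = length(reasons) == 0L, ratio = ratio,
                 ratio_used = ratio_used, ratio_rule = ratio_rule,
                 reasons = reasons),
            class = "rbc_screen")
}

#' @export
print.rbc_screen <- function(x, ...) {
  cat(sprintf("biconcave model %s (t/d = %.3f, rule: %s)\n",
              if (x$valid) "valid" else "invalid", x$ratio, x$ratio_rule))
  for (r in x$reasons) cat("  - ", r, "\n", sep = "")
  invisible(x)
}

#' Surface-area estimation protocol
#'
#' The full four-step estimation chain: (1) take the MCV (from the blood
#' count, or via [mcv_from_count()]); (2) take the mean diameter measured on
#' the smear; (3) derive the thickness by cylinder inversion
#' (`t = 4 MCV / (pi d^2)`); (4) screen validity and compute the surface area
#' with the appropriate model:
#'
#' * verdict **valid** → biconcave-spheroid surface ([biconcave_surface()]);
#' * verdict **invalid** (spherical cells) → sphere surface \eqn{\pi d^2}
#'   from the *measured* diameter (or, with
#'   `sphere_diameter = "mcv_equivalent"`, from the diameter of the sphere
#'   whose volume is the MCV, for cross-checking);
#' * `shape_hint = "elliptical"` (camelids) → elliptical-cylinder formulas,
#'   with the thickness from the elliptical inversion
#'   `t = 4 MCV / (pi a b)`; requires `major` and `minor` diameters.
#'
#' The reported volume is always the MCV itself (the cylinder inversion makes
#' `cylinder_volume(d, t) == mcv` an identity). The biconcave surface is
#' never reported when the verdict is invalid; it is carried alongside as
#' `biconcave_sa` (`NA` when not computable) for inspection.
#'
#' @param diameter measured mean cell diameter, µm.
#' @param mcv mean corpuscular volume, fL.
#' @param central_pallor logical; central pallor seen on the smear (default
#'   `TRUE`; the default is recorded in the notes when not supplied).
#' @param shape_hint optional: `"discocyte"` (default behaviour),
#'   `"spherical"` (skip straight to the sphere), or `"elliptical"`
#'   (camelid path).
#' @param major,minor full major/minor diameters, µm; required when
#'   `shape_hint = "elliptical"`.
#' @param ratio_rule passed to [screen_validity()].
#' @param sphere_diameter `"measured"` (default) or `"mcv_equivalent"`:
#'   which diameter the spherical fallback uses.
#' @return A list of class `"rbc_protocol"` with `diameter`, `mcv`,
#'   `thickness`, `ratio`, `valid`, `model_used` (`"biconcave_spheroid"`,
#'   `"sphere"` or `"elliptical_cylinder"`), `volume`, `surface_area` (`NA`
#'   only if no model applies), `biconcave_sa`, `biconcave_computable`, and
#'   `notes` (the rules that fired and defaults that were assumed).
#' @examples
#' surface_area_protocol(7.2, 90)    # normal discocyte: biconcave model
#' surface_area_protocol(4.0, 90)    # spherocyte: invalid, sphere fallback
#' surface_area_protocol(2.2, 5.6)   # Tragulus javanicus: sphere, SA 15.2
#' surface_area_protocol(8, 90, shape_hint = "elliptical", major = 8, minor = 4)
#' @export
surface_area_protocol <- function(diameter, mcv, central_pallor = TRUE,
                                  shape_hint = NULL, major = NULL, minor = NULL,
                                  ratio_rule = c("rounded_1dp", "unrounded"),
                                  sphere_diameter = c("measured", "mcv_equivalent")) {
  ratio_rule <- match.arg(ratio_rule)
  sphere_diameter <- match.arg(sphere_diameter)
  check_positive(diameter = diameter, mcv = mcv)
  notes <- character(0)
  if (missing(central_pallor))
    notes <- c(notes, "central pallor not reported; assumed present")
  if (!is.null(shape_hint))
    shape_hint <- match.arg(shape_hint, c("discocyte", "spherical", "elliptical"))

  if (identical(shape_hint, "elliptical")) {
    if (is.null(major) || is.null(minor))
      stop("shape_hint = \"elliptical\" requires `major` and `minor` diameters",
           call. = FALSE)
    check_positive(major = major, minor = minor)
    if (major < minor) stop("`major` must be >= `minor`", call. = FALSE)
    t <- 4 * mcv / (pi * major * minor)
    res <- list(diameter = diameter, mcv = mcv, thickness = t,
                ratio = t / diameter, valid = NA,
                model_used = "elliptical_cylinder", volume = mcv,
                surface_area = elliptical_cylinder_surface(major, minor, t),
                biconcave_sa = NA_real_, biconcave_computable = NA,
                notes = c(notes, "elliptical (camelid) cell: validity screen not applicable"))
    return(structure(res, class = "rbc_protocol"))
  }

  t <- thickness_from_mcv(diameter, mcv)
  scr <- screen_validity(diameter, t, central_pallor = central_pallor,
                         ratio_rule = ratio_rule)
  if (identical(shape_hint, "spherical") && scr$valid) {
    scr$valid <- FALSE
    scr$reasons <- c(scr$reasons, "shape_hint: spherical")
  }
  bc_ok <- t / diameter <= 3 / 4
  bc_sa <- if (bc_ok) biconcave_surface(diameter, t) else NA_real_

  if (scr$valid) {
    model <- "biconcave_spheroid"
    sa <- bc_sa
  } else {
    model <- "sphere"
    d_use <- if (sphere_diameter == "measured") diameter else (6 * mcv / pi)^(1 / 3)
    sa <- sphere_surface(d_use)
    if (sphere_diameter == "mcv_equivalent")
      notes <- c(notes, sprintf("sphere fallback uses MCV-equivalent diameter %.3f um", d_use))
    if (!bc_ok)
      notes <- c(notes, "biconcave surface n.c. (imaginary eccentricity)")
  }
  structure(list(diameter = diameter, mcv = mcv, thickness = t,
                 ratio = scr$ratio, valid = scr$valid, model_used = model,
                 volume = mcv, surface_area = sa, biconcave_sa = bc_sa,
                 biconcave_computable = bc_ok,
                 notes = c(notes, scr$reasons)),
            class = "rbc_protocol")
}

#' @export
print.rbc_protocol <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "n.c." else sprintf("%.1f", round_half_up(v, 1))
  cat("Erythrocyte surface-area protocol\n")
  cat(sprintf("  diameter      %.2f um   MCV %.1f fL\n", x$diameter, x$mcv))
  cat(sprintf("  thickness     %s um   t/d ratio %s\n",
              fmt(x$thickness), fmt(x$ratio)))
  if (!is.na(x$valid))
    cat(sprintf("  biconcave model %s\n", if (x$valid) "valid" else "invalid"))
  cat(sprintf("  model used    %s\n", x$model_used))
  cat(sprintf("  volume        %s um^3\n", fmt(x$volume)))
  cat(sprintf("  surface area  %s um^2\n", fmt(x$surface_area)))
  for (n in x$notes) cat("  note: ", n, "\n", sep = "")
  invisible(x)
}
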