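#' Absolute percentage error
#'
#' @param calc calculated value(s).
#' @param meas measured reference value(s), > 0.
#' @return `100 * |calc - meas| / meas`, in percent.
#' @examples
#' absolute_percentage_error(22.7, 23.2)
#' @export
absolute_percentage_error <- function(calc, meas) {
  if (!is.numeric(meas) || any(!is.na(meas) & meas <= 0))
    stop("`meas` must be > 0", call. = FALSE)
  100 * abs(calc - meas) / meas
}

#' Mean absolute percentage error
#'
#' The model-fit metric used for cross-species model comparison. Pairs where
#' either value is missing are dropped (pairwise deletion, never imputation);
#' at least one usable pair must remain.
#'
#' @param calc calculated values.
#' @param meas measured reference values (same length).
#' @return MAPE in percent (unrounded).
#' @examples
#' mape(c(95, 124.7, 162.9), c(90.9, 103, 136))  # sphere surface vs measured
#' @export
mape <- function(calc, meas) {
  if (length(calc) != length(meas))
    stop("`calc` and `meas` must have the same length", call. = FALSE)
  ok <- !is.na(calc) & !is.na(meas)
  if (!any(ok)) stop("no usable (calc, meas) pairs", call. = FALSE)
  mean(absolute_percentage_error(calc[ok], meas[ok]))
}

#' Surface of the sphere with a given volume
#'
#' @param volume volume, µm³ (> 0).
#' @return \eqn{(36\pi)^{1/3} V^{2/3}}, µm² — the smallest surface any closed
#'   shape of that volume can have.
#' @examples
#' sphere_equivalent_surface(90)  # ~97.1 um^2
#' @export
sphere_equivalent_surface <- function(volume) {
  check_positive(volume = volume)
  (36 * pi)^(1 / 3) * volume^(2 / 3)
}

#' Excess surface area relative to the equal-volume sphere
#'
#' How much more membrane a cell carries than the sphere of the same volume,
#' in percent. A normal human discocyte (SA ~136 µm², MCV ~90 fL) carries
#' about 40% excess surface — the geometric reserve that makes it deformable.
#' By the isoperimetric inequality no real closed surface can come out
#' negative; a negative result means the (SA, V) pair is inconsistent and a
#' warning is raised.
#'
#' @param sa measured or calculated surface area, µm².
#' @param volume cell volume, µm³.
#' @return percent excess, `100 * (sa / sphere_equivalent_surface(volume) - 1)`.
#' @examples
#' excess_surface_percent(136, 90)  # ~40
#' @export
excess_surface_percent <- function(sa, volume) {
  check_positive(sa = sa, volume = volume)
  out <- 100 * (sa / sphere_equivalent_surface(volume) - 1)
  if (any(out < 0))
    warning("negative excess surface: inputs violate the isoperimetric inequality",
            call. = FALSE)
  out
}

#' Compare shape models against measured volumes or surface areas
#'
#' Builds a comparative table — one row per species or cell type — of the
#' sphere, cylinder and biconcave-spheroid predictions, their absolute
#' percentage errors against a measured reference column, and the per-model
#' MAPE footer.
#'
#' Two routes for the calculated columns:
#' * `columns = "recompute"` (default): evaluate the closed-form models on
#'   each record's `(d_um, t_um)`.
#' * `columns = "printed"`: take calculated columns already present in
#'   `records` (`vs_um3`/`vc_um3`/`vb_um3` or `sas_um2`/`sac_um2`/`sab_um2`)
#'   as given. Useful to audit a published table whose inputs were rounded
#'   for display after the calculations were done.
#'
#' @param records data frame with columns `species`, `d_um`, `t_um` and the
#'   reference column (`mcv_fl` or `sa_um2`); e.g. from [rbc_fixture()] or
#'   [read_rbc_csv()]. Missing reference cells are allowed and excluded from
#'   MAPE.
#' @param reference `"mcv"` (compare volumes) or `"sa"` (compare surfaces).
#' @param columns `"recompute"` or `"printed"`.
#' @return An object of class `"rbc_eval"`: a list with `table` (per-record
#'   values and APEs), `mape` (named per-model vector, percent, unrounded),
#'   `n_used`, `reference` and `columns`.
#' @examples
#' ev <- evaluate_models(rbc_fixture("table1"), reference = "mcv",
#'                       columns = "printed")
#' round_half_up(ev$mape, 1)
#' @export
evaluate_models <- function(records, reference = c("mcv", "sa"),
                            columns = c("recompute", "printed")) {
  reference <- match.arg(reference)
  columns <- match.arg(columns)
  stopifnot(is.data.frame(records))
  if (is.null(records$species)) records$species <- paste0("record_", seq_len(nrow(records)))

  ref_col <- if (reference == "mcv") "mcv_fl" else "sa_um2"
  if (is.null(records[[ref_col]]) || all(is.na(records[[ref_col]])))
    stop(sprintf("reference column `%s` absent or empty", ref_col), call. = FALSE)
  meas <- records[[ref_col]]

  model_cols <- if (reference == "mcv") {
    c(sphere = "vs_um3", cylinder = "vc_um3", biconcave = "vb_um3")
  } else {
    c(sphere = "sas_um2", cylinder = "sac_um2", biconcave = "sab_um2")
  }

  if (columns == "recompute") {
    usable <- !is.na(records$d_um) & !is.na(records$t_um)
    if (any(!usable))
      warning(sprintf("skipping record(s) without d and t: %s",
                      paste(records$species[!usable], collapse = ", ")),
              call. = FALSE)
    d <- records$d_um; t <- records$t_um
    calc <- data.frame(row.names = seq_len(nrow(records)))
    if (reference == "mcv") {
      calc$sphere <- ifelse(usable, pi / 6 * d^3, NA_real_)
      calc$cylinder <- ifelse(usable, pi / 4 * d^2 * t, NA_real_)
      calc$biconcave <- ifelse(usable, 29 / 144 * pi * d^2 * t, NA_real_)
    } else {
      calc$sphere <- ifelse(usable, pi * d^2, NA_real_)
      calc$cylinder <- ifelse(usable, pi * d * (d / 2 + t), NA_real_)
      bc <- rep(NA_real_, nrow(records))
      can <- usable & t / d <= 3 / 4
      if (any(can)) bc[can] <- suppressWarnings(biconcave_surface(d[can], t[can]))
      calc$biconcave <- bc
    }
  } else {
    missing_cols <- setdiff(unname(model_cols), names(records))
    if (length(missing_cols))
      stop(sprintf("columns = \"printed\" needs column(s): %s",
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    calc <- data.frame(sphere = records[[model_cols[["sphere"]]]],
                       cylinder = records[[model_cols[["cylinder"]]]],
                       biconcave = records[[model_cols[["biconcave"]]]])
  }

  tab <- data.frame(species = records$species, measured = meas,
                    sphere = calc$sphere, cylinder = calc$cylinder,
                    biconcave = calc$biconcave)
  for (m in c("sphere", "cylinder", "biconcave")) {
    tab[[paste0("ape_", m)]] <-
      ifelse(is.na(meas) | is.na(calc[[m]]), NA_real_,
             100 * abs(calc[[m]] - meas) / meas)
  }
  mp <- vapply(c("sphere", "cylinder", "biconcave"),
               function(m) mape(calc[[m]], meas), numeric(1))
  n_used <- vapply(c("sphere", "cylinder", "biconcave"),
                   function(m) sum(!is.na(calc[[m]]) & !is.na(meas)), integer(1))
  structure(list(table = tab, mape = mp, n_used = n_used,
                 reference = reference, columns = columns),
            class = "rbc_eval")
}

#' @export
print.rbc_eval <- function(x, digits = 1, ...) {
  unit <- if (x$reference == "mcv") "volume (um^3)" else "surface area (um^2)"
  cat(sprintf("Model comparison against measured %s [%s columns]\n",
              unit, x$columns))
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v)
    ifelse(is.na(v), "n.a.", sprintf(paste0("%.", digits, "f"),
                                     round_half_up(v, digits))))
  print(tab, row.names = FALSE, right = FALSE)
  cat(sprintf("MAPE: sphere %.1f%%  cylinder %.1f%%  biconcave %.1f%%  (n = %s)\n",
              round_half_up(x$mape[["sphere"]], 1),
              round_half_up(x$mape[["cylinder"]], 1),
              round_half_up(x$mape[["biconcave"]], 1),
              paste(x$n_used, collapse = "/")))
  invisible(x)
}

#' @describeIn evaluate_models flatten an evaluation to a data frame with a
#'   MAPE footer row (species label `"MAPE"`), as rendered by the report
#'   writers.
#' @param x an `"rbc_eval"` object.
#' @param ... unused.
#' @export
as.data.frame.rbc_eval <- function(x, ...) {
  tab <- x$table
  footer <- tab[1, ]
  footer[1, ] <- NA
  footer$species <- "MAPE"
  footer$ape_sphere <- x$mape[["sphere"]]
  footer$ape_cylinder <- x$mape[["cylinder"]]
  footer$ape_biconcave <- x$mape[["biconcave"]]
  rbind(tab, footer)
}
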