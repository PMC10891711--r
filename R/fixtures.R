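#' Packaged comparative hematology tables
#'
#' Three small tables ship with the package as plain CSV under
#' `inst/extdata/` and back the model-comparison examples and tests:
#'
#' * `"table1"` — 14 mammalian species with mean diameter `d_um`, mean
#'   thickness `t_um`, measured MCV `mcv_fl`, and the published calculated
#'   volume columns `vs_um3` (sphere), `vc_um3` (cylinder), `vb_um3`
#'   (biconcave spheroid).
#' * `"table2"` — the same 14 species with measured surface area `sa_um2`
#'   (available for mouse, rat and human only; `NA` elsewhere) and the
#'   published calculated surface columns `sas_um2`, `sac_um2`, `sab_um2`.
#' * `"table3"` — 7 worked protocol cases (normal and abnormal human RBC
#'   types plus *Tragulus javanicus*): input `mcv_fl` and `d_um`, published
#'   calculated thickness, surface area, thickness:diameter ratio and the
#'   validity verdict. The spherocyte's surface is not computable and is
#'   flagged by `sa_computable = FALSE` (distinct from a merely unavailable
#'   measurement, which is a plain `NA`).
#'
#' Published calculated columns are stored verbatim so published MAPE rows
#' can be reproduced exactly even where the source's displayed inputs were
#' rounded after calculation.
#'
#' @param name `"table1"`, `"table2"` or `"table3"`.
#' @return A data frame; attribute `"provenance"` describes the packaging.
#' @examples
#' head(rbc_fixture("table1"))
#' subset(rbc_fixture("table2"), !is.na(sa_um2))
#' @export
rbc_fixture <- function(name) {
  known <- c("table1", "table2", "table3")
  if (length(name) != 1L || !name %in% known)
    stop(sprintf("unknown fixture %s; available: %s",
                 deparse(name), paste(known, collapse = ", ")), call. = FALSE)
  path <- system.file("extdata", paste0(name, ".csv"), package = "rbcgeom",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(species = "character"))
  if (name == "table3") {
    tab$sa_computable <- tab$sa_calc_um2 != "n.c."
    tab$sa_calc_um2 <- suppressWarnings(as.numeric(tab$sa_calc_um2))
    tab$valid <- tab$valid == "yes"
  }
  attr(tab, "provenance") <- "packaged comparative hematology table"
  tab
}
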