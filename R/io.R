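#' Read and write species records as CSV
#'
#' The batch-mode CSV dialect: UTF-8, comma-separated, one row per species or
#' cell type, header
#' `species,d_um,t_um,mcv_fl,sa_um2,central_pallor,shape_hint`. Only
#' `species` and `d_um` plus one of `t_um`/`mcv_fl` are required per row;
#' empty cells become `NA` (absent), never zero. `central_pallor` is
#' `true`/`false` (empty = unspecified), `shape_hint` one of `discocyte`,
#' `spherical`, `elliptical` or empty. Extra columns (e.g. the fixtures'
#' published calculated columns, or `n_cells`) are passed through untouched.
#'
#' `write_rbc_csv(read_rbc_csv(path))` round-trips values at full precision
#' (numbers are written with 15 significant digits).
#'
#' @param path file path.
#' @return `read_rbc_csv`: a data frame of species records. `write_rbc_csv`:
#'   `path`, invisibly.
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' write_rbc_csv(rbc_fixture("table1"), tmp)
#' identical(read_rbc_csv(tmp)$mcv_fl, rbc_fixture("table1")$mcv_fl)
#' @export
read_rbc_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), fileEncoding = "UTF-8")
  if (!"species" %in% names(tab) || !"d_um" %in% names(tab))
    stop("malformed header: need at least `species` and `d_um` columns",
         call. = FALSE)
  num_cols <- intersect(c("d_um", "t_um", "mcv_fl", "sa_um2", "n_cells"),
                        names(tab))
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(tab[[cl]]))
    bad <- which(is.na(v) & !is.na(tab[[cl]]))
    if (length(bad))
      stop(sprintf("non-numeric value in column `%s`, row %d (%s)",
                   cl, bad[1], tab$species[bad[1]]), call. = FALSE)
    tab[[cl]] <- v
  }
  no_d <- which(is.na(tab$d_um))
  if (length(no_d))
    warning(sprintf("row(s) missing d_um: %s",
                    paste(tab$species[no_d], collapse = ", ")), call. = FALSE)
  if ("central_pallor" %in% names(tab))
    tab$central_pallor <- as.logical(tab$central_pallor)
  if ("n_cells" %in% names(tab) && any(tab$n_cells < 100, na.rm = TRUE))
    warning("some records are based on fewer than 100 measured cells",
            call. = FALSE)
  tab
}

#' @rdname read_rbc_csv
#' @param records data frame of species records.
#' @export
write_rbc_csv <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v)
    ifelse(is.na(v), "", format(v, digits = 15, scientific = FALSE, trim = TRUE)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the surface-area protocol over a table of records
#'
#' Applies [surface_area_protocol()] to every row of a species-record table
#' (as read by [read_rbc_csv()]) and appends the derived columns
#' `thickness_um`, `ratio`, `model_used`, `valid`, `volume_um3` and
#' `surface_area_um2` (`NA` where not computable).
#'
#' @param records data frame with at least `d_um` and `mcv_fl`; optional
#'   `central_pallor` and `shape_hint` columns are honoured (elliptical rows
#'   additionally need `major_um`/`minor_um`).
#' @param ... passed on to [surface_area_protocol()] (e.g. `ratio_rule`).
#' @return the input data frame with the derived columns appended.
#' @examples
#' tab <- rbc_fixture("table3")
#' protocol_batch(tab)[, c("species", "model_used", "surface_area_um2")]
#' @export
protocol_batch <- function(records, ...) {
  stopifnot(is.data.frame(records), all(c("d_um", "mcv_fl") %in% names(records)))
  n <- nrow(records)
  res <- lapply(seq_len(n), function(i) {
    pallor <- if (!is.null(records$central_pallor) &&
                  !is.na(records$central_pallor[i])) records$central_pallor[i] else TRUE
    hint <- if (!is.null(records$shape_hint) && !is.na(records$shape_hint[i]) &&
                nzchar(records$shape_hint[i])) records$shape_hint[i] else NULL
    surface_area_protocol(records$d_um[i], records$mcv_fl[i],
                          central_pallor = pallor, shape_hint = hint,
                          major = records$major_um[i], minor = records$minor_um[i],
                          ...)
  })
  records$thickness_um <- vapply(res, `[[`, numeric(1), "thickness")
  records$ratio <- vapply(res, `[[`, numeric(1), "ratio")
  records$model_used <- vapply(res, `[[`, character(1), "model_used")
  records$valid <- vapply(res, `[[`, logical(1), "valid")
  records$volume_um3 <- vapply(res, `[[`, numeric(1), "volume")
  records$surface_area_um2 <- vapply(res, `[[`, numeric(1), "surface_area")
  records
}
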