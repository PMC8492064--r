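#' Read and write the package-standard delimited tables
#'
#' Track tables (`track_id`, `frame`, `t_hours`, `x_um`, `y_um`, `tissue`)
#' and nucleus tables (`id`, `x_um`, `y_um`, `z_um`, `sox2`, `bra`, `dapi`,
#' `tissue`) are stored as headered tab-separated text.
#'
#' @param path File path.
#' @param tracks,records Table to write.
#' @return Readers return validated tibbles; writers return `path`
#'   invisibly.
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_track_table <- function(path) {
  as_track_table(readr::read_tsv(path, show_col_types = FALSE))
}

#' @rdname table_io
#' @export
write_track_table <- function(tracks, path) {
  readr::write_tsv(tracks, path)
  invisible(path)
}

#' @rdname table_io
#' @export
read_nucleus_table <- function(path) {
  rec <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("id", "x_um", "y_um", "z_um", "sox2", "bra", "dapi", "tissue")
  missing <- setdiff(need, names(rec))
  if (length(missing)) {
    stop("nucleus table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(rec$sox2)) || any(rec$sox2 < 0) ||
      any(!is.finite(rec$bra)) || any(rec$bra < 0)) {
    stop("intensities must be finite and >= 0", call. = FALSE)
  }
  rec
}

#' @rdname table_io
#' @export
write_nucleus_table <- function(records, path) {
  readr::write_tsv(records, path)
  invisible(path)
}

#' Write simulation snapshots as delimited text
#'
#' @param result A `sim_result`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_snapshots <- function(result, path) {
  stopifnot(inherits(result, "sim_result"))
  readr::write_tsv(result$snapshots, path)
  invisible(path)
}
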