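# TSV readers/writers for the assay tables the pipeline consumes.

#' Read and write the package's delimited assay tables
#'
#' Thin readr wrappers fixing the expected column types. Band tables carry
#' `sample`, `time_min`, `treatment`, `sc_signal`, `rc_signal` (optional
#' `replicate`); blot tables `batch`, `strain`, `channel`, `time_min`,
#' `western`, `southern`; lane profiles `strain`, `replicate`,
#' `timepoint`, `channel`, `position`, `signal`; DRIP tables `digest`,
#' `rnase_treated`, `fraction`, `channel`, `signal`; spot tables
#' `strain`, `dose`, `culture`, `dilution`, `count`, `volume_ml`.
#'
#' @param path File path.
#' @param x Table to write.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @name uvrdh_io
NULL

#' @rdname uvrdh_io
#' @export
read_band_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname uvrdh_io
#' @export
read_blot_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname uvrdh_io
#' @export
read_lane_profiles <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname uvrdh_io
#' @export
read_drip_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname uvrdh_io
#' @export
read_spot_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname uvrdh_io
#' @export
write_assay_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}
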