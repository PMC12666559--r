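#' Read and write pipeline tables
#'
#' Thin typed wrappers around readr for the package's plain-text formats:
#' long trace tables (`cell_id,time_h,hgem,pip`; CSV or TSV by extension),
#' per-frame label tables, per-cell timing tables, and BED3 peak intervals
#' (0-based half-open, as produced by peak callers).
#'
#' @param path File path. `write_*` functions create parent directories.
#' @param x Tibble to write.
#' @return Readers return a tibble; writers return `x` invisibly.
#' @name fucci_io
NULL

delim_for <- function(path) if (grepl("\\.csv$", path)) "," else "\t"

#' @rdname fucci_io
#' @export
read_traces <- function(path) {
  readr::read_delim(path, delim = delim_for(path), show_col_types = FALSE,
                    col_types = readr::cols(
                      cell_id = readr::col_character(),
                      time_h = readr::col_double(),
                      hgem = readr::col_double(),
                      pip = readr::col_double()))
}

write_table_any <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (delim_for(path) == ",") readr::write_csv(x, path)
  else readr::write_tsv(x, path)
  invisible(x)
}

#' @rdname fucci_io
#' @export
write_traces <- function(x, path) write_table_any(x, path)

#' @rdname fucci_io
#' @export
read_timings <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname fucci_io
#' @export
write_timings <- function(x, path) write_table_any(x, path)

#' @rdname fucci_io
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       comment = "#")
  out <- tibble::tibble(chrom = as.character(x[[1]]),
                        start = as.integer(x[[2]]),
                        end = as.integer(x[[3]]))
  if (ncol(x) >= 4) out$region_id <- as.character(x[[4]])
  validate_intervals(out, "bed")
  out
}

#' @rdname fucci_io
#' @export
write_bed <- function(x, path) {
  validate_intervals(x, "x", allow_empty = TRUE)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  cols <- intersect(c("chrom", "start", "end", "region_id"), names(x))
  readr::write_tsv(x[cols], path, col_names = FALSE)
  invisible(x)
}

#' @rdname fucci_io
#' @param sequences Named character vector of sequences (names become FASTA
#'   headers).
#' @export
write_fasta <- function(sequences, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(sequences)
}

#' @rdname fucci_io
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}
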