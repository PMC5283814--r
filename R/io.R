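# Plain-text readers and writers for the pipeline's interchange formats.
# Events and layouts travel as CSV, phase counts and z-scores as TSV,
# sequences as FASTA, gates as JSON.

EVENT_COLS <- c("plate_id", "well", "replicate", "batch", "cell_id",
                "dna_intensity")
LAYOUT_COLS <- c("plate_id", "well", "role", "gene_id", "batch", "replicate")

#' @rdname screen_io
#' @export
write_events <- function(events, path) {
  readr::write_csv(events, path, progress = FALSE)
  invisible(path)
}

#' Read and write screen interchange files
#'
#' `read_events()`/`write_events()` handle per-cell event CSVs (columns
#' `plate_id, well, replicate, batch, cell_id, dna_intensity`, optionally
#' `edu_intensity` and `true_phase`); `read_layout()`/`write_layout()` handle
#' plate layout CSVs (`plate_id, well, role, gene_id, batch, replicate`);
#' `write_phase_counts()` and `write_zscores()` emit TSVs; `write_gates()`
#' and `read_gates()` round-trip gate sets as JSON.
#'
#' @param path File path.
#' @param events,layout,counts,zscores,gates Tables to write.
#' @name screen_io
#' @export
read_events <- function(path) {
  ev <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(ev, EVENT_COLS, path)
  ev
}

#' @rdname screen_io
#' @export
write_layout <- function(layout, path) {
  readr::write_csv(layout, path, progress = FALSE)
  invisible(path)
}

#' @rdname screen_io
#' @export
read_layout <- function(path) {
  lay <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(lay, LAYOUT_COLS, path)
  lay
}

#' @rdname screen_io
#' @export
write_phase_counts <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' @rdname screen_io
#' @export
read_phase_counts <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname screen_io
#' @export
write_zscores <- function(zscores, path) {
  readr::write_tsv(zscore_wide(zscores), path, progress = FALSE)
  invisible(path)
}

#' @rdname screen_io
#' @export
write_gates <- function(gates, path) {
  jsonlite::write_json(as.data.frame(gates), path, digits = NA)
  invisible(path)
}

#' @rdname screen_io
#' @export
read_gates <- function(path) {
  g <- as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  class(g) <- c("gate_set", class(g))
  g
}

#' Write sequences to FASTA
#'
#' @param seqs A [Biostrings::DNAStringSet].
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
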