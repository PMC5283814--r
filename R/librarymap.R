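# Pooled-siRNA to transcript mapping and the four-siRNA single-gene well
# filter: a well is retained only if each of its siRNAs matches at least one
# transcript exactly (no mismatches, antisense convention) and the
# intersection of the per-siRNA gene sets is exactly one gene.

parse_fasta_tag <- function(names, tag) {
  m <- stringr::str_match(names, paste0(tag, "=(\\S+)"))[, 2]
  m
}

#' Read a tagged FASTA file
#'
#' Reads sequences with [Biostrings::readDNAStringSet()] and checks the
#' alphabet is strictly ACGT.
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_sequences <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) abort(sprintf("empty FASTA: %s", path))
  freq <- Biostrings::alphabetFrequency(seqs, collapse = TRUE)
  extra <- sum(freq) - sum(freq[c("A", "C", "G", "T")])
  if (extra > 0) {
    abort(sprintf("%s: sequences must use the ACGT alphabet only.", path))
  }
  seqs
}

#' Map siRNAs to transcripts by exact antisense match
#'
#' An siRNA "maps" to a transcript when its reverse complement occurs as an
#' exact substring of the transcript sequence (the siRNA is antisense to the
#' mRNA); matching is mismatch-free. The gene set of an siRNA is the union of
#' the gene tags of all transcripts it hits.
#'
#' @param sirnas [Biostrings::DNAStringSet] of siRNAs, with `well=` and
#'   `gene=` tags in the names (as written by [simulate_library()]), or a
#'   FASTA path.
#' @param transcripts [Biostrings::DNAStringSet] with `gene=` tags, or a
#'   FASTA path.
#' @return Tibble, one row per siRNA: `sirna_id`, `well_key`, `gene_claimed`,
#'   `n_transcripts`, `genes` (list-column of matched gene ids).
#' @export
map_sirnas <- function(sirnas, transcripts) {
  if (is.character(sirnas)) sirnas <- read_sequences(sirnas)
  if (is.character(transcripts)) transcripts <- read_sequences(transcripts)
  if (length(sirnas) == 0) abort("empty siRNA set.")
  if (length(transcripts) == 0) abort("empty transcript set.")
  sirna_id <- sub("\\s.*$", "", names(sirnas))
  if (anyDuplicated(sirna_id)) abort("duplicate siRNA ids in library.")
  tx_gene <- parse_fasta_tag(names(transcripts), "gene")
  if (anyNA(tx_gene)) abort("every transcript header needs a gene=<id> tag.")

  widths <- Biostrings::width(sirnas)
  rc <- Biostrings::reverseComplement(sirnas)
  # PDict requires constant width; group by width if needed
  hit_genes <- vector("list", length(sirnas))
  for (w in unique(widths)) {
    idx <- which(widths == w)
    pd <- Biostrings::PDict(rc[idx])
    cnt <- Biostrings::vcountPDict(pd, transcripts)  # patterns x subjects
    for (j in seq_along(idx)) {
      hit_genes[[idx[j]]] <- sort(unique(tx_gene[cnt[j, ] > 0]))
    }
  }

  tibble(
    sirna_id = sirna_id,
    well_key = parse_fasta_tag(names(sirnas), "well"),
    gene_claimed = parse_fasta_tag(names(sirnas), "gene"),
    n_transcripts = vapply(seq_along(sirnas), function(i) {
      length(hit_genes[[i]])
    }, integer(1)),
    genes = hit_genes
  )
}

#' Apply the four-siRNA single-gene well filter
#'
#' Classifies each well from its siRNAs' gene sets: `pass` when every siRNA
#' maps to at least one transcript and the intersection of the per-siRNA gene
#' sets contains exactly one gene; `fail_unmapped` when any siRNA maps
#' nowhere; `fail_discordant` when all map but the intersection is empty;
#' `fail_multi` when the intersection holds more than one gene (the pool is
#' irreducibly ambiguous). With `strict = TRUE`, wells whose individual
#' siRNAs are ambiguous fail even if the shared gene is unique.
#'
#' @param mapping Output of [map_sirnas()].
#' @param strict Require every siRNA to be individually unambiguous
#'   (default `FALSE`: only the pool intersection must be unique).
#' @return Tibble of class `well_filter`: `well_key`, `status`, `gene`
#'   (the single shared gene for passing wells), `n_sirnas`. Attribute
#'   `status_counts` tabulates statuses.
#' @export
filter_wells <- function(mapping, strict = FALSE) {
  require_columns(mapping, c("well_key", "genes"), "mapping")
  out <- mapping |>
    dplyr::group_by(.data$well_key) |>
    dplyr::summarise(
      n_sirnas = dplyr::n(),
      any_unmapped = any(lengths(.data$genes) == 0),
      any_ambiguous = any(lengths(.data$genes) > 1),
      shared = list(Reduce(intersect, .data$genes)),
      .groups = "drop"
    ) |>
    mutate(
      n_shared = lengths(.data$shared),
      status = dplyr::case_when(
        .data$any_unmapped ~ "fail_unmapped",
        strict & .data$any_ambiguous ~ "fail_multi",
        .data$n_shared == 0 ~ "fail_discordant",
        .data$n_shared > 1 ~ "fail_multi",
        TRUE ~ "pass"
      ),
      gene = purrr::map2_chr(.data$shared, .data$status,
                             ~ if (.y == "pass") .x[[1]] else NA_character_)
    ) |>
    dplyr::select("well_key", "status", "gene", "n_sirnas") |>
    dplyr::arrange(.data$well_key)
  attr(out, "status_counts") <- out |> dplyr::count(.data$status)
  class(out) <- c("well_filter", class(out))
  out
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param path GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort(sprintf("empty GMT file: %s", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) {
    abort(sprintf("GMT line(s) with fewer than 3 fields: %s",
                  paste(which(bad), collapse = ", ")))
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(names(sets))) abort("duplicate set names in GMT.")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output file.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}
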