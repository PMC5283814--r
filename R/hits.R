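# Hit calling at a symmetric z cutoff, two-cell-line comparison, phenotype
# profile clustering and hypergeometric set over-representation.

#' Call screen hits at a symmetric z-score cutoff
#'
#' A gene/parameter pair is a hit when `|z| >= cutoff` (inclusive boundary);
#' the sub-G1 parameter is excluded by default as non-informative. A gene is
#' a hit gene when at least one retained parameter fires.
#'
#' @param zscores A `screen_zscores` tibble (long: `gene_id`, optional
#'   `cell_line`, `parameter`, `z`).
#' @param cutoff Absolute z threshold (default 5).
#' @param exclude Parameters never called (default `"subG1"`).
#' @return Tibble of class `hit_calls`: one row per hit gene/parameter with
#'   `z` and `direction` (`"up"`/`"down"`). Missing z values are skipped with
#'   a message. Attribute `n_genes_tested` records the universe size.
#' @export
#' @examples
#' z <- tibble::tibble(gene_id = c("A", "B"), parameter = "S", z = c(5, -2))
#' call_hits(z)
call_hits <- function(zscores, cutoff = 5, exclude = "subG1") {
  require_columns(zscores, c("gene_id", "parameter", "z"), "zscores")
  if (cutoff <= 0) abort("`cutoff` must be > 0.")
  zt <- dplyr::filter(zscores, !.data$parameter %in% exclude)
  n_missing <- sum(is.na(zt$z))
  if (n_missing > 0) {
    inform(sprintf("call_hits: %d missing z value(s) skipped.", n_missing))
    zt <- dplyr::filter(zt, !is.na(.data$z))
  }
  out <- zt |>
    dplyr::filter(abs(.data$z) >= cutoff) |>
    mutate(direction = if_else(.data$z >= 0, "up", "down")) |>
    dplyr::select(dplyr::any_of(c("gene_id", "cell_line")), "parameter",
                  "z", "direction") |>
    dplyr::arrange(dplyr::desc(abs(.data$z)))
  attr(out, "cutoff") <- cutoff
  attr(out, "n_genes_tested") <- dplyr::n_distinct(zscores$gene_id)
  class(out) <- c("hit_calls", class(out))
  out
}

#' Hit genes from hit calls
#'
#' @param hits A `hit_calls` tibble.
#' @return Tibble of distinct `gene_id` (and `cell_line` if present).
#' @export
hit_genes <- function(hits) {
  dplyr::distinct(as_tibble(hits),
                  dplyr::across(dplyr::any_of(c("gene_id", "cell_line"))))
}

#' Compare hit status between two cell lines
#'
#' Intersects the gene universes of two lines and classifies every gene and
#' parameter: `shared` (hit in both lines), `line1_only`, `line2_only`, or
#' `neither`, at the same inclusive cutoff as [call_hits()]. The per-gene
#' summary additionally classifies each gene from its any-parameter hit
#' status. The per-parameter table doubles as the scatter export
#' (gene, z1, z2).
#'
#' @param zscores A `screen_zscores` tibble with a `cell_line` column
#'   covering both lines.
#' @param line1,line2 Cell-line labels to compare.
#' @param cutoff Absolute z threshold (default 5).
#' @param exclude Parameters ignored (default `"subG1"`).
#' @return Tibble of class `line_comparison`: `gene_id`, `parameter`, `z1`,
#'   `z2`, `category`. Attribute `genes` holds the per-gene summary.
#' @export
compare_lines <- function(zscores, line1, line2, cutoff = 5,
                          exclude = "subG1") {
  require_columns(zscores, c("gene_id", "cell_line", "parameter", "z"),
                  "zscores")
  z1 <- dplyr::filter(zscores, .data$cell_line == line1,
                      !.data$parameter %in% exclude)
  z2 <- dplyr::filter(zscores, .data$cell_line == line2,
                      !.data$parameter %in% exclude)
  common <- intersect(unique(z1$gene_id), unique(z2$gene_id))
  if (length(common) == 0) abort("the two lines share no genes.")

  out <- dplyr::inner_join(
    dplyr::select(z1, "gene_id", "parameter", z1 = "z"),
    dplyr::select(z2, "gene_id", "parameter", z2 = "z"),
    by = c("gene_id", "parameter")
  ) |>
    mutate(
      hit1 = !is.na(.data$z1) & abs(.data$z1) >= cutoff,
      hit2 = !is.na(.data$z2) & abs(.data$z2) >= cutoff,
      category = dplyr::case_when(
        .data$hit1 & .data$hit2 ~ "shared",
        .data$hit1 ~ "line1_only",
        .data$hit2 ~ "line2_only",
        TRUE ~ "neither"
      )
    ) |>
    dplyr::select("gene_id", "parameter", "z1", "z2", "category") |>
    dplyr::arrange(.data$gene_id, .data$parameter)

  genes <- out |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      hit1 = any(.data$category %in% c("shared", "line1_only")),
      hit2 = any(.data$category %in% c("shared", "line2_only")),
      .groups = "drop"
    ) |>
    mutate(category = dplyr::case_when(
      .data$hit1 & .data$hit2 ~ "shared",
      .data$hit1 ~ "line1_only",
      .data$hit2 ~ "line2_only",
      TRUE ~ "neither"
    )) |>
    dplyr::select("gene_id", "category")

  attr(out, "lines") <- c(line1, line2)
  attr(out, "cutoff") <- cutoff
  attr(out, "genes") <- genes
  class(out) <- c("line_comparison", class(out))
  out
}

#' Genes differing between the two lines
#'
#' @param comparison A `line_comparison`.
#' @return Per-gene tibble restricted to `line1_only` and `line2_only`.
#' @export
differential_genes <- function(comparison) {
  dplyr::filter(attr(comparison, "genes"),
                .data$category %in% c("line1_only", "line2_only"))
}

#' @export
autoplot.line_comparison <- function(object, parameter = "S", cutoff = NULL, ...) {
  cutoff <- cutoff %||% attr(object, "cutoff")
  lines <- attr(object, "lines")
  df <- dplyr::filter(as_tibble(object), .data$parameter == !!parameter)
  ggplot(df, aes(x = .data$z1, y = .data$z2, colour = .data$category)) +
    geom_hline(yintercept = c(-cutoff, cutoff), linetype = 3) +
    geom_vline(xintercept = c(-cutoff, cutoff), linetype = 3) +
    geom_point(alpha = 0.6) +
    labs(x = sprintf("%s z-score, %s", parameter, lines[1]),
         y = sprintf("%s z-score, %s", parameter, lines[2]),
         colour = NULL)
}

#' Cluster hit phenotype profiles
#'
#' Builds the matrix of z-scores for hit genes (any `|z| >= cutoff` in either
#' line, sub-G1 excluded) over the concatenated parameter x cell-line
#' columns, and clusters rows by average-linkage agglomeration on Euclidean
#' distances. Rows are sorted by gene id before clustering so leaf order is
#' deterministic, ties broken by gene id.
#'
#' @param zscores A `screen_zscores` tibble (one or two cell lines).
#' @param cutoff Hit threshold used to select genes (default 5).
#' @param exclude Parameters dropped from the profile (default `"subG1"`).
#' @return Object of class `phenotype_clusters`: list with `hclust`, the
#'   row-ordered `matrix`, and `newick` (dendrogram as a newick string,
#'   `NULL` if the ape package is unavailable).
#' @export
cluster_profiles <- function(zscores, cutoff = 5, exclude = "subG1") {
  require_columns(zscores, c("gene_id", "parameter", "z"), "zscores")
  zt <- dplyr::filter(zscores, !.data$parameter %in% exclude)
  has_line <- "cell_line" %in% names(zt)
  hits <- zt |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(hit = any(abs(.data$z) >= cutoff, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::filter(.data$hit)
  if (nrow(hits) < 2) abort("need at least 2 hit genes to cluster.")

  wide <- zt |>
    dplyr::filter(.data$gene_id %in% hits$gene_id) |>
    mutate(column = if (has_line) paste(.data$cell_line, .data$parameter, sep = ".")
                    else .data$parameter) |>
    dplyr::select("gene_id", "column", "z") |>
    dplyr::arrange(.data$gene_id, .data$column) |>
    tidyr::pivot_wider(names_from = "column", values_from = "z")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$gene_id
  if (all(apply(m, 2, function(v) diff(range(v, na.rm = TRUE)) == 0))) {
    abort("constant z matrix: nothing to cluster.")
  }
  hc <- hclust(dist(m, method = "euclidean"), method = "average")
  ordered <- m[hc$order, , drop = FALSE]
  newick <- if (requireNamespace("ape", quietly = TRUE)) {
    ape::write.tree(ape::as.phylo(hc))
  }
  structure(list(hclust = hc, matrix = ordered, newick = newick),
            class = "phenotype_clusters")
}

#' @export
print.phenotype_clusters <- function(x, ...) {
  cat(sprintf("<phenotype_clusters> %d genes x %d profile columns\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat("leaf order:", paste(head(rownames(x$matrix), 8), collapse = ", "),
      if (nrow(x$matrix) > 8) "..." else "", "\n")
  invisible(x)
}

#' Cut clustered profiles into k classes
#'
#' @param clusters A `phenotype_clusters` object.
#' @param k Number of classes.
#' @return Tibble `gene_id`, `class`.
#' @export
cut_profiles <- function(clusters, k) {
  cl <- stats::cutree(clusters$hclust, k = k)
  tibble(gene_id = names(cl), class = unname(cl))
}

#' @export
autoplot.phenotype_clusters <- function(object, ...) {
  df <- as_tibble(object$matrix, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "profile", values_to = "z") |>
    mutate(gene_id = factor(.data$gene_id, levels = rev(rownames(object$matrix))))
  ggplot(df, aes(x = .data$profile, y = .data$gene_id, fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    labs(x = NULL, y = NULL, fill = "z") +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Hypergeometric gene-set over-representation
#'
#' For each gene set, tests whether the hit list contains more set members
#' than expected by chance: one-sided hypergeometric tail
#' `p = P(X >= k)` with `k` hits in the set, `K` set members in the universe,
#' `n` hits and `N` universe genes, followed by Benjamini-Hochberg adjustment
#' across sets. Sets are intersected with the universe first; hits must be a
#' subset of the universe.
#'
#' @param hits Character vector of hit gene ids (or a `hit_calls` tibble).
#' @param universe Character vector of all analyzed gene ids.
#' @param gene_sets Named list of character vectors (see [read_gmt()]).
#' @param method Test; only `"hypergeometric"` is implemented.
#' @param min_size Drop sets with fewer members in the universe (default 1).
#' @return Tibble of class `enrichment`: `set_id`, `k`, `K`, `n`, `N`, `p`,
#'   `q`, sorted by `p`.
#' @export
#' @examples
#' enrich(c("a", "b"), letters[1:10], list(s1 = c("a", "b", "c")))
enrich <- function(hits, universe, gene_sets, method = "hypergeometric",
                   min_size = 1) {
  method <- match.arg(method, "hypergeometric")
  if (inherits(hits, "hit_calls") || is.data.frame(hits)) {
    hits <- unique(hits$gene_id)
  }
  universe <- unique(universe)
  if (length(universe) == 0) abort("empty universe.")
  if (length(gene_sets) == 0) abort("no gene sets.")
  extra <- setdiff(hits, universe)
  if (length(extra) > 0) {
    abort(sprintf("%d hit(s) outside the universe (e.g. %s).",
                  length(extra), extra[1]))
  }
  hits <- unique(hits)
  n <- length(hits); N <- length(universe)

  rows <- purrr::imap_dfr(gene_sets, function(members, set_id) {
    in_univ <- intersect(unique(members), universe)
    K <- length(in_univ)
    if (K < min_size) return(NULL)
    k <- length(intersect(in_univ, hits))
    tibble(set_id = set_id, k = k, K = K, n = n, N = N,
           p = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  if (nrow(rows) == 0) abort("no gene set overlaps the universe.")
  rows$q <- p.adjust(rows$p, method = "BH")
  out <- dplyr::arrange(rows, .data$p, .data$set_id)
  class(out) <- c("enrichment", class(out))
  out
}
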