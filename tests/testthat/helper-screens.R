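# Shared fixture builders: all synthetic, generated at test time.

tiny_design <- function(n_plates = 2, replicates = 3, batches = 1, seed = 42) {
  screen_design(n_plates = n_plates, replicates = replicates,
                batches = batches, seed = seed)
}

# Counts-level simulation through to z-scores.
sim_to_zscores <- function(sim) {
  wells <- well_phenotypes(sim$counts, sim$layout)
  zscore_genes(normalize_screen(wells))
}

# Hand-built well-phenotype table: one parameter ("S"), arbitrary values.
# Wells are laid out on a single plate unless plate/position vectors given.
manual_wells <- function(values, roles = NULL, wells = NULL, plate = "P001",
                         replicate = 1) {
  n <- length(values)
  tibble::tibble(
    plate_id = rep(plate, n),
    well = wells %||% well_names()[seq_len(n)],
    replicate = rep(replicate, n),
    role = roles %||% rep("sample", n),
    gene_id = ifelse((roles %||% rep("sample", n)) == "sample",
                     sprintf("G%03d", seq_len(n)), NA_character_),
    S = as.numeric(values)
  )
}

# Adjusted Rand index between two labelings.
rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Brute-force hypergeometric upper tail by exhaustive enumeration of all
# size-n draws from a universe of N with K marked elements.
enumerate_tail_p <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= k)
}
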