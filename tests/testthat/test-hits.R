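# Hit calling, cross-line comparison, profile clustering and set
# over-representation.

zt <- function(...) tibble::tibble(...)

test_that("the cutoff is inclusive, symmetric, and sub-G1 is never called", {
  z <- zt(gene_id = c("A", "B", "C", "D"),
          parameter = c("S", "S", "subG1", "G2M"),
          z = c(5, -5, 12, 4.999))
  h <- call_hits(z, cutoff = 5)
  expect_setequal(h$gene_id, c("A", "B"))
  expect_equal(h$direction[h$gene_id == "A"], "up")
  expect_equal(h$direction[h$gene_id == "B"], "down")
  expect_false("C" %in% h$gene_id)   # subG1-only is not a hit
  expect_false("D" %in% h$gene_id)   # below the inclusive boundary
})

test_that("missing z values are skipped with a message", {
  z <- zt(gene_id = c("A", "A"), parameter = c("S", "G1"), z = c(NA, 7))
  expect_message(h <- call_hits(z), "missing")
  expect_equal(nrow(h), 1)
})

test_that("line comparison categorizes genes and rejects empty overlap", {
  z <- zt(gene_id = rep(c("A", "B", "C", "D"), 2),
          cell_line = rep(c("L1", "L2"), each = 4),
          parameter = "S",
          z = c(9, 9, 1, 0, 9, 1, 9, 0))
  cmp <- compare_lines(z, "L1", "L2")
  got <- setNames(cmp$category, cmp$gene_id)
  expect_equal(unname(got[c("A", "B", "C", "D")]),
               c("shared", "line1_only", "line2_only", "neither"))
  expect_setequal(differential_genes(cmp)$gene_id, c("B", "C"))

  z2 <- zt(gene_id = c("A", "B"), cell_line = c("L1", "L2"),
           parameter = "S", z = c(1, 1))
  expect_error(compare_lines(z2, "L1", "L2"), "share no genes")
})

test_that("clustering merges identical profiles first and orders leaves", {
  z <- zt(gene_id = rep(c("g1", "g2", "g3"), each = 2),
          parameter = rep(c("S", "G2M"), 3),
          z = c(6, 0, 6, 0, 0, 16))
  cl <- cluster_profiles(z, cutoff = 5)
  # g1 and g2 are identical: merged at height 0 before g3 joins
  expect_equal(cl$hclust$height[1], 0)
  leaf_order <- rownames(cl$matrix)
  expect_equal(abs(diff(match(c("g1", "g2"), leaf_order))), 1)  # adjacent
  expect_equal(nrow(cl$matrix), 3)
  expect_true(is.character(cl$newick) && nzchar(cl$newick))

  zc <- zt(gene_id = c("g1", "g2"), parameter = "S", z = c(6, 6))
  expect_error(cluster_profiles(zc), "constant")
  expect_error(cluster_profiles(zt(gene_id = "g1", parameter = "S", z = 9)),
               "at least 2")
})

test_that("two simulated phenotype classes are recovered by a k = 2 cut", {
  m <- cell_cycle_model()
  d <- screen_design(n_plates = 2, replicates = 3, batches = 1, seed = 91)
  mult_s <- spike_multiplier(m, "S", 9, 2000)
  mult_g2 <- spike_multiplier(m, "G2M", 9, 2000)
  genes_s <- sprintf("G%05d", 1:10)
  genes_g2 <- sprintf("G%05d", 11:20)
  spikes <- dplyr::bind_rows(
    purrr::map_dfr(genes_s, ~ spike_spec(.x, "line1", c(S = mult_s))),
    purrr::map_dfr(genes_g2, ~ spike_spec(.x, "line1", c(G2M = mult_g2)))
  )
  sim <- simulate_screen(d, m, spikes = spikes, mean_cells = 2000,
                         growth_factor = 1, level = "counts",
                         cell_line = "line1", seed = 92)
  z <- sim_to_zscores(sim)
  cl <- cluster_profiles(z, cutoff = 5)
  classes <- cut_profiles(cl, k = 2)
  truth <- ifelse(classes$gene_id %in% genes_s, "S_up", "G2M_up")
  expect_gte(rand_index(classes$class, truth), 0.9)
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # worked case: N = 10, K = 5, n = 4, k = 4 -> 5 / 210
  r <- enrich(hits = letters[1:4], universe = letters[1:10],
              gene_sets = list(s = letters[1:5]))
  expect_equal(r$p, 5 / 210, tolerance = 1e-12)

  # exhaustive oracle across small configurations
  for (N in c(6, 9, 12)) {
    for (K in c(2, floor(N / 2))) {
      for (n in c(2, min(5, N - 1))) {
        univ <- sprintf("g%02d", seq_len(N))
        marked <- univ[seq_len(K)]
        hits <- univ[seq_len(n)]
        r <- enrich(hits, univ, list(set = marked))
        expect_equal(r$p, enumerate_tail_p(N, K, n, r$k), tolerance = 1e-10)
      }
    }
  }
})

test_that("enrichment saturates and degrades correctly", {
  univ <- letters[1:6]
  expect_equal(enrich(univ, univ, list(all = univ))$p, 1)     # k=K=n=N
  r0 <- enrich(letters[1:2], univ, list(s = letters[5:6]))    # k = 0
  expect_equal(r0$p, 1)
  expect_error(enrich("z", univ, list(s = "a")), "outside the universe")
  expect_error(enrich(character(), character(), list(s = "a")), "empty")
})

test_that("BH adjustment dominates p and is monotone after ranking", {
  set.seed(4)
  univ <- sprintf("g%03d", 1:200)
  hits <- sample(univ, 30)
  sets <- purrr::map(1:15, ~ sample(univ, sample(5:40, 1)))
  names(sets) <- sprintf("set%02d", 1:15)
  r <- enrich(hits, univ, sets)
  expect_true(all(r$q >= r$p))
  expect_true(!is.unsorted(r$p))
  expect_true(!is.unsorted(cummax(r$q[order(r$p)])))
})

test_that("a pure-null screen produces essentially no |z| >= 5 calls", {
  # 10,000 genes, no spikes: the per-parameter call fraction is bounded by
  # the Gaussian tail at the realized control variance
  d <- screen_design(n_plates = 125, replicates = 3, batches = 16, seed = 131)
  sim <- simulate_screen(d, cell_cycle_model(), mean_cells = 1000,
                         growth_factor = 1, level = "counts")
  z <- sim_to_zscores(sim)
  h <- call_hits(z, cutoff = 5)
  per_param_fraction <- nrow(h) / (5 * dplyr::n_distinct(z$gene_id))
  expect_lte(per_param_fraction, 1e-4)
})
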