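# Gate estimation from negative-control histograms and per-event phase
# classification.

make_two_peak_events <- function(n = 60000, g1 = 100, cv = 0.05, seed = 1) {
  withr::with_seed(seed, {
    ph <- sample(c("G1", "G2M"), n, TRUE, c(0.6, 0.4))
    x <- ifelse(ph == "G1", rnorm(n, g1, cv * g1),
                rnorm(n, 2 * g1, cv * 2 * g1))
    tibble::tibble(plate_id = "P001",
                   well = rep(c("A01", "A12"), length.out = n),
                   replicate = 1, batch = 1, cell_id = seq_len(n),
                   dna_intensity = x, true_phase = ph)
  })
}

two_peak_layout <- tibble::tibble(
  plate_id = "P001", well = c("A01", "A12"),
  role = c("neg_ctrl", "gfp_ctrl"), gene_id = NA_character_,
  batch = 1, replicate = 1
)

test_that("gates on a clean two-Gaussian mixture match mu +/- n.sigma", {
  ev <- make_two_peak_events()
  g <- estimate_gates(ev, two_peak_layout, n_sigma = 2.5)
  # closed form: b = {87.5, 112.5, 175, 225}; allow ~1 histogram bin
  bin <- quantile(ev$dna_intensity, 0.995) / 256
  expect_lt(abs(g$b0 - 87.5), 2 * bin)
  expect_lt(abs(g$b1 - 112.5), 2 * bin)
  expect_lt(abs(g$b2 - 175), 2 * bin)
  expect_lt(abs(g$b3 - 225), 2 * bin)
  # determinism
  expect_identical(as.data.frame(g),
                   as.data.frame(estimate_gates(ev, two_peak_layout)))
})

test_that("a G1-only histogram is rejected as degenerate", {
  ev <- make_two_peak_events()
  ev$dna_intensity <- rnorm(nrow(ev), 100, 5)
  expect_error(estimate_gates(ev, two_peak_layout), "degenerate histogram")
  expect_error(estimate_gates(ev[1:100, ], two_peak_layout), "need >=")
})

test_that("count_phases applies half-open-right boundaries and partitions", {
  gates <- tibble::tibble(batch = 1, b0 = 80, b1 = 120, b2 = 170, b3 = 230)
  ev <- tibble::tibble(
    plate_id = "P001", well = "B02", replicate = 1, batch = 1,
    cell_id = 1:14,
    dna_intensity = c(rep(100, 10), 120, 170, 230, 79.999)
  )
  pc <- count_phases(ev, gates)
  expect_equal(pc$total, 14)
  expect_equal(pc$n_G1, 10)       # the ten peak events
  expect_equal(pc$n_S, 1)         # 120 is exactly b1 -> S (right interval)
  expect_equal(pc$n_G2M, 1)       # 170 is exactly b2 -> G2M
  expect_equal(pc$n_overG2, 1)    # 230 is exactly b3 -> overG2
  expect_equal(pc$n_subG1, 1)     # just below b0
  expect_equal(pc$total,
               pc$n_subG1 + pc$n_G1 + pc$n_S + pc$n_G2M + pc$n_overG2)
})

test_that("negative intensities are rejected with a count", {
  gates <- tibble::tibble(batch = 1, b0 = 80, b1 = 120, b2 = 170, b3 = 230)
  ev <- tibble::tibble(plate_id = "P001", well = "B02", replicate = 1,
                       batch = 1, cell_id = 1:3,
                       dna_intensity = c(100, -5, 150))
  expect_message(pc <- count_phases(ev, gates), "rejected 1")
  expect_equal(pc$total, 2)
  expect_equal(attr(pc, "n_rejected"), 1)
})

test_that("scaling all intensities scales gates and preserves counts", {
  ev <- make_two_peak_events(n = 40000, seed = 8)
  g1 <- estimate_gates(ev, two_peak_layout)
  pc1 <- count_phases(ev, g1)
  ev2 <- dplyr::mutate(ev, dna_intensity = dna_intensity * 3)
  g2 <- estimate_gates(ev2, two_peak_layout)
  expect_equal(g2$b1 / g1$b1, 3, tolerance = 0.02)
  expect_equal(g2$b2 / g1$b2, 3, tolerance = 0.02)
  pc2 <- count_phases(ev2, g2)
  expect_equal(pc1$n_G1, pc2$n_G1, tolerance = 0.005)
  expect_equal(pc1$n_G2M, pc2$n_G2M, tolerance = 0.005)
})

test_that("gated labels recover true G1/G2M assignments away from the S plateau", {
  d <- tiny_design(n_plates = 1, replicates = 2, seed = 21)
  sim <- simulate_screen(d, cell_cycle_model(), mean_cells = 800,
                         growth_factor = 1, level = "events")
  g <- estimate_gates(sim$events, sim$layout)
  called <- gate_phase(sim$events$dna_intensity, g)
  peaks <- sim$events$true_phase %in% c("G1", "G2M")
  expect_gt(mean(called[peaks] == sim$events$true_phase[peaks]), 0.9)
})

test_that("EdU split recovers the simulated slow-replication weight", {
  d <- tiny_design(n_plates = 1, replicates = 3, seed = 17)
  low_w <- c(G00005 = 0.4, G00006 = 0.15)
  em <- edu_model(low_weight_by_gene = low_w)
  sim <- simulate_screen(d, cell_cycle_model(), mean_cells = 3000,
                         growth_factor = 1, level = "events", edu = em)
  g <- estimate_gates(sim$events, sim$layout)
  bi <- classify_bivariate(sim$events, g, sim$layout)
  bi <- dplyr::left_join(bi, dplyr::select(sim$layout, plate_id, well,
                                           replicate, gene_id),
                         by = c("plate_id", "well", "replicate"))
  for (gene in names(low_w)) {
    rows <- dplyr::filter(bi, gene_id == gene)
    est <- sum(rows$n_S_edu_low) / sum(rows$n_S)
    se <- sqrt(low_w[[gene]] * (1 - low_w[[gene]]) / sum(rows$n_S))
    expect_lt(abs(est - low_w[[gene]]), 3 * se + 0.02)
  }
  # unspiked wells: essentially no low-EdU S cells beyond the quantile level
  base <- dplyr::filter(bi, !gene_id %in% names(low_w) | is.na(gene_id))
  expect_lt(sum(base$n_S_edu_low) / sum(base$n_S), 0.03)
  # partition: S splits exhaust S, and never touch non-S events
  expect_equal(bi$n_S, bi$n_S_edu_low + bi$n_S_edu_high)
})

test_that("EdU split requires negative-control S events", {
  gates <- tibble::tibble(batch = 1, b0 = 80, b1 = 120, b2 = 170, b3 = 230)
  ev <- tibble::tibble(plate_id = "P001", well = "B02", replicate = 1,
                       batch = 1, cell_id = 1:5,
                       dna_intensity = rep(150, 5), edu_intensity = 1000)
  lay <- tibble::tibble(plate_id = "P001", well = "B02", role = "sample",
                        gene_id = "G1", batch = 1, replicate = 1)
  expect_error(classify_bivariate(ev, gates, lay), "negative-control")
})
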