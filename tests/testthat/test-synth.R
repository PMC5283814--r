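# Synthetic-screen generators: determinism, degenerate cases, effect
# calibration, and conservation of the true phase labels.

test_that("identical design and seed reproduce identical outputs", {
  d <- tiny_design(n_plates = 1, replicates = 2, seed = 11)
  m <- cell_cycle_model()
  s1 <- simulate_screen(d, m, mean_cells = 300, growth_factor = 1,
                        level = "events")
  s2 <- simulate_screen(d, m, mean_cells = 300, growth_factor = 1,
                        level = "events")
  expect_identical(s1$events, s2$events)
  expect_identical(s1$layout, s2$layout)

  lib1 <- simulate_library(20, transcriptome_size = 25, offtarget_rate = 0.3,
                           seed = 7)
  lib2 <- simulate_library(20, transcriptome_size = 25, offtarget_rate = 0.3,
                           seed = 7)
  expect_identical(as.character(lib1$sirnas), as.character(lib2$sirnas))
  expect_identical(lib1$truth, lib2$truth)
})

test_that("a single-phase population with tiny cv lands on the G1 peak", {
  m <- cell_cycle_model(cv = 0.01,
                        phase_probs = c(subG1 = 0, G1 = 1, S = 0,
                                        G2M = 0, overG2 = 0))
  d <- tiny_design(n_plates = 1, replicates = 1, seed = 2)
  sim <- simulate_screen(d, m, mean_cells = 200, growth_factor = 1,
                         level = "events", pos_ctrl_effects = NULL)
  expect_true(all(sim$events$true_phase == "G1"))
  expect_true(all(abs(sim$events$dna_intensity - m$g1_mean) <
                    5 * 0.01 * m$g1_mean))
})

test_that("positive-control wells lose cells according to their multiplier", {
  # oracle: mean over >= 1000 wells of each role, ratio vs the 0.2x setting
  d <- screen_design(n_plates = 9, replicates = 3, batches = 1, seed = 31)
  sim <- simulate_screen(d, cell_cycle_model(), mean_cells = 500,
                         growth_factor = 1, level = "counts",
                         plate_effect_sd = 0.05, wellpos_effect_sd = 0.02,
                         pos_ctrl_effects = c(cellNumber = 0.2, G2M = 3))
  pos <- sim$counts$total[sim$counts$role == "pos_ctrl"]
  base <- sim$counts$total[sim$counts$role %in% c("sample", "neg_ctrl")]
  expect_gt(length(pos), 100)
  ratio <- mean(pos) / mean(base)
  se <- sqrt(var(pos) / length(pos)) / mean(base)
  expect_lt(abs(ratio - 0.2), 3 * se + 0.01)
  # and the G2M occupancy is visibly raised
  frac_pos <- sim$counts$n_G2M[sim$counts$role == "pos_ctrl"] / pos
  frac_base <- sim$counts$n_G2M[sim$counts$role == "sample"] /
    sim$counts$total[sim$counts$role == "sample"]
  expect_gt(median(frac_pos), 2 * median(frac_base))
})

test_that("true-phase counts are conserved between counts and events levels", {
  d <- tiny_design(n_plates = 1, replicates = 1, seed = 9)
  m <- cell_cycle_model()
  sc <- simulate_screen(d, m, mean_cells = 150, growth_factor = 1,
                        level = "counts")
  se <- simulate_screen(d, m, mean_cells = 150, growth_factor = 1,
                        level = "events")
  tall <- dplyr::count(se$events, plate_id, well, true_phase)
  for (ph in c("G1", "S", "G2M")) {
    ev_counts <- tall |>
      dplyr::filter(true_phase == ph) |>
      dplyr::arrange(plate_id, well)
    cc <- sc$counts |>
      dplyr::filter(.data[[paste0("n_", ph)]] > 0) |>
      dplyr::arrange(plate_id, well)
    expect_equal(ev_counts$n, cc[[paste0("n_", ph)]])
  }
})

test_that("raising an S spike multiplier never lowers the expected S fraction", {
  m <- cell_cycle_model()
  d <- screen_design(n_plates = 7, replicates = 1, batches = 1, seed = 5)
  mean_s <- vapply(c(1, 1.3, 1.6), function(mult) {
    spikes <- purrr::map_dfr(sprintf("G%05d", 1:560),
                             ~ spike_spec(.x, "line1", c(S = mult)))
    sim <- simulate_screen(d, m, spikes = spikes, mean_cells = 400,
                           growth_factor = 1, level = "counts",
                           seed = 100 + round(10 * mult))
    with(dplyr::filter(sim$counts, role == "sample"), mean(n_S / total))
  }, numeric(1))
  expect_true(all(diff(mean_s) > 0))
})

test_that("spiking a gene that sits on no sample well is rejected", {
  d <- tiny_design(n_plates = 1, replicates = 1)
  bad <- spike_spec("CDK1_ctrl", "line1", c(G2M = 2))
  expect_error(
    simulate_screen(d, cell_cycle_model(), spikes = bad, mean_cells = 100,
                    growth_factor = 1, level = "counts", cell_line = "line1"),
    "sample well"
  )
  expect_error(
    simulate_screen(d, cell_cycle_model(), mean_cells = -5, level = "counts"),
    "must be > 0"
  )
})

test_that("library generator counts and corruption labels are exact", {
  lib <- simulate_library(n_genes = 1, sirnas_per_gene = 4,
                          transcriptome_size = 1, seed = 3)
  expect_length(lib$sirnas, 4)
  expect_length(lib$transcripts, 1)
  expect_true(all(Biostrings::width(lib$sirnas) == 21))

  clean <- simulate_library(30, transcriptome_size = 40, offtarget_rate = 0,
                            seed = 4)
  expect_true(all(clean$truth$expected_status == "pass"))
  expect_error(simulate_library(10, transcriptome_size = 5),
               "transcriptome_size")
})

test_that("fiber generator obeys the closed-form length and symmetry", {
  tr <- simulate_fibers(5, speed_kb_min = 1.295, pulse_min = 20, noise_cv = 0)
  expect_equal(tr$cldu_len, rep(10, 5))   # 1.295 * 20 / 2.59
  expect_equal(tr$idu_len / tr$cldu_len, rep(1, 5))
  expect_error(simulate_fibers(0, 1.3), "`n` must be > 0")
})
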