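# Two-stage median normalization and control-based z-scoring.

test_that("plate normalization divides by the non-positive-control median", {
  w <- manual_wells(c(10, 20, 30))
  out <- normalize_plate(w, params = "S", min_wells = 3)
  expect_equal(out$S, c(0.5, 1.0, 1.5))

  # a positive control on the plate is excluded from the median but scaled
  w2 <- manual_wells(c(10, 20, 30, 90),
                     roles = c("sample", "sample", "sample", "pos_ctrl"))
  out2 <- normalize_plate(w2, params = "S", min_wells = 3)
  expect_equal(out2$S, c(0.5, 1.0, 1.5, 4.5))

  # constant plate -> all ones
  w3 <- manual_wells(rep(50, 10))
  expect_equal(normalize_plate(w3, params = "S")$S, rep(1, 10))
})

test_that("zero plate median flags the parameter as missing", {
  w <- manual_wells(rep(0, 8))
  expect_warning(out <- normalize_plate(w, params = "S"), "zero")
  expect_true(all(is.na(out$S)))
})

test_that("well-position normalization removes an injected edge effect", {
  # 40 physical plates, identical wells except a 2x effect on column 1
  set.seed(33)
  base <- purrr::map_dfr(1:40, function(p) {
    w <- manual_wells(rlnorm(96, 0, 0.1), plate = sprintf("P%03d", p))
    w$replicate <- 1
    w
  })
  col1 <- substr(base$well, 2, 3) == "01"
  perturbed <- dplyr::mutate(base, S = ifelse(col1, 2 * S, S))
  out <- normalize_wellposition(perturbed, params = "S")
  m_edge <- median(out$S[col1])
  m_int <- median(out$S[!col1])
  expect_lt(abs(m_edge / m_int - 1), 0.02)
})

test_that("well-position normalization is idempotent", {
  set.seed(12)
  base <- purrr::map_dfr(1:5, function(p) {
    manual_wells(rlnorm(96, 0, 0.2), plate = sprintf("P%03d", p))
  })
  once <- normalize_wellposition(base, params = "S")
  twice <- normalize_wellposition(once, params = "S")
  expect_equal(twice$S, once$S, tolerance = 1e-12)
})

test_that("z-scores follow the control-median / control-sd definition", {
  # controls {0.9, 1.0, 1.1, 1.0}: mu = 1, sigma = 0.0816497
  roles <- c(rep("neg_ctrl", 2), rep("gfp_ctrl", 2), rep("sample", 3))
  w <- manual_wells(c(0.9, 1.0, 1.1, 1.0, 1.2, 1.2, 1.2), roles = roles)
  w$gene_id[roles == "sample"] <- "GX"
  z <- zscore_genes(w, params = "S", min_controls = 4)
  expect_equal(z$x, 1.2)
  expect_equal(z$z, (1.2 - 1) / sd(c(0.9, 1.0, 1.1, 1.0)), tolerance = 1e-9)
  expect_equal(z$z, 2.449, tolerance = 1e-3)
})

test_that("a gene at the control median scores exactly zero", {
  roles <- c(rep("neg_ctrl", 10), rep("gfp_ctrl", 10), rep("sample", 3))
  vals <- c(seq(0.8, 1.2, length.out = 20), rep(1, 3))
  w <- manual_wells(vals, roles = roles)
  w$gene_id[roles == "sample"] <- "GM"
  z <- zscore_genes(w, params = "S")
  expect_identical(z$z, 0)  # median of the controls is exactly 1
})

test_that("mock wells stay out of the negative-control pool", {
  roles <- c(rep("neg_ctrl", 10), rep("gfp_ctrl", 10), rep("mock", 5),
             rep("sample", 3))
  vals <- c(rep(c(0.9, 1.1), 10), rep(100, 5), rep(1.1, 3))
  w <- manual_wells(vals, roles = roles)
  w$gene_id[roles == "sample"] <- "GX"
  z <- zscore_genes(w, params = "S")
  ctrl <- attr(z, "control_stats")
  expect_equal(ctrl$mu, 1)                    # unpolluted by the mock 100s
  expect_equal(ctrl$n_controls, 20)
})

test_that("degenerate control spread yields missing z with a warning", {
  roles <- c(rep("neg_ctrl", 20), rep("sample", 3))
  w <- manual_wells(c(rep(1, 20), rep(1.5, 3)), roles = roles)
  w$gene_id[roles == "sample"] <- "GX"
  expect_warning(z <- zscore_genes(w, params = "S"), "degenerate")
  expect_true(is.na(z$z))
  expect_equal(attr(z, "degenerate"), "S")
})

test_that("z is strictly increasing in the gene value", {
  roles <- c(rep("neg_ctrl", 20), rep("sample", 1))
  make_z <- function(x) {
    w <- manual_wells(c(seq(0.9, 1.1, length.out = 20), x), roles = roles)
    w$gene_id[21] <- "GX"
    zscore_genes(w, params = "S")$z
  }
  zs <- vapply(c(0.5, 1, 1.5, 3), make_z, numeric(1))
  expect_true(all(diff(zs) > 0))
})

test_that("plate- and position-level multiplicative factors cancel in z", {
  d <- screen_design(n_plates = 4, replicates = 3, batches = 1, seed = 61)
  sim <- simulate_screen(d, cell_cycle_model(), mean_cells = 400,
                         growth_factor = 1, level = "counts")
  wells <- well_phenotypes(sim$counts, sim$layout)
  z0 <- zscore_genes(normalize_screen(wells))

  # scale one physical plate's raw values
  w1 <- dplyr::mutate(wells, dplyr::across(
    dplyr::all_of(c("cellNumber", "subG1", "G1", "S", "G2M", "overG2")),
    ~ ifelse(plate_id == "P002" & replicate == 2, .x * 3.7, .x)))
  z1 <- zscore_genes(normalize_screen(w1))
  expect_equal(z1$z, z0$z, tolerance = 1e-9)

  # scale one well position on every plate: cancelled by the position stage
  # (applied to plate-normalized values, which that stage consumes)
  plate_norm <- normalize_plate(wells)
  w2 <- dplyr::mutate(plate_norm, dplyr::across(
    dplyr::all_of(c("cellNumber", "subG1", "G1", "S", "G2M", "overG2")),
    ~ ifelse(well == "C07", .x * 0.41, .x)))
  z2 <- zscore_genes(normalize_wellposition(w2))
  z0b <- zscore_genes(normalize_wellposition(plate_norm))
  expect_equal(z2$z, z0b$z, tolerance = 1e-9)
})

test_that("a planted strong spike is recovered near its generative z", {
  m <- cell_cycle_model()
  mult <- spike_multiplier(m, "S", target_z = 8, n_cells = 2000)
  d <- screen_design(n_plates = 4, replicates = 3, batches = 1, seed = 77)
  hits <- replicate(20, NA_real_)
  for (r in 1:20) {
    spikes <- spike_spec("G00042", "line1", c(S = mult))
    sim <- simulate_screen(d, m, spikes = spikes, mean_cells = 2000,
                           growth_factor = 1, level = "counts",
                           seed = 1000 + r)
    z <- sim_to_zscores(sim)
    hits[r] <- z$z[z$gene_id == "G00042" & z$parameter == "S"]
  }
  expect_gte(mean(hits >= 5 & hits <= 11), 0.95)
  expect_equal(mean(hits), 8, tolerance = 0.15 * 8)
})
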