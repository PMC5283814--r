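# Ground-truth validation studies: seeded simulations that exercise the full
# analysis chain against the generators' known truth. These back the test
# suite and the reproducibility script with a single implementation.

#' Gating accuracy against generator truth
#'
#' Simulates one batch of event-level data, estimates gates from the
#' negative-control wells, classifies every event and compares the gated
#' labels and per-phase fractions with the generator's true labels.
#'
#' @param n_events Approximate total number of events to simulate.
#' @param model A [cell_cycle_model()] (default: package default profile).
#' @param n_sigma Gate half-width (default 2.5).
#' @param seed RNG seed.
#' @return List: `accuracy` (per-event), `fraction_error` (max absolute
#'   gated-vs-true phase fraction difference, percentage points),
#'   `per_phase` (tibble of true/gated fractions), `n_events`.
#' @export
gating_accuracy_study <- function(n_events = 1e6, model = cell_cycle_model(),
                                  n_sigma = 2.5, seed = 1) {
  n_wells <- 192  # one plate, two replicate transfections
  design <- screen_design(n_plates = 1, replicates = 2, batches = 1,
                          seed = seed)
  sim <- simulate_screen(design, model, mean_cells = ceiling(n_events / n_wells),
                         growth_factor = 1, level = "events", seed = seed)
  gates <- estimate_gates(sim$events, sim$layout, n_sigma = n_sigma)
  called <- gate_phase(sim$events$dna_intensity, gates)
  truth <- sim$events$true_phase
  per_phase <- tibble(
    phase = PHASES,
    true_fraction = vapply(PHASES, function(p) mean(truth == p), numeric(1)),
    gated_fraction = vapply(PHASES, function(p) mean(called == p), numeric(1))
  )
  list(
    accuracy = mean(called == truth),
    fraction_error = 100 * max(abs(per_phase$gated_fraction -
                                     per_phase$true_fraction)),
    per_phase = per_phase,
    n_events = nrow(sim$events),
    gates = gates
  )
}

#' Spiked-hit recovery and cross-line category recovery
#'
#' Repeated two-cell-line screens with spiked S-phase phenotypes of known
#' generative effect size: `n_spiked` genes are planted among `n_null` nulls
#' (half shared between the lines, a quarter specific to each), each sized by
#' [spike_multiplier()] to sit `target_z` control standard deviations from
#' the control median. Each replicate simulates counts, runs the two-stage
#' normalization and z-scoring, calls hits at the cutoff, and classifies
#' genes across lines; recall and category recovery are averaged over
#' replicates.
#'
#' @param n_null,n_spiked Null and spiked gene counts (default 2000 and 40).
#' @param target_z Generative z-score of the spikes (default 8).
#' @param n_reps Simulation replicates (default 200).
#' @param cutoff Hit threshold (default 5).
#' @param mean_cells Cells per well entering the multinomial (default 2000).
#' @param replicates,batches Design parameters (defaults 3 and 16).
#' @param model A [cell_cycle_model()].
#' @param seed RNG seed.
#' @return List: `recall` (fraction of spiked genes called in the line they
#'   were spiked in), `category_recovery` (fraction of spiked genes with the
#'   correct shared/line-specific S-phase category), `fpr` (fraction of
#'   null gene/line combinations called), `n_reps`, `multiplier`.
#' @export
hit_recovery_study <- function(n_null = 2000, n_spiked = 40, target_z = 8,
                               n_reps = 200, cutoff = 5, mean_cells = 2000,
                               replicates = 3, batches = 16,
                               model = cell_cycle_model(), seed = 1) {
  n_genes_needed <- n_null + n_spiked
  n_plates <- ceiling(n_genes_needed / 80)
  mult <- spike_multiplier(model, "S", target_z, mean_cells)
  lines <- c("line1", "line2")

  n_shared <- floor(n_spiked / 2)
  n_only <- n_spiked - n_shared
  n_l1 <- ceiling(n_only / 2)
  n_l2 <- n_only - n_l1

  rec <- cat_rec <- fpr <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    rep_seed <- child_seed(seed, r)
    design <- screen_design(n_plates = n_plates, replicates = replicates,
                            batches = batches, seed = rep_seed)
    gene_ids <- sprintf("G%05d", seq_len(design$n_genes))
    spiked_genes <- with_seed(rep_seed, sample(gene_ids, n_spiked))
    truth_cat <- rep(c("shared", "line1_only", "line2_only"),
                     c(n_shared, n_l1, n_l2))
    spike_lines <- list(shared = lines, line1_only = lines[1],
                        line2_only = lines[2])
    spikes <- purrr::map_dfr(seq_len(n_spiked), function(i) {
      purrr::map_dfr(spike_lines[[truth_cat[i]]], function(ln) {
        spike_spec(spiked_genes[i], ln, c(S = mult))
      })
    })

    z <- purrr::map_dfr(seq_along(lines), function(li) {
      sim <- simulate_screen(design, model, spikes = spikes,
                             mean_cells = mean_cells, growth_factor = 1,
                             level = "counts", cell_line = lines[li],
                             seed = child_seed(rep_seed, li))
      wells <- well_phenotypes(sim$counts, sim$layout)
      as_tibble(zscore_genes(normalize_screen(wells)))
    })
    class(z) <- c("screen_zscores", class(z))

    hits <- suppressMessages(call_hits(z, cutoff = cutoff))
    hit_keys <- paste(hits$gene_id, hits$cell_line)
    spiked_in <- purrr::map2(seq_len(n_spiked), truth_cat,
                             function(i, tc) spike_lines[[tc]])
    recovered <- vapply(seq_len(n_spiked), function(i) {
      all(paste(spiked_genes[i], spiked_in[[i]]) %in% hit_keys)
    }, logical(1))
    rec[r] <- mean(recovered)

    null_genes <- setdiff(gene_ids, spiked_genes)
    fpr[r] <- mean(c(paste(null_genes, lines[1]),
                     paste(null_genes, lines[2])) %in% hit_keys)

    cmp <- compare_lines(z, lines[1], lines[2], cutoff = cutoff)
    s_cat <- dplyr::filter(as_tibble(cmp), .data$parameter == "S")
    got <- s_cat$category[match(spiked_genes, s_cat$gene_id)]
    cat_rec[r] <- mean(got == truth_cat)
  }
  list(recall = mean(rec), category_recovery = mean(cat_rec),
       fpr = mean(fpr), n_reps = n_reps, multiplier = mult,
       per_rep = tibble(rep = seq_len(n_reps), recall = rec,
                        category_recovery = cat_rec, fpr = fpr))
}

#' Retention of the four-siRNA single-gene filter under corruption
#'
#' Simulates a library with the given per-well corruption probability, maps
#' the siRNAs and applies the filter; reports the retained-well fraction and
#' its agreement with the generator's labels.
#'
#' @param n_wells Library wells (default 5000).
#' @param corruption Per-well corruption probability (default 0.27).
#' @param extra_transcripts Decoy transcripts beyond the library genes.
#' @param seed RNG seed.
#' @return List: `pass_fraction`, `expected` (1 - corruption),
#'   `binomial_se`, `oracle_agreement` (fraction of wells whose filter
#'   status equals the generator's expectation), `n_wells`.
#' @export
filter_retention_study <- function(n_wells = 5000, corruption = 0.27,
                                   extra_transcripts = 200, seed = 1) {
  lib <- simulate_library(n_genes = n_wells,
                          transcriptome_size = n_wells + extra_transcripts,
                          offtarget_rate = corruption, seed = seed)
  wf <- filter_wells(map_sirnas(lib$sirnas, lib$transcripts))
  joined <- dplyr::inner_join(as_tibble(wf), lib$truth, by = "well_key")
  list(
    pass_fraction = mean(wf$status == "pass"),
    expected = 1 - corruption,
    binomial_se = sqrt(corruption * (1 - corruption) / n_wells),
    oracle_agreement = mean(joined$status == joined$expected_status),
    n_wells = n_wells
  )
}

#' Power of the fork-speed comparison for a two-fold slowdown
#'
#' Repeatedly simulates two fiber populations (control vs two-fold slowdown)
#' and records how often the Mann-Whitney comparison reaches a small
#' p-value.
#'
#' @param n_runs Simulation runs (default 500).
#' @param n_per_arm Fibers per condition (default 100).
#' @param speed_a,speed_b Fork speeds in kb/min (defaults 1.3 and 0.65).
#' @param noise_cv Lognormal CV of the track lengths (default 0.3).
#' @param p_threshold Detection threshold (default 1e-6).
#' @param seed RNG seed.
#' @return List: `detection_rate`, `median_p`, `n_runs`.
#' @export
fiber_power_study <- function(n_runs = 500, n_per_arm = 100, speed_a = 1.3,
                              speed_b = 0.65, noise_cv = 0.3,
                              p_threshold = 1e-6, seed = 1) {
  p <- vapply(seq_len(n_runs), function(r) {
    tr <- dplyr::bind_rows(
      simulate_fibers(n_per_arm, speed_a, noise_cv = noise_cv,
                      condition = "ctrl", seed = child_seed(seed, 2L * r)),
      simulate_fibers(n_per_arm, speed_b, noise_cv = noise_cv,
                      condition = "slow", seed = child_seed(seed, 2L * r + 1L))
    )
    compare_conditions(tr, "ctrl", "slow")$p
  }, numeric(1))
  list(detection_rate = mean(p < p_threshold), median_p = median(p),
       n_runs = n_runs)
}
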