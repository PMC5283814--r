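# Seeded synthetic-screen generators. Every generator emits ground truth
# alongside the data so downstream stages can be validated by parameter
# recovery rather than by eye.

#' EdU channel model for bivariate simulation
#'
#' Per-cell EdU incorporation intensities: replicating (S-phase) cells draw
#' from a high lognormal mode, non-S cells from a low background mode, and a
#' configurable per-gene fraction of S cells draws from a "slow replication"
#' low mode between the two (low EdU at S-phase DNA content).
#'
#' @param high_mean,low_mean,bg_mean Mode means (a.u.).
#' @param cv Lognormal coefficient of variation shared by the modes.
#' @param low_weight_by_gene Named numeric vector, gene id to the fraction of
#'   that gene's S cells drawn from the low mode (ground truth for
#'   [classify_bivariate()] recovery).
#' @return An object of class `edu_model`.
#' @export
edu_model <- function(high_mean = 1000, low_mean = 60, bg_mean = 20,
                      cv = 0.3, low_weight_by_gene = NULL) {
  if (any(c(high_mean, low_mean, bg_mean) <= 0)) abort("EdU means must be > 0.")
  if (low_mean >= high_mean) abort("`low_mean` must be below `high_mean`.")
  if (!is.null(low_weight_by_gene) &&
      (any(low_weight_by_gene < 0) || any(low_weight_by_gene > 1))) {
    abort("`low_weight_by_gene` entries must be in [0, 1].")
  }
  structure(list(high_mean = high_mean, low_mean = low_mean,
                 bg_mean = bg_mean, cv = cv,
                 low_weight_by_gene = low_weight_by_gene),
            class = "edu_model")
}

rlnorm_cv <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# Vectorized multinomial sampling with per-row probability matrices,
# via sequential conditional binomials.
rmultinom_rows <- function(sizes, prob_matrix) {
  n <- length(sizes)
  k <- ncol(prob_matrix)
  out <- matrix(0L, n, k)
  remaining <- as.integer(sizes)
  tails <- matrix(0, n, k)
  tails[, k] <- prob_matrix[, k]
  for (j in (k - 1):1) tails[, j] <- tails[, j + 1] + prob_matrix[, j]
  for (j in seq_len(k - 1)) {
    p_cond <- ifelse(tails[, j] > 0, prob_matrix[, j] / tails[, j], 0)
    p_cond <- pmin(pmax(p_cond, 0), 1)
    draw <- rbinom(n, remaining, p_cond)
    out[, j] <- draw
    remaining <- remaining - draw
  }
  out[, k] <- remaining
  out
}

rnorm_trunc0 <- function(n, mean, sd) {
  u <- runif(n, pnorm(0, mean, sd), 1)
  qnorm(u, mean, sd)
}

# DNA-content intensities for events of one phase.
phase_intensity <- function(n, phase, model) {
  g1 <- model$g1_mean; cv <- model$cv; g2 <- model$g2_ratio * model$g1_mean
  switch(phase,
    subG1  = rnorm_trunc0(n, 0.5 * g1, 2 * cv * 0.5 * g1),
    G1     = rnorm(n, g1, cv * g1),
    S      = runif(n, g1, g2) + rnorm(n, 0, cv * g1),
    G2M    = rnorm(n, g2, cv * g2),
    overG2 = rnorm(n, 2 * g2, cv * 2 * g2)
  )
}

#' Simulate a plate-based cell-cycle RNAi screen
#'
#' Generates one cell line's screen: per-well cell counts around a baseline
#' (seeded cells times a growth factor), perturbed by a per-physical-plate
#' lognormal factor and a per-well-position lognormal factor shared across
#' plates; per-cell phase labels from the model's occupancy vector (shifted
#' for spiked genes); and, at `level = "events"`, per-cell DNA-content
#' intensities from the five-component mixture. At `level = "counts"` the
#' exact true-phase counts per well are returned instead of per-cell events
#' (the shape [count_phases()] would produce), for studies where gating
#' itself is not under test.
#'
#' @param design A [screen_design()].
#' @param model A [cell_cycle_model()].
#' @param spikes Optional spike table ([spike_spec()] rows). Spike gene ids
#'   must exist in the design's sample wells; spikes are applied only where
#'   `cell_line` matches.
#' @param plate_effect_sd Lognormal sigma of the per-physical-plate cell-count
#'   factor (fraction; default 0.1).
#' @param wellpos_effect_sd Lognormal sigma of the per-well-position factor
#'   (default 0.05).
#' @param mean_cells Cells seeded per well (default 4000).
#' @param growth_factor Scalar growth over the incubation (default 2).
#' @param level `"events"` for per-cell rows, `"counts"` for per-well
#'   true-phase counts.
#' @param effect_model `"multiplicative"` (lognormal factors, the default;
#'   matched to median-division normalization) or `"additive"` (Gaussian
#'   offsets of the same relative magnitude, for robustness studies).
#' @param pos_ctrl_effects Named multipliers applied to every
#'   positive-control well, emulating the strong arrest-and-kill phenotype of
#'   the CDK1-directed control: by default the cell count drops to 0.2x and
#'   G2/M occupancy triples. Set to `NULL` to leave positive controls at the
#'   base model.
#' @param cell_line Cell-line label stamped on the outputs.
#' @param edu Optional [edu_model()]; adds an `edu_intensity` column at
#'   `level = "events"`.
#' @param seed RNG seed; defaults to the design's seed.
#' @return A list of class `screen_sim` with elements `events` (or `counts`),
#'   `layout` and `truth` (one row per spiked gene x parameter, with the
#'   multiplier and expected direction).
#' @export
#' @examples
#' d <- screen_design(n_plates = 1, replicates = 2, batches = 1, seed = 7)
#' sim <- simulate_screen(d, cell_cycle_model(), mean_cells = 200,
#'                        growth_factor = 1, level = "counts")
#' head(sim$counts)
simulate_screen <- function(design, model, spikes = NULL,
                            plate_effect_sd = 0.1,
                            wellpos_effect_sd = 0.05,
                            mean_cells = 4000,
                            growth_factor = 2,
                            level = c("events", "counts"),
                            effect_model = c("multiplicative", "additive"),
                            pos_ctrl_effects = c(cellNumber = 0.2, G2M = 3),
                            cell_line = "line1",
                            edu = NULL,
                            seed = design$seed) {
  stopifnot(inherits(design, "screen_design"), inherits(model, "cell_cycle_model"))
  level <- match.arg(level)
  effect_model <- match.arg(effect_model)
  if (mean_cells <= 0 || growth_factor <= 0) {
    abort("`mean_cells` and `growth_factor` must be > 0 (design rejected).")
  }

  layout <- screen_layout(design)
  layout$cell_line <- cell_line

  spikes <- if (is.null(spikes)) tibble(gene_id = character(), cell_line = character(),
                                        effects = list(), penetrance = numeric())
            else spikes
  spikes <- dplyr::filter(spikes, .data$cell_line == !!cell_line)
  if (nrow(spikes) > 0) {
    known <- unique(layout$gene_id[layout$role == "sample"])
    bad <- setdiff(spikes$gene_id, known)
    if (length(bad) > 0) {
      abort(sprintf(paste0("spike gene(s) not assigned to any sample well ",
                           "(spiking control wells is not allowed): %s"),
                    paste(head(bad, 5), collapse = ", ")))
    }
    if (anyDuplicated(spikes$gene_id)) {
      abort("at most one spike per gene per cell line.")
    }
  }

  with_seed(seed, {
    base_count <- mean_cells * growth_factor

    plates <- dplyr::distinct(layout, .data$plate_id, .data$replicate)
    plates$plate_factor <- if (effect_model == "multiplicative") {
      rlnorm(nrow(plates), 0, plate_effect_sd)
    } else {
      pmax(1 + rnorm(nrow(plates), 0, plate_effect_sd), 0.05)
    }
    positions <- tibble(well = well_names())
    positions$pos_factor <- if (effect_model == "multiplicative") {
      rlnorm(nrow(positions), 0, wellpos_effect_sd)
    } else {
      pmax(1 + rnorm(nrow(positions), 0, wellpos_effect_sd), 0.05)
    }

    wells <- layout |>
      left_join(plates, by = c("plate_id", "replicate")) |>
      left_join(positions, by = "well")

    # per-well phase probabilities and cell-number multipliers
    prob <- matrix(rep(model$phase_probs, each = nrow(wells)),
                   nrow(wells), length(PHASES),
                   dimnames = list(NULL, PHASES))
    count_mult <- rep(1, nrow(wells))
    spiked <- rep(FALSE, nrow(wells))
    if (nrow(spikes) > 0) {
      for (i in seq_len(nrow(spikes))) {
        idx <- which(wells$gene_id %in% spikes$gene_id[i])
        hit <- idx[runif(length(idx)) <= spikes$penetrance[i]]
        if (length(hit) == 0) next
        eff <- spikes$effects[[i]]
        prob[hit, ] <- matrix(rep(shift_phase_probs(model$phase_probs, eff),
                                  each = length(hit)),
                              length(hit), length(PHASES))
        if ("cellNumber" %in% names(eff)) {
          count_mult[hit] <- eff[["cellNumber"]]
        }
        spiked[hit] <- TRUE
      }
    }

    if (!is.null(pos_ctrl_effects)) {
      if (!all(names(pos_ctrl_effects) %in% SCREEN_PARAMS)) {
        abort("`pos_ctrl_effects` names must be screen parameters.")
      }
      pc_idx <- which(wells$role == "pos_ctrl")
      if (length(pc_idx) > 0) {
        prob[pc_idx, ] <- matrix(
          rep(shift_phase_probs(model$phase_probs, pos_ctrl_effects),
              each = length(pc_idx)),
          length(pc_idx), length(PHASES))
        if ("cellNumber" %in% names(pos_ctrl_effects)) {
          count_mult[pc_idx] <- pos_ctrl_effects[["cellNumber"]]
        }
      }
    }

    lambda <- base_count * wells$plate_factor * wells$pos_factor * count_mult
    n_cells <- rpois(nrow(wells), lambda)
    counts <- rmultinom_rows(n_cells, prob)
    colnames(counts) <- paste0("n_", PHASES)

    counts_tbl <- dplyr::bind_cols(
      dplyr::select(wells, "plate_id", "well", "replicate", "batch",
                    "role", "gene_id", "cell_line"),
      tibble(total = n_cells),
      as_tibble(counts)
    )
    counts_tbl$spiked <- spiked

    truth <- spike_truth(spikes, model)

    if (level == "counts") {
      return(structure(list(counts = counts_tbl, layout = layout,
                            truth = truth, model = model),
                       class = "screen_sim"))
    }

    events <- expand_events(counts_tbl, model, edu)
    structure(list(events = events, layout = layout, truth = truth,
                   model = model),
              class = "screen_sim")
  })
}

# Ground-truth table: one row per spiked gene x affected parameter.
spike_truth <- function(spikes, model) {
  if (nrow(spikes) == 0) {
    return(tibble(gene_id = character(), cell_line = character(),
                  parameter = character(), multiplier = numeric(),
                  direction = character()))
  }
  purrr::map_dfr(seq_len(nrow(spikes)), function(i) {
    eff <- spikes$effects[[i]]
    tibble(gene_id = spikes$gene_id[i],
           cell_line = spikes$cell_line[i],
           parameter = names(eff),
           multiplier = unname(eff),
           direction = if_else(unname(eff) >= 1, "up", "down"))
  })
}

# Expand per-well phase counts into per-cell event rows with intensities.
expand_events <- function(counts_tbl, model, edu = NULL) {
  long <- counts_tbl |>
    dplyr::select("plate_id", "well", "replicate", "batch", "gene_id",
                  dplyr::all_of(paste0("n_", PHASES))) |>
    tidyr::pivot_longer(dplyr::all_of(paste0("n_", PHASES)),
                        names_to = "true_phase", values_to = "n",
                        names_prefix = "n_") |>
    dplyr::filter(.data$n > 0)

  ev <- long[rep(seq_len(nrow(long)), long$n),
             c("plate_id", "well", "replicate", "batch", "gene_id", "true_phase")]
  ev <- as_tibble(ev)
  ev <- ev |>
    group_by(.data$plate_id, .data$well, .data$replicate) |>
    mutate(cell_id = row_number()) |>
    ungroup()

  dna <- numeric(nrow(ev))
  for (ph in PHASES) {
    i <- which(ev$true_phase == ph)
    if (length(i) > 0) dna[i] <- phase_intensity(length(i), ph, model)
  }
  ev$dna_intensity <- pmax(dna, 0)

  if (!is.null(edu)) {
    stopifnot(inherits(edu, "edu_model"))
    e <- rlnorm_cv(nrow(ev), edu$bg_mean, edu$cv)
    s_idx <- which(ev$true_phase == "S")
    if (length(s_idx) > 0) {
      w <- rep(0, length(s_idx))
      if (!is.null(edu$low_weight_by_gene)) {
        m <- match(ev$gene_id[s_idx], names(edu$low_weight_by_gene))
        w[!is.na(m)] <- edu$low_weight_by_gene[m[!is.na(m)]]
      }
      low <- runif(length(s_idx)) < w
      e[s_idx[low]] <- rlnorm_cv(sum(low), edu$low_mean, edu$cv)
      e[s_idx[!low]] <- rlnorm_cv(sum(!low), edu$high_mean, edu$cv)
    }
    ev$edu_intensity <- e
  }
  dplyr::select(ev, "plate_id", "well", "replicate", "batch", "cell_id",
                "dna_intensity", dplyr::any_of("edu_intensity"),
                "true_phase", "gene_id")
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate a pooled-siRNA library with matched transcripts
#'
#' Builds one transcript per gene (random sequence) plus optional decoy
#' transcripts, and `sirnas_per_gene` siRNAs per well whose reverse
#' complements are exact 21-nt substrings of the well's target transcript
#' (antisense-to-mRNA convention). With probability `offtarget_rate` a WELL is
#' corrupted: one to `sirnas_per_gene` of its siRNAs are replaced by either a
#' substring of a different transcript or a sequence absent from the
#' transcriptome, so the downstream four-siRNA single-gene filter has true
#' negatives with known labels.
#'
#' @param n_genes Number of library genes (one well each).
#' @param sirnas_per_gene siRNAs pooled per well (default 4).
#' @param transcriptome_size Total transcripts, `>= n_genes`; the excess are
#'   decoys carrying their own non-library gene ids.
#' @param offtarget_rate Per-well corruption probability in \[0, 1\].
#' @param transcript_length Length of each random transcript (nt).
#' @param sirna_length siRNA length (nt, default 21).
#' @param gene_ids Optional gene identifiers (defaults to `G00001 ...`).
#' @param seed RNG seed.
#' @return List of class `library_sim`: `sirnas` and `transcripts`
#'   ([Biostrings::DNAStringSet] with `well=`/`gene=` tags in the names) and
#'   `truth` (tibble: `well_key`, `gene_id`, `corrupted`, `n_bad`,
#'   `expected_status`).
#' @export
#' @examples
#' lib <- simulate_library(n_genes = 5, transcriptome_size = 8, seed = 1)
#' lib$truth
simulate_library <- function(n_genes,
                             sirnas_per_gene = 4,
                             transcriptome_size = n_genes,
                             offtarget_rate = 0,
                             transcript_length = 400,
                             sirna_length = 21,
                             gene_ids = NULL,
                             seed = NULL) {
  if (sirnas_per_gene < 1) abort("`sirnas_per_gene` must be >= 1.")
  if (transcriptome_size < n_genes) {
    abort("`transcriptome_size` must be >= `n_genes`.")
  }
  if (offtarget_rate < 0 || offtarget_rate > 1) {
    abort("`offtarget_rate` must be in [0, 1].")
  }
  if (transcript_length < sirna_length) {
    abort("transcripts must be at least one siRNA long.")
  }
  if (is.null(gene_ids)) gene_ids <- sprintf("G%05d", seq_len(n_genes))
  if (length(gene_ids) != n_genes) abort("need one gene id per gene.")

  with_seed(seed, {
    n_decoy <- transcriptome_size - n_genes
    tx_gene <- c(gene_ids, if (n_decoy > 0) sprintf("D%05d", seq_len(n_decoy)))
    tx_seq <- random_dna(transcriptome_size, transcript_length)
    names(tx_seq) <- sprintf("T%05d gene=%s", seq_len(transcriptome_size), tx_gene)

    well_key <- sprintf("W%05d", seq_len(n_genes))
    corrupted <- runif(n_genes) < offtarget_rate

    sir_seq <- character(n_genes * sirnas_per_gene)
    sir_name <- character(length(sir_seq))
    bad_kind <- matrix("ok", n_genes, sirnas_per_gene)

    substring_sirna <- function(tx_index) {
      start <- sample.int(transcript_length - sirna_length + 1L, 1L)
      target <- substr(tx_seq[tx_index], start, start + sirna_length - 1L)
      # siRNA is antisense: its reverse complement is the transcript substring
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(target)))
    }

    for (g in seq_len(n_genes)) {
      n_bad <- if (corrupted[g]) sample.int(sirnas_per_gene, 1L) else 0L
      which_bad <- if (n_bad > 0) sample.int(sirnas_per_gene, n_bad) else integer()
      for (s in seq_len(sirnas_per_gene)) {
        k <- (g - 1L) * sirnas_per_gene + s
        if (s %in% which_bad) {
          if (transcriptome_size > 1 && runif(1) < 0.5) {
            other <- sample(setdiff(seq_len(transcriptome_size), g), 1L)
            sir_seq[k] <- substring_sirna(other)
            bad_kind[g, s] <- "retargeted"
          } else {
            sir_seq[k] <- paste(sample(c("A", "C", "G", "T"), sirna_length,
                                       replace = TRUE), collapse = "")
            bad_kind[g, s] <- "unmapped"
          }
        } else {
          sir_seq[k] <- substring_sirna(g)
        }
        sir_name[k] <- sprintf("%s_s%d well=%s gene=%s",
                               well_key[g], s, well_key[g], gene_ids[g])
      }
    }

    transcripts <- Biostrings::DNAStringSet(tx_seq)
    # Guarantee that "unmapped" siRNAs truly have no transcript match:
    # regenerate the rare random 21-mer that collides with the transcriptome.
    unm <- which(as.vector(t(bad_kind)) == "unmapped")
    if (length(unm) > 0) {
      repeat {
        pd <- Biostrings::PDict(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(sir_seq[unm])))
        hit_counts <- rowSums(Biostrings::vcountPDict(pd, transcripts))
        coll <- which(hit_counts > 0)
        if (length(coll) == 0) break
        sir_seq[unm[coll]] <- random_dna(length(coll), sirna_length)
      }
    }

    names(sir_seq) <- sir_name
    n_bad_per_well <- rowSums(bad_kind != "ok")
    expected_status <- dplyr::case_when(
      rowSums(bad_kind == "unmapped") > 0 ~ "fail_unmapped",
      n_bad_per_well > 0 ~ "fail_discordant",
      TRUE ~ "pass"
    )
    truth <- tibble(well_key = well_key, gene_id = gene_ids,
                    corrupted = corrupted, n_bad = n_bad_per_well,
                    expected_status = expected_status)

    structure(list(sirnas = Biostrings::DNAStringSet(sir_seq),
                   transcripts = transcripts, truth = truth),
              class = "library_sim")
  })
}

#' Simulate dual-label DNA fiber tracks
#'
#' Each fiber receives a CldU and an IdU segment laid down at the given fork
#' speed over one pulse each; measured lengths (in the microscope's length
#' units) are `speed * pulse / factor` per label, with independent lognormal
#' measurement noise of coefficient of variation `noise_cv`.
#'
#' @param n Number of fibers (> 0).
#' @param speed_kb_min Fork speed in kb/min (> 0).
#' @param pulse_min Pulse duration per label in minutes (default 20).
#' @param noise_cv Lognormal noise CV (0 for noiseless tracks).
#' @param factor kb per measured length unit (default 2.59).
#' @param condition Condition label stamped on the rows.
#' @param seed RNG seed.
#' @return Tibble with `fiber_id`, `condition`, `cldu_len`, `idu_len`
#'   (length units) and `true_speed` (kb/min).
#' @export
#' @examples
#' simulate_fibers(3, speed_kb_min = 1.295, noise_cv = 0)
simulate_fibers <- function(n, speed_kb_min, pulse_min = 20, noise_cv = 0.3,
                            factor = 2.59, condition = "control",
                            seed = NULL) {
  if (!is.numeric(n) || n <= 0) abort("`n` must be > 0.")
  if (speed_kb_min <= 0) abort("`speed_kb_min` must be > 0.")
  if (pulse_min <= 0) abort("`pulse_min` must be > 0.")
  with_seed(seed, {
    base_len <- speed_kb_min * pulse_min / factor
    noise <- function(k) {
      if (noise_cv <= 0) rep(1, k) else rlnorm_cv(k, 1, noise_cv)
    }
    tibble(
      fiber_id = sprintf("%s_f%04d", condition, seq_len(n)),
      condition = condition,
      cldu_len = base_len * noise(n),
      idu_len = base_len * noise(n),
      true_speed = speed_kb_min
    )
  })
}
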