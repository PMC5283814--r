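# Generative model descriptors for the synthetic screen: the DNA-content
# mixture, the plate/replicate/batch design, and spiked phenotypes.

#' DNA-content population model for the synthetic screen
#'
#' Describes the per-cell DNA-stain intensity distribution of an unperturbed
#' cycling population as a five-component mixture: sub-G1 (fragmented DNA,
#' below the G1 peak), G1 (2N peak), S (intensities spread between the peaks),
#' G2/M (4N peak at `g2_ratio` times the G1 position) and over-G2
#' (re-replicated, beyond 4N). G1 and G2/M are Gaussian peaks with a common
#' coefficient of variation; S-phase intensity is uniform between the two peak
#' positions convolved with the G1 measurement noise (the standard flat
#' S-plateau approximation for DNA-content histograms).
#'
#' @param g1_mean G1 peak position, arbitrary intensity units. Must be > 0.
#' @param cv Coefficient of variation of the peaks (fraction, in (0, 0.3)).
#' @param g2_ratio G2/M peak position relative to G1 (dimensionless,
#'   in \[1.8, 2.2\]; 2 for a clean 2N/4N doubling).
#' @param phase_probs Named probability vector over
#'   `c("subG1","G1","S","G2M","overG2")`; must sum to 1. The default is a
#'   typical propidium-iodide profile of a cycling near-diploid line.
#' @param s_shape Label for the S-phase intensity law; only `"uniform"` is
#'   implemented.
#' @return An object of class `cell_cycle_model`.
#' @export
#' @examples
#' m <- cell_cycle_model()
#' m$phase_probs
cell_cycle_model <- function(g1_mean = 100,
                             cv = 0.05,
                             g2_ratio = 2,
                             phase_probs = c(subG1 = 0.03, G1 = 0.52,
                                             S = 0.23, G2M = 0.17,
                                             overG2 = 0.05),
                             s_shape = "uniform") {
  if (!is.numeric(g1_mean) || g1_mean <= 0) abort("`g1_mean` must be > 0.")
  if (!is.numeric(cv) || cv <= 0 || cv >= 0.3) {
    abort("`cv` must lie in (0, 0.3).")
  }
  if (g2_ratio < 1.8 || g2_ratio > 2.2) {
    abort("`g2_ratio` must lie in [1.8, 2.2].")
  }
  if (!setequal(names(phase_probs), PHASES)) {
    abort(sprintf("`phase_probs` must be named over {%s}.",
                  paste(PHASES, collapse = ", ")))
  }
  phase_probs <- phase_probs[PHASES]
  if (any(phase_probs < 0) || abs(sum(phase_probs) - 1) > 1e-9) {
    abort("`phase_probs` must be non-negative and sum to 1 (tol 1e-9).")
  }
  s_shape <- match.arg(s_shape, "uniform")
  structure(
    list(g1_mean = g1_mean, cv = cv, g2_ratio = g2_ratio,
         phase_probs = phase_probs, s_shape = s_shape),
    class = "cell_cycle_model"
  )
}

#' @export
print.cell_cycle_model <- function(x, ...) {
  cat("<cell_cycle_model>\n")
  cat(sprintf("  G1 peak %.4g (cv %.3g), G2/M at %.3gx\n",
              x$g1_mean, x$cv, x$g2_ratio))
  cat("  phase occupancy:",
      paste(sprintf("%s=%.3g", names(x$phase_probs), x$phase_probs),
            collapse = " "), "\n")
  invisible(x)
}

# Default control layout: the 16 non-sample wells (columns 1 and 12)
# carry 4 negative-control, 4 GFP, 4 mock and 4 positive-control wells,
# covering the screen's stated controls with margin.
default_control_layout <- function() {
  edge <- c(paste0(LETTERS[1:8], "01"), paste0(LETTERS[1:8], "12"))
  setNames(rep(c("neg_ctrl", "gfp_ctrl", "mock", "pos_ctrl"), each = 4), edge)
}

#' Plate design of a synthetic screen
#'
#' Describes the plate/replicate/batch structure of one screened cell line:
#' 96-well plates with 80 sample wells (one gene each) and a fixed set of
#' control wells, transfected in triplicate, processed in batches. Plates are
#' assigned to batches in contiguous blocks; all replicates of a plate share
#' its batch (replicate transfections are performed simultaneously).
#'
#' @param n_plates Number of distinct library plates.
#' @param wells_per_plate Wells per plate (only 96 supported).
#' @param replicates Replicate transfections per plate (default 3).
#' @param batches Number of processing batches (default 16, capped at
#'   `n_plates`).
#' @param control_layout Named character vector, well name to role for the
#'   non-sample wells. Roles must be among
#'   `c("neg_ctrl","gfp_ctrl","mock","pos_ctrl")`, with at least one
#'   negative-control and GFP well and three mock and positive-control wells.
#' @param seed Integer seed recorded with the design and used as the default
#'   seed of [simulate_screen()].
#' @return An object of class `screen_design`.
#' @export
#' @examples
#' d <- screen_design(n_plates = 2, seed = 1)
#' nrow(screen_layout(d))  # 2 plates x 96 wells x 3 replicates
screen_design <- function(n_plates,
                          wells_per_plate = 96,
                          replicates = 3,
                          batches = 16,
                          control_layout = default_control_layout(),
                          seed = NULL) {
  if (!is.numeric(n_plates) || n_plates < 1) abort("`n_plates` must be >= 1.")
  if (wells_per_plate != 96) {
    abort("only the 96-well format (80 sample wells) is supported.")
  }
  if (replicates < 1) abort("`replicates` must be >= 1.")
  batches <- min(batches, n_plates)
  roles <- unname(control_layout)
  bad <- setdiff(roles, setdiff(WELL_ROLES, "sample"))
  if (length(bad) > 0) {
    abort(sprintf("unknown control role(s): %s", paste(unique(bad), collapse = ", ")))
  }
  if (!all(is_valid_well(names(control_layout)))) {
    abort("control_layout well names must be A01..H12.")
  }
  if (sum(roles == "neg_ctrl") < 1 || sum(roles == "gfp_ctrl") < 1 ||
      sum(roles == "mock") < 3 || sum(roles == "pos_ctrl") < 3) {
    abort(paste0("control_layout must include >= 1 neg_ctrl, >= 1 gfp_ctrl, ",
                 ">= 3 mock and >= 3 pos_ctrl wells."))
  }
  sample_wells <- setdiff(well_names(), names(control_layout))
  structure(
    list(n_plates = as.integer(n_plates),
         wells_per_plate = 96L,
         replicates = as.integer(replicates),
         batches = as.integer(batches),
         control_layout = control_layout,
         sample_wells = sample_wells,
         n_genes = as.integer(n_plates) * length(sample_wells),
         seed = seed),
    class = "screen_design"
  )
}

#' @export
print.screen_design <- function(x, ...) {
  cat("<screen_design>\n")
  cat(sprintf("  %d plates x %d wells (%d sample), %d replicates, %d batches\n",
              x$n_plates, x$wells_per_plate, length(x$sample_wells),
              x$replicates, x$batches))
  cat(sprintf("  %d genes, seed %s\n", x$n_genes,
              if (is.null(x$seed)) "unset" else format(x$seed)))
  invisible(x)
}

#' Expand a screen design into a plate layout table
#'
#' @param design A [screen_design()].
#' @param gene_ids Gene identifiers for the sample wells, recycled across
#'   plates in well order; defaults to `G00001 ...`.
#' @return A tibble with columns `plate_id`, `well`, `role`, `gene_id`
#'   (`NA` for control wells), `batch`, `replicate`.
#' @export
screen_layout <- function(design, gene_ids = NULL) {
  stopifnot(inherits(design, "screen_design"))
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("G%05d", seq_len(design$n_genes))
  }
  if (length(gene_ids) != design$n_genes) {
    abort(sprintf("need exactly %d gene ids (one per sample well).",
                  design$n_genes))
  }
  plate_ids <- sprintf("P%03d", seq_len(design$n_plates))
  # contiguous blocks of plates per batch
  batch_of_plate <- if (design$batches == 1) {
    rep(1L, design$n_plates)
  } else {
    as.integer(cut(seq_len(design$n_plates), breaks = design$batches,
                   labels = FALSE))
  }
  wells <- well_names()
  role <- rep("sample", length(wells))
  names(role) <- wells
  role[names(design$control_layout)] <- design$control_layout

  per_plate <- tibble(
    well = wells,
    role = unname(role[wells])
  )
  gene_map <- split(gene_ids,
                    rep(seq_len(design$n_plates), each = length(design$sample_wells)))

  one_rep <- purrr::map_dfr(seq_len(design$n_plates), function(p) {
    df <- per_plate
    df$plate_id <- plate_ids[p]
    df$batch <- batch_of_plate[p]
    g <- rep(NA_character_, nrow(df))
    g[df$role == "sample"] <- gene_map[[p]]
    df$gene_id <- g
    df
  })
  out <- purrr::map_dfr(seq_len(design$replicates), function(r) {
    df <- one_rep
    df$replicate <- r
    df
  })
  dplyr::select(out, "plate_id", "well", "role", "gene_id", "batch", "replicate")
}

#' Spiked phenotype specification
#'
#' Declares a known perturbation for one gene in one cell line: multiplicative
#' shifts on phase occupancies (which are renormalized to sum to 1) and/or on
#' total cell number. Used to plant ground-truth hits in synthetic screens.
#'
#' @param gene_id Gene identifier (must be a sample-well gene in the layout).
#' @param cell_line Cell line the effect applies to.
#' @param effects Named numeric vector of multipliers; names must be among
#'   `c("cellNumber","subG1","G1","S","G2M","overG2")`. A value of 1 is a
#'   no-op; e.g. `c(S = 1.5)` shifts occupancy toward S-phase,
#'   `c(cellNumber = 0.2)` reduces the cell count to a fifth.
#' @param penetrance Probability that any given replicate well shows the
#'   effect (default 1).
#' @return One-row tibble; bind rows of several specs into a spike table.
#' @export
#' @examples
#' spike_spec("G00001", "RPE1", c(S = 1.5, cellNumber = 0.8))
spike_spec <- function(gene_id, cell_line, effects, penetrance = 1) {
  if (is.null(names(effects)) || !all(names(effects) %in% SCREEN_PARAMS)) {
    abort(sprintf("effect names must be among {%s}.",
                  paste(SCREEN_PARAMS, collapse = ", ")))
  }
  if (any(effects < 0)) abort("effect multipliers must be >= 0.")
  if (penetrance < 0 || penetrance > 1) abort("`penetrance` must be in [0, 1].")
  tibble(
    gene_id = gene_id,
    cell_line = cell_line,
    effects = list(effects),
    penetrance = penetrance
  )
}

# Apply a spike's multipliers to a model's phase probabilities; renormalizes.
shift_phase_probs <- function(phase_probs, effects) {
  mult <- effects[intersect(names(effects), PHASES)]
  if (length(mult) == 0) return(phase_probs)
  p <- phase_probs
  p[names(mult)] <- p[names(mult)] * mult
  s <- sum(p)
  if (s <= 0) abort("spike effects annihilate all phase occupancy.")
  p / s
}

#' Phase-occupancy multiplier targeting a given screen z-score
#'
#' Computes the multiplicative shift on one phase's occupancy that places the
#' expected per-well normalized value `target_z` control standard deviations
#' above the control median, when control variation is pure counting
#' (multinomial) noise at `n_cells` cells per well. Used to plant spikes with
#' a known generative effect size.
#'
#' With baseline occupancy p and n cells, the relative standard deviation of
#' the measured percent is `sqrt(p (1 - p) / n) / p`; the multiplier m solves
#' `m p / (1 + (m - 1) p) = p'` for the shifted occupancy
#' `p' = p (1 + z * rsd)`.
#'
#' @param model A [cell_cycle_model()].
#' @param parameter One of `c("subG1","G1","S","G2M","overG2")`.
#' @param target_z Desired generative z-score (may be negative).
#' @param n_cells Expected cells per well entering the multinomial draw.
#' @return Scalar multiplier for [spike_spec()] `effects`.
#' @export
#' @examples
#' spike_multiplier(cell_cycle_model(), "S", target_z = 8, n_cells = 8000)
spike_multiplier <- function(model, parameter, target_z, n_cells) {
  stopifnot(inherits(model, "cell_cycle_model"))
  parameter <- match.arg(parameter, PHASES)
  p <- unname(model$phase_probs[parameter])
  if (p <= 0 || p >= 1) abort("baseline occupancy must be in (0, 1).")
  rsd <- sqrt(p * (1 - p) / n_cells) / p
  p_new <- p * (1 + target_z * rsd)
  if (p_new <= 0 || p_new >= 1) {
    abort("target z-score pushes occupancy outside (0, 1); reduce |target_z|.")
  }
  (p_new * (1 - p)) / (p * (1 - p_new))
}
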