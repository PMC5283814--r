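# Batch-level gating of DNA-content histograms into the five cell-cycle
# subpopulations: sub-G1, G1, S, G2/M and over-G2. Gates are estimated from
# pooled negative-control events of a batch and applied to every well of
# that batch, replacing per-batch manual gating with a reproducible
# mode-and-moment procedure.

#' Estimate cell-cycle gates for one or more batches
#'
#' For each batch, pools the DNA-content intensities of the batch's
#' negative-control wells (non-targeting and GFP siRNA), histograms them
#' (256 bins over \[0, 99.5th percentile\]), locates the G1 peak as the global
#' mode and the G2/M peak as the highest local mode within 1.8-2.2 times the
#' G1 position, fits local Gaussian moments (mean and sd of events within
#' +/-20\% of each peak), and sets the four boundaries at
#' `mu +/- n_sigma * sigma`: `b0 = mu_G1 - n_sigma*sigma_G1` (sub-G1/G1),
#' `b1 = mu_G1 + n_sigma*sigma_G1` (G1/S), `b2 = mu_G2 - n_sigma*sigma_G2`
#' (S/G2M), `b3 = mu_G2 + n_sigma*sigma_G2` (G2M/over-G2). If the G1 and G2
#' bands touch (`b2 <= b1`) both collapse to their midpoint (zero-width S).
#'
#' @param events Event tibble with `dna_intensity`, `plate_id`, `well`,
#'   `batch` columns (one or several batches).
#' @param layout Layout tibble giving each well's `role`.
#' @param n_sigma Half-width of the peak bands in peak standard deviations
#'   (default 2.5).
#' @param n_bins Histogram bins (default 256).
#' @param min_events Minimum pooled negative-control events per batch
#'   (default 500).
#' @return Tibble of class `gate_set`, one row per batch: `batch`, `b0`,
#'   `b1`, `b2`, `b3`, `mu_g1`, `sigma_g1`, `mu_g2`, `sigma_g2`, `n_events`.
#' @export
#' @examples
#' d <- screen_design(n_plates = 1, replicates = 1, batches = 1, seed = 3)
#' sim <- simulate_screen(d, cell_cycle_model(), mean_cells = 500,
#'                        growth_factor = 1)
#' estimate_gates(sim$events, sim$layout)
estimate_gates <- function(events, layout, n_sigma = 2.5, n_bins = 256,
                           min_events = 500) {
  require_columns(events, c("plate_id", "well", "batch", "dna_intensity"),
                  "events")
  require_columns(layout, c("plate_id", "well", "role"), "layout")
  if (n_sigma <= 0) abort("`n_sigma` must be > 0.")

  neg_wells <- layout |>
    dplyr::filter(.data$role %in% NEGATIVE_ROLES) |>
    dplyr::distinct(.data$plate_id, .data$well)
  neg_events <- dplyr::inner_join(events, neg_wells,
                                  by = c("plate_id", "well"))

  out <- neg_events |>
    dplyr::group_by(.data$batch) |>
    dplyr::group_modify(function(df, key) {
      gates_from_intensities(df$dna_intensity, n_sigma, n_bins, min_events,
                             batch_label = key$batch)
    }) |>
    dplyr::ungroup()
  if (nrow(out) == 0) abort("no negative-control events found in any batch.")
  class(out) <- c("gate_set", class(out))
  out
}

gates_from_intensities <- function(x, n_sigma, n_bins, min_events,
                                   batch_label = NA) {
  x <- x[is.finite(x) & x >= 0]
  if (length(x) < min_events) {
    abort(sprintf("batch %s: %d negative-control events, need >= %d.",
                  format(batch_label), length(x), min_events))
  }
  upper <- quantile(x, 0.995, names = FALSE)
  if (upper <= 0) abort(sprintf("batch %s: degenerate histogram", format(batch_label)))
  breaks <- seq(0, upper, length.out = n_bins + 1L)
  h <- graphics::hist(pmin(x, upper), breaks = breaks, plot = FALSE)
  mids <- h$mids
  counts <- h$counts

  g1_pos <- mids[which.max(counts)]

  # G2/M: highest local mode in [1.8, 2.2] x G1 position
  win <- which(mids >= 1.8 * g1_pos & mids <= 2.2 * g1_pos)
  if (length(win) < 3) abort(sprintf("batch %s: degenerate histogram", format(batch_label)))
  local_max <- win[vapply(win, function(i) {
    lo <- counts[max(i - 1L, 1L)]; hi <- counts[min(i + 1L, length(counts))]
    counts[i] > 0 && counts[i] >= lo && counts[i] >= hi
  }, logical(1))]
  if (length(local_max) == 0 || max(counts[local_max]) == 0) {
    abort(sprintf("batch %s: degenerate histogram (no G2/M mode in [1.8, 2.2] x G1)",
                  format(batch_label)))
  }
  g2_pos <- mids[local_max[which.max(counts[local_max])]]

  moment_fit <- function(peak) {
    sel <- x[x >= 0.8 * peak & x <= 1.2 * peak]
    c(mu = mean(sel), sigma = sd(sel))
  }
  f1 <- moment_fit(g1_pos)
  f2 <- moment_fit(g2_pos)

  b0 <- f1[["mu"]] - n_sigma * f1[["sigma"]]
  b1 <- f1[["mu"]] + n_sigma * f1[["sigma"]]
  b2 <- f2[["mu"]] - n_sigma * f2[["sigma"]]
  b3 <- f2[["mu"]] + n_sigma * f2[["sigma"]]
  if (b2 <= b1) b1 <- b2 <- (b1 + b2) / 2
  b0 <- max(b0, 0)

  tibble(b0 = b0, b1 = b1, b2 = b2, b3 = b3,
         mu_g1 = f1[["mu"]], sigma_g1 = f1[["sigma"]],
         mu_g2 = f2[["mu"]], sigma_g2 = f2[["sigma"]],
         n_events = length(x))
}

#' Classify events and count cell-cycle subpopulations per well
#'
#' Applies each batch's gates to its events with half-open-right intervals:
#' sub-G1 `[0, b0)`, G1 `[b0, b1)`, S `[b1, b2)`, G2/M `[b2, b3)`, over-G2
#' `[b3, Inf)`. An event exactly at a boundary belongs to the interval on the
#' right. Events with negative intensity are rejected and counted in the
#' `n_rejected` attribute.
#'
#' @param events Event tibble (`plate_id`, `well`, `replicate`, `batch`,
#'   `dna_intensity`).
#' @param gates A `gate_set` from [estimate_gates()] covering every batch
#'   present in `events`.
#' @param debris_cutoff Optional fraction of `mu_g1` below which events are
#'   dropped as debris before counting (`NULL`, the default, keeps all).
#' @return Tibble of class `phase_counts`: one row per plate/well/replicate
#'   with `total`, `n_subG1` .. `n_overG2`, the matching `frac_*` columns
#'   (fractions of total; `NaN` where `total = 0`, flagged by `empty`), plus
#'   `batch`. Attribute `n_rejected` counts discarded negative intensities.
#' @export
count_phases <- function(events, gates, debris_cutoff = NULL) {
  require_columns(events, c("plate_id", "well", "replicate", "batch",
                            "dna_intensity"), "events")
  require_columns(gates, c("batch", "b0", "b1", "b2", "b3"), "gates")
  missing_batches <- setdiff(unique(events$batch), gates$batch)
  if (length(missing_batches) > 0) {
    abort(sprintf("no gates for batch(es): %s",
                  paste(missing_batches, collapse = ", ")))
  }

  neg <- events$dna_intensity < 0
  n_rejected <- sum(neg)
  if (n_rejected > 0) {
    inform(sprintf("count_phases: rejected %d event(s) with negative intensity.",
                   n_rejected))
    events <- events[!neg, , drop = FALSE]
  }

  ev <- dplyr::left_join(events,
                         dplyr::select(gates, "batch", "b0", "b1", "b2", "b3"),
                         by = "batch")
  if (!is.null(debris_cutoff)) {
    ev <- dplyr::left_join(ev, dplyr::select(gates, "batch", "mu_g1"),
                           by = "batch")
    ev <- dplyr::filter(ev, .data$dna_intensity >= debris_cutoff * .data$mu_g1)
    ev$mu_g1 <- NULL
  }

  # findInterval with rightmost.closed = FALSE gives the half-open-right rule
  idx <- 1L +
    (ev$dna_intensity >= ev$b0) + (ev$dna_intensity >= ev$b1) +
    (ev$dna_intensity >= ev$b2) + (ev$dna_intensity >= ev$b3)
  ev$phase <- PHASES[idx]

  out <- ev |>
    dplyr::group_by(.data$plate_id, .data$well, .data$replicate, .data$batch) |>
    dplyr::summarise(
      total = dplyr::n(),
      n_subG1 = sum(.data$phase == "subG1"),
      n_G1 = sum(.data$phase == "G1"),
      n_S = sum(.data$phase == "S"),
      n_G2M = sum(.data$phase == "G2M"),
      n_overG2 = sum(.data$phase == "overG2"),
      .groups = "drop"
    ) |>
    mutate(across(dplyr::all_of(paste0("n_", PHASES)),
                  ~ .x / .data$total, .names = "frac_{sub('n_', '', .col)}"),
           empty = .data$total == 0)
  attr(out, "n_rejected") <- n_rejected
  class(out) <- c("phase_counts", class(out))
  out
}

#' Per-event phase labels under a gate set
#'
#' Vector version of the gate rule used by [count_phases()]; useful for
#' accuracy studies against simulated true labels.
#'
#' @param intensity Numeric DNA-content intensities (>= 0).
#' @param gates One row of a `gate_set` (or a list with `b0..b3`).
#' @return Character vector of phase labels.
#' @export
gate_phase <- function(intensity, gates) {
  idx <- 1L + (intensity >= gates$b0[1]) + (intensity >= gates$b1[1]) +
    (intensity >= gates$b2[1]) + (intensity >= gates$b3[1])
  PHASES[idx]
}

#' Split S-phase events by EdU incorporation
#'
#' Within each well, takes the S-phase events (by the DNA-content gates) and
#' splits them at an EdU threshold estimated from the pooled negative-control
#' S-phase events of each batch: cells with S-phase DNA content but low EdU
#' are replicating slowly or not at all. Thresholding is either the `q`
#' lower quantile of the control EdU distribution (`"quantile"`, default) or
#' a two-class Otsu split of the pooled control values (`"otsu"`).
#'
#' @param events Event tibble with `edu_intensity`.
#' @param gates A `gate_set` covering the batches.
#' @param layout Layout with well roles.
#' @param method `"quantile"` or `"otsu"`.
#' @param q Lower-quantile level for `method = "quantile"` (default 0.01).
#' @return Tibble, one row per plate/well/replicate: `n_S`, `n_S_edu_low`,
#'   `n_S_edu_high`, `n_nonS`, `frac_S_edu_low`, and the threshold used.
#' @export
classify_bivariate <- function(events, gates, layout,
                               method = c("quantile", "otsu"), q = 0.01) {
  method <- match.arg(method)
  require_columns(events, c("plate_id", "well", "replicate", "batch",
                            "dna_intensity", "edu_intensity"), "events")
  ev <- dplyr::left_join(events,
                         dplyr::select(gates, "batch", "b0", "b1", "b2", "b3"),
                         by = "batch")
  idx <- 1L + (ev$dna_intensity >= ev$b0) + (ev$dna_intensity >= ev$b1) +
    (ev$dna_intensity >= ev$b2) + (ev$dna_intensity >= ev$b3)
  ev$is_s <- idx == 3L

  neg_wells <- layout |>
    dplyr::filter(.data$role %in% NEGATIVE_ROLES) |>
    dplyr::distinct(.data$plate_id, .data$well)
  ctrl_s <- dplyr::inner_join(ev, neg_wells, by = c("plate_id", "well")) |>
    dplyr::filter(.data$is_s)

  thresholds <- ctrl_s |>
    dplyr::group_by(.data$batch) |>
    dplyr::summarise(edu_threshold = if (dplyr::n() == 0) NA_real_
                     else if (method == "quantile")
                       quantile(.data$edu_intensity, q, names = FALSE)
                     else otsu_threshold(.data$edu_intensity),
                     .groups = "drop")
  if (nrow(thresholds) == 0 || anyNA(thresholds$edu_threshold)) {
    abort("no negative-control S-phase events to set the EdU threshold.")
  }

  ev <- dplyr::left_join(ev, thresholds, by = "batch")
  ev |>
    dplyr::group_by(.data$plate_id, .data$well, .data$replicate) |>
    dplyr::summarise(
      n_S = sum(.data$is_s),
      n_S_edu_low = sum(.data$is_s & .data$edu_intensity < .data$edu_threshold),
      n_S_edu_high = sum(.data$is_s & .data$edu_intensity >= .data$edu_threshold),
      n_nonS = sum(!.data$is_s),
      frac_S_edu_low = .data$n_S_edu_low / pmax(.data$n_S, 1L),
      edu_threshold = first(.data$edu_threshold),
      .groups = "drop"
    )
}

# One-dimensional Otsu threshold: maximizes between-class variance over a
# 256-bin histogram of the values.
otsu_threshold <- function(x, n_bins = 256) {
  r <- range(x)
  if (diff(r) <= 0) return(r[1])
  breaks <- seq(r[1], r[2], length.out = n_bins + 1L)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  p <- h$counts / sum(h$counts)
  omega <- cumsum(p)
  mu <- cumsum(p * h$mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  h$mids[which.max(sigma_b)]
}

#' @export
autoplot.gate_set <- function(object, events = NULL, ...) {
  long <- tidyr::pivot_longer(object, dplyr::all_of(c("b0", "b1", "b2", "b3")),
                              names_to = "boundary", values_to = "intensity")
  p <- ggplot(long, aes(x = .data$intensity))
  if (!is.null(events)) {
    p <- p + geom_histogram(data = events,
                            aes(x = .data$dna_intensity, y = NULL),
                            bins = 128, fill = "grey70")
  }
  p +
    geom_vline(aes(xintercept = .data$intensity, colour = .data$boundary),
               linetype = 2) +
    facet_wrap(~batch, labeller = label_both) +
    labs(x = "DNA-content intensity (a.u.)", y = NULL,
         title = "Cell-cycle gate boundaries by batch")
}
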