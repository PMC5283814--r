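# Two-stage median normalization and control-based z-scoring of per-well
# screen phenotypes. Stage one divides every parameter by its per-plate
# median; stage two divides by the per-well-position median across all
# plates. Z-scores are then computed per gene against the pooled negative
# controls: Z = (x - mu) / sigma with x the median of the gene's replicate
# wells, mu the median and sigma the standard deviation of all
# negative-control wells.

#' Assemble per-well phenotypes from phase counts
#'
#' Joins gated phase counts to the plate layout and derives the six screen
#' parameters: `cellNumber` (total gated cells) and the five phase
#' occupancies as percent of total.
#'
#' @param counts A `phase_counts` tibble from [count_phases()] (or the
#'   `counts` element of a `level = "counts"` [simulate_screen()] run).
#' @param layout Layout tibble (`plate_id`, `well`, `role`, `gene_id`,
#'   `replicate`, optionally `cell_line`).
#' @return Tibble of class `well_phenotypes`: layout keys plus one column per
#'   parameter (`cellNumber`, `subG1`, `G1`, `S`, `G2M`, `overG2`).
#' @export
well_phenotypes <- function(counts, layout) {
  require_columns(counts, c("plate_id", "well", "replicate", "total",
                            paste0("n_", PHASES)), "counts")
  require_columns(layout, c("plate_id", "well", "replicate", "role", "gene_id"),
                  "layout")
  keys <- intersect(c("plate_id", "well", "replicate"), names(layout))
  out <- counts |>
    dplyr::select("plate_id", "well", "replicate", dplyr::any_of("batch"),
                  "total", dplyr::all_of(paste0("n_", PHASES))) |>
    dplyr::inner_join(
      dplyr::select(layout, dplyr::all_of(keys), "role", "gene_id",
                    dplyr::any_of("cell_line")),
      by = keys) |>
    mutate(cellNumber = as.numeric(.data$total),
           across(dplyr::all_of(paste0("n_", PHASES)),
                  ~ 100 * .x / .data$total,
                  .names = "{sub('n_', '', .col)}")) |>
    dplyr::select("plate_id", "well", "replicate", dplyr::any_of("batch"),
                  "role", "gene_id", dplyr::any_of("cell_line"),
                  dplyr::all_of(SCREEN_PARAMS))
  class(out) <- c("well_phenotypes", class(out))
  out
}

#' Plate-median normalization
#'
#' First normalization stage: within each physical plate (a `plate_id` x
#' `replicate` combination), every parameter is divided by the plate's median
#' of that parameter. Positive-control wells are excluded from the median
#' computation but are themselves transformed. A zero plate median flags the
#' parameter for that plate (values set to `NA`).
#'
#' @param wells A `well_phenotypes` tibble.
#' @param params Parameters to normalize (default all six).
#' @param min_wells Minimum wells contributing to each plate median
#'   (default 8).
#' @return The input with the parameter columns replaced by fold-of-plate-
#'   median values.
#' @export
#' @examples
#' # a three-well plate with S = 10, 20, 30 normalizes to 0.5, 1.0, 1.5
normalize_plate <- function(wells, params = SCREEN_PARAMS, min_wells = 8) {
  require_columns(wells, c("plate_id", "replicate", "role", params), "wells")
  grouped <- wells |> dplyr::group_by(.data$plate_id, .data$replicate)
  n_contrib <- grouped |>
    dplyr::summarise(n = sum(.data$role != "pos_ctrl"), .groups = "drop")
  if (any(n_contrib$n < min_wells)) {
    abort(sprintf("plate median needs >= %d non-positive-control wells; worst plate has %d.",
                  min_wells, min(n_contrib$n)))
  }
  out <- grouped |>
    mutate(across(dplyr::all_of(params), function(v) {
      med <- median(v[.data$role != "pos_ctrl"], na.rm = TRUE)
      if (!is.finite(med) || med == 0) {
        warn(sprintf("zero/undefined plate median for %s on %s rep %s; values set to NA.",
                     dplyr::cur_column(), .data$plate_id[1], .data$replicate[1]))
        rep(NA_real_, length(v))
      } else v / med
    })) |>
    ungroup()
  class(out) <- class(wells)
  out
}

#' Well-position median normalization
#'
#' Second normalization stage, applied after [normalize_plate()]: for each
#' well position (e.g. `B07`) and parameter, values are divided by the median
#' of that position across all plates. Positive-control wells are excluded
#' from the medians; a position occupied only by positive controls is divided
#' by the grand median of all non-positive-control values instead. A zero
#' position median flags the parameter at that position (`NA`).
#'
#' @param wells A `well_phenotypes` tibble (plate-normalized).
#' @param params Parameters to normalize.
#' @param min_plates Minimum plates each position must occur on (default 3).
#' @return The input with parameter columns further divided by position
#'   medians.
#' @export
normalize_wellposition <- function(wells, params = SCREEN_PARAMS,
                                   min_plates = 3) {
  require_columns(wells, c("plate_id", "well", "role", params), "wells")
  occ <- wells |>
    dplyr::distinct(.data$well, .data$plate_id, .data$replicate) |>
    dplyr::count(.data$well)
  if (any(occ$n < min_plates)) {
    abort(sprintf("every well position must occur on >= %d plates.", min_plates))
  }
  grand <- vapply(params, function(p) {
    median(wells[[p]][wells$role != "pos_ctrl"], na.rm = TRUE)
  }, numeric(1))
  out <- wells |>
    dplyr::group_by(.data$well) |>
    mutate(across(dplyr::all_of(params), function(v) {
      keep <- .data$role != "pos_ctrl"
      med <- if (any(keep)) median(v[keep], na.rm = TRUE)
             else grand[[dplyr::cur_column()]]
      if (!is.finite(med) || med == 0) {
        warn(sprintf("zero/undefined position median for %s at %s; values set to NA.",
                     dplyr::cur_column(), .data$well[1]))
        rep(NA_real_, length(v))
      } else v / med
    })) |>
    ungroup()
  class(out) <- class(wells)
  out
}

#' Two-stage normalization in one call
#'
#' [normalize_plate()] followed by [normalize_wellposition()]. When the input
#' spans several cell lines the stages are applied within each line.
#'
#' @inheritParams normalize_plate
#' @inheritParams normalize_wellposition
#' @export
normalize_screen <- function(wells, params = SCREEN_PARAMS, min_wells = 8,
                             min_plates = 3) {
  apply_one <- function(w) {
    normalize_wellposition(normalize_plate(w, params, min_wells),
                           params, min_plates)
  }
  if ("cell_line" %in% names(wells) &&
      dplyr::n_distinct(wells$cell_line) > 1) {
    out <- wells |>
      dplyr::group_by(.data$cell_line) |>
      dplyr::group_modify(~ apply_one(.x)) |>
      ungroup()
    class(out) <- class(wells)
    out
  } else {
    apply_one(wells)
  }
}

#' Per-gene z-scores against pooled negative controls
#'
#' For every sample-well gene and parameter: `x` is the median of the gene's
#' replicate wells (after both normalization stages); `mu` is the median and
#' `sigma` the sample standard deviation (denominator n-1) of all pooled
#' negative-control wells (non-targeting and GFP siRNA; mock wells are not
#' part of the negative-control pool); `Z = (x - mu) / sigma`. A degenerate
#' sigma (0 or undefined) flags the parameter: its z-scores become `NA` and
#' the parameter is listed in the `degenerate` attribute.
#'
#' @param wells A normalized `well_phenotypes` tibble.
#' @param params Parameters to score (default all six).
#' @param min_controls Minimum pooled negative-control wells (default 20).
#' @return Tibble of class `screen_zscores`, long format: `gene_id`,
#'   `cell_line` (if present), `parameter`, `x` (triplicate median on the
#'   normalized scale), `z`, `n_wells`. Attributes `control_stats` (tibble of
#'   mu/sigma/n per parameter and cell line) and `degenerate`.
#' @export
#' @examples
#' # controls {0.9, 1.0, 1.1, 1.0} give mu = 1, sigma = 0.08165;
#' # a gene at x = 1.2 scores Z = 2.449
zscore_genes <- function(wells, params = SCREEN_PARAMS, min_controls = 20) {
  require_columns(wells, c("plate_id", "well", "replicate", "role", "gene_id",
                           params), "wells")
  has_line <- "cell_line" %in% names(wells)
  line_key <- if (has_line) "cell_line" else character()

  long <- wells |>
    tidyr::pivot_longer(dplyr::all_of(params), names_to = "parameter",
                        values_to = "value")

  ctrl <- long |>
    dplyr::filter(.data$role %in% NEGATIVE_ROLES) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(line_key, "parameter")))) |>
    dplyr::summarise(mu = median(.data$value, na.rm = TRUE),
                     sigma = sd(.data$value, na.rm = TRUE),
                     n_controls = sum(!is.na(.data$value)),
                     .groups = "drop")
  if (any(ctrl$n_controls < min_controls)) {
    abort(sprintf("need >= %d pooled negative-control wells per parameter; have %d.",
                  min_controls, min(ctrl$n_controls)))
  }
  degenerate <- ctrl$parameter[!is.finite(ctrl$sigma) | ctrl$sigma <= 0]
  if (length(degenerate) > 0) {
    warn(sprintf("degenerate control sigma for parameter(s): %s; z set to NA.",
                 paste(unique(degenerate), collapse = ", ")))
  }

  genes <- long |>
    dplyr::filter(.data$role == "sample", !is.na(.data$gene_id)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("gene_id", line_key, "parameter")))) |>
    dplyr::summarise(x = median(.data$value, na.rm = TRUE),
                     n_wells = sum(!is.na(.data$value)),
                     .groups = "drop")

  out <- genes |>
    dplyr::left_join(ctrl, by = c(line_key, "parameter")) |>
    mutate(z = if_else(is.finite(.data$sigma) & .data$sigma > 0,
                       (.data$x - .data$mu) / .data$sigma, NA_real_)) |>
    dplyr::select(dplyr::all_of(c("gene_id", line_key)), "parameter",
                  "x", "z", "n_wells")

  low_info <- dplyr::filter(out, .data$n_wells < 2)
  if (nrow(low_info) > 0) {
    inform(sprintf("%d gene/parameter value(s) rest on < 2 informative wells.",
                   nrow(low_info)))
  }
  attr(out, "control_stats") <- ctrl
  attr(out, "degenerate") <- unique(degenerate)
  class(out) <- c("screen_zscores", class(out))
  out
}

#' @export
glance.screen_zscores <- function(x, ...) {
  ctrl <- attr(x, "control_stats")
  tibble(
    n_genes = dplyr::n_distinct(x$gene_id),
    n_parameters = dplyr::n_distinct(x$parameter),
    n_degenerate = length(attr(x, "degenerate")),
    min_controls = min(ctrl$n_controls),
    max_abs_z = max(abs(x$z), na.rm = TRUE)
  )
}

#' @export
tidy.screen_zscores <- function(x, ...) {
  as_tibble(x)
}

#' Wide per-gene z-score table
#'
#' Pivots a `screen_zscores` result to one row per gene (and cell line) with
#' `z_<parameter>` columns, the export format of the screen.
#'
#' @param zscores A `screen_zscores` tibble.
#' @return Wide tibble.
#' @export
zscore_wide <- function(zscores) {
  zscores |>
    dplyr::select(-dplyr::any_of(c("x", "n_wells"))) |>
    tidyr::pivot_wider(names_from = "parameter", values_from = "z",
                       names_prefix = "z_")
}
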