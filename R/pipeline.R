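# End-to-end orchestration: synthesize -> gate -> normalize -> map/filter ->
# hits, from a single configuration, with plain-text intermediates and a
# reproducibility manifest of input/output checksums.

#' Default pipeline configuration
#'
#' Returns the complete configuration list consumed by
#' [run_screen_pipeline()], with every stage parameter at its default.
#' Supplied values (or a YAML file read with [read_run_config()]) are merged
#' over these defaults.
#'
#' @param ... Named overrides, e.g. `screen = list(n_plates = 4)`.
#' @return Nested configuration list.
#' @export
default_config <- function(...) {
  base <- list(
    out_dir = "cyclescreen_out",
    seed = 1L,
    cell_lines = c("line1", "line2"),
    screen = list(n_plates = 6, replicates = 3, batches = 2,
                  mean_cells = 4000, growth_factor = 2,
                  plate_effect_sd = 0.1, wellpos_effect_sd = 0.05,
                  level = "counts"),
    model = list(g1_mean = 100, cv = 0.05, g2_ratio = 2),
    spikes = list(),
    library = list(offtarget_rate = 0.27, extra_transcripts = 20,
                   transcript_length = 400),
    gating = list(n_sigma = 2.5),
    hits = list(cutoff = 5),
    fiber = list(pulse_min = 20, factor = 2.59)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    o <- overrides[[nm]]
    named <- is.list(o) && length(o) > 0 && !is.null(names(o)) &&
      all(nzchar(names(o)))
    # merge keyed sub-configs; replace positional lists (e.g. spikes) whole
    base[[nm]] <- if (is.list(base[[nm]]) && named) {
      modifyList(base[[nm]], o)
    } else o
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the [default_config()] fields.
#' @return Full configuration list (file values merged over defaults).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  do.call(default_config, raw)
}

stage_error <- function(stage, parent) {
  abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(parent)),
        class = "cyclescreen_stage_error", stage = stage)
}

run_stage <- function(stage, code) {
  tryCatch(force(code), error = function(e) {
    if (inherits(e, "cyclescreen_stage_error")) stop(e)
    stage_error(stage, e)
  })
}

#' Run the full screen pipeline
#'
#' Executes, in dependency order: synthetic screen generation per cell line
#' (events or counts), library simulation, gating (event level only),
#' phenotype assembly and two-stage normalization, per-gene z-scoring,
#' siRNA-to-transcript mapping with the four-siRNA single-gene filter
#' (z-scores restricted to passing genes), hit calling, two-line comparison
#' (when two cell lines are configured) and profile clustering. All
#' intermediates are written as plain text under `config$out_dir`, and a
#' manifest of checksums is returned and written as JSON.
#'
#' @param config Configuration list from [default_config()] or
#'   [read_run_config()].
#' @return The manifest, invisibly; side effect: files under
#'   `config$out_dir`.
#' @export
#' @examples
#' \donttest{
#' cfg <- default_config(out_dir = tempfile("screen"),
#'                       screen = list(n_plates = 3, mean_cells = 300,
#'                                     growth_factor = 1))
#' manifest <- run_screen_pipeline(cfg)
#' }
run_screen_pipeline <- function(config) {
  config <- do.call(default_config, config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  emit <- function(path) {
    outputs <<- c(outputs, path)
    path
  }

  lines <- config$cell_lines
  level <- config$screen$level

  design <- run_stage("synth", screen_design(
    n_plates = config$screen$n_plates,
    replicates = config$screen$replicates,
    batches = config$screen$batches,
    seed = config$seed
  ))
  model <- run_stage("synth", do.call(cell_cycle_model, config$model))
  spikes <- run_stage("synth", {
    if (length(config$spikes) == 0) NULL
    else purrr::map_dfr(config$spikes, function(s) {
      spike_spec(s$gene_id, s$cell_line, unlist(s$effects),
                 s$penetrance %||% 1)
    })
  })

  sims <- run_stage("synth", {
    purrr::map(seq_along(lines), function(i) {
      sim <- simulate_screen(
        design, model, spikes = spikes,
        plate_effect_sd = config$screen$plate_effect_sd,
        wellpos_effect_sd = config$screen$wellpos_effect_sd,
        mean_cells = config$screen$mean_cells,
        growth_factor = config$screen$growth_factor,
        level = level, cell_line = lines[i],
        seed = child_seed(config$seed, i)
      )
      write_layout(sim$layout,
                   emit(file.path(out_dir, sprintf("layout_%s.csv", lines[i]))))
      if (level == "events") {
        write_events(sim$events,
                     emit(file.path(out_dir, sprintf("events_%s.csv", lines[i]))))
      } else {
        write_phase_counts(sim$counts,
                           emit(file.path(out_dir, sprintf("counts_%s.tsv", lines[i]))))
      }
      readr::write_tsv(sim$truth,
                       emit(file.path(out_dir, sprintf("truth_%s.tsv", lines[i]))),
                       progress = FALSE)
      sim
    }) |> setNames(lines)
  })

  lib <- run_stage("library", {
    lib <- simulate_library(
      n_genes = design$n_genes,
      transcriptome_size = design$n_genes + config$library$extra_transcripts,
      offtarget_rate = config$library$offtarget_rate,
      transcript_length = config$library$transcript_length,
      seed = child_seed(config$seed, 99L)
    )
    write_fasta(lib$sirnas, emit(file.path(out_dir, "sirnas.fasta")))
    write_fasta(lib$transcripts, emit(file.path(out_dir, "transcripts.fasta")))
    readr::write_tsv(lib$truth, emit(file.path(out_dir, "library_truth.tsv")),
                     progress = FALSE)
    lib
  })

  counts <- run_stage("gate", {
    purrr::imap(sims, function(sim, line) {
      if (level == "events") {
        gates <- estimate_gates(sim$events, sim$layout,
                                n_sigma = config$gating$n_sigma)
        write_gates(gates,
                    emit(file.path(out_dir, sprintf("gates_%s.json", line))))
        pc <- count_phases(sim$events, gates)
        write_phase_counts(pc,
                           emit(file.path(out_dir, sprintf("counts_%s.tsv", line))))
        pc
      } else {
        sim$counts
      }
    })
  })

  zscores <- run_stage("normalize", {
    per_line <- purrr::imap(counts, function(pc, line) {
      wells <- well_phenotypes(pc, sims[[line]]$layout)
      wells$cell_line <- line
      z <- zscore_genes(normalize_screen(wells))
      z
    })
    z <- dplyr::bind_rows(per_line)
    class(z) <- c("screen_zscores", class(tibble()))
    write_zscores(z, emit(file.path(out_dir, "zscores_all.tsv")))
    z
  })

  retained <- run_stage("map", {
    mapping <- map_sirnas(lib$sirnas, lib$transcripts)
    wf <- filter_wells(mapping)
    readr::write_tsv(wf, emit(file.path(out_dir, "well_filter.tsv")),
                     progress = FALSE)
    wf$gene[wf$status == "pass"]
  })
  z_retained <- dplyr::filter(zscores, .data$gene_id %in% retained)
  class(z_retained) <- c("screen_zscores", class(tibble()))

  results <- run_stage("hits", {
    hits <- call_hits(z_retained, cutoff = config$hits$cutoff)
    readr::write_tsv(as_tibble(hits), emit(file.path(out_dir, "hits.tsv")),
                     progress = FALSE)
    cmp <- NULL
    if (length(lines) >= 2) {
      cmp <- compare_lines(z_retained, lines[1], lines[2],
                           cutoff = config$hits$cutoff)
      readr::write_tsv(as_tibble(cmp),
                       emit(file.path(out_dir, "line_comparison.tsv")),
                       progress = FALSE)
    }
    clusters <- tryCatch(cluster_profiles(z_retained, config$hits$cutoff),
                         error = function(e) NULL)
    if (!is.null(clusters)) {
      readr::write_tsv(as_tibble(clusters$matrix, rownames = "gene_id"),
                       emit(file.path(out_dir, "hit_profiles.tsv")),
                       progress = FALSE)
      if (!is.null(clusters$newick)) {
        readr::write_lines(clusters$newick,
                           emit(file.path(out_dir, "hit_dendrogram.nwk")))
      }
    }
    list(hits = hits, comparison = cmp, clusters = clusters)
  })

  manifest <- list(
    config_hash = unname(tools::md5sum(write_canonical_config(config, out_dir))),
    seed = config$seed,
    cell_lines = lines,
    n_genes = design$n_genes,
    n_hit_genes = nrow(hit_genes(results$hits)),
    n_retained_genes = length(retained),
    files = file_checksums(outputs),
    versions = list(cyclescreen = as.character(utils::packageVersion("cyclescreen")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

write_canonical_config <- function(config, out_dir) {
  path <- file.path(out_dir, "config_used.json")
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

file_checksums <- function(paths) {
  sums <- tools::md5sum(paths)
  setNames(as.list(unname(sums)), basename(paths))
}

#' Validate pipeline input files
#'
#' Schema checks for the interchange files: required columns, well names in
#' `A01..H12`, the role vocabulary, and a strict ACGT alphabet for FASTA
#' inputs. Returns a report of issues rather than failing on the first.
#'
#' @param events,layout,sirnas,transcripts Optional file paths; only the
#'   supplied ones are checked.
#' @return Tibble of class `validation_report` with columns `file`, `issue`
#'   (zero rows when everything is valid); attribute `ok`.
#' @export
validate_inputs <- function(events = NULL, layout = NULL, sirnas = NULL,
                            transcripts = NULL) {
  issues <- list()
  note <- function(file, issue) {
    issues[[length(issues) + 1L]] <<- tibble(file = file, issue = issue)
  }
  check_table <- function(path, required, checks) {
    if (!file.exists(path)) {
      note(path, "file not found")
      return()
    }
    df <- tryCatch(readr::read_csv(path, show_col_types = FALSE,
                                   progress = FALSE),
                   error = function(e) NULL)
    if (is.null(df)) {
      note(path, "unreadable CSV")
      return()
    }
    missing <- setdiff(required, names(df))
    if (length(missing) > 0) {
      note(path, sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
      return()
    }
    checks(df, path)
  }

  if (!is.null(events)) {
    check_table(events, EVENT_COLS, function(df, path) {
      bad <- unique(df$well[!is_valid_well(df$well)])
      if (length(bad) > 0) {
        note(path, sprintf("invalid well name(s): %s",
                           paste(head(bad, 5), collapse = ", ")))
      }
      if (any(df$dna_intensity < 0, na.rm = TRUE)) {
        note(path, "negative dna_intensity values")
      }
    })
  }
  if (!is.null(layout)) {
    check_table(layout, LAYOUT_COLS, function(df, path) {
      bad <- unique(df$well[!is_valid_well(df$well)])
      if (length(bad) > 0) {
        note(path, sprintf("invalid well name(s): %s",
                           paste(head(bad, 5), collapse = ", ")))
      }
      bad_role <- setdiff(unique(df$role), WELL_ROLES)
      if (length(bad_role) > 0) {
        note(path, sprintf("unknown role(s): %s", paste(bad_role, collapse = ", ")))
      }
    })
  }
  for (fa in c(sirnas, transcripts)) {
    if (!file.exists(fa)) {
      note(fa, "file not found")
      next
    }
    ok <- tryCatch({
      read_sequences(fa)
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) note(fa, ok)
  }

  report <- if (length(issues) == 0) {
    tibble(file = character(), issue = character())
  } else {
    dplyr::bind_rows(issues)
  }
  attr(report, "ok") <- nrow(report) == 0
  class(report) <- c("validation_report", class(report))
  report
}
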