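#' Run a screen end-to-end
#'
#' Orchestrates the full analysis on a synthetic screen: generation
#' (fast-mode well tables, or image rendering followed by nucleus-seeded
#' segmentation and per-well summarization), per-plate DMSO normalization,
#' triplicate aggregation, and four-criteria hit calling, plus the QC
#' metrics a screener checks first (per-plate vehicle CV and the separation
#' of the CHX-like and Torin-like control wells from vehicle). With
#' `output_dir` set, every stage's table, the plate map, the QC report and
#' the serialized configuration are written as CSV/JSON for provenance.
#'
#' @param config `screen_config`.
#' @param mode `"fast"` or `"image"` (see [generate_screen()]).
#' @param thresholds `hit_thresholds`.
#' @param seg named list of [segment_field()] parameter overrides
#'   (image mode).
#' @param pool per-well pooling rule, see [summarize_well()].
#' @param output_dir optional directory for the result bundle.
#' @return list of class `screen_run`: `plate_map`, `wells`, `normalized`,
#'   `dmso_stats`, `scores`, `hits`, `qc`, `truth`, `config`.
#' @export
run_screen <- function(config, mode = c("fast", "image"),
                       thresholds = hit_thresholds(), seg = list(),
                       pool = "cells", output_dir = NULL) {
  mode <- match.arg(mode)
  sim <- generate_screen(config, mode)
  wells <- if (mode == "fast") {
    sim$wells
  } else {
    measure_screen_images(sim, seg = seg, pool = pool)
  }
  analyze_well_table(wells, sim$plate_map, thresholds = thresholds,
                     n_plates = config$n_plates, truth = sim$truth,
                     config = config, output_dir = output_dir)
}

#' Segment and summarize the rendered wells of a synthetic screen
#'
#' @param sim `synthetic_screen` generated in image mode.
#' @param seg named list of [segment_field()] overrides.
#' @param pool see [summarize_well()].
#' @return well-summary data.frame.
#' @export
measure_screen_images <- function(sim, seg = list(), pool = "cells") {
  if (is.null(sim$images)) stop("screen was not generated in image mode")
  rows <- list()
  for (pid in names(sim$images)) {
    for (w in names(sim$images[[pid]])) {
      fields <- sim$images[[pid]][[w]]
      recs <- do.call(rbind, lapply(seq_along(fields), function(f) {
        r <- do.call(segment_field, c(list(fields[[f]]), seg))$records
        if (nrow(r)) cbind(field = f, r) else NULL
      }))
      if (is.null(recs)) {
        recs <- data.frame(field = integer(), on_border = logical(),
                           mean_opp_cytoplasm = numeric())
      }
      rows[[length(rows) + 1L]] <- summarize_well(recs, pid, w, pool = pool)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Analyze a well-summary table through hit calling
#'
#' Tabular entry point: takes per-well readouts (from [generate_screen()]
#' fast mode, from [measure_screen_images()], or read from CSV) plus the
#' plate map, and runs normalization, aggregation, DMSO statistics and hit
#' calling.
#'
#' @param wells well-summary data.frame or CSV path.
#' @param plate_map plate-map data.frame or CSV path.
#' @param thresholds `hit_thresholds`.
#' @param n_plates expected replicates per compound.
#' @param truth optional ground truth carried into the bundle.
#' @param config optional `screen_config` serialized with the outputs.
#' @param output_dir optional output directory.
#' @return `screen_run` bundle, see [run_screen()].
#' @export
analyze_well_table <- function(wells, plate_map,
                               thresholds = hit_thresholds(), n_plates = 3,
                               truth = NULL, config = NULL,
                               output_dir = NULL) {
  if (is.character(wells)) wells <- read.csv(wells, stringsAsFactors = FALSE)
  if (is.character(plate_map)) plate_map <- read.csv(plate_map, stringsAsFactors = FALSE)
  normalized <- normalize_screen(wells, plate_map)
  dmso <- compute_dmso_stats(normalized)
  scores <- aggregate_replicates(normalized, n_plates = n_plates)
  hits <- call_hits(scores, dmso, thresholds)
  qc <- screen_qc(normalized, dmso)
  run <- structure(list(plate_map = plate_map, wells = wells,
                        normalized = normalized, dmso_stats = dmso,
                        scores = scores, hits = hits, qc = qc,
                        truth = truth, config = config),
                   class = "screen_run")
  if (!is.null(output_dir)) write_screen_run(run, output_dir)
  run
}

#' Screen a compound library across plate-triplet batches
#'
#' A library larger than one plate's free wells is screened the way real
#' campaigns run: the compounds are split into consecutive batches, each
#' batch occupying one triplicate set of plates with the shared control
#' layout, and every batch is normalized and hit-called independently
#' before the calls are combined. Batch seeds derive from `seed`.
#'
#' @param compounds data.frame from [planted_compound()].
#' @param seed integer seed.
#' @param thresholds `hit_thresholds`.
#' @param config_args named list of [screen_config()] overrides shared by
#'   all batches.
#' @return list: `hits` (combined hit table with a `batch` column) and
#'   `n_batches`.
#' @export
run_library_screen <- function(compounds, seed = 1,
                               thresholds = hit_thresholds(),
                               config_args = list()) {
  probe <- do.call(screen_config, utils::modifyList(
    config_args, list(compounds = planted_compound(character(0)), seed = 1L)))
  capacity <- probe$plate_rows * probe$plate_cols -
    length(c(probe$dmso_wells, probe$torin_wells, probe$chx_wells))
  idx <- split(seq_len(nrow(compounds)),
               ceiling(seq_len(nrow(compounds)) / capacity))
  hits <- lapply(seq_along(idx), function(b) {
    cfg <- do.call(screen_config, utils::modifyList(config_args, list(
      compounds = compounds[idx[[b]], , drop = FALSE],
      seed = derive_seed(seed, "batch", b))))
    cbind(batch = b, run_screen(cfg, thresholds = thresholds)$hits)
  })
  list(hits = do.call(rbind, hits), n_batches = length(idx))
}

screen_qc <- function(normalized, dmso) {
  ctrl_mean <- function(role) {
    v <- normalized$opp_norm[normalized$role == role]
    if (length(v)) mean(v, na.rm = TRUE) else NA_real_
  }
  list(
    dmso_cv_percent = data.frame(
      plate_id = dmso$per_plate$plate_id,
      cv = 100 * dmso$per_plate$sd / dmso$per_plate$mean),
    chx_opp_norm = ctrl_mean("chx"),
    torin_opp_norm = ctrl_mean("torin"),
    hit_counts = NULL)
}

write_screen_run <- function(run, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write_table(run$plate_map, output_dir, "plate_map")
  write_table(run$wells, output_dir, "well_summaries")
  write_table(run$normalized, output_dir, "normalized_wells")
  write_table(flatten_scores(run$scores), output_dir, "compound_scores")
  write_table(run$hits, output_dir, "hit_calls")
  write_table(run$qc$dmso_cv_percent, output_dir, "qc_dmso_cv")
  if (!is.null(run$config)) {
    jsonlite::write_json(unclass(run$config),
                         file.path(output_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(output_dir)
}

#' @export
print.screen_run <- function(x, ...) {
  counts <- table(factor(x$hits$class, levels = c("up", "down", "null", "excluded")))
  cat("Screen run\n")
  cat(sprintf("  plates: %d   wells: %d   compounds scored: %d\n",
              length(unique(x$wells$plate_id)), nrow(x$wells), nrow(x$scores)))
  cat(sprintf("  hits: %d up, %d down (%d null, %d excluded)\n",
              counts[["up"]], counts[["down"]], counts[["null"]],
              counts[["excluded"]]))
  cat(sprintf("  DMSO CV per plate (%%): %s\n",
              paste(sprintf("%.2f", x$qc$dmso_cv_percent$cv), collapse = ", ")))
  cat(sprintf("  control separation (opp_norm): CHX-like %.3f, Torin-like %.3f\n",
              x$qc$chx_opp_norm, x$qc$torin_opp_norm))
  invisible(x)
}
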