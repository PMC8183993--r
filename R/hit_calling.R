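#' Hit-selection thresholds
#'
#' The four-gate rule of the primary screen: (1) the triplicate-mean
#' normalized OPP signal deviates from the vehicle average by more than
#' `k_sd` standard deviations of the DMSO distribution; (2) viability loss
#' does not exceed `max_toxicity` (nuclei count at least
#' `1 - max_toxicity` of the vehicle mean); (3) the compound is flagged on
#' all replicate plates with a consistent direction; (4) the coefficient of
#' variation across the triplicates is below `max_cv` percent for both the
#' OPP intensity and the nuclei count. All comparisons are strict
#' inequalities.
#'
#' @param k_sd SD multiplier (default 3).
#' @param max_toxicity maximum tolerated viability loss as a fraction
#'   (default 0.30).
#' @param max_cv maximum triplicate CV in percent (default 20).
#' @return `hit_thresholds` list.
#' @export
hit_thresholds <- function(k_sd = 3, max_toxicity = 0.30, max_cv = 20) {
  if (k_sd <= 0 || max_toxicity <= 0 || max_cv <= 0) {
    stop("all thresholds must be strictly positive")
  }
  structure(list(k_sd = k_sd, max_toxicity = max_toxicity, max_cv = max_cv),
            class = "hit_thresholds")
}

#' Vehicle-well statistics per plate
#'
#' Mean and sample SD of the normalized OPP signal of the DMSO wells,
#' per plate and pooled across plates. The per-plate means are 1 by
#' construction of the normalization; the SDs set the hit-calling scale.
#'
#' @param norm_wells output of [normalize_screen()].
#' @return list of class `dmso_stats`: `per_plate` (data.frame `plate_id`,
#'   `mean`, `sd`, `n`) and `pooled` (named vector `mean`, `sd`, `n`).
#' @export
compute_dmso_stats <- function(norm_wells) {
  d <- norm_wells[norm_wells$role == "dmso" & !is.na(norm_wells$opp_norm), ,
                  drop = FALSE]
  per <- do.call(rbind, lapply(split(d, d$plate_id), function(g) {
    if (nrow(g) < 2) stop(sprintf("plate %s: fewer than 2 DMSO wells", g$plate_id[1]))
    data.frame(plate_id = g$plate_id[1], mean = mean(g$opp_norm),
               sd = sd(g$opp_norm), n = nrow(g))
  }))
  rownames(per) <- NULL
  structure(list(per_plate = per,
                 pooled = c(mean = mean(d$opp_norm), sd = sd(d$opp_norm),
                            n = nrow(d))),
            class = "dmso_stats")
}

#' Call hits from triplicate compound scores
#'
#' Applies the four selection criteria (see [hit_thresholds()]) to each
#' complete compound score. The per-plate concordance flag compares each
#' plate's normalized value against that plate's own DMSO mean and SD; the
#' mean-level deviation test uses the DMSO distribution pooled across
#' plates, which is robust to residual plate effects. Classification:
#' `up`/`down` when all four criteria hold; `excluded` for incomplete
#' triplicates (reason `"incomplete_triplicate"`) or viability failure
#' (reason `"toxicity"`); otherwise `null`.
#'
#' @param scores `compound_scores` from [aggregate_replicates()].
#' @param dmso `dmso_stats` from [compute_dmso_stats()].
#' @param thresholds `hit_thresholds`.
#' @return data.frame: `compound_id`, `class`, the four criterion booleans
#'   (`effect_3sd_all_plates`, `viability_ok`, `hit_all_triplicates`,
#'   `cv_ok` — the first is the pooled mean-level test, the third the
#'   per-plate concordance), `direction`, `mean_opp_norm`,
#'   `mean_viability_norm`, `cv_opp`, `cv_viability`, `exclusion_reason`.
#' @export
call_hits <- function(scores, dmso, thresholds = hit_thresholds()) {
  stopifnot(inherits(dmso, "dmso_stats"))
  per <- dmso$per_plate
  rows <- lapply(seq_len(nrow(scores)), function(i) {
    s <- scores[i, ]
    out <- data.frame(
      compound_id = s$compound_id, class = "excluded",
      effect_3sd_all_plates = NA, viability_ok = NA,
      hit_all_triplicates = NA, cv_ok = NA,
      direction = NA_character_,
      mean_opp_norm = s$mean_opp_norm,
      mean_viability_norm = s$mean_viability_norm,
      cv_opp = s$cv_opp, cv_viability = s$cv_viability,
      exclusion_reason = "")
    if (!s$complete) {
      out$exclusion_reason <- "incomplete_triplicate"
      return(out)
    }
    pv <- s$opp_values[[1]]
    pid <- s$plate_ids[[1]]
    st <- per[match(pid, per$plate_id), ]
    dev <- pv - st$mean
    plate_hit <- abs(dev) > thresholds$k_sd * st$sd
    same_sign <- length(unique(sign(dev))) == 1 && all(sign(dev) != 0)
    crit3 <- all(plate_hit) && same_sign
    crit1 <- abs(s$mean_opp_norm - dmso$pooled[["mean"]]) >
      thresholds$k_sd * dmso$pooled[["sd"]]
    crit2 <- (1 - s$mean_viability_norm) <= thresholds$max_toxicity
    crit4 <- !is.na(s$cv_opp) && !is.na(s$cv_viability) &&
      s$cv_opp < thresholds$max_cv && s$cv_viability < thresholds$max_cv
    out$effect_3sd_all_plates <- crit1
    out$viability_ok <- crit2
    out$hit_all_triplicates <- crit3
    out$cv_ok <- crit4
    if (!crit2) {
      out$class <- "excluded"
      out$exclusion_reason <- "toxicity"
    } else if (crit1 && crit3 && crit4) {
      out$class <- if (sign(dev[1]) > 0) "up" else "down"
      out$direction <- out$class
    } else {
      out$class <- "null"
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
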