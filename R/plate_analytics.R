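#' Summarize the cell records of one well
#'
#' Pools the per-cell measurements of all fields of a well into the two
#' screen readouts: the mean cytoplasmic OPP intensity and the nuclei count.
#' Border-touching cells (truncated cytoplasm) are excluded before pooling.
#' By default cells are pooled across fields and weighted equally
#' (`pool = "cells"`); `pool = "fields"` averages per-field means instead.
#' A well with no included cells is flagged `"empty"` and its mean is `NA`,
#' never zero.
#'
#' @param records data.frame of [measure_cells()] rows for every field of
#'   the well, carrying a `field` column for provenance.
#' @param plate_id,well identifiers copied into the summary.
#' @param pool `"cells"` (pool cells across fields) or `"fields"` (mean of
#'   field means).
#' @return one-row data.frame: `plate_id`, `well`, `mean_cyto_opp`,
#'   `nuclei_count`, `n_fields`, `flag`.
#' @export
summarize_well <- function(records, plate_id, well,
                           pool = c("cells", "fields")) {
  pool <- match.arg(pool)
  if (!"field" %in% names(records)) stop("records must carry a field column")
  n_fields <- length(unique(records$field))
  inc <- records[!records$on_border & !is.na(records$mean_opp_cytoplasm), , drop = FALSE]
  n <- nrow(inc)
  m <- if (n == 0) NA_real_ else if (pool == "cells") {
    mean(inc$mean_opp_cytoplasm)
  } else {
    mean(tapply(inc$mean_opp_cytoplasm, inc$field, mean))
  }
  data.frame(plate_id = plate_id, well = well, mean_cyto_opp = m,
             nuclei_count = n, n_fields = n_fields,
             flag = if (n == 0) "empty" else "")
}

usable_wells <- function(wells) {
  wells[wells$nuclei_count > 0 & !is.na(wells$mean_cyto_opp), , drop = FALSE]
}

#' Normalize one plate to its vehicle wells
#'
#' Percent-of-control normalization: each well's mean cytoplasmic OPP and
#' nuclei count are divided by the mean of the plate's DMSO wells, so DMSO
#' wells average exactly 1 per plate by construction and any well-independent
#' multiplicative plate factor cancels. DMSO wells are included in their own
#' reference mean. Wells flagged empty stay `NA`.
#'
#' @param wells well summaries of a single plate.
#' @param plate_map plate map rows (columns `plate_id`, `well`, `role`,
#'   `compound_id`).
#' @return data.frame: `plate_id`, `well`, `role`, `compound_id`,
#'   `opp_norm`, `viability_norm`.
#' @export
normalize_plate <- function(wells, plate_map) {
  pid <- unique(wells$plate_id)
  if (length(pid) != 1) stop("normalize_plate expects a single plate")
  pm <- plate_map[plate_map$plate_id == pid, c("well", "role", "compound_id")]
  x <- merge(wells, pm, by = "well", sort = FALSE)
  ref <- usable_wells(x[x$role == "dmso", , drop = FALSE])
  if (nrow(ref) < 2) {
    stop(sprintf("plate %s: fewer than 2 usable DMSO wells", pid))
  }
  opp_ref <- mean(ref$mean_cyto_opp)
  via_ref <- mean(ref$nuclei_count)
  data.frame(plate_id = pid, well = x$well, role = x$role,
             compound_id = x$compound_id,
             opp_norm = x$mean_cyto_opp / opp_ref,
             viability_norm = x$nuclei_count / via_ref)
}

#' Normalize every plate of a screen
#'
#' Applies [normalize_plate()] per plate and row-binds the results.
#'
#' @param wells well summaries across plates.
#' @param plate_map full plate map.
#' @return data.frame of normalized wells.
#' @export
normalize_screen <- function(wells, plate_map) {
  out <- lapply(split(wells, wells$plate_id), normalize_plate,
                plate_map = plate_map)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate triplicate plates per compound
#'
#' Collapses the normalized per-plate values of each compound into the
#' triplicate mean and the coefficient of variation (100 * sample SD / mean,
#' n - 1 denominator) for both readouts. Compounds present on fewer or more
#' plates than expected, or with missing (empty-well) values, are flagged
#' `complete = FALSE` with reason `"incomplete_triplicate"` and are excluded
#' from hit calling downstream. The result is invariant to plate order.
#'
#' @param norm_wells output of [normalize_screen()].
#' @param n_plates expected replicate count (default 3).
#' @return data.frame of class `compound_scores`: `compound_id`,
#'   `mean_opp_norm`, `mean_viability_norm`, `cv_opp`, `cv_viability`,
#'   `n_plates`, `complete`, `exclusion_reason`, plus list columns
#'   `plate_ids`, `opp_values`, `viability_values` holding the per-plate
#'   values.
#' @export
aggregate_replicates <- function(norm_wells, n_plates = 3) {
  x <- norm_wells[norm_wells$role == "compound" & !is.na(norm_wells$compound_id), ,
                  drop = FALSE]
  x <- x[order(x$plate_id), , drop = FALSE]
  cv <- function(v) if (length(v) < 2 || mean(v) == 0) NA_real_ else
    100 * sd(v) / mean(v)
  rows <- lapply(split(x, x$compound_id), function(g) {
    ok <- nrow(g) == n_plates && !anyNA(g$opp_norm) && !anyNA(g$viability_norm) &&
      !anyDuplicated(g$plate_id)
    data.frame(
      compound_id = g$compound_id[1],
      mean_opp_norm = if (ok) mean(g$opp_norm) else NA_real_,
      mean_viability_norm = if (ok) mean(g$viability_norm) else NA_real_,
      cv_opp = if (ok) cv(g$opp_norm) else NA_real_,
      cv_viability = if (ok) cv(g$viability_norm) else NA_real_,
      n_plates = nrow(g),
      complete = ok,
      exclusion_reason = if (ok) "" else "incomplete_triplicate")
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  g <- split(x, x$compound_id)[res$compound_id]
  res$plate_ids <- lapply(g, `[[`, "plate_id")
  res$opp_values <- lapply(g, `[[`, "opp_norm")
  res$viability_values <- lapply(g, `[[`, "viability_norm")
  class(res) <- c("compound_scores", "data.frame")
  res
}
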