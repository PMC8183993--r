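#' Two-channel imaging field
#'
#' Bundles the nuclei-stain channel and the OPP (nascent-protein) channel of
#' one imaging field as numeric matrices of identical dimension. Pixels are
#' addressed `[row, col]`; ground-truth tables use 0-based `(x, y)` with
#' `x = col - 1`, `y = row - 1`.
#'
#' @param nuclei numeric matrix, nuclear stain intensities (nonnegative).
#' @param opp numeric matrix, OPP click-label intensities, same dimension.
#' @return An object of class `field_image`: a list with elements `nuclei`
#'   and `opp`.
#' @export
field_image <- function(nuclei, opp) {
  nuclei <- as.matrix(nuclei)
  opp <- as.matrix(opp)
  if (!identical(dim(nuclei), dim(opp))) {
    stop("nuclei and opp channels must share dimensions")
  }
  if (!all(is.finite(nuclei)) || !all(is.finite(opp))) {
    stop("channel intensities must be finite")
  }
  structure(list(nuclei = nuclei, opp = opp), class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf("<field_image %d x %d px>\n", nrow(x$nuclei), ncol(x$nuclei)))
  invisible(x)
}

#' Integer label map
#'
#' @param labels integer matrix; 0 is background, objects are labeled with
#'   positive integers.
#' @param kind one of `"nucleus"`, `"cell"`, `"cytoplasm"`.
#' @return A `label_map`: an integer matrix with a `kind` attribute.
#' @export
label_map <- function(labels, kind = c("nucleus", "cell", "cytoplasm")) {
  kind <- match.arg(kind)
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stop("labels must be nonnegative")
  structure(labels, kind = kind, class = c("label_map", class(labels)))
}

map_kind <- function(x) attr(x, "kind")

n_labels <- function(x) {
  u <- unique(as.integer(x))
  length(u[u > 0L])
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map kind=%s %d x %d px, %d objects>\n",
              map_kind(x), nrow(x), ncol(x), n_labels(x)))
  invisible(x)
}

as_int_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  x
}

#' Detect nuclei by thresholding the nuclear stain
#'
#' Light Gaussian smoothing, a global Otsu threshold, 8-connected component
#' labeling, then a size gate: components outside `[min_area, max_area]`
#' pixels are discarded and the survivors renumbered 1..K in scan order.
#' A constant image yields zero nuclei (an empty map, not an error).
#'
#' @param nuclei_channel numeric matrix of nuclear stain intensities.
#' @param min_area,max_area inclusive component-area gate in pixels.
#' @param smooth_sigma Gaussian sigma (pixels) for pre-threshold smoothing;
#'   0 disables smoothing.
#' @return `label_map` of kind `"nucleus"`.
#' @export
segment_nuclei <- function(nuclei_channel, min_area = 40, max_area = 5000,
                           smooth_sigma = 1) {
  x <- as.matrix(nuclei_channel)
  if (!all(is.finite(x))) stop("nuclei channel contains non-finite pixels")
  if (min_area >= max_area) stop("min_area must be below max_area")
  if (diff(range(x)) == 0) {
    return(label_map(matrix(0L, nrow(x), ncol(x)), "nucleus"))
  }
  if (smooth_sigma > 0) {
    sz <- 2L * as.integer(ceiling(3 * smooth_sigma)) + 1L
    brush <- EBImage::makeBrush(sz, shape = "gaussian", sigma = smooth_sigma)
    x <- as.matrix(EBImage::filter2(x, brush, boundary = "replicate"))
  }
  rng <- range(x)
  if (diff(rng) == 0) {
    return(label_map(matrix(0L, nrow(x), ncol(x)), "nucleus"))
  }
  thr <- EBImage::otsu(x, range = rng)
  lab <- cpp_label8(x > thr)
  areas <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- which(areas >= min_area & areas <= max_area)
  remap <- integer(max(lab, 1L))
  remap[keep] <- seq_along(keep)  # preserves scan order
  out <- matrix(0L, nrow(lab), ncol(lab))
  fg <- lab > 0L
  out[fg] <- remap[lab[fg]]
  label_map(out, "nucleus")
}

#' Expand nuclei to whole-cell regions by intensity-guided propagation
#'
#' Each nucleus seeds a region that grows outward over the OPP channel.
#' A step between 4-adjacent pixels p, q costs
#' `sqrt((I(p) - I(q))^2 + lambda_reg)`; every candidate pixel is assigned
#' the label of the seed with minimal cumulative cost (multi-source shortest
#' path), so low `lambda_reg` makes regions hug iso-intensity structure and
#' high `lambda_reg` approaches plain distance-based growth. Expansion stops
#' at `max_distance` steps along the accepted path and never claims pixels at
#' or below `bg_threshold`, which keeps cells off empty plate surface. Seed
#' pixels always retain their own label; ties are broken by
#' (cost, label, scan order) so the partition is deterministic and invariant
#' to seed renumbering.
#'
#' @param nuclei `label_map` of kind `"nucleus"` (or integer matrix).
#' @param opp_channel numeric matrix, same dimension.
#' @param lambda_reg nonnegative regularization added under the square root
#'   of the step cost.
#' @param max_distance maximum number of propagation steps from the nucleus;
#'   0 returns the nuclei unchanged, `Inf` removes the limit.
#' @param bg_threshold background cutoff for expansion; `NULL` (default)
#'   uses an Otsu threshold on the OPP channel clamped below by `bg_floor`.
#' @param bg_floor lower clamp applied to the automatic threshold.
#' @return `label_map` of kind `"cell"`; every cell contains its nucleus and
#'   shares its label.
#' @export
propagate_cells <- function(nuclei, opp_channel, lambda_reg = 0.05,
                            max_distance = 40, bg_threshold = NULL,
                            bg_floor = 0) {
  opp <- as.matrix(opp_channel)
  seeds <- as_int_matrix(nuclei)
  if (!identical(dim(seeds), dim(opp))) stop("dimension mismatch")
  if (!all(is.finite(opp))) stop("opp channel contains non-finite pixels")
  if (lambda_reg < 0) stop("lambda_reg must be nonnegative")
  if (max_distance < 0) stop("max_distance must be nonnegative")
  if (max(seeds) == 0L) {
    return(label_map(matrix(0L, nrow(opp), ncol(opp)), "cell"))
  }
  if (is.null(bg_threshold)) {
    rng <- range(opp)
    bg_threshold <- if (diff(rng) == 0) -Inf else
      max(EBImage::otsu(opp, range = rng), bg_floor)
  }
  out <- cpp_propagate(seeds, opp, lambda_reg, max_distance, bg_threshold)
  label_map(out, "cell")
}

#' Cytoplasm objects: cell minus nucleus
#'
#' Pixelwise set difference: `cytoplasm(p) = cell(p)` where the nucleus map
#' is background, else 0. Labels are preserved. Every cell label must have a
#' matching nucleus label (the propagation contract); a cell without one is
#' an upstream error.
#'
#' @param cells `label_map` of kind `"cell"`.
#' @param nuclei `label_map` of kind `"nucleus"`, same dimension.
#' @return `label_map` of kind `"cytoplasm"`.
#' @export
subtract_nucleus <- function(cells, nuclei) {
  cm <- as_int_matrix(cells)
  nm <- as_int_matrix(nuclei)
  if (!identical(dim(cm), dim(nm))) stop("dimension mismatch")
  orphan <- setdiff(unique(cm[cm > 0L]), unique(nm[nm > 0L]))
  if (length(orphan)) {
    stop("cell labels without a matching nucleus: ",
         paste(sort(orphan), collapse = ", "))
  }
  out <- cm
  out[nm > 0L] <- 0L
  label_map(out, "cytoplasm")
}

mask_stats <- function(lab, values, nbins) {
  idx <- lab > 0L
  l <- lab[idx]
  v <- values[idx]
  area <- tabulate(l, nbins = nbins)
  sums <- numeric(nbins)
  if (length(l)) {
    s <- rowsum(v, group = l)
    sums[as.integer(rownames(s))] <- s[, 1L]
  }
  list(area = area, mean = ifelse(area > 0, sums / area, NA_real_))
}

#' Per-cell intensity measurements
#'
#' Mean OPP intensity over the whole cell, the nucleus, and the cytoplasm
#' mask of every labeled cell, plus the corresponding pixel areas. Cells
#' touching the image border have truncated cytoplasm and are flagged
#' (`on_border = TRUE`) so downstream summaries can exclude them; they are
#' never silently dropped. A cell whose cytoplasm is empty keeps its record
#' with `mean_opp_cytoplasm = NA`.
#'
#' @param field `field_image`.
#' @param nuclei,cells,cytoplasm matching label maps.
#' @return data.frame with one row per cell: `cell_id`, `nucleus_area`,
#'   `cell_area`, `cytoplasm_area`, `mean_opp_total`, `mean_opp_nucleus`,
#'   `mean_opp_cytoplasm`, `on_border`.
#' @export
measure_cells <- function(field, nuclei, cells, cytoplasm) {
  opp <- field$opp
  nm <- as_int_matrix(nuclei)
  cm <- as_int_matrix(cells)
  ym <- as_int_matrix(cytoplasm)
  stopifnot(identical(dim(nm), dim(opp)), identical(dim(cm), dim(opp)),
            identical(dim(ym), dim(opp)))
  K <- max(cm, nm)
  if (K == 0L) {
    return(data.frame(cell_id = integer(), nucleus_area = integer(),
                      cell_area = integer(), cytoplasm_area = integer(),
                      mean_opp_total = numeric(), mean_opp_nucleus = numeric(),
                      mean_opp_cytoplasm = numeric(), on_border = logical()))
  }
  st_cell <- mask_stats(cm, opp, K)
  st_nuc <- mask_stats(nm, opp, K)
  st_cyt <- mask_stats(ym, opp, K)
  border <- unique(c(cm[1, ], cm[nrow(cm), ], cm[, 1], cm[, ncol(cm)]))
  ids <- which(st_cell$area > 0 | st_nuc$area > 0)
  data.frame(
    cell_id = ids,
    nucleus_area = st_nuc$area[ids],
    cell_area = st_cell$area[ids],
    cytoplasm_area = st_cyt$area[ids],
    mean_opp_total = st_cell$mean[ids],
    mean_opp_nucleus = st_nuc$mean[ids],
    mean_opp_cytoplasm = st_cyt$mean[ids],
    on_border = ids %in% border
  )
}

#' Segment and measure one field
#'
#' Convenience wrapper chaining [segment_nuclei()], [propagate_cells()],
#' [subtract_nucleus()] and [measure_cells()] with shared parameters.
#'
#' @param field `field_image`.
#' @param min_area,max_area nucleus size gate (pixels).
#' @param smooth_sigma nuclear-channel smoothing sigma.
#' @param lambda_reg,max_distance,bg_threshold,bg_floor propagation
#'   parameters, see [propagate_cells()].
#' @return list with `nuclei`, `cells`, `cytoplasm` label maps and the
#'   `records` data.frame from [measure_cells()].
#' @export
segment_field <- function(field, min_area = 40, max_area = 5000,
                          smooth_sigma = 1, lambda_reg = 0.05,
                          max_distance = 40, bg_threshold = NULL,
                          bg_floor = 0) {
  nuc <- segment_nuclei(field$nuclei, min_area, max_area, smooth_sigma)
  cells <- propagate_cells(nuc, field$opp, lambda_reg, max_distance,
                           bg_threshold, bg_floor)
  cyt <- subtract_nucleus(cells, nuc)
  list(nuclei = nuc, cells = cells, cytoplasm = cyt,
       records = measure_cells(field, nuc, cells, cyt))
}
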