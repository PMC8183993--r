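#' Well addresses of a plate
#'
#' Row-major addresses `A01..P24` for the default 16 x 24 (384-well) format.
#'
#' @param rows,cols plate dimensions.
#' @return character vector of length `rows * cols`.
#' @export
plate_wells <- function(rows = 16, cols = 24) {
  as.vector(t(outer(LETTERS[seq_len(rows)], seq_len(cols),
                    function(r, c) sprintf("%s%02d", r, c))))
}

#' Describe a planted library compound
#'
#' @param compound_id compound name.
#' @param effect multiplicative factor on the true cytoplasmic OPP intensity
#'   (1 = no effect on translation, < 1 down-regulator, > 1 up-regulator).
#' @param toxicity multiplicative factor on the expected cell count
#'   (1 = none, 0.6 = 40% of cells lost).
#' @param replicate_noise_cv coefficient of variation of the compound's
#'   effect across replicate plates.
#' @return one-row data.frame.
#' @export
planted_compound <- function(compound_id, effect = 1, toxicity = 1,
                             replicate_noise_cv = 0.05) {
  if (length(compound_id) == 0) {
    return(data.frame(compound_id = character(0), effect = numeric(0),
                      toxicity = numeric(0), replicate_noise_cv = numeric(0)))
  }
  if (any(effect <= 0)) stop("effect must be positive")
  if (any(toxicity <= 0 | toxicity > 1)) stop("toxicity must be in (0, 1]")
  if (any(replicate_noise_cv < 0)) stop("replicate_noise_cv must be >= 0")
  data.frame(compound_id = as.character(compound_id), effect = effect,
             toxicity = toxicity, replicate_noise_cv = replicate_noise_cv)
}

#' Configuration of a synthetic OPP screen
#'
#' Defines the layout and statistical structure of a simulated 384-well
#' translation screen: triplicate plates sharing one layout, vehicle (DMSO)
#' wells, Torin-2-like and cycloheximide-like (CHX) control wells, and a
#' compound library with planted effects. Control wells default to the two
#' left-hand columns (column 1 DMSO, column 2 split between Torin-like and
#' CHX-like); compounds fill the remaining wells in row-major order.
#'
#' Per-cell cytoplasmic OPP intensity is
#' `baseline * plate_factor * well_factor * effect * replicate_noise`,
#' with lognormal multiplicative plate and well factors (the level shifts
#' per-plate DMSO normalization must remove) and Gaussian per-cell spread.
#' CHX-like wells get a near-complete block of translation (`chx_effect`),
#' Torin-like wells an intermediate reduction (`torin_effect`), matching the
#' qualitative control ordering a working assay shows.
#'
#' @param compounds data.frame from [planted_compound()] (rbind rows); may be
#'   empty for a controls-only plate.
#' @param n_plates replicate plates sharing the identical layout.
#' @param plate_rows,plate_cols plate format (default 16 x 24 = 384).
#' @param fields_per_well imaging fields acquired per well.
#' @param image_size field side length in pixels (image mode).
#' @param cells_per_well expected cells per well (Poisson mean, summed over
#'   fields).
#' @param dmso_wells,torin_wells,chx_wells well addresses of the control
#'   roles; must be disjoint.
#' @param baseline_opp_mean,baseline_opp_sd per-cell cytoplasmic OPP
#'   intensity baseline (arbitrary 16-bit-scale units).
#' @param nucleus_radius_mean,nucleus_radius_sd nucleus radius in pixels.
#' @param cyto_width cytoplasm annulus width in pixels.
#' @param noise_sd additive Gaussian pixel noise on both channels.
#' @param plate_effect_sd lognormal sdlog of the per-plate intensity factor.
#' @param well_cv lognormal coefficient of variation of the per-well factor.
#' @param torin_effect,chx_effect multiplicative OPP effects of the control
#'   wells.
#' @param nucleus_opp_factor OPP intensity inside the nucleus as a fraction
#'   of the cell's cytoplasmic intensity.
#' @param nuc_fg,nuc_bg,opp_bg rendered foreground/background levels.
#' @param seed integer seed; every random quantity in the screen derives
#'   from it.
#' @return `screen_config` list.
#' @export
screen_config <- function(compounds = planted_compound(character(0)),
                          n_plates = 3, plate_rows = 16, plate_cols = 24,
                          fields_per_well = 4, image_size = 256,
                          cells_per_well = 120,
                          dmso_wells = NULL, torin_wells = NULL,
                          chx_wells = NULL,
                          baseline_opp_mean = 8000, baseline_opp_sd = 1200,
                          nucleus_radius_mean = 7, nucleus_radius_sd = 0.8,
                          cyto_width = 6, noise_sd = 200,
                          plate_effect_sd = 0.1, well_cv = 0.05,
                          torin_effect = 0.5, chx_effect = 0.05,
                          nucleus_opp_factor = 0.5,
                          nuc_fg = 20000, nuc_bg = 300, opp_bg = 400,
                          seed = 1L) {
  wells <- plate_wells(plate_rows, plate_cols)
  if (is.null(dmso_wells)) dmso_wells <- sprintf("%s01", LETTERS[seq_len(plate_rows)])
  if (is.null(torin_wells)) torin_wells <- sprintf("%s02", LETTERS[seq_len(ceiling(plate_rows / 2))])
  if (is.null(chx_wells)) chx_wells <- sprintf("%s02", LETTERS[seq(ceiling(plate_rows / 2) + 1, plate_rows)])
  ctrl <- c(dmso_wells, torin_wells, chx_wells)
  if (anyDuplicated(ctrl)) stop("control well roles overlap")
  if (!all(ctrl %in% wells)) stop("control wells outside the plate")
  n_free <- length(wells) - length(ctrl)
  if (nrow(compounds) > n_free) {
    stop(sprintf("%d compounds exceed the %d free wells", nrow(compounds), n_free))
  }
  if (anyDuplicated(compounds$compound_id)) stop("duplicate compound ids")
  num <- c(n_plates = n_plates, fields_per_well = fields_per_well,
           image_size = image_size, cells_per_well = cells_per_well)
  if (any(num <= 0)) stop("counts must be positive: ",
                          paste(names(num)[num <= 0], collapse = ", "))
  if (length(dmso_wells) < 2) stop("need at least 2 DMSO wells per plate")
  ints <- c(baseline_opp_mean, baseline_opp_sd, noise_sd, nuc_fg, nuc_bg,
            opp_bg, torin_effect, chx_effect, nucleus_opp_factor)
  if (any(ints < 0)) stop("intensity parameters must be nonnegative")
  if (image_size < 8 * nucleus_radius_mean) {
    stop("image_size must be at least 8 * nucleus_radius_mean")
  }
  structure(list(
    compounds = compounds, n_plates = n_plates, plate_rows = plate_rows,
    plate_cols = plate_cols, fields_per_well = fields_per_well,
    image_size = image_size, cells_per_well = cells_per_well,
    dmso_wells = dmso_wells, torin_wells = torin_wells, chx_wells = chx_wells,
    baseline_opp_mean = baseline_opp_mean, baseline_opp_sd = baseline_opp_sd,
    nucleus_radius_mean = nucleus_radius_mean,
    nucleus_radius_sd = nucleus_radius_sd, cyto_width = cyto_width,
    noise_sd = noise_sd, plate_effect_sd = plate_effect_sd, well_cv = well_cv,
    torin_effect = torin_effect, chx_effect = chx_effect,
    nucleus_opp_factor = nucleus_opp_factor, nuc_fg = nuc_fg,
    nuc_bg = nuc_bg, opp_bg = opp_bg, seed = as.integer(seed)
  ), class = "screen_config")
}

build_plate_map <- function(config) {
  wells <- plate_wells(config$plate_rows, config$plate_cols)
  role <- rep("empty", length(wells))
  compound_id <- rep(NA_character_, length(wells))
  dose <- rep(NA_real_, length(wells))
  role[wells %in% config$dmso_wells] <- "dmso"
  role[wells %in% config$torin_wells] <- "torin"
  dose[wells %in% config$torin_wells] <- 0.5
  role[wells %in% config$chx_wells] <- "chx"
  free <- which(role == "empty")
  nc <- nrow(config$compounds)
  if (nc > 0) {
    sel <- free[seq_len(nc)]
    role[sel] <- "compound"
    compound_id[sel] <- config$compounds$compound_id
    dose[sel] <- 10
  }
  keep <- role != "empty"
  one <- data.frame(well = wells[keep], role = role[keep],
                    compound_id = compound_id[keep], dose_uM = dose[keep])
  do.call(rbind, lapply(seq_len(config$n_plates), function(p) {
    cbind(plate_id = sprintf("P%02d", p), one)
  }))
}

effect_class <- function(effect) {
  ifelse(effect > 1, "up", ifelse(effect < 1, "down", "null"))
}

well_truth <- function(config, plate_idx, well_idx, role, compound_row) {
  eff <- switch(role,
    dmso = 1, torin = config$torin_effect, chx = config$chx_effect,
    compound = compound_row$effect)
  tox <- if (identical(role, "compound")) compound_row$toxicity else 1
  rep_cv <- if (identical(role, "compound")) compound_row$replicate_noise_cv else 0
  pf <- with_seed(derive_seed(config$seed, "plate", plate_idx),
                  rlnorm(1, 0, config$plate_effect_sd))
  ws <- derive_seed(config$seed, "well", plate_idx, well_idx)
  wf <- with_seed(ws, {
    w <- rlnorm(1, 0, sqrt(log(1 + config$well_cv^2)))
    rn <- if (rep_cv > 0) max(rnorm(1, 1, rep_cv), 0.05) else 1
    n <- rpois(1, config$cells_per_well * tox)
    c(w, rn, n)
  })
  list(true_mean = config$baseline_opp_mean * pf * wf[1] * eff * wf[2],
       n_cells = as.integer(wf[3]), plate_factor = pf)
}

# Cell-to-cell spread is multiplicative: the per-cell SD scales with the
# well's true mean so a strong down-regulator well has proportionally dim,
# not negative-going, cells. baseline_opp_sd is the SD at the baseline mean.
cell_intensities <- function(config, plate_idx, well_idx, n_cells, true_mean) {
  if (n_cells == 0) return(numeric(0))
  cell_sd <- config$baseline_opp_sd * true_mean / config$baseline_opp_mean
  with_seed(derive_seed(config$seed, "cells", plate_idx, well_idx),
            pmax(rnorm(n_cells, true_mean, cell_sd), 0))
}

#' Generate a synthetic screen
#'
#' Produces the plate map, well-level data and full ground truth for the
#' configured screen. In `"fast"` mode the per-well readouts (mean
#' cytoplasmic OPP over the drawn per-cell intensities, and the cell count)
#' are emitted directly; in `"image"` mode the same per-cell intensities are
#' rendered into two-channel field images via [render_field()], so the two
#' modes share identical ground truth and differ only in whether the readout
#' is measured from pixels. All randomness derives from `config$seed`
#' through per-plate/per-well substreams, so any subset reproduces in
#' isolation and repeated runs are identical.
#'
#' @param config `screen_config`.
#' @param mode `"fast"` (well table) or `"image"` (rendered fields).
#' @return list of class `synthetic_screen`: `plate_map`; `wells` (fast-mode
#'   well summaries, present in both modes as ground-truth reference);
#'   `images` (image mode only: `images[[plate]][[well]]` is a list of
#'   `field_image`); `truth` with `compounds`, `wells` and (image mode)
#'   per-cell geometry; and the `config`.
#' @export
generate_screen <- function(config, mode = c("fast", "image")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "screen_config"))
  plate_map <- build_plate_map(config)
  cmp <- config$compounds
  truth_compounds <- data.frame(
    compound_id = cmp$compound_id,
    class = effect_class(cmp$effect),
    effect = cmp$effect, toxicity = cmp$toxicity)
  one_map <- plate_map[plate_map$plate_id == plate_map$plate_id[1], ]
  wells <- vector("list", config$n_plates)
  truth_wells <- vector("list", config$n_plates)
  images <- if (mode == "image") vector("list", config$n_plates) else NULL
  truth_cells <- list()
  for (p in seq_len(config$n_plates)) {
    pid <- sprintf("P%02d", p)
    n <- nrow(one_map)
    mean_out <- numeric(n); count_out <- integer(n); tm_out <- numeric(n)
    pf_out <- numeric(n)
    plate_imgs <- if (mode == "image") setNames(vector("list", n), one_map$well)
    for (k in seq_len(n)) {
      role <- one_map$role[k]
      crow <- if (identical(role, "compound"))
        cmp[cmp$compound_id == one_map$compound_id[k], ] else NULL
      tr <- well_truth(config, p, k, role, crow)
      iv <- cell_intensities(config, p, k, tr$n_cells, tr$true_mean)
      mean_out[k] <- if (tr$n_cells > 0) mean(iv) else NA_real_
      count_out[k] <- tr$n_cells
      tm_out[k] <- tr$true_mean
      pf_out[k] <- tr$plate_factor
      if (mode == "image") {
        fw <- render_well(config, p, k, iv)
        plate_imgs[[k]] <- fw$fields
        if (nrow(fw$cells)) {
          truth_cells[[length(truth_cells) + 1L]] <-
            cbind(plate_id = pid, well = one_map$well[k], fw$cells)
        }
      }
    }
    wells[[p]] <- data.frame(
      plate_id = pid, well = one_map$well,
      mean_cyto_opp = mean_out, nuclei_count = count_out,
      n_fields = config$fields_per_well, flag = ifelse(count_out == 0, "empty", ""))
    truth_wells[[p]] <- data.frame(
      plate_id = pid, well = one_map$well, role = one_map$role,
      compound_id = one_map$compound_id,
      true_mean_cyto_opp = tm_out, true_n_cells = count_out,
      plate_factor = pf_out)
    if (mode == "image") images[[p]] <- plate_imgs
  }
  if (mode == "image") names(images) <- sprintf("P%02d", seq_len(config$n_plates))
  structure(list(
    plate_map = plate_map,
    wells = do.call(rbind, wells),
    images = images,
    truth = list(
      compounds = truth_compounds,
      wells = do.call(rbind, truth_wells),
      cells = if (length(truth_cells)) do.call(rbind, truth_cells)),
    config = config
  ), class = "synthetic_screen")
}

# Rejection-sample non-overlapping cell positions, assign cells to fields
# round-robin, and render each field. Positions keep the whole cell inside
# the frame so no rendered cell is border-truncated.
render_well <- function(config, plate_idx, well_idx, intensities) {
  n_cells <- length(intensities)
  nf <- config$fields_per_well
  size <- config$image_size
  geom_seed <- derive_seed(config$seed, "geom", plate_idx, well_idx)
  fld <- if (n_cells > 0) rep(seq_len(nf), length.out = n_cells) else integer(0)
  cells <- with_seed(geom_seed, {
    r_nuc <- if (n_cells > 0)
      pmax(rnorm(n_cells, config$nucleus_radius_mean, config$nucleus_radius_sd), 2)
      else numeric(0)
    r_cell <- r_nuc + config$cyto_width
    x <- numeric(n_cells); y <- numeric(n_cells)
    for (f in seq_len(nf)) {
      idx <- which(fld == f)
      if (!length(idx)) next
      placed_x <- numeric(0); placed_y <- numeric(0); placed_r <- numeric(0)
      for (i in idx) {
        margin <- r_cell[i] + 1
        ok <- FALSE
        for (try in seq_len(500)) {
          cx <- runif(1, margin, size - 1 - margin)
          cy <- runif(1, margin, size - 1 - margin)
          if (!length(placed_x) ||
              all((placed_x - cx)^2 + (placed_y - cy)^2 >
                  (placed_r + r_cell[i] + 1)^2)) {
            ok <- TRUE; break
          }
        }
        if (!ok) stop("could not place cells without overlap; ",
                      "reduce cells_per_well or enlarge image_size")
        x[i] <- cx; y[i] <- cy
        placed_x <- c(placed_x, cx); placed_y <- c(placed_y, cy)
        placed_r <- c(placed_r, r_cell[i])
      }
    }
    data.frame(field = fld, cell = seq_len(n_cells), x = x, y = y,
               r_nucleus = r_nuc, r_cell = r_cell,
               opp_cyto = intensities,
               opp_nucleus = config$nucleus_opp_factor * intensities)
  })
  fields <- lapply(seq_len(nf), function(f) {
    render_field(cells[cells$field == f, ], image_size = size,
                 nuc_fg = config$nuc_fg, nuc_bg = config$nuc_bg,
                 opp_bg = config$opp_bg, noise_sd = config$noise_sd,
                 seed = derive_seed(config$seed, "noise", plate_idx, well_idx, f))
  })
  list(fields = fields, cells = cells)
}

#' Render one imaging field
#'
#' Draws each cell as a hard disk nucleus (nuclear channel) plus an annular
#' cytoplasm in the OPP channel at the cell's specified mean intensity, over
#' flat backgrounds, then adds Gaussian pixel noise and clips to the 16-bit
#' range. The fraction of clipped pixels is attached as attribute
#' `clip_fraction`.
#'
#' @param cells data.frame with columns `x`, `y` (0-based centroids),
#'   `r_nucleus`, `r_cell`, `opp_cyto`, `opp_nucleus`; may have zero rows.
#' @param image_size side length in pixels.
#' @param nuc_fg,nuc_bg nuclear channel foreground/background levels.
#' @param opp_bg OPP channel background level.
#' @param noise_sd additive Gaussian noise SD (both channels); 0 disables.
#' @param seed optional seed for the noise draw.
#' @return `field_image` with attribute `clip_fraction`.
#' @export
render_field <- function(cells, image_size, nuc_fg = 20000, nuc_bg = 300,
                         opp_bg = 400, noise_sd = 200, seed = NULL) {
  size <- as.integer(image_size)
  nuc <- matrix(nuc_bg, size, size)
  opp <- matrix(opp_bg, size, size)
  if (nrow(cells) > 0) {
    if (any(cells$x < 0 | cells$x > size - 1 | cells$y < 0 | cells$y > size - 1)) {
      stop("cell centroid outside the image")
    }
    for (i in seq_len(nrow(cells))) {
      cx <- cells$x[i]; cy <- cells$y[i]
      rn <- cells$r_nucleus[i]; rc <- cells$r_cell[i]
      rows <- max(1L, floor(cy - rc)):min(size, ceiling(cy + rc) + 1L)
      cols <- max(1L, floor(cx - rc)):min(size, ceiling(cx + rc) + 1L)
      d2 <- outer((rows - 1) - cy, (cols - 1) - cx,
                  function(a, b) a^2 + b^2)
      in_nuc <- d2 <= rn^2
      in_cyt <- d2 > rn^2 & d2 <= rc^2
      sub_n <- nuc[rows, cols]
      sub_o <- opp[rows, cols]
      sub_n[in_nuc] <- nuc_fg
      sub_o[in_nuc] <- cells$opp_nucleus[i]
      sub_o[in_cyt] <- cells$opp_cyto[i]
      nuc[rows, cols] <- sub_n
      opp[rows, cols] <- sub_o
    }
  }
  add_noise <- function(m) {
    if (noise_sd > 0) m + rnorm(length(m), 0, noise_sd) else m
  }
  if (noise_sd > 0 && !is.null(seed)) {
    ch <- with_seed(seed, list(add_noise(nuc), add_noise(opp)))
  } else {
    ch <- list(add_noise(nuc), add_noise(opp))
  }
  clipped <- sum(ch[[1]] < 0 | ch[[1]] > 65535) + sum(ch[[2]] < 0 | ch[[2]] > 65535)
  fi <- field_image(pmin(pmax(ch[[1]], 0), 65535), pmin(pmax(ch[[2]], 0), 65535))
  attr(fi, "clip_fraction") <- clipped / (2 * length(nuc))
  fi
}
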