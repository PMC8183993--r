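# Independent oracles used across the suite. None of these share code with
# the package implementation paths they check.

# Exhaustive shortest-path labeling oracle for the seeded propagation.
# Builds the full pixel graph (4-adjacency, edge weight sqrt(dI^2 + lambda),
# paths never pass through seed pixels, background-gated) and assigns each
# pixel the label of the seed region at minimal igraph::distances cost,
# ties to the smaller label.
oracle_propagate <- function(seeds, intensity, lambda, bg_threshold = -Inf) {
  nr <- nrow(seeds); nc <- ncol(seeds); n <- nr * nc
  id <- function(i, j) i + (j - 1L) * nr
  labels <- sort(unique(seeds[seeds > 0]))
  allowed <- matrix(intensity > bg_threshold, nr, nc)
  wfun <- function(a, b) sqrt((intensity[a] - intensity[b])^2 + lambda)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  # edges between allowed non-seed pixels
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    p <- id(i, j)
    if (seeds[p] > 0 || !allowed[p]) next
    for (d in list(c(1L, 0L), c(0L, 1L))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii > nr || jj > nc) next
      q <- id(ii, jj)
      if (seeds[q] > 0 || !allowed[q]) next
      from <- c(from, p); to <- c(to, q); w <- c(w, wfun(p, q))
    }
  }
  # one super-source per label, wired to non-seed pixels adjacent to its seeds
  src <- n + seq_along(labels)
  for (k in seq_along(labels)) {
    for (p in which(seeds == labels[k])) {
      i <- (p - 1L) %% nr + 1L; j <- (p - 1L) %/% nr + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        q <- id(ii, jj)
        if (seeds[q] > 0 || !allowed[q]) next
        from <- c(from, src[k]); to <- c(to, q); w <- c(w, wfun(p, q))
      }
    }
  }
  g <- igraph::make_empty_graph(n + length(labels), directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to), weight = w)
  D <- igraph::distances(g, v = src, weights = igraph::E(g)$weight)
  out <- matrix(0L, nr, nc)
  out[seeds > 0] <- seeds[seeds > 0]
  for (p in seq_len(n)) {
    if (seeds[p] > 0 || !allowed[p]) next
    d <- D[, p]
    if (all(!is.finite(d))) next
    out[p] <- labels[which(d == min(d))[1]]  # labels sorted: tie -> smaller
  }
  out
}

# Brute-force Benjamini-Hochberg: sort, p * m / rank, cumulative min from
# the largest rank down.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# Per-pixel accumulation oracle for mean intensity over one label's mask.
oracle_label_mean <- function(labels, values, lab) {
  s <- 0; a <- 0L
  for (p in seq_along(labels)) {
    if (labels[p] == lab) { s <- s + values[p]; a <- a + 1L }
  }
  if (a == 0) NA_real_ else s / a
}

# Render a deterministic test field: cells on a coarse grid, fixed radii.
make_test_field <- function(n_cells = 9, image_size = 128, r_nuc = 6,
                            cyto_width = 5, opp_cyto = 8000,
                            opp_nucleus = 4000, noise_sd = 0, seed = NULL,
                            jitter = 0) {
  side <- ceiling(sqrt(n_cells))
  step <- image_size / (side + 0.35)
  pos <- expand.grid(gx = seq_len(side), gy = seq_len(side))[seq_len(n_cells), ]
  cells <- data.frame(
    x = pos$gx * step - step / 2, y = pos$gy * step - step / 2,
    r_nucleus = r_nuc, r_cell = r_nuc + cyto_width,
    opp_cyto = rep_len(opp_cyto, n_cells),
    opp_nucleus = rep_len(opp_nucleus, n_cells))
  if (jitter > 0 && !is.null(seed)) {
    set.seed(seed)
    cells$x <- cells$x + runif(n_cells, -jitter, jitter)
    cells$y <- cells$y + runif(n_cells, -jitter, jitter)
  }
  list(cells = cells,
       field = render_field(cells, image_size, noise_sd = noise_sd, seed = seed))
}

# True annulus mask of one rendered cell (matrix indices).
true_annulus <- function(cell, image_size) {
  rows <- seq_len(image_size); cols <- seq_len(image_size)
  d2 <- outer((rows - 1) - cell$y, (cols - 1) - cell$x, function(a, b) a^2 + b^2)
  d2 > cell$r_nucleus^2 & d2 <= cell$r_cell^2
}

# Small screen configuration shared by several tests.
tiny_screen_config <- function(..., seed = 42) {
  defaults <- list(
    compounds = rbind(planted_compound("down40", effect = 0.4),
                      planted_compound("up180", effect = 1.8),
                      planted_compound("nullc", effect = 1.0)),
    n_plates = 3, plate_rows = 4, plate_cols = 6,
    dmso_wells = c("A01", "B01", "C01", "D01"),
    torin_wells = c("A02", "B02"), chx_wells = c("C02", "D02"),
    cells_per_well = 120, seed = seed)
  args <- list(...)
  defaults[names(args)] <- args
  do.call(screen_config, defaults)
}
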