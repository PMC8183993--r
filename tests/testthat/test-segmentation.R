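test_that("segment_nuclei finds planted disks and handles degenerate images", {
  # all-zero / constant images: zero nuclei, no error
  expect_equal(n_labels(segment_nuclei(matrix(0, 32, 32))), 0)
  expect_equal(n_labels(segment_nuclei(matrix(7, 32, 32))), 0)
  expect_error(segment_nuclei(matrix(c(NA, 1:15), 4, 4)), "finite")
  expect_error(segment_nuclei(matrix(1, 8, 8), min_area = 10, max_area = 5))

  # 5 disjoint planted disks: K = 5, centroids within 1 px
  tf <- make_test_field(n_cells = 5, image_size = 96, r_nuc = 6)
  nuc <- segment_nuclei(tf$field$nuclei, min_area = 30, max_area = 400)
  expect_equal(n_labels(nuc), 5)
  for (k in seq_len(5)) {
    px <- which(unclass(nuc) == k, arr.ind = TRUE)
    cx <- mean(px[, 2]) - 1; cy <- mean(px[, 1]) - 1
    i <- which.min((tf$cells$x - cx)^2 + (tf$cells$y - cy)^2)
    expect_lt(sqrt((tf$cells$x[i] - cx)^2 + (tf$cells$y[i] - cy)^2), 1)
  }

  # size gate discards a too-small and a too-large component
  img <- matrix(0, 64, 64)
  img[10:12, 10:12] <- 100          # 9 px, below gate
  img[30:45, 30:45] <- 100          # 256 px, above gate
  img[50:55, 50:55] <- 100          # 36 px, kept
  nuc <- segment_nuclei(img, min_area = 20, max_area = 100, smooth_sigma = 0)
  expect_equal(n_labels(nuc), 1)
  expect_equal(sum(unclass(nuc) > 0), 36)
})

test_that("above-threshold bridge merges two disks into one component", {
  img <- matrix(0, 48, 48)
  img[10:20, 8:18] <- 100
  img[10:20, 30:40] <- 100
  img[15, 19:29] <- 100  # bridge
  nuc <- segment_nuclei(img, min_area = 10, max_area = 2000, smooth_sigma = 0)
  expect_equal(n_labels(nuc), 1)
  # same threshold, brute-force components via igraph on the binary mask
  mask <- img > EBImage::otsu(img, range = range(img))
  idx <- which(mask)
  nr <- nrow(img)
  adj <- list()
  for (p in idx) {
    i <- (p - 1) %% nr + 1; j <- (p - 1) %/% nr + 1
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > ncol(img)) next
      q <- ii + (jj - 1) * nr
      if (mask[q] && q > p) adj[[length(adj) + 1]] <- c(p, q)
    }
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, adj), directed = FALSE)
  expect_equal(igraph::count_components(
    igraph::induced_subgraph(g, idx)), 1)
})

test_that("propagation matches the exhaustive shortest-path oracle", {
  # uniform intensity, two seeds: boundary on the equidistant line
  opp <- matrix(1, 9, 9)
  seeds <- matrix(0L, 9, 9); seeds[5, 2] <- 1L; seeds[5, 8] <- 2L
  cells <- propagate_cells(seeds, opp, lambda_reg = 0.05, max_distance = Inf,
                           bg_threshold = -Inf)
  expect_true(all(unclass(cells)[, 1:4] == 1L))
  expect_true(all(unclass(cells)[, 6:9] == 2L))

  # max_distance = 0 leaves the nuclei untouched
  expect_equal(unclass(propagate_cells(seeds, opp, max_distance = 0,
                                       bg_threshold = -Inf))[, ],
               seeds[, ])

  # no seeds -> empty map; negative lambda -> error
  expect_equal(n_labels(propagate_cells(matrix(0L, 5, 5), matrix(1, 5, 5))), 0)
  expect_error(propagate_cells(seeds, opp, lambda_reg = -1), "lambda")

  # high-contrast ridge between two seeds, against the oracle
  set.seed(101)
  opp <- matrix(1, 9, 9); opp[, 5] <- 50
  seeds <- matrix(0L, 9, 9); seeds[3, 2] <- 1L; seeds[7, 8] <- 2L
  got <- propagate_cells(seeds, opp, lambda_reg = 0.05, max_distance = Inf,
                         bg_threshold = -Inf)
  expect_equal(unclass(got)[, ], oracle_propagate(seeds, opp, 0.05)[, ])

  # random instances, random sizes up to 9x9, exact oracle agreement
  for (case in 1:40) {
    set.seed(case)
    nr <- sample(4:9, 1); nc <- sample(4:9, 1)
    opp <- matrix(runif(nr * nc, 0, 10), nr, nc)
    seeds <- matrix(0L, nr, nc)
    ns <- sample(1:3, 1)
    pos <- sample(nr * nc, ns)
    seeds[pos] <- seq_len(ns)
    lam <- sample(c(0.01, 0.05, 1), 1)
    bg <- sample(c(-Inf, 2), 1)
    got <- propagate_cells(seeds, opp, lambda_reg = lam, max_distance = Inf,
                           bg_threshold = bg)
    expect_equal(unclass(got)[, ], oracle_propagate(seeds, opp, lam, bg)[, ],
                 info = sprintf("case %d", case))
  }
})

test_that("propagation partition is invariant to seed renumbering", {
  set.seed(77)
  for (case in 1:10) {
    nr <- 8; nc <- 8
    opp <- matrix(runif(nr * nc, 0, 5), nr, nc)
    seeds <- matrix(0L, nr, nc)
    pos <- sample(nr * nc, 3)
    seeds[pos] <- 1:3
    perm <- sample(3)
    seeds_perm <- matrix(0L, nr, nc)
    seeds_perm[pos] <- perm
    a <- unclass(propagate_cells(seeds, opp, 0.05, Inf, bg_threshold = -Inf))
    b <- unclass(propagate_cells(seeds_perm, opp, 0.05, Inf, bg_threshold = -Inf))
    relabeled <- b
    relabeled[b > 0] <- match(b[b > 0], perm)
    expect_equal(a[, ], relabeled[, ])
  }
})

test_that("subtract_nucleus is the pixelwise set difference", {
  # cells identical to nuclei -> empty cytoplasm
  m <- matrix(0L, 6, 6); m[2:4, 2:4] <- 1L
  expect_equal(n_labels(subtract_nucleus(m, m)), 0)

  # disk nucleus inside annulus-extended cell: areas add up
  tf <- make_test_field(n_cells = 1, image_size = 48)
  seg <- segment_field(tf$field, min_area = 10, max_area = 2000)
  expect_equal(seg$records$cell_area,
               seg$records$nucleus_area + seg$records$cytoplasm_area)

  # orphan cell label -> contract violation
  cells <- matrix(0L, 4, 4); cells[1:2, 1:2] <- 5L
  nuc <- matrix(0L, 4, 4); nuc[4, 4] <- 1L
  expect_error(subtract_nucleus(cells, nuc), "matching nucleus")

  # random label maps against a naive masking oracle
  set.seed(5)
  for (case in 1:10) {
    nuc <- matrix(sample(0:3, 36, replace = TRUE), 6, 6)
    cells <- nuc
    cells[cells == 0L] <- sample(0:3, sum(cells == 0L), replace = TRUE)
    cyt <- subtract_nucleus(cells, nuc)
    naive <- matrix(0L, 6, 6)
    for (p in 1:36) naive[p] <- if (nuc[p] == 0L) cells[p] else 0L
    expect_equal(unclass(cyt)[, ], naive[, ])
  }
})

test_that("measure_cells reports exact means on planted two-level cells", {
  tf <- make_test_field(n_cells = 4, image_size = 96, opp_cyto = 9000,
                        opp_nucleus = 3000)
  seg <- segment_field(tf$field, min_area = 10, max_area = 2000)
  expect_equal(nrow(seg$records), 4)
  expect_equal(seg$records$mean_opp_cytoplasm, rep(9000, 4))
  expect_equal(seg$records$mean_opp_nucleus, rep(3000, 4))

  # constant OPP image: all three means equal the constant
  fld <- field_image(tf$field$nuclei, matrix(1234, 96, 96))
  nuc <- segment_nuclei(fld$nuclei, 10, 2000)
  cells <- propagate_cells(nuc, fld$opp, max_distance = 5, bg_threshold = -Inf)
  cyt <- subtract_nucleus(cells, nuc)
  rec <- measure_cells(fld, nuc, cells, cyt)
  expect_equal(rec$mean_opp_total, rep(1234, 4))
  expect_equal(rec$mean_opp_cytoplasm, rep(1234, 4))
})

test_that("weighted-mean identity holds on random noisy fields", {
  for (case in 1:5) {
    tf <- make_test_field(n_cells = 6, image_size = 96, noise_sd = 300,
                          seed = case, jitter = 3)
    seg <- segment_field(tf$field, min_area = 10, max_area = 2000)
    rec <- seg$records
    expect_gt(nrow(rec), 0)
    expect_equal(rec$cell_area, rec$nucleus_area + rec$cytoplasm_area)
    lhs <- rec$mean_opp_total * rec$cell_area
    rhs <- rec$mean_opp_nucleus * rec$nucleus_area +
      ifelse(rec$cytoplasm_area > 0, rec$mean_opp_cytoplasm * rec$cytoplasm_area, 0)
    expect_equal(lhs, rhs, tolerance = 1e-6)
    # spot-check one label against the per-pixel accumulation oracle
    lab <- rec$cell_id[1]
    expect_equal(rec$mean_opp_total[1],
                 oracle_label_mean(unclass(seg$cells), tf$field$opp, lab),
                 tolerance = 1e-12)
  }
})

test_that("scaling the OPP channel scales means and preserves labels", {
  tf <- make_test_field(n_cells = 4, image_size = 80, noise_sd = 100, seed = 9)
  c1 <- 1; c2 <- 3.7
  run <- function(cc) {
    fld <- field_image(tf$field$nuclei, tf$field$opp * cc)
    nuc <- segment_nuclei(fld$nuclei, 10, 2000)
    # thresholds scaled with the channel: lambda by c^2, background by c
    cells <- propagate_cells(nuc, fld$opp, lambda_reg = 0.05 * cc^2,
                             max_distance = 20,
                             bg_threshold = 1000 * cc)
    cyt <- subtract_nucleus(cells, nuc)
    list(cells = cells, rec = measure_cells(fld, nuc, cells, cyt))
  }
  a <- run(c1); b <- run(c2)
  expect_equal(unclass(a$cells)[, ], unclass(b$cells)[, ])
  expect_equal(b$rec$mean_opp_cytoplasm, a$rec$mean_opp_cytoplasm * c2,
               tolerance = 1e-12)
  expect_equal(b$rec$mean_opp_total, a$rec$mean_opp_total * c2,
               tolerance = 1e-12)
})

test_that("border-touching cells are flagged, not dropped", {
  cells <- data.frame(x = c(2, 40), y = c(40, 40), r_nucleus = 6,
                      r_cell = 11, opp_cyto = 8000, opp_nucleus = 4000)
  fld <- render_field(cells, 80, noise_sd = 0)
  seg <- segment_field(fld, min_area = 10, max_area = 2000)
  expect_equal(nrow(seg$records), 2)
  expect_equal(sum(seg$records$on_border), 1)
})
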