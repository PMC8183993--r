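test_that("screen configuration validates layout and parameters", {
  expect_error(screen_config(dmso_wells = c("A01", "B01"),
                             torin_wells = "A01"), "overlap")
  expect_error(screen_config(dmso_wells = c("Z99", "A01")), "outside")
  expect_error(screen_config(n_plates = 0), "positive")
  expect_error(screen_config(cells_per_well = -5), "positive")
  expect_error(screen_config(baseline_opp_mean = -1), "nonnegative")
  expect_error(screen_config(image_size = 20, nucleus_radius_mean = 7),
               "8 \\* nucleus_radius_mean")
  expect_error(planted_compound("x", effect = 0), "positive")
  expect_error(planted_compound("x", toxicity = 1.2), "toxicity")
  # too many compounds for the free wells
  expect_error(screen_config(
    compounds = planted_compound(sprintf("c%03d", 1:400)),
    plate_rows = 4, plate_cols = 6,
    dmso_wells = c("A01", "B01"), torin_wells = "C01", chx_wells = "D01"),
    "free wells")
})

test_that("ground-truth classes follow the planted effects", {
  cfg <- tiny_screen_config(compounds = rbind(
    planted_compound("a", effect = 1.0), planted_compound("b", effect = 0.4),
    planted_compound("c", effect = 2.0)))
  s <- generate_screen(cfg)
  expect_equal(s$truth$compounds$class, c("null", "down", "up"))
  # all-null config
  cfg0 <- tiny_screen_config(compounds = planted_compound(sprintf("n%d", 1:5)))
  expect_true(all(generate_screen(cfg0)$truth$compounds$class == "null"))
  # every well has exactly one role
  pm <- s$plate_map[s$plate_map$plate_id == "P01", ]
  expect_false(anyDuplicated(pm$well) > 0)
  # replicate plates share the layout
  pm2 <- s$plate_map[s$plate_map$plate_id == "P02", ]
  expect_equal(pm$well, pm2$well)
  expect_equal(pm$compound_id, pm2$compound_id)
})

test_that("generation is deterministic and hierarchically reproducible", {
  cfg <- tiny_screen_config(seed = 123)
  a <- generate_screen(cfg)
  b <- generate_screen(cfg)
  expect_identical(a$wells, b$wells)
  expect_identical(a$plate_map, b$plate_map)
  expect_identical(a$truth$wells, b$truth$wells)
  # different seed changes the draw
  c2 <- generate_screen(tiny_screen_config(seed = 124))
  expect_false(identical(a$wells$mean_cyto_opp, c2$wells$mean_cyto_opp))
  # image mode reproduces byte-identically too
  cfg_img <- tiny_screen_config(plate_rows = 2, plate_cols = 2,
                                dmso_wells = c("A01", "B01"),
                                torin_wells = "A02", chx_wells = "B02",
                                compounds = planted_compound(character(0)),
                                n_plates = 1, fields_per_well = 1,
                                image_size = 192, cells_per_well = 8)
  i1 <- generate_screen(cfg_img, mode = "image")
  i2 <- generate_screen(cfg_img, mode = "image")
  expect_identical(i1$images, i2$images)
})

test_that("control wells show the expected effect ordering", {
  cfg <- tiny_screen_config(seed = 3)
  s <- generate_screen(cfg)
  x <- merge(s$wells, s$plate_map, by = c("plate_id", "well"))
  m <- tapply(x$mean_cyto_opp, x$role, mean)
  # CHX-like near-zero, Torin-like intermediate, DMSO full signal
  expect_lt(m[["chx"]], 0.15 * m[["dmso"]])
  expect_gt(m[["torin"]], 0.3 * m[["dmso"]])
  expect_lt(m[["torin"]], 0.7 * m[["dmso"]])
})

test_that("render_field honors its contract", {
  # zero cells: both channels pure noise around background
  f0 <- render_field(data.frame(x = numeric(), y = numeric(),
                                r_nucleus = numeric(), r_cell = numeric(),
                                opp_cyto = numeric(), opp_nucleus = numeric()),
                     64, noise_sd = 50, seed = 1)
  expect_equal(mean(f0$nuclei), 300, tolerance = 0.05)
  expect_equal(mean(f0$opp), 400, tolerance = 0.05)

  # centroid outside the image errors
  expect_error(render_field(data.frame(x = 99, y = 5, r_nucleus = 4,
                                       r_cell = 8, opp_cyto = 100,
                                       opp_nucleus = 50), 64),
               "outside")

  # one cell, zero noise: mean over the true annulus is exact
  cell <- data.frame(x = 30, y = 30, r_nucleus = 6, r_cell = 11,
                     opp_cyto = 7777, opp_nucleus = 3000)
  f1 <- render_field(cell, 64, noise_sd = 0)
  ann <- true_annulus(cell, 64)
  expect_equal(mean(f1$opp[ann]), 7777)
  expect_equal(attr(f1, "clip_fraction"), 0)

  # 20 noisy cells: per-cell means within 3 * noise_sd / sqrt(area)
  tf <- make_test_field(n_cells = 20, image_size = 196, noise_sd = 250,
                        seed = 8)
  for (i in seq_len(20)) {
    ann <- true_annulus(tf$cells[i, ], 196)
    se <- 250 / sqrt(sum(ann))
    expect_lt(abs(mean(tf$field$opp[ann]) - tf$cells$opp_cyto[i]), 3 * se)
  }

  # clipping is reported
  bright <- data.frame(x = 30, y = 30, r_nucleus = 6, r_cell = 11,
                       opp_cyto = 65535, opp_nucleus = 60000)
  fb <- render_field(bright, 64, noise_sd = 500, seed = 2)
  expect_gt(attr(fb, "clip_fraction"), 0)
  expect_true(all(fb$opp <= 65535 & fb$opp >= 0))
})

test_that("fast mode and image mode agree at zero pixel noise", {
  cfg <- screen_config(
    compounds = planted_compound(sprintf("c%02d", 1:8),
                                 effect = c(0.4, 0.7, 1, 1, 1.3, 1.6, 1, 0.9)),
    n_plates = 1, plate_rows = 3, plate_cols = 4,
    dmso_wells = c("A01", "B01", "C01"), torin_wells = "A02",
    chx_wells = character(0),
    fields_per_well = 2, image_size = 192, cells_per_well = 24,
    noise_sd = 0, seed = 21)
  s <- generate_screen(cfg, mode = "image")
  measured <- measure_screen_images(s)
  m <- merge(measured, s$wells, by = c("plate_id", "well"),
             suffixes = c("_img", "_fast"))
  expect_gte(nrow(m), 10)
  ok <- !is.na(m$mean_cyto_opp_fast)
  rel <- abs(m$mean_cyto_opp_img[ok] / m$mean_cyto_opp_fast[ok] - 1)
  expect_true(all(rel < 0.05))
  expect_equal(m$nuclei_count_img, m$nuclei_count_fast)
})

test_that("empirical DMSO well CV matches the configured noise model", {
  # many vehicle wells on one plate; per-well lognormal factor dominates
  cfg <- screen_config(compounds = planted_compound(character(0)),
                       n_plates = 1, plate_rows = 8, plate_cols = 12,
                       dmso_wells = plate_wells(8, 12)[1:90],
                       torin_wells = "H11", chx_wells = "H12",
                       cells_per_well = 400, well_cv = 0.05, seed = 31)
  s <- generate_screen(cfg)
  v <- s$wells$mean_cyto_opp[1:90]
  # expected CV: well factor plus cell-sampling term
  expected <- sqrt(0.05^2 + (1200 / 8000)^2 / 400)
  cvs <- replicate(500, {
    b <- sample(v, replace = TRUE)
    sd(b) / mean(b)
  })
  ci <- quantile(cvs, c(0.005, 0.995))
  expect_gt(expected, ci[1])
  expect_lt(expected, ci[2])
})

test_that("proteomics generator plants the stated structure", {
  expect_error(generate_proteomics(10, 20, 1, 0.1, seed = 1), "exceed")
  expect_error(generate_proteomics(10, 2, 1, 0, seed = 1), "positive")

  g <- generate_proteomics(100, 10, 0.8, 0.2, seed = 5)
  expect_identical(g$quant, generate_proteomics(100, 10, 0.8, 0.2, seed = 5)$quant)
  expect_equal(sum(g$truth$regulated), 10)
  expect_equal(sum(g$truth$direction == "up"), 5)

  # limit case: effect on the fold-change boundary, vanishing spread
  gb <- generate_proteomics(50, 10, 0.3, 1e-9, seed = 2)
  d <- differential_proteins(gb$quant, lfc_thr = 0.3)
  lfc <- abs(d$log2fc[gb$truth$regulated])
  expect_equal(lfc, rep(0.3, 10), tolerance = 1e-6)

  # global null: type-I error near nominal (single-seed smoke version;
  # the multi-seed check lives in the acceptance suite)
  g0 <- generate_proteomics(2000, 0, 0, 0.2, seed = 7)
  d0 <- differential_proteins(g0$quant)
  expect_gt(mean(d0$p_value < 0.05), 0.03)
  expect_lt(mean(d0$p_value < 0.05), 0.07)
})
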