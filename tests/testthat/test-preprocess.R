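test_that("reflectance calibration has the panel fixed point and gain invariance", {
  B <- 5
  raw <- array(0.5, c(4, 4, B))
  panel <- matrix(FALSE, 4, 4); panel[1:2, 1:2] <- TRUE
  out <- calibrate_reflectance(raw, panel, 0.5)
  expect_equal(out, array(0.5, c(4, 4, B)))

  set.seed(2)
  raw <- array(runif(4 * 4 * B, 0.1, 1), c(4, 4, B))
  a <- calibrate_reflectance(raw, panel, 0.4)
  b <- calibrate_reflectance(raw * 2, panel, 0.4)
  expect_equal(a, b)
})

test_that("calibration inverts a planted per-band gain to 1e-6", {
  B <- 8
  truth <- array(runif(6 * 6 * B, 0, 0.6), c(6, 6, B))
  panel <- matrix(FALSE, 6, 6); panel[1:2, 5:6] <- TRUE
  pr <- runif(B, 0.3, 0.6)
  for (b in seq_len(B)) truth[, , b][panel] <- pr[b]
  gains <- runif(B, 0.5, 3)
  raw <- truth
  for (b in seq_len(B)) raw[, , b] <- truth[, , b] * gains[b]
  rec <- calibrate_reflectance(raw, panel, pr)
  expect_lt(max(abs(rec - truth)), 1e-6)

  raw[, , 3] <- 0
  expect_error(calibrate_reflectance(raw, panel, pr), "band 3")
})

test_that("tiling follows floor arithmetic, identity, and errors on small scenes", {
  fake <- list(rgb = array(0L, c(636, 1590, 3)),
               mask = matrix(0L, 636, 1590))
  ts <- tile_scene(fake, 318)
  expect_length(ts$tiles, 10)          # 2 x 5

  one <- list(rgb = array(7L, c(318, 318, 3)), mask = matrix(1L, 318, 318))
  t1 <- tile_scene(one, 318)
  expect_length(t1$tiles, 1)
  expect_identical(t1$tiles[[1]]$mask, one$mask)
  expect_identical(t1$tiles[[1]]$rgb, one$rgb)

  expect_error(tile_scene(list(mask = matrix(0L, 100, 400)), 318), "smaller")
})

test_that("tiling then stitching by provenance reconstructs the cropped region", {
  sc <- render_scene(scene_config(height_px = 192, width_px = 288, seed = 4),
                     lib176, include_cube = FALSE)
  ts <- tile_scene(sc, 96)
  expect_length(ts$tiles, 2 * 3)
  back <- stitch_tiles(ts, "mask")
  expect_identical(back, sc$mask[1:192, 1:288])
  back_rgb <- stitch_tiles(ts, "rgb")
  expect_identical(back_rgb[, , 2], sc$rgb[1:192, 1:288, 2])
})

test_that("the seeded split is sized by floor, disjoint, and exhaustive", {
  fake <- list(rgb = array(0L, c(96, 96, 3)), mask = matrix(0L, 96, 96))
  sets <- lapply(1:10, function(i) tile_scene(fake, 96, scene_id = paste0("s", i)))
  ts <- combine_tilesets(sets)
  sp <- split_tiles(ts, 0.7, seed = 1)
  expect_length(sp$train$tiles, 7)
  expect_length(sp$val$tiles, 3)
  ids <- function(x) sort(vapply(x$tiles, `[[`, character(1), "scene_id"))
  expect_identical(sort(c(ids(sp$train), ids(sp$val))), ids(ts))

  sp2 <- split_tiles(ts, 0.7, seed = 2)
  expect_length(sp2$train$tiles, 7)
  expect_false(identical(ids(sp$train), ids(sp2$train)))
  expect_error(split_tiles(structure(list(tiles = list(), tile_size = 96L),
                                     class = "tile_set"), 0.7, 1), "empty")
})

test_that("vegetation indices match their closed forms and a per-pixel oracle", {
  nir <- matrix(0.5, 1, 1); red <- matrix(0.1, 1, 1)
  expect_equal(compute_index(nir, red, "NDVI")$values[1, 1], 0.4 / 0.6)
  expect_equal(compute_index(nir, nir, "NDVI")$values[1, 1], 0)
  expect_equal(compute_index(nir, nir, "SAVI", list(L = 0.25))$values[1, 1], 0)
  expect_equal(compute_index(nir, red, "RVI")$values[1, 1], 5)
  expect_equal(compute_index(nir, red, "SAVI")$params$L, 0.5)

  set.seed(6)
  a <- matrix(runif(256, 0.05, 0.9), 16)
  b <- matrix(runif(256, 0.05, 0.9), 16)
  ndvi <- compute_index(a, b, "NDVI")$values
  for (i in sample(256, 20)) {
    expect_equal(ndvi[i], (a[i] - b[i]) / (a[i] + b[i]))
  }
  expect_true(all(abs(ndvi) <= 1))

  # scale invariance of the ratio-based indices
  expect_equal(compute_index(3 * a, 3 * b, "NDVI")$values, ndvi)
  expect_equal(compute_index(3 * a, 3 * b, "RVI")$values,
               compute_index(a, b, "RVI")$values)

  # zero denominators are flagged, shapes enforced
  z <- matrix(0, 2, 2)
  expect_true(all(is.nan(compute_index(z, z, "NDVI")$values)))
  expect_error(compute_index(a, b[1:8, ], "NDVI"), "shape")
})

test_that("narrowband NDVI resolves wavelengths and degenerates correctly", {
  sc <- render_scene(scene_config(seed = 3), lib176)
  nb <- narrowband_ndvi(sc$cube, sc$wavelengths_nm, 960, 719)
  expect_lt(abs(nb$params$resolved_a - 960), 1.8)
  expect_lt(abs(nb$params$resolved_b - 719), 1.8)
  expect_true(all(abs(nb$values) <= 1, na.rm = TRUE))

  same <- narrowband_ndvi(sc$cube, sc$wavelengths_nm, 800, 800)
  expect_true(all(same$values == 0))

  flat <- array(0.4, c(4, 4, 176))
  expect_true(all(narrowband_ndvi(flat, sc$wavelengths_nm, 960, 719)$values == 0))
  expect_error(narrowband_ndvi(sc$cube, sc$wavelengths_nm, 1200, 719),
               "outside")
})

test_that("ENVI cubes and mask PNGs round-trip through disk", {
  tmp <- withr::local_tempdir()
  cube <- array(runif(6 * 5 * 12, 0, 1), c(6, 5, 12))
  wl <- seq(400, 1000, length.out = 12)
  write_envi_cube(cube, wl, file.path(tmp, "cube"))
  back <- read_envi_cube(file.path(tmp, "cube"))
  expect_equal(back$wavelengths_nm, wl, tolerance = 1e-4)
  expect_equal(back$cube, cube, tolerance = 1e-6)   # float32 storage

  mask <- matrix(sample(0:2, 64, replace = TRUE), 8)
  write_mask_png(mask, file.path(tmp, "mask.png"))
  expect_identical(read_mask_png(file.path(tmp, "mask.png")), mask)
})
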