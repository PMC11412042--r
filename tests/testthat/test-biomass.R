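test_that("canopy cover counts pixels over the full denominator", {
  expect_equal(canopy_cover(matrix(2L, 5, 5), 2L), 1)
  expect_equal(canopy_cover(matrix(c(0L, 1L), 5, 4), 2L), 0)
  set.seed(2)
  mask <- matrix(sample(0:2, 100, replace = TRUE), 10)
  expect_equal(canopy_cover(mask, 2L), sum(mask == 2) / 100)
  expect_equal(canopy_cover(mask, 0L), sum(mask == 0) / 100)
  expect_error(canopy_cover(matrix(integer(0), 0, 0)), "empty")
})

test_that("mask mean spectra equal the per-band mean oracle", {
  cube <- array(0.3, c(4, 4, 6))
  mask <- matrix(0L, 4, 4); mask[1, 1] <- 2L
  expect_equal(mask_mean_spectrum(cube, mask, 2L), rep(0.3, 6))

  set.seed(4)
  cube <- array(runif(4 * 4 * 6), c(4, 4, 6))
  mask <- matrix(sample(0:2, 16, replace = TRUE), 4)
  sel <- which(mask == 1L)
  oracle <- vapply(1:6, function(b) mean(cube[, , b][sel]), numeric(1))
  expect_equal(mask_mean_spectrum(cube, mask, 1L), oracle)

  # single-pixel class returns that pixel's spectrum
  mask2 <- matrix(0L, 4, 4); mask2[2, 3] <- 2L
  expect_equal(mask_mean_spectrum(cube, mask2, 2L), cube[2, 3, ])
  expect_error(mask_mean_spectrum(cube, matrix(0L, 4, 4), 2L), "no pixels")
})

test_that("a planted perfectly linear pair is recovered with r = 1", {
  wl <- lib176$wavelengths_nm
  ia <- nearest_band(lib176, 960); ib <- nearest_band(lib176, 719)
  bio <- seq(10, 400, length.out = 20)
  spec <- matrix(0.4, 20, length(wl))
  spec[, ia] <- 0.4 * (1 + 0.2 * bio / 400)
  spec[, ib] <- 0.4 * (1 - 0.2 * bio / 400)
  sw <- band_pair_sweep(spec, bio, wl)
  expect_equal(unname(sw$best_pair), c(wl[ia], wl[ib]))
  expect_equal(abs(sw$best_r), 1, tolerance = 1e-9)
})

test_that("independent biomass yields no strong pair (null behaviour)", {
  set.seed(10)
  n <- 100
  spec <- matrix(runif(n * 40, 0.2, 0.6), n, 40)
  bio <- runif(n, 0, 100)
  sw <- band_pair_sweep(spec, bio, seq(400, 1000, length.out = 40))
  expect_lt(abs(sw$best_r), 0.55)
})

test_that("the sweep is invariant to positive affine rescaling of biomass", {
  set.seed(11)
  bio <- runif(30, 0, 400)
  spec <- simulate_mean_spectra(lib176, "weed", "wintering", bio, bmax = 400,
                                seed = 11)
  s1 <- band_pair_sweep(spec, bio, lib176$wavelengths_nm)
  s2 <- band_pair_sweep(spec, 3.5 * bio + 100, lib176$wavelengths_nm)
  expect_equal(s1$corr, s2$corr)
  expect_equal(s1$best_pair, s2$best_pair)
})

test_that("sweep preconditions are enforced and degenerate pairs flagged", {
  wl <- seq(400, 1000, length.out = 25)
  spec <- matrix(0.4, 5, 25)
  expect_error(band_pair_sweep(spec[1:2, ], 1:2, wl), "3 samples")
  expect_error(band_pair_sweep(spec, rep(1, 5), wl), "variance")
  # fully constant spectra: every pair degenerate
  expect_error(band_pair_sweep(spec, 1:5, wl), "degenerate")
  expect_true(is.na(band_pair_sweep(cbind(spec[, 1:24],
                                          seq(0.1, 0.5, length.out = 5)),
                                    1:5, wl)$corr[1, 2]))
})

test_that("a noise-free linear target is recovered almost exactly by the SVR", {
  set.seed(12)
  n <- 60
  X <- data.frame(a = runif(n), b = runif(n))
  y <- 3 * X$a - 2 * X$b + 5
  fit <- fit_biomass_model(X, y, svr_params = list(kernel = "linear",
                                                   cost = 100,
                                                   epsilon = 1e-4),
                           split_seed = 1)
  expect_gt(fit$validation$r2, 0.999)
  expect_gt(fit$modeling$r2, 0.999)
})

test_that("permuted biomass labels carry no validation signal", {
  set.seed(13)
  plots <- simulate_plot_trials(campaign_config(), seed = 13)
  fe <- simulate_plot_features(plots, lib176, seed = 13)
  fe <- fe[fe$stage == "W" & fe$weed_biomass > 0, ]
  yperm <- sample(fe$weed_biomass)
  fit <- fit_biomass_model(fe[c("cc_weed", "ndvi", "rvi", "savi", "nb_ndvi")],
                           yperm, split_seed = 2)
  expect_lt(fit$validation$r2, 0.2)
})

test_that("validation uses training-half standardization only (leakage guard)", {
  set.seed(14)
  plots <- simulate_plot_trials(campaign_config(), seed = 14)
  fe <- simulate_plot_features(plots, lib176, seed = 14)
  fe <- fe[fe$stage == "W" & fe$weed_biomass > 0, ]
  X <- as.matrix(fe[c("cc_weed", "ndvi", "rvi", "savi", "nb_ndvi")])
  y <- fe$weed_biomass
  fit <- fit_biomass_model(X, y, split_seed = 3)
  # the stored standardization comes from the modeling half, not all data
  expect_false(isTRUE(all.equal(unname(fit$center), unname(colMeans(X)))))
  idx_m <- fit$idx_modeling
  expect_equal(unname(fit$center), unname(colMeans(X[idx_m, , drop = FALSE])))
  # re-standardizing the held-out half with full-data statistics changes
  # the inputs the machine would see
  full_std <- scale(X)[fit$idx_validation, , drop = FALSE]
  train_std <- sweep(sweep(X[fit$idx_validation, , drop = FALSE], 2,
                           fit$center), 2, fit$scale, `/`)
  expect_gt(max(abs(full_std - train_std)), 1e-8)
})

test_that("validation accuracy improves monotonically as generator noise vanishes", {
  r2s <- numeric(3)
  noises <- c(0.04, 0.01, 0)
  for (k in seq_along(noises)) {
    plots <- simulate_plot_trials(campaign_config(noise_sd = 0.02), seed = 15)
    fe <- simulate_plot_features(plots, lib176, noise_sd = noises[k],
                                 cc_noise_sd = noises[k], seed = 15)
    fe <- fe[fe$stage == "W" & fe$weed_biomass > 0, ]
    fit <- fit_biomass_model(fe[c("cc_weed", "ndvi", "rvi", "savi",
                                  "nb_ndvi")], fe$weed_biomass,
                             split_seed = 4)
    r2s[k] <- fit$validation$r2
  }
  expect_true(all(diff(r2s) > 0))
  expect_gt(r2s[3], 0.98)
})

test_that("univariate baselines behave and lose to the multivariate model", {
  x <- seq(0, 1, length.out = 20)
  perfect <- baseline_univariate(x, 2 * x + 1)
  expect_equal(perfect$r2, 1)
  set.seed(16)
  noisefit <- baseline_univariate(runif(50), rnorm(50))
  expect_lt(noisefit$r2, 0.2)
  expect_error(baseline_univariate(rep(1, 10), rnorm(10)), "constant")

  # CC-only validation RMSE exceeds the CC+VI model's in >= 3 of 4 cells
  plots <- simulate_plot_trials(campaign_config(), seed = 17)
  fe <- simulate_plot_features(plots, lib176, seed = 17)
  fe <- fe[fe$weed_biomass > 0, ]
  wins <- 0
  for (sg in c("W", "J")) {
    for (sw in c("B", "D")) {
      cell <- fe[fe$stage == sg & fe$sowing == sw, ]
      multi <- fit_biomass_model(cell[c("cc_weed", "ndvi", "rvi", "savi",
                                        "nb_ndvi")], cell$weed_biomass,
                                 split_seed = 5)
      cc_only <- fit_biomass_model(cell["cc_weed"], cell$weed_biomass,
                                   split_seed = 5)
      wins <- wins + (cc_only$validation$rmse > multi$validation$rmse)
    }
  }
  expect_gte(wins, 3)
})

test_that("a saved biomass model carries its seed and hyperparameters in the sidecar", {
  tmp <- withr::local_tempdir()
  set.seed(21)
  X <- data.frame(a = runif(20), b = runif(20))
  y <- 2 * X$a + rnorm(20, 0, 0.05)
  fit <- fit_biomass_model(X, y, split_seed = 9)
  path <- file.path(tmp, "model.rds")
  save_biomass_model(fit, path)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$split_seed, 9)
  expect_equal(side$params$cost, 10)
  expect_equal(side$modeling$r2, fit$modeling$r2)
  back <- readRDS(path)
  expect_equal(predict(back, X), predict(fit, X))
})
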