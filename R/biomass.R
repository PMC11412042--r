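#' Canopy cover of one class
#'
#' Fraction of all mask pixels (soil included in the denominator) assigned
#' to `target_class`.
#'
#' @param mask HxW integer matrix with labels in {0, 1, 2}.
#' @param target_class label (default 2 = weed).
#' @return fraction in [0, 1].
#' @export
canopy_cover <- function(mask, target_class = 2L) {
  if (length(mask) == 0) stop("empty mask")
  labs <- as.integer(mask)
  if (any(!labs %in% 0:2)) stop("mask labels outside {0, 1, 2}")
  mean(labs == as.integer(target_class))
}

#' Mean spectrum over the pixels of one class
#'
#' Per-band mean reflectance over the pixels labeled `target_class`;
#' missing (NA/NaN) reflectances are excluded band-wise.
#'
#' @param cube HxWxB reflectance array.
#' @param mask HxW label matrix co-registered with the cube.
#' @param target_class label whose pixels are averaged.
#' @return numeric vector of length B.
#' @export
mask_mean_spectrum <- function(cube, mask, target_class = 2L) {
  d <- dim(cube)
  if (length(d) != 3) stop("cube must be HxWxB")
  sel <- which(as.integer(mask) == as.integer(target_class))
  if (length(sel) == 0) stop("no pixels of the target class")
  flat <- matrix(cube, d[1] * d[2], d[3])
  colMeans(flat[sel, , drop = FALSE], na.rm = TRUE)
}

#' Exhaustive narrowband NDVI band-pair sweep against biomass
#'
#' For every ordered band pair (lambda_i > lambda_j) computes the
#' narrowband NDVI per sample from the supplied area-mean spectra and its
#' Pearson correlation with biomass. The best pair maximizes |r|; exact
#' ties are broken toward the lowest lambda_i, then the lowest lambda_j.
#' The diagonal (and any pair whose NDVI is constant across samples) is
#' flagged `NA`.
#'
#' @param spectra n x B matrix of area-mean reflectance spectra.
#' @param biomass length-n vector with positive variance; n >= 3.
#' @param wavelengths_nm length-B wavelength grid.
#' @return object of class `band_pair_corr`: list with `corr` (BxB,
#'   antisymmetric: corr[j, i] = -corr[i, j]), `wavelengths_nm`,
#'   `best_pair` (c(nir, red) in nm) and `best_r`.
#' @export
band_pair_sweep <- function(spectra, biomass, wavelengths_nm) {
  spectra <- as.matrix(spectra)
  n <- nrow(spectra); B <- ncol(spectra)
  if (n < 3) stop("need at least 3 samples")
  if (length(biomass) != n) stop("biomass length must match spectra rows")
  if (stats::var(biomass) == 0) stop("biomass variance must be positive")
  if (length(wavelengths_nm) != B) stop("one wavelength per band required")
  corr <- matrix(NA_real_, B, B)
  bc <- biomass - mean(biomass)
  bss <- sqrt(sum(bc^2))
  for (i in 2:B) {
    A <- spectra[, i]
    Mj <- spectra[, seq_len(i - 1), drop = FALSE]
    nd <- (A - Mj) / (A + Mj)
    ndc <- sweep(nd, 2, colMeans(nd))
    ss <- sqrt(colSums(ndc^2))
    r <- as.numeric(crossprod(ndc, bc)) / (ss * bss)
    r[ss == 0] <- NA_real_
    corr[i, seq_len(i - 1)] <- r
    corr[seq_len(i - 1), i] <- -r
  }
  absr <- abs(corr)
  absr[upper.tri(absr, diag = TRUE)] <- NA   # keep lambda_i > lambda_j only
  if (all(is.na(absr))) stop("all band pairs degenerate")
  best <- max(absr, na.rm = TRUE)
  cand <- which(absr == best, arr.ind = TRUE)
  # ties: lowest lambda_i (NIR, the row index), then lowest lambda_j
  cand <- cand[order(wavelengths_nm[cand[, 1]], wavelengths_nm[cand[, 2]]), ,
               drop = FALSE]
  bi <- cand[1, 1]; bj <- cand[1, 2]
  structure(list(corr = corr, wavelengths_nm = wavelengths_nm,
                 best_pair = c(nir = wavelengths_nm[bi],
                               red = wavelengths_nm[bj]),
                 best_r = corr[bi, bj]), class = "band_pair_corr")
}

#' Write a band-pair correlation matrix as CSV and a heatmap PNG
#' @param sweep a `band_pair_corr`.
#' @param csv_path,png_path output paths (`NULL` to skip either).
#' @export
write_band_pair_corr <- function(sweep, csv_path = NULL, png_path = NULL) {
  if (!is.null(csv_path)) {
    m <- sweep$corr
    dimnames(m) <- list(sprintf("%.1f", sweep$wavelengths_nm),
                        sprintf("%.1f", sweep$wavelengths_nm))
    utils::write.csv(m, csv_path)
  }
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 700, height = 600)
    on.exit(grDevices::dev.off())
    graphics::image(sweep$wavelengths_nm, sweep$wavelengths_nm,
                    t(abs(sweep$corr)), xlab = "lambda_j (nm)",
                    ylab = "lambda_i (nm)",
                    main = sprintf("|r| of narrowband NDVI vs biomass; best (%g, %g)",
                                   sweep$best_pair[1], sweep$best_pair[2]))
  }
  invisible(sweep)
}

#' Fit the canopy-cover + vegetation-index SVR biomass model
#'
#' Seeded 50/50 modeling/validation split; features are standardized with
#' the modeling-half statistics only; a support-vector regressor
#' (radial-basis kernel by default) is fitted on the modeling half and
#' scored on both halves.
#'
#' @param features data.frame or matrix of numeric predictors (e.g.
#'   cc_weed, NDVI, RVI, SAVI, designated narrowband NDVI).
#' @param biomass response vector (kg/ha); at least 8 plots.
#' @param svr_params list: `kernel` ("radial"), `cost` (10), `epsilon`
#'   (0.1), `gamma` (default 1 / (n_features x mean feature variance),
#'   computed on the standardized modeling half).
#' @param split_seed seed of the 50/50 split.
#' @return object of class `biomass_model`: list with the fitted svm,
#'   standardization parameters (`center`, `scale`), `modeling` and
#'   `validation` regression scores, the split indices and hyperparameters.
#' @export
fit_biomass_model <- function(features, biomass,
                              svr_params = list(), split_seed = 1) {
  X <- as.matrix(as.data.frame(features)[
    vapply(as.data.frame(features), is.numeric, logical(1))])
  y <- as.numeric(biomass)
  n <- nrow(X)
  if (n < 8) stop("need at least 8 plots")
  if (anyNA(X) || anyNA(y)) stop("missing values in features or biomass")
  p <- list(kernel = "radial", cost = 10, epsilon = 0.1, gamma = NULL)
  p[names(svr_params)] <- svr_params
  set.seed(as.integer(split_seed))
  perm <- sample.int(n)
  idx_m <- perm[seq_len(floor(n / 2))]
  idx_v <- setdiff(perm, idx_m)
  if (stats::var(y[idx_m]) == 0) {
    stop("degenerate split: constant biomass in the modeling half")
  }
  ctr <- colMeans(X[idx_m, , drop = FALSE])
  scl <- apply(X[idx_m, , drop = FALSE], 2, stats::sd)
  scl[scl == 0] <- 1
  std <- function(M) sweep(sweep(M, 2, ctr), 2, scl, `/`)
  Xm <- std(X[idx_m, , drop = FALSE])
  Xv <- std(X[idx_v, , drop = FALSE])
  # the response is standardized with modeling-half statistics as well, so
  # the epsilon tube and cost are on a unit scale; predictions map back
  y_ctr <- mean(y[idx_m])
  y_scl <- stats::sd(y[idx_m])
  if (is.null(p$gamma)) {
    p$gamma <- 1 / (ncol(Xm) * mean(apply(Xm, 2, stats::var)))
  }
  fit <- e1071::svm(x = Xm, y = (y[idx_m] - y_ctr) / y_scl,
                    type = "eps-regression",
                    kernel = p$kernel, cost = p$cost, epsilon = p$epsilon,
                    gamma = p$gamma, scale = FALSE)
  pm <- as.numeric(stats::predict(fit, Xm)) * y_scl + y_ctr
  pv <- as.numeric(stats::predict(fit, Xv)) * y_scl + y_ctr
  structure(list(
    fit = fit, center = ctr, scale = scl, y_center = y_ctr, y_scale = y_scl,
    params = p,
    split_seed = as.integer(split_seed), idx_modeling = idx_m,
    idx_validation = idx_v,
    modeling = regression_scores(pm, y[idx_m]),
    validation = regression_scores(pv, y[idx_v])), class = "biomass_model")
}

#' @export
predict.biomass_model <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[
    vapply(as.data.frame(newdata), is.numeric, logical(1))])
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, `/`)
  as.numeric(stats::predict(object$fit, Xs)) * object$y_scale +
    object$y_center
}

#' Univariate biomass baselines (canopy cover only, or one index only)
#'
#' Ordinary least-squares single-predictor fit of biomass on one feature,
#' reported per (stage, sowing) cell for comparison against the
#' multivariate CC+VI model.
#'
#' @param feature numeric predictor vector (e.g. canopy cover or NDVI).
#' @param biomass response vector, same length; at least 3 plots per cell.
#' @param stage,sowing optional factors defining the reporting cells; when
#'   `NULL` a single overall fit is reported.
#' @return data.frame with stage, sowing, n, rmse, r2 per cell.
#' @export
baseline_univariate <- function(feature, biomass, stage = NULL,
                                sowing = NULL) {
  n <- length(feature)
  if (length(biomass) != n) stop("feature and biomass lengths differ")
  if (is.null(stage)) stage <- rep("all", n)
  if (is.null(sowing)) sowing <- rep("all", n)
  cells <- unique(data.frame(stage = stage, sowing = sowing,
                             stringsAsFactors = FALSE))
  out <- list()
  for (r in seq_len(nrow(cells))) {
    sel <- stage == cells$stage[r] & sowing == cells$sowing[r]
    if (sum(sel) < 3) stop("need at least 3 plots per cell")
    x <- feature[sel]; y <- biomass[sel]
    if (stats::var(x) == 0) stop("constant feature in a cell")
    fit <- stats::lm(y ~ x)
    sc <- regression_scores(stats::fitted(fit), y)
    out[[r]] <- data.frame(stage = cells$stage[r], sowing = cells$sowing[r],
                           n = sum(sel), rmse = sc$rmse, r2 = sc$r2,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Save a biomass model with a JSON sidecar
#'
#' Serializes the fitted model (RDS) and writes a human-readable sidecar
#' JSON with the split seed, hyperparameters, standardization statistics
#' and both score sets.
#'
#' @param model a `biomass_model`.
#' @param path RDS path; the sidecar is written at `paste0(path, ".json")`.
#' @export
save_biomass_model <- function(model, path) {
  saveRDS(model, path)
  sidecar <- list(
    split_seed = model$split_seed,
    params = model$params,
    center = as.list(model$center), scale = as.list(model$scale),
    y_center = model$y_center, y_scale = model$y_scale,
    modeling = unclass(model$modeling),
    validation = unclass(model$validation))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
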