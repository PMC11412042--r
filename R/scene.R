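#' Scene configuration for the synthetic wheat-field generator
#'
#' Describes one synthetic UAV orthoscene: pixel grid, sowing method
#' (drilled rows vs broadcast scatter), growth stage, plant density
#' (low = 180e4, high = 300e4 plant/ha), target weed canopy cover, the
#' fraction of weed pixels occluded by overhanging wheat, reflectance noise
#' and the drill row spacing. Occlusion defaults follow field observation:
#' about 5% during wintering and 10% at jointing, plus 3 points at high
#' plant density, never above 20%.
#'
#' @param height_px,width_px scene size in pixels.
#' @param sowing "drill" or "broadcast".
#' @param stage "wintering" or "jointing".
#' @param density "low" or "high".
#' @param weed_cover_target weed pixel fraction in [0, 1].
#' @param occlusion_rate fraction of weed pixels hidden by wheat, in
#'   [0, 0.2]; `NULL` selects the stage/density default.
#' @param noise_sd additive reflectance noise sd (reflectance units).
#' @param row_spacing_px drill row spacing in pixels.
#' @param seed integer seed; identical (config, seed) gives bit-identical
#'   scenes.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(height_px = 192, width_px = 192,
                         sowing = c("drill", "broadcast"),
                         stage = c("wintering", "jointing"),
                         density = c("low", "high"),
                         weed_cover_target = 0.15, occlusion_rate = NULL,
                         noise_sd = 0.01, row_spacing_px = 16, seed = 1) {
  sowing <- match.arg(sowing)
  stage <- match.arg(stage)
  density <- match.arg(density)
  if (height_px < 8 || width_px < 8) stop("scene must be at least 8x8 px")
  if (weed_cover_target < 0 || weed_cover_target > 1) {
    stop("weed_cover_target must lie in [0, 1]")
  }
  if (is.null(occlusion_rate)) {
    occlusion_rate <- (if (stage == "wintering") 0.05 else 0.10) +
      (if (density == "high") 0.03 else 0)
  }
  if (occlusion_rate < 0 || occlusion_rate > 0.20) {
    stop("occlusion_rate must lie in [0, 0.20]")
  }
  if (row_spacing_px < 2) stop("row_spacing_px must be a positive integer >= 2")
  wheat_cover <- wheat_cover_for(stage, density)
  if (weed_cover_target + wheat_cover > 1) {
    stop(sprintf(
      "infeasible cover: weed_cover_target %.2f + wheat cover %.2f exceeds 1",
      weed_cover_target, wheat_cover))
  }
  structure(list(
    height_px = as.integer(height_px), width_px = as.integer(width_px),
    sowing = sowing, stage = stage, density = density,
    weed_cover_target = weed_cover_target, occlusion_rate = occlusion_rate,
    noise_sd = noise_sd, row_spacing_px = as.integer(row_spacing_px),
    seed = as.integer(seed)), class = "scene_config")
}

# wheat canopy cover implied by stage and plant density
wheat_cover_for <- function(stage, density) {
  base <- if (density == "high") 0.50 else 0.35
  if (stage == "jointing") base + 0.15 else base
}

# add an isotropic Gaussian bump to `field` inside its +-3 sigma window
add_blob <- function(field, cy, cx, sig, amp) {
  H <- nrow(field); W <- ncol(field)
  r <- ceiling(3 * sig)
  y0 <- max(1L, round(cy) - r); y1 <- min(H, round(cy) + r)
  x0 <- max(1L, round(cx) - r); x1 <- min(W, round(cx) + r)
  if (y0 > y1 || x0 > x1) return(field)
  gy <- exp(-((y0:y1) - cy)^2 / (2 * sig^2))
  gx <- exp(-((x0:x1) - cx)^2 / (2 * sig^2))
  field[y0:y1, x0:x1] <- field[y0:y1, x0:x1] + amp * outer(gy, gx)
  field
}

# value of the k-th largest element (threshold for selecting exactly k)
kth_largest <- function(x, k) {
  n <- length(x)
  sort(x, partial = n - k + 1L)[n - k + 1L]
}

# smooth Gaussian random field: coarse white noise bilinearly upsampled
smooth_noise <- function(H, W, cell) {
  Hc <- ceiling(H / cell) + 1L
  Wc <- ceiling(W / cell) + 1L
  Z <- matrix(stats::rnorm(Hc * Wc), Hc, Wc)
  Ur <- upsample_matrix(Hc, cell)[seq_len(H), , drop = FALSE]
  Uc <- upsample_matrix(Wc, cell)[seq_len(W), , drop = FALSE]
  Ur %*% Z %*% t(Uc)
}

# mean reflectance of an endmember over a wavelength window
window_mean <- function(library, spectrum, lo, hi) {
  sel <- library$wavelengths_nm >= lo & library$wavelengths_nm <= hi
  mean(spectrum[sel])
}

#' Render one synthetic scene
#'
#' Produces a co-registered RGB image, optional hyperspectral reflectance
#' cube and 3-class label mask (0 = soil, 1 = wheat, 2 = weed) sharing one
#' pixel grid. Drilled scenes place wheat in parallel, slightly wavy rows;
#' broadcast scenes scatter wheat clumps uniformly. Weed patches are
#' spatially clustered blobs. Wheat and weed receive near-identical RGB
#' colour distributions (both dark green with the same modulation-amplitude
#' statistics) but distinct fine texture: wheat blades render as a
#' high-frequency oriented stripe pattern, weed blades as a coarser pattern
#' with independent orientation. An occlusion step relabels the
#' `occlusion_rate` fraction of weed pixels lying closest to wheat as wheat
#' in image, cube and mask, while the recorded truth covers retain their
#' pre-occlusion values. Cube pixels are class endmember spectra modulated
#' by the local biomass coupling and texture, plus Gaussian noise.
#'
#' RGB is derived from the noise-free cube model by averaging fixed visible
#' windows (B 450-495, G 495-570, R 620-700 nm), so image and cube remain
#' physically consistent.
#'
#' @param config a `scene_config`.
#' @param library a `spectra_library`.
#' @param include_cube generate the hyperspectral cube (set `FALSE` for
#'   RGB/mask-only scenes; the RGB and mask are identical either way).
#' @param include_rgb render the RGB image (requires no cube when `FALSE`).
#'   Mask-only scenes are useful for layout/tiling studies at scale; the
#'   mask and truth fields are identical to a full render of the same
#'   config and seed.
#' @return object of class `weed_scene`: list with `rgb` (HxWx3 integer,
#'   0-255), `cube` (HxWxB reflectance or `NULL`), `mask` (HxW integer),
#'   `truth_weed_cover`, `truth_wheat_cover`, `truth_weed_biomass`,
#'   `truth_wheat_biomass` (kg/ha), `wavelengths_nm`, `meta` (the config).
#' @export
render_scene <- function(config, library = make_endmember_library(),
                         include_cube = TRUE, include_rgb = TRUE) {
  stopifnot(inherits(config, "scene_config"))
  if (include_cube && !include_rgb) {
    stop("the cube render requires the RGB/texture pass")
  }
  H <- config$height_px; W <- config$width_px; n <- H * W
  set.seed(config$seed)

  ## -- weed patches: clustered Gaussian blobs (half-res, then upsampled) ---
  jitter <- matrix(stats::runif(n, 0, 1e-7), H)   # breaks exact field ties
  weed_field <- matrix(0, H, W)
  n_weed <- round(config$weed_cover_target * n)
  if (n_weed > 0) {
    Hc <- ceiling(H / 2) + 1L; Wc <- ceiling(W / 2) + 1L
    wf <- matrix(0, Hc, Wc)
    n_parents <- max(1L, round(config$weed_cover_target * n / 6000))
    py <- stats::runif(n_parents, 1, H); px <- stats::runif(n_parents, 1, W)
    for (p in seq_len(n_parents)) {
      kids <- sample(3:6, 1)
      for (k in seq_len(kids)) {
        wf <- add_blob(wf,
                       (py[p] + stats::rnorm(1, 0, 16)) / 2,
                       (px[p] + stats::rnorm(1, 0, 16)) / 2,
                       stats::runif(1, 8, 16) / 2, stats::runif(1, 0.6, 1))
      }
    }
    Ur <- upsample_matrix(Hc, 2L)[seq_len(H), , drop = FALSE]
    Uc <- upsample_matrix(Wc, 2L)[seq_len(W), , drop = FALSE]
    weed_field <- Ur %*% wf %*% t(Uc) + jitter
  }

  ## -- wheat layout field --------------------------------------------------
  if (config$sowing == "drill") {
    sp <- config$row_spacing_px
    offset <- stats::runif(1, 0, sp)
    yv <- seq_len(H)
    wig <- 1.2 * sin(2 * pi * yv / stats::runif(1, 45, 70) +
                       stats::runif(1, 0, 2 * pi))
    d <- outer(wig - offset, seq_len(W), `+`) %% sp
    d <- pmin(d, sp - d)                       # distance to nearest row
    wheat_field <- exp(-d^2 / (2 * (sp / 5)^2))
    rowmod <- 0.85 + 0.15 * sin(2 * pi * yv / stats::runif(1, 23, 37) +
                                  stats::runif(1, 0, 2 * pi))
    wheat_field <- wheat_field * rowmod        # recycles down columns
  } else {
    # broadcast: smooth two-octave noise field makes irregular wheat clumps
    wheat_field <- smooth_noise(H, W, 8L) + 0.6 * smooth_noise(H, W, 16L)
  }
  wheat_field <- wheat_field + jitter

  ## -- class assignment (exact pixel counts) -------------------------------
  mask <- matrix(0L, H, W)
  if (n_weed > 0) {
    thr <- kth_largest(weed_field, n_weed)
    mask[weed_field >= thr] <- 2L
    n_weed <- sum(mask == 2L)
  }
  wheat_cov <- wheat_cover_for(config$stage, config$density)
  n_wheat <- round(wheat_cov * n)
  if (n_wheat > n - n_weed) {
    stop("infeasible cover: weed patches leave too few pixels for wheat")
  }
  if (n_wheat > 0) {
    cand <- wheat_field
    cand[mask == 2L] <- -Inf
    thr <- kth_largest(cand, n_wheat)
    mask[cand >= thr] <- 1L
    n_wheat <- sum(mask == 1L)
  }

  truth_weed_cover <- n_weed / n
  truth_wheat_cover <- n_wheat / n

  ## -- local canopy-density factor f in [0.3, 1] per vegetation pixel ------
  fmap <- matrix(0, H, W)
  scale01 <- function(v) {
    r <- range(v)
    if (r[2] > r[1]) 0.3 + 0.7 * (v - r[1]) / (r[2] - r[1]) else rep(1, length(v))
  }
  if (n_weed > 0) fmap[mask == 2L] <- scale01(weed_field[mask == 2L])
  if (n_wheat > 0) fmap[mask == 1L] <- scale01(wheat_field[mask == 1L])

  ## -- per-stage biomass scales (kg/ha at full cover, full density) --------
  wb_scale <- if (config$stage == "wintering") 400 else 900
  ww_scale <- if (config$stage == "wintering") 3000 else 8000
  truth_weed_biomass <- if (n_weed > 0) {
    wb_scale * truth_weed_cover * mean(fmap[mask == 2L])
  } else 0
  truth_wheat_biomass <- if (n_wheat > 0) {
    ww_scale * truth_wheat_cover * mean(fmap[mask == 1L])
  } else 0

  ## -- occlusion: wheat overhangs the weed pixels nearest to wheat ---------
  n_occ <- round(config$occlusion_rate * n_weed)
  if (n_occ > 0) {
    widx <- which(mask == 2L)
    occ_rank <- order(wheat_field[widx], decreasing = TRUE)
    occ_idx <- widx[occ_rank[seq_len(n_occ)]]
    mask[occ_idx] <- 1L
    fmap[occ_idx] <- pmax(fmap[occ_idx], 0.5)   # now wheat canopy
  }

  ## -- texture modulation m (skipped for mask-only renders) ----------------
  key <- paste0("_", config$stage)
  classes <- c("soil", "wheat", "weed")
  rgb <- NULL
  m <- NULL
  if (include_rgb) {
    theta_wheat <- if (config$sowing == "drill") {
      pi / 2 + stats::rnorm(1, 0, 0.1)
    } else stats::runif(1, 0, pi)
    theta_weed <- stats::runif(1, 0, pi)
    phase <- stats::runif(2, 0, 2 * pi)
    p_wheat <- 3.2; p_weed <- 7.5
    xs <- matrix(rep(seq_len(W), each = H), H)
    ys <- matrix(rep(seq_len(H), times = W), H)
    idx_wheat <- which(mask == 1L)
    idx_weed <- which(mask == 2L)
    xw <- xs[idx_wheat]; yw <- ys[idx_wheat]
    m <- matrix(1, H, W)
    m[idx_wheat] <- 1 + 0.22 *
      sin(2 * pi * (cos(theta_wheat) * xw + sin(theta_wheat) * yw) /
            p_wheat + phase[1])
    xd <- xs[idx_weed]; yd <- ys[idx_weed]
    m[idx_weed] <- 1 + 0.22 *
      sin(2 * pi * (cos(theta_weed) * xd + sin(theta_weed) * yd) /
            p_weed + phase[2])
    lighting <- 1 + 0.04 * smooth_noise(H, W, 48L)
    m <- pmax(m * lighting, 0.2)

    ## -- RGB from fixed visible windows of the endmembers ------------------
    win <- vapply(classes, function(cl) {
      e <- library$endmembers[[cl]]
      c(r = window_mean(library, e, 620, 700),
        g = window_mean(library, e, 495, 570),
        b = window_mean(library, e, 450, 495))
    }, numeric(3))
    gain <- 2.2 * 255
    mg <- as.numeric(m) * gain
    flat <- matrix(0, n, 3)
    for (ch in 1:3) flat[, ch] <- win[ch, mask + 1L] * mg
    flat <- flat + stats::rnorm(3 * n, 0, 5)
    # +0.5 then truncate = round to nearest
    rgb <- array(as.integer(pmin(pmax(flat, 0), 255) + 0.5), c(H, W, 3))
  }

  ## -- hyperspectral cube (drawn last so RGB/mask are cube-invariant) ------
  cube <- NULL
  if (include_cube) {
    B <- length(library$wavelengths_nm)
    M <- matrix(0, n, B)
    for (cl in 0:2) {
      idx <- which(mask == cl)
      if (length(idx) == 0) next
      cname <- classes[cl + 1L]
      e <- library$endmembers[[cname]]
      a <- if (cl == 0L) numeric(B) else
        library$coupling[[paste0(cname, key)]]
      M[idx, ] <- outer(m[idx], e) + outer(m[idx] * fmap[idx], e * a)
    }
    M <- M + matrix(stats::rnorm(n * B, 0, config$noise_sd), n, B)
    cube <- array(pmin(pmax(M, 0), 1.2), c(H, W, B))
  }

  structure(list(
    rgb = rgb, cube = cube, mask = mask,
    truth_weed_cover = truth_weed_cover,
    truth_wheat_cover = truth_wheat_cover,
    truth_weed_biomass = truth_weed_biomass,
    truth_wheat_biomass = truth_wheat_biomass,
    wavelengths_nm = library$wavelengths_nm,
    meta = config), class = "weed_scene")
}

#' Per-channel RGB histogram intersection between two pixel sets
#'
#' Computes, for each of the R/G/B channels, the intersection
#' sum(min(p_i, q_i)) of the normalized 32-bin intensity histograms of the
#' pixels of two classes, and returns the per-channel values. Values near 1
#' mean the two classes are indistinguishable by colour alone.
#'
#' @param scene a `weed_scene`.
#' @param class_a,class_b labels in {0, 1, 2}.
#' @param bins histogram bin count.
#' @return numeric vector of length 3 (R, G, B intersections).
#' @export
rgb_histogram_intersection <- function(scene, class_a = 1L, class_b = 2L,
                                       bins = 32) {
  sel_a <- scene$mask == class_a
  sel_b <- scene$mask == class_b
  if (!any(sel_a) || !any(sel_b)) stop("one of the classes has no pixels")
  breaks <- seq(0, 256, length.out = bins + 1)
  out <- numeric(3)
  for (ch in 1:3) {
    im <- scene$rgb[, , ch]
    pa <- tabulate(findInterval(im[sel_a], breaks, all.inside = TRUE), bins)
    pb <- tabulate(findInterval(im[sel_b], breaks, all.inside = TRUE), bins)
    out[ch] <- sum(pmin(pa / sum(pa), pb / sum(pb)))
  }
  names(out) <- c("r", "g", "b")
  out
}
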