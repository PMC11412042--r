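#' Synthetic endmember spectral library for soil, wheat and grass weeds
#'
#' Builds reflectance endmembers on a uniform 400-1000 nm grid together with
#' a band-wise biomass-sensitivity ("coupling") profile per vegetation class
#' and growth stage. The wheat and weed endmembers are nearly identical --
#' grass weeds and wheat seedlings overlap spectrally almost everywhere --
#' and differ measurably only inside narrow green and red/red-edge windows.
#' Each (class, stage) carries a designated peak-sensitivity band pair at
#' which a narrowband NDVI tracks biomass most strongly:
#' wheat/wintering (960, 733), weed/wintering (960, 719),
#' wheat/jointing (960, 710), weed/jointing (960, 700) nm.
#'
#' @param band_count number of uniformly spaced bands covering 400-1000 nm
#'   (default 176, approximately the 3.5 nm resolution of a pushbroom
#'   hyperspectral UAV sensor). Must be at least 20.
#' @param seed integer seed for the small random perturbations of the
#'   endmember shapes.
#' @return object of class `spectra_library`: list with `wavelengths_nm`,
#'   `endmembers` (list soil/wheat/weed), `coupling` (list by
#'   "class_stage"), `designated_pairs` (list by "class_stage" of
#'   c(nir, red) nm), and the green/red difference windows.
#' @export
make_endmember_library <- function(band_count = 176, seed = 1) {
  if (band_count < 20) stop("band_count must be >= 20")
  wl <- seq(400, 1000, length.out = band_count)
  step <- wl[2] - wl[1]
  pairs <- list(
    wheat_wintering = c(960, 733), weed_wintering = c(960, 719),
    wheat_jointing  = c(960, 710), weed_jointing   = c(960, 700))
  # every designated wavelength must resolve to a grid band within half the
  # sensor's 3.5 nm spectral resolution, or the band is effectively absent
  for (nm in unlist(pairs)) {
    if (min(abs(wl - nm)) > 3.5 / 2 + 1e-9) {
      stop(sprintf("grid too coarse to place designated band at %g nm", nm))
    }
  }
  set.seed(as.integer(seed))
  gauss <- function(mu, sd) exp(-(wl - mu)^2 / (2 * sd^2))

  # vegetation archetype: green peak, red absorption trough, red-edge rise,
  # NIR plateau with a mild ~970 nm water feature
  veg_base <- 0.045 + 0.095 * gauss(552, 28) +
    0.42 / (1 + exp(-(wl - 716) / 13)) - 0.03 * gauss(972, 22)

  # wheat vs weed: tiny bipolar offsets confined to green (520-580) and
  # red (640-720) windows -- the only regions where the two differ. The
  # offsets integrate to ~0 over the broadband RGB windows, so the two
  # classes stay near-identical in colour while their narrowband spectra
  # separate (blade pigment distribution, not overall brightness).
  green_win <- c(520, 580)
  red_win <- c(640, 720)
  wheat <- veg_base
  weed <- veg_base - 0.010 * gauss(540, 8) + 0.010 * gauss(562, 8) +
    0.012 * gauss(664, 9) - 0.012 * gauss(688, 9)

  # dry agricultural soil: featureless, gently increasing with wavelength
  soil <- 0.10 + 0.00035 * (wl - 400) + 0.01 * gauss(600, 120)

  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  endmembers <- list(soil = clamp01(soil), wheat = clamp01(wheat),
                     weed = clamp01(weed))

  # biomass coupling: reflectance gains at the designated NIR band, loses at
  # the designated red-edge band, with narrow Gaussian falloff so the
  # designated pair is the unique sensitivity optimum. Centers sit on the
  # resolved grid wavelengths (designated bands map to nearest grid bands),
  # making the resolved pair the exact argmax of the sensitivity gap.
  # jointing amplitudes are larger: regrowth canopies span a wider biomass
  # range and their designated red bands sit lower on the red edge
  coupling <- lapply(names(pairs), function(key) {
    p <- pairs[[key]]
    amp <- if (grepl("jointing", key)) c(0.32, 0.50) else c(0.25, 0.35)
    mu_nir <- wl[which.min(abs(wl - p[1]))]
    mu_red <- wl[which.min(abs(wl - p[2]))]
    amp[1] * gauss(mu_nir, 3.5) - amp[2] * gauss(mu_red, 3.5)
  })
  names(coupling) <- names(pairs)

  # nuisance variability: sample-to-sample canopy condition (closure,
  # pigment load, residual illumination geometry) perturbs reflectance
  # multiplicatively with wavelength-dependent amplitudes. A
  # normalized-difference index only cancels a perturbation whose amplitude
  # is EQUAL at its two bands, so two independent factors are used whose
  # profiles coincide at the designated band pair and nowhere jointly
  # else: (1) a spectral ramp pulled to a common value at both designated
  # bands, and (2) a clipped parabola with roots exactly there. At the
  # designated pair -- and only there -- both factors drop out of the
  # narrowband NDVI; this is what makes that pair the empirically best one.
  nuisance <- lapply(pairs, function(p) {
    mu_nir <- wl[which.min(abs(wl - p[1]))]
    mu_red <- wl[which.min(abs(wl - p[2]))]
    ramp <- 0.25 * (wl - 400) / 600
    r_nir <- 0.25 * (mu_nir - 400) / 600
    r_red <- 0.25 * (mu_red - 400) / 600
    K <- (r_nir + r_red) / 2
    c1 <- ramp - (r_nir - K) * gauss(mu_nir, 3.5) -
      (r_red - K) * gauss(mu_red, 3.5)
    quad <- (wl - mu_nir) * (wl - mu_red) / ((mu_nir - mu_red) / 2)^2
    c2 <- 0.10 * pmin(pmax(quad, -1), 1)
    list(ramp = c1, quad = c2)
  })

  structure(list(
    wavelengths_nm = wl, step_nm = step, endmembers = endmembers,
    coupling = coupling, nuisance = nuisance, designated_pairs = pairs,
    green_window_nm = green_win, red_window_nm = red_win,
    seed = as.integer(seed)), class = "spectra_library")
}

#' Nearest grid band for a wavelength
#'
#' @param library a `spectra_library` (or any list with `wavelengths_nm`).
#' @param nm wavelength in nanometres; must lie within the grid range.
#' @return integer band index.
#' @export
nearest_band <- function(library, nm) {
  wl <- library$wavelengths_nm
  if (nm < min(wl) || nm > max(wl)) {
    stop(sprintf("wavelength %g nm outside grid range %g-%g nm",
                 nm, min(wl), max(wl)))
  }
  which.min(abs(wl - nm))
}

# biomass response in [0, 1]; linear in biomass up to bmax
biomass_response <- function(biomass, bmax) pmin(pmax(biomass / bmax, 0), 1)

# canopy response f(biomass) for one (class, stage), parameterized so the
# narrowband NDVI at the designated band pair is exactly linear in biomass:
# with R_a = A(1 + alpha f) and R_b = B(1 + beta f), NDVI(f) is a rational
# function (D0 + D1 f)/(S0 + S1 f); inverting it along a linear NDVI ramp
# gives f. This encodes the premise that the designated narrowband NDVI is
# a linear proxy for biomass; every other band pair inherits residual
# curvature.
canopy_response <- function(library, class, stage, biomass, bmax) {
  key <- paste(class, stage, sep = "_")
  p <- library$designated_pairs[[key]]
  ia <- nearest_band(library, p[1]); ib <- nearest_band(library, p[2])
  e <- library$endmembers[[class]]
  a <- library$coupling[[key]]
  A <- e[ia]; B <- e[ib]; al <- a[ia]; be <- a[ib]
  D0 <- A - B; D1 <- A * al - B * be
  S0 <- A + B; S1 <- A * al + B * be
  ndvi_at <- function(f) (D0 + D1 * f) / (S0 + S1 * f)
  t <- biomass_response(biomass, bmax)
  Nt <- ndvi_at(0) + t * (ndvi_at(1) - ndvi_at(0))
  (S0 * Nt - D0) / (D1 - S1 * Nt)
}

#' Simulate area-mean reflectance spectra for a vegetation class
#'
#' Emulates the per-plot mean spectrum of the pixels of one vegetation class
#' (as extracted from a segmented hyperspectral orthoscene): the class
#' endmember modulated band-wise by the biomass coupling plus additive
#' Gaussian sensor noise.
#'
#' @param library a `spectra_library`.
#' @param class "wheat" or "weed".
#' @param stage "wintering" or "jointing".
#' @param biomass numeric vector of biomass values (kg/ha), one spectrum per
#'   value.
#' @param bmax biomass at which the coupling saturates (default 400 kg/ha for
#'   weeds in winter-scale campaigns; pass the campaign maximum).
#' @param noise_sd additive reflectance noise standard deviation.
#' @param seed integer seed.
#' @return matrix `length(biomass) x band_count` of reflectance in [0, 1.2].
#' @export
simulate_mean_spectra <- function(library, class = c("weed", "wheat"),
                                  stage = c("wintering", "jointing"),
                                  biomass, bmax = max(biomass),
                                  noise_sd = 0.01, seed = 1) {
  class <- match.arg(class)
  stage <- match.arg(stage)
  key <- paste(class, stage, sep = "_")
  e <- library$endmembers[[class]]
  a <- library$coupling[[key]]
  cn <- library$nuisance[[key]]
  set.seed(as.integer(seed))
  f <- canopy_response(library, class, stage, biomass, bmax)
  u1 <- stats::rnorm(length(biomass))       # per-sample canopy condition
  u2 <- stats::rnorm(length(biomass))
  base <- (1 + outer(f, a)) *
    (1 + outer(u1, cn$ramp) + outer(u2, cn$quad))
  spec <- sweep(base, 2, e, `*`)
  spec <- spec + matrix(stats::rnorm(length(spec), 0, noise_sd),
                        nrow = nrow(spec))
  pmin(pmax(spec, 0), 1.2)
}
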