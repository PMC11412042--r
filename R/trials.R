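#' Campaign configuration for the synthetic field trial generator
#'
#' Describes a factorial weed-infestation trial: growth stage of weed
#' emergence (wintering/jointing) x sowing method (broadcast/drill) x plant
#' density (low/high) x ordinal weed infestation level (0 = weed-free
#' control .. `weed_levels`), with `reps` plots per treatment cell.
#'
#' The default reduction schedule is anchored so that the worst cell
#' (broadcast sowing, high density, wintering-emerged weeds, maximum weed
#' level) has a mean wheat dry-weight reduction of 71% and a mean grain
#' yield reduction of 60% -- 4320 kg/ha below its 7200 kg/ha control mean.
#' Effects are attenuated multiplicatively for drill sowing, low density and
#' jointing emergence, so broadcast > drill, high > low and
#' wintering > jointing in effect size. Intermediate weed levels interpolate
#' linearly between control and the maximum.
#'
#' @param reps plots per treatment cell.
#' @param weed_levels number of non-zero infestation levels (levels are
#'   0..weed_levels).
#' @param noise_sd sdlog of the multiplicative log-normal noise on all
#'   measured masses (mean-one parameterization, so cell means are
#'   unbiased).
#' @param control_yield named vector c(low=, high=): weed-free grain yield
#'   mean (kg/ha) by plant density.
#' @param control_dry_weight named vector c(low=, high=): weed-free wheat
#'   dry weight mean (kg/ha) by density.
#' @param max_reduction_dry_weight,max_reduction_yield relative reduction in
#'   the worst cell at the top weed level, each in [0, 1].
#' @param factor_drill,factor_low_density,factor_jointing multiplicative
#'   attenuation of the maximum reduction for the weaker level of each
#'   factor, each in [0, 1].
#' @param weed_biomass_max named vector c(wintering=, jointing=): weed
#'   biomass (kg/ha) at the top weed level.
#' @return object of class `campaign_config`.
#' @export
campaign_config <- function(reps = 10, weed_levels = 3, noise_sd = 0.05,
                            control_yield = c(low = 6800, high = 7200),
                            control_dry_weight = c(low = 7800, high = 8200),
                            max_reduction_dry_weight = 0.71,
                            max_reduction_yield = 0.60,
                            factor_drill = 0.80,
                            factor_low_density = 0.85,
                            factor_jointing = 0.75,
                            weed_biomass_max = c(wintering = 400,
                                                 jointing = 900)) {
  sched <- c(max_reduction_dry_weight, max_reduction_yield,
             factor_drill, factor_low_density, factor_jointing)
  if (any(sched < 0 | sched > 1)) {
    stop("reduction schedule values must lie in [0, 1]")
  }
  if (reps < 1 || weed_levels < 1) stop("reps and weed_levels must be >= 1")
  structure(list(
    reps = as.integer(reps), weed_levels = as.integer(weed_levels),
    noise_sd = noise_sd, control_yield = control_yield,
    control_dry_weight = control_dry_weight,
    max_reduction_dry_weight = max_reduction_dry_weight,
    max_reduction_yield = max_reduction_yield,
    factor_drill = factor_drill, factor_low_density = factor_low_density,
    factor_jointing = factor_jointing,
    weed_biomass_max = weed_biomass_max), class = "campaign_config")
}

# mean-one multiplicative log-normal noise
lnorm_noise <- function(n, sdlog) {
  if (sdlog == 0) return(rep(1, n))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Simulate a factorial weed-infestation field trial
#'
#' Draws one plot table under the campaign's reduction schedule. Expected
#' wheat dry weight and grain yield decrease monotonically in weed level,
#' the weed-free controls sit at their configured means, and the weed
#' biomass grows with level. Codes follow the field convention:
#' stage W/J, sowing B/D, density L/H.
#'
#' @param campaign a `campaign_config`.
#' @param seed integer seed.
#' @return data.frame with columns plot_id, stage, sowing, density,
#'   weed_level, weed_biomass, wheat_dry_weight, grain_yield.
#' @export
simulate_plot_trials <- function(campaign = campaign_config(), seed = 1) {
  stopifnot(inherits(campaign, "campaign_config"))
  set.seed(as.integer(seed))
  cc <- campaign
  grid <- expand.grid(stage = c("W", "J"), sowing = c("B", "D"),
                      density = c("L", "H"),
                      weed_level = 0:cc$weed_levels,
                      rep = seq_len(cc$reps),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  nrows <- nrow(grid)
  s_level <- grid$weed_level / cc$weed_levels       # linear schedule in level
  atten <- ifelse(grid$sowing == "D", cc$factor_drill, 1) *
    ifelse(grid$density == "L", cc$factor_low_density, 1) *
    ifelse(grid$stage == "J", cc$factor_jointing, 1)
  dens_key <- ifelse(grid$density == "L", "low", "high")
  ctrl_dw <- cc$control_dry_weight[dens_key]
  ctrl_gy <- cc$control_yield[dens_key]
  red_dw <- cc$max_reduction_dry_weight * atten * s_level
  red_gy <- cc$max_reduction_yield * atten * s_level
  wb_max <- cc$weed_biomass_max[
    ifelse(grid$stage == "W", "wintering", "jointing")]
  wb <- wb_max * s_level *
    ifelse(grid$sowing == "B", 1, 0.9)       # drilled canopy suppresses weeds

  out <- data.frame(
    plot_id = sprintf("P%04d", seq_len(nrows)),
    stage = grid$stage, sowing = grid$sowing, density = grid$density,
    weed_level = grid$weed_level,
    weed_biomass = wb * lnorm_noise(nrows, cc$noise_sd),
    wheat_dry_weight = ctrl_dw * (1 - red_dw) * lnorm_noise(nrows, cc$noise_sd),
    grain_yield = ctrl_gy * (1 - red_gy) * lnorm_noise(nrows, cc$noise_sd),
    stringsAsFactors = FALSE)
  out$weed_biomass[out$weed_level == 0] <- 0    # weed-free controls
  rownames(out) <- NULL
  attr(out, "seed") <- as.integer(seed)
  attr(out, "campaign") <- campaign
  out
}

#' Simulate per-plot segmentation-and-spectra features for biomass modeling
#'
#' Emulates the downstream observables a full imaging pipeline would deliver
#' per plot: weed canopy cover (a saturating function of weed biomass plus
#' observation noise) and vegetation indices computed from the simulated
#' weed-area mean spectrum (broadband NDVI/RVI/SAVI from designated NIR and
#' red windows, plus the stage-specific designated narrowband NDVI).
#'
#' @param plots plot table from [simulate_plot_trials()].
#' @param library a `spectra_library`.
#' @param noise_sd reflectance noise sd for the mean spectra.
#' @param cc_noise_sd additive noise sd on canopy cover.
#' @param seed integer seed.
#' @return data.frame: plot_id, stage, sowing, cc_weed, ndvi, rvi, savi,
#'   nb_ndvi, weed_biomass.
#' @export
simulate_plot_features <- function(plots, library = make_endmember_library(),
                                   noise_sd = 0.01, cc_noise_sd = 0.03,
                                   seed = 1) {
  set.seed(as.integer(seed))
  stages <- c(W = "wintering", J = "jointing")
  nir_b <- nearest_band(library, 800)
  red_b <- nearest_band(library, 670)
  out <- vector("list", 2)
  i <- 1
  for (sg in c("W", "J")) {
    sel <- plots$stage == sg
    if (!any(sel)) next
    stage <- stages[[sg]]
    wb <- plots$weed_biomass[sel]
    bmax <- max(wb, 1)
    spec <- simulate_mean_spectra(library, "weed", stage, wb, bmax = bmax,
                                  noise_sd = noise_sd,
                                  seed = seed + match(sg, c("W", "J")))
    cc <- 0.45 * wb / (wb + 0.35 * bmax) +
      stats::rnorm(length(wb), 0, cc_noise_sd)
    cc <- pmin(pmax(cc, 0), 1)
    # noise floor keeps the ratio index finite in dark red-absorption bands
    nir <- spec[, nir_b]
    red <- pmax(spec[, red_b], 1e-3)
    pair <- library$designated_pairs[[paste0("weed_", stage)]]
    a <- spec[, nearest_band(library, pair[1])]
    b <- spec[, nearest_band(library, pair[2])]
    out[[i]] <- data.frame(
      plot_id = plots$plot_id[sel], stage = plots$stage[sel],
      sowing = plots$sowing[sel], cc_weed = cc,
      ndvi = (nir - red) / (nir + red), rvi = nir / red,
      savi = 1.5 * (nir - red) / (nir + red + 0.5),
      nb_ndvi = (a - b) / (a + b),
      weed_biomass = wb, stringsAsFactors = FALSE)
    i <- i + 1
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
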