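#' Growth-curve parameters for the synthetic trial
#'
#' Parameters of the logistic biomass trajectory that drives every synthetic
#' plot: per-genotype asymptote, thermal-time inflection and rate, a
#' multiplicative density effect on the growth rate (densities spread
#' biomass accumulation early in the season and converge at the asymptote),
#' a smooth spatial trend over the row-column grid, a lognormal plot
#' residual, and the senescence onset that starts the green-down.
#'
#' @param biomass_asymptote Named numeric vector, asymptotic DW_AGB per
#'   genotype (g/m^2). Unnamed scalar = common asymptote.
#' @param tt_inflection Thermal time of the logistic inflection (degC day).
#' @param growth_rate Logistic rate (1/(degC day)).
#' @param density_effect Named vector of rate multipliers per sowing density
#'   (plants/m).
#' @param spatial_trend_amplitude Amplitude of the smooth row-column trend
#'   at maturity (g/m^2).
#' @param residual_cv Coefficient of variation of the lognormal plot x date
#'   residual (0 = noise free).
#' @param senescence_onset_tt Thermal time at which canopy green-down
#'   starts (degC day).
#' @param senescence_span_tt Thermal time over which the canopy fully
#'   senesces after onset (degC day).
#' @param max_height Asymptotic canopy height (m).
#' @param cover_scale Biomass scale of canopy closure (g/m^2): green cover
#'   is `1 - exp(-DW/cover_scale)` before senescence.
#' @return List of class `growth_params`.
#' @export
growth_params <- function(biomass_asymptote = c(G = 1600),
                          tt_inflection = 1200,
                          growth_rate = 0.004,
                          density_effect = c(`75` = 0.85, `112` = 0.92,
                                             `150` = 1, `187` = 1.06,
                                             `225` = 1.12, `300` = 1.2),
                          spatial_trend_amplitude = 0,
                          residual_cv = 0,
                          senescence_onset_tt = 1600,
                          senescence_span_tt = 600,
                          max_height = 1.0,
                          cover_scale = 250) {
  stopifnot(all(biomass_asymptote > 0), residual_cv >= 0, growth_rate > 0,
            senescence_onset_tt > 0, senescence_span_tt > 0,
            max_height > 0, cover_scale > 0)
  structure(as.list(environment()), class = "growth_params")
}

#' Synthetic daily weather series
#'
#' Sinusoidal seasonal minimum/maximum temperature with Gaussian
#' day-to-day noise, plus occasional rain; shaped after a subtropical
#' winter-cereal season (coolest mid-season, roughly 1800-2400 degC day
#' accumulated over ~170 days at base 0).
#'
#' @param start,end First and last date (Date or ISO string).
#' @param mean_temp Annual mean of daily mean temperature (degC).
#' @param amplitude Seasonal half-range of the daily mean (degC).
#' @param diurnal_range Mean tmax - tmin (degC).
#' @param noise_sd Day-to-day noise on the daily mean (degC).
#' @param seed Integer seed.
#' @return Data.frame `date`, `tmin`, `tmax`, `rain`, `irrigation`.
#' @export
synthetic_weather <- function(start, end, mean_temp = 16, amplitude = 6,
                              diurnal_range = 12, noise_sd = 1.5, seed = 1) {
  d <- seq(as.Date(start), as.Date(end), by = "day")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  doy <- as.integer(format(d, "%j"))
  # southern-hemisphere phase: coolest around day 195 (mid July)
  tmean <- mean_temp + amplitude * cos(2 * pi * (doy - 15) / 365) +
    stats::rnorm(length(d), 0, noise_sd)
  tmin <- tmean - diurnal_range / 2
  tmax <- tmean + diurnal_range / 2
  rain <- ifelse(stats::runif(length(d)) < 0.15,
                 round(stats::rexp(length(d), 1 / 8), 1), 0)
  data.frame(date = d, tmin = round(tmin, 1), tmax = round(tmax, 1),
             rain = rain, irrigation = 0)
}

.logistic_dw <- function(tt, asym, rate, infl) asym / (1 + exp(-rate * (tt - infl)))

.lookup_effect <- function(eff, key, default = 1) {
  if (length(eff) == 1 && is.null(names(eff))) return(unname(eff))
  i <- match(as.character(key), names(eff))
  ifelse(is.na(i), default, unname(eff[i]))
}

#' Simulate per-plot biomass and canopy-state trajectories
#'
#' True aboveground dry biomass follows a logistic curve in cumulative
#' thermal time, with a genotype-specific asymptote, a density-specific
#' rate multiplier, a smooth sinusoidal row-column trend, and (optionally)
#' a mean-one lognormal plot x date residual. Mean canopy height and green
#' cover fraction are saturating functions of realized biomass, so that
#' with noise off both are strictly increasing in true biomass; green cover
#' declines linearly after the senescence onset.
#'
#' @param design A `trial_design` from [generate_design()].
#' @param weather Daily weather covering sowing to the last date.
#' @param params A [growth_params()] object.
#' @param dates Measurement (cut/flight) dates.
#' @param sowing_date Sowing date.
#' @param seed Integer seed.
#' @param base_temp Base temperature for thermal time (degC day).
#' @return Data.frame of class `plot_state`: one row per plot x date with
#'   `plot_id`, `date`, `cut_number`, `tt`, `true_dw_agb` (g/m^2),
#'   `mean_height` (m), `green_fraction`, `senescence` plus the design
#'   columns.
#' @export
simulate_growth <- function(design, weather, params, dates, sowing_date,
                            seed, base_temp = 0) {
  stopifnot(inherits(params, "growth_params"))
  tt_series <- cumulative_thermal_time(weather, sowing_date, base_temp)
  dates <- as.Date(dates)
  tt <- tt_at_date(tt_series, dates)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  grid <- expand.grid(i = seq_len(nrow(design)), k = seq_along(dates))
  d <- design[grid$i, ]
  asym <- .lookup_effect(params$biomass_asymptote, d$genotype,
                         default = mean(params$biomass_asymptote))
  dens <- .lookup_effect(params$density_effect, d$density)
  trend <- sin(pi * d$row / (max(design$row) + 1)) *
    sin(pi * d$column / (max(design$column) + 1)) * 2 - 1   # in [-1, 1]
  tt_k <- tt[grid$k]
  dw <- .logistic_dw(tt_k, asym, params$growth_rate * dens, params$tt_inflection)
  dw <- dw * pmax(0, 1 + params$spatial_trend_amplitude / asym * trend)
  if (params$residual_cv > 0) {
    sdlog <- sqrt(log(1 + params$residual_cv^2))
    dw <- dw * stats::rlnorm(length(dw), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  sen <- pmin(pmax((tt_k - params$senescence_onset_tt) /
                     params$senescence_span_tt, 0), 1)
  height <- params$max_height * (1 - exp(-dw / 300))
  green <- (1 - exp(-dw / params$cover_scale)) * (1 - 0.85 * sen)
  out <- data.frame(
    d, date = dates[grid$k], cut_number = grid$k, tt = tt_k,
    true_dw_agb = dw, mean_height = height, green_fraction = green,
    senescence = sen, row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("plot_state", "data.frame")
  out
}

#' Emit a quadrat cut record consistent with a true biomass
#'
#' Generates the raw quadrat weights (fresh quadrat weight, fresh and dry
#' subsample weights) that a field crew would record for a plot whose true
#' DW_AGB is known, such that [compute_dw_agb()] applied to the record
#' recovers `true_dw_agb * (1 + noise)`. The dry:fresh ratio is drawn
#' uniformly in a physiological range; measurement noise is Gaussian
#' multiplicative with the stated CV.
#'
#' @param true_dw_agb True dry biomass (g/m^2).
#' @param quad_area Quadrat area (m^2), > 0.
#' @param noise_cv Measurement CV, >= 0.
#' @param seed Integer seed.
#' @return One-row data.frame: `fw_quad`, `fw_sub`, `dw_sub`, `quad_area`
#'   (and `dry_fresh_ratio` for reference).
#' @export
sample_biomass <- function(true_dw_agb, quad_area, noise_cv, seed) {
  if (quad_area <= 0) stop("quad_area must be > 0", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ratio <- stats::runif(1, 0.15, 0.45)
  measured <- true_dw_agb * (1 + stats::rnorm(1, 0, noise_cv))
  measured <- max(measured, 0)
  dw_quad <- measured * quad_area
  fw_quad <- dw_quad / ratio
  fw_sub <- if (fw_quad > 0) min(fw_quad, 0.25 * fw_quad + 5) else 0
  dw_sub <- ratio * fw_sub
  data.frame(fw_quad = fw_quad, fw_sub = fw_sub, dw_sub = dw_sub,
             quad_area = quad_area, dry_fresh_ratio = ratio)
}
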