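#' Dry aboveground biomass from a quadrat cut record
#'
#' Converts a destructive quadrat cut to dry weight of aboveground biomass
#' per unit ground area: the quadrat fresh weight is scaled by the
#' subsample dry:fresh ratio and divided by the quadrat area,
#' \deqn{DW_{AGB} = FW_{quad} (DW_{sub}/FW_{sub}) / Quad_{area}.}
#'
#' @param cut A list or one-row data.frame with `fw_quad` (g), `fw_sub` (g),
#'   `dw_sub` (g) and `quad_area` (m^2). Vectorized over rows when given a
#'   data.frame.
#' @return DW_AGB in g/m^2.
#' @examples
#' compute_dw_agb(list(fw_quad = 1000, fw_sub = 200, dw_sub = 50,
#'                     quad_area = 0.5))  # 500 g/m^2
#' @export
compute_dw_agb <- function(cut) {
  fw_quad <- cut$fw_quad; fw_sub <- cut$fw_sub
  dw_sub <- cut$dw_sub;  quad_area <- cut$quad_area
  if (any(quad_area <= 0)) stop("quad_area must be > 0", call. = FALSE)
  if (any(fw_quad < 0)) stop("fw_quad must be >= 0", call. = FALSE)
  if (any(dw_sub > fw_sub)) stop("dry subsample exceeds fresh subsample", call. = FALSE)
  if (any(fw_sub == 0 & fw_quad > 0)) {
    stop("undefined dry:fresh ratio (fw_sub = 0 with fw_quad > 0)", call. = FALSE)
  }
  ratio <- ifelse(fw_sub == 0, 0, dw_sub / fw_sub)
  fw_quad * ratio / quad_area
}

#' Cumulative thermal time since sowing
#'
#' Daily thermal time is the mean of the day's minimum and maximum
#' temperature above a base temperature, floored at zero; cumulative thermal
#' time at a date is the running sum from sowing to that date (inclusive).
#' The default base of 0 degC is the common wheat convention.
#'
#' @param weather Data.frame with `date` (Date or ISO-8601 string), `tmin`,
#'   `tmax` (degC), contiguous daily coverage.
#' @param sowing_date Sowing date (within the weather coverage).
#' @param base_temp Base temperature (degC), default 0.
#' @return Data.frame `date`, `tt` (degC day), non-decreasing, one row per
#'   day from sowing to the end of the weather series.
#' @export
cumulative_thermal_time <- function(weather, sowing_date, base_temp = 0) {
  d <- as.Date(weather$date)
  sowing_date <- as.Date(sowing_date)
  if (sowing_date < min(d) || sowing_date > max(d)) {
    stop("sowing_date outside weather coverage", call. = FALSE)
  }
  if (any(weather$tmax < weather$tmin)) stop("tmax < tmin in weather", call. = FALSE)
  keep <- d >= sowing_date
  inc <- pmax(0, (weather$tmin[keep] + weather$tmax[keep]) / 2 - base_temp)
  data.frame(date = d[keep], tt = cumsum(inc))
}

#' Look up cumulative thermal time at given dates
#'
#' @param tt_series Output of [cumulative_thermal_time()].
#' @param dates Dates to look up; must lie within the series.
#' @return Numeric vector of TT (degC day).
#' @export
tt_at_date <- function(tt_series, dates) {
  dates <- as.Date(dates)
  i <- match(dates, tt_series$date)
  if (anyNA(i)) stop("date outside thermal-time coverage: ",
                     paste(dates[is.na(i)], collapse = ", "), call. = FALSE)
  tt_series$tt[i]
}

#' Fit the phenology spline (trial-mean Zadoks vs thermal time)
#'
#' A generalized additive model of trial-mean Zadoks score on cumulative
#' thermal time: a cubic regression spline with 10 knots, smoothing strength
#' chosen by generalized cross-validation (the fitting is delegated to
#' \pkg{mgcv}). Predictions are clamped to the Zadoks range \[0, 99\].
#'
#' @param zadoks_obs Data.frame with `tt` (degC day) and `score`
#'   (trial-mean Zadoks, 0-99).
#' @param knots Spline basis dimension (default 10 as used for wheat
#'   trial-mean curves).
#' @return Object of class `phenology_model`: the mgcv fit plus the observed
#'   TT range.
#' @export
fit_phenology_model <- function(zadoks_obs, knots = 10) {
  stopifnot(all(c("tt", "score") %in% names(zadoks_obs)))
  if (length(unique(zadoks_obs$tt)) < knots + 1) {
    stop("need more distinct thermal-time values (", knots + 1,
         ") than knots to fit the phenology spline", call. = FALSE)
  }
  fit <- mgcv::gam(score ~ s(tt, k = knots, bs = "cr"), data = zadoks_obs,
                   method = "GCV.Cp")
  structure(
    list(fit = fit, tt_range = range(zadoks_obs$tt),
         sigma = sqrt(fit$sig2)),
    class = "phenology_model"
  )
}

#' Predict Zadoks score from a fitted phenology model
#'
#' @param object A `phenology_model`.
#' @param newdata Data.frame with `tt`, or a numeric TT vector.
#' @param ... Unused.
#' @return Predicted Zadoks scores clamped to \[0, 99\].
#' @export
predict.phenology_model <- function(object, newdata, ...) {
  if (is.numeric(newdata)) newdata <- data.frame(tt = newdata)
  p <- as.numeric(mgcv::predict.gam(object$fit, newdata = newdata))
  pmin(pmax(p, 0), 99)
}

#' Solve the fitted phenology curve for the stage boundaries
#'
#' Finds the smallest thermal time at which the fitted Zadoks curve reaches
#' 50 (head emergence: vegetative/flowering boundary) and 70 (grain
#' development: flowering/grain-fill boundary), by bisection on the fitted
#' smooth to a 0.5 degC day tolerance. Taking the smallest crossing guards
#' against local wiggles of the smooth.
#'
#' @param model A `phenology_model`.
#' @param targets Zadoks scores to solve for (default `c(50, 70)`).
#' @param tol Bisection tolerance in degC day (default 0.5).
#' @return List of class `stage_boundaries` with `tt_veg_flower` and
#'   `tt_flower_grainfill` (degC day).
#' @export
solve_stage_boundaries <- function(model, targets = c(50, 70), tol = 0.5) {
  grid_tt <- seq(model$tt_range[1], model$tt_range[2], length.out = 512)
  pred <- predict(model, grid_tt)
  solve_one <- function(target) {
    above <- pred >= target
    if (!any(above) || !any(!above)) {
      stop("fitted curve never crosses Zadoks ", target,
           " within the observed thermal-time range", call. = FALSE)
    }
    k <- which(above)[1]              # first grid point at/above the target
    if (k == 1) return(grid_tt[1])
    lo <- grid_tt[k - 1]; hi <- grid_tt[k]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (predict(model, mid) >= target) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  b <- vapply(targets, solve_one, numeric(1))
  if (length(targets) == 2 && b[1] >= b[2]) {
    stop("recovered boundaries are not ordered (curve is not monotone ",
         "through the targets)", call. = FALSE)
  }
  structure(list(tt_veg_flower = b[1], tt_flower_grainfill = b[2]),
            class = "stage_boundaries")
}

#' Classify broad growth stage from thermal time
#'
#' Vegetative up to and including the Zadoks-50 boundary, flowering up to
#' and including the Zadoks-70 boundary, grain-fill beyond. The boundaries
#' partition \[0, Inf): every thermal time maps to exactly one stage.
#'
#' @param tt Thermal time(s), degC day, >= 0.
#' @param boundaries A `stage_boundaries` object (or list with
#'   `tt_veg_flower` < `tt_flower_grainfill`).
#' @return Factor with levels `vegetative`, `flowering`, `grain_fill`.
#' @export
classify_stage <- function(tt, boundaries) {
  stopifnot(all(tt >= 0),
            boundaries$tt_veg_flower < boundaries$tt_flower_grainfill)
  out <- ifelse(tt <= boundaries$tt_veg_flower, "vegetative",
                ifelse(tt <= boundaries$tt_flower_grainfill, "flowering",
                       "grain_fill"))
  factor(out, levels = c("vegetative", "flowering", "grain_fill"))
}

#' Synthetic trial-mean Zadoks observations
#'
#' Generates noisy trial-mean Zadoks scores along a logistic development
#' curve parameterized directly by its two stage-boundary crossings: the
#' curve passes through Zadoks 50 at `tt50` and Zadoks 70 at `tt70`, rising
#' from near 0 to the Zadoks ceiling of 99. This is the ground-truth curve
#' against which the fit-and-solve recovery of the boundaries is assessed.
#'
#' @param tt50,tt70 Thermal times (degC day) at which the true curve crosses
#'   Zadoks 50 and 70; `0 < tt50 < tt70`.
#' @param n Number of observations (default 30).
#' @param sigma Gaussian observation noise on the score (default 2).
#' @param tt_range Observation window; default spans well past `tt70`.
#' @param seed Random seed (mandatory for reproducibility).
#' @return Data.frame `tt`, `score`, plus attribute `truth`, the noiseless
#'   curve as a function of TT.
#' @export
simulate_zadoks_obs <- function(tt50, tt70, n = 30, sigma = 2,
                                tt_range = c(0, tt70 * 1.4), seed) {
  stopifnot(tt50 > 0, tt70 > tt50, n >= 2, sigma >= 0)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  # logistic Z(tt) = 99 / (1 + exp(-(tt - a)/b)) through (tt50, 50), (tt70, 70)
  q50 <- log(50 / (99 - 50)); q70 <- log(70 / (99 - 70))
  b <- (tt70 - tt50) / (q70 - q50)
  a <- tt50 - q50 * b
  truth <- function(tt) 99 / (1 + exp(-(tt - a) / b))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tt <- sort(stats::runif(n, tt_range[1], tt_range[2]))
  score <- pmin(pmax(truth(tt) + stats::rnorm(n, 0, sigma), 0), 99)
  structure(data.frame(tt = tt, score = score), truth = truth)
}

# Save/restore the global RNG state so seeded generators are pure functions
# of (inputs, seed) without disturbing the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
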