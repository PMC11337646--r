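#' Construct a plot-scene object
#'
#' A `plot_scene` bundles the five co-registered reflectance rasters, the
#' canopy height model, the ground sample distance, and the ROI polygons of
#' one plot on one date. Rasters are plain numeric matrices; polygon
#' coordinates are meters in the plot frame (origin at the plot corner,
#' x along columns, y along rows).
#'
#' @param plot_id Plot identifier.
#' @param date Acquisition date.
#' @param gsd Ground sample distance (m/pixel), > 0.
#' @param bands Named list of 5 matrices: `blue`, `green`, `red`,
#'   `red_edge`, `nir`, reflectance in \[0, 1\].
#' @param chm Canopy height matrix (m, >= 0), same dimensions as the bands.
#' @param roi_permanent Polygon (matrix of x,y vertices) of the permanent,
#'   never-disturbed ROI.
#' @param roi_precise List of polygons, one per cut, each the footprint of
#'   that cut's quadrat; disjoint from the permanent ROI.
#' @return Object of class `plot_scene`.
#' @export
plot_scene <- function(plot_id, date, gsd, bands, chm, roi_permanent,
                       roi_precise = list()) {
  stopifnot(gsd > 0,
            all(c("blue", "green", "red", "red_edge", "nir") %in% names(bands)))
  dims <- dim(chm)
  for (b in bands) stopifnot(identical(dim(b), dims))
  if (any(chm < 0)) stop("chm must be non-negative", call. = FALSE)
  structure(list(plot_id = plot_id, date = date, gsd = gsd, bands = bands,
                 chm = chm, roi_permanent = roi_permanent,
                 roi_precise = roi_precise),
            class = "plot_scene")
}

# reference reflectance spectra (blue, green, red, red_edge, nir)
.spectra <- list(
  plant_green = c(blue = 0.04, green = 0.09, red = 0.05, red_edge = 0.28, nir = 0.48),
  plant_sen   = c(blue = 0.09, green = 0.14, red = 0.18, red_edge = 0.28, nir = 0.32),
  soil        = c(blue = 0.12, green = 0.16, red = 0.22, red_edge = 0.26, nir = 0.30)
)

.rect <- function(x0, x1, y0, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

#' Render a synthetic plot scene
#'
#' Produces a soil/plant two-component mixture raster from a plot's canopy
#' state: each pixel is plant with probability equal to the (local) green
#' cover fraction; plant pixels get Gaussian-jittered heights around the
#' mean canopy height and a plant reflectance spectrum interpolated from
#' green to senesced by the senescence index, soil pixels get height ~ 0
#' and the soil spectrum. A within-plot heterogeneity knob imposes a linear
#' biomass gradient along the plot so the permanent and the per-cut precise
#' ROIs can see genuinely different canopies.
#'
#' The permanent ROI is a fixed rectangle at the plot's near end; each cut's
#' precise ROI is a non-overlapping rectangle further along the plot.
#'
#' @param state One row of [simulate_growth()] output (fields
#'   `green_fraction`, `mean_height`, `senescence`, `plot_id`, `date`).
#' @param gsd Ground sample distance (m/pixel), > 0.
#' @param dims Raster dimensions `c(nrow, ncol)` (default 64 x 64).
#' @param seed Integer seed.
#' @param heterogeneity Relative amplitude of the along-plot biomass
#'   gradient (0 = homogeneous plot).
#' @param n_cuts Number of precise ROIs to lay out (default 5).
#' @param height_cv Relative sd of plant-pixel height jitter (default 0.1).
#' @param reflectance_sd Per-pixel reflectance noise (default 0.008).
#' @param coverage_mode `"binomial"` (default) draws each pixel's class
#'   independently; `"exact"` assigns classes by a seeded stratified
#'   permutation so the realized plant fraction matches the requested one
#'   to within one pixel — the fully noise-off rendering used when strict
#'   monotonicity of extracted traits in true biomass must hold.
#' @return A [plot_scene()]; attribute `roi_biomass_factor` holds the local
#'   biomass multiplier at each ROI (named `permanent`, `cut1`, ...), and
#'   attribute `plant_fraction` the realized plant-pixel fraction.
#' @export
render_scene <- function(state, gsd, dims = c(64, 64), seed,
                         heterogeneity = 0, n_cuts = 5,
                         height_cv = 0.1, reflectance_sd = 0.008,
                         coverage_mode = c("binomial", "exact")) {
  coverage_mode <- match.arg(coverage_mode)
  if (gsd <= 0) stop("gsd must be > 0", call. = FALSE)
  gf <- state$green_fraction; h <- state$mean_height; sen <- state$senescence
  stopifnot(gf >= 0, gf <= 1, h >= 0, sen >= 0, sen <= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  nr <- dims[1]; nc <- dims[2]
  # along-plot gradient on column position, mean one
  xfrac <- (col(matrix(0, nr, nc)) - 0.5) / nc
  grad <- pmax(0, 1 + heterogeneity * (2 * xfrac - 1))
  gf_local <- pmin(gf * grad, 1)
  u <- if (coverage_mode == "binomial") {
    matrix(stats::runif(nr * nc), nr, nc)
  } else {
    # low-discrepancy dither (R2 additive recurrence): every subregion of
    # the raster realizes the requested fraction to O(log n / n)
    (outer(seq_len(nr) * 0.7548776662, seq_len(nc) * 0.5698402910, "+")) %% 1
  }
  plant <- u < gf_local
  # heights
  hsd <- height_cv * h
  chm <- matrix(0, nr, nc)
  nh <- sum(plant)
  if (nh > 0) {
    chm[plant] <- pmax(0, stats::rnorm(nh, h, hsd)) * grad[plant]
  }
  chm[!plant] <- abs(stats::rnorm(nr * nc - nh, 0, 0.003))
  # reflectance
  plant_spec <- (1 - sen) * .spectra$plant_green + sen * .spectra$plant_sen
  bands <- list()
  for (b in c("blue", "green", "red", "red_edge", "nir")) {
    m <- matrix(.spectra$soil[[b]], nr, nc)
    m[plant] <- plant_spec[[b]]
    m <- m + stats::rnorm(nr * nc, 0, reflectance_sd)
    bands[[b]] <- matrix(pmin(pmax(m, 0.001), 1), nr, nc)
  }
  # ROI layout in meters: permanent at the near end, precise slots beyond
  L <- nc * gsd; W <- nr * gsd
  roi_perm <- .rect(0.04 * L, 0.30 * L, 0.1 * W, 0.9 * W)
  slot_w <- 0.62 / n_cuts
  roi_prec <- lapply(seq_len(n_cuts), function(k) {
    x0 <- (0.34 + (k - 1) * slot_w) * L
    .rect(x0, x0 + (slot_w - 0.015) * L, 0.1 * W, 0.9 * W)
  })
  sc <- plot_scene(state$plot_id, state$date, gsd, bands, chm,
                   roi_perm, roi_prec)
  grad_at <- function(poly) {
    xm <- mean(range(poly[, "x"])) / L
    max(0, 1 + heterogeneity * (2 * xm - 1))
  }
  fac <- c(permanent = grad_at(roi_perm),
           stats::setNames(vapply(roi_prec, grad_at, numeric(1)),
                           paste0("cut", seq_len(n_cuts))))
  attr(sc, "roi_biomass_factor") <- fac
  attr(sc, "plant_fraction") <- nh / (nr * nc)
  sc
}
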