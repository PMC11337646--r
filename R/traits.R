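#' Otsu threshold of an index raster
#'
#' Histogram thresholding that maximizes the between-class variance over a
#' fixed-bin histogram of the supplied values, used here to separate green
#' canopy from soil background on the OSAVI channel.
#'
#' The candidate cut points are the `n_bins - 1` interior bin edges of an
#' equal-width histogram spanning the value range; the returned threshold is
#' the edge with maximal between-class variance (ties resolved to the lowest
#' edge). Pixels strictly above the threshold are classed as canopy.
#'
#' @param values Numeric vector or matrix of index values (e.g. OSAVI over an
#'   ROI). `NA`s are dropped.
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold, in the units of `values`.
#' @seealso [canopy_mask()]
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  if (length(v) < 2 || length(unique(v)) < 2) {
    stop("otsu_threshold needs at least 2 distinct finite values", call. = FALSE)
  }
  rng <- range(v)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(
    pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), n_bins),
    nbins = n_bins
  )
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  w <- counts / sum(counts)
  # cumulative class probability and mean below each interior edge
  w0 <- cumsum(w)[-n_bins]
  mu0 <- cumsum(w * mids)[-n_bins]
  mu_t <- sum(w * mids)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, n_bins - 1)
  sigma_b[valid] <- (mu_t * w0[valid] - mu0[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(sigma_b)
  edges[k + 1]
}

#' Canopy mask from OSAVI and Otsu's method
#'
#' Computes OSAVI over the ROI pixels of a scene, finds the Otsu threshold,
#' and returns the binary canopy mask (`OSAVI > threshold`) together with the
#' canopy coverage fraction. A degenerate (constant) OSAVI field yields
#' coverage 0 with an `NA` threshold, matching the reading that a uniform
#' field contains no separable canopy class.
#'
#' A separability gate guards against thresholding pure noise: when the
#' between-class variance at the Otsu threshold explains less than
#' `min_separability` of the total OSAVI variance, the field is treated as
#' single-class (bare soil or closed canopy cannot be told apart by OSAVI
#' alone) and coverage is 0. A well-mixed soil/plant scene scores ~0.9 on
#' this ratio; unimodal sensor noise scores ~0.64.
#'
#' @param scene A [plot_scene()] object.
#' @param roi_idx Logical matrix marking ROI pixels (see [rasterize_roi()]).
#' @param min_separability Minimum between/total variance ratio to accept
#'   the canopy/soil split (default 0.75).
#' @return List with `mask` (logical matrix, `NA` outside the ROI),
#'   `otsu_threshold`, `separability`, and `coverage`
#'   (masked pixels / ROI pixels).
#' @export
canopy_mask <- function(scene, roi_idx, min_separability = 0.75) {
  osavi <- compute_vi(scene$bands, "OSAVI")
  vals <- osavi[roi_idx]
  n_roi <- sum(roi_idx)
  if (n_roi == 0) stop("ROI covers no pixels", call. = FALSE)
  mask <- matrix(NA, nrow(osavi), ncol(osavi))
  if (length(unique(vals[is.finite(vals)])) < 2) {
    mask[roi_idx] <- FALSE
    return(list(mask = mask, otsu_threshold = NA_real_, coverage = 0))
  }
  thr <- otsu_threshold(vals)
  v <- vals[is.finite(vals)]
  hi <- v > thr
  eta <- if (all(hi) || !any(hi)) 0 else {
    w1 <- mean(hi)
    (1 - w1) * w1 * (mean(v[hi]) - mean(v[!hi]))^2 / mean((v - mean(v))^2)
  }
  if (eta < min_separability) {
    mask[roi_idx] <- FALSE
    return(list(mask = mask, otsu_threshold = NA_real_,
                separability = eta, coverage = 0))
  }
  mask[roi_idx] <- !is.na(osavi[roi_idx]) & osavi[roi_idx] > thr
  list(mask = mask, otsu_threshold = thr, separability = eta,
       coverage = sum(mask[roi_idx]) / n_roi)
}

#' Rasterize an ROI polygon onto the scene grid
#'
#' Pixel inclusion rule: a pixel belongs to the ROI iff its center lies
#' inside the polygon. Pixel (i, j) has its center at
#' `x = (j - 0.5) * gsd`, `y = (i - 0.5) * gsd` in plot coordinates (meters,
#' origin at the plot corner).
#'
#' @param poly Two-column matrix of polygon vertex coordinates (x, y) in
#'   meters.
#' @param dims Raster dimensions `c(nrow, ncol)`.
#' @param gsd Ground sample distance (m/pixel).
#' @return Logical matrix of `dims` marking ROI pixels.
#' @export
rasterize_roi <- function(poly, dims, gsd) {
  stopifnot(gsd > 0, length(dims) == 2)
  poly <- as.matrix(poly)
  cx <- (seq_len(dims[2]) - 0.5) * gsd
  cy <- (seq_len(dims[1]) - 0.5) * gsd
  pts <- cbind(rep(cx, each = dims[1]), rep(cy, times = dims[2]))
  inside <- mgcv::in.out(rbind(poly, poly[1, ]), pts)
  matrix(inside, dims[1], dims[2])
}

#' Spectral traits over an ROI
#'
#' For each of the 33 registry indices, the median over all ROI pixels
#' (unmasked) and the median over canopy-masked pixels only. Masked medians
#' are `NA` when coverage is 0, and are flagged low-support when fewer than
#' `min_mask_pixels` pixels survive the mask (a median of a handful of
#' pixels is unstable; the value is still reported).
#'
#' @param scene A [plot_scene()] object.
#' @param roi_idx Logical ROI membership matrix.
#' @param mask Result of [canopy_mask()].
#' @param registry VI registry, default [vi_registry()].
#' @param min_mask_pixels Low-support flag threshold (default 10).
#' @return Named numeric vector of 66 values (`<VI>_median`,
#'   `<VI>_median_masked`), with attribute `low_support` (logical).
#' @export
spectral_traits <- function(scene, roi_idx, mask, registry = vi_registry(),
                            min_mask_pixels = 10) {
  if (sum(roi_idx) == 0) stop("empty ROI intersection", call. = FALSE)
  masked_idx <- roi_idx & !is.na(mask$mask) & mask$mask
  n_masked <- sum(masked_idx)
  unmasked <- masked <- numeric(0)
  for (nm in names(registry)) {
    v <- compute_vi(scene$bands, nm, registry)
    unmasked[paste0(nm, "_median")] <- stats::median(v[roi_idx], na.rm = TRUE)
    masked[paste0(nm, "_median_masked")] <-
      if (n_masked == 0) NA_real_ else stats::median(v[masked_idx], na.rm = TRUE)
  }
  out <- c(unmasked, masked)
  attr(out, "low_support") <- n_masked > 0 && n_masked < min_mask_pixels
  out
}

#' Geometric traits over an ROI
#'
#' Canopy-height percentiles (p50, p75, p95, p98, meters), the ground area
#' below the p25/p50/p75 height percentiles (strict inequality, m^2), canopy
#' volume (sum of pixel heights x pixel area / ROI area, i.e. mean height
#' when the ROI area equals pixel count x gsd^2), and canopy coverage from
#' the OSAVI-Otsu mask. Percentiles use linear interpolation between order
#' statistics. The height standard deviation is available behind
#' `include_sd` but is not part of the 9-trait contract.
#'
#' @param chm Canopy height matrix (m).
#' @param roi_idx Logical ROI membership matrix.
#' @param mask Result of [canopy_mask()] (supplies coverage).
#' @param gsd Ground sample distance (m/pixel).
#' @param as_fraction Report area-below traits as fractions of ROI area
#'   instead of m^2 (default `FALSE`).
#' @param include_sd Also report the height standard deviation (default
#'   `FALSE`; off to preserve the 9-column contract).
#' @return Named numeric vector of 9 values (10 with `include_sd`).
#' @export
geometric_traits <- function(chm, roi_idx, mask, gsd,
                             as_fraction = FALSE, include_sd = FALSE) {
  stopifnot(gsd > 0)
  h <- chm[roi_idx]
  if (length(h) == 0) stop("empty ROI intersection", call. = FALSE)
  pct <- stats::quantile(h, c(0.25, 0.50, 0.75, 0.95, 0.98),
                         names = FALSE, type = 7)
  px_area <- gsd^2
  roi_area <- length(h) * px_area
  area_below <- function(p) {
    a <- sum(h < p) * px_area
    if (as_fraction) a / roi_area else a
  }
  out <- c(
    height_p50     = pct[2],
    height_p75     = pct[3],
    height_p95     = pct[4],
    height_p98     = pct[5],
    area_below_p25 = area_below(pct[1]),
    area_below_p50 = area_below(pct[2]),
    area_below_p75 = area_below(pct[3]),
    canopy_volume  = sum(h) * px_area / roi_area,
    coverage       = mask$coverage
  )
  if (include_sd) out <- c(out, height_sd = stats::sd(h))
  out
}

#' Extract the full trait record for one ROI of a scene
#'
#' Orchestrates OSAVI -> Otsu -> canopy mask -> 66 spectral + 9 geometric
#' traits for either the permanent ROI or the precise (per-cut) ROI of a
#' scene: one record per plot x date x ROI type.
#'
#' @param scene A [plot_scene()] object.
#' @param roi_type `"permanent"` or `"precise"`.
#' @param cut Cut number selecting the precise ROI (required when
#'   `roi_type = "precise"` and the scene holds several).
#' @inheritParams geometric_traits
#' @return One-row data.frame: `plot_id`, `date`, `roi_type`, then the 9
#'   geometric and 66 spectral trait columns (75 trait fields).
#' @export
extract_traits <- function(scene, roi_type = c("permanent", "precise"),
                           cut = 1L, as_fraction = FALSE) {
  roi_type <- match.arg(roi_type)
  poly <- if (roi_type == "permanent") {
    scene$roi_permanent
  } else {
    if (cut > length(scene$roi_precise)) {
      stop("scene has no precise ROI for cut ", cut, call. = FALSE)
    }
    scene$roi_precise[[cut]]
  }
  dims <- dim(scene$chm)
  roi_idx <- rasterize_roi(poly, dims, scene$gsd)
  if (sum(roi_idx) == 0) stop("ROI covers no pixels", call. = FALSE)
  mk <- canopy_mask(scene, roi_idx)
  sp <- spectral_traits(scene, roi_idx, mk)
  ge <- geometric_traits(scene$chm, roi_idx, mk, scene$gsd,
                         as_fraction = as_fraction)
  out <- data.frame(plot_id = scene$plot_id, date = as.character(scene$date),
                    roi_type = roi_type, t(ge), t(unclass(sp)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "otsu_threshold") <- mk$otsu_threshold
  attr(out, "low_support") <- attr(sp, "low_support")
  out
}

#' Names of the trait columns in their documented order
#'
#' 9 geometric traits, then 33 unmasked VI medians, then 33 masked VI
#' medians (75 fields).
#'
#' @return Character vector of length 75.
#' @export
trait_names <- function() {
  geo <- c("height_p50", "height_p75", "height_p95", "height_p98",
           "area_below_p25", "area_below_p50", "area_below_p75",
           "canopy_volume", "coverage")
  vis <- names(vi_registry())
  c(geo, paste0(vis, "_median"), paste0(vis, "_median_masked"))
}
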