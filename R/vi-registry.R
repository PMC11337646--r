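#' Vegetation-index registry
#'
#' The registry holds the 33 named vegetation indices used for spectral trait
#' extraction. Each entry is a function of the five band reflectances
#' (`blue`, `green`, `red`, `red_edge`, `nir`, all in \[0, 1\]) applied
#' pixel-wise. Only indices whose denominator cannot vanish on strictly
#' positive reflectances are included, so every index is finite wherever the
#' bands are positive; this is what makes median aggregation over an ROI
#' well-defined without ad hoc pixel dropping.
#'
#' OSAVI is the index used for canopy/soil segmentation (see
#' [otsu_threshold()]); GSAVI, the soil-adjusted green analogue, is also
#' present.
#'
#' @return Named list of 33 functions, each with signature
#'   `function(blue, green, red, red_edge, nir)`.
#' @examples
#' reg <- vi_registry()
#' names(reg)
#' reg$NDVI(0.04, 0.08, 0.05, 0.25, 0.45)
#' @export
vi_registry <- function() {
  list(
    # normalized differences
    NDVI   = function(blue, green, red, red_edge, nir) (nir - red) / (nir + red),
    GNDVI  = function(blue, green, red, red_edge, nir) (nir - green) / (nir + green),
    NDRE   = function(blue, green, red, red_edge, nir) (nir - red_edge) / (nir + red_edge),
    NGRDI  = function(blue, green, red, red_edge, nir) (green - red) / (green + red),
    NPCI   = function(blue, green, red, red_edge, nir) (red - blue) / (red + blue),
    # soil-adjusted family
    OSAVI  = function(blue, green, red, red_edge, nir) 1.16 * (nir - red) / (nir + red + 0.16),
    GOSAVI = function(blue, green, red, red_edge, nir) (nir - green) / (nir + green + 0.16),
    SAVI   = function(blue, green, red, red_edge, nir) 1.5 * (nir - red) / (nir + red + 0.5),
    GSAVI  = function(blue, green, red, red_edge, nir) 1.5 * (nir - green) / (nir + green + 0.5),
    MSAVI  = function(blue, green, red, red_edge, nir)
      (2 * nir + 1 - sqrt((2 * nir + 1)^2 - 8 * (nir - red))) / 2,
    EVI2   = function(blue, green, red, red_edge, nir)
      2.5 * (nir - red) / (nir + 2.4 * red + 1),
    # ratios and chlorophyll indices
    SR     = function(blue, green, red, red_edge, nir) nir / red,
    GCI    = function(blue, green, red, red_edge, nir) nir / green - 1,
    RECI   = function(blue, green, red, red_edge, nir) nir / red_edge - 1,
    RGR    = function(blue, green, red, red_edge, nir) red / green,
    CVI    = function(blue, green, red, red_edge, nir) nir * red / green^2,
    MSR    = function(blue, green, red, red_edge, nir)
      (nir / red - 1) / sqrt(nir / red + 1),
    WDRVI  = function(blue, green, red, red_edge, nir)
      (0.2 * nir - red) / (0.2 * nir + red),
    # difference / renormalized
    DVI    = function(blue, green, red, red_edge, nir) nir - red,
    GDVI   = function(blue, green, red, red_edge, nir) nir - green,
    RDVI   = function(blue, green, red, red_edge, nir)
      (nir - red) / sqrt(nir + red),
    NLI    = function(blue, green, red, red_edge, nir)
      (nir^2 - red) / (nir^2 + red),
    MNLI   = function(blue, green, red, red_edge, nir)
      1.5 * (nir^2 - red) / (nir^2 + red + 0.5),
    # triangular / chlorophyll absorption
    TVI    = function(blue, green, red, red_edge, nir)
      0.5 * (120 * (nir - green) - 200 * (red - green)),
    MTVI1  = function(blue, green, red, red_edge, nir)
      1.2 * (1.2 * (nir - green) - 2.5 * (red - green)),
    MCARI  = function(blue, green, red, red_edge, nir)
      ((red_edge - red) - 0.2 * (red_edge - green)) * (red_edge / red),
    TCARI  = function(blue, green, red, red_edge, nir)
      3 * ((red_edge - red) - 0.2 * (red_edge - green) * (red_edge / red)),
    PSRI   = function(blue, green, red, red_edge, nir) (red - green) / red_edge,
    ARI    = function(blue, green, red, red_edge, nir) 1 / green - 1 / red_edge,
    # visible-band (RGB) indices
    ExG    = function(blue, green, red, red_edge, nir) 2 * green - red - blue,
    ExGR   = function(blue, green, red, red_edge, nir) 3 * green - 2.4 * red - blue,
    GLI    = function(blue, green, red, red_edge, nir)
      (2 * green - red - blue) / (2 * green + red + blue),
    MGRVI  = function(blue, green, red, red_edge, nir)
      (green^2 - red^2) / (green^2 + red^2)
  )
}

#' Compute a vegetation index raster
#'
#' Applies a registry formula pixel-wise to the five co-registered band
#' rasters of a scene. Non-finite pixels (possible only when a band is zero
#' or negative, e.g. shadow-clipped reflectance) are returned as `NA` so that
#' downstream medians can exclude them.
#'
#' @param bands Named list of five equal-dimension matrices: `blue`, `green`,
#'   `red`, `red_edge`, `nir`.
#' @param name Index name; must be a key of [vi_registry()].
#' @param registry Registry to look the name up in, by default [vi_registry()].
#' @return Matrix of index values with the band dimensions.
#' @export
compute_vi <- function(bands, name, registry = vi_registry()) {
  if (!name %in% names(registry)) {
    stop("unknown vegetation index '", name, "'; registry has: ",
         paste(names(registry), collapse = ", "), call. = FALSE)
  }
  stopifnot(all(c("blue", "green", "red", "red_edge", "nir") %in% names(bands)))
  dims <- dim(bands$blue)
  for (b in c("green", "red", "red_edge", "nir")) {
    if (!identical(dim(bands[[b]]), dims)) {
      stop("band '", b, "' is not co-registered with 'blue'", call. = FALSE)
    }
  }
  v <- registry[[name]](bands$blue, bands$green, bands$red, bands$red_edge, bands$nir)
  v[!is.finite(v)] <- NA_real_
  if (!is.null(dims)) dim(v) <- dims
  v
}
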