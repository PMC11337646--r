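#' Write a plot scene to disk
#'
#' The five reflectance bands go to one multi-band float TIFF (band order
#' blue, green, red, red_edge, nir), the canopy height model to a separate
#' single-band TIFF, the ROIs to a GeoJSON file with polygon coordinates in
#' the plot frame (meters), and the georeferencing (gsd, plot id, date) to a
#' JSON sidecar. The reverse of [read_scene()].
#'
#' @param scene A [plot_scene()].
#' @param dir Output directory (created if missing).
#' @param stem File stem; defaults to `<plot_id>_<date>`.
#' @return Invisibly, the paths written.
#' @export
write_scene <- function(scene, dir, stem = NULL) {
  if (is.null(stem)) stem <- paste0(scene$plot_id, "_", scene$date)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  band_order <- c("blue", "green", "red", "red_edge", "nir")
  p_bands <- file.path(dir, paste0(stem, "_bands.tif"))
  p_chm <- file.path(dir, paste0(stem, "_chm.tif"))
  p_roi <- file.path(dir, paste0(stem, "_roi.geojson"))
  p_meta <- file.path(dir, paste0(stem, "_meta.json"))
  tiff::writeTIFF(lapply(band_order, function(b) scene$bands[[b]]),
                  p_bands, bits.per.sample = 32L, reduce = FALSE)
  # heights can exceed 1; store in a [0,1]-scaled TIFF with the scale in meta
  h_scale <- max(scene$chm, 1e-9)
  tiff::writeTIFF(scene$chm / h_scale, p_chm, bits.per.sample = 32L)
  feat <- function(poly, props) {
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(rbind(poly, poly[1, , drop = FALSE]))))
  }
  feats <- c(list(feat(scene$roi_permanent, list(roi_type = "permanent"))),
             lapply(seq_along(scene$roi_precise), function(k) {
               feat(scene$roi_precise[[k]],
                    list(roi_type = "precise", cut = k))
             }))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       p_roi, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(plot_id = scene$plot_id,
                            date = as.character(scene$date),
                            gsd = scene$gsd, chm_scale = h_scale,
                            band_order = band_order),
                       p_meta, auto_unbox = TRUE, digits = NA)
  invisible(c(bands = p_bands, chm = p_chm, roi = p_roi, meta = p_meta))
}

#' Read a plot scene from disk
#'
#' @param dir Directory holding the files written by [write_scene()].
#' @param stem File stem (`<plot_id>_<date>`).
#' @return A [plot_scene()].
#' @export
read_scene <- function(dir, stem) {
  meta <- jsonlite::read_json(file.path(dir, paste0(stem, "_meta.json")),
                              simplifyVector = TRUE)
  raw <- tiff::readTIFF(file.path(dir, paste0(stem, "_bands.tif")), all = TRUE)
  bands <- stats::setNames(raw, meta$band_order)
  chm <- tiff::readTIFF(file.path(dir, paste0(stem, "_chm.tif"))) * meta$chm_scale
  gj <- jsonlite::read_json(file.path(dir, paste0(stem, "_roi.geojson")))
  polys <- lapply(gj$features, function(f) {
    m <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                               function(p) unlist(p)))
    colnames(m) <- c("x", "y")
    m[-nrow(m), , drop = FALSE]   # drop closing vertex
  })
  types <- vapply(gj$features, function(f) f$properties$roi_type, character(1))
  prec <- polys[types == "precise"]
  cuts <- vapply(gj$features[types == "precise"],
                 function(f) f$properties$cut, numeric(1))
  plot_scene(meta$plot_id, as.Date(meta$date), meta$gsd, bands, chm,
             roi_permanent = polys[[which(types == "permanent")[1]]],
             roi_precise = prec[order(cuts)])
}

#' Read / write the tabular interchange formats
#'
#' Plain CSV with documented headers: weather
#' (`date,tmin,tmax,rain,irrigation`), quadrat cuts
#' (`plot_id,date,cut_number,fw_quad,fw_sub,dw_sub,quad_area`), Zadoks
#' observations (`date,score` or `tt,score`), trait tables (one row per
#' plot x date x ROI type, columns in [trait_names()] order). Dates are
#' ISO-8601.
#'
#' @param path CSV path.
#' @return Data.frame.
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_weather_csv <- function(path) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("date", "tmin", "tmax") %in% names(w)))
  w$date <- as.Date(w$date)
  w
}

#' @rdname table_io
#' @export
read_cuts_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("plot_id", "date", "fw_quad", "fw_sub", "dw_sub",
                  "quad_area") %in% names(x)))
  x$date <- as.Date(x$date)
  x
}

#' @rdname table_io
#' @export
read_zadoks_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot("score" %in% names(x))
  if ("date" %in% names(x)) x$date <- as.Date(x$date)
  x
}

#' @rdname table_io
#' @param x Data.frame to write.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
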