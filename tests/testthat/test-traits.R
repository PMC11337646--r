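test_that("otsu threshold separates a bimodal raster and matches brute force", {
  v <- c(rep(0.1, 50), rep(0.7, 50))
  thr <- otsu_threshold(v)
  expect_gt(thr, 0.1)
  expect_lt(thr, 0.7)
  # exhaustive-search oracle equivalence on random rasters up to 1e4 pixels
  set.seed(11)
  for (i in 1:20) {
    n <- sample(c(64, 500, 2500, 10000), 1)
    x <- c(rnorm(n / 2, 0.15, 0.05), rnorm(n / 2, 0.6, 0.08))
    expect_equal(otsu_threshold(x), otsu_bruteforce(x), tolerance = 1e-12)
  }
})

test_that("otsu threshold is translation-equivariant at fixed binning", {
  set.seed(3)
  x <- c(rnorm(300, 0.2, 0.05), rnorm(300, 0.7, 0.05))
  expect_equal(otsu_threshold(x + 2.5), otsu_threshold(x) + 2.5,
               tolerance = 1e-9)
})

test_that("otsu rejects degenerate input", {
  expect_error(otsu_threshold(rep(1, 10)), "distinct")
  expect_error(otsu_threshold(0.5), "distinct")
})

test_that("geometric traits on a uniform canopy are degenerate as expected", {
  sc <- make_constant_scene(height = 0.42)
  roi <- rasterize_roi(sc$roi_permanent, dim(sc$chm), sc$gsd)
  mk <- canopy_mask(sc, roi)  # constant OSAVI -> coverage 0
  g <- geometric_traits(sc$chm, roi, mk, sc$gsd)
  expect_equal(unname(g[c("height_p50", "height_p75", "height_p95",
                          "height_p98")]), rep(0.42, 4))
  expect_equal(unname(g["canopy_volume"]), 0.42)   # volume = mean height
  expect_equal(unname(g[c("area_below_p25", "area_below_p50",
                          "area_below_p75")]), rep(0, 3))  # strict inequality
  expect_equal(unname(g["coverage"]), 0)
})

test_that("geometric traits match direct pixel enumeration on a toy chm", {
  sc <- make_constant_scene(nr = 10, nc = 10, gsd = 0.1)
  h <- matrix(seq(0.01, 1, by = 0.01), 10, 10)   # heights 1..100 cm
  sc$chm <- h
  roi <- rasterize_roi(sc$roi_permanent, dim(h), sc$gsd)
  expect_true(all(roi))
  mk <- list(mask = roi, coverage = 1, otsu_threshold = 0)
  g <- geometric_traits(h, roi, mk, sc$gsd)
  hv <- as.numeric(h)
  for (p in c(50, 75, 95, 98)) {
    expect_equal(unname(g[paste0("height_p", p)]),
                 unname(quantile(hv, p / 100, type = 7)), tolerance = 1e-12)
  }
  for (p in c(25, 50, 75)) {
    expect_equal(unname(g[paste0("area_below_p", p)]),
                 sum(hv < quantile(hv, p / 100, type = 7)) * 0.1^2,
                 tolerance = 1e-12)
  }
  expect_equal(unname(g["canopy_volume"]), mean(hv), tolerance = 1e-12)
  # fraction option divides areas by ROI area
  gf <- geometric_traits(h, roi, mk, sc$gsd, as_fraction = TRUE)
  expect_equal(unname(gf["area_below_p50"]),
               unname(g["area_below_p50"]) / (100 * 0.1^2), tolerance = 1e-12)
  # opt-in height sd gives a 10th field
  gs <- geometric_traits(h, roi, mk, sc$gsd, include_sd = TRUE)
  expect_length(gs, 10)
  expect_equal(unname(gs["height_sd"]), sd(hv))
})

test_that("height percentiles are monotone on arbitrary rasters", {
  set.seed(5)
  for (i in 1:25) {
    sc <- make_constant_scene(nr = 8, nc = 8, gsd = 0.05)
    sc$chm <- matrix(rexp(64, 3), 8, 8)
    roi <- rasterize_roi(sc$roi_permanent, dim(sc$chm), sc$gsd)
    mk <- list(mask = roi, coverage = 1, otsu_threshold = 0)
    g <- geometric_traits(sc$chm, roi, mk, sc$gsd)
    expect_true(g["height_p50"] <= g["height_p75"] &&
                g["height_p75"] <= g["height_p95"] &&
                g["height_p95"] <= g["height_p98"])
  }
})

test_that("spectral traits: constant field makes masked equal unmasked", {
  sc <- make_constant_scene()
  roi <- rasterize_roi(sc$roi_permanent, dim(sc$chm), sc$gsd)
  mk <- list(mask = roi, coverage = 1, otsu_threshold = -Inf)
  sp <- spectral_traits(sc, roi, mk)
  expect_length(sp, 66)
  for (nm in names(vi_registry())) {
    expect_equal(unname(sp[paste0(nm, "_median")]),
                 unname(sp[paste0(nm, "_median_masked")]),
                 info = nm)
  }
})

test_that("soil pixels depress the unmasked NDVI median on a mixed scene", {
  # left half plant spectrum, right half soil spectrum
  sc <- make_constant_scene(nr = 16, nc = 16)
  soil <- c(blue = 0.12, green = 0.16, red = 0.22, red_edge = 0.26, nir = 0.30)
  for (b in names(soil)) sc$bands[[b]][, 9:16] <- soil[[b]]
  sc$chm[, 9:16] <- 0
  roi <- rasterize_roi(sc$roi_permanent, dim(sc$chm), sc$gsd)
  mk <- canopy_mask(sc, roi)
  expect_gt(mk$coverage, 0.4); expect_lt(mk$coverage, 0.6)
  sp <- spectral_traits(sc, roi, mk)
  expect_gt(sp["NDVI_median_masked"], sp["NDVI_median"])
})

test_that("extract_traits yields one 75-field record per scene and ROI type", {
  sc <- render_scene(make_state(0.5, 0.4), gsd = 0.02, dims = c(48, 48),
                     seed = 9)
  for (rt in c("permanent", "precise")) {
    rec <- extract_traits(sc, rt, cut = 1)
    expect_equal(nrow(rec), 1)
    expect_setequal(setdiff(names(rec), c("plot_id", "date", "roi_type")),
                    trait_names())
    expect_length(trait_names(), 75)
  }
})

test_that("bare-soil and closed-canopy scenes hit the coverage extremes", {
  bare <- render_scene(make_state(0, 0), gsd = 0.02, dims = c(48, 48),
                       seed = 2)
  rec <- extract_traits(bare, "permanent")
  expect_lt(rec$coverage, 0.1)
  if (rec$coverage == 0) expect_true(is.na(rec$NDVI_median_masked))
  full <- make_constant_scene(nr = 32, nc = 32, height = 0.6)
  rec2 <- extract_traits(full, "permanent")
  expect_equal(rec2$coverage, 0)  # constant OSAVI: no separable canopy class
})

test_that("precise ROIs are disjoint from the permanent ROI", {
  sc <- render_scene(make_state(0.5, 0.4), gsd = 0.02, dims = c(64, 64),
                     seed = 4, n_cuts = 5)
  dims <- dim(sc$chm)
  perm <- rasterize_roi(sc$roi_permanent, dims, sc$gsd)
  for (k in seq_along(sc$roi_precise)) {
    prec <- rasterize_roi(sc$roi_precise[[k]], dims, sc$gsd)
    expect_equal(sum(perm & prec), 0, info = paste("cut", k))
    for (j in seq_len(k - 1)) {
      other <- rasterize_roi(sc$roi_precise[[j]], dims, sc$gsd)
      expect_equal(sum(other & prec), 0)
    }
  }
})

test_that("trait extraction runs in under a second per ROI", {
  sc <- render_scene(make_state(0.5, 0.4), gsd = 0.02, dims = c(64, 64),
                     seed = 1)
  t0 <- Sys.time()
  extract_traits(sc, "permanent")
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1)
})
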