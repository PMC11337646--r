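test_that("quadrat arithmetic: DW_AGB from the raw weights", {
  expect_equal(compute_dw_agb(list(fw_quad = 1000, fw_sub = 200, dw_sub = 50,
                                   quad_area = 0.5)), 500)
  # dry:fresh ratio of 1 collapses to fresh weight per area
  expect_equal(compute_dw_agb(list(fw_quad = 800, fw_sub = 100, dw_sub = 100,
                                   quad_area = 2)), 400)
  # homogeneity: linear in fw_quad, inverse in area
  base <- list(fw_quad = 600, fw_sub = 150, dw_sub = 60, quad_area = 0.4)
  d0 <- compute_dw_agb(base)
  base2 <- base; base2$fw_quad <- 2 * base$fw_quad
  expect_equal(compute_dw_agb(base2), 2 * d0)
  base3 <- base; base3$quad_area <- 2 * base$quad_area
  expect_equal(compute_dw_agb(base3), d0 / 2)
})

test_that("quadrat records with impossible weights are rejected", {
  expect_error(compute_dw_agb(list(fw_quad = 10, fw_sub = 0, dw_sub = 0,
                                   quad_area = 1)), "undefined")
  expect_error(compute_dw_agb(list(fw_quad = 10, fw_sub = 5, dw_sub = 6,
                                   quad_area = 1)), "exceeds")
  expect_error(compute_dw_agb(list(fw_quad = 10, fw_sub = 5, dw_sub = 2,
                                   quad_area = 0)), "quad_area")
})

test_that("thermal time accumulates mean temperature above base", {
  w <- data.frame(date = seq(as.Date("2021-05-01"), by = "day", length.out = 12),
                  tmin = 10, tmax = 20)
  tts <- cumulative_thermal_time(w, "2021-05-01", base_temp = 0)
  expect_equal(tts$tt[1], 15)              # (10+20)/2
  expect_equal(tts$tt[10], 150)            # linear accumulation
  expect_true(all(diff(tts$tt) >= 0))
  # day below base contributes nothing
  w2 <- w; w2$tmin[3] <- -10; w2$tmax[3] <- 2
  tts2 <- cumulative_thermal_time(w2, "2021-05-01", base_temp = 5)
  expect_equal(tts2$tt[3] - tts2$tt[2], 0)
  expect_error(cumulative_thermal_time(w, "2021-04-01"), "coverage")
  expect_error(tt_at_date(tts, "2022-01-01"), "coverage")
})

test_that("phenology spline interpolates a noiseless cubic and flat signals", {
  tt <- seq(100, 2000, length.out = 25)
  cub <- 5 + 15 * (tt / 1000) + 5 * (tt / 1000)^2 + 2 * (tt / 1000)^3
  m <- fit_phenology_model(data.frame(tt = tt, score = cub))
  expect_lt(max(abs(predict(m, tt) - cub)), 0.1)
  flat <- fit_phenology_model(data.frame(tt = tt, score = rep(40, 25)))
  expect_equal(unname(predict(flat, tt)), rep(40, 25), tolerance = 1e-8)
})

test_that("phenology spline smooths noise below the observation sigma", {
  errs <- sapply(1:10, function(s) {
    z <- simulate_zadoks_obs(1189, 1523, n = 30, sigma = 2, seed = s)
    truth <- attr(z, "truth")
    m <- fit_phenology_model(z)
    grid <- seq(min(z$tt), max(z$tt), length.out = 200)
    sqrt(mean((predict(m, grid) - pmin(truth(grid), 99))^2))
  })
  expect_lt(median(errs), 2)
})

test_that("too few distinct observations fail the spline fit", {
  expect_error(fit_phenology_model(data.frame(tt = 1:8 * 100, score = 1:8)),
               "distinct")
})

test_that("stage boundaries are solved at the fitted curve's crossings", {
  # noiseless curve crossing 50 at 1200: recovered to the solver tolerance
  z <- simulate_zadoks_obs(1200, 1550, n = 40, sigma = 0, seed = 1)
  m <- fit_phenology_model(z)
  b <- solve_stage_boundaries(m)
  expect_lt(abs(predict(m, b$tt_veg_flower) - 50), 0.2)
  expect_lt(abs(predict(m, b$tt_flower_grainfill) - 70), 0.2)
  expect_equal(b$tt_veg_flower, 1200, tolerance = 0.02)
  expect_true(b$tt_veg_flower < b$tt_flower_grainfill)
  # a curve that never reaches 70 is unresolvable
  z2 <- simulate_zadoks_obs(1200, 1550, n = 40, sigma = 0, seed = 1,
                            tt_range = c(0, 1300))
  m2 <- fit_phenology_model(z2)
  expect_error(solve_stage_boundaries(m2), "never crosses")
})

test_that("boundary recovery under noise: median error below 3 percent", {
  err <- t(sapply(1:20, function(s) {
    z <- simulate_zadoks_obs(1189, 1523, n = 30, sigma = 2, seed = s)
    b <- solve_stage_boundaries(fit_phenology_model(z))
    c(abs(b$tt_veg_flower - 1189) / 1189,
      abs(b$tt_flower_grainfill - 1523) / 1523)
  }))
  expect_lt(median(err[, 1]), 0.03)
  expect_lt(median(err[, 2]), 0.03)
})

test_that("stage classification partitions thermal time with inclusive bounds", {
  b <- structure(list(tt_veg_flower = 1189, tt_flower_grainfill = 1523),
                 class = "stage_boundaries")
  expect_equal(as.character(classify_stage(1000, b)), "vegetative")
  expect_equal(as.character(classify_stage(1189, b)), "vegetative")
  expect_equal(as.character(classify_stage(1190, b)), "flowering")
  expect_equal(as.character(classify_stage(1523, b)), "flowering")
  expect_equal(as.character(classify_stage(1600, b)), "grain_fill")
  # exactly one stage for any tt
  tt <- seq(0, 2500, by = 7)
  st <- classify_stage(tt, b)
  expect_false(anyNA(st))
  expect_equal(length(st), length(tt))
})
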