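test_that("planted variance components are recovered with replication", {
  v_g_hat <- sapply(1:20, function(s) {
    d <- make_trial_values(n_geno = 30, n_reps = 3, v_g = 4, v_r = 1, seed = s)
    fit_spatial_model(d)$v_g
  })
  expect_lt(abs(median(v_g_hat) - 4) / 4, 0.3)
})

test_that("null genotypic signal shrinks V_G and ED_g toward zero", {
  # REML variance estimates under a true zero are a half-null mixture, so the
  # right check is on the typical (median) estimate plus a loose upper tail
  est <- sapply(1:20, function(s) {
    d <- make_trial_values(n_geno = 20, n_reps = 3, v_g = 0, v_r = 1, seed = s)
    fit <- fit_spatial_model(d)
    c(v_g = fit$v_g, ed = effective_dimension(fit, "genotype"),
      w2 = compute_w2(fit))
  })
  expect_lt(median(est["v_g", ]), 0.1)
  expect_lt(median(est["ed", ]), 5)
  expect_lt(median(est["w2", ]), 0.2)
  expect_gte(mean(est["w2", ] < 0.5), 0.9)
})

test_that("adding a constant moves only the intercept", {
  d <- make_trial_values(n_geno = 15, n_reps = 3, v_g = 2, v_r = 1, seed = 3)
  f1 <- fit_spatial_model(d)
  d2 <- d; d2$value <- d2$value + 500
  f2 <- fit_spatial_model(d2)
  expect_equal(f1$v_g, f2$v_g, tolerance = 1e-4)
  expect_equal(f1$v_r, f2$v_r, tolerance = 1e-4)
  expect_equal(f1$ed, f2$ed, tolerance = 1e-3)
})

test_that("effective dimensions match a dense hat-matrix trace", {
  # small instance: assemble X and the penalized hat matrix explicitly
  d <- make_trial_values(n_geno = 4, n_reps = 3, v_g = 3, v_r = 0.5, seed = 5)
  fit <- fit_spatial_model(d)
  g <- fit$fit
  X <- stats::model.matrix(g)
  S <- matrix(0, ncol(X), ncol(X))
  k <- 1
  for (sm in g$smooth) {
    idx <- sm$first.para:sm$last.para
    for (j in seq_along(sm$S)) {
      S[idx, idx] <- S[idx, idx] + g$sp[k] * sm$S[[j]]
      k <- k + 1
    }
  }
  F <- solve(crossprod(X) + S, crossprod(X))
  for (comp in c("genotype", "row", "col")) {
    sm <- g$smooth[[grep(comp, vapply(g$smooth, `[[`, "", "label"))[1]]]
    idx <- sm$first.para:sm$last.para
    expect_equal(effective_dimension(fit, comp), sum(diag(F)[idx]),
                 tolerance = 1e-6, info = comp)
  }
  # ED conservation: components + residual = n
  expect_equal(sum(fit$ed[c("intercept", "genotype", "row", "col", "surface")],
                   na.rm = TRUE) + fit$ed[["residual"]], nrow(d))
  expect_error(effective_dimension(fit, "nope"), "unknown component")
})

test_that("w2 hits its limits: ~0 without signal, ~1 without noise", {
  d0 <- make_trial_values(n_geno = 20, n_reps = 3, v_g = 0, v_r = 1, seed = 1)
  expect_lt(compute_w2(fit_spatial_model(d0)), 0.05)
  d1 <- make_trial_values(n_geno = 20, n_reps = 3, v_g = 25, v_r = 1e-4,
                          seed = 1)
  f1 <- fit_spatial_model(d1)
  expect_gt(compute_w2(f1), 0.95)
  # unshrunken limit: ED_g -> n_geno - 1
  expect_equal(effective_dimension(f1, "genotype"), 19, tolerance = 0.5)
  # printed-denominator audit variant is smaller by construction here
  expect_lt(compute_w2(f1, eq6_as_printed = TRUE), compute_w2(f1))
})

test_that("w2 is monotone in the planted heritability", {
  h2 <- c(0.2, 0.5, 0.8)
  med <- sapply(h2, function(h) {
    median(sapply(1:15, function(s) {
      d <- make_trial_values(n_geno = 30, n_reps = 3, v_g = h, v_r = 1 - h,
                             seed = s)
      compute_w2(fit_spatial_model(d))
    }))
  })
  expect_true(all(diff(med) > 0))
})

test_that("a planted spatial trend does not masquerade as genotypic variance", {
  ratio <- sapply(1:10, function(s) {
    base <- make_trial_values(n_geno = 20, n_reps = 3, v_g = 2, v_r = 1,
                              trend_amp = 0, seed = s)
    trended <- make_trial_values(n_geno = 20, n_reps = 3, v_g = 2, v_r = 1,
                                 trend_amp = 6, seed = s)
    fit_spatial_model(trended)$v_g / fit_spatial_model(base)$v_g
  })
  expect_lt(median(ratio), 1.2)
})

test_that("degenerate trials are rejected", {
  d <- make_trial_values(n_geno = 10, n_reps = 1, seed = 1)
  expect_error(fit_spatial_model(d), "unreplicated|inestimable")
  d2 <- make_trial_values(n_geno = 2, n_reps = 3, seed = 1)
  d2$genotype <- "G01"
  expect_error(fit_spatial_model(d2), "2 genotypes")
})

test_that("the trajectory tabulates one row per experiment x cut", {
  preds <- do.call(rbind, lapply(1:2, function(e) {
    do.call(rbind, lapply(1:3, function(cutn) {
      d <- make_trial_values(n_geno = 10, n_reps = 3,
                             v_g = cutn, v_r = 1, seed = e * 10 + cutn)
      data.frame(experiment_id = paste0("E", e), cut_number = cutn,
                 d[, c("row", "column", "genotype")], pred = d$value)
    }))
  }))
  tab <- repeatability_trajectory(preds)
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$w2 >= 0 & tab$w2 <= 1))
  expect_true(all(tab$v_g >= 0))
  # genotype effects grow with cut number -> so does V_G (pooled across exps)
  agg <- aggregate(v_g ~ cut_number, tab, mean)
  expect_true(all(diff(agg$v_g) > 0))
})
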