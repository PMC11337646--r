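# Shared fixtures, generated in code.

# a minimal canopy state row for render_scene()
make_state <- function(green_fraction = 0.6, mean_height = 0.5,
                       senescence = 0, plot_id = "P1",
                       date = as.Date("2021-08-01")) {
  data.frame(plot_id = plot_id, date = date,
             green_fraction = green_fraction, mean_height = mean_height,
             senescence = senescence, stringsAsFactors = FALSE)
}

# a scene with hand-set constant bands/chm (no randomness)
make_constant_scene <- function(nr = 16, nc = 16, gsd = 0.02,
                                blue = 0.04, green = 0.09, red = 0.05,
                                red_edge = 0.28, nir = 0.48, height = 0.5) {
  bands <- list(blue = matrix(blue, nr, nc), green = matrix(green, nr, nc),
                red = matrix(red, nr, nc), red_edge = matrix(red_edge, nr, nc),
                nir = matrix(nir, nr, nc))
  full <- cbind(x = c(0, nc, nc, 0) * gsd, y = c(0, 0, nr, nr) * gsd)
  plot_scene("P1", as.Date("2021-08-01"), gsd, bands,
             matrix(height, nr, nc), roi_permanent = full)
}

# brute-force Otsu: explicit loop over all interior bin edges
otsu_bruteforce <- function(values, n_bins = 256) {
  v <- as.numeric(values); v <- v[is.finite(v)]
  rng <- range(v)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  best <- -Inf; best_k <- NA
  for (k in 1:(n_bins - 1)) {
    lo <- bin <= k; hi <- !lo
    if (!any(lo) || !any(hi)) next
    w0 <- mean(lo); w1 <- 1 - w0
    mu0 <- mean(mids[bin[lo]]); mu1 <- mean(mids[bin[hi]])
    s <- w0 * w1 * (mu0 - mu1)^2
    if (s > best + 1e-15) { best <- s; best_k <- k }
  }
  edges[best_k + 1]
}

# linear regression data with a planted sparse signal
make_planted_data <- function(n = 100, p = 20, k_true = 2, snr = 10, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- sprintf("f%02d", seq_len(p))
  beta <- rep(0, p); beta[seq_len(k_true)] <- 1
  signal <- X %*% beta
  noise_sd <- sqrt(as.numeric(var(signal)) / snr)
  y <- as.numeric(signal + rnorm(n, 0, noise_sd))
  list(X = X, y = y, true_features = colnames(X)[seq_len(k_true)])
}

# a replicated row-column trial with known variance components
make_trial_values <- function(n_geno = 30, n_reps = 3, v_g = 4, v_r = 1,
                              trend_amp = 0, seed = 1) {
  set.seed(seed)
  n <- n_geno * n_reps
  nc <- ceiling(sqrt(n)); nr <- ceiling(n / nc)
  cells <- expand.grid(row = seq_len(nr), column = seq_len(nc))[seq_len(n), ]
  g <- sprintf("G%02d", seq_len(n_geno))
  d <- data.frame(cells, genotype = sample(rep(g, n_reps)))
  ge <- rnorm(n_geno, 0, sqrt(v_g)); names(ge) <- g
  trend <- trend_amp * sin(pi * d$row / (nr + 1)) * cos(pi * d$column / (nc + 1))
  d$value <- 100 + ge[d$genotype] + trend + rnorm(n, 0, sqrt(v_r))
  d
}
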