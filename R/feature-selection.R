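#' Unsupervised pairwise-correlation filter
#'
#' Iteratively removes columns until no pair of retained columns has
#' absolute Pearson correlation above the cutoff. At each step the worst
#' offending pair is found and the member with the larger mean absolute
#' correlation to all other retained columns is dropped — the conventional
#' heuristic for collinearity pre-filtering. The result is idempotent:
#' filtering a filtered matrix removes nothing further.
#'
#' @param X Numeric matrix or data.frame of candidate predictors (>= 3
#'   rows). Constant columns are removed first (their correlation is
#'   undefined).
#' @param cutoff Absolute correlation threshold (default 0.95).
#' @return Character vector of retained column names, in original order.
#' @export
correlation_filter <- function(X, cutoff = 0.95) {
  X <- as.matrix(X)
  if (nrow(X) < 3) stop("need at least 3 rows to estimate correlations",
                        call. = FALSE)
  if (ncol(X) < 2) return(colnames(X))
  keep <- colnames(X)
  const <- apply(X, 2, stats::sd) == 0
  keep <- keep[!const]
  while (length(keep) >= 2) {
    cm <- abs(stats::cor(X[, keep, drop = FALSE]))
    diag(cm) <- 0
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    if (cm[worst[1], worst[2]] <= cutoff) break
    mean_abs <- rowMeans(cm) * length(keep) / (length(keep) - 1)
    drop_i <- if (mean_abs[worst[1]] >= mean_abs[worst[2]]) worst[1] else worst[2]
    keep <- keep[-drop_i]
  }
  keep
}

#' Recursive feature elimination with a PLSR base learner
#'
#' Nested resampled validation of every feature-subset size: the data are
#' resampled `n_resamples` times into training and validation sets with an
#' 80:20 split (stratified on `strata` when given). Within each resample a
#' PLSR model is fitted on the training part with its component count tuned
#' by tenfold cross-validation over 1..p components, validation RMSE is
#' recorded, the lowest-importance feature (by [plsr_importance()]) is
#' dropped, and the fit-score-drop cycle repeats until one feature remains.
#' Standardization happens inside [fit_plsr()] on each training set only, so
#' no validation information leaks into the fit.
#'
#' @param X Predictor matrix or data.frame with named columns.
#' @param y Response (DW_AGB, g/m^2).
#' @param strata Optional stratification labels (e.g. experiment) for the
#'   resampling splits.
#' @param n_resamples Number of outer resamples (default 30).
#' @param split Training fraction of each resample (default 0.8).
#' @param seed Integer seed; inner CV fold seeds are derived from
#'   `(seed, resample index)`.
#' @param inner_folds Folds of the inner component-tuning CV (default 10).
#' @return Object of class `rfe_profile`: data.frame `profile` (per subset
#'   size: `size`, `rmse_mean`, `rmse_se`), matrix `rmse` (resample x size),
#'   `ranks` (mean elimination-order rank per feature, 1 = eliminated last
#'   = best, ties broken alphabetically), `chosen_size`, `chosen` (the
#'   1-SE-selected feature set).
#' @export
rfe <- function(X, y, strata = NULL, n_resamples = 30, split = 0.8, seed = 1,
                inner_folds = 10) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 10) stop("need at least 10 rows for resampled RFE", call. = FALSE)
  if (p < 2) stop("need at least 2 features", call. = FALSE)
  if (stats::var(y) == 0) stop("degenerate response: zero variance", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  feats <- colnames(X)
  rmse_mat <- matrix(NA_real_, n_resamples, p,
                     dimnames = list(NULL, as.character(seq_len(p))))
  # elimination position per resample: p = first out, 1 = survivor
  elim_rank <- matrix(NA_real_, n_resamples, p, dimnames = list(NULL, feats))
  for (r in seq_len(n_resamples)) {
    idx_tr <- .stratified_sample(n, split, strata, seed = .derive_seed(seed, r))
    Xtr <- X[idx_tr, , drop = FALSE]; ytr <- y[idx_tr]
    Xva <- X[-idx_tr, , drop = FALSE]; yva <- y[-idx_tr]
    active <- feats
    while (length(active) >= 1) {
      s <- length(active)
      Xa <- Xtr[, active, drop = FALSE]
      tune <- cv_plsr_ncomp(Xa, ytr, max_ncomp = s, folds = inner_folds,
                            seed = .derive_seed(seed, r, s))
      fit <- fit_plsr(Xa, ytr, ncomp = tune$ncomp)
      pr <- predict(fit, Xva[, active, drop = FALSE])
      rmse_mat[r, s] <- sqrt(mean((pr - yva)^2))
      if (s == 1) {
        elim_rank[r, active] <- 1
        break
      }
      imp <- plsr_importance(fit)
      # drop the least important; ties broken alphabetically (drop the later name)
      ord <- order(imp, -xtfrm(active))
      out <- active[ord[1]]
      elim_rank[r, out] <- s
      active <- setdiff(active, out)
    }
  }
  mean_rank <- colMeans(elim_rank)
  mean_rank <- mean_rank[order(mean_rank, names(mean_rank))]
  profile <- data.frame(size = seq_len(p),
                        rmse_mean = colMeans(rmse_mat),
                        rmse_se = apply(rmse_mat, 2, stats::sd) / sqrt(n_resamples))
  res <- structure(list(profile = profile, rmse = rmse_mat,
                        ranks = mean_rank, n_resamples = n_resamples),
                   class = "rfe_profile")
  sel <- select_subset_1se(res)
  res$chosen_size <- attr(sel, "size")
  res$chosen <- sel
  res
}

#' One-standard-error subset choice on an RFE profile
#'
#' Chooses the smallest subset size whose mean validation RMSE is within
#' one standard error of the best (lowest-RMSE) size, where the SE is that
#' of the best size's RMSE over the resamples; returns the top features by
#' aggregated elimination rank.
#'
#' @param profile An `rfe_profile`.
#' @return Character vector of chosen features with attribute `size`.
#' @export
select_subset_1se <- function(profile) {
  pr <- profile$profile
  best <- which.min(pr$rmse_mean)
  thresh <- pr$rmse_mean[best] + pr$rmse_se[best]
  size <- pr$size[which(pr$rmse_mean <= thresh)[1]]
  chosen <- names(profile$ranks)[seq_len(size)]
  attr(chosen, "size") <- size
  chosen
}

# deterministic per-(resample, stage) seeds below 2^31
.derive_seed <- function(seed, ...) {
  ix <- abs(c(seed, ...)) %% 2147483563
  mult <- c(1, 7919, 104729, 1299709)[seq_along(ix)]
  as.integer(sum(ix * mult) %% 2147483562 + 1)
}

# indices of a stratified training sample of fraction `split`
.stratified_sample <- function(n, split, strata = NULL, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(strata)) strata <- rep(1, n)
  idx <- unlist(lapply(split(seq_len(n), strata), function(ii) {
    k <- max(1, round(length(ii) * split))
    if (length(ii) == 1) ii else sample(ii, k)
  }), use.names = FALSE)
  sort(idx)
}
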