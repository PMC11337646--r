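#' Partial least squares regression (SIMPLS)
#'
#' Univariate-response PLSR by the SIMPLS algorithm. Predictors are
#' centered and (by default) unit-scaled; the response is centered. All
#' component counts from 1 to `ncomp` are fitted in one pass, and the
#' per-component coefficient increments are retained — these are what the
#' feature-importance score is built from.
#'
#' @param X Numeric matrix (n x p) of predictors.
#' @param y Numeric response vector, length n.
#' @param ncomp Maximum number of latent components (capped at
#'   `min(n - 1, p)`).
#' @param scale Unit-scale the predictors (default `TRUE`).
#' @return Object of class `plsr_fit` with elements `coef` (p x ncomp
#'   cumulative coefficients on the original predictor scale), `comp_coef`
#'   (p x ncomp per-component increments on the standardized scale),
#'   `q2` (per-component explained response sum of squares), `x_center`,
#'   `x_scale`, `y_center`, `ncomp`.
#' @export
fit_plsr <- function(X, y, ncomp = NULL, scale = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n >= 2, p >= 1)
  if (stats::var(y) == 0) stop("degenerate response: zero variance", call. = FALSE)
  max_comp <- min(n - 1, p)
  if (is.null(ncomp)) ncomp <- max_comp
  ncomp <- min(ncomp, max_comp)
  xc <- colMeans(X)
  xs <- if (scale) sqrt(pmax(colSums(X^2) - n * xc^2, 0) / (n - 1)) else rep(1, p)
  xs[xs < 1e-300] <- 1
  Xs <- (X - rep(xc, each = n)) / rep(xs, each = n)
  yc <- mean(y)
  ys <- y - yc
  s <- crossprod(Xs, ys)
  R <- P <- V <- matrix(0, p, ncomp)
  Q <- numeric(ncomp)
  a_used <- 0
  for (a in seq_len(ncomp)) {
    r <- s
    t_sc <- Xs %*% r
    nt <- sqrt(sum(t_sc^2))
    if (nt < 1e-12) break
    t_sc <- t_sc / nt; r <- r / nt
    pv <- crossprod(Xs, t_sc)
    q <- sum(ys * t_sc)
    v <- pv
    if (a > 1) {
      Vp <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pv)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) break
    v <- v / nv
    s <- s - v %*% crossprod(v, s)
    R[, a] <- r; P[, a] <- pv; V[, a] <- v; Q[a] <- q
    a_used <- a
  }
  if (a_used == 0) stop("no usable PLS component (predictors are constant?)",
                        call. = FALSE)
  R <- R[, seq_len(a_used), drop = FALSE]
  Q <- Q[seq_len(a_used)]
  comp_coef <- R * rep(Q, each = p)                # standardized-scale increments
  U <- upper.tri(diag(a_used), diag = TRUE) * 1    # column-wise cumulation
  coef_std <- comp_coef %*% U
  coef_orig <- coef_std / xs                        # back to original scale
  rownames(coef_orig) <- rownames(comp_coef) <- colnames(X)
  structure(list(coef = coef_orig, comp_coef = comp_coef, q2 = Q^2,
                 x_center = xc, x_scale = xs, y_center = yc,
                 intercepts = yc - as.numeric(crossprod(xc, coef_orig)),
                 ncomp = a_used),
            class = "plsr_fit")
}

#' Predict from a PLSR fit
#'
#' @param object A `plsr_fit`.
#' @param newdata Matrix of predictors.
#' @param ncomp Number of components to use (default: all fitted).
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.plsr_fit <- function(object, newdata, ncomp = object$ncomp, ...) {
  ncomp <- min(ncomp, object$ncomp)
  as.numeric(as.matrix(newdata) %*% object$coef[, ncomp]) +
    object$intercepts[ncomp]
}

#' PLSR feature importance
#'
#' Importance of each predictor as the weighted sum over components of the
#' absolute per-component regression coefficients on the standardized
#' predictors, weights proportional to the response variance each component
#' explains. Scores are non-negative, and symmetric under duplicated
#' predictor columns.
#'
#' @param fit A `plsr_fit`.
#' @param ncomp Number of components to aggregate over (default: all).
#' @return Named non-negative numeric vector (names from the fitted
#'   predictor columns when available).
#' @export
plsr_importance <- function(fit, ncomp = fit$ncomp) {
  if (!inherits(fit, "plsr_fit")) stop("not a fitted PLSR model", call. = FALSE)
  ncomp <- min(ncomp, fit$ncomp)
  w <- fit$q2[seq_len(ncomp)]
  w <- w / sum(w)
  imp <- abs(fit$comp_coef[, seq_len(ncomp), drop = FALSE]) %*% w
  stats::setNames(as.numeric(imp), rownames(fit$coef))
}

#' Choose the PLSR component count by k-fold cross-validation
#'
#' @param X Predictor matrix.
#' @param y Response.
#' @param max_ncomp Largest component count to consider (default p).
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return List: `ncomp` (the RMSE-minimizing count), `rmse` (per count).
#' @export
cv_plsr_ncomp <- function(X, y, max_ncomp = ncol(X), folds = 10, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  folds <- min(folds, n)
  max_ncomp <- min(max_ncomp, n - ceiling(n / folds) - 1, ncol(X))
  max_ncomp <- max(max_ncomp, 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  se <- matrix(NA_real_, n, max_ncomp)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (stats::var(y[tr]) == 0) next
    fit <- fit_plsr(X[tr, , drop = FALSE], y[tr], ncomp = max_ncomp)
    pr <- .predict_all(fit, X[!tr, , drop = FALSE])   # one multiply, all comps
    a_max <- min(max_ncomp, fit$ncomp)
    se[!tr, seq_len(a_max)] <- (pr[, seq_len(a_max), drop = FALSE] - y[!tr])^2
  }
  rmse <- sqrt(colMeans(se, na.rm = TRUE))
  list(ncomp = which.min(rmse), rmse = rmse)
}

# predictions at every component count in one matrix product (n x ncomp)
.predict_all <- function(fit, newX) {
  newX <- as.matrix(newX)
  newX %*% fit$coef + rep(fit$intercepts, each = nrow(newX))
}
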