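#' Fit the row-column spatial mixed model
#'
#' Plot values are decomposed into a fixed intercept, random genotype
#' effects, random row and column effects, and a smooth two-dimensional
#' surface over the (row, column) grid — a tensor-product P-spline (cubic
#' B-spline marginal bases, second-order difference penalties, one penalty
#' per axis, i.e. anisotropic). All variance components are estimated by
#' REML; the penalized-smooth machinery is \pkg{mgcv}'s, which is the same
#' mixed-model representation the SpATS family of spatial trial models
#' uses. Genotype effects are random (shrunken), as required for the
#' effective-dimension repeatability below.
#'
#' The smooth surface is dropped automatically (with a flag) when the grid
#' has fewer than 4 distinct rows or columns, where a cubic tensor basis is
#' not constructible.
#'
#' @param plot_values Data.frame with `row`, `column` (integer grid
#'   coordinates), `genotype`, and `value`.
#' @param knots Marginal basis dimensions `c(k_row, k_col)`; each is capped
#'   at the number of distinct coordinates (default 10 per axis).
#' @return Object of class `spatial_model_fit`: the mgcv fit, per-component
#'   effective dimensions, variance components `v_g` and `v_r`,
#'   `n_geno`, `n_obs`, `converged`.
#' @export
fit_spatial_model <- function(plot_values, knots = c(10, 10)) {
  d <- as.data.frame(plot_values)
  stopifnot(all(c("row", "column", "genotype", "value") %in% names(d)))
  d$genotype <- factor(d$genotype)
  n_geno <- nlevels(d$genotype)
  if (n_geno < 2) stop("need at least 2 genotypes", call. = FALSE)
  if (max(table(d$genotype)) < 2) {
    stop("every genotype is unreplicated: genotypic variance is ",
         "inestimable", call. = FALSE)
  }
  d$row_f <- factor(d$row); d$col_f <- factor(d$column)
  nr <- nlevels(d$row_f); nc <- nlevels(d$col_f)
  kr <- min(knots[1], nr); kc <- min(knots[2], nc)
  has_surface <- kr >= 4 && kc >= 4
  terms <- c("s(genotype, bs = \"re\")",
             if (nr >= 2) "s(row_f, bs = \"re\")",
             if (nc >= 2) "s(col_f, bs = \"re\")",
             if (has_surface)
               sprintf("te(row, column, bs = \"ps\", k = c(%d, %d), m = c(2, 2))",
                       kr, kc))
  form <- stats::as.formula(paste("value ~", paste(terms, collapse = " + ")))
  fit <- mgcv::gam(form, data = d, method = "REML",
                   control = mgcv::gam.control(maxit = 200))
  eds <- .component_eds(fit)
  sp <- fit$sp
  v_g <- unname(fit$sig2 / sp[grep("genotype", names(sp))][1])
  structure(list(fit = fit, ed = eds, v_g = v_g, v_r = fit$sig2,
                 n_geno = n_geno, n_obs = nrow(d),
                 has_surface = has_surface,
                 converged = isTRUE(fit$converged)),
            class = "spatial_model_fit")
}

# per-component effective dimensions (sums of mgcv's per-coefficient edf)
.component_eds <- function(fit) {
  labs <- vapply(fit$smooth, function(s) s$label, character(1))
  eds <- vapply(fit$smooth, function(s) {
    sum(fit$edf[s$first.para:s$last.para])
  }, numeric(1))
  names(eds) <- labs
  out <- c(intercept = sum(fit$edf[1:(fit$smooth[[1]]$first.para - 1)]))
  key <- function(pat) {
    i <- grep(pat, labs)
    if (length(i)) eds[i[1]] else NA_real_
  }
  out["genotype"] <- key("genotype")
  out["row"] <- key("row_f")
  out["col"] <- key("col_f")
  out["surface"] <- key("^te\\(")
  out["residual"] <- length(fit$y) - sum(fit$edf)
  out
}

#' Effective dimension of a model component
#'
#' The trace of the block of the hat matrix mapping the observations to the
#' component's fitted contribution — the component's equivalent degrees of
#' freedom after penalization.
#'
#' @param fit A `spatial_model_fit`.
#' @param component One of `"genotype"`, `"row"`, `"col"`, `"surface"`,
#'   `"intercept"`, `"residual"`.
#' @return Effective dimension (scalar).
#' @export
effective_dimension <- function(fit, component) {
  stopifnot(inherits(fit, "spatial_model_fit"))
  if (!component %in% names(fit$ed)) {
    stop("unknown component '", component, "'; have: ",
         paste(names(fit$ed), collapse = ", "), call. = FALSE)
  }
  unname(fit$ed[component])
}

#' Within-season repeatability from effective dimensions
#'
#' \deqn{w^2 = ED_g / (n_{geno} - 1)}: the genetic component's effective
#' dimension relative to its fixed-effect (unshrunken) maximum, clamped to
#' \[0, 1\]. With no genetic signal the genotype effects shrink to zero and
#' `ED_g -> 0`; with replicated genotypes and vanishing residual noise
#' `ED_g -> n_geno - 1` and `w^2 -> 1`. `eq6_as_printed = TRUE` computes
#' the audit variant with the total observation count in the denominator
#' (which cannot reach 1 in the noiseless limit; kept for traceability
#' only).
#'
#' @param fit A `spatial_model_fit`.
#' @param eq6_as_printed Audit flag (default `FALSE`).
#' @return w^2 in \[0, 1\].
#' @export
compute_w2 <- function(fit, eq6_as_printed = FALSE) {
  stopifnot(inherits(fit, "spatial_model_fit"))
  if (fit$n_geno < 2) stop("w2 undefined with fewer than 2 genotypes",
                           call. = FALSE)
  ed_g <- effective_dimension(fit, "genotype")
  denom <- if (eq6_as_printed) fit$n_obs - 1 else fit$n_geno - 1
  min(max(ed_g / denom, 0), 1)
}

#' Repeatability trajectory over experiments and cuts
#'
#' Fits the spatial mixed model to the predicted biomass of every
#' experiment x cut cell and tabulates the genotypic variance, residual
#' variance, genetic effective dimension and within-season repeatability —
#' the inputs of the V_G / V_R / w^2 vs cut trajectory plots. Cells whose
#' model cannot be fitted (e.g. unreplicated genotypes) are skipped with a
#' message.
#'
#' @param predictions Data.frame with `experiment_id`, `cut_number`,
#'   `row`, `column`, `genotype`, and the predicted value column.
#' @param value_col Name of the value column (default `"pred"`).
#' @param knots Passed to [fit_spatial_model()].
#' @return Data.frame: `experiment_id`, `cut_number`, `v_g`, `v_r`, `ed_g`,
#'   `w2`, `converged`; one row per fitted cell.
#' @export
repeatability_trajectory <- function(predictions, value_col = "pred",
                                     knots = c(10, 10)) {
  stopifnot(all(c("experiment_id", "cut_number", "row", "column",
                  "genotype", value_col) %in% names(predictions)))
  cells <- unique(predictions[, c("experiment_id", "cut_number")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sub <- predictions[predictions$experiment_id == cells$experiment_id[i] &
                         predictions$cut_number == cells$cut_number[i], ]
    sub$value <- sub[[value_col]]
    fit <- tryCatch(fit_spatial_model(sub, knots),
                    error = function(e) {
                      message("skipping ", cells$experiment_id[i], " cut ",
                              cells$cut_number[i], ": ", conditionMessage(e))
                      NULL
                    })
    if (is.null(fit)) next
    rows[[i]] <- data.frame(
      experiment_id = cells$experiment_id[i],
      cut_number = cells$cut_number[i],
      v_g = fit$v_g, v_r = fit$v_r,
      ed_g = effective_dimension(fit, "genotype"),
      w2 = compute_w2(fit), converged = fit$converged
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
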