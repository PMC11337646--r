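#' Study configuration
#'
#' Bundles every knob of the full experiment grid: trial design, growth and
#' scene parameters, the stage and variable-set axes (4 stages x 3 variable
#' sets = 12 modelling cells), the learners, the ROI types, and the
#' cross-validation shape. Defaults mirror the study's structure at desk
#' scale: 8 experiments of ~24 plots (8 genotypes x 3 replicates on a
#' row-column grid), 5 cuts spanning the season, 64 x 64-pixel scenes.
#'
#' @param n_experiments Number of experiments (default 8).
#' @param n_geno,n_reps NVT design shape per experiment (default 8 x 3).
#' @param n_cuts Biomass cuts per experiment (default 5).
#' @param cut_tt Target cumulative thermal times of the cuts (degC day).
#' @param dims,gsd Scene raster shape and ground sample distance.
#' @param heterogeneity Within-plot biomass gradient amplitude (default 0).
#' @param geno_sd Genotypic sd of the biomass asymptote (g/m^2).
#' @param residual_cv Plot x date lognormal residual CV (default 0.1).
#' @param quad_area,cut_noise_cv Quadrat area (m^2) and biomass
#'   measurement CV.
#' @param stages Stage axis (default the 3 broad stages plus `"all"`).
#' @param variable_sets Variable-set axis (default spectral, geometric,
#'   combined).
#' @param learners Learner families to train.
#' @param roi_types ROI types to extract (default both).
#' @param rfe_resamples RFE outer resamples (default 30).
#' @param cv_folds,cv_repeats Repeated k-fold CV shape (default 10 x 10).
#' @param zadoks_tt50,zadoks_tt70 True stage-boundary crossings of the
#'   synthetic development curve (degC day).
#' @param num_trees Random-forest tree count.
#' @return List of class `study_config`.
#' @export
study_config <- function(n_experiments = 8, n_geno = 8, n_reps = 3,
                         n_cuts = 5,
                         cut_tt = c(500, 900, 1300, 1650, 2000),
                         dims = c(64, 64), gsd = 0.02,
                         heterogeneity = 0, geno_sd = 150,
                         residual_cv = 0.1,
                         quad_area = 0.5, cut_noise_cv = 0.05,
                         stages = c("vegetative", "flowering", "grain_fill", "all"),
                         variable_sets = c("spectral", "geometric", "combined"),
                         learners = c("plsr", "rf", "svm_poly", "xgboost"),
                         roi_types = c("permanent", "precise"),
                         rfe_resamples = 30, cv_folds = 10, cv_repeats = 10,
                         zadoks_tt50 = 1189, zadoks_tt70 = 1523,
                         num_trees = 200) {
  stopifnot(n_experiments >= 1, n_cuts == length(cut_tt))
  structure(as.list(environment()), class = "study_config")
}

#' Enumerate the stage x variable-set modelling grid
#'
#' @param config A [study_config()].
#' @return Data.frame with columns `stage` and `variable_set`; 12 rows
#'   under the default axes.
#' @export
study_grid <- function(config = study_config()) {
  expand.grid(stage = config$stages, variable_set = config$variable_sets,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Trait-column names of a variable set
#'
#' @param variable_set `"spectral"`, `"geometric"`, or `"combined"`.
#' @return Character vector of trait column names.
#' @export
variable_set_columns <- function(variable_set) {
  tn <- trait_names()
  geo <- tn[1:9]; spec <- tn[10:75]
  switch(variable_set,
         geometric = geo, spectral = spec, combined = c(geo, spec),
         stop("unknown variable set '", variable_set, "'", call. = FALSE))
}

#' Simulate the full study dataset
#'
#' Generates every experiment's design, weather, growth trajectories,
#' rendered scenes, trait extractions (both ROI types) and quadrat cut
#' records, plus the phenology observations and the solved stage
#' boundaries. The quadrat for each cut is taken at the precise-ROI
#' location, so under within-plot heterogeneity the ground truth tracks the
#' precise ROI and not the plot mean.
#'
#' @param config A [study_config()].
#' @param seed Integer master seed; all per-experiment/plot/date seeds are
#'   derived from it.
#' @return List: `traits` (one row per plot x date x ROI type, 75 trait
#'   columns plus identifiers, `tt`, `stage`, `dw_agb`), `states`,
#'   `designs`, `boundaries`, `phenology`.
#' @export
simulate_study_data <- function(config = study_config(), seed = 1) {
  stopifnot(inherits(config, "study_config"))
  all_traits <- list(); all_states <- list(); designs <- list()
  for (e in seq_len(config$n_experiments)) {
    eid <- paste0("E", e)
    des <- generate_design(design_template("nvt", n_geno = config$n_geno,
                                           n_reps = config$n_reps),
                           seed = .derive_seed(seed, e, 1),
                           experiment_id = eid)
    sow <- as.Date("2021-05-05") + (e - 1) %% 4 * 7
    wx <- synthetic_weather(sow - 10, sow + 230,
                            seed = .derive_seed(seed, e, 2))
    tts <- cumulative_thermal_time(wx, sow)
    cut_dates <- as.Date(vapply(config$cut_tt, function(tt0) {
      as.character(tts$date[which(tts$tt >= tt0)[1]])
    }, character(1)))
    # freeze genotype effects on the derived stream, independent of plot noise
    old <- .Random.seed_save()
    set.seed(.derive_seed(seed, e, 3))
    asym <- stats::rnorm(config$n_geno, 1500, config$geno_sd)
    .Random.seed_restore(old)
    names(asym) <- sprintf("G%02d", seq_len(config$n_geno))
    par <- growth_params(biomass_asymptote = pmax(asym, 300),
                         spatial_trend_amplitude = 80,
                         residual_cv = config$residual_cv)
    st <- simulate_growth(des, wx, par, cut_dates, sow,
                          seed = .derive_seed(seed, e, 4))
    st$experiment_id <- eid
    # scenes, traits and ground-truth cuts
    tr_rows <- vector("list", nrow(st) * length(config$roi_types))
    k <- 0
    st$dw_agb <- NA_real_
    for (i in seq_len(nrow(st))) {
      sc <- render_scene(st[i, ], gsd = config$gsd, dims = config$dims,
                         seed = .derive_seed(seed, e, 5, i),
                         heterogeneity = config$heterogeneity,
                         n_cuts = config$n_cuts)
      fac <- attr(sc, "roi_biomass_factor")
      cutn <- st$cut_number[i]
      true_local <- st$true_dw_agb[i] * fac[[paste0("cut", cutn)]]
      rec <- sample_biomass(true_local, config$quad_area, config$cut_noise_cv,
                            seed = .derive_seed(seed, e, 6, i))
      st$dw_agb[i] <- compute_dw_agb(rec)
      for (rt in config$roi_types) {
        k <- k + 1
        tr <- extract_traits(sc, rt, cut = cutn)
        tr$experiment_id <- eid
        tr$cut_number <- cutn
        tr_rows[[k]] <- tr
      }
    }
    traits <- do.call(rbind, tr_rows[seq_len(k)])
    meta_cols <- c("plot_id", "cut_number", "tt", "dw_agb", "row", "column",
                   "genotype", "density", "true_dw_agb")
    traits <- merge(traits, st[, meta_cols], by = c("plot_id", "cut_number"))
    all_traits[[e]] <- traits
    all_states[[e]] <- st
    designs[[e]] <- des
  }
  traits <- do.call(rbind, all_traits)
  states <- do.call(rbind, all_states)
  # phenology: one trial-mean curve for the study
  zad <- simulate_zadoks_obs(config$zadoks_tt50, config$zadoks_tt70,
                             seed = .derive_seed(seed, 999))
  phen <- fit_phenology_model(zad)
  bnd <- solve_stage_boundaries(phen)
  traits$stage <- classify_stage(traits$tt, bnd)
  states$stage <- classify_stage(states$tt, bnd)
  list(traits = traits, states = states, designs = designs,
       boundaries = bnd, phenology = phen)
}

#' Run feature selection and model training for one grid cell
#'
#' Correlation-filters the cell's variable set at 0.95, runs resampled RFE
#' with the PLSR base learner, selects the 1-SE subset, and trains the
#' configured learners on the selected features under repeated k-fold CV.
#'
#' @param traits Trait table (one ROI type) from [simulate_study_data()].
#' @param stage Stage cell (`"all"` for the whole season).
#' @param variable_set Variable-set cell.
#' @param config A [study_config()].
#' @param seed Integer seed.
#' @return List: `cell`, `filtered`, `rfe`, `selected`, `fits` (per
#'   learner), `metrics` (data.frame of cv/test metrics per learner).
#' @export
run_cell <- function(traits, stage, variable_set, config = study_config(),
                     seed = 1) {
  rows <- if (stage == "all") traits else traits[traits$stage == stage, ]
  rows <- rows[!is.na(rows$dw_agb), ]
  cols <- variable_set_columns(variable_set)
  X0 <- rows[, cols, drop = FALSE]
  ok <- colSums(is.na(X0)) == 0
  X0 <- X0[, ok, drop = FALSE]
  if (nrow(X0) < 20) stop("cell ", stage, " x ", variable_set,
                          " has too few rows (", nrow(X0), ")", call. = FALSE)
  keep <- correlation_filter(X0, 0.95)
  sp <- split_train_test(rows, 0.8, strata = "experiment_id",
                         seed = .derive_seed(seed, 11))
  prof <- rfe(sp$train[, keep, drop = FALSE], sp$train$dw_agb,
              strata = sp$train$experiment_id,
              n_resamples = config$rfe_resamples,
              seed = .derive_seed(seed, 12))
  sel <- prof$chosen
  fits <- list(); metrics <- list()
  for (ln in config$learners) {
    cfg <- model_config(ln, cv_folds = config$cv_folds,
                        cv_repeats = config$cv_repeats,
                        seed = .derive_seed(seed, 13, match(ln, config$learners)),
                        num_trees = config$num_trees)
    fit <- train_model(sp$train, sp$test, sel, "dw_agb", cfg)
    fits[[ln]] <- fit
    metrics[[ln]] <- data.frame(
      learner = ln, stage = stage, variable_set = variable_set,
      n_train = nrow(sp$train), n_test = nrow(sp$test),
      n_selected = length(sel),
      cv_rmse = unname(fit$cv_metrics["rmse"]),
      test_r2 = unname(fit$test_metrics["r2"]),
      test_rmse = unname(fit$test_metrics["rmse"]),
      test_rrmse = unname(fit$test_metrics["rrmse"])
    )
  }
  list(cell = list(stage = stage, variable_set = variable_set),
       filtered = keep, rfe = prof, selected = sel, fits = fits,
       metrics = do.call(rbind, metrics), split = sp)
}

#' Run the full study
#'
#' Executes the whole pipeline: simulate -> extract (both ROI types) ->
#' stage-classify -> correlation filter -> RFE -> train all learners over
#' the stage x variable-set grid -> general/specific comparisons ->
#' within-season repeatability of out-of-fold predicted biomass. Writes the
#' results tables and a provenance manifest when `out_dir` is given.
#'
#' @param config A [study_config()].
#' @param seed Integer master seed.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @param roi_for_models ROI type used for the modelling grid (default
#'   `"permanent"`; the other type is still extracted for the ROI
#'   comparison).
#' @return List of class `study_results`: `data`, `cells` (per grid cell),
#'   `results` (metrics table), `general_specific`, `repeatability`,
#'   `roi_comparison` (when both ROI types present), `manifest`.
#' @export
run_study <- function(config = study_config(), seed = 1, out_dir = NULL,
                      roi_for_models = "permanent") {
  dat <- simulate_study_data(config, seed)
  grid <- study_grid(config)
  cells <- list(); metrics <- list()
  for (rt in config$roi_types) {
    tr <- dat$traits[dat$traits$roi_type == rt, ]
    for (i in seq_len(nrow(grid))) {
      key <- paste(rt, grid$stage[i], grid$variable_set[i], sep = ".")
      cell <- tryCatch(
        run_cell(tr, grid$stage[i], grid$variable_set[i], config,
                 seed = .derive_seed(seed, 20, i)),
        error = function(e) {
          warning("cell ", key, " skipped: ", conditionMessage(e))
          NULL
        })
      if (is.null(cell)) next
      cells[[key]] <- cell
      m <- cell$metrics; m$roi_type <- rt
      metrics[[key]] <- m
    }
  }
  results <- do.call(rbind, metrics); rownames(results) <- NULL
  # general vs specific comparisons on the combined set, whole season
  tr_m <- dat$traits[dat$traits$roi_type == roi_for_models, ]
  base_cell <- cells[[paste(roi_for_models, "all", "combined", sep = ".")]]
  gs <- list()
  if (!is.null(base_cell)) {
    cfg <- model_config(config$learners[1], cv_folds = config$cv_folds,
                        cv_repeats = config$cv_repeats,
                        seed = .derive_seed(seed, 31))
    ok_rows <- !is.na(tr_m$dw_agb)
    for (axis in c("stage", "experiment_id")) {
      gs[[axis]] <- tryCatch(
        compare_general_specific(tr_m[ok_rows, ], axis, base_cell$selected,
                                 "dw_agb", cfg, seed = .derive_seed(seed, 32)),
        error = function(e) NULL)
    }
  }
  # repeatability of out-of-fold cv-predicted biomass, per experiment x cut
  rep_tab <- NULL
  if (!is.null(base_cell)) {
    fit0 <- base_cell$fits[[1]]
    pred_all <- tr_m
    pred_all$pred <- fit0$model(as.matrix(tr_m[, base_cell$selected,
                                               drop = FALSE]))
    # use out-of-fold predictions where the row was in the training split
    oof <- base_cell$split$train
    oof_pred <- fit0$oof_predictions$pred
    key_tr <- paste(oof$plot_id, oof$cut_number)
    m <- match(paste(pred_all$plot_id, pred_all$cut_number), key_tr)
    pred_all$pred[!is.na(m)] <- oof_pred[m[!is.na(m)]]
    rep_tab <- repeatability_trajectory(pred_all, "pred")
  }
  manifest <- list(
    config_hash = .fnv1a(paste(utils::capture.output(utils::str(config)),
                               collapse = "\n")),
    seed = seed, r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("canopybiomass")),
    n_cells = length(cells), created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  out <- structure(list(data = dat, cells = cells, results = results,
                        general_specific = gs, repeatability = rep_tab,
                        manifest = manifest),
                   class = "study_results")
  if (length(config$roi_types) == 2) {
    out$roi_comparison <- roi_comparison(out)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table_csv(results, file.path(out_dir, "results.csv"))
    write_table_csv(dat$traits, file.path(out_dir, "traits.csv"))
    if (!is.null(rep_tab)) {
      write_table_csv(rep_tab, file.path(out_dir, "repeatability.csv"))
    }
    if (!is.null(out$roi_comparison)) {
      write_table_csv(out$roi_comparison, file.path(out_dir, "roi_comparison.csv"))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Paired ROI_permanent vs ROI_precise comparison
#'
#' One row per stage x variable-set x learner cell with the cv/test metrics
#' of the permanent-ROI and precise-ROI runs side by side and their
#' differences.
#'
#' @param results A `study_results` from [run_study()] (with both ROI
#'   types).
#' @return Data.frame of paired metrics.
#' @export
roi_comparison <- function(results) {
  r <- results$results
  if (is.null(r) || !all(c("permanent", "precise") %in% r$roi_type)) {
    stop("both ROI-type runs are required for the comparison", call. = FALSE)
  }
  a <- r[r$roi_type == "permanent", ]
  b <- r[r$roi_type == "precise", ]
  key <- c("learner", "stage", "variable_set")
  m <- merge(a, b, by = key, suffixes = c("_permanent", "_precise"))
  miss <- setdiff(paste(a$stage, a$variable_set, a$learner),
                  paste(m$stage, m$variable_set, m$learner))
  if (length(miss)) stop("missing precise-ROI cells: ",
                         paste(miss, collapse = "; "), call. = FALSE)
  m$test_rmse_diff <- m$test_rmse_precise - m$test_rmse_permanent
  m[, c(key, "test_rmse_permanent", "test_rmse_precise", "test_rmse_diff",
        "test_r2_permanent", "test_r2_precise")]
}

# deterministic polynomial hash of a string, as a hex manifest hash
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
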