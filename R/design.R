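#' Trial design templates
#'
#' Three templates mirror the field layouts the pipeline targets:
#' \describe{
#'   \item{`nvt`}{National variety trial: `n_geno` genotypes in a
#'     row-column layout with `n_reps` replicates (default 3) at a single
#'     sowing density.}
#'   \item{`biocal_2021`}{Biomass calibration trial, 2020/21 pattern: 6
#'     genotypes x 3 densities (75, 150, 225 plants/m), plus a check
#'     genotype at densities 150, 187 and 112 — 21 plots.}
#'   \item{`biocal_2022`}{2022 pattern totalling 27 plots: 7 genotypes x 3
#'     densities (75, 150, 300 plants/m) unreplicated, plus a check
#'     genotype at all 3 densities with 2 replicates each
#'     (21 + 6 = 27). The printed description of this layout admits more
#'     than one reading; this template reproduces the stated total with
#'     the check as the doubly-replicated entry.}
#' }
#'
#' @param template One of `"nvt"`, `"biocal_2021"`, `"biocal_2022"`.
#' @param n_geno Genotype count for `nvt` (default 30).
#' @param n_reps Replicates for `nvt` (default 3).
#' @param n_cols Columns of the row-column grid (rows are derived).
#' @return A design specification list for [generate_design()].
#' @export
design_template <- function(template = c("nvt", "biocal_2021", "biocal_2022"),
                            n_geno = 30, n_reps = 3, n_cols = NULL) {
  template <- match.arg(template)
  spec <- switch(template,
    nvt = {
      g <- sprintf("G%02d", seq_len(n_geno))
      list(trial_type = "NVT",
           entries = data.frame(genotype = rep(g, each = n_reps),
                                density = 150,
                                replicate = rep(seq_len(n_reps), times = n_geno)))
    },
    biocal_2021 = {
      g <- sprintf("B%d", 1:6)
      base <- expand.grid(genotype = g, density = c(75, 150, 225),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      base$replicate <- 1L
      chk <- data.frame(genotype = "CHECK", density = c(150, 187, 112),
                        replicate = 1L)
      list(trial_type = "BioCal", entries = rbind(base, chk))
    },
    biocal_2022 = {
      g <- sprintf("B%d", 1:7)
      base <- expand.grid(genotype = g, density = c(75, 150, 300),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      base$replicate <- 1L
      chk <- expand.grid(genotype = "CHECK", density = c(75, 150, 300),
                         replicate = 1:2,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      list(trial_type = "BioCal", entries = rbind(base, chk))
    }
  )
  n <- nrow(spec$entries)
  spec$n_cols <- if (is.null(n_cols)) ceiling(sqrt(n)) else n_cols
  spec$n_rows <- ceiling(n / spec$n_cols)
  spec$template <- template
  spec
}

#' Generate a randomized trial design
#'
#' Assigns the specification's entries (genotype x density x replicate) to
#' positions on the row-column grid by seeded randomization. The entry list
#' itself is fixed by the template arithmetic; only positions are random.
#'
#' @param spec A specification from [design_template()] (fields
#'   `trial_type`, `entries`, `n_rows`, `n_cols`).
#' @param seed Integer seed; the same (spec, seed) always yields the same
#'   design.
#' @param experiment_id Label for the experiment (default `"E1"`).
#' @return Data.frame of class `trial_design`: `experiment_id`, `plot_id`,
#'   `row`, `column`, `genotype`, `density`, `replicate`, `trial_type`.
#' @export
generate_design <- function(spec, seed, experiment_id = "E1") {
  n <- nrow(spec$entries)
  n_cells <- spec$n_rows * spec$n_cols
  if (n_cells < n) {
    stop("grid (", spec$n_rows, " x ", spec$n_cols, ") too small for ",
         n, " plots", call. = FALSE)
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cells <- expand.grid(row = seq_len(spec$n_rows), column = seq_len(spec$n_cols))
  pos <- cells[sample.int(n_cells, n), ]
  out <- data.frame(
    experiment_id = experiment_id,
    plot_id = sprintf("%s_P%03d", experiment_id, seq_len(n)),
    row = pos$row, column = pos$column,
    genotype = as.character(spec$entries$genotype),
    density = spec$entries$density,
    replicate = spec$entries$replicate,
    trial_type = spec$trial_type,
    stringsAsFactors = FALSE
  )
  class(out) <- c("trial_design", "data.frame")
  out
}
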