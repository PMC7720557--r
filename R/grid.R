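# Orchestration of an analysis grid: labeled model combinations run on the
# same data, summarized into cross-model comparison tables.

#' Build an analysis grid
#' @param configs list of [run_config()] objects with unique labels.
#' @return an `analysis_grid`.
#' @export
analysis_grid <- function(configs) {
  labels <- vapply(configs, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop2("duplicate grid labels")
  names(configs) <- labels
  structure(configs, class = "analysis_grid")
}

#' Run a grid of analyses and assemble cross-model tables
#'
#' Runs every configuration on the shared data, summarizes each posterior
#' into MRC and MCT trees, and merges divergence-time, FBD/clock-parameter
#' and depth-bias tables across model labels. A failed run is recorded and
#' the grid continues.
#'
#' @param grid an [analysis_grid()].
#' @param mat a [morph_matrix()].
#' @param calibrations a [calibration_table()].
#' @param focal_clades named list of taxon vectors for the divergence table.
#' @param out_dir optional directory: per-label subdirectories receive
#'   annotated summary trees and CSV tables, merged CSVs go at the top.
#' @return list with `fits`, `summaries` (MRC), `mct`, `divergence`,
#'   `parameters`, `depth_bias`, and `failed`.
#' @export
run_grid <- function(grid, mat, calibrations, focal_clades = NULL,
                     out_dir = NULL) {
  stopifnot(inherits(grid, "analysis_grid"))
  fits <- list(); mrcs <- list(); mcts <- list(); failed <- character(0)
  par_rows <- list()
  for (lab in names(grid)) {
    res <- tryCatch({
      fit <- run_mcmc(grid[[lab]], mat, calibrations)
      ps <- posterior_samples(fit)
      list(fit = fit, ps = ps,
           mrc = majority_rule_consensus(ps$trees, rel_rates = ps$rel_rates),
           mct = maximum_compatibility_tree(ps$trees, rel_rates = ps$rel_rates))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("run '", lab, "' failed: ", conditionMessage(res), call. = FALSE)
      failed <- c(failed, lab)
      next
    }
    fits[[lab]] <- res$fit
    mrcs[[lab]] <- res$mrc
    mcts[[lab]] <- res$mct
    tr <- res$ps$trace
    med <- vapply(tr[setdiff(names(tr), c("gen", "run"))],
                  stats::median, numeric(1))
    par_rows[[lab]] <- data.frame(model = lab, t(med))
  }
  if (is.null(focal_clades) && length(mrcs))
    focal_clades <- list(Root = sort(calibrations$taxon))
  div <- if (length(mrcs)) divergence_table(mrcs, focal_clades) else NULL
  db <- if (length(mrcs)) depth_bias_report(mrcs) else NULL
  params <- if (length(par_rows)) {
    cols <- Reduce(union, lapply(par_rows, names))
    do.call(rbind, lapply(par_rows, function(r) {
      r[setdiff(cols, names(r))] <- NA; r[cols]
    }))
  } else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (lab in names(mrcs)) {
      d <- file.path(out_dir, gsub("[^A-Za-z0-9_.-]", "_", lab))
      dir.create(d, showWarnings = FALSE)
      summary_tree_newick(mrcs[[lab]], file.path(d, "mrc.nwk"))
      summary_tree_newick(mcts[[lab]], file.path(d, "mct.nwk"))
      utils::write.csv(mrcs[[lab]]$clades, file.path(d, "clades.csv"),
                       row.names = FALSE)
    }
    if (!is.null(div)) utils::write.csv(div, file.path(out_dir, "divergence.csv"),
                                        row.names = FALSE)
    if (!is.null(params)) utils::write.csv(params,
      file.path(out_dir, "parameters.csv"), row.names = FALSE)
  }
  list(fits = fits, summaries = mrcs, mct = mcts, divergence = div,
       parameters = params, depth_bias = db, failed = failed)
}
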