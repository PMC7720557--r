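# Convergence diagnostics: ASDSF across runs, PSRF and ESS per parameter.

#' Average standard deviation of split frequencies
#'
#' Computes, for every non-trivial clade reaching `min_freq` in at least one
#' run, the across-run (population) standard deviation of its sample
#' frequency, and averages over those clades. Values near 0.01 indicate
#' topological convergence between independent runs.
#'
#' @param tree_samples_per_run list (one element per run) of lists of
#'   [timetree()] samples.
#' @param min_freq clades below this frequency in every run are excluded.
#' @return the ASDSF (0 when all runs sampled identical topologies).
#' @export
compute_asdsf <- function(tree_samples_per_run, min_freq = 0.1) {
  if (length(tree_samples_per_run) < 2L)
    stop2("ASDSF needs at least two independent runs")
  freqs <- lapply(tree_samples_per_run, function(trees) {
    if (!length(trees)) stop2("a run has no retained trees")
    n_tip <- trees[[1]]$n_tip
    counts <- new.env(hash = TRUE)
    for (tr in trees) {
      keys <- clade_keys(tr)[(n_tip + 1L):length(tr$parent)]
      keys <- keys[keys != paste(sort(tr$tip_label), collapse = ",")]
      for (k in unique(keys))
        assign(k, (get0(k, counts, inherits = FALSE) %||% 0) + 1, counts)
    }
    out <- unlist(as.list(counts)) / length(trees)
    out
  })
  all_keys <- unique(unlist(lapply(freqs, names)))
  fmat <- vapply(freqs, function(f) {
    v <- f[all_keys]; v[is.na(v)] <- 0; v
  }, numeric(length(all_keys)))
  fmat <- matrix(fmat, nrow = length(all_keys))
  keep <- apply(fmat, 1, max) >= min_freq
  if (!any(keep)) return(0)
  sds <- apply(fmat[keep, , drop = FALSE], 1, function(x)
    sqrt(mean((x - mean(x))^2)))
  mean(sds)
}

#' Potential scale reduction factor (Gelman-Rubin)
#'
#' Between/within-run variance ratio; approaches 1 as independent runs
#' converge on the same distribution.
#'
#' @param traces list of numeric vectors, one per run (equal lengths).
#' @return the PSRF estimate.
#' @export
compute_psrf <- function(traces) {
  if (length(traces) < 2L) stop2("PSRF needs at least two runs")
  n <- min(lengths(traces))
  x <- vapply(traces, function(t) t[seq_len(n)], numeric(n))
  W <- mean(apply(x, 2, stats::var))
  B <- n * stats::var(colMeans(x))
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size
#'
#' `n / (1 + 2 sum(rho_k))` with the autocorrelation sum truncated by
#' Geyer's initial positive sequence rule.
#'
#' @param x a numeric trace.
#' @return the ESS; a constant trace returns `length(x)` with a warning.
#' @export
compute_ess <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0 || is.na(stats::sd(x))) {
    warning("constant trace: ESS undefined, reporting n", call. = FALSE)
    return(n)
  }
  rho <- stats::acf(x, lag.max = min(n - 1L, 1000L), plot = FALSE)$acf[-1]
  s <- 0
  k <- 1L
  while (k < length(rho)) {
    pair <- rho[k] + (if (k + 1L <= length(rho)) rho[k + 1L] else 0)
    if (pair < 0) break
    s <- s + pair
    k <- k + 2L
  }
  max(1, min(n, n / (1 + 2 * s)))
}

#' PSRF and ESS for every numeric parameter of a set of runs
#'
#' @param fit an `mcmc_runs` object (or a list of trace data frames).
#' @param burnin_frac burn-in fraction to discard.
#' @return data frame with columns `parameter`, `psrf`, `ess` (ESS summed
#'   over runs).
#' @export
compute_psrf_ess <- function(fit, burnin_frac = NULL) {
  traces <- if (inherits(fit, "mcmc_runs")) {
    burnin_frac <- burnin_frac %||% fit$config$burnin_frac
    lapply(fit$runs, function(r) {
      n <- nrow(r$trace)
      r$trace[seq.int(floor(n * burnin_frac) + 1L, n), , drop = FALSE]
    })
  } else fit
  pars <- setdiff(names(traces[[1]]), c("gen", "run"))
  pars <- pars[vapply(pars, function(p) is.numeric(traces[[1]][[p]]), logical(1))]
  out <- data.frame(parameter = pars, psrf = NA_real_, ess = NA_real_)
  for (i in seq_along(pars)) {
    cols <- lapply(traces, `[[`, pars[i])
    out$psrf[i] <- if (length(traces) > 1) compute_psrf(cols) else NA
    out$ess[i] <- sum(vapply(cols, function(x)
      suppressWarnings(compute_ess(x)), numeric(1)))
    if (any(vapply(cols, function(x) stats::sd(x) == 0, logical(1))))
      warning("constant trace for '", pars[i], "': ESS reported as n",
              call. = FALSE)
  }
  out
}
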