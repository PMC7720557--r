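# Morphological clock models: strict, uncorrelated (IGR) and autocorrelated
# (TK02), base-rate prior derivation, and partitioned clocks.

#' Derive the base clock-rate prior from a non-clock analysis
#'
#' The prior mean is the median tree height in substitutions per character
#' divided by the median root age (Ma), i.e. substitutions/character/Myr.
#' Lognormal parameters place the log-mean at `log(ratio)` with a broad
#' log-sd of `exp(ratio)`; gamma parameters use mean `ratio` and sd 0.5.
#'
#' @param tree_height_substitutions median posterior tree height, expected
#'   substitutions per character (> 0).
#' @param root_age_prior_median median of the root-age prior, Ma (> 0).
#' @return list with `mean`, `lognormal` (meanlog, sdlog) and `gamma`
#'   (mean, sd, shape, rate).
#' @export
derive_clock_prior <- function(tree_height_substitutions, root_age_prior_median) {
  if (tree_height_substitutions <= 0 || root_age_prior_median <= 0)
    stop2("both inputs must be > 0")
  ratio <- tree_height_substitutions / root_age_prior_median
  gmean <- ratio; gsd <- 0.5
  list(mean = ratio,
       lognormal = list(meanlog = log(ratio), sdlog = exp(ratio)),
       gamma = list(mean = gmean, sd = gsd,
                    shape = (gmean / gsd)^2, rate = gmean / gsd^2))
}

#' Minimum characters per partition
#'
#' A partition should carry at least as many characters as the tree has
#' branches (each character contributing about one state change), i.e.
#' `2n - 1` for `n` taxa.
#'
#' @param n_taxa number of taxa.
#' @return the bound `2 * n_taxa - 1`.
#' @export
partition_min_characters <- function(n_taxa) 2L * as.integer(n_taxa) - 1L

#' Strict-clock effective branch lengths
#' @param tr a [timetree()].
#' @param base_rate clock rate, substitutions/character/Myr.
#' @return numeric over nodes: `base_rate * duration` (NA at the root).
#' @export
strict_effective_lengths <- function(tr, base_rate) {
  base_rate * branch_durations(tr)
}

#' Sample IGR effective branch lengths from their prior
#'
#' Under the independent gamma rates clock each effective length is a free
#' parameter with prior `Gamma(mean = c t, variance = c t nu)` (shape
#' `c t / nu`, rate `1 / nu`); rates may change sharply between neighboring
#' branches. `nu -> 0` collapses to the strict clock.
#'
#' @param durations branch durations over nodes, Myr (NA at the root).
#' @param base_rate clock base rate `c` (> 0).
#' @param nu_igr IGR variance parameter (>= 0).
#' @return numeric vector of effective lengths over nodes (NA at the root).
#' @export
igr_sample_lengths <- function(durations, base_rate, nu_igr) {
  if (base_rate <= 0) stop2("base_rate must be > 0")
  if (nu_igr < 0) stop2("nu_igr must be >= 0")
  v <- durations * base_rate
  if (nu_igr < 1e-12) return(v)
  ok <- which(!is.na(durations) & durations > 0)
  v[ok] <- stats::rgamma(length(ok), shape = base_rate * durations[ok] / nu_igr,
                         rate = 1 / nu_igr)
  v
}

#' IGR log-prior of effective branch lengths
#' @inheritParams igr_sample_lengths
#' @param v effective lengths over nodes (NA at the root).
#' @return log prior density; `-Inf` when a zero-duration branch carries a
#'   positive effective length.
#' @export
igr_log_prior <- function(v, durations, base_rate, nu_igr) {
  ok <- which(!is.na(durations))
  zero <- durations[ok] <= 0
  if (any(zero)) {
    if (any(v[ok][zero] > SA_TOL)) return(-Inf)
    ok <- ok[!zero]
  }
  if (nu_igr < 1e-12)
    return(if (all(abs(v[ok] - base_rate * durations[ok]) < 1e-6)) 0 else -Inf)
  sum(stats::dgamma(v[ok], shape = base_rate * durations[ok] / nu_igr,
                    rate = 1 / nu_igr, log = TRUE))
}

#' Sample TK02 node rates from their prior
#'
#' Autocorrelated lognormal ("geometric Brownian") rates: the root rate is
#' the base rate `c`; each child's rate is lognormal around its parent's
#' with log-variance `nu_tk * t` (log-mean `log r_parent - nu_tk t / 2`), so
#' `E[r_child | r_parent] = r_parent`.
#'
#' @param tr a [timetree()].
#' @param base_rate root rate `c` (> 0).
#' @param nu_tk TK02 variance parameter per Myr (>= 0).
#' @return numeric node rates (root = `base_rate`).
#' @export
tk02_sample_rates <- function(tr, base_rate, nu_tk) {
  if (base_rate <= 0) stop2("base_rate must be > 0")
  if (nu_tk < 0) stop2("nu_tk must be >= 0")
  m <- length(tr$parent)
  rates <- numeric(m)
  root <- tree_root(tr)
  rates[root] <- base_rate
  for (v in c(rev(postorder_nodes(tr)), seq_len(tr$n_tip))) {
    if (v == root) next
    t <- tr$age[tr$parent[v]] - tr$age[v]
    rp <- rates[tr$parent[v]]
    if (rp == 0) { rates[v] <- 0; next }
    s2 <- nu_tk * t
    rates[v] <- if (s2 <= 0) rp else
      stats::rlnorm(1, meanlog = log(rp) - s2 / 2, sdlog = sqrt(s2))
  }
  rates
}

#' TK02 log-prior of node rates
#' @inheritParams tk02_sample_rates
#' @param rates node-rate vector (root entry must equal `base_rate`).
#' @return log prior density; `-Inf` for non-positive rates.
#' @export
tk02_log_prior <- function(rates, tr, base_rate, nu_tk) {
  root <- tree_root(tr)
  if (any(rates <= 0)) return(-Inf)
  if (abs(rates[root] - base_rate) > 1e-12 * base_rate) return(-Inf)
  nr <- which(tr$parent > 0L)
  t <- tr$age[tr$parent[nr]] - tr$age[nr]
  s2 <- nu_tk * t
  rp <- rates[tr$parent[nr]]
  z <- s2 <= 0
  if (any(z) && any(abs(rates[nr][z] - rp[z]) > 1e-9 * rp[z])) return(-Inf)
  sum(stats::dlnorm(rates[nr][!z], meanlog = log(rp[!z]) - s2[!z] / 2,
                    sdlog = sqrt(s2[!z]), log = TRUE))
}

#' TK02 effective branch lengths from node rates
#'
#' The rate on a branch is the arithmetic mean of its endpoint node rates;
#' effective length = duration * (r_parent + r_child) / 2.
#'
#' @param tr a [timetree()].
#' @param rates node rates (from [tk02_sample_rates()] or MCMC).
#' @return numeric effective lengths over nodes (NA at the root).
#' @export
tk02_effective_lengths <- function(tr, rates) {
  d <- branch_durations(tr)
  nr <- which(tr$parent > 0L)
  out <- rep(NA_real_, length(d))
  out[nr] <- d[nr] * (rates[tr$parent[nr]] + rates[nr]) / 2
  out
}

#' Per-partition effective lengths and joint likelihood
#'
#' Applies one clock per partition on a shared tree (topology and node ages
#' linked, clock states unlinked); the joint log-likelihood is the sum of
#' per-partition Mkv log-likelihoods. Warns when a partition carries fewer
#' than `2n - 1` characters.
#'
#' @param tr shared [timetree()].
#' @param mat a partitioned [morph_matrix()].
#' @param clock_states named list (one per partition label) with fields
#'   `model` ("strict", "igr", "tk02"), `base_rate`, and the model's
#'   per-branch state (`v` for IGR, `rates` for TK02).
#' @param spec an [mk_model_spec()] shared across partitions.
#' @return list with `eff_lengths` (named list per partition), `loglik`
#'   (total), and `per_partition` log-likelihoods.
#' @export
apply_partition_clocks <- function(tr, mat, clock_states, spec = mk_model_spec()) {
  if (is.null(mat$partition)) stop2("matrix has no partition map")
  labels <- unique(mat$partition)
  if (!all(labels %in% names(clock_states)))
    stop2("missing clock state for partition(s): ",
          paste(setdiff(labels, names(clock_states)), collapse = ", "))
  bound <- partition_min_characters(length(mat$taxa))
  small <- labels[table(mat$partition)[labels] < bound]
  if (length(small))
    warning("partition(s) below the 2n-1 = ", bound, " character bound: ",
            paste(small, collapse = ", "), call. = FALSE)
  eff <- list(); ll <- numeric(0)
  for (lab in labels) {
    cs <- clock_states[[lab]]
    eff[[lab]] <- switch(cs$model,
      strict = strict_effective_lengths(tr, cs$base_rate),
      igr = cs$v,
      tk02 = tk02_effective_lengths(tr, cs$rates),
      stop2("unknown clock model '", cs$model, "'"))
    ll[lab] <- matrix_log_likelihood(tr, eff[[lab]], subset_partition(mat, lab), spec)
  }
  list(eff_lengths = eff, loglik = sum(ll), per_partition = ll)
}
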