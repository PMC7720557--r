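# Stepping-stone estimation of marginal model likelihoods and Bayes factors
# on the 2 ln scale.

#' Stepping-stone power schedule
#'
#' Powers beta taken at quantiles of Beta(`alpha`, 1) — the usual schedule
#' that concentrates steps near the prior where the integrand changes
#' fastest.
#'
#' @param n_steps number of stones (the study used 50).
#' @param alpha Beta-distribution shape (default 0.4).
#' @return increasing vector of `n_steps + 1` powers from 0 to 1.
#' @export
ss_schedule <- function(n_steps, alpha = 0.4) {
  stats::qbeta(seq(0, 1, length.out = n_steps + 1L), alpha, 1)
}

#' Stepping-stone marginal log-likelihood from power-posterior samples
#'
#' Each stone estimates the ratio of normalizing constants between adjacent
#' powers from samples at the lower power:
#' `lnML = sum_k ln mean exp((beta_{k+1} - beta_k) * lnL_k)`,
#' computed in log space for stability. A constant likelihood `L0` gives
#' exactly `ln L0`.
#'
#' @param loglik_samples list of numeric vectors; element `k` holds data
#'   log-likelihoods sampled from the power posterior at `betas[k]`.
#' @param betas increasing powers of length `length(loglik_samples) + 1`,
#'   starting at 0 and ending at 1.
#' @return the estimated marginal log-likelihood.
#' @export
stepping_stone_lnML <- function(loglik_samples, betas) {
  K <- length(loglik_samples)
  if (length(betas) != K + 1L) stop2("need one more beta than sample sets")
  if (is.unsorted(betas, strictly = TRUE)) stop2("betas must increase")
  if (any(vapply(loglik_samples, length, integer(1)) == 0L))
    stop2("a step has zero samples")
  total <- 0
  for (k in seq_len(K)) {
    db <- betas[k + 1L] - betas[k]
    total <- total + logmeanexp(db * loglik_samples[[k]])
  }
  total
}

#' Run stepping-stone sampling for one model configuration
#'
#' Runs the MCMC engine along a descending power ladder (posterior toward
#' prior, each stone seeded by the previous one's final state), discards the
#' first `step_burnin` fraction of each stone, and returns the estimated
#' marginal log-likelihood.
#'
#' @param config a [run_config()] (its `generations` field is ignored here).
#' @param mat,calibrations data as for [run_mcmc()].
#' @param n_steps number of stones.
#' @param gens_per_step generations per stone.
#' @param step_burnin per-stone burn-in fraction.
#' @param alpha Beta shape of the power schedule.
#' @return list with `lnML`, `betas`, per-stone mean log-likelihoods, and
#'   the per-stone sample lists.
#' @export
run_stepping_stone <- function(config, mat, calibrations, n_steps = 20,
                               gens_per_step = 2000, step_burnin = 0.25,
                               alpha = 0.4) {
  stopifnot(inherits(config, "run_config"))
  if (!config$likelihood_on) stop2("stepping stone needs the likelihood on")
  ctx <- build_ctx(config, mat, calibrations)
  weights <- active_moves(config)
  betas <- ss_schedule(n_steps, alpha)
  set.seed(derive_seed(config$seed, 977L))
  cfg_step <- config
  cfg_step$generations <- as.integer(gens_per_step)
  ctx$cfg <- cfg_step
  # seeding pass at beta = 1
  ctx$beta <- 1
  st <- mcmc_single_run(ctx, weights, run_id = 0L)$final_state
  samples <- vector("list", n_steps)
  means <- numeric(n_steps)
  for (k in rev(seq_len(n_steps))) {     # beta_k descending: K..1
    ctx$beta <- betas[k]
    run <- mcmc_single_run(ctx, weights, run_id = k, init_st = st,
                           record_raw = TRUE)
    st <- run$final_state
    n <- nrow(run$trace)
    keep <- seq.int(floor(n * step_burnin) + 1L, n)
    samples[[k]] <- run$trace$raw_loglik[keep]
    means[k] <- mean(samples[[k]])
  }
  list(lnML = stepping_stone_lnML(samples, betas), betas = betas,
       step_means = means, samples = samples)
}

#' Bayes factor on the 2 ln scale
#'
#' `2 ln B12 = 2 (lnML1 - lnML2)`; by the usual interpretation bands, values
#' above 10 are strong support for model 1, 6-10 strong-ish, 2-6 positive,
#' 0-2 barely worth mentioning.
#'
#' @param lnML_1,lnML_2 marginal log-likelihoods.
#' @return the scalar `2 ln B12`.
#' @export
bayes_factor_2ln <- function(lnML_1, lnML_2) {
  if (!is.finite(lnML_1) || !is.finite(lnML_2)) stop2("lnML must be finite")
  2 * (lnML_1 - lnML_2)
}

#' Rank models by marginal likelihood
#'
#' @param lnML named numeric vector of marginal log-likelihoods.
#' @return data frame sorted best first with `lnML`, `rank`, and
#'   `bf2ln_vs_best` (`2 ln BF` of the best model over each model; the
#'   second row therefore holds the headline best-vs-second-best value).
#' @export
model_rank_table <- function(lnML) {
  ord <- order(-lnML)
  data.frame(model = names(lnML)[ord], lnML = unname(lnML[ord]),
             rank = seq_along(lnML),
             bf2ln_vs_best = 2 * (max(lnML) - unname(lnML[ord])))
}
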