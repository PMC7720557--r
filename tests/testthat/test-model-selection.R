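test_that("stepping-stone estimator is exact for a constant likelihood", {
  betas <- ss_schedule(10)
  samp <- rep(list(rep(-7.3, 200)), 10)
  expect_equal(stepping_stone_lnML(samp, betas), -7.3, tolerance = 1e-12)
})

test_that("stepping stone recovers the conjugate binomial marginal", {
  # y = 3 successes in n = 10 with a uniform prior: lnML = ln(1/11)
  set.seed(40)
  K <- 20
  betas <- ss_schedule(K)
  samp <- lapply(seq_len(K), function(k) {
    b <- betas[k]
    p <- rbeta(2000, b * 3 + 1, b * 7 + 1)   # power posterior, conjugate
    dbinom(3, 10, p, log = TRUE)
  })
  lnml <- stepping_stone_lnML(samp, betas)
  expect_equal(lnml, log(1 / 11), tolerance = 0.05)
  # two independent estimates agree within combined Monte Carlo error
  samp2 <- lapply(seq_len(K), function(k) {
    b <- betas[k]
    p <- rbeta(2000, b * 3 + 1, b * 7 + 1)
    dbinom(3, 10, p, log = TRUE)
  })
  expect_equal(stepping_stone_lnML(samp2, betas), lnml, tolerance = 0.1)
})

test_that("the estimator is invariant to shifting all log-likelihoods", {
  set.seed(41)
  betas <- ss_schedule(8)
  samp <- lapply(1:8, function(k) rnorm(300, -500, 3))
  base <- stepping_stone_lnML(samp, betas)
  shifted <- stepping_stone_lnML(lapply(samp, function(x) x - 1e4), betas)
  expect_equal(shifted, base - 1e4, tolerance = 1e-9)
  expect_error(stepping_stone_lnML(list(numeric(0)), ss_schedule(1)),
               "zero samples")
})

test_that("Bayes factors on the 2 ln scale reproduce the published gap", {
  lnml <- c(`IGR+ga` = -1211.33, `IGR+ln` = -1208.93,
            `TK02+ga` = -1209.39, `TK02+ln` = -1195.67)
  tab <- model_rank_table(lnml)
  expect_equal(tab$model[1], "TK02+ln")
  expect_equal(tab$bf2ln_vs_best[2], 26.52, tolerance = 1e-9)
  expect_equal(bayes_factor_2ln(-5, -5), 0)
  expect_equal(unname(bayes_factor_2ln(lnml["TK02+ln"], lnml["IGR+ln"])),
               26.52, tolerance = 1e-9)
})

test_that("beta schedule is strictly increasing from 0 to 1", {
  b <- ss_schedule(50)
  expect_equal(b[1], 0)
  expect_equal(b[51], 1)
  expect_true(all(diff(b) > 0))
  # Beta(0.4, 1) quantiles concentrate steps near the prior
  expect_lt(b[26], 0.5)
})

test_that("stepping stone through the MCMC engine matches a grid-computed
           marginal likelihood on a tiny fixed-tree problem", {
  # fixed tree and topology, strict clock: the only sampled quantities that
  # touch the likelihood are the base rate (and node ages, held fixed here),
  # so lnML = log integral of L(c) over the prior on c, computable by
  # quadrature
  set.seed(42)
  cal <- calibration_table(c("t1", "t2", "t3", "t4"),
                           c(0, 0, 4, 8), c(0, 0, 4, 8))
  start <- timetree(c(5, 5, 6, 7, 6, 7, 0), c(0, 0, 4, 8, 2, 6, 12),
                    c("t1", "t2", "t3", "t4"))
  sp <- simulation_spec(root_age = 12, d = 0.05, r = 0.3, s = 0.3,
                        strategy = "random", n_extant_range = c(1, 99), partitions = c(all = 12),
                        clock_model = "strict", base_rate = 0.1,
                        acrv_kind = "none", autapomorphy_target = NA,
                        missing_fraction = 0, x_cut = 0, seed = 43,
                        taxa_range = c(2, 10))
  mat <- simulate_matrix(start, sp)
  cfg <- run_config(label = "ss", clock_model = "strict", acrv_kind = "none",
                    strategy = "fossiltip",
                    clock_rate_prior = list(kind = "lognormal",
                                            meanlog = log(0.1), sdlog = 0.6),
                    fbd_fixed = list(d = 0.05, r = 0.3, s = 0.3),
                    root_prior = root_calibration("offset_exponential",
                                                  offset = 11.9, mean = 12),
                    topology_fixed = TRUE, starting_tree = start,
                    move_weights = c(node_age = 0, root_age = 0, tip_age = 0,
                                     base_rate = 5),
                    sample_every = 5, n_runs = 1, seed = 44)
  ss <- run_stepping_stone(cfg, mat, cal, n_steps = 12, gens_per_step = 1500)
  loglik_c <- function(cc) matrix_log_likelihood(
    start, strict_effective_lengths(start, cc), mat, mk_model_spec("none"))
  shift <- loglik_c(0.1)
  quad <- integrate(function(cc) {
    vapply(cc, function(one)
      exp(loglik_c(one) - shift) * dlnorm(one, log(0.1), 0.6), numeric(1))
  }, 1e-4, 2, rel.tol = 1e-8)
  truth <- log(quad$value) + shift
  expect_equal(ss$lnML, truth, tolerance = 0.25)
})

test_that("stepping stone through the engine prefers the generating clock
           model on uncorrelated-rates data", {
  pref_rep <- function(seed) {
    set.seed(seed)
    sp <- simulation_spec(root_age = 60, d = 0.04, r = 0.5, s = 0.4,
                          strategy = "random", n_extant_range = c(1, 99),
                          taxa_range = c(8, 12), partitions = c(all = 130),
                          clock_model = "igr", base_rate = 0.04,
                          clock_variance = 0.1, acrv_kind = "none",
                          autapomorphy_target = NA, missing_fraction = 0,
                          x_cut = 0, seed = seed * 7 + 5)
    sim <- try(simulate_fbd_tree(sp, max_tries = 300), silent = TRUE)
    if (inherits(sim, "try-error")) return(NA)
    mat <- simulate_matrix(sim$tree, sp)
    ss_for <- function(model) {
      cfg <- run_config(label = model, clock_model = model,
                        strategy = "fossiltip", acrv_kind = "none",
                        clock_rate_prior = list(kind = "lognormal",
                                                meanlog = log(0.04),
                                                sdlog = 0.6),
                        fbd_fixed = list(d = 0.04, r = 0.5, s = 0.4),
                        topology_fixed = TRUE, starting_tree = sim$tree,
                        root_prior = root_calibration("offset_exponential",
                                                      offset = 55, mean = 90),
                        sample_every = 5, n_runs = 1, seed = seed)
      run_stepping_stone(cfg, mat, sim$calibrations, n_steps = 10,
                         gens_per_step = 1000)$lnML
    }
    bayes_factor_2ln(ss_for("tk02"), ss_for("igr"))
  }
  bf <- vapply(1:3, pref_rep, numeric(1))
  bf <- bf[!is.na(bf)]
  expect_gte(length(bf), 2)
  expect_gte(sum(bf < 0), length(bf) - 1)   # IGR preferred
  expect_lt(mean(bf), 0)
})
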