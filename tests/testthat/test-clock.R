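test_that("clock-rate prior derivation reproduces the worked values", {
  cp <- derive_clock_prior(5.3456, 267.1)
  expect_equal(round(cp$mean, 2), 0.02)
  expect_equal(cp$lognormal$meanlog, -3.9120, tolerance = 5e-4)
  expect_equal(cp$lognormal$sdlog, 1.0202, tolerance = 5e-4)
  expect_equal(cp$gamma$mean, 0.02, tolerance = 1e-3)
  expect_equal(cp$gamma$sd, 0.5)
  # implied shape/rate reproduce the stated mean and sd
  expect_equal(cp$gamma$shape / cp$gamma$rate, cp$gamma$mean)
  expect_equal(sqrt(cp$gamma$shape) / cp$gamma$rate, 0.5)
  expect_error(derive_clock_prior(0, 100), "> 0")
})

test_that("partition size bound is 2n - 1", {
  expect_equal(partition_min_characters(35), 69L)
  expect_equal(partition_min_characters(10), 19L)
})

test_that("IGR reduces to the strict clock as its variance vanishes", {
  tr <- fossil4()
  d <- branch_durations(tr)
  set.seed(1)
  v <- igr_sample_lengths(d, 0.02, 1e-13)
  expect_equal(v[!is.na(d)], 0.02 * d[!is.na(d)], tolerance = 1e-6)
})

test_that("IGR prior has the stated moments", {
  # c=0.02, t=10, nu=0.02: mean 0.2, variance 0.004
  set.seed(2)
  draws <- rgamma(1e5, shape = 0.02 * 10 / 0.02, rate = 1 / 0.02)
  expect_equal(mean(draws), 0.2, tolerance = 3 * sd(draws) / sqrt(1e5))
  d <- c(10, NA)
  v <- igr_sample_lengths(d, 0.02, 0.02)
  lp <- igr_log_prior(v, d, 0.02, 0.02)
  expect_equal(lp, dgamma(v[1], shape = 10, rate = 50, log = TRUE))
  # Monte Carlo mean of sampled lengths matches c*t
  set.seed(3)
  many <- replicate(1e4, igr_sample_lengths(d, 0.02, 0.02)[1])
  expect_equal(mean(many), 0.2, tolerance = 3 * sd(many) / sqrt(1e4))
  # zero-duration branch with positive effective length is impossible
  tr <- timetree(c(5, 5, 6, 7, 6, 7, 0), c(0, 3, 4, 0, 3, 6, 10),
                 c("A", "B", "C", "D"))
  dz <- branch_durations(tr)
  vz <- igr_sample_lengths(dz, 0.02, 0.01)
  vz[2] <- 0.1   # SA tip branch has zero duration
  expect_identical(igr_log_prior(vz, dz, 0.02, 0.01), -Inf)
})

test_that("TK02 preserves the parent rate in expectation and reduces to a
           strict clock at zero variance", {
  tr <- fossil4()
  set.seed(4)
  r0 <- tk02_sample_rates(tr, 0.02, 0)
  expect_equal(r0, rep(0.02, 7))
  eff <- tk02_effective_lengths(tr, r0)
  d <- branch_durations(tr)
  expect_equal(eff[!is.na(d)], 0.02 * d[!is.na(d)])
  # increment variance matches nu * t (sampling oracle)
  nu <- 0.3; t <- 2.5
  set.seed(5)
  logs <- log(rlnorm(1e5, log(0.02) - nu * t / 2, sqrt(nu * t))) - log(0.02)
  expect_equal(var(logs), nu * t, tolerance = 3 * 0.02)
  expect_equal(mean(exp(logs)), 1, tolerance = 0.02)  # mean preservation
  # prior rejects non-positive rates
  r0[2] <- -1
  expect_identical(tk02_log_prior(r0, tr, 0.02, 0.1), -Inf)
})

test_that("effective lengths scale linearly in the base rate", {
  tr <- fossil4()
  expect_equal(strict_effective_lengths(tr, 0.04),
               2 * strict_effective_lengths(tr, 0.02))
  set.seed(6)
  r <- tk02_sample_rates(tr, 0.02, 0.1)
  expect_equal(tk02_effective_lengths(tr, 2 * r),
               2 * tk02_effective_lengths(tr, r))
})

test_that("partitioned clocks sum to the single-clock likelihood when
           clock states are identical", {
  sp <- simulation_spec(root_age = 60, d = 0.05, r = 0.5, s = 0.4,
                        strategy = "random", n_extant_range = c(1, 99), taxa_range = c(6, 12),
                        partitions = c(skull = 10, mandible = 10,
                                       postcranial = 8),
                        clock_model = "strict", base_rate = 0.05,
                        acrv_kind = "none", autapomorphy_target = NA,
                        missing_fraction = 0, x_cut = 0, seed = 21)
  sim <- simulate_fbd_tree(sp)
  mat <- simulate_matrix(sim$tree, sp)
  cs <- list(model = "strict", base_rate = 0.05)
  states <- list(skull = cs, mandible = cs, postcranial = cs)
  spec <- mk_model_spec("none")
  expect_warning(apply_partition_clocks(sim$tree, mat, states, spec),
                 "2n-1")   # all three partitions are under the size bound
  res <- suppressWarnings(apply_partition_clocks(sim$tree, mat, states, spec))
  single <- matrix_log_likelihood(sim$tree,
                                  strict_effective_lengths(sim$tree, 0.05),
                                  mat, spec)
  expect_equal(res$loglik, single, tolerance = 1e-9)
  expect_error(apply_partition_clocks(sim$tree, mat, states["skull"], spec),
               "missing clock state")
})

test_that("distinct per-partition rates are recovered in the right order", {
  sp <- simulation_spec(root_age = 60, d = 0.05, r = 0.5, s = 0.4,
                        strategy = "random", n_extant_range = c(1, 99), taxa_range = c(8, 14),
                        partitions = c(slow = 40, medium = 40, fast = 40),
                        clock_model = "strict", base_rate = 1,
                        acrv_kind = "none", autapomorphy_target = NA,
                        missing_fraction = 0, x_cut = 0, seed = 22)
  sim <- simulate_fbd_tree(sp)
  rates <- c(slow = 0.01, medium = 0.04, fast = 0.12)
  mats <- lapply(names(rates), function(p) {
    spp <- sp
    spp$partitions <- stats::setNames(40, p)
    spp$base_rate <- rates[[p]]
    simulate_matrix(sim$tree, spp)
  })
  # profile the strict-clock likelihood over a rate grid per partition
  grid <- exp(seq(log(0.002), log(0.5), length.out = 40))
  est <- vapply(mats, function(m) {
    ll <- vapply(grid, function(cc)
      matrix_log_likelihood(sim$tree, strict_effective_lengths(sim$tree, cc),
                            m, mk_model_spec("none")), numeric(1))
    grid[which.max(ll)]
  }, numeric(1))
  expect_true(est[1] < est[2] && est[2] < est[3])
})
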