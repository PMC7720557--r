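test_that("Mk transition probabilities match the closed form and expm", {
  P <- mk_transition_probability(2, 0.1)
  expect_equal(P[1, 1], 0.90937, tolerance = 1e-4)
  expect_equal(P[1, 2], 0.09063, tolerance = 1e-4)
  expect_equal(mk_transition_probability(3, 0), diag(3))
  # stationarity limit
  expect_equal(mk_transition_probability(4, 50),
               matrix(0.25, 4, 4), tolerance = 1e-8)
  # rows are distributions
  for (k in 2:5) {
    P <- mk_transition_probability(k, 0.37)
    expect_equal(rowSums(P), rep(1, k), tolerance = 1e-12)
    expect_true(all(P >= 0))
  }
  # independent oracle: matrix exponential of the unit-mean-rate generator
  for (k in c(2L, 4L)) for (nu in c(0.05, 0.6, 2)) {
    Q <- matrix(1 / (k - 1), k, k); diag(Q) <- -1
    Pexp <- as.matrix(Matrix::expm(Q * nu))
    expect_equal(mk_transition_probability(k, nu), Pexp, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  expect_error(mk_transition_probability(2, -0.1), "nu")
})

test_that("ACRV discretization gives mean-1 equal-weight category means", {
  one <- discretize_acrv(mk_model_spec("gamma", 0.5, n_rate_categories = 1))
  expect_equal(one$rate, 1)
  d <- discretize_acrv(mk_model_spec("gamma", 0.5, n_rate_categories = 4))
  expect_equal(sum(d$rate * d$weight), 1, tolerance = 1e-9)
  expect_true(all(diff(d$rate) > 0))
  # quadrature oracle for the category means of Gamma(0.5, 0.5)
  br <- qgamma(seq(0, 1, 0.25), 0.5, rate = 0.5)
  for (i in 1:4) {
    num <- integrate(function(x) x * dgamma(x, 0.5, rate = 0.5),
                     br[i], min(br[i + 1], 1e3))$value
    expect_equal(d$rate[i], num * 4, tolerance = 1e-3)
  }
  # degenerate gamma: huge shape collapses all rates to 1
  dd <- discretize_acrv(mk_model_spec("gamma", 1e6, n_rate_categories = 4))
  expect_equal(dd$rate, rep(1, 4), tolerance = 1e-2)
  dl <- discretize_acrv(mk_model_spec("lognormal", 0.8, n_rate_categories = 4))
  expect_equal(sum(dl$rate * dl$weight), 1, tolerance = 1e-9)
  expect_error(discretize_acrv(mk_model_spec("gamma", -1)), "acrv_shape")
})

test_that("asymmetric frequency mixtures follow the Beta quantile oracle", {
  fm <- asymmetric_frequency_mixture(2, 1, 4)
  expect_equal(fm$freqs[, 1], qbeta(c(1, 3, 5, 7) / 8, 1, 1), tolerance = 1e-12)
  expect_equal(fm$freqs[, 1], rev(fm$freqs[, 2]))          # symmetric pairs
  expect_equal(colSums(fm$freqs * fm$weights), c(0.5, 0.5), tolerance = 1e-9)
  # concentration limit: categories collapse to uniform frequencies
  fmL <- asymmetric_frequency_mixture(3, 1e6, 4)
  expect_true(max(abs(fmL$freqs - 1 / 3)) < 1e-2)
  # k > 2 lattice keeps the weighted mean exactly uniform
  fm3 <- asymmetric_frequency_mixture(4, 0.3, 3)
  expect_equal(colSums(fm3$freqs * fm3$weights), rep(0.25, 4),
               tolerance = 1e-9)
  expect_error(asymmetric_frequency_mixture(2, 0), "alpha_dir")
})

test_that("two-taxon likelihood matches hand enumeration", {
  tr2 <- timetree(c(3, 3, 0), c(0, 0, 10), c("A", "B"))
  m2 <- morph_matrix(rbind(A = "0", B = "1"))
  ll <- matrix_log_likelihood(tr2, c(0.05, 0.05, NA), m2,
                              mk_model_spec("none", correct = FALSE))
  expect_equal(exp(ll), 0.04532, tolerance = 1e-4)
  # corrected: the two variable binary patterns are equiprobable and
  # exhaust the variable-pattern space
  for (v in list(c(0.3, 0.2), c(0.01, 0.5), c(1, 1))) {
    llc <- matrix_log_likelihood(tr2, c(v, NA), m2, mk_model_spec("none"))
    expect_equal(exp(llc), 0.5, tolerance = 1e-12)
  }
})

test_that("pruning equals exhaustive enumeration for every model variant", {
  tr <- tree5()
  mm <- matrix5()
  eff <- c(0.1, 0.25, 0.07, 0.3, 0.12, 0.2, 0.15, 0.08, NA)
  specs <- list(
    mk_model_spec("none"),
    mk_model_spec("none", correct = FALSE),
    mk_model_spec("gamma", 0.6, 4),
    mk_model_spec("lognormal", 0.9, 3),
    mk_model_spec("gamma", 0.6, 4, freq_model = "asymmetric",
                  alpha_dir = 0.7, n_freq_categories = 3))
  for (spec in specs) {
    expect_equal(matrix_log_likelihood(tr, eff, mm, spec),
                 brute_mk_loglik(tr, eff, mm, spec), tolerance = 1e-10)
  }
})

test_that("high-concentration asymmetric model converges to symmetric", {
  tr <- tree5()
  mm <- matrix5()
  eff <- c(0.1, 0.25, 0.07, 0.3, 0.12, 0.2, 0.15, 0.08, NA)
  sym <- matrix_log_likelihood(tr, eff, mm, mk_model_spec("gamma", 1, 4))
  asym <- matrix_log_likelihood(tr, eff, mm,
            mk_model_spec("gamma", 1, 4, freq_model = "asymmetric",
                          alpha_dir = 20, n_freq_categories = 4))
  expect_lt(abs(sym - asym), 0.1)
})

test_that("two-taxon pattern likelihoods are continuous and monotone in
           branch length before correction", {
  tr2 <- timetree(c(3, 3, 0), c(0, 0, 10), c("A", "B"))
  m2 <- morph_matrix(rbind(A = "0", B = "1"))
  nus <- seq(0.2, 3, 0.2)
  # the variable pattern rises monotonically toward its stationary value
  # 1/4; the constant pattern (computed directly from the transition
  # probabilities) decreases toward the same limit
  lls <- vapply(nus, function(nu)
    matrix_log_likelihood(tr2, c(nu / 2, nu / 2, NA), m2,
                          mk_model_spec("none", correct = FALSE)),
    numeric(1))
  expect_true(all(diff(lls) > 0))
  expect_true(all(lls < log(0.25)))
  const <- vapply(nus, function(nu) {
    P <- mk_transition_probability(2, nu / 2)
    log(0.5 * (P[1, 1]^2 + P[1, 2]^2))   # both tips in the same state
  }, numeric(1))
  expect_true(all(diff(const) < 0))
})

test_that("constant and all-missing characters are rejected, not absorbed", {
  tr <- ultra4()
  eff <- c(0.1, 0.1, 0.1, 0.1, 0.1, 0.1, NA)
  base <- morph_matrix(rbind(A = "0", B = "1", C = "0", D = "1"))
  ll0 <- matrix_log_likelihood(tr, eff, base, mk_model_spec("none"))
  with_const <- suppressWarnings(
    morph_matrix(rbind(A = c("0", "0"), B = c("1", "0"),
                       C = c("0", "0"), D = c("1", "0"))))
  expect_error(matrix_log_likelihood(tr, eff, with_const, mk_model_spec("none")),
               "ascertainment")
  with_missing_col <- suppressWarnings(
    morph_matrix(rbind(A = c("0", "?"), B = c("1", "?"),
                       C = c("0", "?"), D = c("1", "?"))))
  expect_error(matrix_log_likelihood(tr, eff, with_missing_col,
                                     mk_model_spec("none")), "ascertainment")
  expect_equal(ll0, matrix_log_likelihood(tr, eff, base, mk_model_spec("none")))
})
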