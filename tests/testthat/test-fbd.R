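test_that("(d, r, s) <-> (lambda, mu, psi) conversions are mutual inverses", {
  expect_equal(to_canonical(0.1, 0.5, 0.5),
               c(lambda = 0.2, mu = 0.1, psi = 0.1))
  expect_equal(to_canonical(0.3, 0, 0), c(lambda = 0.3, mu = 0, psi = 0))
  set.seed(10)
  for (i in 1:1000) {
    d <- runif(1, 1e-4, 2); r <- runif(1); s <- runif(1)
    if (r >= 1 || s >= 1) next
    can <- to_canonical(d, r, s)
    back <- from_canonical(can[1], can[2], can[3])
    expect_true(max(abs(back - c(d = d, r = r, s = s))) < 1e-12)
  }
  expect_error(to_canonical(0.1, 1, 0.5), "r must be")
  expect_error(to_canonical(-0.1, 0.5, 0.5), "d must be")
})

test_that("FBD density collapses to Yule and birth-death closed forms", {
  tr <- ultra4()
  expect_equal(fbd_log_density(tr, fbd_params(0.3, 0, 0, rho = 1),
                               sampling_strategy("fossiltip")),
               yule_log_density_oracle(tr, 0.3), tolerance = 1e-9)
  lambda <- 0.3; mu <- 0.1
  expect_equal(fbd_log_density(tr, fbd_params(lambda - mu, mu / lambda, 0),
                               sampling_strategy("fossiltip")),
               bd_log_density_oracle(tr, lambda, mu), tolerance = 1e-9)
  # psi -> 0 approaches the BD value continuously
  near <- fbd_log_density(tr, fbd_params(lambda - mu, mu / lambda, 1e-9),
                          sampling_strategy("fossiltip"))
  expect_equal(near, bd_log_density_oracle(tr, lambda, mu), tolerance = 1e-5)
})

test_that("skyline with identical slices equals the constant FBD", {
  p <- fbd_params(0.15, 0.4, 0.3)
  trf <- fossil4()
  for (shifts in list(6.5, c(6.5, 2.5), c(8, 5, 1.5))) {
    g <- skyline_grid(shifts, rep(list(p), length(shifts) + 1))
    expect_equal(skyline_fbd_log_density(trf, g, sampling_strategy("random")),
                 fbd_log_density(trf, p, sampling_strategy("random")),
                 tolerance = 1e-9)
  }
})

test_that("skyline masks constrain shared parameters and count free ones", {
  p1 <- fbd_params(0.1, 0.4, 0.3)
  p2 <- fbd_params(0.1, 0.4, 0.05)
  g <- skyline_grid(145, list(p1, p2), free_mask = "s")
  expect_equal(skyline_free_parameters(g), 2 + 2)   # l + 2 with l = 2
  g3 <- skyline_grid(c(145, 66), list(p1, p1, p2), free_mask = "sdr")
  expect_equal(skyline_free_parameters(g3), 9)      # 3 l with l = 3
  px <- fbd_params(0.2, 0.4, 0.05)
  expect_error(skyline_grid(145, list(p1, px), free_mask = "s"),
               "equal across slices")
  expect_error(skyline_grid(c(66, 145), list(p1, p1, p2)), "decreasing")
})

test_that("density is invariant to tip relabeling and finite on valid input", {
  trf <- fossil4()
  p <- fbd_params(0.15, 0.4, 0.3)
  f1 <- fbd_log_density(trf, p, sampling_strategy("random"))
  relab <- trf; relab$tip_label <- c("D", "C", "B", "A")
  expect_equal(fbd_log_density(relab, p, sampling_strategy("random")), f1)
  expect_true(is.finite(f1))
  # never NaN across a sweep of valid parameters
  for (d in c(1e-4, 0.05, 1)) for (r in c(0, 0.5, 0.95)) for (s in c(0.01, 0.7)) {
    v <- fbd_log_density(trf, fbd_params(d, r, s), sampling_strategy("random"))
    expect_false(is.nan(v))
  }
})

test_that("each fossil contributes an increasing term in psi", {
  trf <- fossil4()
  lls <- vapply(c(0.1, 0.2, 0.3, 0.4), function(s)
    fbd_log_density(trf, fbd_params(0.15, 0.4, s), sampling_strategy("random")),
    numeric(1))
  expect_true(all(diff(lls) > 0))
})

test_that("strategies police sampled ancestors and the diversity cutoff", {
  trsa <- timetree(c(5, 5, 6, 7, 6, 7, 0), c(0, 3, 4, 0, 3, 6, 10),
                   c("A", "B", "C", "D"))
  p <- fbd_params(0.15, 0.4, 0.3)
  expect_identical(fbd_log_density(trsa, p, sampling_strategy("fossiltip")),
                   -Inf)
  expect_identical(fbd_log_density(trsa, p, sampling_strategy("nosa_diversity",
                                                              x_cut = 1)),
                   -Inf)
  expect_true(is.finite(fbd_log_density(trsa, p, sampling_strategy("random"))))
  # fossil younger than x_cut is impossible under diversity sampling
  trf <- fossil4()   # fossils at 1.2 and 4
  expect_identical(fbd_log_density(trf, p, sampling_strategy("nosa_diversity",
                                                             x_cut = 2)),
                   -Inf)
  expect_true(is.finite(
    fbd_log_density(trf, p, sampling_strategy("nosa_diversity", x_cut = 1))))
})

test_that("root calibrations have the documented support and mode", {
  oe <- root_calibration("offset_exponential", offset = 247.2, mean = 287)
  lp <- vapply(c(247.2, 260, 290, 350), morphoclock:::root_log_prior,
               numeric(1), cal = oe)
  expect_true(all(diff(lp) < 0))                  # maximal at the offset
  expect_identical(morphoclock:::root_log_prior(247.1, oe), -Inf)
  nor <- root_calibration("truncated_normal", mean = 270, sd = 15,
                          min = 247.2, max = 298.9)
  expect_identical(morphoclock:::root_log_prior(299.0, nor), -Inf)
  expect_identical(morphoclock:::root_log_prior(240, nor), -Inf)
  expect_true(is.finite(morphoclock:::root_log_prior(280, nor)))
  expect_error(root_calibration("offset_exponential", offset = 300, mean = 287),
               "offset")
})

test_that("tip age priors are uniform on ranges and reject bad configurations", {
  trf <- fossil4()
  cal <- calibration_table(c("A", "B", "C", "D"), c(0, 1, 3, 0), c(0, 2, 5, 0))
  oe <- root_calibration()
  trx <- trf; trx$age[which(trx$parent == 0L)] <- 280
  lp <- root_and_tip_log_priors(trx, oe, cal)
  expect_equal(lp, morphoclock:::root_log_prior(280, oe) +
                 dunif(1.2, 1, 2, log = TRUE) + dunif(4, 3, 5, log = TRUE))
  # fossil outside its range
  cal2 <- calibration_table(c("A", "B", "C", "D"), c(0, 2, 3, 0), c(0, 3, 5, 0))
  expect_identical(root_and_tip_log_priors(trx, oe, cal2), -Inf)
  # extant tip with nonzero age is a validation error
  cal3 <- calibration_table(c("A", "B", "C", "D"), c(0, 0, 3, 0), c(0, 0, 5, 0))
  expect_error(root_and_tip_log_priors(trx, oe, cal3), "extant tip")
})
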