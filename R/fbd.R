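# Fossilized birth-death (FBD) tree priors: constant-rate and skyline,
# four taxon-sampling strategies, sampled ancestors, and root/tip age priors.
#
# Parameterization follows the (d, r, s) convention: net diversification
# d = lambda - mu, turnover r = mu / lambda, fossil-sampling proportion
# s = psi / (mu + psi), plus extant-sampling probability rho.

#' Convert (d, r, s) to canonical (lambda, mu, psi)
#' @param d net diversification, events/Myr (> 0).
#' @param r turnover in [0, 1).
#' @param s fossil-sampling proportion in [0, 1).
#' @return named vector `c(lambda, mu, psi)`.
#' @export
to_canonical <- function(d, r, s) {
  if (any(d <= 0)) stop2("d must be > 0")
  if (any(r < 0 | r >= 1)) stop2("r must be in [0, 1)")
  if (any(s < 0 | s >= 1)) stop2("s must be in [0, 1)")
  lambda <- d / (1 - r)
  mu <- lambda * r
  psi <- mu * s / (1 - s)
  c(lambda = unname(lambda), mu = unname(mu), psi = unname(psi))
}

#' Convert canonical (lambda, mu, psi) back to (d, r, s)
#' @param lambda,mu,psi speciation, extinction and fossil-sampling rates.
#' @return named vector `c(d, r, s)`.
#' @export
from_canonical <- function(lambda, mu, psi) {
  c(d = unname(lambda - mu), r = unname(mu / lambda),
    s = unname(if (mu + psi > 0) psi / (mu + psi) else 0))
}

#' FBD parameter set
#' @inheritParams to_canonical
#' @param rho extant-sampling probability in (0, 1].
#' @return an `fbd_params` list (with canonical rates attached).
#' @export
fbd_params <- function(d, r, s, rho = 1) {
  if (rho <= 0 || rho > 1) stop2("rho must be in (0, 1]")
  can <- to_canonical(d, r, s)
  structure(list(d = d, r = r, s = s, rho = rho,
                 lambda = can[["lambda"]], mu = can[["mu"]], psi = can[["psi"]]),
            class = "fbd_params")
}

#' Taxon-sampling strategy
#'
#' `fossiltip`: random sampling, fossils as tips only. `random`: random
#' sampling, fossils may be sampled ancestors. `diversity`: diversified
#' extant sampling with cutoff `x_cut`, ancestors allowed. `nosa_diversity`:
#' diversity sampling with sampled-ancestor moves disabled (fossils as tips
#' only).
#'
#' @param name one of `"fossiltip"`, `"random"`, `"diversity"`,
#'   `"nosa_diversity"`.
#' @param x_cut cutoff time (Ma) after which no fossils are sampled, used by
#'   the diversity strategies.
#' @return a `sampling_strategy` list with `sa_allowed` and `diversified`
#'   flags.
#' @export
sampling_strategy <- function(name = c("fossiltip", "random", "diversity",
                                       "nosa_diversity"),
                              x_cut = 66) {
  name <- match.arg(name)
  structure(list(name = name,
                 sa_allowed = name %in% c("random", "diversity"),
                 diversified = name %in% c("diversity", "nosa_diversity"),
                 x_cut = x_cut),
            class = "sampling_strategy")
}

#' Skyline grid of piecewise-constant FBD parameters
#'
#' @param shift_times rate-shift times (Ma), strictly decreasing; the slices
#'   tile (root age, 0].
#' @param params list of [fbd_params()] of length `length(shift_times) + 1`,
#'   ordered oldest slice first.
#' @param free_mask which parameters vary by slice: `"s"` (d, r shared) or
#'   `"sdr"` (all free).
#' @param x_cut diversity-sampling cutoff (Ma).
#' @return a `skyline_grid`.
#' @export
skyline_grid <- function(shift_times, params, free_mask = c("s", "sdr"),
                         x_cut = 66) {
  free_mask <- match.arg(free_mask)
  if (length(shift_times) && any(diff(shift_times) >= 0))
    stop2("shift_times must be strictly decreasing (oldest first)")
  if (length(params) != length(shift_times) + 1L)
    stop2("need one fbd_params per slice (", length(shift_times) + 1L, ")")
  if (free_mask == "s") {
    d0 <- params[[1]]$d; r0 <- params[[1]]$r
    same <- vapply(params, function(p) abs(p$d - d0) < 1e-12 &&
                     abs(p$r - r0) < 1e-12, logical(1))
    if (!all(same)) stop2("free_mask 's': d and r must be equal across slices")
  }
  structure(list(shift_times = as.numeric(shift_times), params = params,
                 free_mask = free_mask, x_cut = x_cut),
            class = "skyline_grid")
}

#' Number of free tree-model parameters of a skyline grid
#' @param grid a [skyline_grid()].
#' @return `3l` under the full mask, `l + 2` when only `s` shifts
#'   (`l` = number of slices).
#' @export
skyline_free_parameters <- function(grid) {
  l <- length(grid$shift_times) + 1L
  if (grid$free_mask == "sdr") 3L * l else l + 2L
}

# --- slice machinery -------------------------------------------------------
#
# Boundaries young to old: 0 = b0 < t_l < ... < t_1 < Inf. Within a slice
# with bottom (younger) boundary t_b where p0(t_b) = p_b is known:
#   A = sqrt((lambda-mu-psi)^2 + 4 lambda psi)
#   B = ((1 - 2 p_b) lambda + mu + psi) / A
#   p0(t) = [lambda+mu+psi - A ((1+B) - (1-B) E) / ((1+B) + (1-B) E)] / (2 lambda)
#   q(t)  = 4 E / ((1+B) + (1-B) E)^2,   E = exp(-A (t - t_b))
# (at the present, p_b = 1 - rho reproduces the usual c1/c2 constants).
# q is normalized to 1 at each slice bottom; because its ODE is linear,
# within-slice ratios equal the continuous solution's ratios.

make_slices <- function(boundaries, lambda, mu, psi, rho) {
  ns <- length(lambda)
  sl <- vector("list", ns)
  p_b <- 1 - rho
  for (i in seq_len(ns)) {   # young -> old
    la <- lambda[i]; m <- mu[i]; ps <- psi[i]
    A <- sqrt((la - m - ps)^2 + 4 * la * ps)
    crit <- A < 1e-10
    B <- if (crit) NA_real_ else ((1 - 2 * p_b) * la + m + ps) / A
    sl[[i]] <- list(bottom = boundaries[i], top = boundaries[i + 1L],
                    lambda = la, mu = m, psi = ps,
                    A = A, B = B, p_b = p_b, critical = crit)
    if (i < ns) p_b <- slice_p0(sl[[i]], boundaries[i + 1L])
  }
  sl
}

slice_p0 <- function(sl, t) {
  dt <- t - sl$bottom
  if (!is.finite(dt) || dt < 0) stop2("time outside slice")
  if (sl$critical) {            # lambda = mu, psi = 0
    one_m <- (1 - sl$p_b) / (1 + sl$lambda * dt * (1 - sl$p_b))
    return(1 - one_m)
  }
  E <- exp(-sl$A * dt)
  (sl$lambda + sl$mu + sl$psi -
     sl$A * ((1 + sl$B) - (1 - sl$B) * E) / ((1 + sl$B) + (1 - sl$B) * E)) /
    (2 * sl$lambda)
}

slice_logq <- function(sl, t) {
  dt <- t - sl$bottom
  if (sl$critical)
    return(-2 * log1p(sl$lambda * dt * (1 - sl$p_b)))
  E <- exp(-sl$A * dt)
  log(4) - sl$A * dt - 2 * log((1 + sl$B) + (1 - sl$B) * E)
}

slice_index <- function(boundaries, t) {
  # slice i spans [b_i, b_{i+1}): a boundary age belongs to the older slice
  i <- findInterval(t, boundaries)
  max(1L, min(i, length(boundaries) - 1L))
}

# log q(t2)/q(t1), t2 >= t1, crossing boundaries as needed
logq_ratio <- function(slices, boundaries, t1, t2) {
  if (t2 < t1 - 1e-9) stop2("segment endpoints out of order")
  lq <- logq_global(slices, boundaries, c(t1, t2))
  lq[2] - lq[1]
}

# continuous log q over all slices: within-slice value plus the cumulative
# boundary constants (q's ODE is linear, so ratios within a slice match the
# continuous solution)
logq_global <- function(slices, boundaries, t) {
  ns <- length(slices)
  consts <- numeric(ns)
  if (ns > 1L) for (i in seq_len(ns - 1L))
    consts[i + 1L] <- consts[i] + slice_logq(slices[[i]], boundaries[i + 1L])
  idx <- pmin(pmax(findInterval(t, boundaries), 1L), ns)
  out <- numeric(length(t))
  for (i in unique(idx)) {
    sel <- idx == i
    sl <- slices[[i]]
    dt <- t[sel] - sl$bottom
    out[sel] <- consts[i] + if (sl$critical)
      -2 * log1p(sl$lambda * dt * (1 - sl$p_b))
    else {
      E <- exp(-sl$A * dt)
      log(4) - sl$A * dt - 2 * log((1 + sl$B) + (1 - sl$B) * E)
    }
  }
  out
}

p0_at <- function(slices, boundaries, t) slice_p0(slices[[slice_index(boundaries, t)]], t)

#' Skyline FBD log-density of a calibrated tree
#'
#' Piecewise-constant sampled-ancestor FBD density, conditioned on the root
#' age and on sampling at least one extant lineage. Under the diversity
#' strategies an extra slice boundary is placed at `x_cut` with zero fossil
#' sampling below it, and any fossil younger than `x_cut` gives `-Inf`.
#' With a single slice this is the constant-rate FBD density.
#'
#' @param tr a [timetree()]; extant tips at age 0, fossil tips older,
#'   zero-duration fossil attachments read as sampled ancestors.
#' @param grid a [skyline_grid()] (or a single [fbd_params()]).
#' @param strategy a [sampling_strategy()].
#' @return log-density (`-Inf` for configurations the strategy forbids).
#' @export
skyline_fbd_log_density <- function(tr, grid, strategy = sampling_strategy("random")) {
  if (inherits(grid, "fbd_params"))
    grid <- skyline_grid(numeric(0), list(grid), x_cut = strategy$x_cut)
  root <- tree_root(tr)
  root_age <- tr$age[root]
  if (length(grid$shift_times) && max(grid$shift_times) >= root_age)
    stop2("shift time older than the root age")
  rho <- grid$params[[length(grid$params)]]$rho  # youngest slice governs rho

  # boundaries young -> old; params per slice young -> old
  sh <- sort(grid$shift_times)                  # increasing
  par_young_first <- rev(grid$params)
  lambda <- vapply(par_young_first, `[[`, numeric(1), "lambda")
  mu <- vapply(par_young_first, `[[`, numeric(1), "mu")
  psi <- vapply(par_young_first, `[[`, numeric(1), "psi")
  if (strategy$diversified && strategy$x_cut > 0) {
    if (!(strategy$x_cut %in% sh)) {
      j <- slice_index(c(0, sh, Inf), strategy$x_cut)
      lambda <- append(lambda, lambda[j], after = j - 1L)
      mu <- append(mu, mu[j], after = j - 1L)
      psi <- append(psi, psi[j], after = j - 1L)
      sh <- sort(c(sh, strategy$x_cut))
    }
    psi[seq_len(which(sh == strategy$x_cut))] <- 0  # no fossils after x_cut
  }
  boundaries <- c(0, sh, Inf)
  slices <- make_slices(boundaries, lambda, mu, psi, rho)

  sa <- sampled_ancestors(tr) & tr$age[seq_len(tr$n_tip)] > SA_TOL
  if (any(sa) && !strategy$sa_allowed) return(-Inf)
  extant <- tr$age[seq_len(tr$n_tip)] <= SA_TOL
  fossil_tip <- which(!extant & !sa)
  if (strategy$diversified &&
      any(tr$age[c(fossil_tip, which(sa))] < strategy$x_cut - 1e-9))
    return(-Inf)

  sa_parents <- tr$parent[which(sa)]
  lq <- logq_global(slices, boundaries, tr$age)
  nr <- which(tr$parent > 0L)
  lp <- sum(lq[tr$parent[nr]] - lq[nr])   # telescoped q-ratios over branches
  # birth events: internal nodes except root and sampled-ancestor attachments
  births <- setdiff((tr$n_tip + 1L):length(tr$parent), c(root, sa_parents))
  if (length(births)) {
    idx <- pmin(pmax(findInterval(tr$age[births], boundaries), 1L),
                length(slices))
    lp <- lp + sum(log(lambda[idx]))
  }
  # fossil tips: sampled, then lineage leaves no further samples
  for (v in fossil_tip) {
    y <- tr$age[v]
    ps <- psi[slice_index(boundaries, y)]
    if (ps <= 0) return(-Inf)
    lp <- lp + log(ps) + log(p0_at(slices, boundaries, y))
  }
  # sampled ancestors: sampling event on a surviving lineage
  for (v in which(sa)) {
    ps <- psi[slice_index(boundaries, tr$age[v])]
    if (ps <= 0) return(-Inf)
    lp <- lp + log(ps)
  }
  lp <- lp + sum(extant) * log(rho)
  # condition on >= 1 sampled extant lineage from the two root lineages
  surv <- make_slices(boundaries, lambda, mu, rep(0, length(psi)), rho)
  e_root <- p0_at(surv, boundaries, root_age)
  lp - log1p(-e_root^2)
}

#' Constant-rate FBD log-density
#' @inheritParams skyline_fbd_log_density
#' @param params an [fbd_params()].
#' @return log-density.
#' @export
fbd_log_density <- function(tr, params, strategy = sampling_strategy("random")) {
  skyline_fbd_log_density(tr, params, strategy)
}

# --- root and tip calibrations --------------------------------------------

#' Root-age calibration prior
#'
#' Either an offset exponential (soft upper bound: density maximal at the
#' offset, exponentially decaying above it) or a truncated normal with a
#' hard upper bound (the "NoR" style prior that forbids unreasonably old
#' roots).
#'
#' @param kind `"offset_exponential"` or `"truncated_normal"`.
#' @param offset minimum root age, Ma (offset exponential).
#' @param mean prior mean, Ma.
#' @param sd standard deviation, Ma (truncated normal).
#' @param min,max truncation bounds, Ma (truncated normal).
#' @return a `root_calibration`.
#' @export
root_calibration <- function(kind = c("offset_exponential", "truncated_normal"),
                             offset = 247.2, mean = 287, sd = 15,
                             min = 247.2, max = 298.9) {
  kind <- match.arg(kind)
  if (kind == "offset_exponential" && offset >= mean)
    stop2("offset must be < mean")
  if (kind == "truncated_normal" && min >= max) stop2("min must be < max")
  structure(list(kind = kind, offset = offset, mean = mean, sd = sd,
                 min = min, max = max),
            class = "root_calibration")
}

root_log_prior <- function(age, cal) {
  if (cal$kind == "offset_exponential") {
    if (age < cal$offset) return(-Inf)
    stats::dexp(age - cal$offset, rate = 1 / (cal$mean - cal$offset), log = TRUE)
  } else {
    if (age < cal$min || age > cal$max) return(-Inf)
    z <- stats::dnorm(age, cal$mean, cal$sd, log = TRUE)
    norm <- stats::pnorm(cal$max, cal$mean, cal$sd) -
      stats::pnorm(cal$min, cal$mean, cal$sd)
    z - log(norm)
  }
}

# sample a root age from its calibration prior
root_sample_age <- function(cal) {
  if (cal$kind == "offset_exponential")
    cal$offset + stats::rexp(1, rate = 1 / (cal$mean - cal$offset))
  else {
    repeat {
      a <- stats::rnorm(1, cal$mean, cal$sd)
      if (a >= cal$min && a <= cal$max) return(a)
    }
  }
}

#' Root and tip age log-prior
#'
#' Root age under its [root_calibration()]; each fossil tip uniform on its
#' stratigraphic range (`-Inf` outside); extant tips must sit at age 0.
#'
#' @param tr a [timetree()].
#' @param root_cal a [root_calibration()].
#' @param calibrations a [calibration_table()] covering all tips.
#' @return log prior density.
#' @export
root_and_tip_log_priors <- function(tr, root_cal, calibrations) {
  idx <- match(tr$tip_label, calibrations$taxon)
  if (anyNA(idx))
    stop2("tips missing from calibration table: ",
          paste(tr$tip_label[is.na(idx)], collapse = ", "))
  ages <- tr$age[seq_len(tr$n_tip)]
  ext <- calibrations$is_extant[idx]
  if (any(ext & ages > SA_TOL))
    stop2("extant tip with nonzero age: ",
          paste(tr$tip_label[ext & ages > SA_TOL], collapse = ", "))
  lo <- calibrations$age_min[idx]; hi <- calibrations$age_max[idx]
  lp <- root_log_prior(tr$age[tree_root(tr)], root_cal)
  for (i in which(!ext)) {
    if (ages[i] < lo[i] - 1e-9 || ages[i] > hi[i] + 1e-9) return(-Inf)
    if (hi[i] > lo[i]) lp <- lp + stats::dunif(ages[i], lo[i], hi[i], log = TRUE)
  }
  lp
}
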