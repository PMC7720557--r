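# Structured run configuration: model choices, priors, MCMC settings and
# move weights, with YAML round-trip.

#' Build a run configuration
#'
#' Encodes one named model combination (e.g. "SFBD(s)2l + TK02 under NoSA
#' diversity sampling") together with all MCMC settings. Every enumerated
#' choice is validated; the seed is recorded in all outputs.
#'
#' @param label free-form label for the analysis.
#' @param clock_model `"strict"`, `"igr"` or `"tk02"`.
#' @param acrv_kind among-character rate variation: `"gamma"`, `"lognormal"`
#'   or `"none"`.
#' @param n_rate_categories discrete ACRV categories.
#' @param freq_model `"symmetric"` or `"asymmetric"` state frequencies.
#' @param n_freq_categories frequency categories per state (asymmetric model).
#' @param alpha_dir_bounds uniform prior support for the symmetric-Dirichlet
#'   concentration.
#' @param strategy taxon-sampling strategy name (see [sampling_strategy()]).
#' @param x_cut diversity-sampling fossil cutoff, Ma.
#' @param rho extant-sampling probability.
#' @param shift_times skyline rate-shift times, Ma (empty = constant FBD).
#' @param skyline_mask `"s"` or `"sdr"`: which FBD parameters shift.
#' @param clock_rate_prior list: `kind` `"lognormal"` (meanlog, sdlog) or
#'   `"gamma"` (mean, sd). Default: the informative prior derived from a
#'   non-clock tree height of 5.3456 substitutions over a 267.1 Ma root.
#' @param clock_variance_prior_rate exponential-prior rate on the clock
#'   variance parameter (IGR or TK02).
#' @param acrv_shape_prior_rate exponential-prior rate on the ACRV shape.
#' @param d_prior_rate exponential-prior rate on net diversification.
#' @param r_prior,s_prior Beta prior shapes on turnover and fossil-sampling
#'   proportion; `r_prior = c(1, 9)` renders the low-extinction ("LExct")
#'   assumption.
#' @param root_prior a [root_calibration()].
#' @param partitioned one clock per partition (`TRUE`) or a single clock.
#' @param topology_fixed,base_rate_fixed constraint switches ("clock rate +
#'   topology" style runs).
#' @param starting_tree optional [timetree()] to start from.
#' @param likelihood_on `FALSE` runs the sampler on the prior alone.
#' @param tree_prior_on `FALSE` drops the FBD tree density as well, so the
#'   sampler targets the bare parameter priors — a sampler-validation mode:
#'   marginals of d, r, s then match their hyperpriors exactly, which under
#'   the joint prior they cannot (the tree density modulates them).
#' @param fbd_fixed optional `list(d =, r =, s =)` holding the FBD parameters
#'   fixed (no moves proposed on them); `s` may be a per-slice vector.
#' @param mode `"clock"` (calibrated) or `"nonclock"` (free branch lengths,
#'   used to derive the clock-rate prior and starting trees).
#' @param generations,sample_every,burnin_frac,n_runs MCMC settings.
#' @param seed integer seed; all runs derive their streams from it.
#' @param move_weights named numeric vector overriding default proposal
#'   weights; weights of `add_branch`/`delete_branch` are forced to zero
#'   whenever the strategy forbids sampled ancestors.
#' @return a validated `run_config` list.
#' @export
run_config <- function(label = "analysis",
                       clock_model = c("igr", "tk02", "strict"),
                       acrv_kind = c("gamma", "lognormal", "none"),
                       n_rate_categories = 4L,
                       freq_model = c("symmetric", "asymmetric"),
                       n_freq_categories = 4L,
                       alpha_dir_bounds = c(0.05, 20),
                       strategy = c("nosa_diversity", "fossiltip", "random",
                                    "diversity"),
                       x_cut = 66, rho = 1,
                       shift_times = numeric(0),
                       skyline_mask = c("s", "sdr"),
                       clock_rate_prior = list(kind = "lognormal",
                                               meanlog = log(0.02),
                                               sdlog = exp(0.02)),
                       clock_variance_prior_rate = 10,
                       acrv_shape_prior_rate = 1,
                       d_prior_rate = 10,
                       r_prior = c(1, 1), s_prior = c(1, 1),
                       root_prior = root_calibration(),
                       partitioned = FALSE,
                       topology_fixed = FALSE, base_rate_fixed = FALSE,
                       starting_tree = NULL,
                       likelihood_on = TRUE,
                       tree_prior_on = TRUE,
                       fbd_fixed = NULL,
                       mode = c("clock", "nonclock"),
                       generations = 20000L, sample_every = 10L,
                       burnin_frac = 0.25, n_runs = 2L, seed = 1L,
                       move_weights = NULL, tuning = NULL) {
  cfg <- list(label = label,
              clock_model = match.arg(clock_model),
              acrv_kind = match.arg(acrv_kind),
              n_rate_categories = as.integer(n_rate_categories),
              freq_model = match.arg(freq_model),
              n_freq_categories = as.integer(n_freq_categories),
              alpha_dir_bounds = alpha_dir_bounds,
              strategy = match.arg(strategy),
              x_cut = x_cut, rho = rho,
              shift_times = as.numeric(shift_times),
              skyline_mask = match.arg(skyline_mask),
              clock_rate_prior = clock_rate_prior,
              clock_variance_prior_rate = clock_variance_prior_rate,
              acrv_shape_prior_rate = acrv_shape_prior_rate,
              d_prior_rate = d_prior_rate,
              r_prior = r_prior, s_prior = s_prior,
              root_prior = root_prior,
              partitioned = isTRUE(partitioned),
              topology_fixed = isTRUE(topology_fixed),
              base_rate_fixed = isTRUE(base_rate_fixed),
              starting_tree = starting_tree,
              likelihood_on = isTRUE(likelihood_on),
              tree_prior_on = isTRUE(tree_prior_on),
              fbd_fixed = fbd_fixed,
              mode = match.arg(mode),
              generations = as.integer(generations),
              sample_every = as.integer(sample_every),
              burnin_frac = burnin_frac,
              n_runs = as.integer(n_runs),
              seed = as.integer(seed),
              tuning = tuning)
  if (cfg$generations < 1L || cfg$sample_every < 1L) stop2("bad MCMC settings")
  if (cfg$burnin_frac < 0 || cfg$burnin_frac >= 1) stop2("burnin_frac in [0,1)")
  if (!is.list(clock_rate_prior) || is.null(clock_rate_prior$kind) ||
      !clock_rate_prior$kind %in% c("lognormal", "gamma"))
    stop2("clock_rate_prior$kind must be 'lognormal' or 'gamma'")
  w <- default_move_weights(cfg)
  if (!is.null(move_weights)) {
    unknown <- setdiff(names(move_weights), names(w))
    if (length(unknown)) stop2("unknown move(s): ", paste(unknown, collapse = ", "))
    w[names(move_weights)] <- move_weights
  }
  if (!sampling_strategy(cfg$strategy)$sa_allowed)
    w[c("add_branch", "delete_branch")] <- 0
  if (any(w < 0)) stop2("move weights must be >= 0")
  if (sum(w) <= 0) stop2("configuration error: all move weights are zero")
  if (!cfg$topology_fixed && cfg$mode == "clock" &&
      (w["exchange"] + w["spr"]) <= 0)
    stop2("a topology move needs positive weight unless topology is fixed")
  cfg$move_weights <- w
  class(cfg) <- "run_config"
  cfg
}

default_move_weights <- function(cfg) {
  c(node_age = 10, root_age = 3, tip_age = 5,
    exchange = if (cfg$topology_fixed) 0 else 5,
    spr = if (cfg$topology_fixed) 0 else 3,
    base_rate = if (cfg$base_rate_fixed) 0 else 3,
    clock_variance = if (cfg$clock_model == "strict") 0 else 3,
    branch_rate = if (cfg$clock_model == "strict") 0 else 10,
    acrv_shape = if (cfg$acrv_kind == "none") 0 else 2,
    alpha_dir = if (cfg$freq_model == "asymmetric") 2 else 0,
    fbd_d = if (is.null(cfg$fbd_fixed)) 3 else 0,
    fbd_r = if (is.null(cfg$fbd_fixed)) 3 else 0,
    fbd_s = if (is.null(cfg$fbd_fixed)) 3 else 0,
    add_branch = 3, delete_branch = 3)
}

#' Write a run configuration as YAML
#' @param cfg a [run_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$root_prior <- unclass(x$root_prior)
  x$starting_tree <- if (!is.null(x$starting_tree))
    write_annotated_tree(x$starting_tree) else NULL
  x$move_weights <- as.list(x$move_weights)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML file written by [write_run_config()].
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  rp <- x$root_prior
  x$root_prior <- root_calibration(rp$kind, offset = rp$offset, mean = rp$mean,
                                   sd = rp$sd, min = rp$min, max = rp$max)
  if (!is.null(x$starting_tree))
    x$starting_tree <- read_annotated_tree(x$starting_tree)$tree
  mw <- unlist(x$move_weights)
  x$move_weights <- NULL
  x$alpha_dir_bounds <- unlist(x$alpha_dir_bounds)
  x$r_prior <- unlist(x$r_prior); x$s_prior <- unlist(x$s_prior)
  do.call(run_config, c(x, list(move_weights = mw)))
}
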