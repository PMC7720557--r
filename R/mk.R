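# Mkv model of morphological character evolution: transition probabilities,
# discretized among-character rate variation (ACRV), symmetric-Dirichlet
# state-frequency mixtures, and the ascertainment-corrected likelihood.

#' Specify an Mk substitution model
#'
#' @param acrv_kind distribution of among-character rate variation: `"gamma"`
#'   (shape `acrv_shape`, mean 1) or `"lognormal"` (log-sd `acrv_shape`,
#'   linear-scale mean 1); `"none"` disables ACRV.
#' @param acrv_shape positive shape (gamma) or log-sd (lognormal).
#' @param n_rate_categories number of equal-weight discrete rate categories
#'   (category means). Default 4, the usual discretization.
#' @param freq_model `"symmetric"` (uniform state frequencies) or
#'   `"asymmetric"` (symmetric-Dirichlet mixture over frequencies).
#' @param alpha_dir symmetric-Dirichlet concentration; during MCMC it is
#'   sampled on `alpha_dir_bounds`.
#' @param n_freq_categories base number of frequency categories per state.
#' @param alpha_dir_bounds support of the uniform prior on `alpha_dir`;
#'   `c(0.05, 20)` spans high to low asymmetry.
#' @param correct apply the Mkv variable-characters-only ascertainment
#'   correction (default) or the plain Mk likelihood.
#' @return an `mk_model_spec` list.
#' @export
mk_model_spec <- function(acrv_kind = c("gamma", "lognormal", "none"),
                          acrv_shape = 1, n_rate_categories = 4L,
                          freq_model = c("symmetric", "asymmetric"),
                          alpha_dir = 1, n_freq_categories = 4L,
                          alpha_dir_bounds = c(0.05, 20),
                          correct = TRUE) {
  acrv_kind <- match.arg(acrv_kind)
  freq_model <- match.arg(freq_model)
  if (acrv_kind != "none" && acrv_shape <= 0) stop2("acrv_shape must be > 0")
  if (n_rate_categories < 1L) stop2("need >= 1 rate category")
  structure(list(acrv_kind = acrv_kind, acrv_shape = acrv_shape,
                 n_rate_categories = as.integer(n_rate_categories),
                 freq_model = freq_model, alpha_dir = alpha_dir,
                 n_freq_categories = as.integer(n_freq_categories),
                 alpha_dir_bounds = alpha_dir_bounds, correct = correct),
            class = "mk_model_spec")
}

#' Mk transition probability matrix
#'
#' For the unordered k-state Mk model, `P_ii = 1/k + ((k-1)/k) exp(-k v/(k-1))`
#' and `P_ij = 1/k - (1/k) exp(-k v/(k-1))`; with non-uniform frequencies the
#' equal-exchange generalization `P_ij = e^{-mu v} d_ij + (1-e^{-mu v}) pi_j`,
#' `mu = 1/(1 - sum pi^2)`, is used (branch length `v` in expected
#' substitutions per character).
#'
#' @param k number of states (>= 2).
#' @param nu expected substitutions per character (>= 0).
#' @param freqs optional stationary frequencies (length `k`, sums to 1);
#'   uniform by default.
#' @return a `k x k` stochastic matrix.
#' @export
mk_transition_probability <- function(k, nu, freqs = NULL) {
  if (k < 2) stop2("k must be >= 2")
  if (!is.finite(nu) && nu != Inf) stop2("nu must be numeric")
  if (nu < 0) stop2("nu must be >= 0")
  if (is.null(freqs)) freqs <- rep(1 / k, k)
  if (length(freqs) != k || abs(sum(freqs) - 1) > 1e-8)
    stop2("freqs must have length k and sum to 1")
  mu <- 1 / (1 - sum(freqs^2))
  e <- exp(-mu * nu)
  P <- matrix((1 - e) * rep(freqs, each = k), k, k)
  diag(P) <- diag(P) + e
  P
}

#' Discretize among-character rate variation
#'
#' Equal-weight categories at the category means of a mean-1 gamma (shape
#' `acrv_shape`) or mean-1 lognormal (log-sd `acrv_shape`); the weighted mean
#' of the category rates is renormalized to exactly 1.
#'
#' @param spec an [mk_model_spec()] (or kind/shape/n given directly).
#' @return data frame with columns `rate`, `weight`.
#' @export
discretize_acrv <- function(spec) {
  kind <- spec$acrv_kind; shape <- spec$acrv_shape
  n <- spec$n_rate_categories
  if (kind == "none" || n == 1L)
    return(data.frame(rate = 1, weight = 1))
  br <- seq(0, 1, length.out = n + 1L)
  if (kind == "gamma") {
    if (shape <= 0) stop2("gamma shape must be > 0")
    b <- stats::qgamma(br, shape = shape, rate = shape)
    # partial expectations of Gamma(a, a): E[X; X<b] = pgamma(b, a+1, a)
    pe <- stats::pgamma(b, shape = shape + 1, rate = shape)
  } else {
    if (shape <= 0) stop2("lognormal log-sd must be > 0")
    mu <- -shape^2 / 2  # linear-scale mean 1
    b <- stats::qlnorm(br, meanlog = mu, sdlog = shape)
    z <- (log(b) - mu) / shape - shape
    z[1] <- -Inf; z[n + 1L] <- Inf
    pe <- stats::pnorm(z)
  }
  rates <- n * diff(pe)
  rates <- rates / mean(rates)
  data.frame(rate = rates, weight = rep(1 / n, n))
}

#' Discrete symmetric-Dirichlet frequency mixture
#'
#' Models variation in state frequencies across characters. For `k = 2` the
#' categories are the quantile midpoints of `Beta(alpha_dir, alpha_dir)`
#' (symmetric about 1/2). For `k > 2`, marginal levels are taken at the
#' quantile midpoints of `Beta(alpha_dir, (k-1) alpha_dir)` (the symmetric
#' Dirichlet marginal) for a focal state, the remainder spread evenly, and
#' the focal state rotated over all `k` states, so the weighted mean
#' frequency vector is exactly uniform.
#'
#' @param k state count (>= 2).
#' @param alpha_dir concentration (> 0); large values collapse to the
#'   symmetric model.
#' @param n_categories quantile midpoints per (focal) state.
#' @return list with `freqs` (categories x k matrix) and `weights`.
#' @export
asymmetric_frequency_mixture <- function(k, alpha_dir, n_categories = 4L) {
  if (k < 2) stop2("k must be >= 2")
  if (alpha_dir <= 0) stop2("alpha_dir must be > 0")
  n <- as.integer(n_categories)
  q <- (seq_len(n) - 0.5) / n
  if (k == 2L) {
    p <- stats::qbeta(q, alpha_dir, alpha_dir)
    freqs <- cbind(p, 1 - p)
    w <- rep(1 / n, n)
  } else {
    p <- stats::qbeta(q, alpha_dir, (k - 1) * alpha_dir)
    freqs <- matrix(NA_real_, n * k, k)
    for (s in seq_len(k)) {
      block <- matrix(rep((1 - p) / (k - 1), k), n, k)
      block[, s] <- p
      freqs[(s - 1L) * n + seq_len(n), ] <- block
    }
    w <- rep(1 / (n * k), n * k)
  }
  dimnames(freqs) <- NULL
  list(freqs = freqs, weights = w)
}

freq_mixture_for <- function(k, spec) {
  if (spec$freq_model == "symmetric")
    list(freqs = matrix(1 / k, 1, k), weights = 1)
  else
    asymmetric_frequency_mixture(k, spec$alpha_dir, spec$n_freq_categories)
}

# tip partial array (k x n_tip x n_char) for one state-count class
class_tip_partials <- function(mat, chars, k, tip_order) {
  n_tip <- length(tip_order)
  arr <- array(0, dim = c(k, n_tip, length(chars)))
  for (ci in seq_along(chars)) {
    st <- mat$states[[chars[ci]]]
    for (t in seq_len(n_tip)) {
      if (is.na(tip_order[t])) { arr[, t, ci] <- 1; next }  # tip without data
      s <- st[[tip_order[t]]]
      if (!length(s)) arr[, t, ci] <- 1 else arr[s + 1L, t, ci] <- 1
    }
  }
  arr
}

#' Mkv log-likelihood of a character matrix on a tree
#'
#' Felsenstein pruning over all characters, mixed over discrete ACRV (and,
#' for the asymmetric model, frequency) categories, with the Mkv
#' variable-characters-only ascertainment correction applied per state-count
#' class: each character contributes
#' `log( L_char / (1 - sum_s L_const(s)) )`.
#'
#' @param tr a [timetree()] containing every matrix taxon as a tip.
#' @param eff_lengths numeric vector over tree nodes: expected substitutions
#'   per character on the branch above each node (ignored at the root).
#' @param mat a [morph_matrix()].
#' @param spec an [mk_model_spec()].
#' @param per_character return the per-character log-likelihood vector
#'   instead of the sum.
#' @return total log-likelihood (or per-character vector).
#' @export
matrix_log_likelihood <- function(tr, eff_lengths, mat, spec = mk_model_spec(),
                                  per_character = FALSE) {
  stopifnot(inherits(tr, "timetree"), inherits(mat, "morph_matrix"))
  if (!all(mat$taxa %in% tr$tip_label))
    stop2("matrix taxa missing from tree: ",
          paste(setdiff(mat$taxa, tr$tip_label), collapse = ", "))
  if (any(mat$k < 2L))
    stop2("ascertainment error: character(s) ",
          paste(which(mat$k < 2L), collapse = ", "),
          " have <2 observed states (variable-only matrices required)")
  if (any(!is.finite(eff_lengths[-tree_root(tr)])) ||
      any(eff_lengths[-tree_root(tr)] < 0))
    stop2("effective branch lengths must be finite and >= 0")
  tip_order <- match(tr$tip_label, mat$taxa)
  po <- postorder_nodes(tr)
  ch <- children_list(tr)
  children <- do.call(rbind, ch[po])
  nu <- eff_lengths; nu[tree_root(tr)] <- 0
  acrv <- discretize_acrv(spec)
  out <- numeric(mat$n_char)
  for (kk in sort(unique(mat$k))) {
    chars <- which(mat$k == kk)
    fm <- freq_mixture_for(kk, spec)
    tp <- class_tip_partials(mat, chars, kk, tip_order)
    out[chars] <- mk_class_loglik_cpp(po, children, nu, as.numeric(tp),
                                      kk, tr$n_tip,
                                      acrv$rate, acrv$weight,
                                      fm$freqs, fm$weights, spec$correct)
  }
  if (per_character) out else sum(out)
}
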