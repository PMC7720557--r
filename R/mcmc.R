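# Metropolis-Hastings-within-Gibbs sampler over (tree, ages, clock,
# substitution-model, FBD) space, with reversible-jump sampled-ancestor
# add/delete moves whose weights can be zeroed (the NoSA device).

# ---- context and state ----------------------------------------------------

build_ctx <- function(cfg, mat, calibrations) {
  strategy <- sampling_strategy(cfg$strategy, x_cut = cfg$x_cut)
  if (cfg$partitioned) {
    if (is.null(mat$partition)) stop2("partitioned clocks need a partition map")
    labels <- unique(mat$partition)
    mats <- lapply(labels, function(l) subset_partition(mat, l))
    names(mats) <- labels
  } else {
    labels <- "all"
    mats <- list(all = mat)
  }
  tip_label <- if (!is.null(cfg$starting_tree)) cfg$starting_tree$tip_label
               else calibrations$taxon
  caches <- lapply(mats, function(m) {
    lapply(sort(unique(m$k)), function(kk) {
      chars <- which(m$k == kk)
      cl <- list(k = kk, chars = chars,
                 tp = as.numeric(class_tip_partials(m, chars, kk,
                                                    match(tip_label, m$taxa))))
      if (cfg$freq_model == "symmetric") {
        cl$freqs <- matrix(1 / kk, 1, kk); cl$fweights <- 1
      }
      cl
    })
  })
  list(cfg = cfg, mats = mats, labels = labels, calibrations = calibrations,
       strategy = strategy, caches = caches, beta = 1,
       memo = new.env(parent = emptyenv()),
       l_slices = length(cfg$shift_times) + 1L)
}

mk_spec_for <- function(ctx, clock_entry, alpha_dir) {
  structure(list(acrv_kind = ctx$cfg$acrv_kind,
                 acrv_shape = clock_entry$acrv_shape,
                 n_rate_categories = ctx$cfg$n_rate_categories,
                 freq_model = ctx$cfg$freq_model,
                 alpha_dir = alpha_dir,
                 n_freq_categories = ctx$cfg$n_freq_categories,
                 alpha_dir_bounds = ctx$cfg$alpha_dir_bounds,
                 correct = TRUE),
            class = "mk_model_spec")
}

# likelihood with precomputed tip partials (tip order fixed during a run);
# the ACRV discretization is memoized on the shape value
loglik_cached <- function(tr, eff, cache, spec, memo = NULL) {
  po <- postorder_nodes(tr)
  ch <- children_list(tr)
  children <- matrix(unlist(ch[po]), ncol = 2L, byrow = TRUE)
  nu <- eff; nu[tree_root(tr)] <- 0
  acrv <- NULL
  if (!is.null(memo) && identical(memo$acrv_key,
                                  c(spec$acrv_shape, spec$n_rate_categories)))
    acrv <- memo$acrv
  if (is.null(acrv)) {
    acrv <- discretize_acrv(spec)
    if (!is.null(memo)) {
      memo$acrv <- acrv
      memo$acrv_key <- c(spec$acrv_shape, spec$n_rate_categories)
    }
  }
  classes <- cache
  if (spec$freq_model == "asymmetric" || is.null(cache[[1]]$freqs)) {
    classes <- lapply(cache, function(cl) {
      fm <- freq_mixture_for(cl$k, spec)
      cl$freqs <- fm$freqs; cl$fweights <- fm$weights
      cl
    })
  }
  mk_matrix_loglik_cpp(po, children, nu, classes, tr$n_tip,
                       acrv$rate, acrv$weight, spec$correct)
}

eff_lengths_of <- function(tr, ce) {
  switch(ce$model,
         strict = strict_effective_lengths(tr, ce$base_rate),
         igr = ce$v,
         tk02 = tk02_effective_lengths(tr, ce$rates),
         free = ce$v)
}

mc_loglik <- function(st, ctx) {
  b <- ctx$beta %||% 1
  if (!ctx$cfg$likelihood_on || b == 0) return(0)
  b * mc_raw_loglik(st, ctx)
}

# untempered data log-likelihood (used for power-posterior recording too)
mc_raw_loglik <- function(st, ctx) {
  total <- 0
  for (l in ctx$labels) {
    ce <- st$clock[[l]]
    spec <- mk_spec_for(ctx, ce, st$alpha_dir)
    total <- total + loglik_cached(st$tr, eff_lengths_of(st$tr, ce),
                                   ctx$caches[[l]], spec, ctx$memo)
    if (!is.finite(total)) return(-Inf)
  }
  total
}

build_grid <- function(st, ctx) {
  cfg <- ctx$cfg
  l <- ctx$l_slices
  dd <- if (length(st$fbd$d) == l) st$fbd$d else rep(st$fbd$d, l)
  rr <- if (length(st$fbd$r) == l) st$fbd$r else rep(st$fbd$r, l)
  params <- lapply(seq_len(l), function(i)
    fbd_params(dd[i], rr[i], st$fbd$s[i], rho = cfg$rho))
  if (l == 1L) params[[1]]
  else skyline_grid(cfg$shift_times, params, free_mask = cfg$skyline_mask,
                    x_cut = cfg$x_cut)
}

mc_tree_prior <- function(st, ctx) {
  if (ctx$cfg$mode == "nonclock") return(0)
  lp <- root_and_tip_log_priors(st$tr, ctx$cfg$root_prior, ctx$calibrations)
  if (!is.finite(lp)) return(-Inf)
  if (!ctx$cfg$tree_prior_on) return(lp)
  root_age <- st$tr$age[tree_root(st$tr)]
  if (length(ctx$cfg$shift_times) && max(ctx$cfg$shift_times) >= root_age)
    return(-Inf)
  lp + skyline_fbd_log_density(st$tr, build_grid(st, ctx), ctx$strategy)
}

rate_prior_density <- function(x, prior) {
  if (prior$kind == "lognormal")
    stats::dlnorm(x, prior$meanlog, prior$sdlog, log = TRUE)
  else
    stats::dgamma(x, shape = (prior$mean / prior$sd)^2,
                  rate = prior$mean / prior$sd^2, log = TRUE)
}

mc_clock_prior <- function(st, ctx) {
  cfg <- ctx$cfg
  lp <- 0
  d <- branch_durations(st$tr)
  for (l in ctx$labels) {
    ce <- st$clock[[l]]
    if (ce$model == "free") {
      lp <- lp + sum(stats::dexp(ce$v[!is.na(d)], rate = 10, log = TRUE))
      next
    }
    lp <- lp + rate_prior_density(ce$base_rate, cfg$clock_rate_prior)
    if (ce$model != "strict")
      lp <- lp + stats::dexp(ce$nu, rate = cfg$clock_variance_prior_rate,
                             log = TRUE)
    lp <- lp + switch(ce$model,
      strict = 0,
      igr = igr_log_prior(ce$v, d, ce$base_rate, ce$nu),
      tk02 = tk02_log_prior(ce$rates, st$tr, ce$base_rate, ce$nu))
    if (!is.finite(lp)) return(-Inf)
  }
  lp
}

mc_param_prior <- function(st, ctx) {
  cfg <- ctx$cfg
  lp <- 0
  if (cfg$acrv_kind != "none")
    for (l in ctx$labels)
      lp <- lp + stats::dexp(st$clock[[l]]$acrv_shape,
                             rate = cfg$acrv_shape_prior_rate, log = TRUE)
  if (cfg$freq_model == "asymmetric") {
    b <- cfg$alpha_dir_bounds
    if (st$alpha_dir < b[1] || st$alpha_dir > b[2]) return(-Inf)
    lp <- lp - log(b[2] - b[1])
  }
  if (is.null(cfg$fbd_fixed) && cfg$mode == "clock") {
    lp <- lp + sum(stats::dexp(st$fbd$d, rate = cfg$d_prior_rate, log = TRUE))
    lp <- lp + sum(stats::dbeta(st$fbd$r, cfg$r_prior[1], cfg$r_prior[2], log = TRUE))
    lp <- lp + sum(stats::dbeta(st$fbd$s, cfg$s_prior[1], cfg$s_prior[2], log = TRUE))
  }
  lp
}

part_fns <- list(lik = mc_loglik, tree = mc_tree_prior,
                 clock = mc_clock_prior, param = mc_param_prior)

recompute_parts <- function(st, ctx, parts) {
  for (p in parts) st[[paste0("lp_", p)]] <- part_fns[[p]](st, ctx)
  st
}

state_posterior <- function(st) st$lp_lik + st$lp_tree + st$lp_clock + st$lp_param

init_clock_entry <- function(cfg, tr) {
  c0 <- if (cfg$clock_rate_prior$kind == "lognormal")
    exp(cfg$clock_rate_prior$meanlog) else cfg$clock_rate_prior$mean
  nu0 <- 1 / cfg$clock_variance_prior_rate
  ce <- list(model = if (cfg$mode == "nonclock") "free" else cfg$clock_model,
             base_rate = c0, nu = nu0, acrv_shape = 1)
  d <- branch_durations(tr)
  if (ce$model == "igr") {
    ce$v <- c0 * d
  } else if (ce$model == "tk02") {
    ce$rates <- rep(c0, length(tr$parent))
  } else if (ce$model == "free") {
    ce$v <- ifelse(is.na(d), NA_real_, 0.1)
  }
  ce
}

init_state <- function(ctx) {
  cfg <- ctx$cfg
  for (try in seq_len(100L)) {
    tr <- if (!is.null(cfg$starting_tree)) cfg$starting_tree
          else random_calibrated_tree(ctx$calibrations,
                 root_min = if (cfg$root_prior$kind == "offset_exponential")
                   cfg$root_prior$offset else cfg$root_prior$min)
    clock <- lapply(ctx$labels, function(l) init_clock_entry(cfg, tr))
    names(clock) <- ctx$labels
    fx <- cfg$fbd_fixed
    l <- ctx$l_slices
    nd <- if (cfg$skyline_mask == "sdr") l else 1L
    st <- list(tr = tr, clock = clock,
               alpha_dir = mean(cfg$alpha_dir_bounds),
               fbd = list(d = rep(fx$d %||% (1 / cfg$d_prior_rate), nd)[seq_len(nd)],
                          r = rep(fx$r %||% 0.2, nd)[seq_len(nd)],
                          s = rep(fx$s %||% 0.2, length.out = l)))
    st <- recompute_parts(st, ctx, names(part_fns))
    if (is.finite(state_posterior(st))) return(st)
    if (!is.null(cfg$starting_tree))
      stop2("starting tree has log posterior -Inf under this configuration")
  }
  stop2("could not initialize a finite-posterior state in 100 attempts")
}

# ---- small tree helpers ---------------------------------------------------

subtree_nodes <- function(tr, v) {
  ch <- children_list(tr)
  out <- integer(0); stack <- v
  while (length(stack)) {
    x <- stack[[1]]; stack <- stack[-1]
    out <- c(out, x)
    stack <- c(stack, ch[[x]])
  }
  out
}

is_sa_tip <- function(tr, v) {
  v <= tr$n_tip && tr$parent[v] > 0L &&
    tr$age[tr$parent[v]] - tr$age[v] <= SA_TOL && tr$age[v] > SA_TOL
}

sa_attachment <- function(tr, p) {
  # is internal node p the attachment of a sampled-ancestor tip?
  ch <- which(tr$parent == p)
  any(vapply(ch, function(x) is_sa_tip(tr, x), logical(1)))
}

tune <- function(ctx, name, default) {
  tu <- ctx$cfg$tuning
  if (!is.null(tu) && !is.null(tu[[name]])) tu[[name]] else default
}

# ---- proposals ------------------------------------------------------------
# each returns NULL (no valid proposal) or list(st, logH, parts)

prop_node_age <- function(st, ctx) {
  tr <- st$tr
  cand <- setdiff((tr$n_tip + 1L):length(tr$parent), tree_root(tr))
  cand <- cand[!vapply(cand, function(p) sa_attachment(tr, p), logical(1))]
  if (!length(cand)) return(NULL)
  v <- if (length(cand) == 1L) cand else sample(cand, 1L)
  kids <- which(tr$parent == v)
  lo <- max(tr$age[kids]); hi <- tr$age[tr$parent[v]]
  if (hi - lo <= 0) return(NULL)
  tr$age[v] <- stats::runif(1, lo, hi)
  st$tr <- tr
  list(st = st, logH = 0, parts = c("lik", "tree", "clock"))
}

prop_root_age <- function(st, ctx, delta = tune(ctx, "root_age", 10)) {
  tr <- st$tr
  root <- tree_root(tr)
  lo <- max(tr$age[which(tr$parent == root)])
  a <- tr$age[root] + stats::runif(1, -delta, delta)
  if (a < lo) a <- 2 * lo - a           # reflect at the floor
  tr$age[root] <- a
  st$tr <- tr
  list(st = st, logH = 0, parts = c("lik", "tree", "clock"))
}

prop_tip_age <- function(st, ctx) {
  tr <- st$tr
  cal <- ctx$calibrations
  idx <- match(tr$tip_label, cal$taxon)
  movable <- which(cal$age_max[idx] > cal$age_min[idx])
  if (!length(movable)) return(NULL)
  f <- if (length(movable) == 1L) movable else sample(movable, 1L)
  p <- tr$parent[f]
  lo <- cal$age_min[idx[f]]; hi <- cal$age_max[idx[f]]
  if (is_sa_tip(tr, f)) {
    sib <- setdiff(which(tr$parent == p), f)
    g <- tr$parent[p]
    lo <- max(lo, tr$age[sib])
    if (g > 0L) hi <- min(hi, tr$age[g])
    if (hi - lo <= 0) return(NULL)
    a <- stats::runif(1, lo, hi)
    tr$age[f] <- a; tr$age[p] <- a
  } else {
    hi <- min(hi, tr$age[p])
    if (hi - lo <= 0) return(NULL)
    tr$age[f] <- stats::runif(1, lo, hi)
  }
  st$tr <- tr
  list(st = st, logH = 0, parts = c("lik", "tree", "clock"))
}

prop_exchange <- function(st, ctx) {
  tr <- st$tr
  root <- tree_root(tr)
  cand <- setdiff((tr$n_tip + 1L):length(tr$parent), root)
  if (!length(cand)) return(NULL)
  p <- if (length(cand) == 1L) cand else sample(cand, 1L)
  g <- tr$parent[p]
  a <- setdiff(which(tr$parent == g), p)
  kids <- which(tr$parent == p)
  w <- kids[sample.int(2L, 1L)]
  if (is_sa_tip(tr, w)) return(NULL)
  if (ctx$cfg$mode == "clock" && tr$age[p] <= tr$age[a]) return(NULL)
  tr$parent[a] <- p; tr$parent[w] <- g
  if (ctx$cfg$mode == "nonclock") tr <- relevel_ages(tr)
  st$tr <- tr
  list(st = st, logH = 0, parts = c("lik", "tree", "clock"))
}

relevel_ages <- function(tr) {
  tr$age[seq_len(tr$n_tip)] <- 0
  ch <- children_list(tr)
  for (v in (tr$n_tip + 1L):length(tr$parent)) tr$age[v] <- 0  # reset
  repeat {
    changed <- FALSE
    for (v in (tr$n_tip + 1L):length(tr$parent)) {
      a <- max(tr$age[ch[[v]]]) + 1
      if (a != tr$age[v]) { tr$age[v] <- a; changed <- TRUE }
    }
    if (!changed) break
  }
  tr
}

spr_eligible <- function(tr) {
  root <- tree_root(tr)
  cand <- which(tr$parent > 0L)
  cand <- cand[tr$parent[cand] != root]
  keep <- vapply(cand, function(v) {
    p <- tr$parent[v]
    !sa_attachment(tr, p)
  }, logical(1))
  cand[keep]
}

spr_targets <- function(tr_pruned_parent, tr, v, p, clockmode) {
  # candidate regraft edges (x -> y) in the pruned tree
  m <- length(tr_pruned_parent)
  sub <- subtree_nodes_parent(tr_pruned_parent, v, tr$n_tip)
  ys <- setdiff(which(tr_pruned_parent > 0L), c(sub, p))
  if (clockmode) {
    ok <- vapply(ys, function(y) {
      x <- tr_pruned_parent[y]
      tr$age[x] > max(tr$age[v], tr$age[y])
    }, logical(1))
    ys <- ys[ok]
  }
  ys
}

subtree_nodes_parent <- function(parent, v, n_tip) {
  out <- v
  repeat {
    more <- which(parent %in% out & !(seq_along(parent) %in% out))
    if (!length(more)) break
    out <- c(out, more)
  }
  out
}

prop_spr <- function(st, ctx) {
  tr <- st$tr
  clockmode <- ctx$cfg$mode == "clock"
  elig <- spr_eligible(tr)
  if (!length(elig)) return(NULL)
  v <- if (length(elig) == 1L) elig else sample(elig, 1L)
  p <- tr$parent[v]
  g <- tr$parent[p]
  sib <- setdiff(which(tr$parent == p), v)
  # prune: sib takes p's place under g
  pruned <- tr$parent
  pruned[sib] <- g
  pruned[p] <- 0L   # floating
  targets <- spr_targets(pruned, tr, v, p, clockmode)
  if (!length(targets)) return(NULL)
  y <- if (length(targets) == 1L) targets else sample(targets, 1L)
  x <- pruned[y]
  newtr <- tr
  newtr$parent <- pruned
  newtr$parent[y] <- p
  newtr$parent[p] <- x
  logH <- 0
  if (clockmode) {
    lo <- max(tr$age[v], tr$age[y]); hi <- tr$age[x]
    newtr$age[p] <- stats::runif(1, lo, hi)
    lo_rev <- max(tr$age[v], tr$age[sib]); hi_rev <- tr$age[g]
    logH <- log(hi_rev - lo_rev) - log(hi - lo)
  } else {
    newtr <- relevel_ages(newtr)
  }
  n_e <- length(elig)
  n_e_rev <- length(spr_eligible(newtr))
  logH <- logH + log(n_e) - log(n_e_rev)
  st$tr <- newtr
  list(st = st, logH = logH, parts = c("lik", "tree", "clock"))
}

pick_label <- function(ctx) {
  if (length(ctx$labels) == 1L) ctx$labels else sample(ctx$labels, 1L)
}

prop_base_rate <- function(st, ctx, delta = tune(ctx, "base_rate", 0.4)) {
  l <- pick_label(ctx)
  ce <- st$clock[[l]]
  u <- stats::runif(1, -delta, delta)
  ce$base_rate <- ce$base_rate * exp(u)
  logH <- u
  parts <- "clock"
  if (ce$model == "tk02") {
    # scale all node rates with the base rate so relative rates persist
    ce$rates <- ce$rates * exp(u)
    logH <- length(ce$rates) * u
    parts <- c("lik", "clock")
  } else if (ce$model == "igr") {
    # alternate two proposals: a joint scaling of c with all effective
    # lengths (keeps v/c ratios; mixes the overall scale) and a solo move
    # of c against the fixed v vector (mixes c given data-pinned lengths)
    if (stats::runif(1) < 0.5) {
      nb <- sum(!is.na(ce$v))
      ce$v <- ce$v * exp(u)
      logH <- (1 + nb) * u
      parts <- c("lik", "clock")
    } else {
      parts <- "clock"
    }
  } else if (ce$model == "strict") {
    parts <- c("lik", "clock")
  }
  st$clock[[l]] <- ce
  list(st = st, logH = logH, parts = parts)
}

prop_clock_variance <- function(st, ctx, delta = tune(ctx, "clock_variance", 0.6)) {
  l <- pick_label(ctx)
  u <- stats::runif(1, -delta, delta)
  st$clock[[l]]$nu <- st$clock[[l]]$nu * exp(u)
  list(st = st, logH = u, parts = "clock")
}

prop_branch_rate <- function(st, ctx, delta = tune(ctx, "branch_rate", 0.7)) {
  l <- pick_label(ctx)
  ce <- st$clock[[l]]
  tr <- st$tr
  d <- branch_durations(tr)
  if (ce$model == "strict") return(NULL)
  cand <- if (ce$model == "free") which(!is.na(d))
          else which(!is.na(d) & d > SA_TOL)
  if (!length(cand)) return(NULL)
  b <- if (length(cand) == 1L) cand else sample(cand, 1L)
  u <- stats::runif(1, -delta, delta)
  if (ce$model == "tk02") ce$rates[b] <- ce$rates[b] * exp(u)
  else ce$v[b] <- ce$v[b] * exp(u)
  st$clock[[l]] <- ce
  list(st = st, logH = u, parts = c("lik", "clock"))
}

prop_acrv_shape <- function(st, ctx, delta = tune(ctx, "acrv_shape", 0.5)) {
  l <- pick_label(ctx)
  u <- stats::runif(1, -delta, delta)
  st$clock[[l]]$acrv_shape <- st$clock[[l]]$acrv_shape * exp(u)
  list(st = st, logH = u, parts = c("lik", "param"))
}

reflect_into <- function(x, lo, hi) {
  width <- hi - lo
  while (x < lo || x > hi) {
    if (x < lo) x <- 2 * lo - x
    if (x > hi) x <- 2 * hi - x
  }
  x
}

prop_alpha_dir <- function(st, ctx, delta = tune(ctx, "alpha_dir", 2)) {
  b <- ctx$cfg$alpha_dir_bounds
  st$alpha_dir <- reflect_into(st$alpha_dir + stats::runif(1, -delta, delta),
                               b[1], b[2])
  list(st = st, logH = 0, parts = c("lik", "param"))
}

prop_fbd_d <- function(st, ctx, delta = tune(ctx, "fbd_d", 0.5)) {
  i <- sample.int(length(st$fbd$d), 1L)
  u <- stats::runif(1, -delta, delta)
  st$fbd$d[i] <- st$fbd$d[i] * exp(u)
  list(st = st, logH = u, parts = c("tree", "param"))
}

prop_fbd_r <- function(st, ctx, delta = tune(ctx, "fbd_r", 0.15)) {
  i <- sample.int(length(st$fbd$r), 1L)
  st$fbd$r[i] <- reflect_into(st$fbd$r[i] + stats::runif(1, -delta, delta),
                              1e-9, 1 - 1e-9)
  list(st = st, logH = 0, parts = c("tree", "param"))
}

prop_fbd_s <- function(st, ctx, delta = tune(ctx, "fbd_s", 0.15)) {
  i <- sample.int(length(st$fbd$s), 1L)
  st$fbd$s[i] <- reflect_into(st$fbd$s[i] + stats::runif(1, -delta, delta),
                              1e-9, 1 - 1e-9)
  list(st = st, logH = 0, parts = c("tree", "param"))
}

# reversible-jump pair: fossil tip <-> sampled ancestor
add_eligible <- function(tr) {
  cand <- which(tr$age[seq_len(tr$n_tip)] > SA_TOL)
  keep <- vapply(cand, function(f) {
    p <- tr$parent[f]
    if (p == 0L || tr$parent[p] == 0L) return(FALSE)
    if (is_sa_tip(tr, f)) return(FALSE)
    sib <- setdiff(which(tr$parent == p), f)
    if (is_sa_tip(tr, sib)) return(FALSE)
    y <- tr$age[f]
    tr$age[sib] <= y && y <= tr$age[tr$parent[p]]
  }, logical(1))
  cand[keep]
}

del_eligible <- function(tr) {
  cand <- which(vapply(seq_len(tr$n_tip), function(f) is_sa_tip(tr, f),
                       logical(1)))
  keep <- vapply(cand, function(f) {
    p <- tr$parent[f]
    if (tr$parent[p] == 0L) return(FALSE)
    sib <- setdiff(which(tr$parent == p), f)
    lo <- max(tr$age[f], tr$age[sib]); hi <- tr$age[tr$parent[p]]
    hi > lo
  }, logical(1))
  cand[keep]
}

# branch-variable birth density used when an SA reverts to a regular tip
branch_var_logdens <- function(ce, value, t_branch) {
  if (ce$model == "igr")
    stats::dgamma(value, shape = ce$base_rate * t_branch / ce$nu,
                  rate = 1 / ce$nu, log = TRUE)
  else if (ce$model == "tk02") NA  # handled with parent rate by caller
  else 0
}

prop_add_branch <- function(st, ctx) {
  if (!ctx$strategy$sa_allowed) return(NULL)
  tr <- st$tr
  elig <- add_eligible(tr)
  if (!length(elig)) return(NULL)
  f <- if (length(elig) == 1L) elig else sample(elig, 1L)
  p <- tr$parent[f]; g <- tr$parent[p]
  sib <- setdiff(which(tr$parent == p), f)
  y <- tr$age[f]
  old_p_age <- tr$age[p]
  lo <- max(y, tr$age[sib]); hi <- tr$age[g]
  tr$age[p] <- y
  st$tr <- tr
  logg <- 0
  for (l in ctx$labels) {
    ce <- st$clock[[l]]
    if (ce$model == "igr") {
      logg <- logg + stats::dgamma(ce$v[f],
                shape = ce$base_rate * (old_p_age - y) / ce$nu,
                rate = 1 / ce$nu, log = TRUE)
      ce$v[f] <- 0
    } else if (ce$model == "tk02") {
      s2 <- ce$nu * (old_p_age - y)
      logg <- logg + stats::dlnorm(ce$rates[f],
                meanlog = log(ce$rates[p]) - s2 / 2, sdlog = sqrt(s2),
                log = TRUE)
      ce$rates[f] <- ce$rates[p]
    }
    st$clock[[l]] <- ce
  }
  n_del_rev <- length(del_eligible(tr))
  if (!n_del_rev) return(NULL)
  logH <- (-log(n_del_rev) - log(hi - lo) + logg) - (-log(length(elig)))
  list(st = st, logH = logH, parts = c("lik", "tree", "clock"))
}

prop_delete_branch <- function(st, ctx) {
  if (!ctx$strategy$sa_allowed) return(NULL)
  tr <- st$tr
  elig <- del_eligible(tr)
  if (!length(elig)) return(NULL)
  f <- if (length(elig) == 1L) elig else sample(elig, 1L)
  p <- tr$parent[f]; g <- tr$parent[p]
  sib <- setdiff(which(tr$parent == p), f)
  y <- tr$age[f]
  lo <- max(y, tr$age[sib]); hi <- tr$age[g]
  new_age <- stats::runif(1, lo, hi)
  tr$age[p] <- new_age
  st$tr <- tr
  logg <- 0
  for (l in ctx$labels) {
    ce <- st$clock[[l]]
    if (ce$model == "igr") {
      sh <- ce$base_rate * (new_age - y) / ce$nu
      ce$v[f] <- stats::rgamma(1, shape = sh, rate = 1 / ce$nu)
      logg <- logg + stats::dgamma(ce$v[f], shape = sh, rate = 1 / ce$nu,
                                   log = TRUE)
    } else if (ce$model == "tk02") {
      s2 <- ce$nu * (new_age - y)
      ml <- log(ce$rates[p]) - s2 / 2
      ce$rates[f] <- stats::rlnorm(1, meanlog = ml, sdlog = sqrt(s2))
      logg <- logg + stats::dlnorm(ce$rates[f], meanlog = ml,
                                   sdlog = sqrt(s2), log = TRUE)
    }
    st$clock[[l]] <- ce
  }
  n_add_rev <- length(add_eligible(tr))
  if (!n_add_rev) return(NULL)
  logH <- (-log(n_add_rev)) - (-log(length(elig)) - log(hi - lo) + logg)
  list(st = st, logH = logH, parts = c("lik", "tree", "clock"))
}

move_table <- list(node_age = prop_node_age, root_age = prop_root_age,
                   tip_age = prop_tip_age, exchange = prop_exchange,
                   spr = prop_spr, base_rate = prop_base_rate,
                   clock_variance = prop_clock_variance,
                   branch_rate = prop_branch_rate,
                   acrv_shape = prop_acrv_shape, alpha_dir = prop_alpha_dir,
                   fbd_d = prop_fbd_d, fbd_r = prop_fbd_r, fbd_s = prop_fbd_s,
                   add_branch = prop_add_branch,
                   delete_branch = prop_delete_branch)

active_moves <- function(cfg) {
  w <- cfg$move_weights
  if (cfg$mode == "nonclock") {
    keep <- c("exchange", "spr", "branch_rate", "acrv_shape", "alpha_dir")
    w[setdiff(names(w), keep)] <- 0
    w["branch_rate"] <- max(w["branch_rate"], 10)
  }
  w[w > 0]
}

# ---- main loop ------------------------------------------------------------

#' Run the MCMC sampler
#'
#' Metropolis-Hastings-within-Gibbs over tree topology, node/tip ages, clock
#' state, substitution-model parameters and FBD parameters, in `n_runs`
#' independent runs with seeds derived from `config$seed`. With
#' `likelihood_on = FALSE` the chain targets the prior. Identical seed and
#' configuration reproduce the samples bit for bit.
#'
#' @param config a [run_config()].
#' @param mat a [morph_matrix()] (ignored in prior-only runs but still
#'   required for its taxon set when no calibration table is given).
#' @param calibrations a [calibration_table()] covering the matrix taxa.
#' @return an object of class `mcmc_runs`: per run a `trace` data frame
#'   (one row per retained sample), the sampled trees, and per-sample
#'   relative branch rates; plus acceptance rates per move.
#' @export
run_mcmc <- function(config, mat, calibrations) {
  stopifnot(inherits(config, "run_config"))
  ctx <- build_ctx(config, mat, calibrations)
  weights <- active_moves(config)
  if (!length(weights)) stop2("configuration error: no active moves")
  runs <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    set.seed(derive_seed(config$seed, r))
    runs[[r]] <- mcmc_single_run(ctx, weights, run_id = r)
  }
  structure(list(config = config, runs = runs, seed = config$seed,
                 labels = ctx$labels),
            class = "mcmc_runs")
}

mcmc_single_run <- function(ctx, weights, run_id, init_st = NULL,
                            record_raw = FALSE) {
  cfg <- ctx$cfg
  st <- if (is.null(init_st)) init_state(ctx)
        else recompute_parts(init_st, ctx, names(part_fns))
  mv_names <- names(weights)
  probs <- weights / sum(weights)
  n_keep <- cfg$generations %/% cfg$sample_every
  trace <- vector("list", n_keep)
  trees <- vector("list", n_keep)
  relr <- vector("list", n_keep)
  att <- acc <- stats::setNames(numeric(length(mv_names)), mv_names)
  ki <- 0L
  for (gen in seq_len(cfg$generations)) {
    mv <- sample(mv_names, 1L, prob = probs)
    att[mv] <- att[mv] + 1
    prop <- move_table[[mv]](st, ctx)
    if (!is.null(prop)) {
      pst <- recompute_parts(prop$st, ctx, prop$parts)
      lr <- state_posterior(pst) - state_posterior(st) + prop$logH
      if (is.finite(lr) || lr == Inf) {
        if (lr >= 0 || log(stats::runif(1)) < lr) {
          st <- pst
          acc[mv] <- acc[mv] + 1
        }
      }
    }
    if (gen %% cfg$sample_every == 0L) {
      ki <- ki + 1L
      trace[[ki]] <- record_row(st, ctx, gen, run_id)
      if (record_raw) trace[[ki]]$raw_loglik <- mc_raw_loglik(st, ctx)
      trees[[ki]] <- st$tr
      relr[[ki]] <- record_rel_rates(st, ctx)
    }
  }
  list(trace = do.call(rbind, trace), trees = trees, rel_rates = relr,
       acceptance = ifelse(att > 0, acc / att, NA_real_), attempts = att,
       final_state = st)
}

record_row <- function(st, ctx, gen, run_id) {
  row <- data.frame(gen = gen, run = run_id,
                    loglik = st$lp_lik,
                    logprior = st$lp_tree + st$lp_clock + st$lp_param,
                    root_age = st$tr$age[tree_root(st$tr)],
                    n_sa = sum(sampled_ancestors(st$tr) &
                                 st$tr$age[seq_len(st$tr$n_tip)] > SA_TOL),
                    alpha_dir = st$alpha_dir)
  for (l in ctx$labels) {
    suff <- if (length(ctx$labels) == 1L) "" else paste0("_", l)
    row[[paste0("base_rate", suff)]] <- st$clock[[l]]$base_rate
    row[[paste0("clock_var", suff)]] <- st$clock[[l]]$nu %||% NA_real_
    row[[paste0("acrv_shape", suff)]] <- st$clock[[l]]$acrv_shape
  }
  for (i in seq_along(st$fbd$d)) row[[paste0("d", i)]] <- st$fbd$d[i]
  for (i in seq_along(st$fbd$r)) row[[paste0("r", i)]] <- st$fbd$r[i]
  for (i in seq_along(st$fbd$s)) row[[paste0("s", i)]] <- st$fbd$s[i]
  row
}

record_rel_rates <- function(st, ctx) {
  d <- branch_durations(st$tr)
  out <- matrix(NA_real_, length(d), length(ctx$labels),
                dimnames = list(NULL, ctx$labels))
  for (l in ctx$labels) {
    ce <- st$clock[[l]]
    if (ce$model == "free") {
      # non-clock mode: store the free branch lengths themselves
      out[, l] <- ce$v
      next
    }
    eff <- eff_lengths_of(st$tr, ce)
    br <- eff / d
    br[is.na(d) | d <= SA_TOL] <- NA_real_
    out[, l] <- br / ce$base_rate
  }
  out
}

#' @export
print.mcmc_runs <- function(x, ...) {
  cat("mcmc_runs:", length(x$runs), "run(s) of", x$config$generations,
      "generations (", x$config$label, ")\n")
  cat("  retained samples per run:", nrow(x$runs[[1]]$trace), "\n")
  invisible(x)
}

#' Post-burn-in samples from a set of runs
#' @param fit an `mcmc_runs` object.
#' @param burnin_frac fraction of retained samples to discard (default from
#'   the run configuration).
#' @return list with `trace` (combined data frame), `trees`, `rel_rates`.
#' @export
posterior_samples <- function(fit, burnin_frac = NULL) {
  burnin_frac <- burnin_frac %||% fit$config$burnin_frac
  traces <- list(); trees <- list(); relr <- list()
  for (r in seq_along(fit$runs)) {
    n <- nrow(fit$runs[[r]]$trace)
    keep <- seq.int(floor(n * burnin_frac) + 1L, n)
    traces[[r]] <- fit$runs[[r]]$trace[keep, , drop = FALSE]
    trees <- c(trees, fit$runs[[r]]$trees[keep])
    relr <- c(relr, fit$runs[[r]]$rel_rates[keep])
  }
  list(trace = do.call(rbind, traces), trees = trees, rel_rates = relr)
}

#' Tree height in expected substitutions per character
#'
#' Maximum root-to-tip sum of effective branch lengths; used with the root
#' age to derive the base clock-rate prior from a non-clock analysis.
#'
#' @param tr a [timetree()].
#' @param eff effective branch lengths over nodes.
#' @return height in substitutions per character.
#' @export
tree_height_substitutions <- function(tr, eff) {
  root <- tree_root(tr)
  h <- numeric(length(tr$parent))
  for (v in c(rev(postorder_nodes(tr)), seq_len(tr$n_tip)))
    if (v != root) h[v] <- h[tr$parent[v]] + eff[v]
  max(h[seq_len(tr$n_tip)])
}
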