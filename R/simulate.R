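# Forward simulation of fossilized birth-death time trees and clocked
# morphological matrices: study-shaped inputs for calibration and
# parameter-recovery experiments.

#' Specify a simulation
#'
#' Defaults emulate the shape of a sphenodontian-like data set: about 35
#' taxa (one extant, the rest fossil tips spanning the Triassic to the Late
#' Cretaceous), 131 unordered characters of which three anatomical
#' partitions (47/44/38) cover 129 — the remainder goes to a default
#' partition, as unlabeled characters do on reading — mostly binary states,
#' about 17% direct
#' autapomorphies, diversified extant sampling with a fossil cutoff at
#' 66 Ma, and an informative morphological clock around 0.02
#' substitutions/character/Myr.
#'
#' @param root_age true root age, Ma.
#' @param d,r,s net diversification, turnover and fossil-sampling
#'   proportion of the generating FBD process; `s` may be a vector (one
#'   value per skyline slice, oldest first) with `shift_times` giving the
#'   rate-shift ages.
#' @param shift_times skyline shift times, Ma (empty = constant rates).
#' @param rho extant-sampling probability (random strategy).
#' @param strategy extant sampling: `"diversified"` keeps one extant
#'   representative per lineage crossing `x_cut` and samples no fossil
#'   younger than `x_cut`; `"random"` samples extant tips with probability
#'   `rho`.
#' @param x_cut fossil cutoff for the diversified strategy, Ma.
#' @param retain_ancestors keep fossils on sampled lineages as sampled
#'   ancestors (zero-length tips); otherwise they are dropped and only
#'   terminal fossils of extinct lineages become tips.
#' @param partitions named integer vector of characters per partition.
#' @param state_probs probabilities of 2..5 states per character.
#' @param clock_model,base_rate,clock_variance the generating clock.
#' @param acrv_kind,acrv_shape generating among-character rate variation.
#' @param autapomorphy_target target fraction of direct autapomorphies,
#'   steered by rejection within +-5 percentage points.
#' @param missing_fraction per-cell probability of missing data.
#' @param fossil_range_width bounds (Myr) of the uniform stratigraphic
#'   range width wrapped around each true fossil age.
#' @param taxa_range acceptable total taxon count; simulations outside it
#'   are retried.
#' @param n_extant_range acceptable number of sampled extant tips; the
#'   default conditions on a single living representative.
#' @param seed integer seed (mandatory; recorded in all outputs).
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(root_age = 280,
                            d = 0.001, r = 0.983, s = 0.5,
                            shift_times = numeric(0), rho = 1,
                            strategy = c("diversified", "random"),
                            x_cut = 66, retain_ancestors = FALSE,
                            partitions = c(skull = 47, mandible = 44,
                                           postcranial = 38, default = 2),
                            state_probs = c(`2` = 0.75, `3` = 0.15,
                                            `4` = 0.06, `5` = 0.04),
                            clock_model = c("igr", "strict", "tk02"),
                            base_rate = 0.02, clock_variance = 0.02,
                            acrv_kind = c("gamma", "lognormal", "none"),
                            acrv_shape = 1,
                            autapomorphy_target = 0.17,
                            missing_fraction = 0.25,
                            fossil_range_width = c(2, 10),
                            taxa_range = c(25, 45),
                            n_extant_range = c(1, 1),
                            seed = 1L) {
  if (any(c(d) <= 0) || any(r < 0 | r >= 1) || any(s < 0 | s >= 1))
    stop2("invalid FBD parameters")
  if (length(s) != length(shift_times) + 1L)
    stop2("s must have one value per slice")
  structure(list(root_age = root_age, d = d, r = r, s = s,
                 shift_times = as.numeric(shift_times), rho = rho,
                 strategy = match.arg(strategy), x_cut = x_cut,
                 retain_ancestors = isTRUE(retain_ancestors),
                 partitions = partitions, state_probs = state_probs,
                 clock_model = match.arg(clock_model),
                 base_rate = base_rate, clock_variance = clock_variance,
                 acrv_kind = match.arg(acrv_kind), acrv_shape = acrv_shape,
                 autapomorphy_target = autapomorphy_target,
                 missing_fraction = missing_fraction,
                 fossil_range_width = fossil_range_width,
                 taxa_range = taxa_range,
                 n_extant_range = n_extant_range, seed = as.integer(seed)),
            class = "simulation_spec")
}

# piecewise-constant rates at age t (oldest slice first in spec$s)
sim_rates_at <- function(spec, t) {
  lam <- spec$d / (1 - spec$r)
  mu <- lam * spec$r
  bnd <- c(Inf, spec$shift_times, 0)
  i <- which(t <= bnd[-length(bnd)] & t > bnd[-1])[1]
  if (is.na(i)) i <- length(spec$s)
  psi <- mu * spec$s[i] / (1 - spec$s[i])
  # rates govern the segment just below t: at t = x_cut the remaining
  # segment lies inside the no-fossil window
  if (spec$strategy == "diversified" && t <= spec$x_cut) psi <- 0
  c(lambda = lam, mu = mu, psi = psi)
}

next_slice_bottom <- function(spec, t) {
  bnd <- sort(c(spec$shift_times,
                if (spec$strategy == "diversified") spec$x_cut), decreasing = TRUE)
  below <- bnd[bnd < t]
  if (length(below)) below[1] else 0
}

# forward-simulate one lineage from age t0 toward the present
sim_lineage <- function(spec, t0) {
  fossils <- numeric(0)
  t <- t0
  repeat {
    rt <- sim_rates_at(spec, t)
    tot <- sum(rt)
    nxt <- if (tot > 0) t - stats::rexp(1, tot) else -Inf
    bottom <- next_slice_bottom(spec, t)
    if (nxt <= bottom) {
      if (bottom <= 0) {
        return(list(fossils = fossils, fate = "extant", split_age = NA,
                    left = NULL, right = NULL))
      }
      t <- bottom
      next
    }
    t <- nxt
    ev <- sample(c("birth", "death", "fossil"), 1L, prob = rt)
    if (ev == "birth") {
      return(list(fossils = fossils, fate = "split", split_age = t,
                  left = sim_lineage(spec, t), right = sim_lineage(spec, t)))
    }
    if (ev == "death")
      return(list(fossils = fossils, fate = "extinct", split_age = NA,
                  left = NULL, right = NULL))
    fossils <- c(fossils, t)
  }
}

# decide which extant tips are sampled, then prune to the sampled tree
prune_sampled <- function(spec, lin) {
  # recursively assemble: returns NULL or
  # list(kind = "tip"/"node", age, is_extant, children, sa_ages)
  build <- function(node) {
    below <- NULL
    if (node$fate == "split") {
      L <- build(node$left); R <- build(node$right)
      if (!is.null(L) && !is.null(R))
        below <- list(kind = "node", age = node$split_age, is_extant = FALSE,
                      children = list(L, R), sa_ages = numeric(0))
      else below <- L %||% R
    } else if (node$fate == "extant" && node$sampled_extant) {
      below <- list(kind = "tip", age = 0, is_extant = TRUE,
                    children = NULL, sa_ages = numeric(0))
    }
    fos <- sort(node$fossils)   # youngest first
    if (is.null(below)) {
      if (!length(fos)) return(NULL)
      below <- list(kind = "tip", age = fos[1], is_extant = FALSE,
                    children = NULL, sa_ages = numeric(0))
      fos <- fos[-1]
    }
    if (length(fos) && spec$retain_ancestors)
      below$sa_ages <- c(below$sa_ages, fos)
    below
  }
  build(lin)
}

mark_extant_sampling <- function(spec, node, crossing = FALSE) {
  # annotate each terminal "extant" fate with sampled_extant
  if (node$fate == "split") {
    node$left <- mark_extant_sampling(spec, node$left)
    node$right <- mark_extant_sampling(spec, node$right)
  } else if (node$fate == "extant") {
    node$sampled_extant <- stats::runif(1) < spec$rho
  }
  node
}

mark_diversified_sampling <- function(spec, node, t_top) {
  # one extant representative per lineage crossing x_cut
  collect_extant <- function(nd) {
    if (nd$fate == "split")
      c(collect_extant(nd$left), collect_extant(nd$right))
    else if (nd$fate == "extant") list(nd) else list()
  }
  pick <- function(nd, t_from) {
    if (nd$fate == "split" && nd$split_age > spec$x_cut) {
      nd$left <- pick(nd$left, nd$split_age)
      nd$right <- pick(nd$right, nd$split_age)
      return(nd)
    }
    # this whole subtree hangs from one lineage crossing x_cut
    mark_one <- local({
      chosen <- FALSE
      function(x) {
        if (x$fate == "split") {
          x$left <- mark_one(x$left); x$right <- mark_one(x$right)
        } else if (x$fate == "extant") {
          if (!chosen) { x$sampled_extant <- TRUE; chosen <<- TRUE }
          else x$sampled_extant <- FALSE
        }
        x
      }
    })
    mark_one(nd)
  }
  zero_all <- function(nd) {
    if (nd$fate == "split") {
      nd$left <- zero_all(nd$left); nd$right <- zero_all(nd$right)
    } else if (nd$fate == "extant") nd$sampled_extant <- FALSE
    nd
  }
  node <- zero_all(node)
  pick(node, t_top)
}

assembled_to_timetree <- function(asm, spec) {
  tips <- list(); nodes <- list()
  # expand sampled-ancestor attachments into zero-length tip branches
  expand <- function(x) {
    core <- x
    core$sa_ages <- NULL
    if (!is.null(core$children) && length(core$children))
      core$children <- lapply(core$children, expand)
    for (z in sort(x$sa_ages %||% numeric(0))) {   # youngest SA deepest
      core <- list(kind = "node", age = z, is_extant = FALSE,
                   children = list(core,
                                   list(kind = "tip", age = z,
                                        is_extant = FALSE, children = NULL)))
    }
    core
  }
  asm <- expand(asm)
  n_tip_ctr <- 0L
  count_tips <- function(x) {
    if (x$kind == "tip") return(1L)
    sum(vapply(x$children, count_tips, integer(1)))
  }
  n <- count_tips(asm)
  parent <- integer(2L * n - 1L)
  age <- numeric(2L * n - 1L)
  extant <- logical(n)
  tip_i <- 0L; int_i <- n
  walk <- function(x, par) {
    if (x$kind == "tip") {
      tip_i <<- tip_i + 1L
      parent[tip_i] <<- par
      age[tip_i] <<- x$age
      extant[tip_i] <<- isTRUE(x$is_extant)
      return(tip_i)
    }
    int_i <<- int_i + 1L
    me <- int_i
    parent[me] <<- par
    age[me] <<- x$age
    for (ch in x$children) walk(ch, me)
    me
  }
  walk(asm, 0L)
  labels <- character(n)
  labels[extant] <- sprintf("extant_%02d", seq_len(sum(extant)))
  labels[!extant] <- sprintf("fossil_%02d", seq_len(sum(!extant)))
  list(tree = timetree(parent, age, labels), extant = extant)
}

#' Simulate a sampled FBD time tree and its calibration table
#'
#' Forward birth-death simulation from the root age with Poisson fossil
#' sampling along lineages, extant sampling by the configured strategy,
#' and pruning to the sampled tree. Fossil tip ages are wrapped in uniform
#' stratigraphic ranges of random width. Simulations ending with no sampled
#' extant tip (or a taxon count outside `taxa_range`) are retried.
#'
#' @param spec a [simulation_spec()].
#' @param max_tries retry cap before giving up.
#' @return list with `tree` (a [timetree()], true ages), `calibrations`
#'   (a [calibration_table()] of stratigraphic ranges), and `truth`
#'   (the generating parameters).
#' @export
simulate_fbd_tree <- function(spec, max_tries = 500L) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  for (i in seq_len(max_tries)) {
    lin <- list(fossils = numeric(0), fate = "split",
                split_age = spec$root_age,
                left = sim_lineage(spec, spec$root_age),
                right = sim_lineage(spec, spec$root_age))
    lin <- if (spec$strategy == "diversified")
      mark_diversified_sampling(spec, lin, spec$root_age)
    else mark_extant_sampling(spec, lin)
    asm <- prune_sampled(spec, lin)
    if (is.null(asm) || asm$kind != "node") next
    res <- assembled_to_timetree(asm, spec)
    n <- res$tree$n_tip
    ner <- spec$n_extant_range %||% c(1, Inf)
    if (sum(res$extant) < ner[1] || sum(res$extant) > ner[2]) next
    if (n < spec$taxa_range[1] || n > spec$taxa_range[2]) next
    if (abs(res$tree$age[tree_root(res$tree)] - spec$root_age) > 1e-6) next
    tr <- res$tree
    w <- stats::runif(n, spec$fossil_range_width[1], spec$fossil_range_width[2])
    frac <- stats::runif(n)
    lo <- pmax(0, tr$age[seq_len(n)] - frac * w)
    hi <- tr$age[seq_len(n)] + (1 - frac) * w
    if (spec$strategy == "diversified") lo <- pmax(lo, spec$x_cut)
    lo[res$extant] <- 0; hi[res$extant] <- 0
    hi <- pmax(hi, lo)
    cal <- calibration_table(tr$tip_label, lo, hi)
    return(list(tree = tr, calibrations = cal,
                truth = list(root_age = spec$root_age, d = spec$d,
                             r = spec$r, s = spec$s,
                             n_extant = sum(res$extant),
                             n_fossil = sum(!res$extant),
                             n_sa = sum(sampled_ancestors(tr)))))
  }
  stop2("no acceptable simulation in ", max_tries,
        " tries (total extinction or taxon count out of range)")
}

# sample true per-branch effective lengths under the generating clock
true_effective_lengths <- function(tr, spec) {
  d <- branch_durations(tr)
  switch(spec$clock_model,
         strict = spec$base_rate * d,
         igr = igr_sample_lengths(d, spec$base_rate, spec$clock_variance),
         tk02 = tk02_effective_lengths(
           tr, tk02_sample_rates(tr, spec$base_rate, spec$clock_variance)))
}

sim_one_char <- function(tr, eff, k, rate_mult) {
  m <- length(tr$parent)
  states <- integer(m)
  root <- tree_root(tr)
  states[root] <- sample.int(k, 1L)
  for (v in rev(order(tr$age))) {
    if (v == root) next
    P <- mk_transition_probability(k, eff[v] * rate_mult)
    states[v] <- sample.int(k, 1L, prob = P[states[tr$parent[v]], ])
  }
  states[seq_len(tr$n_tip)] - 1L
}

char_is_autapomorphic <- function(tipstates) {
  tab <- table(tipstates)
  length(tab) >= 2L && any(tab == 1L)
}

#' Simulate a clocked morphological character matrix on a tree
#'
#' Characters evolve under the unordered Mk process with continuous
#' among-character rate variation along the true clock's effective branch
#' lengths; constant characters are rejected and resimulated
#' (variable-characters-only ascertainment), and the fraction of direct
#' autapomorphies is steered toward the target (+-5 percentage points) by
#' rejection quotas, never by editing simulated states.
#'
#' @param tr a [timetree()] (e.g. from [simulate_fbd_tree()]).
#' @param spec a [simulation_spec()].
#' @param eff optional true effective branch lengths (sampled from the
#'   generating clock when omitted).
#' @return a [morph_matrix()] with the true effective lengths in
#'   `attr(, "true_eff")` and the achieved autapomorphy fraction in
#'   `attr(, "autapomorphy_fraction")`.
#' @export
simulate_matrix <- function(tr, spec, eff = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (is.null(eff)) eff <- true_effective_lengths(tr, spec)
  if (all(eff[-tree_root(tr)] <= 0, na.rm = TRUE))
    stop2("all branch lengths zero: every character would be constant")
  n_char <- sum(spec$partitions)
  target <- spec$autapomorphy_target
  steer <- !is.na(target)   # NA: plain Mk characters, no quota conditioning
  n_aut_target <- if (steer) round(target * n_char) else NA_integer_
  ks <- as.integer(names(spec$state_probs))
  draw_rate <- function() {
    if (spec$acrv_kind == "none") 1
    else if (spec$acrv_kind == "gamma")
      stats::rgamma(1, shape = spec$acrv_shape, rate = spec$acrv_shape)
    else stats::rlnorm(1, -spec$acrv_shape^2 / 2, spec$acrv_shape)
  }
  n <- tr$n_tip
  cells <- matrix(NA_character_, n, n_char)
  got_aut <- 0L; got_non <- 0L; filled <- 0L
  tries <- 0L; max_tries <- 400L * n_char
  while (filled < n_char && tries < max_tries) {
    tries <- tries + 1L
    k <- sample(ks, 1L, prob = spec$state_probs)
    st <- sim_one_char(tr, eff, k, draw_rate())
    if (length(unique(st)) < 2L) next        # ascertainment: variable only
    aut <- char_is_autapomorphic(st)
    if (steer && aut && got_aut >= n_aut_target) next
    if (steer && !aut && got_non >= n_char - n_aut_target) next
    filled <- filled + 1L
    cells[, filled] <- as.character(st)
    if (aut) got_aut <- got_aut + 1L else got_non <- got_non + 1L
  }
  if (filled < n_char)
    stop2("could not fill the matrix under the ascertainment/autapomorphy ",
          "constraints (zero branch lengths?)")
  achieved <- got_aut / n_char
  if (steer && abs(achieved - target) > 0.05)
    warning(sprintf("autapomorphy target %.2f not met: achieved %.2f",
                    target, achieved), call. = FALSE)
  if (spec$missing_fraction > 0) {
    miss <- matrix(stats::runif(n * n_char) < spec$missing_fraction, n, n_char)
    # never blank a whole character or reduce it below two observed states
    for (j in seq_len(n_char)) {
      if (length(unique(cells[!miss[, j], j])) < 2L) miss[, j] <- FALSE
    }
    cells[miss] <- "?"
  }
  rownames(cells) <- tr$tip_label
  part <- rep(names(spec$partitions), spec$partitions)
  out <- morph_matrix(cells, tr$tip_label, partition = part)
  attr(out, "true_eff") <- eff
  # recomputed on the final matrix: masking can shift singleton states
  attr(out, "autapomorphy_fraction") <- autapomorphy_stats(out)$fraction
  out
}

#' Generate a complete study-shaped input bundle
#'
#' Simulates an FBD time tree, calibration table and partitioned character
#' matrix with the spec's study-shaped defaults, writes them (NEXUS matrix,
#' CSV calibrations, YAML run configuration) together with a sidecar file
#' recording the generating truth, and returns everything in memory.
#'
#' @param spec a [simulation_spec()].
#' @param dir output directory (created if needed); `NULL` skips writing.
#' @return list with `tree`, `calibrations`, `matrix`, `truth`, and
#'   `paths` (when written).
#' @export
make_study_bundle <- function(spec, dir = NULL) {
  sim <- simulate_fbd_tree(spec)
  mat <- simulate_matrix(sim$tree, spec)
  truth <- c(sim$truth, list(base_rate = spec$base_rate,
                             clock_variance = spec$clock_variance,
                             clock_model = spec$clock_model,
                             autapomorphy_fraction =
                               attr(mat, "autapomorphy_fraction"),
                             seed = spec$seed))
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(matrix = file.path(dir, "matrix.nex"),
                  calibrations = file.path(dir, "calibrations.csv"),
                  tree = file.path(dir, "true_tree.nwk"),
                  config = file.path(dir, "config.yaml"),
                  truth = file.path(dir, "truth.yaml"))
    write_nexus_matrix(mat, paths$matrix)
    write_calibrations(sim$calibrations, paths$calibrations)
    write_annotated_tree(sim$tree, paths$tree)
    cfg <- run_config(label = "study-bundle",
                      clock_model = spec$clock_model,
                      strategy = if (spec$strategy == "diversified")
                        "nosa_diversity" else "fossiltip",
                      x_cut = spec$x_cut, seed = spec$seed)
    write_run_config(cfg, paths$config)
    yaml::write_yaml(truth, paths$truth)
  }
  list(tree = sim$tree, calibrations = sim$calibrations, matrix = mat,
       truth = truth, paths = paths)
}
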