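# Posterior tree summarization: 50% majority-rule consensus (MRC), maximum
# compatibility tree (MCT), HPD node ages, and relative branch rates.

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing `ceiling(mass * n)` of the sorted
#' samples.
#'
#' @param x numeric samples.
#' @param mass interval mass (default 0.95).
#' @return numeric `c(low, high)`.
#' @export
hpd_interval <- function(x, mass = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 1L) stop2("empty sample")
  if (n < 20L)
    warning("fewer than 20 samples: HPD estimator variance is large",
            call. = FALSE)
  k <- ceiling(mass * n)
  if (k >= n) return(c(x[1], x[n]))
  starts <- seq_len(n - k + 1L)
  widths <- x[starts + k - 1L] - x[starts]
  i <- which.min(widths)
  c(x[i], x[i + k - 1L])
}

# accumulate per-clade statistics over tree samples
clade_statistics <- function(trees, rel_rates = NULL) {
  n_tip <- trees[[1]]$n_tip
  n_samp <- length(trees)
  env <- new.env(hash = TRUE)
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    keys <- clade_keys(tr)
    rr <- if (!is.null(rel_rates)) rel_rates[[i]] else NULL
    for (v in seq_along(keys)) {
      k <- keys[v]
      rec <- get0(k, env, inherits = FALSE)
      if (is.null(rec)) rec <- list(count = 0, ages = numeric(0),
                                    rates = NULL, size = NA_integer_)
      rec$count <- rec$count + 1
      rec$ages <- c(rec$ages, tr$age[v])
      if (!is.null(rr)) {
        if (is.null(rec$rates))
          rec$rates <- matrix(numeric(0), 0, ncol(rr),
                              dimnames = list(NULL, colnames(rr)))
        rec$rates <- rbind(rec$rates, rr[v, , drop = FALSE])
      }
      if (is.na(rec$size))
        rec$size <- length(strsplit(k, ",", fixed = TRUE)[[1]])
      assign(k, rec, env)
    }
  }
  keys <- ls(env)
  list(env = env, keys = keys, n_samples = n_samp, n_tip = n_tip,
       taxa = sort(trees[[1]]$tip_label))
}

clades_compatible <- function(a, b) {
  ia <- intersect(a, b)
  length(ia) == 0L || length(ia) == length(a) || length(ia) == length(b)
}

# assemble a summary tree (possibly multifurcating) from a nested clade set
build_summary_tree <- function(stats, accepted_keys, clip_log = TRUE) {
  taxa <- stats$taxa
  full <- paste(taxa, collapse = ",")
  if (!(full %in% accepted_keys)) accepted_keys <- c(accepted_keys, full)
  sets <- lapply(accepted_keys, function(k) strsplit(k, ",", fixed = TRUE)[[1]])
  sizes <- lengths(sets)
  ord <- order(sizes)
  sets <- sets[ord]; accepted_keys <- accepted_keys[ord]; sizes <- sizes[ord]
  n <- length(taxa)
  n_int <- length(sets)
  # parent of each element = smallest accepted clade strictly containing it
  node_id <- function(i) n + i
  parent <- integer(n + n_int)
  for (t in seq_len(n)) {
    for (i in seq_along(sets)) {
      if (sizes[i] > 1L && taxa[t] %in% sets[[i]]) {
        parent[t] <- node_id(i); break
      }
    }
  }
  for (i in seq_len(n_int)) {
    parent[node_id(i)] <- 0L
    for (j in seq_along(sets)) {
      if (j == i) next
      if (sizes[j] > sizes[i] && all(sets[[i]] %in% sets[[j]])) {
        parent[node_id(i)] <- node_id(j); break
      }
    }
  }
  # clade summaries
  rows <- lapply(seq_len(n_int), function(i) {
    rec <- get(accepted_keys[i], stats$env, inherits = FALSE)
    hpd <- hpd_interval_quiet(rec$ages)
    rates <- if (!is.null(rec$rates))
      apply(rec$rates, 2, function(x) stats::median(x, na.rm = TRUE))
    else NULL
    data.frame(clade = accepted_keys[i], size = sizes[i],
               pp = rec$count / stats$n_samples,
               median_age = stats::median(rec$ages),
               hpd_low = hpd[1], hpd_high = hpd[2],
               hpd_range = hpd[2] - hpd[1],
               median_rel_rate = if (!is.null(rates)) rates[1] else NA_real_)
  })
  clades <- do.call(rbind, rows)
  # tip summaries (ages fixed/uniform; rates meaningful)
  ages <- numeric(n + n_int)
  for (t in seq_len(n)) {
    rec <- get0(taxa[t], stats$env, inherits = FALSE)
    ages[t] <- if (!is.null(rec)) stats::median(rec$ages) else 0
  }
  ages[n + seq_len(n_int)] <- clades$median_age
  # enforce parent >= child after independent median summarization
  n_clip <- 0L
  ordn <- order(-ages[n + seq_len(n_int)])
  for (pass in 1:3) for (v in seq_len(n + n_int)) {
    p <- parent[v]
    if (p > 0L && ages[v] > ages[p]) { ages[v] <- ages[p]; n_clip <- n_clip + 1L }
  }
  structure(list(taxa = taxa, parent = parent, age = ages,
                 n_tip = n, clades = clades, n_age_clips = n_clip,
                 n_samples = stats$n_samples),
            class = "summary_tree")
}

hpd_interval_quiet <- function(x) suppressWarnings(hpd_interval(x))

#' @export
print.summary_tree <- function(x, ...) {
  cat("summary_tree:", x$n_tip, "tips,", nrow(x$clades), "clades from",
      x$n_samples, "samples\n")
  print(utils::head(x$clades[order(-x$clades$pp),
                             c("clade", "pp", "median_age", "hpd_range")], 10))
  invisible(x)
}

#' 50% majority-rule consensus tree
#'
#' Clades with posterior frequency above `threshold` (mutually compatible by
#' construction for thresholds >= 0.5) form the consensus; node ages are the
#' medians over samples containing each clade, with 95% HPD bounds and the
#' median relative branch rate. Children whose median age exceeds their
#' parent's after independent summarization are clipped to the parent age
#' (count reported in `n_age_clips`).
#'
#' @param trees list of [timetree()] posterior samples.
#' @param threshold inclusion frequency (default 0.5).
#' @param rel_rates optional list (parallel to `trees`) of per-node relative
#'   rate matrices, as stored by [run_mcmc()].
#' @return a `summary_tree` with a `clades` data frame.
#' @export
majority_rule_consensus <- function(trees, threshold = 0.5, rel_rates = NULL) {
  if (!length(trees)) stop2("empty tree sample")
  stats <- clade_statistics(trees, rel_rates)
  keep <- Filter(function(k) {
    rec <- get(k, stats$env, inherits = FALSE)
    rec$size > 1L && rec$count / stats$n_samples > threshold
  }, stats$keys)
  build_summary_tree(stats, unlist(keep) %||% character(0))
}

#' Maximum compatibility tree
#'
#' Greedy construction: clades are considered in decreasing posterior
#' frequency (ties broken by the lexicographic order of the clade's sorted
#' taxon string) and accepted when compatible with everything already
#' accepted, yielding the most resolved tree compatible with the sample.
#' Its clade set always contains the 50% majority-rule clades.
#'
#' @inheritParams majority_rule_consensus
#' @return a `summary_tree`.
#' @export
maximum_compatibility_tree <- function(trees, rel_rates = NULL) {
  if (!length(trees)) stop2("empty tree sample")
  stats <- clade_statistics(trees, rel_rates)
  cand <- Filter(function(k) {
    rec <- get(k, stats$env, inherits = FALSE)
    rec$size > 1L
  }, stats$keys)
  cand <- unlist(cand) %||% character(0)
  freq <- vapply(cand, function(k) get(k, stats$env, inherits = FALSE)$count, numeric(1))
  ord <- order(-freq, cand)
  accepted <- list()
  for (k in cand[ord]) {
    set <- strsplit(k, ",", fixed = TRUE)[[1]]
    if (all(vapply(accepted, function(a) clades_compatible(a, set),
                   logical(1))))
      accepted[[k]] <- set
  }
  build_summary_tree(stats, names(accepted))
}

#' Median relative branch rates per clade
#'
#' Ratio of branch rate to base clock rate summarized per clade over the
#' samples containing it; values above 1 mark rate acceleration on that
#' branch, values below 1 deceleration.
#'
#' @param trees list of [timetree()] samples.
#' @param rel_rates list of per-node relative-rate matrices (from
#'   [run_mcmc()]); an error for non-clock samples.
#' @param partition which partition's rates to summarize.
#' @return data frame with `clade`, `median_rel_rate`, and a `regime`
#'   label (`accelerating`/`decelerating`/`clock-like`).
#' @export
relative_branch_rates <- function(trees, rel_rates, partition = NULL) {
  if (is.null(rel_rates) || !length(rel_rates) ||
      all(is.na(rel_rates[[1]])))
    stop2("samples carry no branch rates (non-clock analysis?)")
  stats <- clade_statistics(trees, rel_rates)
  col <- partition %||% colnames(rel_rates[[1]])[1]
  rows <- lapply(stats$keys, function(k) {
    rec <- get(k, stats$env, inherits = FALSE)
    if (is.null(rec$rates)) return(NULL)
    r <- stats::median(rec$rates[, col], na.rm = TRUE)
    if (is.na(r)) return(NULL)
    data.frame(clade = k, size = rec$size,
               pp = rec$count / stats$n_samples, median_rel_rate = r,
               regime = if (r > 1) "accelerating"
                        else if (r < 1) "decelerating" else "clock-like")
  })
  out <- do.call(rbind, rows)
  out[order(-out$median_rel_rate), ]
}

#' Cross-model divergence-time table
#'
#' Emits the median age (`M`) and 95% HPD range (`Rng_HPD`) of each focal
#' clade for each completed analysis, in the layout of per-model divergence
#' tables (one row per model label).
#'
#' @param summaries named list of `summary_tree` objects (names = model
#'   labels).
#' @param focal_clades named list of taxon vectors (e.g.
#'   `list(Root = all_taxa, CladeX = c("a","b"))`).
#' @return data frame with columns `model`, then `<clade>_M`,
#'   `<clade>_RngHPD` pairs; `NA` where a summary lacks the clade.
#' @export
divergence_table <- function(summaries, focal_clades) {
  rows <- lapply(names(summaries), function(lab) {
    s <- summaries[[lab]]
    row <- data.frame(model = lab)
    for (cn in names(focal_clades)) {
      key <- paste(sort(focal_clades[[cn]]), collapse = ",")
      i <- match(key, s$clades$clade)
      row[[paste0(cn, "_M")]] <- if (!is.na(i)) s$clades$median_age[i] else NA
      row[[paste0(cn, "_RngHPD")]] <- if (!is.na(i)) s$clades$hpd_range[i] else NA
    }
    row
  })
  do.call(rbind, rows)
}

#' Convert a summary tree to an annotated Newick string
#'
#' @param s a `summary_tree`.
#' @param path optional output file.
#' @return the Newick string (with `age`, `pp` and `rate` annotations),
#'   invisibly if written.
#' @export
summary_tree_newick <- function(s, path = NULL) {
  ch <- vector("list", length(s$parent))
  for (i in which(s$parent > 0L)) ch[[s$parent[i]]] <- c(ch[[s$parent[i]]], i)
  root <- which(s$parent == 0L & seq_along(s$parent) > s$n_tip)
  note <- function(v) {
    if (v > s$n_tip) {
      i <- v - s$n_tip
      sprintf("[&age=%.6g,pp=%.4g,rate=%.6g]", s$age[v], s$clades$pp[i],
              s$clades$median_rel_rate[i])
    } else sprintf("[&age=%.6g]", s$age[v])
  }
  rec <- function(v) {
    core <- if (v <= s$n_tip) s$taxa[v]
      else paste0("(", paste(vapply(ch[[v]], rec, character(1)),
                             collapse = ","), ")")
    len <- if (s$parent[v] > 0L) sprintf(":%.6g", max(0, s$age[s$parent[v]] - s$age[v])) else ""
    paste0(core, note(v), len)
  }
  out <- paste0(rec(root), ";")
  if (!is.null(path)) { writeLines(out, path); return(invisible(out)) }
  out
}
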