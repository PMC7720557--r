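# Validation-grade maximum parsimony: vectorized bitmask Fitch scoring for
# unordered characters, random-addition-sequence + SPR heuristic search,
# and the implied-weighting fit function.

# per-taxon bitmasks (nchar columns); missing/inapplicable = full mask
fitch_masks <- function(mat) {
  n <- length(mat$taxa)
  out <- matrix(0L, n, mat$n_char)
  for (j in seq_len(mat$n_char)) {
    full <- bitwShiftL(1L, max(1L, mat$k[j])) - 1L
    out[, j] <- vapply(mat$states[[j]], function(s) {
      if (!length(s)) full else sum(bitwShiftL(1L, s))
    }, integer(1))
  }
  out
}

parent_postorder <- function(parent, n_tip) {
  depth <- integer(length(parent))
  for (v in seq_along(parent)) {
    p <- v; d <- 0L
    while (parent[p] > 0L) { p <- parent[p]; d <- d + 1L }
    depth[v] <- d
  }
  internal <- seq_along(parent)[-seq_len(n_tip)]
  internal[order(-depth[internal])]
}

fitch_steps_masks <- function(parent, n_tip, tip_masks) {
  nc <- ncol(tip_masks)
  m <- length(parent)
  masks <- matrix(0L, m, nc)
  masks[seq_len(n_tip), ] <- tip_masks
  steps <- integer(nc)
  kids <- vector("list", m)
  for (v in which(parent > 0L)) kids[[parent[v]]] <- c(kids[[parent[v]]], v)
  po <- parent_postorder(parent, n_tip)
  po <- po[vapply(po, function(v) length(kids[[v]]) == 2L, logical(1))]
  for (v in po) {
    a <- masks[kids[[v]][1], ]
    b <- masks[kids[[v]][2], ]
    inter <- bitwAnd(a, b)
    miss <- inter == 0L
    steps <- steps + miss
    inter[miss] <- bitwOr(a[miss], b[miss])
    masks[v, ] <- inter
  }
  steps
}

#' Fitch parsimony length
#'
#' Set-intersection step counts for unordered characters, with missing,
#' inapplicable and ambiguity cells treated as uncertainty sets; the length
#' is invariant to root placement.
#'
#' @param tree a [timetree()] (or any list with `parent`, `n_tip`,
#'   `tip_label`) whose tips cover the matrix taxa.
#' @param mat a [morph_matrix()].
#' @param per_character return the per-character step vector.
#' @return total steps (or the per-character vector).
#' @export
fitch_length <- function(tree, mat, per_character = FALSE) {
  stopifnot(inherits(mat, "morph_matrix"))
  if (!setequal(tree$tip_label, mat$taxa))
    stop2("tree tips and matrix taxa differ")
  tm <- fitch_masks(mat)[match(tree$tip_label, mat$taxa), , drop = FALSE]
  steps <- fitch_steps_masks(tree$parent, tree$n_tip, tm)
  if (per_character) steps else sum(steps)
}

#' Implied-weighting fit of per-character step counts
#'
#' `fit = sum_i K / (K + h_i)` with homoplasy `h_i` = observed steps minus
#' the character's minimum conceivable steps (observed states - 1). Higher
#' is better; `K -> Inf` ranks trees identically to equal weights.
#'
#' @param steps per-character step counts.
#' @param mat the scored [morph_matrix()] (for the per-character minima).
#' @param K concavity constant (the study used 12).
#' @return the total fit.
#' @export
implied_weighting_fit <- function(steps, mat, K = 12) {
  h <- pmax(steps - pmax(mat$k - 1L, 0L), 0L)
  sum(K / (K + h))
}

search_score <- function(parent, n_tip, tm, mat, weighting, K) {
  steps <- fitch_steps_masks(parent, n_tip, tm)
  if (weighting == "equal") sum(steps)
  else -implied_weighting_fit(steps, mat, K)   # minimized
}

# attach tip t onto the edge above node e (parent vector grows by 2 slots
# pre-allocated by the caller); p is the index of the new internal node
attach_tip <- function(parent, t, e, p) {
  parent[p] <- parent[e]
  parent[e] <- p
  parent[t] <- p
  parent
}

#' Heuristic maximum-parsimony search
#'
#' Random-addition sequences (each taxon inserted at its best position)
#' followed by SPR hill climbing, under equal weights or implied weighting;
#' seeded and reproducible. Zero-length branches (no reconstruction forces a
#' change) are reported but trees are kept binary — collapsing them does not
#' change the Fitch length.
#'
#' @param mat a [morph_matrix()].
#' @param n_ras number of random addition sequences.
#' @param hold maximum number of equally best trees retained.
#' @param weighting `"equal"` or `"implied"`.
#' @param K concavity constant for implied weighting.
#' @param seed integer seed.
#' @return a `parsimony_result`: `best_length` (steps of the best tree(s)),
#'   `best_fit` (implied-weighting fit), `trees` (list of tree structures
#'   with `parent`, `n_tip`, `tip_label`), `per_char_steps`, `homoplasy`.
#' @export
heuristic_search <- function(mat, n_ras = 10, hold = 10,
                             weighting = c("equal", "implied"), K = 12,
                             seed = 1) {
  weighting <- match.arg(weighting)
  if (n_ras < 1) stop2("n_ras must be >= 1")
  set.seed(seed)
  n <- length(mat$taxa)
  if (n < 4) stop2("need >= 4 taxa")
  tm_all <- fitch_masks(mat)
  m <- 2L * n - 1L
  best_score <- Inf
  best_trees <- list()
  for (ras in seq_len(n_ras)) {
    ord <- sample.int(n)
    # start from the first three taxa
    parent <- integer(m)
    p0 <- n + 1L; p1 <- n + 2L
    parent[c(ord[1], ord[2])] <- p1
    parent[p1] <- p0
    parent[ord[3]] <- p0
    used_int <- n + 2L
    for (i in seq.int(4L, n)) {
      t <- ord[i]
      newp <- used_int + 1L
      cand <- which(parent > 0L)
      sc <- vapply(cand, function(e)
        search_score(attach_tip(parent, t, e, newp), n, tm_all, mat,
                     weighting, K), numeric(1))
      e <- cand[which.min(sc)]
      parent <- attach_tip(parent, t, e, newp)
      used_int <- newp
    }
    res <- spr_hill_climb(parent, n, tm_all, mat, weighting, K)
    if (res$score < best_score - 1e-9) {
      best_score <- res$score
      best_trees <- list(res$parent)
    } else if (abs(res$score - best_score) <= 1e-9 &&
               length(best_trees) < hold &&
               !any(vapply(best_trees, identical, logical(1), res$parent))) {
      best_trees <- c(best_trees, list(res$parent))
    }
  }
  tr1 <- list(parent = best_trees[[1]], n_tip = n, tip_label = mat$taxa)
  steps <- fitch_length(tr1, mat, per_character = TRUE)
  structure(list(
    best_length = sum(steps),
    best_fit = implied_weighting_fit(steps, mat, K),
    best_score = best_score, weighting = weighting, K = K,
    trees = lapply(best_trees, function(p)
      list(parent = p, n_tip = n, tip_label = mat$taxa)),
    per_char_steps = steps,
    homoplasy = pmax(steps - pmax(mat$k - 1L, 0L), 0L),
    n_ras = n_ras, seed = seed), class = "parsimony_result")
}

#' @export
print.parsimony_result <- function(x, ...) {
  cat("parsimony_result:", length(x$trees), "best tree(s), length",
      x$best_length, "steps, implied fit", format(x$best_fit, digits = 6),
      "(", x$weighting, "weights )\n")
  invisible(x)
}

spr_hill_climb <- function(parent, n_tip, tm, mat, weighting, K, max_sweeps = 30) {
  score <- search_score(parent, n_tip, tm, mat, weighting, K)
  root <- which(parent == 0L)
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    nodes <- which(parent > 0L)
    nodes <- nodes[parent[nodes] != root]
    for (v in sample(nodes)) {
      p <- parent[v]
      g <- parent[p]
      sib <- setdiff(which(parent == p), v)
      pruned <- parent
      pruned[sib] <- g
      pruned[p] <- -1L
      sub <- subtree_nodes_parent(pruned, v, n_tip)
      targets <- setdiff(which(pruned > 0L), c(sub, sib))
      for (y in targets) {
        cand <- pruned
        cand[p] <- cand[y]
        cand[y] <- p
        cand[v] <- p
        sc <- search_score(cand, n_tip, tm, mat, weighting, K)
        if (sc < score - 1e-9) {
          parent <- cand
          score <- sc
          improved <- TRUE
          break
        }
      }
      if (improved) break
    }
    if (!improved) break
    root <- which(parent == 0L)
  }
  list(parent = parent, score = score)
}

#' Convert a parsimony search tree to an ape "phylo"
#' @param tree element of a `parsimony_result`'s `trees` list.
#' @return an unrooted-style `phylo` cladogram (no branch lengths).
#' @export
parsimony_tree_phylo <- function(tree) {
  n <- tree$n_tip
  kids <- vector("list", length(tree$parent))
  for (v in which(tree$parent > 0L))
    kids[[tree$parent[v]]] <- c(kids[[tree$parent[v]]], v)
  rec <- function(v) {
    if (v <= n) return(tree$tip_label[v])
    paste0("(", paste(vapply(kids[[v]], rec, character(1)), collapse = ","), ")")
  }
  ape::read.tree(text = paste0(rec(which(tree$parent == 0L)), ";"))
}
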