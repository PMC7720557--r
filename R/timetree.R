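# Rooted binary time trees with node ages in Ma before present.
#
# Representation: nodes 1..n are tips, n+1..2n-1 internal; `parent` is 0 at
# the root. Ages increase rootward; branch duration = parent age - child age.
# A fossil tip whose attachment branch has zero duration is a sampled
# ancestor (a degree-2 node in the underlying tree).

SA_TOL <- 1e-9

#' Construct a time tree
#'
#' @param parent integer vector over all nodes (tips first), 0 at the root.
#' @param age numeric node ages in Ma before present.
#' @param tip_label character labels for nodes `1..n_tip`.
#' @return a `timetree` object.
#' @export
timetree <- function(parent, age, tip_label) {
  n <- length(tip_label)
  m <- length(parent)
  if (m != 2L * n - 1L) stop2("a binary tree on ", n, " tips needs ", 2 * n - 1, " nodes")
  if (length(age) != m) stop2("age/parent length mismatch")
  root <- which(parent == 0L)
  if (length(root) != 1L) stop2("tree must have exactly one root")
  kids <- tabulate(parent[parent > 0L], nbins = m)
  if (any(kids[seq_len(n)] > 0L)) stop2("a tip cannot be a parent")
  if (any(kids[(n + 1L):m] != 2L)) stop2("internal nodes must be binary")
  nr <- which(parent > 0L)
  if (any(age[parent[nr]] < age[nr] - SA_TOL))
    stop2("parent age must be >= child age")
  structure(list(parent = as.integer(parent), age = as.numeric(age),
                 tip_label = as.character(tip_label), n_tip = n),
            class = "timetree")
}

tree_root <- function(tr) which(tr$parent == 0L)

children_list <- function(tr) {
  m <- length(tr$parent)
  ch <- vector("list", m)
  for (i in which(tr$parent > 0L)) ch[[tr$parent[i]]] <- c(ch[[tr$parent[i]]], i)
  ch
}

# internal nodes ordered children-before-parents (ascending age suffices:
# zero-duration internal-internal branches are never produced)
postorder_nodes <- function(tr) {
  internal <- (tr$n_tip + 1L):length(tr$parent)
  internal[order(tr$age[internal])]
}

#' Branch durations in Myr
#' @param tr a [timetree()].
#' @return numeric vector over nodes; duration of the branch above each
#'   non-root node, `NA` at the root.
#' @export
branch_durations <- function(tr) {
  d <- rep(NA_real_, length(tr$parent))
  nr <- which(tr$parent > 0L)
  d[nr] <- tr$age[tr$parent[nr]] - tr$age[nr]
  d
}

#' Sampled-ancestor flags
#' @param tr a [timetree()].
#' @return logical over tips: `TRUE` where the tip sits on a zero-duration
#'   attachment branch (fossil placed as a direct ancestor).
#' @export
sampled_ancestors <- function(tr) {
  d <- branch_durations(tr)[seq_len(tr$n_tip)]
  abs(d) <= SA_TOL
}

#' Convert to an ape "phylo" tree
#' @param tr a [timetree()].
#' @return an [ape::read.tree()]-style `phylo` with branch lengths in Myr.
#' @export
as_phylo <- function(tr) {
  n <- tr$n_tip
  m <- length(tr$parent)
  nr <- which(tr$parent > 0L)
  # ape wants internal nodes numbered n+1.. with root = n+1
  root <- tree_root(tr)
  internal <- (n + 1L):m
  remap <- integer(m)
  remap[seq_len(n)] <- seq_len(n)
  remap[root] <- n + 1L
  remap[setdiff(internal, root)] <- (n + 2L):m
  edge <- cbind(remap[tr$parent[nr]], remap[nr])
  len <- tr$age[tr$parent[nr]] - tr$age[nr]
  phy <- list(edge = edge, edge.length = pmax(len, 0),
              Nnode = n - 1L, tip.label = tr$tip_label)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Convert an ape "phylo" time tree to a timetree
#'
#' Branch lengths are read as durations (Myr); ages are assigned so that the
#' youngest tip sits at `youngest_age` (0 by default).
#'
#' @param phy a rooted, binary `phylo`.
#' @param youngest_age age of the youngest tip, Ma.
#' @return a [timetree()].
#' @export
from_phylo <- function(phy, youngest_age = 0) {
  if (!ape::is.rooted(phy) || !ape::is.binary(phy))
    stop2("need a rooted binary tree")
  n <- length(phy$tip.label)
  m <- n + phy$Nnode
  depth <- numeric(m)
  parent <- integer(m)
  ord <- ape::reorder.phylo(phy, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    p <- ord$edge[e, 1]; c <- ord$edge[e, 2]
    parent[c] <- p
    depth[c] <- depth[p] + ord$edge.length[e]
  }
  age <- max(depth) - depth + youngest_age
  timetree(parent, age, phy$tip.label)
}

#' @export
print.timetree <- function(x, ...) {
  cat("timetree:", x$n_tip, "tips, root age",
      format(x$age[tree_root(x)], digits = 5), "Ma,",
      sum(sampled_ancestors(x)), "sampled ancestor(s)\n")
  invisible(x)
}

# clade key: comma-joined sorted tip labels under each internal node
clade_keys <- function(tr) {
  ch <- children_list(tr)
  m <- length(tr$parent)
  sets <- vector("list", m)
  for (i in seq_len(tr$n_tip)) sets[[i]] <- tr$tip_label[i]
  for (v in postorder_nodes(tr)) {
    sets[[v]] <- c(sets[[ch[[v]][1]]], sets[[ch[[v]][2]]])
  }
  vapply(sets, function(s) paste(sort(s), collapse = ","), character(1))
}

#' Write a tree with per-node annotations
#'
#' Serializes to Newick with bracketed `[&key=value,...]` metadata comments
#' before branch lengths (the dialect used by common tree-annotation tools).
#' Node ages are always included so the file round-trips losslessly through
#' [read_annotated_tree()]. Sampled ancestors are flagged with `sa=1`.
#'
#' @param tr a [timetree()].
#' @param path output file; `NULL` returns the Newick string.
#' @param annotations optional named list: each element a numeric/character
#'   vector over all nodes (tips first), written as `[&name=value]`.
#' @return the Newick string, invisibly if written to file.
#' @export
write_annotated_tree <- function(tr, path = NULL, annotations = list()) {
  d <- branch_durations(tr)
  if (any(d < -SA_TOL, na.rm = TRUE)) stop2("negative branch duration")
  sa <- rep(FALSE, length(tr$parent)); sa[seq_len(tr$n_tip)] <- sampled_ancestors(tr)
  ch <- children_list(tr)
  note <- function(v) {
    kv <- c(sprintf("age=%.10g", tr$age[v]),
            if (sa[v]) "sa=1",
            vapply(names(annotations), function(nm) {
              val <- annotations[[nm]][v]
              if (is.na(val)) NA_character_ else
                sprintf("%s=%s", nm, format(val, digits = 10))
            }, character(1)))
    kv <- kv[!is.na(kv)]
    paste0("[&", paste(kv, collapse = ","), "]")
  }
  rec <- function(v) {
    core <- if (v <= tr$n_tip) tr$tip_label[v] else
      paste0("(", rec(ch[[v]][1]), ",", rec(ch[[v]][2]), ")")
    if (tr$parent[v] == 0L) paste0(core, note(v))
    else paste0(core, note(v), ":", sprintf("%.10g", max(d[v], 0)))
  }
  s <- paste0(rec(tree_root(tr)), ";")
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Read an annotated Newick tree
#'
#' Reads the dialect written by [write_annotated_tree()]; plain Newick
#' without comments is also accepted (ages then derived from branch lengths
#' with the youngest tip at age 0).
#'
#' @param path file path or a Newick string.
#' @return list with `tree` (a [timetree()]) and `annotations` (data frame
#'   of parsed key=value pairs per node, in the tree's node order).
#' @export
read_annotated_tree <- function(path) {
  s <- if (file.exists(path)) paste(readLines(path, warn = FALSE), collapse = "") else path
  s <- gsub("[[:space:]]", "", s)
  nodes <- list()   # each: label, children idx, note, length
  pos <- 1L
  n_str <- nchar(s)
  peek <- function() substr(s, pos, pos)
  read_while <- function(re) {
    start <- pos
    while (pos <= n_str && grepl(re, substr(s, pos, pos))) pos <<- pos + 1L
    substr(s, start, pos - 1L)
  }
  parse_node <- function() {
    kids <- integer(0)
    label <- ""
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        kids <- c(kids, parse_node())
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        stop2("malformed newick near position ", pos)
      }
      label <- read_while("[^,():;\\[]")
    } else {
      label <- read_while("[^,():;\\[]")
      if (!nzchar(label)) stop2("malformed newick: empty tip label at ", pos)
    }
    note <- ""
    if (peek() == "[") {
      end <- regexpr("]", substr(s, pos, n_str), fixed = TRUE)
      if (end < 0) stop2("unclosed comment")
      note <- substr(s, pos, pos + end - 1L)
      pos <<- pos + end
    }
    len <- NA_real_
    if (peek() == ":") {
      pos <<- pos + 1L
      if (peek() == "[") {  # tolerate comment before length
        end <- regexpr("]", substr(s, pos, n_str), fixed = TRUE)
        pos <<- pos + end
      }
      len <- as.numeric(read_while("[0-9eE.+-]"))
    }
    nodes[[length(nodes) + 1L]] <<- list(label = label, kids = kids,
                                         note = note, len = len)
    length(nodes)
  }
  root_id <- parse_node()
  if (peek() != ";") stop2("newick must end with ';'")

  is_tip <- vapply(nodes, function(x) length(x$kids) == 0L, logical(1))
  n <- sum(is_tip)
  remap <- integer(length(nodes))
  remap[is_tip] <- seq_len(n)
  remap[!is_tip] <- n + seq_len(sum(!is_tip))
  m <- length(nodes)
  parent <- integer(m); lens <- rep(NA_real_, m)
  notes <- character(m)
  for (i in seq_along(nodes)) {
    for (k in nodes[[i]]$kids) parent[remap[k]] <- remap[i]
    lens[remap[i]] <- nodes[[i]]$len
    notes[remap[i]] <- nodes[[i]]$note
  }
  tip_label <- vapply(nodes[is_tip], `[[`, character(1), "label")[order(remap[is_tip])]
  # ages: prefer age= annotations, else depths from branch lengths
  ann <- parse_note_table(notes)
  if (!is.null(ann$age) && !anyNA(ann$age)) {
    age <- as.numeric(ann$age)
  } else {
    depth <- numeric(m)
    for (i in order(vapply(seq_len(m), function(v) {
      d <- 0L; p <- v
      while (parent[p] > 0L) { p <- parent[p]; d <- d + 1L }
      d
    }, integer(1)))) {
      if (parent[i] > 0L) depth[i] <- depth[parent[i]] + (lens[i] %||% 0)
    }
    age <- max(depth) - depth
  }
  list(tree = timetree(parent, age, tip_label), annotations = ann)
}

parse_note_table <- function(notes) {
  kvs <- lapply(notes, function(nt) {
    if (!nzchar(nt)) return(list())
    body <- sub("^\\[&?", "", sub("\\]$", "", nt))
    parts <- strsplit(body, ",")[[1]]
    vals <- sub("^[^=]*=", "", parts)
    names(vals) <- sub("=.*$", "", parts)
    as.list(vals)
  })
  keys <- unique(unlist(lapply(kvs, names)))
  out <- data.frame(row.names = seq_along(notes))
  for (k in keys) {
    col <- vapply(kvs, function(x) x[[k]] %||% NA_character_, character(1))
    num <- suppressWarnings(as.numeric(col))
    out[[k]] <- if (all(is.na(num) == is.na(col))) num else col
  }
  out
}

#' Random calibrated starting tree
#'
#' Sequential random coalescence respecting tip ages: lineages become
#' available at their tip ages and pairs are joined at ages older than both
#' members, giving a valid starting state for MCMC.
#'
#' @param calibrations a [calibration_table()]; tip ages are drawn uniformly
#'   from their ranges.
#' @param root_min minimum root age, Ma.
#' @return a [timetree()].
#' @export
random_calibrated_tree <- function(calibrations, root_min = NULL) {
  n <- nrow(calibrations)
  tip_age <- stats::runif(n, calibrations$age_min, calibrations$age_max)
  m <- 2L * n - 1L
  parent <- integer(m)
  age <- c(tip_age, numeric(n - 1L))
  active <- seq_len(n)
  nxt <- n + 1L
  while (length(active) > 1L) {
    pick <- sample(length(active), 2L)
    a <- active[pick[1]]; b <- active[pick[2]]
    base <- max(age[a], age[b], if (length(active) == 2L) root_min %||% 0 else 0)
    age[nxt] <- base + stats::rexp(1, rate = 1 / 15) + 1e-3
    parent[c(a, b)] <- nxt
    active <- c(setdiff(active, c(a, b)), nxt)
    nxt <- nxt + 1L
  }
  timetree(parent, age, calibrations$taxon)
}
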