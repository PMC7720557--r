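# Morphological character matrices: construction, validation, NEXUS I/O.
#
# Cells are coded with digit symbols; `?` is missing, `-` inapplicable
# (treated as missing for likelihood purposes), `{..}` or `(..)` an
# ambiguity set. States are recoded densely to 0..k-1 per character.

#' Construct a morphological character matrix
#'
#' Builds a validated `morph_matrix` from a taxon-by-character matrix of
#' symbol strings. States are recoded densely per character to `0..k-1`
#' where `k` is the number of states observed across scored taxa
#' (ambiguity-set members count as observed). Inapplicable cells (`-`) are
#' retained as such but scored as missing in all likelihood computations.
#'
#' @param cells character matrix (taxa in rows, characters in columns) of
#'   symbols: a digit, `?`, `-`, or an ambiguity set like `{01}` / `(01)`.
#' @param taxa character vector of unique taxon labels (defaults to rownames).
#' @param partition optional character vector of per-character partition
#'   labels; `NA` entries are assigned to `"default"`.
#' @param on_constant what to do with characters with fewer than two observed
#'   states, which violate the variable-characters-only ascertainment the Mkv
#'   model assumes: warn (keep), error, or drop them.
#' @return an object of class `morph_matrix` with fields `taxa`, `n_char`,
#'   `states` (per character, per taxon integer state sets; empty = missing),
#'   `k` (per-character observed state counts), `inapplicable`,
#'   `state_labels` (dense index to original symbol), and `partition`.
#' @export
morph_matrix <- function(cells, taxa = rownames(cells), partition = NULL,
                         on_constant = c("warn", "error", "drop")) {
  on_constant <- match.arg(on_constant)
  cells <- as.matrix(cells)
  if (is.null(taxa)) stop2("taxon labels are required")
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa)) stop2("duplicate taxon label: ",
                                 paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  if (nrow(cells) != length(taxa)) stop2("cells/taxa dimension mismatch")
  n_char <- ncol(cells)
  if (!is.null(partition)) {
    partition <- as.character(partition)
    if (length(partition) != n_char) stop2("partition map length != number of characters")
    partition[is.na(partition) | partition == ""] <- "default"
  }
  states <- vector("list", n_char)
  k <- integer(n_char)
  labels <- vector("list", n_char)
  inap <- matrix(FALSE, length(taxa), n_char, dimnames = list(taxa, NULL))
  for (j in seq_len(n_char)) {
    raw <- lapply(cells[, j], parse_cell_symbol)
    inap[, j] <- vapply(raw, function(x) isTRUE(attr(x, "inapplicable")), logical(1))
    observed <- sort(unique(unlist(raw)))
    labels[[j]] <- observed
    k[j] <- length(observed)
    states[[j]] <- lapply(raw, function(x) {
      if (!length(x)) integer(0) else match(x, observed) - 1L
    })
  }
  constant <- k < 2L
  if (any(constant)) {
    msg <- paste0(sum(constant), " character(s) with <2 observed states ",
                  "violate variable-only ascertainment: ",
                  paste(utils::head(which(constant), 10), collapse = ", "))
    if (on_constant == "error") stop2(msg)
    if (on_constant == "warn") warning(msg, call. = FALSE)
    if (on_constant == "drop") {
      keep <- !constant
      states <- states[keep]; k <- k[keep]; labels <- labels[keep]
      inap <- inap[, keep, drop = FALSE]
      if (!is.null(partition)) partition <- partition[keep]
      n_char <- sum(keep)
    }
  }
  structure(list(taxa = taxa, n_char = n_char, states = states, k = k,
                 state_labels = labels, inapplicable = inap,
                 partition = partition),
            class = "morph_matrix")
}

parse_cell_symbol <- function(sym) {
  sym <- gsub("[[:space:]]", "", sym)
  if (sym %in% c("?", "")) return(character(0))
  if (sym == "-") return(structure(character(0), inapplicable = TRUE))
  if (grepl("^[{(].*[})]$", sym)) {
    inner <- gsub("[{}()]", "", sym)
    st <- strsplit(inner, "")[[1]]
    if (!length(st) || !all(grepl("^[0-9A-Za-z]$", st)))
      stop2("malformed ambiguity set: '", sym, "'")
    return(unique(st))
  }
  if (!grepl("^[0-9A-Za-z]$", sym)) stop2("unrecognized cell symbol: '", sym, "'")
  sym
}

#' @export
print.morph_matrix <- function(x, ...) {
  cat("morph_matrix:", length(x$taxa), "taxa x", x$n_char, "characters\n")
  cat("  state counts:", paste(names(table(x$k)), "states:",
                               table(x$k), collapse = "; "), "\n")
  if (!is.null(x$partition))
    cat("  partitions:", paste(names(table(x$partition)),
                               table(x$partition), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a NEXUS morphological matrix
#'
#' Parses the `CHARACTERS`/`DATA` block of a NEXUS file with digit symbols.
#' `?` maps to missing, `-` to inapplicable (scored as missing), and
#' `{..}`/`(..)` to ambiguity sets. A `CHARPARTITION` or a supplied partition
#' map may label characters; unlabeled characters go to a `"default"`
#' partition.
#'
#' @param path path to a NEXUS file.
#' @inheritParams morph_matrix
#' @return a [morph_matrix()].
#' @export
read_nexus_matrix <- function(path, partition = NULL,
                              on_constant = c("warn", "error", "drop")) {
  lines <- readLines(path, warn = FALSE)
  up <- toupper(lines)
  mstart <- grep("^\\s*MATRIX\\b", up)
  if (!length(mstart))
    stop2("parse error: no MATRIX statement found in '", path, "'")
  mstart <- mstart[1]
  dim_line <- grep("DIMENSIONS", up)
  ntax_decl <- nchar_decl <- NA_integer_
  if (length(dim_line)) {
    dl <- up[dim_line[1]]
    if (grepl("NTAX\\s*=\\s*[0-9]+", dl))
      ntax_decl <- as.integer(sub(".*NTAX\\s*=\\s*([0-9]+).*", "\\1", dl))
    if (grepl("NCHAR\\s*=\\s*[0-9]+", dl))
      nchar_decl <- as.integer(sub(".*NCHAR\\s*=\\s*([0-9]+).*", "\\1", dl))
  }
  rows <- list(); taxa <- character(0)
  i <- mstart + 1L
  while (i <= length(lines)) {
    ln <- sub("\\[.*?\\]", "", lines[i])  # strip comments
    if (grepl("^\\s*;", ln) || grepl(";\\s*$", ln) && !grepl("[0-9?{}()-]", ln)) break
    trimmed <- trimws(sub(";\\s*$", "", ln))
    if (nzchar(trimmed)) {
      m <- regmatches(trimmed, regexec("^('[^']+'|\\S+)\\s+(.+)$", trimmed))[[1]]
      if (length(m) != 3)
        stop2("parse error at line ", i, " of '", path, "': cannot split taxon/states")
      tx <- gsub("^'|'$", "", m[2])
      if (tx %in% taxa)
        stop2("duplicate taxon label '", tx, "' at line ", i)
      row <- tokenize_states(gsub("\\s", "", m[3]), line = i)
      taxa <- c(taxa, tx)
      rows[[tx]] <- row
    }
    if (grepl(";\\s*$", ln)) break
    i <- i + 1L
  }
  if (!length(rows)) stop2("parse error: empty MATRIX in '", path, "'")
  lens <- lengths(rows)
  if (length(unique(lens)) != 1)
    stop2("parse error: unequal row lengths in MATRIX (",
          paste(unique(lens), collapse = ", "), ")")
  if (!is.na(ntax_decl) && ntax_decl != length(taxa))
    stop2("parse error: NTAX=", ntax_decl, " but ", length(taxa), " rows read")
  if (!is.na(nchar_decl) && nchar_decl != lens[1])
    stop2("parse error: NCHAR=", nchar_decl, " but ", lens[1], " columns read")
  cells <- do.call(rbind, rows)
  rownames(cells) <- taxa
  morph_matrix(cells, taxa, partition = partition, on_constant = on_constant)
}

tokenize_states <- function(s, line = NA) {
  out <- character(0)
  i <- 1L; n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch %in% c("{", "(")) {
      close <- if (ch == "{") "}" else ")"
      j <- regexpr(close, substr(s, i, n), fixed = TRUE)
      if (j < 0) stop2("parse error at line ", line, ": unclosed ambiguity set")
      out <- c(out, substr(s, i, i + j - 1L))
      i <- i + j
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  out
}

#' Write a morphological matrix as NEXUS
#'
#' Inverse of [read_nexus_matrix()]: `read_nexus_matrix(write_nexus_matrix(x))`
#' reproduces `x` cell for cell (dense state indices are written back through
#' the original symbol labels).
#'
#' @param x a [morph_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_nexus_matrix <- function(x, path) {
  stopifnot(inherits(x, "morph_matrix"))
  n <- length(x$taxa)
  rows <- vapply(seq_len(n), function(i) {
    paste0(vapply(seq_len(x$n_char), function(j) {
      st <- x$states[[j]][[i]]
      if (!length(st)) {
        if (x$inapplicable[i, j]) "-" else "?"
      } else {
        sym <- x$state_labels[[j]][st + 1L]
        if (length(sym) > 1) paste0("{", paste(sym, collapse = ""), "}") else sym
      }
    }, character(1)), collapse = "")
  }, character(1))
  maxw <- max(nchar(x$taxa))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("#NEXUS", "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", n, x$n_char),
               "  FORMAT DATATYPE=STANDARD SYMBOLS=\"0123456789\" MISSING=? GAP=-;",
               "  MATRIX"), con)
  writeLines(sprintf(paste0("    %-", maxw + 2L, "s%s"), x$taxa, rows), con)
  writeLines(c("  ;", "END;"), con)
  invisible(path)
}

#' Per-character state counts
#' @param x a [morph_matrix()].
#' @return integer vector of observed state counts `k` per character.
#' @export
char_state_counts <- function(x) {
  stopifnot(inherits(x, "morph_matrix"))
  x$k
}

#' Direct-autapomorphy census
#'
#' A character carries a direct autapomorphy when some state is scored
#' unambiguously in exactly one terminal taxon. Such characters inform tip
#' branch lengths but not grouping.
#'
#' @param x a [morph_matrix()].
#' @return list with `is_autapomorphy` (logical per character), `count`,
#'   and `fraction` of the matrix.
#' @export
autapomorphy_stats <- function(x) {
  stopifnot(inherits(x, "morph_matrix"))
  is_aut <- vapply(seq_len(x$n_char), function(j) {
    sing <- unlist(Filter(function(s) length(s) == 1L, x$states[[j]]))
    if (length(sing) < 2L) return(FALSE)
    any(tabulate(sing + 1L, nbins = x$k[j]) == 1L)
  }, logical(1))
  list(is_autapomorphy = is_aut, count = sum(is_aut),
       fraction = sum(is_aut) / max(1L, x$n_char))
}

#' Restrict a matrix to one partition
#' @param x a [morph_matrix()].
#' @param label partition label to keep.
#' @return a [morph_matrix()] with only that partition's characters.
#' @export
subset_partition <- function(x, label) {
  stopifnot(inherits(x, "morph_matrix"))
  if (is.null(x$partition)) stop2("matrix has no partition map")
  keep <- x$partition == label
  if (!any(keep)) stop2("empty partition '", label, "'")
  structure(list(taxa = x$taxa, n_char = sum(keep), states = x$states[keep],
                 k = x$k[keep], state_labels = x$state_labels[keep],
                 inapplicable = x$inapplicable[, keep, drop = FALSE],
                 partition = x$partition[keep]),
            class = "morph_matrix")
}
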