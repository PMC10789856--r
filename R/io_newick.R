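# Newick IO on `ape::phylo` trees.
#
# Dialect: unquoted labels, no comments; internal labels are kept as node
# annotations (bootstrap supports in practice). Missing branch lengths become
# 0 with a warning so topology-only trees still parse; the timing statistic
# refuses such trees downstream because its denominator would be 0.

#' Read a Newick tree
#'
#' @param source path to a file containing a single Newick string, or the
#'   string itself (must end in `;`).
#' @return an [ape::phylo] tree. Tip labels are preserved; internal labels are
#'   stored in `node.label`.
#' @export
read_newick <- function(source) {
  lines <- read_source_lines(source, starter = "(")
  txt <- trimws(paste(lines, collapse = ""))
  if (!nzchar(txt)) stop("empty Newick input")
  if (!endsWith(txt, ";")) stop("Newick string must end in ';'")
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close) {
    stop("unbalanced parentheses in Newick string (", n_open, " '(' vs ",
         n_close, "')')")
  }
  if (n_open == 0) return(parse_single_tip_newick(txt))
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("Newick parse error")
  if (inherits(tree, "multiPhylo")) stop("expected exactly one Newick tree")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    warning("no branch lengths in Newick input; all set to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("missing branch length(s) in Newick input; set to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch length in Newick input")
  tree
}

# degenerate one-tip tree, e.g. "A:0;" or "A;"
parse_single_tip_newick <- function(txt) {
  body <- sub(";$", "", txt)
  parts <- strsplit(body, ":", fixed = TRUE)[[1]]
  if (!nzchar(parts[[1]])) stop("Newick parse error: empty tip label")
  len <- if (length(parts) > 1) suppressWarnings(as.numeric(parts[[2]])) else 0
  if (is.na(len)) stop("Newick parse error: bad branch length '", parts[[2]], "'")
  if (len < 0) stop("negative branch length in Newick input")
  structure(list(edge = matrix(c(2L, 1L), 1, 2), edge.length = len,
                 tip.label = parts[[1]], Nnode = 1L),
            class = "phylo", order = "cladewise")
}

#' Write a Newick string
#'
#' Branch lengths are formatted with a fixed number of decimals so output is
#' byte-deterministic; `read_newick(write_newick(t))` reproduces topology,
#' labels and lengths to that precision.
#'
#' @param tree an [ape::phylo] tree.
#' @param precision decimal places for branch lengths (default 6).
#' @param path optional output file.
#' @return the Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, precision = 6, path = NULL) {
  stopifnot(inherits(tree, "phylo"), precision >= 0)
  n <- length(tree$tip.label)
  fmt <- function(x) sprintf(paste0("%.", precision, "f"), x)
  if (n == 1) {
    txt <- paste0(tree$tip.label, ":", fmt(tree$edge.length %||% 0), ";")
  } else {
    kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
    node_lab <- function(node) {
      if (node <= n) return(tree$tip.label[[node]])
      if (is.null(tree$node.label)) "" else tree$node.label[[node - n]]
    }
    rec <- function(node) {
      es <- kids[[as.character(node)]]
      if (is.null(es)) return(node_lab(node))
      parts <- vapply(es, function(e) {
        len <- if (is.null(tree$edge.length)) 0 else tree$edge.length[[e]]
        paste0(rec(tree$edge[e, 2]), ":", fmt(len))
      }, character(1))
      paste0("(", paste(parts, collapse = ","), ")", node_lab(node))
    }
    txt <- paste0(rec(n + 1L), ";")
  }
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

`%||%` <- function(a, b) if (is.null(a)) b else a
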