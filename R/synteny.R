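# Local-synteny orthology scoring.
#
# Candidate orthologues are compared by the gene content of their local
# neighbourhoods (set membership only -- order and orientation are ignored,
# matching how shared-neighbour tables are read). Symbols are normalized
# case-insensitively through an explicit synonym map (cross-species
# neighbours are homologues, not identical symbols; no fuzzy matching).
# Assignment maximizes total Jaccard over injective query-to-reference maps,
# exhaustively (the use case is a handful of paralogues, not genomes), and
# an ambiguity flag makes "the neighbour lists overlap too much to call
# orthology" a computable output.

normalize_symbols <- function(symbols, synonym_map = NULL) {
  s <- toupper(symbols)
  if (!is.null(synonym_map)) {
    map <- stats::setNames(toupper(synonym_map), toupper(names(synonym_map)))
    hit <- match(s, names(map))
    s[!is.na(hit)] <- map[hit[!is.na(hit)]]
  }
  unique(s)
}

neighborhood_symbols <- function(nb, window = Inf, synonym_map = NULL) {
  stopifnot(inherits(nb, "gene_neighborhood"))
  keep <- abs(nb$offsets) <= window
  syms <- nb$symbols[keep]
  if (!length(syms)) {
    stop("empty neighbourhood for ", nb$focal_id, " after windowing")
  }
  normalize_symbols(syms, synonym_map)
}

#' Shared neighbours of two neighbourhoods
#'
#' @param q,r [gene_neighborhood()] objects.
#' @param synonym_map named character vector mapping symbol variants to a
#'   canonical symbol (case-insensitive).
#' @param window compare only neighbours with |offset| <= window.
#' @return list with `count`, `jaccard`, and the sorted shared `symbols`.
#' @export
shared_neighbors <- function(q, r, synonym_map = NULL, window = Inf) {
  qs <- neighborhood_symbols(q, window, synonym_map)
  rs <- neighborhood_symbols(r, window, synonym_map)
  shared <- sort(intersect(qs, rs))
  list(count = length(shared),
       jaccard = length(shared) / length(union(qs, rs)),
       symbols = shared)
}

#' Shared-neighbour evidence matrix
#'
#' @param queries,references lists of [gene_neighborhood()] objects.
#' @param window neighbours with |offset| <= window are compared (default
#'   10 genes each side).
#' @param synonym_map see [shared_neighbors()].
#' @return object of class `synteny_matrix`: `counts` and `jaccard` matrices
#'   (queries x references) and a matching list-matrix of shared symbols.
#' @export
synteny_matrix <- function(queries, references, window = 10, synonym_map = NULL) {
  stopifnot(window >= 1, length(queries) >= 1, length(references) >= 1)
  qn <- vapply(queries, `[[`, "", "focal_id")
  rn <- vapply(references, `[[`, "", "focal_id")
  counts <- matrix(0L, length(queries), length(references),
                   dimnames = list(qn, rn))
  jac <- matrix(0, length(queries), length(references), dimnames = list(qn, rn))
  shared <- vector("list", length(queries) * length(references))
  dim(shared) <- dim(counts)
  dimnames(shared) <- dimnames(counts)
  for (i in seq_along(queries)) {
    for (j in seq_along(references)) {
      s <- shared_neighbors(queries[[i]], references[[j]], synonym_map, window)
      counts[i, j] <- s$count
      jac[i, j] <- s$jaccard
      shared[[i, j]] <- s$symbols
    }
  }
  structure(list(counts = counts, jaccard = jac, shared = shared,
                 queries = qn, references = rn, window = window),
            class = "synteny_matrix")
}

#' @export
print.synteny_matrix <- function(x, ...) {
  cat(sprintf("synteny matrix: %d query x %d reference (window %s)\n",
              length(x$queries), length(x$references), format(x$window)))
  print(round(x$jaccard, 3))
  invisible(x)
}

#' Diagnostic ("witness") neighbours per reference
#'
#' For each reference neighbourhood, the symbols appearing in no other
#' reference's neighbourhood: a single such witness gene next to a candidate
#' identifies which paralogue it is.
#'
#' @param references list of >= 2 [gene_neighborhood()] objects.
#' @inheritParams synteny_matrix
#' @return named list of character vectors (possibly empty).
#' @export
find_diagnostic_neighbors <- function(references, window = Inf, synonym_map = NULL) {
  stopifnot(length(references) >= 2)
  sets <- lapply(references, neighborhood_symbols, window = window,
                 synonym_map = synonym_map)
  names(sets) <- vapply(references, `[[`, "", "focal_id")
  out <- lapply(seq_along(sets), function(i) {
    sort(setdiff(sets[[i]], unlist(sets[-i], use.names = FALSE)))
  })
  names(out) <- names(sets)
  out
}

#' Optimal one-to-one orthology assignment
#'
#' Maximizes the total Jaccard over injective query-to-reference mappings by
#' exhaustive search (matrices up to 8 x 8). Queries whose optimal cell has
#' Jaccard 0 stay unassigned. The result is flagged ambiguous when a
#' different mapping scores within `epsilon` of the optimum, or when some
#' query's two best (non-zero) cells differ by less than `epsilon`.
#'
#' @param sm a [synteny_matrix()].
#' @param epsilon ambiguity margin on Jaccard totals (default 0.05).
#' @return object of class `orthology_assignment`: `mapping` (named character,
#'   `NA` = unassigned), `score`, `ambiguous`, `alternatives` (list of
#'   near-optimal mappings with scores).
#' @export
assign_orthologs <- function(sm, epsilon = 0.05) {
  stopifnot(inherits(sm, "synteny_matrix"), epsilon >= 0)
  J <- sm$jaccard
  nq <- nrow(J); nr <- ncol(J)
  if (nq > 8 || nr > 8) stop("exhaustive assignment is limited to 8 x 8")
  # suffix upper bound for branch & bound: best any completion could add
  suffix_ub <- rev(cumsum(rev(apply(J, 1, max))))
  # a query may only go unassigned when no reference is left (J >= 0 makes
  # unassigned-while-possible dominated; canon() below restores ties)
  search <- function(keep_within) {
    hits <- list()
    best <- -Inf
    rec <- function(i, used, map, score) {
      if (i > nq) {
        if (score > best) best <<- score
        if (score >= best - keep_within) {
          hits[[length(hits) + 1L]] <- list(map = map, score = score)
          if (length(hits) > 5000L) {
            hits <- hits[vapply(hits, `[[`, 0, "score") >= best - keep_within]
          }
          hits <<- hits
        }
        return()
      }
      if (score + suffix_ub[[i]] < best - keep_within) return()
      free <- which(!used)
      if (length(free) < nq - i + 1L) rec(i + 1L, used, c(map, NA_integer_), score)
      for (j in free) {
        used[[j]] <- TRUE
        rec(i + 1L, used, c(map, j), score + J[i, j])
        used[[j]] <- FALSE
      }
    }
    rec(1L, rep(FALSE, nr), integer(), 0)
    hits[vapply(hits, `[[`, 0, "score") >= best - keep_within]
  }
  all_maps <- search(epsilon)
  scores <- vapply(all_maps, `[[`, 0, "score")
  opt <- max(scores)
  canon <- function(map) {       # unassigned and zero-score cells are equivalent
    m <- map
    m[!is.na(m) & J[cbind(seq_len(nq), m)] == 0] <- NA_integer_
    m
  }
  opt_map <- canon(all_maps[[which.max(scores)]]$map)
  near <- which(scores >= opt - epsilon)
  alt_maps <- unique(lapply(all_maps[near], function(a) canon(a$map)))
  alt_maps <- Filter(function(m) !identical(m, opt_map), alt_maps)
  ambiguous <- FALSE
  if (opt > 0) {
    if (length(alt_maps)) ambiguous <- TRUE
    for (i in seq_len(nq)) {
      srt <- sort(J[i, ], decreasing = TRUE)
      if (nr >= 2 && srt[[1]] > 0 && srt[[1]] - srt[[2]] < epsilon) {
        ambiguous <- TRUE
      }
    }
  }
  mapping <- stats::setNames(ifelse(is.na(opt_map), NA_character_,
                                    sm$references[opt_map]), sm$queries)
  alternatives <- lapply(alt_maps[seq_len(min(length(alt_maps), 10L))],
                         function(m) {
    stats::setNames(ifelse(is.na(m), NA_character_, sm$references[m]), sm$queries)
  })
  structure(list(mapping = mapping, score = opt, ambiguous = ambiguous,
                 alternatives = alternatives, epsilon = epsilon),
            class = "orthology_assignment")
}

#' @export
print.orthology_assignment <- function(x, ...) {
  cat(sprintf("orthology assignment (score %.3f%s):\n", x$score,
              if (x$ambiguous) ", AMBIGUOUS" else ""))
  for (q in names(x$mapping)) {
    cat(sprintf("  %s -> %s\n", q,
                if (is.na(x$mapping[[q]])) "(unassigned)" else x$mapping[[q]]))
  }
  invisible(x)
}
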