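# Pairwise evolutionary distances with pairwise deletion.
#
# For every sequence pair, alignment columns where either sequence carries a
# gap or ambiguity character are removed before anything is counted
# (pairwise deletion). Corrections that would need the log of a non-positive
# argument mark the cell "saturated" instead of crashing; downstream
# neighbour joining refuses matrices containing such cells rather than
# silently clipping deep branches.

resolve_record <- function(aln, a) {
  if (is.character(a)) {
    i <- match(a, aln$ids)
    if (is.na(i)) stop("unknown record id '", a, "'")
    return(i)
  }
  i <- as.integer(a)
  if (i < 1 || i > length(aln$ids)) stop("record index out of range: ", a)
  i
}

#' Columns comparable for a sequence pair
#'
#' @param aln an [alignment()].
#' @param a,b record ids or indices.
#' @return 1-based column indices where neither sequence has a gap or
#'   ambiguity character. Errors if no column is comparable.
#' @export
pairwise_valid_columns <- function(aln, a, b) {
  stopifnot(inherits(aln, "alignment"))
  i <- resolve_record(aln, a)
  j <- resolve_record(aln, b)
  mask <- aln_state_mask(aln)
  cols <- which(mask[i, ] & mask[j, ])
  if (!length(cols)) {
    stop("uncomparable pair (", aln$ids[[i]], ", ", aln$ids[[j]],
         "): no shared unambiguous columns")
  }
  cols
}

#' Observed proportion of differences (p-distance)
#'
#' @inheritParams pairwise_valid_columns
#' @param cols optional precomputed column set (internal reuse).
#' @export
p_distance <- function(aln, a, b, cols = NULL) {
  i <- resolve_record(aln, a)
  j <- resolve_record(aln, b)
  if (is.null(cols)) cols <- pairwise_valid_columns(aln, i, j)
  m <- aln_char_matrix(aln)
  mean(m[i, cols] != m[j, cols])
}

#' Distance corrections of the observed difference proportion
#'
#' Closed forms: poisson `-log(1 - p)`; gamma
#' `alpha * ((1 - p)^(-1/alpha) - 1)`; Kimura's empirical protein correction
#' `-log(1 - p - 0.2 p^2)`; JC69 (DNA) `-(3/4) log(1 - 4 p / 3)`. The
#' identity method `"p"` returns p itself. All are strictly increasing in p
#' on their valid domain and map 0 to 0. Saturated inputs (log argument
#' <= 0) yield `NA`; callers flag the cell rather than aborting.
#'
#' @param p observed difference proportion(s) in `[0, 1]`.
#' @param method `"p"`, `"poisson"`, `"gamma"`, `"kimura_protein"`, `"jc69"`.
#' @param alpha gamma shape (method `"gamma"`, default 1).
#' @return corrected distance(s); `NA` where saturated.
#' @export
correct_distance <- function(p, method = c("poisson", "p", "gamma",
                                           "kimura_protein", "jc69"),
                             alpha = 1) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  d <- switch(method,
    p = p,
    poisson = ifelse(p < 1, -log(1 - p), NA_real_),
    gamma = {
      stopifnot(alpha > 0)
      ifelse(p < 1, alpha * ((1 - p)^(-1 / alpha) - 1), NA_real_)
    },
    kimura_protein = {
      arg <- 1 - p - 0.2 * p^2
      ifelse(arg > 0, -log(arg), NA_real_)
    },
    jc69 = {
      arg <- 1 - 4 * p / 3
      ifelse(arg > 0, -0.75 * log(arg), NA_real_)
    })
  unname(d)
}

#' Kimura two-parameter (K2P) distance
#'
#' @param P transition difference proportion.
#' @param Q transversion difference proportion.
#' @return `-(1/2) log(1 - 2P - Q) - (1/4) log(1 - 2Q)`; `NA` when saturated.
#' @export
k2p_distance <- function(P, Q) {
  if (any(P < 0 | Q < 0 | P + Q > 1)) stop("invalid (P, Q) fractions")
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  ifelse(a1 > 0 & a2 > 0, -0.5 * log(a1) - 0.25 * log(a2), NA_real_)
}

# transition/transversion split for one DNA pair (on valid columns)
count_ts_tv <- function(xa, xb) {
  diff <- xa != xb
  purine <- c("A", "G")
  ts <- diff & ((xa %in% purine) == (xb %in% purine))
  c(P = mean(ts), Q = mean(diff & !ts))
}

ML_T_MAX <- 20
ML_T_MIN <- 1e-6

#' Maximum-likelihood pairwise distance under an empirical model
#'
#' Maximizes `sum_sites log(pi[x] * P[x, y](t))` over `t` in
#' `[1e-6, 20]` (bounded scalar search, tolerance 1e-6), with optional
#' 4-category discrete-gamma rate heterogeneity. The optimizer hitting the
#' upper bound marks the pair saturated (`NA` distance).
#'
#' @inheritParams pairwise_valid_columns
#' @param model an `ml_empirical` [substitution_model()].
#' @return the ML distance, with attribute `saturated` (logical).
#' @export
ml_distance_empirical <- function(aln, a, b, model) {
  stopifnot(inherits(model, "substitution_model"))
  if (model$name != "ml_empirical") stop("model must be ml_empirical")
  i <- resolve_record(aln, a)
  j <- resolve_record(aln, b)
  cols <- pairwise_valid_columns(aln, i, j)
  m <- aln_char_matrix(aln)
  xi <- match(m[i, cols], model$states)
  xj <- match(m[j, cols], model$states)
  if (anyNA(xi) || anyNA(xj)) {
    stop("alignment characters outside the model alphabet for pair (",
         aln$ids[[i]], ", ", aln$ids[[j]], ")")
  }
  k <- length(model$states)
  counts <- matrix(tabulate((xi - 1L) * k + xj, nbins = k * k), k, k, byrow = TRUE)
  nz <- which(counts > 0, arr.ind = TRUE)
  nn <- counts[nz]
  lpi <- log(model$frequencies[nz[, 1]])
  loglik <- function(t) {
    P <- prob_matrix_mixture(model, t)
    sum(nn * (lpi + log(pmax(P[nz], 1e-300))))
  }
  opt <- stats::optimize(loglik, c(ML_T_MIN, ML_T_MAX), maximum = TRUE,
                         tol = 1e-6)
  saturated <- opt$maximum >= ML_T_MAX - 1e-3
  structure(if (saturated) NA_real_ else opt$maximum, saturated = saturated)
}

#' Percent identity over a column interval
#'
#' `100 * (1 - p)` on the pairwise-valid columns within `region`; the
#' complement of [p_distance()] on the same column set.
#'
#' @inheritParams pairwise_valid_columns
#' @param region optional `c(from, to)` column interval (1-based, inclusive).
#' @export
percent_identity <- function(aln, a, b, region = NULL) {
  i <- resolve_record(aln, a)
  j <- resolve_record(aln, b)
  cols <- pairwise_valid_columns(aln, i, j)
  if (!is.null(region)) {
    stopifnot(length(region) == 2)
    if (region[[1]] < 1 || region[[2]] > aln$length || region[[1]] > region[[2]]) {
      stop("region outside the alignment")
    }
    cols <- cols[cols >= region[[1]] & cols <= region[[2]]]
    if (!length(cols)) stop("no comparable columns in the requested region")
  }
  100 * (1 - p_distance(aln, i, j, cols = cols))
}

#' Pairwise distance matrix with pairwise deletion
#'
#' @param aln an [alignment()].
#' @param model a [substitution_model()]; counting corrections apply their
#'   closed form to each pair's p-distance, `"k2p"` uses per-pair
#'   transition/transversion fractions, `"ml_empirical"` optimizes the pair
#'   likelihood.
#' @return object of class `dist_matrix`: `labels`, symmetric `values`
#'   (substitutions/site, `NA` where saturated), and `flags`
#'   (`"ok"`/`"saturated"`).
#' @export
distance_matrix <- function(aln, model) {
  stopifnot(inherits(aln, "alignment"), inherits(model, "substitution_model"))
  if (model$name %in% c("jc69", "k2p") && aln$molecule != "dna") {
    stop(model$name, " applies to DNA alignments")
  }
  if (model$name == "kimura_protein" && aln$molecule != "protein") {
    stop("kimura_protein applies to protein alignments")
  }
  if (model$name == "ml_empirical" &&
      length(model$states) != length(mol_states(aln$molecule))) {
    stop("model alphabet does not match alignment molecule type")
  }
  n <- length(aln$ids)
  values <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  flags <- matrix("ok", n, n, dimnames = list(aln$ids, aln$ids))
  mask <- aln_state_mask(aln)
  m <- aln_char_matrix(aln)
  bad_pairs <- character()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cols <- which(mask[i, ] & mask[j, ])
      if (!length(cols)) {
        bad_pairs <- c(bad_pairs, paste0("(", aln$ids[[i]], ", ", aln$ids[[j]], ")"))
        next
      }
      d <- if (model$name == "ml_empirical") {
        as.numeric(ml_distance_empirical(aln, i, j, model))
      } else if (model$name == "k2p") {
        pq <- count_ts_tv(m[i, cols], m[j, cols])
        k2p_distance(pq[["P"]], pq[["Q"]])
      } else {
        p <- mean(m[i, cols] != m[j, cols])
        correct_distance(p, model$name, alpha = model$alpha %||% 1)
      }
      values[i, j] <- values[j, i] <- d
      if (is.na(d)) flags[i, j] <- flags[j, i] <- "saturated"
    }
  }
  if (length(bad_pairs)) {
    stop("uncomparable pair(s): ", paste(bad_pairs, collapse = ", "))
  }
  structure(list(labels = aln$ids, values = values, flags = flags,
                 model = model$name),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  nsat <- sum(x$flags == "saturated") / 2
  cat(sprintf("distance matrix (%s): %d taxa, %d saturated pair(s)\n",
              x$model, length(x$labels), nsat))
  invisible(x)
}

#' Export a distance matrix
#'
#' @param dm a `dist_matrix`.
#' @param path output file.
#' @param format `"phylip"` (square) or `"tsv"` (long form with a status
#'   column so saturated cells stay visible).
#' @export
write_distance_matrix <- function(dm, path, format = c("phylip", "tsv")) {
  format <- match.arg(format)
  n <- length(dm$labels)
  if (format == "phylip") {
    rows <- vapply(seq_len(n), function(i) {
      paste(c(sprintf("%-10s", dm$labels[[i]]),
              sprintf("%.6f", dm$values[i, ])), collapse = " ")
    }, character(1))
    writeLines(c(sprintf("%5d", n), rows), path)
  } else {
    lines <- "a\tb\tdistance\tstatus"
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        lines <- c(lines, sprintf("%s\t%s\t%s\t%s", dm$labels[[i]], dm$labels[[j]],
                                  format(dm$values[i, j], digits = 10),
                                  dm$flags[i, j]))
      }
    }
    writeLines(lines, path)
  }
  invisible(path)
}
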