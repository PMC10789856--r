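# Neighbour joining (Saitou & Nei agglomeration) and bootstrap support.
#
# Determinism: ties in the Q criterion are broken by the lexicographically
# smallest pair of cluster keys (a cluster's key is its smallest tip label),
# so identical input always yields an identical tree. Negative branch-length
# estimates are clamped to 0 with the deficit transferred to the sister
# branch, preserving the pair's summed length.

#' Neighbour-joining tree from a distance matrix
#'
#' `Q(i, j) = (n - 2) d(i, j) - sum_k d(i, k) - sum_k d(j, k)`; branch
#' lengths from the standard two-point formulas. Consistent on additive
#' inputs: recovers topology and path lengths exactly.
#'
#' @param dm a [distance_matrix()] result (no saturated cells), or a plain
#'   symmetric matrix with dimnames.
#' @return an unrooted [ape::phylo] tree (basal trifurcation).
#' @export
neighbor_joining <- function(dm) {
  if (inherits(dm, "dist_matrix")) {
    if (any(dm$flags == "saturated")) {
      sat <- which(dm$flags == "saturated" & upper.tri(dm$flags), arr.ind = TRUE)
      stop("saturated cell(s) in distance matrix: ",
           paste(paste0("(", dm$labels[sat[, 1]], ", ", dm$labels[sat[, 2]], ")"),
                 collapse = ", "))
    }
    d <- dm$values
    labels <- dm$labels
  } else {
    d <- as.matrix(dm)
    labels <- rownames(d)
    if (is.null(labels)) stop("distance matrix needs labels")
    if (anyNA(d)) stop("NA in distance matrix")
  }
  n <- length(labels)
  if (n < 3) stop("neighbour joining needs >= 3 taxa")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")

  frag <- labels                  # growing Newick fragment per cluster
  key <- labels                   # smallest contained tip label, for ties
  active <- d
  fmt <- function(x) sprintf("%.17g", x)

  while (nrow(active) > 3) {
    m <- nrow(active)
    r <- rowSums(active)
    Q <- (m - 2) * active - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)) & upper.tri(Q),
                  arr.ind = TRUE)
    if (nrow(cand) > 1) {
      pair_key <- apply(cand, 1, function(ij) {
        ks <- sort(c(key[[ij[[1]]]], key[[ij[[2]]]]))
        paste(ks, collapse = "\r")
      })
      cand <- cand[order(pair_key)[1], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    dij <- active[i, j]
    vi <- 0.5 * dij + (r[[i]] - r[[j]]) / (2 * (m - 2))
    vj <- dij - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    new_frag <- paste0("(", frag[[i]], ":", fmt(vi), ",", frag[[j]], ":", fmt(vj), ")")
    new_key <- min(key[[i]], key[[j]])
    others <- setdiff(seq_len(m), c(i, j))
    dnew <- 0.5 * (active[i, others] + active[j, others] - dij)
    active <- rbind(cbind(active[others, others, drop = FALSE], dnew),
                    c(dnew, 0))
    frag <- c(frag[others], new_frag)
    key <- c(key[others], new_key)
  }

  # final three clusters: three-point formulas around the central node
  dxy <- active[1, 2]; dxz <- active[1, 3]; dyz <- active[2, 3]
  v <- c((dxy + dxz - dyz) / 2, (dxy + dyz - dxz) / 2, (dxz + dyz - dxy) / 2)
  for (i in seq_len(3)) {
    if (v[[i]] < 0) {              # no unique sister at the trifurcation:
      v[-i] <- v[-i] + v[[i]] / 2  # split the deficit across the other two
      v[[i]] <- 0
    }
  }
  v <- pmax(v, 0)
  ord <- order(key)
  txt <- paste0("(", paste0(frag[ord], ":", fmt(v[ord]), collapse = ","), ");")
  ape::read.tree(text = txt)
}

# Canonical bipartition strings of a tree (non-trivial splits only).
# The side NOT containing the alphabetically smallest tip is sorted and
# joined with "|": stable across rootings and tip orderings.

#' Non-trivial bipartitions of a tree
#'
#' @param tree an [ape::phylo] tree (rooted or not).
#' @return character vector of canonical split strings (the side not
#'   containing the alphabetically first tip, sorted, `|`-separated).
#' @export
tree_splits <- function(tree) {
  n <- length(tree$tip.label)
  ref <- min(tree$tip.label)
  all_tips <- tree$tip.label
  desc <- node_descendant_tips(tree)
  out <- character()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= n) next
    s <- desc[[child]]
    if (length(s) < 2 || length(s) > n - 2) next
    side <- if (ref %in% s) sort(setdiff(all_tips, s)) else sort(s)
    out <- c(out, paste(side, collapse = "|"))
  }
  unique(out)
}

# tip labels below every node (index = node id)
node_descendant_tips <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  desc <- vector("list", nn)
  for (i in seq_len(n)) desc[[i]] <- tree$tip.label[[i]]
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1]; ch <- edges[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

#' Bootstrap support for neighbour-joining splits
#'
#' Resamples alignment columns with replacement, recomputes the distance
#' matrix and NJ tree per replicate, and counts bipartition occurrences.
#' Replicates whose matrix has an uncomparable or saturated pair are dropped
#' and counted; more than 20% dropped is an error. Bit-reproducible for a
#' fixed seed.
#'
#' @param aln an [alignment()].
#' @param model a [substitution_model()].
#' @param replicates number of bootstrap replicates (default 500).
#' @param seed integer seed (mandatory).
#' @return object of class `bootstrap_result`: data frame of splits with
#'   support fractions in `[0, 1]`, replicate counts, and tip labels.
#' @export
bootstrap_support <- function(aln, model, replicates = 500, seed) {
  stopifnot(inherits(aln, "alignment"), replicates >= 1)
  if (missing(seed)) stop("a seed is mandatory for bootstrap_support")
  set.seed(seed)
  L <- aln$length
  idx <- matrix(sample.int(L, L * replicates, replace = TRUE), nrow = replicates)
  counts <- new.env(parent = emptyenv())
  dropped <- 0L
  for (rr in seq_len(replicates)) {
    rep_aln <- aln_subset_columns(aln, idx[rr, ])
    tr <- tryCatch(neighbor_joining(distance_matrix(rep_aln, model)),
                   error = function(e) NULL)
    if (is.null(tr)) {
      dropped <- dropped + 1L
      next
    }
    for (s in tree_splits(tr)) {
      counts[[s]] <- get0(s, envir = counts, ifnotfound = 0L) + 1L
    }
  }
  if (dropped > 0.2 * replicates) {
    stop(dropped, "/", replicates, " bootstrap replicates dropped (> 20%)")
  }
  kept <- replicates - dropped
  splits <- sort(ls(counts))
  df <- data.frame(split = splits,
                   count = vapply(splits, function(s) counts[[s]], integer(1)),
                   stringsAsFactors = FALSE)
  df$support <- if (kept > 0) df$count / kept else numeric(nrow(df))
  rownames(df) <- NULL
  structure(list(splits = df, replicates = replicates, kept = kept,
                 dropped = dropped, tip_labels = aln$ids),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap: %d replicates (%d kept), %d distinct split(s)\n",
              x$replicates, x$kept, nrow(x$splits)))
  invisible(x)
}

#' Support for one bipartition
#'
#' @param bs a [bootstrap_support()] result.
#' @param tips tip labels of one side of the split.
#' @return support fraction (0 when the split never occurred).
#' @export
split_support <- function(bs, tips) {
  ref <- min(bs$tip_labels)
  side <- if (ref %in% tips) sort(setdiff(bs$tip_labels, tips)) else sort(tips)
  s <- paste(side, collapse = "|")
  hit <- bs$splits$support[bs$splits$split == s]
  if (length(hit)) hit[[1]] else 0
}
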