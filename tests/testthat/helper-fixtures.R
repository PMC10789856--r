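# Fixtures are built in code: nothing binary, nothing downloaded.

# --- synteny -----------------------------------------------------------------
# Reference neighbourhoods with planted witness genes (one neighbour unique
# to each paralogue) over a shared background pool.
witness_references <- function() {
  pool <- paste0("BG", 1:9)            # background genes shared by >= 2 refs
  mk <- function(id, chrom, syms) {
    gene_neighborhood(id, chrom, syms, seq_along(syms) - ceiling(length(syms) / 2) -
                        ifelse(seq_along(syms) > ceiling(length(syms) / 2), 0, 1))
  }
  list(
    foxg1a = mk("foxg1a", "chrA", c("NOVA1", pool[1:9])),
    foxg1b = mk("foxg1b", "chrB", c("SLC30A5", pool[1:9])),
    foxg1c = mk("foxg1c", "chrC", c("SNRPD2", pool[1:9]))
  )
}

# Query neighbourhoods overlapping several references: the top two cells of
# the first query tie exactly, so orthology is ambiguous at epsilon = 0.05.
overlapping_queries <- function() {
  refs <- witness_references()
  rs <- lapply(refs, function(r) r$symbols)
  mk <- function(id, syms) {
    gene_neighborhood(id, "chrL", syms,
                      offsets = c(rev(-seq_len(ceiling(length(syms) / 2))),
                                  seq_len(floor(length(syms) / 2))))
  }
  list(
    foxg1alpha = mk("foxg1alpha", c(rs$foxg1a[1:6], rs$foxg1b[1],
                                    paste0("LMP", 1:2))),
    foxg1beta = mk("foxg1beta", c(rs$foxg1b[1:5], rs$foxg1a[1:2],
                                  paste0("LMP", 3:4))),
    foxg1gamma = mk("foxg1gamma", c(rs$foxg1c[1:6], paste0("LMP", 5:7)))
  )
}

# Exhaustive injective-assignment optimum: independent oracle for
# assign_orthologs (queries = rows assigned to distinct columns).
brute_force_assignment_max <- function(J) {
  nq <- nrow(J); nr <- ncol(J)
  best <- -Inf
  rec <- function(i, used, score) {
    if (i > nq) {
      best <<- max(best, score)
      return()
    }
    for (j in seq_len(nr)) {
      if (!used[[j]]) {
        used[[j]] <- TRUE
        rec(i + 1L, used, score + J[i, j])
        used[[j]] <- FALSE
      }
    }
    if (sum(!used) < nq - i + 1L) rec(i + 1L, used, score)
  }
  rec(1L, rep(FALSE, nr), 0)
  best
}

# --- trees -------------------------------------------------------------------
# Random rooted tree with uniform branch lengths: additive-matrix oracle.
random_additive_tree <- function(n, min_len = 0.01, max_len = 1) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), min_len, max_len)
  tr
}

# --- alignments --------------------------------------------------------------
# protein pair with an exact number of mismatches, uniform-ish composition
protein_pair_with_p <- function(L, mismatches) {
  base <- paste(rep_len(ohnotime:::AA_STATES, L), collapse = "")
  other <- strsplit(base, "")[[1]]
  idx <- seq_len(mismatches)
  swap <- ohnotime:::AA_STATES[(match(other[idx], ohnotime:::AA_STATES)) %% 20 + 1]
  other[idx] <- swap
  alignment(c("s1", "s2"), c(base, paste(other, collapse = "")), "protein")
}
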