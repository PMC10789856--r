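# The relative-timing statistic for gene duplications.
#
# On an outgroup-rooted tree: node a is the root's ingroup-side child (the
# point where the ingroup lineage begins after the outgroup split -- ab
# therefore excludes the outgroup stem, making the ratio independent of
# outgroup branch length); node b is the MRCA of the two paralogue groups;
# c are the present-day paralogue tips. ab is the a-b path length, bc the
# arithmetic mean of the b-to-tip path lengths, and bc/ab the dimensionless
# relative age of the duplication: large ratios mean the duplication closely
# followed the outgroup split (ancient, scenario I), small ratios a recent
# duplication (scenario II). Default classification thresholds (ancient
# >= 1, recent <= 0.5) are calibrated to the two observed regimes (ratios
# above 1 for the shared vertebrate rounds vs 0.15 for the teleost-specific
# round); they are configuration, not biology.

#' Label tips by paralogue group
#'
#' @param paralog_1,paralog_2 tip labels of the two paralogue groups.
#' @param outgroup tip labels used for rooting.
#' @param other tip labels present in the tree but in no group.
#' @return object of class `paralog_labeling`.
#' @export
paralog_labeling <- function(paralog_1, paralog_2, outgroup, other = character()) {
  groups <- list(paralog_1 = unique(as.character(paralog_1)),
                 paralog_2 = unique(as.character(paralog_2)),
                 outgroup = unique(as.character(outgroup)),
                 other = unique(as.character(other)))
  empty <- names(groups)[vapply(groups[1:3], length, 1L) == 0]
  if (length(empty)) stop("empty group(s): ", paste(empty, collapse = ", "))
  all_tips <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_tips)) {
    stop("tip(s) in more than one group: ",
         paste(unique(all_tips[duplicated(all_tips)]), collapse = ", "))
  }
  structure(groups, class = "paralog_labeling")
}

#' Classification thresholds for the bc/ab ratio
#'
#' @param ancient ratio at or above which a duplication is called ancient.
#' @param recent ratio at or below which it is called recent.
#' @export
timing_thresholds <- function(ancient = 1.0, recent = 0.5) {
  stopifnot(ancient > recent, recent > 0)
  list(ancient = ancient, recent = recent)
}

#' Locate the timing nodes a and b
#'
#' @param tree a rooted [ape::phylo] tree (root binary, as produced by
#'   [root_with_outgroup()]).
#' @param labeling a [paralog_labeling()].
#' @return list with `node_a`, `node_b`, and `warnings` (character; a
#'   non-monophyletic-duplication warning is recorded, not thrown).
#' @export
locate_timing_nodes <- function(tree, labeling) {
  stopifnot(inherits(tree, "phylo"), inherits(labeling, "paralog_labeling"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted (see root_with_outgroup)")
  n <- length(tree$tip.label)
  root <- n + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  if (length(kids) != 2) stop("root must have exactly two children")
  desc <- node_descendant_tips(tree)
  og <- intersect(labeling$outgroup, tree$tip.label)
  if (!length(og)) stop("no outgroup tips present in the tree")
  og_side <- vapply(kids, function(k) all(og %in% desc[[k]]), logical(1))
  if (sum(og_side) != 1) stop("outgroup tips are not confined to one root child")
  node_a <- kids[[which(!og_side)]]
  all_par <- c(labeling$paralog_1, labeling$paralog_2)
  par_tips <- intersect(all_par, intersect(tree$tip.label, desc[[node_a]]))
  warnings <- character()
  misplaced <- setdiff(all_par, par_tips)
  if (length(misplaced)) {
    # tree error or absent sequence: excluded from bc, never fatal
    warnings <- c(warnings,
                  paste0("paralogue tip(s) not descended from node b, ",
                         "excluded from bc: ",
                         paste(sort(misplaced), collapse = ", ")))
  }
  if (!length(intersect(labeling$paralog_1, par_tips)) ||
      !length(intersect(labeling$paralog_2, par_tips))) {
    stop("both paralogue groups must have tips below the ingroup root")
  }
  node_b <- mrca(tree, par_tips)
  if (node_b == node_a) {
    stop("duplication node coincides with the ingroup root: ab undefined")
  }
  b_kids <- tree$edge[tree$edge[, 1] == node_b, 2]
  in_kid <- function(group) {
    hit <- vapply(b_kids, function(k) {
      any(intersect(labeling[[group]], par_tips) %in% desc[[k]])
    }, logical(1))
    which(hit)
  }
  k1 <- in_kid("paralog_1"); k2 <- in_kid("paralog_2")
  if (length(k1) != 1 || length(k2) != 1 || identical(k1, k2)) {
    warnings <- c(warnings,
                  "paralogue groups are not separately monophyletic below node b")
  }
  list(node_a = node_a, node_b = node_b, warnings = warnings)
}

#' Compute the bc/ab timing statistic
#'
#' @inheritParams locate_timing_nodes
#' @param thresholds a [timing_thresholds()] list.
#' @return object of class `timing_result`: `node_a`, `node_b`, `ab`,
#'   `bc_per_tip`, `bc` (mean), `ratio`, `classification`, `outgroup_used`,
#'   `warnings`.
#' @export
compute_timing <- function(tree, labeling, thresholds = timing_thresholds()) {
  loc <- locate_timing_nodes(tree, labeling)
  ab <- path_length(tree, loc$node_a, loc$node_b)
  if (ab <= 1e-9) stop("degenerate stem: ab = ", format(ab), " <= 1e-9")
  desc <- node_descendant_tips(tree)
  par_tips <- intersect(c(labeling$paralog_1, labeling$paralog_2), tree$tip.label)
  below <- intersect(par_tips, desc[[loc$node_b]])
  excluded <- setdiff(par_tips, below)
  warnings <- loc$warnings
  if (length(excluded)) {
    warnings <- c(warnings, paste0("paralogue tip(s) not descended from node b, ",
                                   "excluded from bc: ",
                                   paste(sort(excluded), collapse = ", ")))
  }
  warnings <- unique(warnings)
  dn <- ape::dist.nodes(tree)
  tip_ids <- match(below, tree$tip.label)
  bc_per_tip <- dn[loc$node_b, tip_ids]
  names(bc_per_tip) <- below
  bc <- mean(bc_per_tip)
  ratio <- bc / ab
  structure(list(node_a = loc$node_a, node_b = loc$node_b, ab = ab,
                 bc_per_tip = bc_per_tip, bc = bc, ratio = ratio,
                 classification = classify_duplication(ratio, thresholds),
                 outgroup_used = intersect(labeling$outgroup, tree$tip.label),
                 warnings = warnings, thresholds = thresholds),
            class = "timing_result")
}

#' @export
print.timing_result <- function(x, ...) {
  cat(sprintf("bc/ab timing: ab = %.4f, bc = %.4f, ratio = %.4f -> %s\n",
              x$ab, x$bc, x$ratio, x$classification))
  cat("  outgroup:", paste(x$outgroup_used, collapse = ", "), "\n")
  if (length(x$warnings)) cat("  warning:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Classify a duplication from its bc/ab ratio
#'
#' @param ratio finite positive bc/ab ratio.
#' @param thresholds a [timing_thresholds()] list.
#' @return `"ancient"`, `"recent"`, or `"indeterminate"`.
#' @export
classify_duplication <- function(ratio, thresholds = timing_thresholds()) {
  if (!is.finite(ratio) || ratio <= 0) stop("ratio must be finite and positive")
  if (ratio >= thresholds$ancient) "ancient"
  else if (ratio <= thresholds$recent) "recent"
  else "indeterminate"
}

#' Timing report over multiple cases and outgroup configurations
#'
#' Each case supplies either a tree or an alignment (run through
#' [distance_matrix()] + [neighbor_joining()] first), a labeling, and
#' optionally several outgroup configurations; each case x outgroup
#' combination yields one row. Per-case errors are collected into the `note`
#' column, not thrown. The `concordance` column is max/min ratio across that
#' case's successful outgroup configurations (NA with fewer than two).
#'
#' @param cases list of case lists with elements `name`, `tree` or
#'   `alignment`, `labeling`, optional `molecule`, `model`, `outgroups`
#'   (list of character vectors; defaults to the labeling's outgroup).
#' @param config a [run_config()]; supplies the default model and thresholds.
#' @return data frame: case, molecule, outgroup, ab, bc, ratio,
#'   classification, concordance, note.
#' @export
timing_report <- function(cases, config = run_config()) {
  rows <- list()
  for (case in cases) {
    name <- case$name %||% "case"
    labeling <- case$labeling
    molecule <- case$molecule %||%
      (if (!is.null(case$alignment)) case$alignment$molecule else NA_character_)
    tree <- case$tree
    err <- NULL
    if (is.null(tree)) {
      tree <- tryCatch({
        model <- case$model %||% config$model
        neighbor_joining(distance_matrix(case$alignment, model))
      }, error = function(e) { err <<- conditionMessage(e); NULL })
    }
    outgroups <- case$outgroups %||% list(labeling$outgroup)
    case_rows <- list()
    for (og in outgroups) {
      row <- data.frame(case = name, molecule = molecule,
                        outgroup = paste(og, collapse = "+"),
                        ab = NA_real_, bc = NA_real_, ratio = NA_real_,
                        classification = NA_character_,
                        concordance = NA_real_, note = NA_character_,
                        stringsAsFactors = FALSE)
      if (is.null(tree)) {
        row$note <- err
      } else {
        res <- tryCatch({
          rooted <- root_with_outgroup(tree, og)
          lab2 <- paralog_labeling(
            setdiff(labeling$paralog_1, og), setdiff(labeling$paralog_2, og),
            og,
            setdiff(union(labeling$other, labeling$outgroup), og))
          compute_timing(rooted, lab2, config$thresholds)
        }, error = function(e) conditionMessage(e))
        if (inherits(res, "timing_result")) {
          row$ab <- res$ab; row$bc <- res$bc; row$ratio <- res$ratio
          row$classification <- res$classification
          if (length(res$warnings)) row$note <- paste(res$warnings, collapse = "; ")
        } else {
          row$note <- res
        }
      }
      case_rows[[length(case_rows) + 1L]] <- row
    }
    case_df <- do.call(rbind, case_rows)
    ok <- is.finite(case_df$ratio)
    if (sum(ok) >= 2) {
      case_df$concordance <- max(case_df$ratio[ok]) / min(case_df$ratio[ok])
    }
    rows[[length(rows) + 1L]] <- case_df
  }
  if (!length(rows)) {
    return(data.frame(case = character(), molecule = character(),
                      outgroup = character(), ab = numeric(), bc = numeric(),
                      ratio = numeric(), classification = character(),
                      concordance = numeric(), note = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
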