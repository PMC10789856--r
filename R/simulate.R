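# Synthetic gene families with known duplication times.
#
# A scenario states a clock tree in arbitrary time units: the ingroup splits
# from its closest outgroup lineage (OUT1) at height A, a duplication at
# height B < A creates two paralogue clades, and each clade is expanded to
# n species. A second, more distant outgroup taxon (OUT2, labeled "other")
# is always present: without it the outgroup attaches at mrca(paralogues) in
# any inferred unrooted tree and node a would coincide with node b, leaving
# ab undefined. With OUT2 in place, the OUT1 attachment node sits exactly at
# height A and the true bc/ab ratio is B / (A - B).
#
# Sequences evolve along the tree under a reversible continuous-time Markov
# model scaled to one expected substitution per site per time unit, sites
# independent (optionally with discrete-gamma rate categories), no indels.
# Everything is deterministic under the scenario seed.

#' Specify a duplication scenario
#'
#' @param A height of the ingroup/outgroup (OUT1) split, > 0 time units.
#' @param B duplication height, 0 < B < A. Under `resolution = "lor"` each
#'   species lineage duplicates independently at height B after speciation.
#' @param A_far height of the distant second outgroup OUT2 (> A; default
#'   `A + 0.4`).
#' @param n_species_per_clade species sampled per paralogue clade (>= 1).
#' @param resolution `"aor"` (duplication precedes speciation: orthologues
#'   cluster) or `"lor"` (speciation precedes per-lineage duplication:
#'   within-species paralogues cluster).
#' @param speciation_heights species-split heights; defaults to an evenly
#'   spaced ladder below B (`"aor"`) or between B and A (`"lor"`).
#' @param loss_probability per-duplicate-tip loss probability in `[0, 1)`.
#' @param rate_multipliers named positive factors applied to the pendant
#'   branch durations of matching tips (lineage-specific acceleration).
#' @param sequence_length alignment columns (>= 1).
#' @param model an `ml_empirical` [substitution_model()] (defines molecule
#'   type and the simulating process).
#' @param seed integer seed (mandatory).
#' @return object of class `wgd_scenario`.
#' @export
wgd_scenario <- function(A, B, A_far = A + 0.4, n_species_per_clade = 2,
                         resolution = c("aor", "lor"),
                         speciation_heights = NULL, loss_probability = 0,
                         rate_multipliers = NULL, sequence_length = 500,
                         model = model_uniform(20, alpha = 1), seed) {
  resolution <- match.arg(resolution)
  stopifnot(A > 0, B > 0, B < A, A_far > A, n_species_per_clade >= 1,
            loss_probability >= 0, loss_probability < 1, sequence_length >= 1)
  if (missing(seed)) stop("a seed is mandatory for a scenario")
  if (!is.null(rate_multipliers) &&
      (is.null(names(rate_multipliers)) || any(rate_multipliers <= 0))) {
    stop("rate_multipliers must be a named vector of positive factors")
  }
  n <- n_species_per_clade
  if (is.null(speciation_heights)) {
    speciation_heights <- if (n == 1) numeric() else {
      if (resolution == "aor") B * ((n - 1):1) / n
      else B + (min((A + B) / 2, A * 0.9) - B) * ((n - 1):1) / (n - 1)
    }
  }
  speciation_heights <- sort(as.numeric(speciation_heights), decreasing = TRUE)
  if (n > 1) {
    if (length(speciation_heights) != n - 1) {
      stop("need ", n - 1, " speciation height(s)")
    }
    if (resolution == "aor" && any(speciation_heights >= B)) {
      stop("aor speciation heights must lie below the duplication height B")
    }
    if (resolution == "lor" &&
        (any(speciation_heights <= B) || any(speciation_heights >= A))) {
      stop("lor speciation heights must lie between B and A")
    }
  }
  stopifnot(inherits(model, "substitution_model"), model$name == "ml_empirical")
  structure(list(A = A, B = B, A_far = A_far,
                 n_species_per_clade = n, resolution = resolution,
                 speciation_heights = speciation_heights,
                 loss_probability = loss_probability,
                 rate_multipliers = rate_multipliers,
                 sequence_length = as.integer(sequence_length),
                 molecule = if (length(model$states) == 4) "dna" else "protein",
                 model = model, seed = as.integer(seed)),
            class = "wgd_scenario")
}

#' Preset duplication scenarios
#'
#' `ancient_2R`: A = 1.8, B = 1.0 (true ratio 1.25) -- the regime of the
#' shared early-vertebrate rounds. `recent_TSWGD`: A = 2.3, B = 0.3 (true
#' ratio 0.15) -- the teleost-specific round. `sturgeon_AOR` /
#' `sturgeon_LOR`: two-species scenarios whose tree shapes distinguish
#' ancestral vs lineage-specific ohnologue resolution. Heights are arbitrary
#' time units bracketing the two observed regimes, not absolute ages.
#'
#' @param name preset name.
#' @param seed integer seed (mandatory).
#' @param ... overrides passed on to [wgd_scenario()].
#' @export
preset_scenario <- function(name = c("ancient_2R", "recent_TSWGD",
                                     "sturgeon_LOR", "sturgeon_AOR"),
                            seed, ...) {
  name <- match.arg(name)
  if (missing(seed)) stop("a seed is mandatory for a scenario")
  args <- switch(name,
    ancient_2R = list(A = 1.8, B = 1.0, A_far = 2.2, n_species_per_clade = 3),
    recent_TSWGD = list(A = 2.3, B = 0.3, A_far = 2.7, n_species_per_clade = 3),
    sturgeon_AOR = list(A = 1.5, B = 0.8, A_far = 1.9, n_species_per_clade = 2,
                        resolution = "aor", speciation_heights = 0.4),
    sturgeon_LOR = list(A = 1.5, B = 0.4, A_far = 1.9, n_species_per_clade = 2,
                        resolution = "lor", speciation_heights = 0.8))
  over <- list(...)
  args[names(over)] <- over
  do.call(wgd_scenario, c(args, list(seed = seed)))
}

# ladder ((...((x1,x2)h_k, x3)h_{k-1} ...) of fragments with given heights;
# items: list(frag=, height=) in join order; joins: descending heights
join_ladder <- function(items, join_heights, fmt) {
  cur <- items[[1]]
  hs <- sort(join_heights)           # join closest relatives first
  for (k in seq_along(items)[-1]) {
    h <- hs[[k - 1]]
    nxt <- items[[k]]
    cur <- list(frag = paste0("(", cur$frag, ":", fmt(h - cur$height), ",",
                              nxt$frag, ":", fmt(h - nxt$height), ")"),
                height = h)
  }
  cur
}

#' Build the true time tree of a scenario
#'
#' Ultrametric in time units (every tip at height 0) before any rate
#' multipliers; duplicate losses are drawn under the scenario seed.
#'
#' @param scenario a [wgd_scenario()].
#' @param .reseed set the RNG from the scenario seed (default); internal
#'   callers that already seeded pass `FALSE`.
#' @return an [ape::phylo] tree with branch lengths in time units. Tips are
#'   `sp<i>_P1` / `sp<i>_P2`, `OUT1` (outgroup at height A) and `OUT2`
#'   (distant outgroup at `A_far`).
#' @export
build_true_tree <- function(scenario, .reseed = TRUE) {
  stopifnot(inherits(scenario, "wgd_scenario"))
  if (.reseed) set.seed(scenario$seed)
  fmt <- function(x) sprintf("%.17g", x)
  n <- scenario$n_species_per_clade
  sp <- paste0("sp", seq_len(n))
  B <- scenario$B
  sh <- scenario$speciation_heights
  if (scenario$resolution == "aor") {
    clade <- function(copy) {
      tips <- lapply(paste0(sp, "_", copy),
                     function(t) list(frag = t, height = 0))
      if (n == 1) tips[[1]] else join_ladder(tips, sh, fmt)
    }
    c1 <- clade("P1"); c2 <- clade("P2")
    ingroup <- list(frag = paste0("(", c1$frag, ":", fmt(B - c1$height), ",",
                                  c2$frag, ":", fmt(B - c2$height), ")"),
                    height = B)
  } else {
    lineages <- lapply(sp, function(s) {
      list(frag = paste0("(", s, "_P1:", fmt(B), ",", s, "_P2:", fmt(B), ")"),
           height = B)
    })
    ingroup <- if (n == 1) lineages[[1]] else join_ladder(lineages, sh, fmt)
  }
  A <- scenario$A; Af <- scenario$A_far
  txt <- paste0("((", ingroup$frag, ":", fmt(A - ingroup$height),
                ",OUT1:", fmt(A), "):", fmt(Af - A),
                ",OUT2:", fmt(Af), ");")
  tree <- ape::read.tree(text = txt)
  if (scenario$loss_probability > 0) {
    par_tips <- sort(grep("_P[12]$", tree$tip.label, value = TRUE))
    lost <- par_tips[stats::runif(length(par_tips)) < scenario$loss_probability]
    for (grp in c("_P1$", "_P2$")) {
      grp_tips <- grep(grp, par_tips, value = TRUE)
      if (all(grp_tips %in% lost)) {
        stop("scenario-degenerate: all tips of one paralogue group were lost")
      }
    }
    if (length(lost)) tree <- ape::drop.tip(tree, lost)
  }
  tree
}

#' Expected difference proportion under the uniform 20-state model
#'
#' Closed form `(19/20) (1 - exp(-20 t / 19))`: the analytic oracle used to
#' calibrate the simulator. Monotone in `t` with asymptote 0.95.
#'
#' @param t branch length (expected substitutions/site), >= 0.
#' @export
expected_p_jc20 <- function(t) {
  if (any(t < 0)) stop("t must be >= 0")
  (19 / 20) * (1 - exp(-20 * t / 19))
}

#' Evolve an alignment along a tree
#'
#' Root sequence drawn from the model's equilibrium frequencies; each branch
#' applies the transition matrix of its duration (time x optional rate
#' multiplier), independently per site. With a gamma model, each site is
#' assigned one of the discrete rate categories.
#'
#' @param tree an [ape::phylo] tree with branch lengths in time units.
#' @param model an `ml_empirical` [substitution_model()].
#' @param length number of columns (>= 1).
#' @param seed optional integer seed (callers composing several draws seed
#'   once themselves and pass `NULL`).
#' @param rate_multipliers named positive factors for pendant branches.
#' @return an [alignment()] of the tip sequences.
#' @export
evolve_alignment <- function(tree, model, length, seed = NULL,
                             rate_multipliers = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "substitution_model"),
            model$name == "ml_empirical")
  if (length < 1) stop("alignment length must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  L <- as.integer(length)
  k <- length(model$states)
  ncat <- length(model$rates)
  site_cat <- if (ncat > 1) sample.int(ncat, L, replace = TRUE) else rep(1L, L)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  seqs <- matrix(NA_integer_, nn, L)
  root <- ntip + 1L
  seqs[root, ] <- sample.int(k, L, replace = TRUE, prob = model$frequencies)
  ord <- ape::reorder.phylo(tree, "cladewise")
  lens <- ord$edge.length
  for (e in seq_len(nrow(ord$edge))) {
    p <- ord$edge[e, 1]; ch <- ord$edge[e, 2]
    t_e <- lens[[e]]
    if (ch <= ntip && !is.null(rate_multipliers)) {
      hit <- match(tree$tip.label[[ch]], names(rate_multipliers))
      if (!is.na(hit)) t_e <- t_e * rate_multipliers[[hit]]
    }
    child <- integer(L)
    for (cat in seq_len(ncat)) {
      sites <- which(site_cat == cat)
      if (!length(sites)) next
      P <- prob_matrix(model, t_e * model$rates[[cat]])
      par_states <- seqs[p, sites]
      for (s in seq_len(k)) {
        idx <- sites[par_states == s]
        if (length(idx)) {
          child[idx] <- sample.int(k, length(idx), replace = TRUE, prob = P[s, ])
        }
      }
    }
    seqs[ch, ] <- child
  }
  tip_seqs <- vapply(seq_len(ntip), function(i) {
    paste(model$states[seqs[i, ]], collapse = "")
  }, character(1))
  alignment(tree$tip.label, tip_seqs,
            molecule = if (k == 4) "dna" else "protein")
}

#' Simulate a gene family end to end
#'
#' Composes [build_true_tree()] and [evolve_alignment()] under one seed and
#' packages the ground truth for recovery tests.
#'
#' @param scenario a [wgd_scenario()].
#' @return object of class `simulated_family`: `tree` (true time tree),
#'   `alignment`, `labeling` (a [paralog_labeling()]: P1/P2 tips, OUT1 as
#'   outgroup, OUT2 as other), `truth` (A, B, and exact ratio `B/(A-B)`),
#'   and the scenario.
#' @export
simulate_family <- function(scenario) {
  stopifnot(inherits(scenario, "wgd_scenario"))
  set.seed(scenario$seed)
  tree <- build_true_tree(scenario, .reseed = FALSE)
  aln <- evolve_alignment(tree, scenario$model, scenario$sequence_length,
                          seed = NULL,
                          rate_multipliers = scenario$rate_multipliers)
  labeling <- paralog_labeling(
    paralog_1 = grep("_P1$", tree$tip.label, value = TRUE),
    paralog_2 = grep("_P2$", tree$tip.label, value = TRUE),
    outgroup = "OUT1",
    other = intersect("OUT2", tree$tip.label))
  truth <- list(A = scenario$A, B = scenario$B,
                ratio = scenario$B / (scenario$A - scenario$B))
  structure(list(tree = tree, alignment = aln, labeling = labeling,
                 truth = truth, scenario = scenario),
            class = "simulated_family")
}

#' @export
print.simulated_family <- function(x, ...) {
  cat(sprintf("simulated family: %d tips, L = %d, true bc/ab = %.4f (%s)\n",
              length(x$tree$tip.label), x$alignment$length, x$truth$ratio,
              x$scenario$resolution))
  invisible(x)
}

#' Write a simulated family to a directory
#'
#' Emits `alignment.fasta`, `true_tree.nwk`, `labeling.tsv` (tip, group) and
#' `truth.json`.
#'
#' @param family a [simulate_family()] result.
#' @param dir output directory (created if needed).
#' @export
write_family <- function(family, dir) {
  stopifnot(inherits(family, "simulated_family"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(family$alignment, file.path(dir, "alignment.fasta"))
  write_newick(family$tree, precision = 10, path = file.path(dir, "true_tree.nwk"))
  lab <- family$labeling
  rows <- unlist(lapply(names(lab), function(g) {
    if (length(lab[[g]])) paste(lab[[g]], g, sep = "\t") else character()
  }))
  writeLines(c("tip\tgroup", rows), file.path(dir, "labeling.tsv"))
  jsonlite::write_json(family$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
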