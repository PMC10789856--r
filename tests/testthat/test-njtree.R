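test_that("NJ solves the three-taxon case in closed form", {
  d <- matrix(c(0, .3, .5, .3, 0, .6, .5, .6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  n <- length(tr$tip.label)
  pend <- setNames(tr$edge.length[match(1:n, tr$edge[, 2])], tr$tip.label)
  expect_equal(pend[c("A", "B", "C")], c(A = 0.1, B = 0.2, C = 0.4))
})

test_that("NJ is consistent on additive matrices (oracle: true path sums)", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    true <- random_additive_tree(n)
    D <- ape::cophenetic.phylo(true)
    est <- neighbor_joining(D)
    expect_equal(ape::dist.topo(ape::unroot(true), ape::unroot(est)), 0,
                 ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(est)[rownames(D), colnames(D)], D,
                 tolerance = 1e-9)
  }
})

test_that("NJ refuses saturated cells and tiny matrices", {
  a <- alignment(c("a", "b"), c("ACGT", "ACGA"), "dna")
  dm <- distance_matrix(a, substitution_model("jc69"))
  expect_error(neighbor_joining(dm), ">= 3 taxa")
  sat <- alignment(c("a", "b", "c"),
                   c("ACGTACGTAC", "CATCTATGCA", "ACGTACGTAA"), "dna")
  dms <- distance_matrix(sat, substitution_model("jc69"))
  expect_error(neighbor_joining(dms), "saturated")
})

test_that("NJ output is deterministic under exact Q ties", {
  # ultrametric four-taxon matrix with two interchangeable cherries
  labs <- c("A", "B", "C", "D")
  D <- matrix(0.8, 4, 4, dimnames = list(labs, labs))
  D[1, 2] <- D[2, 1] <- 0.2
  D[3, 4] <- D[4, 3] <- 0.2
  diag(D) <- 0
  t1 <- write_newick(neighbor_joining(D), 10)
  t2 <- write_newick(neighbor_joining(D), 10)
  expect_identical(t1, t2)
  # permuting the input rows does not change the splits found
  perm <- c(3, 1, 4, 2)
  t3 <- neighbor_joining(D[perm, perm])
  expect_setequal(tree_splits(t3), tree_splits(neighbor_joining(D)))
})

test_that("total branch length is invariant under rooting", {
  fam <- simulate_family(preset_scenario("sturgeon_AOR", seed = 3,
                                         sequence_length = 200))
  dm <- distance_matrix(fam$alignment, fam$scenario$model)
  tr <- neighbor_joining(dm)
  rooted <- root_with_outgroup(tr, "OUT1")
  expect_equal(sum(rooted$edge.length), sum(tr$edge.length), tolerance = 1e-9)
})

test_that("root_with_outgroup splits the separating branch 50/50", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  r <- root_with_outgroup(tr, "C")
  n <- length(r$tip.label)
  root_kids <- r$edge[r$edge[, 1] == n + 1, 2]
  lens <- r$edge.length[match(root_kids, r$edge[, 2])]
  expect_equal(sort(lens), c(1, 1))                  # C's branch was length 2
  ingroup_child <- root_kids[[which(root_kids != match("C", r$tip.label))]]
  expect_equal(path_length(r, ingroup_child, "A"), 2.0)
  # any single tip is a valid outgroup; the full tip set is not
  expect_s3_class(root_with_outgroup(tr, "A"), "phylo")
  expect_error(root_with_outgroup(tr, c("A", "B", "C")), "proper subset")
})

test_that("non-monophyletic outgroups are refused with the conflicting tips", {
  tr <- read_newick("((A:1,C:1):1,(B:1,D:1):1);")
  err <- tryCatch(root_with_outgroup(tr, c("C", "D")), error = conditionMessage)
  expect_match(err, "not monophyletic")
  expect_match(err, "A|B")
})

test_that("mrca and path_length behave on rooted trees", {
  tr <- read_newick("((P1:1,P2:1)x:1,OG:2);")
  r <- root_with_outgroup(tr, "OG")
  p1 <- match("P1", r$tip.label)
  expect_equal(mrca(r, "P1"), p1)                    # single tip is its own mrca
  expect_equal(mrca(r, r$tip.label), length(r$tip.label) + 1L)  # all tips: root
  cherry <- mrca(r, c("P1", "P2"))
  expect_equal(sort(ohnotime:::node_descendant_tips(r)[[cherry]]), c("P1", "P2"))
  expect_equal(path_length(r, "P1", "P1"), 0)
  expect_equal(path_length(r, "P1", "P2"), 2)
  expect_error(path_length(r, "P1", "nope"), "unknown label")
})

test_that("tip triples satisfy the triangle inequality on random trees", {
  set.seed(11)
  for (rep in 1:3) {
    tr <- random_additive_tree(7)
    D <- ape::cophenetic.phylo(tr)
    tips <- rownames(D)
    combs <- combn(tips, 3)
    for (k in seq_len(ncol(combs))) {
      u <- combs[1, k]; v <- combs[2, k]; w <- combs[3, k]
      expect_lte(D[u, v], D[u, w] + D[w, v] + 1e-12)
    }
  }
})

test_that("bootstrap support is reproducible and bounded", {
  a <- alignment(c("a", "b", "c", "d"),
                 rep("ARNDCQEGHIKLMNPQRSTV", 4), "protein")
  bs1 <- bootstrap_support(a, substitution_model("poisson"), replicates = 25,
                           seed = 5)
  bs2 <- bootstrap_support(a, substitution_model("poisson"), replicates = 25,
                           seed = 5)
  expect_identical(bs1$splits, bs2$splits)
  expect_true(all(bs1$splits$support <= 1))
  expect_error(bootstrap_support(a, substitution_model("poisson"), 10),
               "seed")
})

test_that("a long internal branch earns high, seed-stable support", {
  fam <- simulate_family(preset_scenario("ancient_2R", seed = 21,
                                         n_species_per_clade = 2))
  mod <- substitution_model("poisson")
  bs <- bootstrap_support(fam$alignment, mod, replicates = 100, seed = 1)
  par_tips <- grep("_P", fam$alignment$ids, value = TRUE)
  expect_gte(split_support(bs, par_tips), 0.95)
  # binomial wobble between two seeds stays within 0.1 at 500 replicates
  bs_a <- bootstrap_support(fam$alignment, mod, replicates = 500, seed = 2)
  bs_b <- bootstrap_support(fam$alignment, mod, replicates = 500, seed = 3)
  expect_lt(abs(split_support(bs_a, par_tips) - split_support(bs_b, par_tips)),
            0.1)
})
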