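lab3 <- function() paralog_labeling("P1", "P2", "OG")

test_that("timing nodes are located; degenerate placements error", {
  r <- root_with_outgroup(read_newick("((P1:4,P2:4):1,OG:5);"), "OG")
  loc <- locate_timing_nodes(r, lab3())
  expect_false(loc$node_a == loc$node_b)
  expect_length(loc$warnings, 0)
  # duplication at the ingroup root leaves ab undefined
  r2 <- root_with_outgroup(read_newick("((P1:1,OG:1):1,P2:2);"), "OG")
  expect_error(locate_timing_nodes(r2, lab3()), "ab undefined")
})

test_that("multi-species paralogue clades put b on the duplication stem", {
  txt <- "(((s1_P1:1,s2_P1:1):1,(s1_P2:1,s2_P2:1):1):1,OG:4);"
  lab <- paralog_labeling(c("s1_P1", "s2_P1"), c("s1_P2", "s2_P2"), "OG")
  r <- root_with_outgroup(read_newick(txt), "OG")
  res <- compute_timing(r, lab)
  expect_equal(res$ab, 1)
  expect_equal(res$bc, 2)
  expect_equal(res$ratio, 2)
  expect_length(res$warnings, 0)
  # mixed clades trigger the non-monophyletic warning, not an error
  lab_swapped <- paralog_labeling(c("s1_P1", "s1_P2"), c("s2_P1", "s2_P2"), "OG")
  res2 <- compute_timing(r, lab_swapped)
  expect_match(res2$warnings, "not separately monophyletic", all = FALSE)
})

test_that("compute_timing reproduces the constructed examples", {
  res <- compute_timing(root_with_outgroup(
    read_newick("((P1:4.0,P2:4.0):1.0,OG:5.0);"), "OG"), lab3())
  expect_equal(res$ab, 1.0)
  expect_equal(res$bc, 4.0)
  expect_equal(res$ratio, 4.0)
  expect_equal(res$classification, "ancient")
  res2 <- compute_timing(root_with_outgroup(
    read_newick("((P1:0.3,P2:0.3):2.0,OG:2.3);"), "OG"), lab3())
  expect_equal(res2$ratio, 0.15)
  expect_equal(res2$classification, "recent")
})

test_that("classification thresholds partition the ratio axis", {
  expect_equal(classify_duplication(1.23), "ancient")
  expect_equal(classify_duplication(0.15), "recent")
  expect_equal(classify_duplication(0.75), "indeterminate")
  expect_equal(classify_duplication(1.0), "ancient")    # boundary inclusive
  expect_equal(classify_duplication(0.5), "recent")
  expect_error(classify_duplication(-1), "positive")
  expect_error(classify_duplication(Inf), "finite")
  custom <- timing_thresholds(ancient = 2, recent = 0.1)
  expect_equal(classify_duplication(1.23, custom), "indeterminate")
})

test_that("the ratio is scale invariant", {
  tr <- read_newick("((P1:4.0,P2:3.0):1.1,OG:5.0);")
  base <- compute_timing(root_with_outgroup(tr, "OG"), lab3())$ratio
  for (k in c(0.1, 10)) {
    scaled <- tr
    scaled$edge.length <- scaled$edge.length * k
    r <- compute_timing(root_with_outgroup(scaled, "OG"), lab3())$ratio
    expect_lt(abs(r - base), 1e-12)
  }
})

test_that("clock identity: ratio = B/(A-B) exactly on the true tree", {
  sc <- wgd_scenario(A = 2.0, B = 0.8, A_far = 2.5, n_species_per_clade = 2,
                     sequence_length = 10, seed = 1)
  tree <- build_true_tree(sc)
  lab <- paralog_labeling(grep("_P1$", tree$tip.label, value = TRUE),
                          grep("_P2$", tree$tip.label, value = TRUE),
                          "OUT1", "OUT2")
  res <- compute_timing(root_with_outgroup(tree, "OUT1"), lab)
  expect_equal(res$ab, 2.0 - 0.8, tolerance = 1e-12)
  expect_equal(res$bc, 0.8, tolerance = 1e-12)
  expect_equal(res$ratio, 0.8 / (2.0 - 0.8), tolerance = 1e-12)
})

test_that("moving the root along the outgroup stem changes nothing", {
  tr <- read_newick("((P1:4.0,P2:4.0):1.0,OG:5.0);")
  r <- root_with_outgroup(tr, "OG")
  base <- compute_timing(r, lab3())
  n <- length(r$tip.label)
  og_edge <- which(r$edge[, 2] == match("OG", r$tip.label))
  in_edge <- which(r$edge[, 1] == n + 1 & r$edge[, 2] != match("OG", r$tip.label))
  total <- r$edge.length[[og_edge]] + r$edge.length[[in_edge]]
  for (q in c(0.1, 0.9)) {
    shifted <- r
    shifted$edge.length[[og_edge]] <- total * q
    shifted$edge.length[[in_edge]] <- total * (1 - q)
    res <- compute_timing(shifted, lab3())
    expect_equal(res$ab, base$ab, tolerance = 1e-12)
    expect_equal(res$bc, base$bc, tolerance = 1e-12)
    expect_equal(res$ratio, base$ratio, tolerance = 1e-12)
  }
})

test_that("degenerate stems and topology-only trees are refused", {
  expect_warning(tr <- read_newick("((P1,P2),OG);"), "branch length")
  expect_error(compute_timing(root_with_outgroup(tr, "OG"), lab3()),
               "degenerate stem")
})

test_that("paralogue tips astray of node b are excluded with a warning", {
  # P1b was (wrongly) placed inside the outgroup clade of this rooted tree
  txt <- "((((P1a:1,P2a:1):1,P2b:2):1,X:3):1,(OG:1,P1b:1):3);"
  lab <- paralog_labeling(c("P1a", "P1b"), c("P2a", "P2b"), "OG", other = "X")
  res <- compute_timing(read_newick(txt), lab)
  expect_match(res$warnings, "excluded from bc", all = FALSE)
  expect_false("P1b" %in% names(res$bc_per_tip))
  expect_setequal(names(res$bc_per_tip), c("P1a", "P2a", "P2b"))
})

test_that("timing_report rows, classifications and concordance", {
  cases <- list(
    list(name = "anc", tree = read_newick("((P1:4.0,P2:4.0):1.0,OG:5.0);"),
         labeling = lab3(), molecule = "protein"),
    list(name = "rec", tree = read_newick("((P1:0.3,P2:0.3):2.0,OG:2.3);"),
         labeling = lab3(), molecule = "protein"))
  rep <- timing_report(cases)
  expect_equal(nrow(rep), 2)
  expect_equal(rep$classification, c("ancient", "recent"))
  expect_equal(rep$ratio, c(4.0, 0.15))
  expect_equal(nrow(timing_report(list())), 0)
  # errors are collected per case, not fatal
  bad <- list(list(name = "bad", tree = read_newick("((P1:1,OG:1):1,P2:2);"),
                   labeling = lab3()))
  rep2 <- timing_report(bad)
  expect_true(is.na(rep2$ratio))
  expect_match(rep2$note, "ab undefined")
})

test_that("two outgroups on a clock family give concordant estimates", {
  sc <- wgd_scenario(A = 1.8, B = 1.0, A_far = 2.1, n_species_per_clade = 2,
                     sequence_length = 10, seed = 2)
  tree <- build_true_tree(sc)
  lab <- paralog_labeling(grep("_P1$", tree$tip.label, value = TRUE),
                          grep("_P2$", tree$tip.label, value = TRUE),
                          "OUT1", "OUT2")
  rep <- timing_report(list(list(name = "clock", tree = tree, labeling = lab,
                                 outgroups = list("OUT1", "OUT2"))))
  expect_equal(nrow(rep), 2)
  expect_true(all(is.finite(rep$ratio)))
  expect_lte(rep$concordance[[1]], 1.5)
})
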