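test_that("pairwise deletion keeps exactly the shared unambiguous columns", {
  a <- alignment(c("a", "b"), c("M-KX", "MLK-"), "protein")
  expect_equal(pairwise_valid_columns(a, "a", "b"), c(1L, 3L))
  expect_equal(p_distance(a, "a", "b"), 0)              # both valid columns match
  b <- alignment(c("a", "b"), c("--", "AA"), "dna")
  expect_error(pairwise_valid_columns(b, "a", "b"), "uncomparable")
  full <- alignment(c("a", "b"), c("ACGT", "ACGA"), "dna")
  expect_equal(pairwise_valid_columns(full, "a", "b"), 1:4)
  expect_equal(p_distance(full, "a", "b"), 0.25)
})

test_that("distance corrections match their closed forms on a p grid", {
  p <- seq(0, 0.7, by = 0.05)
  expect_equal(correct_distance(p, "poisson"), -log(1 - p), tolerance = 1e-12)
  expect_equal(correct_distance(p, "gamma", alpha = 0.7),
               0.7 * ((1 - p)^(-1 / 0.7) - 1), tolerance = 1e-12)
  expect_equal(correct_distance(p, "kimura_protein"),
               -log(1 - p - 0.2 * p^2), tolerance = 1e-12)
  pj <- seq(0, 0.70, by = 0.05)
  expect_equal(correct_distance(pj, "jc69"), -0.75 * log(1 - 4 * pj / 3),
               tolerance = 1e-12)
  expect_equal(correct_distance(0.25, "poisson"), 0.287682, tolerance = 1e-6)
  expect_equal(correct_distance(0.25, "kimura_protein"), 0.304489,
               tolerance = 1e-6)
  # p = 0 maps to 0 for every method; corrections strictly increasing
  for (m in c("p", "poisson", "gamma", "kimura_protein", "jc69")) {
    expect_identical(correct_distance(0, m), 0)
    d <- correct_distance(p, m)
    expect_true(all(diff(d) > 0))
  }
  expect_equal(k2p_distance(0.1, 0.05),
               -0.5 * log(1 - 0.2 - 0.05) - 0.25 * log(1 - 0.1),
               tolerance = 1e-12)
  expect_identical(k2p_distance(0, 0), 0)
})

test_that("saturation yields NA, never a crash", {
  expect_true(is.na(correct_distance(0.8, "jc69")))
  expect_true(is.na(correct_distance(0.9, "kimura_protein")))
  expect_true(is.na(k2p_distance(0.48, 0.2)))
})

test_that("ML distance under the uniform model equals the JC20 inverse", {
  mod <- model_uniform(20)
  for (k in c(5, 30, 100, 250)) {
    a <- protein_pair_with_p(500, k)
    p <- k / 500
    jc20 <- -(19 / 20) * log(1 - 20 * p / 19)
    expect_equal(as.numeric(ml_distance_empirical(a, "s1", "s2", mod)), jc20,
                 tolerance = 1e-4)
  }
  ident <- alignment(c("x", "y"), c("ARNDCQ", "ARNDCQ"), "protein")
  expect_lte(as.numeric(ml_distance_empirical(ident, "x", "y", mod)), 1e-4)
})

test_that("ML distance agrees with phangorn's JTT distances", {
  fam <- simulate_family(preset_scenario("sturgeon_AOR", seed = 5,
                                         sequence_length = 300,
                                         model = model_jtt()))
  m <- do.call(rbind, strsplit(fam$alignment$seqs, ""))
  rownames(m) <- fam$alignment$ids
  oracle <- as.matrix(phangorn::dist.ml(phangorn::phyDat(m, type = "AA"),
                                        model = "JTT"))
  mine <- distance_matrix(fam$alignment, model_jtt())
  expect_equal(mine$values[rownames(oracle), colnames(oracle)], oracle,
               tolerance = 2e-3, ignore_attr = TRUE)
})

test_that("doubling a branch doubles the ML distance (L = 10000)", {
  mod <- model_uniform(20)
  t1 <- ape::read.tree(text = "(A:0.25,B:0.25);")
  t2 <- ape::read.tree(text = "(A:0.5,B:0.5);")
  d1 <- as.numeric(ml_distance_empirical(evolve_alignment(t1, mod, 10000, seed = 42),
                                         "A", "B", mod))
  d2 <- as.numeric(ml_distance_empirical(evolve_alignment(t2, mod, 10000, seed = 42),
                                         "A", "B", mod))
  expect_equal(d2 / d1, 2, tolerance = 0.05)
})

test_that("percent identity is the complement of p-distance", {
  a <- alignment(c("x", "y"), c("MKVRW-", "MKVRYX"), "protein")
  expect_equal(percent_identity(a, "x", "y"), 100 * (1 - p_distance(a, "x", "y")))
  expect_equal(percent_identity(a, "x", "y", region = c(1, 4)), 100)
  expect_equal(percent_identity(a, "x", "y", region = c(4, 5)), 50)
  expect_error(percent_identity(a, "x", "y", region = c(6, 6)), "no comparable")
  expect_error(percent_identity(a, "x", "y", region = c(0, 9)), "outside")
})

test_that("distance_matrix is symmetric, zero-diagonal, flags saturation", {
  a <- alignment(c("a", "b", "c"), c("ARND", "ARND", "ARND"), "protein")
  dm <- distance_matrix(a, substitution_model("poisson"))
  expect_true(all(dm$values == 0))
  expect_true(all(dm$flags == "ok"))
  two <- alignment(c("a", "b"), c("AAAA", "AAAT"), "dna")
  dm2 <- distance_matrix(two, substitution_model("jc69"))
  expect_equal(dm2$values["a", "b"], correct_distance(0.25, "jc69"))
  expect_equal(dm2$values, t(dm2$values))
  # a saturated DNA pair is flagged, not fatal
  sat <- alignment(c("a", "b"), c("ACGTACGTAC", "CATCTATGCA"), "dna")
  dm3 <- distance_matrix(sat, substitution_model("jc69"))
  expect_equal(dm3$flags["a", "b"], "saturated")
  expect_true(is.na(dm3$values["a", "b"]))
  # molecule/model mismatches are refused
  expect_error(distance_matrix(two, substitution_model("kimura_protein")),
               "protein")
  expect_error(distance_matrix(a, substitution_model("jc69")), "DNA")
})

test_that("matrix of a simulated family is close to the true path lengths", {
  sc <- wgd_scenario(A = 1.0, B = 0.5, A_far = 1.3, n_species_per_clade = 1,
                     sequence_length = 10000, model = model_uniform(20),
                     seed = 99)
  fam <- simulate_family(sc)
  truth <- ape::cophenetic.phylo(fam$tree)
  dm <- distance_matrix(fam$alignment, fam$scenario$model)
  td <- truth[dm$labels, dm$labels]
  # delta-method standard error of the JC20-inverted estimate
  se <- function(d) {
    p <- expected_p_jc20(d)
    sqrt(p * (1 - p) / 10000) / exp(-20 * d / 19)
  }
  for (i in 1:3) for (j in (i + 1):4) {
    expect_lt(abs(dm$values[i, j] - td[i, j]), 3 * se(td[i, j]))
  }
})

test_that("exported matrices carry the status column", {
  a <- alignment(c("a", "b", "c"), c("ARNDAR", "ARNDAA", "ARRDAR"), "protein")
  dm <- distance_matrix(a, substitution_model("poisson"))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(dm, tmp, "tsv")
  tab <- read.delim(tmp)
  expect_named(tab, c("a", "b", "distance", "status"))
  expect_equal(nrow(tab), 3)
  tmp2 <- withr::local_tempfile(fileext = ".phy")
  write_distance_matrix(dm, tmp2, "phylip")
  expect_equal(as.integer(trimws(readLines(tmp2)[[1]])), 3L)
})
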