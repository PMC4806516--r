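# likelihood engine: closed forms, exhaustive oracle, invariances, optimizer

test_that("two identical taxa at distance zero give lnL = log(1/4)", {
  aln <- two_taxon_aln("A", "A")
  jc <- substitution_model("111111")
  expect_equal(log_likelihood(two_taxon_tree(0, 0), aln, jc), log(1 / 4),
               tolerance = 1e-10)
})

test_that("two-taxon JC likelihood matches the pairwise closed form", {
  jc <- substitution_model("111111", alpha = 1)
  for (t in c(0.1, 0.6)) {
    tree <- two_taxon_tree(t / 2, t / 2)
    # one category = no rate heterogeneity
    expect_equal(log_likelihood(tree, two_taxon_aln("A", "A"), jc, ncat = 1),
                 oracle_jc_site(t, match = TRUE), tolerance = 1e-9)
    expect_equal(log_likelihood(tree, two_taxon_aln("A", "G"), jc, ncat = 1),
                 oracle_jc_site(t, match = FALSE), tolerance = 1e-9)
  }
  # huge alpha approaches the homogeneous limit with 4 categories
  jc_flat <- substitution_model("111111", alpha = 1e7)
  expect_equal(log_likelihood(two_taxon_tree(0.2, 0.2),
                              two_taxon_aln("A", "G"), jc_flat),
               oracle_jc_site(0.4, match = FALSE), tolerance = 1e-4)
})

test_that("pruning equals the exhaustive state-sum oracle (4 taxa, Gamma4)", {
  set.seed(5)
  tree <- read_newick("((a:0.12,b:0.31):0.08,c:0.45,d:0.2);")
  mat <- rbind(a = c("A", "C", "G"), b = c("A", "C", "T"),
               c = c("A", "G", "G"), d = c("A", "C", "G"))
  aln <- dna_alignment(mat)
  m <- substitution_model("123456", rates = c(1.2, 3.5, 0.6, 1.4, 4.8, 1),
                          freqs = c(.31, .19, .23, .27), alpha = 0.62)
  expect_equal(log_likelihood(tree, aln, m),
               oracle_loglik(tree, mat, as.numeric(m$rates),
                             as.numeric(m$freqs), m$alpha),
               tolerance = 1e-7)
})

test_that("lnL is invariant to virtual-root placement", {
  set.seed(8)
  tr <- random_tree(8, 0.15)
  m <- random_model("121321", seed = 3)
  aln <- simulate_alignment(simulation_spec(tr, m, 300, seed = 9))
  base <- log_likelihood(tr, aln, m)
  ntip <- 8L
  for (node in (ntip + 1L):(ntip + tr$Nnode)) {
    rerooted <- ape::root(tr, node = node, resolve.root = FALSE)
    expect_equal(log_likelihood(rerooted, aln, m), base, tolerance = 1e-8)
  }
})

test_that("site-pattern probabilities sum to one (4 and 5 taxa)", {
  for (ntaxa in 4:5) {
    set.seed(ntaxa)
    tr <- random_tree(ntaxa, 0.2)
    m <- random_model("123141", seed = ntaxa + 10)
    pats <- do.call(expand.grid,
                    rep(list(c("A", "C", "G", "T")), ntaxa))
    mat <- t(as.matrix(pats))
    rownames(mat) <- tr$tip.label
    aln <- dna_alignment(mat)
    # all patterns distinct: per-site likelihoods via per-pattern lnL
    arr <- gtrspace:::tree_arrays(tr)
    masks <- gtrspace:::masks_for_tree(arr$tree, aln)
    kern <- gtrspace:::kernel_from_model(m, 4L)
    site_l <- vapply(seq_len(ncol(masks)), function(j)
      exp(gtrspace:::.cpp_loglik(masks[, j, drop = FALSE], 1, arr$edge,
                                 arr$edge_length, arr$ntip, kern$U, kern$Uinv,
                                 kern$lambda, kern$pi, kern$crates)),
      numeric(1))
    expect_equal(sum(site_l), 1, tolerance = 1e-9)
  }
})

test_that("pattern compression and column order do not change lnL", {
  set.seed(21)
  tr <- random_tree(6, 0.1)
  m <- substitution_model("121121", rates = c(1, 3), alpha = 0.8)
  aln <- simulate_alignment(simulation_spec(tr, m, 400, seed = 2))
  # duplicate + shuffle columns: same multiset of sites twice
  mat2 <- aln$matrix[, c(sample(ncol(aln$matrix)), sample(ncol(aln$matrix)))]
  expect_equal(log_likelihood(tr, dna_alignment(mat2), m),
               2 * log_likelihood(tr, aln, m), tolerance = 1e-8)
})

test_that("ambiguity codes act as partial indicators", {
  jc <- substitution_model("111111")
  tree <- two_taxon_tree(0.1, 0.1)
  # N vs A: summing the closed form over the 4 states of the ambiguous tip
  lA <- exp(oracle_jc_site(0.2, TRUE))
  lO <- exp(oracle_jc_site(0.2, FALSE))
  expect_equal(log_likelihood(tree, two_taxon_aln("N", "A"), jc, ncat = 1),
               log(lA + 3 * lO), tolerance = 1e-9)
  # R = A or G
  expect_equal(log_likelihood(tree, two_taxon_aln("R", "A"), jc, ncat = 1),
               log(lA + lO), tolerance = 1e-9)
  # gap-only column: likelihood 1
  expect_equal(log_likelihood(tree, two_taxon_aln("-", "-"), jc, ncat = 1), 0,
               tolerance = 1e-9)
})

test_that("free-parameter count follows the convention", {
  expect_identical(count_free_params("123456", "ml_estimated", 10), 26L)
  expect_identical(count_free_params("123456", "empirical", 10), 23L)
  expect_identical(count_free_params("111111", "empirical", 10,
                                     include_branch_lengths = FALSE), 1L)
  expect_identical(count_free_params("121121", "fixed_equal", 4), 7L)
})

test_that("optimizer recovers JC lnL and parameters on simulated data", {
  set.seed(31)
  tr <- random_tree(6, 0.12)
  jc <- substitution_model("111111", alpha = 0.9)
  aln <- simulate_alignment(simulation_spec(tr, jc, 5000, seed = 13))
  truth <- log_likelihood(tr, aln, jc)
  fit <- optimize_on_fixed_tree(tr, aln, "111111", "fixed_equal")
  expect_true(fit$logLik >= truth - 1e-6)       # ML beats the true parameters
  # ... by about chi^2_p / 2 where p = 10 free parameters (9 branches +
  # alpha): mean 5, sd 2.24; 15 is a > 4-sigma bound
  expect_true(fit$logLik - truth < 15)
})

test_that("lnL is monotone in the optimization budget", {
  set.seed(33)
  tr <- random_tree(6, 0.12)
  m <- substitution_model("123456", rates = c(1.2, 3.5, 0.6, 1.4, 4.8, 1),
                          freqs = c(.31, .19, .23, .27), alpha = 0.62)
  aln <- simulate_alignment(simulation_spec(tr, m, 500, seed = 3))
  lnls <- vapply(1:4, function(k)
    suppressWarnings(
      optimize_on_fixed_tree(tr, aln, "123456", "empirical",
                             control = list(max_sweeps = k))$logLik),
    numeric(1))
  expect_true(all(diff(lnls) >= -1e-9))
})

test_that("GTR fit dominates nested fits on the same tree and data", {
  set.seed(35)
  tr <- random_tree(5, 0.15)
  m <- substitution_model("121121", rates = c(1, 3), alpha = 1)
  aln <- simulate_alignment(simulation_spec(tr, m, 300, seed = 8))
  gtr <- optimize_on_fixed_tree(tr, aln, "123456", "empirical")
  for (ms in c("111111", "121121", "123321", "112233")) {
    sub <- optimize_on_fixed_tree(tr, aln, ms, "empirical")
    expect_true(gtr$logLik >= sub$logLik - 1e-3,
                label = paste("GTR >=", ms))
  }
})

test_that("alpha is recovered within the stated band at 5000 sites", {
  set.seed(40)
  tr <- random_tree(10, 0.12)
  m <- substitution_model("111111", alpha = 0.5)
  aln <- simulate_alignment(simulation_spec(tr, m, 5000, seed = 77))
  fit <- optimize_on_fixed_tree(tr, aln, "111111", "fixed_equal")
  expect_gt(fit$model$alpha, 0.35)
  expect_lt(fit$model$alpha, 0.7)
})

test_that("newick io round-trips and collapses rooted input", {
  txt <- "((A:0.1,B:0.1):0.05,C:0.2,D:0.2);"
  tr <- read_newick(txt)
  expect_identical(write_newick(tr), txt)
  rooted <- read_newick("((A:0.1,B:0.1):0.05,(C:0.2,D:0.2):0.1);")
  expect_false(ape::is.rooted(rooted))
  expect_identical(ape::Ntip(rooted), 4L)
  f <- tempfile()
  write_newick(tr, f)
  expect_identical(write_newick(read_newick(path = f)), txt)
  expect_error(read_newick("((A:0.1,B:0.1"), "parse")
})
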