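# Robinson-Foulds distances and the significance procedure

test_that("identical trees are at distance zero", {
  set.seed(100)
  tr <- random_tree(8)
  expect_identical(rf_distance(tr, tr), 0L)
  expect_identical(relative_rf(tr, tr), 0)
})

test_that("5-taxon hand-enumerated bipartition difference", {
  # caterpillar ((a,b),c,(d,e)) has splits {ab|cde, de|abc};
  # swapping b and d gives splits {ad|bce, be|acd}: disjoint sets, RF = 4
  t1 <- read_newick("((a:1,b:1):1,c:1,(d:1,e:1):1);")
  t2 <- read_newick("((a:1,d:1):1,c:1,(b:1,e:1):1);")
  expect_identical(rf_distance(t1, t2), 4L)
  expect_equal(relative_rf(t1, t2), 1)          # 4 / (2 * (5 - 3))
  # sharing one cherry: RF = 2
  t3 <- read_newick("((a:1,b:1):1,e:1,(d:1,c:1):1);")
  expect_identical(rf_distance(t1, t3), 2L)
  expect_equal(relative_rf(t1, t3), 0.5)
})

test_that("rf_distance agrees with phangorn on 100 random 10-taxon pairs", {
  set.seed(101)
  for (i in 1:100) {
    t1 <- random_tree(10)
    t2 <- random_tree(10)
    expect_identical(rf_distance(t1, t2),
                     as.integer(phangorn::RF.dist(t1, t2)))
  }
})

test_that("rf_distance is a metric on random triples", {
  set.seed(102)
  for (i in 1:25) {
    trees <- lapply(1:3, function(j) random_tree(8))
    d12 <- rf_distance(trees[[1]], trees[[2]])
    d13 <- rf_distance(trees[[1]], trees[[3]])
    d23 <- rf_distance(trees[[2]], trees[[3]])
    expect_identical(d12, rf_distance(trees[[2]], trees[[1]]))
    expect_lte(d13, d12 + d23)
    if (d12 == 0)
      expect_identical(sort(bipartitions(trees[[1]])),
                       sort(bipartitions(trees[[2]])))
  }
})

test_that("rRF is invariant under consistent relabeling", {
  set.seed(103)
  t1 <- random_tree(9)
  t2 <- random_tree(9)
  d <- relative_rf(t1, t2)
  perm <- sample(t1$tip.label)
  relabel <- function(tr) {
    tr$tip.label <- perm[match(tr$tip.label, sort(tr$tip.label))]
    tr
  }
  # apply one fixed label permutation (keyed on sorted labels) to both trees
  expect_identical(relative_rf(relabel(t1), relabel(t2)), d)
  expect_error(rf_distance(t1, random_tree(9, labels = paste0("x", 1:9))),
               "leaf sets")
})

test_that("branch score matches a hand computation and detects itself", {
  t1 <- read_newick("((a:1,b:2):3,c:4,d:5);")
  expect_identical(branch_score(t1, t1), 0)
  t2 <- read_newick("((a:1,b:2):1,c:4,d:5);")
  expect_equal(branch_score(t1, t2), 2)          # only the ab|cd branch moved
  # different topology: the internal branches contribute fully
  t3 <- read_newick("((a:1,c:4):3,b:2,d:5);")
  expect_equal(branch_score(t1, t3), sqrt(3^2 + 3^2))
})

test_that("significance analysis: identical sets are indistinguishable", {
  tr <- read_newick("((a:1,b:1):1,c:1,(d:1,e:1):1);")
  res <- significance_analysis(rep(list(tr), 3), rep(list(tr), 3),
                               n_perm = 200, seed = 1)
  expect_identical(res$mean_cross_rrf, 0)
  expect_identical(res$random_expectation, 0)
  expect_identical(res$classification, "indistinguishable")
  expect_gte(res$p_value, 0.99)
  expect_error(significance_analysis(list(tr), list(tr, tr)), "at least 2")
})

test_that("significance analysis matches a hand-computed two-topology case", {
  ta <- read_newick("((a:1,b:1):1,c:1,(d:1,e:1):1);")
  tb <- read_newick("((a:1,d:1):1,c:1,(b:1,e:1):1);")  # rRF(ta, tb) = 1
  # GTR set alternates the two topologies; best-fit set is all ta
  gtr <- list(ta, tb, ta, tb)
  best <- list(ta, ta, ta)
  res <- significance_analysis(best, gtr, n_perm = 500, seed = 2)
  # cross pairs: 3 best x 4 gtr, the 2 tb's distance 1 each: 6/12
  expect_equal(res$mean_cross_rrf, 0.5)
  # within-gtr pairs: 4 of 6 pairs differ
  expect_equal(res$random_expectation, 4 / 6)
  expect_true(res$p_value > 0 && res$p_value <= 1)
})

test_that("permutation test is calibrated under the null", {
  # both sets drawn from the same two-topology pool: no systematic rejection
  ta <- read_newick("((a:1,b:1):1,c:1,(d:1,e:1):1);")
  tb <- read_newick("((a:1,d:1):1,c:1,(b:1,e:1):1);")
  set.seed(104)
  rejections <- 0L
  for (i in 1:30) {
    pick <- function(n) lapply(sample(c(TRUE, FALSE), n, replace = TRUE),
                               function(x) if (x) ta else tb)
    res <- significance_analysis(pick(5), pick(5), n_perm = 400,
                                 seed = 1000 + i)
    if (res$classification != "indistinguishable") rejections <- rejections + 1L
  }
  expect_lte(rejections, 3L)   # alpha = 0.01, 30 draws
})

test_that("rrf_matrix is symmetric with zero diagonal", {
  set.seed(105)
  trees <- lapply(1:4, function(i) random_tree(7))
  m <- rrf_matrix(trees, letters[1:4])
  expect_identical(m, t(m))
  expect_identical(diag(m), setNames(rep(0, 4), letters[1:4]))
  expect_identical(m["a", "b"], relative_rf(trees[[1]], trees[[2]]))
})
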