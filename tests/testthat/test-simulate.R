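# sequence simulator: degenerate cases, closed forms, determinism, pattern
# frequencies against the analytic pattern probabilities

test_that("zero-length branches copy the root draw to every taxon", {
  tr <- read_newick("((a:0,b:0):0,c:0,d:0);")
  m <- substitution_model("123456", rates = c(1.5, 3, .5, 1.2, 4, 1),
                          freqs = c(.3, .2, .25, .25), alpha = 0.5)
  aln <- simulate_alignment(simulation_spec(tr, m, 200, seed = 1))
  for (tx in aln$taxa[-1])
    expect_identical(aln$matrix[tx, ], unname(aln$matrix[aln$taxa[1], ]))
})

test_that("simulation is byte-identical given the seed", {
  set.seed(110)
  tr <- random_tree(6, 0.1)
  m <- substitution_model("121121", rates = c(1, 4), alpha = 0.7)
  a1 <- simulate_alignment(simulation_spec(tr, m, 500, seed = 42))
  a2 <- simulate_alignment(simulation_spec(tr, m, 500, seed = 42))
  a3 <- simulate_alignment(simulation_spec(tr, m, 500, seed = 43))
  expect_identical(a1$matrix, a2$matrix)
  expect_false(identical(a1$matrix, a3$matrix))
})

test_that("long star tree under JC drifts to uniform base composition", {
  # 4 tips at distance 8 from the center: essentially stationary draws
  tr <- read_newick("(a:8,b:8,c:8,d:8);")
  m <- substitution_model("111111", alpha = 10)
  n <- 1e5
  aln <- simulate_alignment(simulation_spec(tr, m, n, seed = 7))
  for (tx in aln$taxa) {
    p <- table(factor(aln$matrix[tx, ], levels = c("A", "C", "G", "T"))) / n
    sigma <- sqrt(0.25 * 0.75 / n)
    expect_true(all(abs(p - 0.25) < 3 * sigma + 1e-3))
  }
})

test_that("two-taxon JC mismatch proportion matches the closed form", {
  t_tot <- 0.5
  alpha <- 0.7
  tr <- two_taxon_tree(t_tot / 2, t_tot / 2)
  m <- substitution_model("111111", alpha = alpha)
  n <- 4e4
  aln <- simulate_alignment(simulation_spec(tr, m, n, seed = 11))
  obs <- mean(aln$matrix["a", ] != aln$matrix["b", ])
  rates <- gamma_category_rates(alpha, 4)
  expected <- mean(3 / 4 * (1 - exp(-4 * t_tot * rates / 3)))
  sigma <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(obs - expected), 4 * sigma)
})

test_that("pattern frequencies match analytic pattern probabilities (chi^2)", {
  set.seed(115)
  tr <- random_tree(4, 0.25)
  m <- substitution_model("121121", rates = c(1, 3),
                          freqs = c(.3, .2, .25, .25), alpha = 0.9)
  n <- 1e5
  aln <- simulate_alignment(simulation_spec(tr, m, n, seed = 116))
  # analytic probabilities of all 256 patterns from the likelihood engine
  pats <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), 4))
  patmat <- t(as.matrix(pats))
  rownames(patmat) <- tr$tip.label
  full <- dna_alignment(patmat)
  arr <- gtrspace:::tree_arrays(tr)
  masks <- gtrspace:::masks_for_tree(arr$tree, full)
  kern <- gtrspace:::kernel_from_model(m, 4L)
  probs <- vapply(seq_len(ncol(masks)), function(j)
    exp(gtrspace:::.cpp_loglik(masks[, j, drop = FALSE], 1, arr$edge,
                               arr$edge_length, arr$ntip, kern$U, kern$Uinv,
                               kern$lambda, kern$pi, kern$crates)),
    numeric(1))
  expect_equal(sum(probs), 1, tolerance = 1e-8)
  key <- apply(patmat, 2, paste, collapse = "")
  obs_key <- apply(aln$matrix[tr$tip.label, , drop = FALSE], 2, paste,
                   collapse = "")
  counts <- as.numeric(table(factor(obs_key, levels = key)))
  keep <- probs * n >= 5            # standard chi^2 validity pooling
  chi <- sum((counts[keep] - n * probs[keep])^2 / (n * probs[keep])) +
    (sum(counts[!keep]) - n * sum(probs[!keep]))^2 /
      max(n * sum(probs[!keep]), 1e-9)
  df <- sum(keep)                    # pooled cell adds one, minus one for n
  expect_lt(chi, qchisq(0.99, df))
})

test_that("recovery_experiment aggregates a perfect single replicate", {
  set.seed(120)
  tr <- random_tree(6, 0.15)
  m <- substitution_model("121121", rates = c(1, 4),
                          freqs = c(.3, .2, .2, .3), alpha = 1)
  rep1 <- suppressWarnings(recovery_experiment(
    tr, m, n_replicates = 1, n_sites = 2000, seeds = 7L,
    criteria = c("BIC-S"),
    models = c("111111", "121121", "123456"),
    search = TRUE,
    control = list(max_sweeps = 3L, tol = 1e-2)))
  expect_s3_class(rep1, "recovery_report")
  tab <- rep1$report
  expect_identical(tab$criterion, c("BIC-S", "GTR+G"))
  expect_true(all(tab$TTR %in% c(0, 1)))
  expect_identical(tab$TMR[tab$criterion == "GTR+G"], 0)
  expect_identical(rep1$failures, 0L)
  # if the truth was recovered the distances collapse to zero
  if (tab$TTR[1] == 1) {
    expect_identical(tab$RF[1], 0)
    expect_lt(tab$BS[1], 0.5)
  }
})
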