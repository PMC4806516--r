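# information criteria, mergeable result lists, the 203-model scan

test_that("sample_size implements the S and M definitions", {
  expect_identical(sample_size("S", 1000, 20), 1000)
  expect_identical(sample_size("M", 1000, 20), 20000)
  expect_identical(sample_size("M", 1, 1), 1)
  expect_error(sample_size("Q", 10, 2), "unknown")
  expect_error(sample_size("S", 0, 2), ">= 1")
})

test_that("criterion scores match hand evaluations", {
  expect_identical(criterion_score("AIC", lnL = 0, n_free = 0), 0)
  expect_identical(criterion_score("BIC", lnL = -100, n_free = 5,
                                   n_sample = 1), 200)
  expect_equal(criterion_score("AICc", lnL = -100, n_free = 5, n_sample = 100),
               210 + 60 / 94, tolerance = 1e-12)
  # AICc undefined when n <= k + 1
  expect_true(is.na(criterion_score("AICc", -10, 5, 6)))
  # spec objects work the same way
  sp <- criterion_specs(c("BIC-M"))[[1]]
  expect_equal(criterion_score(sp, -100, 5, sample_size("M", 10, 10)),
               5 * log(100) + 200)
})

test_that("criterion_specs exposes exactly the five variants", {
  specs <- criterion_specs()
  expect_identical(names(specs),
                   c("AIC", "AICc-S", "AICc-M", "BIC-S", "BIC-M"))
  expect_error(criterion_specs("DT"), "unknown")
})

test_that("AICc converges to AIC as the sample size grows", {
  aic <- criterion_score("AIC", -5000, 20)
  aicc <- criterion_score("AICc", -5000, 20, 1e9)
  expect_lt(abs(aicc - aic), 1e-6)
})

test_that("merge is an order-invariant monoid with lexicographic ties", {
  set.seed(90)
  models <- all_model_strings()
  scores <- setNames(round(runif(203, 100, 200), 1), models)
  # force a tie on the minimum between two models
  scores[c("123456", "111111")] <- 99
  singles <- lapply(models, function(ms) {
    update_result_list(new_result_list("BIC-S"),
                       ms, c("BIC-S" = unname(scores[ms])))
  })
  fold <- function(idx) Reduce(merge_results, singles[idx],
                               new_result_list("BIC-S"))
  ref <- fold(seq_along(singles))
  expect_identical(ref$entries[["BIC-S"]]$best_model, "111111")  # tie -> lex
  expect_identical(ref$entries[["BIC-S"]]$best_score, 99)
  for (i in 1:10)
    expect_identical(fold(sample(203))$entries, ref$entries)
  # identity, commutativity
  a <- singles[[5]]; b <- singles[[100]]
  expect_identical(merge_results(a, new_result_list("BIC-S"))$entries,
                   a$entries)
  expect_identical(merge_results(a, b)$entries, merge_results(b, a)$entries)
  expect_error(merge_results(a, new_result_list(c("AIC"))), "criterion sets")
})

test_that("the model scan is invariant to the worker count", {
  set.seed(95)
  tr <- random_tree(5, 0.15)
  m <- substitution_model("121121", rates = c(1, 3), alpha = 1,
                          freqs = c(.3, .2, .25, .25))
  aln <- simulate_alignment(simulation_spec(tr, m, 200, seed = 96))
  start <- parsimony_start_tree(aln, 1)
  models <- c("111111", "121121", "123456", "112233", "121321", "123321")
  e1 <- suppressWarnings(
    evaluate_all_models(aln, start, "empirical", workers = 1L,
                        models = models))
  e3 <- suppressWarnings(
    evaluate_all_models(aln, start, "empirical", workers = 3L,
                        models = models))
  expect_equal(e1$table, e3$table, tolerance = 1e-12)
  for (cn in names(e1$results$entries)) {
    expect_identical(e1$results$entries[[cn]]$best_model,
                     e3$results$entries[[cn]]$best_model)
    expect_equal(e1$results$entries[[cn]]$best_score,
                 e3$results$entries[[cn]]$best_score, tolerance = 1e-12)
  }
})

test_that("scan table satisfies the BIC-vs-AIC penalty ordering", {
  set.seed(97)
  tr <- random_tree(5, 0.15)
  m <- substitution_model("111111", alpha = 1)
  aln <- simulate_alignment(simulation_spec(tr, m, 300, seed = 98))
  start <- parsimony_start_tree(aln, 2)
  models <- c("111111", "121121", "112211", "123456")
  ev <- suppressWarnings(
    evaluate_all_models(aln, start, "empirical", models = models))
  tab <- ev$table
  # ln(n) > 2 here, so BIC penalizes extra parameters harder than AIC:
  # the BIC-S winner never has more free parameters than the AIC winner
  kw_aic <- tab$n_free[which.min(tab$AIC)]
  kw_bic <- tab$n_free[which.min(tab$`BIC-S`)]
  expect_lte(kw_bic, kw_aic)
  # and per-model, BIC-S - AIC grows with n_free
  gap <- tab$`BIC-S` - tab$AIC
  expect_true(all(diff(gap[order(tab$n_free)]) >= -1e-9))
})

test_that("undefined AICc excludes only the affected criterion", {
  # tiny alignment: n = 5 sites <= n_free + 1 for every model (n_free >= 6
  # with branch lengths counted) -> AICc-S undefined, AICc-M (n = 20) fine
  set.seed(99)
  tr <- random_tree(4, 0.2)
  m <- substitution_model("111111", alpha = 1)
  aln <- simulate_alignment(simulation_spec(tr, m, 5, seed = 99))
  start <- parsimony_start_tree(aln, 1)
  ev <- suppressWarnings(
    evaluate_all_models(aln, start, "empirical",
                        models = c("111111", "123456")))
  tab <- ev$table
  expect_true(all(is.na(tab$`AICc-S`)))
  expect_true(all(is.finite(tab$`BIC-S`)))
  expect_true(is.na(ev$results$entries[["AICc-S"]]$best_model))
  expect_false(is.na(ev$results$entries[["BIC-S"]]$best_model))
})
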