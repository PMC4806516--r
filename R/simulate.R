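#' Specification of a simulation
#'
#' @param tree generating `phylo` tree; branch lengths in expected
#'   substitutions per site.
#' @param model generating `substitution_model`.
#' @param n_sites number of sites (>= 1).
#' @param seed integer seed; together with the spec it fully determines the
#'   alignment.
#' @param ncat number of Gamma categories (default 4).
#' @return a `simulation_spec`.
#' @export
simulation_spec <- function(tree, model, n_sites, seed, ncat = 4L) {
  tree <- check_tree(tree)
  stopifnot(inherits(model, "substitution_model"))
  if (n_sites < 1L) stop("n_sites must be >= 1", call. = FALSE)
  structure(list(tree = tree, model = model, n_sites = as.integer(n_sites),
                 seed = as.integer(seed), ncat = as.integer(ncat)),
            class = "simulation_spec")
}

#' Simulate an alignment along a tree
#'
#' Root states are drawn from the stationary frequencies; each site is
#' assigned one of the discrete-Gamma category rates with equal probability
#' (drawn once and shared across the whole tree); states then evolve along
#' each branch by sampling from the corresponding transition-probability
#' rows. Gap-free, substitutions only. Byte-identical output for identical
#' spec and seed.
#'
#' @param spec a `simulation_spec`.
#' @return a `dna_alignment` over the tree's tip labels.
#' @export
simulate_alignment <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    arr <- tree_arrays(spec$tree)
    qm <- build_q(spec$model)
    crates <- gamma_category_rates(spec$model$alpha, spec$ncat)
    n <- spec$n_sites
    pi <- as.numeric(spec$model$freqs)

    cats <- sample.int(spec$ncat, n, replace = TRUE)
    nnode <- max(arr$edge)
    states <- matrix(0L, nnode, n)
    root <- setdiff(arr$edge[, 1L], arr$edge[, 2L])[1L]
    states[root, ] <- sample.int(4L, n, replace = TRUE, prob = pi)

    ## preorder: reverse postorder guarantees parents before children
    for (e in rev(seq_len(nrow(arr$edge)))) {
      p <- arr$edge[e, 1L]; ch <- arr$edge[e, 2L]
      t <- arr$edge_length[e]
      for (cat in seq_len(spec$ncat)) {
        pmat <- transition_probs(qm, t, crates[cat])
        in_cat <- cats == cat
        for (a in 1:4) {
          idx <- which(in_cat & states[p, ] == a)
          if (length(idx))
            states[ch, idx] <- sample.int(4L, length(idx), replace = TRUE,
                                          prob = pmat[a, ])
        }
      }
    }
    mat <- matrix(NUC[states[seq_len(arr$ntip), , drop = FALSE]],
                  nrow = arr$ntip)
    rownames(mat) <- arr$tip_label
    dna_alignment(mat)
  })
}

#' Model- and topology-recovery experiment
#'
#' Replicates the accuracy-under-simulation design: for each replicate an
#' alignment is simulated under the true tree and model, the full pipeline is
#' run (parsimony starting tree, scan of all 203 models, per-criterion
#' winners, an ML search per distinct winning model, plus a GTR+Gamma
#' baseline search), and the result is compared against the truth. Aggregates
#' per criterion (and for the GTR baseline): true-topology recovery rate
#' (TTR), mean rRF to the true tree, mean branch-score difference (BS), and
#' true-model recovery rate (TMR; 0 by construction for the baseline, which
#' never selects).
#'
#' @param true_tree generating `phylo` tree.
#' @param true_model generating `substitution_model`.
#' @param n_replicates number of simulation replicates.
#' @param n_sites sites per replicate.
#' @param seeds integer vector of per-replicate seeds (default derived from
#'   `1:n_replicates`).
#' @param freq_mode frequency handling for fits.
#' @param criteria criterion names to evaluate.
#' @param models model strings to scan (default all 203).
#' @param search run the ML tree searches (`TRUE`) or score winners on the
#'   parsimony tree only (`FALSE`, faster; TTR/rRF/BS then reflect the
#'   starting topology).
#' @param control optimizer control passed through.
#' @return a `recovery_report`: data.frame with one row per criterion plus
#'   the `GTR+G` baseline and columns TTR, RF, BS, TMR; per-replicate winner
#'   strings in `winners`; failed replicate count in `failures`.
#' @export
recovery_experiment <- function(true_tree, true_model,
                                n_replicates, n_sites,
                                seeds = NULL,
                                freq_mode = c("empirical", "ml_estimated",
                                              "fixed_equal"),
                                criteria = CRITERION_NAMES,
                                models = all_model_strings(),
                                search = TRUE,
                                control = list()) {
  freq_mode <- match.arg(freq_mode)
  stopifnot(n_replicates >= 1L)
  if (is.null(seeds)) seeds <- vapply(seq_len(n_replicates), derive_seed,
                                      integer(1), seed = 20160324L)
  stopifnot(length(seeds) == n_replicates)
  groups <- c(criteria, "GTR+G")
  acc <- stats::setNames(
    rep(list(list(ttr = 0, rrf = 0, bs = 0, tmr = 0, n = 0)), length(groups)),
    groups)
  winners <- matrix(NA_character_, n_replicates, length(criteria),
                    dimnames = list(NULL, criteria))
  failures <- 0L

  for (rep_i in seq_len(n_replicates)) {
    res <- tryCatch({
      spec <- simulation_spec(true_tree, true_model, n_sites, seeds[rep_i])
      aln <- simulate_alignment(spec)
      start <- parsimony_start_tree(aln, derive_seed(seeds[rep_i], 1L))
      ev <- evaluate_all_models(aln, start, freq_mode, criteria = criteria,
                                models = models, control = control)
      win <- vapply(criteria, function(cn)
        ev$results$entries[[cn]]$best_model, character(1))
      ## one search per distinct winning model, reused across criteria
      search_for <- function(ms) {
        if (search) ml_search(start, aln, ms, freq_mode, control)
        else optimize_on_fixed_tree(start, aln, ms, freq_mode, control)
      }
      distinct <- unique(c(win, "123456"))
      fits <- stats::setNames(lapply(distinct, search_for), distinct)
      list(win = win, fits = fits)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1L
      warning("replicate ", rep_i, " failed: ", conditionMessage(res),
              call. = FALSE)
      next
    }
    winners[rep_i, ] <- res$win
    for (g in groups) {
      ms <- if (g == "GTR+G") "123456" else res$win[[g]]
      fit <- res$fits[[ms]]
      rrf <- relative_rf(fit$tree, true_tree)
      a <- acc[[g]]
      a$n <- a$n + 1
      a$ttr <- a$ttr + (rrf == 0)
      a$rrf <- a$rrf + rrf
      a$bs <- a$bs + branch_score(fit$tree, true_tree)
      if (g != "GTR+G")
        a$tmr <- a$tmr + (ms == true_model$model_string)
      acc[[g]] <- a
    }
  }

  report <- do.call(rbind, lapply(groups, function(g) {
    a <- acc[[g]]
    n <- max(a$n, 1)
    data.frame(criterion = g, TTR = a$ttr / n, RF = a$rrf / n,
               BS = a$bs / n, TMR = if (g == "GTR+G") 0 else a$tmr / n)
  }))
  structure(list(report = report, winners = winners, failures = failures,
                 true_model = true_model$model_string),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Recovery experiment (true model ", x$true_model, ", ",
      nrow(x$winners), " replicates, ", x$failures, " failures):\n", sep = "")
  print(x$report, row.names = FALSE, digits = 3)
  invisible(x)
}
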