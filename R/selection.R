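CRITERION_NAMES <- c("AIC", "AICc-S", "AICc-M", "BIC-S", "BIC-M")

#' The five information-criterion variants
#'
#' AIC has no sample-size notion; AICc and BIC each come in two flavours
#' differing in how the sample size n is defined: `S` uses the number of
#' alignment sites, `M` the number of sites times the number of taxa.
#'
#' @param names subset of `"AIC"`, `"AICc-S"`, `"AICc-M"`, `"BIC-S"`,
#'   `"BIC-M"` (default: all five).
#' @return named list of specs with fields `family` and `sample_size_mode`.
#' @export
criterion_specs <- function(names = CRITERION_NAMES) {
  bad <- setdiff(names, CRITERION_NAMES)
  if (length(bad))
    stop("unknown criteria: ", paste(bad, collapse = ", "), call. = FALSE)
  specs <- list(
    "AIC"    = list(family = "AIC",  sample_size_mode = NA_character_),
    "AICc-S" = list(family = "AICc", sample_size_mode = "S"),
    "AICc-M" = list(family = "AICc", sample_size_mode = "M"),
    "BIC-S"  = list(family = "BIC",  sample_size_mode = "S"),
    "BIC-M"  = list(family = "BIC",  sample_size_mode = "M"))
  specs[names]
}

#' Sample size under the S / M definitions
#'
#' @param mode `"S"` (#sites) or `"M"` (#sites x #taxa).
#' @param sites number of alignment sites.
#' @param taxa number of taxa.
#' @return integer-valued sample size.
#' @export
sample_size <- function(mode, sites, taxa) {
  if (sites < 1 || taxa < 1) stop("sites and taxa must be >= 1", call. = FALSE)
  switch(mode,
         S = sites,
         M = sites * taxa,
         stop("unknown sample size mode '", mode, "'", call. = FALSE))
}

#' Information-criterion score
#'
#' AIC = 2k - 2 lnL; AICc = AIC + 2k(k+1)/(n-k-1); BIC = k ln(n) - 2 lnL,
#' with k the number of free parameters and n the sample size. Lower is
#' better. AICc is undefined when n <= k+1; `NA` is returned and the model is
#' excluded from that criterion's minimization.
#'
#' @param spec a single spec from [criterion_specs()], or a family name
#'   (`"AIC"`, `"AICc"`, `"BIC"`).
#' @param lnL maximized log-likelihood.
#' @param n_free free-parameter count.
#' @param n_sample sample size (ignored by AIC).
#' @return numeric score (`NA_real_` where undefined).
#' @export
criterion_score <- function(spec, lnL, n_free, n_sample = NA) {
  family <- if (is.list(spec)) spec$family else spec
  switch(family,
         AIC = 2 * n_free - 2 * lnL,
         AICc = {
           if (is.na(n_sample) || n_sample - n_free - 1 <= 0) {
             NA_real_
           } else {
             2 * n_free - 2 * lnL +
               2 * n_free * (n_free + 1) / (n_sample - n_free - 1)
           }
         },
         BIC = n_free * log(n_sample) - 2 * lnL,
         stop("unknown criterion family '", family, "'", call. = FALSE))
}

#' Empty per-criterion best-result list
#'
#' A `result_list` keeps, per criterion, the minimum score seen so far
#' together with the model that achieved it. It is the mergeable accumulator
#' that makes the model scan order- and partition-invariant.
#'
#' @param criteria character vector of criterion names.
#' @return a `result_list`.
#' @export
new_result_list <- function(criteria = CRITERION_NAMES) {
  entries <- stats::setNames(
    lapply(criteria, function(cn)
      list(best_score = Inf, best_model = NA_character_, fit = NULL)),
    criteria)
  structure(list(entries = entries), class = "result_list")
}

#' Update a result list with one model's scores
#'
#' @param rl a `result_list`.
#' @param model_string model string.
#' @param scores named numeric vector of criterion scores (NA = undefined,
#'   skipped).
#' @param fit optional `model_fit` stored with a new minimum.
#' @return the updated `result_list`.
#' @export
update_result_list <- function(rl, model_string, scores, fit = NULL) {
  stopifnot(inherits(rl, "result_list"))
  for (cn in names(rl$entries)) {
    sc <- scores[[cn]]
    if (is.null(sc) || is.na(sc)) next
    e <- rl$entries[[cn]]
    if (sc < e$best_score ||
        (sc == e$best_score && !is.na(e$best_model) &&
         model_string < e$best_model)) {
      rl$entries[[cn]] <- list(best_score = sc, best_model = model_string,
                               fit = fit)
    }
  }
  rl
}

#' Merge two result lists by per-criterion minimum
#'
#' Associative and commutative, with ties broken toward the lexicographically
#' smaller model string, so any fold order (and any worker partition) yields
#' the same global result. The empty list from [new_result_list()] is the
#' identity element.
#'
#' @param a,b `result_list` objects over the same criterion set.
#' @return the merged `result_list`.
#' @export
merge_results <- function(a, b) {
  stopifnot(inherits(a, "result_list"), inherits(b, "result_list"))
  if (!identical(names(a$entries), names(b$entries)))
    stop("cannot merge result lists over different criterion sets",
         call. = FALSE)
  out <- a
  for (cn in names(a$entries)) {
    ea <- a$entries[[cn]]; eb <- b$entries[[cn]]
    pick <- if (eb$best_score < ea$best_score) eb
            else if (ea$best_score < eb$best_score) ea
            else if (!is.na(eb$best_model) && !is.na(ea$best_model) &&
                     eb$best_model < ea$best_model) eb
            else ea
    out$entries[[cn]] <- pick
  }
  out
}

#' @export
print.result_list <- function(x, ...) {
  cat("Best models per criterion:\n")
  for (cn in names(x$entries)) {
    e <- x$entries[[cn]]
    cat(sprintf("  %-7s %s  score = %s\n", cn,
                ifelse(is.na(e$best_model), "<none>", e$best_model),
                format(e$best_score, digits = 10)))
  }
  invisible(x)
}

#' Score all 203 models on a fixed tree
#'
#' Runs [optimize_on_fixed_tree()] for every model string, computes the five
#' criterion scores from each fit, and reduces them through the mergeable
#' minimum contract. The scan is split into `workers` chunks whose local
#' result lists are merged at the end, so the outcome is identical for any
#' worker count; with `workers > 1` on a Unix host the chunks run in forked
#' processes.
#'
#' @param aln a `dna_alignment`.
#' @param tree the fixed topology (typically a parsimony starting tree).
#' @param freq_mode frequency handling, as in [optimize_on_fixed_tree()].
#' @param workers number of chunks / parallel workers (>= 1).
#' @param criteria criterion names to track.
#' @param models model strings to scan (default: all 203).
#' @param control optimizer control passed through.
#' @return list with `results` (the global `result_list`) and `table` (a
#'   data.frame with one row per model: model, k, n_free, lnL and all
#'   criterion scores).
#' @export
evaluate_all_models <- function(aln, tree,
                                freq_mode = c("empirical", "ml_estimated",
                                              "fixed_equal"),
                                workers = 1L,
                                criteria = CRITERION_NAMES,
                                models = all_model_strings(),
                                control = list()) {
  freq_mode <- match.arg(freq_mode)
  stopifnot(workers >= 1L)
  specs <- criterion_specs(criteria)
  sites <- aln$n_sites
  taxa <- length(aln$taxa)

  ## warm start everything from a single GTR fit: rates of a tied class start
  ## at the mean of the GTR rates it pools. The anchor fit always runs at the
  ## full default convergence settings (any caps in `control` apply to the
  ## 202 warm-started fits only): every nested parameterization is also a GTR
  ## parameterization, so a converged anchor bounds all other fits.
  gtr_control <- control
  gtr_control$max_sweeps <- NULL
  gtr_control$tol <- NULL
  gtr_fit <- optimize_on_fixed_tree(tree, aln, "123456", freq_mode,
                                    gtr_control)
  gtr_rates <- gtr_fit$model$rates

  fit_one <- function(ms) {
    if (ms == "123456") {
      fit <- gtr_fit
    } else {
      d <- model_digits(ms)
      init <- vapply(sort(unique(d)),
                     function(cl) mean(gtr_rates[d == cl]), numeric(1))
      ctl <- control
      ctl$init_rates <- init
      ctl$init_alpha <- gtr_fit$model$alpha
      ctl$init_freqs <- as.numeric(gtr_fit$model$freqs)
      fit <- optimize_on_fixed_tree(gtr_fit$tree, aln, ms, freq_mode, ctl)
    }
    scores <- vapply(specs, function(sp) {
      n <- if (is.na(sp$sample_size_mode)) NA
           else sample_size(sp$sample_size_mode, sites, taxa)
      criterion_score(sp, fit$logLik, fit$n_free, n)
    }, numeric(1))
    list(model = ms, fit = fit, scores = scores)
  }

  chunks <- split(models, rep_len(seq_len(workers), length(models)))
  eval_chunk <- function(chunk) {
    rl <- new_result_list(criteria)
    rows <- vector("list", length(chunk))
    for (i in seq_along(chunk)) {
      r <- fit_one(chunk[[i]])
      rl <- update_result_list(rl, r$model, r$scores, r$fit)
      rows[[i]] <- data.frame(model = r$model, k = k_of(r$model),
                              n_free = r$fit$n_free, lnL = r$fit$logLik,
                              as.list(stats::setNames(r$scores, criteria)),
                              check.names = FALSE)
    }
    list(rl = rl, rows = do.call(rbind, rows))
  }

  locals <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(chunks, eval_chunk, mc.cores = workers)
  } else {
    lapply(chunks, eval_chunk)
  }
  failed <- vapply(locals, inherits, logical(1), "try-error")
  if (any(failed)) stop("model evaluation failed in a worker chunk",
                        call. = FALSE)

  global <- Reduce(merge_results, lapply(locals, `[[`, "rl"),
                   new_result_list(criteria))
  tab <- do.call(rbind, lapply(locals, `[[`, "rows"))
  tab <- tab[order(tab$k, tab$model), , drop = FALSE]
  rownames(tab) <- NULL
  list(results = global, table = tab)
}

#' Write the per-model score table as TSV
#'
#' @param table the `table` component of [evaluate_all_models()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
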