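## eigendecomposed kernel inputs for the C++ pruning functions
model_kernel <- function(freqs, class_rates, digits, alpha, ncat = 4L) {
  rates6 <- class_rates[match(digits, as.integer(names(class_rates)))]
  q <- matrix(0, 4, 4)
  for (m in seq_len(6)) {
    i <- RATE_PAIRS[m, 1L]; j <- RATE_PAIRS[m, 2L]
    q[i, j] <- rates6[m] * freqs[j]
    q[j, i] <- rates6[m] * freqs[i]
  }
  diag(q) <- -rowSums(q)
  scale <- -sum(freqs * diag(q))
  q <- q / scale
  sp <- sqrt(freqs)
  b <- (q * rep(sp, times = 4)) / rep(sp, each = 4)
  eig <- eigen((b + t(b)) / 2, symmetric = TRUE)
  list(U = eig$vectors / sp,
       Uinv = t(eig$vectors) * rep(sp, each = 4),
       lambda = eig$values,
       pi = as.numeric(freqs),
       crates = gamma_category_rates(alpha, ncat))
}

kernel_from_model <- function(model, ncat = 4L) {
  d <- model_digits(model$model_string)
  model_kernel(as.numeric(model$freqs), model$class_rates, d, model$alpha, ncat)
}

#' Phylogenetic log-likelihood under a Gamma-mixture model
#'
#' Felsenstein pruning over compressed site patterns: the site likelihood is
#' the equal-weight average over the discrete-Gamma category likelihoods, and
#' the alignment lnL is the multiplicity-weighted sum of pattern log
#' likelihoods. Because the model is time-reversible the result does not
#' depend on where the virtual root sits. IUPAC ambiguity codes (and gaps, as
#' full ambiguity) enter as indicator vectors at the tips; per-node rescaling
#' guards against underflow on deep trees.
#'
#' @param tree a `phylo` tree whose tip labels match the alignment taxa.
#' @param aln a `dna_alignment`.
#' @param model a `substitution_model`.
#' @param ncat number of Gamma categories (default 4).
#' @return the log-likelihood (a single numeric value).
#' @export
log_likelihood <- function(tree, aln, model, ncat = 4L) {
  stopifnot(inherits(aln, "dna_alignment"), inherits(model, "substitution_model"))
  arr <- tree_arrays(tree)
  masks <- masks_for_tree(arr$tree, aln)
  kern <- kernel_from_model(model, ncat)
  .cpp_loglik(masks, aln$weights, arr$edge, arr$edge_length, arr$ntip,
              kern$U, kern$Uinv, kern$lambda, kern$pi, kern$crates)
}

#' Free-parameter count of a fitted model
#'
#' k-1 free exchangeability rates for a k-model, plus 3 frequency parameters
#' when frequencies are ML-estimated (0 when empirical or fixed), plus 1 for
#' the Gamma shape, plus the 2T-3 branch lengths when
#' `include_branch_lengths` is `TRUE` (the default; both conventions for the
#' "degrees of freedom" entering the information criteria are supported).
#'
#' @param model_string six-digit model string.
#' @param freq_mode frequency handling mode.
#' @param n_taxa number of taxa T.
#' @param include_branch_lengths count the 2T-3 branch lengths?
#' @return integer.
#' @export
count_free_params <- function(model_string,
                              freq_mode = c("empirical", "ml_estimated",
                                            "fixed_equal"),
                              n_taxa,
                              include_branch_lengths = TRUE) {
  freq_mode <- match.arg(freq_mode)
  k <- k_of(model_string)
  as.integer((k - 1L) + (if (freq_mode == "ml_estimated") 3L else 0L) + 1L +
               (if (include_branch_lengths) 2L * n_taxa - 3L else 0L))
}

default_fit_control <- function(control = list()) {
  def <- list(tol = 1e-4, max_sweeps = 25L, branch_sweeps = 10L,
              min_bl = 1e-8, max_bl = 6, ncat = 4L, brent_tol = 1e-4,
              nm_maxit = 400L, nm_reltol = 1e-7,
              init_alpha = 1.0, init_rates = NULL, init_freqs = NULL,
              include_branch_lengths = TRUE)
  def[names(control)] <- control
  def
}

#' Optimize all model parameters on a fixed topology
#'
#' Coordinate ascent: branch lengths by Brent's method per branch (on cached
#' directional partials in the compiled kernel), then exchangeability rates,
#' the Gamma shape, and (when `freq_mode = "ml_estimated"`) the base
#' frequencies jointly by Nelder-Mead on log/softmax-transformed parameters.
#' Rounds repeat until the lnL gain falls below `control$tol` (default 1e-4)
#' or `control$max_sweeps` (default 25) is hit, in which case the best-so-far
#' fit is returned with a warning. lnL is non-decreasing across rounds.
#'
#' @param tree fixed topology (`phylo`); its branch lengths are the starting
#'   point.
#' @param aln a `dna_alignment`.
#' @param model_string one of the 203 normalized model strings.
#' @param freq_mode `"empirical"` (counted from the data), `"ml_estimated"`,
#'   or `"fixed_equal"`.
#' @param control list overriding `tol`, `max_sweeps`, `branch_sweeps`,
#'   `min_bl`, `max_bl`, `ncat`, `nm_maxit`, `nm_reltol`, `init_alpha`,
#'   `init_rates` (per-class), `init_freqs`, `include_branch_lengths`.
#' @return a `model_fit`: fitted `substitution_model`, tree with optimized
#'   branch lengths, `logLik`, `n_free`, rounds used and convergence flag.
#' @export
optimize_on_fixed_tree <- function(tree, aln, model_string,
                                   freq_mode = c("empirical", "ml_estimated",
                                                 "fixed_equal"),
                                   control = list()) {
  freq_mode <- match.arg(freq_mode)
  if (!is_normalized(normalize_model(model_string)) ||
      model_string != normalize_model(model_string))
    stop("model_string must be normalized; got '", model_string, "'",
         call. = FALSE)
  ctl <- default_fit_control(control)
  arr <- tree_arrays(tree)
  masks <- masks_for_tree(arr$tree, aln)
  w <- aln$weights
  d <- model_digits(model_string)
  classes <- sort(unique(d))
  k <- length(classes)
  gt_class <- d[6L]
  free_classes <- setdiff(classes, gt_class)

  freqs <- switch(freq_mode,
                  empirical = as.numeric(empirical_frequencies(aln)),
                  ml_estimated = if (is.null(ctl$init_freqs))
                    as.numeric(empirical_frequencies(aln))
                  else as.numeric(ctl$init_freqs),
                  fixed_equal = rep(0.25, 4))
  class_rates <- stats::setNames(rep(1, k), classes)
  if (!is.null(ctl$init_rates)) {
    ir <- rep_len(as.numeric(ctl$init_rates), k)
    class_rates[] <- ir / ir[match(gt_class, classes)]
  }
  alpha <- ctl$init_alpha
  edge_len <- pmin(pmax(arr$edge_length, ctl$min_bl), ctl$max_bl)

  lnl_at <- function(cr, a, fr, el) {
    kern <- model_kernel(fr, cr, d, a, ctl$ncat)
    .cpp_loglik(masks, w, arr$edge, el, arr$ntip,
                kern$U, kern$Uinv, kern$lambda, kern$pi, kern$crates)
  }

  opt_params <- function(cr, a, fr, el) {
    ml_freqs <- freq_mode == "ml_estimated"
    par <- c(log(cr[as.character(free_classes)]), log(a),
             if (ml_freqs) log(fr[1:3] / fr[4]))
    unpack <- function(p) {
      nf <- length(free_classes)
      cr2 <- class_rates
      cr2[as.character(free_classes)] <- exp(pmin(pmax(p[seq_len(nf)], -12), 12))
      cr2[as.character(gt_class)] <- 1
      a2 <- exp(pmin(pmax(p[nf + 1L], -7), 9))
      fr2 <- fr
      if (ml_freqs) {
        e <- exp(pmin(pmax(p[(nf + 2L):(nf + 4L)], -20), 20))
        fr2 <- c(e, 1) / (sum(e) + 1)
      }
      list(cr = cr2, a = a2, fr = fr2)
    }
    neg <- function(p) {
      u <- unpack(p)
      -lnl_at(u$cr, u$a, u$fr, el)
    }
    if (length(par) == 1L) {
      o <- stats::optimize(function(x) neg(x), interval = c(-7, 9), tol = 1e-6)
      u <- unpack(o$minimum)
      c(u, list(lnl = -o$objective))
    } else {
      o <- stats::optim(par, neg, method = "Nelder-Mead",
                        control = list(maxit = ctl$nm_maxit,
                                       reltol = ctl$nm_reltol))
      u <- unpack(o$par)
      c(u, list(lnl = -o$value))
    }
  }

  cur <- lnl_at(class_rates, alpha, freqs, edge_len)
  converged <- FALSE
  rounds <- 0L
  for (it in seq_len(ctl$max_sweeps)) {
    rounds <- it
    round_start <- cur
    kern <- model_kernel(freqs, class_rates, d, alpha, ctl$ncat)
    bl <- .cpp_optimize_branches(masks, w, arr$edge, edge_len, arr$ntip,
                                 kern$U, kern$Uinv, kern$lambda, kern$pi,
                                 kern$crates, ctl$branch_sweeps,
                                 ctl$tol / 10, ctl$min_bl, ctl$max_bl,
                                 ctl$brent_tol)
    if (bl$loglik >= cur) {
      edge_len <- bl$edge_length
      cur <- bl$loglik
    }
    op <- opt_params(class_rates, alpha, freqs, edge_len)
    if (op$lnl >= cur) {
      class_rates <- op$cr; alpha <- op$a; freqs <- op$fr
      cur <- op$lnl
    }
    if (it > 1L && cur - round_start < ctl$tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("optimize_on_fixed_tree: no convergence for ", model_string,
            " after ", ctl$max_sweeps, " rounds; returning best-so-far",
            call. = FALSE)

  fitted_tree <- arr$tree
  fitted_tree$edge.length <- edge_len
  model <- substitution_model(model_string, rates = as.numeric(class_rates),
                              freqs = freqs, alpha = alpha,
                              freq_mode = freq_mode)
  structure(
    list(model = model, tree = fitted_tree, logLik = cur,
         n_free = count_free_params(model_string, freq_mode, arr$ntip,
                                    ctl$include_branch_lengths),
         rounds = rounds, converged = converged),
    class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("ML fit of model", x$model$model_string,
      sprintf("(freqs: %s)\n", x$model$freq_mode))
  cat("  lnL =", format(x$logLik, digits = 10),
      "  free parameters =", x$n_free,
      "  rounds =", x$rounds,
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  invisible(x)
}
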