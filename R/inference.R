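#' Fitch parsimony score
#'
#' Minimum number of state changes over the tree, summed over site patterns
#' weighted by multiplicity. Ambiguity codes contribute their full state set.
#'
#' @param tree a `phylo` tree over the alignment taxa.
#' @param aln a `dna_alignment`.
#' @return numeric parsimony score.
#' @export
fitch_score <- function(tree, aln) {
  stopifnot(inherits(aln, "dna_alignment"))
  arr <- tree_arrays(tree)
  masks <- masks_for_tree(arr$tree, aln)
  .cpp_fitch(masks, aln$weights, arr$edge, arr$ntip)
}

## minimal 3-taxon unrooted tree (the unique topology)
star3 <- function(labels, bl = 0.1) {
  out <- list(edge = cbind(4L, 1:3),
              edge.length = rep(bl, 3),
              tip.label = labels,
              Nnode = 1L)
  class(out) <- "phylo"
  out
}

#' Randomized stepwise-addition parsimony starting tree
#'
#' Taxa are inserted in a seed-shuffled order; each new taxon is attached to
#' the branch where the Fitch parsimony score of the extended tree is minimal
#' (first-best on ties, in the postorder edge order). Branch lengths are set
#' to a fixed default of 0.1. Deterministic given the seed.
#'
#' @param aln a `dna_alignment` with at least 3 taxa.
#' @param seed integer seed controlling the addition order.
#' @param default_bl default branch length of the returned tree.
#' @return an unrooted `phylo` tree.
#' @export
parsimony_start_tree <- function(aln, seed, default_bl = 0.1) {
  stopifnot(inherits(aln, "dna_alignment"))
  n <- length(aln$taxa)
  if (n < 3L) stop("stepwise addition needs at least 3 taxa", call. = FALSE)
  ord <- with_seed(seed, sample.int(n))
  labels <- aln$taxa[ord]
  tree <- star3(labels[1:3], default_bl)
  if (n > 3L) {
    for (i in 4:n) {
      sub <- sub_alignment(aln, c(labels[1:(i - 1L)], labels[i]))
      best <- NULL
      best_score <- Inf
      po <- ape::reorder.phylo(tree, "postorder")
      for (e in seq_len(nrow(po$edge))) {
        cand <- insert_tip(po, labels[i], e, tip_length = default_bl)
        sc <- fitch_score(cand, sub)
        if (sc < best_score) {
          best_score <- sc
          best <- cand
        }
      }
      tree <- best
    }
  }
  tree$edge.length <- rep(default_bl, nrow(tree$edge))
  tree
}

## restriction of an alignment to a taxon subset (keeps column order)
sub_alignment <- function(aln, taxa) {
  if (setequal(taxa, aln$taxa)) {
    return(aln)
  }
  dna_alignment(aln$matrix[taxa, , drop = FALSE])
}

#' Maximum-likelihood tree search by NNI hill climbing
#'
#' Starting from `start`, all nearest-neighbour-interchange rearrangements are
#' evaluated with branch-length re-optimization; the best improving neighbor
#' is accepted and all model parameters are re-optimized on it. The search
#' terminates when no neighbor improves the lnL by more than `tol`, returning
#' a tree that is locally optimal in the NNI neighborhood, with lnL at least
#' that of the start tree. Ties and traversal order are deterministic.
#'
#' @param start starting `phylo` tree.
#' @param aln a `dna_alignment`.
#' @param model_string one of the 203 normalized model strings.
#' @param freq_mode frequency handling, as in [optimize_on_fixed_tree()].
#' @param control optimizer control; additionally `max_rounds` (default 30)
#'   caps the number of accepted moves and `nni_tol` (default 1e-3) is the
#'   acceptance threshold.
#' @return a `model_fit` on the final topology.
#' @export
ml_search <- function(start, aln, model_string,
                      freq_mode = c("empirical", "ml_estimated", "fixed_equal"),
                      control = list()) {
  freq_mode <- match.arg(freq_mode)
  ctl <- default_fit_control(control)
  max_rounds <- if (is.null(control$max_rounds)) 30L else control$max_rounds
  nni_tol <- if (is.null(control$nni_tol)) 1e-3 else control$nni_tol

  fit <- optimize_on_fixed_tree(start, aln, model_string, freq_mode, control)
  warm <- function(f) {
    c(control, list(init_alpha = f$model$alpha,
                    init_rates = as.numeric(f$model$class_rates),
                    init_freqs = as.numeric(f$model$freqs)))
  }

  ## score a candidate topology: fixed params, branch-length re-optimization
  score_neighbor <- function(cand, f) {
    arr <- tree_arrays(cand)
    masks <- masks_for_tree(arr$tree, aln)
    kern <- kernel_from_model(f$model, ctl$ncat)
    bl <- .cpp_optimize_branches(masks, aln$weights, arr$edge,
                                 pmin(pmax(arr$edge_length, ctl$min_bl),
                                      ctl$max_bl),
                                 arr$ntip, kern$U, kern$Uinv, kern$lambda,
                                 kern$pi, kern$crates, 2L, ctl$tol,
                                 ctl$min_bl, ctl$max_bl, ctl$brent_tol)
    list(loglik = bl$loglik, tree = {
      t2 <- arr$tree
      t2$edge.length <- bl$edge_length
      t2
    })
  }

  for (round in seq_len(max_rounds)) {
    nbrs <- nni_neighbors(fit$tree)
    if (length(nbrs) == 0L) break
    best <- NULL
    best_lnl <- fit$logLik + nni_tol
    for (nb in nbrs) {
      sc <- score_neighbor(nb, fit)
      if (sc$loglik > best_lnl) {
        best_lnl <- sc$loglik
        best <- sc$tree
      }
    }
    if (is.null(best)) break
    fit <- optimize_on_fixed_tree(best, aln, model_string, freq_mode,
                                  warm(fit))
  }
  fit
}
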