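#' Nontrivial bipartitions of a tree
#'
#' Each internal edge splits the taxa into two sides; the bipartition is
#' canonicalized as the sorted label set of the side NOT containing the
#' reference taxon (the lexicographically smallest label), encoded as a single
#' string key. Trees with T taxa have at most T-3 nontrivial bipartitions.
#'
#' @param tree a `phylo` tree.
#' @return character vector of bipartition keys.
#' @export
bipartitions <- function(tree) {
  tree <- check_tree(tree)
  ntip <- length(tree$tip.label)
  if (ntip < 4L) return(character(0))
  po <- ape::reorder.phylo(tree, "postorder")
  ref <- sort(tree$tip.label)[1L]
  nnode <- max(po$edge)
  below <- vector("list", nnode)
  for (t in seq_len(ntip)) below[[t]] <- po$tip.label[t]
  keys <- character(0)
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
    if (ch > ntip) {
      side <- below[[ch]]
      if (length(side) >= 2L && length(side) <= ntip - 2L) {
        if (ref %in% side) side <- setdiff(po$tip.label, side)
        keys <- c(keys, paste(sort(side), collapse = "|"))
      }
    }
  }
  unique(keys)
}

#' Robinson-Foulds distance
#'
#' Size of the symmetric difference of the two trees' nontrivial bipartition
#' sets.
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @return integer RF distance.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets", call. = FALSE)
  b1 <- bipartitions(t1)
  b2 <- bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Relative Robinson-Foulds distance
#'
#' RF divided by its maximum 2(T-3); in \[0, 1\] for fully resolved trees.
#' The 2(T-3) denominator is used regardless of resolution.
#'
#' @param t1,t2 `phylo` trees over the same leaf set (T >= 4).
#' @return numeric in \[0, 1\].
#' @export
relative_rf <- function(t1, t2) {
  ntaxa <- length(t1$tip.label)
  if (ntaxa < 4L) stop("relative RF needs at least 4 taxa", call. = FALSE)
  rf_distance(t1, t2) / (2 * (ntaxa - 3))
}

#' Branch score difference
#'
#' Square root of the summed squared differences of branch lengths over
#' matched bipartitions (including the trivial tip branches, matched by
#' label); a bipartition absent from one tree contributes its full length.
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @return numeric branch score.
#' @export
branch_score <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets", call. = FALSE)
  lens <- function(tree) {
    tree <- check_tree(tree)
    po <- ape::reorder.phylo(tree, "postorder")
    ntip <- length(po$tip.label)
    ref <- sort(po$tip.label)[1L]
    nnode <- max(po$edge)
    below <- vector("list", nnode)
    for (t in seq_len(ntip)) below[[t]] <- po$tip.label[t]
    out <- numeric(0)
    for (e in seq_len(nrow(po$edge))) {
      p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
      below[[p]] <- c(below[[p]], below[[ch]])
      side <- below[[ch]]
      if (length(side) <= ntip - 1L) {
        if (ref %in% side) side <- setdiff(po$tip.label, side)
        key <- paste(sort(side), collapse = "|")
        out[key] <- sum(out[key], po$edge.length[e], na.rm = TRUE)
      }
    }
    out
  }
  l1 <- lens(t1); l2 <- lens(t2)
  keys <- union(names(l1), names(l2))
  v1 <- ifelse(keys %in% names(l1), l1[keys], 0)
  v2 <- ifelse(keys %in% names(l2), l2[keys], 0)
  sqrt(sum((v1 - v2)^2))
}

#' Significance of best-fit-vs-GTR topological differences
#'
#' Compares the mean rRF distance across all (best-fit, GTR) tree pairs with
#' the random expectation, defined as the mean rRF among all within-GTR
#' pairs. Significance comes from a two-sided permutation test that shuffles
#' the set labels of the pooled trees and recomputes the mean cross-set rRF;
#' the result is classified `higher` / `lower` / `indistinguishable` at
#' `alpha`.
#'
#' @param best_fit_trees,gtr_trees lists of `phylo` trees (>= 2 each) over the
#'   same leaf set, from independent seeded searches.
#' @param n_perm number of label permutations (default 1000).
#' @param seed seed for the permutation draw.
#' @param alpha significance level (default 0.01).
#' @return list with `mean_cross_rrf`, `random_expectation`, `p_value`,
#'   `classification`, and the pooled pairwise-distance matrix `rrf_matrix`.
#' @export
significance_analysis <- function(best_fit_trees, gtr_trees,
                                  n_perm = 1000L, seed = 1L, alpha = 0.01) {
  if (length(best_fit_trees) < 2L || length(gtr_trees) < 2L)
    stop("need at least 2 trees in each set", call. = FALSE)
  pool <- c(best_fit_trees, gtr_trees)
  n1 <- length(best_fit_trees)
  n <- length(pool)
  is_a <- c(rep(TRUE, n1), rep(FALSE, n - n1))
  dmat <- matrix(0, n, n)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      dmat[i, j] <- dmat[j, i] <- relative_rf(pool[[i]], pool[[j]])

  cross_mean <- function(a_idx) {
    mean(dmat[a_idx, !seq_len(n) %in% a_idx])
  }
  obs <- cross_mean(which(is_a))
  expectation <- {
    g <- which(!is_a)
    m <- dmat[g, g]
    mean(m[upper.tri(m)])
  }

  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    cross_mean(sample.int(n, n1))
  }, numeric(1)))
  ## two-sided: how extreme is the observed mean under label exchange
  p_hi <- (sum(perm >= obs) + 1) / (n_perm + 1)
  p_lo <- (sum(perm <= obs) + 1) / (n_perm + 1)
  p <- min(1, 2 * min(p_hi, p_lo))

  classification <- if (p >= alpha) "indistinguishable"
                    else if (obs > expectation) "higher" else "lower"
  list(mean_cross_rrf = obs, random_expectation = expectation,
       p_value = p, classification = classification, rrf_matrix = dmat)
}

#' Pairwise rRF matrix of a list of trees
#'
#' @param trees list of `phylo` trees over the same leaf set.
#' @param labels optional names for rows/columns.
#' @return symmetric numeric matrix of relative RF distances.
#' @export
rrf_matrix <- function(trees, labels = names(trees)) {
  n <- length(trees)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  if (n >= 2L)
    for (i in seq_len(n - 1L))
      for (j in (i + 1L):n)
        m[i, j] <- m[j, i] <- relative_rf(trees[[i]], trees[[j]])
  m
}
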