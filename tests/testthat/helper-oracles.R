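# Independent oracles used to freeze expected values. These deliberately do
# not share code paths with the package internals they check.

# --- set partitions ---------------------------------------------------------

# All set partitions of 1..n as canonical block-assignment strings: element i
# gets the (1-based) index of its block, blocks ordered by smallest member.
# This is an independent enumeration of restricted-growth strings.
oracle_set_partitions <- function(n) {
  parts <- list(list(1L))   # partitions of {1}: one block
  if (n > 1L) {
    for (el in 2:n) {
      nxt <- list()
      for (p in parts) {
        for (b in seq_along(p)) {
          q <- p
          q[[b]] <- c(q[[b]], el)
          nxt[[length(nxt) + 1L]] <- q
        }
        nxt[[length(nxt) + 1L]] <- c(p, list(el))
      }
      parts <- nxt
    }
  }
  vapply(parts, function(p) {
    assign <- integer(n)
    for (b in seq_along(p)) assign[p[[b]]] <- b
    paste(assign, collapse = "")
  }, character(1))
}

oracle_stirling2 <- function(n, k) {
  # direct recurrence S(n,k) = k S(n-1,k) + S(n-1,k-1)
  s <- matrix(0, n + 1, k + 1)
  s[1, 1] <- 1
  for (i in 1:n)
    for (j in 1:min(i, k))
      s[i + 1, j + 1] <- j * s[i, j + 1] + s[i, j]
  s[n + 1, k + 1]
}

# position-tie partition of a model string, as a canonical key
tie_partition <- function(s) {
  d <- strsplit(s, "")[[1]]
  paste(sort(vapply(unique(d), function(x)
    paste(which(d == x), collapse = ","), character(1))), collapse = ";")
}

# --- rate matrices and transition probabilities -----------------------------

# Q assembled directly from the definition (no shared code with build_q)
oracle_q <- function(rates6, freqs) {
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  q <- matrix(0, 4, 4)
  for (m in 1:6) {
    q[pairs[m, 1], pairs[m, 2]] <- rates6[m] * freqs[pairs[m, 2]]
    q[pairs[m, 2], pairs[m, 1]] <- rates6[m] * freqs[pairs[m, 1]]
  }
  diag(q) <- -rowSums(q)
  q / -sum(freqs * diag(q))
}

# quadrature oracle for mean-per-quantile-interval discrete Gamma rates
oracle_gamma_rates <- function(alpha, ncat) {
  qb <- qgamma(seq(0, 1, length.out = ncat + 1), shape = alpha, rate = alpha)
  r <- vapply(seq_len(ncat), function(i) {
    ncat * integrate(function(x) x * dgamma(x, shape = alpha, rate = alpha),
                     qb[i], qb[i + 1], rel.tol = 1e-10)$value
  }, numeric(1))
  r / mean(r)
}

# --- brute-force tree likelihood --------------------------------------------

# lnL by exhaustive summation over all internal-node state assignments,
# mixing over Gamma categories computed by the quadrature oracle. P(t) comes
# from ape::matexpo, an implementation unrelated to the package's
# eigendecomposition path. States: alignment of plain ACGT characters.
oracle_loglik <- function(tree, mat, rates6, freqs, alpha, ncat = 4) {
  stopifnot(all(mat %in% c("A", "C", "G", "T")))
  q <- oracle_q(rates6, freqs)
  crates <- if (ncat == 1) 1 else oracle_gamma_rates(alpha, ncat)
  tree <- ape::reorder.phylo(tree, "postorder")
  edge <- tree$edge
  ntip <- length(tree$tip.label)
  nnode <- max(edge)
  internal <- setdiff(seq_len(nnode), seq_len(ntip))
  root <- setdiff(edge[, 1], edge[, 2])
  code <- c(A = 1L, C = 2L, G = 4L, T = 8L)  # only used as 1:4 below
  idx <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  tipstate <- idx[mat[tree$tip.label, , drop = FALSE]]
  dim(tipstate) <- dim(mat)

  total <- 0
  for (site in seq_len(ncol(mat))) {
    site_l <- 0
    for (cat in seq_len(ncat)) {
      pmats <- lapply(seq_len(nrow(edge)), function(e)
        ape::matexpo(q * crates[cat] * tree$edge.length[e]))
      grid <- do.call(expand.grid, rep(list(1:4), length(internal)))
      acc <- 0
      for (g in seq_len(nrow(grid))) {
        st <- integer(nnode)
        st[seq_len(ntip)] <- tipstate[, site]
        st[internal] <- as.integer(grid[g, ])
        pr <- freqs[st[root]]
        for (e in seq_len(nrow(edge)))
          pr <- pr * pmats[[e]][st[edge[e, 1]], st[edge[e, 2]]]
        acc <- acc + pr
      }
      site_l <- site_l + acc / ncat
    }
    total <- total + log(site_l)
  }
  total
}

# JC pairwise closed form: site log-likelihood of a match / mismatch at
# distance t (sum of the two branch lengths), no rate heterogeneity
oracle_jc_site <- function(t, match) {
  p_same <- 1 / 4 + 3 / 4 * exp(-4 * t / 3)
  p_diff <- 1 / 4 - 1 / 4 * exp(-4 * t / 3)
  log(0.25 * if (match) p_same else p_diff)
}

# --- misc -------------------------------------------------------------------

two_taxon_aln <- function(s1, s2) {
  dna_alignment(rbind(a = strsplit(s1, "")[[1]], b = strsplit(s2, "")[[1]]))
}

two_taxon_tree <- function(t1, t2) {
  tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
             edge.length = c(t1, t2), tip.label = c("a", "b"), Nnode = 1L)
  class(tr) <- "phylo"
  tr
}

# deterministic toy alignment over the given taxa
toy_alignment <- function(taxa = c("a", "b", "c", "d"),
                          sites = c("A", "C", "G", "T", "A", "C")) {
  mat <- t(vapply(seq_along(taxa), function(i) {
    # rotate so rows differ
    sites[((seq_along(sites) + i - 2) %% length(sites)) + 1]
  }, character(length(sites))))
  rownames(mat) <- taxa
  dna_alignment(mat)
}

# random substitution model over a given model string
random_model <- function(ms, seed) {
  set.seed(seed)
  k <- k_of(ms)
  substitution_model(ms, rates = c(exp(runif(k - 1, -1.5, 1.5)), 1),
                     freqs = as.numeric(gtools_dirichlet()),
                     alpha = exp(runif(1, -1, 1)))
}

gtools_dirichlet <- function() {
  x <- rgamma(4, shape = 5)
  x / sum(x)
}
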