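NUC <- c("A", "C", "G", "T")

## six (row, col) index pairs of the upper triangle in rate-class order
RATE_PAIRS <- matrix(c(1, 2, 1, 3, 1, 4, 2, 3, 2, 4, 3, 4),
                     ncol = 2, byrow = TRUE,
                     dimnames = list(RATE_CLASS_NAMES, c("i", "j")))

#' Construct a time-reversible substitution model
#'
#' Bundles a model string (the rate-tie structure), the six exchangeability
#' rates, the stationary base frequencies, and the shape of the
#' discrete-Gamma model of among-site rate heterogeneity.
#'
#' Positions of the model string sharing a digit must share a rate value; the
#' rate class containing the GT position is the relative-rate reference and is
#' rescaled to 1. A k-model therefore carries k-1 free rate parameters.
#'
#' @param model_string six-digit model string over 1-6.
#' @param rates numeric vector of 6 exchangeabilities in the order
#'   (AC, AG, AT, CG, CT, GT), or a vector of k per-class rates (one per
#'   distinct digit, in digit order). `NULL` means all rates equal.
#' @param freqs stationary frequencies (A, C, G, T); rescaled to sum to 1.
#' @param alpha Gamma shape parameter (> 0).
#' @param freq_mode one of `"empirical"`, `"ml_estimated"`, `"fixed_equal"`;
#'   recorded for the free-parameter count.
#' @return an object of class `substitution_model`.
#' @examples
#' substitution_model("121121", rates = c(1, 4), alpha = 0.5)
#' @export
substitution_model <- function(model_string,
                               rates = NULL,
                               freqs = rep(0.25, 4),
                               alpha = 1,
                               freq_mode = c("empirical", "ml_estimated",
                                             "fixed_equal")) {
  check_model_string(model_string)
  freq_mode <- match.arg(freq_mode)
  d <- model_digits(model_string)
  classes <- sort(unique(d))
  k <- length(classes)

  if (is.null(rates)) {
    class_rates <- stats::setNames(rep(1, k), classes)
  } else if (length(rates) == 6L) {
    ## full vector: check tie consistency
    for (cl in classes) {
      vals <- rates[d == cl]
      if (diff(range(vals)) > 1e-12 * max(abs(vals)))
        stop("rates at positions sharing digit ", cl,
             " must be equal under model ", model_string, call. = FALSE)
    }
    class_rates <- stats::setNames(
      vapply(classes, function(cl) rates[d == cl][1L], numeric(1)), classes)
  } else if (length(rates) == k) {
    class_rates <- stats::setNames(as.numeric(rates), classes)
  } else {
    stop("rates must have length 6 or k = ", k, call. = FALSE)
  }
  if (any(!is.finite(class_rates)) || any(class_rates <= 0))
    stop("all rates must be positive and finite", call. = FALSE)

  ## fix the class containing GT to 1
  gt_class <- d[6L]
  class_rates <- class_rates / class_rates[as.character(gt_class)]

  freqs <- as.numeric(freqs)
  if (length(freqs) != 4L || any(!is.finite(freqs)) || any(freqs <= 0))
    stop("freqs must be 4 positive finite values", call. = FALSE)
  freqs <- freqs / sum(freqs)

  if (!is.finite(alpha) || alpha <= 0)
    stop("alpha must be a positive finite Gamma shape", call. = FALSE)

  structure(
    list(model_string = model_string,
         rates = stats::setNames(class_rates[as.character(d)],
                                 RATE_CLASS_NAMES),
         class_rates = class_rates,
         freqs = stats::setNames(freqs, NUC),
         alpha = alpha,
         freq_mode = freq_mode),
    class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat("Substitution model", x$model_string,
      sprintf("(k = %d)", k_of(x$model_string)), "\n")
  cat("  rates:", paste(sprintf("%s=%.4g", names(x$rates), x$rates),
                        collapse = " "), "\n")
  cat("  freqs:", paste(sprintf("%s=%.4g", NUC, x$freqs), collapse = " "),
      sprintf(" (%s)", x$freq_mode), "\n")
  cat("  Gamma shape alpha:", format(x$alpha, digits = 4), "\n")
  invisible(x)
}

#' Build the scaled instantaneous rate matrix Q
#'
#' Off-diagonals are q_ij = r_ij * pi_j, rows sum to zero, and the matrix is
#' rescaled so that -sum_i pi_i q_ii = 1, i.e. branch lengths are measured in
#' expected substitutions per site. Time-reversibility (detailed balance
#' pi_i q_ij = pi_j q_ji) holds by construction.
#'
#' @param model a `substitution_model`.
#' @return an object of class `rate_matrix` with fields `q` (the scaled 4x4
#'   matrix), `freqs`, and `scale` (the pre-normalization expected rate).
#' @export
build_q <- function(model) {
  stopifnot(inherits(model, "substitution_model"))
  pi <- model$freqs
  q <- matrix(0, 4, 4, dimnames = list(NUC, NUC))
  for (m in seq_len(6)) {
    i <- RATE_PAIRS[m, 1L]; j <- RATE_PAIRS[m, 2L]
    q[i, j] <- model$rates[m] * pi[j]
    q[j, i] <- model$rates[m] * pi[i]
  }
  diag(q) <- -rowSums(q)
  scale <- -sum(pi * diag(q))
  if (scale <= 0) stop("degenerate rate matrix: zero total rate", call. = FALSE)
  structure(list(q = q / scale, freqs = pi, scale = scale),
            class = "rate_matrix")
}

#' Eigendecomposition of a reversible rate matrix
#'
#' Decomposes Q via the pi-symmetrized matrix
#' B = diag(sqrt(pi)) Q diag(1/sqrt(pi)), which is real symmetric for a
#' time-reversible Q, so the decomposition is numerically stable and all
#' eigenvalues are real and non-positive. Returns U, lambda and U^{-1} with
#' Q = U diag(lambda) U^{-1}; one decomposition is reused across all branches
#' and rate categories.
#'
#' @param qm a `rate_matrix`.
#' @return list with `values` (4 eigenvalues) and matrices `U`, `Uinv`.
#' @keywords internal
decompose_q <- function(qm) {
  stopifnot(inherits(qm, "rate_matrix"))
  sp <- sqrt(qm$freqs)
  b <- (qm$q * rep(sp, times = 4)) / rep(sp, each = 4)  # D^1/2 Q D^-1/2
  b <- (b + t(b)) / 2                                   # symmetrize roundoff
  eig <- eigen(b, symmetric = TRUE)
  list(values = eig$values,
       U = eig$vectors / sp,          # D^-1/2 V
       Uinv = t(eig$vectors) * rep(sp, each = 4))  # V' D^1/2
}

#' Transition probability matrix P(t) = exp(Q r t)
#'
#' @param qm a `rate_matrix`.
#' @param t branch length in expected substitutions per site (>= 0).
#' @param r rate-category multiplier (> 0).
#' @return 4x4 stochastic matrix; rows sum to 1.
#' @export
transition_probs <- function(qm, t, r = 1) {
  stopifnot(inherits(qm, "rate_matrix"))
  if (!is.finite(t) || t < 0) stop("branch length t must be >= 0", call. = FALSE)
  if (!is.finite(r) || r <= 0) stop("category rate r must be > 0", call. = FALSE)
  dec <- decompose_q(qm)
  p <- dec$U %*% (exp(dec$values * r * t) * dec$Uinv)
  p[p < 0] <- 0                      # clip eigen roundoff
  p <- p / rowSums(p)
  dimnames(p) <- list(NUC, NUC)
  p
}

#' Discrete-Gamma category rates
#'
#' Divides the Gamma(alpha, alpha) distribution (mean 1) into `ncat`
#' equal-probability categories and represents each by its conditional mean,
#' computed in closed form from the incomplete-gamma identity
#' \eqn{\int_0^x u f_{\alpha,\alpha}(u) du = F_{\alpha+1,\alpha}(x)}. The
#' rates are renormalized to average exactly 1.
#'
#' @param alpha Gamma shape (> 0).
#' @param ncat number of categories (>= 1).
#' @return numeric vector of `ncat` positive rates with mean 1.
#' @export
gamma_category_rates <- function(alpha, ncat = 4L) {
  if (!is.finite(alpha) || alpha <= 0)
    stop("alpha must be a positive finite Gamma shape", call. = FALSE)
  ncat <- as.integer(ncat)
  if (ncat < 1L) stop("ncat must be >= 1", call. = FALSE)
  if (ncat == 1L) return(1)
  qb <- stats::qgamma(seq(0, 1, length.out = ncat + 1L),
                      shape = alpha, rate = alpha)
  mass <- diff(stats::pgamma(qb, shape = alpha + 1, rate = alpha))
  r <- ncat * mass
  r / mean(r)
}
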