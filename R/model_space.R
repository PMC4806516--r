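#' @useDynLib gtrspace, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## Rate-position order is fixed as (AC, AG, AT, CG, CT, GT), matching the
## layout of the time-reversible rate matrix.
RATE_CLASS_NAMES <- c("AC", "AG", "AT", "CG", "CT", "GT")

#' Validate a six-digit model string
#'
#' A model string encodes which of the six exchangeability rates
#' (AC, AG, AT, CG, CT, GT) are constrained to be equal: positions holding the
#' same digit share one rate. Digits are drawn from \{1,...,6\}.
#'
#' @param s character scalar.
#' @return `s`, invisibly, after validation.
#' @keywords internal
check_model_string <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s))
    stop("model string must be a single character value", call. = FALSE)
  if (nchar(s) != 6L)
    stop("model string must have exactly 6 characters, got '", s, "'",
         call. = FALSE)
  if (grepl("[^1-6]", s))
    stop("model string may only contain digits 1-6, got '", s, "'",
         call. = FALSE)
  invisible(s)
}

model_digits <- function(s) {
  check_model_string(s)
  as.integer(strsplit(s, "", fixed = TRUE)[[1L]])
}

digits_to_string <- function(d) paste(d, collapse = "")

#' Test the normalization property of a model string
#'
#' A model string is normalized when, at the first occurrence of each digit
#' value v, the preceding characters are exactly the set \{1, ..., v-1\}.
#' Normalized strings are the canonical representatives of the semantic
#' equivalence classes (they are restricted-growth strings over the six rate
#' positions): a normalized string always starts with 1 and its n-th digit is
#' at most n.
#'
#' @param s a six-character model string over digits 1-6.
#' @return logical scalar.
#' @examples
#' is_normalized("123111") # TRUE
#' is_normalized("311111") # FALSE
#' @export
is_normalized <- function(s) {
  d <- model_digits(s)
  seen_max <- 0L
  for (x in d) {
    if (x > seen_max + 1L) return(FALSE)
    if (x == seen_max + 1L) seen_max <- x
  }
  TRUE
}

#' Normalize a model string
#'
#' Re-maps the digits so the normalization property holds while preserving the
#' position-tie partition (which positions share a digit). Each rate class is
#' assigned a new digit incrementally from 1 in order of its leftmost
#' position. Idempotent on normalized input.
#'
#' @param s a six-character model string over digits 1-6.
#' @return the normalized model string.
#' @examples
#' normalize_model("311111") # "122222"
#' normalize_model("124356") # "123456"
#' @export
normalize_model <- function(s) {
  d <- model_digits(s)
  map <- integer(6)          # old digit -> new digit, 0 = unassigned
  nxt <- 0L
  out <- integer(6)
  for (i in seq_along(d)) {
    if (map[d[i]] == 0L) {
      nxt <- nxt + 1L
      map[d[i]] <- nxt
    }
    out[i] <- map[d[i]]
  }
  digits_to_string(out)
}

#' Number of distinct substitution rates of a model
#'
#' A model with exactly k distinct digits is a k-model; k-1 of its rates are
#' free parameters (one rate is fixed at 1 as the relative-rate reference).
#'
#' @param s a six-character model string over digits 1-6.
#' @return integer in 1..6.
#' @examples
#' k_of("111111") # 1 (Jukes-Cantor)
#' k_of("123456") # 6 (GTR)
#' @export
k_of <- function(s) length(unique(model_digits(s)))

#' k-prefix of a normalized model string
#'
#' The shortest prefix containing every one of the k digit values. Defined for
#' any k-model whose digit set is exactly \{1,...,k\} (all normalized strings
#' qualify, but normalization is not required). During inductive derivation
#' the characters inside the k-prefix are protected from replacement.
#'
#' @param s a model string whose digits are exactly \{1,...,k\}.
#' @return the k-prefix as a character scalar.
#' @examples
#' k_prefix("124311") # "1243"
#' @export
k_prefix <- function(s) {
  d <- model_digits(s)
  k <- max(d)
  if (!setequal(unique(d), seq_len(k)))
    stop("k_prefix() requires the digit set {1..k}; got '", s, "'",
         call. = FALSE)
  end <- 0L
  seen <- logical(k)
  for (i in seq_along(d)) {
    if (!seen[d[i]]) {
      seen[d[i]] <- TRUE
      end <- i
      if (all(seen)) break
    }
  }
  substr(s, 1L, end)
}

#' Convert to the 0-based engine alphabet
#'
#' Likelihood engines conventionally specify the same tie structure over the
#' alphabet \{0,...,5\}; each digit is decremented by one.
#'
#' @param s a six-character model string over digits 1-6.
#' @return a six-character string over digits 0-5.
#' @examples
#' to_engine_string("121121") # "010010"
#' @export
to_engine_string <- function(s) {
  digits_to_string(model_digits(s) - 1L)
}

new_model_set <- function(models, candidates) {
  models <- as.character(models)
  k <- vapply(models, k_of, integer(1), USE.NAMES = FALSE)
  ord <- order(k, models)
  models <- models[ord]
  per_k <- table(factor(k[ord], levels = 1:6))
  structure(
    list(models = models,
         per_k_counts = stats::setNames(as.integer(per_k), 1:6),
         enumerated_candidates = as.integer(candidates)),
    class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat("Time-reversible nucleotide model set:", length(x$models), "models\n")
  cat("  per-k counts:",
      paste(sprintf("k=%d:%d", 1:6, x$per_k_counts), collapse = "  "), "\n")
  cat("  candidate strings inspected:", x$enumerated_candidates, "\n")
  invisible(x)
}

#' Enumerate all non-redundant models by brute force
#'
#' Enumerates raw six-digit strings, normalizes each, and keeps the first
#' occurrence of every normalized form. With `optimized = FALSE` all
#' 6^6 = 46656 strings are inspected (counting from 111111 to 666666 in
#' base 6). With `optimized = TRUE` only strings whose n-th position draws
#' from \{1,...,n\} are generated, reducing the enumeration to
#' 1*2*3*4*5*6 = 720 candidates. Both settings yield the identical set of 203
#' non-redundant normalized model strings.
#'
#' @param optimized logical; restrict position n to digits 1..n.
#' @return a `model_set` with fields `models`, `per_k_counts` and
#'   `enumerated_candidates`.
#' @export
enumerate_brute_force <- function(optimized = TRUE) {
  digit_sets <- if (optimized) lapply(1:6, seq_len) else rep(list(1:6), 6L)
  ## odometer enumeration, leftmost position most significant
  grid <- expand.grid(rev(digit_sets), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, 6:1, drop = FALSE]
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  kept <- character(0)
  for (i in seq_len(nrow(grid))) {
    norm <- normalize_model(digits_to_string(as.integer(grid[i, ])))
    if (is.null(seen[[norm]])) {
      seen[[norm]] <- TRUE
      kept <- c(kept, norm)
    }
  }
  new_model_set(kept, nrow(grid))
}

#' Derive all (k+1)-models from a single normalized k-model
#'
#' The induction step replaces occurrences of the digit k by k+1 in two
#' phases. Phase 1: every occurrence of k outside the protected k-prefix
#' spawns one new model with that single character replaced (the replacement
#' extends the prefix). Phase 2: each phase-1 model is expanded recursively by
#' replacing further unprotected occurrences of k, considering only positions
#' strictly right of the last replaced one, so that sets derived from distinct
#' source models stay disjoint.
#'
#' @param s a normalized k-model string with k < 6.
#' @return character vector of normalized (k+1)-model strings.
#' @examples
#' derive_models("111111") # the five phase-1 strings 121111 ... 111112 plus
#'                         # their recursive expansions (31 models in total
#'                         # when unioned over phase 2)
#' @export
derive_models <- function(s) {
  if (!is_normalized(s))
    stop("derive_models() requires a normalized model string, got '", s, "'",
         call. = FALSE)
  d <- model_digits(s)
  k <- max(d)
  if (k == 6L)
    stop("cannot derive models beyond k = 6: '", s, "' is already the GTR ",
         "string", call. = FALSE)
  prefix_len <- which(d == k)[1L]
  out <- character(0)

  expand <- function(d, from) {
    ## phase 2: replace unprotected k's strictly right of the last replacement
    pos <- which(d == k)
    pos <- pos[pos > from]
    for (p in pos) {
      d2 <- d
      d2[p] <- k + 1L
      out <<- c(out, digits_to_string(d2))
      expand(d2, p)
    }
  }

  ## phase 1: one model per unprotected occurrence of k
  first_pos <- which(d == k)
  first_pos <- first_pos[first_pos > prefix_len]
  for (p in first_pos) {
    d1 <- d
    d1[p] <- k + 1L
    out <- c(out, digits_to_string(d1))
    expand(d1, p)
  }
  out
}

#' Generate all models by the inductive algorithm
#'
#' Starts from the single 1-model 111111 and applies the induction step
#' k -> k+1 to every k-model until the sole 6-model 123456 is produced. The
#' per-k set sizes are 1, 31, 90, 65, 15 and 1 (the Stirling numbers of the
#' second kind S(6, k)); the union holds all 203 models (the Bell number
#' B(6)).
#'
#' @return a `model_set`; `enumerated_candidates` equals the total number of
#'   strings produced (each exactly once, so it equals 203).
#' @export
generate_inductive <- function() {
  sets <- vector("list", 6L)
  sets[[1L]] <- "111111"
  for (k in 1:5)
    sets[[k + 1L]] <- unlist(lapply(sets[[k]], derive_models), use.names = FALSE)
  all <- unlist(sets, use.names = FALSE)
  new_model_set(all, length(all))
}

#' All 203 model strings
#'
#' Convenience accessor returning the sorted model strings from the inductive
#' generator (sorted by k, then lexicographically).
#'
#' @return character vector of length 203.
#' @export
all_model_strings <- function() generate_inductive()$models

#' Write model strings to a plain-text file
#'
#' One model per line, in the stable order (by k, then lexicographic), in
#' either the 1-based or the 0-based engine alphabet.
#'
#' @param models a `model_set` or character vector of model strings.
#' @param path output file path.
#' @param alphabet `"one"` for digits 1-6, `"zero"` for the engine digits 0-5.
#' @return `path`, invisibly.
#' @export
write_model_strings <- function(models, path, alphabet = c("one", "zero")) {
  alphabet <- match.arg(alphabet)
  if (inherits(models, "model_set")) models <- models$models
  vapply(models, check_model_string, character(1))
  if (alphabet == "zero")
    models <- vapply(models, to_engine_string, character(1), USE.NAMES = FALSE)
  writeLines(models, path)
  invisible(path)
}
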