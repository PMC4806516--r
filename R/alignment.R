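## IUPAC nucleotide codes as bitmasks over (A=1, C=2, G=4, T=8). Gaps,
## '?' and '.' are treated as full ambiguity (all-ones), the standard pruning
## treatment.
IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L,
  N = 15L, "-" = 15L, "?" = 15L, "." = 15L, X = 15L
)

#' Construct an alignment object from a character matrix
#'
#' Rows are taxa, columns are sites; entries are IUPAC DNA codes (case
#' insensitive). Site columns are compressed to unique patterns with
#' multiplicities, which is what the likelihood and parsimony kernels consume.
#'
#' @param mat character matrix with unique, non-empty rownames (the taxa).
#' @return an object of class `dna_alignment` with fields `taxa`, `matrix`,
#'   `masks` (taxa x patterns integer bitmask matrix), `weights` (pattern
#'   multiplicities) and `n_sites`.
#' @export
dna_alignment <- function(mat) {
  if (!is.matrix(mat) || !is.character(mat))
    stop("alignment must be a character matrix (taxa x sites)", call. = FALSE)
  taxa <- rownames(mat)
  if (is.null(taxa) || anyNA(taxa) || any(taxa == ""))
    stop("alignment rows must be named with taxon labels", call. = FALSE)
  if (anyDuplicated(taxa))
    stop("duplicate taxon labels: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "), call. = FALSE)
  if (nrow(mat) < 2L || ncol(mat) < 1L)
    stop("alignment needs at least 2 taxa and 1 site", call. = FALSE)
  mat <- toupper(mat)
  bad <- !(mat %in% names(IUPAC_MASK))
  if (any(bad))
    stop("unrecognized residue(s): ",
         paste(unique(mat[bad]), collapse = " "), call. = FALSE)

  codes <- matrix(IUPAC_MASK[mat], nrow = nrow(mat))
  keys <- apply(codes, 2L, paste, collapse = ",")
  first <- !duplicated(keys)
  masks <- codes[, first, drop = FALSE]
  weights <- as.numeric(table(keys)[keys[first]])
  storage.mode(masks) <- "integer"

  structure(
    list(taxa = taxa, matrix = mat, masks = masks, weights = weights,
         n_sites = ncol(mat)),
    class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("DNA alignment:", length(x$taxa), "taxa x", x$n_sites, "sites",
      sprintf("(%d unique site patterns)\n", ncol(x$masks)))
  invisible(x)
}

#' Read a DNA alignment from FASTA or PHYLIP
#'
#' PHYLIP files may be sequential or interleaved; both are attempted. Parsing
#' is delegated to \pkg{ape}; shape and alphabet validation (ragged rows,
#' duplicate taxa, empty files) happens here.
#'
#' @param path file path.
#' @param format `"auto"` (detect FASTA by a leading `>`), `"fasta"` or
#'   `"phylip"`.
#' @return a `dna_alignment`.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "phylip")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(trimws(lines))))
    stop("empty alignment file: ", path, call. = FALSE)
  if (format == "auto") {
    first <- trimws(lines[nzchar(trimws(lines))][1L])
    format <- if (startsWith(first, ">")) "fasta" else "phylip"
  }
  if (format == "fasta") {
    dna <- tryCatch(ape::read.FASTA(path),
                    error = function(e) stop("FASTA parse error in ", path,
                                             ": ", conditionMessage(e),
                                             call. = FALSE))
    chars <- lapply(as.character(dna), toupper)
    lens <- lengths(chars)
    if (length(unique(lens)) != 1L)
      stop("ragged FASTA: sequence lengths ",
           paste(unique(lens), collapse = ", "), " in ", path, call. = FALSE)
    mat <- do.call(rbind, chars)
    rownames(mat) <- names(dna)
  } else {
    mat <- NULL
    errs <- character(0)
    for (ph in c("sequential", "interleaved")) {
      got <- tryCatch(ape::read.dna(path, format = ph, as.character = TRUE),
                      error = function(e) conditionMessage(e))
      if (is.matrix(got)) { mat <- toupper(got); break }
      errs <- c(errs, got)
    }
    if (is.null(mat))
      stop("PHYLIP parse error in ", path, ": ",
           paste(unique(errs), collapse = " / "), call. = FALSE)
    if (anyNA(mat) || is.null(rownames(mat)) || anyNA(rownames(mat)))
      stop("PHYLIP parse error in ", path,
           ": fewer sequences or sites than the header announces",
           call. = FALSE)
    hdr <- as.integer(strsplit(trimws(lines[nzchar(trimws(lines))][1L]),
                               "\\s+")[[1L]][1:2])
    if (!anyNA(hdr) && (nrow(mat) != hdr[1L] || ncol(mat) != hdr[2L]))
      stop("PHYLIP header announces ", hdr[1L], " x ", hdr[2L],
           " but ", nrow(mat), " x ", ncol(mat), " was parsed in ", path,
           call. = FALSE)
  }
  dna_alignment(mat)
}

#' Write an alignment to FASTA or PHYLIP (sequential)
#'
#' @param aln a `dna_alignment`.
#' @param path output file path.
#' @param format `"fasta"` or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  stopifnot(inherits(aln, "dna_alignment"))
  seqs <- apply(aln$matrix, 1L, paste, collapse = "")
  if (format == "fasta") {
    writeLines(as.vector(rbind(paste0(">", aln$taxa), seqs)), path)
  } else {
    writeLines(c(paste(length(aln$taxa), aln$n_sites),
                 paste(formatC(aln$taxa, width = -max(10L, nchar(aln$taxa))),
                       seqs)), path)
  }
  invisible(path)
}

#' Empirical base frequencies
#'
#' Counts unambiguous characters only; each base gets a +1/4 pseudo-count so
#' no frequency is ever zero.
#'
#' @param aln a `dna_alignment`.
#' @return named numeric vector (A, C, G, T) summing to 1.
#' @export
empirical_frequencies <- function(aln) {
  stopifnot(inherits(aln, "dna_alignment"))
  counts <- vapply(NUC, function(b) sum(aln$matrix == b), numeric(1))
  counts <- counts + 0.25
  counts / sum(counts)
}
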