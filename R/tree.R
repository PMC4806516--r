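## Trees are ape "phylo" objects. Inferred trees are unrooted binary trees
## stored in ape's rooted representation with a basal trifurcation.

check_tree <- function(tree) {
  if (!inherits(tree, "phylo"))
    stop("expected an ape 'phylo' tree", call. = FALSE)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0.1, nrow(tree$edge))
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed", call. = FALSE)
  tree
}

#' Read a tree from Newick text or file
#'
#' Rooted input is collapsed to the unrooted form (basal trifurcation).
#'
#' @param text Newick string, or `NULL` when `path` is given.
#' @param path optional file containing one Newick tree per line (the first is
#'   returned unless `all = TRUE`).
#' @param all return all trees in `path` as a list.
#' @return a `phylo` tree (or list of trees).
#' @export
read_newick <- function(text = NULL, path = NULL, all = FALSE) {
  if (is.null(text) == is.null(path))
    stop("supply exactly one of 'text' or 'path'", call. = FALSE)
  trees <- tryCatch(suppressWarnings({
    if (!is.null(text)) c(ape::read.tree(text = text))
    else c(ape::read.tree(file = path))
  }), error = function(e) stop("Newick parse error: ", conditionMessage(e),
                               call. = FALSE))
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (is.null(trees) || length(trees) == 0L)
    stop("Newick parse error: no tree found", call. = FALSE)
  trees <- lapply(trees, function(tr) {
    tr <- check_tree(tr)
    if (ape::is.rooted(tr) && ape::Ntip(tr) > 2L) tr <- ape::unroot(tr)
    tr
  })
  if (all) trees else trees[[1L]]
}

#' Serialize a tree to Newick
#'
#' @param tree a `phylo` tree.
#' @param path optional output file; when `NULL` the Newick string is
#'   returned.
#' @param digits printed branch-length precision.
#' @return the Newick string (invisibly when written to `path`).
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  tree <- check_tree(tree)
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

## postorder edge matrix + lengths for the C++ kernels
tree_arrays <- function(tree) {
  tree <- check_tree(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  list(edge = po$edge, edge_length = po$edge.length,
       ntip = length(po$tip.label), tip_label = po$tip.label, tree = po)
}

## masks reordered to tree tip order
masks_for_tree <- function(tree, aln) {
  idx <- match(tree$tip.label, aln$taxa)
  if (anyNA(idx))
    stop("tree tips not in alignment: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "), call. = FALSE)
  if (length(tree$tip.label) != length(aln$taxa))
    stop("tree and alignment have different taxon sets", call. = FALSE)
  aln$masks[idx, , drop = FALSE]
}

## Insert a new tip into `edge_index` of an unrooted tree, splitting the edge
## with a new internal node. Node ids are renumbered to keep ape's convention
## (tips first, then internals).
insert_tip <- function(tree, label, edge_index, tip_length = 0.1) {
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  len <- tree$edge.length
  ## shift internal ids up by one to make room for the new tip id ntip+1
  edge[edge > ntip] <- edge[edge > ntip] + 1L
  new_tip <- ntip + 1L
  new_int <- ntip + 1L + tree$Nnode + 1L
  a <- edge[edge_index, 1L]; b <- edge[edge_index, 2L]
  half <- len[edge_index] / 2
  edge[edge_index, ] <- c(a, new_int)
  len[edge_index] <- half
  edge <- rbind(edge, c(new_int, b), c(new_int, new_tip))
  len <- c(len, half, tip_length)
  out <- list(edge = edge, edge.length = len,
              tip.label = c(tree$tip.label, label),
              Nnode = tree$Nnode + 1L)
  class(out) <- "phylo"
  attr(out, "order") <- NULL
  out
}

## The two NNI rearrangements across internal edge (u, v): swap one fixed
## child x of u with each child of v. Swapping child entries of the edge
## matrix (keeping each edge's length with its position) realizes the move.
nni_neighbors_of_edge <- function(tree, edge_index) {
  edge <- tree$edge
  ntip <- length(tree$tip.label)
  u <- edge[edge_index, 1L]; v <- edge[edge_index, 2L]
  if (v <= ntip) return(list())            # tip edge: no NNI
  x_edges <- which(edge[, 1L] == u & edge[, 2L] != v)
  if (length(x_edges) == 0L) return(list())
  xe <- x_edges[1L]
  v_children <- which(edge[, 1L] == v)
  lapply(v_children, function(ce) {
    e2 <- edge
    e2[xe, 2L] <- edge[ce, 2L]
    e2[ce, 2L] <- edge[xe, 2L]
    out <- tree
    out$edge <- e2
    attr(out, "order") <- NULL
    out
  })
}

## all NNI neighbors of an unrooted binary tree
nni_neighbors <- function(tree) {
  ntip <- length(tree$tip.label)
  internal <- which(tree$edge[, 2L] > ntip)
  out <- list()
  for (e in internal) out <- c(out, nni_neighbors_of_edge(tree, e))
  out
}

#' Random unrooted tree
#'
#' Uniform random addition-order topology with exponential branch lengths,
#' for simulation inputs.
#'
#' @param ntaxa number of taxa (>= 3).
#' @param mean_branch_length mean of the exponential branch-length draw.
#' @param labels optional tip labels (default t1..tn).
#' @return an unrooted `phylo` tree.
#' @export
random_tree <- function(ntaxa, mean_branch_length = 0.1, labels = NULL) {
  if (ntaxa < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (is.null(labels)) labels <- paste0("t", seq_len(ntaxa))
  tr <- ape::rtree(ntaxa, rooted = FALSE, tip.label = labels)
  tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 1 / mean_branch_length)
  tr
}
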