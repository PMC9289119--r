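#' Read a set of Newick trees
#'
#' Reads one or more Newick strings (one per line) and checks that all trees
#' share the same tip label set, as required for consensus building and for
#' robustness analyses over a tree sample.
#'
#' @param path File with one Newick string per line.
#' @return List of `phylo` objects.
#' @export
read_trees <- function(path) {
  trees <- ape::read.tree(path)
  if (is.null(trees)) stop("could not parse any tree from ", path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    tips <- sort(trees[[i]]$tip.label)
    if (!identical(tips, ref)) {
      extra <- setdiff(tips, ref)
      missing <- setdiff(ref, tips)
      stop("tree ", i, " has a different tip set than tree 1",
           if (length(missing)) paste0("; missing: ",
                                       paste(missing, collapse = ", ")),
           if (length(extra)) paste0("; extra: ",
                                     paste(extra, collapse = ", ")))
    }
  }
  trees
}

# tip-set key of every edge of a tree: list mapping "tipA\rtipB\r..." (sorted)
# to the length of the edge subtending exactly that clade
.clade_lengths <- function(tree) {
  ntip <- length(tree$tip.label)
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  # postorder so children are resolved before parents
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    par <- eo[k, 1]; child <- eo[k, 2]
    desc[[par]] <- c(desc[[par]], desc[[child]])
  }
  keys <- vapply(tree$edge[, 2],
                 function(nd) paste(sort(desc[[nd]]), collapse = "\r"), "")
  stats::setNames(tree$edge.length, keys)
}

#' Majority-rule consensus tree with mean clade branch lengths
#'
#' Builds the consensus of a sample of rooted trees over the same tips.
#' Under the (default) majority rule, a clade is retained when it occurs in
#' strictly more than `threshold` of the trees; regions without a majority
#' clade collapse to polytomies. Each retained edge (including tip edges)
#' gets the mean of its branch lengths over the trees that contain that
#' clade. `method = "strict"` retains only clades present in every tree.
#'
#' @param trees List of `phylo` objects sharing one tip set.
#' @param threshold Retention frequency for the majority rule (default 0.5;
#'   a clade at exactly the threshold is not retained).
#' @param method `"majority"` (default) or `"strict"`.
#' @return A `phylo` consensus tree with branch lengths.
#' @export
consensus_tree <- function(trees, threshold = 0.5,
                           method = c("majority", "strict")) {
  method <- match.arg(method)
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 0) stop("empty tree list")
  if (length(trees) == 1) return(trees[[1]])
  class(trees) <- "multiPhylo"
  cons <- if (method == "strict") {
    ape::consensus(trees, p = 1, rooted = TRUE)
  } else {
    ape::consensus(trees, p = threshold, rooted = TRUE)
  }
  # mean branch length over the trees containing each retained clade
  per_tree <- lapply(trees, .clade_lengths)
  desc <- vector("list", length(cons$tip.label) + cons$Nnode)
  for (i in seq_along(cons$tip.label)) desc[[i]] <- cons$tip.label[i]
  eo <- ape::reorder.phylo(cons, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    desc[[eo[k, 1]]] <- c(desc[[eo[k, 1]]], desc[[eo[k, 2]]])
  }
  cons$edge.length <- vapply(cons$edge[, 2], function(nd) {
    key <- paste(sort(desc[[nd]]), collapse = "\r")
    lens <- unlist(lapply(per_tree, function(cl) unname(cl[key])))
    lens <- lens[!is.na(lens)]
    if (length(lens) == 0) 0 else mean(lens)
  }, 0)
  cons
}

#' Brownian-motion variance-covariance matrix of a phylogeny
#'
#' Under Brownian trait evolution, the covariance of two tips is
#' proportional to the shared path length from the root to their most recent
#' common ancestor; the diagonal holds root-to-tip distances. The matrix is
#' returned unscaled (the Brownian rate is profiled out by the GLS fit). Any
#' `root.edge` of the tree is added to every entry, so that pruning a tree
#' (keeping the stem to the old root) and building the matrix commutes with
#' building the full matrix and subsetting rows and columns.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param species_order Optional character vector: subset/reorder the matrix
#'   to these species; all must be tips of the tree.
#' @return Symmetric positive semi-definite species x species matrix.
#' @export
brownian_vcv <- function(tree, species_order = NULL) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  V <- ape::vcv(tree)
  if (!is.null(tree$root.edge) && !is.na(tree$root.edge))
    V <- V + tree$root.edge
  if (!is.null(species_order)) {
    miss <- setdiff(species_order, rownames(V))
    if (length(miss) > 0)
      stop("species missing from tree: ", paste(miss, collapse = ", "))
    V <- V[species_order, species_order, drop = FALSE]
  }
  V
}
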