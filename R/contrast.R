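#' Precompute contrast-sampling pools for every leaf
#'
#' At every branching point on the path from the root down to a focal leaf,
#' the embedding trainer samples one species from the branch(es) the focal
#' leaf is *not* on. This helper precomputes, for every leaf, the list of
#' those sibling-subtree leaf pools (one pool per branching point), so that
#' sampling during training is a cheap indexed draw. For a polytomy the pool
#' is the union of all non-focal child subtrees.
#'
#' @param tree a validated `phylo` object.
#' @return an object of class `contrast_index`: a list with `pools` (per leaf,
#'   a list of integer vectors of tip indices) and `labels` (tip labels).
#' @export
contrast_index <- function(tree) {
  validate_phylo(tree)
  n <- length(tree$tip.label)
  if (n == 1) {
    return(structure(list(pools = list(list()), labels = tree$tip.label),
                     class = "contrast_index"))
  }
  edge <- tree$edge
  nnode <- max(edge)
  parent <- integer(nnode)
  parent[edge[, 2]] <- edge[, 1]
  root <- setdiff(unique(edge[, 1]), edge[, 2])

  # postorder pass: clade tip sets for every node
  po <- ape::reorder.phylo(tree, "postorder")$edge
  clade <- vector("list", nnode)
  for (i in seq_len(n)) clade[[i]] <- i
  for (k in seq_len(nrow(po))) {
    p <- po[k, 1]; ch <- po[k, 2]
    clade[[p]] <- c(clade[[p]], clade[[ch]])
  }

  pools <- vector("list", n)
  for (leaf in seq_len(n)) {
    node <- leaf
    path_pools <- list()
    while (node != root) {
      p <- parent[node]
      pool <- setdiff(clade[[p]], clade[[node]])
      path_pools[[length(path_pools) + 1L]] <- pool
      node <- p
    }
    pools[[leaf]] <- path_pools
  }
  structure(list(pools = pools, labels = tree$tip.label),
            class = "contrast_index")
}

#' Sample a contrast set for one focal species
#'
#' Draws one species at random from each branching point's sibling pool on
#' the root-to-focal path, so the set mixes close relatives (deep branching
#' points) with distant ones (near the root). Its size equals the number of
#' internal nodes on that path. Uses R's RNG; seed with [set.seed()] for
#' reproducibility.
#'
#' @param tree a `phylo` object (ignored when `index` is supplied).
#' @param focal focal species (a tip label).
#' @param index optional precomputed [contrast_index()].
#' @return character vector of species ids (empty for a single-leaf tree).
#' @export
sample_contrast_set <- function(tree, focal, index = NULL) {
  if (is.null(index)) index <- contrast_index(tree)
  leaf <- match(focal, index$labels)
  if (is.na(leaf)) stop("focal species '", focal, "' is not a leaf of the tree")
  idx <- sample_contrast_idx(index, leaf)
  index$labels[idx]
}

# integer-index version used in the training loop
sample_contrast_idx <- function(index, leaf) {
  pools <- index$pools[[leaf]]
  if (length(pools) == 0) return(integer(0))
  vapply(pools, function(p) if (length(p) == 1L) p else p[sample.int(length(p), 1L)],
         integer(1))
}
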