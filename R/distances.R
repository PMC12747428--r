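#' Patristic distance matrix of a phylogeny
#'
#' Sum of branch lengths along the path between every pair of leaves, in the
#' tree's branch-length units.
#'
#' @param tree a validated `phylo` object.
#' @return symmetric numeric matrix, rows/columns in `tree$tip.label` order,
#'   zero diagonal.
#' @export
patristic_distances <- function(tree) {
  validate_phylo(tree)
  if (length(tree$tip.label) == 1) {
    m <- matrix(0, 1, 1, dimnames = list(tree$tip.label, tree$tip.label))
    return(m)
  }
  D <- ape::cophenetic.phylo(tree)
  D[tree$tip.label, tree$tip.label]
}

#' Normalize a patristic distance matrix
#'
#' The embedding loss compares tree distances with cosine distances, so tree
#' distances are rescaled to a bounded range first. `"max_pairwise"` (default)
#' divides by the largest pairwise distance, mapping to \[0, 1\];
#' `"tree_diameter_x2"` additionally doubles, mapping to \[0, 2\] so the full
#' cosine range is usable. Both are monotone, so the ranking of pairs is
#' unchanged.
#'
#' @param D matrix from [patristic_distances()].
#' @param mode `"max_pairwise"` or `"tree_diameter_x2"`.
#' @return matrix of the same shape.
#' @export
normalize_distances <- function(D, mode = c("max_pairwise", "tree_diameter_x2")) {
  mode <- match.arg(mode)
  mx <- max(D)
  if (mx == 0) stop("all-zero distance matrix (single species?) cannot be normalized")
  if (mode == "max_pairwise") D / mx else 2 * D / mx
}

#' Cosine distance between two vectors
#'
#' One minus the cosine similarity; ranges over \[0, 2\] (0 parallel,
#' 1 orthogonal, 2 antipodal).
#'
#' @param x,y nonzero numeric vectors of equal length.
#' @return scalar in \[0, 2\].
#' @export
cosine_distance <- function(x, y) {
  nx <- sqrt(sum(x * x)); ny <- sqrt(sum(y * y))
  if (nx == 0 || ny == 0) stop("cosine distance undefined for a zero vector")
  d <- 1 - sum(x * y) / (nx * ny)
  min(max(d, 0), 2)  # clamp floating-point spill outside [0, 2]
}

# Row-normalize a matrix to unit L2 norm; errors on zero rows.
row_unit <- function(m) {
  n <- sqrt(rowSums(m * m))
  if (any(n == 0)) stop("zero vector cannot be normalized")
  m / n
}

# Cosine distances between rows of A (a x d) and rows of B (b x d): a x b.
cosine_distance_matrix <- function(A, B) {
  d <- 1 - tcrossprod(row_unit(A), row_unit(B))
  d[d < 0] <- 0
  d[d > 2] <- 2
  d
}

#' Squared-error loss between tree distances and embedding cosine distances
#'
#' For one focal species and its sampled contrast set: the sum over contrast
#' members of the squared difference between the normalized tree distance and
#' the cosine distance of the two embedding vectors.
#'
#' @param focal_vec numeric embedding of the focal species.
#' @param contrast_vecs matrix with one row per contrast species.
#' @param normalized_dists numeric vector of normalized tree distances, one
#'   per contrast row.
#' @return nonnegative scalar.
#' @export
tree_embedding_loss <- function(focal_vec, contrast_vecs, normalized_dists) {
  if (is.vector(contrast_vecs)) contrast_vecs <- matrix(contrast_vecs, nrow = 1)
  if (nrow(contrast_vecs) != length(normalized_dists)) {
    stop("contrast_vecs rows (", nrow(contrast_vecs),
         ") must match normalized_dists length (", length(normalized_dists), ")")
  }
  dc <- as.numeric(cosine_distance_matrix(matrix(focal_vec, nrow = 1), contrast_vecs))
  sum((normalized_dists - dc)^2)
}
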