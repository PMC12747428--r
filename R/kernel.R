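#' Temperature kernel on cosine distance
#'
#' `exp(-d_cos(x, y) / tau)`: 1 for parallel vectors, strictly decreasing in
#' the cosine distance; small temperatures sharpen the contrast between near
#' and far species.
#'
#' @param x,y nonzero numeric vectors.
#' @param tau temperature (> 0); default 0.05.
#' @return scalar in (0, 1\].
#' @export
kernel_similarity <- function(x, y, tau = 0.05) {
  if (tau <= 0) stop("temperature tau must be > 0")
  exp(-cosine_distance(x, y) / tau)
}

#' Species probability vectors from embedding-space positions
#'
#' Normalizes the temperature kernel between a query vector and every species
#' embedding — a soft nearest-neighbour assignment over the full species set.
#' Computed in log space with max-subtraction: at `tau = 0.05` the raw kernel
#' underflows for cosine distances beyond about 1.7.
#'
#' @param query numeric vector, or matrix with one query per row.
#' @param embeddings species x dim matrix with species row names, or a
#'   `phyloshot_embedding`.
#' @param tau temperature (> 0).
#' @return numeric matrix (queries x species) whose rows sum to 1; column
#'   names are species ids.
#' @export
species_probabilities <- function(query, embeddings, tau = 0.05) {
  if (tau <= 0) stop("temperature tau must be > 0")
  if (inherits(embeddings, "phyloshot_embedding")) {
    embeddings <- embeddings$embeddings
  }
  if (is.null(dim(embeddings)) || nrow(embeddings) == 0) {
    stop("empty embedding table")
  }
  if (is.vector(query)) query <- matrix(query, nrow = 1)
  logk <- -cosine_distance_matrix(query, embeddings) / tau
  mx <- apply(logk, 1, max)
  w <- exp(logk - mx)
  p <- w / rowSums(w)
  colnames(p) <- rownames(embeddings)
  p
}

#' Tidy per-species probabilities for a single query
#'
#' @param query numeric vector in embedding space.
#' @param embeddings species embedding matrix or fit.
#' @param tau temperature.
#' @param top_n optionally keep only the `top_n` most probable species.
#' @return tibble with `species_id`, `probability`, sorted by decreasing
#'   probability (ties by species id).
#' @export
species_probability_table <- function(query, embeddings, tau = 0.05,
                                      top_n = NULL) {
  p <- species_probabilities(query, embeddings, tau)[1, ]
  out <- tibble::tibble(species_id = names(p), probability = unname(p))
  out <- dplyr::arrange(out, dplyr::desc(.data$probability), .data$species_id)
  if (!is.null(top_n)) out <- head(out, top_n)
  out
}

#' Top-1 species prediction from a probability vector
#'
#' Argmax with deterministic tie-breaking: among tied maxima, the
#' lexicographically smallest species id wins.
#'
#' @param p named numeric probability vector, or a 1-row matrix from
#'   [species_probabilities()].
#' @return a species id (character scalar).
#' @export
top1_prediction <- function(p) {
  if (is.matrix(p)) {
    if (nrow(p) != 1) stop("use top1_predictions() for multi-row matrices")
    p <- p[1, ]
  }
  if (is.null(names(p))) stop("probability vector must be named by species")
  top1_predictions(matrix(p, nrow = 1, dimnames = list(NULL, names(p))))
}

#' Row-wise top-1 species predictions
#'
#' @param P probability matrix (queries x species, species column names).
#' @return character vector of species ids, lexicographic tie-break.
#' @export
top1_predictions <- function(P) {
  sp <- colnames(P)
  ord <- order(sp)
  Ps <- P[, ord, drop = FALSE]
  sp[ord][max.col(Ps, ties.method = "first")]
}
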