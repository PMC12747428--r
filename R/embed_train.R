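#' Configuration for species-embedding training
#'
#' Defaults follow the full-scale setting (64 dimensions, 100 epochs,
#' constant learning rate 0.01, batches of 64 focal species, AdamW).
#'
#' @param embed_dim embedding dimension (>= 2).
#' @param epochs full randomized passes over all species.
#' @param learning_rate constant AdamW learning rate.
#' @param batch_size focal species per optimizer step.
#' @param seed RNG seed controlling initialization, shuffling and contrast
#'   sampling.
#' @param distance_normalization how tree distances are rescaled before
#'   matching (see [normalize_distances()]).
#' @param weight_decay decoupled weight decay (0 disables it).
#' @return a list of class `embed_config`.
#' @export
embed_config <- function(embed_dim = 64, epochs = 100, learning_rate = 0.01,
                         batch_size = 64, seed = 1,
                         distance_normalization = c("max_pairwise",
                                                    "tree_diameter_x2"),
                         weight_decay = 0) {
  stopifnot(embed_dim >= 2, epochs >= 1, learning_rate > 0, batch_size >= 1)
  structure(list(
    embed_dim = as.integer(embed_dim), epochs = as.integer(epochs),
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    seed = as.integer(seed),
    distance_normalization = match.arg(distance_normalization),
    weight_decay = weight_decay
  ), class = "embed_config")
}

#' Learn species embeddings from a phylogeny
#'
#' Optimizes one vector per species directly (no network) by stochastic
#' gradient descent so that pairwise cosine distances match normalized
#' patristic distances. Each step takes a batch of focal species; for each
#' focal, a contrast set is freshly sampled (one species per branching point
#' on the root path, from the other branch), and the squared distance
#' mismatch over those pairs is minimized with AdamW. Vectors are initialized
#' i.i.d. Gaussian and scaled to unit norm; they are not renormalized during
#' training (cosine distance is scale-invariant).
#'
#' @param tree a validated `phylo` with >= 2 leaves.
#' @param config an [embed_config()].
#' @return object of class `phyloshot_embedding` with elements `embeddings`
#'   (species x dim matrix, row names are species ids), `loss_trace`
#'   (tibble: epoch, loss — mean per-focal loss), and `config`. Has
#'   [tidy()], [glance()] and [ggplot2::autoplot()] methods.
#' @export
train_species_embeddings <- function(tree, config = embed_config()) {
  validate_phylo(tree)
  n <- length(tree$tip.label)
  if (n < 2) stop("embedding training needs a tree with >= 2 leaves")
  Dn <- normalize_distances(patristic_distances(tree),
                            config$distance_normalization)
  idx <- contrast_index(tree)

  set.seed(config$seed)
  X <- matrix(rnorm(n * config$embed_dim), n, config$embed_dim)
  X <- row_unit(X)
  opt <- adamw_init(list(X = X), lr = config$learning_rate,
                    weight_decay = config$weight_decay)

  trace <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    epoch_loss <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      focals <- perm[start:min(start + config$batch_size - 1L, n)]
      I <- integer(0); J <- integer(0)
      for (f in focals) {
        js <- sample_contrast_idx(idx, f)
        I <- c(I, rep.int(f, length(js))); J <- c(J, js)
      }
      if (length(I) == 0) next
      X <- opt$params$X
      XI <- X[I, , drop = FALSE]; XJ <- X[J, , drop = FALSE]
      ni <- sqrt(rowSums(XI * XI)); nj <- sqrt(rowSums(XJ * XJ))
      s <- rowSums(XI * XJ) / (ni * nj)
      d <- 1 - s
      tgt <- Dn[cbind(I, J)]
      resid <- tgt - d
      batch_loss <- sum(resid^2)
      if (!is.finite(batch_loss)) {
        stop("non-finite embedding loss at epoch ", epoch,
             "; try a smaller learning rate")
      }
      epoch_loss <- epoch_loss + batch_loss
      # dL/d(cos sim) = 2 * resid ; grad of cos sim wrt each vector
      cf <- 2 * resid
      gI <- cf * (XJ / (ni * nj) - s * XI / ni^2)
      gJ <- cf * (XI / (ni * nj) - s * XJ / nj^2)
      G <- matrix(0, n, config$embed_dim)
      acc <- rowsum(rbind(gI, gJ), group = c(I, J))
      G[as.integer(rownames(acc)), ] <- acc
      opt <- adamw_step(opt, list(X = G))
    }
    trace[epoch] <- epoch_loss / n
  }
  emb <- opt$params$X
  rownames(emb) <- tree$tip.label
  structure(list(
    embeddings = emb,
    loss_trace = tibble::tibble(epoch = seq_len(config$epochs), loss = trace),
    config = config
  ), class = "phyloshot_embedding")
}

#' @export
print.phyloshot_embedding <- function(x, ...) {
  cat("<phyloshot_embedding> ", nrow(x$embeddings), " species x ",
      ncol(x$embeddings), " dims; final mean loss ",
      signif(utils::tail(x$loss_trace$loss, 1), 4), "\n", sep = "")
  invisible(x)
}

#' Tidy a species-embedding fit
#'
#' @param x a `phyloshot_embedding`.
#' @param ... unused.
#' @return tibble with `species_id` and one column per embedding dimension
#'   (`v1..vd`).
#' @export
tidy.phyloshot_embedding <- function(x, ...) {
  m <- x$embeddings
  df <- tibble::as_tibble(m, .name_repair = ~ paste0("v", seq_along(.x)))
  dplyr::bind_cols(tibble::tibble(species_id = rownames(m)), df)
}

#' One-row summary of a species-embedding fit
#'
#' @param x a `phyloshot_embedding`.
#' @param ... unused.
#' @return tibble with `n_species`, `embed_dim`, `epochs`, `final_loss`.
#' @export
glance.phyloshot_embedding <- function(x, ...) {
  tibble::tibble(
    n_species = nrow(x$embeddings),
    embed_dim = ncol(x$embeddings),
    epochs = x$config$epochs,
    final_loss = utils::tail(x$loss_trace$loss, 1)
  )
}

#' Plot the embedding training loss curve
#'
#' @param object a `phyloshot_embedding`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.phyloshot_embedding <- function(object, ...) {
  ggplot2::ggplot(object$loss_trace, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "Epoch", y = "Mean per-species loss",
                  title = "Phylogenetic embedding training") +
    ggplot2::theme_minimal()
}

#' Fidelity of an embedding to its tree
#'
#' Spearman rank correlation between all-pairs cosine distances in the
#' embedding and normalized patristic distances — the desk-scale proxy for a
#' loss-versus-dimension sweep.
#'
#' @param embeddings species x dim matrix with species row names, or a
#'   `phyloshot_embedding`.
#' @param tree the phylogeny the embedding was trained on.
#' @param mode distance normalization mode (must match training).
#' @return scalar Spearman correlation.
#' @export
embedding_tree_fidelity <- function(embeddings, tree, mode = "max_pairwise") {
  if (inherits(embeddings, "phyloshot_embedding")) {
    mode <- embeddings$config$distance_normalization
    embeddings <- embeddings$embeddings
  }
  Dn <- normalize_distances(patristic_distances(tree), mode)
  Dn <- Dn[rownames(embeddings), rownames(embeddings)]
  Dc <- cosine_distance_matrix(embeddings, embeddings)
  lt <- lower.tri(Dn)
  cor(Dn[lt], Dc[lt], method = "spearman")
}

# broom-style generics (broom is not a dependency; define our own)

#' Turn a phyloshot fit into a tidy tibble
#' @param x a fitted object.
#' @param ... passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model summary of a phyloshot fit
#' @param x a fitted object.
#' @param ... passed to methods.
#' @export
glance <- function(x, ...) UseMethod("glance")
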