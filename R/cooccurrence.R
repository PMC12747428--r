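#' Initialize a co-occurrence modulation model
#'
#' The modulation layer holds two learnable matrices `U`, `V` of shape
#' (number of species x m). A sequence's log-probabilities are shifted by
#' `U V'` applied to the mean probability vector of the other sequences at
#' the site, then renormalized with a softmax. `U` starts at zero — so the
#' untrained layer is exactly the identity — and `V` starts small Gaussian,
#' giving a smooth departure from the unmodulated model.
#'
#' @param species_ids character vector, in the embedding table's row order.
#' @param m low-rank width; default 256.
#' @param seed RNG seed for the `V` initialization.
#' @return object of class `phyloshot_cooc`.
#' @export
new_cooccurrence_model <- function(species_ids, m = 256, seed = 1) {
  n <- length(species_ids)
  stopifnot(n >= 2, m >= 1)
  set.seed(seed)
  structure(list(
    species_ids = species_ids,
    U = matrix(0, n, m),
    V = matrix(rnorm(n * m, sd = 0.1), n, m),
    m = as.integer(m),
    trained = FALSE, loss_trace = NULL, train_config = NULL
  ), class = "phyloshot_cooc")
}

#' Configuration for co-occurrence training
#'
#' One optimizer step per site visit (the batch is the site; no batching over
#' multiple sites), sites visited in seeded random order each pass.
#'
#' @param m low-rank width of `U`, `V`.
#' @param learning_rate constant AdamW learning rate.
#' @param epochs passes over the site list.
#' @param seed RNG seed (site order, sequence choice, embedding noise).
#' @param sigma std of the isotropic Gaussian added to the embeddings of
#'   co-occurring species without reference sequences; see
#'   [calibrate_noise_sigma()].
#' @param tau kernel temperature used to build the initial probability
#'   vectors.
#' @param sequenceless how species without reference sequences enter
#'   training sites: `"noise"` (noisy embeddings; default) or `"drop"`
#'   (discard them).
#' @return a list of class `cooc_config`.
#' @export
cooc_config <- function(m = 256, learning_rate = 0.001, epochs = 10, seed = 1,
                        sigma = 0.1, tau = 0.05,
                        sequenceless = c("noise", "drop")) {
  stopifnot(m >= 1, learning_rate > 0, epochs >= 1, sigma >= 0, tau > 0)
  structure(list(
    m = as.integer(m), learning_rate = learning_rate,
    epochs = as.integer(epochs), seed = as.integer(seed),
    sigma = sigma, tau = tau, sequenceless = match.arg(sequenceless)
  ), class = "cooc_config")
}

# floor probabilities before log; zeros cannot occur analytically with the
# exponential kernel but can after floating-point underflow
PROB_FLOOR <- 1e-30

row_softmax <- function(Z) {
  mx <- apply(Z, 1, max)
  w <- exp(Z - mx)
  w / rowSums(w)
}

#' Modulate one probability vector with its site context
#'
#' Applies the learned co-occurrence shift: softmax of (log p_i + U V' times
#' the mean of the other probability vectors at the site). With no other
#' sequences at the site (M = 1) the mean is undefined and `p_i` is returned
#' unchanged.
#'
#' @param p_i numeric probability vector over all species.
#' @param others list of probability vectors (or a matrix with one per row)
#'   for the co-detected sequences; may be empty.
#' @param model a `phyloshot_cooc`.
#' @return modulated probability vector, same length and names as `p_i`.
#' @export
modulate <- function(p_i, others, model) {
  nms <- names(p_i)
  if (is.matrix(others)) others <- asplit(others, 1)
  if (length(others) == 0) return(p_i)
  n <- nrow(model$U)
  if (length(p_i) != n || any(lengths(others) != n)) {
    stop("probability vectors must have length ", n,
         " (the model's species count)")
  }
  a <- Reduce(`+`, lapply(others, as.numeric)) / length(others)
  z <- log(pmax(as.numeric(p_i), PROB_FLOOR)) +
    as.numeric(model$U %*% crossprod(model$V, a))
  out <- as.numeric(row_softmax(matrix(z, nrow = 1)))
  names(out) <- nms
  out
}

# site-level batched modulation: P is M x n (one row per sequence at the
# site); each row is modulated by the mean of the other rows.
modulate_site <- function(P, model) {
  M <- nrow(P)
  if (M < 2) return(P)
  A <- (matrix(colSums(P), M, ncol(P), byrow = TRUE) - P) / (M - 1)
  Z <- log(pmax(P, PROB_FLOOR)) + (A %*% model$V) %*% t(model$U)
  out <- row_softmax(Z)
  colnames(out) <- colnames(P)
  out
}

#' Mean negative log-likelihood of the true species at one site
#'
#' @param modulated matrix (sequences x species) of modulated probability
#'   vectors, or a list of vectors.
#' @param truth integer vector of true-species column indices, one per row.
#' @return nonnegative scalar.
#' @export
site_nll <- function(modulated, truth) {
  if (is.list(modulated)) modulated <- do.call(rbind, modulated)
  M <- nrow(modulated)
  if (length(truth) != M) stop("need one truth index per probability vector")
  if (any(truth < 1 | truth > ncol(modulated))) stop("truth index out of range")
  -mean(log(pmax(modulated[cbind(seq_len(M), truth)], PROB_FLOOR)))
}

#' Initial probability vectors for the species observed at a site
#'
#' Builds the training-time inputs of the co-occurrence model. A species with
#' at least one reference sequence is represented by the DNA encoder's
#' mapping of one of its sequences (uniform seeded choice); a species without
#' any reference sequence is represented by its phylogenetic embedding plus
#' isotropic Gaussian noise (tuned to mimic the encoder's zero-shot error).
#' Each vector is then passed through the temperature kernel.
#'
#' @param site_species character vector of species observed at the site.
#' @param embeddings species x dim matrix (row names = species), or a
#'   `phyloshot_embedding`.
#' @param dna_model a trained `phyloshot_dna_encoder`.
#' @param reference reference records tibble (`species_id`, `sequence`).
#' @param sigma noise std for sequence-less species.
#' @param tau kernel temperature.
#' @return matrix (length(site_species) x n species) of probability vectors,
#'   rows named by site species.
#' @export
site_initial_probs <- function(site_species, embeddings, dna_model, reference,
                               sigma = 0.1, tau = 0.05) {
  if (inherits(embeddings, "phyloshot_embedding")) {
    embeddings <- embeddings$embeddings
  }
  missing <- setdiff(site_species, rownames(embeddings))
  if (length(missing) > 0) {
    stop("site species without an embedding: ", paste(missing, collapse = ", "))
  }
  Q <- site_query_vectors(site_species, embeddings, dna_model, reference, sigma)
  P <- species_probabilities(Q, embeddings, tau)
  rownames(P) <- site_species
  P
}

# embedding-space query vectors for a set of species (DNA-mapped when a
# reference sequence exists, noisy embedding otherwise); uses R's RNG
site_query_vectors <- function(site_species, embeddings, dna_model, reference,
                               sigma) {
  d <- ncol(embeddings)
  Q <- matrix(0, length(site_species), d)
  has_seq <- site_species %in% reference$species_id
  if (any(has_seq)) {
    seqs <- vapply(site_species[has_seq], function(sp) {
      cand <- reference$sequence[reference$species_id == sp]
      cand[sample.int(length(cand), 1L)]
    }, character(1))
    Q[has_seq, ] <- embed_sequences(dna_model, seqs)
  }
  if (any(!has_seq)) {
    E <- embeddings[site_species[!has_seq], , drop = FALSE]
    Q[!has_seq, ] <- E + matrix(rnorm(nrow(E) * d, sd = sigma), nrow(E), d)
  }
  Q
}

#' Train the co-occurrence modulation layer
#'
#' Minimizes the mean negative log-likelihood of the true species in the
#' modulated probability vectors, site by site: each site visit is one AdamW
#' step whose batch is the site's species set. Sites with a single species
#' are skipped (the modulation mean is undefined there). DNA-mapped vectors
#' for species with reference sequences are computed once; Gaussian noise for
#' sequence-less species is redrawn at every site visit.
#'
#' @param sites tibble with `site_id`, `species_id` (e.g. from
#'   [read_assemblages()] or [grid_to_cooccurrence()]).
#' @param embeddings species x dim matrix or `phyloshot_embedding`.
#' @param dna_model a trained `phyloshot_dna_encoder`.
#' @param reference reference records tibble (`species_id`, `sequence`).
#' @param config a [cooc_config()].
#' @return a trained `phyloshot_cooc` with a `loss_trace` tibble (epoch,
#'   loss = mean site NLL). Has [glance()] and [ggplot2::autoplot()] methods.
#' @export
train_cooccurrence <- function(sites, embeddings, dna_model, reference,
                               config = cooc_config()) {
  if (inherits(embeddings, "phyloshot_embedding")) {
    embeddings <- embeddings$embeddings
  }
  species_ids <- rownames(embeddings)
  n <- length(species_ids)
  if (nrow(sites) == 0) stop("no sites to train on")
  bad <- setdiff(unique(sites$species_id), species_ids)
  if (length(bad) > 0) {
    stop("site species without an embedding: ", paste(head(bad, 5), collapse = ", "))
  }
  site_list <- split(sites$species_id, sites$site_id)
  if (config$sequenceless == "drop") {
    with_seq <- unique(reference$species_id)
    site_list <- lapply(site_list, function(sp) intersect(sp, with_seq))
  }
  sizes <- lengths(site_list)
  if (any(sizes < 2)) {
    warning(sum(sizes < 2), " site(s) with fewer than 2 usable species skipped")
    site_list <- site_list[sizes >= 2]
  }
  if (length(site_list) == 0) stop("all sites degenerate (fewer than 2 species)")

  set.seed(config$seed)
  # fixed DNA-mapped query vectors for species that have sequences
  ref_species <- intersect(unique(unlist(site_list)),
                           unique(reference$species_id))
  dna_q <- NULL
  if (length(ref_species) > 0) {
    seqs <- vapply(ref_species, function(sp) {
      cand <- reference$sequence[reference$species_id == sp]
      cand[sample.int(length(cand), 1L)]
    }, character(1))
    dna_q <- embed_sequences(dna_model, seqs)
    rownames(dna_q) <- ref_species
  }
  truth_idx <- lapply(site_list, function(sp) match(sp, species_ids))

  model <- new_cooccurrence_model(species_ids, m = config$m,
                                  seed = config$seed)
  opt <- adamw_init(list(U = model$U, V = model$V),
                    lr = config$learning_rate)
  d <- ncol(embeddings)
  trace <- numeric(config$epochs)
  nsite <- length(site_list)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(nsite)
    epoch_loss <- 0
    for (k in ord) {
      sp <- site_list[[k]]
      M <- length(sp)
      Q <- matrix(0, M, d)
      has_seq <- sp %in% ref_species
      if (any(has_seq)) Q[has_seq, ] <- dna_q[sp[has_seq], , drop = FALSE]
      if (any(!has_seq)) {
        E <- embeddings[sp[!has_seq], , drop = FALSE]
        Q[!has_seq, ] <- E + matrix(rnorm(nrow(E) * d, sd = config$sigma),
                                    nrow(E), d)
      }
      P <- species_probabilities(Q, embeddings, config$tau)
      U <- opt$params$U; V <- opt$params$V
      A <- (matrix(colSums(P), M, n, byrow = TRUE) - P) / (M - 1)
      AV <- A %*% V
      Z <- log(pmax(P, PROB_FLOOR)) + AV %*% t(U)
      S <- row_softmax(Z)
      y <- truth_idx[[k]]
      loss <- -mean(log(pmax(S[cbind(seq_len(M), y)], PROB_FLOOR)))
      if (!is.finite(loss)) stop("non-finite co-occurrence loss at epoch ", epoch)
      epoch_loss <- epoch_loss + loss
      G <- S
      G[cbind(seq_len(M), y)] <- G[cbind(seq_len(M), y)] - 1
      G <- G / M
      grads <- list(U = crossprod(G, AV), V = crossprod(A, G %*% U))
      opt <- adamw_step(opt, grads)
    }
    trace[epoch] <- epoch_loss / nsite
  }
  model$U <- opt$params$U
  model$V <- opt$params$V
  model$trained <- TRUE
  model$loss_trace <- tibble::tibble(epoch = seq_len(config$epochs),
                                     loss = trace)
  model$train_config <- config
  model
}

#' Derive site assemblages from an occurrence grid
#'
#' Treats any two species as co-occurring when they are present in the same
#' grid cell: each occupied cell becomes one site containing every species
#' present there. Single-species cells are kept (they are filtered at
#' training time).
#'
#' @param grid tibble with `species_id`, `cell_row`, `cell_col` (integer cell
#'   coordinates, e.g. a 1-degree grid).
#' @return tibble with `site_id` (`"cell_<row>_<col>"`), `species_id`.
#' @export
grid_to_cooccurrence <- function(grid) {
  if (nrow(grid) == 0) stop("empty occurrence grid")
  stopifnot(all(c("species_id", "cell_row", "cell_col") %in% names(grid)))
  out <- tibble::tibble(
    site_id = paste0("cell_", grid$cell_row, "_", grid$cell_col),
    species_id = grid$species_id
  )
  dplyr::distinct(out)
}

#' Calibrate the embedding-noise standard deviation
#'
#' Finds `sigma` such that the median cosine distance between a species
#' embedding and its noisy copy matches a target — typically the DNA
#' encoder's median mapping error on held-out species, so that noisy
#' embeddings of sequence-less species look like realistic encoder outputs.
#'
#' @param embeddings species x dim matrix or `phyloshot_embedding`.
#' @param target_dcos target median cosine perturbation.
#' @param n_draws Monte Carlo draws per candidate sigma.
#' @param seed RNG seed.
#' @return calibrated `sigma` (scalar).
#' @export
calibrate_noise_sigma <- function(embeddings, target_dcos, n_draws = 400,
                                  seed = 1) {
  if (inherits(embeddings, "phyloshot_embedding")) {
    embeddings <- embeddings$embeddings
  }
  stopifnot(target_dcos >= 0, target_dcos < 2)
  if (target_dcos == 0) return(0)
  set.seed(seed)
  d <- ncol(embeddings)
  rows <- sample.int(nrow(embeddings), n_draws, replace = TRUE)
  E <- embeddings[rows, , drop = FALSE]
  Z <- matrix(rnorm(n_draws * d), n_draws, d)
  med_pert <- function(sigma) {
    N <- E + sigma * Z
    median(1 - rowSums(E * N) / (sqrt(rowSums(E^2)) * sqrt(rowSums(N^2))))
  }
  lo <- 1e-4; hi <- 10
  for (i in 1:60) {
    mid <- sqrt(lo * hi)
    if (med_pert(mid) < target_dcos) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' @export
print.phyloshot_cooc <- function(x, ...) {
  cat("<phyloshot_cooc> ", nrow(x$U), " species, m=", x$m,
      if (x$trained) paste0("; trained, final NLL ",
                            signif(utils::tail(x$loss_trace$loss, 1), 4))
      else "; untrained", "\n", sep = "")
  invisible(x)
}

#' One-row summary of a co-occurrence model
#'
#' @param x a `phyloshot_cooc`.
#' @param ... unused.
#' @return tibble with size fields and the final mean site NLL.
#' @export
glance.phyloshot_cooc <- function(x, ...) {
  tibble::tibble(
    n_species = nrow(x$U), m = x$m,
    epochs = if (x$trained) x$train_config$epochs else NA_integer_,
    final_nll = if (x$trained) utils::tail(x$loss_trace$loss, 1) else NA_real_
  )
}

#' Plot the co-occurrence training loss curve
#'
#' @param object a trained `phyloshot_cooc`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.phyloshot_cooc <- function(object, ...) {
  if (!object$trained) stop("co-occurrence model has not been trained")
  ggplot2::ggplot(object$loss_trace,
                  ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::labs(x = "Pass over sites", y = "Mean site NLL",
                  title = "Co-occurrence modulation training") +
    ggplot2::theme_minimal()
}
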