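#' Configuration for DNA-encoder training
#'
#' Defaults follow the full-scale setting: learning rate 1e-3, AdamW, batch
#' size 16, a fixed number of epochs with no early stopping and no validation
#' split. `holdout` species are excluded from every training batch; their
#' sequences are what the zero-shot evaluation queries.
#'
#' @param learning_rate constant AdamW learning rate.
#' @param batch_size sequences per optimizer step.
#' @param epochs fixed number of passes over the training records.
#' @param seed RNG seed for shuffling.
#' @param holdout character vector of species ids to exclude from training.
#' @return a list of class `dna_train_config`.
#' @export
dna_train_config <- function(learning_rate = 1e-3, batch_size = 16,
                             epochs = 30, seed = 1, holdout = character(0)) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(list(
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), seed = as.integer(seed),
    holdout = as.character(holdout)
  ), class = "dna_train_config")
}

#' Train the DNA encoder against frozen species embeddings
#'
#' Each (sequence, species) reference record is a training example; the loss
#' is the cosine distance between the encoder's output and the species'
#' fixed phylogenetic embedding. Species embeddings are never updated.
#' Training runs for a fixed number of epochs with seeded shuffling — no
#' early stopping, no validation split. Records of `holdout` species are
#' removed before the first batch; duplicate sequences shared by several
#' species each stay as their own example.
#'
#' @param records tibble with `species_id` and `sequence` columns (e.g. from
#'   [read_reference_db()]).
#' @param embeddings species x dim matrix with species row names, or a
#'   `phyloshot_embedding`.
#' @param config a [dna_train_config()].
#' @param model optionally, an untrained [new_dna_encoder()] to control the
#'   architecture; by default one is created with `embed_dim` matching the
#'   embeddings and all other architecture defaults.
#' @return the trained `phyloshot_dna_encoder` with a `loss_trace` tibble
#'   (epoch, loss = mean per-sequence cosine loss). Has [glance()] and
#'   [ggplot2::autoplot()] methods.
#' @export
train_dna_encoder <- function(records, embeddings, config = dna_train_config(),
                              model = NULL) {
  if (inherits(embeddings, "phyloshot_embedding")) {
    embeddings <- embeddings$embeddings
  }
  stopifnot(is.matrix(embeddings), !is.null(rownames(embeddings)))
  records <- records[!(records$species_id %in% config$holdout), , drop = FALSE]
  if (nrow(records) == 0) stop("no training records left after holdout removal")
  missing <- setdiff(unique(records$species_id), rownames(embeddings))
  if (length(missing) > 0) {
    stop("training species without an embedding: ",
         paste(head(missing, 5), collapse = ", "))
  }
  if (is.null(model)) {
    model <- new_dna_encoder(embed_dim = ncol(embeddings), seed = config$seed)
  }
  if (model$embed_dim != ncol(embeddings)) {
    stop("encoder embed_dim (", model$embed_dim,
         ") does not match embedding dimension (", ncol(embeddings), ")")
  }
  tokens <- encode_sequences(records$sequence, model$max_len)
  tgt_all <- embeddings[records$species_id, , drop = FALSE]
  tgt_norm <- sqrt(rowSums(tgt_all^2))
  if (any(tgt_norm == 0)) stop("zero-norm species embedding")

  nrec <- nrow(records)
  set.seed(config$seed)
  opt <- adamw_init(model$params, lr = config$learning_rate)
  trace <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(nrec)
    epoch_loss <- 0
    for (start in seq(1, nrec, by = config$batch_size)) {
      ids <- perm[start:min(start + config$batch_size - 1L, nrec)]
      model$params <- opt$params
      cache <- encoder_forward_full(model, tokens[ids, , drop = FALSE],
                                    keep_cache = TRUE)
      out <- cache$out
      Tm <- tgt_all[ids, , drop = FALSE]
      no <- sqrt(rowSums(out^2)); nt <- tgt_norm[ids]
      s <- rowSums(out * Tm) / (no * nt)
      loss <- sum(1 - s)
      if (!is.finite(loss)) {
        stop("non-finite encoder loss at epoch ", epoch,
             "; try a smaller learning rate")
      }
      epoch_loss <- epoch_loss + loss
      B <- length(ids)
      dOut <- -(Tm / (no * nt) - s * out / no^2) / B
      grads <- encoder_backward(model, cache, dOut)
      opt <- adamw_step(opt, grads)
    }
    trace[epoch] <- epoch_loss / nrec
  }
  model$params <- opt$params
  model$trained <- TRUE
  model$loss_trace <- tibble::tibble(epoch = seq_len(config$epochs),
                                     loss = trace)
  model$train_config <- config
  model$species_fingerprint <- embedding_fingerprint(embeddings)
  model
}

# cheap fingerprint used to detect model/embedding species-order mismatches
embedding_fingerprint <- function(embeddings) {
  paste0(nrow(embeddings), ":", ncol(embeddings), ":",
         substr(paste(rownames(embeddings), collapse = ","), 1, 1000))
}

#' @export
print.phyloshot_dna_encoder <- function(x, ...) {
  cat("<phyloshot_dna_encoder> d=", x$embed_dim, ", channels=", x$channels,
      ", hidden=", x$hidden_dim, ", max_len=", x$max_len,
      if (x$trained) paste0("; trained, final loss ",
                            signif(utils::tail(x$loss_trace$loss, 1), 4))
      else "; untrained", "\n", sep = "")
  invisible(x)
}

#' One-row summary of a trained DNA encoder
#'
#' @param x a `phyloshot_dna_encoder`.
#' @param ... unused.
#' @return tibble with architecture fields and the final mean cosine loss.
#' @export
glance.phyloshot_dna_encoder <- function(x, ...) {
  tibble::tibble(
    embed_dim = x$embed_dim, channels = x$channels,
    hidden_dim = x$hidden_dim, max_len = x$max_len,
    aggregation = x$aggregation,
    epochs = if (x$trained) x$train_config$epochs else NA_integer_,
    final_loss = if (x$trained) utils::tail(x$loss_trace$loss, 1) else NA_real_
  )
}

#' Plot the DNA-encoder training loss curve
#'
#' @param object a trained `phyloshot_dna_encoder`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.phyloshot_dna_encoder <- function(object, ...) {
  if (!object$trained) stop("encoder has not been trained")
  ggplot2::ggplot(object$loss_trace,
                  ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "Epoch", y = "Mean cosine mapping loss",
                  title = "DNA encoder training") +
    ggplot2::theme_minimal()
}
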