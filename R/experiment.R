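#' Run the full zero-shot evaluation protocol on a synthetic world
#'
#' Trains the three components on a [build_synthetic_world()] and evaluates
#' them the way the method is meant to be validated:
#'
#' 1. species embeddings from the world's tree;
#' 2. the DNA encoder on the reference records (gap species, which have no
#'    reference sequences, are the zero-shot holdout);
#' 3. the embedding noise level, calibrated so the median cosine
#'    perturbation matches the encoder's median mapping error on the gap
#'    species' true sequences;
#' 4. co-occurrence models on the community assemblages and/or on the
#'    occurrence-grid co-occurrences;
#' 5. per-species macro-averaged rank accuracies for every method
#'    ("single" = kernel on the DNA mapping alone; "community"/"grid" =
#'    single + the corresponding trained modulation, applied at the sites
#'    where the species occurs, using DNA-mapped vectors for co-occurring
#'    species with sequences and noisy embeddings for the rest).
#'
#' Training species are scored on their reference sequences; gap (holdout)
#' species on their true sequences, which the encoder never saw. Both sets
#' are restricted to species observed in at least one assemblage so that
#' modulated and unmodulated scores cover the same species.
#'
#' The default problem sizes are the package's desk-scale choices (embedding
#' dimension 32, encoder channels 32 / hidden 256 / padded length 96,
#' modulation rank 256); the full-scale defaults of the individual
#' constructors remain available through the arguments.
#'
#' @param world a `phyloshot_world`.
#' @param seed seed for this experiment (defaults to the world's).
#' @param embed_dim,embed_epochs species-embedding size and epochs.
#' @param encoder_channels,encoder_hidden,encoder_max_len,encoder_epochs
#'   encoder architecture and training length.
#' @param cooc_m,cooc_epochs modulation rank and passes over sites.
#' @param max_sites_per_species at most this many sites (seeded draw) per
#'   species in the modulated evaluation.
#' @param tau kernel temperature.
#' @param methods which co-occurrence models to train: subset of
#'   `c("community", "grid")`.
#' @return object of class `phyloshot_experiment`: list with `embedding_fit`,
#'   `encoder`, `cooc` (named list of trained models), `sigma`,
#'   `fidelity` (embedding-tree Spearman), `accuracy` (tibble: dataset,
#'   method, rank, accuracy, n_species) and `predictions` (tibble: dataset,
#'   method, species_id, predicted, probability, correctness flags per rank).
#' @export
zero_shot_experiment <- function(world, seed = world$seed,
                                 embed_dim = 32, embed_epochs = 100,
                                 encoder_channels = 32, encoder_hidden = 256,
                                 encoder_max_len = 96, encoder_epochs = 30,
                                 cooc_m = 256, cooc_epochs = 10,
                                 max_sites_per_species = 3, tau = 0.05,
                                 methods = c("community", "grid")) {
  methods <- match.arg(methods, several.ok = TRUE)
  emb_fit <- train_species_embeddings(
    world$tree, embed_config(embed_dim = embed_dim, epochs = embed_epochs,
                             seed = seed))
  E <- emb_fit$embeddings
  arch <- new_dna_encoder(embed_dim = embed_dim, channels = encoder_channels,
                          hidden_dim = encoder_hidden,
                          max_len = encoder_max_len, seed = seed)
  encoder <- train_dna_encoder(
    world$reference, E,
    dna_train_config(epochs = encoder_epochs, seed = seed,
                     holdout = world$gap_species),
    model = arch)

  # noise level: match the encoder's median zero-shot mapping error
  hold_q <- embed_sequences(encoder, unname(world$sequences[world$gap_species]))
  hold_err <- vapply(seq_along(world$gap_species), function(i) {
    cosine_distance(hold_q[i, ], E[world$gap_species[i], ])
  }, numeric(1))
  sigma <- calibrate_noise_sigma(E, median(hold_err), seed = seed)

  site_tabs <- list(community = world$sites)
  if ("grid" %in% methods) site_tabs$grid <- grid_to_cooccurrence(world$grid)
  cooc <- list()
  for (m in methods) {
    cooc[[m]] <- train_cooccurrence(
      site_tabs[[m]], E, encoder, world$reference,
      cooc_config(m = cooc_m, epochs = cooc_epochs, seed = seed,
                  sigma = sigma, tau = tau))
  }

  # ---- evaluation queries -------------------------------------------------
  observed <- unique(world$sites$species_id)
  hold_sp <- intersect(world$gap_species, observed)
  train_sp <- intersect(setdiff(rownames(E), world$gap_species), observed)
  train_rec <- world$reference[world$reference$species_id %in% train_sp, ]
  queries <- dplyr::bind_rows(
    tibble::tibble(dataset = "holdout", species_id = hold_sp,
                   sequence = unname(world$sequences[hold_sp])),
    tibble::tibble(dataset = "train", species_id = train_rec$species_id,
                   sequence = train_rec$sequence)
  )
  Qp <- species_probabilities(embed_sequences(encoder, queries$sequence),
                              E, tau)

  preds <- list()
  single <- tibble::tibble(
    dataset = queries$dataset, method = "single",
    species_id = queries$species_id,
    predicted = top1_predictions(Qp),
    probability = apply(Qp, 1, max)
  )
  preds[["single"]] <- single

  if (length(methods) > 0) {
    # per-species context probability vectors (fixed per experiment):
    # DNA-mapped for species with sequences, noisy embeddings for the rest
    set.seed(seed + 7L)
    Cq <- site_query_vectors(rownames(E), E, encoder, world$reference, sigma)
    Cp <- species_probabilities(Cq, E, tau)
    rownames(Cp) <- rownames(E)
    site_list <- split(world$sites$species_id, world$sites$site_id)
    site_sum <- t(vapply(site_list, function(sp) colSums(Cp[sp, , drop = FALSE]),
                         numeric(ncol(Cp))))
    site_size <- lengths(site_list)
    sites_of <- split(rep(names(site_list), site_size),
                      unlist(site_list, use.names = FALSE))
    # evaluation units: query x (up to max_sites_per_species of its sites)
    set.seed(seed + 11L)
    picked <- lapply(sites_of, function(s) {
      if (length(s) <= max_sites_per_species) s
      else sample(s, max_sites_per_species)
    })
    unit_q <- integer(0); unit_site <- character(0)
    for (qi in seq_len(nrow(queries))) {
      ss <- picked[[queries$species_id[qi]]]
      ss <- ss[site_size[ss] >= 2]
      unit_q <- c(unit_q, rep.int(qi, length(ss)))
      unit_site <- c(unit_site, ss)
    }
    M <- site_size[unit_site]
    A <- (site_sum[unit_site, , drop = FALSE] -
            Cp[queries$species_id[unit_q], , drop = FALSE]) / (M - 1)
    logP <- log(pmax(Qp[unit_q, , drop = FALSE], PROB_FLOOR))
    for (m in methods) {
      Z <- logP + (A %*% cooc[[m]]$V) %*% t(cooc[[m]]$U)
      S <- row_softmax(Z)
      colnames(S) <- colnames(Qp)
      preds[[m]] <- tibble::tibble(
        dataset = queries$dataset[unit_q], method = m,
        species_id = queries$species_id[unit_q],
        predicted = top1_predictions(S),
        probability = apply(S, 1, max)
      )
    }
  }
  predictions <- dplyr::bind_rows(preds)
  tax <- world$taxonomy
  ti <- match(predictions$species_id, tax$species_id)
  pi <- match(predictions$predicted, tax$species_id)
  predictions$correct_species <- predictions$predicted == predictions$species_id
  predictions$correct_genus <- tax$genus[pi] == tax$genus[ti]
  predictions$correct_family <- tax$family[pi] == tax$family[ti]
  predictions$correct_order <- tax$order[pi] == tax$order[ti]

  accuracy <- predictions |>
    dplyr::group_by(.data$dataset, .data$method) |>
    dplyr::group_modify(function(df, key) {
      ev <- rank_accuracy(df, tax)
      out <- ev$summary
      out$n_species <- ev$n_species
      out
    }) |>
    dplyr::ungroup()

  structure(list(
    embedding_fit = emb_fit, encoder = encoder, cooc = cooc, sigma = sigma,
    fidelity = embedding_tree_fidelity(emb_fit, world$tree),
    accuracy = accuracy, predictions = predictions
  ), class = "phyloshot_experiment")
}

#' @export
print.phyloshot_experiment <- function(x, ...) {
  cat("<phyloshot_experiment> embedding fidelity (Spearman) ",
      signif(x$fidelity, 3), "; noise sigma ", signif(x$sigma, 3), "\n",
      sep = "")
  print(tidyr::pivot_wider(x$accuracy, names_from = "rank",
                           values_from = "accuracy"))
  invisible(x)
}

#' Tidy experiment accuracies
#' @param x a `phyloshot_experiment`.
#' @param ... unused.
#' @return the accuracy tibble (dataset, method, rank, accuracy, n_species).
#' @export
tidy.phyloshot_experiment <- function(x, ...) x$accuracy

#' One-row experiment summary
#' @param x a `phyloshot_experiment`.
#' @param ... unused.
#' @return tibble with embedding fidelity, noise sigma and the headline
#'   species-level accuracies.
#' @export
glance.phyloshot_experiment <- function(x, ...) {
  sp <- x$accuracy[x$accuracy$rank == "species", ]
  key <- paste0(sp$dataset, "_", sp$method, "_species_acc")
  out <- tibble::as_tibble(as.list(setNames(sp$accuracy, key)))
  dplyr::bind_cols(tibble::tibble(fidelity = x$fidelity, sigma = x$sigma), out)
}

#' Plot experiment rank accuracies
#'
#' @param object a `phyloshot_experiment`.
#' @param ... unused.
#' @return a ggplot faceted by dataset (training vs zero-shot holdout).
#' @exportS3Method ggplot2::autoplot
autoplot.phyloshot_experiment <- function(object, ...) {
  ggplot2::ggplot(object$accuracy,
                  ggplot2::aes(x = .data$rank, y = .data$accuracy,
                               fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~ .data$dataset) +
    ggplot2::labs(x = "Taxonomic rank", y = "Top-1 accuracy",
                  title = "Zero-shot evaluation") +
    ggplot2::theme_minimal()
}
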