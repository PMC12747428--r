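# all length-1-deletion variants of one sequence (plus the sequence itself):
# two sequences are within edit distance 1 only if they share one of these
# keys, so the keys index candidate neighbours; candidates are verified with
# an exact edit-distance computation (shared keys can also arise at distance
# 2).
deletion_keys <- function(s) {
  l <- nchar(s)
  if (l == 1) return(c(s, ""))
  c(s, paste0(substring(s, 1, 0:(l - 1)), substring(s, 2:(l + 1), l)))
}

#' Cluster reads by iterative single-linkage at small edit distance
#'
#' A simplified SWARM-style clustering: reads are dereplicated, then grown
#' into clusters by single linkage — starting from the most abundant
#' unassigned sequence, repeatedly absorbing unassigned sequences within
#' edit distance `d` of any cluster member. Clusters whose total abundance
#' falls below `min_size` are discarded (their abundance is reported in the
#' `filtered_abundance` attribute). Deterministic given the input: ties in
#' abundance break by lexicographically smallest sequence.
#'
#' @param reads a tibble with `sequence` and optional `count` column, a
#'   character vector of sequences, or a FASTA path (usearch-style
#'   `;size=N` abundances honoured).
#' @param d single-linkage edit-distance threshold (default 1, the SWARM
#'   default).
#' @param min_size minimum total cluster abundance to retain (default 3).
#' @return tibble with `cluster_id`, `representative` (most abundant member
#'   sequence), `abundance` (total read copies), `n_unique` (distinct member
#'   sequences) and `members` (list column of member tibbles). Attribute
#'   `filtered_abundance` holds the total abundance of discarded clusters.
#' @export
cluster_reads <- function(reads, d = 1, min_size = 3) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    reads <- read_reads_fasta(reads)
  }
  if (is.character(reads)) {
    reads <- tibble::tibble(sequence = reads, count = 1L)
  }
  empty <- tibble::tibble(cluster_id = character(), representative = character(),
                          abundance = integer(), n_unique = integer(),
                          members = list())
  attr(empty, "filtered_abundance") <- 0L
  if (nrow(reads) == 0) return(empty)
  if (!"count" %in% names(reads)) reads$count <- 1L
  derep <- reads |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$sequence)
  nu <- nrow(derep)
  # candidate neighbour pairs via shared deletion keys (d = 1 fast path),
  # else all pairs; verified by exact edit distance
  if (nu > 1) {
    if (d == 1) {
      keys <- lapply(derep$sequence, deletion_keys)
      key_df <- data.frame(key = unlist(keys),
                           idx = rep.int(seq_len(nu), lengths(keys)))
      groups <- split(key_df$idx, key_df$key)
      groups <- groups[lengths(groups) > 1]
      pairs <- unique(do.call(rbind, lapply(groups, function(g) {
        g <- sort(unique(g))
        if (length(g) < 2) return(NULL)
        t(utils::combn(g, 2))
      })))
    } else {
      pairs <- t(utils::combn(seq_len(nu), 2))
    }
    if (!is.null(pairs) && nrow(pairs) > 0) {
      keep <- vapply(seq_len(nrow(pairs)), function(k) {
        utils::adist(derep$sequence[pairs[k, 1]],
                     derep$sequence[pairs[k, 2]])[1, 1] <= d
      }, logical(1))
      pairs <- pairs[keep, , drop = FALSE]
    }
  } else {
    pairs <- matrix(integer(0), 0, 2)
  }
  if (is.null(pairs) || nrow(pairs) == 0) {
    comp <- seq_len(nu)          # no neighbours: every sequence its own cluster
  } else {
    g <- igraph::make_empty_graph(nu, directed = FALSE)
    g <- igraph::add_edges(g, t(pairs))
    comp <- igraph::components(g)$membership
  }
  # seed order: most abundant first (derep already sorted), so clusters are
  # numbered by decreasing seed abundance
  seen <- logical(max(comp))
  out <- list()
  filtered <- 0L
  for (i in seq_len(nu)) {
    cid <- comp[i]
    if (seen[cid]) next
    seen[cid] <- TRUE
    members <- derep[comp == cid, , drop = FALSE]
    ab <- sum(members$count)
    if (ab < min_size) {
      filtered <- filtered + ab
      next
    }
    rep_seq <- members$sequence[order(-members$count, members$sequence)][1]
    out[[length(out) + 1]] <- tibble::tibble(
      representative = rep_seq, abundance = as.integer(ab),
      n_unique = nrow(members), members = list(members)
    )
  }
  if (length(out) == 0) {
    attr(empty, "filtered_abundance") <- as.integer(filtered)
    return(empty)
  }
  res <- dplyr::bind_rows(out)
  res <- dplyr::bind_cols(
    tibble::tibble(cluster_id = sprintf("cl%04d", seq_len(nrow(res)))), res)
  attr(res, "filtered_abundance") <- as.integer(filtered)
  res
}

#' Annotate an eDNA sample end to end
#'
#' Clusters the sample's reads, embeds each cluster representative with the
#' DNA encoder, converts the positions to species probabilities with the
#' temperature kernel and — when a co-occurrence model is supplied and
#' `use_modulation` is `TRUE` — modulates each cluster's probabilities with
#' the unmodulated vectors of all other clusters in the sample (a single
#' pass). Every retained cluster receives a species-level prediction.
#'
#' @param reads reads as accepted by [cluster_reads()].
#' @param dna_model a trained `phyloshot_dna_encoder`.
#' @param embeddings species x dim matrix or `phyloshot_embedding`.
#' @param cooc_model optional trained `phyloshot_cooc`.
#' @param tau kernel temperature.
#' @param use_modulation apply co-occurrence modulation (requires
#'   `cooc_model`).
#' @param min_cluster_size minimum cluster abundance (default 3).
#' @param d clustering edit-distance threshold.
#' @param pre_clustered treat each input record as an already-clustered
#'   representative (abundance = its count), skipping clustering.
#' @param top_k how many top species to keep per cluster.
#' @return annotation tibble: `cluster_id`, `abundance`, `representative`,
#'   `species_id` (top-1), `probability`, and `top_k` (list column of
#'   per-cluster tibbles `species_id`, `probability`). Empty when no cluster
#'   survives filtering (with a warning).
#' @export
annotate_sample <- function(reads, dna_model, embeddings, cooc_model = NULL,
                            tau = 0.05, use_modulation = !is.null(cooc_model),
                            min_cluster_size = 3, d = 1,
                            pre_clustered = FALSE, top_k = 5) {
  if (inherits(embeddings, "phyloshot_embedding")) {
    embeddings <- embeddings$embeddings
  }
  if (!is.null(dna_model$species_fingerprint) &&
      !identical(dna_model$species_fingerprint,
                 embedding_fingerprint(embeddings))) {
    stop("DNA model was trained against a different embedding table ",
         "(species fingerprint mismatch)")
  }
  if (use_modulation) {
    if (is.null(cooc_model)) stop("use_modulation requires a cooc_model")
    if (!identical(cooc_model$species_ids, rownames(embeddings))) {
      stop("co-occurrence model species order does not match the embeddings")
    }
  }
  if (pre_clustered) {
    if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
      reads <- read_reads_fasta(reads)
    }
    if (is.character(reads)) reads <- tibble::tibble(sequence = reads, count = 1L)
    if (!"count" %in% names(reads)) reads$count <- 1L
    clusters <- tibble::tibble(
      cluster_id = sprintf("cl%04d", seq_len(nrow(reads))),
      representative = reads$sequence,
      abundance = as.integer(reads$count),
      n_unique = 1L,
      members = lapply(seq_len(nrow(reads)), function(i) {
        tibble::tibble(sequence = reads$sequence[i], count = reads$count[i])
      })
    )
  } else {
    clusters <- cluster_reads(reads, d = d, min_size = min_cluster_size)
  }
  if (nrow(clusters) == 0) {
    warning("no cluster survived filtering; returning an empty annotation table")
    return(tibble::tibble(cluster_id = character(), abundance = integer(),
                          representative = character(),
                          species_id = character(), probability = double(),
                          top_k = list()))
  }
  Q <- embed_sequences(dna_model, clusters$representative)
  P <- species_probabilities(Q, embeddings, tau)
  if (use_modulation && nrow(P) >= 2) {
    P <- modulate_site(P, cooc_model)
  }
  pred <- top1_predictions(P)
  prob <- P[cbind(seq_len(nrow(P)), match(pred, colnames(P)))]
  topk <- lapply(seq_len(nrow(P)), function(i) {
    ord <- order(-P[i, ], colnames(P))[seq_len(min(top_k, ncol(P)))]
    tibble::tibble(species_id = colnames(P)[ord],
                   probability = unname(P[i, ord]))
  })
  tibble::tibble(
    cluster_id = clusters$cluster_id,
    abundance = clusters$abundance,
    representative = clusters$representative,
    species_id = pred,
    probability = unname(prob),
    top_k = topk
  )
}
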