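#' Read and validate a species phylogeny
#'
#' Reads a Newick file with branch lengths and checks the invariants the rest
#' of the pipeline relies on: a single root, unique non-empty leaf labels, and
#' nonnegative branch lengths on every edge.
#'
#' @param path path to a Newick file.
#' @return an [ape::read.tree()] `phylo` object that passed validation.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1):1,C:2);", tf)
#' tr <- read_phylo_tree(tf)
#' tr$tip.label
read_phylo_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tree <- tryCatch(
    ape::read.tree(path),
    error = function(e) stop("malformed Newick in '", path, "': ",
                             conditionMessage(e), call. = FALSE),
    warning = function(w) stop("malformed Newick in '", path, "': ",
                               conditionMessage(w), call. = FALSE)
  )
  if (is.null(tree)) stop("malformed Newick in '", path, "' (parser returned nothing)")
  validate_phylo(tree)
  tree
}

#' Validate a `phylo` object against the pipeline's tree invariants
#'
#' @param tree an [ape] `phylo` object.
#' @return `tree`, invisibly, if valid; otherwise an error.
#' @export
validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  n <- length(tree$tip.label)
  if (n < 1) stop("tree has no leaves")
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; every edge must carry one")
  }
  if (anyNA(tree$edge.length)) {
    bad <- which(is.na(tree$edge.length))[1]
    stop("missing branch length on edge ", tree$edge[bad, 1], "->",
         tree$edge[bad, 2])
  }
  if (any(tree$edge.length < 0)) {
    bad <- which(tree$edge.length < 0)[1]
    stop("negative branch length on edge ", tree$edge[bad, 1], "->",
         tree$edge[bad, 2])
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  if (any(!nzchar(tree$tip.label))) stop("empty leaf label")
  if (n >= 2) {
    # exactly one root: one node that never appears as a child
    kids <- tree$edge[, 2]
    parents <- tree$edge[, 1]
    roots <- setdiff(unique(parents), kids)
    if (length(roots) != 1) stop("tree must have exactly one root, found ",
                                 length(roots))
  }
  invisible(tree)
}

#' Write a phylogeny to Newick
#'
#' @param tree a `phylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylo_tree <- function(tree, path) {
  validate_phylo(tree)
  ape::write.tree(tree, file = path)
  invisible(path)
}

# Species id from a FASTA header line (without ">"):
# first whitespace-delimited token; if it contains "|", the species id is the
# part after the first "|" (accession|Genus_species convention).
header_species_id <- function(headers) {
  tok <- sub("\\s.*$", "", headers)
  has_pipe <- grepl("|", tok, fixed = TRUE)
  tok[has_pipe] <- sub("^[^|]*\\|", "", tok[has_pipe])
  tok
}

#' Read a reference sequence database and its taxonomy
#'
#' The FASTA header convention is strict and documented: the species id is the
#' first whitespace-delimited token of the header, or — when that token
#' contains a `|` — the part after the first `|`
#' (`>ACC123|Gadus_morhua desc...`). A `species_map` named character vector
#' (full header token -> species id) overrides the convention for awkward
#' headers. Multiple sequences per species are allowed and kept.
#'
#' @param fasta_path FASTA file of reference marker sequences.
#' @param taxonomy_path TSV with columns `species_id`, `genus`, `family`,
#'   `order` (header row required).
#' @param species_map optional named character vector mapping header tokens to
#'   species ids.
#' @return a list with `records` (tibble: `sequence_id`, `species_id`,
#'   `sequence`) and `taxonomy` (tibble: `species_id`, `genus`, `family`,
#'   `order`).
#' @export
read_reference_db <- function(fasta_path, taxonomy_path, species_map = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  headers <- names(seqs)
  if (is.null(headers) || any(!nzchar(headers))) stop("FASTA record without a header")
  sequence <- as.character(seqs)
  if (any(nchar(sequence) == 0)) {
    stop("empty sequence for record(s): ",
         paste(head(headers[nchar(sequence) == 0], 5), collapse = ", "))
  }
  tok <- sub("\\s.*$", "", headers)
  species_id <- header_species_id(headers)
  if (!is.null(species_map)) {
    hit <- tok %in% names(species_map)
    species_id[hit] <- unname(species_map[tok[hit]])
  }
  taxonomy <- read_taxonomy(taxonomy_path)
  missing <- setdiff(unique(species_id), taxonomy$species_id)
  if (length(missing) > 0) {
    stop("species in FASTA absent from taxonomy: ",
         paste(missing, collapse = ", "))
  }
  records <- tibble::tibble(
    sequence_id = tok,
    species_id = species_id,
    sequence = unname(toupper(sequence))
  )
  list(records = records, taxonomy = taxonomy)
}

#' Read a species taxonomy table
#'
#' @param path TSV with header `species_id`, `genus`, `family`, `order`.
#' @return tibble with those four character columns.
#' @export
read_taxonomy <- function(path) {
  tax <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  needed <- c("species_id", "genus", "family", "order")
  if (!all(needed %in% names(tax))) {
    stop("taxonomy TSV must have columns: ", paste(needed, collapse = ", "))
  }
  tax <- tax[needed]
  if (any(!stats::complete.cases(tax)) || any(as.matrix(tax) == "")) {
    stop("taxonomy contains empty rank values")
  }
  if (anyDuplicated(tax$species_id)) {
    stop("duplicate species_id in taxonomy: ",
         paste(unique(tax$species_id[duplicated(tax$species_id)]), collapse = ", "))
  }
  tax
}

#' Read site-by-species assemblage data
#'
#' Rows are `(site_id, species_id)` pairs in a TSV (header row required).
#' Duplicate pairs within a site are collapsed with a warning. If `species`
#' (e.g. a tree's leaf set) is supplied, unknown species are either dropped
#' with a warning (default) or raise an error.
#'
#' @param path TSV with columns `site_id`, `species_id`.
#' @param species optional character vector of known species ids.
#' @param unknown what to do with species not in `species`: `"drop"` or
#'   `"error"`.
#' @return tibble with columns `site_id`, `species_id`, one row per
#'   (site, species) pair.
#' @export
read_assemblages <- function(path, species = NULL,
                             unknown = c("drop", "error")) {
  unknown <- match.arg(unknown)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (nrow(df) == 0) {
    return(tibble::tibble(site_id = character(), species_id = character()))
  }
  if (!all(c("site_id", "species_id") %in% names(df))) {
    stop("assemblage TSV must have columns site_id, species_id")
  }
  df <- tibble::as_tibble(df[c("site_id", "species_id")])
  ndup <- sum(duplicated(df))
  if (ndup > 0) {
    warning(ndup, " duplicate (site, species) row(s) collapsed")
    df <- dplyr::distinct(df)
  }
  if (!is.null(species)) {
    bad <- setdiff(unique(df$species_id), species)
    if (length(bad) > 0) {
      if (unknown == "error") {
        stop("unknown species in assemblages: ", paste(bad, collapse = ", "))
      }
      warning(length(bad), " unknown species dropped from assemblages: ",
              paste(head(bad, 5), collapse = ", "),
              if (length(bad) > 5) ", ..." else "")
      df <- df[df$species_id %in% species, , drop = FALSE]
    }
  }
  df
}

#' Read demultiplexed reads with optional usearch-style abundances
#'
#' FASTA headers may carry `;size=N` annotations; absent annotations count as
#' one copy each.
#'
#' @param path FASTA of primer-trimmed reads.
#' @return tibble with `read_id`, `sequence`, `count`.
#' @export
read_reads_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  headers <- sub("\\s.*$", "", names(seqs))
  count <- rep(1L, length(seqs))
  has_size <- grepl(";size=\\d+", headers)
  count[has_size] <- as.integer(sub("^.*;size=(\\d+).*$", "\\1", headers[has_size]))
  tibble::tibble(
    read_id = sub(";size=\\d+.*$", "", headers),
    sequence = toupper(unname(as.character(seqs))),
    count = count
  )
}

#' Write sequences to FASTA
#'
#' @param sequences named character vector (names become headers).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Write a species embedding table to TSV (+ JSON sidecar)
#'
#' @param embeddings numeric matrix with species ids as row names, or an
#'   embedding fit from [train_species_embeddings()].
#' @param path output TSV path; a `.json` sidecar with metadata is written
#'   alongside.
#' @param meta optional list of metadata stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(embeddings, path, meta = list()) {
  if (inherits(embeddings, "phyloshot_embedding")) {
    meta <- c(meta, list(config = unclass(embeddings$config),
                         final_loss = glance(embeddings)$final_loss))
    embeddings <- embeddings$embeddings
  }
  stopifnot(is.matrix(embeddings), !is.null(rownames(embeddings)))
  df <- tibble::as_tibble(embeddings, .name_repair = ~ paste0("v", seq_along(.x)))
  df <- dplyr::bind_cols(tibble::tibble(species_id = rownames(embeddings)), df)
  readr::write_tsv(df, path)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a species embedding table written by [write_embeddings()]
#'
#' @param path TSV path.
#' @return numeric matrix, rows named by species id.
#' @export
read_embeddings <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    species_id = readr::col_character(), .default = readr::col_double()))
  m <- as.matrix(df[-1])
  rownames(m) <- df$species_id
  m
}
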