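#' Simulate a Yule (pure-birth) phylogeny
#'
#' Gillespie simulation of a constant-rate birth process started from a
#' single lineage, run until `n_leaves` lineages exist; all surviving
#' lineages are extended to the stopping time, so the tree is ultrametric in
#' time units. Leaves are labelled `sp0001`, `sp0002`, ...
#'
#' @param n_leaves number of leaves (>= 2).
#' @param birth_rate speciation rate per lineage per time unit.
#' @param seed RNG seed.
#' @return an ultrametric `phylo` object with `n_leaves` tips.
#' @export
simulate_yule_tree <- function(n_leaves, birth_rate = 1, seed = 1) {
  if (n_leaves < 2) stop("n_leaves must be >= 2")
  if (birth_rate <= 0) stop("birth_rate must be > 0")
  set.seed(seed)
  n <- as.integer(n_leaves)
  # tips are nodes 1..n, internal nodes n+1..2n-1 in order of creation
  parent_of <- integer(2L * n - 1L)     # 0 = no parent (the root)
  split_time <- numeric(2L * n - 1L)    # for internal nodes
  next_internal <- n + 1L
  # live lineages: the parent node each hangs from, and its start time
  live_parent <- 0L
  live_start <- 0
  t <- 0
  k <- 1L
  while (k < n) {
    t <- t + stats::rexp(1, rate = birth_rate * k)
    i <- sample.int(k, 1L)
    node <- next_internal; next_internal <- next_internal + 1L
    parent_of[node] <- live_parent[i]
    split_time[node] <- t
    live_parent <- c(live_parent[-i], node, node)
    live_start <- c(live_start[-i], t, t)
    k <- k + 1L
  }
  edge <- matrix(0L, 2L * (n - 1L), 2)
  edge_len <- numeric(2L * (n - 1L))
  e <- 0L
  for (tip in seq_len(n)) {           # surviving lineages become tips at t
    e <- e + 1L
    edge[e, ] <- c(live_parent[tip], tip)
    edge_len[e] <- t - live_start[tip]
  }
  if (n > 2) {
    for (node in (n + 2L):(2L * n - 1L)) {  # root (n+1) has no parent edge
      e <- e + 1L
      edge[e, ] <- c(parent_of[node], node)
      edge_len[e] <- split_time[node] - split_time[parent_of[node]]
    }
  }
  tree <- list(
    edge = edge[seq_len(e), , drop = FALSE],
    edge.length = edge_len[seq_len(e)],
    tip.label = sprintf("sp%04d", seq_len(n)),
    Nnode = n - 1L
  )
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  # split times relative to the root's split (= tree time zero) support
  # lineage-through-time checks; the stem before the first split is dropped
  attr(tree, "split_times") <- split_time[(n + 1L):(2L * n - 1L)] - split_time[n + 1L]
  validate_phylo(tree)
  tree
}

#' Rescale a tree's branch lengths to unit height
#'
#' @param tree a `phylo` object.
#' @return the tree with branch lengths divided by the maximum root-to-tip
#'   depth.
#' @export
rescale_tree_height <- function(tree) {
  depth <- max(ape::node.depth.edgelength(tree))
  if (depth <= 0) stop("tree has zero height")
  tree$edge.length <- tree$edge.length / depth
  tree
}

# JC69 transition: probability a site differs from its parent after a branch
# of expected substitutions nu*t is (3/4)(1 - exp(-4*nu*t/3)); when it
# changes, the new base is uniform over the three alternatives.
jc_mutate <- function(seq_idx, brlen, rate) {
  p_diff <- 0.75 * (1 - exp(-4 * rate * brlen / 3))
  hit <- runif(length(seq_idx)) < p_diff
  if (any(hit)) {
    # uniform over the three other bases
    shift <- sample.int(3L, sum(hit), replace = TRUE)
    seq_idx[hit] <- ((seq_idx[hit] - 1L + shift) %% 4L) + 1L
  }
  seq_idx
}

#' Evolve marker sequences along a phylogeny under Jukes-Cantor
#'
#' The root sequence is uniform over A/C/G/T; each branch applies JC69
#' substitutions with expected `subst_rate * branch_length` substitutions per
#' site. Every species receives the full-length alignment and is then
#' truncated to its own amplicon length, drawn uniformly from
#' `seq_len_range` (mimicking the length variation of a short marker).
#'
#' @param tree a validated `phylo`.
#' @param seq_len_range integer length-2 vector (min, max amplicon length);
#'   give a single value for fixed-length sequences.
#' @param subst_rate expected substitutions per site per unit branch length
#'   (>= 0).
#' @param seed RNG seed.
#' @return named character vector: species id -> sequence.
#' @export
evolve_sequences_jc <- function(tree, seq_len_range = c(29, 96),
                                subst_rate = 0.3, seed = 1) {
  validate_phylo(tree)
  if (subst_rate < 0) stop("subst_rate must be >= 0")
  if (length(seq_len_range) == 1) seq_len_range <- rep(seq_len_range, 2)
  if (seq_len_range[1] < 1) stop("seq_len_range must be >= 1")
  set.seed(seed)
  n <- length(tree$tip.label)
  L <- as.integer(seq_len_range[2])
  bases <- c("A", "C", "G", "T")
  root_seq <- sample.int(4L, L, replace = TRUE)
  if (n == 1) {
    len_choices <- seq(seq_len_range[1], seq_len_range[2])
    l <- len_choices[sample.int(length(len_choices), 1L)]
    return(setNames(paste(bases[root_seq[seq_len(l)]], collapse = ""),
                    tree$tip.label))
  }
  edge <- ape::reorder.phylo(tree, "cladewise")$edge
  elen <- ape::reorder.phylo(tree, "cladewise")$edge.length
  root <- setdiff(unique(edge[, 1]), edge[, 2])
  seqs <- vector("list", max(edge))
  seqs[[root]] <- root_seq
  # cladewise order guarantees parents are visited before children
  for (k in seq_len(nrow(edge))) {
    seqs[[edge[k, 2]]] <- jc_mutate(seqs[[edge[k, 1]]], elen[k], subst_rate)
  }
  len_choices <- seq(seq_len_range[1], seq_len_range[2])
  lens <- len_choices[sample.int(length(len_choices), n, replace = TRUE)]
  out <- vapply(seq_len(n), function(i) {
    paste(bases[seqs[[i]][seq_len(lens[i])]], collapse = "")
  }, character(1))
  setNames(out, tree$tip.label)
}

#' Derive a nested taxonomy from tree cuts
#'
#' Cuts an ultrametric tree at three heights (fractions of tree height,
#' measured from the tips): the connected components below each cut become
#' genera, families and orders. Deeper cuts give coarser ranks, so the ranks
#' nest: same genus implies same family implies same order.
#'
#' @param tree an ultrametric `phylo`.
#' @param cut_depths increasing fractions (genus, family, order) strictly
#'   between 0 and 1.
#' @return taxonomy tibble: `species_id`, `genus`, `family`, `order`.
#' @export
derive_taxonomy_from_tree <- function(tree, cut_depths = c(0.2, 0.45, 0.7)) {
  validate_phylo(tree)
  if (length(cut_depths) != 3 || any(diff(cut_depths) <= 0) ||
      cut_depths[1] <= 0 || cut_depths[3] >= 1) {
    stop("cut_depths must be three increasing fractions in (0, 1)")
  }
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)     # from root
  H <- max(depth)
  height <- H - depth                            # from tips
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])
  group_at <- function(h) {
    # each leaf's group = highest ancestor with height <= h
    vapply(seq_len(n), function(leaf) {
      node <- leaf
      while (node != root && height[parent[node]] <= h) node <- parent[node]
      node
    }, integer(1))
  }
  ranks <- lapply(cut_depths * H, group_at)
  relabel <- function(g, prefix) {
    paste0(prefix, sprintf("%03d", match(g, sort(unique(g)))))
  }
  tibble::tibble(
    species_id = tree$tip.label,
    genus = relabel(ranks[[1]], "g"),
    family = relabel(ranks[[2]], "f"),
    order = relabel(ranks[[3]], "o")
  )
}

#' Simulate geographically segregated assemblages and an occurrence grid
#'
#' Assigns species to regions so that the two members of a sister pair
#' (a cherry of the tree) land in different regions with probability
#' `segregation_strength` — the geographic dissociation of close relatives
#' that the co-occurrence model exploits. Each site then samples `richness`
#' species uniformly without replacement from its region's pool. Regions are
#' laid out as contiguous `region_cells x region_cells` blocks of grid
#' cells; every species is marked present in all cells of its region, so
#' grid-derived co-occurrence is a coarsened version of the community data.
#'
#' @param tree the species phylogeny.
#' @param n_regions number of regions.
#' @param sites_per_region sites sampled per region.
#' @param richness species per site.
#' @param segregation_strength probability that a sister pair is forced into
#'   different regions (0 = independent placement).
#' @param seed RNG seed.
#' @param region_cells side length of each region's grid block.
#' @return list with `sites` (tibble `site_id`, `species_id`), `grid`
#'   (tibble `species_id`, `cell_row`, `cell_col`) and `regions` (tibble
#'   `species_id`, `region`).
#' @export
simulate_assemblages <- function(tree, n_regions = 8, sites_per_region = 40,
                                 richness = 15, segregation_strength = 0.9,
                                 seed = 1, region_cells = 3) {
  validate_phylo(tree)
  stopifnot(n_regions >= 2, segregation_strength >= 0,
            segregation_strength <= 1)
  species <- tree$tip.label
  n <- length(species)
  if (richness > ceiling(n / n_regions) * 2) {
    stop("richness ", richness, " infeasible for ", n, " species in ",
         n_regions, " regions")
  }
  set.seed(seed)
  region <- sample.int(n_regions, n, replace = TRUE)
  # sister pairs: internal nodes whose children are both leaves
  ch <- split(tree$edge[, 2], tree$edge[, 1])
  cherries <- Filter(function(x) length(x) == 2 && all(x <= n), ch)
  for (pair in cherries) {
    if (runif(1) < segregation_strength) {
      region[pair[1]] <- sample.int(n_regions, 1L)
      others <- setdiff(seq_len(n_regions), region[pair[1]])
      region[pair[2]] <- others[sample.int(length(others), 1L)]
    }
  }
  pools <- split(species, region)
  small <- lengths(pools) < richness
  if (any(small)) {
    stop("region pool smaller than richness; lower richness or n_regions")
  }
  sites <- purrr::map_dfr(seq_len(n_regions), function(r) {
    purrr::map_dfr(seq_len(sites_per_region), function(s) {
      pool <- pools[[as.character(r)]]
      tibble::tibble(
        site_id = sprintf("r%02d_s%03d", r, s),
        species_id = pool[sample.int(length(pool), richness)]
      )
    })
  })
  # region r occupies a block of cells in a horizontal strip
  grid <- purrr::map_dfr(seq_len(n_regions), function(r) {
    cells <- expand.grid(cell_row = seq_len(region_cells),
                         cell_col = (r - 1) * region_cells +
                           seq_len(region_cells))
    tidyr::crossing(tibble::tibble(species_id = pools[[as.character(r)]]),
                    tibble::as_tibble(cells))
  })
  list(
    sites = sites,
    grid = grid[c("species_id", "cell_row", "cell_col")],
    regions = tibble::tibble(species_id = species, region = region)
  )
}

#' Simulate an eDNA read set for one site
#'
#' Each species present at the site contributes reads copied from its marker
#' sequence with independent per-base substitution errors; per-species
#' abundances are drawn log-uniformly over `abundance_range`.
#'
#' @param site_species character vector of species at the site.
#' @param sequences named character vector (species id -> marker sequence).
#' @param abundance_range length-2 numeric; reads per species are drawn
#'   log-uniformly between these bounds.
#' @param error_rate per-base substitution probability in \[0, 1).
#' @param seed RNG seed.
#' @return tibble with `read_id`, `sequence`, `species_id` (truth label),
#'   `count` (always 1; reads are emitted uncollapsed).
#' @export
simulate_edna_reads <- function(site_species, sequences,
                                abundance_range = c(10, 100),
                                error_rate = 0.005, seed = 1) {
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  missing <- setdiff(site_species, names(sequences))
  if (length(missing) > 0) {
    stop("site species without a sequence: ", paste(missing, collapse = ", "))
  }
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  out <- purrr::map_dfr(site_species, function(sp) {
    nread <- round(exp(runif(1, log(abundance_range[1]),
                             log(abundance_range[2]))))
    src <- utf8ToInt(sequences[[sp]])
    idx <- match(intToUtf8(src, multiple = TRUE), bases)
    reads <- vapply(seq_len(nread), function(i) {
      r <- idx
      hit <- runif(length(r)) < error_rate
      if (any(hit)) {
        shift <- sample.int(3L, sum(hit), replace = TRUE)
        r[hit] <- ((r[hit] - 1L + shift) %% 4L) + 1L
      }
      paste(bases[r], collapse = "")
    }, character(1))
    tibble::tibble(species_id = sp, sequence = reads)
  })
  out$read_id <- sprintf("read%06d", seq_len(nrow(out)))
  out$count <- 1L
  out[c("read_id", "sequence", "species_id", "count")]
}

#' Build a complete synthetic world
#'
#' Generates every input the annotation method consumes, with the structure
#' it relies on: a Yule tree rescaled to unit height; Jukes-Cantor marker
#' sequences (amplicon lengths 29-96 bp); a nested taxonomy from tree cuts;
#' region-segregated assemblages plus an occurrence grid; and a reference
#' database covering only `1 - gap_fraction` of the species. The species
#' absent from the reference database ("gap" species, chosen among species
#' observed in at least one assemblage) are the zero-shot holdout: their true
#' sequences exist as ground truth but the encoder never sees them. Species
#' in the reference database get 1-2 slightly divergent copies of their true
#' sequence (intraspecific variation).
#'
#' @param n_species number of species.
#' @param gap_fraction fraction of species left out of the reference
#'   database.
#' @param segregation probability that sister species are forced into
#'   different regions.
#' @param seed master seed; every stochastic component derives from it.
#' @param n_regions,sites_per_region,richness assemblage layout.
#' @param subst_rate JC substitution rate per unit (rescaled) branch length.
#' @param seq_len_range amplicon length range.
#' @param birth_rate Yule speciation rate (before rescaling).
#' @return object of class `phyloshot_world`: a list with `tree`,
#'   `sequences` (truth, all species), `reference` (records tibble),
#'   `taxonomy`, `sites`, `grid`, `regions`, `gap_species`, `seed`.
#' @export
build_synthetic_world <- function(n_species = 600, gap_fraction = 0.2,
                                  segregation = 0.9, seed = 1,
                                  n_regions = 8, sites_per_region = 40,
                                  richness = 15, subst_rate = 0.3,
                                  seq_len_range = c(29, 96), birth_rate = 1) {
  stopifnot(gap_fraction >= 0, gap_fraction < 1)
  tree <- simulate_yule_tree(n_species, birth_rate, seed = seed)
  tree <- rescale_tree_height(tree)
  sequences <- evolve_sequences_jc(tree, seq_len_range, subst_rate,
                                   seed = seed + 1L)
  taxonomy <- derive_taxonomy_from_tree(tree)
  asm <- simulate_assemblages(tree, n_regions, sites_per_region, richness,
                              segregation, seed = seed + 2L)
  set.seed(seed + 3L)
  observed <- intersect(tree$tip.label, unique(asm$sites$species_id))
  n_gap <- round(gap_fraction * n_species)
  if (n_gap > length(observed)) stop("not enough observed species for the gap")
  gap_species <- sort(sample(observed, n_gap))
  ref_species <- setdiff(tree$tip.label, gap_species)
  n_copies <- 1L + rbinom(length(ref_species), 1L, 1 / 3)
  bases <- c("A", "C", "G", "T")
  records <- purrr::map_dfr(seq_along(ref_species), function(i) {
    sp <- ref_species[i]
    seqs <- character(n_copies[i])
    seqs[1] <- sequences[[sp]]
    if (n_copies[i] > 1) {
      # extra copies carry ~0.5% intraspecific divergence
      idx <- match(strsplit(sequences[[sp]], "")[[1]], bases)
      for (j in 2:n_copies[i]) {
        hit <- runif(length(idx)) < 0.005
        r <- idx
        if (any(hit)) {
          shift <- sample.int(3L, sum(hit), replace = TRUE)
          r[hit] <- ((r[hit] - 1L + shift) %% 4L) + 1L
        }
        seqs[j] <- paste(bases[r], collapse = "")
      }
    }
    tibble::tibble(
      sequence_id = paste0(sp, "_seq", seq_len(n_copies[i])),
      species_id = sp, sequence = seqs
    )
  })
  structure(list(
    tree = tree, sequences = sequences, reference = records,
    taxonomy = taxonomy, sites = asm$sites, grid = asm$grid,
    regions = asm$regions, gap_species = gap_species, seed = seed
  ), class = "phyloshot_world")
}

#' @export
print.phyloshot_world <- function(x, ...) {
  cat("<phyloshot_world> ", length(x$tree$tip.label), " species; ",
      nrow(x$reference), " reference sequences (", length(x$gap_species),
      " gap species); ", length(unique(x$sites$site_id)), " sites\n", sep = "")
  invisible(x)
}

#' Write a synthetic world to plain-text files
#'
#' Emits `tree.nwk`, `ref.fasta`, `tax.tsv`, `sites.tsv`, `grid.tsv` and
#' `truth.fasta` (all species' true sequences) under `dir`.
#'
#' @param world a `phyloshot_world`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_phylo_tree(world$tree, file.path(dir, "tree.nwk"))
  refseq <- setNames(world$reference$sequence,
                     paste0(world$reference$sequence_id, "|",
                            world$reference$species_id))
  write_fasta(refseq, file.path(dir, "ref.fasta"))
  write_fasta(world$sequences, file.path(dir, "truth.fasta"))
  readr::write_tsv(world$taxonomy, file.path(dir, "tax.tsv"))
  readr::write_tsv(world$sites, file.path(dir, "sites.tsv"))
  readr::write_tsv(world$grid, file.path(dir, "grid.tsv"))
  invisible(dir)
}
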