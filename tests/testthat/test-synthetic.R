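test_that("yule trees have the right shape and are ultrametric", {
  tr <- simulate_yule_tree(2, 1, seed = 1)
  d <- ape::node.depth.edgelength(tr)
  expect_equal(d[1], d[2])                 # both root-to-leaf paths equal

  tr <- simulate_yule_tree(8, 1, seed = 2)
  expect_equal(tr$Nnode, 7)                # bifurcating: n - 1 internals
  depths <- ape::node.depth.edgelength(tr)[1:8]
  expect_lt(diff(range(depths)), 1e-9)     # ultrametric
  expect_error(simulate_yule_tree(1), ">= 2")
})

test_that("lineage counts grow like the Yule expectation", {
  # after the root split there are 2 lineages; the unconditioned pure-birth
  # expectation at time t is 2 * exp(lambda * t). Conditioning on the final
  # leaf count is negligible for small t and large n.
  lambda <- 1
  t_eval <- 0.8
  counts <- vapply(1:200, function(s) {
    tr <- simulate_yule_tree(200, lambda, seed = s)
    st <- attr(tr, "split_times")
    2 + sum(st > 0 & st <= t_eval)
  }, numeric(1))
  expected <- 2 * exp(lambda * t_eval)
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 0.05 * expected)
})

test_that("JC sequence evolution matches its closed form", {
  tr <- tree3()
  # rate 0: everything identical to the root
  s0 <- evolve_sequences_jc(tr, seq_len_range = 40, subst_rate = 0, seed = 1)
  expect_equal(length(unique(substr(s0, 1, 40))), 1)

  # expected per-site difference across a branch of length t:
  # (3/4)(1 - exp(-4 t / 3)), checked on a 2-leaf tree over 10^4 sites
  t_br <- 0.3
  f <- write_newick(sprintf("(X:%f,Y:%f);", t_br / 2, t_br / 2))
  tr2 <- read_phylo_tree(f)
  s <- evolve_sequences_jc(tr2, seq_len_range = 10000, subst_rate = 1,
                           seed = 42)
  diff_obs <- mean(strsplit(s[["X"]], "")[[1]] != strsplit(s[["Y"]], "")[[1]])
  p_exp <- 0.75 * (1 - exp(-4 * t_br / 3))
  se <- sqrt(p_exp * (1 - p_exp) / 10000)
  expect_lt(abs(diff_obs - p_exp), 3 * se)

  # determinism and length range
  s1 <- evolve_sequences_jc(tr, seq_len_range = c(29, 96), subst_rate = 0.3,
                            seed = 5)
  s2 <- evolve_sequences_jc(tr, seq_len_range = c(29, 96), subst_rate = 0.3,
                            seed = 5)
  expect_identical(s1, s2)
  expect_true(all(nchar(s1) >= 29 & nchar(s1) <= 96))
  expect_error(evolve_sequences_jc(tr, 40, subst_rate = -1), ">= 0")
})

test_that("tree-cut taxonomy is nested and groups cherries", {
  # a shallow cherry must share its genus
  tr <- balanced4()
  tax <- derive_taxonomy_from_tree(tr, cut_depths = c(0.6, 0.7, 0.8))
  expect_equal(tax$genus[tax$species_id == "A"],
               tax$genus[tax$species_id == "B"])

  # nestedness on random trees: same genus -> same family -> same order
  for (s in 1:30) {
    tr <- random_tree(24, seed = s)
    tax <- derive_taxonomy_from_tree(tr)
    by_genus <- split(tax$family, tax$genus)
    expect_true(all(vapply(by_genus, function(x) length(unique(x)) == 1,
                           logical(1))))
    by_family <- split(tax$order, tax$family)
    expect_true(all(vapply(by_family, function(x) length(unique(x)) == 1,
                           logical(1))))
  }
  expect_error(derive_taxonomy_from_tree(tr, cut_depths = c(0.5, 0.4, 0.7)),
               "increasing")
})

test_that("assemblages separate sister species when segregation is full", {
  tr <- random_tree(40, seed = 3)
  asm <- simulate_assemblages(tr, n_regions = 4, sites_per_region = 10,
                              richness = 5, segregation_strength = 1,
                              seed = 9)
  # find cherries
  n <- length(tr$tip.label)
  ch <- split(tr$edge[, 2], tr$edge[, 1])
  cherries <- Filter(function(x) length(x) == 2 && all(x <= n), ch)
  site_sets <- split(asm$sites$species_id, asm$sites$site_id)
  for (pair in cherries) {
    labs <- tr$tip.label[pair]
    expect_false(any(vapply(site_sets, function(s) all(labs %in% s),
                            logical(1))))
  }
  # every site has exactly `richness` distinct species
  expect_true(all(lengths(site_sets) == 5))
  expect_true(all(vapply(site_sets, anyDuplicated, integer(1)) == 0))
})

test_that("zero segregation leaves sister placement at the random expectation", {
  n_regions <- 4
  same_region_rate <- function(strength, seeds) {
    mean(vapply(seeds, function(s) {
      tr <- random_tree(60, seed = s)
      asm <- simulate_assemblages(tr, n_regions = n_regions,
                                  sites_per_region = 2, richness = 5,
                                  segregation_strength = strength, seed = s)
      reg <- setNames(asm$regions$region, asm$regions$species_id)
      ch <- split(tr$edge[, 2], tr$edge[, 1])
      cherries <- Filter(function(x) length(x) == 2 && all(x <= 60), ch)
      rates <- vapply(cherries, function(p) {
        reg[tr$tip.label[p[1]]] == reg[tr$tip.label[p[2]]]
      }, logical(1))
      mean(rates)
    }, numeric(1)))
  }
  r0 <- same_region_rate(0, 1:30)
  expect_lt(abs(r0 - 1 / n_regions), 0.08)   # random expectation 0.25
  r1 <- same_region_rate(1, 1:10)
  expect_equal(r1, 0)
})

test_that("read simulation conserves counts and matches its error rate", {
  seqs <- c(sp1 = strrep("ACGT", 16))
  reads <- simulate_edna_reads("sp1", seqs, abundance_range = c(20, 20),
                               error_rate = 0, seed = 1)
  expect_true(all(reads$sequence == seqs[["sp1"]]))
  expect_equal(nrow(reads), 20)

  reads <- simulate_edna_reads("sp1", seqs, abundance_range = c(500, 500),
                               error_rate = 0.01, seed = 2)
  hd <- vapply(reads$sequence, function(r) {
    sum(strsplit(r, "")[[1]] != strsplit(seqs[["sp1"]], "")[[1]])
  }, numeric(1))
  p <- mean(hd) / 64
  se <- sqrt(0.01 * 0.99 / (64 * 500))
  expect_lt(abs(p - 0.01), 3 * se)
  expect_error(simulate_edna_reads("sp1", seqs, error_rate = 1), "error_rate")
})

test_that("a synthetic world is reproducible field by field", {
  w1 <- build_synthetic_world(n_species = 40, seed = 11, n_regions = 4,
                              sites_per_region = 6, richness = 5)
  w2 <- build_synthetic_world(n_species = 40, seed = 11, n_regions = 4,
                              sites_per_region = 6, richness = 5)
  expect_identical(w1$sequences, w2$sequences)
  expect_identical(w1$reference, w2$reference)
  expect_identical(w1$sites, w2$sites)
  expect_identical(w1$gap_species, w2$gap_species)
  expect_identical(ape::write.tree(w1$tree), ape::write.tree(w2$tree))
  # gap species truly lack reference records but have truth sequences
  expect_false(any(w1$gap_species %in% w1$reference$species_id))
  expect_true(all(w1$gap_species %in% names(w1$sequences)))
  # world files round-trip as plain text
  d <- tempfile(); write_world(w1, d)
  expect_true(all(file.exists(file.path(d, c("tree.nwk", "ref.fasta",
                                             "tax.tsv", "sites.tsv",
                                             "grid.tsv")))))
  db <- read_reference_db(file.path(d, "ref.fasta"), file.path(d, "tax.tsv"))
  expect_equal(nrow(db$records), nrow(w1$reference))
  expect_equal(db$records$species_id, w1$reference$species_id)
})
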