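# shared in-code fixtures; everything is generated, nothing is stored

write_newick <- function(text) {
  f <- tempfile(fileext = ".nwk")
  writeLines(text, f)
  f
}

tree3 <- function() read_phylo_tree(write_newick("((A:1,B:1):1,C:2);"))

balanced4 <- function() read_phylo_tree(write_newick("((A:1,B:1):1,(C:1,D:1):1);"))

caterpillar4 <- function() read_phylo_tree(write_newick("(((A:1,B:1):1,C:2):1,D:3);"))

# small world used by several training tests (built once per test run)
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- build_synthetic_world(
        n_species = 64, gap_fraction = 0.2, segregation = 0.9, seed = 7,
        n_regions = 4, sites_per_region = 12, richness = 8)
    }
    cache
  }
})

# independent patristic oracle: shortest paths on the tree's weighted graph
patristic_oracle <- function(tree) {
  g <- igraph::graph_from_edgelist(tree$edge, directed = FALSE)
  igraph::E(g)$weight <- tree$edge.length
  n <- length(tree$tip.label)
  D <- igraph::distances(g, v = seq_len(n), to = seq_len(n))
  dimnames(D) <- list(tree$tip.label, tree$tip.label)
  D
}

random_tree <- function(n, seed) simulate_yule_tree(n, birth_rate = 1, seed = seed)
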