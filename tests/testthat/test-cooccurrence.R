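test_that("an untrained modulation layer is the identity", {
  sp <- sprintf("s%02d", 1:10)
  m <- new_cooccurrence_model(sp, m = 4, seed = 1)   # U = 0
  p <- setNames(runif(10), sp); p <- p / sum(p)
  others <- list(setNames(rep(0.1, 10), sp))
  expect_equal(modulate(p, others, m), p, tolerance = 1e-12)
  # no co-detected sequences: p returned untouched
  expect_identical(modulate(p, list(), m), p)
})

test_that("modulation matches an independent scalar implementation", {
  sp <- c("a", "b", "c")
  m <- new_cooccurrence_model(sp, m = 2, seed = 3)
  m$U <- matrix(c(0, 1, 0, 0.5, -1, 2), 3, 2)
  m$V <- matrix(c(1, 0, -1, 2, 0.3, 0), 3, 2)
  p_i <- c(a = 0.6, b = 0.3, c = 0.1)
  others <- list(c(a = 0, b = 1, c = 0), c(a = 0.2, b = 0.2, c = 0.6))
  got <- modulate(p_i, others, m)
  # scalar re-implementation: loops, no matrix algebra
  a <- numeric(3)
  for (k in 1:3) a[k] <- (others[[1]][k] + others[[2]][k]) / 2
  z <- numeric(3)
  for (i in 1:3) {
    shift <- 0
    for (j in 1:3) for (r in 1:2) shift <- shift + m$U[i, r] * m$V[j, r] * a[j]
    z[i] <- log(p_i[i]) + shift
  }
  want <- exp(z - max(z)); want <- want / sum(want)
  expect_equal(unname(got), unname(want), tolerance = 1e-12)
  expect_lt(abs(sum(got) - 1), 1e-9)
})

test_that("site NLL matches its closed forms", {
  # one-hot at the truth -> 0
  P <- diag(3); colnames(P) <- letters[1:3]
  expect_equal(site_nll(P, c(1, 2, 3)), 0)
  # uniform over 100 species -> ln(100)
  P <- matrix(1 / 100, 2, 100)
  expect_equal(site_nll(P, c(5, 50)), log(100), tolerance = 1e-12)
  # mixed probabilities
  P <- rbind(c(0.5, 0.5), c(0.25, 0.75))
  expect_equal(site_nll(P, c(1, 1)), -(log(0.5) + log(0.25)) / 2)
  expect_error(site_nll(P, c(1, 3)), "out of range")
  expect_error(site_nll(P, 1), "one truth index")
})

test_that("grid cells become co-occurrence sites", {
  grid <- tibble::tibble(
    species_id = c("A", "B"), cell_row = c(0, 0), cell_col = c(0, 0))
  sites <- grid_to_cooccurrence(grid)
  expect_equal(nrow(sites), 2)
  expect_equal(length(unique(sites$site_id)), 1)

  grid <- tibble::tibble(
    species_id = c("A", "B"), cell_row = c(0, 5), cell_col = c(0, 5))
  sites <- grid_to_cooccurrence(grid)
  expect_equal(length(unique(sites$site_id)), 2)

  grid <- tibble::tibble(
    species_id = c("A", "A", "B", "C"),
    cell_row = c(0, 0, 0, 0), cell_col = c(0, 1, 1, 1))
  sites <- grid_to_cooccurrence(grid)
  tab <- split(sites$species_id, sites$site_id)
  expect_setequal(tab[["cell_0_0"]], "A")
  expect_setequal(tab[["cell_0_1"]], c("A", "B", "C"))
})

test_that("noise calibration hits the target median perturbation", {
  set.seed(1)
  E <- matrix(rnorm(200 * 16), 200, 16,
              dimnames = list(sprintf("s%03d", 1:200), NULL))
  for (target in c(0.05, 0.2)) {
    sig <- calibrate_noise_sigma(E, target, seed = 2)
    set.seed(99)
    N <- E + matrix(rnorm(length(E), sd = sig), nrow(E))
    med <- median(1 - rowSums(E * N) /
                    (sqrt(rowSums(E^2)) * sqrt(rowSums(N^2))))
    expect_lt(abs(med - target), 0.25 * target)
  }
  expect_equal(calibrate_noise_sigma(E, 0), 0)
})

test_that("co-occurrence training reduces the site NLL reproducibly", {
  w <- small_world()
  emb <- train_species_embeddings(
    w$tree, embed_config(embed_dim = 16, epochs = 80, seed = 1))
  enc <- train_dna_encoder(
    w$reference, emb,
    dna_train_config(epochs = 12, seed = 1, holdout = w$gap_species),
    model = new_dna_encoder(embed_dim = 16, channels = 16, hidden_dim = 64,
                            max_len = 96, seed = 1))
  cfg <- cooc_config(m = 32, epochs = 6, seed = 5, sigma = 0.1)
  cc <- train_cooccurrence(w$sites, emb, enc, w$reference, cfg)
  tl <- cc$loss_trace$loss
  expect_lt(tail(tl, 1), tl[1])
  cc2 <- train_cooccurrence(w$sites, emb, enc, w$reference, cfg)
  expect_identical(cc$loss_trace, cc2$loss_trace)

  # discarding sequence-less species is the alternative to noisy embeddings:
  # training still runs and still reduces the NLL
  cc3 <- suppressWarnings(   # sites may fall below 2 usable species
    train_cooccurrence(w$sites, emb, enc, w$reference,
                       cooc_config(m = 32, epochs = 3, seed = 5,
                                   sequenceless = "drop")))
  expect_lt(tail(cc3$loss_trace$loss, 1), cc3$loss_trace$loss[1])

  # degenerate sites are skipped with a warning; all-degenerate errors
  singleton <- tibble::tibble(site_id = "s1",
                              species_id = w$tree$tip.label[1])
  expect_error(
    suppressWarnings(train_cooccurrence(singleton, emb, enc, w$reference, cfg)),
    "degenerate")
})

test_that("site initial probabilities recover the species when noise-free", {
  w <- small_world()
  emb <- train_species_embeddings(
    w$tree, embed_config(embed_dim = 16, epochs = 80, seed = 1))
  enc <- train_dna_encoder(
    w$reference, emb,
    dna_train_config(epochs = 12, seed = 1, holdout = w$gap_species),
    model = new_dna_encoder(embed_dim = 16, channels = 16, hidden_dim = 64,
                            max_len = 96, seed = 1))
  # sigma = 0: a sequence-less species sits exactly on its own embedding,
  # so the kernel must rank it first
  gap3 <- w$gap_species[1:3]
  set.seed(1)
  P <- site_initial_probs(gap3, emb, enc, w$reference, sigma = 0)
  expect_equal(nrow(P), 3)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
  expect_equal(top1_predictions(P), gap3)
  expect_error(site_initial_probs("nope", emb, enc, w$reference),
               "without an embedding")
})
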