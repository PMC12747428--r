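test_that("sequence tokenization pads, truncates and maps ambiguity codes", {
  e <- encode_sequence("ACGT", max_len = 8)
  expect_equal(as.integer(e), c(1L, 2L, 3L, 4L, 6L, 6L, 6L, 6L))
  e <- encode_sequence("ACNT", max_len = 8)
  expect_equal(e[[3]], 5L)
  expect_warning(
    e <- encode_sequence(strrep("A", 200), max_len = 128),
    "truncated")
  expect_length(e, 128)
  expect_true(attr(e, "truncated"))
  expect_error(encode_sequence(""), "non-empty")
})

test_that("the encoder preserves sequence length through both conv stages", {
  # shape arithmetic holds for several padded lengths (incl. the boundary 21)
  for (L in c(21, 64, 128)) {
    m <- new_dna_encoder(embed_dim = 6, base_dim = 4, channels = 8,
                         hidden_dim = 16, max_len = L, seed = 1)
    out <- encoder_forward(m, encode_sequences("ACGTACGTACGT", L))
    expect_equal(dim(out), c(1, 6))
    expect_true(all(is.finite(out)))
  }
  expect_error(new_dna_encoder(max_len = 20), ">= 21")
  # default output dimension matches the 64-dim embedding space
  m64 <- new_dna_encoder(max_len = 64, channels = 8, hidden_dim = 32, seed = 1)
  expect_equal(ncol(encoder_forward(m64, encode_sequences("ACGT", 64))), 64)
})

test_that("identical sequences map to identical outputs", {
  m <- new_dna_encoder(embed_dim = 8, base_dim = 4, channels = 8,
                       hidden_dim = 16, max_len = 32, seed = 2)
  o <- embed_sequences(m, c("ACGTTGCA", "ACGTTGCA"))
  expect_equal(o[1, ], o[2, ])
  # mismatched encoded length is rejected
  expect_error(encoder_forward(m, encode_sequences("ACGT", 64)), "max_len")
})

test_that("backpropagation matches numerical gradients", {
  m <- new_dna_encoder(embed_dim = 3, base_dim = 2, channels = 3,
                       hidden_dim = 16, max_len = 21, seed = 4)
  toks <- encode_sequences(c("ACGTNACGTTGCA", "TTGACGTAC"), 21)
  set.seed(11)
  # move the zero-initialized biases off the ReLU kinks: pad inputs are
  # exactly zero, so zero biases would park activations exactly where the
  # numerical derivative of ReLU is ill-defined
  m$params$b1 <- rnorm(length(m$params$b1), sd = 0.3)
  m$params$b2 <- rnorm(length(m$params$b2), sd = 0.3)
  m$params$b3 <- rnorm(length(m$params$b3), sd = 0.3)
  tgt <- matrix(rnorm(2 * 3), 2, 3)
  # guard against a degenerate (all-dead-ReLU) configuration, where the
  # cosine loss itself is undefined
  expect_gt(min(sqrt(rowSums(encoder_forward(m, toks)^2))), 1e-8)
  loss_fn <- function(params) {
    m2 <- m; m2$params <- params
    out <- encoder_forward_full(m2, toks)
    no <- sqrt(rowSums(out^2)); nt <- sqrt(rowSums(tgt^2))
    sum(1 - rowSums(out * tgt) / (no * nt)) / nrow(out)
  }
  cache <- encoder_forward_full(m, toks, keep_cache = TRUE)
  out <- cache$out
  no <- sqrt(rowSums(out^2)); nt <- sqrt(rowSums(tgt^2))
  s <- rowSums(out * tgt) / (no * nt)
  dOut <- -(tgt / (no * nt) - s * out / no^2) / nrow(out)
  grads <- encoder_backward(m, cache, dOut)
  eps <- 1e-6
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    idx <- seq_len(min(6, length(p)))   # spot-check a few entries per tensor
    for (k in idx) {
      pp <- m$params; pp[[nm]][k] <- pp[[nm]][k] + eps
      pm <- m$params; pm[[nm]][k] <- pm[[nm]][k] - eps
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      expect_equal(grads[[nm]][k], num, tolerance = 1e-5,
                   label = paste("grad", nm, k))
    }
  }
})

test_that("the mapping loss hits its landmark values", {
  expect_equal(dna_mapping_loss(c(1, 1), c(2, 2)), 0)
  expect_equal(dna_mapping_loss(c(1, 0), c(0, 1)), 1)
  expect_equal(dna_mapping_loss(c(1, 0), c(-2, 0)), 2)
})

test_that("encoder training fits a synthetic world and honours the holdout", {
  w <- small_world()
  emb <- train_species_embeddings(w$tree,
                                  embed_config(embed_dim = 16, epochs = 80,
                                               seed = 1))
  cfg <- dna_train_config(epochs = 12, seed = 1, holdout = w$gap_species)
  arch <- new_dna_encoder(embed_dim = 16, channels = 16, hidden_dim = 64,
                          max_len = 96, seed = 1)
  enc <- train_dna_encoder(w$reference, emb, cfg, model = arch)
  expect_lt(tail(enc$loss_trace$loss, 1), 0.1)

  # holdout species never contribute a training example: training a model
  # with records ONLY from holdout species must fail for lack of data
  only_hold <- w$reference[w$reference$species_id %in% w$gap_species, ]
  expect_equal(nrow(only_hold), 0)  # gap species have no reference records
  expect_error(train_dna_encoder(only_hold, emb, cfg, model = arch),
               "no training records")

  # determinism: identical loss trace for the same seed
  enc2 <- train_dna_encoder(w$reference, emb, cfg, model = arch)
  expect_identical(enc$loss_trace, enc2$loss_trace)

  # a missing embedding is caught before training starts
  emb_small <- emb$embeddings[-1, ]
  missing_sp <- setdiff(unique(w$reference$species_id), rownames(emb_small))
  if (length(missing_sp) > 0) {
    expect_error(train_dna_encoder(w$reference, emb_small, cfg, model = arch),
                 "without an embedding")
  }
})
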