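test_that("the temperature kernel evaluates and orders correctly", {
  expect_equal(kernel_similarity(c(1, 0), c(2, 0), tau = 0.05), 1)
  # d_cos = 0.5 at tau = 0.05 -> e^{-10}
  x <- c(1, 0); y <- c(cos(pi / 3), sin(pi / 3))  # cos distance = 0.5
  expect_equal(kernel_similarity(x, y, 0.05), exp(-10), tolerance = 1e-9)
  expect_gt(kernel_similarity(c(1, 0.2), c(1, 0), 0.05),
            kernel_similarity(c(1, 0.4), c(1, 0), 0.05))
  expect_error(kernel_similarity(c(1, 0), c(1, 0), tau = 0), "tau")
})

test_that("species probabilities normalize and follow the two-point closed form", {
  E <- rbind(a = c(1, 0), b = c(0, 1))
  p <- species_probabilities(c(1, 1), E)   # equidistant
  expect_equal(unname(p[1, ]), c(0.5, 0.5))

  # K equidistant species -> uniform
  K <- 8
  EK <- matrix(0, K, 3, dimnames = list(paste0("s", 1:K), NULL))
  EK[, 1] <- 1; EK[, 2] <- rep(c(1, -1), 4); EK[, 3] <- 0
  pK <- species_probabilities(c(1, 0, 0), EK)
  expect_equal(unname(pK[1, ]), rep(1 / K, K))

  # two species at d_cos 0 and 0.5, tau = 0.05 -> 1 / (1 + e^{-10})
  E2 <- rbind(near = c(1, 0), far = c(cos(pi / 3), sin(pi / 3)))
  p2 <- species_probabilities(c(1, 0), E2, tau = 0.05)
  expect_equal(unname(p2[1, "near"]), 1 / (1 + exp(-10)), tolerance = 1e-9)

  expect_error(species_probabilities(c(1, 0), matrix(0, 0, 2)), "empty")
})

test_that("probabilities sum to one and argmax matches brute-force NN", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:50, 1); d <- sample(2:8, 1)
    E <- matrix(rnorm(n * d), n, d,
                dimnames = list(sprintf("sp%03d", sample(n)), NULL))
    q <- rnorm(d)
    p <- species_probabilities(q, E, tau = 0.05)
    expect_lt(abs(sum(p) - 1), 1e-9)
    # brute-force nearest neighbour by cosine distance
    dists <- apply(E, 1, function(e) cosine_distance(q, e))
    expect_equal(top1_predictions(p), names(which.min(dists)))
  }
})

test_that("top-1 prediction breaks ties lexicographically", {
  p <- c(B = 0.5, A = 0.5)
  expect_equal(top1_prediction(p), "A")
  expect_equal(top1_prediction(c(A = 0.7, B = 0.3)), "A")
  # a species' own embedding is its own best match
  E <- matrix(rnorm(15), 5, 3, dimnames = list(letters[1:5], NULL))
  p <- species_probabilities(E["c", ], E)
  expect_equal(top1_predictions(p), "c")
})

test_that("shrinking the temperature concentrates mass on the nearest species", {
  set.seed(7)
  E <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(sprintf("s%02d", 1:30), NULL))
  q <- rnorm(4)
  p_sharp <- species_probabilities(q, E, tau = 1e-4)
  p_soft <- species_probabilities(q, E, tau = 0.05)
  nn <- top1_predictions(p_soft)
  expect_equal(top1_predictions(p_sharp), nn)
  expect_gt(p_sharp[1, nn], 1 - 1e-6)
  expect_gte(p_sharp[1, nn], p_soft[1, nn])
})
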