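toy_taxonomy <- function() {
  tibble::tibble(
    species_id = c("A", "A2", "B", "C"),
    genus = c("gA", "gA", "gB", "gC"),
    family = c("f1", "f1", "f1", "f2"),
    order = c("o1", "o1", "o1", "o2")
  )
}

test_that("zero-shot splits are disjoint, exhaustive and seeded", {
  sp <- sprintf("s%03d", 1:100)
  sp_split <- zero_shot_split(sp, 20, seed = 3)
  expect_length(sp_split$holdout, 20)
  expect_length(sp_split$train, 80)
  expect_length(intersect(sp_split$train, sp_split$holdout), 0)
  expect_setequal(c(sp_split$train, sp_split$holdout), sp)
  expect_identical(zero_shot_split(sp, 20, seed = 3), sp_split)
  expect_error(zero_shot_split(sp, 100), "smaller")
  # the full-scale holdout size is accepted for large species sets
  big <- sprintf("s%05d", 1:5000)
  expect_length(zero_shot_split(big, 431, seed = 1)$holdout, 431)
})

test_that("rank accuracy applies per-species-then-macro averaging", {
  # worked example: species A has 2 sequences, one predicted as its
  # congener A2; species B has 1 sequence predicted correctly
  preds <- tibble::tibble(
    species_id = c("A", "A", "B"),
    predicted = c("A", "A2", "B")
  )
  ev <- rank_accuracy(preds, toy_taxonomy())
  acc <- setNames(ev$summary$accuracy, as.character(ev$summary$rank))
  expect_equal(acc[["species"]], 0.75)   # mean(0.5, 1.0)
  expect_equal(acc[["genus"]], 1.0)
  expect_equal(acc[["family"]], 1.0)
  expect_equal(ev$n_species, 2)

  # all-correct predictions give 1 at every rank
  preds <- tibble::tibble(species_id = c("A", "B", "C"),
                          predicted = c("A", "B", "C"))
  ev <- rank_accuracy(preds, toy_taxonomy())
  expect_equal(ev$summary$accuracy, rep(1, 4))

  # duplicating one species' sequences leaves the report unchanged
  preds <- tibble::tibble(species_id = c("A", "A", "B"),
                          predicted = c("A", "A2", "B"))
  dup <- dplyr::bind_rows(preds, preds[preds$species_id == "A", ])
  expect_equal(rank_accuracy(dup, toy_taxonomy())$summary,
               rank_accuracy(preds, toy_taxonomy())$summary)

  expect_error(rank_accuracy(
    tibble::tibble(species_id = "Z", predicted = "A"), toy_taxonomy()),
    "missing")
})

test_that("rank accuracy ignores relabeling below the scored rank", {
  preds <- tibble::tibble(species_id = c("A", "B"), predicted = c("A2", "B"))
  tax <- toy_taxonomy()
  base <- rank_accuracy(preds, tax)$summary
  # scramble species identity below genus: genus-level rows unchanged
  tax2 <- tax
  tax2$species_id[tax2$species_id == "A2"] <- "A2x"
  preds2 <- preds; preds2$predicted[1] <- "A2x"
  new <- rank_accuracy(preds2, tax2)$summary
  expect_equal(new$accuracy[-1], base$accuracy[-1])
})

test_that("calibration bins are 5% wide and honest about empty bins", {
  # a single prediction at p = 0.52 lands in (0.50, 0.55]
  one <- tibble::tibble(probability = 0.52, correct = TRUE)
  cal <- calibration_curve(one)
  expect_equal(nrow(cal), 20)
  hit <- cal[cal$count > 0, ]
  expect_equal(hit$bin_lo, 0.50)
  expect_equal(hit$bin_hi, 0.55)
  expect_equal(sum(cal$count), 1)
  expect_true(all(is.na(cal$prop_correct[cal$count == 0])))

  # all-correct predictions: every non-empty bin proportion is 1
  ac <- tibble::tibble(probability = runif(200, 0.01, 1), correct = TRUE)
  cal <- calibration_curve(ac)
  expect_true(all(cal$prop_correct[cal$count > 0] == 1))
  expect_equal(sum(cal$count), 200)

  expect_error(calibration_curve(tibble::tibble(probability = 0,
                                                correct = TRUE)), "0, 1")
})

test_that("perfectly calibrated input tracks the bin centers", {
  set.seed(5)
  n <- 20000
  p <- runif(n, 0.025, 1)
  sim <- tibble::tibble(probability = p, correct = rbinom(n, 1, p) == 1)
  cal <- calibration_curve(sim)
  busy <- cal[cal$count >= 200, ]
  # binomial CI: proportion within ~3 SE of the bin center
  se <- sqrt(busy$bin_mid * (1 - busy$bin_mid) / busy$count)
  expect_true(all(abs(busy$prop_correct - busy$bin_mid) < 3 * se + 0.025))
  # correctness proportion rises with predicted probability
  expect_gt(cor(busy$bin_mid, busy$prop_correct, method = "spearman"), 0.9)
})

test_that("agreement categories follow the shallower assignment depth", {
  tax <- toy_taxonomy()
  ours <- tibble::tibble(cluster_id = c("m1", "m2", "m3", "m4"),
                         species_id = c("A", "A", "A", "A"))
  external <- tibble::tibble(
    cluster_id = c("m1", "m2", "m3", "m5"),
    assigned_rank = c("species", "genus", "order", "species"),
    assigned_name = c("A", "gA", "o2", "A")
  )
  out <- agreement_table(ours, external, tax)
  counts <- setNames(out$n, out$category)
  expect_equal(counts[["species"]], 1)   # both said species A
  expect_equal(counts[["genus"]], 1)     # external stopped at A's genus
  expect_equal(counts[["mismatch"]], 1)  # different orders
  # m4/m5 appear on only one side each -> excluded
  expect_equal(sum(out$n), 3)

  # a species-level disagreement within the same genus degrades to genus
  ours2 <- tibble::tibble(cluster_id = "x", species_id = "A")
  ext2 <- tibble::tibble(cluster_id = "x", assigned_rank = "species",
                         assigned_name = "A2")
  out2 <- agreement_table(ours2, ext2, tax)
  expect_equal(out2$n[out2$category == "genus"], 1)

  expect_error(agreement_table(
    dplyr::bind_rows(ours, ours[1, ]), external, tax), "duplicate")
})
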