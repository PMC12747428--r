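#' Split species into training and zero-shot holdout sets
#'
#' @param species character vector of species ids.
#' @param n_holdout number of species to hold out (must be < number of
#'   species); the full-scale protocol holds out 431 species.
#' @param seed RNG seed.
#' @return list with `train` and `holdout` character vectors (disjoint,
#'   exhaustive).
#' @export
zero_shot_split <- function(species, n_holdout, seed = 1) {
  species <- unique(species)
  if (n_holdout >= length(species)) {
    stop("n_holdout (", n_holdout, ") must be smaller than the number of species (",
         length(species), ")")
  }
  set.seed(seed)
  holdout <- sort(sample(species, n_holdout))
  list(train = setdiff(species, holdout), holdout = holdout)
}

#' Per-species macro-averaged rank accuracies
#'
#' A prediction is counted correct at a rank when the predicted species'
#' genus/family/order equals the true species' (species rank: exact match).
#' Results are first averaged per true species over all of its predictions,
#' then averaged unweighted over species — so sequence-rich species do not
#' dominate.
#'
#' @param predictions tibble with columns `species_id` (truth) and
#'   `predicted` (predicted species id); extra columns are ignored.
#' @param taxonomy taxonomy tibble (`species_id`, `genus`, `family`,
#'   `order`) covering every species appearing on either side.
#' @return object of class `phyloshot_eval`: list with `summary` (tibble
#'   rank/accuracy), `per_species` (tibble of per-species accuracies) and
#'   `n_species`. Has [tidy()] and [glance()] methods.
#' @export
rank_accuracy <- function(predictions, taxonomy) {
  need <- unique(c(predictions$species_id, predictions$predicted))
  missing <- setdiff(need, taxonomy$species_id)
  if (length(missing) > 0) {
    stop("species missing from taxonomy: ", paste(head(missing, 5), collapse = ", "))
  }
  tax <- taxonomy[match(predictions$species_id, taxonomy$species_id), ]
  pax <- taxonomy[match(predictions$predicted, taxonomy$species_id), ]
  hits <- tibble::tibble(
    species_id = predictions$species_id,
    species = predictions$predicted == predictions$species_id,
    genus = pax$genus == tax$genus,
    family = pax$family == tax$family,
    order = pax$order == tax$order
  )
  per_species <- hits |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(dplyr::across(c("species", "genus", "family", "order"),
                                   mean), .groups = "drop")
  summary <- tibble::tibble(
    rank = factor(c("species", "genus", "family", "order"),
                  levels = c("species", "genus", "family", "order")),
    accuracy = c(mean(per_species$species), mean(per_species$genus),
                 mean(per_species$family), mean(per_species$order))
  )
  structure(list(summary = summary, per_species = per_species,
                 n_species = nrow(per_species)),
            class = "phyloshot_eval")
}

#' @export
print.phyloshot_eval <- function(x, ...) {
  cat("<phyloshot_eval> ", x$n_species, " species\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Tidy rank accuracies
#' @param x a `phyloshot_eval`.
#' @param ... unused.
#' @return the summary tibble (rank, accuracy).
#' @export
tidy.phyloshot_eval <- function(x, ...) x$summary

#' One-row rank-accuracy summary
#' @param x a `phyloshot_eval`.
#' @param ... unused.
#' @return tibble with one column per rank plus `n_species`.
#' @export
glance.phyloshot_eval <- function(x, ...) {
  out <- tidyr::pivot_wider(x$summary, names_from = "rank",
                            values_from = "accuracy")
  out$n_species <- x$n_species
  out
}

#' Calibration table over 5%-wide probability bins
#'
#' Bins the top-1 predicted probabilities into twenty bins of width 0.05 on
#' (0, 1\] and reports, per bin, the number of predictions and the proportion
#' correct for every supplied correctness column. Empty bins are reported
#' with count 0 and missing (NA) proportions — no calibration is fabricated
#' where there is no data.
#'
#' @param predictions tibble with a `probability` column in (0, 1\] and one
#'   or more logical correctness columns (default: every logical column).
#' @param correctness names of the correctness columns to summarize.
#' @return tibble of class `phyloshot_calibration` with `bin_lo`, `bin_hi`,
#'   `bin_mid`, `count`, and one `prop_<name>` column per correctness column.
#' @export
calibration_curve <- function(predictions,
                              correctness = NULL) {
  p <- predictions$probability
  if (any(p <= 0 | p > 1)) stop("probabilities must lie in (0, 1]")
  if (is.null(correctness)) {
    correctness <- names(predictions)[vapply(predictions, is.logical, logical(1))]
  }
  if (length(correctness) == 0) stop("no correctness column found")
  edges <- seq(0, 1, by = 0.05)
  bin <- cut(p, breaks = edges, include.lowest = FALSE, labels = FALSE)
  out <- tibble::tibble(
    bin_lo = edges[-21], bin_hi = edges[-1],
    bin_mid = (edges[-21] + edges[-1]) / 2,
    count = as.integer(tabulate(bin, nbins = 20))
  )
  for (nm in correctness) {
    v <- predictions[[nm]]
    prop <- rep(NA_real_, 20)
    agg <- tapply(v, factor(bin, levels = 1:20), mean)
    prop[!is.na(agg)] <- agg[!is.na(agg)]
    out[[paste0("prop_", nm)]] <- prop
  }
  class(out) <- c("phyloshot_calibration", class(out))
  out
}

#' Plot a calibration table
#'
#' Reliability curve per rank with the perfect-calibration diagonal and a
#' bar panel of prediction counts per bin.
#'
#' @param object a `phyloshot_calibration`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.phyloshot_calibration <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = dplyr::starts_with("prop_"),
                              names_to = "rank", values_to = "proportion",
                              names_prefix = "prop_")
  ggplot2::ggplot(dplyr::filter(long, !is.na(.data$proportion)),
                  ggplot2::aes(x = .data$bin_mid, y = .data$proportion,
                               colour = .data$rank)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Predicted top-1 probability",
                  y = "Proportion correct",
                  title = "Calibration of species probabilities") +
    ggplot2::theme_minimal()
}

RANK_DEPTH <- c(species = 4L, genus = 3L, family = 2L, order = 1L)

#' Agreement between phyloshot annotations and an external pipeline
#'
#' Joins per-cluster annotations on cluster id and classifies every shared
#' record into the deepest taxonomic category at which the two assignments
#' agree, evaluated at the shallower of the two assignment depths (phyloshot
#' always assigns at species level; an external LCA pipeline may stop at
#' genus, family or order). Records present on only one side are excluded.
#'
#' @param ours tibble with `cluster_id` and `species_id` (phyloshot's
#'   species-level prediction).
#' @param external tibble with `cluster_id`, `assigned_rank` (one of
#'   species/genus/family/order) and `assigned_name`.
#' @param taxonomy taxonomy tibble used to expand both assignments to all
#'   ranks.
#' @return tibble with `category` (species, genus, family, order, mismatch)
#'   and `n`; counts sum to the number of joined records.
#' @export
agreement_table <- function(ours, external, taxonomy) {
  if (anyDuplicated(ours$cluster_id) || anyDuplicated(external$cluster_id)) {
    stop("duplicate cluster ids in an annotation table")
  }
  shared <- intersect(ours$cluster_id, external$cluster_id)
  ours <- ours[match(shared, ours$cluster_id), ]
  external <- external[match(shared, external$cluster_id), ]
  if (!all(external$assigned_rank %in% names(RANK_DEPTH))) {
    stop("external assigned_rank must be one of species/genus/family/order")
  }
  ours_tax <- taxonomy[match(ours$species_id, taxonomy$species_id), ]
  categories <- vapply(seq_along(shared), function(i) {
    depth <- RANK_DEPTH[[external$assigned_rank[i]]]
    name <- external$assigned_name[i]
    # expand the external assignment to all ranks at or above its depth
    ext <- switch(external$assigned_rank[i],
      species = {
        row <- taxonomy[match(name, taxonomy$species_id), ]
        c(species = name, genus = row$genus, family = row$family,
          order = row$order)
      },
      genus = {
        row <- taxonomy[match(name, taxonomy$genus), ]
        c(species = NA, genus = name, family = row$family, order = row$order)
      },
      family = {
        row <- taxonomy[match(name, taxonomy$family), ]
        c(species = NA, genus = NA, family = name, order = row$order)
      },
      order = c(species = NA, genus = NA, family = NA, order = name)
    )
    mine <- c(species = ours$species_id[i], genus = ours_tax$genus[i],
              family = ours_tax$family[i], order = ours_tax$order[i])
    for (rk in names(sort(RANK_DEPTH[RANK_DEPTH <= depth],
                          decreasing = TRUE))) {
      if (!is.na(ext[[rk]]) && identical(ext[[rk]], mine[[rk]])) return(rk)
    }
    "mismatch"
  }, character(1))
  counts <- table(factor(categories,
                         levels = c("species", "genus", "family", "order",
                                    "mismatch")))
  tibble::tibble(category = names(counts), n = as.integer(counts))
}
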