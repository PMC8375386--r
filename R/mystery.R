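#' Run the mystery-class augmentation protocol
#'
#' In each repetition, 20% of the mystery samples are held out as the test
#' slice; the training set is the full main dataset (city-year labels) plus
#' the remaining mystery samples under the single extra label `"mystery"`. An
#' MLP is fitted per repetition and votes are accumulated for each mystery
#' sample over the repetitions in which it was held out, so a sample's vote
#' total equals the number of times it was tested.
#'
#' @param main_x Normalized main-dataset tibble restricted to the working
#'   feature set.
#' @param index [build_group_index()] of the main dataset.
#' @param mystery_x Normalized mystery tibble over the same features (a
#'   mismatch errors, listing the missing taxa).
#' @param test_frac Held-out fraction of mystery samples per repetition.
#' @param n_reps Number of repetitions.
#' @param spec An MLP [learner_spec()].
#' @param seed Seed.
#' @return A `vote_tally` over the main classes plus `"mystery"`; truth
#'   labels are `NA` (unknown by construction).
#' @export
run_mystery_protocol <- function(main_x, index, mystery_x, test_frac = 0.2,
                                 n_reps = 100, spec = learner_spec("mlp"),
                                 seed = 1L) {
  taxa <- setdiff(names(main_x), "sample_id")
  missing <- setdiff(taxa, names(mystery_x))
  if (length(missing) > 0L) {
    abort(sprintf(
      "mystery table is missing taxa: %s", paste(missing, collapse = ", ")
    ))
  }
  mystery_x <- select_features(mystery_x, taxa)

  xm_main <- counts_matrix(main_x)
  xm_myst <- counts_matrix(mystery_x)
  classes <- c(index$groups, "mystery")
  y_main <- group_of(index, rownames(xm_main))

  myst_ids <- rownames(xm_myst)
  n_test <- max(1L, round_half_up(test_frac * length(myst_ids)))
  votes <- matrix(0L, length(myst_ids), length(classes),
    dimnames = list(myst_ids, classes)
  )
  seeds <- derive_seeds(seed, 2L * n_reps, salt = 13L)

  for (r in seq_len(n_reps)) {
    test <- withr::with_seed(seeds[r], sample(myst_ids, n_test))
    train_myst <- setdiff(myst_ids, test)
    x_train <- rbind(xm_main, xm_myst[train_myst, , drop = FALSE])
    y_train <- factor(
      c(y_main, rep("mystery", length(train_myst))),
      levels = classes
    )
    fit <- mlp_fit(
      x_train, y_train,
      hidden = spec$hidden, dropout = spec$dropout,
      epochs = spec$epochs, batch_size = spec$batch_size, lr = spec$lr,
      patience = spec$patience, seed = seeds[n_reps + r]
    )
    pred <- as.character(predict(fit, xm_myst[test, , drop = FALSE]))
    votes[cbind(match(test, myst_ids), match(pred, classes))] <-
      votes[cbind(match(test, myst_ids), match(pred, classes))] + 1L
  }

  new_vote_tally(votes,
    truth = setNames(rep(NA_character_, length(myst_ids)), myst_ids),
    n_reps = n_reps
  )
}

#' Fraction of unseen-city samples flagged as "mystery"
#'
#' @param tally A [run_mystery_protocol()] tally.
#' @param sample_ids The mystery samples known (from simulation truth) to
#'   come from cities absent from the main dataset.
#' @return Fraction whose top-voted class is `"mystery"`.
#' @export
mystery_detection_rate <- function(tally, sample_ids) {
  ids <- intersect(sample_ids, rownames(tally$votes))
  if (length(ids) == 0L) abort("no unseen-city samples in the tally")
  flagged <- vapply(ids, function(s) {
    v <- tally$votes[s, ]
    "mystery" %in% topk_classes(v, 1)
  }, logical(1))
  mean(flagged)
}

#' Fit the multi-output trait model
#'
#' One network with a shared ReLU trunk and six softmax heads maps a sample's
#' microbial profile to the six categorical city traits. Samples from the
#' same city collected in different years share the same trait labels (years
#' are merged: climate does not change materially between consecutive years).
#' A stratified 20% of samples is held out to report per-trait
#' misclassification rates.
#'
#' @param x Normalized tibble restricted to the working feature set.
#' @param meta Sample metadata (`sample_id`, `city`).
#' @param trait_profiles Trait table (city x six ordinal traits), e.g. from
#'   [discretize_city_traits()]; every city in `meta` must appear.
#' @param holdout_frac Held-out fraction for the error report.
#' @param spec An MLP [learner_spec()].
#' @param seed Seed.
#' @return A list of class `trait_model`: the fitted `mlp_model`, the trait
#'   level sets, and `holdout_error` (tibble trait x error).
#' @export
fit_multioutput_traits <- function(x, meta, trait_profiles,
                                   holdout_frac = 0.2,
                                   spec = learner_spec("mlp"),
                                   seed = 1L) {
  traits <- setdiff(names(trait_profiles), "city")
  missing <- setdiff(unique(meta$city), trait_profiles$city)
  if (length(missing) > 0L) {
    abort(sprintf(
      "city missing a trait profile: %s", paste(missing, collapse = ", ")
    ))
  }
  xm <- counts_matrix(x)
  labels <- meta |>
    dplyr::select("sample_id", "city") |>
    dplyr::left_join(trait_profiles, by = "city") |>
    dplyr::slice(match(rownames(xm), .data$sample_id))
  y <- purrr::map(
    setNames(traits, traits),
    ~ factor(labels[[.x]], levels = sort(unique(trait_profiles[[.x]])))
  )

  holdout <- withr::with_seed(seed, {
    unlist(purrr::map(
      split(rownames(xm), labels$city),
      ~ sample(.x, max(1L, round_half_up(holdout_frac * length(.x))))
    ), use.names = FALSE)
  })
  train <- setdiff(rownames(xm), holdout)
  tr <- match(train, rownames(xm))
  ho <- match(holdout, rownames(xm))

  fit <- mlp_fit(
    xm[tr, , drop = FALSE], purrr::map(y, ~ .x[tr]),
    hidden = spec$hidden, dropout = spec$dropout, epochs = spec$epochs,
    batch_size = spec$batch_size, lr = spec$lr,
    x_val = xm[ho, , drop = FALSE], y_val = purrr::map(y, ~ .x[ho]),
    patience = spec$patience, seed = seed
  )
  pred <- predict(fit, xm[ho, , drop = FALSE])
  holdout_error <- tibble::tibble(
    trait = traits,
    error = purrr::map2_dbl(pred, purrr::map(y, ~ .x[ho]), ~ mean(.x != .y))
  )
  structure(
    list(
      fit = fit, traits = traits,
      levels = purrr::map(y, levels),
      holdout_error = holdout_error
    ),
    class = "trait_model"
  )
}

#' Predict trait levels for new samples
#'
#' @param object A [fit_multioutput_traits()] model.
#' @param newdata Normalized tibble over the model's feature set.
#' @param ... Unused.
#' @return A tibble `sample_id` plus one predicted integer level per trait.
#' @export
predict.trait_model <- function(object, newdata, ...) {
  xm <- counts_matrix(newdata)
  pred <- predict(object$fit, xm)
  tibble::tibble(sample_id = rownames(xm)) |>
    dplyr::bind_cols(purrr::map_dfc(pred, ~ as.integer(as.character(.x))))
}

#' @export
print.trait_model <- function(x, ...) {
  cat(sprintf(
    "<trait_model> %d traits, mean held-out error %.3f\n",
    length(x$traits), mean(x$holdout_error$error)
  ))
  invisible(x)
}

#' Average predicted trait profile per city
#'
#' Arithmetic mean of the per-sample predicted levels for each city and
#' trait; a fractional mean flags disagreement among a city's samples.
#'
#' @param predictions Output of [predict.trait_model()].
#' @param cities Character vector: city of each sample (same order).
#' @return Tibble city x mean predicted level per trait.
#' @export
average_profiles <- function(predictions, cities) {
  predictions |>
    dplyr::mutate(city = cities) |>
    dplyr::summarise(
      dplyr::across(-"sample_id", mean),
      .by = "city"
    )
}

#' Match an averaged trait profile against known city profiles
#'
#' Rounds each averaged level to the nearest integer and ranks the known
#' cities by L1 distance between the rounded query and each city's profile
#' (ties share a rank). On binary traits the distance equals the number of
#' mismatched traits.
#'
#' @param avg_profile Named numeric vector or one-row tibble of averaged
#'   levels (six traits).
#' @param known_profiles Trait table (city x traits), e.g.
#'   [metasub_city_traits()] or [discretize_city_traits()] output.
#' @return Tibble `city`, `distance`, `rank`, sorted by distance.
#' @export
match_pattern <- function(avg_profile, known_profiles) {
  traits <- setdiff(names(known_profiles), "city")
  if (is.data.frame(avg_profile)) {
    avg_profile <- unlist(avg_profile[1, intersect(names(avg_profile), traits)])
  }
  if (!all(traits %in% names(avg_profile))) {
    abort("query profile must carry the same traits as the known profiles")
  }
  query <- round(avg_profile[traits])
  dist <- vapply(seq_len(nrow(known_profiles)), function(i) {
    sum(abs(query - unlist(known_profiles[i, traits])))
  }, numeric(1))
  tibble::tibble(
    city = known_profiles$city,
    distance = dist
  ) |>
    dplyr::arrange(.data$distance, .data$city) |>
    dplyr::mutate(rank = dplyr::dense_rank(.data$distance))
}
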