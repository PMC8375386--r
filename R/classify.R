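#' Learner specification for the repeated-split protocol
#'
#' Back-ends: `rf` — random forest with 1,000 trees and `floor(sqrt(p))`
#' variables per split; `svm` — RBF-kernel SVM with gamma/cost chosen on the
#' validation split over decade grids; `mlp` — ReLU/softmax/dropout network
#' (see [mlp_fit()]) with early stopping on the validation split.
#'
#' @param method One of `"rf"`, `"svm"`, `"mlp"`.
#' @param n_trees Random forest tree count.
#' @param vars_per_split Variables tried per split (`NULL` = `floor(sqrt(p))`).
#' @param gamma_grid,cost_grid SVM tuning grids.
#' @param hidden,dropout,epochs,batch_size,lr,patience MLP hyperparameters.
#' @param seed Base seed; each repetition derives its own sub-seed.
#' @return A list of class `learner_spec`.
#' @export
learner_spec <- function(method = c("mlp", "rf", "svm"),
                         n_trees = 1000,
                         vars_per_split = NULL,
                         gamma_grid = 10^(-3:1),
                         cost_grid = 10^(-1:3),
                         hidden = c(64, 32),
                         dropout = 0.3,
                         epochs = 150,
                         batch_size = 32,
                         lr = 1e-3,
                         patience = 15,
                         seed = 1L) {
  structure(
    list(
      method = match.arg(method), n_trees = n_trees,
      vars_per_split = vars_per_split, gamma_grid = gamma_grid,
      cost_grid = cost_grid, hidden = hidden, dropout = dropout,
      epochs = epochs, batch_size = batch_size, lr = lr,
      patience = patience, seed = as.integer(seed)
    ),
    class = "learner_spec"
  )
}

#' Build the repeated-split plan
#'
#' Per city-year group, `round(test_frac * n)` samples (minimum 1,
#' round-half-up) are drawn once and fixed as the test set for every
#' repetition. In each of `n_reps` repetitions the remaining samples of each
#' group are split anew into training and validation
#' (`round(val_frac * remainder)` validation samples, round-half-up). The
#' validation split tunes the SVM grid and stops the MLP; the test set is
#' only ever predicted.
#'
#' @param index A [build_group_index()].
#' @param test_frac Fraction of each group fixed as test.
#' @param val_frac Fraction of each group's remainder used for validation per
#'   repetition.
#' @param n_reps Number of repetitions (votes per test sample).
#' @param seed Seed; the plan is deterministic given the seed.
#' @return An object of class `split_plan`: `test` ids, `reps` (list of
#'   train/val id lists), `n_reps`, `seed`.
#' @export
make_split_plan <- function(index, test_frac = 0.2, val_frac = 0.2,
                            n_reps = 100, seed = 1L) {
  sizes <- lengths(index$members)
  if (any(sizes < 3L)) {
    warn(sprintf(
      "group(s) with < 3 samples: %s",
      paste(names(sizes)[sizes < 3L], collapse = ", ")
    ))
  }
  withr::with_seed(seed, {
    test <- unlist(purrr::map(index$members, function(ids) {
      n_test <- max(1L, round_half_up(test_frac * length(ids)))
      sample(ids, n_test)
    }), use.names = FALSE)
    remainder <- purrr::map(index$members, ~ setdiff(.x, test))
    if (any(lengths(remainder) == 0L)) {
      abort("a group has no samples left outside the test set")
    }
    reps <- purrr::map(seq_len(n_reps), function(r) {
      val <- unlist(purrr::map(remainder, function(ids) {
        n_val <- min(round_half_up(val_frac * length(ids)), length(ids) - 1L)
        if (n_val < 1L) {
          return(character(0)) # group too small for a validation slice
        }
        sample(ids, n_val)
      }), use.names = FALSE)
      train <- setdiff(unlist(remainder, use.names = FALSE), val)
      list(train = train, val = val)
    })
  })
  structure(
    list(test = test, reps = reps, n_reps = n_reps, seed = seed),
    class = "split_plan"
  )
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf(
    "<split_plan> %d fixed test samples, %d repetitions\n",
    length(x$test), x$n_reps
  ))
  invisible(x)
}

# Fit one learner on the training slice and predict the test slice.
fit_predict <- function(method, spec, x_train, y_train, x_val, y_val,
                        x_test, seed) {
  y_train <- droplevels(y_train)
  if (method == "rf") {
    mtry <- spec$vars_per_split %||% max(1L, floor(sqrt(ncol(x_train))))
    fit <- withr::with_seed(seed, randomForest::randomForest(
      x = x_train, y = y_train, ntree = spec$n_trees, mtry = mtry
    ))
    as.character(predict(fit, x_test))
  } else if (method == "svm") {
    grid <- tidyr::expand_grid(gamma = spec$gamma_grid, cost = spec$cost_grid)
    if (length(y_val) > 0L) {
      acc <- purrr::pmap_dbl(grid, function(gamma, cost) {
        fit <- e1071::svm(
          x = x_train, y = y_train, kernel = "radial",
          gamma = gamma, cost = cost
        )
        mean(as.character(predict(fit, x_val)) == as.character(y_val))
      })
      best <- grid[which.max(acc), ]
    } else {
      best <- tibble::tibble(gamma = 1 / ncol(x_train), cost = 1)
    }
    fit <- e1071::svm(
      x = x_train, y = y_train, kernel = "radial",
      gamma = best$gamma, cost = best$cost
    )
    as.character(predict(fit, x_test))
  } else {
    has_val <- length(y_val) > 0L
    fit <- mlp_fit(
      x_train, y_train,
      hidden = spec$hidden, dropout = spec$dropout,
      epochs = spec$epochs, batch_size = spec$batch_size, lr = spec$lr,
      x_val = if (has_val) x_val else NULL,
      y_val = if (has_val) factor(y_val, levels = levels(y_train)) else NULL,
      patience = spec$patience, seed = seed
    )
    as.character(predict(fit, x_test))
  }
}

#' Run the repeated-split voting protocol
#'
#' For every repetition of the plan, fits the learner on that repetition's
#' training slice (validation slice used for SVM tuning / MLP early
#' stopping), predicts the fixed test set, and accumulates one vote per test
#' sample per repetition. A failing repetition is retried with a fresh
#' sub-seed; more than five failures abort.
#'
#' @param x Normalized tibble restricted to the working feature set.
#' @param index A [build_group_index()] covering the samples.
#' @param plan A [make_split_plan()].
#' @param spec A [learner_spec()].
#' @return A `vote_tally`: integer vote matrix (test samples x classes),
#'   truth labels, and per-sample tested counts.
#' @export
run_protocol <- function(x, index, plan, spec = learner_spec("mlp")) {
  xm <- counts_matrix(x)
  grp <- group_of(index, rownames(xm))
  classes <- index$groups
  y <- factor(grp, levels = classes)

  test_ids <- intersect(plan$test, rownames(xm))
  votes <- matrix(0L, length(test_ids), length(classes),
    dimnames = list(test_ids, classes)
  )
  seeds <- derive_seeds(spec$seed, plan$n_reps, salt = 7L)

  for (r in seq_len(plan$n_reps)) {
    rep_ids <- plan$reps[[r]]
    train <- intersect(rep_ids$train, rownames(xm))
    val <- intersect(rep_ids$val, rownames(xm))
    pred <- NULL
    seed_r <- seeds[r]
    for (attempt in 1:6) {
      pred <- tryCatch(
        fit_predict(
          spec$method, spec,
          xm[train, , drop = FALSE], y[match(train, rownames(xm))],
          xm[val, , drop = FALSE], y[match(val, rownames(xm))],
          xm[test_ids, , drop = FALSE], seed_r
        ),
        error = function(e) {
          warn(sprintf("repetition %d failed (%s); retrying", r, conditionMessage(e)))
          NULL
        }
      )
      if (!is.null(pred)) break
      seed_r <- seed_r + 1000003L
    }
    if (is.null(pred)) abort("more than 5 learner failures in one repetition")
    hit <- pred %in% classes
    votes[cbind(which(hit), match(pred[hit], classes))] <-
      votes[cbind(which(hit), match(pred[hit], classes))] + 1L
  }

  new_vote_tally(votes,
    truth = setNames(as.character(grp[match(test_ids, rownames(xm))]), test_ids),
    n_reps = plan$n_reps
  )
}

new_vote_tally <- function(votes, truth, n_reps) {
  structure(
    list(
      votes = votes, truth = truth, n_reps = n_reps,
      n_tested = rowSums(votes)
    ),
    class = "vote_tally"
  )
}

#' @export
print.vote_tally <- function(x, ...) {
  cat(sprintf(
    "<vote_tally> %d test samples, %d classes, %d repetitions\n",
    nrow(x$votes), ncol(x$votes), x$n_reps
  ))
  invisible(x)
}

# Classes holding the k highest distinct vote ranks for one vote row.
topk_classes <- function(v, k) {
  vals <- sort(unique(v[v > 0]), decreasing = TRUE)
  if (length(vals) == 0L) {
    return(character(0))
  }
  vals <- vals[seq_len(min(k, length(vals)))]
  names(v)[v %in% vals]
}

#' Top-k vote error of a tally
#'
#' With `k = 1`, a test sample is correct iff its true class is in the argmax
#' set of its votes (ties are generous: a tie that includes the truth counts
#' as correct). With `k = 2`, the classes holding the two highest distinct
#' vote ranks are all eligible, mirroring the use of the highest and
#' second-highest vote together. Consequently top-2 error never exceeds top-1
#' error.
#'
#' @param tally A `vote_tally`.
#' @param k 1 or 2.
#' @param ties `"generous"` (default; a tie containing the truth is correct)
#'   or `"strict"` (the truth must hold the top rank alone for `k = 1`).
#' @return The error rate over test samples.
#' @export
topk_error <- function(tally, k = 1, ties = c("generous", "strict")) {
  ties <- match.arg(ties)
  if (nrow(tally$votes) == 0L) abort("empty vote tally")
  correct <- vapply(seq_len(nrow(tally$votes)), function(i) {
    top <- topk_classes(tally$votes[i, ], k)
    if (ties == "strict" && k == 1 && length(top) > 1L) {
      return(FALSE)
    }
    tally$truth[i] %in% top
  }, logical(1))
  mean(!correct)
}

#' Per-group top-k error
#'
#' @inheritParams topk_error
#' @param index A [build_group_index()].
#' @return A tibble `group`, `n_test`, `error` (NA for groups without test
#'   samples).
#' @export
per_group_error <- function(tally, index, k = 1) {
  grp <- group_of(index, rownames(tally$votes))
  correct <- vapply(seq_len(nrow(tally$votes)), function(i) {
    tally$truth[i] %in% topk_classes(tally$votes[i, ], k)
  }, logical(1))
  tibble::tibble(group = index$groups) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      n_test = sum(grp == .data$group),
      error = if (.data$n_test == 0L) {
        NA_real_
      } else {
        mean(!correct[grp == .data$group])
      }
    ) |>
    dplyr::ungroup()
}

# Single top-voted class of a vote row; a tie containing the truth resolves
# to the truth, otherwise ties break lexicographically.
top_class <- function(v, truth = NULL) {
  arg <- names(v)[v == max(v)]
  if (!is.null(truth) && truth %in% arg) {
    return(truth)
  }
  lex_sort(arg)[1]
}

#' Same-city-different-year confusion count
#'
#' Among test samples from cities sampled in more than one year, counts how
#' many have a top-voted class that is the same city with a different
#' collection year — the signature of year-to-year batch effects dominating
#' geography.
#'
#' @param tally A `vote_tally` whose classes are city-year group labels.
#' @param index A [build_group_index()].
#' @return A list with `count` and `denominator` (test samples from
#'   multi-year cities); both 0 when no city has multiple years.
#' @export
year_confusion <- function(tally, index) {
  multi_year <- index$meta |>
    dplyr::summarise(n_years = dplyr::n_distinct(.data$year), .by = "city") |>
    dplyr::filter(.data$n_years > 1L) |>
    dplyr::pull("city")
  ids <- rownames(tally$votes)
  cities <- city_of(index, ids)
  eligible <- which(cities %in% multi_year)
  if (length(eligible) == 0L) {
    return(list(count = 0L, denominator = 0L))
  }
  confused <- vapply(eligible, function(i) {
    pred <- top_class(tally$votes[i, ], tally$truth[i])
    pred_city <- sub("_[0-9]+$", "", pred)
    pred != tally$truth[i] && pred_city == cities[i]
  }, logical(1))
  list(count = sum(confused), denominator = length(eligible))
}
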