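#' Elastic-net specification for one-vs-rest feature selection
#'
#' The mixing parameter `alpha` balances feature retention and removal
#' (alpha = 0 is ridge and never sparsifies, alpha = 1 is the lasso); the
#' study default is 0.4, held fixed across all one-vs-rest fits. `lambda` is
#' either `"cv"` (penalty strength chosen by cross-validation minimizing
#' binomial deviance) or a fixed non-negative number.
#'
#' @param alpha Elastic-net mixing parameter in \[0, 1\].
#' @param lambda `"cv"` or a fixed penalty value (0 = unpenalized).
#' @param n_cv_folds Folds for the cross-validation (stratified by class).
#' @param lambda_rule `"min"` (deviance-minimizing lambda, default) or
#'   `"1se"`.
#' @param seed Seed for the fold assignment.
#' @return A list of class `elastic_net_spec`.
#' @export
elastic_net_spec <- function(alpha = 0.4, lambda = "cv", n_cv_folds = 10,
                             lambda_rule = c("min", "1se"), seed = 1L) {
  assert_scalar_number(alpha, "alpha", 0, 1)
  structure(
    list(
      alpha = alpha, lambda = lambda, n_cv_folds = as.integer(n_cv_folds),
      lambda_rule = match.arg(lambda_rule), seed = as.integer(seed)
    ),
    class = "elastic_net_spec"
  )
}

# Stratified fold ids so every CV fold sees both classes.
stratified_folds <- function(y, nfolds, seed) {
  withr::with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(nfolds), length(idx))
    }
    fold
  })
}

#' Fit one one-vs-rest elastic-net logistic regression
#'
#' Samples of `target_group` are labeled 1 and every other group 0, and a
#' binomial-deviance elastic net is fitted on the normalized (log2-CPM)
#' feature matrix. The retained set of the fit is the taxa with nonzero
#' coefficients at the chosen penalty. Degenerate cross-validation fits fall
#' back to the 1-SE lambda, with a warning.
#'
#' @param x Normalized tibble (`sample_id` + taxon columns).
#' @param index A [build_group_index()].
#' @param target_group Group label to contrast against the rest.
#' @param spec An [elastic_net_spec()].
#' @return A list of class `elastic_net_fit`: `target`, `intercept`, `beta`
#'   (named coefficient vector), `lambda`, `retained` (taxa with nonzero
#'   coefficients).
#' @export
fit_one_vs_rest <- function(x, index, target_group, spec = elastic_net_spec()) {
  if (!target_group %in% index$groups) {
    abort(sprintf("unknown group '%s'", target_group))
  }
  xm <- counts_matrix(x)
  y <- as.integer(group_of(index, x$sample_id) == target_group)
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L) {
    abort("need >= 2 samples inside and outside the target group")
  }

  if (is.numeric(spec$lambda)) {
    if (spec$lambda == 0) {
      # unpenalized fit along a path ending at 0 (glmnet convention)
      fit <- glmnet::glmnet(xm, y,
        family = "binomial", alpha = spec$alpha,
        lambda = c(0.1, 0.01, 0)
      )
      beta <- as.numeric(stats::coef(fit, s = 0))
      lambda <- 0
    } else {
      fit <- glmnet::glmnet(xm, y,
        family = "binomial", alpha = spec$alpha,
        lambda = spec$lambda
      )
      beta <- as.numeric(stats::coef(fit, s = spec$lambda))
      lambda <- spec$lambda
    }
  } else {
    foldid <- stratified_folds(y, spec$n_cv_folds, spec$seed)
    # a one-vs-rest positive class is small by design; glmnet's advisory
    # about classes below 8 observations is expected, not actionable
    cvfit <- withCallingHandlers(
      withr::with_seed(spec$seed, glmnet::cv.glmnet(
        xm, y,
        family = "binomial", alpha = spec$alpha,
        foldid = foldid, type.measure = "deviance"
      )),
      warning = function(w) {
        if (grepl("fewer than 8", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    lambda <- if (spec$lambda_rule == "min") cvfit$lambda.min else cvfit$lambda.1se
    beta <- tryCatch(
      as.numeric(stats::coef(cvfit, s = lambda)),
      error = function(e) {
        warn(sprintf(
          "degenerate fit for %s; falling back to 1-SE lambda", target_group
        ))
        lambda <<- cvfit$lambda.1se
        as.numeric(stats::coef(cvfit, s = cvfit$lambda.1se))
      }
    )
  }

  taxa <- colnames(xm)
  structure(
    list(
      target = target_group,
      intercept = beta[1],
      beta = setNames(beta[-1], taxa),
      lambda = lambda,
      retained = taxa[beta[-1] != 0]
    ),
    class = "elastic_net_fit"
  )
}

#' Retention profile over a set of one-vs-rest fits
#'
#' Counts, per taxon, in how many of the one-vs-rest elastic-net models it
#' received a nonzero coefficient. The more models retain a taxon, the more
#' likely it separates at least one city from the rest.
#'
#' @param fits List of [fit_one_vs_rest()] results sharing one feature set.
#' @return A tibble of class `retention_profile` with columns `taxon` and
#'   `count`, sorted by decreasing count.
#' @export
retention_profile <- function(fits) {
  feature_sets <- purrr::map(fits, ~ names(.x$beta))
  if (length(unique(feature_sets)) != 1L) {
    abort("all fits must share the same feature set")
  }
  taxa <- feature_sets[[1]]
  counts <- purrr::map(fits, ~ as.integer(taxa %in% .x$retained)) |>
    purrr::reduce(`+`)
  out <- tibble::tibble(taxon = taxa, count = as.integer(counts)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$taxon)
  attr(out, "n_models") <- length(fits)
  class(out) <- c("retention_profile", class(out))
  out
}

#' Select taxa whose retention count meets a cutoff
#'
#' @param profile A [retention_profile()].
#' @param cutoff Minimum retention count (inclusive: taxa retained in at
#'   least `cutoff` models are kept).
#' @return Character vector of taxon ids; non-increasing in `cutoff`.
#' @export
select_by_cutoff <- function(profile, cutoff) {
  if (cutoff < 0) abort("cutoff must be >= 0")
  profile$taxon[profile$count >= cutoff]
}

#' Fit all one-vs-rest models and tally retention
#'
#' Convenience wrapper fitting one elastic net per city-year group and
#' tallying the retention profile.
#'
#' @inheritParams fit_one_vs_rest
#' @return A list with `fits` and `profile`.
#' @export
one_vs_rest_retention <- function(x, index, spec = elastic_net_spec()) {
  seeds <- derive_seeds(spec$seed, length(index$groups))
  fits <- purrr::map2(index$groups, seeds, function(g, s) {
    spec_g <- spec
    spec_g$seed <- s
    fit_one_vs_rest(x, index, g, spec_g)
  })
  list(fits = fits, profile = retention_profile(fits))
}

#' Error-rate sweep over retention cutoffs
#'
#' For each cutoff, restricts the normalized matrix to the taxa selected at
#' that cutoff and runs the repeated-split protocol with each requested
#' learner, recording feature-set size and top-1/top-2 test error (the
#' cutoff-by-method error table used to pick the working feature set).
#'
#' @param x Normalized tibble.
#' @param index A [build_group_index()].
#' @param profile A [retention_profile()].
#' @param cutoffs Integer vector of retention cutoffs.
#' @param methods Character subset of `c("rf", "svm", "mlp")`.
#' @param plan A [make_split_plan()] for the samples of `x`.
#' @param specs Optional named list of [learner_spec()]s keyed by method.
#' @return A tibble with one row per cutoff x method: `cutoff`, `n_features`,
#'   `method`, `top1_error`, `top2_error` (NA when the feature set is empty).
#' @export
cutoff_sweep <- function(x, index, profile, cutoffs, methods = c("rf", "svm", "mlp"),
                         plan, specs = NULL) {
  purrr::map_dfr(cutoffs, function(cutoff) {
    taxa <- select_by_cutoff(profile, cutoff)
    purrr::map_dfr(methods, function(method) {
      if (length(taxa) == 0L) {
        return(tibble::tibble(
          cutoff = cutoff, n_features = 0L, method = method,
          top1_error = NA_real_, top2_error = NA_real_
        ))
      }
      spec <- specs[[method]] %||% learner_spec(method)
      tally <- run_protocol(select_features(x, taxa), index, plan, spec)
      tibble::tibble(
        cutoff = cutoff, n_features = length(taxa), method = method,
        top1_error = topk_error(tally, 1), top2_error = topk_error(tally, 2)
      )
    })
  })
}

#' @export
print.retention_profile <- function(x, ...) {
  cat(sprintf(
    "<retention_profile> %d taxa over %d one-vs-rest models\n",
    nrow(x), attr(x, "n_models")
  ))
  NextMethod()
}
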