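# A fixed small normalized dataset shared by the elastic-net tests.
enet_fixture <- function(seed = 7) {
  sim <- strong_sim(seed = seed, n_cities = 4, samples_per_group = 10,
                    effect = 3, batch = 0.2,
                    n_taxa_per_rank = c(order = 15, family = 15, species = 30),
                    n_signature_taxa_per_city = 4)
  out <- normalized_from_sim(sim)
  out$truth <- sim$truth
  out
}

test_that("retention counting tallies nonzero coefficients across models", {
  taxa <- c("o__A", "o__B", "o__C")
  mkfit <- function(retained) {
    structure(
      list(
        target = "g", intercept = 0,
        beta = setNames(as.numeric(taxa %in% retained), taxa),
        lambda = 0.1, retained = retained
      ),
      class = "elastic_net_fit"
    )
  }
  fits <- list(mkfit(c("o__A", "o__B")), mkfit("o__A"), mkfit("o__A"))
  profile <- retention_profile(fits)
  expect_equal(
    setNames(profile$count, profile$taxon),
    c(o__A = 3L, o__B = 1L, o__C = 0L)
  )
  expect_true(all(profile$count <= length(fits)))
  bad <- mkfit("o__A")
  bad$beta <- bad$beta[1:2]
  expect_error(retention_profile(list(fits[[1]], bad)), "feature set")
})

test_that("cutoff selection thresholds at >= and nests monotonically", {
  profile <- structure(
    tibble::tibble(taxon = c("A", "B", "C"), count = c(20L, 12L, 6L)),
    class = c("retention_profile", class(tibble::tibble()))
  )
  expect_setequal(select_by_cutoff(profile, 12), c("A", "B"))
  expect_setequal(select_by_cutoff(profile, 0), c("A", "B", "C"))
  expect_equal(select_by_cutoff(profile, 21), character(0))

  withr::with_seed(4, {
    rnd <- structure(
      tibble::tibble(taxon = sprintf("t%02d", 1:40),
                     count = sample(0:28, 40, replace = TRUE)),
      class = c("retention_profile", class(tibble::tibble()))
    )
  })
  sets <- lapply(0:28, select_by_cutoff, profile = rnd)
  for (i in seq_len(length(sets) - 1L)) {
    expect_true(all(sets[[i + 1L]] %in% sets[[i]]))
  }
})

test_that("ridge and unpenalized limits retain every feature", {
  fx <- enet_fixture()
  target <- fx$index$groups[1]
  ridge <- fit_one_vs_rest(fx$x, fx$index, target,
    elastic_net_spec(alpha = 0, lambda = 0.5)
  )
  expect_equal(length(ridge$retained), length(fx$taxa))
  unpen <- fit_one_vs_rest(fx$x, fx$index, target,
    elastic_net_spec(alpha = 0.4, lambda = 0)
  )
  expect_equal(length(unpen$retained), length(fx$taxa))
})

test_that("a strongly planted taxon is retained by its city's CV-tuned model", {
  fx <- enet_fixture()
  # single-year cities: group label maps directly onto the city
  target <- fx$index$groups[1]
  city <- sub("_.*", "", target)
  fit <- fit_one_vs_rest(fx$x, fx$index, target,
    elastic_net_spec(alpha = 0.4, n_cv_folds = 5, seed = 9)
  )
  sig <- intersect(fx$truth$signature_taxa[[city]], fx$taxa)
  expect_gt(length(intersect(fit$retained, sig)), 0L)
})

test_that("the cutoff sweep reports sizes and errors per cutoff and method", {
  fx <- enet_fixture()
  ret <- one_vs_rest_retention(fx$x, fx$index,
    elastic_net_spec(n_cv_folds = 5, seed = 2)
  )
  plan <- make_split_plan(fx$index, n_reps = 2, seed = 6)
  hi <- max(ret$profile$count)
  sweep <- cutoff_sweep(
    fx$x, fx$index, ret$profile,
    cutoffs = c(1L, hi + 1L), methods = "rf", plan = plan,
    specs = list(rf = learner_spec("rf", n_trees = 200, seed = 3))
  )
  expect_equal(nrow(sweep), 2L)
  expect_true(all(diff(sweep$n_features) <= 0))
  # an empty feature set yields an NA-error row, not a failure
  expect_equal(sweep$n_features[2], 0L)
  expect_true(is.na(sweep$top1_error[2]))
  expect_false(is.na(sweep$top1_error[1]))
  expect_lte(sweep$top2_error[1], sweep$top1_error[1])
})
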