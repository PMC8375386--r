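test_that("profile matching ranks an exact match first at distance zero", {
  known <- metasub_city_traits()
  q <- known[known$city == "DOH", -1]
  res <- match_pattern(q, known)
  expect_equal(res$city[1], "DOH")
  expect_equal(res$distance[1], 0)
})

test_that("the (1,0,1,1,0,1) profile ties Berlin and Kiev at distance zero", {
  q <- c(
    summer_temperature = 1, winter_temperature = 0, summer_humidity = 1,
    winter_humidity = 1, coastal = 0, urbanization = 1
  )
  res <- match_pattern(q, metasub_city_traits())
  at_zero <- res$city[res$distance == 0]
  expect_setequal(at_zero, c("BER", "IEV"))
  expect_true(all(res$rank[res$city %in% c("BER", "IEV")] == 1L))
})

test_that("on binary traits the distance equals the number of mismatches", {
  known <- tibble::tibble(
    city = "K", t1 = 0L, t2 = 0L, t3 = 0L, t4 = 0L
  )
  for (k in 0:4) {
    q <- c(t1 = 0, t2 = 0, t3 = 0, t4 = 0)
    if (k > 0) q[seq_len(k)] <- 1
    expect_equal(match_pattern(q, known)$distance, k)
  }
})

test_that("averaged levels round before matching", {
  known <- tibble::tibble(city = c("A", "B"), t1 = c(1L, 2L), t2 = c(0L, 0L))
  # 1.583 rounds to 2 -> city B wins
  res <- match_pattern(c(t1 = 1.583, t2 = 0.1), known)
  expect_equal(res$city[1], "B")
})

test_that("average profiles are arithmetic means within city", {
  pred <- tibble::tibble(
    sample_id = sprintf("m%02d", 1:12),
    trait_a = c(rep(1L, 5), rep(2L, 7)),
    trait_b = rep(1L, 12)
  )
  avg <- average_profiles(pred, rep("K", 12))
  expect_equal(avg$trait_a, (5 * 1 + 7 * 2) / 12)
  expect_equal(avg$trait_b, 1)
})

test_that("the mystery protocol votes only when a sample is tested", {
  sim <- simulate_metasub(sim_config(
    seed = 10, n_cities = 3,
    years_per_city = setNames(rep(list(2017L), 3), c("CTA", "CTB", "CTC")),
    samples_per_group = 10, signature_effect = 3, batch_effect_sd = 0,
    outlier_fraction = 0, n_mystery_new_cities = 1,
    mystery_samples_per_city = 10
  ))
  fx <- normalized_from_sim(sim)
  myst <- log2_cpm(select_features(sim$mystery$otu, fx$taxa))
  tally <- run_mystery_protocol(
    fx$x, fx$index, myst,
    n_reps = 8, spec = learner_spec("mlp", epochs = 40), seed = 5
  )
  expect_true("mystery" %in% colnames(tally$votes))
  expect_equal(unname(rowSums(tally$votes)), unname(tally$n_tested))
  expect_equal(sum(tally$n_tested), 8 * max(1, round(0.2 * nrow(myst))))
  unseen <- sim$mystery$meta$sample_id[
    sim$mystery$meta$city %in% sim$truth$mystery_cities
  ]
  rate <- mystery_detection_rate(tally, unseen)
  expect_gte(rate, 0)
  expect_lte(rate, 1)
})

test_that("feature mismatches between main and mystery tables are fatal", {
  sim <- strong_sim(seed = 11, n_cities = 3, samples_per_group = 6)
  fx <- normalized_from_sim(sim)
  broken <- fx$x[, -2]
  expect_error(
    run_mystery_protocol(fx$x, fx$index, broken, n_reps = 1),
    "missing taxa"
  )
})

test_that("trait predictions stay within each trait's level set", {
  sim <- strong_sim(seed = 12, n_cities = 4, samples_per_group = 8)
  fx <- normalized_from_sim(sim)
  traits <- discretize_city_traits(sim$traits_raw, seed = 3)
  model <- fit_multioutput_traits(
    fx$x, fx$meta, traits,
    spec = learner_spec("mlp", epochs = 40), seed = 4
  )
  expect_equal(model$holdout_error$trait, setdiff(names(traits), "city"))
  pred <- predict(model, fx$x)
  for (trait in model$traits) {
    expect_true(all(pred[[trait]] %in% as.integer(model$levels[[trait]])))
  }
  expect_error(
    fit_multioutput_traits(fx$x, fx$meta, traits[-1, ]),
    "missing a trait profile"
  )
})
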