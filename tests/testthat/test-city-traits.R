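test_that("month-to-season mapping mirrors across hemispheres", {
  expect_equal(month_to_season(7, "N"), "summer")
  expect_equal(month_to_season(7, "S"), "winter")
  expect_equal(month_to_season(1, "S"), "summer")
  expect_equal(month_to_season(1, "N"), "winter")
  # meteorological blocks: Dec-Feb, Mar-May, Jun-Aug, Sep-Nov
  north <- vapply(1:12, month_to_season, character(1), hemisphere = "N")
  expect_equal(sum(north == "summer"), 3L)
  expect_equal(which(north == "summer"), 6:8)
  expect_equal(which(north == "winter"), c(1, 2, 12))
  south <- vapply(1:12, month_to_season, character(1), hemisphere = "S")
  expect_equal(which(south == "summer"), c(1, 2, 12))
  expect_error(month_to_season(13, "N"), "1..12")
})

test_that("k-means discretization orders labels by cluster mean", {
  labels <- kmeans_discretize(c(1, 1, 1, 10, 10, 10), k = 2, seed = 3)
  expect_equal(labels, c(0L, 0L, 0L, 1L, 1L, 1L))

  withr::with_seed(5, {
    values <- c(rnorm(10, 0), rnorm(10, 8), rnorm(10, 20))
  })
  labels3 <- kmeans_discretize(values, k = 3, seed = 3)
  means <- tapply(values, labels3, mean)
  expect_true(all(diff(means[order(as.integer(names(means)))]) > 0))
  expect_setequal(unique(labels3), 0:2)

  expect_equal(kmeans_discretize(rep(4, 5), k = 1), rep(0L, 5))
  expect_error(kmeans_discretize(c(1, 1, 2), k = 3), "distinct")
})

test_that("silhouette-based k selection finds well-separated clouds", {
  withr::with_seed(8, {
    two <- c(rnorm(12, 0, 0.3), rnorm(12, 10, 0.3))
  })
  expect_equal(choose_k(two, 2:5), 2L)
  expect_equal(choose_k(rep(1, 10)), 1L) # constant vector degenerates to k=1
})

test_that("urbanization scores follow the anthrome ladder and are symmetric", {
  expect_equal(urbanization_score(rep("wildlands", 3)), 0L)
  expect_equal(urbanization_score(rep("dense settlements", 3)), 15L)
  expect_equal(urbanization_score(c("croplands", "villages", "rangelands")), 9L)
  expect_equal(
    urbanization_score(c("rangelands", "croplands", "villages")),
    urbanization_score(c("villages", "rangelands", "croplands"))
  )
  expect_error(urbanization_score(c("city", "villages", "croplands")), "unknown")
  expect_error(urbanization_score(c("villages", "croplands")), "three")
})

test_that("median binarization uses the >= convention and is shift-invariant", {
  scores <- c(A = 3, B = 9, C = 15)
  expect_equal(binarize_urbanization(scores), c(A = 0L, B = 1L, C = 1L))
  expect_equal(binarize_urbanization(c(A = 5, B = 5)), c(A = 1L, B = 1L))
  expect_equal(
    binarize_urbanization(scores + 7),
    binarize_urbanization(scores)
  )
})

test_that("combination counts are products of level cardinalities", {
  expect_equal(combination_count(c(3, 4, 3, 2, 2, 2)), 288)
  expect_equal(combination_count(rep(1, 6)), 1)
  expect_equal(combination_count(c(2, 3)), 6)
  expect_error(combination_count(c(2, 0)), ">= 1")
})

test_that("discretization recovers planted trait levels under wide separation", {
  sim <- simulate_metasub(sim_config(seed = 42, n_cities = 6,
                                     samples_per_group = 5))
  got <- discretize_city_traits(sim$traits_raw, seed = 2)
  want <- sim$truth$city_trait_levels[
    match(got$city, sim$truth$city_trait_levels$city),
  ]
  for (trait in setdiff(names(got), "city")) {
    expect_equal(got[[trait]], want[[trait]], info = trait)
  }
})
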