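test_that("the generator is bit-identical under a fixed seed", {
  cfg <- sim_config(seed = 11, n_cities = 3, samples_per_group = 6,
                    n_taxa_per_rank = c(order = 10, family = 10, species = 20),
                    n_signature_taxa_per_city = 3,
                    n_mystery_new_cities = 1)
  a <- simulate_metasub(cfg)
  b <- simulate_metasub(cfg)
  expect_identical(a$otu, b$otu)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth, b$truth)
  expect_identical(a$traits_raw, b$traits_raw)
  expect_identical(a$mystery$otu, b$mystery$otu)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(samples_per_group = 3), "samples_per_group")
  expect_error(sim_config(outlier_depth_factor = 0.25), "outlier_depth_factor")
  expect_error(
    sim_config(n_signature_taxa_per_city = 500,
               n_taxa_per_rank = c(order = 10, family = 10, species = 20)),
    "signatures"
  )
})

test_that("without planted outliers the depth filter removes nothing", {
  sim <- strong_sim(seed = 5, n_cities = 3, samples_per_group = 8)
  index <- build_group_index(sim$meta)
  res <- order_sum_filter(sim$otu, index)
  expect_equal(length(unlist(res$report$removed)), 0L)
  expect_equal(length(sim$truth$outlier_samples), 0L)
})

test_that("planted low-depth outliers fall below the 20%-of-median cutoff", {
  # a tight library-size distribution so no genuine sample strays below 20%
  # of the group median on its own
  sim <- simulate_metasub(sim_config(
    seed = 21, n_cities = 4, samples_per_group = 20,
    outlier_fraction = 0.1, library_size_dispersion = 0.3
  ))
  index <- build_group_index(sim$meta)
  res <- order_sum_filter(sim$otu, index)
  removed <- unlist(res$report$removed)
  expect_setequal(removed, sim$truth$outlier_samples)
})

test_that("signature taxa are more abundant in their own city", {
  sim <- strong_sim(seed = 13, n_cities = 4, samples_per_group = 10, effect = 2)
  m <- geotrace:::counts_matrix(sim$otu)
  rel <- m / rowSums(m)
  for (city in names(sim$truth$signature_taxa)) {
    own <- sim$meta$city == city
    for (taxon in sim$truth$signature_taxa[[city]]) {
      expect_gt(mean(rel[own, taxon]), mean(rel[!own, taxon]))
    }
  }
})

test_that("with no signal and no batch effect cities are exchangeable in log2-CPM space", {
  sim <- strong_sim(seed = 31, n_cities = 3, samples_per_group = 15,
                    effect = 0, batch = 0)
  norm <- geotrace:::counts_matrix(log2_cpm(sim$otu))
  centroids <- t(vapply(
    split(seq_len(nrow(norm)), sim$meta$city),
    function(i) colMeans(norm[i, , drop = FALSE]),
    numeric(ncol(norm))
  ))
  between <- mean(dist(centroids))
  within <- mean(vapply(
    split(seq_len(nrow(norm)), sim$meta$city),
    function(i) mean(dist(norm[i, , drop = FALSE])),
    numeric(1)
  ))
  expect_lt(between, within)
})

test_that("with strong signal group centroids separate beyond within-group spread", {
  sim <- strong_sim(seed = 37, n_cities = 3, samples_per_group = 15, effect = 4)
  norm <- geotrace:::counts_matrix(log2_cpm(sim$otu))
  split_idx <- split(seq_len(nrow(norm)), sim$meta$group)
  centroids <- t(vapply(
    split_idx, function(i) colMeans(norm[i, , drop = FALSE]),
    numeric(ncol(norm))
  ))
  between <- min(dist(centroids))
  within <- max(vapply(split_idx, function(i) {
    mean(sqrt(rowSums(sweep(
      norm[i, , drop = FALSE], 2, colMeans(norm[i, , drop = FALSE])
    )^2)))
  }, numeric(1)))
  expect_gt(between, within)
})

test_that("emitted seasons follow each city's hemisphere (southern summer is Dec-Feb)", {
  # many cities so both hemispheres are represented at this seed
  sim <- simulate_metasub(sim_config(seed = 17, n_cities = 12,
                                     samples_per_group = 5))
  cities <- sim$traits_raw$cities
  expect_setequal(unique(cities$hemisphere), c("N", "S"))
  climate <- sim$traits_raw$climate
  levels <- sim$truth$city_trait_levels
  for (i in seq_len(nrow(cities))) {
    city <- cities$city[i]
    # only compare cities whose planted summer level exceeds the winter one
    planted <- levels[levels$city == city, ]
    s_center <- geotrace:::trait_centers$summer_temperature[
      planted$summer_temperature + 1L
    ]
    w_center <- geotrace:::trait_centers$winter_temperature[
      planted$winter_temperature + 1L
    ]
    if (s_center <= w_center) next
    temps <- climate[climate$city == city & climate$stat == "temperature_mean", ]
    djf <- mean(temps$value[temps$month %in% c(12, 1, 2)])
    jja <- mean(temps$value[temps$month %in% c(6, 7, 8)])
    if (cities$hemisphere[i] == "S") {
      expect_gt(djf, jja)
    } else {
      expect_gt(jja, djf)
    }
  }
})

test_that("planted urbanization levels agree with the biome-score binarization", {
  sim <- simulate_metasub(sim_config(seed = 23, n_cities = 6))
  cities <- sim$traits_raw$cities
  scores <- vapply(seq_len(nrow(cities)), function(i) {
    urbanization_score(unlist(cities[i, c("biome_1", "biome_2", "biome_3")]))
  }, integer(1)) |> setNames(cities$city)
  bin <- binarize_urbanization(scores)
  planted <- setNames(
    sim$truth$city_trait_levels$urbanization,
    sim$truth$city_trait_levels$city
  )
  expect_equal(bin[names(planted)], planted)
})
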