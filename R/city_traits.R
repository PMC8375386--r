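#' Map a calendar month to its meteorological season
#'
#' Meteorological seasons are fixed three-month blocks; because climate data
#' from the same months correspond to different seasons in the two
#' hemispheres, the mapping is mirrored for southern-hemisphere cities (July
#' is northern summer and southern winter).
#'
#' @param month Integer 1-12.
#' @param hemisphere `"N"` or `"S"`.
#' @return One of `"winter"`, `"spring"`, `"summer"`, `"autumn"`.
#' @export
month_to_season <- function(month, hemisphere = c("N", "S")) {
  hemisphere <- match.arg(hemisphere)
  if (!is.numeric(month) || length(month) != 1L || is.na(month) ||
    month != trunc(month) || month < 1 || month > 12) {
    abort("`month` must be an integer in 1..12")
  }
  north <- c(
    "winter", "winter", "spring", "spring", "spring", "summer",
    "summer", "summer", "autumn", "autumn", "autumn", "winter"
  )
  season <- north[month]
  if (hemisphere == "S") {
    flip <- c(
      winter = "summer", summer = "winter",
      spring = "autumn", autumn = "spring"
    )
    season <- flip[[season]]
  }
  season
}

#' Choose the number of clusters for trait discretization
#'
#' Picks the `k` in `k_range` maximizing the mean silhouette width of a
#' k-means clustering (multiple restarts), a compact stand-in for running an
#' ensemble of cluster-number indices plus visual inspection. A per-trait
#' override via configuration always wins when supplied.
#'
#' @param values Numeric vector (one value per city).
#' @param k_range Candidate cluster counts (k >= 2; k = 1 cannot be scored by
#'   silhouette and is returned only for degenerate inputs).
#' @param seed Seed for the k-means restarts.
#' @return The chosen integer k.
#' @export
choose_k <- function(values, k_range = 2:4, seed = 1L) {
  n_distinct <- dplyr::n_distinct(values)
  if (n_distinct < min(k_range)) {
    return(n_distinct)
  }
  k_range <- k_range[k_range <= n_distinct & k_range < length(values)]
  if (length(k_range) == 0L) {
    return(n_distinct)
  }
  d <- stats::dist(values)
  scores <- withr::with_seed(seed, vapply(k_range, function(k) {
    cl <- kmeans(values, centers = k, nstart = 25)
    mean(cluster::silhouette(cl$cluster, d)[, "sil_width"])
  }, numeric(1)))
  k_range[which.max(scores)]
}

#' Discretize a continuous trait by k-means into ordered levels
#'
#' Runs k-means with multiple restarts and relabels the clusters by ascending
#' cluster mean, so that higher labels always indicate higher values (label 0
#' is the coldest/driest cluster).
#'
#' @param values Numeric vector.
#' @param k Number of clusters (must not exceed the number of distinct
#'   values).
#' @param seed Seed for the restarts.
#' @return Integer labels in `0:(k-1)`, ordered by cluster mean.
#' @export
kmeans_discretize <- function(values, k, seed = 1L) {
  if (k < 1L) abort("k must be >= 1")
  if (k > dplyr::n_distinct(values)) {
    abort("k exceeds the number of distinct values")
  }
  if (k == 1L) {
    return(rep(0L, length(values)))
  }
  if (k == dplyr::n_distinct(values)) {
    # each distinct value is its own cluster; labels are the value order
    return(match(values, sort(unique(values))) - 1L)
  }
  cl <- withr::with_seed(seed, kmeans(values, centers = k, nstart = 25))
  relabel <- rank(cl$centers[, 1]) - 1L # ascending-mean order
  as.integer(relabel[cl$cluster])
}

anthrome_scores <- c(
  "wildlands" = 0L, "forested" = 1L, "rangelands" = 2L,
  "croplands" = 3L, "villages" = 4L, "dense settlements" = 5L
)

#' Urbanization score of three neighboring biomes
#'
#' Each neighboring biome is scored on the anthrome ladder (wildlands 0,
#' forested 1, rangelands 2, croplands 3, villages 4, dense settlements 5)
#' and the three scores are summed, giving a 0-15 score that proxies
#' population density around the sampling city.
#'
#' @param biomes Character vector of exactly three biome labels.
#' @return Integer score in 0..15.
#' @export
urbanization_score <- function(biomes) {
  if (length(biomes) != 3L) abort("exactly three neighboring biomes required")
  unknown <- setdiff(biomes, names(anthrome_scores))
  if (length(unknown) > 0L) {
    abort(sprintf("unknown biome label(s): %s", paste(unknown, collapse = ", ")))
  }
  sum(anthrome_scores[biomes])
}

#' Binarize urbanization scores at the median
#'
#' Cities at or above the median score over all cities get level 1, others 0.
#'
#' @param scores Named numeric vector (city -> urbanization score), length
#'   >= 2.
#' @return Named integer vector of 0/1 levels.
#' @export
binarize_urbanization <- function(scores) {
  if (length(scores) < 2L) abort("need scores for at least two cities")
  as.integer(scores >= median(scores)) |> setNames(names(scores))
}

#' Number of distinct trait-profile combinations
#'
#' Product of per-trait level counts; e.g. six traits with 3, 4, 3, 2, 2 and
#' 2 levels allow at most 288 combinations.
#'
#' @param cardinalities Integer vector of per-trait level counts (all >= 1).
#' @return Integer product.
#' @export
combination_count <- function(cardinalities) {
  if (any(cardinalities < 1)) abort("all cardinalities must be >= 1")
  prod(as.numeric(cardinalities))
}

#' Build the six-trait ordinal profile table from raw city data
#'
#' Transforms the continuous monthly climate series into the six ordered
#' categorical traits: monthly values are remapped to meteorological seasons
#' per hemisphere, the seasonal mean of the chosen statistic is discretized
#' by k-means with value-ordered labels, the coastal indicator passes
#' through, and the three neighboring biomes are scored and binarized at the
#' median urbanization score.
#'
#' @param traits_raw List with `climate` and `cities` tibbles, as produced by
#'   [simulate_city_traits()] or read from the corresponding TSVs.
#' @param stat Which monthly statistic feeds the climate traits (default the
#'   monthly mean).
#' @param k Named integer vector forcing the number of levels per climate
#'   trait; entries set to `NA` fall back to [choose_k()].
#' @param seed Seed for the k-means steps.
#' @return A tibble city x six ordinal traits (the trait-profile table).
#' @export
discretize_city_traits <- function(traits_raw,
                                   stat = "mean",
                                   k = c(
                                     summer_temperature = 3L,
                                     winter_temperature = 4L,
                                     summer_humidity = 3L,
                                     winter_humidity = 2L
                                   ),
                                   seed = 1L) {
  cities <- traits_raw$cities
  climate <- traits_raw$climate |>
    dplyr::left_join(
      dplyr::select(cities, "city", "hemisphere"),
      by = "city"
    ) |>
    dplyr::rowwise() |>
    dplyr::mutate(season = month_to_season(.data$month, .data$hemisphere)) |>
    dplyr::ungroup() |>
    tidyr::separate_wider_delim("stat", "_", names = c("measure", "statistic")) |>
    dplyr::filter(
      .data$statistic == stat,
      .data$season %in% c("summer", "winter")
    ) |>
    dplyr::summarise(
      value = mean(.data$value),
      .by = c("city", "season", "measure")
    ) |>
    dplyr::mutate(trait = dplyr::case_when(
      .data$measure == "temperature" ~ paste0(.data$season, "_temperature"),
      .default = paste0(.data$season, "_humidity")
    ))

  seeds <- derive_seeds(seed, 4L)
  climate_levels <- purrr::imap_dfr(
    split(climate, climate$trait)[names(k)],
    function(df, trait) {
      seed_t <- seeds[[match(trait, names(k))]]
      ki <- k[[trait]]
      if (is.na(ki)) ki <- choose_k(df$value, seed = seed_t)
      tibble::tibble(
        city = df$city,
        trait = trait,
        level = kmeans_discretize(df$value, ki, seed = seed_t)
      )
    }
  ) |>
    tidyr::pivot_wider(names_from = "trait", values_from = "level")

  urb_scores <- vapply(seq_len(nrow(cities)), function(i) {
    urbanization_score(unlist(cities[i, c("biome_1", "biome_2", "biome_3")]))
  }, integer(1)) |> setNames(cities$city)

  climate_levels |>
    dplyr::left_join(
      tibble::tibble(
        city = cities$city,
        coastal = as.integer(cities$coastal),
        urbanization = unname(binarize_urbanization(urb_scores)[cities$city])
      ),
      by = "city"
    ) |>
    dplyr::select(
      "city", "summer_temperature", "winter_temperature",
      "summer_humidity", "winter_humidity", "coastal", "urbanization"
    )
}
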