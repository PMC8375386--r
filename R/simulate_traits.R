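# Planted city trait levels and the raw (continuous) trait tables that the
# discretization module is expected to recover.

# Level cardinalities of the six categorical city traits: three summer
# temperature levels, four winter temperature, three summer humidity, two
# winter humidity, coastal yes/no, urbanization high/low.
trait_cardinalities <- function() {
  c(
    summer_temperature = 3L, winter_temperature = 4L,
    summer_humidity = 3L, winter_humidity = 2L,
    coastal = 2L, urbanization = 2L
  )
}

# Spread k levels over n cities so every level is represented when n >= k.
assign_levels <- function(n, k) {
  sample(rep(seq_len(k) - 1L, length.out = n))
}

plant_trait_levels <- function(cities) {
  n <- length(cities)
  card <- trait_cardinalities()
  tibble::tibble(
    city = cities,
    summer_temperature = assign_levels(n, card[["summer_temperature"]]),
    winter_temperature = assign_levels(n, card[["winter_temperature"]]),
    summer_humidity = assign_levels(n, card[["summer_humidity"]]),
    winter_humidity = assign_levels(n, card[["winter_humidity"]]),
    coastal = assign_levels(n, 2L),
    urbanization = assign_levels(n, 2L)
  )
}

# Cluster centers per planted level; gaps are wide relative to the monthly
# noise so k-means on seasonal means recovers the planted levels.
trait_centers <- list(
  summer_temperature = c(14, 22, 30),
  winter_temperature = c(-12, -2, 8, 18),
  summer_humidity = c(45, 65, 85),
  winter_humidity = c(50, 80)
)

low_urban_biomes <- c("wildlands", "forested", "rangelands")
high_urban_biomes <- c("croplands", "villages", "dense settlements")

#' Generate raw continuous city trait tables
#'
#' Emits monthly temperature and humidity statistics (min/mean/max) whose
#' seasonal means separate into the planted ordinal levels, a hemisphere flag
#' (meteorological summer of a southern-hemisphere city is Dec-Feb in the
#' emitted series), a coastal indicator and three neighboring-biome labels
#' whose urbanization-score binarization matches the planted level.
#'
#' @param config A [sim_config()].
#' @param truth The `truth` element of a [simulate_metasub()] result (only
#'   `city_trait_levels` is used).
#' @return A list with `climate` (tibble: city, month, stat, value) and
#'   `cities` (tibble: city, hemisphere, coastal, biome_1..biome_3).
#' @export
simulate_city_traits <- function(config, truth) {
  levels <- truth$city_trait_levels
  cities <- levels$city
  n <- length(cities)
  hemisphere <- sample(c("N", "S"), n, replace = TRUE, prob = c(2 / 3, 1 / 3))

  month_sd <- 0.8
  climate <- purrr::map2_dfr(cities, hemisphere, function(city, hemi) {
    row <- levels[levels$city == city, ]
    summer_t <- trait_centers$summer_temperature[row$summer_temperature + 1L]
    winter_t <- trait_centers$winter_temperature[row$winter_temperature + 1L]
    summer_h <- trait_centers$summer_humidity[row$summer_humidity + 1L]
    winter_h <- trait_centers$winter_humidity[row$winter_humidity + 1L]
    season <- vapply(1:12, month_to_season, character(1), hemisphere = hemi)
    center_t <- dplyr::case_when(
      season == "summer" ~ summer_t,
      season == "winter" ~ winter_t,
      .default = (summer_t + winter_t) / 2
    )
    center_h <- dplyr::case_when(
      season == "summer" ~ summer_h,
      season == "winter" ~ winter_h,
      .default = (summer_h + winter_h) / 2
    )
    mean_t <- center_t + rnorm(12, 0, month_sd)
    mean_h <- center_h + rnorm(12, 0, month_sd)
    tibble::tibble(
      city = city,
      month = rep(1:12, 6L),
      stat = rep(
        c(
          "temperature_min", "temperature_mean", "temperature_max",
          "humidity_min", "humidity_mean", "humidity_max"
        ),
        each = 12L
      ),
      value = c(mean_t - 4, mean_t, mean_t + 4, mean_h - 8, mean_h, mean_h + 8)
    )
  })

  biomes <- t(vapply(levels$urbanization, function(u) {
    if (u >= 1L) {
      sample(high_urban_biomes, 3L, replace = TRUE)
    } else {
      sample(low_urban_biomes, 3L, replace = TRUE)
    }
  }, character(3)))

  list(
    climate = climate,
    cities = tibble::tibble(
      city = cities,
      hemisphere = hemisphere,
      coastal = levels$coastal,
      biome_1 = biomes[, 1],
      biome_2 = biomes[, 2],
      biome_3 = biomes[, 3]
    )
  )
}
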