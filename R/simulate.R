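#' Configuration for the synthetic city-microbiome generator
#'
#' Builds the configuration for [simulate_metasub()]. Defaults emulate a
#' desk-scale version of a multi-city urban microbiome survey: a handful of
#' cities, some sampled in two consecutive years (so city-year groups absorb
#' batch effects), rank-tagged taxa at order/family/species resolution,
#' city-specific signature taxa shifted on the log-abundance scale,
#' per-city-year batch shifts, log-normal library sizes and a small minority
#' of extreme low-depth samples that the depth filter is expected to remove.
#'
#' @param n_cities Number of cities in the main dataset.
#' @param years_per_city Named list city -> integer years. By default the
#'   first two cities are sampled in 2016 and 2017 and the rest in 2017 only.
#' @param samples_per_group Samples per city-year group (>= 5).
#' @param n_taxa_per_rank Named integer vector with entries `order`, `family`,
#'   `species`.
#' @param n_signature_taxa_per_city Number of taxa planted as city signatures.
#' @param signature_effect Log-scale abundance shift of planted taxa in their
#'   own city (0 = no city signal).
#' @param batch_effect_sd SD of the per-city-year log-scale shift applied to
#'   every taxon (0 = no batch effect).
#' @param library_size_mean,library_size_dispersion Mean and log-scale SD of
#'   the log-normal library-size distribution.
#' @param outlier_fraction Fraction of samples planted as low-depth outliers.
#' @param outlier_depth_factor Depth multiplier for planted outliers; must be
#'   strictly below 0.2 so outliers fall below the 20%-of-median cutoff.
#' @param n_mystery_new_cities,n_mystery_resampled_cities,mystery_samples_per_city
#'   Size of the optional mystery dataset: cities never seen in the main data
#'   (fresh signatures) and cities resampled from the main data.
#' @param seed Integer seed; all output is bit-identical given the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cities = 6,
                       years_per_city = NULL,
                       samples_per_group = 20,
                       n_taxa_per_rank = c(order = 40, family = 60, species = 120),
                       n_signature_taxa_per_city = 8,
                       signature_effect = 2,
                       batch_effect_sd = 0.3,
                       library_size_mean = 2e4,
                       library_size_dispersion = 0.6,
                       outlier_fraction = 0.05,
                       outlier_depth_factor = 0.05,
                       n_mystery_new_cities = 0,
                       n_mystery_resampled_cities = 0,
                       mystery_samples_per_city = 15,
                       seed = 1L) {
  cities <- sprintf("CT%s", LETTERS[seq_len(n_cities)])
  if (is.null(years_per_city)) {
    years_per_city <- setNames(
      c(
        rep(list(c(2016L, 2017L)), min(2L, n_cities)),
        rep(list(2017L), max(0L, n_cities - 2L))
      ),
      cities
    )
  } else {
    cities <- names(years_per_city)
    n_cities <- length(cities)
  }
  cfg <- structure(
    list(
      cities = cities,
      years_per_city = years_per_city,
      samples_per_group = as.integer(samples_per_group),
      n_taxa_per_rank = n_taxa_per_rank,
      n_signature_taxa_per_city = as.integer(n_signature_taxa_per_city),
      signature_effect = signature_effect,
      batch_effect_sd = batch_effect_sd,
      library_size_mean = library_size_mean,
      library_size_dispersion = library_size_dispersion,
      outlier_fraction = outlier_fraction,
      outlier_depth_factor = outlier_depth_factor,
      n_mystery_new_cities = as.integer(n_mystery_new_cities),
      n_mystery_resampled_cities = as.integer(n_mystery_resampled_cities),
      mystery_samples_per_city = as.integer(mystery_samples_per_city),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$samples_per_group < 5L) abort("samples_per_group must be >= 5")
  if (cfg$samples_per_group < 2L) abort("every group needs >= 2 samples")
  total_taxa <- sum(cfg$n_taxa_per_rank)
  n_sig_total <- cfg$n_signature_taxa_per_city *
    (length(cfg$cities) + cfg$n_mystery_new_cities)
  if (n_sig_total > total_taxa) {
    abort("not enough taxa for disjoint city signatures")
  }
  assert_scalar_number(cfg$signature_effect, "signature_effect", 0)
  assert_scalar_number(cfg$batch_effect_sd, "batch_effect_sd", 0)
  assert_scalar_number(cfg$outlier_fraction, "outlier_fraction", 0, 1 - 1e-9)
  if (cfg$outlier_depth_factor <= 0 || cfg$outlier_depth_factor >= 0.2) {
    abort("outlier_depth_factor must lie strictly in (0, 0.2)")
  }
  if (!all(c("order", "family", "species") %in% names(cfg$n_taxa_per_rank))) {
    abort("n_taxa_per_rank must name order, family and species")
  }
  cfg
}

sim_taxon_ids <- function(n_taxa_per_rank) {
  c(
    sprintf("o__Ord%03d", seq_len(n_taxa_per_rank[["order"]])),
    sprintf("f__Fam%03d", seq_len(n_taxa_per_rank[["family"]])),
    # roughly a fifth of species resolve only to genus ("<genus>.spp")
    ifelse(seq_len(n_taxa_per_rank[["species"]]) %% 5L == 0L,
      sprintf("s__Gen%03d.spp", seq_len(n_taxa_per_rank[["species"]])),
      sprintf("s__Sp%03d", seq_len(n_taxa_per_rank[["species"]]))
    )
  )
}

#' Generate a synthetic multi-city OTU dataset
#'
#' Draws, per sample: a library size from a log-normal (scaled down by
#' `outlier_depth_factor` for planted outliers); taxon proportions per rank
#' from a softmax over baseline log-abundances plus the city signature shift
#' plus the city-year batch shift; and counts from a multinomial given the
#' proportions and the library size. Each rank receives its own multinomial
#' with the same library size, mimicking counts aggregated independently at
#' the three ranks. Optionally also generates a mystery dataset with unseen
#' and resampled cities, and the raw city trait tables via
#' [simulate_city_traits()].
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_data`: `otu`, `meta`, `traits_raw`, `truth`
#'   and, when requested, `mystery` (its own `otu`/`meta`).
#' @export
simulate_metasub <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  withr::with_seed(config$seed, simulate_metasub_impl(config))
}

simulate_metasub_impl <- function(cfg) {
  taxa <- sim_taxon_ids(cfg$n_taxa_per_rank)
  rank_of <- taxon_rank(taxa)
  p <- length(taxa)

  mystery_new <- character(0)
  if (cfg$n_mystery_new_cities > 0L) {
    mystery_new <- sprintf("MY%s", LETTERS[seq_len(cfg$n_mystery_new_cities)])
  }
  sig_cities <- c(cfg$cities, mystery_new)

  # disjoint city signatures over the pooled rank-tagged taxa
  pool <- sample(taxa)
  signature_taxa <- split(
    pool[seq_len(cfg$n_signature_taxa_per_city * length(sig_cities))],
    rep(sig_cities, each = cfg$n_signature_taxa_per_city)
  )[sig_cities]

  # wide log-scale spread so rare taxa drop out of some samples, as in real
  # OTU tables (the ubiquity screen then has work to do)
  baseline <- rnorm(p, 0, 2.5)
  names(baseline) <- taxa
  # signature taxa come from the mid-abundance flora (informative city
  # fingerprints are common orders/families, not rarities or dominants):
  # too low and the planted shift drowns in count noise, too high and the
  # shifted taxon swallows the rank's simplex and compositionally dilutes
  # the city's other signatures below their rest-of-world share
  sig_pool <- unique(unlist(signature_taxa))
  band <- quantile(baseline, c(0.4, 0.8))
  baseline[sig_pool] <- pmin(pmax(baseline[sig_pool], band[1]), band[2])

  city_shift <- function(city) {
    shift <- numeric(p)
    names(shift) <- taxa
    shift[signature_taxa[[city]]] <- cfg$signature_effect
    shift
  }

  draw_group <- function(city, year, n, prefix) {
    eta <- rnorm(p, 0, cfg$batch_effect_sd) # shared batch shift of the group
    logit <- baseline + city_shift(city) + eta
    libs <- rlnorm(n, log(cfg$library_size_mean), cfg$library_size_dispersion)
    counts <- matrix(0L, n, p, dimnames = list(NULL, taxa))
    for (r in c("order", "family", "species")) {
      idx <- which(rank_of == r)
      prob <- exp(logit[idx] - max(logit[idx]))
      prob <- prob / sum(prob)
      for (i in seq_len(n)) {
        counts[i, idx] <- rmultinom(1, round(libs[i]), prob)[, 1]
      }
    }
    ids <- sprintf("%s_%s_%02d_%03d", prefix, city, year %% 100L, seq_len(n))
    rownames(counts) <- ids
    list(counts = counts, libs = libs)
  }

  groups <- tidyr::expand_grid(city = cfg$cities) |>
    dplyr::mutate(years = cfg$years_per_city[.data$city]) |>
    tidyr::unnest_longer("years", values_to = "year")

  blocks <- purrr::pmap(groups, function(city, year) {
    draw_group(city, year, cfg$samples_per_group, "S")
  })
  counts <- do.call(rbind, purrr::map(blocks, "counts"))
  meta <- groups |>
    dplyr::mutate(n = cfg$samples_per_group) |>
    tidyr::uncount(.data$n) |>
    dplyr::mutate(sample_id = rownames(counts), .before = 1L) |>
    dplyr::select("sample_id", "city", "year") |>
    add_group_label()

  # plant low-depth outliers by rescaling counts (depth only, not composition)
  n_out <- floor(cfg$outlier_fraction * nrow(counts))
  outliers <- character(0)
  if (n_out > 0L) {
    outliers <- sample(rownames(counts), n_out)
    for (s in outliers) {
      kept <- counts[s, ]
      counts[s, ] <- as.integer(round(kept * cfg$outlier_depth_factor))
    }
  }

  truth <- list(
    signature_taxa = signature_taxa[cfg$cities],
    outlier_samples = outliers,
    city_trait_levels = plant_trait_levels(cfg$cities),
    mystery_cities = mystery_new,
    mystery_resampled = character(0)
  )
  verify_signature_separation(counts, meta, truth, cfg)

  out <- list(
    otu = counts_tibble(counts) |>
      dplyr::mutate(dplyr::across(-"sample_id", as.integer)),
    meta = meta,
    truth = truth,
    config = cfg
  )
  out$traits_raw <- simulate_city_traits(cfg, truth)

  if (cfg$n_mystery_new_cities > 0L || cfg$n_mystery_resampled_cities > 0L) {
    resampled <- head(cfg$cities, cfg$n_mystery_resampled_cities)
    out$truth$mystery_resampled <- resampled
    mcities <- c(mystery_new, resampled)
    mblocks <- purrr::map(mcities, function(city) {
      draw_group(city, 2018L, cfg$mystery_samples_per_city, "M")
    })
    mcounts <- do.call(rbind, purrr::map(mblocks, "counts"))
    out$mystery <- list(
      otu = counts_tibble(mcounts) |>
        dplyr::mutate(dplyr::across(-"sample_id", as.integer)),
      meta = tibble::tibble(
        sample_id = rownames(mcounts),
        city = rep(mcities, each = cfg$mystery_samples_per_city),
        year = 2018L
      ) |> add_group_label()
    )
  }
  structure(out, class = "sim_data")
}

# Empirical check of the planted-signal contract: each signature taxon has a
# strictly higher mean relative abundance in its own city than elsewhere.
verify_signature_separation <- function(counts, meta, truth, cfg) {
  if (cfg$signature_effect <= 0) {
    return(invisible(TRUE))
  }
  rel <- counts / pmax(rowSums(counts), 1)
  for (city in names(truth$signature_taxa)) {
    own <- meta$city == city
    for (taxon in truth$signature_taxa[[city]]) {
      if (mean(rel[own, taxon]) <= mean(rel[!own, taxon])) {
        warn(sprintf(
          "planted signature %s not separated for city %s", taxon, city
        ))
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.sim_data <- function(x, ...) {
  cat(sprintf(
    "<sim_data> %d samples x %d taxa, %d city-year groups%s\n",
    nrow(x$otu), ncol(x$otu) - 1L, dplyr::n_distinct(x$meta$group),
    if (!is.null(x$mystery)) {
      sprintf(" (+%d mystery samples)", nrow(x$mystery$otu))
    } else {
      ""
    }
  ))
  invisible(x)
}
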