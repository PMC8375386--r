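#' Default run configuration
#'
#' A fully serializable nested list of every pipeline parameter: simulation
#' settings, filter fractions, elastic-net alpha and retention cutoff(s),
#' learner choice and repetition counts, and the top-level seed from which
#' each stage derives its own sub-seed. Any subset can be overridden; a copy
#' of the effective config is archived in the output directory of a run.
#'
#' @param ... Named overrides, nested lists merged over the defaults (e.g.
#'   `classify = list(n_reps = 100)`).
#' @return A list of class `geotrace_config`.
#' @export
geotrace_config <- function(...) {
  defaults <- list(
    seed = 1L,
    out = NULL,
    data = list(counts = NULL, meta = NULL), # paths; NULL = simulate
    sim = list(
      n_cities = 6, samples_per_group = 20,
      n_signature_taxa_per_city = 8, signature_effect = 2,
      batch_effect_sd = 0.3, outlier_fraction = 0.05,
      outlier_depth_factor = 0.05,
      n_mystery_new_cities = 2, n_mystery_resampled_cities = 2,
      mystery_samples_per_city = 15
    ),
    preprocess = list(fraction = 0.2, ubiquity = 0.6),
    select = list(alpha = 0.4, cutoff = NULL, cutoffs = NULL, n_cv_folds = 5),
    classify = list(
      method = "mlp", n_reps = 25, test_frac = 0.2, val_frac = 0.2,
      epochs = 80
    ),
    mystery = list(n_reps = 25, epochs = 60)
  )
  overrides <- list(...)
  merge_config <- function(base, new) {
    for (nm in names(new)) {
      base[[nm]] <- if (is.list(new[[nm]]) && is.list(base[[nm]])) {
        merge_config(base[[nm]], new[[nm]])
      } else {
        new[[nm]]
      }
    }
    base
  }
  structure(merge_config(defaults, overrides), class = "geotrace_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file of overrides over [geotrace_config()] defaults.
#' @return A `geotrace_config`.
#' @export
read_config <- function(path) {
  do.call(geotrace_config, yaml::read_yaml(path))
}

write_stage <- function(out, name, tbl) {
  if (!is.null(out)) {
    readr::write_tsv(tbl, file.path(out, paste0(name, ".tsv")), progress = FALSE)
  }
  invisible(tbl)
}

#' Run the full geolocation workflow
#'
#' Orchestrates simulate (or load) -> depth filter -> ubiquity filter ->
#' log2-CPM -> one-vs-rest retention selection -> repeated-split voting
#' classification (optionally a cutoff sweep) -> trait discretization and the
#' multi-output trait model -> mystery-class protocol with candidate-city
#' ranking. Every stage logs sample/feature counts; with `config$out` set,
#' each stage's table and the effective config are written to the directory,
#' and the whole bundle is reproducible from the archived config and seed.
#'
#' @param config A [geotrace_config()].
#' @param verbose Print stage-level progress.
#' @return A list of class `geotrace_run` with the stage outputs: `data`,
#'   `filter_report`, `profile`, `selected_taxa`, `tally`, `errors`, `sweep`,
#'   `trait_table`, `trait_model`, `mystery` (tally, detection, candidates).
#' @export
run_end_to_end <- function(config = geotrace_config(), verbose = TRUE) {
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  seeds <- derive_seeds(config$seed, 8L)
  out <- config$out
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
  if (!is.null(out)) {
    yaml::write_yaml(unclass(config), file.path(out, "config.yaml"))
  }

  # -- data ------------------------------------------------------------
  if (is.null(config$data$counts)) {
    sim_args <- config$sim
    sim_args$seed <- seeds[1]
    sim <- simulate_metasub(do.call(sim_config, sim_args))
    otu <- sim$otu
    meta <- sim$meta
    say("simulated %d samples x %d taxa", nrow(otu), ncol(otu) - 1L)
    if (!is.null(out)) { # ground-truth sidecar for recovery checks
      truth <- sim$truth
      truth$city_trait_levels <- as.list(truth$city_trait_levels)
      yaml::write_yaml(truth, file.path(out, "truth.yaml"))
    }
  } else {
    sim <- NULL
    otu <- read_counts(config$data$counts)
    meta <- read_sample_meta(config$data$meta)
    say("loaded %d samples x %d taxa", nrow(otu), ncol(otu) - 1L)
  }
  index <- build_group_index(meta)
  if (!is.null(out)) write_counts(otu, file.path(out, "counts.tsv"))
  write_stage(out, "meta", meta)

  # -- preprocess ------------------------------------------------------
  filt <- order_sum_filter(otu, index, config$preprocess$fraction)
  say(
    "depth filter: %d -> %d samples", nrow(otu), nrow(filt$otu)
  )
  taxa_kept <- ubiquity_filter(filt$otu, config$preprocess$ubiquity)
  say(
    "ubiquity filter: %d -> %d taxa", ncol(otu) - 1L, length(taxa_kept)
  )
  meta <- dplyr::filter(meta, .data$sample_id %in% filt$otu$sample_id)
  index <- build_group_index(meta)
  norm <- log2_cpm(select_features(filt$otu, taxa_kept))
  write_stage(
    out, "filter_report",
    dplyr::mutate(filt$report, removed = purrr::map_chr(
      .data$removed, paste,
      collapse = ","
    ))
  )

  # -- feature selection ----------------------------------------------
  enet <- elastic_net_spec(
    alpha = config$select$alpha,
    n_cv_folds = config$select$n_cv_folds, seed = seeds[2]
  )
  retention <- one_vs_rest_retention(norm, index, enet)
  profile <- retention$profile
  write_stage(out, "retention_profile", tibble::as_tibble(profile))
  cutoff <- config$select$cutoff %||%
    max(1L, round_half_up(length(index$groups) / 4))
  selected <- select_by_cutoff(profile, cutoff)
  say(
    "retention cutoff %d: %d taxa selected", cutoff, length(selected)
  )
  if (length(selected) == 0L) abort("empty feature set at the chosen cutoff")

  # -- classification --------------------------------------------------
  plan <- make_split_plan(
    index,
    test_frac = config$classify$test_frac,
    val_frac = config$classify$val_frac,
    n_reps = config$classify$n_reps, seed = seeds[3]
  )
  lspec <- learner_spec(config$classify$method,
    epochs = config$classify$epochs, seed = seeds[4]
  )
  tally <- run_protocol(select_features(norm, selected), index, plan, lspec)
  errors <- glance(tally)
  say(
    "%s protocol: top-1 error %.3f, top-2 error %.3f",
    config$classify$method, errors$top1_error, errors$top2_error
  )
  write_stage(out, "vote_tally", tidy(tally))
  write_stage(
    out, "error_summary",
    dplyr::bind_rows(
      dplyr::mutate(per_group_error(tally, index, 1), metric = "top-1"),
      dplyr::mutate(per_group_error(tally, index, 2), metric = "top-2")
    )
  )

  sweep_tbl <- NULL
  if (!is.null(config$select$cutoffs)) {
    sweep_tbl <- cutoff_sweep(
      norm, index, profile, config$select$cutoffs,
      methods = config$classify$method, plan = plan,
      specs = setNames(list(lspec), config$classify$method)
    )
    write_stage(out, "cutoff_sweep", sweep_tbl)
  }

  # -- city traits -----------------------------------------------------
  trait_table <- trait_model <- NULL
  if (!is.null(sim)) {
    trait_table <- discretize_city_traits(sim$traits_raw, seed = seeds[5])
    write_stage(out, "city_traits", trait_table)
    trait_model <- fit_multioutput_traits(
      select_features(norm, selected), meta, trait_table,
      spec = learner_spec("mlp", epochs = config$classify$epochs),
      seed = seeds[6]
    )
    say(
      "trait model mean held-out error %.3f",
      mean(trait_model$holdout_error$error)
    )
    write_stage(out, "trait_errors", trait_model$holdout_error)
  }

  # -- mystery ---------------------------------------------------------
  mystery <- NULL
  if (!is.null(sim) && !is.null(sim$mystery)) {
    myst_norm <- log2_cpm(select_features(sim$mystery$otu, taxa_kept))
    mtally <- run_mystery_protocol(
      select_features(norm, selected), index,
      select_features(myst_norm, selected),
      n_reps = config$mystery$n_reps,
      spec = learner_spec("mlp", epochs = config$mystery$epochs),
      seed = seeds[7]
    )
    unseen <- sim$mystery$meta$sample_id[
      sim$mystery$meta$city %in% sim$truth$mystery_cities
    ]
    detection <- mystery_detection_rate(mtally, unseen)
    say("mystery detection rate %.3f", detection)

    pred <- predict(trait_model, select_features(myst_norm, selected))
    avg <- average_profiles(
      pred,
      sim$mystery$meta$city[match(pred$sample_id, sim$mystery$meta$sample_id)]
    )
    candidates <- purrr::map_dfr(
      which(avg$city %in% sim$truth$mystery_cities),
      function(i) {
        dplyr::mutate(
          match_pattern(avg[i, ], trait_table),
          query_city = avg$city[i], .before = 1L
        )
      }
    )
    write_stage(out, "mystery_votes", tidy(mtally))
    write_stage(out, "average_profiles", avg)
    write_stage(out, "candidate_ranking", candidates)
    mystery <- list(
      tally = mtally, detection_rate = detection,
      average_profiles = avg, candidates = candidates
    )
  }

  structure(
    list(
      config = config, data = list(otu = otu, meta = meta, sim = sim),
      filter_report = filt$report, taxa_kept = taxa_kept,
      profile = profile, selected_taxa = selected,
      plan = plan, tally = tally, errors = errors, sweep = sweep_tbl,
      trait_table = trait_table, trait_model = trait_model,
      mystery = mystery
    ),
    class = "geotrace_run"
  )
}

#' @export
print.geotrace_run <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<geotrace_run> %d samples, %d groups, %d selected taxa\n",
      "  top-1 error %.3f | top-2 error %.3f%s\n"
    ),
    nrow(x$data$otu), length(unique(x$data$meta$group)),
    length(x$selected_taxa),
    x$errors$top1_error, x$errors$top2_error,
    if (!is.null(x$mystery)) {
      sprintf(" | mystery detection %.3f", x$mystery$detection_rate)
    } else {
      ""
    }
  ))
  invisible(x)
}
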