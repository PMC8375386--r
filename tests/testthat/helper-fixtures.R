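# Small fixtures built in code: a hand-sized OTU table whose order-rank
# depths are chosen exactly, matching metadata, and a vote tally constructor.

tiny_otu <- function(order_sums, city = "AAA", year = 2017L) {
  n <- length(order_sums)
  tibble::tibble(
    sample_id = sprintf("%s_s%02d", city, seq_len(n)),
    # one order taxon carries the whole order-level depth
    o__Ord001 = as.integer(order_sums),
    f__Fam001 = rep(5L, n),
    s__Sp001 = rep(3L, n)
  )
}

tiny_meta <- function(otu, city = "AAA", year = 2017L) {
  geotrace::add_group_label(tibble::tibble(
    sample_id = otu$sample_id, city = city, year = as.integer(year)
  ))
}

# A vote tally with explicit vote rows (matrix samples x classes).
manual_tally <- function(votes, truth) {
  geotrace:::new_vote_tally(votes, truth = truth, n_reps = max(rowSums(votes)))
}

# Small strongly-signalled simulation shared by several tests.
strong_sim <- function(seed = 7, n_cities = 5, samples_per_group = 20,
                       effect = 3, batch = 0, ...) {
  cities <- sprintf("CT%s", LETTERS[seq_len(n_cities)])
  simulate_metasub(sim_config(
    seed = seed, n_cities = n_cities,
    years_per_city = setNames(rep(list(2017L), n_cities), cities),
    samples_per_group = samples_per_group,
    signature_effect = effect, batch_effect_sd = batch,
    outlier_fraction = 0, ...
  ))
}

normalized_from_sim <- function(sim) {
  index <- build_group_index(sim$meta)
  filt <- order_sum_filter(sim$otu, index)
  taxa <- ubiquity_filter(filt$otu)
  meta <- dplyr::filter(sim$meta, sample_id %in% filt$otu$sample_id)
  index <- build_group_index(meta)
  list(
    x = log2_cpm(select_features(filt$otu, taxa)),
    index = index, meta = meta, taxa = taxa
  )
}
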