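# Internal helpers shared across modules.

# Deterministically derive independent sub-seeds from one top-level seed.
# Keeps every derived seed a valid 32-bit integer.
derive_seeds <- function(seed, n, salt = 0L) {
  withr::with_seed(as.integer(seed %% .Machine$integer.max) + as.integer(salt), {
    sample.int(.Machine$integer.max - 1L, n)
  })
}

# Round-half-up, the convention used for stratified split sizes.
round_half_up <- function(x) floor(x + 0.5)

# Stable lexicographic ordering independent of the session locale.
lex_sort <- function(x) {
  x[order(x, method = "radix")]
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", name, lower, upper))
  }
  invisible(x)
}

# Extract the numeric count matrix (samples x taxa) from an OTU tibble whose
# first column is `sample_id`.
counts_matrix <- function(otu) {
  m <- as.matrix(otu[, setdiff(names(otu), "sample_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- otu$sample_id
  m
}

# Rebuild the tibble form from a matrix with sample ids in rownames.
counts_tibble <- function(m) {
  tibble::as_tibble(m, .name_repair = "minimal") |>
    dplyr::mutate(sample_id = rownames(m), .before = 1L)
}

taxon_rank <- function(taxon_ids) {
  pref <- substr(taxon_ids, 1L, 3L)
  dplyr::case_when(
    pref == "o__" ~ "order",
    pref == "f__" ~ "family",
    pref == "s__" ~ "species",
    .default = NA_character_
  )
}
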