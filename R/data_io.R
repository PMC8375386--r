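#' Read an OTU count table
#'
#' Reads a tab-separated count table with samples as rows. The first column
#' must be `sample_id`; every remaining column is a taxon whose name carries a
#' rank prefix (`o__`, `f__`, `s__`). Counts are validated (finite,
#' non-negative, integral) and integer-coerced; row and column order are
#' preserved.
#'
#' @param path Path to a TSV file with a header row.
#' @return A tibble with `sample_id` plus one integer column per taxon.
#' @export
read_counts <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  if (names(tbl)[1] != "sample_id") {
    abort("first column of a count table must be `sample_id`")
  }
  validate_otu_table(tbl)
  tbl |>
    dplyr::mutate(dplyr::across(-"sample_id", as.integer))
}

#' Write an OTU count table
#'
#' @param otu A count tibble as returned by [read_counts()] or
#'   [simulate_counts()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(otu, path) {
  readr::write_tsv(otu, path, progress = FALSE)
  invisible(path)
}

validate_otu_table <- function(otu) {
  if (anyDuplicated(otu$sample_id)) {
    abort("duplicate sample ids in count table")
  }
  taxa <- setdiff(names(otu), "sample_id")
  if (anyDuplicated(taxa)) abort("duplicate taxon ids in count table")
  for (taxon in taxa) {
    v <- otu[[taxon]]
    bad <- which(!is.finite(v) | v < 0 | v != trunc(v))
    if (length(bad) > 0L) {
      abort(sprintf(
        "invalid count at sample '%s', taxon '%s': %s",
        otu$sample_id[bad[1]], taxon, format(v[bad[1]])
      ))
    }
  }
  invisible(otu)
}

#' Read sample metadata
#'
#' Reads the per-sample metadata TSV (`sample_id`, `city`, `year`) and derives
#' the `group` label `CITY_YY` that is the unit of classification: samples
#' collected in the same city in different years form distinct groups, which
#' absorbs year-to-year batch effects.
#'
#' @param path Path to a TSV with columns `sample_id`, `city`, `year`.
#' @return A tibble with columns `sample_id`, `city`, `year`, `group`.
#' @export
read_sample_meta <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    city = readr::col_character(),
    year = readr::col_integer()
  ), progress = FALSE)
  add_group_label(meta)
}

#' @rdname read_sample_meta
#' @param meta A tibble with `sample_id`, `city`, `year`.
#' @export
add_group_label <- function(meta) {
  if (any(is.na(meta$city)) || any(is.na(meta$year))) {
    abort("sample with missing city or year in metadata")
  }
  dplyr::mutate(meta, group = group_label(.data$city, .data$year))
}

group_label <- function(city, year) {
  sprintf("%s_%02d", city, as.integer(year) %% 100L)
}

#' Build the city-year group index
#'
#' One group per distinct (city, year) pair, ordered lexicographically. The
#' groups partition the samples and are the classification classes throughout
#' the pipeline (the study design fits one one-vs-rest model per group, e.g.
#' 28 models over 23 cities when five cities are sampled in two years).
#'
#' @param meta Sample metadata tibble with `sample_id`, `city`, `year` (a
#'   `group` column is derived if absent).
#' @return An object of class `group_index`: list with `groups` (ordered
#'   labels), `members` (named list group -> sample ids), and the metadata.
#' @export
build_group_index <- function(meta) {
  if (!all(c("sample_id", "city", "year") %in% names(meta))) {
    abort("metadata must have sample_id, city, year columns")
  }
  if (!"group" %in% names(meta)) meta <- add_group_label(meta)
  if (anyDuplicated(meta$sample_id)) abort("duplicate sample ids in metadata")
  groups <- lex_sort(unique(meta$group))
  members <- lapply(groups, function(g) meta$sample_id[meta$group == g])
  names(members) <- groups
  structure(
    list(groups = groups, members = members, meta = meta),
    class = "group_index"
  )
}

#' @export
print.group_index <- function(x, ...) {
  cat(sprintf(
    "<group_index> %d groups over %d cities, %d samples\n",
    length(x$groups), length(unique(x$meta$city)), nrow(x$meta)
  ))
  invisible(x)
}

# Group label for each sample id, in the order requested.
group_of <- function(index, sample_ids) {
  setNames(index$meta$group, index$meta$sample_id)[sample_ids]
}

city_of <- function(index, sample_ids) {
  setNames(index$meta$city, index$meta$sample_id)[sample_ids]
}

#' Bundled city/year and trait tables
#'
#' `metasub_city_years()` returns the published city/collection-year lists of
#' the 23-city benchmark (28 city-year groups); `metasub_city_traits()` the
#' published six-trait ordinal profile per city (summer/winter temperature,
#' summer/winter humidity, coastal indicator, urbanization of neighboring
#' biomes).
#'
#' @return A tibble.
#' @export
metasub_city_years <- function() {
  path <- system.file("extdata", "metasub_city_years.tsv", package = "geotrace")
  readr::read_tsv(path, col_types = "cci", progress = FALSE) |>
    dplyr::select("sample_id" = "city_name", "city", "year") |>
    dplyr::mutate(sample_id = paste0(.data$city, "_", .data$year))
}

#' @rdname metasub_city_years
#' @export
metasub_city_traits <- function() {
  path <- system.file("extdata", "metasub_city_traits.tsv", package = "geotrace")
  readr::read_tsv(path, col_types = "ciiiiii", progress = FALSE)
}
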