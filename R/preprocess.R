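#' Remove extreme low-depth samples by the order-sum rule
#'
#' For each city-year group, the total count over order-rank taxa is computed
#' per sample and samples whose total falls strictly below `fraction` times
#' the group median are dropped. Low-depth outliers carry little compositional
#' information and degrade the downstream classifiers; the default cutoff is
#' 20% of the within-group median order-level depth.
#'
#' @param otu Count tibble (`sample_id` + taxon columns with rank prefixes).
#' @param index A [build_group_index()] object covering the samples.
#' @param fraction Cutoff as a fraction of the group median order-level depth.
#' @return A list with `otu` (filtered table) and `report`, a tibble with one
#'   row per group: median depth, cutoff (= `fraction` x median exactly),
#'   samples before/after and the removed ids (list column).
#' @export
order_sum_filter <- function(otu, index, fraction = 0.2) {
  assert_scalar_number(fraction, "fraction", 0, 1)
  taxa <- setdiff(names(otu), "sample_id")
  order_taxa <- taxa[taxon_rank(taxa) == "order"]
  if (length(order_taxa) == 0L) abort("no order-rank taxa (o__ prefix) in table")

  m <- counts_matrix(otu)
  depth <- rowSums(m[, order_taxa, drop = FALSE])
  grp <- group_of(index, otu$sample_id)

  report <- tibble::tibble(group = intersect(index$groups, unique(grp))) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      median_order_depth = median(depth[which(grp == .data$group)]),
      cutoff = fraction * .data$median_order_depth,
      n_before = sum(grp == .data$group, na.rm = TRUE),
      removed = list(otu$sample_id[which(grp == .data$group &
                                           depth < .data$cutoff)]),
      n_after = .data$n_before - length(.data$removed)
    ) |>
    dplyr::ungroup()

  small <- report$group[report$n_after < 2L]
  if (length(small) > 0L) {
    warn(sprintf(
      "group(s) with < 2 samples after depth filtering (retained): %s",
      paste(small, collapse = ", ")
    ))
  }
  removed <- unlist(report$removed, use.names = FALSE)
  list(
    otu = otu[!otu$sample_id %in% removed, , drop = FALSE],
    report = report
  )
}

#' Ubiquity pre-filter
#'
#' Ubiquity of a taxon is the fraction of (already depth-filtered) samples in
#' which it has a nonzero count. Taxa are kept only when ubiquity is strictly
#' greater than `threshold` (default 0.6): a taxon present in exactly 60 of
#' 100 samples is removed. This is the relaxed "common feature" screen that
#' precedes the elastic-net selection.
#'
#' @param otu Count tibble.
#' @param threshold Strict lower bound on ubiquity.
#' @return Character vector of retained taxon ids.
#' @export
ubiquity_filter <- function(otu, threshold = 0.6) {
  if (nrow(otu) == 0L) abort("empty count table")
  m <- counts_matrix(otu)
  ubiq <- colMeans(m > 0)
  names(ubiq)[ubiq > threshold]
}

#' log2 counts-per-million normalization
#'
#' The voom convention: `log2((count + 0.5) / (library_size + 1) * 1e6)`,
#' where the library size is the sample's total over the taxa present in the
#' table being normalized. The 0.5/1 offsets bound values away from minus
#' infinity, so the result is finite everywhere.
#'
#' @param otu Count tibble (optionally already restricted to a feature set).
#' @param prior_count Offset added to each count (default 0.5).
#' @param lib_offset Offset added to each library size (default 1).
#' @return A tibble of the same shape with real-valued log2-CPM entries.
#' @export
log2_cpm <- function(otu, prior_count = 0.5, lib_offset = 1) {
  m <- counts_matrix(otu)
  lib <- rowSums(m)
  if (any(lib <= 0)) {
    abort(sprintf(
      "zero library size for sample '%s'",
      otu$sample_id[which(lib <= 0)[1]]
    ))
  }
  norm <- log2((m + prior_count) / (lib + lib_offset) * 1e6)
  out <- counts_tibble(norm)
  out$sample_id <- otu$sample_id
  out
}

#' Restrict a normalized (or count) table to a feature set
#'
#' @param tbl Tibble with `sample_id` plus taxon columns.
#' @param taxa Character vector of taxon ids to keep.
#' @return Tibble with `sample_id` and the requested taxa, in `taxa` order.
#' @export
select_features <- function(tbl, taxa) {
  missing <- setdiff(taxa, names(tbl))
  if (length(missing) > 0L) {
    abort(sprintf("taxa absent from table: %s", paste(missing, collapse = ", ")))
  }
  tbl[, c("sample_id", taxa), drop = FALSE]
}
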