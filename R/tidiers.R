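# broom-style accessors and ggplot2 views for the fitted result objects.

#' @export
tidy.vote_tally <- function(x, ...) {
  tibble::as_tibble(x$votes, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "class", values_to = "votes") |>
    dplyr::left_join(
      tibble::tibble(sample_id = names(x$truth), truth = unname(x$truth)),
      by = "sample_id"
    )
}

#' @export
glance.vote_tally <- function(x, ...) {
  has_truth <- !all(is.na(x$truth))
  tibble::tibble(
    n_test = nrow(x$votes),
    n_classes = ncol(x$votes),
    n_reps = x$n_reps,
    top1_error = if (has_truth) topk_error(x, 1) else NA_real_,
    top2_error = if (has_truth) topk_error(x, 2) else NA_real_
  )
}

#' @export
autoplot.vote_tally <- function(object, ...) {
  tidy(object) |>
    dplyr::mutate(share = .data$votes / pmax(object$n_tested[.data$sample_id], 1)) |>
    ggplot2::ggplot(ggplot2::aes(.data$class, .data$sample_id, fill = .data$share)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "vote share") +
    ggplot2::labs(x = "predicted class", y = "test sample") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @export
tidy.retention_profile <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
autoplot.retention_profile <- function(object, min_count = 1, ...) {
  dplyr::filter(object, .data$count >= min_count) |>
    dplyr::mutate(taxon = stats::reorder(.data$taxon, .data$count)) |>
    ggplot2::ggplot(ggplot2::aes(.data$count, .data$taxon)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "one-vs-rest models retaining the taxon", y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @export
tidy.trait_model <- function(x, ...) {
  x$holdout_error
}

#' @export
glance.trait_model <- function(x, ...) {
  tibble::tibble(
    n_traits = length(x$traits),
    mean_holdout_error = mean(x$holdout_error$error),
    max_holdout_error = max(x$holdout_error$error)
  )
}

#' Per-group error bar chart
#'
#' Top-1 and top-2 error per city-year group from one tally, the per-city
#' view of the protocol's performance.
#'
#' @param tally A `vote_tally` with truth labels.
#' @param index A [build_group_index()].
#' @return A ggplot.
#' @export
plot_group_error <- function(tally, index) {
  dplyr::bind_rows(
    dplyr::mutate(per_group_error(tally, index, 1), metric = "top-1"),
    dplyr::mutate(per_group_error(tally, index, 2), metric = "top-2")
  ) |>
    ggplot2::ggplot(ggplot2::aes(.data$group, .data$error, fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "test error") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
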