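#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-cluster summary of a sample partition
#'
#' @param x a `sample_partition` from [sample_negatives()].
#' @param ... unused.
#' @return tibble with one row per cluster: `cluster`, `size`,
#'   `n_positive`, `positive_fraction`, `selected`.
#' @export
tidy.sample_partition <- function(x, ...) {
  if (is.null(x$labels)) {
    rlang::abort("uniform-draw partitions have no clustering to tidy")
  }
  k <- x$k
  sizes <- tabulate(x$labels, nbins = k)
  n_pos <- tabulate(x$labels[x$positive_idx], nbins = k)
  tibble::tibble(
    cluster = seq_len(k),
    size = sizes,
    n_positive = n_pos,
    positive_fraction = x$p,
    selected = seq_len(k) %in% x$selected_clusters
  )
}

#' One-row summary of a sample partition
#'
#' @inheritParams tidy.sample_partition
#' @return one-row tibble: totals, counts and configuration.
#' @export
glance.sample_partition <- function(x, ...) {
  tibble::tibble(
    n_total = nrow(x$pairs),
    n_positive = length(x$positive_idx),
    n_unlabeled = nrow(x$pairs) - length(x$positive_idx),
    n_negative = length(x$negative_idx),
    k = x$k,
    n_select = x$n_select,
    seed = x$seed
  )
}

#' Per-fold cross-validation metrics
#'
#' @param x an `mda_cv` from [cross_validate()].
#' @param ... unused.
#' @return tibble with one row per repeat x fold.
#' @export
tidy.mda_cv <- function(x, ...) {
  x$metrics
}

#' Cross-validation summary (mean and sd per metric)
#'
#' @inheritParams tidy.mda_cv
#' @return one-row tibble with `<metric>_mean` and `<metric>_sd` columns.
#' @export
glance.mda_cv <- function(x, ...) {
  mets <- c("precision", "recall", "f1", "accuracy", "auroc", "aupr")
  out <- purrr::map(mets, function(mname) {
    v <- x$metrics[[mname]]
    tibble::tibble(
      "{mname}_mean" := mean(v), "{mname}_sd" := stats::sd(v)
    )
  })
  dplyr::bind_cols(out)
}

#' Per-member summary of an ensemble
#'
#' @param x an `mda_ensemble`.
#' @param ... unused.
#' @return tibble with one row per member.
#' @export
tidy.mda_ensemble <- function(x, ...) {
  tibble::tibble(
    member = seq_len(x$m),
    learner = x$learner,
    n_selected = vapply(x$members, function(m) length(m$selected_features), integer(1)),
    n_disease_features = vapply(
      x$members,
      function(m) sum(startsWith(x$feature_names[m$selected_features], "d:")),
      integer(1)
    )
  )
}

#' One-row summary of an ensemble
#'
#' @inheritParams tidy.mda_ensemble
#' @return one-row tibble.
#' @export
glance.mda_ensemble <- function(x, ...) {
  tibble::tibble(
    m = x$m, learner = x$learner,
    feature_fraction = x$feature_fraction,
    n_feature = x$n_feature, seed = x$seed
  )
}

#' Plot the silhouette curve of a cluster-count scan
#'
#' @param object a `k_selection` from [select_k()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.k_selection <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$k, y = .data$silhouette)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_k, linetype = 2, color = "red") +
    ggplot2::labs(
      x = "number of clusters K", y = "mean silhouette coefficient",
      title = sprintf("Silhouette-selected K = %d", object$best_k)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-cluster contamination of a sample partition
#'
#' Bar chart of the positive-sample fraction per cluster, highlighting
#' the harvested (negative-source) clusters.
#'
#' @param partition a `sample_partition` from [sample_negatives()].
#' @return a ggplot.
#' @export
plot_cluster_contamination <- function(partition) {
  df <- tidy(partition)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$cluster), y = .data$positive_fraction,
    fill = .data$selected
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#2c7fb8", `FALSE` = "grey70"),
      name = "harvested"
    ) +
    ggplot2::labs(
      x = "cluster", y = "positive fraction p(i)",
      title = "Cluster contamination by known positives"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the per-fold metric distribution of a cross-validation
#'
#' @param object an `mda_cv` from [cross_validate()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mda_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$metrics,
    cols = dplyr::any_of(c("precision", "recall", "f1", "accuracy", "auroc", "aupr")),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = "held-out value", title = "Cross-validated metrics") +
    ggplot2::theme_minimal()
}
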