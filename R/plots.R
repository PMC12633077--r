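#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cosinor fit over its data
#'
#' Observed values against clock time with the fitted cosine, the MESOR
#' (dashed) and the acrophase (dotted vertical).
#'
#' @param object A [fit_cosinor()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cosinor_fit <- function(object, ...) {
  grid <- tibble::tibble(time_h = seq(0, object$period_h, length.out = 241))
  grid$value <- predict(object, grid$time_h)
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$time_h, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, color = "#2166ac") +
    ggplot2::geom_hline(yintercept = object$mesor, linetype = "dashed",
                        color = "grey40") +
    ggplot2::labs(x = "Time (h)", y = "Value",
                  title = sprintf("Cosinor fit: M = %.3g, A = %.3g",
                                  object$mesor, object$amplitude)) +
    ggplot2::theme_minimal()
  if (object$amplitude_defined) {
    p <- p + ggplot2::geom_vline(xintercept = object$acrophase_h,
                                 linetype = "dotted", color = "grey40")
  }
  p
}

#' Plot cohort time courses with per-group cosinor curves
#'
#' One panel per feature: the observations colored by group, overlaid with
#' each group's fitted cosine (groups with an unfittable design are shown
#' as points only).
#'
#' @param cohort A cohort tibble (schema of [read_cohort()]).
#' @param features Features to show (default: all).
#' @param period Cosinor period in hours (default 24).
#' @return A ggplot.
#' @export
plot_cohort <- function(cohort, features = NULL, period = 24) {
  stopifnot(all(cohort_cols %in% names(cohort)))
  if (!is.null(features)) {
    cohort <- dplyr::filter(cohort, .data$feature %in% features)
  }
  curves <- cohort |>
    dplyr::group_by(.data$feature, .data$group) |>
    dplyr::group_modify(function(df, key) {
      fit <- tryCatch(fit_cosinor(df, period = period),
                      error = function(e) NULL)
      if (is.null(fit)) return(tibble::tibble())
      grid <- seq(0, period, length.out = 241)
      tibble::tibble(time_h = grid, value = predict(fit, grid))
    }) |>
    dplyr::ungroup()
  ggplot2::ggplot(cohort, ggplot2::aes(x = .data$time_h, y = .data$value,
                                       color = .data$group)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = curves) +
    ggplot2::facet_wrap(ggplot2::vars(.data$feature), scales = "free_y") +
    ggplot2::labs(x = "Zeitgeber time (h)", y = "Value", color = "Group") +
    ggplot2::theme_minimal()
}

#' Stacked relative-abundance bars over the circadian cycle
#'
#' Mean relative abundance per group and timepoint, stacked by taxon,
#' optionally after aggregation at a rank — the standard overview of a
#' community's compositional oscillation.
#'
#' @param tt A [taxa_table()].
#' @param rank Optional rank to aggregate at (e.g. `"phylum"`).
#' @return A ggplot.
#' @export
plot_abundance <- function(tt, rank = NULL) {
  stopifnot(inherits(tt, "taxa_table"))
  if (!is.null(rank)) tt <- aggregate_rank(tt, rank)
  if (tt$mode == "counts") tt <- relative_abundance(tt)
  long <- tibble::as_tibble(tt$counts, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "taxon",
                        values_to = "proportion") |>
    dplyr::inner_join(tt$metadata, by = "sample_id") |>
    dplyr::group_by(.data$group, .data$time_h, .data$taxon) |>
    dplyr::summarise(proportion = mean(.data$proportion), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$time_h),
                                     y = .data$proportion,
                                     fill = .data$taxon)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(ggplot2::vars(.data$group)) +
    ggplot2::labs(x = "Zeitgeber time (h)", y = "Relative abundance",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
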