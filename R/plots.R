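#' Complexity through ontogeny
#'
#' Scatter of a complexity score against relative developmental age, per
#' suture, with least-squares trend lines — the package's standard view of
#' ontogenetic complexity change.
#'
#' @param records a complexity table (see [complexity_table()]).
#' @param study the originating study (for `relative_age`).
#' @param metric `"fd"` or `"psd"`.
#' @return a ggplot.
#' @export
plot_complexity_ontogeny <- function(records, study, metric = c("fd", "psd")) {
  metric <- match.arg(metric)
  df <- dplyr::left_join(
    records,
    tibble::as_tibble(study)[c("specimen_id", "relative_age")],
    by = "specimen_id"
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$relative_age, y = .data[[metric]],
    colour = .data$suture
  )) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE, linewidth = 0.6) +
    ggplot2::labs(
      x = "relative age (% of adult centroid size)",
      y = toupper(metric), colour = "suture"
    ) +
    ggplot2::theme_minimal()
}

#' Distribution of complexity scores by suture
#'
#' @param records a complexity table.
#' @param metric `"fd"` or `"psd"`.
#' @return a ggplot boxplot.
#' @export
plot_complexity_by_suture <- function(records, metric = c("fd", "psd")) {
  metric <- match.arg(metric)
  ggplot2::ggplot(records, ggplot2::aes(
    x = .data$suture, y = .data[[metric]],
    fill = .data$suture
  )) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = toupper(metric)) +
    ggplot2::theme_minimal()
}
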