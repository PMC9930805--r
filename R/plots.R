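# Plots -----------------------------------------------------------------------

#' Plot a fitted calibration
#'
#' Draws the fitted sex-specific quadratic score-age curves, optionally over
#' the (age, sum score) scatter of the cohort they were fitted on.
#'
#' @param object a `dental_calibration`.
#' @param data optional cohort tibble with `sex`, `ca_years`, `nolla_sum`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot dental_calibration
#' @export
autoplot.dental_calibration <- function(object, data = NULL, ...) {
  curves <- purrr::map_dfr(object, function(m) {
    ages <- seq(m$age_domain[1], m$age_domain[2], length.out = 200)
    tibble::tibble(sex = m$sex, ca_years = ages, nolla_sum = suppressWarnings(predict_score(m, ages)))
  })
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$ca_years, y = .data$nolla_sum, colour = .data$sex))
  if (!is.null(data)) {
    data <- tibble::as_tibble(data)
    if (!"nolla_sum" %in% names(data)) data <- add_nolla_sum(data)
    p <- p + ggplot2::geom_point(data = data, alpha = 0.3, size = 0.8)
  }
  p +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::labs(
      x = "Chronological age (years)", y = "Nolla sum score",
      colour = NULL, title = "Quadratic score-age calibration"
    ) +
    ggplot2::theme_minimal()
}

#' Compare per-group MAD across methods
#'
#' Bar chart of the mean absolute difference per age group and sex for
#' several evaluated methods (the classical comparison figure for
#' age-estimation studies).
#'
#' @param reports a named list of accuracy-report tibbles from
#'   [evaluate_method()], one per method.
#' @return a ggplot object.
#' @export
plot_mad_comparison <- function(reports) {
  stopifnot(is.list(reports), !is.null(names(reports)))
  combined <- purrr::imap_dfr(reports, function(rep, nm) {
    dplyr::mutate(rep, method = nm, .before = 1)
  })
  combined <- dplyr::filter(combined, .data$group != "total", .data$sex != "total")
  ggplot2::ggplot(
    combined,
    ggplot2::aes(x = .data$group, y = .data$mad, fill = .data$method)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~sex, ncol = 1) +
    ggplot2::labs(
      x = "Age group (years)", y = "Mean absolute difference (years)",
      fill = NULL
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
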