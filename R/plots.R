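# ggplot2 visualisations for the main result types.

#' Plot posterior population-level parameters
#'
#' Density of the posterior population mean of each free scalar parameter
#' (natural scale), facetted by parameter, coloured by group; or trace
#' plots for convergence checks.
#'
#' @param object A [fit_hierarchical()] result.
#' @param type `"population"` (densities) or `"trace"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wr_fit <- function(object, type = c("population", "trace"), ...) {
  type <- match.arg(type)
  to_nat <- function(p, v) if (p %in% KAPPA_IDX) exp(v) else stats::plogis(v)
  long <- purrr::map_dfr(object$egroups, function(g) {
    purrr::map_dfr(object$free_idx, function(p) {
      tibble::tibble(
        group = g, parameter = PARAM_NAMES[p],
        chain = factor(object$chain),
        draw = seq_along(object$chain),
        value = to_nat(p, object$draws$pop_mean[[g]][, p])
      )
    })
  })
  if (type == "population") {
    ggplot2::ggplot(long, ggplot2::aes(x = .data$value, colour = .data$group)) +
      ggplot2::geom_density() +
      ggplot2::facet_wrap(~parameter, scales = "free") +
      ggplot2::labs(x = "population mean (natural scale)", y = "posterior density") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(long, ggplot2::aes(x = .data$draw, y = .data$value,
                                       colour = .data$chain)) +
      ggplot2::geom_line(alpha = 0.7) +
      ggplot2::facet_grid(parameter ~ group, scales = "free_y") +
      ggplot2::labs(x = "retained draw", y = "population mean") +
      ggplot2::theme_minimal()
  }
}

#' Plot the composition of swap errors
#'
#' Group-mean percentage of swap trials classified as symmetric
#' misbinding, asymmetric misattribution by feature guessing, and by
#' object guessing, with Loftus-Masson within-subject SEM error bars when
#' more than one group is present.
#'
#' @param fit A [fit_hierarchical()] result.
#' @return A ggplot object.
#' @export
plot_composition <- function(fit) {
  tb <- summarize_errors(fit)
  long <- tidyr::pivot_longer(
    tb, c("pct_symmetric", "pct_asym_feature", "pct_asym_object"),
    names_to = "component", values_to = "pct"
  )
  long$component <- factor(
    long$component,
    levels = c("pct_symmetric", "pct_asym_feature", "pct_asym_object"),
    labels = c("symmetric misbinding", "asymmetric: feature guess",
               "asymmetric: object guess")
  )
  agg <- long |>
    dplyr::group_by(.data$group, .data$component) |>
    dplyr::summarise(mean = mean(.data$pct), .groups = "drop")
  # within-subject SEM across groups, per component
  sems <- long |>
    dplyr::group_by(.data$component) |>
    dplyr::group_modify(function(d, key) {
      m <- tidyr::pivot_wider(d[, c("subject", "group", "pct")],
                              names_from = "group", values_from = "pct")
      m <- as.matrix(m[, -1, drop = FALSE])
      if (ncol(m) < 2 || anyNA(m)) {
        tibble::tibble(group = colnames(m),
                       sem = apply(m, 2, stats::sd) / sqrt(nrow(m)))
      } else {
        ws <- within_subject_sem(m)
        tibble::tibble(group = ws$condition, sem = ws$sem)
      }
    }) |> dplyr::ungroup()
  agg <- dplyr::left_join(agg, sems, by = c("group", "component"))
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$component, y = .data$mean,
                                    fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = "% of swap trials") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}

#' Plot a Bayes-factor prior-sensitivity curve
#'
#' @param sensitivity Output of [bf_sensitivity()].
#' @return A ggplot object.
#' @export
plot_bf_sensitivity <- function(sensitivity) {
  ggplot2::ggplot(sensitivity,
                  ggplot2::aes(x = .data$prior_scale, y = .data$bf10)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(1 / 3, 1, 3), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Cauchy prior scale", y = expression(BF[10])) +
    ggplot2::theme_minimal()
}

#' Histogram of raw unsigned recall error
#'
#' @param data Trial table.
#' @param binwidth Degrees per bin.
#' @return A ggplot object.
#' @export
plot_absolute_error <- function(data, binwidth = 10) {
  err <- absolute_error(data)
  ggplot2::ggplot(err, ggplot2::aes(x = .data$error)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::facet_grid(dimension ~ condition) +
    ggplot2::labs(x = "absolute error (degrees)", y = "count") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
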