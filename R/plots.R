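# ggplot2 visualisations for the main result types

#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_ribbon geom_line
#'   geom_col geom_text labs facet_wrap theme_minimal position_dodge
NULL

#' @export
ggplot2::autoplot

#' Plot a Kaplan-Meier fit
#'
#' @param object A [kaplan_meier()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.blc_km <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$time, y = .data$surv,
                           colour = .data$group)) +
    geom_step() +
    labs(x = "Years since diagnosis", y = "Survival probability",
         colour = NULL) +
    theme_minimal()
}

#' Plot cumulative incidence curves with a standard-error band
#'
#' @param object A [cumulative_incidence()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.blc_cif <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$time, y = .data$cif,
                           colour = .data$group, fill = .data$group)) +
    geom_ribbon(aes(ymin = pmax(0, .data$cif - .data$se),
                    ymax = pmin(1, .data$cif + .data$se)),
                alpha = 0.2, colour = NA) +
    geom_step() +
    labs(x = "Years since diagnosis",
         y = paste("Cumulative incidence of", object$event),
         colour = NULL, fill = NULL) +
    theme_minimal()
}

#' Plot mutation density over age
#'
#' Shows the smoothed mutation frequency over age per gene, the central
#' readout of the cutoff-free age analysis.
#'
#' @param curves Output of [age_density_curves()].
#' @param genes Optional subset of genes.
#' @param relative Plot the curve relative to its pediatric mean instead of
#'   the absolute frequency.
#' @return A ggplot object.
#' @export
plot_age_density <- function(curves, genes = NULL, relative = FALSE) {
  if (!is.null(genes)) curves <- curves %>% filter(.data$gene %in% genes)
  y <- if (relative) "relative_to_children" else "smoothed_frequency"
  ggplot(curves, aes(x = .data$age, y = .data[[y]])) +
    geom_line() +
    facet_wrap(~gene, scales = "free_y") +
    labs(x = "Age (years)",
         y = if (relative) "Mutation density relative to children"
             else "Smoothed mutation frequency") +
    theme_minimal()
}

#' Plot association test results as paired frequency bars
#'
#' @param assoc Output of [run_comparisons()].
#' @param top Show at most this many genes, ordered by p-value.
#' @return A ggplot object.
#' @export
plot_association <- function(assoc, top = 15) {
  df <- assoc %>%
    arrange(.data$p) %>%
    head(top) %>%
    tidyr::pivot_longer(c("freq_a", "freq_b"), names_to = "side",
                        values_to = "frequency") %>%
    mutate(group = if_else(.data$side == "freq_a", .data$group_a,
                           .data$group_b),
           gene = factor(.data$gene, levels = unique(.data$gene)))
  stars <- df %>% distinct(.data$gene, .data$stars, .data$p)
  ggplot(df, aes(x = .data$gene, y = .data$frequency, fill = .data$group)) +
    geom_col(position = position_dodge()) +
    geom_text(data = stars, aes(x = .data$gene, y = Inf, label = .data$stars),
              vjust = 1.2, inherit.aes = FALSE) +
    labs(x = NULL, y = "Mutation frequency", fill = NULL) +
    theme_minimal()
}

#' Plot per-step retention of the filter hierarchy
#'
#' @param result A [apply_filter_hierarchy()] result.
#' @return A ggplot object.
#' @export
plot_retention <- function(result) {
  df <- result$retention %>%
    mutate(step = factor(.data$step, levels = .data$step))
  ggplot(df, aes(x = .data$step, y = .data$pct_remaining)) +
    geom_col() +
    labs(x = NULL, y = "% of discovered variants remaining") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
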