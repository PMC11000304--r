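# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of reversibility-class calls
#'
#' @param object A `reversibility_calls` tibble from [classify_all()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reversibility_calls <- function(object, ...) {
  counts <- glance.reversibility_calls(object) %>%
    tidyr::pivot_longer(c("n", "n_strong"), names_to = "set",
                        values_to = "count") %>%
    dplyr::mutate(set = dplyr::recode(.data$set, n = "all calls",
                                      n_strong = "strong effect"))
  ggplot2::ggplot(counts, ggplot2::aes(
    x = factor(.data$cls, levels = CLASS_LEVELS),
    y = .data$count, fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "reversibility class", y = "genes", fill = NULL,
                  title = sprintf("Smoke-injury dynamics (%s cohort)",
                                  attr(object, "cohort") %||% "?")) +
    ggplot2::theme_minimal()
}

#' Transition heatmap between two cohorts' reversibility classes
#'
#' @param object A `cohort_comparison` from [compare_cohorts()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_comparison <- function(object, ...) {
  long <- tidy.cohort_comparison(object)
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$cohort_b, levels = CLASS_LEVELS),
    y = factor(.data$cohort_a, levels = rev(CLASS_LEVELS)),
    fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "class in cohort B", y = "class in cohort A",
                  fill = "genes") +
    ggplot2::theme_minimal()
}

#' Mean ROC curves across cross-validation rounds
#'
#' @param object A `cv_report` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_report <- function(object, ...) {
  curves <- object$scores %>%
    dplyr::group_by(.data$round) %>%
    dplyr::group_modify(~ roc_points(.x$score, .x$label)) %>%
    dplyr::ungroup()
  ggplot2::ggplot(curves, ggplot2::aes(.data$fpr, .data$tpr,
                                       group = .data$round)) +
    ggplot2::geom_step(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "false-positive rate", y = "sensitivity",
                  title = sprintf("ROC over %d CV rounds (mean AUC %.3f)",
                                  object$rounds,
                                  mean(object$summary$auc_roc))) +
    ggplot2::theme_minimal()
}

#' Enrichment dot plot for TF regulons
#'
#' @param object An `enrichment_records` tibble from
#'   [regulon_overrepresentation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_records <- function(object, ...) {
  df <- tibble::as_tibble(object) %>%
    dplyr::arrange(.data$p_adjusted) %>%
    dplyr::mutate(tf_id = factor(.data$tf_id, levels = rev(.data$tf_id)))
  ggplot2::ggplot(df, ggplot2::aes(-log10(.data$p_adjusted), .data$tf_id,
                                   size = .data$hits, colour = .data$fold)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = expression(-log[10] ~ "adjusted p"), y = NULL,
                  size = "hits", colour = "fold") +
    ggplot2::theme_minimal()
}

#' Tile plot of metascore-risk correlations by stratum
#'
#' @param correlations Tibble from [correlate_with_risk()].
#' @return A ggplot object with Spearman rho fills and significance stars.
#' @export
plot_risk_correlations <- function(correlations) {
  ggplot2::ggplot(correlations, ggplot2::aes(
    x = .data$stratum, y = .data$geneset, fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$stars) | .data$stars == "ns", "",
                     .data$stars))) +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "steelblue", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal()
}
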