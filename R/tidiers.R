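# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a risk model's coefficients
#'
#' @param x A `risk_model` from [train_classifier()].
#' @param ... Unused.
#' @return Tibble with term, estimate and a selected flag (nonzero at the
#'   chosen penalty).
#' @export
tidy.risk_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$features),
    estimate = c(x$intercept, unname(x$coefficients)),
    selected = c(TRUE, unname(x$coefficients != 0))
  )
}

#' One-row summary of a risk model
#'
#' @param x A `risk_model`.
#' @param ... Unused.
#' @return Tibble with target, lambda, feature counts.
#' @export
glance.risk_model <- function(x, ...) {
  tibble::tibble(
    target = x$target, lambda = x$lambda,
    n_features = length(x$features),
    n_selected = sum(x$coefficients != 0)
  )
}

#' Per-round cross-validation performance
#'
#' @param x A `cv_report` from [cross_validate()].
#' @param ... Unused.
#' @return Tibble with round, auc_roc, auc_pr.
#' @export
tidy.cv_report <- function(x, ...) x$summary

#' One-row cross-validation summary
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return Tibble with CV geometry and mean/sd of both AUCs.
#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(
    rounds = x$rounds, folds = x$folds,
    auc_roc_mean = mean(x$summary$auc_roc), auc_roc_sd = sd(x$summary$auc_roc),
    auc_pr_mean = mean(x$summary$auc_pr), auc_pr_sd = sd(x$summary$auc_pr)
  )
}

#' Class-transition counts as a long tibble
#'
#' @param x A `cohort_comparison` from [compare_cohorts()].
#' @param ... Unused.
#' @return Tibble with cohort_a class, cohort_b class, n.
#' @export
tidy.cohort_comparison <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$counts, responseName = "n")) %>%
    dplyr::mutate(dplyr::across(c("cohort_a", "cohort_b"), as.character))
}

#' One-row summary of a cohort comparison
#'
#' @param x A `cohort_comparison`.
#' @param ... Unused.
#' @return Tibble with shared-gene and response-gene counts and the
#'   strong-overlap chi-squared test.
#' @export
glance.cohort_comparison <- function(x, ...) {
  tibble::tibble(
    n_shared = x$n_shared,
    n_response = length(x$response_genes),
    overlap_chisq = unname(x$strong_overlap_test$statistic),
    overlap_p = x$strong_overlap_test$p.value
  )
}

#' Per-class call counts for a cohort
#'
#' @param x A `reversibility_calls` tibble from [classify_all()].
#' @param ... Unused.
#' @return Tibble with cls, n and n_strong per reversibility class.
#' @export
glance.reversibility_calls <- function(x, ...) {
  tibble::as_tibble(x) %>%
    dplyr::mutate(cls = factor(.data$cls, levels = CLASS_LEVELS)) %>%
    dplyr::group_by(.data$cls, .drop = FALSE) %>%
    dplyr::summarise(n = dplyr::n(), n_strong = sum(.data$strong),
                     .groups = "drop") %>%
    dplyr::mutate(cls = as.character(.data$cls))
}
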