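# Hypergeometric overrepresentation of gene sets in TF regulons, a simple
# per-sample regulon activity score, and group comparison of activities.

#' Overrepresentation of a geneset in TF regulons
#'
#' One-tailed hypergeometric test per TF: with N genes in the universe, m
#' targets in the TF's regulon, k geneset members and q hits (geneset
#' members among the targets), the p-value is the upper tail P(X >= q)
#' (survival function evaluated at q - 1). Benjamini-Hochberg adjustment
#' across TFs is applied unless `adjust = FALSE` (appropriate when only a
#' handful of pre-selected TFs are tested).
#'
#' @param regulons Regulon tibble (tf_id, target, mode), see
#'   [read_regulons()].
#' @param geneset Character vector of gene ids; must lie in the universe.
#' @param universe Character vector of all gene ids (e.g. rownames of the
#'   expression matrix), or a single integer universe size (then membership
#'   checks are skipped and targets/geneset are taken as within-universe).
#' @param adjust Apply BH correction across TFs (default TRUE).
#' @return Tibble of class `enrichment_records`: tf_id, regulon_size,
#'   universe_size, geneset_size, hits, expected, fold, p_raw, p_adjusted.
#' @export
regulon_overrepresentation <- function(regulons, geneset, universe,
                                       adjust = TRUE) {
  validate_regulons(regulons)
  geneset <- unique(geneset)
  if (is.character(universe)) {
    N <- length(unique(universe))
    offenders <- setdiff(geneset, universe)
    assert_that(length(offenders) == 0,
                paste("geneset members outside the universe:",
                      paste(utils::head(offenders, 5), collapse = ", ")))
    regulons <- regulons[regulons$target %in% universe, , drop = FALSE]
  } else {
    N <- as.integer(universe)
  }
  k <- length(geneset)
  out <- regulons %>%
    dplyr::group_by(tf_id = .data$tf_id) %>%
    dplyr::summarise(
      regulon_size = dplyr::n_distinct(.data$target),
      hits = sum(unique(.data$target) %in% geneset),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      universe_size = N,
      geneset_size = k,
      expected = .data$regulon_size * k / N,
      fold = .data$hits / .data$expected,
      p_raw = phyper(.data$hits - 1, k, N - k, .data$regulon_size,
                     lower.tail = FALSE)
    )
  out$p_adjusted <- if (adjust) p.adjust(out$p_raw, method = "BH") else out$p_raw
  class(out) <- c("enrichment_records", class(out))
  out
}

#' Per-sample regulon activity score
#'
#' A deliberately simple surrogate for network-based activity inference:
#' each target gene is z-scored across samples, multiplied by its
#' regulation mode (+1 activating, -1 repressing), and the scores are
#' averaged over the regulon's targets present in the matrix. A target
#' with constant expression contributes 0, so a regulon of constant genes
#' scores 0 everywhere.
#'
#' @param expr Expression matrix (genes x samples).
#' @param regulons Regulon tibble (tf_id, target, mode); may contain one or
#'   many TFs.
#' @return Tibble with sample_id and one column of activity per TF.
#' @export
activity_score <- function(expr, regulons) {
  validate_regulons(regulons)
  z <- t(scale(t(expr)))
  z[!is.finite(z)] <- 0  # constant genes carry no activity information
  tfs <- unique(regulons$tf_id)
  scores <- purrr::map(tfs, function(tf) {
    reg <- regulons[regulons$tf_id == tf, ]
    present <- reg$target %in% rownames(expr)
    assert_that(any(present),
                sprintf("regulon %s has no targets in the expression matrix", tf))
    reg <- reg[present, ]
    colMeans(z[reg$target, , drop = FALSE] * reg$mode)
  })
  dplyr::bind_cols(tibble::tibble(sample_id = colnames(expr)),
                   tibble::as_tibble(setNames(purrr::map(scores, as.numeric), tfs)))
}

#' Compare regulon activity between sample groups
#'
#' Welch two-sample t-test per TF for every pair of groups, with the usual
#' significance stars (ns and * / ** / *** / **** at 0.05 / 0.01 / 0.001 /
#' 0.0001). Groups with fewer than two samples are skipped with a warning.
#'
#' @param scores Activity tibble from [activity_score()].
#' @param metadata Sample metadata.
#' @param group_var Metadata column defining the groups (e.g. "cohort" or
#'   "diagnosis").
#' @return Tibble with tf_id, group_1, group_2, n_1, n_2, t_stat, p_value,
#'   stars.
#' @export
compare_activity <- function(scores, metadata, group_var = "cohort") {
  assert_that(group_var %in% names(metadata),
              sprintf("metadata has no column '%s'", group_var))
  grp <- metadata[[group_var]][match(scores$sample_id, metadata$sample_id)]
  tfs <- setdiff(names(scores), "sample_id")
  groups <- sort(unique(grp[!is.na(grp)]))
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    i1 <- which(grp == pr[1])
    i2 <- which(grp == pr[2])
    if (length(i1) < 2 || length(i2) < 2) {
      rlang::warn(sprintf("group pair %s/%s has < 2 samples; skipped",
                          pr[1], pr[2]))
      return(tibble::tibble())
    }
    purrr::map_dfr(tfs, function(tf) {
      tt <- t.test(scores[[tf]][i1], scores[[tf]][i2])
      tibble::tibble(tf_id = tf, group_1 = pr[1], group_2 = pr[2],
                     n_1 = length(i1), n_2 = length(i2),
                     t_stat = unname(tt$statistic), p_value = tt$p.value,
                     stars = p_stars(tt$p.value))
    })
  })
}
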