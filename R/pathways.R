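# Geneset metascores on batch-corrected expression and their correlation
# with risk scores, stratified by smoking status.

#' Regress the experimental batch effect out of an expression matrix
#'
#' Per gene, ordinary least-squares residuals of expression on the batch
#' indicator(s), with the gene's grand mean added back so values stay on
#' the normalized-expression scale. A single-level batch passes the matrix
#' through unchanged with a warning.
#'
#' @param expr Expression matrix (genes x samples).
#' @param batch Batch label per sample (aligned with columns).
#' @return Residual expression matrix of the same shape.
#' @export
regress_out_batch <- function(expr, batch) {
  validate_expression(expr)
  assert_that(length(batch) == ncol(expr), "batch must align with samples")
  batch <- factor(batch)
  if (nlevels(batch) < 2) {
    rlang::warn("batch has a single level; returning expression unchanged")
    return(expr)
  }
  if (any(table(batch) == 1)) {
    rlang::warn("a batch level has a single sample; batch still fit")
  }
  X <- stats::model.matrix(~batch)
  res <- t(resid_on(t(expr), X))
  res + rowMeans(expr)
}

#' Per-sample metascore of a geneset
#'
#' Unweighted mean of (batch-corrected) normalized expression over the
#' geneset members present in the matrix. Coverage (fraction of members
#' present) is attached as an attribute; absent members are ignored.
#'
#' @param expr Expression matrix, typically from [regress_out_batch()].
#' @param geneset Character vector of member gene ids.
#' @param zscore Standardise each member gene across samples before
#'   averaging (off by default; the plain mean keeps expression units).
#' @return Named numeric vector of per-sample scores, with a `coverage`
#'   attribute.
#' @export
metascore <- function(expr, geneset, zscore = FALSE) {
  members <- intersect(geneset, rownames(expr))
  assert_that(length(members) > 0,
              paste("no geneset members present in the expression matrix"))
  coverage <- length(members) / length(unique(geneset))
  if (coverage < 1) {
    rlang::inform(sprintf("geneset coverage: %d/%d members present",
                          length(members), length(unique(geneset))))
  }
  sub <- expr[members, , drop = FALSE]
  if (zscore) {
    sub <- t(scale(t(sub)))
    sub[!is.finite(sub)] <- 0
  }
  out <- colMeans(sub)
  attr(out, "coverage") <- coverage
  out
}

#' Metascores for a collection of genesets
#'
#' Convenience wrapper: batch-corrects the matrix (unless `batch` is NULL)
#' and scores every geneset.
#'
#' @param expr Expression matrix (genes x samples).
#' @param genesets Named list of gene-id vectors (see [read_genesets()]).
#' @param batch Optional batch labels; when given, the batch effect is
#'   regressed out first.
#' @param zscore See [metascore()].
#' @return Tibble with sample_id and one column per geneset.
#' @examples
#' # eight representative pathway genesets ship as a synthetic fixture
#' gmt <- system.file("extdata", "representative_genesets_synthetic.gmt",
#'                    package = "airwaysmoke")
#' genesets <- read_genesets(gmt)
#' @export
metascore_table <- function(expr, genesets, batch = NULL, zscore = FALSE) {
  if (!is.null(batch)) expr <- regress_out_batch(expr, batch)
  scores <- purrr::map(genesets, ~ metascore(expr, .x, zscore = zscore))
  dplyr::bind_cols(tibble::tibble(sample_id = colnames(expr)),
                   tibble::as_tibble(purrr::map(scores, as.numeric)))
}

#' Correlate pathway metascores with risk scores by smoking stratum
#'
#' Spearman correlation between each geneset's metascore and the risk
#' score, computed separately for current smokers and long-term former
#' smokers (quit > 12 months, stratum FS1), with two-sided p-values and
#' significance stars (0.05 / 0.01 / 0.001).
#'
#' @param metascores Tibble from [metascore_table()].
#' @param risk_scores Named numeric vector of per-sample risk scores (names
#'   are sample ids) or a tibble with sample_id and score.
#' @param metadata Sample metadata.
#' @param strata Named list mapping stratum label to the smoking statuses it
#'   contains; default current smokers and > 12-month former smokers.
#' @return Tibble with geneset, stratum, n, rho, p_value, stars.
#' @export
correlate_with_risk <- function(metascores, risk_scores, metadata,
                                strata = list(CS = "CS", FS_gt12mo = "FS1")) {
  if (is.data.frame(risk_scores)) {
    risk_scores <- setNames(risk_scores$score, risk_scores$sample_id)
  }
  genesets <- setdiff(names(metascores), "sample_id")
  purrr::map_dfr(names(strata), function(st) {
    ids <- metadata$sample_id[metadata$smoking_status %in% strata[[st]]]
    ids <- intersect(intersect(ids, metascores$sample_id), names(risk_scores))
    if (length(ids) < 10) {
      rlang::warn(sprintf("stratum %s has %d samples (< 10); skipped",
                          st, length(ids)))
      return(tibble::tibble())
    }
    rs <- risk_scores[ids]
    purrr::map_dfr(genesets, function(gs) {
      ms <- metascores[[gs]][match(ids, metascores$sample_id)]
      if (stats::sd(ms) == 0) {
        return(tibble::tibble(geneset = gs, stratum = st, n = length(ids),
                              rho = NA_real_, p_value = NA_real_,
                              stars = NA_character_))
      }
      ct <- suppressWarnings(
        stats::cor.test(ms, rs, method = "spearman", exact = FALSE)
      )
      tibble::tibble(geneset = gs, stratum = st, n = length(ids),
                     rho = unname(ct$estimate), p_value = ct$p.value,
                     stars = p_stars(ct$p.value))
    })
  })
}
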