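#' Read a normalized gene-by-sample expression matrix from TSV
#'
#' The file must have gene identifiers in the first column, sample
#' identifiers in the header row, and a numeric body. Expression values are
#' assumed to be on a variance-stabilized-like scale (unitless); no count
#' normalization is performed here.
#'
#' @param path Path to a tab-separated matrix file.
#' @return A numeric matrix (genes x samples) with unique dimnames.
#' @export
read_expression <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  assert_that(ncol(tab) >= 2, "expression table needs gene ids plus >= 1 sample column")
  gene_ids <- tab[[1]]
  body <- as.data.frame(tab[, -1, drop = FALSE])
  vals <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(tab))))
  if (nrow(tab) == 1) vals <- matrix(vals, nrow = 1, dimnames = list(NULL, names(body)))
  bad <- which(is.na(vals) & !(as.matrix(body) %in% c("NA")), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    rlang::abort(sprintf(
      "non-numeric expression value at gene '%s', sample '%s'",
      gene_ids[bad[1, 1]], colnames(vals)[bad[1, 2]]
    ))
  }
  m <- matrix(vals, nrow = length(gene_ids),
              dimnames = list(gene_ids, colnames(vals)))
  validate_expression(m)
}

#' Write an expression matrix to TSV
#'
#' @param expr Numeric matrix, genes x samples, with dimnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  validate_expression(expr)
  tab <- tibble::as_tibble(expr, rownames = "gene_id")
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Validate an expression matrix
#'
#' Checks finiteness and uniqueness of gene and sample identifiers.
#'
#' @param expr Numeric matrix, genes x samples.
#' @return The validated matrix, invisibly usable in pipes.
#' @export
validate_expression <- function(expr) {
  assert_that(is.matrix(expr) && is.numeric(expr), "expression must be a numeric matrix")
  assert_that(!is.null(rownames(expr)) && !is.null(colnames(expr)),
              "expression matrix needs gene and sample ids as dimnames")
  assert_that(!anyDuplicated(rownames(expr)), "duplicated gene ids in expression matrix")
  assert_that(!anyDuplicated(colnames(expr)), "duplicated sample ids in expression matrix")
  assert_that(all(is.finite(expr)), "non-finite values in expression matrix")
  expr
}

#' Drop genes with near-constant expression
#'
#' Removes genes whose natural-log sample variance across samples falls at or
#' below `min_log_var`. The default of -4 reflects the usual low-information
#' filter applied to variance-stabilized expression before model fitting.
#'
#' @param expr Expression matrix (genes x samples).
#' @param min_log_var Retain genes with `log(var) > min_log_var`.
#' @return The filtered matrix.
#' @export
filter_low_variance <- function(expr, min_log_var = -4) {
  validate_expression(expr)
  v <- apply(expr, 1, stats::var)
  keep <- log(v) > min_log_var
  keep[is.na(keep)] <- FALSE
  expr[keep, , drop = FALSE]
}
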