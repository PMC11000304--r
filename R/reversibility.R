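# Per-gene Bayesian linear-model selection over the smoking-status encoding
# and assignment of post-cessation reversibility classes.
#
# Smoking status enters through three variables: CS (0/1, current smoker),
# FSS (0/1, former smoker of any recency) and FS (0/1/2/3, cessation
# recency: 0 never/current, 1 quit > 1 year, 2 quit 1-12 months, 3 quit
# < 1 month). All eight subsets of {CS, FSS, FS} are fitted (confounders
# always included) and converted to posterior model probabilities; groups
# of models correspond to reversibility classes.

# model space in fixed order; labels name the included smoking variables
MODEL_SPACE <- list(
  none        = character(0),
  cs          = "cs",
  fss         = "fss",
  fs          = "fs",
  cs_fss      = c("cs", "fss"),
  cs_fs       = c("cs", "fs"),
  fss_fs      = c("fss", "fs"),
  cs_fss_fs   = c("cs", "fss", "fs")
)

# model -> reversibility class map. RR: only a current-smoker shift (former
# smokers look like never smokers). SR: a recency gradient in former smokers.
# IR: former smokers keep the current-smoker shift, flat in recency.
# CA: former smokers differ but current smokers look like never smokers.
MODEL_CLASS <- c(
  none = "US", cs = "RR", fss = "CA", fs = "CA", cs_fss = "IR",
  cs_fs = "SR", fss_fs = "CA", cs_fss_fs = "SR"
)

#' Build the smoking-status design from sample metadata
#'
#' Encodes smoking status into the CS/FSS/FS variables and carries the
#' confounders (age class, sex as 0/1, batch) as numeric columns. Never
#' smokers are the reference level (all three variables 0); CS and FSS are
#' mutually exclusive by construction.
#'
#' @param metadata Sample metadata tibble (see [validate_metadata()]).
#' @return Tibble with sample_id, cs, fss, fs, age_class, sex, batch.
#' @export
build_design <- function(metadata) {
  bad <- setdiff(unique(metadata$smoking_status), SMOKING_LEVELS)
  assert_that(length(bad) == 0,
              paste("unknown smoking_status label(s):", paste(bad, collapse = ", ")))
  tibble::tibble(
    sample_id = metadata$sample_id,
    cs = as.numeric(metadata$smoking_status == "CS"),
    fss = as.numeric(metadata$smoking_status %in% c("FS1", "FS2", "FS3")),
    fs = dplyr::recode(metadata$smoking_status,
                       NV = 0, FS1 = 1, FS2 = 2, FS3 = 3, CS = 0),
    age_class = as.numeric(metadata$age_class),
    sex = as.numeric(metadata$sex == "M"),
    batch = as.numeric(metadata$batch)
  )
}

# Core fitting engine, vectorized over genes. Y is samples x genes.
# Returns posterior (8 x G), model-averaged coefficients, and per-model fits.
fit_model_space_engine <- function(Y, design,
                                   prior = c("bic", "gprior"), g = NULL) {
  prior <- match.arg(prior)
  Y <- as.matrix(Y)
  n <- nrow(Y)
  G <- ncol(Y)
  conf <- cbind(intercept = 1, age_class = design$age_class,
                sex = design$sex, batch = design$batch)
  # drop constant confounders (e.g. single-batch designs) to keep full rank
  keep <- c(TRUE, apply(conf[, -1, drop = FALSE], 2, function(x) sd(x) > 0))
  conf <- conf[, keep, drop = FALSE]
  smoke <- cbind(cs = design$cs, fss = design$fss, fs = design$fs)

  full <- cbind(conf, smoke)
  qr_full <- qr(full)
  if (qr_full$rank < ncol(full)) {
    dropped <- colnames(full)[qr_full$pivot[(qr_full$rank + 1):ncol(full)]]
    rlang::abort(paste("design is rank deficient; collinear column(s):",
                       paste(dropped, collapse = ", ")))
  }
  if (is.null(g)) g <- n

  nm <- length(MODEL_SPACE)
  logpost <- matrix(NA_real_, nm, G)
  beta_store <- array(0, dim = c(nm, 3, G),
                      dimnames = list(names(MODEL_SPACE), c("cs", "fss", "fs"), NULL))
  tss <- colSums(scale(Y, scale = FALSE)^2)
  for (m in seq_len(nm)) {
    vars <- MODEL_SPACE[[m]]
    X <- cbind(conf, smoke[, vars, drop = FALSE])
    fit <- lm.fit(X, Y)
    res <- as.matrix(fit$residuals)
    rss <- colSums(res^2)
    k <- ncol(X)
    if (prior == "bic") {
      bic <- n * log(pmax(rss, 1e-12) / n) + k * log(n)
      logpost[m, ] <- -bic / 2
    } else {
      # Zellner g-prior on all non-intercept coefficients, fixed g
      k1 <- k - 1
      r2 <- pmin(1 - rss / pmax(tss, 1e-12), 1 - 1e-12)
      logpost[m, ] <- ((n - 1 - k1) / 2) * log(1 + g) -
        ((n - 1) / 2) * log(1 + g * (1 - r2))
    }
    if (length(vars) > 0) {
      # coefficient rows for the smoking terms sit after the confounders
      cf <- as.matrix(fit$coefficients)[ncol(conf) + seq_along(vars), , drop = FALSE]
      if (prior == "gprior") cf <- cf * g / (1 + g)
      beta_store[m, vars, ] <- cf
    }
  }
  # normalize per gene under a uniform model prior
  mx <- apply(logpost, 2, max)
  post <- exp(sweep(logpost, 2, mx))
  post <- sweep(post, 2, colSums(post), "/")
  # constant response: no signal by definition -> all mass on the empty model
  flat <- apply(Y, 2, sd) < 1e-12
  if (any(flat)) {
    post[, flat] <- 0
    post[1, flat] <- 1
    beta_store[, , flat] <- 0
  }
  rownames(post) <- names(MODEL_SPACE)
  betas <- vapply(seq_len(G), function(j) post[, j] %*% beta_store[, , j],
                  numeric(3))
  rownames(betas) <- c("cs", "fss", "fs")
  list(posterior = post, betas = betas)
}

#' Fit the eight-model smoking space for one gene
#'
#' Ordinary least squares of expression on every subset of \{CS, FSS, FS\}
#' (confounders always included), converted to posterior model
#' probabilities via the BIC approximation under a uniform model prior.
#' Coefficients are Bayesian-model-averaged estimates (a coefficient is 0 in
#' models that exclude it). A Zellner g-prior (default g = n) is available
#' for sensitivity analysis.
#'
#' @param y Numeric vector of one gene's expression across samples.
#' @param design Design tibble from [build_design()] (rows aligned with `y`).
#' @param prior `"bic"` (default) or `"gprior"`.
#' @param g g-prior scale; defaults to the number of samples.
#' @return List with `posterior` (named, sums to 1 over the 8 models) and
#'   `betas` (named model-averaged cs/fss/fs coefficients).
#' @export
fit_model_space <- function(y, design, prior = c("bic", "gprior"), g = NULL) {
  fit <- fit_model_space_engine(matrix(y, ncol = 1), design, prior, g)
  list(posterior = fit$posterior[, 1], betas = fit$betas[, 1])
}

#' Assign a reversibility class from a model posterior
#'
#' Classes are groups of models; the gene is assigned to the class with the
#' highest aggregated posterior probability (ties prefer the class of the
#' smaller model, logged). The `strong` flag requires |beta_cs| above
#' `thresholds["cs"]` for RR/SR/IR genes and |beta_fss| above
#' `thresholds["fss"]` for CA genes.
#'
#' @param posterior Named posterior over the 8 models (sums to 1).
#' @param betas Named model-averaged coefficients (cs, fss, fs).
#' @param thresholds Named effect-size thresholds, default c(cs=0.4, fss=0.25).
#' @return One-row tibble: best_model, cls, strong, beta_cs, beta_fss,
#'   beta_fs and the five class posteriors.
#' @export
classify_gene <- function(posterior, betas, thresholds = c(cs = 0.4, fss = 0.25)) {
  assert_that(abs(sum(posterior) - 1) < 1e-9, "posterior must sum to 1")
  post_cls <- vapply(CLASS_LEVELS, function(cl) {
    sum(posterior[names(MODEL_CLASS)[MODEL_CLASS == cl]])
  }, numeric(1))
  # tie-break: classes ordered by the size of their smallest model
  cls_order <- c("US", "RR", "CA", "IR", "SR")
  ranked <- post_cls[cls_order]
  top <- which(ranked == max(ranked))
  if (length(top) > 1) {
    rlang::inform(sprintf("posterior tie between classes %s; keeping %s",
                          paste(cls_order[top], collapse = "/"),
                          cls_order[top[1]]))
  }
  cls <- cls_order[top[1]]
  model_sizes <- lengths(MODEL_SPACE)
  ord <- order(-posterior, model_sizes[names(posterior)])
  best_model <- names(posterior)[ord[1]]
  strong <- switch(cls,
    US = FALSE,
    CA = abs(betas[["fss"]]) > thresholds[["fss"]],
    abs(betas[["cs"]]) > thresholds[["cs"]]
  )
  tibble::tibble(
    best_model = best_model, cls = cls, strong = strong,
    beta_cs = betas[["cs"]], beta_fss = betas[["fss"]], beta_fs = betas[["fs"]],
    p_US = post_cls[["US"]], p_RR = post_cls[["RR"]], p_SR = post_cls[["SR"]],
    p_IR = post_cls[["IR"]], p_CA = post_cls[["CA"]]
  )
}

#' Classify every gene's post-cessation dynamics in one cohort
#'
#' Fits the eight-model space for each gene on the selected cohort's nasal
#' samples and assigns reversibility classes. For the clinic cohort, which
#' has no never smokers, healthy-volunteer never smokers are appended as the
#' reference group.
#'
#' @param expr Expression matrix (genes x samples), already normalized and
#'   variance-filtered (see [filter_low_variance()]).
#' @param metadata Sample metadata tibble.
#' @param cohort `"HV"` or `"CLINIC"`.
#' @param tissue Tissue to analyse (default nasal).
#' @param thresholds Strong-effect thresholds, see [classify_gene()].
#' @param prior,g Posterior computation options, see [fit_model_space()].
#' @return A `reversibility_calls` tibble, one row per gene, with class
#'   posteriors, model-averaged coefficients, assigned class and strong flag.
#' @export
classify_all <- function(expr, metadata, cohort = c("HV", "CLINIC"),
                         tissue = "nasal",
                         thresholds = c(cs = 0.4, fss = 0.25),
                         prior = c("bic", "gprior"), g = NULL) {
  cohort <- match.arg(cohort)
  validate_expression(expr)
  keep <- metadata$tissue == tissue & metadata$cohort == cohort
  if (cohort == "CLINIC") {
    # healthy-volunteer never smokers serve as the reference group
    keep <- keep | (metadata$tissue == tissue & metadata$cohort == "HV" &
                      metadata$smoking_status == "NV")
  }
  meta <- metadata[keep, , drop = FALSE]
  assert_that(nrow(meta) > 0, sprintf("no %s samples in cohort %s", tissue, cohort))
  meta <- meta[meta$sample_id %in% colnames(expr), , drop = FALSE]
  assert_that(nrow(meta) > 0, "no selected samples present in the expression matrix")
  design <- build_design(meta)
  Y <- t(expr[, meta$sample_id, drop = FALSE])
  fit <- fit_model_space_engine(Y, design, prior = prior, g = g)
  calls <- purrr::map_dfr(seq_len(ncol(Y)), function(j) {
    classify_gene(fit$posterior[, j], fit$betas[, j], thresholds)
  })
  calls <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(expr)), calls)
  class(calls) <- c("reversibility_calls", class(calls))
  attr(calls, "cohort") <- cohort
  attr(calls, "n_samples") <- nrow(meta)
  calls
}

#' Compare reversibility classes between two cohorts
#'
#' Builds the 5x5 class-transition table over the genes shared by both call
#' sets, derives the response-gene set (strong in at least one cohort and
#' not unaffected in both) and tests the overlap of the two strong sets
#' against independence with a Pearson chi-squared test.
#'
#' @param calls_a,calls_b `reversibility_calls` tibbles from
#'   [classify_all()] (e.g. healthy volunteers and clinic patients).
#' @param strong_in `"any"` (default: response genes must be strong in at
#'   least one cohort) or `"both"`.
#' @return List of class `cohort_comparison`: `counts` (5x5 matrix, rows =
#'   cohort A class), `response_genes`, `strong_overlap_test` (htest) and
#'   `n_shared`.
#' @export
compare_cohorts <- function(calls_a, calls_b, strong_in = c("any", "both")) {
  strong_in <- match.arg(strong_in)
  shared <- intersect(calls_a$gene_id, calls_b$gene_id)
  assert_that(length(shared) > 0, "call tables have disjoint gene universes")
  a <- calls_a[match(shared, calls_a$gene_id), ]
  b <- calls_b[match(shared, calls_b$gene_id), ]
  counts <- table(
    factor(a$cls, levels = CLASS_LEVELS),
    factor(b$cls, levels = CLASS_LEVELS)
  )
  counts <- unclass(counts)
  names(dimnames(counts)) <- c("cohort_a", "cohort_b")
  strong_hit <- if (strong_in == "any") a$strong | b$strong else a$strong & b$strong
  not_us_both <- !(a$cls == "US" & b$cls == "US")
  response_genes <- shared[strong_hit & not_us_both]
  overlap <- table(factor(a$strong, levels = c(FALSE, TRUE)),
                   factor(b$strong, levels = c(FALSE, TRUE)))
  test <- suppressWarnings(stats::chisq.test(overlap, correct = FALSE))
  structure(list(
    counts = counts, response_genes = response_genes,
    strong_overlap_test = test, n_shared = length(shared)
  ), class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("<cohort_comparison> %d shared genes, %d response genes\n",
              x$n_shared, length(x$response_genes)))
  print(x$counts)
  cat(sprintf("strong-set overlap: chi-squared = %.2f, p = %.3g\n",
              unname(x$strong_overlap_test$statistic),
              x$strong_overlap_test$p.value))
  invisible(x)
}
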