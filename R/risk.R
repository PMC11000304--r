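# L1-penalised logistic risk scores from response-gene expression plus
# encoded clinical covariates, with cross-validated performance, operating
# points, random-gene baselines and stability selection.

#' Encode clinical covariates as numeric features
#'
#' Sex F/M -> 0/1; age class stays ordinal 0-3; smoking status maps
#' NV/FS1/FS2/FS3/CS -> 0/1/2/3/4 (increasing exposure recency); pack-years
#' PY1-PY4 -> 0-3.
#'
#' @param metadata Sample metadata tibble.
#' @return Tibble with sample_id, sex, age_class, smoking_numeric,
#'   pack_years_numeric.
#' @export
encode_clinical <- function(metadata) {
  tibble::tibble(
    sample_id = metadata$sample_id,
    sex = as.numeric(metadata$sex == "M"),
    age_class = as.numeric(metadata$age_class),
    smoking_numeric = dplyr::recode(metadata$smoking_status,
                                    NV = 0, FS1 = 1, FS2 = 2, FS3 = 3, CS = 4),
    pack_years_numeric = dplyr::recode(metadata$pack_years,
                                       PY1 = 0, PY2 = 1, PY3 = 2, PY4 = 3)
  )
}

#' Binary labels for the population and clinic risk targets
#'
#' Population target: clinic patient = 1, healthy volunteer = 0. Clinic
#' target: cancer = 1, no cancer (clinic benign and healthy volunteers) = 0.
#' Ineligible diagnoses are excluded from both targets; only nasal samples
#' are labelled.
#'
#' @param metadata Sample metadata tibble.
#' @param target `"population"` or `"clinic"`.
#' @return Tibble with sample_id and integer label.
#' @export
make_labels <- function(metadata, target = c("population", "clinic")) {
  target <- match.arg(target)
  meta <- metadata[metadata$tissue == "nasal" &
                     metadata$diagnosis != "INELIGIBLE", , drop = FALSE]
  label <- if (target == "population") {
    as.integer(meta$cohort == "CLINIC")
  } else {
    as.integer(meta$diagnosis == "CANCER")
  }
  assert_that(any(label == 1) && any(label == 0),
              sprintf("target '%s' needs both positive and negative samples", target))
  tibble::tibble(sample_id = meta$sample_id, label = label)
}

#' Assemble the feature matrix for a risk model
#'
#' @param expr Expression matrix (genes x samples).
#' @param metadata Sample metadata.
#' @param genes Feature gene ids (e.g. the response genes); NULL for none.
#' @param clinical Include the four encoded clinical covariates?
#' @param samples Sample ids to keep (default: all nasal samples).
#' @return Numeric samples x features matrix.
#' @export
risk_features <- function(expr, metadata, genes = NULL, clinical = TRUE,
                          samples = NULL) {
  if (is.null(samples)) {
    samples <- metadata$sample_id[metadata$tissue == "nasal"]
  }
  samples <- intersect(samples, colnames(expr))
  parts <- list()
  if (!is.null(genes) && length(genes) > 0) {
    missing <- setdiff(genes, rownames(expr))
    assert_that(length(missing) == 0,
                paste("feature genes absent from matrix:",
                      paste(utils::head(missing, 5), collapse = ", ")))
    parts$genes <- t(expr[genes, samples, drop = FALSE])
  }
  if (clinical) {
    enc <- encode_clinical(metadata)
    enc <- enc[match(samples, enc$sample_id), ]
    parts$clinical <- as.matrix(enc[, c("sex", "age_class", "smoking_numeric",
                                        "pack_years_numeric")])
    rownames(parts$clinical) <- samples
  }
  X <- do.call(cbind, parts)
  assert_that(all(is.finite(X)), "non-finite feature values")
  X
}

#' Train an L1-penalised logistic risk model
#'
#' Fits the lasso path with `glmnet` and picks the penalty that minimises
#' the mean cross-validated binomial deviance (`lambda.min`). Features are
#' standardised internally on the training data, so gene-expression and
#' clinical covariates are penalised comparably; coefficients are reported
#' on the original scale. The risk score of a sample is the linear
#' predictor (log-odds).
#'
#' @param X Samples x features numeric matrix.
#' @param y Binary labels (0/1) aligned with the rows of `X`.
#' @param nfolds Folds for the internal lambda-selection CV.
#' @param seed Seed for the internal fold assignment.
#' @param target Optional tag ("population"/"clinic") carried in the model.
#' @return A `risk_model` object (features, coefficients, intercept, lambda).
#' @export
train_classifier <- function(X, y, nfolds = 10, seed = 1, target = NULL) {
  assert_that(all(is.finite(X)), "non-finite feature values")
  assert_that(length(y) == nrow(X), "labels must align with feature rows")
  cvfit <- with_seed(seed,
    glmnet::cv.glmnet(X, y, family = "binomial", alpha = 1,
                      nfolds = nfolds, standardize = TRUE)
  )
  cf <- as.numeric(coef(cvfit, s = "lambda.min"))
  structure(list(
    features = colnames(X),
    coefficients = setNames(cf[-1], colnames(X)),
    intercept = cf[1],
    lambda = cvfit$lambda.min,
    target = target %||% NA_character_
  ), class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> target=%s, lambda=%.4g, %d/%d features selected\n",
              x$target, x$lambda, sum(x$coefficients != 0), length(x$features)))
  invisible(x)
}

#' Score samples with a risk model
#'
#' @param object A `risk_model`.
#' @param newdata Samples x features matrix containing the model's features.
#' @param ... Unused.
#' @return Named numeric vector of log-odds scores.
#' @export
predict.risk_model <- function(object, newdata, ...) {
  X <- newdata[, object$features, drop = FALSE]
  drop(X %*% object$coefficients) + object$intercept
}

# Stratified fold assignment: samples shuffled within each class, folds
# dealt round-robin so class balance is preserved in every fold.
make_folds <- function(y, folds, seed) {
  assert_that(min(table(y)) >= folds,
              "each class needs at least `folds` members for stratification")
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold
  })
}

#' Repeated stratified cross-validation of a risk model
#'
#' Runs `rounds` rounds of `folds`-fold stratified cross-validation. In
#' each fold the model (including its penalty) is trained on the training
#' split only and the held-out samples are scored, so every sample is
#' scored out-of-fold exactly once per round. Per round, the model is also
#' refit on the full data at that round's cross-validated lambda; these
#' per-round models feed [stability_selection()].
#'
#' @param X Samples x features matrix.
#' @param y Binary labels (0/1).
#' @param rounds,folds Cross-validation geometry (default 10 x 10-fold).
#' @param seed Global seed; rounds derive deterministic child seeds.
#' @param inner_nfolds Folds for the lambda-selection CV inside each
#'   training split.
#' @return A `cv_report`: `scores` (round, fold, sample, label, score),
#'   `summary` (per-round AUC-ROC / AUC-PR), `models` (per-round refits).
#' @export
cross_validate <- function(X, y, rounds = 10, folds = 10, seed = 1,
                           inner_nfolds = 10) {
  assert_that(nrow(X) >= folds, "need at least `folds` samples")
  sample_ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
  all_scores <- vector("list", rounds)
  models <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    rseed <- child_seed(seed, 100L + r)
    fold <- make_folds(y, folds, rseed)
    sc <- rep(NA_real_, length(y))
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2) {
        # degenerate single-class training split: refold with a new seed
        rlang::warn("single-class training split; refolding")
        fold <- make_folds(y, folds, rseed + 1L)
        tr <- fold != f
      }
      fit <- train_classifier(X[tr, , drop = FALSE], y[tr],
                              nfolds = inner_nfolds,
                              seed = child_seed(rseed, f))
      sc[!tr] <- predict(fit, X[!tr, , drop = FALSE])
    }
    all_scores[[r]] <- tibble::tibble(
      round = r, fold = fold, sample_id = sample_ids, label = y, score = sc
    )
    models[[r]] <- train_classifier(X, y, nfolds = inner_nfolds,
                                    seed = child_seed(rseed, 999L))
  }
  scores <- dplyr::bind_rows(all_scores)
  summary <- scores %>%
    dplyr::group_by(.data$round) %>%
    dplyr::summarise(
      auc_roc = auc_roc(.data$score, .data$label),
      auc_pr = auc_pr(.data$score, .data$label),
      .groups = "drop"
    )
  structure(list(scores = scores, summary = summary, models = models,
                 rounds = rounds, folds = folds, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report> %d rounds x %d-fold CV\n  AUC-ROC %.3f (sd %.3f), AUC-PR %.3f (sd %.3f)\n",
    x$rounds, x$folds,
    mean(x$summary$auc_roc), sd(x$summary$auc_roc),
    mean(x$summary$auc_pr), sd(x$summary$auc_pr)))
  invisible(x)
}

#' ROC curve points over all score thresholds
#'
#' Thresholds are the unique scores (descending), with the convention
#' score >= threshold => positive call.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1).
#' @return Tibble with threshold, tpr (sensitivity), fpr.
#' @export
roc_points <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  thr <- sort(unique(scores), decreasing = TRUE)
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / nn, numeric(1))
  tibble::tibble(threshold = thr, tpr = tpr, fpr = fpr)
}

#' Area under the ROC curve (trapezoid rule)
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1).
#' @return AUC-ROC between 0 and 1.
#' @export
auc_roc <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  fpr <- c(0, pts$fpr, 1)
  tpr <- c(0, pts$tpr, 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Area under the precision-recall curve (average precision)
#'
#' Computed as the sum over threshold steps of precision times the recall
#' increment (average-precision form, robust to ties).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1).
#' @return AUC-PR between 0 and 1.
#' @export
auc_pr <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  np <- sum(labels == 1)
  tp <- vapply(thr, function(t) sum(scores >= t & labels == 1), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & labels == 0), numeric(1))
  recall <- tp / np
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Operating point at a target sensitivity
#'
#' Returns the largest score threshold whose sensitivity (score >= threshold
#' => positive) reaches the target, i.e. the minimum false-positive rate at
#' that sensitivity, and the resulting FPR.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1).
#' @param sensitivity Target sensitivity in (0, 1].
#' @return Tibble with threshold, sensitivity achieved, fpr.
#' @export
operating_point <- function(scores, labels, sensitivity = 0.95) {
  assert_that(sensitivity > 0 && sensitivity <= 1,
              "sensitivity must be in (0, 1]")
  assert_that(sum(labels == 1) > 0, "no positive samples")
  pts <- roc_points(scores, labels)
  ok <- pts$tpr >= sensitivity
  assert_that(any(ok), "target sensitivity unattainable")
  best <- which(ok)[which.max(pts$threshold[ok])]
  tibble::tibble(threshold = pts$threshold[best],
                 sensitivity = pts$tpr[best],
                 fpr = pts$fpr[best])
}

#' Random-gene baseline for a risk model
#'
#' Draws `n_sets` random gene sets of the same size as the response-gene
#' feature set and cross-validates each on identical folds (same seed), so
#' baseline AUCs are directly comparable to the response-gene model's.
#'
#' @param expr Expression matrix (genes x samples).
#' @param metadata Sample metadata.
#' @param target `"population"` or `"clinic"`.
#' @param set_size Genes per random set.
#' @param n_sets Number of random sets (default 20).
#' @param rounds,folds,seed,inner_nfolds Passed to [cross_validate()].
#' @param clinical Include clinical covariates alongside the random genes.
#' @return Tibble with set index, mean AUC-ROC and mean AUC-PR.
#' @export
random_gene_baseline <- function(expr, metadata, target = "population",
                                 set_size, n_sets = 20, rounds = 1, folds = 10,
                                 seed = 1, inner_nfolds = 10, clinical = TRUE) {
  universe <- rownames(expr)
  assert_that(set_size <= length(universe), "set_size exceeds the gene universe")
  labels <- make_labels(metadata, target)
  sets <- with_seed(child_seed(seed, 55L), {
    purrr::map(seq_len(n_sets), function(i) sample(universe, set_size))
  })
  purrr::map_dfr(seq_len(n_sets), function(i) {
    X <- risk_features(expr, metadata, genes = sets[[i]], clinical = clinical,
                       samples = labels$sample_id)
    y <- labels$label[match(rownames(X), labels$sample_id)]
    cv <- cross_validate(X, y, rounds = rounds, folds = folds, seed = seed,
                         inner_nfolds = inner_nfolds)
    tibble::tibble(set = i, auc_roc = mean(cv$summary$auc_roc),
                   auc_pr = mean(cv$summary$auc_pr))
  })
}

#' Genes selected consistently across cross-validation rounds
#'
#' A feature counts as selected in a round when its coefficient is nonzero
#' in that round's full-data refit at the round's cross-validated lambda.
#' Features selected in strictly more than `threshold` of rounds are
#' returned.
#'
#' @param cv A `cv_report` from [cross_validate()].
#' @param threshold Selection-frequency cutoff (default 0.8, strict).
#' @return Tibble with feature, n_selected, frequency, selected flag.
#' @export
stability_selection <- function(cv, threshold = 0.8) {
  stopifnot(inherits(cv, "cv_report"))
  sel <- vapply(cv$models, function(m) m$coefficients != 0,
                logical(length(cv$models[[1]]$coefficients)))
  if (is.null(dim(sel))) sel <- matrix(sel, nrow = 1)
  freq <- unname(rowMeans(sel))
  tibble::tibble(
    feature = cv$models[[1]]$features,
    n_selected = unname(rowSums(sel)),
    frequency = freq,
    selected = freq > threshold
  )
}
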