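# Genotype QC (MAF filter, VIF-based LD pruning), covariate-adjusted
# cis-eQTL scan with two-step multiple-testing correction, genotype x
# smoking interaction tests, and GWAS-locus linkage.

#' LD-pruning configuration
#'
#' The VIF cutoff relates to multiple correlation as VIF = 1 / (1 - R^2),
#' so the default `vif_max = 20` removes SNPs with R^2 > 0.95 on the rest
#' of their window.
#'
#' @param maf_min Minimum minor allele frequency (strictly greater than).
#' @param window Sliding window size in SNPs.
#' @param step Window step in SNPs (plink-style window/step convention).
#' @param vif_max Maximum tolerated variance inflation factor.
#' @return A validated `prune_config` list.
#' @export
prune_config <- function(maf_min = 0.01, window = 50, step = 5, vif_max = 20) {
  assert_that(vif_max > 1, "vif_max must exceed 1")
  assert_that(window >= 2, "window must be at least 2 SNPs")
  assert_that(step >= 1, "step must be at least 1")
  structure(list(maf_min = maf_min, window = window, step = step,
                 vif_max = vif_max), class = "prune_config")
}

#' Filter SNPs by minor allele frequency
#'
#' Retains SNPs with MAF strictly greater than `maf_min`, preserving order.
#'
#' @param geno A [genotype_table()].
#' @param maf_min MAF cutoff (default 0.01, i.e. > 1%).
#' @return The filtered genotype table.
#' @export
maf_filter <- function(geno, maf_min = 0.01) {
  stopifnot(inherits(geno, "genotype_table"))
  keep <- geno$snps$maf > maf_min
  genotype_table(geno$snps[keep, , drop = FALSE],
                 geno$dosage[keep, , drop = FALSE])
}

# Multiple correlation R^2 of column j of Z on the remaining columns
# (intercept included). Normal-equations fast path on the centred
# cross-product matrix; falls back to a rank-tolerant qr fit when the
# submatrix is singular (perfectly collinear SNPs get R^2 = 1).
window_r2 <- function(Z) {
  p <- ncol(Z)
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  S <- crossprod(Zc)
  qr_r2 <- function(j) {
    y <- Z[, j]
    X <- cbind(1, Z[, -j, drop = FALSE])
    sum(qr.resid(qr(X), y)^2)
  }
  vapply(seq_len(p), function(j) {
    tss <- S[j, j]
    if (tss == 0) return(1)  # constant SNP: degenerate, treat as removable
    rss <- tryCatch({
      b <- solve(S[-j, -j, drop = FALSE], S[-j, j])
      max(tss - sum(S[-j, j] * b), 0)
    }, error = function(e) qr_r2(j))
    max(0, min(1, 1 - rss / tss))
  }, numeric(1))
}

#' Prune SNPs in linkage disequilibrium by variance inflation factor
#'
#' Slides windows of `window` SNPs (stepping by `step`) along each
#' chromosome in position order. Within a window, the SNP with the largest
#' VIF (1 / (1 - R^2) of its dosage on the other SNPs in the window) is
#' removed and VIFs recomputed until all remaining VIFs are at most
#' `vif_max`. Ties are broken by lower MAF, then later position. A SNP
#' removed in any window stays removed; constant SNPs are removed as
#' degenerate. The result is idempotent: pruning a pruned panel removes
#' nothing.
#'
#' @param geno A [genotype_table()] with SNPs position-sorted per chromosome.
#' @param config A [prune_config()].
#' @return The pruned genotype table.
#' @export
vif_prune <- function(geno, config = prune_config()) {
  stopifnot(inherits(geno, "genotype_table"), inherits(config, "prune_config"))
  snps <- geno$snps
  removed <- rep(FALSE, nrow(snps))
  for (ch in unique(snps$chrom)) {
    on_ch <- which(snps$chrom == ch)
    on_ch <- on_ch[order(snps$pos[on_ch])]
    starts <- seq(1, length(on_ch), by = config$step)
    for (s in starts) {
      win <- on_ch[s:min(s + config$window - 1, length(on_ch))]
      repeat {
        alive <- win[!removed[win]]
        if (length(alive) < 2) break
        Z <- t(geno$dosage[alive, , drop = FALSE]) * 1.0
        r2 <- window_r2(Z)
        vif <- 1 / pmax(1 - r2, .Machine$double.eps)
        if (max(vif) <= config$vif_max) break
        worst <- which(vif == max(vif))
        if (length(worst) > 1) {  # lower MAF first, then later position
          key <- order(snps$maf[alive[worst]], -snps$pos[alive[worst]])
          worst <- worst[key[1]]
        }
        removed[alive[worst]] <- TRUE
      }
      # lone constant SNP in a window is degenerate too
      alive <- win[!removed[win]]
      mono <- alive[apply(geno$dosage[alive, , drop = FALSE], 1, sd) == 0]
      if (length(mono) > 0) {
        rlang::warn(sprintf("removing %d constant SNP(s) as degenerate",
                            length(mono)))
        removed[mono] <- TRUE
      }
    }
  }
  genotype_table(snps[!removed, , drop = FALSE],
                 geno$dosage[!removed, , drop = FALSE])
}

#' Enumerate cis gene-SNP pairs
#'
#' A SNP is in cis with a gene when it lies on the same chromosome within
#' `window_bp` of the gene's outermost coordinates (closed interval on both
#' ends): pos between gene_start - window_bp and gene_end - 1 + window_bp in the
#' 0-based convention. This realises a 500-kb window upstream of the TSS
#' and downstream of the TTS symmetrically, independent of strand.
#'
#' @param genes Gene annotation tibble (see [read_gene_annotation()]).
#' @param geno A [genotype_table()] (or its `snps` tibble).
#' @param window_bp Window size in bp (default 500,000).
#' @return Tibble with gene_id, snp_id.
#' @export
cis_pairs <- function(genes, geno, window_bp = 500000) {
  snps <- if (inherits(geno, "genotype_table")) geno$snps else geno
  out <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    if (is.na(genes$chrom[i])) {
      rlang::warn(sprintf("gene %s has unknown chromosome; skipped",
                          genes$gene_id[i]))
      return(tibble::tibble())
    }
    lo <- genes$start[i] - window_bp
    hi <- genes$end[i] - 1L + window_bp
    hit <- snps$chrom == genes$chrom[i] & snps$pos >= lo & snps$pos <= hi
    if (!any(hit)) return(tibble::tibble())
    tibble::tibble(gene_id = genes$gene_id[i], snp_id = snps$snp_id[hit])
  })
  out
}

# Numeric covariate matrix for the eQTL scan: sex (0/1), age (0-3),
# batch (0/1), smoking status (0-4), pack-years (0-3).
eqtl_covariates <- function(metadata) {
  enc <- encode_clinical(metadata)
  cbind(sex = enc$sex, age = enc$age_class, batch = as.numeric(metadata$batch),
        smoking = enc$smoking_numeric, pack_years = enc$pack_years_numeric)
}

#' Covariate-adjusted cis-eQTL scan with two-step correction
#'
#' Per (gene, SNP) pair, ordinary least squares of expression on alt-allele
#' dosage plus fixed covariates; the dosage coefficient's two-sided t
#' p-value is computed via the residualised-correlation identity (expression
#' and dosage are each residualised on the covariates once, then the
#' per-pair statistic is the correlation of residuals). Correction is
#' two-step: per gene, Bonferroni over the variants tested for that gene;
#' then Benjamini-Hochberg across the per-gene lead variants (smallest
#' adjusted p; ties broken by raw p, then genomic position). e-genes are
#' leads with global q-value at or below `fdr`.
#'
#' @param expr Expression matrix (genes x samples).
#' @param geno A [genotype_table()].
#' @param metadata Sample metadata (covariates are derived from it).
#' @param pairs Tibble of gene_id/snp_id pairs from [cis_pairs()].
#' @param fdr e-gene FDR level on the global lead q-values (default 0.10).
#' @return Tibble of class `eqtl_records`: gene_id, snp_id, beta, t_stat,
#'   p_raw, p_gene_bonferroni, is_lead, q_global (leads only), is_egene.
#' @export
eqtl_scan <- function(expr, geno, metadata, pairs, fdr = 0.10) {
  stopifnot(inherits(geno, "genotype_table"))
  samples <- intersect(colnames(expr), colnames(geno$dosage))
  samples <- intersect(samples, metadata$sample_id)
  assert_that(length(samples) > 3, "too few shared samples")
  meta <- metadata[match(samples, metadata$sample_id), ]
  C <- cbind(1, eqtl_covariates(meta))
  n <- length(samples)
  df <- n - ncol(C) - 1
  assert_that(df > 0, "fewer samples than model parameters")

  genes_used <- intersect(unique(pairs$gene_id), rownames(expr))
  snps_used <- intersect(unique(pairs$snp_id), geno$snps$snp_id)
  pairs <- pairs[pairs$gene_id %in% genes_used & pairs$snp_id %in% snps_used, ]
  assert_that(nrow(pairs) > 0, "no testable gene-SNP pairs")

  Yr <- resid_on(t(expr[genes_used, samples, drop = FALSE]), C)
  Gr <- resid_on(t(geno$dosage[snps_used, samples, drop = FALSE]) * 1.0, C)
  ss_y <- colSums(Yr^2)
  ss_g <- colSums(Gr^2)
  gi <- match(pairs$gene_id, genes_used)
  si <- match(pairs$snp_id, snps_used)
  # chunked so large pair lists never materialise an n x pairs matrix
  num <- numeric(nrow(pairs))
  chunk <- 200000L
  for (start in seq(1, nrow(pairs), by = chunk)) {
    idx <- start:min(start + chunk - 1, nrow(pairs))
    num[idx] <- colSums(Yr[, gi[idx], drop = FALSE] *
                          Gr[, si[idx], drop = FALSE])
  }
  denom <- sqrt(ss_y[gi] * ss_g[si])
  ok <- ss_g[si] > 0 & ss_y[gi] > 0
  if (any(!ok)) {
    rlang::warn(sprintf("%d pair(s) with constant dosage or expression skipped",
                        sum(!ok)))
  }
  r <- ifelse(ok, num / denom, NA_real_)
  r <- pmin(pmax(r, -1), 1)
  t_stat <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p_raw <- 2 * pt(-abs(t_stat), df)
  beta <- ifelse(ok, num / ss_g[si], NA_real_)

  rec <- tibble::tibble(
    gene_id = pairs$gene_id, snp_id = pairs$snp_id,
    pos = geno$snps$pos[match(pairs$snp_id, geno$snps$snp_id)],
    beta = as.numeric(beta), t_stat = as.numeric(t_stat),
    p_raw = as.numeric(p_raw)
  )
  rec <- rec[ok, , drop = FALSE]
  rec <- rec %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::mutate(p_gene_bonferroni = pmin(1, .data$p_raw * dplyr::n())) %>%
    dplyr::mutate(is_lead = seq_along(.data$p_raw) ==
                    order(.data$p_gene_bonferroni, .data$p_raw, .data$pos)[1]) %>%
    dplyr::ungroup()
  rec$q_global <- NA_real_
  leads <- which(rec$is_lead)
  rec$q_global[leads] <- p.adjust(rec$p_gene_bonferroni[leads], method = "BH")
  rec$is_egene <- rec$is_lead & !is.na(rec$q_global) & rec$q_global <= fdr
  class(rec) <- c("eqtl_records", class(rec))
  rec
}

#' Genotype-by-smoking interaction test at lead eQTL variants
#'
#' For each gene with a lead eQTL variant, fits expression on dosage,
#' smoking (0/1/2 never/former/current), their interaction, and covariates
#' (age, sex, pack-years, optionally batch), and reports the two-sided t
#' p-value on the interaction coefficient. Per-gene Bonferroni (one variant
#' per gene) then Benjamini-Hochberg across genes.
#'
#' @param expr Expression matrix (genes x samples).
#' @param geno A [genotype_table()].
#' @param metadata Sample metadata.
#' @param lead_records `eqtl_records` rows (leads are extracted), or a
#'   tibble with gene_id/snp_id.
#' @param gene_subset Restrict to these genes (e.g. response genes with a
#'   lead variant); default all leads.
#' @param include_batch Include experimental batch as a covariate.
#' @return Tibble of class `gxe_records`: gene_id, snp_id,
#'   beta_interaction, p_raw, p_adjusted.
#' @export
gxe_test <- function(expr, geno, metadata, lead_records, gene_subset = NULL,
                     include_batch = TRUE) {
  stopifnot(inherits(geno, "genotype_table"))
  leads <- lead_records
  if ("is_lead" %in% names(leads)) leads <- leads[leads$is_lead, ]
  if (!is.null(gene_subset)) leads <- leads[leads$gene_id %in% gene_subset, ]
  assert_that(nrow(leads) > 0, "no lead variants to test")
  samples <- intersect(colnames(expr), colnames(geno$dosage))
  samples <- intersect(samples, metadata$sample_id)
  meta <- metadata[match(samples, metadata$sample_id), ]
  enc <- encode_clinical(meta)
  smk012 <- dplyr::case_when(
    meta$smoking_status == "NV" ~ 0,
    meta$smoking_status == "CS" ~ 2,
    TRUE ~ 1
  )
  out <- purrr::map_dfr(seq_len(nrow(leads)), function(i) {
    g <- leads$gene_id[i]
    s <- leads$snp_id[i]
    if (!(g %in% rownames(expr)) || !(s %in% geno$snps$snp_id)) {
      return(tibble::tibble())
    }
    dos <- as.numeric(geno$dosage[s, samples])
    y <- as.numeric(expr[g, samples])
    X <- cbind(1, dosage = dos, smoking = smk012, inter = dos * smk012,
               age = enc$age_class, sex = enc$sex,
               pack_years = enc$pack_years_numeric)
    if (include_batch) X <- cbind(X, batch = as.numeric(meta$batch))
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      rlang::warn(sprintf("gene %s: interaction design collinear; skipped", g))
      return(tibble::tibble())
    }
    fit <- lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    dof <- length(y) - ncol(X)
    sigma2 <- rss / dof
    XtX_inv <- solve(crossprod(X))
    se <- sqrt(sigma2 * XtX_inv["inter", "inter"])
    tval <- fit$coefficients[["inter"]] / se
    tibble::tibble(gene_id = g, snp_id = s,
                   beta_interaction = fit$coefficients[["inter"]],
                   p_raw = 2 * pt(-abs(tval), dof))
  })
  assert_that(nrow(out) > 0, "all interaction tests were degenerate")
  # one variant per gene: per-gene Bonferroni is the identity, then BH
  out$p_adjusted <- p.adjust(pmin(1, out$p_raw), method = "BH")
  class(out) <- c("gxe_records", class(out))
  out
}

#' Link lead eQTL variants to GWAS risk loci by distance and LD
#'
#' A lead eQTL variant is linked to a GWAS locus when they lie on the same
#' chromosome within `window_bp`, a genotyped SNP exists at the locus
#' position, and the in-sample squared Pearson correlation of dosages
#' exceeds `r2_min`. Loci with no genotyped SNP in range are counted as
#' unlinked.
#'
#' @param lead_records `eqtl_records` (leads are used; typically
#'   significant ones — filter beforehand if desired).
#' @param gwas GWAS locus tibble (see [read_gwas_loci()]).
#' @param geno A [genotype_table()].
#' @param r2_min LD cutoff (links require r2 strictly greater, default 0.8).
#' @param window_bp Distance bound (default 500,000).
#' @return List of class `gwas_links`: `links` tibble (locus_id, snp_id,
#'   gene_id, r2_with_locus, distance_bp) and `summary` (unique loci and
#'   genes linked, loci without a genotyped SNP).
#' @export
map_gwas <- function(lead_records, gwas, geno, r2_min = 0.8,
                     window_bp = 500000) {
  stopifnot(inherits(geno, "genotype_table"))
  leads <- lead_records
  if ("is_lead" %in% names(leads)) leads <- leads[leads$is_lead, ]
  snp_idx <- match(leads$snp_id, geno$snps$snp_id)
  leads <- leads[!is.na(snp_idx), ]
  snp_idx <- snp_idx[!is.na(snp_idx)]
  lead_chrom <- geno$snps$chrom[snp_idx]
  lead_pos <- geno$snps$pos[snp_idx]
  no_snp <- 0L
  links <- purrr::map_dfr(seq_len(nrow(gwas)), function(k) {
    li <- which(geno$snps$chrom == gwas$chrom[k] & geno$snps$pos == gwas$pos[k])
    if (length(li) == 0) {
      no_snp <<- no_snp + 1L
      return(tibble::tibble())
    }
    locus_dos <- as.numeric(geno$dosage[li[1], ])
    near <- which(lead_chrom == gwas$chrom[k] &
                    abs(lead_pos - gwas$pos[k]) <= window_bp)
    if (length(near) == 0) return(tibble::tibble())
    purrr::map_dfr(near, function(j) {
      dos <- as.numeric(geno$dosage[snp_idx[j], ])
      if (sd(dos) == 0 || sd(locus_dos) == 0) return(tibble::tibble())
      r2 <- cor(dos, locus_dos)^2
      if (r2 <= r2_min) return(tibble::tibble())
      tibble::tibble(locus_id = gwas$locus_id[k], snp_id = leads$snp_id[j],
                     gene_id = leads$gene_id[j], r2_with_locus = r2,
                     distance_bp = abs(lead_pos[j] - gwas$pos[k]))
    })
  })
  if (nrow(links) == 0) {
    links <- tibble::tibble(locus_id = character(), snp_id = character(),
                            gene_id = character(), r2_with_locus = numeric(),
                            distance_bp = integer())
  }
  summary <- tibble::tibble(
    n_loci_linked = dplyr::n_distinct(links$locus_id),
    n_genes_linked = dplyr::n_distinct(links$gene_id),
    n_loci_no_snp = no_snp,
    n_loci_total = nrow(gwas)
  )
  structure(list(links = links, summary = summary), class = "gwas_links")
}

#' @export
print.gwas_links <- function(x, ...) {
  cat(sprintf("<gwas_links> %d links: %d loci -> %d genes (%d/%d loci had no genotyped SNP)\n",
              nrow(x$links), x$summary$n_loci_linked, x$summary$n_genes_linked,
              x$summary$n_loci_no_snp, x$summary$n_loci_total))
  invisible(x)
}
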