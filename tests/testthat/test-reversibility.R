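test_that("smoking design encodes every stratum per the CS/FSS/FS scheme", {
  meta <- toy_metadata()
  d <- build_design(meta)
  nv <- which(meta$smoking_status == "NV")[1]
  expect_equal(unlist(d[nv, c("cs", "fss", "fs")]),
               c(cs = 0, fss = 0, fs = 0))
  fs2 <- which(meta$smoking_status == "FS2")[1]
  expect_equal(unlist(d[fs2, c("cs", "fss", "fs")]),
               c(cs = 0, fss = 1, fs = 2))
  cs <- which(meta$smoking_status == "CS")[1]
  expect_equal(unlist(d[cs, c("cs", "fss", "fs")]),
               c(cs = 1, fss = 0, fs = 0))
  # CS and FSS are mutually exclusive for every sample
  expect_true(all(d$cs * d$fss == 0))
  bad <- meta
  bad$smoking_status[1] <- "VAPER"
  expect_error(build_design(bad), "unknown smoking_status")
})

test_that("model posteriors are proper and respond to signal as expected", {
  sim <- simulate_cohort(sim_config(
    n_hv = 120, n_clinic = 10, n_genes = 20,
    class_counts = c(RR = 3, SR = 3, IR = 3, CA = 3),
    noise_sd = 0, covariate_effect_sd = 0, batch_effect_sd = 0,
    n_cohort_genes = 0, n_snps = 50, n_eqtl = 0, n_gxe = 0, seed = 31))
  meta <- sim$metadata[sim$metadata$cohort == "HV", ]
  design <- build_design(meta)

  # constant response: all mass on the empty model
  fit0 <- fit_model_space(rep(2.5, nrow(meta)), design)
  expect_gt(fit0$posterior[["none"]], 0.99)
  expect_true(all(abs(fit0$betas) < 1e-12))
  expect_equal(sum(fit0$posterior), 1, tolerance = 1e-9)

  # noiseless rapidly-reversible gene: {CS} wins and beta_cs is exact
  tr <- sim$truth$genes
  rr <- tr$gene_id[tr$class_hv == "RR"][1]
  s <- tr$sign[tr$gene_id == rr]
  fit <- fit_model_space(sim$expr[rr, meta$sample_id], design)
  expect_identical(names(which.max(fit$posterior)), "cs")
  expect_equal(unname(fit$betas[["cs"]]), s * 1, tolerance = 1e-6)
  expect_equal(sum(fit$posterior), 1, tolerance = 1e-9)

  # intercept invariance: adding a constant leaves the posterior unchanged
  y <- sim$expr[rr, meta$sample_id]
  fit_shift <- fit_model_space(y + 100, design)
  expect_equal(fit_shift$posterior, fit$posterior, tolerance = 1e-8)
})

test_that("the g-prior sensitivity option behaves like BIC on strong signal", {
  sim <- simulate_cohort(sim_config(
    n_hv = 150, n_clinic = 10, n_genes = 10, class_counts = c(RR = 2),
    noise_sd = 0.3, covariate_effect_sd = 0, batch_effect_sd = 0,
    n_cohort_genes = 0, n_snps = 50, n_eqtl = 0, n_gxe = 0, seed = 32))
  meta <- sim$metadata[sim$metadata$cohort == "HV", ]
  design <- build_design(meta)
  tr <- sim$truth$genes
  rr <- tr$gene_id[tr$class_hv == "RR"][1]
  y <- sim$expr[rr, meta$sample_id]
  fit_g <- fit_model_space(y, design, prior = "gprior")
  expect_identical(names(which.max(fit_g$posterior)), "cs")
  expect_equal(sum(fit_g$posterior), 1, tolerance = 1e-9)
})

test_that("classify_gene maps model groups to classes with thresholds", {
  point_mass <- function(model) {
    p <- setNames(rep(0, 8), c("none", "cs", "fss", "fs", "cs_fss",
                               "cs_fs", "fss_fs", "cs_fss_fs"))
    p[model] <- 1
    p
  }
  betas <- c(cs = 1, fss = 0, fs = 0)
  expect_identical(classify_gene(point_mass("cs"), betas)$cls, "RR")
  expect_identical(classify_gene(point_mass("none"), betas)$cls, "US")
  expect_identical(classify_gene(point_mass("cs_fss"), betas)$cls, "IR")
  expect_identical(classify_gene(point_mass("cs_fs"), betas)$cls, "SR")
  expect_identical(classify_gene(point_mass("cs_fss_fs"), betas)$cls, "SR")
  expect_identical(classify_gene(point_mass("fss"), betas)$cls, "CA")
  expect_identical(classify_gene(point_mass("fs"), betas)$cls, "CA")

  # weak cessation-associated gene: called CA but not strong
  weak <- classify_gene(point_mass("fss"), c(cs = 0, fss = 0.2, fs = 0))
  expect_identical(weak$cls, "CA")
  expect_false(weak$strong)
  strong <- classify_gene(point_mass("fss"), c(cs = 0, fss = 0.3, fs = 0))
  expect_true(strong$strong)
  # strong RR requires |beta_cs| > 0.4; sign is irrelevant
  expect_true(classify_gene(point_mass("cs"), c(cs = -0.5, fss = 0, fs = 0))$strong)
  expect_false(classify_gene(point_mass("cs"), c(cs = 0.39, fss = 0, fs = 0))$strong)
})

test_that("zero-noise cohorts are classified exactly and clinic runs use the HV reference", {
  cfg <- sim_config(n_hv = 120, n_clinic = 80, n_genes = 40,
                    class_counts = list(hv = c(RR = 5, SR = 5, IR = 5, CA = 5),
                                        clinic = c(SR = 5, RR = 5, CA = 5,
                                                   IR = 5)),
                    noise_sd = 0, covariate_effect_sd = 0, batch_effect_sd = 0,
                    n_cohort_genes = 0, n_snps = 50, n_eqtl = 0, n_gxe = 0,
                    seed = 33)
  sim <- simulate_cohort(cfg)
  tr <- sim$truth$genes
  calls_hv <- quietly(classify_all(sim$expr, sim$metadata, cohort = "HV"))
  expect_identical(calls_hv$cls[match(tr$gene_id, calls_hv$gene_id)],
                   tr$class_hv)
  g <- glance(calls_hv)
  expect_identical(g$n[g$cls == "RR"], 5L)
  expect_identical(g$n_strong[g$cls == "RR"], 5L)

  # the clinic run must include HV never smokers as the reference group
  calls_cl <- quietly(classify_all(sim$expr, sim$metadata, cohort = "CLINIC"))
  expect_identical(calls_cl$cls[match(tr$gene_id, calls_cl$gene_id)],
                   tr$class_clinic)
  expect_gt(attr(calls_cl, "n_samples"),
            sum(sim$metadata$cohort == "CLINIC"))
})

test_that("posteriors always sum to one across a whole cohort", {
  sim <- simulate_cohort(sim_config(
    n_hv = 60, n_clinic = 10, n_genes = 30, class_counts = c(RR = 3, CA = 3),
    noise_sd = 0.7, n_cohort_genes = 0, n_snps = 50, n_eqtl = 0, n_gxe = 0,
    seed = 35))
  calls <- quietly(classify_all(sim$expr, sim$metadata, cohort = "HV"))
  sums <- calls$p_US + calls$p_RR + calls$p_SR + calls$p_IR + calls$p_CA
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("permuting smoking labels destroys class recovery", {
  cfg <- sim_config(n_hv = 150, n_clinic = 10, n_genes = 40,
                    class_counts = c(RR = 10, SR = 10, IR = 10, CA = 10),
                    effect_size_cs = 1, effect_size_fss = 1, noise_sd = 0.5,
                    n_cohort_genes = 0, n_snps = 50, n_eqtl = 0, n_gxe = 0,
                    seed = 36)
  sim <- simulate_cohort(cfg)
  meta <- sim$metadata
  hv <- meta$cohort == "HV"
  set.seed(99)
  meta$smoking_status[hv] <- sample(meta$smoking_status[hv])
  meta$pack_years[meta$smoking_status == "NV"] <- "PY1"
  calls_perm <- quietly(classify_all(sim$expr, meta, cohort = "HV"))
  expect_lte(mean(calls_perm$strong), 0.05)
  calls_true <- quietly(classify_all(sim$expr, sim$metadata, cohort = "HV"))
  expect_gte(mean(calls_true$strong), 0.9)
})

test_that("cohort comparison counts transitions and derives response genes", {
  # self-comparison gives a diagonal transition table
  sim <- simulate_cohort(sim_config(
    n_hv = 80, n_clinic = 10, n_genes = 20, class_counts = c(RR = 4, CA = 4),
    noise_sd = 0, covariate_effect_sd = 0, batch_effect_sd = 0,
    n_cohort_genes = 0, n_snps = 50, n_eqtl = 0, n_gxe = 0, seed = 37))
  calls <- quietly(classify_all(sim$expr, sim$metadata, cohort = "HV"))
  cmp_self <- compare_cohorts(calls, calls)
  expect_identical(sum(cmp_self$counts), cmp_self$n_shared)
  expect_identical(sum(diag(cmp_self$counts)), cmp_self$n_shared)

  # planted transition genes land in the right off-diagonal cell
  cfg <- sim_config(n_hv = 120, n_clinic = 120, n_genes = 30,
                    class_counts = list(hv = c(RR = 6), clinic = c(SR = 6)),
                    noise_sd = 0, covariate_effect_sd = 0, batch_effect_sd = 0,
                    n_cohort_genes = 0, n_snps = 50, n_eqtl = 0, n_gxe = 0,
                    seed = 38)
  sim2 <- simulate_cohort(cfg)
  a <- quietly(classify_all(sim2$expr, sim2$metadata, cohort = "HV"))
  b <- quietly(classify_all(sim2$expr, sim2$metadata, cohort = "CLINIC"))
  cmp <- compare_cohorts(a, b)
  expect_identical(cmp$counts["RR", "SR"], 6L)
  expect_identical(sum(cmp$counts) - cmp$counts["US", "US"] -
                     cmp$counts["RR", "SR"], 0L)
  expect_setequal(cmp$response_genes,
                  sim2$truth$genes$gene_id[sim2$truth$genes$class_hv == "RR"])
  # genes unaffected in both cohorts are never response genes
  us_both <- a$gene_id[a$cls == "US" & b$cls[match(a$gene_id, b$gene_id)] == "US"]
  expect_length(intersect(cmp$response_genes, us_both), 0)
})

test_that("the strong-set overlap test equals the hand-computed Pearson statistic", {
  calls_stub <- function(strong, cls) {
    tibble::tibble(gene_id = sprintf("g%02d", seq_along(strong)),
                   cls = cls, strong = strong)
  }
  # fixed 2x2 membership: a=TRUE in 1-10, b=TRUE in 6-15, universe 30
  a <- calls_stub(c(rep(TRUE, 10), rep(FALSE, 20)), rep("RR", 30))
  b <- calls_stub(c(rep(FALSE, 5), rep(TRUE, 10), rep(FALSE, 15)),
                  rep("SR", 30))
  cmp <- compare_cohorts(a, b)
  tab <- table(a$strong, b$strong)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  pearson <- sum((tab - expected)^2 / expected)
  expect_equal(unname(cmp$strong_overlap_test$statistic), pearson,
               tolerance = 1e-12)
  expect_error(compare_cohorts(a, calls_stub(TRUE, "RR")[0, ]), "disjoint")
})
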