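toy_geno <- function(dosage, chrom = "1", pos = seq_len(nrow(dosage)) * 1000L) {
  colnames(dosage) <- sprintf("S%03d", seq_len(ncol(dosage)))
  genotype_table(
    tibble::tibble(snp_id = sprintf("v%03d", seq_len(nrow(dosage))),
                   chrom = chrom, pos = as.integer(pos), ref = "A", alt = "G"),
    dosage
  )
}

test_that("MAF filtering matches a direct allele-count oracle", {
  set.seed(1)
  d <- matrix(rbinom(100 * 50, 2, runif(100, 0.005, 0.3)), 100, 50)
  d[1, ] <- 0L  # monomorphic SNP must always drop
  storage.mode(d) <- "integer"
  geno <- toy_geno(d)
  kept <- maf_filter(geno, 0.01)
  oracle <- vapply(seq_len(nrow(d)), function(i) {
    af <- sum(d[i, ]) / (2 * ncol(d))
    min(af, 1 - af) > 0.01
  }, logical(1))
  expect_identical(kept$snps$snp_id, geno$snps$snp_id[oracle])
  expect_false("v001" %in% kept$snps$snp_id)
  # maf_min = 0 keeps every polymorphic SNP
  all_poly <- maf_filter(geno, 0)
  expect_identical(all_poly$snps$snp_id,
                   geno$snps$snp_id[geno$snps$maf > 0])
})

test_that("VIF pruning removes exactly one of two identical SNPs and spares independent ones", {
  set.seed(2)
  base <- rbinom(60, 2, 0.4)
  dup <- rbind(base, base, rbinom(60, 2, 0.4))
  storage.mode(dup) <- "integer"
  pruned <- vif_prune(toy_geno(dup), prune_config(window = 3, step = 3))
  expect_identical(nrow(pruned$snps), 2L)

  indep <- matrix(rbinom(8 * 500, 2, 0.5), 8, 500)
  storage.mode(indep) <- "integer"
  pruned2 <- vif_prune(toy_geno(indep), prune_config(window = 8, step = 8))
  expect_identical(nrow(pruned2$snps), 8L)
  # the implied r-squared cutoff at vif_max = 20 is exactly 0.95
  expect_equal(1 - 1 / prune_config()$vif_max, 0.95)
})

test_that("VIF pruning agrees with the explicit-OLS oracle on 10-SNP windows", {
  set.seed(3)
  for (rep in 1:5) {
    founder <- rbinom(80, 2, 0.3)
    d <- rbind(
      founder,
      ifelse(runif(80) < 0.05, rbinom(80, 2, 0.3), founder),
      ifelse(runif(80) < 0.05, rbinom(80, 2, 0.3), founder),
      matrix(rbinom(7 * 80, 2, runif(7, 0.2, 0.5)), 7, 80)
    )
    storage.mode(d) <- "integer"
    geno <- toy_geno(d)
    pruned <- quietly(vif_prune(geno, prune_config(window = 10, step = 10,
                                                   vif_max = 20)))
    alive <- oracle_vif_prune_window(d, geno$snps$maf, geno$snps$pos,
                                     vif_max = 20)
    expect_identical(pruned$snps$snp_id, geno$snps$snp_id[sort(alive)])
  }
})

test_that("VIF pruning is idempotent", {
  set.seed(4)
  founder <- rbinom(100, 2, 0.4)
  d <- rbind(founder,
             ifelse(runif(100) < 0.03, rbinom(100, 2, 0.4), founder),
             matrix(rbinom(6 * 100, 2, 0.4), 6, 100))
  storage.mode(d) <- "integer"
  once <- quietly(vif_prune(toy_geno(d), prune_config(window = 4, step = 2)))
  twice <- quietly(vif_prune(once, prune_config(window = 4, step = 2)))
  expect_identical(twice$snps$snp_id, once$snps$snp_id)
})

test_that("cis windows are closed intervals on the right chromosome", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "1", start = 600000L,
                          end = 610000L, strand = "+", tss = 600000L,
                          tts = 609999L)
  snps <- tibble::tibble(
    snp_id = c("at_edge", "outside", "wrong_chrom", "inside"),
    chrom = c("1", "1", "2", "1"),
    pos = c(100000L, 99999L, 100000L, 605000L),
    ref = "A", alt = "G"
  )
  pairs <- cis_pairs(genes, snps, window_bp = 500000)
  # SNP exactly at gene_start - 500 kb is included; one bp further is not
  expect_setequal(pairs$snp_id, c("at_edge", "inside"))
})

test_that("cis pair enumeration equals the exhaustive double-loop oracle", {
  set.seed(5)
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:20),
    chrom = sample(c("1", "2"), 20, replace = TRUE),
    start = sample(1e6, 20)
  )
  genes$end <- genes$start + sample(5e3:5e4, 20)
  genes$strand <- "+"
  genes$tss <- genes$start
  genes$tts <- genes$end - 1L
  snps <- tibble::tibble(
    snp_id = sprintf("v%03d", 1:200),
    chrom = sample(c("1", "2"), 200, replace = TRUE),
    pos = sample(1.5e6, 200), ref = "A", alt = "G"
  )
  w <- 2e5
  pairs <- cis_pairs(genes, snps, window_bp = w)
  oracle <- list()
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(snps))) {
      if (genes$chrom[i] == snps$chrom[j] &&
          snps$pos[j] >= genes$start[i] - w &&
          snps$pos[j] <= genes$end[i] - 1 + w) {
        oracle[[length(oracle) + 1]] <- paste(genes$gene_id[i], snps$snp_id[j])
      }
    }
  }
  expect_setequal(paste(pairs$gene_id, pairs$snp_id), unlist(oracle))
})

test_that("noiseless planted eQTL effects are recovered exactly", {
  set.seed(6)
  n <- 100
  meta <- simulate_cohort(sim_config(
    n_hv = n, n_clinic = 10, n_genes = 2, class_counts = c(RR = 1),
    noise_sd = 0, covariate_effect_sd = 0, batch_effect_sd = 0,
    n_cohort_genes = 0, n_snps = 10, n_eqtl = 0, n_gxe = 0, n_gwas_loci = 2,
    seed = 61))$metadata
  dos <- matrix(rbinom(3 * nrow(meta), 2, 0.4), 3, nrow(meta))
  storage.mode(dos) <- "integer"
  dos[, 1:3] <- c(0L, 1L, 2L)  # guarantee polymorphism
  geno <- toy_geno(dos)
  colnames(geno$dosage) <- meta$sample_id
  expr <- matrix(5 + 0.75 * geno$dosage[2, ], 1, nrow(meta),
                 dimnames = list("gene1", meta$sample_id))
  pairs <- tibble::tibble(gene_id = "gene1", snp_id = c("v001", "v002", "v003"))
  rec <- eqtl_scan(expr, geno, meta, pairs)
  lead <- rec[rec$is_lead, ]
  expect_identical(lead$snp_id, "v002")
  expect_equal(lead$beta, 0.75, tolerance = 1e-9)
  # single-variant genes: Bonferroni with m = 1 is the identity
  rec1 <- eqtl_scan(expr, geno, meta,
                    tibble::tibble(gene_id = "gene1", snp_id = "v002"))
  expect_equal(rec1$p_gene_bonferroni, rec1$p_raw)
})

test_that("two-step correction satisfies the Bonferroni and BH properties", {
  set.seed(7)
  sim <- simulate_study(sim_config(
    n_hv = 60, n_clinic = 60, n_genes = 30, class_counts = c(RR = 2),
    n_cohort_genes = 0, n_snps = 100, snp_spacing = 3000,
    n_eqtl = 5, eqtl_beta = 1, n_gxe = 0, n_gwas_loci = 10, seed = 71))
  pairs <- cis_pairs(sim$genes, sim$genotypes, window_bp = 100000)
  rec <- quietly(eqtl_scan(sim$expr, sim$genotypes, sim$metadata, pairs))
  expect_true(all(rec$p_gene_bonferroni >= rec$p_raw))
  expect_true(all(rec$p_gene_bonferroni <= 1))
  # exactly one lead per tested gene
  by_gene <- dplyr::count(rec[rec$is_lead, ], gene_id)
  expect_true(all(by_gene$n == 1))
  expect_identical(sort(unique(rec$gene_id)), sort(by_gene$gene_id))
  # BH on the leads is monotone in the sorted adjusted p-values
  leads <- rec[rec$is_lead, ]
  ord <- order(leads$p_gene_bonferroni)
  expect_true(all(diff(leads$q_global[ord]) >= -1e-12))
})

test_that("planted interactions are detected and degenerate designs skipped", {
  set.seed(8)
  sim <- simulate_study(sim_config(
    n_hv = 150, n_clinic = 150, n_genes = 30, class_counts = c(RR = 2),
    n_cohort_genes = 0, n_snps = 100, n_eqtl = 10, eqtl_beta = 0.8,
    n_gxe = 5, gxe_beta = 1, n_gwas_loci = 10, seed = 81))
  leads <- sim$truth$eqtl
  gx <- gxe_test(sim$expr, sim$genotypes, sim$metadata, leads)
  planted <- gx[gx$gene_id %in% sim$truth$gxe$gene_id, ]
  others <- gx[!gx$gene_id %in% sim$truth$gxe$gene_id, ]
  expect_true(all(planted$p_raw < 0.01))
  expect_gt(min(others$p_raw), min(planted$p_raw))

  # constant dosage makes the interaction column collinear: skipped with log
  meta <- sim$metadata
  dos <- matrix(1L, 1, nrow(meta))
  geno1 <- toy_geno(dos)
  colnames(geno1$dosage) <- meta$sample_id
  expr1 <- matrix(rnorm(nrow(meta)), 1,
                  dimnames = list("gx", meta$sample_id))
  expect_error(
    expect_warning(
      gxe_test(expr1, geno1, meta,
               tibble::tibble(gene_id = "gx", snp_id = "v001")),
      "collinear"),
    "degenerate")
})

test_that("GWAS linkage respects distance and LD bounds and matches the r2 oracle", {
  set.seed(9)
  n <- 200
  founder <- rbinom(n, 2, 0.4)
  flip <- function(p) ifelse(runif(n) < p, rbinom(n, 2, 0.4), founder)
  d <- rbind(founder, flip(0.02), flip(0.6), rbinom(n, 2, 0.4), founder)
  storage.mode(d) <- "integer"
  geno <- toy_geno(d, pos = c(1000L, 2000L, 3000L, 4000L, 700000L))
  leads <- tibble::tibble(gene_id = paste0("g", 1:5),
                          snp_id = sprintf("v%03d", 1:5))
  gwas <- tibble::tibble(locus_id = "L1", chrom = "1", pos = 1000L,
                         study_id = "ST01")
  links <- map_gwas(leads, gwas, geno, r2_min = 0.8, window_bp = 500000)
  # identical variant: r2 = 1, linked
  expect_true("v001" %in% links$links$snp_id)
  expect_equal(links$links$r2_with_locus[links$links$snp_id == "v001"], 1)
  # 699 kb away: excluded by the distance bound regardless of LD
  expect_false("v005" %in% links$links$snp_id)
  # exhaustive pairwise oracle within range
  for (j in 1:4) {
    r2 <- cor(d[j, ], d[1, ])^2
    expect_identical(geno$snps$snp_id[j] %in% links$links$snp_id, r2 > 0.8)
  }
  # a locus with no genotyped SNP is counted as unlinked
  gwas2 <- tibble::tibble(locus_id = "L2", chrom = "1", pos = 1234L,
                          study_id = "ST01")
  links2 <- map_gwas(leads, gwas2, geno)
  expect_identical(links2$summary$n_loci_no_snp, 1L)
  expect_identical(nrow(links2$links), 0L)
})
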