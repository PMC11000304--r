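#' Configuration for the synthetic study generator
#'
#' Defaults describe a desk-scale analogue of a two-cohort nasal-epithelium
#' study: cohort sizes and the smoking-status mix follow the real cohort's
#' published composition (114 healthy volunteers; 299 clinic nasal samples;
#' 45 never, 234/45/10 former by cessation recency, 153 current smokers out
#' of 487 donors), while gene and SNP counts are desk-scale (2,000 genes,
#' 20,000 SNPs) rather than transcriptome/genome scale.
#'
#' @param n_hv,n_clinic Samples in the healthy-volunteer and clinic cohorts.
#' @param smoking_mix Named proportions over NV/FS1/FS2/FS3/CS (must sum to
#'   1). The clinic cohort contains no never smokers; its mix is the same
#'   vector renormalized over FS1..CS.
#' @param diagnosis_mix Named proportions over CANCER/INELIGIBLE/BENIGN for
#'   clinic samples (healthy volunteers are always diagnosis NONE).
#' @param n_genes Number of genes in the expression matrix.
#' @param class_counts Planted genes per reversibility class, either a named
#'   vector (same classes in both cohorts) or `list(hv = ..., clinic = ...)`
#'   of named vectors over RR/SR/IR/CA. The two vectors are applied
#'   positionally to the same gene slots, so differing vectors plant
#'   transition genes; unplanted genes are US in both cohorts.
#' @param effect_size_cs,effect_size_fss Planted current-smoker and
#'   former-smoker effect sizes (normalized-expression units). The defaults
#'   sit well above the 0.4 / 0.25 strong-effect calling thresholds.
#' @param noise_sd Residual Gaussian noise standard deviation.
#' @param batch_effect_sd,covariate_effect_sd SDs of the per-gene additive
#'   batch and sex/age nuisance coefficients (0 disables them).
#' @param n_cohort_genes,cohort_effect Genes carrying an additive
#'   clinic-vs-volunteer cohort shift (the population-classifier signal).
#' @param baseline_mean,baseline_sd Per-gene baseline expression draw.
#' @param n_snps,ld_block_size,ld_flip_prob,maf_range,snp_spacing,n_chrom
#'   Genotype panel: SNPs arranged in LD blocks built by copying a block
#'   founder and re-drawing each genotype with probability `ld_flip_prob`;
#'   founder dosages are Hardy-Weinberg binomial draws at a MAF uniform in
#'   `maf_range`; positions are `snp_spacing` bp apart across `n_chrom`
#'   chromosomes.
#' @param n_eqtl,eqtl_beta Planted cis-eQTL (gene, SNP) pairs and their
#'   per-alt-allele effect.
#' @param n_gxe,gxe_beta Of the planted eQTL genes, how many also carry a
#'   genotype-by-smoking interaction `gxe_beta * dosage * smoking(0/1/2)`.
#' @param n_gwas_loci GWAS catalogue size; half the loci are placed on
#'   planted eQTL variants (linkable), the rest at random SNP positions.
#' @param n_tfs,regulon_size_range,n_enriched_tfs,planted_enrichment_fold,
#'   enrichment_geneset_size Regulatory-network block: TF count, uniform
#'   regulon size range, number of TFs whose target draw favours the
#'   planted geneset by `planted_enrichment_fold`, and that geneset's size.
#' @param seed Single integer seed; it fully determines all outputs.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(
    n_hv = 114, n_clinic = 299,
    smoking_mix = c(NV = 45, FS1 = 234, FS2 = 45, FS3 = 10, CS = 153) / 487,
    diagnosis_mix = c(CANCER = 245, INELIGIBLE = 56, BENIGN = 72) / 373,
    n_genes = 2000,
    class_counts = c(RR = 10, SR = 10, IR = 10, CA = 10),
    effect_size_cs = 1, effect_size_fss = 0.5,
    noise_sd = 0.5,
    batch_effect_sd = 0.3, covariate_effect_sd = 0.1,
    n_cohort_genes = 100, cohort_effect = 1,
    baseline_mean = 8, baseline_sd = 1,
    n_snps = 20000, ld_block_size = 10, ld_flip_prob = 0.05,
    maf_range = c(0.05, 0.5), snp_spacing = 1500, n_chrom = 2,
    n_eqtl = 50, eqtl_beta = 1,
    n_gxe = 20, gxe_beta = 1,
    n_gwas_loci = 50,
    n_tfs = 50, regulon_size_range = NULL, n_enriched_tfs = 4,
    planted_enrichment_fold = 5, enrichment_geneset_size = NULL,
    seed = 1) {
  if (!is.list(class_counts)) {
    class_counts <- list(hv = class_counts, clinic = class_counts)
  }
  # network defaults scale down with small gene universes
  if (is.null(regulon_size_range)) {
    upper <- max(1, min(100, floor(n_genes / 4), n_genes - 1))
    lower <- max(1, min(20, floor(n_genes / 10), upper))
    regulon_size_range <- c(lower, upper)
  }
  if (is.null(enrichment_geneset_size)) {
    enrichment_geneset_size <- max(1, min(50, floor(n_genes / 8)))
  }
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  assert_that(all(c("hv", "clinic") %in% names(cfg$class_counts)),
              "class_counts must be a vector or list(hv=, clinic=)")
  for (coh in c("hv", "clinic")) {
    cc <- cfg$class_counts[[coh]]
    assert_that(all(names(cc) %in% c("RR", "SR", "IR", "CA", "US")),
                "class_counts names must be reversibility classes")
    assert_that(sum(cc) <= cfg$n_genes,
                "class_counts exceed n_genes")
  }
  assert_that(abs(sum(cfg$smoking_mix) - 1) < 1e-8, "smoking_mix must sum to 1")
  assert_that(identical(sort(names(cfg$smoking_mix)), sort(SMOKING_LEVELS)),
              "smoking_mix needs names NV/FS1/FS2/FS3/CS")
  assert_that(abs(sum(cfg$diagnosis_mix) - 1) < 1e-8, "diagnosis_mix must sum to 1")
  counts <- c(cfg$n_hv, cfg$n_clinic, cfg$n_genes, cfg$n_snps,
              cfg$ld_block_size, cfg$n_tfs)
  assert_that(all(counts > 0), "all counts must be positive")
  assert_that(cfg$n_eqtl <= cfg$n_genes && cfg$n_eqtl <= cfg$n_snps,
              "more planted eQTL than genes or SNPs")
  assert_that(cfg$n_gwas_loci <= cfg$n_snps,
              "more GWAS loci than SNP positions")
  assert_that(cfg$n_gxe <= cfg$n_eqtl,
              "planted GxE genes must be a subset of planted eQTL genes")
  assert_that(max(cfg$regulon_size_range) < cfg$n_genes,
              "regulon size range exceeds the gene universe")
  assert_that(cfg$n_cohort_genes + sum(cfg$class_counts$hv) <= cfg$n_genes,
              "cohort-shift genes plus planted class genes exceed n_genes")
  assert_that(cfg$ld_flip_prob >= 0 && cfg$ld_flip_prob <= 1,
              "ld_flip_prob must be in [0,1]")
  assert_that(length(cfg$seed) == 1 && is.finite(cfg$seed), "seed must be a number")
  cfg
}
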