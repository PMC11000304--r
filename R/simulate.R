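# Synthetic two-cohort study generator. All structure is planted and
# recorded in a truth object so downstream stages can be tested without
# access-controlled data. One global seed; each generator derives a fixed
# child seed, so components re-run standalone reproduce a full-study run.

#' Simulate expression and metadata for a two-cohort smoking study
#'
#' Generates per-sample metadata (cohort, smoking status with cessation
#' strata, pack-years, sex, age class, batch, diagnosis) and a genes x
#' samples expression matrix in which planted genes follow the mean
#' structure of their reversibility class:
#' \describe{
#'   \item{US}{unaffected: constant across smoking strata}
#'   \item{RR}{rapidly reversible: shifted in current smokers only}
#'   \item{SR}{slowly reversible: full shift in current smokers, linear
#'     decay over cessation recency in former smokers (`beta * FS/3`,
#'     FS = 3 for the most recent quitters)}
#'   \item{IR}{irreversible: identical shift in current and all former
#'     smokers}
#'   \item{CA}{cessation-associated: shifted in former smokers only}
#' }
#' A gene may carry a different class in each cohort (transition genes).
#' Sex, age and batch act as additive per-gene Gaussian nuisance effects;
#' a subset of genes carries an additive clinic-vs-volunteer cohort shift.
#'
#' @param config A [sim_config()].
#' @return List with `expr` (matrix), `metadata` (tibble) and `truth`
#'   (list; `$genes` holds per-gene classes, signs and flags).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, 1L), {
    metadata <- simulate_metadata(config)
    n <- nrow(metadata)
    n_genes <- config$n_genes
    gene_ids <- sprintf("G%04d", seq_len(n_genes))

    # positional class slots: hv and clinic vectors over the same genes
    hv_lab <- rep(names(config$class_counts$hv), config$class_counts$hv)
    cl_lab <- rep(names(config$class_counts$clinic), config$class_counts$clinic)
    n_planted <- max(length(hv_lab), length(cl_lab))
    hv_lab <- c(hv_lab, rep("US", n_planted - length(hv_lab)))
    cl_lab <- c(cl_lab, rep("US", n_planted - length(cl_lab)))
    class_hv <- rep("US", n_genes)
    class_clinic <- rep("US", n_genes)
    planted_idx <- if (n_planted > 0) sample(n_genes, n_planted) else integer(0)
    class_hv[planted_idx] <- hv_lab
    class_clinic[planted_idx] <- cl_lab

    free_idx <- setdiff(seq_len(n_genes), planted_idx)
    cohort_idx <- if (config$n_cohort_genes > 0) {
      sample(free_idx, config$n_cohort_genes)
    } else integer(0)

    baseline <- rnorm(n_genes, config$baseline_mean, config$baseline_sd)
    sign <- sample(c(-1, 1), n_genes, replace = TRUE)
    coef_sex <- rnorm(n_genes, 0, config$covariate_effect_sd)
    coef_age <- rnorm(n_genes, 0, config$covariate_effect_sd)
    coef_batch <- rnorm(n_genes, 0, config$batch_effect_sd)

    # per-sample smoking codes
    cs <- as.numeric(metadata$smoking_status == "CS")
    fss <- as.numeric(metadata$smoking_status %in% c("FS1", "FS2", "FS3"))
    fs_code <- dplyr::recode(metadata$smoking_status,
                             NV = 0, FS1 = 1, FS2 = 2, FS3 = 3, CS = 0)
    sex01 <- as.numeric(metadata$sex == "M")
    clinic01 <- as.numeric(metadata$cohort == "CLINIC")

    # class multiplier rows (per sample), split into the CS-scaled part and
    # the FSS-scaled part (only CA uses the latter)
    mult_cs <- rbind(US = 0 * cs, RR = cs, SR = cs + fss * fs_code / 3,
                     IR = cs + fss, CA = 0 * cs)
    mult_fss <- rbind(US = 0 * cs, RR = 0 * cs, SR = 0 * cs, IR = 0 * cs,
                      CA = fss)

    expr <- matrix(rnorm(n_genes * n, 0, config$noise_sd), n_genes, n,
                   dimnames = list(gene_ids, metadata$sample_id))
    expr <- expr + baseline +
      outer(coef_sex, sex01) +
      outer(coef_age, metadata$age_class) +
      outer(coef_batch, as.numeric(metadata$batch))
    for (coh in c("HV", "CLINIC")) {
      cols <- which(metadata$cohort == coh)
      cls <- if (coh == "HV") class_hv else class_clinic
      for (cl in CLASS_LEVELS) {
        rows <- which(cls == cl)
        if (length(rows) == 0 || length(cols) == 0 || cl == "US") next
        shift <- config$effect_size_cs * mult_cs[cl, cols] +
          config$effect_size_fss * mult_fss[cl, cols]
        expr[rows, cols] <- expr[rows, cols] + outer(sign[rows], shift)
      }
    }
    if (length(cohort_idx) > 0) {
      expr[cohort_idx, ] <- expr[cohort_idx, ] +
        config$cohort_effect * outer(sign[cohort_idx], clinic01)
    }

    truth <- list(genes = tibble::tibble(
      gene_id = gene_ids, class_hv = class_hv, class_clinic = class_clinic,
      sign = sign, cohort_gene = seq_len(n_genes) %in% cohort_idx,
      baseline = baseline
    ))
    list(expr = expr, metadata = metadata, truth = truth)
  })
}

simulate_metadata <- function(config) {
  mix_hv <- config$smoking_mix[SMOKING_LEVELS]
  mix_cl <- config$smoking_mix[c("FS1", "FS2", "FS3", "CS")]
  mix_cl <- mix_cl / sum(mix_cl)  # the clinic cohort has no never smokers
  n_hv <- config$n_hv
  n_cl <- config$n_clinic
  cohort <- c(rep("HV", n_hv), rep("CLINIC", n_cl))
  smoking <- c(
    sample(names(mix_hv), n_hv, replace = TRUE, prob = mix_hv),
    sample(names(mix_cl), n_cl, replace = TRUE, prob = mix_cl)
  )
  diagnosis <- c(
    rep("NONE", n_hv),
    sample(names(config$diagnosis_mix), n_cl, replace = TRUE,
           prob = config$diagnosis_mix)
  )
  pack_years <- ifelse(
    smoking == "NV", "PY1",
    sample(c("PY2", "PY3", "PY4"), n_hv + n_cl, replace = TRUE,
           prob = c(0.25, 0.45, 0.30))
  )
  age_class <- vapply(seq_along(cohort), function(i) {  # clinic skews older
    p <- if (cohort[i] == "HV") c(0.3, 0.3, 0.2, 0.2) else c(0.1, 0.2, 0.3, 0.4)
    sample(0:3, 1, prob = p)
  }, integer(1))
  tibble::tibble(
    sample_id = sprintf("S%04d", seq_along(cohort)),
    cohort = cohort,
    diagnosis = diagnosis,
    smoking_status = smoking,
    pack_years = pack_years,
    sex = sample(c("F", "M"), length(cohort), replace = TRUE),
    age_class = age_class,
    batch = sample(0:1, length(cohort), replace = TRUE),
    copd = ifelse(cohort == "HV", "no",
                  sample(c("no", "yes", "unknown"), length(cohort),
                         replace = TRUE, prob = c(0.6, 0.3, 0.1))),
    tissue = "nasal"
  )
}

#' Simulate LD-blocked genotypes, gene coordinates and planted genetic effects
#'
#' SNP dosages are Hardy-Weinberg binomial draws at a block-level MAF; LD
#' blocks are built by copying a founder SNP and re-drawing each genotype
#' with probability `ld_flip_prob` (0 gives perfectly correlated blocks).
#' Planted cis-eQTL add `eqtl_beta * dosage` to their target gene's
#' expression; planted interactions add `gxe_beta * dosage * smoking(0/1/2)`
#' (never/former/current). A GWAS catalogue is emitted with half its loci
#' sitting on planted eQTL variants.
#'
#' @param config A [sim_config()].
#' @param metadata Sample metadata from [simulate_cohort()].
#' @param expr Expression matrix to plant genetic effects into (required if
#'   `n_eqtl > 0`).
#' @param truth Truth list to extend (optional).
#' @return List with `genotypes` ([genotype_table()]), `genes` (annotation
#'   tibble), `expr` (with effects added), `gwas` (locus tibble) and
#'   `truth` (extended with `$eqtl` and `$gxe` tibbles).
#' @export
simulate_genotypes <- function(config, metadata, expr = NULL, truth = list()) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_eqtl > 0) {
    assert_that(!is.null(expr), "expr is required to plant eQTL effects")
  }
  with_seed(child_seed(config$seed, 2L), {
    n <- nrow(metadata)
    n_snps <- config$n_snps
    bs <- config$ld_block_size
    n_blocks <- ceiling(n_snps / bs)
    dosage <- matrix(0L, n_snps, n)
    block_of <- rep(seq_len(n_blocks), each = bs)[seq_len(n_snps)]
    mafs <- runif(n_blocks, config$maf_range[1], config$maf_range[2])
    for (b in seq_len(n_blocks)) {
      idx <- which(block_of == b)
      p <- mafs[b]
      founder <- rbinom(n, 2, p)
      for (j in idx) {
        d <- founder
        flip <- runif(n) < config$ld_flip_prob
        if (any(flip)) d[flip] <- rbinom(sum(flip), 2, p)
        dosage[j, ] <- as.integer(d)
      }
    }
    # positions: contiguous blocks of SNPs per chromosome, fixed spacing
    chrom_sizes <- diff(round(seq(0, n_snps, length.out = config$n_chrom + 1)))
    chrom <- rep(as.character(seq_len(config$n_chrom)), chrom_sizes)
    pos <- unlist(lapply(chrom_sizes, function(k) seq_len(k) * config$snp_spacing),
                  use.names = FALSE)
    snps <- tibble::tibble(
      snp_id = sprintf("snp%05d", seq_len(n_snps)),
      chrom = chrom, pos = as.integer(pos), ref = "A", alt = "G"
    )
    colnames(dosage) <- metadata$sample_id
    genotypes <- genotype_table(snps, dosage)

    # gene coordinates spread over the same span as the SNPs
    gene_ids <- if (!is.null(expr)) rownames(expr) else
      sprintf("G%04d", seq_len(config$n_genes))
    n_genes <- length(gene_ids)
    g_chrom <- sample(as.character(seq_len(config$n_chrom)), n_genes, replace = TRUE)
    span <- tapply(snps$pos, snps$chrom, max)
    g_start <- vapply(g_chrom, function(ch) {
      as.integer(round(runif(1, 0, span[[ch]] * 0.95)))
    }, integer(1))
    g_len <- as.integer(round(runif(n_genes, 5e3, 5e4)))
    g_strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    genes <- tibble::tibble(
      gene_id = gene_ids, chrom = g_chrom, start = g_start,
      end = g_start + g_len, strand = g_strand,
      tss = ifelse(g_strand == "+", g_start, g_start + g_len - 1L),
      tts = ifelse(g_strand == "+", g_start + g_len - 1L, g_start)
    )

    # planted eQTL: nearest SNP to each chosen gene's TSS (always in cis)
    eqtl_truth <- tibble::tibble(gene_id = character(), snp_id = character(),
                                 beta = numeric())
    gxe_truth <- tibble::tibble(gene_id = character(), snp_id = character(),
                                beta_interaction = numeric())
    if (config$n_eqtl > 0) {
      eqtl_genes <- sample(gene_ids, config$n_eqtl)
      smk012 <- dplyr::case_when(
        metadata$smoking_status == "NV" ~ 0,
        metadata$smoking_status == "CS" ~ 2,
        TRUE ~ 1
      )
      eqtl_snps <- character(config$n_eqtl)
      for (k in seq_len(config$n_eqtl)) {
        gi <- match(eqtl_genes[k], genes$gene_id)
        on_chrom <- which(snps$chrom == genes$chrom[gi])
        si <- on_chrom[which.min(abs(snps$pos[on_chrom] - genes$tss[gi]))]
        eqtl_snps[k] <- snps$snp_id[si]
        if (config$eqtl_beta != 0) {
          expr[eqtl_genes[k], ] <- expr[eqtl_genes[k], ] +
            config$eqtl_beta * dosage[si, ]
        }
        if (k <= config$n_gxe && config$gxe_beta != 0) {
          expr[eqtl_genes[k], ] <- expr[eqtl_genes[k], ] +
            config$gxe_beta * dosage[si, ] * smk012
        }
      }
      if (config$eqtl_beta != 0) {
        eqtl_truth <- tibble::tibble(gene_id = eqtl_genes, snp_id = eqtl_snps,
                                     beta = config$eqtl_beta)
      }
      if (config$n_gxe > 0 && config$gxe_beta != 0) {
        gxe_truth <- tibble::tibble(
          gene_id = eqtl_genes[seq_len(config$n_gxe)],
          snp_id = eqtl_snps[seq_len(config$n_gxe)],
          beta_interaction = config$gxe_beta
        )
      }
    }

    # GWAS catalogue: half the loci on planted eQTL variants, half random
    n_loci <- config$n_gwas_loci
    n_on_eqtl <- min(nrow(eqtl_truth), floor(n_loci / 2))
    loci_snps <- c(
      if (n_on_eqtl > 0) eqtl_truth$snp_id[seq_len(n_on_eqtl)],
      sample(setdiff(snps$snp_id, eqtl_truth$snp_id), n_loci - n_on_eqtl)
    )
    li <- match(loci_snps, snps$snp_id)
    gwas <- tibble::tibble(
      locus_id = sprintf("locus%03d", seq_len(n_loci)),
      chrom = snps$chrom[li], pos = snps$pos[li],
      study_id = sample(sprintf("ST%02d", 1:13), n_loci, replace = TRUE)
    )
    gwas <- gwas[!duplicated(gwas[, c("chrom", "pos")]), , drop = FALSE]

    truth$eqtl <- eqtl_truth
    truth$gxe <- gxe_truth
    truth$gwas_eqtl_loci <- gwas$locus_id[seq_len(n_on_eqtl)]
    list(genotypes = genotypes, genes = genes, expr = expr, gwas = gwas,
         truth = truth)
  })
}

#' Simulate transcription-factor regulons with planted geneset enrichment
#'
#' Each TF's targets are drawn uniformly from the gene universe, except for
#' `n_enriched_tfs` TFs whose draw weights members of the planted geneset by
#' `planted_enrichment_fold` (1 = no enrichment, the hypergeometric null).
#' Regulation modes are random signs.
#'
#' @param config A [sim_config()].
#' @param universe Character vector of gene ids.
#' @param geneset Planted geneset; defaults to a random draw of
#'   `enrichment_geneset_size` genes from the universe.
#' @param truth Truth list to extend (optional).
#' @return List with `regulons` (tibble tf_id/target/mode), `geneset` and
#'   `truth` (extended with `$tfs`).
#' @export
simulate_network <- function(config, universe, geneset = NULL, truth = list()) {
  stopifnot(inherits(config, "sim_config"))
  assert_that(max(config$regulon_size_range) < length(universe),
              "regulon size range exceeds the gene universe")
  with_seed(child_seed(config$seed, 3L), {
    if (is.null(geneset)) {
      geneset <- sample(universe, config$enrichment_geneset_size)
    }
    tf_ids <- sprintf("TF%03d", seq_len(config$n_tfs))
    enriched <- rep(FALSE, config$n_tfs)
    enriched[seq_len(min(config$n_enriched_tfs, config$n_tfs))] <- TRUE
    rng <- config$regulon_size_range
    sizes <- rng[1] + sample.int(rng[2] - rng[1] + 1, config$n_tfs,
                                 replace = TRUE) - 1L
    # enriched TFs hit the geneset at `fold` times the background rate k/N:
    # the number of geneset targets is Binomial(size, fold * k / N), so the
    # expected hit count is fold * size * k / N
    members <- intersect(geneset, universe)
    outside <- setdiff(universe, members)
    hit_rate <- min(1, config$planted_enrichment_fold *
                      length(members) / length(universe))
    edges <- purrr::map_dfr(seq_len(config$n_tfs), function(i) {
      if (enriched[i] && config$planted_enrichment_fold != 1) {
        n_hit <- min(rbinom(1, sizes[i], hit_rate), length(members), sizes[i])
        tgt <- c(sample(members, n_hit),
                 sample(outside, sizes[i] - n_hit))
      } else {
        tgt <- sample(universe, sizes[i])
      }
      tibble::tibble(
        tf_id = tf_ids[i], target = tgt,
        mode = sample(c(-1L, 1L), sizes[i], replace = TRUE)
      )
    })
    truth$tfs <- tibble::tibble(tf_id = tf_ids, enriched = enriched,
                                size = sizes)
    truth$geneset <- geneset
    list(regulons = validate_regulons(edges), geneset = geneset, truth = truth)
  })
}

#' Simulate a complete synthetic study
#'
#' Orchestrates [simulate_cohort()], [simulate_genotypes()] and
#' [simulate_network()] under one seed and assembles all artifacts plus the
#' combined planted truth.
#'
#' @param config A [sim_config()].
#' @return List with expr, metadata, genotypes, genes, gwas, regulons,
#'   genesets (named list; `planted` is the enrichment target), truth and
#'   the config.
#' @export
simulate_study <- function(config = sim_config()) {
  coh <- simulate_cohort(config)
  gen <- simulate_genotypes(config, coh$metadata, coh$expr, coh$truth)
  net <- simulate_network(config, rownames(gen$expr), truth = gen$truth)
  list(
    expr = gen$expr, metadata = coh$metadata, genotypes = gen$genotypes,
    genes = gen$genes, gwas = gen$gwas, regulons = net$regulons,
    genesets = list(planted = net$geneset), truth = net$truth, config = config
  )
}

#' Write all artifacts of a simulated study to plain-text fixture files
#'
#' Emits expression.tsv, metadata.tsv, genotypes.vcf, genes.bed,
#' gwas_loci.tsv, regulons.tsv, genesets.gmt and truth_genes.tsv into `dir`.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression(study$expr, file.path(dir, "expression.tsv"))
  write_metadata(study$metadata, file.path(dir, "metadata.tsv"))
  write_genotypes(study$genotypes, file.path(dir, "genotypes.vcf"))
  write_gene_annotation(study$genes, file.path(dir, "genes.bed"))
  write_gwas_loci(study$gwas, file.path(dir, "gwas_loci.tsv"))
  write_regulons(study$regulons, file.path(dir, "regulons.tsv"))
  write_genesets(study$genesets, file.path(dir, "genesets.gmt"))
  readr::write_tsv(study$truth$genes, file.path(dir, "truth_genes.tsv"),
                   progress = FALSE)
  invisible(dir)
}
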