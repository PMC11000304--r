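#' Construct and validate a genotype table
#'
#' A genotype table couples a SNP annotation tibble (`snp_id`, `chrom`,
#' `pos`, `ref`, `alt`; positions 0-based internally) with an integer dosage
#' matrix (SNP x sample) counting alternate alleles: 0 = Ref/Ref,
#' 1 = Alt/Ref, 2 = Alt/Alt. Minor allele frequencies are computed from the
#' dosages and always lie between 0 and 0.5.
#'
#' @param snps Tibble with columns snp_id, chrom, pos, ref, alt.
#' @param dosage Integer matrix in \{0,1,2\} (NA allowed for missing),
#'   rownames = snp ids, colnames = sample ids.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(snps, dosage) {
  snps <- tibble::as_tibble(snps)
  need <- c("snp_id", "chrom", "pos", "ref", "alt")
  assert_that(all(need %in% names(snps)),
              paste("snps needs columns:", paste(need, collapse = ", ")))
  assert_that(!anyDuplicated(snps$snp_id), "duplicated snp ids")
  assert_that(is.matrix(dosage), "dosage must be a matrix")
  assert_that(nrow(dosage) == nrow(snps), "dosage rows must match snps")
  assert_that(all(dosage %in% c(0L, 1L, 2L, NA)), "dosages must be 0/1/2 or NA")
  rownames(dosage) <- snps$snp_id
  snps$maf <- snp_maf(dosage)
  structure(list(snps = snps, dosage = dosage), class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d SNPs x %d samples\n",
              nrow(x$dosage), ncol(x$dosage)))
  print(utils::head(x$snps, 5))
  invisible(x)
}

# Minor allele frequency per SNP from alt-allele dosages (pairwise-complete).
snp_maf <- function(dosage) {
  af <- rowMeans(dosage, na.rm = TRUE) / 2
  unname(pmin(af, 1 - af))
}

#' Read biallelic genotypes from a VCF file
#'
#' Parses GT fields into alternate-allele dosages. Multi-allelic records are
#' skipped with a warning; SNPs with all genotypes missing are dropped.
#' Positions are converted from VCF's 1-based convention to the package's
#' 0-based internal convention.
#'
#' @param path Path to a VCF (4.x) file.
#' @param missing How to treat missing genotypes: `"drop"` keeps them as NA
#'   (tests use pairwise-complete samples), `"mean"` imputes the rounded
#'   mean dosage of the SNP.
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path, missing = c("drop", "mean")) {
  missing <- match.arg(missing)
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  assert_that(!is.null(gt), "VCF has no GT field")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  multi <- S4Vectors::elementNROWS(alt) > 1
  if (any(multi)) {
    rlang::warn(sprintf("skipping %d multi-allelic record(s)", sum(multi)))
  }
  snps <- tibble::tibble(
    snp_id = names(rr),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr) - 1L,  # VCF 1-based -> internal 0-based
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = vapply(as.list(alt), function(a) as.character(a)[1], character(1))
  )
  snps <- snps[!multi, , drop = FALSE]
  gt <- gt[!multi, , drop = FALSE]
  dosage <- apply(gt, c(1, 2), gt_to_dosage)
  if (nrow(snps) == 1) {
    dosage <- matrix(dosage, nrow = 1, dimnames = list(snps$snp_id, colnames(gt)))
  }
  all_missing <- rowSums(!is.na(dosage)) == 0
  if (any(all_missing)) {
    rlang::warn(sprintf("dropping %d SNP(s) with all genotypes missing",
                        sum(all_missing)))
    dosage <- dosage[!all_missing, , drop = FALSE]
    snps <- snps[!all_missing, , drop = FALSE]
  }
  if (missing == "mean" && anyNA(dosage)) {
    mu <- as.integer(round(rowMeans(dosage, na.rm = TRUE)))
    idx <- which(is.na(dosage), arr.ind = TRUE)
    dosage[idx] <- mu[idx[, 1]]
  }
  colnames(dosage) <- colnames(gt)
  genotype_table(snps, dosage)
}

# "0/0" -> 0, "0/1"/"1|0" -> 1, "1/1" -> 2, any missing allele -> NA.
gt_to_dosage <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_integer_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_integer_)
  sum(as.integer(alleles))
}

#' Write a genotype table to a minimal VCF 4.2 file
#'
#' Dosages are emitted as unphased GT calls (0/0, 0/1, 1/1, ./.);
#' internal 0-based positions are converted back to VCF's 1-based POS.
#'
#' @param geno A [genotype_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_table"))
  gt_codes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix(gt_codes[as.character(geno$dosage)], nrow = nrow(geno$dosage))
  gt[is.na(gt)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(geno$dosage)), collapse = "\t")
  )
  body <- cbind(
    geno$snps$chrom, geno$snps$pos + 1L, geno$snps$snp_id,
    geno$snps$ref, geno$snps$alt, ".", "PASS", ".", "GT", gt
  )
  lines <- c(header, apply(body, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}
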