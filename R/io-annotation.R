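#' Read gene models from a BED6 file
#'
#' BED coordinates (0-based half-open) are kept natively as the package's
#' internal convention. The transcription start site (TSS) is the 5' end of
#' the gene by strand: `start` for `+` genes, `end - 1` for `-` genes; the
#' transcription termination site (TTS) is the opposite end, so `tss > tts`
#' for minus-strand genes.
#'
#' @param path Path to a BED6 file (chrom, start, end, name, score, strand).
#' @return Tibble with gene_id, chrom, start, end, strand, tss, tts.
#' @export
read_gene_annotation <- function(path) {
  bed <- readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicdc", progress = FALSE)
  assert_that(!anyDuplicated(bed$name), "duplicated gene ids in BED")
  assert_that(all(bed$strand %in% c("+", "-")), "BED strand must be + or -")
  assert_that(all(bed$end > bed$start), "BED intervals must have end > start")
  tibble::tibble(
    gene_id = bed$name,
    chrom = bed$chrom,
    start = bed$start,
    end = bed$end,
    strand = bed$strand,
    tss = ifelse(bed$strand == "+", bed$start, bed$end - 1L),
    tts = ifelse(bed$strand == "+", bed$end - 1L, bed$start)
  )
}

#' Write gene models to BED6
#'
#' @param genes Gene annotation tibble from [read_gene_annotation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path) {
  bed <- tibble::tibble(
    chrom = genes$chrom, start = genes$start, end = genes$end,
    name = genes$gene_id, score = 0, strand = genes$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read genesets from a GMT file
#'
#' Standard GMT: one geneset per line — name, description, then
#' tab-separated member gene ids. Members are de-duplicated; genesets with
#' no members are skipped with a warning.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene ids.
#' @export
read_genesets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    name <- parts[1]
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      rlang::warn(sprintf("geneset '%s' has no members; skipped", name))
      next
    }
    out[[name]] <- members
  }
  out
}

#' Write genesets to a GMT file
#'
#' @param genesets Named list of character vectors.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genesets <- function(genesets, path) {
  lines <- vapply(names(genesets), function(nm) {
    paste(c(nm, nm, genesets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read transcription-factor regulons from a TSV edge list
#'
#' Columns: `tf_id`, `target_id`, `mode` (+1 activating / -1 repressing).
#' Self-loops (a TF targeting itself) are invalid.
#'
#' @param path Path to the edge-list TSV.
#' @return Tibble with columns tf_id, target, mode.
#' @export
read_regulons <- function(path) {
  edges <- readr::read_tsv(path, col_types = readr::cols(
    tf_id = readr::col_character(),
    target_id = readr::col_character(),
    mode = readr::col_integer()
  ), progress = FALSE)
  reg <- tibble::tibble(tf_id = edges$tf_id, target = edges$target_id,
                        mode = edges$mode)
  validate_regulons(reg)
}

#' Write regulons to a TSV edge list
#'
#' @param regulons Regulon tibble (tf_id, target, mode).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_regulons <- function(regulons, path) {
  validate_regulons(regulons)
  readr::write_tsv(
    tibble::tibble(tf_id = regulons$tf_id, target_id = regulons$target,
                   mode = regulons$mode),
    path, progress = FALSE)
  invisible(path)
}

validate_regulons <- function(regulons) {
  assert_that(all(c("tf_id", "target", "mode") %in% names(regulons)),
              "regulons need columns tf_id, target, mode")
  assert_that(all(regulons$mode %in% c(-1L, 1L)), "regulon mode must be +1 or -1")
  assert_that(!any(regulons$tf_id == regulons$target),
              "a TF may not be in its own target set")
  assert_that(nrow(regulons) > 0, "empty regulon table")
  dup <- duplicated(regulons[, c("tf_id", "target")])
  assert_that(!any(dup), "duplicated (tf, target) edges")
  tibble::as_tibble(regulons)
}

#' Read a GWAS risk-locus catalogue from TSV
#'
#' Columns: `locus_id`, `chrom`, `pos` (1-based in the file, converted to
#' the internal 0-based convention), `study_id`. Loci duplicated at the same
#' (chrom, pos) are de-duplicated keeping the first.
#'
#' @param path Path to the catalogue TSV.
#' @return Tibble with locus_id, chrom, pos, study_id.
#' @export
read_gwas_loci <- function(path) {
  loci <- readr::read_tsv(path, col_types = readr::cols(
    locus_id = readr::col_character(),
    chrom = readr::col_character(),
    pos = readr::col_integer(),
    study_id = readr::col_character()
  ), progress = FALSE)
  loci$pos <- loci$pos - 1L
  loci[!duplicated(loci[, c("chrom", "pos")]), , drop = FALSE]
}

#' Write a GWAS risk-locus catalogue to TSV
#'
#' @param loci GWAS locus tibble (internal 0-based positions).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gwas_loci <- function(loci, path) {
  out <- loci
  out$pos <- out$pos + 1L
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
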