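# Shared fixtures built in code; no data files on disk.

# Small deterministic metadata tibble covering both cohorts and all strata.
toy_metadata <- function() {
  tibble::tibble(
    sample_id = sprintf("S%02d", 1:12),
    cohort = rep(c("HV", "CLINIC"), each = 6),
    diagnosis = c(rep("NONE", 6), "BENIGN", "CANCER", "CANCER", "INELIGIBLE",
                  "BENIGN", "CANCER"),
    smoking_status = c("NV", "NV", "FS1", "FS2", "FS3", "CS",
                       "FS1", "FS2", "FS3", "CS", "CS", "FS1"),
    pack_years = c("PY1", "PY1", "PY2", "PY3", "PY4", "PY3",
                   "PY2", "PY3", "PY4", "PY4", "PY2", "PY3"),
    sex = rep(c("F", "M"), 6),
    age_class = rep(0:3, 3),
    batch = rep(0:1, 6),
    copd = c(rep("no", 6), "yes", "no", "unknown", "yes", "no", "no"),
    tissue = "nasal"
  )
}

# Write VCF text lines for given GT strings; returns the file path.
toy_vcf <- function(gt_rows, samples = sprintf("S%d", seq_len(ncol(gt_rows))),
                    chrom = "1", pos = seq_len(nrow(gt_rows)) * 100L,
                    alt = rep("G", nrow(gt_rows))) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(gt_rows)), function(i) {
    paste(c(chrom, pos[i], sprintf("v%03d", i), "A", alt[i], ".", "PASS", ".",
            "GT", gt_rows[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# Independent per-character GT oracle: counts "1" alleles in a GT string.
oracle_gt_dosage <- function(gt) {
  chars <- strsplit(gt, "")[[1]]
  if (any(chars == ".")) return(NA_integer_)
  sum(chars == "1")
}

# Exact upper-tail hypergeometric probability P(X >= q) by explicit
# log-binomial tail summation (independent of phyper's algorithm).
oracle_hyper_tail <- function(N, m, k, q) {
  hi <- min(m, k)
  if (q > hi) return(0)
  i <- max(q, 0):hi
  sum(exp(lchoose(k, i) + lchoose(N - k, m - i) - lchoose(N, m)))
}

# Brute-force iterative VIF pruning of one window using explicit lm() fits.
oracle_vif_prune_window <- function(dosage, maf, pos, vif_max = 20) {
  alive <- seq_len(nrow(dosage))
  repeat {
    if (length(alive) < 2) break
    r2 <- vapply(seq_along(alive), function(j) {
      y <- dosage[alive[j], ]
      if (stats::sd(y) == 0) return(1)
      others <- t(dosage[alive[-j], , drop = FALSE])
      fit <- stats::lm(y ~ others)
      suppressWarnings(stats::summary.lm(fit)$r.squared)
    }, numeric(1))
    vif <- 1 / pmax(1 - r2, .Machine$double.eps)
    if (max(vif) <= vif_max) break
    worst <- which(vif == max(vif))
    if (length(worst) > 1) {
      worst <- worst[order(maf[alive[worst]], -pos[alive[worst]])[1]]
    }
    alive <- alive[-worst]
  }
  alive
}

# Quiet wrappers: several calls emit coverage/tie messages by design.
quietly <- function(expr) suppressMessages(suppressWarnings(expr))
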