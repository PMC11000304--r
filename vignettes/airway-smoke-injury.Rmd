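---
title: "Methods: smoke-injury dynamics, risk scores and regulatory genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smoke-injury dynamics, risk scores and regulatory genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical methods: the
models, their assumptions, the tunable parameters, what the synthetic data
do and do not emulate, and the numerical and design choices that were
genuinely open.

## The scientific setting

Tobacco smoke alters gene expression across the whole exposed airway
epithelium, so nasal samples act as an accessible window on the injury.
After cessation, genes revert on very different timescales, and people
referred to a chest clinic differ from healthy volunteers both in overall
expression and in how their smoke response resolves. The package analyses a
two-cohort design: healthy volunteers (including never smokers, the
reference group) and clinic patients (current and former smokers only).
Smoking status is stratified as never (NV), former by cessation recency
(FS1 > 1 year, FS2 1–12 months, FS3 < 1 month) and current (CS); cumulative
exposure is categorised into four pack-years strata.

## Reversibility classification

For one gene with expression $y$ (variance-stabilised scale), the full
model is

$$y \sim \mathrm{CS} + \mathrm{FSS} + \mathrm{FS} + \text{confounders},$$

where CS is the 0/1 current-smoker indicator, FSS the 0/1 former-smoker
indicator and FS the 0–3 recency code (0 for never and current smokers; by
construction $\mathrm{CS}\cdot\mathrm{FSS}=0$). Age class, sex and batch
are always included. All $2^3$ subsets of the smoking terms are fitted by
ordinary least squares; under a uniform model prior, posterior model
probabilities use the BIC approximation
$p(M\mid y)\propto\exp(-\mathrm{BIC}_M/2)$. Assumptions: Gaussian,
homoscedastic errors per gene; additive confounders; independence across
samples. BIC was chosen over a specific g-prior because it needs no
hyper-parameter, is asymptotically consistent for model selection and is
exactly reproducible; a Zellner g-prior (`prior = "gprior"`, default
$g = n$, coefficients shrunk by $g/(1+g)$) is provided purely as a
sensitivity analysis.

Classes are groups of models: `{}` → US; `{CS}` → RR; `{CS,FS}` and
`{CS,FSS,FS}` → SR; `{CS,FSS}` → IR; `{FSS}`, `{FS}`, `{FSS,FS}` → CA.
This map encodes the verbal class definitions: RR means former smokers are
indistinguishable from never smokers; IR means former smokers keep the
current-smoker shift with no recency trend; SR means a recency gradient;
CA means only former smokers differ. A gene is assigned to the class with
the largest *aggregated* posterior (the sum over its models), which is the
class-level reading of "highest posterior probability"; the single best
model is also reported. Coefficients are Bayesian-model-averaged (zero in
models that exclude them), and the `strong` flag requires
$|\beta_{CS}| > 0.4$ for RR/SR/IR or $|\beta_{FSS}| > 0.25$ for CA —
absolute values, since both up- and down-regulated genes are of interest.
Both thresholds are arguments, not constants.

Numerical choices: residual sums of squares are floored at $10^{-12}$
before the log so that noiseless fits do not produce $-\infty$; among
models that fit exactly, the BIC penalty then prefers the smallest, which
is the intended parsimony behaviour. A gene with exactly constant
expression short-circuits to a point mass on the empty model. Exact
posterior ties (essentially only possible in degenerate inputs) break
toward the class whose smallest member model is smallest (US, RR, CA, IR,
SR) and are logged. A rank-deficient design is an error naming the
collinear columns; constant confounders (e.g. a single batch) are dropped
silently since they are absorbed by the intercept.

For the clinic cohort, which contains no never smokers, healthy-volunteer
never smokers are appended as the reference group — the same pragmatic
choice the two-cohort design forces on any analysis of this shape.

`compare_cohorts()` builds the 5×5 class-transition table over the shared
gene universe and derives *response genes*: strong in at least one cohort
and not unaffected in both. The published response-gene count is not an
exact arithmetic function of the published per-cohort counts, so the
membership rule is a documented, parameterised choice (`strong_in =
"any"` or `"both"`). The overlap of the two strong sets is tested against
independence with an uncorrected Pearson chi-squared on the 2×2 membership
table.

## Risk classifiers

Labels: the population target separates clinic patients (1) from healthy
volunteers (0); the clinic target separates cancer (1) from no cancer
(clinic-benign and healthy volunteers, 0). Ineligible diagnoses (tumours
of other histologies) are excluded from both. Features are response-gene
expression plus four numeric clinical covariates — sex 0/1, age class 0–3,
smoking status NV/FS1/FS2/FS3/CS → 0–4, pack-years → 0–3.

The model is an L1-penalised logistic regression fitted with glmnet; the
penalty is chosen at the minimum mean cross-validated binomial deviance
(`lambda.min`). Features are standardised internally on each training set
(glmnet's default), so genes and clinical covariates face comparable
penalties while coefficients stay on the original scale; the published
description is silent on scaling, and this is the choice that makes the
penalty exchangeable across feature types. The risk score is the linear
predictor (log-odds), and a sample is called positive when its score is at
or above the threshold.

`cross_validate()` runs repeated stratified K-fold CV (default 10×10;
folds are dealt round-robin within each class from a seeded shuffle, since
no fold-construction recipe is published). Within each fold the penalty is
re-selected on the training split only, so every sample is scored strictly
out-of-fold once per round. AUC-ROC is the trapezoid over the full ROC
(equal, up to floating point, to the Mann–Whitney statistic — a property
the tests assert); AUC-PR is average precision over threshold steps, which
is robust to ties. `operating_point()` returns the *largest* threshold
whose sensitivity reaches the target, i.e. the minimum false-positive rate
at that sensitivity. (A specification that asks for the "smallest"
threshold under this calling convention would be degenerate — every
sufficiently small threshold reaches any sensitivity — so the package
implements the only useful reading.)

Random-gene baselines redraw feature sets of the same size and reuse the
identical fold assignments, making baseline AUCs directly comparable.
Stability selection refits the model once per round on the full data at
that round's cross-validated penalty and keeps features with nonzero
coefficients in strictly more than 80% of rounds.

## Pathway metascores

The batch effect is removed per gene by OLS on the batch indicator, with
the gene's grand mean re-added ($y - X(X^\top X)^{-1}X^\top y + \bar y$).
A metascore is the unweighted mean of these residuals over the geneset
members present in the matrix (absent members are ignored; coverage is
reported; an empty intersection is an error naming the geneset). A
`zscore` flag standardises member genes first for users who prefer
scale-free averaging; the default keeps expression units. Note one
consequence of re-adding the grand mean: adding a constant shift to one
batch moves every metascore by a constant (the shifted grand mean) while
leaving all sample-to-sample structure, and hence every downstream
correlation, untouched. Spearman correlations with the risk scores are
computed separately for current smokers and long-term former smokers
(quit > 12 months, FS1), with two-sided p-values and conventional star
annotations; a constant metascore yields a missing correlation rather than
an error.

## Regulatory genetics

Internally all genomic coordinates are 0-based half-open: BED is consumed
natively, VCF positions are shifted by −1 on read and +1 on write. The TSS
is the 5′ end of the gene by strand, and cis windows are built on the
unstranded interval [gene start − W, gene end + W] with W = 500 kb, closed
on both ends — this realises "upstream of the TSS, downstream of the TTS"
symmetrically without strand case analysis.

Genotypes are alt-allele dosages 0/1/2 from biallelic GT fields;
multi-allelic records are skipped with a warning, missing genotypes stay
missing by default (pairwise-complete analyses) with an optional
mean-imputation flag, since real pipelines impute upstream. SNPs with MAF
≤ 1% are removed. LD pruning slides 50-SNP windows (step 5, the plink-like
convention; the published description fixes only the window size) and
iteratively removes the SNP with the largest VIF $=1/(1-R^2)$ until all
are ≤ 20 (equivalently $R^2 \le 0.95$); ties break by lower MAF, then
later position, and constant SNPs are removed as degenerate. The procedure
is idempotent.

The eQTL scan regresses expression on dosage plus fixed covariates (sex,
age, batch, smoking 0–4, pack-years 0–3). Implementation-wise, expression
and dosage are each residualised on the covariates once and the per-pair
t statistic comes from the residual correlation — algebraically identical
to the per-pair OLS t-test but orders of magnitude faster, and evaluated
in chunks so large pair lists never materialise huge matrices. Correction
is two-step: per-gene Bonferroni over the variants tested for that gene,
then Benjamini–Hochberg across the per-gene lead variants (smallest
adjusted p; ties break by raw p, then position). e-genes are leads at the
chosen FDR (default 10% here, matching the response-gene analysis; 1% is
the stricter published choice for transcriptome-wide e-gene counts).

The interaction test refits, per lead variant, expression on dosage,
smoking recoded 0/1/2 (never/former/current), their product and the
covariates, reading the two-sided t p-value on the product term. The
published covariate list for this test omits batch — most plausibly an
elision — so batch is included by default behind an argument. Designs in
which the interaction column is collinear (e.g. dosage constant within
smoking strata) are skipped with a log message.

GWAS linkage joins lead eQTL variants to catalogue loci on the same
chromosome within 500 kb whose genotyped locus SNP has in-sample dosage
$r^2 > 0.8$ with the lead variant. In-sample LD replaces the published
external UK reference panel: the package must be self-contained, and for
synthetic data in-sample LD is the ground truth. Loci without a genotyped
SNP at the locus position are counted as unlinked. Both constraints are
applied jointly; the alternative "nearest locus first" reading of the
published text is ambiguous and not used.

## Regulon enrichment and activity

Overrepresentation of a geneset (size $k$) in a TF's regulon (size $m$)
within a universe of $N$ genes uses the upper-tail hypergeometric
probability $P(X \ge q)$ (survival function at $q-1$), with BH correction
across TFs and a flag to skip adjustment when only a handful of
pre-selected TFs are tested. The universe defaults to the supplied gene
vector's length and is always a parameter: the published analysis itself
uses two slightly different universe sizes in different places, and its
"expected hits" column is not reproducible from its printed $m$, $k$, $N$
— so exact published p-values are deliberately not used as test targets;
the tests instead assert agreement with an exact combinatorial tail sum to
$10^{-12}$.

Because full network-inference-based activity scoring is out of scope, the
activity score is a documented simple surrogate: per sample, the mean over
regulon targets of the regulation-mode-signed z-scored expression
(constant genes contribute zero). Group differences use Welch's t-test
with conventional star levels.

## The synthetic study

`sim_config()` states the world once; a single seed determines everything
(sub-generators derive fixed child seeds, so a component re-run standalone
matches a full-study run). Cohort sizes and the smoking mix default to the
published cohort's composition (114 healthy volunteers, 299 clinic nasal
samples; 45/234/45/10/153 across NV/FS1/FS2/FS3/CS, with the clinic mix
renormalised without NV); gene and SNP counts are desk-scale (2,000 and
20,000) by design. Planted genes follow their class's mean structure
exactly; the SR decay is linear in the recency code (former-smoker mean =
never + β·FS/3), the simplest shape consistent with "intermediate levels"
and with the regression encoding. Effect sizes default to β_CS = 1,
β_FSS = 0.5 (comfortably above the 0.4/0.25 calling thresholds), residual
noise to sd 0.5, all in normalized-expression units. Sex/age (sd 0.1) and
batch (sd 0.3) act as additive per-gene Gaussian coefficients — magnitudes
are unpublished, so these are testability choices, large enough to matter
and small enough not to swamp the planted signal. A set of 100 genes
carries a unit clinic-vs-volunteer shift (the population-classifier
signal).

Genotypes are Hardy–Weinberg binomial dosages at a block-level MAF drawn
from [0.05, 0.5], arranged in LD blocks of 10 built by copying a founder
SNP and re-drawing each genotype with probability 0.05 — direct control of
within-block r² without a coalescent. Planted cis-eQTL add β·dosage at the
SNP nearest the target gene's TSS; planted interactions add
β·dosage·smoking(0/1/2). Half the GWAS catalogue sits on planted eQTL
variants (linkable by construction), half on random SNPs. Enriched TF
regulons draw their geneset hit count as Binomial(size, fold·k/N), so the
expected hit count is exactly fold times the background rate.

What the generator does *not* emulate: count-level noise and library-size
effects (expression is emitted already normalized), realistic LD decay and
allele-frequency spectra, population structure, correlated gene modules,
dropout or batch-by-covariate confounding beyond the additive shifts. A
green test therefore establishes that the algorithms are implemented
correctly and calibrated under their own assumptions — not that the
pipeline would reproduce any particular published cohort result. One
instructive interaction the generator *does* expose: because the cohorts
differ in age and smoking composition, demographic expression effects make
*any* gene set weakly cohort-informative, so a "random genes perform at
chance" check is only meaningful in the confounder-free configuration
(the acceptance test says so explicitly and draws baseline sets from the
signal-free remainder of the universe).

## Known limitations

- The BIC posterior is an approximation; with very small strata (e.g. few
  recent quitters) class boundaries between SR/IR/CA are soft, and weak
  genes drift toward CA calls that the strong-effect threshold then
  filters — interpret unthresholded class counts cautiously.
- The activity score is not a substitute for network-based activity
  inference; it ignores target overlap between TFs and mode uncertainty.
- In-sample LD on a few hundred samples is noisy near the r² = 0.8
  cutoff; linkage counts should be read as illustrative at desk scale.
- p-values from the Spearman correlation use the asymptotic
  approximation (`exact = FALSE`) because metascores can tie.
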