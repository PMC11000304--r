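# Internal helpers shared across modules.

# Deterministic child seed derivation: one global seed per run, sub-generators
# get fixed offsets so components can be re-run independently and still match
# a full-study run. Kept strictly below 2^31 - 1.
child_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  as.integer((abs(seed) * 1103L + k * 7919L) %% 2147483629)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) rlang::abort(msg)
  invisible(TRUE)
}

# Significance stars used in the figures: ns / * / ** / *** / ****.
p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p <= 1e-4 ~ "****",
    p <= 1e-3 ~ "***",
    p <= 1e-2 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

# Residual-maker: residuals of each column of Y on the column space of X
# (X must include an intercept column if one is wanted).
resid_on <- function(Y, X) {
  qr.resid(qr(X), Y)
}
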