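# Internal helpers shared across modules.

# Derive a reproducible sub-seed for a pipeline stage from a master seed.
# Kept strictly below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) {
    return(NULL)
  }
  as.integer((as.double(seed) + 1000003 * stage) %% 2147483647L)
}

# Run `expr` under `seed` without touching the caller's RNG state.
# A NULL seed uses (and advances) the current RNG stream.
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

# Index of the global-MAF bin a frequency falls in. MAF lives in [0, 0.5];
# the top bin is closed so maf = 0.5 does not fall off the end.
maf_bin_index <- function(maf, width = 0.02) {
  n_bins <- ceiling(0.5 / width)
  pmin(floor(maf / width), n_bins - 1L)
}

# Count reporting for filtering steps: every filter says what went in and
# what survived.
log_counts <- function(step, n_in, n_out, what = "SNPs") {
  inform(sprintf("%s: %d %s in, %d retained, %d dropped",
                 step, n_in, what, n_out, n_in - n_out))
}

# The eight functional categories SNPs are matched on.
functional_categories <- function() {
  c("frameshift", "nonsense", "missense", "untranslated",
    "near-gene", "intron", "coding-synonymous", "unknown")
}

`%||%` <- rlang::`%||%`
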