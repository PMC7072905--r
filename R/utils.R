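# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed when one is supplied, leaving the caller's
# RNG stream untouched; otherwise use the current stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", name, min, max))
  }
  invisible(x)
}

# Canonical genotype codes used throughout: "AA" (parent-A / SN265-type
# homozygote), "BB" (parent-B / LTH-type), "HET", or NA for missing.
GENOTYPES <- c("AA", "BB", "HET")

# Numeric genotype score used by the QTL machinery: AA -> -1, BB -> +1,
# HET -> 0, missing -> NA.
geno_score <- function(g) {
  out <- rep(NA_real_, length(g))
  out[g == "AA"] <- -1
  out[g == "BB"] <- 1
  out[g == "HET"] <- 0
  out
}

# Homozygote coding for recombination-fraction estimation: AA -> 0, BB -> 1,
# HET and missing -> NA.
homo_code <- function(g) {
  out <- rep(NA_real_, length(g))
  out[g == "AA"] <- 0
  out[g == "BB"] <- 1
  out
}

default_chrom_names <- function(n) sprintf("chr%02d", seq_len(n))

named_lengths <- function(lengths, what) {
  if (is.null(lengths) || length(lengths) == 0L || any(!is.finite(lengths)) ||
      any(lengths <= 0)) {
    abort(sprintf("`%s` must be a vector of positive lengths.", what))
  }
  if (is.null(names(lengths))) {
    names(lengths) <- default_chrom_names(length(lengths))
  }
  lengths
}
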