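# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles are written as plain loops, deliberately unlike the vectorised
# implementations they check.

# Run-length smoothing oracle: classify each window position by scanning runs
# with explicit loops; returns the final genotype-per-window vector after
# absorbing missing runs, collapsing HET transition ribbons, and absorbing
# short runs -- the same semantics as detect_breakpoints(), coded naively.
oracle_smooth_windows <- function(g, min_run, max_het_transition = 20) {
  runs <- list()
  i <- 1
  while (i <= length(g)) {
    j <- i
    while (j < length(g) && identical(g[j + 1], g[i])) j <- j + 1
    runs[[length(runs) + 1]] <- list(val = g[i], from = i, to = j)
    i <- j + 1
  }
  # absorb missing runs (first such run each pass)
  repeat {
    k <- NULL
    for (m in seq_along(runs)) if (is.na(runs[[m]]$val)) { k <- m; break }
    if (is.null(k) || length(runs) == 1) break
    runs <- oracle_absorb(runs, k)
  }
  # collapse HET ribbons between opposite homozygotes
  repeat {
    k <- NULL
    for (m in seq_along(runs)) {
      r <- runs[[m]]
      if (m > 1 && m < length(runs) && identical(r$val, "HET") &&
          (r$to - r$from + 1) <= max_het_transition &&
          runs[[m - 1]]$val %in% c("AA", "BB") &&
          runs[[m + 1]]$val %in% c("AA", "BB") &&
          runs[[m - 1]]$val != runs[[m + 1]]$val) { k <- m; break }
    }
    if (is.null(k)) break
    len <- runs[[k]]$to - runs[[k]]$from + 1
    half <- runs[[k]]$from + floor((len - 1) / 2)
    runs[[k - 1]]$to <- half
    runs[[k + 1]]$from <- half + 1
    runs <- runs[-k]
  }
  # absorb short runs, smallest first
  repeat {
    lens <- vapply(runs, function(r) r$to - r$from + 1, numeric(1))
    short <- which(lens < min_run)
    if (length(short) == 0 || length(runs) == 1) break
    k <- short[order(lens[short])][1]
    runs <- oracle_absorb(runs, k)
  }
  out <- rep(NA_character_, length(g))
  for (r in runs) out[r$from:r$to] <- r$val
  out
}

oracle_absorb <- function(runs, k) {
  n <- length(runs)
  if (k > 1 && k < n && identical(runs[[k - 1]]$val, runs[[k + 1]]$val)) {
    runs[[k - 1]]$to <- runs[[k + 1]]$to
    runs <- runs[-c(k, k + 1)]
  } else if (k > 1) {
    runs[[k - 1]]$to <- runs[[k]]$to
    runs <- runs[-k]
  } else {
    runs[[k + 1]]$from <- runs[[k]]$from
    runs <- runs[-k]
  }
  runs
}

# Exhaustive cell-merge oracle for the bin map: genotype per cell midpoint per
# line, then a left-to-right scan pasting genotype vectors into string keys.
oracle_bin_count <- function(segments, grid_bp, chrom_len) {
  lines <- sort(unique(segments$line))
  starts <- seq(1, chrom_len, by = grid_bp)
  ends <- pmin(starts + grid_bp - 1, chrom_len)
  keys <- character(length(starts))
  for (c_i in seq_along(starts)) {
    mid <- (starts[c_i] + ends[c_i]) / 2
    gvec <- character(length(lines))
    for (l_i in seq_along(lines)) {
      s <- segments[segments$line == lines[l_i], ]
      g <- NA_character_
      for (r in seq_len(nrow(s))) {
        if (mid >= s$start_bp[r] && mid <= s$end_bp[r]) g <- s$genotype[r]
      }
      gvec[l_i] <- ifelse(is.na(g), ".", g)
    }
    keys[c_i] <- paste(gvec, collapse = "|")
  }
  n_bins <- 1
  for (c_i in seq_along(keys)[-1]) {
    if (keys[c_i] != keys[c_i - 1]) n_bins <- n_bins + 1
  }
  n_bins
}

# Two-interval chain enumeration oracle for conditional RIL genotype
# probabilities: P(BB at the middle position | flanking genotypes).
oracle_p_bb <- function(g_left, g_right, d_left, d_right, map_function) {
  trans <- function(from, to, d) {
    r <- if (map_function == "haldane") (1 - exp(-d / 50)) / 2
         else tanh(d / 50) / 2
    R <- 2 * r / (1 + 2 * r)
    if (from == to) 1 - R else R
  }
  w <- c(AA = 0, BB = 0)
  for (x in c("AA", "BB")) {
    w[x] <- trans(g_left, x, d_left) * trans(x, g_right, d_right)
  }
  unname(w["BB"] / sum(w))
}

# Brute-force substitution-mapping oracle: widest contiguous marker interval
# on which every line is both constant and phenotype-concordant.
oracle_delimit <- function(geno, classes, positions) {
  n_mark <- ncol(geno)
  best <- NULL
  for (i in seq_len(n_mark)) {
    for (j in i:n_mark) {
      ok <- TRUE
      for (l in seq_len(nrow(geno))) {
        expect <- if (classes[l] == "tolerant") "BB" else "AA"
        for (m in i:j) if (geno[l, m] != expect) ok <- FALSE
      }
      if (ok && (is.null(best) || (j - i) > (best[2] - best[1]))) best <- c(i, j)
    }
  }
  best
}

# Small synthetic population shared by several tests.
make_test_population <- function(n_lines = 50, seed = 42,
                                 chrom_lengths_bp = c(chr01 = 20e6),
                                 genetic_lengths_cM = c(chr01 = 80),
                                 mean_depth = 8, error_rate = 0.01) {
  snps <- simulate_parents(chrom_lengths_bp, 0.33, seed = seed)
  mosaics <- simulate_ril_mosaics(genetic_lengths_cM, n_lines, 11,
                                  seed = seed + 1,
                                  chrom_lengths_bp = chrom_lengths_bp)
  calls <- sample_origin_calls(mosaics, snps, mean_depth, error_rate,
                               seed = seed + 2)
  list(snps = snps, mosaics = mosaics, calls = calls)
}

# True breakpoints (bp) of each line on one chromosome from the simulated
# mosaic segments.
true_breakpoints <- function(mosaics, chrom) {
  segs <- mosaics[mosaics$chrom == chrom, ]
  out <- list()
  for (ln in unique(segs$line)) {
    e <- segs$end_bp[segs$line == ln]
    out[[ln]] <- head(e, -1)
  }
  out
}
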