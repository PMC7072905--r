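# Interval mapping and composite interval mapping over a bin map:
# conditional genotype probabilities, Haley-Knott regression scans,
# permutation thresholds, 1.5-LOD support intervals, and QTL reports.

# Recombinant-line fraction between RIL genotypes separated by d cM.
ril_transition_R <- function(d, map_function) {
  r <- inverse_map_function(d, map_function)
  2 * r / (1 + 2 * r)
}

#' Conditional genotype probabilities on a cM grid
#'
#' Evaluates, for every line and every grid position (fixed `step_cM` step
#' plus all marker positions), the probability of the BB genotype given the
#' nearest flanking non-missing homozygous bin genotypes. Transitions between
#' positions d cM apart use the selfed-RIL relation `R(d) = 2r/(1+2r)` with
#' `r` from the inverse map function; HET and missing marker genotypes are
#' uninformative, and a position with no typed flank gets probability 1/2.
#'
#' @param bin_map A `bin_map`.
#' @param genetic_map A `genetic_map` over the same bins.
#' @param step_cM Grid step in cM (default 1).
#' @return A `prob_grid` object: list with `positions` (tibble `chrom`,
#'   `pos_cM`, `pos_bp` linearly interpolated between markers) and `p_bb`
#'   (matrix lines x positions).
#' @export
genotype_probabilities <- function(bin_map, genetic_map, step_cM = 1) {
  stopifnot_scalar_number(step_cM, "step_cM", min = 1e-9)
  map_function <- attr(genetic_map, "map_function") %||% "kosambi"
  lines <- rownames(bin_map$geno)
  code <- matrix(homo_code(bin_map$geno), nrow = nrow(bin_map$geno),
                 dimnames = dimnames(bin_map$geno))
  pos_list <- list()
  pbb_list <- list()
  for (chrom in unique(genetic_map$chrom)) {
    gm <- genetic_map[genetic_map$chrom == chrom, , drop = FALSE]
    mpos <- gm$pos_cM
    grid <- sort(unique(c(seq(0, max(mpos), by = step_cM), mpos)))
    if (length(mpos) > 1L) {
      bp <- approx(mpos, gm$pos_bp, xout = grid, rule = 2, ties = mean)$y
    } else {
      bp <- rep(gm$pos_bp[1], length(grid))
    }
    idx <- match(gm$bin_id, colnames(code))
    pbb <- matrix(0.5, nrow = length(lines), ncol = length(grid),
                  dimnames = list(lines, NULL))
    for (i in seq_along(lines)) {
      o <- code[i, idx]
      typed <- which(!is.na(o))
      if (length(typed) == 0L) next
      tm <- mpos[typed]
      tg <- o[typed]
      li <- findInterval(grid, tm)
      ri <- li + 1L
      has_l <- li >= 1L
      has_r <- ri <= length(tm)
      dl <- grid - tm[pmax(li, 1L)]
      dr <- tm[pmin(ri, length(tm))] - grid
      Rl <- ril_transition_R(pmax(dl, 0), map_function)
      Rr <- ril_transition_R(pmax(dr, 0), map_function)
      gl <- tg[pmax(li, 1L)]
      gr <- tg[pmin(ri, length(tm))]
      wBB <- ifelse(has_l, ifelse(gl == 1, 1 - Rl, Rl), 1) *
        ifelse(has_r, ifelse(gr == 1, 1 - Rr, Rr), 1)
      wAA <- ifelse(has_l, ifelse(gl == 0, 1 - Rl, Rl), 1) *
        ifelse(has_r, ifelse(gr == 0, 1 - Rr, Rr), 1)
      pbb[i, ] <- wBB / (wBB + wAA)
    }
    pos_list[[chrom]] <- tibble(chrom = chrom, pos_cM = grid, pos_bp = bp)
    pbb_list[[chrom]] <- pbb
  }
  structure(list(positions = dplyr::bind_rows(pos_list),
                 p_bb = do.call(cbind, pbb_list),
                 map_function = map_function),
            class = "prob_grid")
}

#' @exportS3Method base::print
print.prob_grid <- function(x, ...) {
  cat(sprintf("<prob_grid> %d lines x %d positions on %d chromosome(s)\n",
              nrow(x$p_bb), nrow(x$positions),
              length(unique(x$positions$chrom))))
  invisible(x)
}

# Coerce a phenotype tibble (line, value) or named numeric to a vector
# aligned with `lines`; lines without a phenotype are dropped by the caller.
phenotype_vector <- function(phenotype, lines) {
  if (is.numeric(phenotype) && !is.null(names(phenotype))) {
    y <- phenotype
  } else {
    ph <- as_tibble(phenotype)
    if (!all(c("line", "value") %in% names(ph))) {
      abort("`phenotype` needs columns `line` and `value` (or be a named numeric).")
    }
    if ("trait" %in% names(ph) && length(unique(ph$trait)) > 1L) {
      abort("`phenotype` contains several traits; filter to one first.")
    }
    ph <- ph |>
      dplyr::group_by(.data$line) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
    y <- setNames(ph$value, ph$line)
  }
  y[intersect(lines, names(y))]
}

# Covariate marker scores: AA -> -1, BB -> +1, HET -> 0, missing imputed to
# the marker mean.
marker_scores <- function(bin_map) {
  s <- matrix(geno_score(bin_map$geno), nrow = nrow(bin_map$geno),
              dimnames = dimnames(bin_map$geno))
  for (j in seq_len(ncol(s))) {
    nas <- is.na(s[, j])
    if (any(nas)) s[nas, j] <- if (all(nas)) 0 else mean(s[!nas, j])
  }
  s
}

# Haley-Knott scan of y on each column of X, adjusting for covariate matrix
# C0 (may be NULL). Returns lod, additive effect, and flags.
hk_scan_core <- function(X, y, C0, lod_ceiling) {
  n <- length(y)
  C <- cbind(rep(1, n), C0)
  qC <- qr(C)
  ry <- qr.resid(qC, y)
  rss0 <- sum(ry^2)
  p <- ncol(X)
  if (rss0 < 1e-10) {
    return(list(lod = rep(0, p), a = rep(0, p), zero_variance = TRUE,
                capped = rep(FALSE, p)))
  }
  RX <- qr.resid(qC, X)
  sxx <- colSums(RX^2)
  sxy <- colSums(RX * ry)
  ok <- sxx > 1e-12
  a <- ifelse(ok, sxy / sxx, 0)
  rss1 <- rss0 - ifelse(ok, sxy^2 / sxx, 0)
  capped <- rss1 <= rss0 * 1e-12
  lod <- ifelse(capped, lod_ceiling,
                pmax(0, n / 2 * log10(rss0 / pmax(rss1, 1e-300))))
  lod <- pmin(lod, lod_ceiling)
  list(lod = lod, a = a, zero_variance = FALSE, capped = capped)
}

#' Select background covariate markers for CIM
#'
#' Greedy forward selection of bin markers by residual-sum-of-squares
#' reduction of the phenotype regression, up to `max_cov` markers. During a
#' CIM scan, selected covariates within the exclusion window of the test
#' position are dropped position-wise by [scan_qtl()].
#'
#' @param bin_map A `bin_map`.
#' @param genetic_map Matching `genetic_map` (provides covariate cM
#'   positions).
#' @param phenotype Phenotype tibble (`line`, `value`) or named numeric.
#' @param max_cov Maximum number of covariate markers (default 5).
#' @return Tibble `bin_id`, `chrom`, `pos_cM`, ordered by selection.
#' @export
select_cim_covariates <- function(bin_map, genetic_map, phenotype,
                                  max_cov = 5) {
  stopifnot_scalar_number(max_cov, "max_cov", min = 0)
  lines <- rownames(bin_map$geno)
  y <- phenotype_vector(phenotype, lines)
  S <- marker_scores(bin_map)[names(y), , drop = FALSE]
  chosen <- integer(0)
  if (max_cov >= 1) {
    for (step in seq_len(max_cov)) {
      C <- cbind(rep(1, length(y)),
                 if (length(chosen)) S[, chosen, drop = FALSE])
      qC <- qr(C)
      ry <- qr.resid(qC, y)
      RS <- qr.resid(qC, S)
      sxx <- colSums(RS^2)
      sxy <- colSums(RS * ry)
      gain <- ifelse(sxx > 1e-12, sxy^2 / sxx, 0)
      gain[chosen] <- 0
      j <- which.max(gain)
      if (gain[j] <= 1e-12) break
      chosen <- c(chosen, j)
    }
  }
  ids <- colnames(S)[chosen]
  tibble(bin_id = ids,
         chrom = genetic_map$chrom[match(ids, genetic_map$bin_id)],
         pos_cM = genetic_map$pos_cM[match(ids, genetic_map$bin_id)])
}

#' Genome scan by Haley-Knott regression (IM or CIM)
#'
#' At every grid position the phenotype is regressed on the expected
#' genotype score `x = P(BB) - P(AA)`; for CIM, background covariate markers
#' are included, dropping any covariate within `exclusion_window_cM` of the
#' test position (same chromosome). The LOD is
#' `(n/2) log10(RSS_reduced / RSS_full)` where the reduced model omits only
#' `x`; the additive effect is the regression coefficient of `x` (trait
#' units per allele substitution, positive when the BB / LTH allele
#' increases the trait).
#'
#' @param prob_grid A `prob_grid` from [genotype_probabilities()].
#' @param phenotype Phenotype tibble (`line`, `value`) or named numeric;
#'   at least 10 phenotyped lines are required.
#' @param method `"im"` or `"cim"`.
#' @param bin_map,genetic_map Required for `method = "cim"` unless
#'   `covariates` is given.
#' @param covariates Optional covariate tibble from
#'   [select_cim_covariates()]; if `NULL` under CIM it is selected here.
#' @param max_cov,exclusion_window_cM CIM controls (defaults 5 and 10 cM).
#' @param lod_ceiling Cap for infinite LODs from perfect fits (default 50).
#' @return A `qtl_scan` tibble: `chrom`, `pos_cM`, `pos_bp`, `lod`,
#'   `add_effect`, `capped`; attributes `n`, `method`, `covariates`,
#'   `zero_variance`.
#' @export
scan_qtl <- function(prob_grid, phenotype, method = c("im", "cim"),
                     bin_map = NULL, genetic_map = NULL, covariates = NULL,
                     max_cov = 5, exclusion_window_cM = 10,
                     lod_ceiling = 50) {
  method <- match.arg(method)
  lines <- rownames(prob_grid$p_bb)
  y <- phenotype_vector(phenotype, lines)
  if (length(y) < 10L) abort("Phenotype must be defined for at least 10 lines.")
  keep <- match(names(y), lines)
  X <- 2 * prob_grid$p_bb[keep, , drop = FALSE] - 1
  pos <- prob_grid$positions
  if (method == "cim" && is.null(covariates)) {
    if (is.null(bin_map) || is.null(genetic_map)) {
      abort("CIM needs `bin_map` and `genetic_map` (or an explicit `covariates` table).")
    }
    covariates <- select_cim_covariates(bin_map, genetic_map, phenotype,
                                        max_cov)
  }
  if (method == "im") covariates <- NULL
  n_cov <- if (is.null(covariates)) 0L else nrow(covariates)
  lod <- numeric(nrow(pos))
  a <- numeric(nrow(pos))
  capped <- logical(nrow(pos))
  zero_var <- FALSE
  if (n_cov == 0L) {
    res <- hk_scan_core(X, unname(y), NULL, lod_ceiling)
    lod <- res$lod
    a <- res$a
    capped <- res$capped
    zero_var <- res$zero_variance
  } else {
    S <- marker_scores(bin_map)[names(y), covariates$bin_id, drop = FALSE]
    active <- matrix(TRUE, nrow = nrow(pos), ncol = n_cov)
    for (k in seq_len(n_cov)) {
      active[, k] <- !(pos$chrom == covariates$chrom[k] &
                         abs(pos$pos_cM - covariates$pos_cM[k]) <=
                           exclusion_window_cM)
    }
    key <- apply(active, 1, paste, collapse = "")
    for (kk in unique(key)) {
      rows <- which(key == kk)
      act <- active[rows[1], ]
      res <- hk_scan_core(X[, rows, drop = FALSE], unname(y),
                          if (any(act)) S[, act, drop = FALSE] else NULL,
                          lod_ceiling)
      lod[rows] <- res$lod
      a[rows] <- res$a
      capped[rows] <- res$capped
      zero_var <- zero_var || res$zero_variance
    }
  }
  out <- tibble(chrom = pos$chrom, pos_cM = pos$pos_cM, pos_bp = pos$pos_bp,
                lod = lod, add_effect = a, capped = capped)
  class(out) <- c("qtl_scan", class(out))
  attr(out, "n") <- length(y)
  attr(out, "method") <- method
  attr(out, "covariates") <- covariates
  attr(out, "zero_variance") <- zero_var
  out
}

#' Genome-wide permutation LOD threshold
#'
#' Permutes the phenotype across lines `n_perm` times, rescans the genome
#' each time (covariate selection is redone per permutation under CIM, so
#' the null stays exchangeable), and returns the empirical `1 - alpha`
#' quantile of the genome-wide maximum LOD.
#'
#' @inheritParams scan_qtl
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param alpha Genome-wide type-I level (default 0.05).
#' @param seed Optional integer seed; a fixed seed gives an identical
#'   threshold.
#' @param ... Further arguments passed to [scan_qtl()].
#' @return The LOD threshold (numeric scalar) with attribute `max_lods`,
#'   the permutation maxima.
#' @export
permutation_threshold <- function(prob_grid, phenotype, n_perm = 1000,
                                  alpha = 0.05, seed = NULL, method = "im",
                                  ...) {
  stopifnot_scalar_number(n_perm, "n_perm", min = 100)
  stopifnot_scalar_number(alpha, "alpha", min = 1e-12, max = 1 - 1e-12)
  lines <- rownames(prob_grid$p_bb)
  y <- phenotype_vector(phenotype, lines)
  max_lods <- with_seed_if(seed, {
    vapply(seq_len(n_perm), function(i) {
      yp <- setNames(sample(unname(y)), names(y))
      max(scan_qtl(prob_grid, yp, method = method, ...)$lod)
    }, numeric(1))
  })
  thr <- as.numeric(quantile(max_lods, 1 - alpha, names = FALSE))
  attr(thr, "max_lods") <- max_lods
  thr
}

#' LOD-drop support interval around a peak
#'
#' The widest interval around the peak on which the LOD stays within `drop`
#' units of the peak LOD: its bounds are the outermost positions (within
#' `bounds`, by default the whole chromosome) whose LOD is at least
#' `peak_lod - drop`, so noise dips between them do not truncate the
#' interval. Endpoints are linearly interpolated to the threshold crossing
#' between grid positions (both in cM and bp) and truncated at chromosome
#' ends.
#'
#' @param scan A `qtl_scan`.
#' @param chrom,peak_cM Peak location; defaults to the genome-wide maximum.
#' @param drop LOD drop defining the interval (default 1.5).
#' @param bounds Optional integer pair restricting the search to a range of
#'   grid indices on the peak's chromosome (used to keep multiple QTL
#'   records on one chromosome distinct).
#' @return One-row tibble: `chrom`, `peak_cM`, `peak_bp`, `peak_lod`,
#'   `ci_lo_cM`, `ci_hi_cM`, `ci_lo_bp`, `ci_hi_bp`; attribute `flat` when
#'   the curve never drops and the whole chromosome is returned.
#' @export
support_interval <- function(scan, chrom = NULL, peak_cM = NULL, drop = 1.5,
                             bounds = NULL) {
  stopifnot_scalar_number(drop, "drop", min = 1e-12)
  if (is.null(chrom)) {
    i_all <- which.max(scan$lod)
    chrom <- scan$chrom[i_all]
  }
  s <- scan[scan$chrom == chrom, , drop = FALSE]
  bounds <- bounds %||% c(1L, nrow(s))
  i <- if (is.null(peak_cM)) {
    bounds[1] - 1L + which.max(s$lod[bounds[1]:bounds[2]])
  } else {
    which.min(abs(s$pos_cM - peak_cM))
  }
  thr <- s$lod[i] - drop
  interp <- function(j_out, j_in) {
    t <- (thr - s$lod[j_out]) / (s$lod[j_in] - s$lod[j_out])
    c(cM = s$pos_cM[j_out] + t * (s$pos_cM[j_in] - s$pos_cM[j_out]),
      bp = s$pos_bp[j_out] + t * (s$pos_bp[j_in] - s$pos_bp[j_out]))
  }
  above <- which(s$lod >= thr)
  above <- above[above >= bounds[1] & above <= bounds[2]]
  j <- min(above)
  lo <- if (j == bounds[1]) c(cM = s$pos_cM[j], bp = s$pos_bp[j]) else interp(j - 1L, j)
  k <- max(above)
  hi <- if (k == bounds[2]) c(cM = s$pos_cM[k], bp = s$pos_bp[k]) else interp(k + 1L, k)
  out <- tibble(chrom = chrom, peak_cM = s$pos_cM[i], peak_bp = s$pos_bp[i],
                peak_lod = s$lod[i],
                ci_lo_cM = unname(lo["cM"]), ci_hi_cM = unname(hi["cM"]),
                ci_lo_bp = unname(lo["bp"]), ci_hi_bp = unname(hi["bp"]))
  attr(out, "flat") <- (j == bounds[1] && k == bounds[2] &&
                          min(s$lod[bounds[1]:bounds[2]]) >= thr)
  out
}

#' Percentage of phenotypic variance explained by a LOD score
#'
#' `100 (1 - 10^(-2 LOD / n))`, the standard conversion for an n-line
#' population.
#'
#' @param lod LOD score(s).
#' @param n Number of lines.
#' @return Variance explained, in percent.
#' @examples
#' var_explained(7.38, 144) # ~21.0
#' @export
var_explained <- function(lod, n) {
  100 * (1 - 10^(-2 * lod / n))
}

#' Report QTLs above a threshold
#'
#' One record per chromosome-wise LOD peak at or above `threshold`; two
#' above-threshold stretches on a chromosome are distinct QTLs only when the
#' LOD dips below `threshold - dip` between them. Each record carries the
#' peak, the `drop`-LOD support interval (cM and Mb), the LOD, variance
#' explained, additive effect, and the parent contributing the
#' trait-increasing allele.
#'
#' @param scan A `qtl_scan`.
#' @param threshold LOD threshold (from [permutation_threshold()] or fixed,
#'   e.g. 3).
#' @param drop Support-interval LOD drop (default 1.5).
#' @param dip Required dip below `threshold - dip` separating peaks
#'   (default 1).
#' @param n Line count for the variance conversion; defaults to the scan's.
#' @param name_prefix QTL name prefix (default "qLTG").
#' @param parents Named character `c(low = , high = )`: parents carrying the
#'   trait-decreasing (AA) and trait-increasing (BB) genome.
#' @return A `qtl_report` tibble (possibly empty): `qtl`, `chrom`,
#'   `peak_cM`, `peak_Mb`, `ci_lo_cM`, `ci_hi_cM`, `ci_lo_Mb`, `ci_hi_Mb`,
#'   `lod`, `var_pct`, `add_effect`, `positive_allele`.
#' @export
qtl_report <- function(scan, threshold, drop = 1.5, dip = 1,
                       n = attr(scan, "n"), name_prefix = "qLTG",
                       parents = c(low = "SN265", high = "LTH")) {
  records <- list()
  for (chrom in unique(scan$chrom)) {
    s <- scan[scan$chrom == chrom, , drop = FALSE]
    above <- which(s$lod >= threshold)
    if (length(above) == 0L) next
    # runs of consecutive above-threshold grid indices
    run_id <- cumsum(c(1L, diff(above) > 1L))
    runs <- split(above, run_id)
    # merge runs not separated by a dip below threshold - dip
    cluster <- integer(length(runs))
    cluster[1] <- 1L
    if (length(runs) > 1L) {
      for (m in 2:length(runs)) {
        gap <- (max(runs[[m - 1L]]) + 1L):(min(runs[[m]]) - 1L)
        cluster[m] <- if (min(s$lod[gap]) < threshold - dip)
          cluster[m - 1L] + 1L else cluster[m - 1L]
      }
    }
    cluster_runs <- split(runs, cluster)
    peaks <- vapply(cluster_runs, function(rr) {
      idx <- unlist(rr)
      idx[which.max(s$lod[idx])]
    }, integer(1))
    # restrict each record's support interval to its own cluster region,
    # splitting neighbouring clusters at the LOD minimum between them
    cluster_bounds <- matrix(c(1L, nrow(s)), length(peaks), 2, byrow = TRUE)
    if (length(peaks) > 1L) {
      for (m in seq_len(length(peaks) - 1L)) {
        gap <- (max(unlist(cluster_runs[[m]])) + 1L):
          (min(unlist(cluster_runs[[m + 1L]])) - 1L)
        cut <- gap[which.min(s$lod[gap])]
        cluster_bounds[m, 2] <- cut
        cluster_bounds[m + 1L, 1] <- cut + 1L
      }
    }
    chrom_num <- sub("^[^0-9]*0?", "", chrom)
    for (q in seq_along(peaks)) {
      i <- peaks[q]
      ci <- support_interval(scan, chrom = chrom, peak_cM = s$pos_cM[i],
                             drop = drop, bounds = cluster_bounds[q, ])
      suffix <- if (length(peaks) > 1L) letters[q] else ""
      records[[length(records) + 1L]] <- tibble(
        qtl = paste0(name_prefix, chrom_num, suffix),
        chrom = chrom,
        peak_cM = s$pos_cM[i], peak_Mb = s$pos_bp[i] / 1e6,
        ci_lo_cM = ci$ci_lo_cM, ci_hi_cM = ci$ci_hi_cM,
        ci_lo_Mb = ci$ci_lo_bp / 1e6, ci_hi_Mb = ci$ci_hi_bp / 1e6,
        lod = s$lod[i], var_pct = var_explained(s$lod[i], n),
        add_effect = s$add_effect[i],
        positive_allele = unname(
          if (s$add_effect[i] > 0) parents["high"] else parents["low"]))
    }
  }
  out <- if (length(records)) dplyr::bind_rows(records) else
    tibble(qtl = character(), chrom = character(), peak_cM = numeric(),
           peak_Mb = numeric(), ci_lo_cM = numeric(), ci_hi_cM = numeric(),
           ci_lo_Mb = numeric(), ci_hi_Mb = numeric(), lod = numeric(),
           var_pct = numeric(), add_effect = numeric(),
           positive_allele = character())
  class(out) <- c("qtl_report", class(out))
  attr(out, "threshold") <- as.numeric(threshold)
  out
}

#' Add support-interval widths to a QTL table
#'
#' Convenience helper computing `width_Mb` (and `width_cM` when both cM
#' bounds are present) from the interval bounds of a QTL report or
#' compatible reference table.
#'
#' @param qtl_tbl Tibble with `ci_lo_Mb`/`ci_hi_Mb` (and optionally
#'   `ci_lo_cM`/`ci_hi_cM`).
#' @return The table with `width_Mb` (and `width_cM`) appended.
#' @export
qtl_interval_widths <- function(qtl_tbl) {
  out <- dplyr::mutate(qtl_tbl, width_Mb = .data$ci_hi_Mb - .data$ci_lo_Mb)
  if (all(c("ci_lo_cM", "ci_hi_cM") %in% names(qtl_tbl))) {
    out <- dplyr::mutate(out, width_cM = .data$ci_hi_cM - .data$ci_lo_cM)
  }
  out
}
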