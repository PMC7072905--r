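# Genetic-map estimation over bin markers: adjacent-pair recombination
# fractions, the Haldane-Waddington selfed-RIL correction, and map functions.

#' Estimate the observed recombinant fraction between two markers
#'
#' Counts lines whose homozygous genotypes are discordant between the two
#' markers, over lines homozygous at both (HET or missing lines are
#' excluded). Raw fractions above 0.5 are capped at 0.4999 and flagged, as
#' the RIL correction is undefined beyond 0.5.
#'
#' @param g1,g2 Equal-length genotype vectors over lines ("AA", "BB", "HET"
#'   or NA).
#' @return One-row tibble: `R_obs`, `n_informative`, `capped` (logical),
#'   `undefined` (TRUE when no line is informative; `R_obs` is then NA).
#' @export
estimate_rf <- function(g1, g2) {
  if (length(g1) != length(g2)) abort("`g1` and `g2` must have equal length.")
  x <- homo_code(g1)
  y <- homo_code(g2)
  inf <- !is.na(x) & !is.na(y)
  n_inf <- sum(inf)
  if (n_inf == 0L) {
    return(tibble(R_obs = NA_real_, n_informative = 0L, capped = FALSE,
                  undefined = TRUE))
  }
  raw <- sum(x[inf] != y[inf]) / n_inf
  capped <- raw > 0.5
  tibble(R_obs = if (capped) 0.4999 else raw, n_informative = n_inf,
         capped = capped, undefined = FALSE)
}

#' Haldane-Waddington correction for selfed RILs
#'
#' In a population of fully inbred selfed lines the fraction of recombinant
#' lines between two loci is `R = 2r / (1 + 2r)`, where `r` is the
#' per-meiosis recombination fraction; this inverts that relation,
#' `r = R / (2 (1 - R))`.
#'
#' @param R_obs Observed recombinant fraction(s), in `[0, 0.5]`.
#' @return Meiotic recombination fraction(s) `r`.
#' @examples
#' ril_correct(1 / 3) # 0.25
#' @export
ril_correct <- function(R_obs) {
  if (any(R_obs < 0 | R_obs > 0.5, na.rm = TRUE)) {
    abort("`R_obs` must lie in [0, 0.5]; cap upstream with `estimate_rf()`.")
  }
  R_obs / (2 * (1 - R_obs))
}

#' Convert a recombination fraction to map distance
#'
#' Haldane: `d = -50 ln(1 - 2r)`; Kosambi: `d = 25 ln((1 + 2r) / (1 - 2r))`.
#' Fractions at or above 0.5 (infinite distance) are reported as
#' `ceiling_cM` with attribute `capped`.
#'
#' @param r Recombination fraction(s) in `[0, 0.5]`.
#' @param map_function `"kosambi"` (default; standard for rice) or
#'   `"haldane"`.
#' @param ceiling_cM Distance assigned to unlinked pairs (default 50).
#' @return Numeric distance(s) in cM, attribute `capped` marking ceilinged
#'   entries.
#' @examples
#' map_distance(0.25, "haldane") # 34.657
#' map_distance(0.25, "kosambi") # 27.465
#' @export
map_distance <- function(r, map_function = c("kosambi", "haldane"),
                         ceiling_cM = 50) {
  map_function <- match.arg(map_function)
  if (any(r < 0 | r > 0.5, na.rm = TRUE)) abort("`r` must lie in [0, 0.5].")
  d <- switch(map_function,
              haldane = -50 * log(1 - 2 * r),
              kosambi = 25 * log((1 + 2 * r) / (1 - 2 * r)))
  capped <- !is.na(d) & (d > ceiling_cM | !is.finite(d))
  d[capped] <- ceiling_cM
  attr(d, "capped") <- capped
  d
}

# Inverse map functions: cM -> r.
inverse_map_function <- function(d, map_function = c("kosambi", "haldane")) {
  map_function <- match.arg(map_function)
  switch(map_function,
         haldane = (1 - exp(-d / 50)) / 2,
         kosambi = tanh(d / 50) / 2)
}

#' Build a genetic map over ordered bin markers
#'
#' Marker order is the physical order; each adjacent interval's distance is
#' `map_distance(ril_correct(estimate_rf(...)))` and positions accumulate
#' from 0 cM per chromosome. Intervals with no informative line get distance
#' 0 and are flagged.
#'
#' @param bin_map A `bin_map` from [build_bin_map()].
#' @inheritParams map_distance
#' @return A tibble (class `genetic_map`): `chrom`, `bin_id`, `pos_cM`,
#'   `pos_bp` (bin midpoint), `d_cM` (distance from the previous marker),
#'   `n_informative`, `flagged`; attribute `map_function`.
#' @export
build_genetic_map <- function(bin_map, map_function = c("kosambi", "haldane"),
                              ceiling_cM = 50) {
  map_function <- match.arg(map_function)
  bins <- bin_map$bins
  code <- matrix(homo_code(bin_map$geno), nrow = nrow(bin_map$geno),
                 dimnames = dimnames(bin_map$geno))
  out <- purrr::map_dfr(unique(bins$chrom), function(chrom) {
    idx <- which(bins$chrom == chrom)
    n <- length(idx)
    d <- numeric(n)
    n_inf <- integer(n)
    flag <- logical(n)
    if (n > 1L) {
      for (k in 2:n) {
        x <- code[, idx[k - 1L]]
        y <- code[, idx[k]]
        ok <- !is.na(x) & !is.na(y)
        n_inf[k] <- sum(ok)
        if (n_inf[k] == 0L) {
          d[k] <- 0
          flag[k] <- TRUE
        } else {
          R <- sum(x[ok] != y[ok]) / n_inf[k]
          if (R > 0.5) {
            R <- 0.4999
            flag[k] <- TRUE
          }
          dk <- map_distance(ril_correct(R), map_function, ceiling_cM)
          flag[k] <- flag[k] || attr(dk, "capped")
          d[k] <- as.numeric(dk)
        }
      }
    }
    tibble(chrom = chrom, bin_id = bins$bin_id[idx], pos_cM = cumsum(d),
           pos_bp = bins$midpoint_bp[idx], d_cM = d,
           n_informative = n_inf, flagged = flag)
  })
  class(out) <- c("genetic_map", class(out))
  attr(out, "map_function") <- map_function
  out
}
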