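# Shared small fixture: fully-typed two-chromosome bin map with a strong QTL
# on chr01 and nothing on chr02.
make_scan_fixture <- function(n = 60, seed = 99) {
  withr::with_seed(seed, {
    mk_chrom <- function(chrom, n_bins, spacing_bp) {
      tibble::tibble(
        bin_id = sprintf("%s_%02d", chrom, seq_len(n_bins)), chrom = chrom,
        start_bp = (seq_len(n_bins) - 1) * spacing_bp + 1,
        end_bp = seq_len(n_bins) * spacing_bp,
        midpoint_bp = (seq_len(n_bins) - 0.5) * spacing_bp)
    }
    bins <- dplyr::bind_rows(mk_chrom("chr01", 12, 5e5), mk_chrom("chr02", 8, 5e5))
    mos <- simulate_ril_mosaics(c(chr01 = 60, chr02 = 40), n_lines = n,
                                n_generations = 11, seed = seed,
                                chrom_lengths_bp = c(chr01 = 6e6, chr02 = 4e6))
    lines <- unique(mos$line)
    geno <- matrix(NA_character_, n, nrow(bins),
                   dimnames = list(lines, bins$bin_id))
    for (ln in lines) {
      for (ch in c("chr01", "chr02")) {
        segs <- mos[mos$line == ln & mos$chrom == ch, ]
        idx <- bins$chrom == ch
        geno[ln, idx] <- ltgmap:::mosaic_genotype_at(segs, bins$midpoint_bp[idx])
      }
    }
    bm <- ltgmap:::new_bin_map(bins, geno)
    gm <- build_genetic_map(bm, "haldane")
    list(mosaics = mos, bin_map = bm, genetic_map = gm)
  })
}

test_that("genotype probabilities honour typed markers and match the chain oracle", {
  fx <- make_scan_fixture()
  pg <- genotype_probabilities(fx$bin_map, fx$genetic_map, step_cM = 1)
  # at a typed marker the observed genotype has probability 1
  gm <- fx$genetic_map
  for (ln in sample(rownames(fx$bin_map$geno), 5)) {
    for (k in sample(nrow(gm), 4)) {
      g_obs <- fx$bin_map$geno[ln, gm$bin_id[k]]
      if (is.na(g_obs) || g_obs == "HET") next
      col <- which(pg$positions$chrom == gm$chrom[k] &
                     abs(pg$positions$pos_cM - gm$pos_cM[k]) < 1e-9)[1]
      expect_equal(unname(pg$p_bb[ln, col]), ifelse(g_obs == "BB", 1, 0))
    }
  }
  # untyped line: probability 1/2 everywhere
  geno2 <- fx$bin_map$geno
  geno2["RIL001", ] <- NA_character_
  bm2 <- ltgmap:::new_bin_map(fx$bin_map$bins, geno2)
  pg2 <- genotype_probabilities(bm2, fx$genetic_map, step_cM = 2)
  expect_true(all(pg2$p_bb["RIL001", ] == 0.5))
  # two-interval chain oracle at interior grid points
  mf <- pg$map_function
  for (ln in sample(rownames(fx$bin_map$geno), 4)) {
    o <- ltgmap:::homo_code(fx$bin_map$geno[ln, gm$bin_id[gm$chrom == "chr01"]])
    typed <- which(!is.na(o))
    if (length(typed) < 2) next
    m1 <- typed[1]
    m2 <- typed[2]
    cm <- gm$pos_cM[gm$chrom == "chr01"]
    mid <- (cm[m1] + cm[m2]) / 2
    col <- which(pg$positions$chrom == "chr01" &
                   abs(pg$positions$pos_cM - mid) ==
                     min(abs(pg$positions$pos_cM[pg$positions$chrom == "chr01"] - mid)))[1]
    d_l <- pg$positions$pos_cM[col] - cm[m1]
    d_r <- cm[m2] - pg$positions$pos_cM[col]
    if (d_l < 0 || d_r < 0) next
    want <- oracle_p_bb(c("AA", "BB")[o[m1] + 1], c("AA", "BB")[o[m2] + 1],
                        d_l, d_r, mf)
    expect_equal(unname(pg$p_bb[ln, col]), want, tolerance = 1e-12)
  }
})

test_that("a single fully-typed marker reproduces the closed-form LOD", {
  fx <- make_scan_fixture()
  pg <- genotype_probabilities(fx$bin_map, fx$genetic_map, step_cM = 1)
  col <- which(pg$positions$chrom == "chr01" &
                 abs(pg$positions$pos_cM - fx$genetic_map$pos_cM[5]) < 1e-9)[1]
  withr::with_seed(7, {
    x <- 2 * pg$p_bb[, col] - 1  # typed marker column: p is 0/1
    y <- x + rnorm(length(x), 0, 1)
  })
  names(y) <- rownames(pg$p_bb)
  sc <- scan_qtl(pg, y, method = "im")
  # closed form at the same column from the observed R^2
  r2 <- summary(lm(y ~ x))$r.squared
  want <- length(y) / 2 * log10(1 / (1 - r2))
  expect_equal(sc$lod[col], want, tolerance = 1e-9)
  # n = 20 and R^2 = 1/2 gives LOD = 10 log10(2) = 3.0103: construct a
  # phenotype with that exact fit on a balanced marker
  x20 <- rep(c(-1, 1), each = 10)
  y20 <- x20 + rep(c(-1, 1), 10) # residual SS equals model SS -> R^2 = 0.5
  names(y20) <- rownames(pg$p_bb)[1:20]
  r2_20 <- summary(lm(y20 ~ x20))$r.squared
  expect_equal(r2_20, 0.5)
  expect_equal(20 / 2 * log10(1 / (1 - r2_20)), 3.0103, tolerance = 1e-4)
})

test_that("LOD is invariant to affine phenotype rescaling and null scans stay low", {
  fx <- make_scan_fixture(n = 80)
  pg <- genotype_probabilities(fx$bin_map, fx$genetic_map, step_cM = 2)
  withr::with_seed(17, y <- rnorm(80))
  names(y) <- rownames(pg$p_bb)
  sc <- scan_qtl(pg, y, method = "im")
  sc2 <- scan_qtl(pg, 3.5 * y + 40, method = "im")
  expect_equal(sc2$lod, sc$lod, tolerance = 1e-9)
  expect_equal(sc2$add_effect, 3.5 * sc$add_effect, tolerance = 1e-9)
  # phenotype independent of genotype: genome-wide LOD stays small
  expect_lt(max(sc$lod), 3.5)
})

test_that("degenerate phenotypes are flagged rather than scored", {
  fx <- make_scan_fixture()
  pg <- genotype_probabilities(fx$bin_map, fx$genetic_map, step_cM = 2)
  # zero phenotypic variance
  y0 <- setNames(rep(5, nrow(pg$p_bb)), rownames(pg$p_bb))
  sc0 <- scan_qtl(pg, y0, method = "im")
  expect_true(all(sc0$lod == 0))
  expect_true(attr(sc0, "zero_variance"))
  # y identical to a marker score: capped at the LOD ceiling with a flag
  yx <- setNames(2 * pg$p_bb[, 3] - 1, rownames(pg$p_bb))
  scx <- scan_qtl(pg, yx, method = "im", lod_ceiling = 40)
  expect_equal(max(scx$lod), 40)
  expect_true(any(scx$capped))
  # fewer than 10 phenotyped lines rejected
  expect_error(scan_qtl(pg, yx[1:5], method = "im"), "10")
})

test_that("CIM with no covariates equals IM, and covariates respect the window", {
  fx <- make_scan_fixture(n = 70, seed = 31)
  pg <- genotype_probabilities(fx$bin_map, fx$genetic_map, step_cM = 2)
  ph <- simulate_phenotypes(fx$mosaics,
                            tibble::tibble(chrom = "chr01", pos_bp = 3e6,
                                           weight = 1),
                            residual_sd = 18, seed = 5)
  im <- scan_qtl(pg, ph, method = "im")
  cim0 <- scan_qtl(pg, ph, method = "cim", bin_map = fx$bin_map,
                   genetic_map = fx$genetic_map, max_cov = 0)
  expect_equal(cim0$lod, im$lod, tolerance = 1e-12)
  # the nearest marker to a strong QTL on another chromosome is picked first
  ph2 <- simulate_phenotypes(fx$mosaics,
                             tibble::tibble(chrom = "chr02", pos_bp = 2e6,
                                            weight = 1),
                             residual_sd = 25, seed = 6)
  cov <- select_cim_covariates(fx$bin_map, fx$genetic_map, ph2, max_cov = 3)
  expect_equal(cov$chrom[1], "chr02")
  expect_lt(abs(fx$bin_map$bins$midpoint_bp[match(cov$bin_id[1],
                                                  fx$bin_map$bins$bin_id)] - 2e6),
            1e6)
  # a covariate within the exclusion window cannot inflate its own position:
  # LOD at the covariate marker equals the IM LOD there (covariate dropped)
  cim <- scan_qtl(pg, ph2, method = "cim", bin_map = fx$bin_map,
                  genetic_map = fx$genetic_map, max_cov = 1,
                  exclusion_window_cM = 10)
  gm2 <- fx$genetic_map
  cov_pos <- cov$pos_cM[1]
  near <- which(pg$positions$chrom == "chr02" &
                  abs(pg$positions$pos_cM - cov_pos) <= 1e-9)
  im2 <- scan_qtl(pg, ph2, method = "im")
  expect_equal(cim$lod[near], im2$lod[near], tolerance = 1e-9)
})

test_that("permutation thresholds are reproducible and monotone in alpha", {
  fx <- make_scan_fixture(n = 40, seed = 55)
  pg <- genotype_probabilities(fx$bin_map, fx$genetic_map, step_cM = 2)
  withr::with_seed(3, y <- rnorm(40))
  names(y) <- rownames(pg$p_bb)
  t1 <- permutation_threshold(pg, y, n_perm = 100, alpha = 0.05, seed = 8)
  t2 <- permutation_threshold(pg, y, n_perm = 100, alpha = 0.05, seed = 8)
  expect_equal(as.numeric(t1), as.numeric(t2))
  t01 <- permutation_threshold(pg, y, n_perm = 100, alpha = 0.01, seed = 8)
  expect_gte(as.numeric(t01), as.numeric(t1))
})

test_that("support intervals interpolate the LOD-drop crossing", {
  # triangular LOD peak 6.0 at 50 cM, slope 0.5 per cM -> [47, 53]
  pos <- 0:100
  lod <- pmax(0, 6 - 0.5 * abs(pos - 50))
  sc <- tibble::tibble(chrom = "chr01", pos_cM = pos, pos_bp = pos * 1e5,
                       lod = lod, add_effect = 1, capped = FALSE)
  class(sc) <- c("qtl_scan", class(sc))
  attr(sc, "n") <- 144
  ci <- support_interval(sc, drop = 1.5)
  expect_equal(ci$ci_lo_cM, 47)
  expect_equal(ci$ci_hi_cM, 53)
  expect_equal(ci$ci_lo_bp, 47e5)
  # peak at position 0 -> one-sided interval
  lod0 <- pmax(0, 6 - 0.5 * pos)
  sc0 <- dplyr::mutate(sc, lod = lod0)
  class(sc0) <- c("qtl_scan", class(sc0))
  ci0 <- support_interval(sc0, drop = 1.5)
  expect_equal(ci0$ci_lo_cM, 0)
  expect_equal(ci0$ci_hi_cM, 3)
  # flat curve: whole chromosome, flagged
  scf <- dplyr::mutate(sc, lod = 2)
  class(scf) <- c("qtl_scan", class(scf))
  cif <- support_interval(scf, drop = 1.5)
  expect_true(attr(cif, "flat"))
  expect_equal(c(cif$ci_lo_cM, cif$ci_hi_cM), c(0, 100))
})

test_that("QTL reports apply the variance formula and allele-sign convention", {
  pos <- 0:100
  mk_scan <- function(lod, a) {
    sc <- tibble::tibble(chrom = "chr10", pos_cM = pos, pos_bp = pos * 2e5,
                         lod = lod, add_effect = a, capped = FALSE)
    class(sc) <- c("qtl_scan", class(sc))
    attr(sc, "n") <- 144
    sc
  }
  lod <- pmax(0, 7.38 - 0.4 * abs(pos - 40))
  rep1 <- qtl_report(mk_scan(lod, 12), threshold = 3)
  expect_equal(nrow(rep1), 1)
  expect_equal(rep1$lod, 7.38)
  expect_equal(rep1$var_pct, 21.0, tolerance = 0.05)
  expect_equal(rep1$positive_allele, "LTH")
  expect_equal(rep1$qtl, "qLTG10")
  rep2 <- qtl_report(mk_scan(lod, -9.3), threshold = 3)
  expect_equal(rep2$positive_allele, "SN265")
  # all LOD below threshold -> empty report
  expect_equal(nrow(qtl_report(mk_scan(rep(1, 101), 1), threshold = 3)), 0)
  # two peaks separated by a deep dip are distinct records with letter suffixes
  lod2 <- pmax(pmax(0, 5 - 0.5 * abs(pos - 20)), pmax(0, 6 - 0.5 * abs(pos - 80)))
  rep3 <- qtl_report(mk_scan(lod2, 5), threshold = 3, dip = 1)
  expect_equal(rep3$qtl, c("qLTG10a", "qLTG10b"))
  # a shallow dip keeps one record
  lod3 <- pmax(lod2, 2.5)
  rep4 <- qtl_report(mk_scan(lod3, 5), threshold = 3, dip = 1)
  expect_equal(nrow(rep4), 1)
})

test_that("the variance-explained conversion matches its closed form", {
  expect_equal(var_explained(7.38, 144), 100 * (1 - 10^(-2 * 7.38 / 144)))
  expect_equal(var_explained(0, 144), 0)
})
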