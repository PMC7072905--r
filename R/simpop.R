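# Synthetic RIL population generator: parents, single-seed-descent mosaics,
# low-coverage parental-origin calls, and additive multi-QTL phenotypes.

#' Simulate a parental SNP set
#'
#' Draws biallelic SNP positions that distinguish the two inbred parents of a
#' RIL cross, uniformly along each chromosome. Positions are sorted and
#' deduplicated, so at high densities the realised site count can fall below
#' `length * density`.
#'
#' @param chrom_lengths_bp Named numeric vector of chromosome lengths in bp.
#'   Unnamed vectors are labelled `chr01`, `chr02`, ...
#' @param snp_density_per_kb Expected SNPs per kb (default 0.332, the density
#'   of ~124k parent-distinguishing SNPs over a ~373 Mb rice genome).
#' @param seed Optional integer seed; a fixed seed gives a bit-identical set.
#' @return A tibble with columns `chrom`, `pos` (1-based bp, strictly
#'   increasing within chromosome), `allele_A` and `allele_B` (the SN265-like
#'   and LTH-like base at the site).
#' @examples
#' simulate_parents(c(chr01 = 1e6), snp_density_per_kb = 0.1, seed = 1)
#' @export
simulate_parents <- function(chrom_lengths_bp, snp_density_per_kb = 0.332,
                             seed = NULL) {
  chrom_lengths_bp <- named_lengths(chrom_lengths_bp, "chrom_lengths_bp")
  stopifnot_scalar_number(snp_density_per_kb, "snp_density_per_kb", min = 1e-12)
  bases <- c("A", "C", "G", "T")
  with_seed_if(seed, {
    purrr::imap_dfr(as.list(chrom_lengths_bp), function(len, chrom) {
      n <- max(1L, round(len * snp_density_per_kb / 1000))
      pos <- sort(unique(ceiling(runif(n, 0, len))))
      ref <- sample(bases, length(pos), replace = TRUE)
      # alternate allele differs from the reference base at every site
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
      tibble(chrom = chrom, pos = as.integer(pos),
             allele_A = ref, allele_B = unname(alt))
    })
  })
}

# --- haplotype machinery -----------------------------------------------------
# A haplotype along one chromosome is a step function stored as segment end
# positions (cM, ascending, last == chromosome length) and a parental origin
# (0 = parent A, 1 = parent B) per segment. Segment i covers
# (end[i-1], end[i]].

hap_pure <- function(L, origin) list(end = L, origin = as.integer(origin))

hap_extract <- function(h, a, b) {
  starts <- c(0, h$end[-length(h$end)])
  idx <- which(h$end > a & starts < b)
  list(end = pmin(h$end[idx], b), origin = h$origin[idx])
}

hap_merge_runs <- function(end, origin) {
  if (length(origin) > 1L) {
    keep <- c(origin[-1L] != origin[-length(origin)], TRUE)
    end <- end[keep]
    origin <- origin[keep]
  }
  list(end = end, origin = origin)
}

# One meiosis: crossover count ~ Poisson(L/100) (Haldane, no interference),
# crossover positions uniform, random starting strand.
hap_meiosis <- function(h1, h2, L) {
  ncx <- rpois(1L, L / 100)
  first <- runif(1) < 0.5
  if (ncx == 0L) return(if (first) h1 else h2)
  cx <- sort(runif(ncx, 0, L))
  bounds <- c(0, cx, L)
  haps <- list(h1, h2)
  cur <- if (first) 1L else 2L
  end <- numeric(0)
  origin <- integer(0)
  for (k in seq_len(length(bounds) - 1L)) {
    piece <- hap_extract(haps[[cur]], bounds[k], bounds[k + 1L])
    end <- c(end, piece$end)
    origin <- c(origin, piece$origin)
    cur <- 3L - cur
  }
  hap_merge_runs(end, origin)
}

# Overlay the two haplotypes of a diploid into genotype segments.
hap_diplotype <- function(h1, h2) {
  end <- sort(unique(c(h1$end, h2$end)))
  mid <- (c(0, end[-length(end)]) + end) / 2
  o1 <- h1$origin[findInterval(mid, h1$end) + 1L]
  o2 <- h2$origin[findInterval(mid, h2$end) + 1L]
  g <- c("AA", "HET", "BB")[o1 + o2 + 1L]
  if (length(g) > 1L) {
    keep <- c(g[-1L] != g[-length(g)], TRUE)
    end <- end[keep]
    g <- g[keep]
  }
  list(end = end, genotype = g)
}

#' Simulate RIL genome mosaics by single-seed descent
#'
#' Starting from the F1 of two inbred parents, each line is selfed for
#' `n_generations - 1` rounds of single-seed descent. Every meiosis draws a
#' Poisson number of crossovers per chromosome (expectation = length in
#' Morgans) with uniform positions and no interference. The final-generation
#' diploid genotype mosaic of each line is returned.
#'
#' @param genetic_lengths_cM Named numeric vector of chromosome genetic
#'   lengths (cM).
#' @param n_lines Number of RILs.
#' @param n_generations Filial generation of the returned lines (11 = F11,
#'   the generation genotyped in the SN265 x LTH population). Must be >= 2.
#' @param seed Optional integer seed.
#' @param chrom_lengths_bp Optional named physical lengths (bp); when given,
#'   segment boundaries are also reported in bp assuming a uniform cM/bp rate
#'   per chromosome, which downstream call sampling and phenotype simulation
#'   require.
#' @return A tibble of genotype segments: `line`, `chrom`, `start_cM`,
#'   `end_cM`, `genotype` ("AA"/"BB"/"HET"), and `start_bp`/`end_bp` when
#'   `chrom_lengths_bp` is supplied. Segments tile each chromosome and
#'   adjacent segments differ in genotype.
#' @examples
#' simulate_ril_mosaics(c(chr01 = 100), n_lines = 2, n_generations = 6, seed = 1)
#' @export
simulate_ril_mosaics <- function(genetic_lengths_cM, n_lines,
                                 n_generations = 11, seed = NULL,
                                 chrom_lengths_bp = NULL) {
  genetic_lengths_cM <- named_lengths(genetic_lengths_cM, "genetic_lengths_cM")
  stopifnot_scalar_number(n_lines, "n_lines", min = 1)
  stopifnot_scalar_number(n_generations, "n_generations", min = 2)
  if (!is.null(chrom_lengths_bp)) {
    chrom_lengths_bp <- named_lengths(chrom_lengths_bp, "chrom_lengths_bp")
    if (!identical(names(chrom_lengths_bp), names(genetic_lengths_cM))) {
      abort("`chrom_lengths_bp` must name the same chromosomes as `genetic_lengths_cM`.")
    }
  }
  line_ids <- sprintf("RIL%03d", seq_len(n_lines))
  with_seed_if(seed, {
    purrr::map_dfr(line_ids, function(id) {
      purrr::imap_dfr(as.list(genetic_lengths_cM), function(L, chrom) {
        h1 <- hap_pure(L, 0L)
        h2 <- hap_pure(L, 1L)
        for (gen in seq_len(n_generations - 1L)) {
          g1 <- hap_meiosis(h1, h2, L)
          g2 <- hap_meiosis(h1, h2, L)
          h1 <- g1
          h2 <- g2
        }
        d <- hap_diplotype(h1, h2)
        out <- tibble(line = id, chrom = chrom,
                      start_cM = c(0, d$end[-length(d$end)]),
                      end_cM = d$end, genotype = d$genotype)
        if (!is.null(chrom_lengths_bp)) {
          Lbp <- chrom_lengths_bp[[chrom]]
          bnd <- round(d$end / L * Lbp)
          bnd[length(bnd)] <- Lbp
          out$start_bp <- c(1, bnd[-length(bnd)] + 1)
          out$end_bp <- bnd
        }
        out
      })
    })
  })
}

# Genotype of one line at given bp positions on one chromosome.
mosaic_genotype_at <- function(segments, pos_bp) {
  idx <- findInterval(pos_bp - 0.5, segments$end_bp) + 1L
  bad <- idx > nrow(segments)
  if (any(bad)) abort("Position outside the simulated chromosome.")
  segments$genotype[idx]
}

#' Sample low-coverage parental-origin calls over a SNP set
#'
#' Emulates the per-site genotyping signal of low-coverage resequencing: the
#' read depth at each line x site is Poisson(`mean_depth`); depth zero yields
#' a missing call, otherwise the call is the parental origin of the segment
#' carrying the site, flipped with probability `error_rate`. Sites inside
#' heterozygous segments emit either parent with probability 1/2.
#'
#' @param mosaics Segment tibble from [simulate_ril_mosaics()] including
#'   `start_bp`/`end_bp` columns.
#' @param snps Parental SNP tibble from [simulate_parents()].
#' @param mean_depth Mean sequencing depth (default 7.75, the mean RIL
#'   resequencing depth of the SN265 x LTH population).
#' @param error_rate Per-call flip probability in `[0, 0.5)`.
#' @param seed Optional integer seed.
#' @return An `origin_calls` object: a list with `snps` (the input SNP
#'   tibble), `calls` (character matrix, lines x sites, entries "A", "B" or
#'   NA) and `chrom_lengths_bp`.
#' @export
sample_origin_calls <- function(mosaics, snps, mean_depth = 7.75,
                                error_rate = 0.01, seed = NULL) {
  stopifnot_scalar_number(mean_depth, "mean_depth", min = 0)
  stopifnot_scalar_number(error_rate, "error_rate", min = 0, max = 0.5 - 1e-12)
  if (!all(c("start_bp", "end_bp") %in% names(mosaics))) {
    abort("`mosaics` must carry physical coordinates (pass `chrom_lengths_bp` to `simulate_ril_mosaics()`).")
  }
  lines <- unique(mosaics$line)
  snps <- dplyr::arrange(snps, .data$chrom, .data$pos)
  n_snp <- nrow(snps)
  chrom_lengths <- tapply(mosaics$end_bp, mosaics$chrom, max)
  chrom_lengths <- setNames(as.numeric(chrom_lengths), names(chrom_lengths))
  snp_split <- split(seq_len(n_snp), snps$chrom)
  calls <- matrix(NA_character_, nrow = length(lines), ncol = n_snp,
                  dimnames = list(lines, NULL))
  with_seed_if(seed, {
    for (ln in lines) {
      truth <- rep(NA_character_, n_snp)
      segs <- mosaics[mosaics$line == ln, , drop = FALSE]
      for (chrom in names(snp_split)) {
        j <- snp_split[[chrom]]
        g <- mosaic_genotype_at(segs[segs$chrom == chrom, , drop = FALSE],
                                snps$pos[j])
        truth[j] <- dplyr::case_when(g == "AA" ~ "A", g == "BB" ~ "B",
                                     TRUE ~ NA_character_)
        het <- j[is.na(truth[j])]
        if (length(het)) {
          truth[het] <- ifelse(runif(length(het)) < 0.5, "A", "B")
        }
      }
      depth <- rpois(n_snp, mean_depth)
      flip <- runif(n_snp) < error_rate
      obs <- ifelse(flip, ifelse(truth == "A", "B", "A"), truth)
      obs[depth == 0L] <- NA_character_
      calls[ln, ] <- obs
    }
  })
  new_origin_calls(snps, calls, chrom_lengths)
}

new_origin_calls <- function(snps, calls, chrom_lengths_bp) {
  structure(list(snps = snps, calls = calls,
                 chrom_lengths_bp = chrom_lengths_bp),
            class = "origin_calls")
}

#' @exportS3Method base::print
print.origin_calls <- function(x, ...) {
  cat(sprintf("<origin_calls> %d lines x %d SNP sites on %d chromosome(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$snps$chrom))))
  frac_na <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * frac_na))
  invisible(x)
}

#' Simulate additive multi-QTL phenotypes for RILs
#'
#' Phenotypes follow `y = midparent + sum_j a_j x_j + e` with `x_j = +1` for
#' the BB (LTH-type) genotype at QTL j, `-1` for AA, `0` for HET, and
#' `e ~ Normal(0, residual_sd^2)`. By default the per-QTL `weight`s are used
#' as relative effects and rescaled so that their sum equals half the
#' parental difference; a noise-free all-BB genome then scores exactly the
#' high-parent mean and an all-AA genome the low-parent mean. Values are
#' truncated to `[0, 100]` after noise, as befits a germination percentage.
#'
#' @param mosaics Segment tibble with physical coordinates.
#' @param qtl_effects Tibble with columns `chrom`, `pos_bp`, `weight`
#'   (signed; positive = LTH allele increases the trait).
#' @param parent_means Length-2 numeric `c(low, high)`: trait means of the
#'   parental genotypes (default `c(SN265 = 15.4, LTH = 86.5)`, the day-6
#'   germination percentages of the two parents at 15 degrees C).
#' @param residual_sd Residual standard deviation in trait units.
#' @param seed Optional integer seed.
#' @param trait Trait name stored in the output.
#' @param n_rep Replicate measurements per line (independent noise).
#' @param scale_to_parents If `TRUE` (default) rescale weights so parental
#'   genotypes reproduce `parent_means` exactly; if `FALSE`, use the weights
#'   as absolute additive effects.
#' @return A tibble `line`, `trait`, `replicate`, `value`.
#' @export
simulate_phenotypes <- function(mosaics, qtl_effects,
                                parent_means = c(SN265 = 15.4, LTH = 86.5),
                                residual_sd = 10, seed = NULL,
                                trait = "germination_d6", n_rep = 1,
                                scale_to_parents = TRUE) {
  if (any(parent_means < 0) || any(parent_means > 100)) {
    abort("`parent_means` must lie in [0, 100].")
  }
  stopifnot_scalar_number(residual_sd, "residual_sd", min = 0)
  if (!all(c("chrom", "pos_bp", "weight") %in% names(qtl_effects))) {
    abort("`qtl_effects` needs columns chrom, pos_bp, weight.")
  }
  chrom_lengths <- tapply(mosaics$end_bp, mosaics$chrom, max)
  for (k in seq_len(nrow(qtl_effects))) {
    chrom <- qtl_effects$chrom[k]
    if (!chrom %in% names(chrom_lengths) ||
        qtl_effects$pos_bp[k] < 1 ||
        qtl_effects$pos_bp[k] > chrom_lengths[[chrom]]) {
      abort(sprintf("QTL %d at %s:%s lies off the simulated chromosomes.",
                    k, chrom, format(qtl_effects$pos_bp[k], scientific = FALSE)))
    }
  }
  midparent <- mean(parent_means)
  half_diff <- diff(range(parent_means)) / 2
  a <- qtl_effects$weight
  if (scale_to_parents) {
    if (sum(a) <= 0) abort("Summed QTL weights must be positive to anchor parental means.")
    a <- a * half_diff / sum(a)
  }
  lines <- unique(mosaics$line)
  # genotype score of every line at every QTL
  x <- matrix(0, nrow = length(lines), ncol = length(a),
              dimnames = list(lines, NULL))
  for (k in seq_along(a)) {
    segs <- mosaics[mosaics$chrom == qtl_effects$chrom[k], , drop = FALSE]
    g <- vapply(lines, function(ln) {
      mosaic_genotype_at(segs[segs$line == ln, , drop = FALSE],
                         qtl_effects$pos_bp[k])
    }, character(1))
    x[, k] <- geno_score(g)
  }
  genetic <- midparent + drop(x %*% a)
  with_seed_if(seed, {
    purrr::map_dfr(seq_len(n_rep), function(rep_i) {
      y <- genetic + rnorm(length(lines), 0, residual_sd)
      tibble(line = lines, trait = trait, replicate = rep_i,
             value = pmin(100, pmax(0, y)))
    })
  }) |>
    dplyr::arrange(.data$line, .data$replicate)
}

#' Simulate a fully penetrant single-locus trait
#'
#' A major-locus special case of [simulate_phenotypes()] emulating a
#' qualitative trait such as DEP1-type panicle curvature: lines homozygous
#' for the B (LTH) allele score 1, A-homozygotes 0, residual heterozygotes
#' 0.5, with no environmental noise.
#'
#' @inheritParams simulate_phenotypes
#' @param chrom,pos_bp Location of the causal locus.
#' @export
simulate_major_locus_trait <- function(mosaics, chrom, pos_bp,
                                       trait = "panicle_curvature") {
  simulate_phenotypes(mosaics,
                      tibble(chrom = chrom, pos_bp = pos_bp, weight = 1),
                      parent_means = c(0, 1), residual_sd = 0,
                      trait = trait)
}

#' Default simulation configuration matching the mapped population
#'
#' Returns the parameter list the simulator treats as its study conditions:
#' 144 F11 lines from two inbred rice parents, 12 chromosomes with the
#' physical lengths of the SN265 x LTH bin map, ~124k parent-distinguishing
#' SNPs (0.332 per kb), 7.75x mean depth, 1% call error, and 11 additive
#' germination QTLs whose relative weights are the published additive
#' effects, rescaled so the parental genotypes hit 15.4% and 86.5% day-6
#' germination. Genetic lengths assume 4 cM/Mb. Any element can be
#' overridden.
#'
#' @param ... Named overrides of the default elements.
#' @return A named list of simulation parameters.
#' @export
ril_sim_config <- function(...) {
  phys_Mb <- rice_ril_map_reference()$length_Mb
  chroms <- default_chrom_names(12)
  qtl <- rice_ltg_qtl_reference()
  cfg <- list(
    n_lines = 144,
    n_generations = 11,
    chrom_lengths_bp = setNames(round(phys_Mb * 1e6), chroms),
    genetic_lengths_cM = setNames(phys_Mb * 4, chroms),
    snp_density_per_kb = 0.332,
    mean_depth = 7.75,
    error_rate = 0.01,
    qtl_effects = tibble(chrom = sprintf("chr%02d", qtl$chrom),
                         pos_bp = round(qtl$peak_Mb * 1e6),
                         weight = qtl$add_effect),
    parent_means = c(SN265 = 15.4, LTH = 86.5),
    residual_sd = 10,
    seed = 1L
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad)) abort(paste0("Unknown simulation parameter(s): ",
                                paste(bad, collapse = ", ")))
  cfg[names(overrides)] <- overrides
  cfg
}

#' Simulate a complete RIL mapping population
#'
#' Convenience wrapper running [simulate_parents()],
#' [simulate_ril_mosaics()], [sample_origin_calls()] and
#' [simulate_phenotypes()] under one configuration (see [ril_sim_config()]).
#'
#' @param config List from [ril_sim_config()].
#' @return A list with `snps`, `mosaics`, `calls` (an `origin_calls`
#'   object), `phenotypes`, and the `config` used.
#' @export
simulate_ril_population <- function(config = ril_sim_config()) {
  seed <- as.integer(config$seed)
  snps <- simulate_parents(config$chrom_lengths_bp, config$snp_density_per_kb,
                           seed = seed)
  mosaics <- simulate_ril_mosaics(config$genetic_lengths_cM, config$n_lines,
                                  config$n_generations, seed = seed + 1L,
                                  chrom_lengths_bp = config$chrom_lengths_bp)
  calls <- sample_origin_calls(mosaics, snps, config$mean_depth,
                               config$error_rate, seed = seed + 2L)
  phenotypes <- simulate_phenotypes(mosaics, config$qtl_effects,
                                    config$parent_means, config$residual_sd,
                                    seed = seed + 3L)
  list(snps = snps, mosaics = mosaics, calls = calls,
       phenotypes = phenotypes, config = config)
}

#' Convert true mosaics into an exact segment set
#'
#' Bypasses call sampling and window calling: the simulated genotype segments
#' themselves become the per-line segment set, in the format produced by
#' [call_segments()]. Used for error-free map and scan studies.
#'
#' @param mosaics Segment tibble with physical coordinates.
#' @return A tibble `line`, `chrom`, `start_bp`, `end_bp`, `genotype`.
#' @export
mosaics_as_segments <- function(mosaics) {
  if (!all(c("start_bp", "end_bp") %in% names(mosaics))) {
    abort("`mosaics` must carry physical coordinates.")
  }
  dplyr::select(mosaics, "line", "chrom", "start_bp", "end_bp", "genotype")
}
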