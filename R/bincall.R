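# Sliding-window genotype calling, breakpoint detection, and population
# bin-map assembly from per-site parental-origin calls.

#' Call sliding-window genotypes from per-site origin calls
#'
#' Classifies overlapping windows of `window_size` consecutive SNP calls
#' (step 1 SNP) by the ratio of parent-A to parent-B calls. With the default
#' 20-call window this is the published 15:5 rule: a window with an A
#' fraction of at least 0.75 is the AA (SN265-type) homozygote, at most 0.25
#' the BB (LTH-type) homozygote, anything between is heterozygous. Windows
#' with fewer than `min_informative` non-missing calls are missing.
#'
#' @param calls Character vector of per-site calls for one line on one
#'   chromosome, in map order: "A", "B" or NA.
#' @param window_size Calls per window (>= 2; default 20).
#' @param min_informative Minimum non-missing calls for a confident window
#'   (default 10).
#' @return Character vector of length `length(calls) - window_size + 1`
#'   ("AA", "BB", "HET" or NA); empty if there are fewer calls than one
#'   window.
#' @examples
#' call_window_genotypes(rep(c("A", "A", "A", "B"), 5), window_size = 20)
#' @export
call_window_genotypes <- function(calls, window_size = 20,
                                  min_informative = 10) {
  stopifnot_scalar_number(window_size, "window_size", min = 2)
  n <- length(calls)
  if (n < window_size) return(character(0))
  ca <- cumsum(c(0L, calls == "A" & !is.na(calls)))
  cb <- cumsum(c(0L, calls == "B" & !is.na(calls)))
  i <- seq_len(n - window_size + 1L)
  a <- ca[i + window_size] - ca[i]
  b <- cb[i + window_size] - cb[i]
  tot <- a + b
  frac <- ifelse(tot > 0, a / tot, NA_real_)
  out <- rep(NA_character_, length(i))
  ok <- tot >= min_informative
  out[ok & frac >= 0.75] <- "AA"
  out[ok & frac <= 0.25] <- "BB"
  out[ok & frac > 0.25 & frac < 0.75] <- "HET"
  out
}

# Collapse a genotype sequence to runs, treating NA as its own level.
geno_runs <- function(g) {
  key <- ifelse(is.na(g), ".NA.", g)
  r <- rle(key)
  ends <- cumsum(r$lengths)
  tibble(genotype = ifelse(r$values == ".NA.", NA_character_, r$values),
         start = ends - r$lengths + 1L, end = ends, length = r$lengths)
}

# Absorb run `i` into its flanks. If both flanks share a genotype the three
# runs merge; otherwise the run joins the preceding run (ties -> preceding),
# or the following run when it is first.
absorb_run <- function(runs, i) {
  n <- nrow(runs)
  if (n == 1L) return(runs)
  if (i > 1L && i < n && identical(runs$genotype[i - 1L], runs$genotype[i + 1L])) {
    runs$end[i - 1L] <- runs$end[i + 1L]
    runs$length[i - 1L] <- runs$end[i - 1L] - runs$start[i - 1L] + 1L
    runs <- runs[-c(i, i + 1L), , drop = FALSE]
  } else if (i > 1L) {
    runs$end[i - 1L] <- runs$end[i]
    runs$length[i - 1L] <- runs$end[i - 1L] - runs$start[i - 1L] + 1L
    runs <- runs[-i, , drop = FALSE]
  } else {
    runs$start[i + 1L] <- runs$start[i]
    runs$length[i + 1L] <- runs$end[i + 1L] - runs$start[i + 1L] + 1L
    runs <- runs[-i, , drop = FALSE]
  }
  runs
}

#' Detect recombination breakpoints from window genotypes
#'
#' Consecutive windows sharing a genotype form runs. Missing-window runs are
#' absorbed into their flanks first. A sliding ratio rule necessarily emits
#' a short heterozygous ribbon wherever the window straddles a clean
#' homozygous breakpoint (about half a window of intermediate ratios), so
#' HET runs no longer than `max_het_transition` windows that sit between
#' opposite homozygous runs are collapsed onto their centre -- the point
#' where the parental ratio crosses 50% -- rather than called as segments.
#' Remaining runs shorter than `min_run` windows (noise at low coverage)
#' are absorbed smallest-first into the flanking runs (flanks sharing a
#' genotype merge; otherwise the preceding run wins ties). A breakpoint is
#' placed at the midpoint between the anchor position of the last window of
#' one run and that of the first window of the next; the first and last
#' runs extend to the chromosome ends.
#'
#' @param window_genotypes Character vector from [call_window_genotypes()].
#' @param window_positions Numeric vector, one representative bp position per
#'   window (conventionally the centre SNP of the window).
#' @param min_run Minimum run length in windows (default 3).
#' @param max_het_transition Longest HET run between opposite homozygotes
#'   treated as a breakpoint transition zone (default 20, one window span;
#'   a real heterozygous segment shorter than a window is undetectable
#'   anyway).
#' @param chrom_length_bp Chromosome length; defaults to the last window
#'   position.
#' @return A tibble of segments `start_bp`, `end_bp`, `genotype` tiling
#'   `[1, chrom_length_bp]`, 1-based inclusive. If every window is missing, a
#'   single NA-genotype segment is returned with attribute
#'   `all_missing = TRUE`.
#' @export
detect_breakpoints <- function(window_genotypes, window_positions,
                               min_run = 3, max_het_transition = 20,
                               chrom_length_bp = NULL) {
  stopifnot_scalar_number(min_run, "min_run", min = 1)
  if (length(window_genotypes) != length(window_positions)) {
    abort("`window_genotypes` and `window_positions` must have equal length.")
  }
  chrom_length_bp <- chrom_length_bp %||% max(window_positions)
  if (length(window_genotypes) == 0L || all(is.na(window_genotypes))) {
    out <- tibble(start_bp = 1, end_bp = as.numeric(chrom_length_bp),
                  genotype = NA_character_)
    attr(out, "all_missing") <- TRUE
    return(out)
  }
  runs <- geno_runs(window_genotypes)
  # absorb missing runs first (regardless of length)
  repeat {
    i <- which(is.na(runs$genotype))[1]
    if (is.na(i) || nrow(runs) == 1L) break
    runs <- absorb_run(runs, i)
  }
  # collapse HET transition ribbons between opposite homozygotes: split the
  # run at its centre so the breakpoint lands where the ratio crosses 50%
  repeat {
    n <- nrow(runs)
    cand <- which(runs$genotype == "HET" &
                    runs$length <= max_het_transition &
                    seq_len(n) > 1L & seq_len(n) < n)
    cand <- cand[runs$genotype[cand - 1L] %in% c("AA", "BB") &
                   runs$genotype[cand + 1L] %in% c("AA", "BB") &
                   runs$genotype[cand - 1L] != runs$genotype[cand + 1L]]
    if (length(cand) == 0L) break
    i <- cand[1]
    half <- runs$start[i] + floor((runs$length[i] - 1L) / 2)
    runs$end[i - 1L] <- half
    runs$start[i + 1L] <- half + 1L
    runs$length[i - 1L] <- runs$end[i - 1L] - runs$start[i - 1L] + 1L
    runs$length[i + 1L] <- runs$end[i + 1L] - runs$start[i + 1L] + 1L
    runs <- runs[-i, , drop = FALSE]
  }
  # then absorb short runs, smallest first
  repeat {
    short <- which(runs$length < min_run)
    if (length(short) == 0L || nrow(runs) == 1L) break
    i <- short[which.min(runs$length[short])]
    runs <- absorb_run(runs, i)
  }
  n <- nrow(runs)
  if (n == 1L) {
    return(tibble(start_bp = 1, end_bp = as.numeric(chrom_length_bp),
                  genotype = runs$genotype))
  }
  bp <- (window_positions[runs$end[-n]] + window_positions[runs$start[-1L]]) / 2
  bp <- floor(bp)
  tibble(start_bp = c(1, bp + 1), end_bp = c(bp, as.numeric(chrom_length_bp)),
         genotype = runs$genotype)
}

#' Call genotype segments for every line and chromosome
#'
#' Runs [call_window_genotypes()] and [detect_breakpoints()] over an
#' `origin_calls` object. Each window is anchored at its centre SNP.
#'
#' @param calls An `origin_calls` object (see [sample_origin_calls()] or
#'   [read_origin_calls_vcf()]).
#' @inheritParams call_window_genotypes
#' @inheritParams detect_breakpoints
#' @return A tibble `line`, `chrom`, `start_bp`, `end_bp`, `genotype`.
#' @export
call_segments <- function(calls, window_size = 20, min_informative = 10,
                          min_run = 3, max_het_transition = window_size) {
  snp_idx <- split(seq_len(nrow(calls$snps)), calls$snps$chrom)
  lines <- rownames(calls$calls)
  centre_off <- floor((window_size - 1) / 2)
  purrr::map_dfr(lines, function(ln) {
    purrr::imap_dfr(snp_idx, function(j, chrom) {
      wg <- call_window_genotypes(calls$calls[ln, j], window_size,
                                  min_informative)
      if (length(wg) == 0L) {
        seg <- tibble(start_bp = 1,
                      end_bp = as.numeric(calls$chrom_lengths_bp[[chrom]]),
                      genotype = NA_character_)
      } else {
        wp <- calls$snps$pos[j][seq_along(wg) + centre_off]
        seg <- detect_breakpoints(wg, wp, min_run, max_het_transition,
                                  chrom_length_bp = calls$chrom_lengths_bp[[chrom]])
      }
      dplyr::mutate(seg, line = ln, chrom = chrom, .before = 1)
    })
  })
}

#' Assemble a population-level bin map from segment sets
#'
#' Each chromosome is tiled into `grid_bp` cells (default 15 kb); a line's
#' genotype in a cell is the genotype of its segment covering the cell
#' midpoint. Adjacent cells whose genotype vector across *all* lines is
#' identical are merged into one bin marker, so every bin boundary marks a
#' recombination breakpoint in at least one line.
#'
#' @param segments Tibble from [call_segments()] or [mosaics_as_segments()].
#' @param grid_bp Quantisation grid in bp (default 15000).
#' @param chrom_lengths_bp Optional named chromosome lengths; defaults to the
#'   maximum segment end per chromosome.
#' @return A `bin_map` object: list with `bins` (tibble `bin_id`, `chrom`,
#'   `start_bp`, `end_bp`, `midpoint_bp`) and `geno` (character matrix,
#'   lines x bins).
#' @export
build_bin_map <- function(segments, grid_bp = 15000, chrom_lengths_bp = NULL) {
  stopifnot_scalar_number(grid_bp, "grid_bp", min = 1)
  lines <- unique(segments$line)
  if (length(lines) == 0L) abort("`segments` contains no lines.")
  if (is.null(chrom_lengths_bp)) {
    chrom_lengths_bp <- tapply(segments$end_bp, segments$chrom, max)
    chrom_lengths_bp <- setNames(as.numeric(chrom_lengths_bp),
                                 names(chrom_lengths_bp))
  }
  chroms <- names(chrom_lengths_bp)
  bins_list <- list()
  geno_list <- list()
  for (chrom in chroms) {
    L <- chrom_lengths_bp[[chrom]]
    starts <- seq(1, L, by = grid_bp)
    ends <- pmin(starts + grid_bp - 1, L)
    mids <- (starts + ends) / 2
    cell_geno <- matrix(NA_character_, nrow = length(lines),
                        ncol = length(starts), dimnames = list(lines, NULL))
    segs_c <- segments[segments$chrom == chrom, , drop = FALSE]
    for (ln in lines) {
      s <- segs_c[segs_c$line == ln, , drop = FALSE]
      if (nrow(s) == 0L) next
      s <- s[order(s$start_bp), , drop = FALSE]
      idx <- findInterval(mids, s$end_bp + 0.5) + 1L
      idx[idx > nrow(s)] <- nrow(s)
      cell_geno[ln, ] <- s$genotype[idx]
    }
    # merge adjacent cells with identical genotype vectors across all lines
    if (ncol(cell_geno) > 1L) {
      same <- vapply(seq_len(ncol(cell_geno) - 1L), function(k) {
        identical(cell_geno[, k], cell_geno[, k + 1L])
      }, logical(1))
      grp <- cumsum(c(TRUE, !same))
    } else {
      grp <- 1L
    }
    bin_start <- tapply(starts, grp, min)
    bin_end <- tapply(ends, grp, max)
    first_cell <- match(unique(grp), grp)
    bins_list[[chrom]] <- tibble(chrom = chrom,
                                 start_bp = as.numeric(bin_start),
                                 end_bp = as.numeric(bin_end))
    geno_list[[chrom]] <- cell_geno[, first_cell, drop = FALSE]
  }
  bins <- dplyr::bind_rows(bins_list)
  bins <- dplyr::mutate(bins,
                        bin_id = sprintf("%s_%09d", .data$chrom, .data$start_bp),
                        midpoint_bp = (.data$start_bp + .data$end_bp) / 2,
                        .before = 1)
  geno <- do.call(cbind, geno_list)
  colnames(geno) <- bins$bin_id
  new_bin_map(bins, geno)
}

new_bin_map <- function(bins, geno) {
  structure(list(bins = bins, geno = geno), class = "bin_map")
}

#' @exportS3Method base::print
print.bin_map <- function(x, ...) {
  cat(sprintf("<bin_map> %d lines x %d bin markers on %d chromosome(s)\n",
              nrow(x$geno), nrow(x$bins), length(unique(x$bins$chrom))))
  invisible(x)
}

#' Summarise a bin map in linkage-map report form
#'
#' One row per chromosome: marker count, genetic and physical length, mean
#' marker spacing on both scales (length divided by marker count), and bin
#' physical-interval statistics (the count below 1 Mb and the smallest and
#' largest intervals).
#'
#' @param bin_map A `bin_map`.
#' @param genetic_map Optional genetic map from [build_genetic_map()]; when
#'   omitted the cM columns are NA.
#' @return A tibble with columns `chrom`, `n_markers`, `length_cM`,
#'   `length_Mb`, `avg_spacing_cM`, `avg_spacing_kb`, `n_gap_lt_1Mb`,
#'   `min_gap_kb`, `max_gap_Mb`.
#' @export
binmap_summary <- function(bin_map, genetic_map = NULL) {
  bins <- bin_map$bins
  per_chrom <- bins |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(
      n_markers = dplyr::n(),
      length_Mb = max(.data$end_bp) / 1e6,
      n_gap_lt_1Mb = sum(.data$end_bp - .data$start_bp + 1 < 1e6),
      min_gap_kb = min(.data$end_bp - .data$start_bp + 1) / 1e3,
      max_gap_Mb = max(.data$end_bp - .data$start_bp + 1) / 1e6,
      .groups = "drop")
  if (!is.null(genetic_map)) {
    len_cM <- genetic_map |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(length_cM = max(.data$pos_cM), .groups = "drop")
    per_chrom <- dplyr::left_join(per_chrom, len_cM, by = "chrom")
  } else {
    per_chrom$length_cM <- NA_real_
  }
  per_chrom |>
    dplyr::mutate(avg_spacing_cM = .data$length_cM / .data$n_markers,
                  avg_spacing_kb = .data$length_Mb * 1000 / .data$n_markers) |>
    dplyr::select("chrom", "n_markers", "length_cM", "length_Mb",
                  "avg_spacing_cM", "avg_spacing_kb", "n_gap_lt_1Mb",
                  "min_gap_kb", "max_gap_Mb")
}

#' Whole-map totals for a per-chromosome linkage-map summary
#'
#' Collapses a per-chromosome summary (from [binmap_summary()] or a
#' compatible reference table) into one row of totals and means.
#'
#' @param summary_tbl Tibble with columns `n_markers`, `length_cM`,
#'   `length_Mb`.
#' @return One-row tibble: `n_chrom`, `total_markers`, `total_cM`,
#'   `total_Mb`, `mean_spacing_cM`, `mean_spacing_kb`.
#' @export
linkage_map_totals <- function(summary_tbl) {
  tibble(n_chrom = nrow(summary_tbl),
         total_markers = sum(summary_tbl$n_markers),
         total_cM = sum(summary_tbl$length_cM),
         total_Mb = sum(summary_tbl$length_Mb),
         mean_spacing_cM = sum(summary_tbl$length_cM) / sum(summary_tbl$n_markers),
         mean_spacing_kb = sum(summary_tbl$length_Mb) * 1000 /
           sum(summary_tbl$n_markers))
}
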