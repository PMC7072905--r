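# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' Tidy a QTL scan
#'
#' @param x A `qtl_scan`.
#' @param ... Unused.
#' @return A plain tibble of per-position results (`chrom`, `pos_cM`,
#'   `pos_bp`, `lod`, `add_effect`).
#' @export
tidy.qtl_scan <- function(x, ...) {
  as_tibble(x)[c("chrom", "pos_cM", "pos_bp", "lod", "add_effect")]
}

#' One-row summary of a QTL scan
#'
#' @param x A `qtl_scan`.
#' @param ... Unused.
#' @return Tibble: `method`, `n_lines`, `n_positions`, `n_covariates`,
#'   `max_lod`, and the location of the genome-wide maximum.
#' @export
glance.qtl_scan <- function(x, ...) {
  i <- which.max(x$lod)
  cov <- attr(x, "covariates")
  tibble(method = attr(x, "method"), n_lines = attr(x, "n"),
         n_positions = nrow(x),
         n_covariates = if (is.null(cov)) 0L else nrow(cov),
         max_lod = x$lod[i], peak_chrom = x$chrom[i],
         peak_cM = x$pos_cM[i])
}

#' Tidy a bin map
#'
#' @param x A `bin_map`.
#' @param ... Unused.
#' @return Long tibble `line`, `bin_id`, `chrom`, `start_bp`, `end_bp`,
#'   `genotype`.
#' @export
tidy.bin_map <- function(x, ...) {
  long <- as_tibble(x$geno, rownames = "line") |>
    tidyr::pivot_longer(-"line", names_to = "bin_id", values_to = "genotype")
  dplyr::left_join(long, x$bins[c("bin_id", "chrom", "start_bp", "end_bp")],
                   by = "bin_id") |>
    dplyr::select("line", "bin_id", "chrom", "start_bp", "end_bp", "genotype")
}

#' One-row summary of a bin map
#'
#' @param x A `bin_map`.
#' @param ... Unused.
#' @return Tibble: `n_lines`, `n_bins`, `n_chrom`, `mean_bin_kb`,
#'   `pct_missing`.
#' @export
glance.bin_map <- function(x, ...) {
  tibble(n_lines = nrow(x$geno), n_bins = nrow(x$bins),
         n_chrom = length(unique(x$bins$chrom)),
         mean_bin_kb = mean(x$bins$end_bp - x$bins$start_bp + 1) / 1e3,
         pct_missing = 100 * mean(is.na(x$geno)))
}

#' LOD curve plot of a QTL scan
#'
#' @param object A `qtl_scan`.
#' @param threshold Optional LOD threshold drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot: LOD against physical position, one facet per
#'   chromosome.
#' @export
autoplot.qtl_scan <- function(object, threshold = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos_bp / 1e6, y = .data$lod)) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = "LOD") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = as.numeric(threshold),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Recombination-mosaic plot of a bin map
#'
#' Draws every line's bin genotypes along the physical map, the usual
#' visual check of a RIL bin map.
#'
#' @param object A `bin_map`.
#' @param ... Unused.
#' @return A ggplot with one tile row per line, faceted by chromosome.
#' @export
autoplot.bin_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(xmin = .data$start_bp / 1e6,
                                   xmax = .data$end_bp / 1e6,
                                   ymin = as.integer(factor(.data$line)) - 0.5,
                                   ymax = as.integer(factor(.data$line)) + 0.5,
                                   fill = .data$genotype)) +
    ggplot2::geom_rect() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::scale_fill_manual(values = c(AA = "#3B6FB6", BB = "#C03A2B",
                                          HET = "#8E7CC3"),
                               na.value = "grey85") +
    ggplot2::labs(x = "Position (Mb)", y = "Line", fill = "Genotype") +
    ggplot2::theme_minimal()
}
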