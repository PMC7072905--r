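# Substitution fine mapping from key homozygous recombinant lines, and
# candidate-gene extraction from an annotation table.

#' Classify progeny-tested lines against the parents
#'
#' Assigns each line a phenotype class: under the `"midpoint"` rule a line is
#' tolerant when its mean trait value exceeds the midparent (ties are
#' unclassified); under the `"t_test"` rule (default, mirroring progeny
#' testing) each line's replicate values are tested against both parent
#' means, and the class is the parent the line does *not* differ from at
#' level `alpha` -- lines differing from both or neither are unclassified.
#'
#' @param progeny Tibble with `line` and `value` (one row per replicate
#'   measurement).
#' @param parent_means Length-2 numeric: the two parents' trait means; the
#'   larger defines the tolerant class (default `c(SN265 = 15.4,
#'   LTH = 86.5)`).
#' @param rule `"t_test"` or `"midpoint"`.
#' @param alpha Test level for the t-test rule (default 0.05).
#' @return Tibble `line`, `n`, `mean`, `class` ("tolerant", "sensitive" or
#'   "unclassified").
#' @export
classify_progeny <- function(progeny, parent_means = c(SN265 = 15.4, LTH = 86.5),
                             rule = c("t_test", "midpoint"), alpha = 0.05) {
  rule <- match.arg(rule)
  if (nrow(progeny) == 0L) abort("`progeny` is empty.")
  mid <- mean(parent_means)
  tol_mean <- max(parent_means)
  sen_mean <- min(parent_means)
  progeny |>
    dplyr::group_by(.data$line) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data$value),
                     class = {
                       v <- .data$value
                       if (rule == "midpoint") {
                         if (mean(v) > mid) "tolerant"
                         else if (mean(v) < mid) "sensitive"
                         else "unclassified"
                       } else {
                         if (length(v) < 2L || stats::sd(v) == 0) {
                           # no within-line variance: fall back to midpoint
                           if (mean(v) > mid) "tolerant"
                           else if (mean(v) < mid) "sensitive"
                           else "unclassified"
                         } else {
                           p_tol <- t.test(v, mu = tol_mean)$p.value
                           p_sen <- t.test(v, mu = sen_mean)$p.value
                           tol_ok <- p_tol >= alpha
                           sen_ok <- p_sen >= alpha
                           if (tol_ok && !sen_ok) "tolerant"
                           else if (sen_ok && !tol_ok) "sensitive"
                           else "unclassified"
                         }
                       }
                     },
                     .groups = "drop")
}

#' Delimit a QTL interval by substitution mapping
#'
#' Given key homozygous recombinant lines genotyped at ordered fine markers
#' and progeny-tested into tolerant/sensitive classes, finds the
#' marker-bounded interval on which every line's (constant) genotype
#' predicts its class: tolerant lines carry the high-parent (BB) genotype,
#' sensitive lines the low-parent (AA) genotype. Computed as the longest
#' contiguous run of markers at which all classified lines are concordant
#' (the intersection of per-line concordant regions).
#'
#' @param panel Long tibble with columns `line`, `marker`, `pos_bp`,
#'   `genotype` ("AA" or "BB"; key lines are homozygous throughout), and
#'   `class` ("tolerant", "sensitive"; "unclassified" lines are dropped with
#'   a warning).
#' @return One-row tibble `left_marker`, `right_marker`, `left_bp`,
#'   `right_bp`, `width_bp`, `n_lines`; attribute `whole_region` when no
#'   line is recombinant-informative and the full marker range is returned.
#' @export
delimit_interval <- function(panel) {
  need <- c("line", "marker", "pos_bp", "genotype", "class")
  if (!all(need %in% names(panel))) {
    abort(paste0("`panel` needs columns: ", paste(need, collapse = ", ")))
  }
  dropped <- unique(panel$line[!panel$class %in% c("tolerant", "sensitive")])
  if (length(dropped)) {
    warn(paste0("Dropping unclassified line(s): ",
                paste(dropped, collapse = ", ")))
    panel <- panel[panel$class %in% c("tolerant", "sensitive"), , drop = FALSE]
  }
  if (nrow(panel) == 0L) abort("No classified recombinant lines in `panel`.")
  markers <- panel |>
    dplyr::distinct(.data$marker, .data$pos_bp) |>
    dplyr::arrange(.data$pos_bp)
  wide <- panel |>
    dplyr::mutate(concordant =
                    (.data$class == "tolerant" & .data$genotype == "BB") |
                    (.data$class == "sensitive" & .data$genotype == "AA")) |>
    dplyr::select("line", "marker", "concordant") |>
    tidyr::pivot_wider(names_from = "marker", values_from = "concordant")
  conc <- as.matrix(wide[, markers$marker, drop = FALSE])
  never <- wide$line[rowSums(conc, na.rm = TRUE) == 0]
  if (length(never)) {
    abort(paste0("Phenotype class contradicts the genotype across the whole ",
                 "region for line(s): ", paste(never, collapse = ", ")))
  }
  all_ok <- apply(conc, 2, function(z) all(z, na.rm = FALSE))
  all_ok[is.na(all_ok)] <- FALSE
  if (!any(all_ok)) {
    abort(paste0("No marker is concordant with every line; conflicting ",
                 "lines: ", paste(wide$line, collapse = ", ")))
  }
  if (all(all_ok)) {
    warn("No informative recombinant in the region; returning the whole region.")
    run <- c(1L, nrow(markers))
    whole <- TRUE
  } else {
    r <- rle(all_ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok_runs <- which(r$values)
    best <- ok_runs[which.max(r$lengths[ok_runs])]
    run <- c(starts[best], ends[best])
    whole <- FALSE
  }
  out <- tibble(left_marker = markers$marker[run[1]],
                right_marker = markers$marker[run[2]],
                left_bp = markers$pos_bp[run[1]],
                right_bp = markers$pos_bp[run[2]],
                width_bp = markers$pos_bp[run[2]] - markers$pos_bp[run[1]],
                n_lines = nrow(wide))
  attr(out, "whole_region") <- whole
  out
}

#' Genes overlapping an interval
#'
#' Returns annotation entries overlapping the interval by at least 1 bp,
#' ordered by start. Gene coordinates are normalised to `start <= end`
#' first, so minus-strand entries listed end-before-start are handled.
#'
#' @param genes Tibble with `gene_id`, `start_bp`, `end_bp` and optionally
#'   `product`.
#' @param interval Numeric length-2 `c(left, right)` in bp, or a one-row
#'   tibble from [delimit_interval()].
#' @return The overlapping genes, coordinates normalised, ordered by
#'   `start_bp`.
#' @export
candidate_genes <- function(genes, interval) {
  if (is.data.frame(interval)) {
    interval <- c(interval$left_bp[1], interval$right_bp[1])
  }
  if (length(interval) != 2L || any(!is.finite(interval))) {
    abort("`interval` must be two finite positions.")
  }
  interval <- sort(as.numeric(interval))
  if (nrow(genes) == 0L) return(genes)
  genes |>
    dplyr::mutate(start_bp = pmin(.data$start_bp, .data$end_bp),
                  end_bp = pmax(genes$start_bp, genes$end_bp)) |>
    dplyr::filter(.data$end_bp >= interval[1], .data$start_bp <= interval[2]) |>
    dplyr::arrange(.data$start_bp)
}

#' Read a gene annotation table
#'
#' Accepts either a tab-separated table with columns `gene_id`, `start_bp`,
#' `end_bp` (optionally `chrom`, `product`), or a GFF3 file (gene features
#' only; `ID` or `Name` attribute becomes `gene_id`). Coordinates are
#' normalised to `start_bp <= end_bp`.
#'
#' @param path File path.
#' @return Tibble `gene_id`, `start_bp`, `end_bp`, `product` (and `chrom`
#'   when present).
#' @export
read_gene_annotation <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^##gff", first)) {
    gff <- readr::read_tsv(path, comment = "#",
                           col_names = c("seqid", "source", "type", "start",
                                         "end", "score", "strand", "phase",
                                         "attributes"),
                           col_types = "ccciicccc", progress = FALSE)
    gff <- dplyr::filter(gff, .data$type == "gene")
    get_attr <- function(attrs, key) {
      m <- regmatches(attrs, regexpr(paste0(key, "=[^;]+"), attrs))
      ifelse(lengths(regmatches(attrs, gregexpr(paste0(key, "=[^;]+"), attrs))) > 0,
             sub(paste0(key, "="), "", m), NA_character_)
    }
    ids <- vapply(gff$attributes, function(a) {
      m <- regmatches(a, regexpr("(ID|Name)=[^;]+", a))
      if (length(m)) sub("^(ID|Name)=", "", m) else NA_character_
    }, character(1))
    out <- tibble(gene_id = unname(ids), chrom = gff$seqid,
                  start_bp = gff$start, end_bp = gff$end,
                  product = vapply(gff$attributes, function(a) {
                    m <- regmatches(a, regexpr("product=[^;]+", a))
                    if (length(m)) sub("^product=", "", m) else NA_character_
                  }, character(1), USE.NAMES = FALSE))
  } else {
    out <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
    if (!all(c("gene_id", "start_bp", "end_bp") %in% names(out))) {
      abort("Annotation TSV needs columns gene_id, start_bp, end_bp.")
    }
  }
  dplyr::mutate(out, start_bp = pmin(.data$start_bp, .data$end_bp),
                end_bp = pmax(out$start_bp, out$end_bp))
}
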