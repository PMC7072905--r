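# Published characteristics of the SN265 x LTH japonica RIL resource, kept
# as worked examples and validation anchors for the reporting functions.

#' Published per-chromosome characteristics of the SN265 x LTH bin map
#'
#' The high-density bin map of the 144-line SN265 x LTH rice RIL population:
#' per chromosome, the bin-marker count, genetic and physical length, the
#' printed mean marker spacing on both scales, and bin physical-interval
#' statistics. Summing the rows gives the published totals of 2,828 bin
#' markers over 2,840.12 cM.
#'
#' @return A 12-row tibble: `chrom`, `n_markers`, `length_cM`, `length_Mb`,
#'   `avg_cM_printed`, `avg_kb_printed`, `n_gap_lt_1Mb`, `min_gap_kb`,
#'   `max_gap_Mb`.
#' @export
rice_ril_map_reference <- function() {
  tibble::tribble(
    ~chrom, ~n_markers, ~length_cM, ~length_Mb, ~avg_cM_printed,
    ~avg_kb_printed, ~n_gap_lt_1Mb, ~min_gap_kb, ~max_gap_Mb,
    1L,  254L, 338.65, 42.93, 1.33, 169.03, 246L, 15.27, 3.16,
    2L,  254L, 227.11, 31.61, 0.89, 124.46, 252L, 15.47, 3.45,
    3L,  313L, 284.80, 36.14, 0.91, 115.45, 310L, 15.06, 1.57,
    4L,  281L, 300.18, 34.29, 1.07, 122.03, 275L, 15.63, 1.91,
    5L,  239L, 269.15, 29.68, 1.13, 124.19, 235L, 15.32, 1.08,
    6L,  247L, 181.10, 28.63, 0.73, 115.92, 244L, 15.53, 3.63,
    7L,  187L, 217.94, 29.23, 1.17, 156.34, 184L, 17.18, 1.46,
    8L,  238L, 193.86, 28.12, 0.82, 118.15, 237L, 15.02, 0.99,
    9L,  188L, 111.32, 22.30, 0.59, 118.61, 185L, 15.89, 1.92,
    10L, 234L, 199.84, 22.99, 0.85,  98.23, 230L, 15.77, 1.27,
    11L, 186L, 323.32, 28.49, 1.74, 153.18, 183L, 15.01, 3.48,
    12L, 207L, 192.85, 26.70, 0.93, 130.43, 202L, 15.63, 2.33)
}

#' Published low-temperature-germinability QTLs of the SN265 x LTH RILs
#'
#' The 11 day-6 germination QTLs mapped in the 144-line population: peak
#' positions on the genetic (cM) and physical (Mb) scales, support-interval
#' bounds, LOD, variance explained, additive effect (positive = LTH allele
#' increases germination) and the parent contributing the positive allele.
#'
#' @return An 11-row tibble: `qtl`, `chrom`, `peak_cM`, `peak_Mb`,
#'   `ci_lo_cM`, `ci_hi_cM`, `ci_lo_Mb`, `ci_hi_Mb`, `lod`, `var_pct`,
#'   `add_effect`, `positive_allele`.
#' @export
rice_ltg_qtl_reference <- function() {
  tibble::tribble(
    ~qtl, ~chrom, ~peak_cM, ~peak_Mb, ~ci_lo_cM, ~ci_hi_cM, ~ci_lo_Mb,
    ~ci_hi_Mb, ~lod, ~var_pct, ~add_effect, ~positive_allele,
    "qLTG1",   1L, 116.34, 16.90, 103.19, 128.81, 11.48, 19.34, 5.59, 16.40,  10.16, "LTH",
    "qLTG3",   3L,   3.95,  1.10,   0.00,  10.78,  0.00,  1.31, 4.71, 14.02,   9.18, "LTH",
    "qLTG4",   4L,  54.58,  6.27,  36.64,  77.67,  6.10, 11.41, 4.85, 14.43,  -9.30, "SN265",
    "qLTG6",   6L,   0.18,  1.34,   0.18,   1.07,  0.34,  0.74, 3.64, 11.05,   8.13, "LTH",
    "qLTG7a",  7L, 104.99,  8.88,  87.28, 107.84,  6.98,  9.21, 4.98, 14.72,   9.80, "LTH",
    "qLTG7b",  7L, 152.12, 20.32, 148.13, 162.80, 18.93, 21.76, 7.39, 21.04,  11.26, "LTH",
    "qLTG9a",  9L,   4.31,  6.07,   4.35,   8.38,  5.91,  6.83, 4.17, 12.53,   8.68, "LTH",
    "qLTG9b",  9L,  79.24, 15.27,  71.69, 102.85, 14.91, 21.38, 5.29, 15.60,  -9.76, "SN265",
    "qLTG10", 10L,  13.93,  1.60,   8.55,  14.06,  1.20,  1.60, 7.38, 21.00,  12.00, "LTH",
    "qLTG12a", 12L,  6.17,  0.87,   4.72,  16.25,  0.86,  2.35, 5.14, 15.20,   9.65, "LTH",
    "qLTG12b", 12L, 131.25, 22.79, 111.25, 145.46, 21.05, 25.16, 3.41, 10.30, -8.12, "SN265")
}

#' Annotated genes of the fine-mapped qLTG6 region
#'
#' The seven gene models of the ~45.8 kb chromosome-6 target region to which
#' qLTG6 was delimited by substitution mapping. Coordinates are returned as
#' published -- one minus-strand entry (LOC_Os06g01270) is listed
#' end-before-start -- unless `normalize = TRUE`.
#'
#' @param normalize Normalise coordinates to `start_bp <= end_bp`
#'   (default FALSE).
#' @return A 7-row tibble: `gene_id`, `start_bp`, `end_bp`, `product`.
#' @export
qltg6_gene_reference <- function(normalize = FALSE) {
  genes <- tibble::tribble(
    ~gene_id, ~start_bp, ~end_bp, ~product,
    "LOC_Os06g01250", 163205L, 165539L, "Cytochrome P450",
    "LOC_Os06g01260", 167364L, 174331L, "Glutathione gamma-glutamylcysteinyltransferase 1",
    "LOC_Os06g01270", 178580L, 178343L, "Expressed protein",
    "LOC_Os06g01280", 180215L, 181423L, "Retrotransposon protein",
    "LOC_Os06g01290", 182104L, 184623L, "Expressed protein",
    "LOC_Os06g01304", 185692L, 191452L, "Spotted leaf 11",
    "LOC_Os06g01320", 195018L, 208583L, "Chromodomain, helicase/ATPase, and DNA-binding domain (CHD) proteins")
  if (normalize) {
    genes <- dplyr::mutate(genes,
                           start_bp = pmin(genes$start_bp, genes$end_bp),
                           end_bp = pmax(genes$start_bp, genes$end_bp))
  }
  genes
}
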