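# Readers, writers, configuration and the end-to-end pipeline driver.
# VCF is the interchange format for parent-polarised origin calls: 0/0
# encodes parent-A (SN265) origin, 1/1 parent-B (LTH), ./. missing.

#' Write origin calls as a minimal VCF
#'
#' One sample column per line; REF is the parent-A allele, ALT the parent-B
#' allele, genotypes `0/0`, `1/1` or `./.`.
#'
#' @param calls An `origin_calls` object.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_origin_calls_vcf <- function(calls, path) {
  snps <- calls$snps
  lines <- rownames(calls$calls)
  gt <- matrix("./.", nrow = nrow(snps), ncol = length(lines))
  gt[t(calls$calls) == "A"] <- "0/0"
  gt[t(calls$calls) == "B"] <- "1/1"
  header <- c("##fileformat=VCFv4.2",
              "##source=ltgmap",
              paste0("##contig=<ID=", names(calls$chrom_lengths_bp),
                     ",length=", format(calls$chrom_lengths_bp,
                                        scientific = FALSE, trim = TRUE), ">"),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Parental origin genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", lines), collapse = "\t"))
  body <- cbind(snps$chrom, snps$pos, ".", snps$allele_A, snps$allele_B,
                ".", ".", ".", "GT", gt)
  writeLines(c(header, apply(body, 1, paste, collapse = "\t")), path)
  invisible(path)
}

#' Read parent-polarised origin calls from a VCF
#'
#' Inverse of [write_origin_calls_vcf()]. Genotypes `0/0` map to "A", `1/1`
#' to "B", `./.` (or `.`) to missing; heterozygous genotypes (`0/1`, `1/0`)
#' are counted and mapped to missing with one summary warning. Positions
#' must be sorted within chromosome and any other genotype code is an error
#' naming the offending record.
#'
#' @param path VCF path.
#' @param chrom_lengths_bp Optional named chromosome lengths; defaults to
#'   contig headers when present, else the maximum position per chromosome.
#' @return An `origin_calls` object.
#' @export
read_origin_calls_vcf <- function(path, chrom_lengths_bp = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  snps <- tibble(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                 allele_A = fix[, "REF"], allele_B = fix[, "ALT"])
  unsorted <- snps |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(ok = !is.unsorted(.data$pos, strictly = TRUE),
                     .groups = "drop")
  if (any(!unsorted$ok)) {
    abort(paste0("VCF positions are not strictly increasing on: ",
                 paste(unsorted$chrom[!unsorted$ok], collapse = ", ")))
  }
  gt <- vcfR::extract.gt(v)
  known <- c("0/0", "1/1", "./.", ".", "0|0", "1|1", ".|.", "0/1", "1/0",
             "0|1", "1|0")
  bad <- which(!(gt %in% known) & !is.na(gt))
  if (length(bad)) {
    site <- ((bad[1] - 1) %% nrow(gt)) + 1
    abort(sprintf("Unknown genotype code '%s' at record %d (%s:%d).",
                  gt[bad[1]], site, snps$chrom[site], snps$pos[site]))
  }
  n_het <- sum(gt %in% c("0/1", "1/0", "0|1", "1|0"), na.rm = TRUE)
  if (n_het > 0) {
    warn(sprintf("%d heterozygous VCF genotype(s) mapped to missing.", n_het))
  }
  calls <- matrix(NA_character_, nrow = ncol(gt), ncol = nrow(gt),
                  dimnames = list(colnames(gt), NULL))
  calls[t(gt) %in% c("0/0", "0|0")] <- "A"
  calls[t(gt) %in% c("1/1", "1|1")] <- "B"
  if (is.null(chrom_lengths_bp)) {
    meta <- grep("^##contig", v@meta, value = TRUE)
    if (length(meta)) {
      ids <- sub('.*ID=([^,>]+).*', "\\1", meta)
      lens <- suppressWarnings(as.numeric(sub('.*length=([0-9]+).*', "\\1", meta)))
      if (!any(is.na(lens))) chrom_lengths_bp <- setNames(lens, ids)
    }
    if (is.null(chrom_lengths_bp)) {
      chrom_lengths_bp <- tapply(snps$pos, snps$chrom, max)
      chrom_lengths_bp <- setNames(as.numeric(chrom_lengths_bp),
                                   names(chrom_lengths_bp))
    }
  }
  new_origin_calls(snps, calls, chrom_lengths_bp[unique(snps$chrom)])
}

#' Write / read a phenotype table
#'
#' Comma-separated with columns `line`, `trait`, `replicate`, `value`.
#'
#' @param phenotypes Tibble as produced by [simulate_phenotypes()].
#' @param path CSV path.
#' @return `path` invisibly; `read_phenotypes()` returns the tibble.
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_csv(phenotypes, path)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
}

#' Write / read a bin map as TSV
#'
#' Columns `bin_id`, `chrom`, `start_bp`, `end_bp` followed by one genotype
#' column per line.
#'
#' @param bin_map A `bin_map`.
#' @param path TSV path.
#' @return `path` invisibly; `read_bin_map()` returns the `bin_map`.
#' @export
write_bin_map <- function(bin_map, path) {
  geno <- t(bin_map$geno)
  colnames(geno) <- rownames(bin_map$geno)
  tbl <- dplyr::bind_cols(
    dplyr::select(bin_map$bins, "bin_id", "chrom", "start_bp", "end_bp"),
    as_tibble(geno))
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' @rdname write_bin_map
#' @export
read_bin_map <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  meta <- c("bin_id", "chrom", "start_bp", "end_bp")
  bins <- dplyr::mutate(tbl[meta],
                        midpoint_bp = (.data$start_bp + .data$end_bp) / 2)
  geno <- t(as.matrix(tbl[setdiff(names(tbl), meta)]))
  colnames(geno) <- bins$bin_id
  new_bin_map(bins, geno)
}

#' Write / read a genetic map as TSV
#'
#' @param genetic_map A `genetic_map`.
#' @param path TSV path.
#' @return `path` invisibly; `read_genetic_map()` returns the map.
#' @export
write_genetic_map <- function(genetic_map, path) {
  tbl <- as_tibble(genetic_map)
  attr(tbl, "map_function") <- NULL
  readr::write_tsv(dplyr::mutate(tbl,
                                 map_function = attr(genetic_map, "map_function")),
                   path)
  invisible(path)
}

#' @rdname write_genetic_map
#' @export
read_genetic_map <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  mf <- tbl$map_function[1]
  tbl$map_function <- NULL
  class(tbl) <- c("genetic_map", class(tbl))
  attr(tbl, "map_function") <- mf
  tbl
}

#' Pipeline configuration
#'
#' All stage parameters of the end-to-end pipeline with their defaults:
#' sliding window of 20 calls with 10 informative minimum, 3-window minimum
#' run, 15 kb bin grid, Kosambi map function, 1 cM scan step, CIM with 5
#' covariates and a 10 cM exclusion window, 1000 permutations at alpha
#' 0.05, 1.5-LOD support intervals, and the simulation conditions of
#' [ril_sim_config()]. The configuration round-trips through YAML
#' unchanged.
#'
#' @param ... Named overrides of any element (unknown names error).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    window_size = 20,
    min_informative = 10,
    min_run = 3,
    grid_bp = 15000,
    map_function = "kosambi",
    step_cM = 1,
    method = "cim",
    max_cov = 5,
    exclusion_window_cM = 10,
    n_perm = 1000,
    alpha = 0.05,
    drop = 1.5,
    dip = 1,
    seed = 1L,
    simulate = TRUE,
    sim = ril_sim_config(),
    calls_vcf = NULL,
    phenotypes_csv = NULL
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad)) abort(paste0("Unknown pipeline parameter(s): ",
                                paste(bad, collapse = ", ")))
  cfg[names(overrides)] <- overrides
  structure(cfg, class = c("pipeline_config", "list"))
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  ser <- unclass(config)
  ser$sim$qtl_effects <- as.list(as.data.frame(ser$sim$qtl_effects))
  ser$sim$chrom_lengths_bp <- as.list(ser$sim$chrom_lengths_bp)
  ser$sim$genetic_lengths_cM <- as.list(ser$sim$genetic_lengths_cM)
  ser$sim$parent_means <- as.list(ser$sim$parent_means)
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$sim$qtl_effects <- as_tibble(raw$sim$qtl_effects)
  raw$sim$chrom_lengths_bp <- unlist(raw$sim$chrom_lengths_bp)
  raw$sim$genetic_lengths_cM <- unlist(raw$sim$genetic_lengths_cM)
  raw$sim$parent_means <- unlist(raw$sim$parent_means)
  cfg <- pipeline_config()
  cfg[names(raw)] <- raw
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full bin-map / QTL pipeline
#'
#' Executes simulate (optional) -> window calling and breakpoint detection
#' -> bin map -> genetic map -> permutation threshold and scan -> QTL
#' report, writing every artifact plus a manifest to `out_dir`. Identical
#' configuration and seed give byte-identical outputs. Any stage failure
#' aborts with a stage-named error.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `calls`, `phenotypes`, `segments`,
#'   `bin_map`, `genetic_map`, `summary`, `prob_grid`, `threshold`, `scan`,
#'   `report`, and the paths written.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (isTRUE(config$simulate)) {
    pop <- stage("simulate", simulate_ril_population(config$sim))
    calls <- pop$calls
    phenotypes <- pop$phenotypes
  } else {
    calls <- stage("read_calls", {
      if (is.null(config$calls_vcf)) abort("`calls_vcf` is not set.")
      read_origin_calls_vcf(config$calls_vcf)
    })
    phenotypes <- stage("read_phenotypes", {
      if (is.null(config$phenotypes_csv)) abort("`phenotypes_csv` is not set.")
      read_phenotypes(config$phenotypes_csv)
    })
  }
  segments <- stage("callbins",
                    call_segments(calls, config$window_size,
                                  config$min_informative, config$min_run))
  bin_map <- stage("binmap",
                   build_bin_map(segments, config$grid_bp,
                                 calls$chrom_lengths_bp))
  genetic_map <- stage("map",
                       build_genetic_map(bin_map, config$map_function))
  map_summary <- stage("map", binmap_summary(bin_map, genetic_map))
  prob_grid <- stage("scan",
                     genotype_probabilities(bin_map, genetic_map,
                                            config$step_cM))
  threshold <- stage("scan",
                     permutation_threshold(prob_grid, phenotypes,
                                           n_perm = config$n_perm,
                                           alpha = config$alpha,
                                           seed = as.integer(config$seed) + 10L,
                                           method = config$method,
                                           bin_map = bin_map,
                                           genetic_map = genetic_map,
                                           max_cov = config$max_cov,
                                           exclusion_window_cM = config$exclusion_window_cM))
  scan <- stage("scan",
                scan_qtl(prob_grid, phenotypes, method = config$method,
                         bin_map = bin_map, genetic_map = genetic_map,
                         max_cov = config$max_cov,
                         exclusion_window_cM = config$exclusion_window_cM))
  report <- stage("report",
                  qtl_report(scan, threshold, drop = config$drop,
                             dip = config$dip))
  paths <- list(
    calls_vcf = file.path(out_dir, "calls.vcf"),
    phenotypes_csv = file.path(out_dir, "phenotypes.csv"),
    bins_tsv = file.path(out_dir, "bins.tsv"),
    map_tsv = file.path(out_dir, "map.tsv"),
    map_summary_tsv = file.path(out_dir, "map_summary.tsv"),
    scan_tsv = file.path(out_dir, "scan.tsv"),
    report_tsv = file.path(out_dir, "qtl_report.tsv"),
    threshold_json = file.path(out_dir, "threshold.json"),
    manifest_json = file.path(out_dir, "manifest.json"))
  stage("report", {
    write_origin_calls_vcf(calls, paths$calls_vcf)
    write_phenotypes(phenotypes, paths$phenotypes_csv)
    write_bin_map(bin_map, paths$bins_tsv)
    write_genetic_map(genetic_map, paths$map_tsv)
    readr::write_tsv(map_summary, paths$map_summary_tsv)
    readr::write_tsv(as_tibble(scan), paths$scan_tsv)
    readr::write_tsv(as_tibble(report), paths$report_tsv)
    jsonlite::write_json(list(threshold = as.numeric(threshold),
                              n_perm = config$n_perm, alpha = config$alpha),
                         paths$threshold_json, auto_unbox = TRUE, digits = NA)
    manifest <- list(
      package = "ltgmap",
      version = as.character(utils::packageVersion("ltgmap")),
      seed = as.integer(config$seed),
      config_hash = rlang::hash(unclass(config)),
      parameters = list(window_size = config$window_size,
                        min_informative = config$min_informative,
                        min_run = config$min_run, grid_bp = config$grid_bp,
                        map_function = config$map_function,
                        step_cM = config$step_cM, method = config$method,
                        max_cov = config$max_cov,
                        exclusion_window_cM = config$exclusion_window_cM,
                        n_perm = config$n_perm, alpha = config$alpha,
                        drop = config$drop, dip = config$dip))
    jsonlite::write_json(manifest, paths$manifest_json, auto_unbox = TRUE,
                         digits = NA)
  })
  invisible(list(calls = calls, phenotypes = phenotypes, segments = segments,
                 bin_map = bin_map, genetic_map = genetic_map,
                 summary = map_summary, prob_grid = prob_grid,
                 threshold = threshold, scan = scan, report = report,
                 paths = paths))
}
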