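make_panel <- function(geno, classes, positions = NULL) {
  n_mark <- ncol(geno)
  if (is.null(positions)) positions <- seq_len(n_mark) * 1000
  markers <- paste0("M", sprintf("%03d", seq_len(n_mark)))
  tidyr::expand_grid(line = rownames(geno), marker = markers) |>
    dplyr::mutate(pos_bp = positions[match(.data$marker, markers)],
                  genotype = geno[cbind(match(.data$line, rownames(geno)),
                                        match(.data$marker, markers))],
                  class = classes[.data$line])
}

test_that("progeny classification matches the parents it resembles", {
  # a line germinating like LTH is tolerant under both rules
  prog <- tibble::tibble(line = rep("K1", 3), value = c(85, 87, 86))
  expect_equal(classify_progeny(prog, rule = "t_test")$class, "tolerant")
  expect_equal(classify_progeny(prog, rule = "midpoint")$class, "tolerant")
  # a line at exactly the midparent is unclassified under the midpoint rule
  mid <- mean(c(15.4, 86.5))
  tie <- tibble::tibble(line = "K2", value = mid)
  expect_equal(classify_progeny(tie, rule = "midpoint")$class, "unclassified")
  # a line between the parents, far from both, is unclassified by t-test
  amb <- tibble::tibble(line = rep("K3", 4), value = c(49, 50, 51, 52))
  expect_equal(classify_progeny(amb, rule = "t_test")$class, "unclassified")
  expect_error(classify_progeny(tibble::tibble(line = character(),
                                               value = numeric())),
               "empty")
})

test_that("substitution mapping delimits the concordant-intersection interval", {
  geno <- rbind(
    K1 = c("AA", "BB", "BB", "BB", "BB"),  # tolerant, AA at M1 only
    K2 = c("BB", "BB", "BB", "BB", "AA"),  # tolerant, AA at M5 only
    K3 = c("AA", "AA", "AA", "AA", "AA"),  # sensitive everywhere
    K4 = c("BB", "BB", "BB", "AA", "AA"))  # tolerant on M1..M3
  colnames(geno) <- paste0("M", sprintf("%03d", 1:5))
  classes <- c(K1 = "tolerant", K2 = "tolerant", K3 = "sensitive",
               K4 = "tolerant")
  iv <- delimit_interval(make_panel(geno, classes))
  expect_equal(iv$left_marker, "M002")
  expect_equal(iv$right_marker, "M003")
  expect_equal(iv$width_bp, 1000)
  # matches the brute-force oracle
  expect_equal(oracle_delimit(geno, classes, 1:5 * 1000), c(2, 3))
})

test_that("non-recombinant and contradictory panels are handled explicitly", {
  geno <- rbind(K1 = rep("BB", 4), K2 = rep("AA", 4))
  colnames(geno) <- paste0("M", sprintf("%03d", 1:4))
  classes <- c(K1 = "tolerant", K2 = "sensitive")
  expect_warning(iv <- delimit_interval(make_panel(geno, classes)),
                 "whole region")
  expect_equal(c(iv$left_marker, iv$right_marker), c("M001", "M004"))
  # a tolerant line that is AA across the whole region contradicts the model
  bad <- c(K1 = "tolerant", K2 = "tolerant")
  expect_error(suppressWarnings(delimit_interval(make_panel(geno, bad))),
               "contradicts")
  # unclassified lines are dropped with a warning
  geno3 <- rbind(K1 = c("AA", "BB", "BB"), K2 = c("BB", "BB", "AA"),
                 K3 = c("AA", "AA", "AA"))
  colnames(geno3) <- paste0("M", sprintf("%03d", 1:3))
  cls3 <- c(K1 = "tolerant", K2 = "tolerant", K3 = "unclassified")
  expect_warning(iv3 <- delimit_interval(make_panel(geno3, cls3)),
                 "unclassified")
  expect_equal(c(iv3$left_marker, iv3$right_marker), c("M002", "M002"))
})

test_that("delimitation agrees with the brute-force oracle on random panels", {
  withr::with_seed(404, {
    tested <- 0
    for (rep_i in 1:300) {
      n_lines <- sample(1:5, 1)
      n_mark <- sample(2:6, 1)
      geno <- matrix(sample(c("AA", "BB"), n_lines * n_mark, replace = TRUE),
                     n_lines, n_mark,
                     dimnames = list(paste0("K", seq_len(n_lines)),
                                     paste0("M", sprintf("%03d", seq_len(n_mark)))))
      classes <- setNames(sample(c("tolerant", "sensitive"), n_lines,
                                 replace = TRUE), rownames(geno))
      want <- oracle_delimit(geno, classes, seq_len(n_mark) * 1000)
      panel <- make_panel(geno, classes)
      if (is.null(want)) {
        expect_error(suppressWarnings(delimit_interval(panel)))
      } else {
        got <- suppressWarnings(delimit_interval(panel))
        expect_equal(match(got$left_marker, colnames(geno)), want[1],
                     info = paste("case", rep_i))
        expect_equal(match(got$right_marker, colnames(geno)), want[2],
                     info = paste("case", rep_i))
        tested <- tested + 1
      }
    }
    expect_gt(tested, 50)
  })
})

test_that("adding a consistent line never widens the interval", {
  withr::with_seed(505, {
    for (rep_i in 1:30) {
      n_mark <- 6
      qtl_at <- sample(n_mark, 1)
      mk_line <- function() {
        bp <- sort(sample(0:n_mark, sample(0:2, 1)))
        g <- character(n_mark)
        cur <- sample(c("AA", "BB"), 1)
        for (m in seq_len(n_mark)) {
          if (m %in% (bp + 1)) cur <- setdiff(c("AA", "BB"), cur)
          g[m] <- cur
        }
        g
      }
      lines <- lapply(1:4, function(i) mk_line())
      geno <- do.call(rbind, lines)
      rownames(geno) <- paste0("K", 1:4)
      colnames(geno) <- paste0("M", sprintf("%03d", 1:n_mark))
      classes <- setNames(ifelse(geno[, qtl_at] == "BB", "tolerant",
                                 "sensitive"), rownames(geno))
      w3 <- suppressWarnings(
        delimit_interval(make_panel(geno[1:3, , drop = FALSE],
                                    classes[1:3])))$width_bp
      w4 <- suppressWarnings(
        delimit_interval(make_panel(geno, classes)))$width_bp
      expect_lte(w4, w3)
    }
  })
})

test_that("candidate genes overlap the interval and survive coordinate quirks", {
  genes <- qltg6_gene_reference()
  span <- range(c(genes$start_bp, genes$end_bp))
  hits <- candidate_genes(genes, span)
  expect_equal(nrow(hits), 7)
  expect_equal(hits$gene_id[1], "LOC_Os06g01250")
  expect_equal(hits$gene_id[7], "LOC_Os06g01320")
  # reversed (minus-strand) coordinates are normalised
  expect_true(all(hits$start_bp <= hits$end_bp))
  # row order of the input does not matter
  shuffled <- candidate_genes(genes[sample(7), ], span)
  expect_equal(shuffled$gene_id, hits$gene_id)
  # zero-width interval between genes -> no genes
  expect_equal(nrow(candidate_genes(genes, c(166000, 166000))), 0)
  # a gene straddling the left endpoint is included
  expect_equal(candidate_genes(genes, c(165000, 166000))$gene_id,
               "LOC_Os06g01250")
  expect_equal(nrow(candidate_genes(genes[0, ], c(1, 2))), 0)
})

test_that("annotation files round-trip through the TSV reader", {
  genes <- qltg6_gene_reference()
  f <- tempfile(fileext = ".tsv")
  readr::write_tsv(genes, f)
  back <- read_gene_annotation(f)
  expect_equal(back$gene_id, genes$gene_id)
  expect_true(all(back$start_bp <= back$end_bp))
  # the reversed entry is normalised on load
  rev_row <- back[back$gene_id == "LOC_Os06g01270", ]
  expect_equal(c(rev_row$start_bp, rev_row$end_bp), c(178343, 178580))
})
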