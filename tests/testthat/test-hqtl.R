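make_toy_windows <- function() {
  make_windows(data.frame(chrom = c("A01", "C01"), length = c(1e6, 5e5)), 1e5)
}

test_that("window-heterosis correlations match the direct Pearson formula", {
  set.seed(40)
  w <- make_toy_windows()
  n <- 20
  P <- matrix(runif(n * nrow(w)), n, nrow(w),
              dimnames = list(sprintf("H%02d", 1:n), window_keys(w)))
  attr(P, "windows") <- w
  class(P) <- c("pgsi_matrix", "matrix", "array")
  het <- data.frame(hybrid_id = rownames(P), female_id = "F", male_id = "M",
                    trait = "GY", F1 = NA, HP = NA, MP = NA,
                    HPH = -P[, 3] + rnorm(n, 0, 1e-9), MPH = rnorm(n))
  wc <- window_heterosis_correlations(P, het, "GY", "HPH")
  expect_equal(wc$r[3], -1, tolerance = 1e-6)
  wc2 <- window_heterosis_correlations(P, het, "GY", "MPH")
  for (j in c(1, 5, 9))
    expect_equal(wc2$r[j], cor(P[, j], het$MPH), tolerance = 1e-12)
  # constant PGSI column has no defined correlation
  P2 <- P; P2[, 2] <- 0.5
  wc3 <- window_heterosis_correlations(P2, het, "GY", "MPH")
  expect_true(is.na(wc3$r[2]))
})

test_that("chromosome influence stacks absolute correlations and aggregates subgenomes", {
  corr <- data.frame(window = c("a", "b", "c"),
                     chrom = c("A01", "A01", "C01"),
                     start = c(0, 1e5, 0), end = c(1e5, 2e5, 1e5),
                     trait = "GY", heterosis_type = "HPH",
                     r = c(0.1, -0.2, 0.5), n = 20)
  infl <- chromosome_influence(corr)
  expect_equal(infl$influence[infl$chrom == "A01"], 0.3)
  expect_equal(infl$influence[infl$chrom == "C01"], 0.5)
  expect_equal(unname(attr(infl, "subgenome")[c("A", "C")]), c(0.3, 0.5))
  # missing r contributes zero; invariant to row order
  corr$r[1] <- NA
  i2 <- chromosome_influence(corr)
  i3 <- chromosome_influence(corr[c(3, 1, 2), ])
  expect_equal(i2$influence[i2$chrom == "A01"], 0.2)
  expect_equal(i2, i3)
})

test_that("h-QTL extraction flags top and bottom deciles with stable tie-breaks", {
  w <- make_toy_windows()
  keys <- window_keys(w)
  sel <- keys[1:15]
  coefs <- stats::setNames(seq(-0.7, 0.7, length.out = 15), sel)
  fit <- structure(list(selected = sel, coef = coefs, feature_keys = keys,
                        empty = FALSE),
                   class = "lasso_fit")
  hq <- extract_hqtls(fit, w, trait = "GY", which = "HPH")
  expect_equal(nrow(hq), 15L)
  # ceil(0.1 * 15) = 2 at each end
  expect_equal(sum(hq$impact == "high"), 4L)
  hi <- hq[hq$impact == "high", ]
  expect_setequal(round(hi$coefficient, 10),
                  round(c(sort(coefs)[1:2], sort(coefs, decreasing = TRUE)[1:2]), 10))
  # negative coefficient = dissimilarity-favoring = "positive" effect
  expect_true(all(hq$effect[hq$coefficient < 0] == "positive"))
  expect_true(all(hq$effect[hq$coefficient > 0] == "negative"))
  expect_true(all(hq$mappable))
  # intercept-only fit gives an empty record set
  f0 <- structure(list(selected = character(0), coef = numeric(0),
                       feature_keys = keys, empty = TRUE),
                  class = "lasso_fit")
  expect_message(h0 <- extract_hqtls(f0, w), "no h-QTL")
  expect_equal(nrow(h0), 0L)
})

test_that("20 selected windows give exactly 2 + 2 high-impact records", {
  w <- make_windows(data.frame(chrom = "A01", length = 2e6), 1e5)
  keys <- window_keys(w)
  set.seed(41)
  coefs <- stats::setNames(rnorm(20), keys)
  fit <- structure(list(selected = keys, coef = coefs, feature_keys = keys,
                        empty = FALSE), class = "lasso_fit")
  hq <- extract_hqtls(fit, w)
  expect_equal(sum(hq$impact == "high"), 4L)
})

test_that("naming numbers h-QTLs from the chromosome top, stable under shuffling", {
  rec <- data.frame(name = NA_character_,
                    chrom = c("C01", "C01", "A05"),
                    start = c(1.2e6, 0.3e6, 5e5),
                    end = c(1.3e6, 0.4e6, 6e5),
                    coefficient = c(1, -1, 0.5),
                    effect = "negative", impact = "regular", mappable = TRUE,
                    trait = "GY", heterosis_type = "HPH",
                    stringsAsFactors = FALSE)
  named <- name_hqtls(rec)
  expect_equal(named$name[named$start == 0.3e6], "Chr.C01-01")
  expect_equal(named$name[named$start == 1.2e6], "Chr.C01-02")
  expect_equal(named$name[named$chrom == "A05"], "Chr.A05-01")
  shuffled <- name_hqtls(rec[c(3, 1, 2), ])
  expect_equal(shuffled, named)
  # padding grows past 99 records on one chromosome
  many <- data.frame(name = NA_character_, chrom = "A01",
                     start = (0:119) * 1e5, end = (1:120) * 1e5,
                     coefficient = 1, effect = "negative", impact = "regular",
                     mappable = TRUE, trait = "GY", heterosis_type = "HPH")
  nm <- name_hqtls(many)
  expect_equal(nm$name[1], "Chr.A01-001")
  expect_equal(nm$name[120], "Chr.A01-120")
})

test_that("gene lookup intersects half-open windows against a GFF3 annotation", {
  genes <- data.frame(chrom = c("A01", "A01", "A01", "C01"),
                      start1 = c(150001, 199950, 200001, 10),
                      end1 = c(160000, 200050, 210000, 40),
                      id = c("inside", "spanning", "abutting", "otherchrom"))
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_toy_gff3(gff, genes)
  rec <- data.frame(name = "Chr.A01-01", chrom = "A01",
                    start = 1e5, end = 2e5, coefficient = -1,
                    effect = "positive", impact = "high", mappable = TRUE,
                    trait = "GY", heterosis_type = "HPH",
                    stringsAsFactors = FALSE)
  res <- genes_in_windows(rec, gff)
  # window [1e5, 2e5): gene starting exactly at window end (200001 in 1-based
  # = position 2e5 in 0-based) is excluded by the half-open convention
  expect_setequal(res[["Chr.A01-01"]], c("inside", "spanning"))
  # brute-force interval scan oracle on a random window set
  set.seed(42)
  genes2 <- data.frame(chrom = "A01",
                       start1 = sort(sample.int(9e5, 10)),
                       id = sprintf("g%02d", 1:10))
  genes2$end1 <- genes2$start1 + sample.int(5e4, 10)
  gff2 <- withr::local_tempfile(fileext = ".gff3")
  write_toy_gff3(gff2, genes2)
  w <- make_toy_windows()
  rec2 <- data.frame(name = sprintf("W%d", 1:4), chrom = "A01",
                     start = c(0, 2e5, 5e5, 8e5), end = c(1e5, 3e5, 6e5, 9e5),
                     coefficient = 1, effect = "negative", impact = "regular",
                     mappable = TRUE, trait = "GY", heterosis_type = "HPH",
                     stringsAsFactors = FALSE)
  res2 <- genes_in_windows(rec2, gff2)
  for (i in 1:4) {
    hits <- genes2$id[genes2$start1 <= rec2$end[i] &
                        genes2$end1 >= rec2$start[i] + 1]
    expect_setequal(res2[[rec2$name[i]]], hits)
  }
})

test_that("h-QTL tables export as TSV plus a BED track", {
  rec <- data.frame(name = c("Chr.A01-01", "Chr.Scf-01"),
                    chrom = c("A01", "Scaffold9"), start = c(0, 0),
                    end = c(1e5, 1e5), coefficient = c(-0.4, 0.2),
                    effect = c("positive", "negative"),
                    impact = c("high", "regular"),
                    mappable = c(TRUE, FALSE),
                    trait = "GY", heterosis_type = "HPH",
                    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hqtl_tsv(rec, f)
  back <- read.delim(f)
  expect_equal(nrow(back), 2L)
  bed <- read.delim(sub("\\.tsv$", ".bed", f), header = FALSE)
  expect_equal(nrow(bed), 1L)  # unmappable records stay out of the track
})
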