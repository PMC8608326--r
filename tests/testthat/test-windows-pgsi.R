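test_that("window partition is contiguous, half-open, with a short last window", {
  w <- make_windows(data.frame(chrom = "A01", length = 250), 100)
  expect_equal(w$start, c(0, 100, 200))
  expect_equal(w$end, c(100, 200, 250))
  expect_equal(w$index_on_chrom, 1:3)
  w2 <- make_windows(data.frame(chrom = c("A01", "C01"), length = c(100, 50)), 100)
  expect_equal(nrow(w2), 2L)
  expect_equal(window_keys(w2), c("A01:0-100", "C01:0-50"))
  # ceil(length/width) windows per chromosome on a larger table
  tab <- data.frame(chrom = sprintf("A%02d", 1:5),
                    length = c(1e6, 1.5e6, 999999, 2e6 + 1, 5e5))
  for (width in c(1e5, 5e5, 1e6))
    expect_equal(nrow(make_windows(tab, width)), sum(ceiling(tab$length / width)))
  expect_error(make_windows(data.frame(chrom = c("A01", "A01"),
                                       length = c(10, 10)), 5), "duplicate")
})

test_that("windows can be built from an FAI-style file", {
  path <- withr::local_tempfile(fileext = ".fai")
  writeLines(c("A01\t300\t10\t60\t61", "C01\t120\t400\t60\t61"), path)
  w <- make_windows(path, 100)
  expect_equal(nrow(w), 3 + 2)
  expect_equal(attr(w, "width"), 100)
})

test_that("site marks follow the 2/1/0 similarity rule on all allele pairs", {
  ref <- "A"; alts <- c("C", "G", "T")
  all_nt <- c(ref, alts)
  for (p1 in all_nt) for (p2 in all_nt) {
    expected <- if (p1 == p2) 2L
      else if (p1 == ref || p2 == ref) 1L
      else 0L
    expect_identical(site_mark(p1, p2, ref), expected)
  }
  expect_error(site_mark("A", NA, "A"), "missing")
})

test_that("block PGSI normalizes marks to [0,1]; literal mode kept for audit", {
  expect_equal(block_pgsi(c(2, 2, 2, 2)), 1)
  expect_equal(block_pgsi(c(1, 1)), 0.5)
  expect_equal(block_pgsi(c(2, 0)), 0.5)
  expect_equal(block_pgsi(c(0, 0)), 0)
  expect_equal(block_pgsi(c(1, 1), literal = TRUE), 2)
  expect_true(is.na(block_pgsi(integer(0))))
})

test_that("identical parents score 1 everywhere; ref-hom vs alt-hom scores 0.5", {
  g <- random_parent_geno(2, 60, seed = 3, miss_rate = 0)
  g$a1[, 2] <- g$a1[, 1]; g$a2[, 2] <- g$a2[, 1]
  plan <- data.frame(female_id = "S01", male_id = "S02", hybrid_id = "H1")
  w <- make_windows(data.frame(chrom = c("A01", "C01"), length = c(1000, 1000)), 250)
  p <- compute_pgsi_matrix(g, plan, w)
  expect_true(all(p[1, attr(p, "n_loci")[1, ] > 0] == 1))
  # one parent all reference, the other all alternate: every site marks 1
  g2 <- g
  g2$a1[, 1] <- 0L; g2$a2[, 1] <- 0L
  g2$a1[, 2] <- 1L; g2$a2[, 2] <- 1L
  p2 <- compute_pgsi_matrix(g2, plan, w)
  expect_true(all(p2[1, attr(p2, "n_loci")[1, ] > 0] == 0.5))
})

test_that("PGSI matrix equals the brute-force per-site oracle", {
  for (seed in 1:6) {
    g <- random_parent_geno(5, 80, seed = seed, miss_rate = 0.1, multi_rate = 0.1)
    plan <- random_plan(g, 4, seed = seed + 100)
    w <- make_windows(data.frame(chrom = c("A01", "C01"), length = c(1000, 1000)),
                      sample(c(150, 250, 400), 1))
    got <- suppressMessages(compute_pgsi_matrix(g, plan, w))
    want <- pgsi_oracle(g, plan, w)
    expect_equal(unclass(got), want, ignore_attr = TRUE, tolerance = 1e-12)
    got_lit <- suppressMessages(compute_pgsi_matrix(g, plan, w, literal = TRUE,
                                                    empty = "missing"))
    want_lit <- pgsi_oracle(g, plan, w, literal = TRUE, empty = "missing")
    expect_equal(unclass(got_lit), want_lit, ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("PGSI is symmetric in the parents and monotone in site agreement", {
  g <- random_parent_geno(4, 60, seed = 12, miss_rate = 0)
  w <- make_windows(data.frame(chrom = c("A01", "C01"), length = c(1000, 1000)), 500)
  plan_fm <- data.frame(female_id = "S01", male_id = "S02", hybrid_id = "H1")
  plan_mf <- data.frame(female_id = "S02", male_id = "S01", hybrid_id = "H1")
  expect_equal(unclass(compute_pgsi_matrix(g, plan_fm, w)),
               unclass(compute_pgsi_matrix(g, plan_mf, w)),
               ignore_attr = TRUE)
  # flipping one agreeing site to disagreement never raises its window PGSI
  agree <- which(g$a1[, 1] == g$a1[, 2])[1]
  g2 <- g
  g2$a1[agree, 2] <- 1L - g2$a1[agree, 2]
  g2$a2[agree, 2] <- g2$a1[agree, 2]
  p_before <- compute_pgsi_matrix(g, plan_fm, w)
  p_after <- compute_pgsi_matrix(g2, plan_fm, w)
  expect_true(all(p_after <= p_before + 1e-12))
})

test_that("merging two windows gives the locus-weighted mean of their PGSIs", {
  g <- random_parent_geno(4, 100, seed = 30, miss_rate = 0.05,
                          chroms = "A01", chrom_len = 1000)
  plan <- random_plan(g, 3, seed = 31)
  w_fine <- make_windows(data.frame(chrom = "A01", length = 1000), 250)
  w_coarse <- make_windows(data.frame(chrom = "A01", length = 1000), 500)
  pf <- suppressMessages(compute_pgsi_matrix(g, plan, w_fine, empty = "missing"))
  pc <- suppressMessages(compute_pgsi_matrix(g, plan, w_coarse, empty = "missing"))
  nf <- attr(pf, "n_loci")
  for (ci in 1:3) for (wc in 1:2) {
    parts <- (2 * wc - 1):(2 * wc)
    n <- nf[ci, parts]
    if (sum(n) == 0) next
    expect_equal(unname(pc[ci, wc]),
                 sum(pf[ci, parts] * n, na.rm = TRUE) / sum(n))
  }
})

test_that("empty windows follow the configured policy and are flagged", {
  g <- random_parent_geno(2, 10, seed = 8, miss_rate = 0, chroms = "A01",
                          chrom_len = 400)
  plan <- data.frame(female_id = "S01", male_id = "S02", hybrid_id = "H1")
  w <- make_windows(data.frame(chrom = c("A01", "C09"), length = c(400, 400)), 200)
  p1 <- compute_pgsi_matrix(g, plan, w)
  expect_true(all(p1[1, grepl("^C09", colnames(p1))] == 1))
  expect_true(all(attr(p1, "empty_cells")[1, grepl("^C09", colnames(p1))]))
  p2 <- compute_pgsi_matrix(g, plan, w, empty = "missing")
  expect_true(all(is.na(p2[1, grepl("^C09", colnames(p2))])))
  g_bad <- g; g_bad$chrom <- rep("Z01", length(g$chrom))
  expect_error(compute_pgsi_matrix(g_bad, plan, w), "disjoint")
})

test_that("PGSI TSV round-trips and windows export as BED", {
  g <- random_parent_geno(3, 40, seed = 14, miss_rate = 0)
  plan <- random_plan(g, 2, seed = 15)
  w <- make_windows(data.frame(chrom = c("A01", "C01"), length = c(1000, 1000)), 500)
  p <- suppressMessages(compute_pgsi_matrix(g, plan, w))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pgsi_tsv(p, f)
  back <- read_pgsi_tsv(f)
  expect_equal(back, unclass(p), ignore_attr = TRUE)
  b <- withr::local_tempfile(fileext = ".bed")
  write_windows_bed(w, b)
  bed <- read.delim(b, header = FALSE)
  expect_equal(nrow(bed), nrow(w))
  expect_equal(bed$V2, as.integer(w$start))
})
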