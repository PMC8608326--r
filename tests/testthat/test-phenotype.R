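test_that("single-environment BLUEs are replicate means; variance comps degenerate", {
  gv <- c(G1 = 10, G2 = 12, G3 = 9)
  rec <- make_records(gv, environments = "E1", reps = 1:3, noise = 1, seed = 4)
  fit <- fit_blue(rec, "T1")
  means <- c(tapply(rec$value, rec$sample_id, mean))
  expect_equal(fit$blue[names(means)], means)
  expect_true(all(is.na(fit$varcomp)))
})

test_that("balanced two-environment data: BLUE differences equal raw mean differences", {
  gv <- c(G1 = 10, G2 = 12, G3 = 9, G4 = 14)
  rec <- rbind(make_records(gv, "E1", 1:3, noise = 0.5, seed = 1),
               make_records(gv, "E2", 1:3, noise = 0.5, seed = 2,
                            env_offset = 3))
  fit <- fit_blue(rec, "T1")
  raw <- tapply(rec$value, rec$sample_id, mean)
  d_blue <- outer(fit$blue, fit$blue, "-")
  d_raw <- outer(raw[names(fit$blue)], raw[names(fit$blue)], "-")
  expect_equal(d_blue, d_raw, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("unbalanced layout matches the lme4 REML oracle", {
  skip_if_not_installed("lme4")
  set.seed(77)
  gv <- stats::setNames(rnorm(8, 20, 2), sprintf("G%d", 1:8))
  rec <- rbind(make_records(gv, "E1", 1:3, noise = 1, seed = 5),
               make_records(gv, "E2", 1:2, noise = 1, seed = 6, env_offset = 2),
               make_records(gv, "E3", 1:3, noise = 1, seed = 7, env_offset = -1))
  # unbalance: drop some genotype x environment cells entirely
  drop_rows <- with(rec, (sample_id == "G2" & environment == "E3") |
                      (sample_id == "G5" & environment == "E1"))
  rec <- rec[!drop_rows, ]
  fit <- fit_blue(rec, "T1")
  ge <- stats::aggregate(value ~ sample_id + environment, rec, mean)
  lfit <- lme4::lmer(value ~ 0 + sample_id + (1 | environment), data = ge,
                     REML = TRUE)
  oracle <- lme4::fixef(lfit)
  names(oracle) <- sub("^sample_id", "", names(oracle))
  expect_equal(fit$blue[names(oracle)], oracle, tolerance = 1e-6)
  vc <- as.data.frame(lme4::VarCorr(lfit))
  expect_equal(unname(fit$varcomp["environment"]),
               vc$vcov[vc$grp == "environment"], tolerance = 1e-4)
  expect_equal(unname(fit$varcomp["residual"]),
               vc$vcov[vc$grp == "Residual"], tolerance = 1e-4)
})

test_that("heterosis follows the high/mid-parent definitions", {
  blues <- data.frame(row.names = c("H1", "P1", "P2"), GY = c(150, 120, 100))
  plan <- data.frame(female_id = "P1", male_id = "P2", hybrid_id = "H1")
  h <- compute_heterosis(blues, plan)
  expect_equal(h$HPH, 0.25)
  expect_equal(h$MPH, (150 - 110) / 110, tolerance = 1e-12)
  # F1 equal to the better parent
  blues$GY <- c(120, 120, 100)
  expect_equal(compute_heterosis(blues, plan)$HPH, 0)
  # F1 at midparent: MPH 0, HPH <= 0
  blues$GY <- c(110, 120, 100)
  h3 <- compute_heterosis(blues, plan)
  expect_equal(h3$MPH, 0)
  expect_lte(h3$HPH, 0)
  # non-positive denominator -> missing with warning
  blues$GY <- c(5, -1, -3)
  expect_warning(h4 <- compute_heterosis(blues, plan), "denominator")
  expect_true(is.na(h4$HPH) && is.na(h4$MPH))
})

test_that("heterosis is scale-free and symmetric in parent labels", {
  set.seed(3)
  ids <- c(sprintf("H%d", 1:6), sprintf("F%d", 1:3), sprintf("M%d", 1:2))
  blues <- data.frame(row.names = ids, GY = runif(11, 50, 150))
  plan <- data.frame(female_id = rep(sprintf("F%d", 1:3), 2),
                     male_id = rep(sprintf("M%d", 1:2), 3),
                     hybrid_id = sprintf("H%d", 1:6))
  h1 <- compute_heterosis(blues, plan)
  h2 <- compute_heterosis(blues * 7, plan)
  expect_equal(h1$HPH, h2$HPH, tolerance = 1e-12)
  expect_equal(h1$MPH, h2$MPH, tolerance = 1e-12)
  plan_sw <- data.frame(female_id = plan$male_id, male_id = plan$female_id,
                        hybrid_id = plan$hybrid_id)
  h3 <- compute_heterosis(blues, plan_sw)
  expect_equal(h1$HPH, h3$HPH)
  expect_equal(h1$MPH, h3$MPH)
})

test_that("trait correlations match the direct Pearson formula", {
  set.seed(10)
  tbl <- data.frame(A = rnorm(10))
  tbl$B <- 2 * tbl$A
  tbl$C <- -tbl$A + 5
  tbl$D <- rnorm(10)
  r <- trait_correlation_matrix(tbl)
  expect_equal(unname(r["A", "B"]), 1)
  expect_equal(unname(r["A", "C"]), -1)
  pearson <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(unname(r["A", "D"]), pearson(tbl$A, tbl$D), tolerance = 1e-12)
  tbl$E <- 1
  expect_true(is.na(trait_correlation_matrix(tbl)["A", "E"]))
})

test_that("parent-offspring correlations recover exact parental dependence", {
  set.seed(12)
  fem <- sprintf("F%d", 1:10); mal <- sprintf("M%d", 1:3)
  plan <- expand.grid(female_id = fem, male_id = mal, stringsAsFactors = FALSE)
  plan$hybrid_id <- paste0(plan$female_id, "x", plan$male_id)
  pv <- stats::setNames(rnorm(13, 100, 10), c(fem, mal))
  blues <- data.frame(row.names = c(names(pv), plan$hybrid_id),
                      GY = c(pv, pv[plan$male_id]))
  expect_equal(unname(parent_offspring_correlation(blues, plan, "male")["GY"]), 1)
  blues2 <- blues
  blues2[plan$hybrid_id, "GY"] <- (pv[plan$female_id] + pv[plan$male_id]) / 2
  expect_equal(unname(parent_offspring_correlation(blues2, plan, "midparent")["GY"]), 1)
  # against the plain formula on random hybrids
  blues3 <- blues
  blues3[plan$hybrid_id, "GY"] <- rnorm(nrow(plan), 100, 5)
  r <- parent_offspring_correlation(blues3, plan, "female")
  expect_equal(unname(r["GY"]),
               cor(blues3[plan$hybrid_id, "GY"], pv[plan$female_id]),
               tolerance = 1e-12)
})

test_that("top-fraction summary ranks, counts and averages correctly", {
  het <- data.frame(hybrid_id = sprintf("H%d", 1:10), female_id = "F",
                    male_id = "M", trait = "GY", F1 = NA, HP = NA, MP = NA,
                    HPH = seq(0.1, 1, by = 0.1), MPH = seq(0.1, 1, by = 0.1))
  s <- top_fraction_summary(het, "GY", "HPH", 0.1)
  expect_equal(s$mean, 1)
  expect_equal(s$n_selected, 1L)
  expect_equal(top_fraction_summary(het, "GY", "HPH", 1)$mean, mean(het$HPH))
  # ceil count contract at n = 400
  het400 <- het[rep(1:10, 40), ]
  het400$hybrid_id <- sprintf("H%d", 1:400)
  expect_equal(top_fraction_summary(het400, "GY", "HPH", 0.1)$n_selected, 40L)
  # monotone non-increasing in fraction
  ms <- vapply(c(0.1, 0.3, 0.6, 1), function(f)
    top_fraction_summary(het, "GY", "HPH", f)$mean, numeric(1))
  expect_true(all(diff(ms) <= 1e-12))
})

test_that("heterosis export writes rounded percent columns", {
  het <- data.frame(hybrid_id = c("H1", "H2"), female_id = "F", male_id = "M",
                    trait = "GY", F1 = NA, HP = NA, MP = NA,
                    HPH = c(0.12345, -0.2), MPH = c(0.5, 0.25))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_heterosis_tsv(het, f)
  out <- read.delim(f)
  expect_equal(out$GY_HPH_pct, c(12.35, -20))
  expect_equal(out$GY_MPH_pct, c(50, 25))
})
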