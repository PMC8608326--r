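#' Simulation configuration for a synthetic cross population
#'
#' The defaults emulate the design of a factorial hybrid trial in an
#' Ogura-CMS breeding scheme: 50 homozygous female (CMS) lines crossed
#' to 8 homozygous male (restorer) lines giving 400 F1s, phenotyped for
#' six agronomic traits in 3 environments with 3 replicates, with
#' window-structured similarity effects on heterosis. The default
#' genome is deliberately small (4 chromosomes of 5 Mb at 1 SNP/kb) so
#' the full pipeline runs in minutes; `paper_scale_shape = TRUE`
#' switches to 19 A/C-named chromosomes for naming/subgenome logic.
#'
#' Trait architecture per trait: hybrid genetic value =
#' mu + GCA_female + GCA_male + sum_w beta_w PGSI_w(cross); parental
#' value = mu + 2 GCA - delta (inbreeding depression); observed value =
#' genetic value + environment offset + replicate noise. Window effects
#' are scaled so they explain `pgsi_var_frac` of the hybrid genetic
#' variance (total genetic variance is 1 on the trait scale), and
#' replicate noise is set from the entry-mean heritability `h2`.
#'
#' @param n_females,n_males,n_test_males Parent counts; test males feed
#'   an independent validation population (e.g. 2 x 50 = 100 hybrids).
#' @param chromosomes Named numeric vector of chromosome lengths (bp).
#' @param snp_per_bp SNP density (default 1/kb).
#' @param founder_pool_size Founder haplotypes per chromosome mosaic.
#' @param segment_length Mosaic segment length in bp (block LD scale).
#' @param window_width Width of the effect windows (bp).
#' @param n_window_neg,n_window_pos Planted windows with negative
#'   (dissimilarity-favoring) and positive PGSI coefficients.
#' @param pgsi_var_frac Fraction of hybrid genetic variance explained
#'   by the planted windows (remainder split between the two GCA terms).
#' @param h2 Entry-mean heritability of the hybrid genetic value.
#' @param mu Trait mean (kept large so heterosis denominators stay
#'   positive).
#' @param delta Inbreeding depression of the parents, in genetic-SD
#'   units (makes mid-parent heterosis visibly positive).
#' @param n_env,n_rep Environments and replicates per environment.
#' @param env_sd SD of the random environment offsets.
#' @param traits Trait names to simulate.
#' @param paper_scale_shape Use a 19-chromosome A/C genome shape.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_females = 50, n_males = 8, n_test_males = 0,
                       chromosomes = NULL, snp_per_bp = 1e-3,
                       founder_pool_size = 8, segment_length = 2.5e5,
                       window_width = 1e5,
                       n_window_neg = 10, n_window_pos = 10,
                       pgsi_var_frac = 0.5, h2 = 0.7,
                       mu = 10, delta = 0.5,
                       n_env = 3, n_rep = 3, env_sd = 0.5,
                       traits = c("PH", "NBP", "NSP", "NSS", "TSW", "GY"),
                       paper_scale_shape = FALSE) {
  if (is.null(chromosomes)) {
    chromosomes <- if (paper_scale_shape) {
      stats::setNames(rep(2e6, 19),
                      c(sprintf("A%02d", 1:10), sprintf("C%02d", 1:9)))
    } else c(A01 = 5e6, A02 = 5e6, C01 = 5e6, C02 = 5e6)
  }
  chromosomes <- unlist(chromosomes)  # tolerate YAML-style lists
  traits <- as.character(unlist(traits))
  cfg <- list(n_females = n_females, n_males = n_males,
              n_test_males = n_test_males, chromosomes = chromosomes,
              snp_per_bp = snp_per_bp, founder_pool_size = founder_pool_size,
              segment_length = segment_length, window_width = window_width,
              n_window_neg = n_window_neg, n_window_pos = n_window_pos,
              pgsi_var_frac = pgsi_var_frac, h2 = h2, mu = mu, delta = delta,
              n_env = n_env, n_rep = n_rep, env_sd = env_sd, traits = traits)
  stopifnot(n_females >= 1, n_males >= 1, founder_pool_size >= 1,
            snp_per_bp > 0, pgsi_var_frac >= 0, pgsi_var_frac <= 1,
            h2 > 0, h2 <= 1, n_env >= 1, n_rep >= 1, env_sd >= 0)
  class(cfg) <- "sim_config"
  cfg
}

.parent_ids <- function(config) {
  list(females = sprintf("F%02d", seq_len(config$n_females)),
       males = sprintf("M%02d", seq_len(config$n_males)),
       test_males = if (config$n_test_males > 0)
         sprintf("T%02d", seq_len(config$n_test_males)) else character(0))
}

#' Simulate inbred parent genomes
#'
#' Founder haplotypes are drawn per site from alternate-allele
#' frequencies distributed Beta(0.5, 0.5) truncated to (0.05, 0.95);
#' each inbred parent is a homozygous mosaic of founder haplotypes in
#' fixed-grid segments of the configured length, creating block-wise
#' linkage disequilibrium.
#'
#' @param config A [sim_config].
#' @param seed Integer seed.
#' @return List: `geno` (a [parent_geno] with females, males, and any
#'   test males), `chrom_sizes` (data frame), `alt_freq` (the drawn
#'   per-site alternate-allele frequencies).
#' @export
simulate_parent_genomes <- function(config, seed) {
  ids <- .parent_ids(config)
  samples <- c(ids$females, ids$males, ids$test_males)
  with_seed(seed, {
    chrom <- pos <- NULL
    for (ch in names(config$chromosomes)) {
      len <- config$chromosomes[[ch]]
      n_snp <- round(len * config$snp_per_bp)
      if (n_snp < 1)
        stop_user("snp density x length gives no SNPs on chromosome ", ch)
      p <- sort(sample.int(len, n_snp))
      chrom <- c(chrom, rep(ch, n_snp)); pos <- c(pos, p)
    }
    n_sites <- length(pos)
    nts <- c("A", "C", "G", "T")
    ref <- sample(nts, n_sites, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(nts, r), 1), "")
    # truncated Beta(0.5, 0.5) via inverse CDF on the truncated range
    lo <- stats::pbeta(0.05, 0.5, 0.5); hi <- stats::pbeta(0.95, 0.5, 0.5)
    alt_freq <- stats::qbeta(stats::runif(n_sites, lo, hi), 0.5, 0.5)
    founders <- matrix(stats::rbinom(n_sites * config$founder_pool_size,
                                     1, alt_freq),
                       nrow = n_sites)
    seg <- (pos - 1) %/% config$segment_length
    seg_id <- paste(chrom, seg)
    seg_f <- factor(seg_id, levels = unique(seg_id))
    n_seg <- nlevels(seg_f)
    a <- matrix(NA_integer_, n_sites, length(samples))
    for (j in seq_along(samples)) {
      pick <- sample.int(config$founder_pool_size, n_seg, replace = TRUE)
      a[, j] <- founders[cbind(seq_len(n_sites), pick[as.integer(seg_f)])]
    }
    geno <- parent_geno(chrom, pos, ref, as.list(alt), a1 = a, a2 = a,
                        samples = samples)
    list(geno = geno,
         chrom_sizes = data.frame(chrom = names(config$chromosomes),
                                  length = as.numeric(config$chromosomes),
                                  stringsAsFactors = FALSE),
         alt_freq = alt_freq)
  })
}

#' Build the factorial cross plan
#'
#' Full factorial of females x males; with `test = TRUE`, females x
#' test males (the independent validation population).
#'
#' @param config A [sim_config].
#' @param test Return the held-out test plan instead of the training
#'   plan.
#' @return A cross-plan data frame.
#' @export
make_cross_plan <- function(config, test = FALSE) {
  ids <- .parent_ids(config)
  males <- if (test) {
    if (length(ids$test_males) == 0)
      stop_user("config has no test males (n_test_males = 0)")
    ids$test_males
  } else ids$males
  grid <- expand.grid(female_id = ids$females, male_id = males,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$hybrid_id <- paste(grid$female_id, grid$male_id, sep = "x")
  validate_cross_plan(grid)
}

#' Plant window-level heterosis effects
#'
#' Samples disjoint windows without replacement; `n_window_neg` of them
#' get negative PGSI coefficients (dissimilarity-favoring) and
#' `n_window_pos` positive ones. Raw magnitudes are |N(0,1)| + 0.5;
#' [simulate_phenotypes] rescales them per trait so the planted windows
#' explain `pgsi_var_frac` of the hybrid genetic variance, and the
#' final scaled coefficients are written back into the truth object.
#'
#' @param windows A `genome_windows` object.
#' @param config A [sim_config].
#' @param seed Integer seed.
#' @return A `sim_truth` list: `window_idx`, `window_key`, `beta`
#'   (raw, pre-scaling), `scaled` flag.
#' @export
plant_window_effects <- function(windows, config, seed) {
  n_eff <- config$n_window_neg + config$n_window_pos
  if (n_eff > nrow(windows))
    stop_user("more effect windows requested than windows available")
  with_seed(seed, {
    idx <- sort(sample.int(nrow(windows), n_eff))
    signs <- sample(c(rep(-1, config$n_window_neg), rep(1, config$n_window_pos)))
    beta <- signs * (abs(stats::rnorm(n_eff)) + 0.5)
    structure(list(window_idx = idx, window_key = window_keys(windows)[idx],
                   beta = beta, scaled = FALSE),
              class = "sim_truth")
  })
}

#' Simulate multi-environment phenotypes for parents and hybrids
#'
#' Applies the generative trait model described in [sim_config] to one
#' trait, using the realized PGSI of the planted windows for the given
#' cross plan. Window coefficients and the two GCA vectors are scaled
#' empirically so the window term explains exactly `pgsi_var_frac` of a
#' unit hybrid genetic variance.
#'
#' @param parents Output of [simulate_parent_genomes] (`$geno`).
#' @param plan Training cross plan; `test_plan` optional extra plan
#'   whose hybrids are phenotyped with the same truth.
#' @param truth A `sim_truth` from [plant_window_effects].
#' @param windows The `genome_windows` the truth refers to.
#' @param config A [sim_config].
#' @param seed Integer seed.
#' @param trait Trait name recorded in the output.
#' @param test_plan Optional held-out cross plan.
#' @param pgsi Optional precomputed PGSI matrix over `windows` for the
#'   combined training + test plan (avoids recomputation per trait).
#' @return List: `records` (long phenotype data frame for parents and
#'   all hybrids), `truth` (with scaled `beta`, `gca_f`, `gca_m`,
#'   `env_offsets`, `noise_sd`), `genetic_values` (named vector).
#' @export
simulate_phenotypes <- function(parents, plan, truth, windows, config, seed,
                                trait = "GY", test_plan = NULL, pgsi = NULL) {
  full_plan <- rbind(plan, test_plan)
  if (is.null(pgsi))
    pgsi <- suppressMessages(
      compute_pgsi_matrix(parents, full_plan, windows, empty = "one"))
  P <- unclass(pgsi)[full_plan$hybrid_id, truth$window_idx, drop = FALSE]
  with_seed(seed, {
    ids <- .parent_ids(config)
    frac <- config$pgsi_var_frac
    raw_g <- drop(P %*% truth$beta)
    sd_raw <- stats::sd(raw_g[seq_len(nrow(plan))])
    scale_w <- if (frac > 0 && sd_raw > 0) sqrt(frac) / sd_raw else 0
    beta <- truth$beta * scale_w
    g_window <- raw_g * scale_w
    g_window <- g_window - mean(g_window[seq_len(nrow(plan))])
    scale_unit <- function(x, target_var) {
      x <- x - mean(x)
      s <- stats::sd(x)
      if (s == 0 || target_var == 0) rep(0, length(x)) else x * sqrt(target_var) / s
    }
    gca_f <- stats::setNames(scale_unit(stats::rnorm(config$n_females),
                                        (1 - frac) / 2), ids$females)
    n_m_all <- config$n_males + config$n_test_males
    gca_m <- stats::setNames(scale_unit(stats::rnorm(n_m_all), (1 - frac) / 2),
                             c(ids$males, ids$test_males))
    g_hyb <- config$mu + gca_f[full_plan$female_id] + gca_m[full_plan$male_id] +
      g_window
    names(g_hyb) <- full_plan$hybrid_id
    g_par <- config$mu +
      2 * c(gca_f, gca_m)[c(ids$females, ids$males, ids$test_males)] -
      config$delta
    names(g_par) <- c(ids$females, ids$males, ids$test_males)
    gv <- c(g_hyb, g_par)
    env_offsets <- stats::rnorm(config$n_env, 0, config$env_sd)
    names(env_offsets) <- sprintf("E%d", seq_len(config$n_env))
    noise_sd <- sqrt(config$n_env * config$n_rep * (1 - config$h2) / config$h2)
    rec <- expand.grid(sample_id = names(gv),
                       environment = names(env_offsets),
                       replicate = seq_len(config$n_rep),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rec$trait <- trait
    rec$value <- gv[rec$sample_id] + env_offsets[rec$environment] +
      stats::rnorm(nrow(rec), 0, noise_sd)
    truth$beta <- beta
    truth$scaled <- TRUE
    truth$gca_f <- gca_f; truth$gca_m <- gca_m
    truth$env_offsets <- env_offsets; truth$noise_sd <- noise_sd
    truth$trait <- trait
    list(records = validate_phenotypes(rec), truth = truth,
         genetic_values = gv)
  })
}

#' Simulate a complete dataset (genomes, plans, truth, phenotypes)
#'
#' Convenience wrapper running [simulate_parent_genomes],
#' [make_cross_plan], [make_windows], [plant_window_effects] (one
#' independent truth per trait) and [simulate_phenotypes] for every
#' configured trait, all from a single seed.
#'
#' @param config A [sim_config].
#' @param seed Integer seed.
#' @return List: `geno`, `chrom_sizes`, `plan`, `test_plan` (or NULL),
#'   `windows`, `truths` (per trait), `records` (all traits combined),
#'   `config`, `seed`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1L) {
  gen <- simulate_parent_genomes(config, derive_seed(seed, 1))
  plan <- make_cross_plan(config)
  test_plan <- if (config$n_test_males > 0) make_cross_plan(config, test = TRUE)
  windows <- make_windows(gen$chrom_sizes, config$window_width)
  pg_full <- suppressMessages(
    compute_pgsi_matrix(gen$geno, rbind(plan, test_plan), windows, empty = "one"))
  truths <- list()
  records <- NULL
  for (i in seq_along(config$traits)) {
    tr <- config$traits[i]
    truth <- plant_window_effects(windows, config, derive_seed(seed, 2, i))
    sim <- simulate_phenotypes(gen$geno, plan, truth, windows, config,
                               derive_seed(seed, 3, i), trait = tr,
                               test_plan = test_plan, pgsi = pg_full)
    truths[[tr]] <- sim$truth
    records <- rbind(records, sim$records)
  }
  list(geno = gen$geno, chrom_sizes = gen$chrom_sizes, alt_freq = gen$alt_freq,
       plan = plan, test_plan = test_plan, windows = windows, pgsi = pg_full,
       truths = truths, records = records, config = config, seed = seed)
}

#' Write the planted truth as JSON
#' @param truths Per-trait truth list from [simulate_dataset].
#' @param path Output path.
#' @export
write_truth_json <- function(truths, path) {
  out <- lapply(truths, function(tr) {
    list(trait = tr$trait, window_key = tr$window_key, beta = tr$beta,
         noise_sd = tr$noise_sd, env_offsets = as.list(tr$env_offsets))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
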