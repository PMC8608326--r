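#' Pipeline run configuration
#'
#' Reads a YAML run configuration and applies defaults. Recognized
#' fields: paths (`vcf`, `chrom_sizes`, `plan`, `test_plan`,
#' `phenotypes`, `annotation`), `widths` (bp vector), `models`,
#' `traits`, `heterosis_types`, `seed`, `out_dir`, cross-validation
#' settings (`cv_k`, `cv_replicates`), `snp_fraction`.
#'
#' @param path YAML file path, or a list of settings.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- list(widths = c(1e5, 5e5, 1e6),
                   models = MODEL_SPECS,
                   traits = NULL, heterosis_types = c("HPH", "MPH"),
                   seed = 1L, out_dir = "pgsihet_out",
                   cv_k = 10, cv_replicates = 100, snp_fraction = 5e-4)
  for (nm in names(defaults)) cfg[[nm]] <- cfg[[nm]] %||% defaults[[nm]]
  bad <- setdiff(cfg$models, MODEL_SPECS)
  if (length(bad) > 0)
    stop_user("unknown model(s): ", paste(bad, collapse = ", "),
              "; valid: ", paste(MODEL_SPECS, collapse = ", "))
  for (f in c("vcf", "chrom_sizes", "plan", "test_plan", "phenotypes", "annotation"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop_user("configured path does not exist: ", f, " = ", cfg[[f]])
  structure(cfg, class = "run_config")
}

.provenance <- function(out_dir, config_obj, seed, extra = list()) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config_obj), tmp)
  prov <- c(list(package = "pgsihet",
                 version = as.character(utils::packageVersion("pgsihet")),
                 r_version = R.version.string,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 seed = seed,
                 config_hash = unname(tools::md5sum(tmp)),
                 config = config_obj),
            extra)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(prov)
}

#' Simulate a dataset and write it to disk
#'
#' Writes VCF, chromosome-size TSV, cross-plan TSV(s), phenotype TSV,
#' the planted truth (JSON) and a provenance record.
#'
#' @param config A [sim_config] (or NULL for defaults).
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param force Overwrite an existing output directory.
#' @return The dataset list from [simulate_dataset], invisibly.
#' @export
pipeline_simulate <- function(config = NULL, out_dir, seed = 1L, force = FALSE) {
  config <- config %||% sim_config()
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force)
    stop_user("output directory exists and is non-empty (use force = TRUE): ", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulate_dataset(config, seed)
  write_parent_vcf(ds$geno, file.path(out_dir, "parents.vcf"))
  utils::write.table(ds$chrom_sizes, file.path(out_dir, "chrom_sizes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(ds$plan, file.path(out_dir, "cross_plan.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(ds$test_plan))
    utils::write.table(ds$test_plan, file.path(out_dir, "test_plan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$records, file.path(out_dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_truth_json(ds$truths, file.path(out_dir, "truth.json"))
  .provenance(out_dir, unclass(config), seed,
              list(n_hybrids = nrow(ds$plan), n_sites = length(ds$geno$pos)))
  message(sprintf("simulated %d parents, %d hybrids, %d sites, %d trait(s)",
                  length(ds$geno$samples), nrow(ds$plan),
                  length(ds$geno$pos), length(config$traits)))
  invisible(ds)
}

#' Compute PGSI matrices for the configured window widths
#'
#' @param config A `run_config` (see [read_run_config]) with `vcf`,
#'   `chrom_sizes` and `plan` paths.
#' @param out_dir Output directory.
#' @return Named list of `pgsi_matrix` objects (one per width),
#'   invisibly.
#' @export
pipeline_pgsi <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geno <- read_parent_vcf(config$vcf)
  plan <- read_cross_plan(config$plan)
  out <- list()
  for (w in config$widths) {
    windows <- make_windows(config$chrom_sizes, w)
    pg <- compute_pgsi_matrix(geno, plan, windows)
    n_empty <- sum(attr(pg, "empty_cells"))
    if (n_empty > 0)
      message(sprintf("width %g: %d window cell(s) without informative loci", w, n_empty))
    lab <- sprintf("pgsi_%g.tsv", w)
    write_pgsi_tsv(pg, file.path(out_dir, lab))
    out[[as.character(w)]] <- pg
  }
  .provenance(out_dir, unclass(config), config$seed)
  invisible(out)
}

#' Compute BLUEs and heterosis from configured phenotypes
#'
#' @param config A `run_config` with `phenotypes` and `plan` paths.
#' @param out_dir Output directory.
#' @return List with `blues` and `heterosis`, invisibly.
#' @export
pipeline_heterosis <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_phenotypes(config$phenotypes)
  plan <- read_cross_plan(config$plan)
  blues <- blue_table(records, config$traits)
  het <- compute_heterosis(blues, plan)
  utils::write.table(data.frame(sample_id = rownames(blues), blues),
                     file.path(out_dir, "blues.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_heterosis_tsv(het, file.path(out_dir, "heterosis.tsv"))
  invisible(list(blues = blues, heterosis = het))
}

#' Run the model x trait x heterosis prediction grid
#'
#' Fits every configured model for every trait and heterosis type,
#' estimates predictability by replicated k-fold cross-validation,
#' writes a report shaped like a predictability table (one row per
#' model x trait x heterosis type), h-QTL tables for the window-LASSO
#' models, and (when a test plan is configured) external-validation
#' scatter data.
#'
#' @param config A `run_config` with `vcf`, `chrom_sizes`, `plan` and
#'   `phenotypes` paths.
#' @param out_dir Output directory.
#' @return List with `report` (data frame) and `hqtls`, invisibly.
#' @export
pipeline_predict <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geno <- read_parent_vcf(config$vcf)
  plan <- read_cross_plan(config$plan)
  records <- read_phenotypes(config$phenotypes)
  traits <- config$traits %||% unique(records$trait)
  blues <- blue_table(records, traits)
  het <- compute_heterosis(blues, plan)
  needs_pgsi <- intersect(config$models, names(.lasso_widths))
  pgs <- list()
  for (m in needs_pgsi) {
    w <- .lasso_widths[[m]]
    pgs[[m]] <- compute_pgsi_matrix(geno, plan, make_windows(config$chrom_sizes, w))
  }
  codes <- kin <- kin2 <- sub_codes <- NULL
  if (any(c("GBLUP_A", "GBLUP_AD", "LASSO_SNP") %in% config$models)) {
    f1 <- infer_f1_genotypes(geno, plan)
    codes <- code_additive(f1)
    if ("LASSO_SNP" %in% config$models)
      sub_codes <- subsample_markers(codes, config$snp_fraction,
                                     derive_seed(config$seed, 99))
    if (any(c("GBLUP_A", "GBLUP_AD") %in% config$models))
      kin <- additive_kinship(codes)
    if ("GBLUP_AD" %in% config$models)
      kin2 <- dominance_kinship(code_dominance(f1))
  }
  report <- NULL
  hqtls <- list()
  for (tr in traits) for (ht in config$heterosis_types) {
    y <- heterosis_vector(het, tr, ht)
    y <- y[!is.na(y)]
    for (m in config$models) {
      inputs <- if (m %in% c("GBLUP_A", "GBLUP_AD")) {
        list(kinship = kin$values[names(y), names(y)],
             kinship2 = if (m == "GBLUP_AD") kin2$values[names(y), names(y)])
      } else if (m == "LASSO_SNP") {
        Xm <- sub_codes$values[names(y), , drop = FALSE]
        colnames(Xm) <- paste0(sub_codes$marker_keys$chrom, ":",
                               sub_codes$marker_keys$pos)
        list(features = Xm)
      } else {
        list(features = unclass(pgs[[m]])[names(y), , drop = FALSE])
      }
      cv <- cross_validate(y, m, inputs, k = config$cv_k,
                           replicates = config$cv_replicates,
                           seed = derive_seed(config$seed, match(m, MODEL_SPECS),
                                              match(tr, traits),
                                              match(ht, c("HPH", "MPH"))))
      report <- rbind(report,
                      data.frame(trait = tr, heterosis_type = ht, model = m,
                                 mean = cv$mean, sd = cv$sd,
                                 replicates = cv$replicates, k = cv$k,
                                 seed = cv$seed, stringsAsFactors = FALSE))
      if (m %in% names(.lasso_widths)) {
        fit <- build_model(m, y, pgsi = pgs[[m]],
                           seed = derive_seed(config$seed, 7, match(m, MODEL_SPECS)))
        hq <- extract_hqtls(fit, attr(pgs[[m]], "windows"), trait = tr, which = ht)
        hqtls[[paste(tr, ht, m, sep = "_")]] <- hq
        write_hqtl_tsv(hq, file.path(out_dir,
                                     sprintf("hqtl_%s_%s_%s.tsv", tr, ht, m)))
      }
    }
  }
  utils::write.table(report, file.path(out_dir, "predictability.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .provenance(out_dir, unclass(config), config$seed)
  invisible(list(report = report, hqtls = hqtls))
}
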