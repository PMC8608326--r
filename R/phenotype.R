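#' Read a long-format phenotype table
#'
#' Expected columns: `sample_id`, `environment`, `replicate`, `trait`,
#' `value` (one row per plot-level observation).
#'
#' @param path TSV path.
#' @return A validated data frame.
#' @export
read_phenotypes <- function(path) {
  rec <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_phenotypes(rec)
}

#' @rdname read_phenotypes
#' @param records A data frame to validate.
#' @export
validate_phenotypes <- function(records) {
  need <- c("sample_id", "environment", "replicate", "trait", "value")
  if (!all(need %in% names(records)))
    stop_user("phenotype records need columns: ", paste(need, collapse = ", "))
  key <- do.call(paste, records[, c("sample_id", "environment", "replicate", "trait")])
  if (anyDuplicated(key))
    stop_user("duplicate (sample, environment, replicate, trait) rows")
  if (any(!is.finite(records$value) & !is.na(records$value)))
    stop_user("non-finite phenotype values")
  records[, need]
}

# Profiled REML for the genotype-fixed / environment-random layout.
# Input: data frame with columns sample_id, environment, y (one row per
# genotype x environment mean). Exploits the compound-symmetry structure
# V = sigma_e^2 (I + lambda * same-environment indicator), which is
# block-diagonal by environment, so all GLS quantities reduce to
# per-environment sums.
.reml_blue <- function(dat) {
  geno <- factor(dat$sample_id)
  env <- factor(dat$environment)
  y <- dat$y
  n <- length(y); p <- nlevels(geno); k <- nlevels(env)
  gi <- as.integer(geno); ei <- as.integer(env)
  n_e <- tabulate(ei, k)
  # V_e^{-1} = I - c_e * J with c_e = lambda / (1 + n_e * lambda)
  obj <- function(loglam) {
    lam <- exp(loglam)
    ce <- lam / (1 + n_e * lam)
    XtWX <- matrix(0, p, p)
    diag(XtWX) <- tabulate(gi, p)
    XtWy <- rowsum(y, gi)[, 1]
    for (e in seq_len(k)) {
      rows <- ei == e
      v <- tabulate(gi[rows], p)          # genotype presence in env e
      XtWX <- XtWX - ce[e] * tcrossprod(v)
      XtWy <- XtWy - ce[e] * v * sum(y[rows])
    }
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(list(val = Inf))
    beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
    r <- y - beta[gi]
    rWr <- sum(r^2) - sum(ce * rowsum(r, ei)[, 1]^2)
    logdetV <- sum(log1p(n_e * lam))
    logdetX <- 2 * sum(log(diag(ch)))
    val <- logdetV + logdetX + (n - p) * log(rWr)
    list(val = val, beta = beta, rWr = rWr)
  }
  opt <- stats::optimize(function(l) obj(l)$val, c(-12, 12), tol = 1e-9)
  fit <- obj(opt$minimum)
  sigma_e2 <- fit$rWr / (n - p)
  sigma_u2 <- exp(opt$minimum) * sigma_e2
  list(blue = stats::setNames(fit$beta, levels(geno)),
       varcomp = c(environment = sigma_u2, residual = sigma_e2))
}

#' BLUE of one trait across environments
#'
#' Two-step integration: replicate-level records are first collapsed to
#' genotype-by-environment means; the means are then fitted with a
#' linear mixed model in which genotype is fixed and environment is a
#' random effect, with the two variance components estimated by
#' profiled REML. The returned fixed-effect genotype estimates are on
#' the trait scale. With a single environment the model degenerates to
#' per-genotype means.
#'
#' @param records Phenotype records (see [read_phenotypes]).
#' @param trait Trait ID to fit.
#' @return List with `blue` (named numeric vector of genotype BLUEs) and
#'   `varcomp` (environment and residual variances; `NA` when degenerate).
#' @export
fit_blue <- function(records, trait) {
  records <- validate_phenotypes(records)
  rec <- records[records$trait == trait & !is.na(records$value), ]
  if (nrow(rec) == 0) stop_user("no observations for trait ", trait)
  all_ids <- unique(records$sample_id[records$trait == trait])
  dropped <- setdiff(all_ids, rec$sample_id)
  if (length(dropped) > 0)
    warning(sprintf("fit_blue(%s): %d genotype(s) with no observations excluded",
                    trait, length(dropped)))
  ge <- stats::aggregate(value ~ sample_id + environment, rec, mean)
  names(ge)[3] <- "y"
  if (length(unique(ge$environment)) == 1L) {
    mu <- tapply(ge$y, ge$sample_id, mean)
    return(list(blue = stats::setNames(as.numeric(mu), names(mu)),
                varcomp = c(environment = NA_real_, residual = NA_real_)))
  }
  .reml_blue(ge)
}

#' BLUE table over all traits
#'
#' @inheritParams fit_blue
#' @param traits Traits to fit (default: all present).
#' @return Data frame (samples x traits) with sample IDs as row names
#'   and a `varcomp` attribute (per-trait variance components).
#' @export
blue_table <- function(records, traits = NULL) {
  records <- validate_phenotypes(records)
  traits <- traits %||% unique(records$trait)
  fits <- lapply(traits, function(tr) fit_blue(records, tr))
  ids <- sort(unique(unlist(lapply(fits, function(f) names(f$blue)))))
  out <- data.frame(row.names = ids)
  for (j in seq_along(traits)) out[[traits[j]]] <- fits[[j]]$blue[ids]
  attr(out, "varcomp") <- stats::setNames(lapply(fits, `[[`, "varcomp"), traits)
  out
}

#' High-parent and mid-parent heterosis from BLUEs
#'
#' HPH = (F1 - max(P1, P2)) / max(P1, P2) and
#' MPH = (F1 - (P1 + P2)/2) / ((P1 + P2)/2), returned as fractions. The
#' "high parent" is always the larger parental value. Cells with a zero
#' or negative denominator are set missing with a warning.
#'
#' @param blues A [blue_table] data frame (samples x traits).
#' @param plan Cross-plan data frame.
#' @return Long data frame: `hybrid_id`, `female_id`, `male_id`,
#'   `trait`, `F1`, `HP`, `MP`, `HPH`, `MPH`.
#' @export
compute_heterosis <- function(blues, plan) {
  plan <- validate_cross_plan(plan)
  have <- plan$hybrid_id %in% rownames(blues) &
    plan$female_id %in% rownames(blues) & plan$male_id %in% rownames(blues)
  if (!any(have)) stop_user("no cross has hybrid and both parents in the BLUE table")
  plan <- plan[have, ]
  traits <- colnames(blues)
  out <- do.call(rbind, lapply(traits, function(tr) {
    f1 <- blues[plan$hybrid_id, tr]
    p1 <- blues[plan$female_id, tr]
    p2 <- blues[plan$male_id, tr]
    hp <- pmax(p1, p2); mp <- (p1 + p2) / 2
    data.frame(hybrid_id = plan$hybrid_id, female_id = plan$female_id,
               male_id = plan$male_id, trait = tr, F1 = f1, HP = hp, MP = mp,
               HPH = ifelse(hp > 0, (f1 - hp) / hp, NA_real_),
               MPH = ifelse(mp > 0, (f1 - mp) / mp, NA_real_),
               stringsAsFactors = FALSE)
  }))
  n_bad <- sum((out$HP <= 0 | out$MP <= 0), na.rm = TRUE)
  if (n_bad > 0)
    warning(sprintf("%d heterosis cell(s) with non-positive denominator set missing", n_bad))
  rownames(out) <- NULL
  out
}

#' Extract one heterosis column as a named vector
#' @param heterosis Output of [compute_heterosis].
#' @param trait Trait ID.
#' @param which `"HPH"` or `"MPH"`.
#' @return Named numeric vector (names = hybrid IDs).
#' @export
heterosis_vector <- function(heterosis, trait, which = c("HPH", "MPH")) {
  which <- match.arg(which)
  h <- heterosis[heterosis$trait == trait, ]
  if (nrow(h) == 0) stop_user("trait not present: ", trait)
  stats::setNames(h[[which]], h$hybrid_id)
}

#' Pairwise Pearson correlations among traits
#'
#' @param tbl A samples x traits data frame or matrix (BLUEs or a wide
#'   heterosis table).
#' @param ids Optional subset of sample IDs (row names).
#' @return Symmetric correlation matrix (pairwise-complete observations,
#'   unit diagonal; `NA` where a trait is constant).
#' @export
trait_correlation_matrix <- function(tbl, ids = NULL) {
  m <- as.matrix(tbl)
  if (!is.null(ids)) m <- m[ids, , drop = FALSE]
  ok_pairs <- colSums(!is.na(m)) >= 3
  if (any(!ok_pairs)) warning("trait(s) with fewer than 3 observations")
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  diag(r) <- 1
  r
}

#' Parent-offspring correlations per trait
#'
#' Pearson correlation between hybrid BLUEs and the chosen parental
#' BLUEs (female, male, or mid-parent average) over all hybrids.
#'
#' @param blues A [blue_table] data frame.
#' @param plan Cross-plan data frame.
#' @param side `"female"`, `"male"`, or `"midparent"`.
#' @return Named numeric vector of per-trait correlations.
#' @export
parent_offspring_correlation <- function(blues, plan,
                                         side = c("female", "male", "midparent")) {
  side <- match.arg(side)
  plan <- validate_cross_plan(plan)
  have <- plan$hybrid_id %in% rownames(blues) &
    plan$female_id %in% rownames(blues) & plan$male_id %in% rownames(blues)
  plan <- plan[have, ]
  vapply(colnames(blues), function(tr) {
    f1 <- blues[plan$hybrid_id, tr]
    par <- switch(side,
                  female = blues[plan$female_id, tr],
                  male = blues[plan$male_id, tr],
                  midparent = (blues[plan$female_id, tr] + blues[plan$male_id, tr]) / 2)
    ok <- !is.na(f1) & !is.na(par)
    if (sum(ok) < 3 || stats::sd(f1[ok]) == 0 || stats::sd(par[ok]) == 0)
      return(NA_real_)
    stats::cor(f1[ok], par[ok])
  }, numeric(1))
}

#' Mean of the top fraction of a heterosis distribution
#'
#' Ranks hybrids by descending heterosis and averages the top
#' `ceiling(fraction * n)` of them.
#'
#' @param heterosis Output of [compute_heterosis].
#' @param trait Trait ID.
#' @param which `"HPH"` or `"MPH"`.
#' @param fraction Proportion in (0, 1].
#' @return List with `mean`, `n_selected`, and `ids`.
#' @export
top_fraction_summary <- function(heterosis, trait, which = c("HPH", "MPH"),
                                 fraction = 0.1) {
  which <- match.arg(which)
  if (!(fraction > 0 && fraction <= 1)) stop_user("fraction must be in (0, 1]")
  v <- heterosis_vector(heterosis, trait, which)
  v <- v[!is.na(v)]
  if (length(v) == 0) stop_user("all heterosis values missing for ", trait)
  k <- ceiling(fraction * length(v))
  top <- sort(v, decreasing = TRUE)[seq_len(k)]
  list(mean = mean(top), n_selected = k, ids = names(top))
}

#' Export a heterosis table with percent columns
#'
#' Internal values are fractions; the export multiplies by 100 and
#' rounds to 2 decimals (`*_HPH_pct`, `*_MPH_pct` columns).
#'
#' @param heterosis Output of [compute_heterosis].
#' @param path Output TSV path.
#' @export
write_heterosis_tsv <- function(heterosis, path) {
  wide <- NULL
  for (tr in unique(heterosis$trait)) {
    h <- heterosis[heterosis$trait == tr, c("hybrid_id", "HPH", "MPH")]
    names(h)[2:3] <- paste0(tr, c("_HPH_pct", "_MPH_pct"))
    h[2:3] <- lapply(h[2:3], function(x) round(100 * x, 2))
    wide <- if (is.null(wide)) h else merge(wide, h, by = "hybrid_id", all = TRUE)
  }
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
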