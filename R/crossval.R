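#' Random k-fold partition
#'
#' Fold sizes differ by at most one; every individual lands in exactly
#' one fold; the same seed always yields the same assignment.
#'
#' @param n Number of individuals.
#' @param k Number of folds (2 <= k <= n).
#' @param seed Integer seed.
#' @return Integer vector of fold labels (1..k) of length n.
#' @export
kfold_partition <- function(n, k, seed) {
  if (k > n) stop_user("k must not exceed n")
  if (k < 2) stop_user("k must be at least 2")
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  with_seed(seed, sample(rep(seq_len(k), sizes)))
}

# Fit the requested model on the training subset and predict the test
# subset, returning predictions as deviations from the model's own
# fixed-effect/intercept part. Kinships/features are global; subsetting
# happens here. Dropping the per-fold intercept matters: out-of-fold
# predictions are re-anchored at the full-sample mean by the caller, so
# a trait with no genetic signal scores ~0 predictability instead of
# the spurious -1/sqrt(fold size) that fold-specific intercepts induce.
.cv_fit_predict <- function(spec, y, train, test, inputs, fold_seed) {
  if (spec %in% c("GBLUP_A", "GBLUP_AD")) {
    K <- if (inherits(inputs$kinship, "kinship")) inputs$kinship$values else inputs$kinship
    K2 <- if (!is.null(inputs$kinship2)) {
      if (inherits(inputs$kinship2, "kinship")) inputs$kinship2$values else inputs$kinship2
    } else NULL
    fit <- fit_gblup(y[train], K[train, train, drop = FALSE],
                     if (!is.null(K2)) K2[train, train, drop = FALSE])
    blocks <- list(additive = K[test, train, drop = FALSE])
    if (!is.null(K2)) blocks$dominance <- K2[test, train, drop = FALSE]
    predict_gblup(fit, if (is.null(K2)) blocks$additive else blocks) -
      drop(fit$beta)
  } else {
    X <- inputs$features
    fit <- fit_lasso_refit(X[train, , drop = FALSE], y[train], seed = fold_seed)
    predict_linear(fit, X[test, , drop = FALSE]) - fit$intercept
  }
}

#' Predictability by replicated k-fold cross-validation
#'
#' Per replicate, a fresh random partition is drawn; each fold is
#' predicted by a model trained on the remaining k-1 folds, so every
#' individual is predicted exactly once per replicate. The replicate's
#' predictability is the single Pearson correlation between the
#' observed values and the pooled out-of-fold predictions; the reported
#' predictability is the mean over replicates. The LASSO penalty search
#' is nested inside each training fold with a seed derived from
#' (seed, replicate, fold), so no genetic information leaks from the
#' held-out fold. Out-of-fold predictions are anchored at the
#' full-sample mean rather than each training fold's own intercept:
#' with fold-specific intercepts a trait carrying no genetic signal
#' scores a spurious negative predictability of about -1/sqrt(fold
#' size) (the held-out fold is exactly what the training mean is
#' missing), while with genuine signal the two conventions agree
#' closely.
#'
#' @param y Named numeric response (heterosis of the hybrids).
#' @param spec Model name (see [build_model]).
#' @param inputs List of model inputs: `kinship`/`kinship2` (n x n,
#'   aligned to `y`) for GBLUP flavors, or `features` (n x p matrix,
#'   rows aligned to `y`) for LASSO flavors. For `LASSO_SNP` pass the
#'   already-subsampled marker codes as `features`.
#' @param k Folds (default 10).
#' @param replicates CV replicates (default 100).
#' @param seed Integer seed.
#' @return A `predictability` object: per-replicate correlations,
#'   their mean and sd, and the spec echo.
#' @export
cross_validate <- function(y, spec, inputs, k = 10, replicates = 100, seed = 1L) {
  n <- length(y)
  if (!spec %in% MODEL_SPECS)
    stop_user("unknown model spec '", spec, "'")
  rs <- rep(NA_real_, replicates)
  pred_counts <- integer(n)
  for (rep_i in seq_len(replicates)) {
    folds <- kfold_partition(n, k, derive_seed(seed, rep_i))
    pred <- rep(NA_real_, n)
    for (f in seq_len(k)) {
      test <- which(folds == f)
      train <- which(folds != f)
      pred[test] <- .cv_fit_predict(spec, y, train, test, inputs,
                                    derive_seed(seed, rep_i, f))
    }
    pred_counts <- pred_counts + !is.na(pred)
    pred <- pred + mean(y)
    if (stats::sd(pred) == 0 || anyNA(pred)) {
      warning(sprintf("replicate %d: constant or incomplete predictions; r set NA", rep_i))
    } else {
      rs[rep_i] <- stats::cor(y, pred)
    }
  }
  structure(list(r = rs, mean = mean(rs, na.rm = TRUE),
                 sd = stats::sd(rs[!is.na(rs)]),
                 spec = spec, k = k, replicates = replicates, seed = seed,
                 predictions_per_replicate = pred_counts / replicates),
            class = "predictability")
}

#' @export
print.predictability <- function(x, ...) {
  cat(sprintf("%s: predictability %.4f (sd %.4f) over %d x %d-fold CV\n",
              x$spec, x$mean, x$sd %||% NA, x$replicates, x$k))
  invisible(x)
}

#' Validate a fitted model on an independent test population
#'
#' @param fit A fitted model (`lasso_fit` or `gblup_fit`).
#' @param observed Named numeric vector of observed test heterosis;
#'   hybrid IDs must be disjoint from the training hybrids (parents may
#'   overlap).
#' @param features Test feature matrix (LASSO flavors).
#' @param kinship_cross Test x train kinship block(s) (GBLUP flavors).
#' @param groups Optional factor (e.g. male parent) for per-group
#'   correlations.
#' @return List with `r`, per-group `r_by_group`, and a `scatter` data
#'   frame (hybrid_id, observed, predicted, group).
#' @export
external_validate <- function(fit, observed, features = NULL,
                              kinship_cross = NULL, groups = NULL) {
  if (length(observed) < 3) stop_user("external validation needs >= 3 test hybrids")
  train_ids <- if (inherits(fit, "gblup_fit")) fit$ids else fit$train_ids
  if (!is.null(train_ids) && !is.null(names(observed))) {
    overlap <- intersect(names(observed), train_ids)
    if (length(overlap) > 0)
      stop_user("test hybrids overlap training hybrids: ",
                paste(utils::head(overlap, 5), collapse = ", "))
  }
  pred <- if (inherits(fit, "lasso_fit")) {
    if (is.null(features)) stop_user("LASSO validation requires 'features'")
    predict_linear(fit, features)
  } else {
    if (is.null(kinship_cross)) stop_user("GBLUP validation requires 'kinship_cross'")
    predict_gblup(fit, kinship_cross)
  }
  if (stats::sd(observed) == 0) stop_user("observed test values are constant")
  r <- stats::cor(observed, pred, use = "complete.obs")
  scatter <- data.frame(hybrid_id = names(observed) %||% seq_along(observed),
                        observed = as.numeric(observed), predicted = pred,
                        group = if (is.null(groups)) NA else as.character(groups),
                        stringsAsFactors = FALSE)
  r_by_group <- NULL
  if (!is.null(groups)) {
    r_by_group <- vapply(split(scatter, scatter$group), function(d) {
      if (nrow(d) < 3 || stats::sd(d$observed) == 0) NA_real_
      else stats::cor(d$observed, d$predicted)
    }, numeric(1))
  }
  list(r = r, r_by_group = r_by_group, scatter = scatter)
}
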