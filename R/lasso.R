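#' LASSO variable selection with ordinary-least-squares re-estimation
#'
#' Fits an L1-penalized linear model on internally standardized feature
#' columns (PGSI windows or coded markers), chooses the shrinkage
#' penalty by seeded inner 10-fold cross-validation over a 100-point
#' logarithmic path (unless `lambda` is given), extracts the features
#' with nonzero coefficients, and re-estimates their effects by least
#' squares (with a tiny ridge, 1e-8, on the normal equations for
#' numerical safety). Predictions use the re-estimated coefficients
#' only. If the selected set reaches n - 1 features, only the largest
#' |coefficient| floor(n/2) features are kept before the refit.
#'
#' @param features Numeric matrix (individuals x features) with column
#'   names as feature keys. `NA` cells are imputed with the column mean.
#' @param y Numeric response (heterosis values).
#' @param seed Integer seed for the inner cross-validation folds.
#' @param lambda Optional fixed penalty (skips the inner CV).
#' @param nfolds Inner CV folds (default 10).
#' @return A `lasso_fit` object: selected keys, LASSO-path and refit
#'   coefficients, intercept, standardization parameters, penalty, seed.
#' @export
fit_lasso_refit <- function(features, y, seed = 1L, lambda = NULL, nfolds = 10) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  n <- nrow(X)
  if (n < 10) stop_user("LASSO fitting needs at least 10 individuals")
  if (length(y) != n) stop_user("length(y) must match nrow(features)")
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  if (anyNA(X)) {
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  sdv <- apply(X, 2, stats::sd)
  active <- sdv > 0
  sd_safe <- ifelse(active, sdv, 1)
  Xs <- sweep(sweep(X, 2, mu), 2, sd_safe, "/")
  intercept_only <- function(flag) {
    structure(list(feature_keys = colnames(X), selected = character(0),
                   coef = numeric(0), lasso_coef = numeric(0),
                   intercept = mean(y), center = mu, scale = sd_safe,
                   lambda = lambda %||% NA_real_, seed = seed,
                   empty = flag, fitted = rep(mean(y), n),
                   train_ids = rownames(X)),
              class = "lasso_fit")
  }
  if (stats::sd(y) == 0 || !any(active)) return(intercept_only(TRUE))
  Xa <- Xs[, active, drop = FALSE]
  if (is.null(lambda)) {
    nf <- min(nfolds, n)
    foldid <- with_seed(seed, sample(rep(seq_len(nf), length.out = n)))
    cvfit <- glmnet::cv.glmnet(Xa, y, alpha = 1, nlambda = 100,
                               standardize = FALSE, foldid = foldid)
    lambda <- cvfit$lambda.min
    fit <- cvfit$glmnet.fit
  } else {
    fit <- glmnet::glmnet(Xa, y, alpha = 1, standardize = FALSE)
  }
  bmat <- as.matrix(stats::coef(fit, s = lambda, exact = FALSE))
  bl <- stats::setNames(bmat[-1, 1], rownames(bmat)[-1])
  sel <- names(bl)[bl != 0]
  if (length(sel) == 0) {
    out <- intercept_only(TRUE)
    out$lambda <- lambda
    return(out)
  }
  if (length(sel) >= n - 1) {
    keep_n <- floor(n / 2)
    message(sprintf(
      "fit_lasso_refit: %d selected >= n-1; keeping largest-|coef| %d before refit",
      length(sel), keep_n))
    sel <- sel[order(abs(bl[sel]), decreasing = TRUE)][seq_len(keep_n)]
    sel <- sel[order(match(sel, colnames(Xa)))]
  }
  A <- cbind(`(Intercept)` = 1, Xa[, sel, drop = FALSE])
  AtA <- crossprod(A) + 1e-8 * diag(ncol(A))
  coefs <- drop(solve(AtA, crossprod(A, y)))
  structure(list(feature_keys = colnames(X), selected = sel,
                 coef = coefs[-1], lasso_coef = bl[sel],
                 intercept = unname(coefs[1]), center = mu, scale = sd_safe,
                 lambda = lambda, seed = seed, empty = FALSE,
                 fitted = drop(A %*% coefs), train_ids = rownames(X)),
            class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("LASSO fit: %d/%d features selected (lambda = %s)\n",
              length(x$selected), length(x$feature_keys),
              signif(x$lambda, 4)))
  invisible(x)
}

#' Predict from a re-estimated LASSO fit
#'
#' Applies the stored standardization, imputes missing cells with the
#' training column means (standardized zero), and evaluates intercept +
#' refit coefficients.
#'
#' @param fit A `lasso_fit`.
#' @param features Matrix with (at least) the training feature columns;
#'   columns unknown to the fit raise an error.
#' @return Numeric vector of predictions.
#' @export
predict_linear <- function(fit, features) {
  X <- as.matrix(features)
  unknown <- setdiff(colnames(X), fit$feature_keys)
  if (length(unknown) > 0)
    stop_user("unknown feature key(s): ",
              paste(utils::head(unknown, 5), collapse = ", "))
  missing_sel <- setdiff(fit$selected, colnames(X))
  if (length(missing_sel) > 0)
    stop_user("selected feature(s) absent from input: ",
              paste(utils::head(missing_sel, 5), collapse = ", "))
  if (length(fit$selected) == 0) return(rep(fit$intercept, nrow(X)))
  Xsel <- X[, fit$selected, drop = FALSE]
  i <- match(fit$selected, fit$feature_keys)
  Xs <- sweep(sweep(Xsel, 2, fit$center[i]), 2, fit$scale[i], "/")
  Xs[is.na(Xs)] <- 0
  drop(fit$intercept + Xs %*% fit$coef)
}

MODEL_SPECS <- c("GBLUP_A", "GBLUP_AD", "LASSO_SNP",
                 "LASSO_100Kb", "LASSO_500Kb", "LASSO_1Mb")
.lasso_widths <- c(LASSO_100Kb = 1e5, LASSO_500Kb = 5e5, LASSO_1Mb = 1e6)

#' Build one of the six heterosis prediction models
#'
#' Dispatches to [fit_gblup] or [fit_lasso_refit] with the feature
#' construction the model name implies: GBLUP_A uses the additive
#' kinship, GBLUP_AD adds the dominance kinship, LASSO_SNP uses a
#' random subsample of the coded markers as features (default 0.05%),
#' and LASSO_100Kb/500Kb/1Mb use the PGSI matrix at that window width.
#'
#' @param spec Model name (one of `r paste(MODEL_SPECS, collapse=", ")`).
#' @param y Named response vector (heterosis of the training hybrids).
#' @param kinship,kinship2 Kinships for the GBLUP flavors.
#' @param codes Coded marker matrix for LASSO_SNP (hybrid additive codes).
#' @param pgsi PGSI matrix for the window LASSO flavors; its `width`
#'   attribute (when present) must match the model name.
#' @param snp_fraction Marker subsample fraction for LASSO_SNP.
#' @param seed Seed for subsampling and inner CV.
#' @return A `gblup_fit` or `lasso_fit`, with the model name in `$spec`.
#' @export
build_model <- function(spec, y, kinship = NULL, kinship2 = NULL, codes = NULL,
                        pgsi = NULL, snp_fraction = 5e-4, seed = 1L) {
  if (!spec %in% MODEL_SPECS)
    stop_user("unknown model spec '", spec, "'; valid: ",
              paste(MODEL_SPECS, collapse = ", "))
  fit <- switch(spec,
    GBLUP_A = {
      if (is.null(kinship)) stop_user("GBLUP_A requires 'kinship'")
      fit_gblup(y, kinship)
    },
    GBLUP_AD = {
      if (is.null(kinship) || is.null(kinship2))
        stop_user("GBLUP_AD requires 'kinship' and 'kinship2' (dominance)")
      fit_gblup(y, kinship, kinship2)
    },
    LASSO_SNP = {
      if (is.null(codes)) stop_user("LASSO_SNP requires 'codes'")
      sub <- subsample_markers(codes, snp_fraction, seed)
      Xm <- sub$values[names(y), , drop = FALSE]
      colnames(Xm) <- paste0(sub$marker_keys$chrom, ":", sub$marker_keys$pos)
      fit_lasso_refit(Xm, y, seed = seed)
    },
    {
      if (is.null(pgsi)) stop_user(spec, " requires 'pgsi'")
      w <- attr(pgsi, "width")
      if (!is.null(w) && w != .lasso_widths[[spec]])
        stop_user(sprintf("%s expects %g bp windows, got %g bp",
                          spec, .lasso_widths[[spec]], w))
      fit_lasso_refit(unclass(pgsi)[names(y), , drop = FALSE], y, seed = seed)
    })
  fit$spec <- spec
  fit
}

#' Serialize a model fit to a JSON text artifact
#'
#' @param fit A `gblup_fit` or `lasso_fit`.
#' @param path Output path.
#' @export
write_model_json <- function(fit, path) {
  out <- if (inherits(fit, "lasso_fit")) {
    list(kind = "lasso", spec = fit$spec %||% NA, seed = fit$seed,
         lambda = fit$lambda, intercept = fit$intercept,
         selected = fit$selected, coef = as.list(fit$coef))
  } else {
    list(kind = "gblup", spec = fit$spec %||% NA,
         phi2 = fit$phi2, sigma2 = fit$sigma2, lambda = fit$lambda,
         beta = as.numeric(fit$beta))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
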