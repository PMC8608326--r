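#' Marker-generated kinship matrix
#'
#' K = (1/m) Z Z' with Z the marker codes as given (no extra centering
#' or scaling beyond the coding itself). Missing codes are mean-imputed
#' per marker before the cross product.
#'
#' @param codes A `coded_markers` object (additive or dominance).
#' @return A `kinship` object: list with `values` (n x n), `ids`,
#'   `source`, `m`.
#' @export
marker_kinship <- function(codes) {
  Z <- codes$values
  m <- ncol(Z)
  if (m == 0) stop_user("kinship requires at least one marker")
  if (anyNA(Z)) {
    mu <- colMeans(Z, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(Z), arr.ind = TRUE)
    Z[idx] <- mu[idx[, 2]]
  }
  K <- tcrossprod(Z) / m
  structure(list(values = K, ids = rownames(Z), source = codes$coding, m = m),
            class = "kinship")
}

#' @rdname marker_kinship
#' @export
additive_kinship <- function(codes) {
  if (codes$coding != "additive") stop_user("additive_kinship needs additive codes")
  marker_kinship(codes)
}

#' @rdname marker_kinship
#' @export
dominance_kinship <- function(codes) {
  if (codes$coding != "dominance") stop_user("dominance_kinship needs dominance codes")
  marker_kinship(codes)
}

#' @export
print.kinship <- function(x, ...) {
  cat(sprintf("kinship (%s): %d x %d from %d markers\n",
              x$source, nrow(x$values), ncol(x$values), x$m))
  invisible(x)
}

.check_psd <- function(K, tol = 1e-6) {
  if (max(abs(K - t(K))) > 1e-10) stop_user("kinship matrix is not symmetric")
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1))
    stop_user("kinship matrix is not positive semidefinite within tolerance")
  invisible(TRUE)
}

# REML for y = X beta + g + e, var(y) = sigma2 (lambda K + I), via
# eigendecomposition of K and Brent search over log(lambda) in [-6, 6].
.reml_single_k <- function(y, K, X, bounds = c(-6, 6), tol = 1e-8) {
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  ys <- crossprod(eg$vectors, y)[, 1]
  Xs <- crossprod(eg$vectors, X)
  n <- length(y); p <- ncol(X)
  prof <- function(loglam) {
    lam <- exp(loglam)
    w <- lam * d + 1
    XtWX <- crossprod(Xs / w, Xs)
    XtWy <- crossprod(Xs / w, ys)
    ch <- chol(XtWX)
    beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
    r <- ys - Xs %*% beta
    rWr <- sum(r^2 / w)
    list(val = sum(log(w)) + 2 * sum(log(diag(ch))) + (n - p) * log(rWr),
         beta = beta, rWr = rWr)
  }
  opt <- stats::optimize(function(l) prof(l)$val, bounds, tol = tol)
  if (!is.finite(opt$objective)) stop("REML objective is not finite")
  at_bound <- min(abs(opt$minimum - bounds)) < 1e-3
  fit <- prof(opt$minimum)
  sigma2 <- fit$rWr / (n - p)
  lambda <- exp(opt$minimum)
  list(lambda = lambda, sigma2 = sigma2, phi2 = lambda * sigma2,
       beta = drop(fit$beta), at_bound = at_bound)
}

# REML for two kinships via Nelder-Mead on log variance ratios.
.reml_two_k <- function(y, K1, K2, X, maxit = 500) {
  n <- length(y); p <- ncol(X)
  obj <- function(par) {
    lam <- exp(par)
    V <- lam[1] * K1 + lam[2] * K2 + diag(n)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
    Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
    XtVX <- crossprod(X, Vi_X)
    beta <- solve(XtVX, crossprod(X, Vi_y))
    r <- y - X %*% beta
    Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
    rVr <- sum(r * Vi_r)
    2 * sum(log(diag(ch))) + determinant(XtVX)$modulus + (n - p) * log(rVr)
  }
  opt <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  lam <- exp(opt$par)
  V <- lam[1] * K1 + lam[2] * K2 + diag(n)
  ch <- chol(V)
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  beta <- solve(crossprod(X, Vi_X), crossprod(X, backsolve(ch, forwardsolve(t(ch), y))))
  r <- y - X %*% beta
  rVr <- sum(r * backsolve(ch, forwardsolve(t(ch), r)))
  sigma2 <- rVr / (n - p)
  list(lambda = lam, sigma2 = sigma2, phi2 = lam * sigma2,
       beta = drop(beta), at_bound = any(abs(opt$par) > 5.9))
}

#' Fit a GBLUP model by REML
#'
#' Mixed model y = X beta + sum_k g_k + e with g_k ~ N(0, K_k phi_k^2)
#' and e ~ N(0, I sigma^2), so var(y) = sum_k K_k phi_k^2 + I sigma^2.
#' With a single kinship the variance ratio lambda = phi^2/sigma^2 is
#' profiled out by eigendecomposition and Brent search over
#' log(lambda) in [-6, 6]; with two kinships (additive + dominance) a
#' Nelder-Mead search over both log ratios is used. A ratio estimated
#' at the search boundary is reported via `at_bound` (it signals a
#' variance component at, or beyond, the resolvable range, e.g. zero
#' genetic variance).
#'
#' @param y Named numeric response vector (trait or heterosis values).
#' @param kinship A `kinship` object (or bare matrix) for the additive
#'   term.
#' @param kinship2 Optional second `kinship` (dominance term).
#' @param X Fixed-effect design matrix (default: intercept only).
#' @return A `gblup_fit` object.
#' @export
fit_gblup <- function(y, kinship, kinship2 = NULL, X = NULL) {
  K1 <- if (inherits(kinship, "kinship")) kinship$values else kinship
  ids <- if (inherits(kinship, "kinship")) kinship$ids else rownames(K1)
  if (!is.null(names(y)) && !is.null(ids)) {
    if (!all(names(y) %in% ids)) stop_user("response ids missing from kinship")
    keep <- match(names(y), ids)
    K1 <- K1[keep, keep, drop = FALSE]
    ids <- ids[keep]
  }
  n <- length(y)
  if (n < 5) stop_user("GBLUP needs at least 5 individuals")
  .check_psd(K1)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (is.null(kinship2)) {
    est <- .reml_single_k(y, K1, X)
    phi2 <- est$phi2; lambda <- est$lambda
    Vhat <- phi2 * K1 + est$sigma2 * diag(n)
    Ks <- list(additive = K1)
  } else {
    K2 <- if (inherits(kinship2, "kinship")) kinship2$values else kinship2
    ids2 <- if (inherits(kinship2, "kinship")) kinship2$ids else rownames(K2)
    if (!is.null(names(y)) && !is.null(ids2)) {
      keep <- match(names(y), ids2)
      K2 <- K2[keep, keep, drop = FALSE]
    }
    .check_psd(K2)
    est <- .reml_two_k(y, K1, K2, X)
    phi2 <- est$phi2; lambda <- est$lambda
    Vhat <- phi2[1] * K1 + phi2[2] * K2 + est$sigma2 * diag(n)
    Ks <- list(additive = K1, dominance = K2)
  }
  if (est$at_bound)
    message("fit_gblup: variance ratio at search bound (near-zero or dominating component)")
  Vinv_r <- solve(Vhat, y - X %*% est$beta)
  structure(list(phi2 = phi2, sigma2 = est$sigma2, lambda = lambda,
                 beta = est$beta, X = X, y = y, ids = ids %||% names(y),
                 kinships = Ks, Vinv_r = drop(Vinv_r), at_bound = est$at_bound),
            class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat("GBLUP fit:", length(x$y), "individuals,",
      length(x$kinships), "kinship component(s)\n")
  cat("  phi2 =", signif(x$phi2, 4), " sigma2 =", signif(x$sigma2, 4),
      " lambda =", signif(x$lambda, 4), "\n")
  invisible(x)
}

#' Predict genomic values for new individuals from a GBLUP fit
#'
#' Prediction = X_test beta + sum_k K_test,train phi_k^2 V^-1 (y - X beta),
#' i.e. the BLUP of the genetic values of the test individuals given
#' the training phenotypes and the kinship blocks connecting them.
#'
#' @param fit A `gblup_fit`.
#' @param kinship_cross Test x train kinship block (matrix), or a list
#'   of such blocks named like the fit's kinship components.
#' @param X_test Fixed-effect design for test individuals (default:
#'   intercept).
#' @return Numeric vector of predictions.
#' @export
predict_gblup <- function(fit, kinship_cross, X_test = NULL) {
  blocks <- if (is.list(kinship_cross) && !is.matrix(kinship_cross))
    kinship_cross else list(additive = kinship_cross)
  if (!all(names(blocks) %in% names(fit$kinships)))
    stop_user("kinship block names do not match the fit's components")
  n_train <- length(fit$y)
  for (b in blocks) {
    if (ncol(b) != n_train) stop_user("kinship block has wrong training dimension")
    if (!is.null(colnames(b)) && !is.null(fit$ids) &&
        !identical(colnames(b), fit$ids))
      stop_user("kinship block training ids do not match the fit")
  }
  n_test <- nrow(blocks[[1]])
  if (is.null(X_test)) X_test <- matrix(1, n_test, ncol(fit$X))
  phi2 <- stats::setNames(rep(fit$phi2, length.out = length(fit$kinships)),
                          names(fit$kinships))
  g <- rep(0, n_test)
  for (nm in names(blocks)) g <- g + phi2[[nm]] * (blocks[[nm]] %*% fit$Vinv_r)
  drop(X_test %*% fit$beta + g)
}
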