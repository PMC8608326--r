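#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the R RNG, evaluates `expr`, and restores the previous
#' `.Random.seed`, so seeded operations never perturb the caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a parent seed and stream indices
#'
#' Deterministic mixing kept below 2^31 so derived seeds remain valid R
#' integers. Used to give each cross-validation replicate/fold and each
#' inner LASSO penalty search its own reproducible stream.
#'
#' @param seed Parent integer seed.
#' @param ... Further non-negative integer indices (replicate, fold, ...).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(as.numeric(seed), as.numeric(unlist(list(...))))
  h <- 0
  for (v in idx) h <- (h * 1000003 + (v + 17)) %% 2147483629
  as.integer(h + 1)
}

# stop() with a condition class the command-line wrapper maps to exit code 1
stop_user <- function(...) {
  stop(errorCondition(paste0(...), class = c("pgsihet_user_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
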