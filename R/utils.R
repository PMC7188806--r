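# Internal helpers: seed streams, validation, z-scoring.

# Derive a deterministic child seed from a master seed and an index.
# Kept strictly below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %% 2147483629L)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stopifnot_scalar_prob <- function(x, name, open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    if (open) (x > 0 && x < 1) else (x >= 0 && x <= 1)
  if (!ok) {
    abort(sprintf("`%s` must be a single %s number in %s",
                  name, "finite", if (open) "(0, 1)" else "[0, 1]"),
          class = "ctdlearn_domain_error")
  }
  invisible(x)
}

#' Z-score a numeric vector
#'
#' Centers and scales to unit sample standard deviation (denominator `n - 1`).
#' Used to normalize model prediction errors and block-level neural predictors
#' before they enter per-subject regressions, so that coefficients are
#' comparable across subjects at the group level.
#'
#' @param x Numeric vector without missing values.
#' @param name Predictor name used in error messages.
#' @return Numeric vector with mean 0 and sample SD 1.
#' @export
#' @examples
#' zscore(c(1, 2, 3))
zscore <- function(x, name = deparse(substitute(x))) {
  if (anyNA(x)) abort(sprintf("`%s` contains missing values", name),
                      class = "ctdlearn_domain_error")
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort(sprintf("cannot z-score `%s`: zero variance", name),
          class = "ctdlearn_degenerate_error")
  }
  (x - mean(x)) / s
}

# Fast column z-scoring used in hot paths; no error checking.
zscore_ <- function(x) (x - mean(x)) / sd(x)
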