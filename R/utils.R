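# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so that seeded operations do not perturb the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# scalar checks used by constructors; abort() keeps call noise out of errors
abort <- function(...) stop(..., call. = FALSE)

check_fraction <- function(x, name, allow_zero = FALSE) {
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || !lo_ok || x > 1) {
    abort(sprintf("`%s` must be a single number in %s", name,
                  if (allow_zero) "[0, 1]" else "(0, 1]"))
  }
  invisible(x)
}

#' Adjust p-values for multiple testing
#'
#' Thin wrapper around [stats::p.adjust()] used throughout the package:
#' Benjamini-Hochberg step-up control of the false discovery rate for the
#' ASV-trait association screen, and Holm's step-down familywise correction
#' for the diversity group comparisons. `NA` p-values are propagated.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @param method `"BH"` or `"holm"`.
#' @return numeric vector of adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("BH", "holm")) {
  method <- match.arg(method)
  if (length(p) && any(!is.na(p) & (p < 0 | p > 1))) {
    abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = method)
}
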