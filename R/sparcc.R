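# SparCC: correlation inference for compositional count data.
#
# Counts only carry relative information, so ordinary correlations of
# proportions are spurious.  SparCC works from the log-ratio variation
# matrix T_ij = var(log(x_i / x_j)), which is invariant to per-sample
# totals, and solves for approximate "basis" variances w under a sparsity
# assumption: sum_j T_ij ~ (d - 2) w_i + sum_j w_j.  Correlations are then
#   r_ij = (w_i + w_j - T_ij) / (2 sqrt(w_i w_j)),
# and the strongest correlated pair is iteratively removed from the basis
# system (it violates sparsity) before re-solving.

.sparcc_fractions <- function(counts, method) {
  if (method == "pseudocount") {
    sm <- counts + 1
    sm / rowSums(sm)
  } else {
    # one posterior draw from Dirichlet(counts + 1) per sample
    g <- matrix(stats::rgamma(length(counts), shape = counts + 1),
                nrow(counts), ncol(counts), dimnames = dimnames(counts))
    g / rowSums(g)
  }
}

.sparcc_once <- function(frac, exclusion_threshold, exclusion_rounds) {
  d <- ncol(frac)
  Cm <- stats::cov(log(frac))
  v <- diag(Cm)
  Tm <- outer(v, rep(1, d)) + outer(rep(1, d), v) - 2 * Cm
  M <- matrix(1, d, d); diag(M) <- d - 1
  tvec <- rowSums(Tm)
  excluded <- matrix(FALSE, d, d)
  R <- NULL
  for (round in seq_len(exclusion_rounds + 1L)) {
    omega <- tryCatch(solve(M, tvec), error = function(e) rep(NA_real_, d))
    if (anyNA(omega)) break
    omega <- pmax(omega, .Machine$double.eps)
    denom <- 2 * sqrt(outer(omega, omega))
    R <- (outer(omega, rep(1, d)) + outer(rep(1, d), omega) - Tm) / denom
    R[R > 1] <- 1; R[R < -1] <- -1
    diag(R) <- 1
    if (round > exclusion_rounds) break
    cand <- abs(R); cand[excluded] <- 0; diag(cand) <- 0
    mx <- max(cand)
    if (mx <= exclusion_threshold) break
    ij <- which(cand == mx, arr.ind = TRUE)[1L, ]
    i <- ij[1L]; j <- ij[2L]
    excluded[i, j] <- excluded[j, i] <- TRUE
    M[i, i] <- M[i, i] - 1; M[j, j] <- M[j, j] - 1
    M[i, j] <- M[i, j] - 1; M[j, i] <- M[j, i] - 1
    tvec[i] <- tvec[i] - Tm[i, j]
    tvec[j] <- tvec[j] - Tm[i, j]
  }
  dimnames(R) <- list(colnames(frac), colnames(frac))
  list(r = R, excluded_pairs = sum(excluded) / 2)
}

#' SparCC compositional correlations
#'
#' Estimates ASV-ASV correlations from a count table while accounting for
#' compositionality.  With `method = "pseudocount"` (the default) fractions
#' are the deterministic `(counts + 1) /` row total, giving a single,
#' reproducible estimate; with `method = "dirichlet"` fractions are drawn
#' from per-sample Dirichlet posteriors `n_iterations` times and the
#' element-wise median correlation is returned (the original algorithm's
#' behaviour).
#'
#' @param counts samples x ASVs count matrix (or [asv_table()]); at least
#'   3 ASVs.  Constant ASVs (zero log-ratio variance against every partner)
#'   are dropped with a warning.
#' @param n_iterations Dirichlet resampling iterations (ignored for the
#'   pseudocount method).
#' @param exclusion_threshold,exclusion_rounds the strongest correlated
#'   pair with `|r|` above the threshold is excluded from the basis-variance
#'   system and the system re-solved, up to `exclusion_rounds` times.
#' @param method `"pseudocount"` or `"dirichlet"`.
#' @param seed seed for the Dirichlet draws.
#' @return object of class `sparcc`: `r` (symmetric, unit diagonal),
#'   `method`, `excluded_pairs`, `dropped` (constant ASVs).
#' @export
sparcc <- function(counts, n_iterations = 20, exclusion_threshold = 0.1,
                   exclusion_rounds = 10,
                   method = c("pseudocount", "dirichlet"), seed = NULL) {
  if (inherits(counts, "asv_table")) counts <- counts$counts
  method <- match.arg(method)
  if (ncol(counts) < 3L) abort("SparCC needs at least 3 ASVs")
  pf <- (counts + 1) / rowSums(counts + 1)
  const <- apply(log(pf), 2L, stats::var) < .Machine$double.eps
  dropped <- colnames(counts)[const]
  if (length(dropped)) {
    warning("dropping degenerate (constant-fraction) ASV(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    counts <- counts[, !const, drop = FALSE]
    if (ncol(counts) < 3L) abort("fewer than 3 ASVs after dropping degenerates")
  }
  run <- function() {
    frac <- .sparcc_fractions(counts, method)
    .sparcc_once(frac, exclusion_threshold, exclusion_rounds)
  }
  if (method == "pseudocount") {
    res <- run()
    R <- res$r; excl <- res$excluded_pairs
  } else {
    runs <- with_seed(seed, replicate(n_iterations, run(), simplify = FALSE))
    R <- apply(simplify2array(lapply(runs, `[[`, "r")), c(1, 2), stats::median)
    excl <- stats::median(vapply(runs, `[[`, numeric(1), "excluded_pairs"))
  }
  structure(list(r = R, method = method, excluded_pairs = excl,
                 dropped = dropped),
            class = "sparcc")
}

#' Permutation pseudo p-values for SparCC correlations
#'
#' Each of the `n_boot` resamples permutes every ASV's counts independently
#' across samples — destroying all between-ASV correlation while keeping
#' each ASV's marginal distribution — and recomputes the SparCC correlation
#' matrix.  The two-sided pseudo p-value is
#' `(#{|r_perm| >= |r_obs|} + 1) / (n_boot + 1)`, so the smallest
#' attainable value at the default 100 resamples is `1/101`.
#'
#' @param counts the same count matrix (or [asv_table()]) given to
#'   [sparcc()].
#' @param observed a `sparcc` object or correlation matrix.
#' @param n_boot number of resamples (default 100).
#' @param seed integer seed.
#' @param ... passed on to [sparcc()] (method, exclusion settings).
#' @return symmetric matrix of pseudo p-values with unit diagonal.
#' @export
sparcc_pvalues <- function(counts, observed, n_boot = 100, seed = NULL, ...) {
  if (inherits(counts, "asv_table")) counts <- counts$counts
  r_obs <- if (inherits(observed, "sparcc")) observed$r else observed
  counts <- counts[, colnames(r_obs), drop = FALSE]
  a_obs <- abs(r_obs)
  hits <- matrix(0, nrow(a_obs), ncol(a_obs), dimnames = dimnames(a_obs))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      perm <- apply(counts, 2L, sample)
      r_b <- suppressWarnings(sparcc(perm, ...))$r
      hits <- hits + (abs(r_b) >= a_obs)
    }
  })
  p <- (hits + 1) / (n_boot + 1)
  diag(p) <- 1
  p
}
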