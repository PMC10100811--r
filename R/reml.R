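# Restricted maximum likelihood for the additive + maternal animal model.
#
# The model for one ASV's log relative abundance y (length n) is
#   y = X b + Z a + W m + e,
#   a ~ N(0, A s2_a),  m ~ N(0, I s2_m),  e ~ N(0, I s2_e),
# so V = K_a s2_a + K_m s2_m + I s2_e with K_a = Z A Z' and K_m = W W'.
#
# The optimizer is average-information REML: Newton-like steps on the
# variance scale using the AI matrix, guarded by a step-halving line search
# on the restricted likelihood and an EM-style fixed-point fallback when the
# AI direction is unusable.  Variances are floored at `floor` (boundary
# estimates are flagged, not hidden).

# restricted log-likelihood and the quantities reused by the updates
.reml_core <- function(y, X, Vlist, sigma2) {
  n <- length(y)
  V <- matrix(0, n, n)
  for (i in seq_along(Vlist)) V <- V + sigma2[i] * Vlist[[i]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- chol(V + diag(1e-8 * mean(diag(V)), n))
  }
  Vinv <- chol2inv(ch)
  VinvX <- Vinv %*% X
  XtVinvX <- crossprod(X, VinvX)
  chx <- chol(XtVinvX)
  Cmat <- chol2inv(chx)                      # (X'V^-1X)^-1
  Py <- Vinv %*% y - VinvX %*% (Cmat %*% crossprod(VinvX, y))
  logdetV <- 2 * sum(log(diag(ch)))
  logdetX <- 2 * sum(log(diag(chx)))
  ll <- -0.5 * (logdetV + logdetX + sum(y * Py))
  list(Vinv = Vinv, VinvX = VinvX, Cmat = Cmat, Py = Py, ll = ll)
}

.reml_ll <- function(y, X, Vlist, sigma2) .reml_core(y, X, Vlist, sigma2)$ll

#' Fit variance components by AI-REML
#'
#' Maximizes the restricted likelihood of
#' `y ~ N(Xb, sum_i sigma2_i K_i + sigma2_e I)` over the non-negative
#' variance components.  Updates are average-information (AI) steps with a
#' step-halving line search; when the AI proposal is out of bounds or
#' decreases the likelihood even after halving, an expectation-maximization
#' style fixed-point step is taken instead.  Convergence is declared when
#' the maximum relative parameter change falls below `tol_par` or the
#' likelihood change below `tol_ll`.  Components shrinking to the `floor`
#' (default 1e-8) are held there and flagged `boundary`.
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix (full column rank).
#' @param K named list of n x n PSD covariance structure matrices for the
#'   non-residual components (e.g. `list(additive = ZAZt, maternal = WWt)`);
#'   a residual identity component is appended automatically.
#' @param init optional starting variances (length `length(K) + 1`).
#' @param max_iter,tol_par,tol_ll,floor optimizer controls.
#' @return object of class `reml_fit`: `sigma2` (named, incl. `residual`),
#'   `loglik`, `vcov` (inverse of the final AI matrix), `ai`, `gradient`,
#'   `iterations`, `converged`, `boundary`, `n`, `rank_x`.
#' @export
reml_fit <- function(y, X, K, init = NULL, max_iter = 200,
                     tol_par = 1e-8, tol_ll = 1e-10, floor = 1e-8) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) abort("X and y dimensions disagree")
  if (qr(X)$rank < ncol(X)) abort("X must have full column rank (use build_design)")
  if (n <= ncol(X) + length(K)) abort("too few observations for REML")
  Vlist <- c(unname(K), list(diag(n)))
  k <- length(Vlist)
  comp_names <- c(names(K) %||% paste0("K", seq_along(K)), "residual")

  # fit on the residual-variance scale so the optimizer sees O(1) variances
  # and the result is exactly invariant to rescaling y
  r_ols <- stats::lm.fit(X, y)$residuals
  sc2 <- stats::var(r_ols)
  if (!is.finite(sc2) || sc2 <= 0) abort("response has no residual variation")
  y <- y / sqrt(sc2)
  if (!is.null(init)) init <- init / sc2

  if (is.null(init)) init <- rep(1 / k, k)
  sigma2 <- pmax(init, floor)
  core <- .reml_core(y, X, Vlist, sigma2)
  grad <- numeric(k); AI <- matrix(0, k, k)
  converged <- FALSE; iter <- 0

  for (iter in seq_len(max_iter)) {
    # gradient g_i = -0.5 (tr(P K_i) - y'P K_i P y) and AI matrix
    KPy <- lapply(Vlist, function(Ki) Ki %*% core$Py)
    PKPy <- lapply(KPy, function(v) {
      core$Vinv %*% v - core$VinvX %*% (core$Cmat %*% crossprod(core$VinvX, v))
    })
    trPK <- vapply(Vlist, function(Ki) {
      # tr(PK) = tr(V^-1 K) - tr(C (V^-1X)' K (V^-1X)); both symmetric
      sum(core$Vinv * Ki) -
        sum(core$Cmat * crossprod(core$VinvX, Ki %*% core$VinvX))
    }, numeric(1))
    yPKPy <- vapply(KPy, function(v) sum(core$Py * v), numeric(1))
    grad <- -0.5 * (trPK - yPKPy)
    for (i in seq_len(k)) {
      for (j in i:k) {
        AI[i, j] <- AI[j, i] <- 0.5 * sum(KPy[[i]] * PKPy[[j]])
      }
    }

    # active set: components pinned at the floor with an inward-pointing
    # gradient are frozen out of the AI system
    at_floor <- sigma2 <= floor * (1 + 1e-12)
    active <- !(at_floor & grad < 0)
    if (all(abs(grad) < 1e-3 | !active)) { converged <- TRUE; break }

    dir <- numeric(k)
    da <- tryCatch(
      solve(AI[active, active, drop = FALSE] + diag(1e-10, sum(active)),
            grad[active]),
      error = function(e) NULL)
    if (is.null(da) || any(!is.finite(da))) da <- grad[active] / max(abs(grad[active]), 1)
    dir[active] <- da

    step <- 1; new_core <- NULL; new_sigma2 <- sigma2
    for (h in 1:25) {
      cand <- pmax(sigma2 + step * dir, floor)
      cc <- .reml_core(y, X, Vlist, cand)
      if (is.finite(cc$ll) && cc$ll >= core$ll - 1e-12) {
        new_core <- cc; new_sigma2 <- cand; break
      }
      step <- step / 2
    }
    if (is.null(new_core)) {
      # EM-style fixed point: sigma_i <- sigma_i * y'PK_iPy / tr(PK_i)
      ratio <- ifelse(trPK > 0, yPKPy / trPK, 1)
      cand <- pmax(sigma2 * ratio, floor)
      cc <- .reml_core(y, X, Vlist, cand)
      if (!is.finite(cc$ll) || cc$ll < core$ll - 1e-8) { converged <- TRUE; break }
      new_core <- cc; new_sigma2 <- cand
    }

    rel <- max(abs(new_sigma2 - sigma2) / pmax(sigma2, floor))
    dll <- new_core$ll - core$ll
    sigma2 <- new_sigma2; core <- new_core
    if (rel < tol_par || abs(dll) < tol_ll) { converged <- TRUE; break }
  }

  vc <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, k, k))
  boundary_flag <- sigma2 <= floor * (1 + 1e-12)
  # back-transform to the original response scale
  sigma2 <- sigma2 * sc2
  vc <- vc * sc2^2
  AI <- AI / sc2^2
  grad <- grad / sc2
  ll <- core$ll - 0.5 * (n - ncol(X)) * log(sc2)
  dimnames(vc) <- dimnames(AI) <- list(comp_names, comp_names)
  structure(list(sigma2 = stats::setNames(sigma2, comp_names),
                 loglik = ll,
                 ai = AI, vcov = vc,
                 gradient = stats::setNames(grad, comp_names),
                 iterations = iter, converged = converged,
                 boundary = stats::setNames(boundary_flag, comp_names),
                 n = n, rank_x = ncol(X)),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("REML fit:", if (x$converged) "converged" else "NOT converged",
      "in", x$iterations, "iterations; logL =", format(x$loglik), "\n")
  print(round(x$sigma2, 6))
  invisible(x)
}
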