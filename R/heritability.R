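# Per-ASV heritability: design construction, the REML wrapper, h2 with
# delta-method standard errors and t-based p-values, and the heritable-ASV
# screen.

#' Build the mixed-model design for the animal model
#'
#' Constructs, once per data set (the pieces are shared by every ASV):
#' * `X` — intercept, year-season dummies, group (dam/lamb) dummy and
#'   centered age as a covariate; dummy reference levels are the
#'   lexicographically first level; aliased columns are dropped to full
#'   rank and reported;
#' * `K_a = Z A Z'` — additive covariance structure, with `Z` mapping each
#'   sample to its animal in the pedigree;
#' * `K_m = W W'` — maternal covariance structure, with `W` mapping each
#'   sample to the dam of the sampled animal; animals whose dam is unknown
#'   (founders, typically the sampled dams themselves) get an all-zero row,
#'   i.e. no maternal effect.
#'
#' @param metadata data.frame with columns `sample_id`, `animal`, `group`
#'   (`"dam"`/`"lamb"`), `age` (days) and `year_season`.
#' @param ped a [pedigree()] containing every sampled animal.
#' @param A optional precomputed [a_matrix()] (recomputed if missing).
#' @return object of class `herit_design`: `X`, `K_a`, `K_m`, `n`,
#'   `rank_x`, `dropped` (names of aliased columns), `sample_id`,
#'   `maternal_levels`.
#' @export
build_design <- function(metadata, ped, A = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  need <- c("sample_id", "animal", "group", "age", "year_season")
  if (!all(need %in% names(metadata))) {
    abort("metadata needs columns: ", paste(need, collapse = ", "))
  }
  missing_an <- setdiff(metadata$animal, ped$animal)
  if (length(missing_an)) {
    abort("sampled animal(s) absent from pedigree: ",
          paste(missing_an, collapse = ", "))
  }
  n <- nrow(metadata)
  md <- metadata
  md$group <- factor(md$group)
  md$year_season <- factor(md$year_season)
  md$age_c <- md$age - mean(md$age)
  X <- stats::model.matrix(~ year_season + group + age_c, data = md)
  qrx <- qr(X)
  dropped <- character(0)
  if (qrx$rank < ncol(X)) {
    keep <- qrx$pivot[seq_len(qrx$rank)]
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    message("design rank-deficient; dropping aliased column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }

  if (is.null(A)) A <- a_matrix(ped)
  ai <- match(md$animal, ped$animal)
  K_a <- A[ai, ai, drop = FALSE]
  dimnames(K_a) <- list(md$sample_id, md$sample_id)

  dam_of <- ped$dam[ai]                    # NA for founders
  levels_m <- sort(unique(stats::na.omit(dam_of)))
  W <- matrix(0, n, length(levels_m),
              dimnames = list(md$sample_id, levels_m))
  known <- !is.na(dam_of)
  W[cbind(which(known), match(dam_of[known], levels_m))] <- 1
  K_m <- tcrossprod(W)

  structure(list(X = X, K_a = K_a, K_m = K_m, W = W, n = n,
                 rank_x = ncol(X), dropped = dropped,
                 sample_id = md$sample_id, maternal_levels = levels_m),
            class = "herit_design")
}

#' Heritability from variance components
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_m + sigma2_e)`: the fraction of
#' phenotypic variance of the log relative abundance attributable to
#' additive genetic variance.
#'
#' @param fit a [reml_fit()] with components `additive`, `maternal`,
#'   `residual`.
#' @return heritability in `[0, 1]`.
#' @export
heritability <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  s <- fit$sigma2
  tot <- sum(s[c("additive", "maternal", "residual")])
  if (!is.finite(tot) || tot <= 0) abort("total variance must be positive")
  unname(s["additive"] / tot)
}

#' Standard error and p-value of a heritability estimate
#'
#' The SE comes from a first-order Taylor (delta-method) expansion of
#' `h2 = s_a / T`, `T = s_a + s_m + s_e`: the gradient is
#' `((T - s_a)/T^2, -s_a/T^2, -s_a/T^2)` and `SE = sqrt(g' V g)` with `V`
#' the asymptotic covariance of the variance components (inverse AI
#' matrix).  The p-value is an unpaired two-tailed Student t test of
#' `h2 / SE` on `df = n - rank(X)` degrees of freedom.
#'
#' @param fit a [reml_fit()].
#' @param df degrees of freedom; defaults to `fit$n - fit$rank_x`.
#' @return list with `h2`, `se`, `p`, `df`, and `ci95`.
#' @export
heritability_se_p <- function(fit, df = NULL) {
  stopifnot(inherits(fit, "reml_fit"))
  df <- df %||% (fit$n - fit$rank_x)
  s <- fit$sigma2[c("additive", "maternal", "residual")]
  tot <- sum(s)
  h2 <- unname(s[1L] / tot)
  V <- fit$vcov[c("additive", "maternal", "residual"),
                c("additive", "maternal", "residual")]
  if (anyNA(V)) {
    return(list(h2 = h2, se = NA_real_, p = NA_real_, df = df,
                ci95 = c(NA_real_, NA_real_)))
  }
  g <- c((tot - s[1L]) / tot^2, -s[1L] / tot^2, -s[1L] / tot^2)
  se2 <- drop(t(g) %*% V %*% g)
  se <- sqrt(max(se2, 0))
  p <- if (se > 0) 2 * stats::pt(-abs(h2 / se), df = df) else
    as.numeric(h2 == 0)
  list(h2 = h2, se = se, p = p, df = df,
       ci95 = h2 + c(-1, 1) * stats::qt(0.975, df) * se)
}

#' Estimate per-ASV heritability across an ASV table
#'
#' For every ASV, takes the log-transformed relative abundance as the
#' phenotype and fits the additive + maternal animal model by
#' [reml_fit()], returning the heritability, its delta-method SE, the
#' Student-t p-value and the estimated variance components.
#'
#' @param x an [asv_table()] (typically prevalence-filtered).
#' @param metadata sample metadata (see [build_design()]).
#' @param ped a [pedigree()].
#' @param pseudocount pseudocount for the log transform.
#' @param design optional precomputed [build_design()] result.
#' @param asvs optional character vector restricting which ASVs are fitted.
#' @param ... passed to [reml_fit()].
#' @return data.frame, one row per ASV: `asv, h2, se, p, sigma_a2,
#'   sigma_m2, sigma_e2, loglik, converged, boundary`.
#' @export
fit_heritability <- function(x, metadata, ped, pseudocount = 1e-6,
                             design = NULL, asvs = NULL, ...) {
  stopifnot(inherits(x, "asv_table"))
  metadata <- metadata[match(rownames(x$counts), metadata$sample_id), ]
  if (anyNA(metadata$sample_id)) abort("metadata is missing some samples")
  design <- design %||% build_design(metadata, ped)
  logab <- log_transform(relative_abundance(x), pseudocount)
  asvs <- asvs %||% colnames(logab)
  K <- list(additive = design$K_a, maternal = design$K_m)
  rows <- lapply(asvs, function(a) {
    fit <- reml_fit(logab[, a], design$X, K, ...)
    sp <- heritability_se_p(fit)
    data.frame(asv = a, h2 = sp$h2, se = sp$se, p = sp$p,
               sigma_a2 = unname(fit$sigma2["additive"]),
               sigma_m2 = unname(fit$sigma2["maternal"]),
               sigma_e2 = unname(fit$sigma2["residual"]),
               loglik = fit$loglik, converged = fit$converged,
               boundary = any(fit$boundary), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Screen for heritable ASVs
#'
#' Flags ASVs with `h2 > h2_min` and `p < p_max` (strict inequalities, the
#' boundary is excluded) and summarizes: number and percentage of heritable
#' ASVs among those tested, and the combined relative abundance of the
#' heritable set per group as mean +/- SD across samples.
#'
#' @param results data.frame from [fit_heritability()].
#' @param x the [asv_table()] the results refer to.
#' @param metadata sample metadata with `sample_id` and `group`.
#' @param h2_min,p_max screening thresholds (defaults 0.2 and 0.05).
#' @return list with `results` (input plus logical `heritable`),
#'   `heritable_asvs`, and `summary` (`n_heritable`, `n_tested`,
#'   `pct_heritable` as a percentage rounded to one decimal, and
#'   `combined_abundance`: per-group mean and SD of the summed relative
#'   abundance, in percent).
#' @export
screen_heritable <- function(results, x = NULL, metadata = NULL,
                             h2_min = 0.2, p_max = 0.05) {
  results$heritable <- !is.na(results$h2) & !is.na(results$p) &
    results$h2 > h2_min & results$p < p_max
  ids <- results$asv[results$heritable]
  comb <- NULL
  if (!is.null(x) && !is.null(metadata)) {
    prop <- relative_abundance(x)
    tot <- rowSums(prop[, colnames(prop) %in% ids, drop = FALSE]) * 100
    md <- metadata[match(rownames(prop), metadata$sample_id), ]
    comb <- do.call(rbind, lapply(split(tot, md$group), function(v) {
      data.frame(mean_pct = mean(v), sd_pct = stats::sd(v))
    }))
    comb$group <- rownames(comb); rownames(comb) <- NULL
  }
  list(results = results,
       heritable_asvs = ids,
       summary = list(
         n_heritable = length(ids),
         n_tested = nrow(results),
         pct_heritable = round(100 * length(ids) / nrow(results), 1),
         combined_abundance = comb))
}
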