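# Alpha diversity, beta dissimilarity, ordination and group comparisons.

#' Per-sample alpha diversity
#'
#' Computes three metrics per sample:
#' * Chao1 richness, bias-corrected:
#'   \eqn{S_{obs} + f_1 (f_1 - 1) / (2 (f_2 + 1))} with \eqn{f_1},
#'   \eqn{f_2} the numbers of singleton and doubleton ASVs;
#' * Shannon diversity \eqn{H = -\sum p_i \ln p_i} (natural log);
#' * Pielou evenness \eqn{H / \ln S_{obs}}, reported as `NA` for samples
#'   with a single taxon (where \eqn{\ln S_{obs} = 0}).
#'
#' Chao1 assumes integer counts, so apply it to raw or rarefied counts, not
#' proportions.
#'
#' @param x an [asv_table()].
#' @return data.frame with columns `sample_id`, `chao1`, `shannon`,
#'   `evenness`.
#' @export
alpha_diversity <- function(x) {
  stopifnot(inherits(x, "asv_table"))
  counts <- x$counts
  s_obs <- rowSums(counts > 0)
  f1 <- rowSums(counts == 1)
  f2 <- rowSums(counts == 2)
  chao1 <- s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  shannon <- vegan::diversity(counts, index = "shannon")
  evenness <- ifelse(s_obs > 1, shannon / log(s_obs), NA_real_)
  data.frame(sample_id = rownames(counts), chao1 = chao1,
             shannon = as.numeric(shannon), evenness = evenness,
             row.names = NULL)
}

#' Beta dissimilarity between samples
#'
#' Supported metrics:
#' * `bray_curtis` — Bray-Curtis dissimilarity on counts/abundances;
#' * `binary_jaccard` — `1 - |A∩B| / |A∪B|` on presence/absence;
#' * `weighted_unifrac` — normalized weighted UniFrac, requiring a rooted
#'   phylogenetic tree whose tips cover every ASV in the table (computed via
#'   the phyloseq implementation).
#'
#' @param x an [asv_table()].
#' @param metric one of `"bray_curtis"`, `"binary_jaccard"`,
#'   `"weighted_unifrac"`.
#' @param tree an [ape::phylo] tree (weighted UniFrac only).
#' @return a [stats::dist] object over samples.
#' @export
beta_dissimilarity <- function(x,
                               metric = c("bray_curtis", "binary_jaccard",
                                          "weighted_unifrac"),
                               tree = NULL) {
  stopifnot(inherits(x, "asv_table"))
  metric <- match.arg(metric)
  counts <- x$counts
  if (metric == "bray_curtis") {
    return(vegan::vegdist(counts, method = "bray"))
  }
  if (metric == "binary_jaccard") {
    return(vegan::vegdist(counts, method = "jaccard", binary = TRUE))
  }
  if (is.null(tree)) abort("weighted_unifrac requires a `tree`")
  missing <- setdiff(colnames(counts), tree$tip.label)
  if (length(missing)) {
    abort("tree is missing tips for ASVs: ", paste(missing, collapse = ", "))
  }
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(t(counts), taxa_are_rows = TRUE),
    phyloseq::phy_tree(ape::keep.tip(tree, colnames(counts))))
  phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE)
}

#' Principal-coordinate analysis (classical metric scaling)
#'
#' Double-centers \eqn{-\tfrac12 D^2} and eigendecomposes it.  Axes are
#' ordered by decreasing eigenvalue; axes with non-positive eigenvalues are
#' excluded (not corrected), and the proportion of variance explained is
#' reported over the positive eigenvalues only.
#'
#' @param d a symmetric distance matrix or [stats::dist] with zero diagonal.
#' @return list with `coordinates` (samples x axes), `eigenvalues`
#'   (positive ones), `proportion_explained`, and `negative_eigenvalues`
#'   (count dropped).
#' @export
pcoa_ordination <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m) || !isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    abort("distance matrix must be square and symmetric")
  }
  n <- nrow(m)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(m), k = n - 1,
                                          eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > sqrt(.Machine$double.eps) * max(abs(eig), 1))
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  if (length(pos)) colnames(coords) <- paste0("PCo", seq_along(pos))
  list(coordinates = coords,
       eigenvalues = eig[pos],
       proportion_explained = if (length(pos)) eig[pos] / sum(eig[pos]) else numeric(0),
       negative_eigenvalues = sum(eig < 0))
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance (Anderson's pseudo-F on
#' among/within sums of squared distances), delegated to
#' [vegan::adonis2()].  The permutation p-value is
#' `(number of permuted F >= observed + 1) / (n_perm + 1)`, so the smallest
#' attainable p at 999 permutations is 0.001.
#'
#' @param d distance matrix or [stats::dist].
#' @param groups factor of group labels, one per sample (at least two
#'   groups, each with at least two samples).
#' @param n_perm number of permutations (default 999).
#' @param seed optional integer seed.
#' @return list with `f`, `p`, `r2`, `df` and the underlying adonis2 table.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  groups <- as.factor(groups)
  m <- stats::as.dist(d)
  n <- attr(m, "Size")
  if (length(groups) != n) abort("`groups` length must match the matrix")
  tab <- table(groups)
  if (length(tab) < 2L) abort("at least two groups are required")
  if (any(tab < 2L)) {
    abort("every group needs >= 2 samples; too small: ",
          paste(names(tab)[tab < 2L], collapse = ", "))
  }
  df <- data.frame(grp = groups)
  fit <- with_seed(seed, vegan::adonis2(m ~ grp, data = df,
                                        permutations = n_perm))
  list(f = fit$F[1L], p = fit$`Pr(>F)`[1L], r2 = fit$R2[1L],
       df = c(fit$Df[1L], fit$Df[2L]), table = fit)
}

#' Two-sided Wilcoxon rank-sum comparison
#'
#' Mann-Whitney/Wilcoxon rank-sum test: exact for small samples without
#' ties, normal approximation with tie correction otherwise.  When the
#' pooled data are constant the test is uninformative and p = 1 is
#' returned.  Combine several comparisons with
#' `adjust_pvalues(p, "holm")` for a familywise correction.
#'
#' @param a,b numeric vectors (both nonempty).
#' @return list with `p`, `statistic` (the Mann-Whitney U of `a`), and
#'   `method`.
#' @export
rank_sum_test <- function(a, b) {
  if (!length(a) || !length(b)) abort("both groups must be nonempty")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    return(list(p = 1, statistic = length(a) * length(b) / 2,
                method = "degenerate (constant data)"))
  }
  ht <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  list(p = ht$p.value, statistic = unname(ht$statistic), method = ht$method)
}
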