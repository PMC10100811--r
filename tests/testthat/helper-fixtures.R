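# Shared fixtures and independent oracles used across the test files.

# small ASV table built in code
toy_table <- function() {
  counts <- matrix(c(2, 2, 4, 0,
                     1, 0, 3, 6,
                     5, 5, 0, 0), nrow = 3, byrow = TRUE,
                   dimnames = list(c("s1", "s2", "s3"),
                                   c("ASV1", "ASV2", "ASV3", "ASV4")))
  tax <- c(ASV1 = "Bacteria;Bacteroidota;Bacteroidia;Bacteroidales;Prevotellaceae;Prevotella",
           ASV2 = "Bacteria;Bacteroidota;Bacteroidia;Bacteroidales;Prevotellaceae;Prevotella",
           ASV3 = "Bacteria;Firmicutes;Clostridia;Lachnospirales;Lachnospiraceae;Roseburia")
  asv_table(counts, tax)
}

# classic nuclear-family pedigree: sire S, dam D, full sibs C1/C2, and X =
# offspring of the parent-offspring mating C1 x D (F = 0.25)
family_pedigree <- function() {
  pedigree(data.frame(animal = c("S", "D", "C1", "C2", "X"),
                      sire = c(NA, NA, "S", "S", "C1"),
                      dam = c(NA, NA, "D", "D", "D")))
}

# random valid pedigree: founders first, later animals draw parents (with
# some unknowns) from earlier animals of consistent sex
random_pedigree <- function(n, seed, p_unknown = 0.15) {
  set.seed(seed)
  sex <- rep_len(c("M", "F"), n)
  animal <- sprintf("A%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  n_found <- max(2L, floor(n / 3))
  for (i in seq(n_found + 1L, n)) {
    males <- which(sex[seq_len(i - 1L)] == "M")
    females <- which(sex[seq_len(i - 1L)] == "F")
    if (length(males) && stats::runif(1) > p_unknown) {
      sire[i] <- animal[males[sample.int(length(males), 1L)]]
    }
    if (length(females) && stats::runif(1) > p_unknown) {
      dam[i] <- animal[females[sample.int(length(females), 1L)]]
    }
  }
  pedigree(data.frame(animal = animal, sire = sire, dam = dam))
}

# gene-dropping oracle for the relationship matrix: founders get unique
# alleles, descent is simulated n_rep times in parallel, and relationships
# are estimated as 2 * kinship from allele identity frequencies
gene_drop_A <- function(ped, n_rep = 1e5) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  pat <- matrix(0L, n_rep, n)
  mat <- matrix(0L, n_rep, n)
  next_id <- 1L
  for (i in seq_len(n)) {
    if (si[i] == 0L) {
      pat[, i] <- next_id; next_id <- next_id + 1L
    } else {
      pick <- stats::runif(n_rep) < 0.5
      pat[, i] <- ifelse(pick, pat[, si[i]], mat[, si[i]])
    }
    if (di[i] == 0L) {
      mat[, i] <- next_id; next_id <- next_id + 1L
    } else {
      pick <- stats::runif(n_rep) < 0.5
      mat[, i] <- ifelse(pick, pat[, di[i]], mat[, di[i]])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    A[i, i] <- 1 + mean(pat[, i] == mat[, i])
    if (i > 1L) for (j in seq_len(i - 1L)) {
      a <- (mean(pat[, i] == pat[, j]) + mean(pat[, i] == mat[, j]) +
              mean(mat[, i] == pat[, j]) + mean(mat[, i] == mat[, j])) / 2
      A[i, j] <- A[j, i] <- a
    }
  }
  A
}

# exact two-sided Spearman p by full enumeration of all n! orderings
spearman_exact_p <- function(x, y) {
  n <- length(x)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  obs <- abs(stats::cor(x, y, method = "spearman"))
  all_r <- vapply(perms(seq_len(n)),
                  function(p) stats::cor(x, y[p], method = "spearman"),
                  numeric(1))
  mean(abs(all_r) >= obs - 1e-12)
}

# BH step-up computed from its definition, independent of p.adjust
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# brute-force MCODE-style best subcluster: over every vertex subset whose
# induced subgraph is connected and contains a k-core, score = density*size
brute_best_cluster <- function(g, k_core = 2) {
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  best <- NULL
  for (mask in seq_len(2^n - 1)) {
    v <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(v) < 2L) next
    sub <- igraph::induced_subgraph(g, v)
    if (!igraph::is_connected(sub)) next
    if (max(igraph::coreness(sub)) < k_core) next
    nn <- length(v)
    score <- 2 * igraph::ecount(sub) / (nn * (nn - 1)) * nn
    if (is.null(best) || score > best$score) {
      best <- list(members = sort(nm[v]), score = score)
    }
  }
  best
}

# simulate a response under the additive + maternal animal model on a
# given design (used as the REML recovery oracle)
simulate_animal_model_y <- function(design, ped, sigma_a2, sigma_m2,
                                    sigma_e2, beta = NULL) {
  A <- a_matrix(ped)
  R <- chol(A)
  a <- crossprod(R, stats::rnorm(nrow(A))) * sqrt(sigma_a2)
  idx <- match(design$sample_id, ped$animal)
  m_lv <- stats::rnorm(length(design$maternal_levels), 0, sqrt(sigma_m2))
  m <- as.numeric(design$W %*% m_lv)
  e <- stats::rnorm(design$n, 0, sqrt(sigma_e2))
  xb <- if (is.null(beta)) 0 else drop(design$X %*% beta)
  xb + a[idx] + m + e
}

# one shared mid-sized population for the heritability tests
shared_popn <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      params <- synth_params(n_dams = 128, n_asvs = 10, seed = 42)
      pedsim <- simulate_pedigree(params, seed = 42)
      md <- with_seed_meta(pedsim)
      design <- build_design(md, pedsim$ped)
      cache <<- list(params = params, pedsim = pedsim, md = md,
                     design = design)
    }
    cache
  }
})

# minimal metadata for a simulated pedigree without generating counts
with_seed_meta <- function(pedsim, seed = 99) {
  set.seed(seed)
  samples <- c(pedsim$dams, pedsim$lambs$animal)
  is_lamb <- samples %in% pedsim$lambs$animal
  data.frame(
    sample_id = samples, animal = samples,
    group = ifelse(is_lamb, "lamb", "dam"),
    age = ifelse(is_lamb, round(stats::rnorm(length(samples), 60, 2)),
                 round(stats::rnorm(length(samples), 1000, 300))),
    year_season = sample(c("YS1", "YS2"), length(samples), replace = TRUE),
    dam = ifelse(is_lamb, pedsim$lambs$dam[match(samples, pedsim$lambs$animal)], NA),
    litter_size = ifelse(is_lamb,
                         pedsim$lambs$litter_size[match(samples, pedsim$lambs$animal)],
                         NA),
    stringsAsFactors = FALSE)
}
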