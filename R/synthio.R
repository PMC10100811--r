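# Synthetic dam-lamb populations with known variance components.
#
# The generator produces, under one seed: a pedigree of founder dams, a
# finite sire pool and their lambs; per-ASV latent log abundances following
# the additive + maternal animal model y = Xb + Za + Wm + e with a ~
# N(0, A s2_a); compositional count tables (softmax of the latent values,
# multinomial counts at negative-binomial library sizes); growth traits
# linked to designated ASVs; rumen fermentation parameters; and a random
# phylogeny.  The latent matrix is returned so downstream estimates can be
# checked against the exact generative truth.

#' Parameters of the synthetic dam-lamb study
#'
#' Defaults emulate a flock of 128 dams with litter sizes 1-4 at a mean of
#' about 1.4 lambs per dam (~179 lambs), 16 service sires (litters of the
#' same dam share a sire, so littermates are full sibs and lambs of
#' different dams by the same sire are half sibs), 150 ASVs of which the
#' first 10% are heritable with h2 spread evenly between 0.25 and 0.65
#' (maternal variance 0.1, total latent variance 1), and sequencing
#' library sizes with mean 35,000 and standard deviation near 9,500.
#' Heritable ASVs receive a baseline log-abundance boost so they sit in the
#' abundant tail of the composition, mirroring the observation that
#' abundant taxa tend to be the heritable ones.
#'
#' @param n_dams number of founder dams.
#' @param litter_size_probs probability vector over litter sizes 1-4
#'   (must sum to 1).
#' @param n_sires size of the sire pool.
#' @param n_asvs number of ASVs.
#' @param sigma_a2,sigma_m2,sigma_e2 per-ASV variance components on the
#'   latent log-abundance scale (recycled to `n_asvs`); all must be >= 0.
#' @param baseline_sd SD of per-ASV baseline log abundances.
#' @param heritable_boost baseline increment for ASVs with `sigma_a2 > 0`.
#' @param group_effect_sd SD of the per-ASV dam-vs-lamb fixed effect.
#' @param year_season_levels,year_season_effects number of year-season
#'   levels and their fixed effects.
#' @param age_slope fixed-effect slope per day of age.
#' @param library_size_mean,library_size_dispersion negative-binomial mean
#'   and size parameter of per-sample sequencing depth.
#' @param cooccur_blocks,cooccur_block_size,cooccur_rho co-occurring
#'   guilds: `cooccur_blocks` groups of `cooccur_block_size` ASVs whose
#'   residuals share a per-sample factor giving pairwise residual
#'   correlation `cooccur_rho` within the group.  Blocks are placed on the
#'   last `cooccur_blocks * cooccur_block_size` ASVs (non-heritable under
#'   the defaults), so co-abundance structure and heritability are planted
#'   on disjoint ASVs.
#' @param n_trait_asvs number of ASVs causally linked to growth traits
#'   (the first `n_trait_asvs` ASVs; under the defaults these are
#'   heritable).
#' @param trait_effect_bw,trait_effect_ww per-ASV effect of the latent
#'   abundance on birth weight and weaning weight (kg per latent unit).
#' @param trait_noise_bw,trait_noise_ww residual SD of the traits (kg).
#' @param seed default seed used by the simulate_* functions.
#' @return a validated list of class `synth_params`.
#' @export
synth_params <- function(n_dams = 128,
                         litter_size_probs = c(0.65, 0.30, 0.045, 0.005),
                         n_sires = 16,
                         n_asvs = 150,
                         sigma_a2 = NULL, sigma_m2 = NULL, sigma_e2 = NULL,
                         baseline_sd = 1.25,
                         heritable_boost = 1,
                         group_effect_sd = 1,
                         year_season_levels = 2,
                         year_season_effects = c(0, 0.3),
                         age_slope = 0,
                         library_size_mean = 35000,
                         library_size_dispersion = 13.5,
                         cooccur_blocks = NULL,
                         cooccur_block_size = 4,
                         cooccur_rho = 0.7,
                         n_trait_asvs = 5,
                         trait_effect_bw = 0.25,
                         trait_effect_ww = 0.8,
                         trait_noise_bw = 0.4,
                         trait_noise_ww = 1.2,
                         seed = 1) {
  if (n_dams < 1) abort("`n_dams` must be >= 1")
  if (length(litter_size_probs) != 4L || any(litter_size_probs < 0) ||
      abs(sum(litter_size_probs) - 1) > 1e-8) {
    abort("`litter_size_probs` must be 4 non-negative values summing to 1")
  }
  if (is.null(sigma_a2)) {
    n_her <- ceiling(0.10 * n_asvs)
    h2 <- seq(0.25, 0.65, length.out = n_her)
    sigma_a2 <- c(h2, rep(0, n_asvs - n_her))
    sigma_m2 <- c(rep(0.10, n_her), rep(0.15, n_asvs - n_her))
    sigma_e2 <- 1 - sigma_a2 - sigma_m2
  }
  rec <- function(v) rep_len(v, n_asvs)
  sigma_a2 <- rec(sigma_a2); sigma_m2 <- rec(sigma_m2); sigma_e2 <- rec(sigma_e2)
  if (any(c(sigma_a2, sigma_m2, sigma_e2) < 0)) {
    abort("variance components must be >= 0")
  }
  if (n_trait_asvs > n_asvs) abort("`n_trait_asvs` must be <= `n_asvs`")
  if (cooccur_rho < 0 || cooccur_rho >= 1) abort("`cooccur_rho` must be in [0, 1)")
  # guilds default on only when the table is large enough to host them
  # alongside the heritable head
  if (is.null(cooccur_blocks)) cooccur_blocks <- if (n_asvs >= 60) 3 else 0
  n_block_asvs <- cooccur_blocks * cooccur_block_size
  if (n_block_asvs > n_asvs) abort("co-occurrence blocks exceed `n_asvs`")
  cooccur_block <- rep(0L, n_asvs)
  if (n_block_asvs > 0) {
    cooccur_block[seq(n_asvs - n_block_asvs + 1L, n_asvs)] <-
      rep(seq_len(cooccur_blocks), each = cooccur_block_size)
  }
  structure(list(n_dams = n_dams, litter_size_probs = litter_size_probs,
                 n_sires = n_sires, n_asvs = n_asvs,
                 sigma_a2 = sigma_a2, sigma_m2 = sigma_m2,
                 sigma_e2 = sigma_e2,
                 baseline_sd = baseline_sd, heritable_boost = heritable_boost,
                 group_effect_sd = group_effect_sd,
                 year_season_levels = year_season_levels,
                 year_season_effects = rep_len(year_season_effects,
                                               year_season_levels),
                 age_slope = age_slope,
                 library_size_mean = library_size_mean,
                 library_size_dispersion = library_size_dispersion,
                 cooccur_block = cooccur_block,
                 cooccur_rho = cooccur_rho,
                 n_trait_asvs = n_trait_asvs,
                 trait_effect_bw = trait_effect_bw,
                 trait_effect_ww = trait_effect_ww,
                 trait_noise_bw = trait_noise_bw,
                 trait_noise_ww = trait_noise_ww,
                 seed = seed),
            class = "synth_params")
}

#' Simulate a dam-lamb pedigree
#'
#' Dams and sires are founders (unknown parents).  Each dam produces one
#' litter whose size is drawn from `litter_size_probs`; the whole litter
#' has a single sire drawn from the pool, so littermates are full sibs and
#' lambs of different dams can be paternal half sibs.
#'
#' @param params a [synth_params()].
#' @param seed integer seed (defaults to `params$seed`).
#' @return list with `ped` (a [pedigree()]), `lambs` (data.frame `animal,
#'   dam, sire, litter_id, litter_size`), `dams`, `sires`.
#' @export
simulate_pedigree <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "synth_params"))
  with_seed(seed, {
    dams <- sprintf("D%03d", seq_len(params$n_dams))
    sires <- sprintf("S%03d", seq_len(params$n_sires))
    sizes <- sample(1:4, params$n_dams, replace = TRUE,
                    prob = params$litter_size_probs)
    litter_sire <- sample(sires, params$n_dams, replace = TRUE)
    lambs <- do.call(rbind, lapply(seq_len(params$n_dams), function(i) {
      if (sizes[i] == 0L) return(NULL)
      data.frame(dam = dams[i], sire = litter_sire[i],
                 litter_id = dams[i], litter_size = sizes[i],
                 stringsAsFactors = FALSE)[rep(1L, sizes[i]), ]
    }))
    lambs$animal <- sprintf("L%03d", seq_len(nrow(lambs)))
    rownames(lambs) <- NULL
    ped <- pedigree(data.frame(
      animal = c(sires, dams, lambs$animal),
      sire = c(rep(NA, length(sires) + length(dams)), lambs$sire),
      dam = c(rep(NA, length(sires) + length(dams)), lambs$dam),
      stringsAsFactors = FALSE))
    list(ped = ped, lambs = lambs[, c("animal", "dam", "sire",
                                      "litter_id", "litter_size")],
         dams = dams, sires = sires)
  })
}

# rumen-like synthetic lineages used to label simulated ASVs
.synthetic_lineages <- c(
  "Bacteria;Bacteroidota;Bacteroidia;Bacteroidales;Prevotellaceae;Prevotella",
  "Bacteria;Bacteroidota;Bacteroidia;Bacteroidales;Prevotellaceae;Prevotella_7",
  "Bacteria;Bacteroidota;Bacteroidia;Bacteroidales;Prevotellaceae;Prevotellaceae_UCG-001",
  "Bacteria;Firmicutes;Clostridia;Lachnospirales;Lachnospiraceae;Roseburia",
  "Bacteria;Firmicutes;Clostridia;Lachnospirales;Lachnospiraceae;Agathobacter",
  "Bacteria;Firmicutes;Clostridia;Lachnospirales;Lachnospiraceae;Shuttleworthia",
  "Bacteria;Firmicutes;Clostridia;Oscillospirales;Ruminococcaceae;Ruminococcus",
  "Bacteria;Bacteroidota;Bacteroidia;Bacteroidales;Rikenellaceae;Rikenellaceae_RC9_gut_group",
  "Bacteria;Firmicutes;Clostridia;Christensenellales;Christensenellaceae;Christensenellaceae_R-7_group",
  "Bacteria;Proteobacteria;Gammaproteobacteria;Aeromonadales;Succinivibrionaceae;Succinivibrio")

#' Simulate a compositional ASV count table under the animal model
#'
#' For every ASV, latent values are `y = Xb + Za + Wm + e`: `a` is drawn
#' jointly across all pedigree animals from `N(0, A sigma_a2)` using the
#' Cholesky factor of the tabular A; `m` is an i.i.d. `N(0, sigma_m2)`
#' effect of each dam applied to her lambs (founder dams, whose own
#' mothers are unknown, receive none); `e` is i.i.d. residual.  Fixed
#' effects are a per-ASV baseline, a per-ASV dam-vs-lamb contrast,
#' year-season and an age covariate.  Latent values are mapped to
#' per-sample relative abundances by the softmax across ASVs, and counts
#' are drawn multinomially at each sample's library size.
#'
#' @param pedsim result of [simulate_pedigree()].
#' @param params a [synth_params()].
#' @param seed integer seed.
#' @return list with `table` (an [asv_table()] with synthetic taxonomy),
#'   `latent` (samples x ASVs matrix of the latent values), `metadata`
#'   (sample metadata incl. group, age, year-season, litter, dam),
#'   `proportions` (pre-count compositions).
#' @export
simulate_asv_table <- function(pedsim, params, seed = params$seed + 1) {
  stopifnot(inherits(params, "synth_params"))
  ped <- pedsim$ped
  A <- a_matrix(ped)
  R <- tryCatch(chol(A), error = function(e)
    abort("relationship matrix is not positive definite: ", conditionMessage(e)))
  samples <- c(pedsim$dams, pedsim$lambs$animal)
  n <- length(samples)
  is_lamb <- samples %in% pedsim$lambs$animal
  with_seed(seed, {
    age <- ifelse(is_lamb, stats::rnorm(n, 59.8, 1.55),
                  pmax(stats::rnorm(n, 1033, 425), 400))
    ys <- sample(paste0("YS", seq_len(params$year_season_levels)), n,
                 replace = TRUE)
    md <- data.frame(
      sample_id = samples, animal = samples,
      group = ifelse(is_lamb, "lamb", "dam"),
      age = round(age),
      year_season = ys,
      litter_id = ifelse(is_lamb,
                         pedsim$lambs$litter_id[match(samples, pedsim$lambs$animal)],
                         NA),
      dam = ifelse(is_lamb,
                   pedsim$lambs$dam[match(samples, pedsim$lambs$animal)],
                   NA),
      litter_size = ifelse(is_lamb,
                           pedsim$lambs$litter_size[match(samples, pedsim$lambs$animal)],
                           NA),
      stringsAsFactors = FALSE)

    d <- params$n_asvs
    heritable_true <- params$sigma_a2 > 0
    baseline <- stats::rnorm(d, 0, params$baseline_sd) +
      params$heritable_boost * heritable_true
    geff <- stats::rnorm(d, 0, params$group_effect_sd)
    season_eff <- stats::setNames(params$year_season_effects,
                                  paste0("YS", seq_len(params$year_season_levels)))
    age_c <- md$age - mean(md$age)
    dam_of_sample <- md$dam                  # NA for dams themselves

    idx <- match(samples, ped$animal)
    # shared per-sample factors for the co-occurring guilds
    n_blocks <- max(params$cooccur_block)
    block_factor <- if (n_blocks > 0) {
      matrix(stats::rnorm(n * n_blocks), n, n_blocks)
    } else NULL
    rho <- params$cooccur_rho
    latent <- matrix(0, n, d,
                     dimnames = list(samples, sprintf("ASV%04d", seq_len(d))))
    for (j in seq_len(d)) {
      a_all <- crossprod(R, stats::rnorm(nrow(A))) * sqrt(params$sigma_a2[j])
      m_dam <- stats::setNames(stats::rnorm(length(pedsim$dams), 0,
                                            sqrt(params$sigma_m2[j])),
                               pedsim$dams)
      m <- ifelse(is.na(dam_of_sample), 0, m_dam[dam_of_sample])
      z <- stats::rnorm(n)
      b <- params$cooccur_block[j]
      if (b > 0L) z <- sqrt(rho) * block_factor[, b] + sqrt(1 - rho) * z
      e <- z * sqrt(params$sigma_e2[j])
      latent[, j] <- baseline[j] + geff[j] * is_lamb +
        season_eff[md$year_season] + params$age_slope * age_c +
        a_all[idx] + m + e
    }
    # softmax per sample: compositional closure before count draws
    ex <- exp(latent - apply(latent, 1L, max))
    prop <- ex / rowSums(ex)
    lib <- stats::rnbinom(n, mu = params$library_size_mean,
                          size = params$library_size_dispersion)
    lib <- pmax(lib, 1000)
    counts <- t(vapply(seq_len(n), function(i) {
      as.numeric(stats::rmultinom(1L, lib[i], prop[i, ]))
    }, numeric(d)))
    dimnames(counts) <- dimnames(latent)
    taxonomy <- stats::setNames(
      sample(.synthetic_lineages, d, replace = TRUE,
             prob = c(5, 3, 2, 3, 2, 1, 2, 1, 1, 1)),
      colnames(counts))
    list(table = asv_table(counts, taxonomy), latent = latent,
         metadata = md, proportions = prop)
  })
}

#' Simulate growth traits and rumen fermentation parameters
#'
#' Lamb birth weight (BW) and weaning weight (WW) are linear in the latent
#' values of the designated trait ASVs, plus a litter-size effect and
#' Gaussian noise; preweaning weight gain is the exact difference
#' `PWG = WW - BW`.  Rumen fermentation parameters (NH3-N and individual
#' VFA concentrations) are simulated for every sample as linear functions
#' of single ASVs' latent values plus noise.
#'
#' @param pedsim result of [simulate_pedigree()].
#' @param latent latent matrix from [simulate_asv_table()].
#' @param metadata metadata from [simulate_asv_table()].
#' @param params a [synth_params()].
#' @param seed integer seed.
#' @return the metadata with columns `BW`, `WW`, `PWG` (lambs; `NA` for
#'   dams) and fermentation columns `NH3N`, `acetate`, `propionate`,
#'   `butyrate`, `isobutyrate`, `valerate`, `isovalerate` appended.
#' @export
simulate_traits <- function(pedsim, latent, metadata, params,
                            seed = params$seed + 2) {
  stopifnot(inherits(params, "synth_params"))
  k <- params$n_trait_asvs
  trait_asvs <- colnames(latent)[seq_len(k)]
  with_seed(seed, {
    md <- metadata
    n <- nrow(md)
    is_lamb <- md$group == "lamb"
    z <- latent[, trait_asvs, drop = FALSE]
    zsum <- rowSums(z)
    bw <- 4.2 - 0.4 * (md$litter_size - 1) +
      params$trait_effect_bw * zsum + stats::rnorm(n, 0, params$trait_noise_bw)
    ww <- 14 - 1.2 * (md$litter_size - 1) +
      params$trait_effect_ww * zsum + stats::rnorm(n, 0, params$trait_noise_ww)
    md$BW <- ifelse(is_lamb, bw, NA)
    md$WW <- ifelse(is_lamb, ww, NA)
    md$PWG <- md$WW - md$BW
    pick <- function(i) latent[, 1L + (i - 1L) %% ncol(latent)]
    md$NH3N <- 8 + 0.8 * pick(1) + stats::rnorm(n, 0, 1.5)
    md$acetate <- 60 + 1.5 * pick(2) + stats::rnorm(n, 0, 4)
    md$propionate <- 20 + 1.2 * pick(3) + stats::rnorm(n, 0, 3)
    md$butyrate <- 12 + 1.0 * pick(4) + stats::rnorm(n, 0, 2)
    md$isobutyrate <- 1.2 + 0.15 * pick(5) + stats::rnorm(n, 0, 0.3)
    md$valerate <- 1.5 + 0.2 * pick(6) + stats::rnorm(n, 0, 0.35)
    md$isovalerate <- 1.8 + 0.25 * pick(7) + stats::rnorm(n, 0, 0.4)
    attr(md, "trait_asvs") <- trait_asvs
    md
  })
}

#' Simulate a phylogenetic tree over the ASVs
#'
#' A random rooted, strictly bifurcating tree with uniform positive branch
#' lengths, whose tips are exactly the given ASV ids.  Identical seeds
#' give byte-identical newick strings.
#'
#' @param asv_ids at least 2 distinct ASV ids.
#' @param seed integer seed.
#' @return an [ape::phylo] tree.
#' @export
simulate_tree <- function(asv_ids, seed = 1) {
  if (length(asv_ids) < 2L) abort("at least 2 ASV ids are required")
  if (anyDuplicated(asv_ids)) abort("duplicate ASV ids")
  with_seed(seed, ape::rtree(length(asv_ids), tip.label = asv_ids))
}

#' Simulate a complete synthetic study
#'
#' Chains [simulate_pedigree()], [simulate_asv_table()],
#' [simulate_traits()] and [simulate_tree()] under sub-seeds derived from
#' one master seed, and records the generative ground truth.
#'
#' @param params a [synth_params()].
#' @param seed master seed (defaults to `params$seed`).
#' @return list of class `synthetic_study`: `table`, `latent`,
#'   `metadata`, `proportions`, `ped`, `lambs`, `tree`, `truth`
#'   (`h2_true`, variance components, `trait_asvs`).
#' @export
simulate_study <- function(params = synth_params(), seed = params$seed) {
  stopifnot(inherits(params, "synth_params"))
  pedsim <- simulate_pedigree(params, seed = seed)
  tab <- simulate_asv_table(pedsim, params, seed = seed + 1)
  md <- simulate_traits(pedsim, tab$latent, tab$metadata, params,
                        seed = seed + 2)
  tree <- simulate_tree(colnames(tab$table$counts), seed = seed + 3)
  tot <- params$sigma_a2 + params$sigma_m2 + params$sigma_e2
  structure(list(table = tab$table, latent = tab$latent, metadata = md,
                 proportions = tab$proportions,
                 ped = pedsim$ped, lambs = pedsim$lambs, tree = tree,
                 truth = list(
                   h2_true = stats::setNames(
                     ifelse(tot > 0, params$sigma_a2 / tot, 0),
                     colnames(tab$table$counts)),
                   sigma_a2 = params$sigma_a2, sigma_m2 = params$sigma_m2,
                   sigma_e2 = params$sigma_e2,
                   cooccur_block = stats::setNames(params$cooccur_block,
                                                   colnames(tab$table$counts)),
                   trait_asvs = attr(md, "trait_asvs")),
                 params = params, seed = seed),
            class = "synthetic_study")
}

#' Write a synthetic study to plain-text files
#'
#' Emits the count table and taxonomy (TSV), sample metadata (TSV),
#' pedigree (CSV, unknown parents as `0`), tree (newick) and the
#' generative ground truth (JSON) into a directory.
#'
#' @param sim a [simulate_study()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of written paths.
#' @export
write_synthetic_study <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "asv_counts.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             pedigree = file.path(dir, "pedigree.csv"),
             tree = file.path(dir, "tree.nwk"),
             truth = file.path(dir, "truth.json"))
  write_asv_table(sim$table, paths["counts"], paths["taxonomy"])
  utils::write.table(sim$metadata, paths["metadata"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ped_out <- data.frame(animal = sim$ped$animal,
                        sire = ifelse(is.na(sim$ped$sire), "0", sim$ped$sire),
                        dam = ifelse(is.na(sim$ped$dam), "0", sim$ped$dam))
  utils::write.csv(ped_out, paths["pedigree"], row.names = FALSE, quote = FALSE)
  ape::write.tree(sim$tree, paths["tree"])
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
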