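test_that("parameter validation rejects malformed settings", {
  expect_error(synth_params(litter_size_probs = c(0.5, 0.4)), "summing to 1")
  expect_error(synth_params(litter_size_probs = c(0.7, 0.4, 0, 0)), "summing to 1")
  expect_error(synth_params(sigma_a2 = -0.1, sigma_m2 = 0.1, sigma_e2 = 0.8),
               ">= 0")
  expect_error(synth_params(n_asvs = 5, n_trait_asvs = 6), "n_trait_asvs")
})

test_that("pedigree simulation honours the litter-size distribution", {
  params <- synth_params(n_dams = 10, litter_size_probs = c(0, 1, 0, 0))
  sim <- simulate_pedigree(params, seed = 2)
  expect_equal(nrow(sim$lambs), 20)
  expect_true(all(table(sim$lambs$dam) == 2))
  # full sibs: littermates share a sire
  by_litter <- split(sim$lambs$sire, sim$lambs$dam)
  expect_true(all(vapply(by_litter, function(s) length(unique(s)) == 1L,
                         logical(1))))
  # every lamb's dam precedes it in the sorted pedigree
  ped <- sim$ped
  pos <- stats::setNames(seq_len(nrow(ped)), ped$animal)
  kids <- !is.na(ped$dam)
  expect_true(all(pos[ped$dam[kids]] < pos[ped$animal[kids]]))
})

test_that("expected flock size matches the target litter-size mean", {
  params <- synth_params()   # defaults calibrated to ~179 lambs per 128 dams
  n_lambs <- vapply(1:50, function(s) {
    nrow(simulate_pedigree(params, seed = s)$lambs)
  }, numeric(1))
  expect_lt(abs(mean(n_lambs) - 179) / 179, 0.15)
})

test_that("latent values carry the planted relatedness structure", {
  # sigma_a2 = sigma_m2 = 0: full sibs are uncorrelated
  p0 <- synth_params(n_dams = 30, n_asvs = 400,
                     litter_size_probs = c(0, 1, 0, 0),
                     sigma_a2 = 0, sigma_m2 = 0, sigma_e2 = 1,
                     year_season_effects = c(0, 0), seed = 5)
  ps <- simulate_pedigree(p0, seed = 5)
  sim <- simulate_asv_table(ps, p0, seed = 6)
  lambs <- ps$lambs$animal
  res <- sim$latent[lambs, ] -
    matrix(colMeans(sim$latent[lambs, ]), length(lambs), p0$n_asvs,
           byrow = TRUE)
  sib1 <- lambs[seq(1, length(lambs), 2)]
  sib2 <- lambs[seq(2, length(lambs), 2)]
  covs <- vapply(seq_along(sib1), function(i) {
    mean(res[sib1[i], ] * res[sib2[i], ])
  }, numeric(1))
  expect_lt(abs(mean(covs)), 0.05)

  # sigma_a2 = 1, others 0: parent-offspring latent correlation ~ 0.5
  p1 <- synth_params(n_dams = 30, n_asvs = 400,
                     litter_size_probs = c(0, 1, 0, 0),
                     sigma_a2 = 1, sigma_m2 = 0, sigma_e2 = 0,
                     year_season_effects = c(0, 0), seed = 7)
  ps1 <- simulate_pedigree(p1, seed = 7)
  sim1 <- simulate_asv_table(ps1, p1, seed = 8)
  # group effects are per-ASV and differ between dams and lambs; remove the
  # cohort mean separately before correlating
  lamb_rows <- ps1$lambs$animal
  dam_rows <- ps1$lambs$dam
  ctr_l <- sim1$latent[lamb_rows, ] -
    matrix(colMeans(sim1$latent[unique(lamb_rows), ]), length(lamb_rows),
           p1$n_asvs, byrow = TRUE)
  ctr_d <- sim1$latent[dam_rows, ] -
    matrix(colMeans(sim1$latent[unique(dam_rows), ]), length(dam_rows),
           p1$n_asvs, byrow = TRUE)
  rho <- mean(vapply(seq_along(lamb_rows), function(i) {
    stats::cor(ctr_l[i, ], ctr_d[i, ])
  }, numeric(1)))
  expect_lt(abs(rho - 0.5), 0.05)
})

test_that("compositions close to one and counts match their library sizes", {
  params <- synth_params(n_dams = 15, n_asvs = 20, seed = 9)
  ps <- simulate_pedigree(params, seed = 9)
  sim <- simulate_asv_table(ps, params, seed = 10)
  expect_equal(unname(rowSums(sim$proportions)),
               rep(1, nrow(sim$proportions)), tolerance = 1e-12)
  expect_true(all(rowSums(sim$table$counts) >= 1000))
  expect_equal(dim(sim$table$counts), dim(sim$latent))
})

test_that("traits follow their definitions", {
  params <- synth_params(n_dams = 25, n_asvs = 12, seed = 11)
  sim <- simulate_study(params)
  md <- sim$metadata[sim$metadata$group == "lamb", ]
  expect_equal(md$PWG, md$WW - md$BW)
  expect_true(all(is.na(sim$metadata$BW[sim$metadata$group == "dam"])))

  # degenerate: zero effects and zero noise -> identical traits per litter size
  p0 <- synth_params(n_dams = 15, n_asvs = 8, trait_effect_bw = 0,
                     trait_effect_ww = 0, trait_noise_bw = 0,
                     trait_noise_ww = 0, seed = 12)
  s0 <- simulate_study(p0)
  m0 <- s0$metadata[s0$metadata$group == "lamb", ]
  expect_true(all(vapply(split(m0$WW, m0$litter_size),
                         function(v) length(unique(v)) == 1L, logical(1))))

  # strong single-ASV effect with tiny noise is recoverable by rank
  p1 <- synth_params(n_dams = 110, n_asvs = 10, n_trait_asvs = 1,
                     trait_effect_ww = 1, trait_noise_ww = 0.1, seed = 13)
  s1 <- simulate_study(p1)
  m1 <- s1$metadata[s1$metadata$group == "lamb", ]
  ls_adj <- m1$WW + 1.2 * (m1$litter_size - 1)
  rho <- stats::cor(s1$latent[m1$sample_id, s1$truth$trait_asvs],
                    ls_adj, method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("simulated trees are bifurcating, labeled and reproducible", {
  t2 <- simulate_tree(c("a", "b"), seed = 1)
  expect_equal(t2$Nnode, 1)
  t10 <- simulate_tree(paste0("x", 1:10), seed = 2)
  expect_equal(t10$Nnode, 9)
  expect_setequal(t10$tip.label, paste0("x", 1:10))
  expect_true(all(t10$edge.length > 0))
  expect_identical(ape::write.tree(simulate_tree(paste0("x", 1:10), seed = 2)),
                   ape::write.tree(t10))
  expect_error(simulate_tree(c("a", "a"), 1), "duplicate")
  expect_error(simulate_tree("a", 1), "at least 2")
})

test_that("identical parameters and seed reproduce the study exactly", {
  params <- synth_params(n_dams = 12, n_asvs = 10, seed = 3)
  s1 <- simulate_study(params)
  s2 <- simulate_study(params)
  expect_identical(s1$table$counts, s2$table$counts)
  expect_identical(s1$metadata, s2$metadata)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
})

test_that("a written study can be read back consistently", {
  params <- synth_params(n_dams = 10, n_asvs = 8, seed = 4)
  sim <- simulate_study(params)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_study(sim, dir)
  expect_true(all(file.exists(paths)))
  tab <- read_asv_table(paths["counts"], paths["taxonomy"])
  expect_equal(tab$counts, sim$table$counts)
  ped <- read_pedigree(paths["pedigree"])
  expect_setequal(ped$animal, sim$ped$animal)
  tr <- ape::read.tree(paths["tree"])
  expect_setequal(tr$tip.label, colnames(sim$table$counts))
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(unname(unlist(truth$h2_true)), unname(sim$truth$h2_true),
               tolerance = 1e-9)
})

test_that("planted co-occurrence guilds surface as SparCC network edges", {
  params <- synth_params(n_dams = 70, n_asvs = 40, cooccur_blocks = 2,
                         cooccur_block_size = 4, cooccur_rho = 0.8, seed = 21)
  sim <- simulate_study(params)
  lamb_ids <- sim$metadata$sample_id[sim$metadata$group == "lamb"]
  counts <- sim$table$counts[lamb_ids, ]
  sp <- sparcc(counts)
  blocks <- sim$truth$cooccur_block
  in_block <- names(blocks)[blocks > 0]
  # within-block pairs correlate far above the between-block background
  same <- outer(blocks[in_block], blocks[in_block], "==") &
    upper.tri(matrix(0, length(in_block), length(in_block)))
  within <- sp$r[in_block, in_block][same]
  expect_gt(mean(within), 0.5)
  out_block <- names(blocks)[blocks == 0]
  backg <- sp$r[out_block, out_block]
  expect_lt(mean(abs(backg[upper.tri(backg)])), 0.15)
  # and survive thresholding into the network (100 resamples are needed
  # for the pseudo p to clear the 0.01 gate)
  pv <- sparcc_pvalues(counts, sp, n_boot = 100, seed = 22)
  g <- build_network(sp, pv, counts)
  expect_gte(igraph::ecount(g), 4)
  expect_true(all(igraph::V(g)$name %in% in_block))
})
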