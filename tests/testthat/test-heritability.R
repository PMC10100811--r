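test_that("design matrix has the expected structure and rank handling", {
  pop <- shared_popn()
  d <- pop$design
  expect_equal(ncol(d$X), 4)   # intercept + season + group + age
  expect_equal(qr(d$X)$rank, 4)
  # Z A Z' diagonal is 1 + F = 1 for non-inbred animals
  expect_equal(unname(diag(d$K_a)), rep(1, d$n))
  # W: lambs point at their dam's maternal level, founder dams have none
  md <- pop$md
  lamb1 <- which(md$group == "lamb")[1]
  expect_equal(sum(d$W[lamb1, ]), 1)
  expect_equal(colnames(d$W)[d$W[lamb1, ] == 1], md$dam[lamb1])
  expect_true(all(rowSums(d$W[md$group == "dam", , drop = FALSE]) == 0))
  # littermates share a maternal level -> K_m block of ones
  sibs <- which(md$dam == md$dam[lamb1] & md$group == "lamb")
  expect_true(all(d$K_m[sibs, sibs] == 1))

  # age perfectly aliased with group -> dropped with a report
  md2 <- md
  md2$age <- ifelse(md2$group == "dam", 1000, 60)
  expect_message(d2 <- build_design(md2, pop$pedsim$ped), "aliased.*age")
  expect_equal(ncol(d2$X), 3)

  expect_error(build_design(transform(md, animal = paste0("zz", animal)),
                            pop$pedsim$ped), "absent from pedigree")
})

test_that("REML recovers planted variance components", {
  pop <- shared_popn()
  d <- pop$design
  K <- list(additive = d$K_a, maternal = d$K_m)
  set.seed(21)
  h2 <- replicate(8, {
    y <- simulate_animal_model_y(d, pop$pedsim$ped, 0.4, 0.1, 0.5)
    heritability(reml_fit(y, d$X, K))
  })
  expect_lt(abs(mean(h2) - 0.4), 0.12)
})

test_that("REML is attracted to the zero boundary when there is no signal", {
  # pedigree-structured K_a but a pure-noise phenotype: the additive
  # variance should collapse toward zero (about half the replicates pin
  # exactly to the floor, the rest stay near it)
  pop <- shared_popn()
  d <- pop$design
  K <- list(additive = d$K_a)
  set.seed(5)
  sa <- replicate(20, {
    y <- rnorm(d$n)
    fit <- reml_fit(y, d$X, K)
    unname(fit$sigma2["additive"])
  })
  expect_lt(mean(sa), 0.06)
  expect_gte(sum(sa < 0.01), 8)
})

test_that("REML equals the OLS residual variance when A = I, no maternal", {
  set.seed(6)
  n <- 150
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(2, 0.5)) + rnorm(n)
  fit <- reml_fit(y, X, list(additive = diag(n)))
  tot <- sum(fit$sigma2)
  s2_ols <- sum(stats::lm.fit(X, y)$residuals^2) / (n - 2)
  expect_lt(abs(tot - s2_ols) / s2_ols, 0.05)
})

test_that("the fitted point is a local optimum of the restricted likelihood", {
  pop <- shared_popn()
  d <- pop$design
  K <- list(additive = d$K_a, maternal = d$K_m)
  set.seed(31)
  y <- simulate_animal_model_y(d, pop$pedsim$ped, 0.4, 0.1, 0.5)
  fit <- reml_fit(y, d$X, K)
  base <- fit$loglik
  for (i in 1:3) {
    for (delta in c(0.9, 1.1)) {
      s <- fit$sigma2
      s[i] <- s[i] * delta
      ll <- rumenherit:::.reml_ll(y, d$X,
                                  list(d$K_a, d$K_m, diag(d$n)), s)
      expect_lte(ll, base + 1e-6)
    }
  }
})

test_that("h2 is scale invariant and follows its defining ratio", {
  pop <- shared_popn()
  d <- pop$design
  K <- list(additive = d$K_a, maternal = d$K_m)
  set.seed(41)
  y <- simulate_animal_model_y(d, pop$pedsim$ped, 0.3, 0.1, 0.6)
  f1 <- reml_fit(y, d$X, K)
  f2 <- reml_fit(y * 3.7, d$X, K)
  expect_lt(abs(heritability(f1) - heritability(f2)), 1e-6)

  mock <- structure(list(sigma2 = c(additive = 0.3, maternal = 0.1,
                                    residual = 0.6)),
                    class = "reml_fit")
  expect_equal(heritability(mock), 0.3)
  mock$sigma2["additive"] <- 0
  expect_equal(heritability(mock), 0)
})

test_that("delta-method SE matches the hand-computed gradient form", {
  mock <- structure(list(sigma2 = c(additive = 0.3, maternal = 0.1,
                                    residual = 0.6),
                         vcov = matrix(diag(0.01, 3), 3, 3,
                                       dimnames = list(
                                         c("additive", "maternal", "residual"),
                                         c("additive", "maternal", "residual"))),
                         n = 100, rank_x = 4),
                    class = "reml_fit")
  sp <- heritability_se_p(mock)
  # gradient (0.7, -0.3, -0.3); SE = sqrt(0.01 * (0.49 + 0.09 + 0.09))
  expect_equal(sp$se, sqrt(0.01 * 0.67), tolerance = 1e-12)
  expect_equal(sp$p, 2 * pt(-0.3 / sp$se, df = 96), tolerance = 1e-12)
  mock$vcov[] <- 0
  expect_equal(heritability_se_p(mock)$se, 0)
})

test_that("permuting the phenotype destroys heritability", {
  pop <- shared_popn()
  d <- pop$design
  K <- list(additive = d$K_a, maternal = d$K_m)
  set.seed(51)
  y <- simulate_animal_model_y(d, pop$pedsim$ped, 0.5, 0.1, 0.4)
  h2_perm <- replicate(25, {
    fit <- reml_fit(sample(y), d$X, K)
    heritability(fit)
  })
  expect_lt(mean(h2_perm), 0.08)
})

test_that("the heritable screen applies strict thresholds and summarizes", {
  res <- data.frame(asv = c("a", "b", "c", "d"),
                    h2 = c(0.5, 0.2, 0.3, 0.25),
                    p = c(0.01, 0.01, 0.05, 0.2))
  out <- screen_heritable(res)
  expect_equal(out$heritable_asvs, "a")   # b: h2 boundary; c: p boundary; d: p
  expect_equal(out$summary$pct_heritable, 25.0)

  none <- screen_heritable(data.frame(asv = "a", h2 = 0.1, p = 0.9))
  expect_equal(none$summary$n_heritable, 0)

  # combined relative abundance of the heritable set per group
  tab <- toy_table()
  md <- data.frame(sample_id = c("s1", "s2", "s3"),
                   group = c("dam", "lamb", "lamb"))
  res2 <- data.frame(asv = c("ASV1", "ASV2", "ASV3", "ASV4"),
                     h2 = c(0.5, 0.05, 0.5, 0.05), p = c(0.001, 0.5, 0.001, 0.5))
  out2 <- screen_heritable(res2, tab, md)
  comb <- out2$summary$combined_abundance
  expect_equal(comb$mean_pct[comb$group == "dam"], 75)  # (2+4)/8 of s1
})

test_that("fit_heritability estimates every ASV of a small table", {
  params <- synth_params(n_dams = 40, n_asvs = 6, seed = 13)
  sim <- simulate_study(params)
  res <- fit_heritability(sim$table, sim$metadata, sim$ped)
  expect_equal(res$asv, colnames(sim$table$counts))
  expect_true(all(res$h2 >= 0 & res$h2 <= 1))
  expect_true(all(res$converged))
})
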