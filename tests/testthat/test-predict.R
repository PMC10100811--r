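# labeled lamb fixture with litter-size strata
groups_fixture <- function() {
  data.frame(animal = sprintf("L%02d", 1:11),
             litter_size = c(rep(2, 8), rep(1, 3)),
             WW = c(8, 7, 6, 5, 4, 3, 2, 1, 10, 9, 8.5))
}

test_that("trait groups take the top/bottom quarter within each stratum", {
  md <- groups_fixture()
  expect_warning(g <- make_trait_groups(md, "WW"), "stratum 1")
  s2 <- g[g$litter_size == 2, ]
  expect_equal(sum(s2$label == "high"), 2)   # floor(0.25 * 8)
  expect_equal(sum(s2$label == "low"), 2)
  expect_equal(sum(s2$label == "unused"), 4)
  expect_equal(s2$animal[s2$label == "high"], c("L01", "L02"))
  # stratum of 3 -> no labels at all
  expect_true(all(g$label[g$litter_size == 1] == "unused"))
  expect_gt(mean(s2$value[s2$label == "high"]),
            mean(s2$value[s2$label == "low"]))
  # ties broken by stable animal-id order
  md$WW[] <- 5
  expect_warning(gt <- make_trait_groups(md, "WW"))
  s2t <- gt[gt$litter_size == 2, ]
  expect_equal(s2t$animal[s2t$label == "high"], c("L01", "L02"))
})

test_that("feature assembly prefixes cohorts and repeats maternal rows", {
  params <- synth_params(n_dams = 20, n_asvs = 8,
                         litter_size_probs = c(0, 1, 0, 0), seed = 3)
  sim <- simulate_study(params)
  groups <- make_trait_groups(sim$metadata[sim$metadata$group == "lamb", ], "WW")
  bf <- build_features(sim$table, sim$metadata, groups, source = "both")
  expect_equal(ncol(bf$x), 16)
  expect_setequal(unique(sub("_.*", "", colnames(bf$x))), c("lamb", "dam"))
  # littermates (same dam) share the maternal feature block
  lambs <- sim$lambs
  pair <- lambs$animal[lambs$dam == lambs$dam[1]]
  both_in <- pair[pair %in% rownames(bf$x)]
  if (length(both_in) == 2) {
    dam_cols <- grepl("^dam_", colnames(bf$x))
    expect_equal(bf$x[both_in[1], dam_cols], bf$x[both_in[2], dam_cols])
  }
  bd <- build_features(sim$table, sim$metadata, groups, source = "dam")
  expect_true(all(grepl("^dam_", colnames(bd$x))))
})

test_that("the classifier separates separable labels and not permuted ones", {
  set.seed(12)
  n <- 56
  x <- matrix(rnorm(n * 40), n, 40,
              dimnames = list(NULL, paste0("lamb_ASV", 1:40)))
  y <- factor(ifelse(x[, 1] + rnorm(n, 0, 0.05) > 0, "high", "low"),
              levels = c("low", "high"))
  cfg <- rfc_config(trees = 300, depth = 0)
  m <- train_rfc(x, y, cfg, seed = 1)
  r <- evaluate_rfc(m, x, y, seed = 2)
  expect_gte(r$accuracy_cv, 0.95)
  expect_true("lamb_ASV1" %in% m$features)
  # selection keeps only features that met the importance threshold
  expect_true(all(m$importance_selection[m$features] >=
                    cfg$importance_threshold))
  expect_true(all(m$features %in% colnames(x)))

  acc_null <- sapply(1:6, function(i) {
    set.seed(100 + i)
    yp <- sample(y)
    mp <- train_rfc(x, yp, rfc_config(trees = 200, depth = 0), seed = i)
    evaluate_rfc(mp, x, yp, seed = i)$accuracy_cv
  })
  expect_lt(abs(mean(acc_null) - 0.5), 0.15)
})

test_that("ROC starts at (0,0), ends at (1,1) and AUC is 1 when separable", {
  set.seed(9)
  n <- 40
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("lamb_A", 1:5)))
  y <- factor(rep(c("low", "high"), each = n / 2), levels = c("low", "high"))
  x[, 1] <- ifelse(y == "high", 3, -3) + rnorm(n, 0, 0.01)
  m <- train_rfc(x, y, rfc_config(trees = 200, depth = 0), seed = 4)
  r <- evaluate_rfc(m, x, y, seed = 5)
  expect_equal(r$auc, 1)
  expect_equal(r$roc[1, ], data.frame(fpr = 0, tpr = 0), ignore_attr = TRUE)
  expect_equal(unlist(r$roc[nrow(r$roc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$roc$tpr) >= 0) && all(diff(r$roc$fpr) >= 0))
})

test_that("importance report normalizes, ranks and splits by cohort", {
  set.seed(2)
  n <- 40
  x <- matrix(rnorm(n * 12), n, 12,
              dimnames = list(NULL, paste0(rep(c("lamb_", "dam_"), 6),
                                           "ASV", rep(1:6, each = 2))))
  y <- factor(ifelse(x[, 1] > 0, "high", "low"), levels = c("low", "high"))
  m <- train_rfc(x, y, rfc_config(trees = 200, depth = 0,
                                  importance_threshold = 0), seed = 3)
  imp <- importance_report(m, top_k = 5, heritable = "ASV1")
  expect_equal(nrow(imp$table), 5)
  expect_equal(imp$table$rank, 1:5)
  expect_lte(sum(imp$cohort_importance), 1)
  full <- importance_report(m, top_k = 1000)
  expect_equal(sum(full$table$importance), 1, tolerance = 1e-12)
  expect_true(imp$table$heritable[imp$table$asv == "ASV1"][1])

  expect_error(train_rfc(x, factor(rep("high", n))), "both classes")
})

test_that("identical seeds give identical models and reports", {
  set.seed(8)
  x <- matrix(rnorm(50 * 10), 50, 10,
              dimnames = list(NULL, paste0("lamb_A", 1:10)))
  y <- factor(rep(c("low", "high"), 25), levels = c("low", "high"))
  cfg <- rfc_config(trees = c(100, 200), depth = c(0, 4))
  m1 <- train_rfc(x, y, cfg, seed = 7)
  m2 <- train_rfc(x, y, cfg, seed = 7)
  expect_identical(m1$hyperparams, m2$hyperparams)
  expect_identical(m1$features, m2$features)
  r1 <- evaluate_rfc(m1, x, y, seed = 9)
  r2 <- evaluate_rfc(m2, x, y, seed = 9)
  expect_identical(r1$accuracy_cv, r2$accuracy_cv)
  expect_identical(r1$auc, r2$auc)
})
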