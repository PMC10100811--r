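# two-cohort fixture: 6 dams, each with lambs, known prevalence patterns
assoc_fixture <- function(seed = 1) {
  set.seed(seed)
  n_dam <- 8; n_lamb <- 12
  dams <- sprintf("D%02d", 1:n_dam)
  lambs <- sprintf("L%02d", 1:n_lamb)
  dam_of <- rep(dams, length.out = n_lamb)
  counts <- matrix(rpois((n_dam + n_lamb) * 5, 20), n_dam + n_lamb, 5)
  md <- data.frame(sample_id = c(dams, lambs), animal = c(dams, lambs),
                   group = rep(c("dam", "lamb"), c(n_dam, n_lamb)),
                   dam = c(rep(NA, n_dam), dam_of),
                   WW = c(rep(NA, n_dam), rnorm(n_lamb, 14, 2)),
                   stringsAsFactors = FALSE)
  list(counts = counts, md = md, dams = dams, lambs = lambs)
}

test_that("association ASV selection applies the 50% OR rule inclusively", {
  dams <- sprintf("D%02d", 1:10); lambs <- sprintf("L%02d", 1:10)
  counts <- matrix(0, 20, 3,
                   dimnames = list(c(dams, lambs), c("lamby", "nowhere", "edge")))
  counts[11:16, "lamby"] <- 5      # 60% of lambs, 0% of dams -> in
  counts[1:4, "nowhere"] <- 5      # 40% of dams -> out
  counts[15:18, "nowhere"] <- 5    # ... and 40% of lambs
  counts[1:5, "edge"] <- 5         # exactly 50% of dams -> in
  md <- data.frame(sample_id = rownames(counts),
                   group = rep(c("dam", "lamb"), each = 10))
  sel <- select_assoc_asvs(asv_table(counts + 0), md)
  expect_setequal(sel, c("lamby", "edge"))
})

test_that("spearman correlations match brute-force enumeration", {
  # reversal and strict monotonicity
  x <- 1:5
  expect_equal(cor(x, rev(x), method = "spearman"), -1)
  # exact small-sample p against full permutation enumeration
  cases <- list(list(x = c(1, 2, 3, 4), y = c(2, 1, 4, 3)),
                list(x = c(1, 2, 3, 4, 5), y = c(2, 5, 1, 4, 3)),
                list(x = c(3, 1, 4, 2, 6, 5), y = c(1, 2, 3, 4, 5, 6)))
  for (cs in cases) {
    ht <- cor.test(cs$x, cs$y, method = "spearman", exact = TRUE)
    expect_equal(ht$p.value, spearman_exact_p(cs$x, cs$y), tolerance = 1e-10)
  }
  # the documented worked example
  ht <- cor.test(c(1, 2, 3, 4), c(2, 1, 4, 3), method = "spearman",
                 exact = TRUE)
  expect_equal(unname(ht$estimate), 0.6)
  expect_equal(ht$p.value, 10 / 24, tolerance = 1e-10)
})

test_that("BH adjustment matches the step-up definition", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(adjust_pvalues(p, "BH"), rep(0.04, 4))
  expect_equal(adjust_pvalues(rep(0.03, 5), "BH"), rep(0.03, 5))
  expect_equal(adjust_pvalues(0.012, "BH"), 0.012)
  set.seed(2)
  for (i in 1:10) {
    p <- runif(30)
    expect_equal(adjust_pvalues(p, "BH"), bh_stepup(p))
    # monotone in the raw p ranks
    o <- order(p)
    expect_true(all(diff(adjust_pvalues(p, "BH")[o]) >= -1e-12))
  }
})

test_that("BH controls the FDR on independent null p-values", {
  set.seed(3)
  m <- 400; reps <- 60
  fdp <- replicate(reps, {
    p <- runif(m)
    mean(adjust_pvalues(p, "BH") < 0.05) # all rejections are false here
  })
  expect_lt(mean(fdp), 0.05 + 0.02)
})

test_that("assoc edges pair cohorts correctly and respect invariants", {
  fx <- assoc_fixture()
  tab <- asv_table(fx$counts |>
                     (\(m) {dimnames(m) <- list(fx$md$sample_id,
                                                paste0("ASV", 1:5)); m})())
  edges <- spearman_assoc(tab, fx$md, variables = "WW",
                          asvs = paste0("ASV", 1:5))
  expect_true(all(edges$p_adj >= edges$p - 1e-12))
  expect_true(all(abs(edges$rho) <= 1))
  # lamb rows use n = 12 lambs; dam rows one observation per lamb
  expect_true(all(edges$n[edges$cohort == "lamb"] == 12))
  expect_true(all(edges$n[edges$cohort == "dam"] == 12))

  # spearman is invariant to strictly monotone transforms of the trait
  md2 <- fx$md; md2$WW <- exp(md2$WW / 3)
  edges2 <- spearman_assoc(tab, md2, variables = "WW",
                           asvs = paste0("ASV", 1:5))
  expect_equal(edges$rho, edges2$rho, tolerance = 1e-12)
})

test_that("dam-lamb pairing gives littermates identical dam abundances", {
  fx <- assoc_fixture(seed = 4)
  # make one dam ASV strongly predictive of her lambs' WW
  tab_counts <- fx$counts
  dimnames(tab_counts) <- list(fx$md$sample_id, paste0("ASV", 1:5))
  md <- fx$md
  dam_idx <- match(md$dam[md$group == "lamb"], md$sample_id)
  dam_relab <- relative_abundance(asv_table(tab_counts))[dam_idx, "ASV1"]
  md$WW[md$group == "lamb"] <- log(dam_relab + 1e-6) * 4 +
    rnorm(sum(md$group == "lamb"), 0, 0.001)
  edges <- spearman_assoc(asv_table(tab_counts), md, variables = "WW",
                          asvs = "ASV1")
  dam_edge <- edges[edges$cohort == "dam", ]
  expect_gt(dam_edge$rho, 0.9)
})

test_that("assoc summary counts signs and intersects the heritable set", {
  edges <- data.frame(asv = c("a", "b", "c", "d", "a"),
                      cohort = c("lamb", "lamb", "dam", "dam", "lamb"),
                      variable = c("WW", "WW", "WW", "NH3N", "BW"),
                      rho = c(0.5, -0.4, 0.6, -0.7, 0.2),
                      p = 0.001, p_adj = c(0.01, 0.01, 0.01, 0.01, 0.2))
  edges$sign <- ifelse(edges$rho > 0, "positive", "negative")
  edges$significant <- edges$p_adj < 0.05
  s <- assoc_summary(edges, heritable = c("b", "zzz"))
  cw <- s$counts[s$counts$variable == "WW" & s$counts$cohort == "lamb", ]
  expect_equal(sum(cw$Freq[cw$sign == "positive"]), 1)
  expect_equal(sum(cw$Freq[cw$sign == "negative"]), 1)
  expect_equal(s$heritable_overlap$lamb, "b")
  empty <- assoc_summary(edges[edges$p_adj > 0.1, ])
  expect_equal(nrow(empty$counts[empty$counts$Freq > 0, ]), 0)
})
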