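---
title: "Heritability of rumen microbiota in dam-lamb pairs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heritability of rumen microbiota in dam-lamb pairs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `rumenherit`, the assumptions
they make, the tunable parameters and the numerical choices, in the same
spirit in which variance-component and microbiome packages document their
machinery. Nothing here reports an empirical result beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## The animal model for per-ASV heritability

The phenotype analyzed for each amplicon sequence variant (ASV) is the
natural log of its relative abundance in each sample, after adding a
pseudocount. The model is

$$y = Xb + Za + Wm + e,$$

with $a \sim N(0, A\sigma_a^2)$, $m \sim N(0, I\sigma_m^2)$,
$e \sim N(0, I\sigma_e^2)$, and heritability defined as
$h^2 = \sigma_a^2 / (\sigma_a^2 + \sigma_m^2 + \sigma_e^2)$.

Assumptions worth making explicit:

* **Additive genetics enters through the pedigree only.** $A$ is the
  numerator relationship matrix (Henderson's tabular method, diagonal
  $1 + F$); no genomic marker information is used.
* **The maternal effect is an identity-covariance random effect of the
  dam's identity**, uncorrelated with the additive effect. One maternal
  level exists per dam that appears as the mother of a sampled animal.
  Sampled dams whose own mothers are unknown (the founder dams in a
  typical design) receive an all-zero row of $W$ — no maternal effect —
  because nothing identifies it for them. This choice is logged per fit.
* **Fixed effects** are an intercept, year-season dummies, a dam/lamb
  group dummy, and age in days, centered, as a covariate. Dummy reference
  levels are the lexicographically first level and aliased columns are
  dropped to full rank with a report, so fits are bit-for-bit
  reproducible. Whether year-season should be sample-level or dam-level
  is not decidable from the data model; it is implemented sample-level.

### AI-REML

Variance components maximize the restricted likelihood of
$y \sim N(Xb, K_a\sigma_a^2 + K_m\sigma_m^2 + I\sigma_e^2)$ with
$K_a = ZAZ'$, $K_m = WW'$. Updates are average-information (AI) Newton
steps guarded by a step-halving line search on the restricted likelihood;
components pinned at the lower bound with an inward gradient are frozen
out of the AI system (an active-set treatment), and when no AI step
improves the likelihood an EM-style multiplicative fixed-point step
$\sigma_i^2 \leftarrow \sigma_i^2 \, (y'PK_iPy)/\mathrm{tr}(PK_i)$ is
taken instead. Numerical choices:

* the response is internally standardized to unit OLS residual variance
  and results are back-transformed, which makes $h^2$ exactly invariant
  to rescaling the phenotype and keeps the optimizer on an $O(1)$ scale;
* variances are floored at $10^{-8}$ and flagged `boundary` rather than
  silently truncated;
* convergence: relative parameter change $< 10^{-8}$, or likelihood
  change $< 10^{-10}$, or all free gradients below $10^{-3}$; maximum 200
  iterations, with non-convergence flagged, never hidden;
* the asymptotic covariance of the estimates is the inverse of the final
  AI matrix.

### Standard errors, p-values and the screen

$SE(h^2)$ comes from a first-order Taylor (delta-method) expansion: with
$T = \sigma_a^2+\sigma_m^2+\sigma_e^2$ the gradient of $h^2$ is
$((T-\sigma_a^2)/T^2, -\sigma_a^2/T^2, -\sigma_a^2/T^2)$ and
$SE = \sqrt{g'Vg}$. The p-value is a two-tailed Student $t$ test of
$h^2/SE$ on $n - \mathrm{rank}(X)$ degrees of freedom. A $t$ test for a
variance ratio is a convention rather than an exact distribution; it is
implemented as stated because the screening rule is defined with it. The
screen flags ASVs with $h^2 > 0.2$ *and* $p < 0.05$, both strict; the 0.2
threshold is applied to the point estimate, with the 95% CI reported
alongside, since applying it to a confidence bound is the stricter of two
readings and is not recoverable from the rule as usually quoted.

## Table processing

* Prevalence filter: ASVs detected in fewer than 5% of samples are
  removed; an ASV in *exactly* 5% stays (literal reading of a
  "less than" removal rule).
* Rarefaction: one seeded draw per sample without replacement
  (`vegan::rrarefy`); samples below depth are dropped with a warning —
  the alternative (keeping them unrarefied) silently breaks depth
  comparability.
* Log transform: natural log of proportion plus a pseudocount, default
  $10^{-6}$, configurable. The default is roughly one order of magnitude
  below the smallest nonzero proportion at the 10,000-read rarefaction
  depth, so zeros map below every observed value without dominating the
  variance.
* Alpha diversity: bias-corrected Chao1
  $S_{obs} + f_1(f_1-1)/(2(f_2+1))$, Shannon in nats, and evenness as
  Pielou's $H/\ln S_{obs}$ (undefined, hence `NA`, for one-taxon
  samples). "Evenness" is ambiguous without a formula; Pielou is the
  common reading.
* Beta dissimilarity: Bray–Curtis and binary Jaccard via `vegan`,
  weighted UniFrac in its *normalized* form via `phyloseq` (the
  normalization choice matters and is therefore fixed and documented).
  Whether presence/absence comparisons use rarefied or raw counts is a
  user choice; the pipeline uses rarefied counts.
* PCoA: classical scaling of $-\frac12 D^2$; axes with non-positive
  eigenvalues are excluded rather than corrected, and the proportion
  explained is reported over positive eigenvalues only.
* PERMANOVA: `vegan::adonis2` (Anderson's pseudo-F), 999 permutations by
  default, so the smallest attainable p is 0.001.

## SparCC networks

Correlations between ASVs are estimated from log-ratio variances
$T_{ij} = \mathrm{var}\log(x_i/x_j)$, which are invariant to per-sample
totals. Basis variances solve the sparsity-approximation linear system,
and the strongest pair above $|r| = 0.1$ is iteratively excluded from the
system (up to 10 rounds) before re-solving. Zeros are handled by a
deterministic $+1$ pseudocount on counts rather than Dirichlet
resampling; determinism makes the estimate reproducible and testable, and
the Dirichlet path remains available (`method = "dirichlet"`, median over
iterations). Significance comes from resampling: each of 100 resamples
permutes every ASV's counts independently across samples — destroying all
between-ASV dependence while preserving marginals — giving two-sided
pseudo p-values with an add-one correction (minimum $1/101$).

Networks keep ASVs present in more than 20% of the cohort's samples
(dam and lamb networks are built separately) and edges with $|r| > 0.5$
and $p < 0.01$, all strict. Hub = highest degree; keystone = highest
betweenness (exact, unweighted); ties break lexicographically and all
tied ids are reported. MCODE follows the standard three stages (node
weight = highest-k-core density of the closed neighborhood times the
core's $k$; seeded expansion at node score cutoff 0.2; clusters must
contain a 2-core; haircut/fluff off) with cluster score = density × size.

## Associations and prediction

ASVs found in at least 50% of dams *or* 50% of lambs (boundary
inclusive) are correlated with lamb growth traits (BW, WW, PWG) and rumen
fermentation parameters by Spearman's rank correlation with midrank ties:
exact permutation p for $n \le 9$ without ties, $t$ approximation
otherwise. A dam's abundance is paired with each of her lambs, one row
per lamb; those rows are not independent and the output says so.
Benjamini–Hochberg adjustment is applied over the whole ASV × variable
matrix jointly by default (a per-variable option exists), and edges with
adjusted $p < 0.05$ are retained.

Prediction follows a litter-stratified protocol: within each litter-size
stratum lambs are ranked on the trait and the top and bottom
$\lfloor 0.25 n \rfloor$ become the high and low groups (middle lambs are
excluded from training entirely; strata smaller than four lambs
contribute no labels). Features are log relative abundances with a
`lamb_`/`dam_` prefix, maternal features repeated across littermates. The
random forest is trained with impurity-importance feature selection at
$10^{-3}$ (after normalizing importances to sum to 1), tree count chosen
by the 7-fold cross-validation learning curve, then depth and feature
fraction by grid search; the declared default grids are trees
{200, 500, 1000}, depth {unlimited, 5}, mtry `sqrt`. Folds and the 70/30
ROC split are stratified because class counts are small. ROC
probabilities are mean tree vote fractions; AUC is the trapezoidal area.
Cross-validated accuracy and the held-out AUC answer different questions
and both are reported. The protocol has no nested cross-validation, so
the reported CV accuracy of a tuned model is mildly optimistic; this is a
known limitation of the design it follows.

## The synthetic-data generator

The generator exists so the whole pipeline can be validated against known
truth. It emulates a flock of 128 founder dams with litter-size
probabilities (0.65, 0.30, 0.045, 0.005) over sizes 1–4 — mean 1.405, so
about 179 lambs per 128 dams — and a pool of 16 sires, one per litter, so
littermates are full sibs and cross-litter paternal half sibs occur. The
sire-pool size and litter-size frequencies are declared defaults, not
estimates: real flock structure varies and only the mean litter size is
anchored.

Latent per-ASV log abundances follow exactly the animal model above, with
$a$ drawn through the Cholesky factor of $A$ over all pedigree animals.
Latent values map to compositions by a per-sample softmax — the
generative direction is underdetermined by an analysis that only ever
log-transforms proportions, and softmax guarantees valid compositions
whose log-proportions recover the latent values up to a per-sample
constant — then to counts multinomially at negative-binomial library
sizes (mean 35,000, size 13.5, giving an SD near 9,500). By default the
first 10% of ASVs are heritable with $h^2$ spread over 0.25–0.65,
$\sigma_m^2 = 0.1$ and unit total variance, and heritable ASVs get a
baseline log-abundance boost so they sit in the abundant tail, which
mirrors the field observation that abundant taxa tend to be the heritable
ones and keeps their multinomial sampling noise small.

What the generator does *not* emulate: sequencing error and chimeras,
taxonomy-assignment uncertainty (lineages are drawn from a small fixed
vocabulary of rumen taxa), diet and batch structure, and the per-sample
softmax constant couples ASVs weakly (a real compositional effect;
with few, highly dominant ASVs it inflates apparent covariance between
taxa). Passing tests therefore demonstrate correctness of the estimators
under the stated model, not robustness to every artifact of real
amplicon data.

Co-occurring guilds are planted as blocks of ASVs (by default three
blocks of four, on the tail of the ASV list when the table has at least
60 ASVs, so heritability and co-abundance structure live on disjoint
taxa) whose residuals share a per-sample factor giving within-block
residual correlation 0.7. This gives the SparCC stage a true positive
structure to recover while leaving per-ASV variance components untouched;
in real data co-abundance and heritability of course overlap.

Growth traits are linear in the latent values of designated ASVs (by
default the first five, which are heritable) plus a litter-size penalty
and Gaussian noise; PWG is exactly WW − BW. Fermentation parameters are
linear in single ASVs' latent values. Effect sizes and noise SDs were
chosen once to give realistic trait ranges (BW around 4 kg, WW around
14 kg) and a recoverable but not trivial signal.

## Problem sizes used in validation

The test suite validates the estimators at the scales the design targets:
relationship matrices against a gene-dropping oracle (10^6 simulated
meioses) and dense inversion up to 1,000 animals; REML recovery and
delta-method SE calibration on the 128-dam population (~300 sampled
animals) over 30 and 200 replicates respectively; SparCC null and planted
behaviour at 200 samples × 50 ASVs; prediction on 30 replicate
populations of 100 dams. The acceptance script runs the full pipeline at
the 128-dam / 150-ASV design scale. These sizes are the package's own
validation design; larger populations only improve the asymptotics the
tests already probe.

## Known limitations

* The $t$-based p-value for $h^2$ is a convention; a likelihood-ratio or
  permutation test would be better calibrated near the boundary (the
  permutation null is in fact exercised by the test suite, which checks
  the screen's type-I rate).
* Maternal effects of non-founder sampled animals' dams are estimable
  only when those dams appear as mothers of sampled animals.
* SparCC's sparsity assumption degrades with very few ASVs (the basis
  system is solved for $d \ge 3$ but is approximate throughout).
* Importance-based feature selection plus tuning without nested CV gives
  optimistic accuracy estimates; the held-out AUC is the more honest
  number.
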