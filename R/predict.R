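# Litter-stratified high/low growth-trait classification with random
# forests: group construction, dam/lamb feature assembly, tuning with
# importance-based feature selection, cross-validated accuracy, ROC/AUC and
# importance reporting.

#' Assign high/low trait groups within litter-size strata
#'
#' Lambs are ranked on the trait separately within each litter-size
#' stratum; the top `floor(fraction * n)` are labeled `"high"`, the bottom
#' `floor(fraction * n)` `"low"`, and the middle lambs `"unused"`.  Ties
#' are broken by stable animal-id order.  A stratum with fewer than
#' `1 / fraction` lambs yields no labels (with a warning).
#'
#' @param metadata lamb metadata with columns `animal`, `litter_size`, and
#'   the trait.
#' @param trait one of the trait columns, e.g. `"BW"`, `"WW"`, `"PWG"`.
#' @param fraction tail fraction per stratum (default 0.25).
#' @return data.frame `(animal, litter_size, value, label)` with
#'   `label in {high, low, unused}`.
#' @export
make_trait_groups <- function(metadata, trait, fraction = 0.25) {
  check_fraction(fraction, "fraction")
  if (!trait %in% names(metadata)) abort("metadata lacks trait '", trait, "'")
  md <- metadata[!is.na(metadata[[trait]]), , drop = FALSE]
  out <- lapply(split(md, md$litter_size), function(s) {
    s <- s[order(-s[[trait]], s$animal), , drop = FALSE]
    n <- nrow(s); k <- floor(fraction * n)
    label <- rep("unused", n)
    if (k == 0L) {
      warning(sprintf("litter-size stratum %s has only %d lamb(s); no labels",
                      s$litter_size[1L], n), call. = FALSE)
    } else {
      label[seq_len(k)] <- "high"
      label[seq(n - k + 1L, n)] <- "low"
    }
    data.frame(animal = s$animal, litter_size = s$litter_size,
               value = s[[trait]], label = label, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "trait") <- trait
  res
}

#' Assemble the feature matrix for trait classification
#'
#' Features are log-transformed relative abundances.  With
#' `source = "lamb"` each labeled lamb contributes its own ASV profile;
#' with `"dam"` its mother's profile (littermates therefore share
#' identical maternal rows); `"both"` concatenates the two.  Column names
#' are prefixed `lamb_` / `dam_` so the cohort of origin is recoverable
#' from importances.  Labeled lambs whose dam sample is missing are
#' dropped with a warning when maternal features are requested.
#'
#' @param x an [asv_table()] holding both cohorts' samples.
#' @param metadata data.frame with `sample_id`, `animal`, `group`, `dam`.
#' @param groups result of [make_trait_groups()].
#' @param source `"both"`, `"dam"` or `"lamb"`.
#' @param pseudocount pseudocount for the log transform.
#' @param asvs optional restriction of the feature ASVs.
#' @return list with `x` (feature matrix, rows = labeled lambs), `y`
#'   (factor `high`/`low`), `animals`.
#' @export
build_features <- function(x, metadata, groups,
                           source = c("both", "dam", "lamb"),
                           pseudocount = 1e-6, asvs = NULL) {
  stopifnot(inherits(x, "asv_table"))
  source <- match.arg(source)
  logab <- log_transform(relative_abundance(x), pseudocount)
  if (!is.null(asvs)) logab <- logab[, asvs, drop = FALSE]
  lab <- groups[groups$label %in% c("high", "low"), , drop = FALSE]
  md <- metadata[match(lab$animal, metadata$animal), ]
  lamb_sample <- md$sample_id
  dam_sample <- metadata$sample_id[match(md$dam, metadata$animal)]
  if (source %in% c("both", "dam")) {
    ok <- !is.na(dam_sample) & dam_sample %in% rownames(logab)
    if (any(!ok)) {
      warning("dropping ", sum(!ok), " labeled lamb(s) without a dam sample",
              call. = FALSE)
      lab <- lab[ok, , drop = FALSE]
      lamb_sample <- lamb_sample[ok]; dam_sample <- dam_sample[ok]
    }
  }
  parts <- list()
  if (source %in% c("both", "lamb")) {
    m <- logab[lamb_sample, , drop = FALSE]
    colnames(m) <- paste0("lamb_", colnames(m))
    parts <- c(parts, list(m))
  }
  if (source %in% c("both", "dam")) {
    m <- logab[dam_sample, , drop = FALSE]
    colnames(m) <- paste0("dam_", colnames(m))
    parts <- c(parts, list(m))
  }
  feat <- do.call(cbind, parts)
  rownames(feat) <- lab$animal
  list(x = feat, y = factor(lab$label, levels = c("low", "high")),
       animals = lab$animal)
}

#' Random-forest configuration
#'
#' Declares the tuning grids: `trees` is chosen first by the 7-fold
#' cross-validation learning curve (highest mean accuracy, ties to fewer
#' trees), then `depth` (0 = unlimited) and `mtry` (`"sqrt"`, `"log2"` or
#' a fraction of features) by grid search.  `importance_threshold` drops
#' features whose normalized impurity importance in an initial fit falls
#' below it (default 1e-3) before the tuned refit.
#'
#' @param trees,depth,mtry tuning grids.
#' @param importance_threshold feature-selection cutoff.
#' @param folds cross-validation folds (default 7).
#' @return a list of class `rfc_config`.
#' @export
rfc_config <- function(trees = c(200, 500, 1000), depth = c(0, 5),
                       mtry = "sqrt", importance_threshold = 1e-3,
                       folds = 7) {
  structure(list(trees = trees, depth = depth, mtry = mtry,
                 importance_threshold = importance_threshold, folds = folds),
            class = "rfc_config")
}

.mtry_value <- function(mtry, p) {
  if (is.character(mtry)) {
    switch(mtry, sqrt = max(1L, floor(sqrt(p))),
           log2 = max(1L, floor(log2(p))),
           abort("unknown mtry spec '", mtry, "'"))
  } else max(1L, floor(mtry * p))
}

# stratified fold assignment; reduces fold count if a class is too small
.stratified_folds <- function(y, k) {
  k <- min(k, min(table(y)))
  if (k < 2L) abort("too few samples per class for cross-validation")
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.fit_ranger <- function(x, y, trees, depth, mtry, seed, probability = FALSE) {
  ranger::ranger(x = x, y = y, num.trees = trees, max.depth = depth,
                 mtry = .mtry_value(mtry, ncol(x)),
                 importance = "impurity", probability = probability,
                 seed = seed, num.threads = 1)
}

.cv_accuracy <- function(x, y, trees, depth, mtry, folds, seed) {
  fold <- .stratified_folds(y, folds)
  acc <- vapply(sort(unique(fold)), function(f) {
    tr <- fold != f
    fit <- .fit_ranger(x[tr, , drop = FALSE], y[tr], trees, depth, mtry,
                       seed + f)
    pred <- stats::predict(fit, data = x[!tr, , drop = FALSE])$predictions
    mean(pred == y[!tr])
  }, numeric(1))
  mean(acc)
}

#' Train a tuned random-forest trait classifier
#'
#' Protocol: (1) an initial forest ranks features by impurity importance,
#' normalized to sum to 1, and features below
#' `config$importance_threshold` are dropped; (2) the tree count is chosen
#' from `config$trees` by the k-fold cross-validation learning curve;
#' (3) `depth` and `mtry` are grid-searched at the chosen tree count;
#' (4) the final probability forest is refit on all data.  All randomness
#' is derived from `seed`.
#'
#' @param x feature matrix (rows = lambs).
#' @param y factor with levels `low`, `high` (both present, >= 2 each).
#' @param config an [rfc_config()].
#' @param seed integer seed.
#' @return object of class `rfc_model`: `model` (final probability
#'   forest), `features` (selected), `hyperparams`, `cv_table`, `config`,
#'   `seed`.
#' @export
train_rfc <- function(x, y, config = rfc_config(), seed = 1) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) abort("labels must contain both classes")
  if (any(table(y) < 2L)) abort("each class needs at least 2 samples")
  with_seed(seed, {
    sel_fit <- .fit_ranger(x, y, trees = max(config$trees), depth = 0,
                           mtry = config$mtry[[1L]], seed = seed)
    imp <- sel_fit$variable.importance
    imp <- imp / sum(imp)
    keep <- names(imp)[imp >= config$importance_threshold]
    if (length(keep) < 2L) keep <- names(sort(imp, decreasing = TRUE))[1:2]
    xs <- x[, keep, drop = FALSE]

    curve <- vapply(config$trees, function(tr) {
      .cv_accuracy(xs, y, tr, depth = 0, mtry = config$mtry[[1L]],
                   folds = config$folds, seed = seed)
    }, numeric(1))
    best_trees <- config$trees[which.max(curve)]

    grid <- expand.grid(depth = config$depth, mtry = config$mtry,
                        stringsAsFactors = FALSE)
    grid$accuracy <- vapply(seq_len(nrow(grid)), function(i) {
      .cv_accuracy(xs, y, best_trees, grid$depth[i], grid$mtry[[i]],
                   folds = config$folds, seed = seed + 1000L)
    }, numeric(1))
    best <- grid[which.max(grid$accuracy), ]

    final <- .fit_ranger(xs, y, best_trees, best$depth, best$mtry[[1L]],
                         seed = seed, probability = TRUE)
    structure(list(model = final, features = keep,
                   hyperparams = list(trees = best_trees,
                                      depth = best$depth,
                                      mtry = best$mtry[[1L]]),
                   cv_table = list(learning_curve =
                                     data.frame(trees = config$trees,
                                                accuracy = curve),
                                   grid = grid),
                   importance_selection = imp,
                   config = config, seed = seed),
              class = "rfc_model")
  })
}

#' Evaluate a trained classifier
#'
#' Reports (1) the mean stratified k-fold cross-validation accuracy of the
#' chosen hyperparameters on the full labeled set, and (2) ROC and AUC
#' from a single stratified 70/30 train/test split, using the forest's
#' class-probability (mean tree vote) for the `high` class; the AUC is the
#' trapezoidal area under the ROC.
#'
#' @param model an [train_rfc()] result.
#' @param x,y the feature matrix and labels.
#' @param split training fraction of the ROC split (default 0.7).
#' @param seed integer seed (folds and split).
#' @return object of class `prediction_report`: `accuracy_cv`, `auc`,
#'   `roc` (data.frame `fpr`, `tpr`), `hyperparams`, `n`, `seed`.
#' @export
evaluate_rfc <- function(model, x, y, split = 0.7, seed = 1) {
  stopifnot(inherits(model, "rfc_model"))
  y <- droplevels(as.factor(y))
  hp <- model$hyperparams
  xs <- x[, model$features, drop = FALSE]
  with_seed(seed, {
    acc <- .cv_accuracy(xs, y, hp$trees, hp$depth, hp$mtry,
                        folds = model$config$folds, seed = seed)
    # stratified 70/30 split
    tr_idx <- unlist(lapply(levels(y), function(cl) {
      idx <- which(y == cl)
      sample(idx, max(1L, round(split * length(idx))))
    }))
    if (length(unique(y[-tr_idx])) < 2L) {
      abort("test partition lacks both classes; too few samples")
    }
    fit <- .fit_ranger(xs[tr_idx, , drop = FALSE], y[tr_idx], hp$trees,
                       hp$depth, hp$mtry, seed = seed, probability = TRUE)
    prob <- stats::predict(fit, data = xs[-tr_idx, , drop = FALSE])$predictions[, "high"]
    roc <- pROC::roc(response = y[-tr_idx], predictor = prob,
                     levels = c("low", "high"), direction = "<",
                     quiet = TRUE)
    roc_df <- data.frame(fpr = 1 - roc$specificities,
                         tpr = roc$sensitivities)
    roc_df <- roc_df[order(roc_df$fpr, roc_df$tpr), , drop = FALSE]
    rownames(roc_df) <- NULL
    structure(list(accuracy_cv = acc,
                   auc = as.numeric(pROC::auc(roc)),
                   roc = roc_df,
                   hyperparams = hp, n = length(y), seed = seed),
              class = "prediction_report")
  })
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("prediction report: CV accuracy %.3f, held-out AUC %.3f (n = %d)\n",
              x$accuracy_cv, x$auc, x$n))
  invisible(x)
}

#' Ranked feature-importance report
#'
#' Normalizes the final forest's impurity importances to sum to 1, keeps
#' the `top_k`, and sums importance by cohort of origin (the `lamb_` /
#' `dam_` column prefix).  Heritable flags are joined on the bare ASV id.
#'
#' @param model an [train_rfc()] result.
#' @param top_k number of features to report (default 50).
#' @param heritable character vector of heritable ASV ids.
#' @return list with `table` (rank, feature, cohort, asv, importance,
#'   heritable) and `cohort_importance` (named sums over the top_k).
#' @export
importance_report <- function(model, top_k = 50, heritable = NULL) {
  stopifnot(inherits(model, "rfc_model"))
  imp <- model$model$variable.importance
  imp <- sort(imp / sum(imp), decreasing = TRUE)
  top <- utils::head(imp, top_k)
  cohort <- sub("_.*$", "", names(top))
  asv <- sub("^(lamb|dam)_", "", names(top))
  tab <- data.frame(rank = seq_along(top), feature = names(top),
                    cohort = cohort, asv = asv,
                    importance = as.numeric(top),
                    heritable = asv %in% (heritable %||% character(0)),
                    row.names = NULL)
  list(table = tab,
       cohort_importance = tapply(tab$importance, tab$cohort, sum))
}
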