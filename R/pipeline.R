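# Configuration-driven end-to-end run: simulate (or load) -> filter ->
# diversity -> heritability -> networks -> associations -> prediction,
# aggregated into one reproducible report.

#' Pipeline configuration
#'
#' Collects every stage threshold with the pipeline defaults: prevalence
#' filter 5%, rarefaction depth 10,000, heritability screen h2 > 0.2 at
#' p < 0.05, SparCC edges |r| > 0.5 at pseudo-p < 0.01 over ASVs in > 20%
#' of a cohort's samples (bootstrap n = 100), association prevalence 50%
#' with BH 0.05, high/low groups from the top/bottom 25% per litter size,
#' 7-fold cross-validation and a 70/30 ROC split.  Thresholds are
#' validated here, before any compute.
#'
#' @param params a [synth_params()] describing the population to simulate.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param prevalence_min,rarefy_depth,pseudocount table-stage settings.
#' @param h2_min,p_max heritability screen.
#' @param sparcc_r,sparcc_p,sparcc_prevalence,sparcc_boot network stage.
#' @param assoc_prevalence,assoc_alpha association stage.
#' @param group_fraction,cv_folds,train_split,traits,predict_sources,rfc
#'   prediction stage.
#' @param out_dir optional directory for stage artifacts (JSON/TSV).
#' @return validated list of class `run_config`.
#' @export
run_config <- function(params = synth_params(), seed = 1,
                       prevalence_min = 0.05, rarefy_depth = 10000,
                       pseudocount = 1e-6,
                       h2_min = 0.2, p_max = 0.05,
                       sparcc_r = 0.5, sparcc_p = 0.01,
                       sparcc_prevalence = 0.20, sparcc_boot = 100,
                       assoc_prevalence = 0.5, assoc_alpha = 0.05,
                       group_fraction = 0.25, cv_folds = 7,
                       train_split = 0.7,
                       traits = c("BW", "WW", "PWG"),
                       predict_sources = c("dam", "both"),
                       rfc = rfc_config(trees = c(200, 500), depth = c(0, 5)),
                       out_dir = NULL) {
  check_fraction(prevalence_min, "prevalence_min")
  check_fraction(p_max, "p_max")
  check_fraction(sparcc_p, "sparcc_p")
  check_fraction(sparcc_prevalence, "sparcc_prevalence", allow_zero = TRUE)
  check_fraction(assoc_prevalence, "assoc_prevalence")
  check_fraction(assoc_alpha, "assoc_alpha")
  check_fraction(group_fraction, "group_fraction")
  check_fraction(train_split, "train_split")
  if (h2_min < 0 || h2_min >= 1) abort("`h2_min` must be in [0, 1)")
  if (sparcc_r < 0 || sparcc_r >= 1) abort("`sparcc_r` must be in [0, 1)")
  if (rarefy_depth < 1) abort("`rarefy_depth` must be >= 1")
  if (cv_folds < 2) abort("`cv_folds` must be >= 2")
  if (!all(predict_sources %in% c("dam", "lamb", "both"))) {
    abort("`predict_sources` must be among dam, lamb, both")
  }
  structure(as.list(environment()), class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Simulates a study from `config$params`, then executes every stage in
#' order and aggregates a report: prevalent-ASV count, alpha/beta
#' diversity comparisons between dams and lambs, per-ASV heritability with
#' the heritable screen, dam and lamb co-occurrence networks with MCODE
#' clusters and hub/keystone calls, ASV-trait associations, and high/low
#' growth-trait prediction per trait and feature source.  Identical
#' configurations (including the seed) give identical reports.
#'
#' @param config a [run_config()].
#' @return list of class `run_report` with elements `tables`,
#'   `heritability`, `network`, `assoc`, `predict`, `config_summary`; if
#'   `config$out_dir` is set, a JSON report and stage artifacts are also
#'   written there.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  sim <- .stage("simulate", simulate_study(config$params, seed = seed))
  md <- sim$metadata

  tables <- .stage("tables", {
    prevalent <- filter_prevalence(sim$table, config$prevalence_min)
    depth <- min(config$rarefy_depth, max(rowSums(sim$table$counts)))
    rarefied <- suppressWarnings(rarefy(sim$table, depth, seed = seed + 10))
    alpha <- alpha_diversity(rarefied)
    alpha$group <- md$group[match(alpha$sample_id, md$sample_id)]
    alpha_p <- vapply(c("chao1", "shannon", "evenness"), function(mm) {
      v <- alpha[[mm]]
      ok <- !is.na(v)
      rank_sum_test(v[ok & alpha$group == "dam"],
                    v[ok & alpha$group == "lamb"])$p
    }, numeric(1))
    bray <- beta_dissimilarity(prevalent, "bray_curtis")
    ord <- pcoa_ordination(bray)
    perm <- permanova(bray, md$group[match(rownames(prevalent$counts),
                                           md$sample_id)],
                      n_perm = 999, seed = seed + 11)
    venn <- group_presence_summary(prevalent, md)
    list(n_asvs_total = ncol(sim$table$counts),
         n_prevalent = ncol(prevalent$counts),
         alpha_p_holm = adjust_pvalues(alpha_p, "holm"),
         pcoa_prop_explained = utils::head(ord$proportion_explained, 2),
         permanova_f = perm$f, permanova_p = perm$p,
         venn = venn$only, venn_shared = venn$shared,
         prevalent = prevalent)
  })
  prevalent <- tables$prevalent

  herit <- .stage("heritability", {
    res <- fit_heritability(prevalent, md, sim$ped,
                            pseudocount = config$pseudocount)
    screen <- screen_heritable(res, prevalent, md,
                               h2_min = config$h2_min, p_max = config$p_max)
    screen
  })

  network <- .stage("network", {
    lapply(stats::setNames(c("dam", "lamb"), c("dam", "lamb")), function(grp) {
      ids <- md$sample_id[md$group == grp]
      sub <- asv_table(prevalent$counts[ids, , drop = FALSE],
                       prevalent$taxonomy)
      sub <- filter_prevalence(sub, 1e-9)    # drop all-zero columns
      sp <- sparcc(sub)
      pv <- sparcc_pvalues(sub, sp, n_boot = config$sparcc_boot,
                           seed = seed + 20 + (grp == "lamb"))
      g <- build_network(sp, pv, sub, heritable = herit$heritable_asvs,
                         r_threshold = config$sparcc_r,
                         p_threshold = config$sparcc_p,
                         prevalence_min = config$sparcc_prevalence)
      if (igraph::vcount(g) == 0L) {
        return(list(empty = TRUE, n_nodes = 0, n_edges = 0))
      }
      st <- network_stats(g)
      cl <- mcode(g)
      list(empty = FALSE, n_nodes = st$n_nodes, n_edges = st$n_edges,
           clustering_coefficient = st$clustering_coefficient,
           average_degree = st$average_degree, density = st$density,
           hub = st$hub, keystone = st$keystone,
           n_clusters = length(cl),
           top_cluster_score = if (length(cl)) cl[[1L]]$score else NA_real_,
           graph = g, clusters = cl)
    })
  })

  ferment <- c("NH3N", "acetate", "propionate", "butyrate", "isobutyrate",
               "valerate", "isovalerate")
  assoc <- .stage("assoc", {
    edges <- spearman_assoc(prevalent, md,
                            variables = c(config$traits, ferment),
                            asvs = select_assoc_asvs(prevalent, md,
                                                     config$assoc_prevalence),
                            pseudocount = config$pseudocount,
                            alpha = config$assoc_alpha)
    list(edges = edges, summary = assoc_summary(edges, herit$heritable_asvs))
  })

  pred <- .stage("predict", {
    feat_asvs <- select_assoc_asvs(prevalent, md, config$assoc_prevalence)
    out <- list()
    for (trait in config$traits) {
      groups <- suppressWarnings(
        make_trait_groups(md[md$group == "lamb", ], trait,
                          config$group_fraction))
      for (src in config$predict_sources) {
        bf <- build_features(prevalent, md, groups, source = src,
                             pseudocount = config$pseudocount,
                             asvs = feat_asvs)
        model <- train_rfc(bf$x, bf$y, config = config$rfc,
                           seed = seed + 30)
        rep <- evaluate_rfc(model, bf$x, bf$y, split = config$train_split,
                            seed = seed + 31)
        imp <- importance_report(model, top_k = 50,
                                 heritable = herit$heritable_asvs)
        out[[paste(trait, src, sep = "_")]] <-
          list(trait = trait, source = src,
               accuracy_cv = rep$accuracy_cv, auc = rep$auc,
               n = rep$n, hyperparams = rep$hyperparams,
               cohort_importance = as.list(imp$cohort_importance),
               top_importance = imp$table)
      }
    }
    out
  })

  report <- structure(list(
    tables = tables[setdiff(names(tables), "prevalent")],
    heritability = list(summary = herit$summary,
                        heritable_asvs = herit$heritable_asvs,
                        results = herit$results),
    network = lapply(network, function(nw)
      nw[setdiff(names(nw), c("graph", "clusters"))]),
    assoc = list(counts = assoc$summary$counts,
                 n_asvs = assoc$summary$n_asvs,
                 heritable_overlap = assoc$summary$heritable_overlap),
    predict = lapply(pred, function(p) p[setdiff(names(p), "top_importance")]),
    config_summary = list(seed = seed,
                          n_dams = config$params$n_dams,
                          n_asvs = config$params$n_asvs,
                          thresholds = list(
                            prevalence = config$prevalence_min,
                            h2_min = config$h2_min, p_max = config$p_max,
                            sparcc_r = config$sparcc_r,
                            sparcc_p = config$sparcc_p,
                            assoc_alpha = config$assoc_alpha))),
    class = "run_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      rapply(unclass(report), function(x) x, how = "replace"),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE)
    utils::write.table(herit$results,
                       file.path(config$out_dir, "heritability.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(assoc$edges,
                       file.path(config$out_dir, "assoc_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run report\n")
  cat(sprintf("  prevalent ASVs: %d of %d\n", x$tables$n_prevalent,
              x$tables$n_asvs_total))
  cat(sprintf("  heritable: %d of %d (%.1f%%)\n",
              x$heritability$summary$n_heritable,
              x$heritability$summary$n_tested,
              x$heritability$summary$pct_heritable))
  for (nm in names(x$predict)) {
    cat(sprintf("  %s: CV accuracy %.2f, AUC %.2f\n", nm,
                x$predict[[nm]]$accuracy_cv, x$predict[[nm]]$auc))
  }
  invisible(x)
}
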