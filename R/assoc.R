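# Spearman association screen of ASVs against lamb growth traits and rumen
# fermentation parameters, with Benjamini-Hochberg FDR control.

#' Select ASVs for the association screen
#'
#' Keeps ASVs found (count > 0) in at least `prevalence_min` of the dams
#' *or* at least `prevalence_min` of the lambs (boundary inclusive).
#'
#' @param x an [asv_table()].
#' @param metadata data.frame with `sample_id` and `group`.
#' @param prevalence_min per-cohort prevalence threshold (default 0.5).
#' @return character vector of ASV ids.
#' @export
select_assoc_asvs <- function(x, metadata, prevalence_min = 0.5) {
  stopifnot(inherits(x, "asv_table"))
  check_fraction(prevalence_min, "prevalence_min")
  prev_in <- function(grp) {
    s <- metadata$sample_id[metadata$group == grp]
    sub <- x$counts[rownames(x$counts) %in% s, , drop = FALSE]
    colMeans(sub > 0)
  }
  pd <- prev_in("dam"); pl <- prev_in("lamb")
  colnames(x$counts)[pd >= prevalence_min | pl >= prevalence_min]
}

# one Spearman correlation; exact permutation p for n <= 9 without ties,
# t approximation otherwise; NULL if either vector is constant
.spearman_one <- function(xv, yv) {
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 4L) return(NULL)
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) return(NULL)
  ties <- anyDuplicated(xv) || anyDuplicated(yv)
  ht <- suppressWarnings(
    stats::cor.test(xv, yv, method = "spearman",
                    exact = (n <= 9L && !ties)))
  list(rho = unname(ht$estimate), p = ht$p.value, n = n)
}

#' ASV-trait Spearman correlations
#'
#' Correlates log-transformed relative abundances of selected ASVs with
#' lamb-level variables (growth traits and rumen fermentation parameters).
#' Lamb ASVs are paired with the lamb's own variables; dam ASVs are paired
#' with each of the dam's lambs, one observation per lamb (littermates
#' reuse their mother's abundance, so those rows are not independent —
#' noted in the output).  Ties are midranked; p-values are exact (full
#' permutation) for n <= 9 without ties and use the t approximation
#' otherwise.  BH adjustment is applied jointly over the whole ASV x
#' variable matrix by default, or within each variable with
#' `adjust = "per_variable"`.
#'
#' @param x an [asv_table()] holding both cohorts' samples.
#' @param metadata data.frame with `sample_id`, `animal`, `group`, `dam`
#'   (dam id, lambs only) and the variable columns.
#' @param variables character vector of metadata columns to correlate.
#' @param asvs ASVs to test (default [select_assoc_asvs()]).
#' @param pseudocount pseudocount for the log transform.
#' @param adjust `"global"` or `"per_variable"` BH correction.
#' @param alpha significance threshold on adjusted p (default 0.05).
#' @return data.frame of class `assoc_edges`: `asv, cohort, variable, n,
#'   rho, p, p_adj, sign, significant`, with skipped constant pairs
#'   recorded in `attr(, "skipped")`.
#' @export
spearman_assoc <- function(x, metadata, variables, asvs = NULL,
                           pseudocount = 1e-6,
                           adjust = c("global", "per_variable"),
                           alpha = 0.05) {
  stopifnot(inherits(x, "asv_table"))
  adjust <- match.arg(adjust)
  missing_v <- setdiff(variables, names(metadata))
  if (length(missing_v)) {
    abort("metadata lacks variable(s): ", paste(missing_v, collapse = ", "))
  }
  asvs <- asvs %||% select_assoc_asvs(x, metadata)
  logab <- log_transform(relative_abundance(x), pseudocount)
  md <- metadata[match(rownames(logab), metadata$sample_id), ]
  lambs <- md[md$group == "lamb", , drop = FALSE]
  # dam cohort rows: one per lamb, abundance taken from the lamb's dam
  dam_sample <- md$sample_id[match(lambs$dam, md$animal)]
  has_dam <- !is.na(dam_sample)

  rows <- list(); skipped <- list()
  for (a in asvs) {
    lamb_ab <- logab[lambs$sample_id, a]
    dam_ab <- logab[dam_sample[has_dam], a]
    for (v in variables) {
      vals_l <- lambs[[v]]
      res <- .spearman_one(lamb_ab, vals_l)
      if (is.null(res)) {
        skipped[[length(skipped) + 1L]] <- c(a, "lamb", v)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          asv = a, cohort = "lamb", variable = v, n = res$n,
          rho = res$rho, p = res$p, stringsAsFactors = FALSE)
      }
      res <- .spearman_one(dam_ab, vals_l[has_dam])
      if (is.null(res)) {
        skipped[[length(skipped) + 1L]] <- c(a, "dam", v)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          asv = a, cohort = "dam", variable = v, n = res$n,
          rho = res$rho, p = res$p, stringsAsFactors = FALSE)
      }
    }
  }
  edges <- do.call(rbind, rows)
  if (is.null(edges)) edges <- data.frame(asv = character(0),
                                          cohort = character(0),
                                          variable = character(0),
                                          n = numeric(0), rho = numeric(0),
                                          p = numeric(0))
  if (nrow(edges)) {
    if (adjust == "global") {
      edges$p_adj <- adjust_pvalues(edges$p, "BH")
    } else {
      edges$p_adj <- stats::ave(edges$p, edges$variable,
                                FUN = function(p) adjust_pvalues(p, "BH"))
    }
    edges$sign <- ifelse(edges$rho > 0, "positive", "negative")
    edges$significant <- edges$p_adj < alpha
  }
  attr(edges, "skipped") <- skipped
  attr(edges, "pairing") <- "dam abundances repeated across littermates (non-independent rows)"
  class(edges) <- c("assoc_edges", "data.frame")
  edges
}

#' Summarize association edges
#'
#' Counts significant positive and negative correlations per variable and
#' cohort, and intersects the associated ASVs with the heritable set.
#'
#' @param edges result of [spearman_assoc()].
#' @param heritable character vector of heritable ASV ids (optional).
#' @return list with `counts` (variable x cohort x sign), `n_asvs`
#'   (distinct significant ASVs per cohort), and `heritable_overlap`.
#' @export
assoc_summary <- function(edges, heritable = NULL) {
  sig <- edges[!is.na(edges$significant) & edges$significant, , drop = FALSE]
  counts <- if (nrow(sig)) {
    as.data.frame(table(variable = sig$variable, cohort = sig$cohort,
                        sign = sig$sign))
  } else {
    data.frame(variable = character(0), cohort = character(0),
               sign = character(0), Freq = integer(0))
  }
  by_cohort <- lapply(split(sig$asv, sig$cohort), unique)
  overlap <- if (!is.null(heritable)) {
    lapply(by_cohort, function(ids) intersect(ids, heritable))
  } else NULL
  list(counts = counts,
       n_asvs = vapply(by_cohort, length, integer(1)),
       asvs = by_cohort,
       heritable_overlap = overlap)
}
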