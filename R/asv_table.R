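# ASV count table container and the filtering / transformation steps applied
# before any statistics: prevalence filter, rarefaction, relative abundance,
# log transform, taxonomy aggregation and group presence summaries.

#' Construct an ASV count table
#'
#' An `asv_table` holds non-negative integer counts of amplicon sequence
#' variants (ASVs) with samples as rows and ASVs as columns, plus an optional
#' taxonomy map giving a `;`-separated seven-rank lineage per ASV.
#'
#' @param counts numeric matrix (samples x ASVs) of non-negative finite
#'   counts with unique row and column names.
#' @param taxonomy optional named character vector, names are ASV ids,
#'   values are lineage strings such as
#'   `"Bacteria;Bacteroidota;Bacteroidia;Bacteroidales;Prevotellaceae;Prevotella"`.
#'   May cover only a subset of ASVs.
#' @return an object of class `asv_table` with elements `counts` and
#'   `taxonomy`.
#' @export
asv_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort("`counts` must be a numeric matrix (samples x ASVs)")
  }
  if (nrow(counts) == 0L) abort("no samples: `counts` has zero rows")
  if (ncol(counts) == 0L) abort("no ASVs: `counts` has zero columns")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must carry sample ids as rownames and ASV ids as colnames")
  }
  if (anyDuplicated(rownames(counts))) abort("duplicate sample ids in counts")
  if (anyDuplicated(colnames(counts))) abort("duplicate ASV ids in counts")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)[1L, ]
    abort(sprintf("counts must be finite and >= 0; offending cell sample '%s', ASV '%s'",
                  rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]))
  }
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy)) || !is.character(taxonomy)) {
      abort("`taxonomy` must be a named character vector (ASV id -> lineage)")
    }
    taxonomy <- taxonomy[names(taxonomy) %in% colnames(counts)]
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("ASV table: %d samples x %d ASVs (total %s reads)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  if (!is.null(x$taxonomy)) {
    cat(sprintf("taxonomy available for %d ASVs\n", length(x$taxonomy)))
  }
  invisible(x)
}

#' @export
dim.asv_table <- function(x) dim(x$counts)

#' Read and write ASV tables as TSV
#'
#' The on-disk format is a tab-separated table with a header row of ASV ids,
#' a first column `sample_id`, and one row per sample.  Taxonomy travels in a
#' separate two-column TSV (`asv`, `lineage`).  `write_asv_table()` followed
#' by `read_asv_table()` is the identity on the canonical form.
#'
#' @param path TSV file of counts.
#' @param taxonomy_path optional two-column TSV mapping ASV id to lineage.
#' @return `read_asv_table()` returns an [asv_table()];
#'   `write_asv_table()` invisibly returns `path`.
#' @export
read_asv_table <- function(path, taxonomy_path = NULL) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (nrow(raw) == 0L) abort("no samples in ", path)
  if (ncol(raw) < 2L) abort("no ASV columns in ", path)
  samples <- raw[[1L]]
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(mat), dim = dim(mat), dimnames = dimnames(mat)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    abort(sprintf("non-numeric count at sample '%s', ASV '%s'",
                  samples[bad[1L]], colnames(mat)[bad[2L]]))
  }
  rownames(num) <- samples
  taxonomy <- NULL
  if (!is.null(taxonomy_path)) {
    tx <- utils::read.delim(taxonomy_path, header = TRUE, sep = "\t",
                            colClasses = "character", check.names = FALSE)
    taxonomy <- stats::setNames(tx[[2L]], tx[[1L]])
  }
  asv_table(num, taxonomy)
}

#' @rdname read_asv_table
#' @param x an [asv_table()].
#' @export
write_asv_table <- function(x, path, taxonomy_path = NULL) {
  stopifnot(inherits(x, "asv_table"))
  df <- data.frame(sample_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(taxonomy_path) && !is.null(x$taxonomy)) {
    utils::write.table(
      data.frame(asv = names(x$taxonomy), lineage = unname(x$taxonomy)),
      taxonomy_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Filter ASVs by prevalence
#'
#' Removes rare or sparse ASVs: an ASV is retained when it is detected
#' (count > 0) in at least `min_fraction` of all samples.  The boundary is
#' inclusive — removal targets ASVs detected in *less than* the threshold
#' fraction of samples — so at the default 5% an ASV present in exactly 5%
#' of samples stays in.
#'
#' @param x an [asv_table()].
#' @param min_fraction minimum fraction of samples, in `(0, 1]`.
#' @return the filtered [asv_table()]; the sample set is unchanged.
#' @export
filter_prevalence <- function(x, min_fraction = 0.05) {
  stopifnot(inherits(x, "asv_table"))
  check_fraction(min_fraction, "min_fraction")
  prev <- colMeans(x$counts > 0)
  keep <- prev >= min_fraction
  asv_table(x$counts[, keep, drop = FALSE], x$taxonomy)
}

#' Rarefy samples to a common depth
#'
#' Randomly subsamples each sample's reads without replacement down to
#' `depth` sequences (one draw per sample).  Samples with fewer than `depth`
#' total reads cannot be rarefied and are dropped with a warning naming them.
#'
#' @param x an [asv_table()].
#' @param depth target number of sequences per sample (default 10,000).
#' @param seed optional integer seed making the draw reproducible.
#' @return an [asv_table()] whose every row sums to exactly `depth`.
#' @export
rarefy <- function(x, depth = 10000, seed = NULL) {
  stopifnot(inherits(x, "asv_table"))
  if (!is.numeric(depth) || length(depth) != 1L || depth < 1) {
    abort("`depth` must be a single integer >= 1")
  }
  totals <- rowSums(x$counts)
  low <- totals < depth
  if (all(low)) abort("all samples have fewer than `depth` sequences")
  if (any(low)) {
    warning(sprintf("dropping %d sample(s) below rarefaction depth %d: %s",
                    sum(low), depth,
                    paste(rownames(x$counts)[low], collapse = ", ")),
            call. = FALSE)
  }
  keep <- x$counts[!low, , drop = FALSE]
  # vegan warns about small totals even for genuine counts; our own
  # warnings above already cover the cases that matter
  rar <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(keep, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }))
  asv_table(rar, x$taxonomy)
}

#' Relative abundance and log transformation
#'
#' `relative_abundance()` converts counts to per-sample proportions (each
#' row sums to 1).  `log_transform()` applies the natural logarithm after
#' adding a pseudocount, yielding the log-transformed relative abundances
#' that the heritability model treats as the phenotype.
#'
#' @param x an [asv_table()] or a counts matrix.
#' @return a numeric matrix of identical shape.
#' @export
relative_abundance <- function(x) {
  counts <- if (inherits(x, "asv_table")) x$counts else x
  totals <- rowSums(counts)
  if (any(totals <= 0)) {
    abort("zero-total sample(s): ",
          paste(rownames(counts)[totals <= 0], collapse = ", "))
  }
  sweep(counts, 1L, totals, "/")
}

#' @rdname relative_abundance
#' @param proportions matrix of per-sample proportions.
#' @param pseudocount value added before taking logs (default `1e-6`).
#' @export
log_transform <- function(proportions, pseudocount = 1e-6) {
  if (!is.numeric(pseudocount) || pseudocount < 0) {
    abort("`pseudocount` must be >= 0")
  }
  log(proportions + pseudocount)
}

#' Shared and unique ASVs between groups
#'
#' Counts the ASVs detected only in one group, only in the other, and in
#' both — the numbers behind a two-set Venn diagram of dam versus lamb
#' communities.
#'
#' @param x an [asv_table()].
#' @param metadata a data.frame with columns `sample_id` and `group`.
#' @return a list with `only` (named counts per group), `shared`, and the
#'   underlying ASV id sets.
#' @export
group_presence_summary <- function(x, metadata) {
  stopifnot(inherits(x, "asv_table"))
  groups <- split(metadata$sample_id, metadata$group)
  if (length(groups) != 2L) abort("exactly two groups are required")
  present <- lapply(groups, function(s) {
    sub <- x$counts[rownames(x$counts) %in% s, , drop = FALSE]
    colnames(sub)[colSums(sub) > 0]
  })
  shared <- intersect(present[[1L]], present[[2L]])
  only <- vapply(seq_along(present), function(i) {
    length(setdiff(present[[i]], present[[-i + 3L]]))
  }, numeric(1))
  names(only) <- names(present)
  list(only = only, shared = length(shared),
       ids = c(present, list(shared = shared)))
}

# split a lineage string into named ranks, stripping Greengenes-style
# "x__" prefixes; unnamed/empty ranks come back NA
.tax_ranks <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")

parse_lineage <- function(lineage) {
  parts <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1L]])
  parts <- sub("^[a-zA-Z]__", "", parts)
  parts[parts == ""] <- NA_character_
  out <- rep(NA_character_, length(.tax_ranks))
  out[seq_len(min(length(parts), length(.tax_ranks)))] <-
    parts[seq_len(min(length(parts), length(.tax_ranks)))]
  names(out) <- .tax_ranks
  out
}

#' Aggregate relative abundances at a taxonomic rank
#'
#' Sums per-sample ASV proportions into the named rank; ASVs without a
#' lineage, or with an unassigned value at that rank, are pooled as
#' `"unclassified"`, so rank-level proportions still sum to each sample's
#' total.
#'
#' @param x an [asv_table()] with taxonomy.
#' @param rank one of kingdom, phylum, class, order, family, genus, species.
#' @return matrix of samples x taxa proportions.
#' @export
aggregate_taxonomy <- function(x, rank = "genus") {
  stopifnot(inherits(x, "asv_table"))
  if (!(rank %in% .tax_ranks)) {
    abort("unknown rank '", rank, "'; use one of: ",
          paste(.tax_ranks, collapse = ", "))
  }
  if (is.null(x$taxonomy)) abort("table has no taxonomy")
  prop <- relative_abundance(x)
  label <- vapply(colnames(prop), function(a) {
    lin <- x$taxonomy[a]
    if (is.na(lin) || is.null(lin)) return("unclassified")
    v <- parse_lineage(lin)[[rank]]
    if (is.na(v)) "unclassified" else v
  }, character(1))
  agg <- t(rowsum(t(prop), group = label))
  agg[, order(colnames(agg)), drop = FALSE]
}
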