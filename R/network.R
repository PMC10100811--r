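# Co-occurrence network construction, graph statistics, hub/keystone calls
# and MCODE cluster detection.

#' Build a thresholded co-occurrence network
#'
#' Keeps ASVs whose prevalence (fraction of samples with count > 0) exceeds
#' `prevalence_min`, then adds an undirected edge for every pair with
#' `|r| > r_threshold` and `p < p_threshold` (both strict).  Node
#' attributes: mean relative abundance, family (from taxonomy, when
#' available) and heritable flag; edge attributes: `r`, `p` and `sign`.
#'
#' @param result a [sparcc()] object or correlation matrix.
#' @param pvalues matrix from [sparcc_pvalues()].
#' @param counts the count matrix or [asv_table()] (for prevalence and
#'   mean abundance).
#' @param taxonomy optional named lineage vector (family is extracted).
#' @param heritable optional character vector of heritable ASV ids.
#' @param r_threshold,p_threshold,prevalence_min edge and node gates
#'   (defaults 0.5, 0.01, 0.20).
#' @param drop_isolated drop nodes with no retained edge (default TRUE).
#' @return an [igraph] graph (possibly empty).
#' @export
build_network <- function(result, pvalues, counts, taxonomy = NULL,
                          heritable = NULL, r_threshold = 0.5,
                          p_threshold = 0.01, prevalence_min = 0.20,
                          drop_isolated = TRUE) {
  if (inherits(counts, "asv_table")) {
    taxonomy <- taxonomy %||% counts$taxonomy
    counts <- counts$counts
  }
  r <- if (inherits(result, "sparcc")) result$r else result
  check_fraction(p_threshold, "p_threshold")
  if (r_threshold < 0 || r_threshold >= 1) abort("`r_threshold` must be in [0, 1)")
  check_fraction(prevalence_min, "prevalence_min", allow_zero = TRUE)

  prev <- colMeans(counts[, colnames(r), drop = FALSE] > 0)
  keep <- names(prev)[prev > prevalence_min]
  r <- r[keep, keep, drop = FALSE]
  p <- pvalues[keep, keep, drop = FALSE]

  adj <- abs(r) > r_threshold & p < p_threshold
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  edges <- data.frame(from = rownames(r)[idx[, 1L]],
                      to = colnames(r)[idx[, 2L]],
                      r = r[idx], p = p[idx],
                      sign = ifelse(r[idx] > 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  mean_ab <- colMeans(relative_abundance(counts))[keep]
  fam <- if (!is.null(taxonomy)) {
    vapply(keep, function(a) {
      lin <- taxonomy[a]
      if (is.na(lin) || is.null(lin)) return("unclassified")
      v <- parse_lineage(lin)[["family"]]
      if (is.na(v)) "unclassified" else v
    }, character(1))
  } else rep(NA_character_, length(keep))
  nodes <- data.frame(name = keep, mean_abundance = mean_ab, family = fam,
                      heritable = keep %in% (heritable %||% character(0)),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  if (drop_isolated) {
    g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  }
  g
}

#' Graph statistics, hub and keystone species
#'
#' Computes the average local clustering coefficient (nodes with degree < 2
#' contribute 0), average degree, density `2E / (N(N-1))`, and exact
#' unweighted betweenness centrality.  The hub is the node of highest
#' degree, the keystone the node of highest betweenness; ties are broken by
#' lexicographic ASV id and all tied ids are reported.
#'
#' @param g an igraph graph from [build_network()].
#' @return list with `n_nodes`, `n_edges`, `clustering_coefficient`,
#'   `average_degree`, `density`, `nodes` (per-node degree and
#'   betweenness), `hub`, `hub_ties`, `keystone`, `keystone_ties`.
#' @export
network_stats <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0L) abort("graph is empty")
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  local_cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  local_cc[is.na(local_cc)] <- 0
  nm <- igraph::V(g)$name
  pick <- function(v) sort(nm[v == max(v)])
  hubs <- pick(deg); keys <- pick(btw)
  ord <- order(nm)
  list(n_nodes = n, n_edges = igraph::ecount(g),
       clustering_coefficient = mean(local_cc),
       average_degree = mean(deg),
       density = if (n > 1) 2 * igraph::ecount(g) / (n * (n - 1)) else 0,
       nodes = data.frame(asv = nm, degree = as.numeric(deg),
                          betweenness = as.numeric(btw),
                          row.names = NULL)[ord, ],
       hub = hubs[1L], hub_ties = hubs,
       keystone = keys[1L], keystone_ties = keys)
}

# density of an igraph subgraph on >= 2 nodes (0 otherwise)
.subgraph_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2L) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' MCODE cluster detection
#'
#' Molecular complex detection on an undirected simple graph:
#' 1. *Node weighting* — each node's weight is the density of the highest
#'    k-core of its closed neighborhood (the core-clustering coefficient)
#'    multiplied by that core's k.
#' 2. *Complex prediction* — starting from the highest-weight unseen node,
#'    a breadth-first expansion includes neighbors whose weight is at least
#'    `(1 - node_score_cutoff)` times the seed weight, to at most
#'    `max_depth` steps from the seed; nodes join at most one complex.
#' 3. *Post-processing* — complexes that do not contain a `k_core` (a
#'    subgraph of minimum degree `k_core`) are discarded; haircut and fluff
#'    are off.  Each cluster's score is its density times its size, and
#'    clusters are returned in decreasing score order.
#'
#' @param g an igraph graph.
#' @param node_score_cutoff weight tolerance for expansion (default 0.2).
#' @param k_core minimum core a complex must contain (default 2).
#' @param max_depth maximum BFS depth from the seed (default 100).
#' @return list of clusters, each `list(members, size, density, score)`,
#'   ranked by decreasing score; empty list for an empty graph or a graph
#'   with no qualifying core (e.g. a tree with `k_core = 2`).
#' @export
mcode <- function(g, node_score_cutoff = 0.2, k_core = 2, max_depth = 100) {
  n <- igraph::vcount(g)
  if (n == 0L) return(list())
  nm <- igraph::V(g)$name %||% as.character(seq_len(n))

  w <- vapply(seq_len(n), function(v) {
    nb <- c(v, as.integer(igraph::neighbors(g, v)))
    sub <- igraph::induced_subgraph(g, nb)
    cor_num <- igraph::coreness(sub)
    kmax <- max(cor_num)
    if (kmax == 0) return(0)
    core <- igraph::induced_subgraph(sub, which(cor_num >= kmax))
    kmax * .subgraph_density(core)
  }, numeric(1))

  seen <- rep(FALSE, n)
  clusters <- list()
  for (seed in order(-w, nm)) {
    if (seen[seed] || w[seed] <= 0) next
    threshold <- w[seed] * (1 - node_score_cutoff)
    members <- integer(0)
    dq <- c(seed); dd <- c(0L)
    while (length(dq)) {
      v <- dq[1L]; dv <- dd[1L]
      dq <- dq[-1L]; dd <- dd[-1L]
      if (seen[v] || w[v] < threshold || dv > max_depth) next
      seen[v] <- TRUE
      members <- c(members, v)
      nbrs <- as.integer(igraph::neighbors(g, v))
      new <- nbrs[!seen[nbrs]]
      dq <- c(dq, new); dd <- c(dd, rep(dv + 1L, length(new)))
    }
    if (length(members) < 2L) next
    sub <- igraph::induced_subgraph(g, members)
    if (max(igraph::coreness(sub)) < k_core) next
    dens <- .subgraph_density(sub)
    clusters[[length(clusters) + 1L]] <-
      list(members = sort(nm[members]), size = length(members),
           density = dens, score = dens * length(members))
  }
  clusters[order(-vapply(clusters, `[[`, numeric(1), "score"))]
}

#' Export a network to GraphML and edge-list TSV
#'
#' @param g an igraph graph from [build_network()].
#' @param graphml_path,edges_path output paths (either may be `NULL`).
#' @return invisibly, the edge data.frame.
#' @export
export_network <- function(g, graphml_path = NULL, edges_path = NULL) {
  if (!is.null(graphml_path)) {
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  ed <- igraph::as_data_frame(g, what = "edges")
  if (!is.null(edges_path)) {
    utils::write.table(ed, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(ed)
}
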