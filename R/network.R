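#' Build a co-occurrence network from a correlation matrix
#'
#' Nodes are taxa whose total abundance is strictly greater than
#' `node_min_total`; an edge joins two nodes when the absolute correlation
#' is at least `edge_threshold`. Edge weight keeps the sign of the
#' correlation; strength is its magnitude.
#'
#' @param corr symmetric taxon-by-taxon correlation matrix (e.g. from
#'   [sparcc_correlations()]).
#' @param table the [otu_table()] the correlations came from (for the node
#'   abundance filter).
#' @param node_min_total node inclusion threshold on total abundance
#'   (strict >, default 10).
#' @param edge_threshold minimum |correlation| to keep an edge (default 0.3).
#' @return object of class `cooccurrence_network`: `nodes` (data.frame with
#'   `taxon`, `total_abundance`, and after [louvain_partition()] also
#'   `community` and `degree_centrality`), `edges` (data.frame `from`, `to`,
#'   `weight`, `sign`, `strength`), and `graph` (an igraph object).
#' @export
build_cooccurrence_network <- function(corr, table, node_min_total = 10,
                                       edge_threshold = 0.3) {
  corr <- as.matrix(corr)
  if (max(abs(corr - t(corr))) > 1e-8) stop("'corr' must be symmetric")
  counts <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  tot <- rowSums(counts)
  keep <- names(tot)[tot > node_min_total]
  keep <- intersect(rownames(corr), keep)
  if (!length(keep)) stop("no node passes the abundance filter")
  sub <- corr[keep, keep, drop = FALSE]
  idx <- which(upper.tri(sub) & abs(sub) >= edge_threshold, arr.ind = TRUE)
  edges <- data.frame(from = keep[idx[, 1]], to = keep[idx[, 2]],
                      weight = sub[idx],
                      sign = ifelse(sub[idx] >= 0, "positive", "negative"),
                      strength = abs(sub[idx]),
                      stringsAsFactors = FALSE)
  nodes <- data.frame(taxon = keep, total_abundance = unname(tot[keep]),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  n <- length(keep)
  deg <- igraph::degree(g)
  nodes$degree <- unname(deg[nodes$taxon])
  nodes$degree_centrality <- if (n > 1) nodes$degree / (n - 1) else 0
  structure(list(nodes = nodes, edges = edges, graph = g,
                 edge_threshold = edge_threshold,
                 node_min_total = node_min_total),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("Co-occurrence network:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges (|r| >=", x$edge_threshold, ")\n")
  if (!is.null(x$nodes$community))
    cat("Communities:", length(unique(x$nodes$community)),
        sprintf("(modularity Q = %.3f)\n", x$modularity))
  invisible(x)
}

#' Louvain community detection on the co-occurrence network
#'
#' Runs Louvain modularity maximisation on the |weight|-weighted graph and
#' attaches the community assignment and modularity Q to the network.
#' Deterministic under a fixed seed.
#'
#' @param network a [build_cooccurrence_network()] result with >= 1 edge.
#' @param resolution Louvain resolution parameter.
#' @param seed integer seed.
#' @return The network with `nodes$community` filled in and a `modularity`
#'   element.
#' @export
louvain_partition <- function(network, resolution = 1.0, seed = 1L) {
  stopifnot(inherits(network, "cooccurrence_network"))
  if (nrow(network$edges) == 0)
    stop("edgeless network: modularity undefined (m = 0)")
  w <- abs(igraph::E(network$graph)$weight)
  set.seed(seed)
  cl <- igraph::cluster_louvain(network$graph, weights = w,
                                resolution = resolution)
  memb <- igraph::membership(cl)
  network$nodes$community <- unname(memb[network$nodes$taxon])
  network$modularity <- igraph::modularity(network$graph, memb, weights = w)
  network
}

#' Representative species per community
#'
#' In each community the node with the highest degree is its representative
#' provided that node ranks within the global top `top_k` nodes by degree;
#' otherwise the community has no representative. Degree ties are broken by
#' lexicographically smaller species name.
#'
#' @param network network with communities (see [louvain_partition()]).
#' @param top_k global degree-rank cutoff (default 20).
#' @return data.frame with `community`, `representative` (NA when the
#'   community's best node is outside the global top `top_k`), `degree`.
#' @export
representative_species <- function(network, top_k = 20) {
  stopifnot(inherits(network, "cooccurrence_network"))
  nd <- network$nodes
  if (is.null(nd$community)) stop("run louvain_partition() first")
  ord <- order(-nd$degree, nd$taxon)
  top_set <- nd$taxon[utils::head(ord, top_k)]
  out <- do.call(rbind, lapply(sort(unique(nd$community)), function(cm) {
    sub <- nd[nd$community == cm, , drop = FALSE]
    sub <- sub[order(-sub$degree, sub$taxon), , drop = FALSE]
    best <- sub$taxon[1]
    data.frame(community = cm,
               representative = if (best %in% top_set) best else NA_character_,
               degree = sub$degree[1],
               stringsAsFactors = FALSE)
  }))
  out
}

#' Normalized degree-centrality difference between two networks
#'
#' The keystone screen: for every taxon in the union of the two node sets,
#' delta = centrality in the control network minus centrality in the case
#' network (degree/(n-1), each on its own network; absent taxa count 0).
#' Positive delta means the taxon is more influential among controls.
#' Outliers of the delta distribution are flagged by Tukey fences at
#' 1.5 x IQR (pluggable via `outlier_rule`).
#'
#' @param network_control,network_case two co-occurrence networks.
#' @param outlier_rule function taking the delta vector and returning a
#'   logical flag vector; default Tukey 1.5 IQR fences.
#' @return data.frame of class `centrality_delta`: `taxon`,
#'   `centrality_control`, `centrality_case`, `delta`, `outlier`, sorted by
#'   descending delta.
#' @export
centrality_difference <- function(network_control, network_case,
                                  outlier_rule = tukey_outliers) {
  stopifnot(inherits(network_control, "cooccurrence_network"),
            inherits(network_case, "cooccurrence_network"))
  if (nrow(network_control$nodes) == 0 && nrow(network_case$nodes) == 0)
    stop("both networks are empty")
  cc <- stats::setNames(network_control$nodes$degree_centrality,
                        network_control$nodes$taxon)
  cd <- stats::setNames(network_case$nodes$degree_centrality,
                        network_case$nodes$taxon)
  taxa <- sort(union(names(cc), names(cd)))
  ctrl <- ifelse(taxa %in% names(cc), cc[taxa], 0)
  case <- ifelse(taxa %in% names(cd), cd[taxa], 0)
  delta <- ctrl - case
  out <- data.frame(taxon = taxa, centrality_control = unname(ctrl),
                    centrality_case = unname(case), delta = unname(delta),
                    outlier = outlier_rule(unname(delta)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$delta, out$taxon), ]
  rownames(out) <- NULL
  class(out) <- c("centrality_delta", "data.frame")
  out
}

#' Tukey-fence outlier flagging
#'
#' Flags values below Q1 - k IQR or above Q3 + k IQR.
#'
#' @param x numeric vector.
#' @param k fence multiplier (1.5 = the conventional inner fences).
#' @return logical vector.
#' @export
tukey_outliers <- function(x, k = 1.5) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  x < q[1] - k * iqr | x > q[2] + k * iqr
}

#' Export a network as edge-list TSV and GraphML
#'
#' @param network a co-occurrence network.
#' @param edge_tsv,graphml output paths (either may be NULL to skip).
#' @return invisibly, the paths written.
#' @export
write_network <- function(network, edge_tsv = NULL, graphml = NULL) {
  stopifnot(inherits(network, "cooccurrence_network"))
  if (!is.null(edge_tsv))
    utils::write.table(network$edges[, c("from", "to", "weight", "sign")],
                       edge_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(graphml))
    igraph::write_graph(network$graph, graphml, format = "graphml")
  invisible(c(edge_tsv, graphml))
}
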