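# Per-node graph metrics on a term's interaction network and the
# topological gene weight with its zero-substitution rules.

#' Compute the six per-node metrics of an interaction network
#'
#' Builds the undirected, unweighted simple graph of an edge table (scores
#' only gate edge membership) and computes, for every node:
#' \describe{
#'   \item{bc}{betweenness centrality, unnormalized shortest-path pair
#'     counts}
#'   \item{cce}{closeness centrality, normalized within the node's connected
#'     component: (V-1) / sum of distances}
#'   \item{nc}{neighborhood connectivity: mean degree of the node's
#'     neighbors}
#'   \item{cco}{local clustering coefficient; nodes with fewer than two
#'     neighbors score 0}
#'   \item{avp}{average shortest-path length to the other nodes of the
#'     component}
#'   \item{v}{number of vertices of the node's connected component}
#' }
#' Distance-based quantities are computed within connected components, so
#' all values are finite.
#'
#' @param edges data frame with columns `node1`, `node2` (e.g. from
#'   [read_string_interactions()] or [simulate_term_network()]).
#' @return data frame with columns `gene`, `degree`, `bc`, `cce`, `nc`,
#'   `cco`, `avp`, `v`, `component`, sorted by gene; empty (with a warning)
#'   for an empty edge table.
#' @export
compute_node_metrics <- function(edges) {
  empty <- data.frame(gene = character(0), degree = numeric(0),
                      bc = numeric(0), cce = numeric(0), nc = numeric(0),
                      cco = numeric(0), avp = numeric(0), v = numeric(0),
                      component = integer(0))
  if (!nrow(edges)) {
    warning("empty network: no metrics computed", call. = FALSE)
    return(empty)
  }
  g <- igraph::simplify(igraph::graph_from_data_frame(
    edges[, c("node1", "node2")], directed = FALSE))
  comp <- igraph::components(g)
  v <- comp$csize[comp$membership]
  deg <- igraph::degree(g)
  d <- igraph::distances(g)
  within <- outer(comp$membership, comp$membership, "==")
  dsum <- rowSums(ifelse(within, d, 0))
  avp <- ifelse(v > 1, dsum / (v - 1), 0)
  cce <- ifelse(v > 1, (v - 1) / dsum, 1)
  out <- data.frame(
    gene = igraph::V(g)$name,
    degree = as.numeric(deg),
    bc = as.numeric(igraph::betweenness(g, directed = FALSE,
                                        normalized = FALSE)),
    cce = as.numeric(cce),
    nc = as.numeric(igraph::knn(g)$knn),
    cco = as.numeric(igraph::transitivity(g, type = "local",
                                          isolates = "zero")),
    avp = as.numeric(avp),
    v = as.numeric(v),
    component = as.integer(comp$membership),
    stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Replace zero-valued BC, CCe or CCo by the network's smallest non-zero
#' value
#'
#' A node whose betweenness, closeness or clustering coefficient is exactly
#' zero would null the multiplicative part of the gene weight; each zero is
#' therefore replaced by the lowest non-zero value of that same metric in
#' the same network. When a metric is zero for every node, 1e-7 is used
#' instead (a value below any non-zero metric the networks produce).
#' `nc`, `avp` and `v` are never substituted. Idempotent.
#'
#' @param metrics data frame from [compute_node_metrics()] for one network.
#' @return `metrics` with zeros replaced and an added `substituted` column
#'   (comma-joined metric names, `""` when untouched). The replacement used
#'   per metric is attached as attribute `"substitution_log"`.
#' @export
substitute_zeros <- function(metrics) {
  subbed <- rep("", nrow(metrics))
  log_rows <- list()
  for (m in c("bc", "cce", "cco")) {
    z <- metrics[[m]] == 0
    if (!any(z)) next
    nz <- metrics[[m]][!z]
    repl <- if (length(nz)) min(nz) else 1e-7
    metrics[[m]][z] <- repl
    subbed[z] <- ifelse(nzchar(subbed[z]), paste(subbed[z], m, sep = ","), m)
    log_rows[[m]] <- data.frame(metric = m, n_substituted = sum(z),
                                replacement = repl)
  }
  metrics$substituted <- subbed
  attr(metrics, "substitution_log") <-
    if (length(log_rows)) do.call(rbind, c(log_rows, make.row.names = FALSE))
    else data.frame(metric = character(0), n_substituted = integer(0),
                    replacement = numeric(0))
  metrics
}

#' Topological gene weight
#'
#' Computes, per node,
#' \deqn{W = BC \cdot CCe \cdot \log_2(NC) \cdot CCo^2 - \log_2(V \cdot
#'   AVP)}
#' on metrics that have already passed [substitute_zeros()]. The first term
#' rewards nodes that relay many shortest paths, sit close to their
#' component, have well-connected neighbors and a cohesive neighborhood; the
#' subtracted term penalizes large, sparse components where high distances
#' make centrality cheap.
#'
#' @param metrics data frame from [substitute_zeros()].
#' @param term_id optional source term id recorded alongside each weight.
#' @return `metrics` with columns `w` and (when given) `term_id` appended.
#' @export
compute_weights <- function(metrics, term_id = NULL) {
  if (!nrow(metrics)) {
    metrics$w <- numeric(0)
    if (!is.null(term_id)) metrics$term_id <- character(0)
    return(metrics)
  }
  if (any(metrics$nc < 1))
    stop("neighborhood connectivity below 1: metrics must come from a ",
         "graph without isolated nodes", call. = FALSE)
  if (any(metrics$v * metrics$avp <= 0))
    stop("non-positive V*AVP: run compute_node_metrics() first",
         call. = FALSE)
  metrics$w <- metrics$bc * metrics$cce * log2(metrics$nc) *
    metrics$cco^2 - log2(metrics$v * metrics$avp)
  if (!is.null(term_id)) metrics$term_id <- term_id
  metrics
}

#' Score one term network end to end
#'
#' Convenience wrapper: [compute_node_metrics()], [substitute_zeros()],
#' [compute_weights()].
#'
#' @inheritParams compute_node_metrics
#' @param term_id source term id carried into the result.
#' @return per-node data frame with metrics, substitution flags and `w`.
#' @export
score_network <- function(edges, term_id = NULL) {
  compute_weights(substitute_zeros(compute_node_metrics(edges)), term_id)
}
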