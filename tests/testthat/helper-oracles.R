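# Independent brute-force oracles. These deliberately avoid igraph,
# fisher.test and p.adjust so they can cross-check the package's routes.

# ---- graphs ----------------------------------------------------------------

# adjacency matrix from a two-column edge data frame over given node names
adj_from_edges <- function(edges, nodes = sort(unique(c(edges$node1,
                                                        edges$node2)))) {
  n <- length(nodes)
  adj <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    a <- match(edges$node1[i], nodes)
    b <- match(edges$node2[i], nodes)
    adj[a, b] <- 1L
    adj[b, a] <- 1L
  }
  adj
}

# Floyd-Warshall all-pairs shortest distances
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# every shortest path s -> t, enumerated by DFS pruned with the distance
# matrix; returns a list of vertex index vectors
oracle_shortest_paths <- function(adj, d, s, t) {
  if (!is.finite(d[s, t])) return(list())
  paths <- list()
  walk <- function(path) {
    cur <- path[length(path)]
    if (cur == t) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    len <- length(path) - 1L
    for (nb in which(adj[cur, ] > 0)) {
      if (len + 1L + d[nb, t] == d[s, t]) walk(c(path, nb))
    }
  }
  walk(s)
  paths
}

# all six per-node metrics by explicit enumeration
oracle_metrics <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  deg <- rowSums(adj)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      paths <- oracle_shortest_paths(adj, d, s, t)
      if (!length(paths)) next
      inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
      if (length(inner)) {
        counts <- tabulate(inner, nbins = n)
        bc <- bc + counts / length(paths)
      }
    }
  }
  v <- vapply(seq_len(n), function(i) sum(is.finite(d[i, ])), numeric(1))
  dsum <- vapply(seq_len(n), function(i) {
    sum(d[i, is.finite(d[i, ]) & seq_len(n) != i])
  }, numeric(1))
  avp <- ifelse(v > 1, dsum / (v - 1), 0)
  cce <- ifelse(v > 1, (v - 1) / dsum, 1)
  nc <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    if (!length(nb)) return(NA_real_)
    mean(deg[nb])
  }, numeric(1))
  cco <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in seq_len(k - 1)) {
      for (b in seq(a + 1, k)) links <- links + adj[nb[a], nb[b]]
    }
    links / choose(k, 2)
  }, numeric(1))
  data.frame(gene = rownames(adj), degree = as.numeric(deg), bc = bc,
             cce = cce, nc = nc, cco = cco, avp = avp, v = v,
             stringsAsFactors = FALSE)
}

# edge data frame (node1/node2/combined_score) from an adjacency matrix
edges_from_adj <- function(adj) {
  idx <- which(adj > 0 & upper.tri(adj), arr.ind = TRUE)
  data.frame(node1 = rownames(adj)[idx[, 1]],
             node2 = colnames(adj)[idx[, 2]],
             combined_score = rep(0.95, nrow(idx)),
             stringsAsFactors = FALSE)
}

graph_connected <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

# all connected graphs on n labeled nodes, reduced to one representative
# per isomorphism class (canonical form via igraph BLISS)
connected_graphs_up_to_iso <- function(n) {
  pairs <- t(utils::combn(n, 2))
  np <- nrow(pairs)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- list()
  for (mask in seq_len(2^np - 1)) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(np) - 1L)) != 0L)
    adj <- matrix(0L, n, n)
    for (e in sel) {
      adj[pairs[e, 1], pairs[e, 2]] <- 1L
      adj[pairs[e, 2], pairs[e, 1]] <- 1L
    }
    if (!graph_connected(adj)) next
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    perm <- igraph::canonical_permutation(g)$labeling
    cadj <- adj[order(perm), order(perm)]
    key <- paste(cadj[upper.tri(cadj)], collapse = "")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    rownames(adj) <- colnames(adj) <- sprintf("N%02d", seq_len(n))
    out[[length(out) + 1L]] <- adj
  }
  out
}

random_connected_adj <- function(n, p = 0.35) {
  repeat {
    adj <- matrix(0L, n, n)
    up <- which(upper.tri(adj))
    on <- up[stats::runif(length(up)) < p]
    adj[on] <- 1L
    adj <- adj + t(adj)
    if (graph_connected(adj)) {
      rownames(adj) <- colnames(adj) <- sprintf("N%02d", seq_len(n))
      return(adj)
    }
  }
}

# compare compute_node_metrics() against oracle_metrics() on one graph
expect_metrics_match_oracle <- function(adj, tol = 1e-10) {
  got <- compute_node_metrics(edges_from_adj(adj))
  want <- oracle_metrics(adj)
  want <- want[match(got$gene, want$gene), , drop = FALSE]
  for (col in c("degree", "bc", "cce", "nc", "cco", "avp", "v")) {
    expect_equal(got[[col]], want[[col]], tolerance = tol,
                 ignore_attr = TRUE,
                 label = paste0("metric '", col, "'"))
  }
}

# ---- statistics ------------------------------------------------------------

# two-sided Fisher exact p for the 2x2 table with margins (K in term, D
# differential, N universe) and overlap x: enumerate every table with these
# margins and sum the probabilities not exceeding the observed one (with
# the customary relative rounding guard)
oracle_fisher_p <- function(x, K, D, N) {
  lo <- max(0L, K + D - N)
  hi <- min(K, D)
  xs <- lo:hi
  p <- exp(lchoose(D, xs) + lchoose(N - D, K - xs) - lchoose(N, K))
  pobs <- p[xs == x]
  sum(p[p <= pobs * (1 + 1e-7)])
}

# hand step-up Benjamini-Hochberg with monotonicity enforcement
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  stepup <- p[o] * n / seq_len(n)
  stepup <- rev(cummin(rev(stepup)))
  out <- numeric(n)
  out[o] <- pmin(stepup, 1)
  out
}
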