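# Synthetic benchmark data with planted ground truth: DEG tables, term
# memberships with controlled enrichment, and interaction networks with
# planted hubs. Everything downstream can be exercised without a download.

#' Simulate a differential-expression table
#'
#' Generates `n_genes` unique symbols of which exactly
#' `round(frac_deg * n_genes)` are truly differential: their q-values are
#' uniform on \[0, 0.05) and their log2 fold changes are drawn from a
#' zero-mean normal with standard deviation `effect_sd`. The remaining
#' genes receive q-values uniform on \[0.05, 1\] and small background fold
#' changes (sd `effect_sd / 4`). q-values are generated directly rather
#' than through a count model: the pipeline consumes the table, never the
#' counts behind it.
#'
#' @param n_genes number of genes (at least 10).
#' @param frac_deg fraction of truly differential genes, in (0, 1);
#'   `frac_deg * n_genes` must be at least 1.
#' @param effect_sd standard deviation of the differential log2 fold
#'   changes.
#' @param seed integer RNG seed; identical calls reproduce identical
#'   tables.
#' @return list with `table` (data frame `gene`, `log2fc`, `qvalue`, sorted
#'   by gene) and `truth` (list `deg_genes`, `enriched_terms`,
#'   `planted_hubs`, `seed`).
#' @export
simulate_deg_table <- function(n_genes, frac_deg, effect_sd, seed) {
  if (!is.numeric(n_genes) || n_genes < 10)
    stop("n_genes must be at least 10", call. = FALSE)
  if (!is.numeric(frac_deg) || frac_deg <= 0 || frac_deg >= 1)
    stop("frac_deg must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(effect_sd) || effect_sd <= 0)
    stop("effect_sd must be positive", call. = FALSE)
  n_genes <- as.integer(n_genes)
  n_deg <- as.integer(round(frac_deg * n_genes))
  if (n_deg < 1) stop("frac_deg * n_genes must be at least 1", call. = FALSE)
  set.seed(as.integer(seed))
  gene <- sprintf("G%05d", seq_len(n_genes))
  is_deg <- rep(FALSE, n_genes)
  is_deg[sample.int(n_genes, n_deg)] <- TRUE
  q <- numeric(n_genes)
  q[is_deg] <- stats::runif(n_deg, 0, 0.05)
  q[!is_deg] <- stats::runif(n_genes - n_deg, 0.05, 1)
  lfc <- numeric(n_genes)
  lfc[is_deg] <- stats::rnorm(n_deg, 0, effect_sd)
  lfc[!is_deg] <- stats::rnorm(n_genes - n_deg, 0, effect_sd / 4)
  list(table = data.frame(gene = gene, log2fc = lfc, qvalue = q,
                          stringsAsFactors = FALSE),
       truth = list(deg_genes = gene[is_deg],
                    enriched_terms = character(0),
                    planted_hubs = list(),
                    seed = as.integer(seed)))
}

#' Simulate term memberships with controlled DEG enrichment
#'
#' Draws `n_terms` gene sets from the universe, sampling without
#' replacement with per-gene odds `enrichment_odds` for truly differential
#' genes in the first `n_enriched` terms (odds 1 elsewhere, so
#' `enrichment_odds = 1` yields null terms). A shallow parent-to-child
#' hierarchy is emitted by pairing terms: every second term of the first
#' `floor(n_terms / 2)` is redrawn as a subset of its predecessor, so the
#' deepest-child selection rule is exercised downstream.
#'
#' @param universe character vector of gene symbols.
#' @param n_terms number of terms to generate.
#' @param size_range integer pair: inclusive bounds on term size, within
#'   \[2, length(universe)\].
#' @param n_enriched number of terms with planted enrichment (at most
#'   `n_terms`).
#' @param enrichment_odds sampling-odds multiplier for differential genes
#'   inside enriched terms (1 = null).
#' @param truth ground-truth list from [simulate_deg_table()]; provides
#'   `deg_genes`.
#' @param seed integer RNG seed.
#' @return list with `terms` (named list of `term_set`, children filled),
#'   `hierarchy` (data frame `parent_id`, `child_id`) and `truth` with
#'   `enriched_terms` filled.
#' @export
simulate_annotation <- function(universe, n_terms, size_range,
                                n_enriched = 0, enrichment_odds = 1,
                                truth, seed) {
  if (!length(universe)) stop("empty gene universe", call. = FALSE)
  universe <- unique(universe)
  if (length(size_range) != 2 || size_range[1] < 2 ||
      size_range[2] > length(universe) || size_range[1] > size_range[2])
    stop("size_range must lie within [2, length(universe)]", call. = FALSE)
  if (n_enriched > n_terms)
    stop("n_enriched cannot exceed n_terms", call. = FALSE)
  if (enrichment_odds < 1)
    stop("enrichment_odds must be at least 1", call. = FALSE)
  set.seed(as.integer(seed))
  is_deg <- universe %in% truth$deg_genes
  ids <- sprintf("T%04d", seq_len(n_terms))
  enriched <- seq_len(n_terms) <= n_enriched
  terms <- vector("list", n_terms)
  for (i in seq_len(n_terms)) {
    size <- size_range[1] + sample.int(size_range[2] - size_range[1] + 1L,
                                       1L) - 1L
    odds <- if (enriched[i]) ifelse(is_deg, enrichment_odds, 1)
            else rep(1, length(universe))
    members <- sample(universe, size, prob = odds)
    terms[[i]] <- new_term_set(ids[i], paste("synthetic term", i),
                               sort(members))
  }
  names(terms) <- ids
  # Pair (1,2), (3,4), ... among the first half: the even term becomes a
  # subset of the odd one, giving parent -> child edges.
  n_pairs <- floor(n_terms / 4)
  hier <- list()
  for (j in seq_len(n_pairs)) {
    p <- 2L * j - 1L
    k <- 2L * j
    psize <- length(terms[[p]]$members)
    csize <- min(psize, max(size_range[1], ceiling(0.6 * psize)))
    terms[[k]]$members <- sort(sample(terms[[p]]$members, csize))
    enriched[k] <- enriched[k] || enriched[p]
    hier[[j]] <- data.frame(parent_id = ids[p], child_id = ids[k],
                            stringsAsFactors = FALSE)
  }
  hierarchy <- if (length(hier)) do.call(rbind, hier)
               else data.frame(parent_id = character(0),
                               child_id = character(0))
  terms <- attach_hierarchy(terms, hierarchy)
  truth$enriched_terms <- ids[enriched]
  list(terms = terms, hierarchy = hierarchy, truth = truth)
}

#' Simulate a term's interaction network with planted hubs
#'
#' Grows an undirected simple graph over a term's members by preferential
#' attachment: nodes arrive one at a time and attach
#' `max(1, round(mean_degree / 2))` edges to earlier nodes picked with
#' probability proportional to current degree plus a fitness mass. Planted
#' hubs are seeded first and carry fitness `hub_degree_factor * mean_degree`
#' (others 1), concentrating attachment on them and yielding a heavy-tailed
#' degree distribution with the hubs at its top. Each hub's neighborhood is
#' then partially closed into triangles (`hub_clique_prob` per neighbor
#' pair), emulating the dense complex-like neighborhoods of party hubs in
#' protein interaction networks; without this closure a preferential-
#' attachment hub has vanishing clustering and would not rank as
#' top-central under clustering-sensitive scores. Combined scores are drawn
#' uniform on \[0.900, 0.999\] — the pipeline thresholds, not weights,
#' edges.
#'
#' @param term a `term_set` (or plain list with `members`) with at least 3
#'   members.
#' @param mean_degree target mean degree of the network.
#' @param n_hubs number of planted hubs (strictly fewer than the members).
#' @param hub_degree_factor fitness multiplier for hubs (at least 1).
#' @param seed integer RNG seed.
#' @param hub_genes optional character vector naming which members become
#'   hubs (length `n_hubs`); sampled uniformly when `NULL`.
#' @param hub_clique_prob probability that a pair of a hub's neighbors is
#'   connected directly (triadic closure around hubs only).
#' @return list with `edges` (data frame `node1`, `node2`,
#'   `combined_score`) and `hubs` (character vector of planted hub genes).
#' @export
simulate_term_network <- function(term, mean_degree = 4, n_hubs = 0,
                                  hub_degree_factor = 1, seed,
                                  hub_genes = NULL, hub_clique_prob = 0.2) {
  members <- unique(term$members)
  n <- length(members)
  if (n < 3) stop("term must have at least 3 members", call. = FALSE)
  if (n_hubs >= n) stop("n_hubs must be smaller than the term", call. = FALSE)
  if (hub_degree_factor < 1)
    stop("hub_degree_factor must be at least 1", call. = FALSE)
  set.seed(as.integer(seed))
  if (is.null(hub_genes)) {
    hub_genes <- if (n_hubs > 0) sample(members, n_hubs) else character(0)
  } else {
    if (length(hub_genes) != n_hubs || !all(hub_genes %in% members))
      stop("hub_genes must be n_hubs members of the term", call. = FALSE)
  }
  m <- max(1L, as.integer(round(mean_degree / 2)))
  ord <- c(hub_genes, sample(setdiff(members, hub_genes)))
  fitness <- ifelse(ord %in% hub_genes, hub_degree_factor * mean_degree, 1)
  n_seed <- min(n, max(m + 1L, n_hubs + 1L, 2L))
  deg <- numeric(n)
  from <- integer(0)
  to <- integer(0)
  for (i in seq_len(n_seed - 1L)) {        # seed nodes form a path
    from <- c(from, i); to <- c(to, i + 1L)
    deg[i] <- deg[i] + 1; deg[i + 1L] <- deg[i + 1L] + 1
  }
  if (n > n_seed) {
    for (t in seq(n_seed + 1L, n)) {
      prev <- seq_len(t - 1L)
      mt <- min(m, t - 1L)
      targets <- sample(prev, mt, prob = deg[prev] + fitness[prev])
      from <- c(from, rep(t, mt)); to <- c(to, targets)
      deg[t] <- deg[t] + mt
      deg[targets] <- deg[targets] + 1
    }
  }
  if (n_hubs > 0 && hub_clique_prob > 0) {
    keys <- paste(pmin(from, to), pmax(from, to))
    for (h in seq_len(n_hubs)) {          # hubs occupy the first indices
      nb <- sort(unique(c(to[from == h], from[to == h])))
      if (length(nb) < 2) next
      pairs <- utils::combn(nb, 2)
      pk <- paste(pairs[1, ], pairs[2, ])
      add <- stats::runif(ncol(pairs)) < hub_clique_prob & !(pk %in% keys)
      if (any(add)) {
        from <- c(from, pairs[1, add])
        to <- c(to, pairs[2, add])
        keys <- c(keys, pk[add])
      }
    }
  }
  a <- ord[from]
  b <- ord[to]
  edges <- data.frame(node1 = pmin(a, b), node2 = pmax(a, b),
                      combined_score = round(stats::runif(length(a),
                                                          0.900, 0.999), 3),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$node1, edges$node2), , drop = FALSE]
  rownames(edges) <- NULL
  list(edges = edges, hubs = hub_genes)
}
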