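# Overrepresentation of DEGs within gene sets and the term-selection rules
# (significance, positive direction, size cap, deepest child).

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' the output order matches the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric", call. = FALSE)
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Fisher-exact overrepresentation of DEGs in gene sets
#'
#' For every term, the member genes are intersected with the universe and a
#' 2x2 contingency table (in term / not, differential / not) is tested with
#' Fisher's exact test. `expected` is the overlap size expected under
#' independence, `fold_enrichment` the observed/expected ratio, and
#' `direction` is `"positive"` when the observed overlap strictly exceeds
#' the expectation (ties count as negative: the overlap is not
#' over-represented). FDR values are BH-adjusted across all tested terms.
#'
#' @param deg_genes character vector of differential gene symbols (must be a
#'   subset of `universe`).
#' @param universe character vector of all tested gene symbols.
#' @param terms named list of `term_set` objects.
#' @param alternative `"two.sided"` (default) or `"greater"`; the direction
#'   label is computed from the counts either way.
#' @return data frame with one row per tested term, sorted by term id:
#'   `term_id`, `n_universe`, `n_term`, `n_deg`, `n_overlap`, `expected`,
#'   `fold_enrichment`, `direction`, `p_raw`, `fdr`. Terms disjoint from the
#'   universe are skipped with a warning.
#' @export
fisher_overrepresentation <- function(deg_genes, universe, terms,
                                      alternative = c("two.sided",
                                                      "greater")) {
  alternative <- match.arg(alternative)
  universe <- unique(toupper(universe))
  if (!length(universe)) stop("empty gene universe", call. = FALSE)
  deg_genes <- unique(toupper(deg_genes))
  stray <- setdiff(deg_genes, universe)
  if (length(stray))
    stop("DEG(s) absent from the universe: ",
         paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
  n_u <- length(universe)
  n_d <- length(deg_genes)
  ids <- sort(vapply(terms, `[[`, character(1), "term_id"))
  rows <- lapply(ids, function(id) {
    members <- intersect(terms[[id]]$members, universe)
    k <- length(members)
    if (k == 0) {
      warning("term ", id, " is disjoint from the universe; skipped",
              call. = FALSE)
      return(NULL)
    }
    x <- length(intersect(members, deg_genes))
    tab <- matrix(c(x, n_d - x, k - x, n_u - n_d - k + x), nrow = 2)
    p <- min(1, stats::fisher.test(tab, alternative = alternative)$p.value)
    expected <- n_d * k / n_u
    data.frame(term_id = id, n_universe = n_u, n_term = k, n_deg = n_d,
               n_overlap = x, expected = expected,
               fold_enrichment = if (expected > 0) x / expected else 0,
               direction = if (x > expected) "positive" else "negative",
               p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term_id = character(0), n_universe = integer(0),
                      n_term = integer(0), n_deg = integer(0),
                      n_overlap = integer(0), expected = numeric(0),
                      fold_enrichment = numeric(0), direction = character(0),
                      p_raw = numeric(0), fdr = numeric(0)))
  out$fdr <- bh_adjust(out$p_raw)
  rownames(out) <- NULL
  out
}

# All descendants (transitive children) per term id.
term_descendants <- function(terms) {
  kids <- lapply(terms, `[[`, "children")
  names(kids) <- vapply(terms, `[[`, character(1), "term_id")
  desc <- kids
  repeat {
    grown <- FALSE
    for (id in names(desc)) {
      expanded <- unique(c(desc[[id]],
                           unlist(desc[desc[[id]]], use.names = FALSE)))
      if (length(expanded) > length(desc[[id]])) {
        desc[[id]] <- expanded
        grown <- TRUE
      }
    }
    if (!grown) return(desc)
  }
}

#' Select terms for network analysis
#'
#' Applies the retention rules: FDR below `fdr_threshold`, positive
#' direction, term size at most `max_term_size` (networks above the size cap
#' cannot be built), and the deepest-child rule: a term is dropped when one
#' of its descendants in the hierarchy also passes the first three filters,
#' so only the most specific term of each significant branch is kept.
#'
#' @param results data frame from [fisher_overrepresentation()].
#' @param terms named list of `term_set` objects with `children` filled
#'   (possibly empty).
#' @param fdr_threshold significance cut on the BH-adjusted p (default
#'   0.05).
#' @param max_term_size maximum gene-set size for which a network is built
#'   (default 2000).
#' @return list with `retained` (sorted character vector of term ids) and
#'   `exclusions` (data frame `term_id`, `reason` with reasons `"fdr"`,
#'   `"direction"`, `"size"`, `"has_retained_descendant"`).
#' @export
select_terms <- function(results, terms, fdr_threshold = 0.05,
                         max_term_size = 2000) {
  if (!nrow(results))
    return(list(retained = character(0),
                exclusions = data.frame(term_id = character(0),
                                        reason = character(0))))
  reason <- rep(NA_character_, nrow(results))
  reason[is.na(reason) & results$fdr >= fdr_threshold] <- "fdr"
  reason[is.na(reason) & results$direction != "positive"] <- "direction"
  reason[is.na(reason) & results$n_term > max_term_size] <- "size"
  candidates <- results$term_id[is.na(reason)]
  desc <- term_descendants(terms)
  has_deeper <- vapply(candidates, function(id) {
    length(intersect(desc[[id]], candidates)) > 0
  }, logical(1))
  reason[results$term_id %in% candidates[has_deeper]] <-
    "has_retained_descendant"
  retained <- sort(candidates[!has_deeper])
  excl <- data.frame(term_id = results$term_id[!is.na(reason)],
                     reason = reason[!is.na(reason)],
                     stringsAsFactors = FALSE)
  excl <- excl[order(excl$term_id), , drop = FALSE]
  rownames(excl) <- NULL
  for (i in seq_len(nrow(excl)))
    message("term ", excl$term_id[i], " excluded (", excl$reason[i], ")")
  list(retained = retained, exclusions = excl)
}
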