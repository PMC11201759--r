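# Per-structure aggregation: resolve gene weights across ontology terms,
# fold-change and weight summaries, shared-gene tables, top-fraction
# ranking.

# Genes annotated to a category = union of its terms' members, intersected
# with the DEG table.
category_deg_genes <- function(cmap, terms, degs) {
  cats <- sort(unique(cmap$category))
  out <- lapply(cats, function(cat) {
    tids <- cmap$term_id[cmap$category == cat]
    members <- unique(unlist(lapply(terms[tids], `[[`, "members"),
                             use.names = FALSE))
    sort(intersect(members, degs$gene))
  })
  names(out) <- cats
  out
}

#' Resolve gene weights within structure categories
#'
#' A gene annotated to several ontology terms of the same structure keeps
#' its highest weight; the winning term is retained as provenance (ties go
#' to the lexicographically first term id). A gene present in terms of two
#' different categories appears in both, independently.
#'
#' @param weights data frame with columns `gene`, `term_id`, `w` (e.g.
#'   stacked [score_network()] results).
#' @param cmap category map: data frame with columns `category`,
#'   `term_id` covering every term id in `weights`.
#' @return data frame `category`, `gene`, `w`, `term_id`, sorted by
#'   category then gene.
#' @export
resolve_gene_weights <- function(weights, cmap) {
  missing <- setdiff(unique(weights$term_id), cmap$term_id)
  if (length(missing))
    stop("term(s) without a category: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- merge(weights[, c("gene", "term_id", "w")], cmap, by = "term_id")
  df <- df[order(df$category, df$gene, -df$w, df$term_id), , drop = FALSE]
  df <- df[!duplicated(df[, c("category", "gene")]), , drop = FALSE]
  out <- df[, c("category", "gene", "w", "term_id")]
  rownames(out) <- NULL
  out
}

#' Per-structure fold-change sums
#'
#' For every structure category, sums |log2fc|, the positive log2fc and the
#' negative log2fc over the distinct differential genes annotated to the
#' category's terms (a gene in several terms of one category is counted
#' once).
#'
#' @param degs DEG table (`gene`, `log2fc`, `qvalue`), already filtered at
#'   the q-threshold.
#' @param cmap category map (`category`, `term_id`).
#' @param terms named list of `term_set` objects.
#' @param contrast optional label recorded in the output.
#' @return data frame `category`, `contrast`, `sum_abs_fc`, `sum_pos_fc`,
#'   `sum_neg_fc`, `n_genes`, sorted by category.
#' @export
structure_fc_summary <- function(degs, cmap, terms, contrast = NA_character_) {
  sets <- category_deg_genes(cmap, terms, degs)
  fc <- degs$log2fc
  names(fc) <- degs$gene
  rows <- lapply(names(sets), function(cat) {
    x <- fc[sets[[cat]]]
    data.frame(category = cat, contrast = contrast,
               sum_abs_fc = sum(abs(x)),
               sum_pos_fc = sum(x[x > 0]),
               sum_neg_fc = sum(x[x < 0]),
               n_genes = length(x), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-structure weight and weighted fold-change means
#'
#' For every structure category, averages the resolved gene weights and the
#' signed products log2fc * w over the category's weight-bearing
#' differential genes. The product keeps the regulation sign while scaling
#' each gene by its topological importance. Categories without weighted
#' genes report `n_genes = 0` and `NA` means rather than silent zeros.
#'
#' @param degs DEG table (`gene`, `log2fc`, `qvalue`).
#' @param resolved resolved weights from [resolve_gene_weights()].
#' @param contrast optional label recorded in the output.
#' @return data frame `category`, `contrast`, `mean_weight`,
#'   `mean_weighted_fc`, `n_genes`, sorted by category.
#' @export
structure_weighted_summary <- function(degs, resolved,
                                       contrast = NA_character_) {
  fc <- degs$log2fc
  names(fc) <- degs$gene
  rows <- lapply(sort(unique(resolved$category)), function(cat) {
    sub <- resolved[resolved$category == cat & resolved$gene %in% degs$gene,
                    , drop = FALSE]
    if (!nrow(sub))
      return(data.frame(category = cat, contrast = contrast,
                        mean_weight = NA_real_,
                        mean_weighted_fc = NA_real_, n_genes = 0L,
                        stringsAsFactors = FALSE))
    data.frame(category = cat, contrast = contrast,
               mean_weight = mean(sub$w),
               mean_weighted_fc = mean(fc[sub$gene] * sub$w),
               n_genes = nrow(sub), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(category = character(0), contrast = character(0),
                      mean_weight = numeric(0),
                      mean_weighted_fc = numeric(0), n_genes = integer(0))
  rownames(out) <- NULL
  out
}

#' Differential genes shared among structures
#'
#' Tabulates, for every pair of structure categories, how many differential
#' genes their term memberships share, together with a per-gene record of
#' the categories containing it and its regulation sign — the data behind a
#' chord-style sharing diagram.
#'
#' @inheritParams structure_fc_summary
#' @return list with `matrix` (symmetric category-by-category counts;
#'   diagonal = category size) and `genes` (data frame `gene`,
#'   `categories` (comma-joined), `n_categories`, `sign` (`"up"`/`"down"`)).
#' @export
shared_deg_overlap <- function(cmap, terms, degs) {
  sets <- category_deg_genes(cmap, terms, degs)
  cats <- names(sets)
  mat <- matrix(0L, length(cats), length(cats),
                dimnames = list(cats, cats))
  for (i in seq_along(cats)) {
    for (j in seq_along(cats)) {
      mat[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  all_genes <- sort(unique(unlist(sets, use.names = FALSE)))
  fc <- degs$log2fc
  names(fc) <- degs$gene
  genes <- data.frame(
    gene = all_genes,
    categories = vapply(all_genes, function(g) {
      paste(cats[vapply(sets, function(s) g %in% s, logical(1))],
            collapse = ",")
    }, character(1)),
    n_categories = vapply(all_genes, function(g) {
      sum(vapply(sets, function(s) g %in% s, logical(1)))
    }, integer(1)),
    sign = ifelse(fc[all_genes] >= 0, "up", "down"),
    stringsAsFactors = FALSE)
  rownames(genes) <- NULL
  list(matrix = mat, genes = genes)
}

#' Top-fraction gene ranking per structure
#'
#' Sorts each category's resolved genes by weight (descending) and returns
#' the top `ceiling(fraction * n)` with their fold change and winning term.
#' Ties in weight are broken by larger |log2fc|, then by gene symbol, so the
#' ranking is invariant to input row order.
#'
#' @param resolved resolved weights from [resolve_gene_weights()].
#' @param degs DEG table providing the fold changes.
#' @param fraction fraction of each category's genes to keep, in (0, 1\]
#'   (default 0.1, the top 10 percent).
#' @return data frame `category`, `rank`, `gene`, `log2fc`, `w`,
#'   `term_id`.
#' @export
top_fraction <- function(resolved, degs, fraction = 0.1) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]", call. = FALSE)
  fc <- degs$log2fc
  names(fc) <- degs$gene
  rows <- lapply(sort(unique(resolved$category)), function(cat) {
    sub <- resolved[resolved$category == cat & resolved$gene %in% degs$gene,
                    , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    sub$log2fc <- fc[sub$gene]
    sub <- sub[order(-sub$w, -abs(sub$log2fc), sub$gene), , drop = FALSE]
    k <- ceiling(fraction * nrow(sub))
    sub <- sub[seq_len(k), , drop = FALSE]
    data.frame(category = cat, rank = seq_len(k), gene = sub$gene,
               log2fc = sub$log2fc, w = sub$w, term_id = sub$term_id,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(category = character(0), rank = integer(0),
                      gene = character(0), log2fc = numeric(0),
                      w = numeric(0), term_id = character(0))
  rownames(out) <- NULL
  out
}
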