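# Input/output for the three text formats the pipeline consumes
# (DE table, GMT + hierarchy, STRING edge table) and their writers.

parse_numeric <- function(x, col, path) {
  num <- suppressWarnings(as.numeric(x))
  bad <- is.na(num) & !is.na(x)
  if (any(bad)) {
    stop("non-numeric value '", x[which(bad)[1]], "' in column '", col,
         "' of ", path, " (line ", which(bad)[1] + 1L, ")", call. = FALSE)
  }
  num
}

#' Read a differential-expression table and keep significant genes
#'
#' Reads a tab-separated table with a header naming the gene-symbol, log2
#' fold-change and adjusted-p columns, and returns the records whose adjusted
#' p-value (q-value) is strictly below `q_threshold`. Rows with a missing
#' q-value are treated as not significant and dropped, matching DESeq2's
#' independent-filtering `NA` convention. Gene symbols are upper-cased so
#' that DE tables and STRING node names join on a common key.
#'
#' @param path path to a tab-separated file with a header row.
#' @param q_threshold keep records with q-value strictly below this
#'   (default 0.05).
#' @param gene_col,lfc_col,q_col column names for the gene symbol, the log2
#'   fold change and the BH-adjusted p-value.
#' @return a data frame with columns `gene`, `log2fc`, `qvalue`, sorted by
#'   gene symbol.
#' @seealso [read_gene_universe()] for the unfiltered symbol list.
#' @export
read_deg_table <- function(path, q_threshold = 0.05, gene_col = "gene",
                           lfc_col = "log2FoldChange", q_col = "padj") {
  if (!is.numeric(q_threshold) || length(q_threshold) != 1 || q_threshold <= 0)
    stop("q_threshold must be a single positive number", call. = FALSE)
  raw <- read_deg_raw(path, gene_col, lfc_col, q_col)
  keep <- !is.na(raw$qvalue) & raw$qvalue < q_threshold
  if (any(is.na(raw$log2fc[keep])))
    stop("missing log2 fold change for significant gene in ", path,
         call. = FALSE)
  message(sum(keep), " of ", nrow(raw), " genes retained at q < ", q_threshold)
  out <- raw[keep, , drop = FALSE]
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

read_deg_raw <- function(path, gene_col, lfc_col, q_col) {
  if (!file.exists(path)) stop("DE table not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""))
  for (col in c(gene_col, lfc_col, q_col)) {
    if (!col %in% names(raw))
      stop("missing column '", col, "' in ", path, call. = FALSE)
  }
  gene <- toupper(trimws(raw[[gene_col]]))
  if (any(is.na(gene) | gene == ""))
    stop("empty gene symbol in ", path, call. = FALSE)
  dup <- unique(gene[duplicated(gene)])
  if (length(dup))
    stop("duplicated gene symbol(s) in ", path, ": ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  q <- parse_numeric(raw[[q_col]], q_col, path)
  if (any(q < 0 | q > 1, na.rm = TRUE))
    stop("adjusted p-values outside [0,1] in ", path, call. = FALSE)
  data.frame(gene = gene,
             log2fc = parse_numeric(raw[[lfc_col]], lfc_col, path),
             qvalue = q, stringsAsFactors = FALSE)
}

#' Read the tested gene universe from a DE table
#'
#' Returns every gene symbol with a non-missing adjusted p-value, i.e. the
#' background list against which overrepresentation is tested.
#'
#' @inheritParams read_deg_table
#' @return sorted character vector of upper-cased gene symbols.
#' @export
read_gene_universe <- function(path, gene_col = "gene",
                               lfc_col = "log2FoldChange", q_col = "padj") {
  raw <- read_deg_raw(path, gene_col, lfc_col, q_col)
  sort(raw$gene[!is.na(raw$qvalue)])
}

#' Write a DEG table as tab-separated text
#'
#' @param deg data frame with columns `gene`, `log2fc`, `qvalue` (the layout
#'   produced by [simulate_deg_table()]).
#' @param path output path; columns are written as `gene`,
#'   `log2FoldChange`, `padj`.
#' @export
write_deg_table <- function(deg, path) {
  out <- data.frame(gene = deg$gene, log2FoldChange = deg$log2fc,
                    padj = deg$qvalue)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

new_term_set <- function(term_id, term_name, members,
                         children = character(0),
                         category = NA_character_) {
  structure(list(term_id = term_id, term_name = term_name,
                 members = members, children = children,
                 category = category),
            class = "term_set")
}

#' @export
print.term_set <- function(x, ...) {
  cat("<term_set> ", x$term_id, " (", x$term_name, "): ",
      length(x$members), " members, ", length(x$children), " children\n",
      sep = "")
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Each line holds at least three tab-separated fields: term id, term name,
#' then member gene symbols. Members are upper-cased and de-duplicated per
#' term.
#'
#' @param path path to a GMT file.
#' @return a named list of `term_set` objects (id, name, members, children,
#'   category), sorted by term id. Children are empty until
#'   [read_hierarchy()] fills them.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  terms <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line ", i, " has fewer than 3 tab-separated fields",
           call. = FALSE)
    id <- trimws(f[[1]])
    members <- unique(toupper(trimws(f[-(1:2)])))
    members <- members[nzchar(members)]
    if (!length(members))
      stop("term ", id, " has no members", call. = FALSE)
    ids[i] <- id
    terms[[i]] <- new_term_set(id, trimws(f[[2]]), members)
  }
  if (anyDuplicated(ids))
    stop("duplicated term id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(terms) <- ids
  terms[order(ids)]
}

#' Write gene sets in GMT format
#'
#' @param terms named list of `term_set` objects.
#' @param path output path.
#' @export
write_gmt <- function(terms, path) {
  lines <- vapply(terms, function(t) {
    paste(c(t$term_id, t$term_name, t$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a parent-to-child term hierarchy and attach it to term sets
#'
#' The file is a two-column tab-separated table with header
#' `parent_id`/`child_id`. Every id must exist in `terms`; the edge set must
#' be acyclic.
#'
#' @param path path to the hierarchy table.
#' @param terms named list of `term_set` objects from [read_gmt()].
#' @return `terms` with the `children` field filled.
#' @export
read_hierarchy <- function(path, terms) {
  if (!file.exists(path))
    stop("hierarchy file not found: ", path, call. = FALSE)
  edges <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                             colClasses = "character", check.names = FALSE)
  for (col in c("parent_id", "child_id")) {
    if (!col %in% names(edges))
      stop("missing column '", col, "' in ", path, call. = FALSE)
  }
  attach_hierarchy(terms, edges)
}

attach_hierarchy <- function(terms, edges) {
  if (!nrow(edges)) return(terms)
  ids <- c(edges$parent_id, edges$child_id)
  orphan <- setdiff(ids, names(terms))
  if (length(orphan))
    stop("hierarchy id(s) absent from the GMT: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  check_acyclic(edges)
  for (i in seq_len(nrow(edges))) {
    p <- edges$parent_id[i]
    terms[[p]]$children <- sort(unique(c(terms[[p]]$children,
                                         edges$child_id[i])))
  }
  terms
}

# Kahn-style elimination: a leftover node implies a directed cycle.
check_acyclic <- function(edges) {
  if (any(edges$parent_id == edges$child_id))
    stop("hierarchy contains a self-edge (cycle)", call. = FALSE)
  from <- edges$parent_id
  to <- edges$child_id
  repeat {
    leaf <- !(to %in% from)
    if (all(leaf)) return(invisible(TRUE))
    if (!any(leaf)) stop("hierarchy contains a cycle", call. = FALSE)
    from <- from[!leaf]
    to <- to[!leaf]
  }
}

#' Write a term hierarchy as two-column TSV
#'
#' @param edges data frame with columns `parent_id`, `child_id`.
#' @param path output path.
#' @export
write_hierarchy <- function(edges, path) {
  utils::write.table(edges[, c("parent_id", "child_id")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a STRING-style interaction table and threshold it
#'
#' Parses the tab-separated `string_interactions.tsv` dialect (columns
#' `#node1`, `node2`, `combined_score`; extra columns ignored), drops edges
#' whose combined score falls below `score_threshold`, removes self-loops
#' (with a warning) and de-duplicates undirected pairs keeping the highest
#' score. Node symbols are upper-cased.
#'
#' @param path path to the edge table.
#' @param score_threshold minimum combined score to keep an edge; the
#'   default 0.9 is STRING's "highest confidence" cut.
#' @return data frame with columns `node1`, `node2`, `combined_score`,
#'   sorted by node pair; `node1 < node2` within each row.
#' @export
read_string_interactions <- function(path, score_threshold = 0.9) {
  if (!file.exists(path))
    stop("interaction file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "")
  names(raw) <- sub("^#", "", names(raw))
  for (col in c("node1", "node2", "combined_score")) {
    if (!col %in% names(raw))
      stop("missing column '", col, "' in ", path, call. = FALSE)
  }
  score <- parse_numeric(raw$combined_score, "combined_score", path)
  if (any(score < 0 | score > 1, na.rm = TRUE) || anyNA(score))
    stop("combined_score outside [0,1] in ", path, call. = FALSE)
  a <- toupper(trimws(raw$node1))
  b <- toupper(trimws(raw$node2))
  loops <- a == b
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped from ", path, call. = FALSE)
    a <- a[!loops]; b <- b[!loops]; score <- score[!loops]
  }
  keep <- score >= score_threshold
  a <- a[keep]; b <- b[keep]; score <- score[keep]
  n1 <- pmin(a, b)
  n2 <- pmax(a, b)
  edges <- data.frame(node1 = n1, node2 = n2, combined_score = score,
                      stringsAsFactors = FALSE)
  if (nrow(edges)) {
    key <- paste(edges$node1, edges$node2, sep = "\r")
    score_max <- tapply(edges$combined_score, key, max)
    edges <- edges[!duplicated(key), , drop = FALSE]
    edges$combined_score <- as.numeric(
      score_max[paste(edges$node1, edges$node2, sep = "\r")])
    edges <- edges[order(edges$node1, edges$node2), , drop = FALSE]
  }
  rownames(edges) <- NULL
  edges
}

#' Write an edge table in the STRING interaction dialect
#'
#' @param edges data frame with columns `node1`, `node2`, `combined_score`.
#' @param path output path; the header uses STRING's `#node1` spelling.
#' @export
write_string_interactions <- function(edges, path) {
  out <- data.frame(edges$node1, edges$node2, edges$combined_score)
  names(out) <- c("#node1", "node2", "combined_score")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a category map assigning ontology terms to subcellular structures
#'
#' Accepts either a two-column TSV (`category`, `term_id`) or a YAML mapping
#' of category name to a list of term ids. A term may belong to at most one
#' category.
#'
#' @param path path to the map.
#' @return data frame with columns `category`, `term_id`.
#' @export
read_category_map <- function(path) {
  if (!file.exists(path))
    stop("category map not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    lst <- yaml::read_yaml(path)
    cmap <- data.frame(
      category = rep(names(lst), lengths(lst)),
      term_id = unlist(lst, use.names = FALSE),
      stringsAsFactors = FALSE)
  } else {
    cmap <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                              colClasses = "character", check.names = FALSE)
    for (col in c("category", "term_id")) {
      if (!col %in% names(cmap))
        stop("missing column '", col, "' in ", path, call. = FALSE)
    }
    cmap <- cmap[, c("category", "term_id")]
  }
  dup <- unique(cmap$term_id[duplicated(cmap$term_id)])
  if (length(dup))
    stop("term(s) assigned to more than one category: ",
         paste(dup, collapse = ", "), call. = FALSE)
  cmap <- cmap[order(cmap$category, cmap$term_id), , drop = FALSE]
  rownames(cmap) <- NULL
  cmap
}

#' Write a category map as TSV
#'
#' @param cmap data frame with columns `category`, `term_id`.
#' @param path output path.
#' @export
write_category_map <- function(cmap, path) {
  utils::write.table(cmap[, c("category", "term_id")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
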