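# Small in-code fixtures shared across tests.

# path graph A - B - C
p3_edges <- function() {
  data.frame(node1 = c("A", "B"), node2 = c("B", "C"),
             combined_score = c(0.95, 0.95), stringsAsFactors = FALSE)
}

# triangle A - B - C - A
k3_edges <- function() {
  data.frame(node1 = c("A", "A", "B"), node2 = c("B", "C", "C"),
             combined_score = rep(0.95, 3), stringsAsFactors = FALSE)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

toy_deg_file <- function() {
  write_lines_tmp(c(
    "gene\tlog2FoldChange\tpadj",
    "ga\t0.5\t0.01",
    "gb\t-1.2\t0.04",
    "gc\t0.3\t0.05",
    "gd\t2.0\t0.2",
    "ge\t-0.7\tNA"))
}

# fabricate an enrichment-result row for select_terms() contract tests
result_row <- function(term_id, fdr, direction, n_term) {
  data.frame(term_id = term_id, n_universe = 1000L, n_term = n_term,
             n_deg = 100L, n_overlap = 10L, expected = 5,
             fold_enrichment = 2, direction = direction, p_raw = fdr / 2,
             fdr = fdr, stringsAsFactors = FALSE)
}

term_list <- function(ids, children = list()) {
  terms <- lapply(ids, function(id) {
    degnet:::new_term_set(id, id, members = c("X1", "X2", "X3"))
  })
  names(terms) <- ids
  for (id in names(children)) terms[[id]]$children <- children[[id]]
  terms
}
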