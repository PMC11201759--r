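simple_cmap <- function() {
  data.frame(category = c("mito", "mito", "nucleus"),
             term_id = c("T1", "T2", "T3"), stringsAsFactors = FALSE)
}

simple_degs <- function() {
  data.frame(gene = c("A", "B", "C", "D"),
             log2fc = c(0.5, -0.3, 1.2, -2.0),
             qvalue = c(0.01, 0.02, 0.03, 0.04), stringsAsFactors = FALSE)
}

test_that("weights resolve to the per-category maximum with provenance", {
  weights <- data.frame(gene = c("A", "A", "B", "A"),
                        term_id = c("T1", "T2", "T1", "T3"),
                        w = c(1.2, 3.4, 2.0, 0.5))
  res <- resolve_gene_weights(weights, simple_cmap())
  expect_equal(res$w[res$category == "mito" & res$gene == "A"], 3.4)
  expect_equal(res$term_id[res$category == "mito" & res$gene == "A"], "T2")
  expect_equal(res$w[res$category == "mito" & res$gene == "B"], 2.0)
  # same gene in another category is kept independently
  expect_equal(res$w[res$category == "nucleus" & res$gene == "A"], 0.5)
  expect_error(resolve_gene_weights(
    data.frame(gene = "A", term_id = "TX", w = 1), simple_cmap()),
    "without a category")
})

test_that("fold-change sums count each category gene once", {
  terms <- term_list(c("T1", "T2", "T3"))
  terms$T1$members <- c("A", "B")
  terms$T2$members <- c("B", "ZZ")          # B shared within mito
  terms$T3$members <- c("C", "D", "NOTDEG")
  s <- structure_fc_summary(simple_degs(), simple_cmap(), terms, "c1")
  mito <- s[s$category == "mito", ]
  expect_equal(mito$sum_abs_fc, 0.8)
  expect_equal(mito$sum_pos_fc, 0.5)
  expect_equal(mito$sum_neg_fc, -0.3)
  expect_equal(mito$n_genes, 2)
  expect_equal(mito$sum_abs_fc, mito$sum_pos_fc - mito$sum_neg_fc)
  nuc <- s[s$category == "nucleus", ]
  expect_equal(nuc$n_genes, 2)
  expect_equal(nuc$sum_abs_fc, 3.2)

  # category whose terms hold no DEG sums to zero
  terms$T3$members <- "NOTDEG"
  s0 <- structure_fc_summary(simple_degs(), simple_cmap(), terms)
  expect_equal(s0$n_genes[s0$category == "nucleus"], 0)
  expect_equal(s0$sum_abs_fc[s0$category == "nucleus"], 0)
})

test_that("weighted summaries average w and fc * w, flagging empty categories", {
  degs <- data.frame(gene = c("A", "B"), log2fc = c(0.2, -0.2),
                     qvalue = c(0.01, 0.01))
  resolved <- data.frame(category = "mito", gene = c("A", "B"), w = c(5, 5),
                         term_id = "T1")
  s <- structure_weighted_summary(degs, resolved)
  expect_equal(s$mean_weight, 5)
  expect_equal(s$mean_weighted_fc, 0)            # symmetric fc cancel

  one <- structure_weighted_summary(degs[1, ], resolved[1, ])
  expect_equal(one$mean_weighted_fc, 1.0)        # 0.2 * 5

  # equal weights factor out of the mean
  degs2 <- data.frame(gene = c("A", "B"), log2fc = c(0.4, 1.0),
                      qvalue = c(0.01, 0.01))
  s2 <- structure_weighted_summary(degs2, resolved)
  expect_equal(s2$mean_weighted_fc, 5 * mean(degs2$log2fc))

  empty <- structure_weighted_summary(degs,
                                      resolved[resolved$gene == "ZZ", ])
  expect_equal(nrow(empty), 0)
  no_deg <- structure_weighted_summary(degs[0, ], resolved)
  expect_equal(no_deg$n_genes, 0L)
  expect_true(is.na(no_deg$mean_weight))
})

test_that("shared-DEG counts match brute-force set intersections", {
  terms <- term_list(c("T1", "T2", "T3"))
  terms$T1$members <- c("A", "B")
  terms$T2$members <- c("B", "C")
  terms$T3$members <- c("A", "B", "D")
  ov <- shared_deg_overlap(simple_cmap(), terms, simple_degs())
  expect_true(isSymmetric(ov$matrix))
  expect_equal(ov$matrix["mito", "nucleus"], 2L)   # {A, B}
  expect_equal(ov$matrix["mito", "mito"], 3L)
  expect_equal(ov$genes$categories[ov$genes$gene == "A"], "mito,nucleus")
  expect_equal(ov$genes$sign[ov$genes$gene == "D"], "down")

  # disjoint categories give zero off-diagonals
  terms$T3$members <- "D"
  ov0 <- shared_deg_overlap(simple_cmap(), terms, simple_degs())
  expect_equal(ov0$matrix["mito", "nucleus"], 0L)

  # randomized cross-check against direct set arithmetic
  sim <- simulate_deg_table(400, 0.3, 1, seed = 21)
  ann <- simulate_annotation(sim$table$gene, 6, c(20, 60),
                             truth = sim$truth, seed = 22)
  cmap <- data.frame(category = rep(c("c1", "c2", "c3"), each = 2),
                     term_id = names(ann$terms))
  degs <- sim$table[sim$table$qvalue < 0.05, ]
  ov2 <- shared_deg_overlap(cmap, ann$terms, degs)
  sets <- lapply(split(cmap$term_id, cmap$category), function(tids) {
    intersect(unique(unlist(lapply(ann$terms[tids], `[[`, "members"))),
              degs$gene)
  })
  for (a in names(sets)) {
    for (b in names(sets)) {
      expect_equal(ov2$matrix[a, b], length(intersect(sets[[a]], sets[[b]])))
    }
  }
})

test_that("top-fraction ranking uses ceiling and stable tie-breaks", {
  degs <- data.frame(gene = sprintf("G%d", 1:7),
                     log2fc = c(0.1, -0.2, 0.3, 0.4, 0.5, -0.6, 0.7),
                     qvalue = 0.01)
  resolved <- data.frame(category = "mito", gene = degs$gene,
                         w = c(7, 6, 5, 4, 3, 2, 1), term_id = "T1")
  top <- top_fraction(resolved, degs, 0.10)
  expect_equal(nrow(top), 1)                       # ceiling(0.7)
  expect_equal(top$gene, "G1")

  tie_degs <- data.frame(gene = c("A", "B", "C", "D"),
                         log2fc = c(0.1, 0.9, -1.5, 2), qvalue = 0.01)
  tie_res <- data.frame(category = "mito", gene = c("A", "B", "C", "D"),
                        w = c(9, 8, 8, 1), term_id = "T1")
  top2 <- top_fraction(tie_res, tie_degs, 0.5)
  expect_equal(top2$gene, c("A", "C"))             # tie at 8 -> larger |fc|

  all_of <- top_fraction(tie_res, tie_degs, 1.0)
  expect_equal(all_of$gene, c("A", "C", "B", "D"))
  expect_equal(all_of$rank, 1:4)
  expect_error(top_fraction(tie_res, tie_degs, 0), "\\(0, 1\\]")
})

test_that("aggregation outputs are invariant to input row order", {
  sim <- simulate_deg_table(300, 0.3, 1, seed = 31)
  ann <- simulate_annotation(sim$table$gene, 4, c(30, 60),
                             truth = sim$truth, seed = 32)
  cmap <- data.frame(category = rep(c("c1", "c2"), each = 2),
                     term_id = names(ann$terms))
  degs <- sim$table[sim$table$qvalue < 0.05, ]
  weights <- do.call(rbind, lapply(names(ann$terms), function(id) {
    net <- simulate_term_network(ann$terms[[id]], 4, 0, seed = 33)
    w <- score_network(net$edges, id)
    w[w$gene %in% degs$gene, c("gene", "term_id", "w")]
  }))
  set.seed(34)
  wperm <- weights[sample(nrow(weights)), ]
  dperm <- degs[sample(nrow(degs)), ]
  expect_equal(resolve_gene_weights(weights, cmap),
               resolve_gene_weights(wperm, cmap))
  expect_equal(structure_fc_summary(degs, cmap, ann$terms),
               structure_fc_summary(dperm, cmap, ann$terms))
  res <- resolve_gene_weights(weights, cmap)
  expect_equal(top_fraction(res, degs), top_fraction(res, dperm))

  # triangle inequality of the sums
  s <- structure_fc_summary(degs, cmap, ann$terms)
  expect_true(all(s$sum_abs_fc >= abs(s$sum_pos_fc + s$sum_neg_fc) - 1e-12))
})
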