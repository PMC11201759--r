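test_that("simulated DEG tables have the requested composition", {
  sim <- simulate_deg_table(1000, 0.1, 0.3, seed = 1)
  expect_equal(sum(sim$table$qvalue < 0.05), 100)
  expect_equal(sort(sim$truth$deg_genes),
               sort(sim$table$gene[sim$table$qvalue < 0.05]))
  expect_false(anyDuplicated(sim$table$gene) > 0)
  expect_true(all(sim$table$qvalue >= 0 & sim$table$qvalue <= 1))

  tiny <- simulate_deg_table(10, 0.1, 0.3, seed = 7)
  expect_equal(sum(tiny$table$qvalue < 0.05), 1)

  expect_identical(simulate_deg_table(300, 0.2, 0.5, seed = 42),
                   simulate_deg_table(300, 0.2, 0.5, seed = 42))
  expect_error(simulate_deg_table(5, 0.1, 0.3, 1), "at least 10")
  expect_error(simulate_deg_table(100, 1.2, 0.3, 1), "\\(0, 1\\)")
})

test_that("annotation respects term sizes, hierarchy and determinism", {
  sim <- simulate_deg_table(500, 0.1, 0.5, seed = 3)
  ann <- simulate_annotation(sim$table$gene, 3, c(5, 10), truth = sim$truth,
                             seed = 4)
  expect_length(ann$terms, 3)
  sizes <- lengths(lapply(ann$terms, `[[`, "members"))
  expect_true(all(sizes >= 5 & sizes <= 10))
  expect_true(all(unlist(lapply(ann$terms, `[[`, "members")) %in%
                    sim$table$gene))

  # hierarchy children are subsets of their parents
  ann2 <- simulate_annotation(sim$table$gene, 8, c(10, 30),
                              truth = sim$truth, seed = 5)
  expect_gt(nrow(ann2$hierarchy), 0)
  for (i in seq_len(nrow(ann2$hierarchy))) {
    p <- ann2$terms[[ann2$hierarchy$parent_id[i]]]
    k <- ann2$terms[[ann2$hierarchy$child_id[i]]]
    expect_true(all(k$members %in% p$members))
    expect_true(ann2$hierarchy$child_id[i] %in% p$children)
  }
  expect_identical(ann2,
                   simulate_annotation(sim$table$gene, 8, c(10, 30),
                                       truth = sim$truth, seed = 5))
  expect_error(simulate_annotation(character(0), 3, c(5, 10),
                                   truth = sim$truth, seed = 1),
               "empty")
})

test_that("null terms carry the universe DEG fraction, enriched terms exceed it", {
  sim <- simulate_deg_table(1000, 0.1, 0.5, seed = 10)
  # null: mean in-term DEG fraction matches 0.1 within binomial error
  ann <- simulate_annotation(sim$table$gene, 200, c(50, 50),
                             n_enriched = 0, enrichment_odds = 1,
                             truth = sim$truth, seed = 11)
  fracs <- vapply(ann$terms, function(t) {
    mean(t$members %in% sim$truth$deg_genes)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.1), 4 * sqrt(0.1 * 0.9 / (200 * 50)))

  # planted enrichment: in-term fraction exceeds 0.1 in >= 95% of replicates
  above <- 0
  for (s in 1:200) {
    one <- simulate_annotation(sim$table$gene, 1, c(200, 200),
                               n_enriched = 1, enrichment_odds = 10,
                               truth = sim$truth, seed = 1000 + s)
    frac <- mean(one$terms[[1]]$members %in% sim$truth$deg_genes)
    if (frac > 0.1) above <- above + 1
  }
  expect_gte(above / 200, 0.95)
})

test_that("simulated networks are simple, scored above 0.9 and deterministic", {
  members <- sprintf("M%02d", 1:50)
  null_net <- simulate_term_network(list(members = members), mean_degree = 2,
                                    n_hubs = 0, seed = 9)
  hub_net <- simulate_term_network(list(members = members), mean_degree = 2,
                                   n_hubs = 1, hub_degree_factor = 10,
                                   seed = 9)
  degree_of <- function(edges) table(c(edges$node1, edges$node2))
  hub_degree <- as.numeric(degree_of(hub_net$edges)[hub_net$hubs])
  expect_gt(hub_degree, max(degree_of(null_net$edges)))

  expect_true(all(hub_net$edges$combined_score >= 0.9))
  expect_false(any(hub_net$edges$node1 == hub_net$edges$node2))
  key <- paste(hub_net$edges$node1, hub_net$edges$node2)
  expect_false(anyDuplicated(key) > 0)

  tri <- simulate_term_network(list(members = c("A", "B", "C")),
                               mean_degree = 2, seed = 2)
  expect_lte(nrow(tri$edges), 3)

  expect_identical(simulate_term_network(list(members = members), 4, 2, 8,
                                         seed = 5),
                   simulate_term_network(list(members = members), 4, 2, 8,
                                         seed = 5))
  expect_error(simulate_term_network(list(members = c("A", "B", "C")),
                                     2, n_hubs = 3, seed = 1),
               "n_hubs")
})
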