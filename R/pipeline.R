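# End-to-end orchestration: dataset simulation to disk, configured
# pipeline runs, run manifest. Every stage is also exported on its own so
# any step can be rerun from the previous step's files.

default_categories <- c("nucleus", "mitochondria", "endoplasmic_reticulum",
                        "intracellular_complexes")

#' Write a full synthetic dataset to disk
#'
#' Simulates two differential-expression contrasts over one gene universe,
#' a term annotation with hierarchy, one interaction network per term with
#' hubs planted on differential members, and a category map cycling over
#' four subcellular structures. All files use the pipeline's input formats,
#' and the planted truth is written alongside as JSON. A ready-to-run
#' `config.yaml` is placed in `dir`.
#'
#' @param dir output directory (created if needed).
#' @param n_genes,frac_deg,effect_sd see [simulate_deg_table()].
#' @param n_terms,size_range,n_enriched,enrichment_odds see
#'   [simulate_annotation()].
#' @param mean_degree,n_hubs,hub_degree_factor see
#'   [simulate_term_network()]; hubs are drawn from each term's
#'   differential members of the primary contrast when possible.
#' @param n_categories number of structure categories (up to 4).
#' @param seed integer RNG seed for the whole dataset.
#' @return the run configuration (list), invisibly usable with
#'   [run_pipeline()].
#' @export
simulate_dataset <- function(dir, n_genes = 2000, frac_deg = 0.15,
                             effect_sd = 1, n_terms = 12,
                             size_range = c(40, 120), n_enriched = 8,
                             enrichment_odds = 6, mean_degree = 4,
                             n_hubs = 2, hub_degree_factor = 10,
                             n_categories = 4, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net_dir <- file.path(dir, "networks")
  dir.create(net_dir, showWarnings = FALSE)
  seed <- as.integer(seed)

  n_enriched <- min(n_enriched, n_terms)
  primary <- simulate_deg_table(n_genes, frac_deg, effect_sd, seed)
  secondary <- simulate_deg_table(n_genes, frac_deg, effect_sd, seed + 1L)
  ann <- simulate_annotation(primary$table$gene, n_terms, size_range,
                             n_enriched, enrichment_odds, primary$truth,
                             seed + 2L)
  truth <- ann$truth

  # full tables on disk; the pipeline reapplies the q-filter on read
  write_deg_table(primary$table, file.path(dir, "deg_contrast1.tsv"))
  write_deg_table(secondary$table, file.path(dir, "deg_contrast2.tsv"))
  write_gmt(ann$terms, file.path(dir, "terms.gmt"))
  write_hierarchy(ann$hierarchy, file.path(dir, "hierarchy.tsv"))

  for (i in seq_along(ann$terms)) {
    term <- ann$terms[[i]]
    deg_members <- intersect(term$members, truth$deg_genes)
    k <- min(n_hubs, length(deg_members), length(term$members) - 1L)
    hubs <- if (k > 0) sort(deg_members)[seq_len(k)] else NULL
    net <- simulate_term_network(term, mean_degree, k, hub_degree_factor,
                                 seed + 10L + i, hub_genes = hubs)
    write_string_interactions(net$edges,
                              file.path(net_dir,
                                        paste0(term$term_id, ".tsv")))
    truth$planted_hubs[[term$term_id]] <- net$hubs
  }

  cats <- default_categories[seq_len(min(n_categories, 4L))]
  cmap <- data.frame(category = rep_len(cats, n_terms),
                     term_id = names(ann$terms), stringsAsFactors = FALSE)
  write_category_map(cmap, file.path(dir, "category_map.tsv"))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  config <- list(
    de_tables = list(contrast1 = file.path(dir, "deg_contrast1.tsv"),
                     contrast2 = file.path(dir, "deg_contrast2.tsv")),
    gmt = file.path(dir, "terms.gmt"),
    hierarchy = file.path(dir, "hierarchy.tsv"),
    network_dir = net_dir,
    category_map = file.path(dir, "category_map.tsv"),
    output_dir = file.path(dir, "results"),
    q_threshold = 0.05, fdr_threshold = 0.05, max_term_size = 2000,
    score_threshold = 0.9, top_fraction = 0.1, seed = seed)
  yaml::write_yaml(config, file.path(dir, "config.yaml"))
  invisible(config)
}

#' Read a pipeline configuration from YAML
#'
#' @param path path to a YAML file as written by [simulate_dataset()].
#' @return configuration list for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  config <- yaml::read_yaml(path)
  validate_config(config)
}

validate_config <- function(config) {
  defaults <- list(q_threshold = 0.05, fdr_threshold = 0.05,
                   max_term_size = 2000, score_threshold = 0.9,
                   top_fraction = 0.1, hierarchy = NULL, seed = 1L)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  for (nm in c("de_tables", "gmt", "network_dir", "category_map",
               "output_dir")) {
    if (is.null(config[[nm]]))
      stop("config is missing '", nm, "'", call. = FALSE)
  }
  if (is.null(names(config$de_tables)) || any(!nzchar(names(config$de_tables))))
    stop("de_tables must be a named list of contrast -> path", call. = FALSE)
  paths <- c(unlist(config$de_tables), config$gmt, config$category_map,
             config$hierarchy)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!dir.exists(config$network_dir))
    stop("network directory not found: ", config$network_dir, call. = FALSE)
  stopifnot(config$q_threshold > 0, config$fdr_threshold > 0,
            config$max_term_size >= 1,
            config$score_threshold >= 0, config$score_threshold <= 1,
            config$top_fraction > 0, config$top_fraction <= 1)
  config
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full prioritization pipeline
#'
#' Executes the stages in order — read inputs, overrepresentation on the
#' first (primary) contrast, term selection, per-term network scoring,
#' per-structure aggregation for every contrast — and writes the result
#' tables plus a JSON manifest into `config$output_dir`. Reruns with the
#' same configuration produce byte-identical outputs.
#'
#' Output files: `enrichment.tsv` (all tested terms with retention status),
#' `metrics.tsv` (per-node metrics and weights for retained terms),
#' `structure_summary.tsv` (fold-change sums and weighted means per
#' category and contrast), `shared_degs.tsv` + `shared_genes.tsv`
#' (cross-structure sharing), `top_genes.tsv` (top-fraction ranking per
#' category and contrast) and `manifest.json` (configuration snapshot and
#' md5 checksums).
#'
#' @param config configuration list (see [simulate_dataset()]) or path to a
#'   YAML file.
#' @return list with the in-memory results (`enrichment`, `selection`,
#'   `metrics`, `summaries`, `shared`, `top_genes`, `manifest`),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  contrasts <- names(config$de_tables)
  primary <- contrasts[[1]]
  degs <- stage("read", {
    lapply(config$de_tables, read_deg_table,
           q_threshold = config$q_threshold)
  })
  universe <- stage("read", read_gene_universe(config$de_tables[[primary]]))
  terms <- stage("read", {
    t <- read_gmt(config$gmt)
    if (!is.null(config$hierarchy)) t <- read_hierarchy(config$hierarchy, t)
    t
  })
  cmap <- stage("read", read_category_map(config$category_map))

  enrichment <- stage("enrich", {
    fisher_overrepresentation(degs[[primary]]$gene, universe, terms)
  })
  selection <- stage("select", {
    select_terms(enrichment, terms, config$fdr_threshold,
                 config$max_term_size)
  })
  enrichment$retained <- enrichment$term_id %in% selection$retained
  enrichment$exclusion_reason <- ""
  idx <- match(selection$exclusions$term_id, enrichment$term_id)
  enrichment$exclusion_reason[idx] <- selection$exclusions$reason

  metrics <- stage("score", {
    scored <- lapply(selection$retained, function(id) {
      path <- file.path(config$network_dir, paste0(id, ".tsv"))
      if (!file.exists(path))
        stop("no network file for retained term ", id, call. = FALSE)
      edges <- read_string_interactions(path, config$score_threshold)
      score_network(edges, term_id = id)
    })
    out <- do.call(rbind, c(scored, make.row.names = FALSE))
    if (is.null(out))
      out <- data.frame(gene = character(0), degree = numeric(0),
                        bc = numeric(0), cce = numeric(0), nc = numeric(0),
                        cco = numeric(0), avp = numeric(0), v = numeric(0),
                        component = integer(0), substituted = character(0),
                        w = numeric(0), term_id = character(0))
    out
  })

  aggregated <- stage("aggregate", {
    cmap_used <- cmap[cmap$term_id %in% selection$retained, , drop = FALSE]
    weights <- metrics[, c("gene", "term_id", "w")]
    summaries <- list()
    tops <- list()
    shared <- list()
    for (ct in contrasts) {
      deg_ct <- degs[[ct]]
      resolved <- resolve_gene_weights(
        weights[weights$gene %in% deg_ct$gene, , drop = FALSE], cmap_used)
      fc_sum <- structure_fc_summary(deg_ct, cmap_used, terms, ct)
      w_sum <- structure_weighted_summary(deg_ct, resolved, ct)
      summaries[[ct]] <- merge(fc_sum,
                               w_sum[, c("category", "mean_weight",
                                         "mean_weighted_fc", "n_genes")],
                               by = "category",
                               suffixes = c("_annotated", "_weighted"))
      tops[[ct]] <- cbind(contrast = ct,
                          top_fraction(resolved, deg_ct,
                                       config$top_fraction))
      ov <- shared_deg_overlap(cmap_used, terms, deg_ct)
      pairs <- which(upper.tri(ov$matrix, diag = TRUE), arr.ind = TRUE)
      shared[[ct]] <- data.frame(
        contrast = ct,
        category_a = rownames(ov$matrix)[pairs[, 1]],
        category_b = colnames(ov$matrix)[pairs[, 2]],
        n_shared = ov$matrix[pairs], stringsAsFactors = FALSE)
      shared[[paste0(ct, "_genes")]] <- cbind(contrast = ct, ov$genes)
    }
    list(summaries = do.call(rbind, c(summaries, make.row.names = FALSE)),
         tops = do.call(rbind, c(tops, make.row.names = FALSE)),
         pairs = do.call(rbind, c(shared[contrasts],
                                  make.row.names = FALSE)),
         genes = do.call(rbind, c(shared[paste0(contrasts, "_genes")],
                                  make.row.names = FALSE)))
  })

  files <- stage("report", {
    f <- c(
      enrichment = write_tsv(enrichment, file.path(out_dir,
                                                   "enrichment.tsv")),
      metrics = write_tsv(metrics, file.path(out_dir, "metrics.tsv")),
      structure_summary = write_tsv(aggregated$summaries,
                                    file.path(out_dir,
                                              "structure_summary.tsv")),
      shared_degs = write_tsv(aggregated$pairs,
                              file.path(out_dir, "shared_degs.tsv")),
      shared_genes = write_tsv(aggregated$genes,
                               file.path(out_dir, "shared_genes.tsv")),
      top_genes = write_tsv(aggregated$tops,
                            file.path(out_dir, "top_genes.tsv")))
    f
  })

  manifest <- list(
    package = "degnet",
    version = as.character(utils::packageVersion("degnet")),
    config = config,
    weight_formula = "W = BC * CCe * log2(NC) * CCo^2 - log2(V * AVP)",
    n_retained_terms = length(selection$retained),
    retained_terms = selection$retained,
    input_md5 = as.list(tools::md5sum(
      sort(c(unlist(config$de_tables), config$gmt, config$category_map,
             config$hierarchy)))),
    output_md5 = as.list(tools::md5sum(sort(unname(files)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(enrichment = enrichment, selection = selection,
                 metrics = metrics, summaries = aggregated$summaries,
                 shared = aggregated, top_genes = aggregated$tops,
                 manifest = manifest))
}
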