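# End-to-end orchestration: abundance table -> relative abundance ->
# prevalence filter -> Spearman + FDR -> deconvolution -> RMT threshold ->
# signed network -> multi-resolution clusters, hierarchy, hubs, roles,
# negative edges, enrichment, DUF prediction, environment links.

#' Pipeline configuration
#'
#' Collects all tunable parameters with the study defaults: deconvolution
#' alpha = 1, beta = 0.99; edge FDR ceiling q_max = 0.05; prevalence filter
#' at 25 samples; clustering resolutions 1-15.
#'
#' @param abundance abundance matrix, or path to its TSV.
#' @param metadata optional metadata data.frame or TSV path.
#' @param env optional environment matrix or TSV path.
#' @param outdir optional output directory; when given, all artifacts are
#'   written there.
#' @param min_prevalence,min_abundance prevalence filter (see
#'   [classify_prevalence()]).
#' @param alpha,beta deconvolution parameters (see [deconvolve()]).
#' @param grid,test_alpha,min_eigen RMT scan parameters (see [rmt_scan()]).
#' @param threshold optional fixed similarity threshold; skips the RMT scan.
#' @param q_max edge FDR ceiling.
#' @param resolutions clustering resolutions for the hierarchy.
#' @param base_resolution resolution whose clustering drives hubs, roles,
#'   enrichment and prediction.
#' @param min_size dominant-cluster minimum size.
#' @param min_within DUF-candidate minimum within-cluster degree.
#' @param seed top-level seed; all stochastic stages draw sub-seeds from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(abundance, metadata = NULL, env = NULL,
                            outdir = NULL, min_prevalence = 25L,
                            min_abundance = 0, alpha = 1, beta = 0.99,
                            grid = seq(0.30, 0.99, by = 0.01),
                            test_alpha = 0.001, min_eigen = 100L,
                            threshold = NULL, q_max = 0.05,
                            resolutions = 1:15, base_resolution = 1,
                            min_size = 10L, min_within = 3L, seed = 1L) {
  cfg <- list(abundance = abundance, metadata = metadata, env = env,
              outdir = outdir, min_prevalence = as.integer(min_prevalence),
              min_abundance = min_abundance, alpha = alpha, beta = beta,
              grid = grid, test_alpha = test_alpha,
              min_eigen = as.integer(min_eigen), threshold = threshold,
              q_max = q_max, resolutions = resolutions,
              base_resolution = base_resolution,
              min_size = as.integer(min_size),
              min_within = as.integer(min_within), seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

resolve_abundance <- function(x) if (is.character(x)) read_abundance(x) else
  validate_abundance(x)

#' Run the full genetic-correlation-network pipeline
#'
#' Validates the configuration, executes every stage in order, and (when
#' `outdir` is set) writes the edge list, membership, hub, role, enrichment
#' and prediction tables plus a `summary.json` and a run log. Any stage
#' failure aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return list of all stage results, invisibly when writing to disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  ab <- stage("read_abundance", resolve_abundance(config$abundance))
  if (config$min_prevalence > ncol(ab))
    stopf("config error: min_prevalence (%d) exceeds n_samples (%d)",
          config$min_prevalence, ncol(ab))
  meta <- config$metadata
  if (is.character(meta)) meta <- stage("read_metadata", read_gene_metadata(meta))
  env <- config$env
  if (is.character(env)) env <- stage("read_env", read_env_table(env, ab))

  rel <- stage("relative_abundance", relative_abundance(ab))
  prev <- stage("classify_prevalence",
                classify_prevalence(rel, config$min_prevalence,
                                    config$min_abundance))
  kept <- stage("filter_prevalence", filter_prevalence(rel, prev))

  corr <- stage("spearman", spearman_matrix(kept))
  q <- stage("fdr", fdr_adjust(corr$p))
  drho <- stage("deconvolve",
                deconvolve(corr$rho, alpha = config$alpha, beta = config$beta))

  if (is.null(config$threshold)) {
    scan <- stage("rmt_scan",
                  rmt_scan(drho, grid = config$grid,
                           min_eigen = config$min_eigen,
                           test_alpha = config$test_alpha))
    threshold <- scan$chosen_threshold
  } else {
    scan <- NULL
    threshold <- config$threshold
  }

  net <- stage("build_network",
               build_network(drho, q, threshold, q_max = config$q_max,
                             prevalence = prev, metadata = meta))
  topo <- stage("topology", topology_summary(net))
  part <- stage("edge_partition", edge_partition(net))
  negs <- stage("negative_edges", negative_edge_summary(net))

  clusterings <- stage("multires_scan",
                       multires_scan(net, config$resolutions,
                                     seed = derive_seed(config$seed, 10L)))
  hier <- stage("hierarchy", build_hierarchy(clusterings))
  base_i <- match(config$base_resolution, config$resolutions)
  if (is.na(base_i)) stopf("base_resolution must be one of resolutions")
  base <- clusterings[[base_i]]
  dom <- stage("dominant_clusters", dominant_clusters(base, config$min_size))
  roles <- stage("node_roles", node_roles(net, base))
  hubs <- if (length(dom$dominant))
    stage("cluster_hubs", cluster_hubs(net, base, dom$dominant)) else NULL
  conn <- stage("inter_cluster_connectivity",
                inter_cluster_connectivity(net, base))

  enr <- pred <- NULL
  if (!is.null(meta) && length(dom$dominant)) {
    enr <- stage("enrichment", cluster_enrichment(base, meta, dom$dominant))
    pred <- stage("duf_prediction",
                  predict_duf_functions(net, base, roles, enr, dom$dominant,
                                        config$min_within, config$q_max))
  }
  envlinks <- NULL
  if (!is.null(env) && nrow(env) > 0)
    envlinks <- stage("env_links",
                      env_gene_links(env, kept, base, config$q_max))

  summary <- list(
    n_genes_input = nrow(ab), n_samples = ncol(ab),
    n_core = sum(prev$class == "core"),
    n_noncore = sum(prev$class == "noncore"),
    n_excluded = sum(prev$class == "excluded"),
    threshold = threshold,
    n_nodes = topo$n_nodes, n_edges = topo$n_edges,
    n_positive = topo$n_positive, n_negative = topo$n_negative,
    density = topo$density, clustering_coefficient = topo$clustering,
    diameter = topo$diameter, powerlaw_r2 = topo$powerlaw_r2,
    edge_partition = as.list(part),
    negative_class_counts = as.list(negs$class_counts),
    cluster_counts = setNames(
      vapply(clusterings, function(cl) length(unique(cl$membership)), 0L),
      paste0("R", config$resolutions)),
    n_dominant = length(dom$dominant), n_loose = length(dom$loose_nodes),
    n_hubs = if (!is.null(hubs)) nrow(hubs) else 0L,
    hub_roles = if (!is.null(hubs)) as.list(table(hubs$role)) else NULL,
    n_duf_predictions = if (!is.null(pred)) nrow(pred) else 0L,
    seed = config$seed)

  res <- list(config = config, abundance = ab, relative = rel,
              prevalence = prev, correlation = corr, q = q,
              deconvolved = drho, scan = scan, threshold = threshold,
              network = net, topology = topo, edge_partition = part,
              negative = negs, clusterings = clusterings, hierarchy = hier,
              base_clustering = base, dominant = dom, roles = roles,
              hubs = hubs, connectivity = conn, enrichment = enr,
              predictions = pred, env_links = envlinks, summary = summary)

  if (!is.null(config$outdir)) {
    write_run(res, config$outdir)
    return(invisible(res))
  }
  res
}

write_run <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- res$network
  el <- igraph::as_data_frame(net, what = "edges")
  write.table(el, file.path(dir, "edges.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  mem <- NULL
  for (cl in res$clusterings)
    mem <- rbind(mem, data.frame(gene = names(cl$membership),
                                 resolution = cl$resolution,
                                 cluster = unname(cl$membership)))
  write.table(mem, file.path(dir, "membership.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(res$roles, file.path(dir, "roles.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(res$hubs))
    write.table(res$hubs, file.path(dir, "hubs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(res$scan))
    write.table(res$scan$table, file.path(dir, "rmt_scan.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(res$enrichment))
    write.table(res$enrichment, file.path(dir, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(res$predictions))
    write.table(res$predictions, file.path(dir, "duf_predictions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$hierarchy$links))
    write.table(res$hierarchy$links, file.path(dir, "hierarchy_links.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$env_links))
    write.table(res$env_links$links, file.path(dir, "env_links.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  igraph::write_graph(net, file.path(dir, "network.graphml"),
                      format = "graphml")
  jsonlite::write_json(res$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- res$config
  cfg$abundance <- if (is.character(cfg$abundance)) cfg$abundance else
    "<in-memory matrix>"
  cfg$metadata <- if (is.character(cfg$metadata)) cfg$metadata else
    if (is.null(cfg$metadata)) NULL else "<in-memory table>"
  cfg$env <- if (is.character(cfg$env)) cfg$env else
    if (is.null(cfg$env)) NULL else "<in-memory table>"
  log <- c(sprintf("gcnet %s | R %s", as.character(utils::packageVersion("gcnet")),
                   paste(R.version$major, R.version$minor, sep = ".")),
           sprintf("seed: %d", cfg$seed),
           sprintf("config: %s",
                   jsonlite::toJSON(cfg[!vapply(cfg, is.null, TRUE)],
                                    auto_unbox = TRUE, digits = NA)))
  writeLines(log, file.path(dir, "run.log"))
  invisible(dir)
}

#' Render a human-readable report of a completed run
#'
#' Tables for the edge partition, the hub genes, the negative-edge classes,
#' the cluster hierarchy (indented tree of merges), and the DUF predictions.
#' Idempotent: regenerating from the same run gives identical text.
#'
#' @param res result list from [run_pipeline()].
#' @param file optional path; when `NULL`, the report is returned as a
#'   character vector.
#' @return character vector of report lines (invisibly when writing).
#' @export
report_run <- function(res, file = NULL) {
  s <- res$summary
  lines <- c(
    "== Genetic correlation network: run report ==",
    sprintf("Genes: %d input, %d core / %d non-core / %d excluded",
            s$n_genes_input, s$n_core, s$n_noncore, s$n_excluded),
    sprintf("Threshold: %.3f | Nodes: %d | Edges: %d (%d positive, %d negative)",
            s$threshold, s$n_nodes, s$n_edges, s$n_positive, s$n_negative),
    sprintf("Power-law R2 (log-log): %.3f | Clustering coeff: %.3f | Diameter: %d",
            s$powerlaw_r2, s$clustering_coefficient, s$diameter),
    "",
    "-- Edge partition by prevalence class --",
    sprintf("  core-core: %d | noncore-noncore: %d | core-noncore: %d",
            s$edge_partition$core_core, s$edge_partition$noncore_noncore,
            s$edge_partition$core_noncore),
    "",
    sprintf("-- Clusters: %d dominant (%d loose nodes) --", s$n_dominant,
            s$n_loose))
  if (!is.null(res$hubs) && nrow(res$hubs)) {
    lines <- c(lines, "", "-- Cluster hubs --",
               sprintf("  cluster %d: %s (degree %d, kw %d, kb %d, %s%s)",
                       res$hubs$cluster, res$hubs$gene, res$hubs$degree,
                       res$hubs$kw, res$hubs$kb, res$hubs$role,
                       ifelse(is.na(res$hubs$class), "",
                              paste0(", ", res$hubs$class))))
  }
  nc <- res$negative$class_counts
  lines <- c(lines, "", "-- Negative edges --",
             if (sum(nc) == 0) "  none" else
               sprintf("  n-n: %d | n-e: %d | e-e: %d", nc["n_n"], nc["n_e"],
                       nc["e_e"]))
  lines <- c(lines, "", "-- Cluster hierarchy (merges) --")
  mg <- res$hierarchy$merges
  lines <- c(lines, if (!nrow(mg)) "  flat (no merges)" else
    sprintf("  R=%g: clusters {%s} -> parent %d", mg$resolution_to,
            mg$children, mg$parent))
  if (!is.null(res$predictions)) {
    lines <- c(lines, "", "-- DUF function predictions --",
               if (!nrow(res$predictions)) "  none" else
                 sprintf("  %s (cluster %d, kw %d): %s",
                         res$predictions$gene, res$predictions$cluster,
                         res$predictions$kw, res$predictions$top_category))
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
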