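# Signed network construction and topology: edge rule (|rho| > threshold and
# FDR q < q_max), core/non-core subnetworks, degree/power-law summaries, the
# Erdos-Renyi null, and negative-edge analyses.

#' Build the signed genetic correlation network
#'
#' Creates an undirected edge between genes i and j iff
#' `|rho[i, j]| > threshold` and `q[i, j] < q_max`; the edge sign is the sign
#' of the correlation and its weight the correlation value. Genes with no
#' qualifying edge are not network nodes. Prevalence class and metadata
#' (category, DUF flag) are attached as vertex attributes when supplied.
#'
#' @param rho symmetric (deconvolved) correlation matrix with gene ids.
#' @param q symmetric FDR-adjusted p-value matrix of the same shape.
#' @param threshold similarity threshold in (0, 1).
#' @param q_max FDR ceiling for an edge.
#' @param prevalence optional data.frame from [classify_prevalence()].
#' @param metadata optional data.frame with gene, category, is_duf.
#' @return an [igraph::graph] with edge attributes `weight`, `sign` and graph
#'   attributes `threshold`, `q_max`.
#' @export
build_network <- function(rho, q, threshold, q_max = 0.05,
                          prevalence = NULL, metadata = NULL) {
  if (!identical(dim(rho), dim(q)))
    stopf("rho and q matrices must have the same shape")
  if (threshold <= 0 || threshold >= 1) stopf("threshold must lie in (0, 1)")
  ids <- rownames(rho)
  sel <- which(upper.tri(rho) & abs(rho) > threshold & q < q_max,
               arr.ind = TRUE)
  edges <- data.frame(
    from = ids[sel[, 1]], to = ids[sel[, 2]],
    weight = rho[sel], sign = ifelse(rho[sel] > 0, "+", "-"),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  if (!is.null(prevalence)) {
    cls <- setNames(prevalence$class, prevalence$gene)
    igraph::V(g)$class <- unname(cls[igraph::V(g)$name])
  }
  if (!is.null(metadata)) {
    cat <- setNames(metadata$category, metadata$gene)
    duf <- setNames(metadata$is_duf, metadata$gene)
    igraph::V(g)$category <- unname(cat[igraph::V(g)$name])
    igraph::V(g)$is_duf <- unname(duf[igraph::V(g)$name])
  }
  g$threshold <- threshold
  g$q_max <- q_max
  g
}

#' Induced subnetwork of a prevalence class
#'
#' @param net network from [build_network()].
#' @param class `"core"` or `"noncore"`; both endpoints must belong to it.
#' @return induced [igraph::graph].
#' @export
subnetwork_by_class <- function(net, class) {
  if (!class %in% c("core", "noncore")) stopf("unknown class '%s'", class)
  keep <- which(igraph::V(net)$class == class)
  igraph::induced_subgraph(net, keep)
}

#' Partition edges by endpoint prevalence classes
#'
#' @param net network with a `class` vertex attribute on every node.
#' @return named integer vector `core_core`, `noncore_noncore`,
#'   `core_noncore`; sums exactly to the edge count.
#' @export
edge_partition <- function(net) {
  cls <- igraph::V(net)$class
  if (is.null(cls) || anyNA(cls)) stopf("every node needs a prevalence class")
  ends <- igraph::ends(net, igraph::E(net), names = FALSE)
  a <- cls[ends[, 1]]; b <- cls[ends[, 2]]
  c(core_core = sum(a == "core" & b == "core"),
    noncore_noncore = sum(a == "noncore" & b == "noncore"),
    core_noncore = sum(a != b))
}

#' Topology summary of a signed network
#'
#' Density 2m/(n(n-1)); clustering coefficient as the mean local clustering
#' over nodes with degree >= 2 (global transitivity also reported);
#' diameter as the longest shortest path within the largest connected
#' component. Clustering and diameter treat edges as unsigned and unweighted.
#'
#' @param net non-empty network.
#' @return list of summary statistics, including the degree sequence and the
#'   power-law fit of its distribution (`NA` when fewer than 5 distinct
#'   degrees).
#' @export
topology_summary <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0) stopf("empty graph")
  m <- igraph::ecount(net)
  sgn <- igraph::E(net)$sign
  deg <- igraph::degree(net)
  local <- igraph::transitivity(net, type = "local", isolates = "NaN")
  local <- local[deg >= 2]
  comp <- igraph::components(net)
  giant <- igraph::induced_subgraph(
    net, which(comp$membership == which.max(comp$csize)))
  pl <- tryCatch(powerlaw_fit(deg), error = function(e) list(r2 = NA_real_,
                                                             slope = NA_real_))
  list(n_nodes = as.integer(n), n_edges = as.integer(m),
       n_positive = as.integer(sum(sgn == "+")),
       n_negative = as.integer(sum(sgn == "-")),
       density = if (n > 1) 2 * m / (n * (n - 1)) else NA_real_,
       clustering = mean(local, na.rm = TRUE),
       transitivity_global = igraph::transitivity(net, type = "global"),
       diameter = as.integer(igraph::diameter(giant, weights = NA)),
       degree = deg, powerlaw_r2 = pl$r2, powerlaw_slope = pl$slope)
}

#' Power-law fit of a degree distribution
#'
#' Least-squares line on (log10 k, log10 freq(k)) over degrees k >= 1 with
#' nonzero frequency. This is the scale-free diagnostic in log-log space; a
#' maximum-likelihood exponent via [igraph::fit_power_law()] is reported
#' alongside for comparison.
#'
#' @param degrees integer degree sequence with >= 5 distinct positive values.
#' @return list with `r2`, `slope`, `ml_alpha`.
#' @export
powerlaw_fit <- function(degrees) {
  tab <- table(degrees[degrees >= 1])
  k <- as.numeric(names(tab))
  f <- as.numeric(tab)
  if (length(k) < 5) stopf("need at least 5 distinct degrees (got %d)",
                           length(k))
  fit <- stats::lm(log10(f) ~ log10(k))
  ml <- tryCatch(igraph::fit_power_law(degrees[degrees >= 1])$alpha,
                 error = function(e) NA_real_)
  list(r2 = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2]),
       ml_alpha = ml)
}

#' Erdos-Renyi G(n, m) null network
#'
#' Uniform simple graph with exactly the observed numbers of vertices and
#' edges; its degree histogram is the binomial reference against which the
#' observed power-law distribution is judged non-random.
#'
#' @param n_nodes,n_edges size of the null graph.
#' @param seed integer RNG seed.
#' @return list with `graph` and `degree_hist` (a table).
#' @export
er_null <- function(n_nodes, n_edges, seed = 1L) {
  if (n_edges > n_nodes * (n_nodes - 1) / 2)
    stopf("n_edges exceeds the simple-graph maximum")
  set.seed(seed)
  g <- igraph::sample_gnm(n_nodes, n_edges)
  list(graph = g, degree_hist = table(igraph::degree(g)))
}

#' Negative-edge analysis
#'
#' Counts negative edges by endpoint prevalence class — noncore-noncore
#' (n-n), noncore-core (n-e), core-core (e-e) — and returns the per-gene
#' negative-degree table (descending), per-category counts of genes carrying
#' negative edges, and the negative-only subnetwork.
#'
#' @param net network from [build_network()] with class attributes.
#' @return list with `class_counts`, `negative_degree`, `category_counts`,
#'   `subnetwork`.
#' @export
negative_edge_summary <- function(net) {
  neg <- igraph::E(net)[igraph::E(net)$sign == "-"]
  counts <- c(n_n = 0L, n_e = 0L, e_e = 0L)
  ndeg <- setNames(integer(igraph::vcount(net)), igraph::V(net)$name)
  if (length(neg)) {
    ends <- igraph::ends(net, neg, names = FALSE)
    cls <- igraph::V(net)$class
    a <- cls[ends[, 1]]; b <- cls[ends[, 2]]
    counts["n_n"] <- sum(a == "noncore" & b == "noncore")
    counts["e_e"] <- sum(a == "core" & b == "core")
    counts["n_e"] <- length(neg) - counts["n_n"] - counts["e_e"]
    for (v in c(ends[, 1], ends[, 2])) ndeg[v] <- ndeg[v] + 1L
  }
  nd <- data.frame(gene = names(ndeg), negative_degree = as.integer(ndeg),
                   stringsAsFactors = FALSE)
  nd <- nd[order(-nd$negative_degree, nd$gene), ]
  rownames(nd) <- NULL
  cat <- igraph::V(net)$category
  cat_counts <- if (!is.null(cat)) {
    with_neg <- ndeg > 0
    table(cat[with_neg])
  } else table(character(0))
  sub <- igraph::subgraph_from_edges(net, neg, delete.vertices = TRUE)
  list(class_counts = counts, negative_degree = nd,
       category_counts = cat_counts, subnetwork = sub)
}

#' Wilcoxon rank-sum comparison of two samples
#'
#' Two-sided test with average ranks for ties: exact enumeration when the
#' pooled sample is small (<= 12) and tie-free, otherwise the normal
#' approximation with tie correction (via [stats::wilcox.test()]). Used for
#' comparing negative-connection counts between gene groups, whose degree
#' distributions are far from normal.
#'
#' @param x,y non-empty numeric vectors.
#' @return list with `statistic` (rank-sum W) and `p.value`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stopf("both samples must be non-empty")
  exact <- (length(x) + length(y) <= 12) && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       exact = exact)
}
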