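# Multi-resolution modularity clustering, the cluster hierarchy across
# resolutions, between-cluster connectivity, and hub / node-role
# classification.
#
# Resolution convention: larger resolution values R produce larger (more
# merged) clusters. Internally the modularity null-model multiplier is
# gamma = 1/R, so R = 1 is standard modularity and R = 15 merges strongly.

#' Detect clusters by multilevel modularity optimisation
#'
#' Louvain-style local moving and aggregation on the positive-edge,
#' unweighted graph (modularity is not defined for signed graphs; negative
#' edges are reattached for the role and negative-edge analyses).
#' Deterministic given `seed`.
#'
#' @param net network from [build_network()].
#' @param resolution resolution value R > 0; larger merges more (the
#'   null-model multiplier is `1/R`).
#' @param seed integer RNG seed.
#' @param n_restarts independent runs (different node orders); the
#'   partition with the highest modularity is kept. The greedy heuristic
#'   has local optima, especially at coarse resolutions.
#' @return object of class `gc_clustering`: list with `membership` (named
#'   integer), `resolution`, `modularity`, `seed`.
#' @export
detect_clusters <- function(net, resolution = 1, seed = 1L, n_restarts = 5L) {
  if (igraph::vcount(net) == 0) stopf("empty graph")
  if (resolution <= 0) stopf("resolution must be positive")
  pos <- igraph::delete_edges(net, igraph::E(net)[igraph::E(net)$sign == "-"])
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(derive_seed(seed, r))
    cl <- igraph::cluster_louvain(pos, weights = NA,
                                  resolution = 1 / resolution)
    mod <- max(cl$modularity)
    if (is.null(best) || mod > best$mod) best <- list(cl = cl, mod = mod)
  }
  mem <- igraph::membership(best$cl)
  structure(list(membership = setNames(as.integer(mem), names(mem)),
                 resolution = resolution,
                 modularity = best$mod,
                 seed = as.integer(seed)),
            class = "gc_clustering")
}

#' Dominant clusters and loose nodes
#'
#' A dominant cluster meets the minimum-size rule; all nodes of smaller
#' clusters are "loose wired".
#'
#' @param clustering a `gc_clustering`.
#' @param min_size minimum cluster size.
#' @return list with `dominant` (integer cluster ids) and `loose_nodes`
#'   (gene ids).
#' @export
dominant_clusters <- function(clustering, min_size = 10L) {
  sizes <- table(clustering$membership)
  dom <- as.integer(names(sizes)[sizes >= min_size])
  loose <- names(clustering$membership)[
    !clustering$membership %in% dom]
  list(dominant = dom, loose_nodes = loose)
}

#' Clusterings across a range of resolutions
#'
#' @param net network from [build_network()].
#' @param resolutions ascending resolution values.
#' @param seed base RNG seed (same seed policy at every resolution).
#' @return list of `gc_clustering`, one per resolution.
#' @export
multires_scan <- function(net, resolutions = 1:15, seed = 1L) {
  if (is.unsorted(resolutions, strictly = TRUE))
    stopf("resolutions must be ascending")
  lapply(resolutions, function(r) detect_clusters(net, r, seed = seed))
}

#' Cluster hierarchy from the combination pattern across resolutions
#'
#' The parent of cluster c at one level is the cluster at the next level
#' containing the plurality of c's nodes (ties broken by smallest cluster
#' id). A merge event is recorded whenever two or more children share a
#' parent.
#'
#' @param clusterings list of `gc_clustering` at ascending resolutions
#'   (>= 2 levels).
#' @return list with `links` (data.frame: resolution_from, cluster,
#'   resolution_to, parent) and `merges` (data.frame: resolution_to, parent,
#'   n_children, children as comma-joined ids).
#' @export
build_hierarchy <- function(clusterings) {
  if (length(clusterings) < 2) stopf("need at least 2 resolution levels")
  links <- NULL
  merges <- NULL
  for (t in seq_len(length(clusterings) - 1)) {
    lo <- clusterings[[t]]; hi <- clusterings[[t + 1]]
    if (!length(lo$membership) || !length(hi$membership))
      stopf("level with empty membership")
    parent_of <- integer(0)
    for (c_id in sort(unique(lo$membership))) {
      members <- names(lo$membership)[lo$membership == c_id]
      tab <- table(hi$membership[members])
      best <- max(tab)
      parent <- min(as.integer(names(tab)[tab == best]))
      parent_of[as.character(c_id)] <- parent
      links <- rbind(links, data.frame(
        resolution_from = lo$resolution, cluster = c_id,
        resolution_to = hi$resolution, parent = parent))
    }
    for (p in unique(parent_of)) {
      kids <- as.integer(names(parent_of)[parent_of == p])
      if (length(kids) >= 2)
        merges <- rbind(merges, data.frame(
          resolution_to = hi$resolution, parent = p,
          n_children = length(kids),
          children = paste(sort(kids), collapse = ",")))
    }
  }
  list(links = links,
       merges = merges %||% data.frame(resolution_to = numeric(0),
                                       parent = integer(0),
                                       n_children = integer(0),
                                       children = character(0)))
}

#' Between-cluster connectivity matrix
#'
#' Symmetric cluster-by-cluster matrix of edge counts: the diagonal holds
#' within-cluster edge counts, off-diagonal entries the total number of
#' connections between nodes of different clusters. The diagonal plus the
#' upper triangle sums to the network's edge count.
#'
#' @param net network from [build_network()].
#' @param clustering a `gc_clustering` covering the network's nodes.
#' @return integer matrix with cluster ids as dimnames.
#' @export
inter_cluster_connectivity <- function(net, clustering) {
  mem <- clustering$membership
  ids <- sort(unique(mem))
  k <- length(ids)
  idx <- setNames(seq_len(k), ids)
  m <- matrix(0L, k, k, dimnames = list(ids, ids))
  ends <- igraph::ends(net, igraph::E(net))
  for (e in seq_len(nrow(ends))) {
    a <- idx[as.character(mem[ends[e, 1]])]
    b <- idx[as.character(mem[ends[e, 2]])]
    m[a, b] <- m[a, b] + 1L
    if (a != b) m[b, a] <- m[b, a] + 1L
  }
  m
}

#' Within/between-cluster degrees and node roles
#'
#' `kw` counts edges to same-cluster nodes, `kb` edges to other clusters
#' (kw + kb = degree). A node with kb = 0 is an intra-cluster node; with
#' kb > 0, an inter-cluster node.
#'
#' @param net network from [build_network()].
#' @param clustering a `gc_clustering`.
#' @return data.frame: gene, cluster, degree, kw, kb, role.
#' @export
node_roles <- function(net, clustering) {
  mem <- clustering$membership
  nm <- igraph::V(net)$name
  kw <- setNames(integer(length(nm)), nm)
  kb <- kw
  ends <- igraph::ends(net, igraph::E(net))
  same <- mem[ends[, 1]] == mem[ends[, 2]]
  for (e in seq_len(nrow(ends))) {
    if (same[e]) {
      kw[ends[e, 1]] <- kw[ends[e, 1]] + 1L
      kw[ends[e, 2]] <- kw[ends[e, 2]] + 1L
    } else {
      kb[ends[e, 1]] <- kb[ends[e, 1]] + 1L
      kb[ends[e, 2]] <- kb[ends[e, 2]] + 1L
    }
  }
  data.frame(gene = nm, cluster = unname(mem[nm]),
             degree = as.integer(kw + kb), kw = as.integer(kw),
             kb = as.integer(kb),
             role = ifelse(kb == 0, "intra", "inter"),
             stringsAsFactors = FALSE)
}

#' Hub gene of every dominant cluster
#'
#' The hub is the member with the maximum total degree; ties are broken by
#' larger within-cluster degree, then lexicographic gene id. The hub table
#' carries within/between degrees, the intra/inter role, and — when the
#' network has them — prevalence class and DUF flag.
#'
#' @param net network from [build_network()].
#' @param clustering a `gc_clustering`.
#' @param dominant integer ids of dominant clusters (see
#'   [dominant_clusters()]).
#' @return data.frame with one row per dominant cluster.
#' @export
cluster_hubs <- function(net, clustering, dominant) {
  if (!length(dominant)) stopf("empty dominant cluster set")
  roles <- node_roles(net, clustering)
  cls <- igraph::V(net)$class
  duf <- igraph::V(net)$is_duf
  if (!is.null(cls)) names(cls) <- igraph::V(net)$name
  if (!is.null(duf)) names(duf) <- igraph::V(net)$name
  out <- NULL
  for (d in sort(dominant)) {
    rows <- roles[roles$cluster == d, ]
    rows <- rows[order(-rows$degree, -rows$kw, rows$gene), ]
    hub <- rows[1, ]
    hub$class <- if (!is.null(cls)) unname(cls[hub$gene]) else NA_character_
    hub$is_duf <- if (!is.null(duf)) unname(duf[hub$gene]) else NA
    out <- rbind(out, hub)
  }
  rownames(out) <- NULL
  out
}
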