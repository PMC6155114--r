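test_that("modularity clustering separates cliques and keeps wholes whole", {
  g <- make_two_cliques(5)
  cl <- detect_clusters(g, resolution = 1, seed = 1)
  expect_equal(length(unique(cl$membership)), 2)
  # the two clusters are exactly the cliques
  expect_equal(length(unique(cl$membership[1:5])), 1)
  expect_equal(length(unique(cl$membership[6:10])), 1)
  expect_false(cl$membership[1] == cl$membership[6])

  full <- igraph::make_full_graph(8)
  igraph::V(full)$name <- paste0("v", 1:8); igraph::E(full)$sign <- "+"
  expect_equal(length(unique(detect_clusters(full, 1, 1)$membership)), 1)
  expect_error(detect_clusters(full, resolution = 0), "positive")
  expect_error(detect_clusters(igraph::make_empty_graph(0), 1), "empty")
})

test_that("clustering recovers a planted partition", {
  skip_if_not_installed("mclust")
  for (s in 1:5) {
    net <- make_sbm_net(s)
    cl <- detect_clusters(net, resolution = 1, seed = s)
    ari <- mclust::adjustedRandIndex(cl$membership, rep(1:4, each = 25))
    expect_gte(ari, 0.9)
  }
})

test_that("dominant clusters partition nodes into dominant and loose", {
  cl <- structure(list(membership = setNames(
    rep(1:3, c(50, 12, 3)), paste0("g", 1:65)),
    resolution = 1, modularity = 0.5, seed = 1L),
    class = "gc_clustering")
  dom <- dominant_clusters(cl, min_size = 10)
  expect_equal(sort(dom$dominant), c(1L, 2L))
  expect_equal(length(dom$loose_nodes), 3)
  all_dom <- dominant_clusters(cl, min_size = 1)
  expect_equal(length(all_dom$dominant), 3)
  expect_equal(length(all_dom$loose_nodes), 0)
  # partition: dominant member count + loose = all nodes
  n_dom <- sum(cl$membership %in% dom$dominant)
  expect_equal(n_dom + length(dom$loose_nodes), 65)
})

test_that("multi-resolution scan returns one clustering per resolution", {
  net <- make_two_cliques(5)
  cls <- multires_scan(net, resolutions = c(1, 3, 5), seed = 2)
  expect_length(cls, 3)
  expect_equal(vapply(cls, function(x) x$resolution, 0), c(1, 3, 5))
  # a single clique is identical at every resolution
  full <- igraph::make_full_graph(6)
  igraph::V(full)$name <- paste0("v", 1:6); igraph::E(full)$sign <- "+"
  cls2 <- multires_scan(full, resolutions = c(1, 5, 15), seed = 1)
  for (cl in cls2) expect_equal(length(unique(cl$membership)), 1)
  expect_error(multires_scan(net, resolutions = c(3, 1)), "ascending")
})

test_that("hierarchy links every child to one parent and records merges", {
  mk <- function(mem, res) structure(
    list(membership = mem, resolution = res, modularity = 0, seed = 1L),
    class = "gc_clustering")
  nodes <- paste0("g", 1:12)
  fine <- setNames(rep(1:4, each = 3), nodes)
  # identical levels: identity links, no merges
  h0 <- build_hierarchy(list(mk(fine, 1), mk(fine, 2)))
  expect_equal(nrow(h0$merges), 0)
  expect_equal(h0$links$cluster, h0$links$parent)
  # planted nesting: 4 siblings collapse into 2 parents
  coarse <- setNames(rep(c(1L, 2L), each = 6), nodes)
  h <- build_hierarchy(list(mk(fine, 1), mk(coarse, 5)))
  expect_equal(nrow(h$merges), 2)
  expect_equal(sort(h$merges$children), c("1,2", "3,4"))
  expect_equal(h$merges$n_children, c(2L, 2L))
  # every child has exactly one parent
  expect_equal(nrow(h$links), 4)
  expect_false(anyDuplicated(h$links$cluster) > 0)
  expect_error(build_hierarchy(list(mk(fine, 1))), "2 resolution levels")
})

test_that("hierarchy ties break to the smallest parent id", {
  mk <- function(mem, res) structure(
    list(membership = mem, resolution = res, modularity = 0, seed = 1L),
    class = "gc_clustering")
  nodes <- paste0("g", 1:4)
  fine <- setNames(rep(1L, 4), nodes)            # one cluster of 4
  coarse <- setNames(c(2L, 2L, 7L, 7L), nodes)   # split half and half
  h <- build_hierarchy(list(mk(fine, 1), mk(coarse, 2)))
  expect_equal(h$links$parent, 2L)
})

test_that("inter-cluster connectivity conserves the edge count", {
  g <- make_two_cliques(5)
  cl <- detect_clusters(g, 1, seed = 1)
  m <- inter_cluster_connectivity(g, cl)
  expect_true(isSymmetric(m))
  expect_equal(sort(unname(diag(m))), c(10L, 10L))
  expect_equal(m[1, 2], 1L)
  expect_equal(sum(diag(m)) + sum(m[upper.tri(m)]), igraph::ecount(g))
  # conservation on a random planted net
  for (s in 1:3) {
    net <- make_sbm_net(s)
    cl <- detect_clusters(net, 1, seed = s)
    mm <- inter_cluster_connectivity(net, cl)
    expect_equal(sum(diag(mm)) + sum(mm[upper.tri(mm)]), igraph::ecount(net))
  }
})

test_that("node roles split degree into within and between parts", {
  g <- make_two_cliques(5)
  cl <- detect_clusters(g, 1, seed = 1)
  roles <- node_roles(g, cl)
  expect_equal(roles$degree, roles$kw + roles$kb)
  # handshake per class: kw sums to twice the within edges
  m <- inter_cluster_connectivity(g, cl)
  expect_equal(sum(roles$kw), 2 * sum(diag(m)))
  expect_equal(sum(roles$kb), 2 * sum(m[upper.tri(m)]))
  # the two bridge endpoints are inter; everyone else intra
  expect_equal(sum(roles$role == "inter"), 2)
  expect_true(all(roles$role[roles$kb == 0] == "intra"))
})

test_that("cluster hubs are the highest-degree members", {
  # a star inside one cluster: the centre is the hub
  star <- igraph::make_star(7, mode = "undirected")
  igraph::V(star)$name <- paste0("v", 1:7); igraph::E(star)$sign <- "+"
  cl <- structure(list(membership = setNames(rep(1L, 7), paste0("v", 1:7)),
                       resolution = 1, modularity = 0, seed = 1L),
                  class = "gc_clustering")
  hubs <- cluster_hubs(star, cl, dominant = 1L)
  expect_equal(nrow(hubs), 1)
  expect_equal(hubs$gene, "v1")
  expect_equal(hubs$degree, 6L)
  expect_error(cluster_hubs(star, cl, integer(0)), "empty dominant")
})

test_that("planted hubs carry the highest degree in their clusters", {
  rec <- c()
  for (s in 1:5) {
    spec <- synthetic_spec(n_clusters = 5, genes_per_cluster = 15,
                           n_background_genes = 20, frac_core = 1, seed = s)
    sn <- synth_net(spec, threshold = 0.7)
    cl <- detect_clusters(sn$net, 1, seed = s)
    dom <- dominant_clusters(cl, min_size = 10)
    hubs <- cluster_hubs(sn$net, cl, dom$dominant)
    expect_equal(nrow(hubs), length(dom$dominant))  # one hub per cluster
    tr <- sn$sim$truth$gene_cluster
    for (i in seq_len(nrow(hubs))) {
      members <- names(cl$membership)[cl$membership == hubs$cluster[i]]
      k <- majority_truth(members, tr)
      if (is.na(k)) next
      rec <- c(rec, hubs$gene[i] ==
                 sn$sim$truth$hubs[paste0("cluster_", k)])
    }
  }
  expect_gte(mean(rec), 0.8)
})

test_that("sibling clusters merge under their planted parents", {
  spec <- synthetic_spec(
    n_clusters = 4, genes_per_cluster = 15, n_background_genes = 0,
    frac_core = 1,
    nested_parents = list(list(clusters = c(1, 2), loading = 0.8),
                          list(clusters = c(3, 4), loading = 0.8)),
    seed = 1)
  sn <- synth_net(spec, threshold = 0.52, relative = FALSE)
  cls <- multires_scan(sn$net, resolutions = c(1, 15), seed = 1)
  h <- build_hierarchy(cls)
  expect_equal(nrow(h$merges), 2)
  expect_true(all(h$merges$n_children == 2))
  tr <- sn$sim$truth$gene_cluster
  mem1 <- cls[[1]]$membership
  for (i in 1:2) {
    kids <- as.integer(strsplit(h$merges$children[i], ",")[[1]])
    planted <- sort(vapply(kids, function(k)
      majority_truth(names(mem1)[mem1 == k], tr), 0L))
    expect_true(identical(planted, c(1L, 2L)) ||
                  identical(planted, c(3L, 4L)))
  }
})
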