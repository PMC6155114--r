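# Independent brute-force oracles and shared fixture builders.

# Spearman via the classic rank-difference formula (tie-free data only):
# rho = 1 - 6 * sum(d^2) / (n (n^2 - 1))
spearman_brute <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Benjamini-Hochberg step-up computed directly from its definition:
# q_(i) = min_{j >= i} m * p_(j) / j, clipped at 1, in original order.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Graph diameter by breadth-first search from every vertex (adjacency list).
bfs_diameter <- function(adj) {
  n <- length(adj)
  best <- 0
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
    best <- max(best, max(dist, na.rm = TRUE))
  }
  best
}

# Hypergeometric upper tail from its definition.
hyper_tail_brute <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# A planted-partition graph (4 x 25, p_in 0.5, p_out 0.02) as a signed net.
make_sbm_net <- function(seed, sizes = rep(25L, 4), p_in = 0.5, p_out = 0.02) {
  set.seed(seed)
  k <- length(sizes)
  pref <- matrix(p_out, k, k); diag(pref) <- p_in
  g <- igraph::sample_sbm(sum(sizes), pref.matrix = pref, block.sizes = sizes)
  igraph::V(g)$name <- sprintf("n%03d", seq_len(sum(sizes)))
  igraph::E(g)$sign <- "+"
  g
}

# Two c-cliques joined by a single bridge edge, as a signed net.
make_two_cliques <- function(c_size = 5) {
  g <- igraph::make_full_graph(c_size) +
    igraph::make_full_graph(c_size)
  g <- igraph::add_edges(g, c(1, c_size + 1))
  igraph::V(g)$name <- sprintf("v%02d", seq_len(2 * c_size))
  igraph::E(g)$sign <- "+"
  g
}

# Raw-Spearman network over a synthetic abundance run at a fixed threshold,
# used by the planted hub / negative-edge / DUF recovery tests.
synth_net <- function(spec, threshold, relative = TRUE, with_meta = FALSE) {
  sim <- generate_abundance(spec)
  tab <- if (relative) relative_abundance(sim$table) else sim$table
  co <- spearman_matrix(tab)
  q <- fdr_adjust(co$p)
  prev <- classify_prevalence(tab, min_prevalence = min(25L, ncol(tab)))
  meta <- if (with_meta) generate_metadata(spec, sim$truth) else NULL
  net <- build_network(co$rho, q, threshold, prevalence = prev,
                       metadata = meta$metadata)
  list(net = net, sim = sim, meta = meta, rho = co$rho, q = q, prev = prev)
}

# Majority planted cluster of a detected cluster's members.
majority_truth <- function(members, truth) {
  tt <- table(truth[members])
  if (!length(tt)) return(NA_integer_)
  as.integer(names(which.max(tt)))
}
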