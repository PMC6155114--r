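# Per-cluster functional enrichment, guilt-by-association function
# prediction for DUF genes, and environment-gene association.

#' Functional-category enrichment of dominant clusters
#'
#' Hypergeometric upper-tail test of the overlap between each dominant
#' cluster and each functional category, with BH adjustment across all
#' (cluster, category) pairs. The test universe is the set of network nodes;
#' DUF-flagged genes are excluded from both the category counts and the
#' universe (their labels are the quantity being predicted).
#'
#' @param clustering a `gc_clustering` over the network's nodes.
#' @param metadata data.frame with gene, category, is_duf.
#' @param dominant integer ids of dominant clusters.
#' @return data.frame: cluster, category, overlap, cluster_size,
#'   category_size, universe, p, q.
#' @export
cluster_enrichment <- function(clustering, metadata, dominant) {
  mem <- clustering$membership
  cat <- setNames(metadata$category, metadata$gene)
  duf <- setNames(metadata$is_duf, metadata$gene)
  genes <- names(mem)
  universe <- genes[!is.na(duf[genes]) & !duf[genes] & cat[genes] != ""]
  if (!length(universe)) stopf("no annotated genes in the network universe")
  N <- length(universe)
  cats <- unique(cat[universe])
  out <- NULL
  for (d in sort(dominant)) {
    members <- intersect(names(mem)[mem == d], universe)
    n_c <- length(members)
    if (n_c == 0) next
    for (cc in cats) {
      K <- sum(cat[universe] == cc)
      k <- sum(cat[members] == cc)
      p <- phyper(k - 1, K, N - K, n_c, lower.tail = FALSE)
      out <- rbind(out, data.frame(
        cluster = d, category = cc, overlap = k, cluster_size = n_c,
        category_size = K, universe = N, p = p, stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) stopf("no (cluster, category) pairs to test")
  out$q <- p.adjust(out$p, method = "BH")
  out[order(out$cluster, out$q), ]
}

#' Predict functions of DUF genes from their cluster context
#'
#' Candidates are DUF-flagged network nodes lying in a dominant cluster with
#' no between-cluster edges (kb = 0) and at least `min_within`
#' within-cluster edges — genes wired firmly into a single functional
#' module. The prediction is the cluster's significantly enriched categories
#' ranked by q, with the gene's annotated direct neighbours reported as
#' supporting evidence.
#'
#' @param net network from [build_network()] with `is_duf`/`category`
#'   attributes.
#' @param clustering a `gc_clustering`.
#' @param roles data.frame from [node_roles()].
#' @param enrichment data.frame from [cluster_enrichment()].
#' @param dominant integer ids of dominant clusters.
#' @param min_within minimum within-cluster degree for a candidate.
#' @param q_max enrichment significance ceiling.
#' @return data.frame: gene, cluster, kw, kb, top_category,
#'   predicted_categories (comma-joined, ascending q), annotated_neighbors.
#' @export
predict_duf_functions <- function(net, clustering, roles, enrichment,
                                  dominant, min_within = 3L, q_max = 0.05) {
  duf <- setNames(igraph::V(net)$is_duf, igraph::V(net)$name)
  cat <- setNames(igraph::V(net)$category, igraph::V(net)$name)
  cand <- roles[!is.na(duf[roles$gene]) & duf[roles$gene] &
                  roles$cluster %in% dominant &
                  roles$kb == 0 & roles$kw >= min_within, ]
  out <- NULL
  for (i in seq_len(nrow(cand))) {
    g <- cand$gene[i]; cl <- cand$cluster[i]
    enr <- enrichment[enrichment$cluster == cl & enrichment$q < q_max, ]
    enr <- enr[order(enr$q), ]
    nb <- names(igraph::neighbors(net, g))
    nb <- nb[!is.na(cat[nb]) & cat[nb] != "" & !duf[nb]]
    out <- rbind(out, data.frame(
      gene = g, cluster = cl, kw = cand$kw[i], kb = cand$kb[i],
      top_category = if (nrow(enr)) enr$category[1] else NA_character_,
      predicted_categories = paste(enr$category, collapse = ","),
      annotated_neighbors = paste(sort(nb), collapse = ","),
      stringsAsFactors = FALSE))
  }
  out %||% data.frame(gene = character(0), cluster = integer(0),
                      kw = integer(0), kb = integer(0),
                      top_category = character(0),
                      predicted_categories = character(0),
                      annotated_neighbors = character(0))
}

#' Environment-gene association
#'
#' Spearman correlation of every environmental factor against every gene's
#' abundance profile, BH-adjusted across all (factor, gene) pairs.
#' Significant links are counted per factor, and — when a clustering is
#' supplied — each factor's linked genes are tested for hypergeometric
#' concentration within each cluster.
#'
#' @param env factors x samples matrix.
#' @param abundance genes x samples matrix over the same samples.
#' @param clustering optional `gc_clustering` for the concentration test.
#' @param q_max FDR ceiling for a significant link.
#' @return list with `links` (factor, gene, rho, p, q for significant
#'   links), `factor_counts`, and `concentration` (factor, cluster, overlap,
#'   p, q) or `NULL`.
#' @export
env_gene_links <- function(env, abundance, clustering = NULL, q_max = 0.05) {
  if (!identical(colnames(env), colnames(abundance)))
    stopf("environment and abundance tables must share sample ids")
  n <- ncol(env)
  re <- t(apply(env, 1, rank))
  ra <- t(apply(abundance, 1, rank))
  rho <- suppressWarnings(cor(t(re), t(ra)))
  rho[is.na(rho)] <- 0
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  tt[abs(rho) >= 1] <- Inf * sign(rho[abs(rho) >= 1])
  p <- 2 * pt(-abs(tt), df = n - 2)
  q <- matrix(p.adjust(p, method = "BH"), nrow = nrow(p),
              dimnames = dimnames(p))
  sel <- which(q < q_max, arr.ind = TRUE)
  links <- data.frame(
    factor = rownames(env)[sel[, 1]], gene = rownames(abundance)[sel[, 2]],
    rho = rho[sel], p = p[sel], q = q[sel], stringsAsFactors = FALSE)
  links <- links[order(links$factor, links$q), ]
  rownames(links) <- NULL
  fc <- table(factor(links$factor, levels = rownames(env)))
  conc <- NULL
  if (!is.null(clustering) && nrow(links)) {
    mem <- clustering$membership
    uni <- names(mem)
    N <- length(uni)
    for (f in rownames(env)) {
      linked <- intersect(links$gene[links$factor == f], uni)
      nl <- length(linked)
      if (nl == 0) next
      for (cl in sort(unique(mem))) {
        members <- names(mem)[mem == cl]
        k <- length(intersect(linked, members))
        p_c <- phyper(k - 1, length(members), N - length(members), nl,
                      lower.tail = FALSE)
        conc <- rbind(conc, data.frame(factor = f, cluster = cl, overlap = k,
                                       cluster_size = length(members),
                                       n_linked = nl, p = p_c,
                                       stringsAsFactors = FALSE))
      }
    }
    if (!is.null(conc)) conc$q <- p.adjust(conc$p, method = "BH")
  }
  list(links = links, factor_counts = fc, concentration = conc)
}
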