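# Synthetic abundance tables with planted, fully known correlation structure.
#
# The generative model is a latent-factor model: each planted cluster k has a
# latent factor f_k over samples; gene g in cluster k has latent value
#   z_g = w_g * f_k + sqrt(1 - w_g^2) * eps_g,   eps_g ~ iid N(0,1),
# with w_g = hub_loading for the cluster hub and member_loading otherwise, so
# the population correlation of two cluster mates is the product of their
# loadings and the hub is the most strongly wired gene of its cluster.
# Abundance is exp(z): a strictly increasing positive transform, so planted
# rank correlations survive exactly. Absence is imposed afterwards by zeroing
# randomly chosen samples (zero = not detected in that metagenome).

#' Specification for a synthetic metagenome abundance table
#'
#' Defines the planted structure: modular correlation blocks with one
#' high-loading hub gene each, a core / non-core / excluded prevalence
#' structure, optional anti-correlated cluster pairs, optional nesting of
#' sibling clusters under shared parent factors, and environmental factors
#' coupled to chosen clusters. Defaults emulate a 45-sample metagenome survey
#' design.
#'
#' @param n_samples number of samples (columns).
#' @param n_clusters number K of planted gene clusters.
#' @param genes_per_cluster genes per planted cluster (the first is the hub).
#' @param hub_loading factor loading of each cluster hub, in (0, 1].
#' @param member_loading factor loading of non-hub members, in (0, 1].
#' @param n_background_genes unstructured i.i.d. noise genes.
#' @param frac_core fraction of (clustered + background) genes present in all
#'   samples; the rest are non-core.
#' @param noncore_presence_range inclusive integer range of presence counts
#'   for non-core genes.
#' @param n_excluded_genes extra noise genes with presence below the lower
#'   bound of `noncore_presence_range` (dropped by the prevalence filter).
#' @param negative_pairs list of 2-vectors of cluster indices (1-based) whose
#'   latent factors are anti-correlated (sample correlation <= -0.9).
#' @param nested_parents list of `list(clusters =, loading =)` entries
#'   grouping sibling clusters under a shared parent factor at the given
#'   loading in (0, 1).
#' @param env_factors number of environmental factors to simulate.
#' @param env_coupling integer vector of length `env_factors`; entry i is the
#'   cluster whose factor drives environmental factor i, or `NA` for an
#'   uncoupled (pure noise) factor.
#' @param noise_sd standard deviation of the noise added to coupled
#'   environmental factors.
#' @param duf_fraction fraction of each cluster's genes labelled as domains
#'   of unknown function (category withheld; truth retained).
#' @param seed integer RNG seed; identical seeds give bit-identical tables.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 45L, n_clusters = 4L,
                           genes_per_cluster = 15L, hub_loading = 0.95,
                           member_loading = 0.8, n_background_genes = 20L,
                           frac_core = 0.6, noncore_presence_range = c(25L, 44L),
                           n_excluded_genes = 0L, negative_pairs = list(),
                           nested_parents = list(), env_factors = 0L,
                           env_coupling = rep(NA_integer_, env_factors),
                           noise_sd = 0.3, duf_fraction = 0.2, seed = 1L) {
  if (n_clusters < 1) stopf("n_clusters must be >= 1")
  if (genes_per_cluster < 1) stopf("genes_per_cluster must be >= 1")
  for (w in c(hub_loading, member_loading))
    if (w <= 0 || w > 1) stopf("loadings must lie in (0, 1]")
  if (frac_core < 0 || frac_core > 1) stopf("frac_core must lie in [0, 1]")
  rng <- as.integer(noncore_presence_range)
  if (length(rng) != 2 || rng[1] > rng[2] || rng[1] < 1 || rng[2] > n_samples)
    stopf("noncore_presence_range must be an increasing pair within [1, n_samples]")
  if (rng[2] >= n_samples)
    stopf("noncore presence must be < n_samples (presence = n_samples is core)")
  for (p in negative_pairs) {
    p <- as.integer(p)
    if (length(p) != 2 || any(p < 1 | p > n_clusters))
      stopf("negative_pairs entries must be pairs of cluster indices in 1..K")
  }
  for (np in nested_parents) {
    if (is.null(np$clusters) || is.null(np$loading))
      stopf("nested_parents entries need $clusters and $loading")
    if (np$loading <= 0 || np$loading >= 1)
      stopf("parent loadings must lie in (0, 1)")
    if (any(np$clusters < 1 | np$clusters > n_clusters))
      stopf("nested parent cluster indices out of range")
  }
  if (env_factors > 0 && length(env_coupling) != env_factors)
    stopf("env_coupling must have length env_factors")
  if (noise_sd <= 0) stopf("noise_sd must be positive")
  structure(list(
    n_samples = as.integer(n_samples), n_clusters = as.integer(n_clusters),
    genes_per_cluster = as.integer(genes_per_cluster),
    hub_loading = hub_loading, member_loading = member_loading,
    n_background_genes = as.integer(n_background_genes),
    frac_core = frac_core, noncore_presence_range = rng,
    n_excluded_genes = as.integer(n_excluded_genes),
    negative_pairs = lapply(negative_pairs, as.integer),
    nested_parents = nested_parents,
    env_factors = as.integer(env_factors),
    env_coupling = as.integer(env_coupling),
    noise_sd = noise_sd, duf_fraction = duf_fraction,
    seed = as.integer(seed)), class = "synthetic_spec")
}

#' Latent cluster factors for a synthetic specification
#'
#' One row per cluster factor (plus one row per parent factor when clusters
#' are nested). Factors are built from randomly drawn, then exactly
#' orthonormalised (centred) sample vectors, so the planted geometry holds
#' in the realised sample, not merely in expectation: unrelated factors have
#' sample correlation exactly 0, nested children satisfy
#' `cor(child, parent) = loading` exactly (hence
#' `cor(sibling, sibling) = loading^2`), and `negative_pairs` factors have
#' sample correlation exactly `-sqrt(1 - 0.1^2)` (about -0.995, below the
#' -0.9 design requirement). Gene-level noise added downstream is the only
#' stochastic blur on planted correlations.
#'
#' @param spec a [synthetic_spec()].
#' @return numeric matrix, (K + n_parents) x n_samples, rownames
#'   `cluster_<k>` / `parent_<j>`; rows have mean 0, sd 1.
#' @export
generate_latent_factors <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  K <- spec$n_clusters
  P <- length(spec$nested_parents)
  n <- spec$n_samples
  if (K + P >= n)
    stopf("need n_samples > n_clusters + n_parents for orthogonal factors")
  # exactly orthonormal centred sample vectors, scaled to sd 1
  x <- matrix(rnorm(n * (K + P)), nrow = n)
  x <- sweep(x, 2, colMeans(x))
  basis <- qr.Q(qr(x)) * sqrt(n - 1)
  f <- t(basis[, seq_len(K), drop = FALSE])
  rownames(f) <- paste0("cluster_", seq_len(K))
  colnames(f) <- paste0("S", seq_len(n))
  parents <- NULL
  if (P > 0) {
    parents <- basis[, K + seq_len(P), drop = FALSE]
    parents <- t(parents)
    dimnames(parents) <- list(paste0("parent_", seq_len(P)), colnames(f))
    for (j in seq_len(P)) {
      np <- spec$nested_parents[[j]]
      w <- np$loading
      for (k in np$clusters)
        f[k, ] <- w * parents[j, ] + sqrt(1 - w^2) * f[k, ]
    }
  }
  for (p in spec$negative_pairs) {
    delta <- 0.1
    f[p[2], ] <- -sqrt(1 - delta^2) * f[p[1], ] + delta * f[p[2], ]
  }
  rbind(f, parents)
}

#' Generate a synthetic abundance table and its ground truth
#'
#' Draws latent gene values from the planted factor model, maps them through
#' `exp()` (strictly increasing, so planted rank correlations are preserved
#' exactly), then imposes the prevalence structure by zeroing randomly chosen
#' samples of non-core genes. Excluded genes fall below the prevalence filter
#' by construction.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `table` (genes x samples abundance matrix) and `truth`,
#'   a `ground_truth` list: `gene_cluster` (named integer, `NA` for
#'   background/excluded genes), `hubs` (cluster -> hub gene id),
#'   `prevalence` (data.frame gene/class/presence), `negative_pairs`,
#'   `nested_parents`, `env_coupling`.
#' @export
generate_abundance <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  fac <- generate_latent_factors(spec)  # seeds the stream
  K <- spec$n_clusters
  n <- spec$n_samples
  gpc <- spec$genes_per_cluster

  ids <- character(0); clus <- integer(0)
  lat <- NULL
  for (k in seq_len(K)) {
    w <- c(spec$hub_loading, rep(spec$member_loading, gpc - 1))
    g_ids <- sprintf("c%02d_g%03d", k, seq_len(gpc))
    g_ids[1] <- sprintf("c%02d_hub", k)
    z <- w %o% fac[k, ] +
      sqrt(1 - w^2) * matrix(rnorm(gpc * n), nrow = gpc)
    rownames(z) <- g_ids
    lat <- rbind(lat, z)
    ids <- c(ids, g_ids); clus <- c(clus, rep(k, gpc))
  }
  if (spec$n_background_genes > 0) {
    bg <- matrix(rnorm(spec$n_background_genes * n),
                 nrow = spec$n_background_genes)
    rownames(bg) <- sprintf("bg_g%03d", seq_len(spec$n_background_genes))
    lat <- rbind(lat, bg)
    ids <- c(ids, rownames(bg)); clus <- c(clus, rep(NA_integer_, nrow(bg)))
  }
  if (spec$n_excluded_genes > 0) {
    ex <- matrix(rnorm(spec$n_excluded_genes * n),
                 nrow = spec$n_excluded_genes)
    rownames(ex) <- sprintf("ex_g%03d", seq_len(spec$n_excluded_genes))
    lat <- rbind(lat, ex)
    ids <- c(ids, rownames(ex)); clus <- c(clus, rep(NA_integer_, nrow(ex)))
  }
  colnames(lat) <- colnames(fac)
  ab <- exp(lat)

  # prevalence: core / non-core split over clustered + background genes;
  # excluded genes always fall below the filter
  g_main <- length(ids) - spec$n_excluded_genes
  n_core <- round(spec$frac_core * g_main)
  core_idx <- if (g_main > 0) sample(seq_len(g_main), n_core) else integer(0)
  class <- rep("noncore", length(ids))
  class[core_idx] <- "core"
  if (spec$n_excluded_genes > 0)
    class[(g_main + 1):length(ids)] <- "excluded"
  lo <- spec$noncore_presence_range[1]
  hi <- spec$noncore_presence_range[2]
  presence <- rep(n, length(ids))
  for (i in seq_along(ids)) {
    pres <- switch(class[i],
      core = n,
      noncore = sample(lo:hi, 1),
      excluded = sample(seq_len(lo - 1), 1))
    if (pres > n) stopf("requested presence exceeds n_samples")
    if (pres < n) ab[i, sample(n, n - pres)] <- 0
    presence[i] <- pres
  }

  hubs <- setNames(sprintf("c%02d_hub", seq_len(K)), paste0("cluster_", seq_len(K)))
  truth <- structure(list(
    gene_cluster = setNames(clus, ids),
    hubs = hubs,
    prevalence = data.frame(gene = ids, class = class, presence = presence,
                            stringsAsFactors = FALSE),
    negative_pairs = spec$negative_pairs,
    nested_parents = spec$nested_parents,
    env_coupling = spec$env_coupling,
    factors = fac), class = "ground_truth")
  list(table = ab, truth = truth)
}

# pool of domain-family-style category labels for planted clusters
.category_pool <- c(
  "Peptidase", "Glyco_transf", "Oxidoreductase", "ABC_transporter",
  "Ribosomal", "Kinase", "Fer4_ferredoxin", "Hydrolase", "MgtC_membrane",
  "HTH_regulator", "Nitrogen_util", "Phosphatase", "SpoVG_sporulation",
  "CTP_transf", "Cu_oxidase", "Antitoxin", "OmpH_outer_membrane",
  "GST_transferase", "DAO_oxidase", "PaaA_catabolic", "Rrf2_regulator",
  "Glyco_hydro", "Ppx_kinase", "SHOCT_binding", "RadC_repair",
  "Pro_dh_dehydrogenase", "Chaperone")

#' Gene metadata for a synthetic run
#'
#' Each planted cluster gets a distinct functional-category label; a fraction
#' of each cluster's genes (floor of `duf_fraction * genes_per_cluster`,
#' never the hub) is flagged as a domain of unknown function (DUF): the
#' category is withheld from the metadata but retained as ground truth.
#' Background genes share a `"background"` label.
#'
#' @param spec a [synthetic_spec()].
#' @param truth ground truth from [generate_abundance()] run with `spec`.
#' @return list with `metadata` (data.frame gene/category/is_duf),
#'   `cluster_labels` (cluster index -> category), and `withheld` (DUF gene
#'   -> true category).
#' @export
generate_metadata <- function(spec, truth) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(truth, "ground_truth"))
  set.seed(derive_seed(spec$seed, 1L))
  K <- spec$n_clusters
  labels <- rep_len(.category_pool, K)
  labels <- paste0(labels, "_", seq_len(K))  # distinct even if pool recycles
  ids <- names(truth$gene_cluster)
  category <- ifelse(is.na(truth$gene_cluster), "background",
                     labels[truth$gene_cluster])
  is_duf <- rep(FALSE, length(ids))
  n_duf <- floor(spec$duf_fraction * spec$genes_per_cluster)
  withheld <- character(0)
  for (k in seq_len(K)) {
    members <- which(!is.na(truth$gene_cluster) & truth$gene_cluster == k &
                       ids != truth$hubs[k])
    if (n_duf > 0 && length(members) > 0) {
      duf <- sample(members, min(n_duf, length(members)))
      is_duf[duf] <- TRUE
      withheld[ids[duf]] <- labels[k]
      category[duf] <- ""
    }
  }
  list(metadata = data.frame(gene = ids, category = category, is_duf = is_duf,
                             stringsAsFactors = FALSE),
       cluster_labels = setNames(labels, seq_len(K)),
       withheld = withheld)
}

#' Environmental factor table for a synthetic run
#'
#' Coupled factors are the corresponding cluster's latent factor plus
#' Gaussian noise at `spec$noise_sd`; uncoupled factors are pure standard
#' normal noise.
#'
#' @param spec a [synthetic_spec()].
#' @param factors latent factor matrix from [generate_latent_factors()] (or
#'   `truth$factors`).
#' @return factors x samples numeric matrix (0-row matrix when
#'   `env_factors = 0`).
#' @export
generate_env <- function(spec, factors) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(derive_seed(spec$seed, 2L))
  n <- spec$n_samples
  env <- matrix(0, nrow = spec$env_factors, ncol = n,
                dimnames = list(if (spec$env_factors > 0)
                  paste0("env_", seq_len(spec$env_factors)) else NULL,
                  colnames(factors) %||% paste0("S", seq_len(n))))
  for (i in seq_len(spec$env_factors)) {
    k <- spec$env_coupling[i]
    env[i, ] <- if (is.na(k)) rnorm(n)
                else factors[k, ] + rnorm(n, sd = spec$noise_sd)
  }
  env
}

#' Planted block correlation matrix
#'
#' A correlation-like symmetric matrix with unit diagonal, dense high-valued
#' diagonal blocks and a low-valued between-block noise band. Used to
#' exercise threshold selection: below the noise band's upper edge the blocks
#' are coupled into one matrix (correlated, GOE-like spectrum); above it the
#' blocks decouple and the spectrum is a superposition of independent block
#' spectra (Poisson spacings).
#'
#' @param n_blocks number of diagonal blocks.
#' @param block_size genes per block.
#' @param within_range range of within-block |rho| values.
#' @param between_range range of between-block |rho| values (the noise band).
#' @param seed integer RNG seed.
#' @return symmetric matrix with unit diagonal.
#' @export
planted_block_matrix <- function(n_blocks = 8L, block_size = 20L,
                                 within_range = c(0.85, 0.95),
                                 between_range = c(0.15, 0.35),
                                 seed = 1L) {
  set.seed(seed)
  n <- n_blocks * block_size
  m <- matrix(runif(n * n, between_range[1], between_range[2]), n, n)
  for (b in seq_len(n_blocks)) {
    idx <- ((b - 1) * block_size + 1):(b * block_size)
    m[idx, idx] <- runif(block_size^2, within_range[1], within_range[2])
  }
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 1
  rownames(m) <- colnames(m) <- sprintf("g%04d", seq_len(n))
  m
}

#' Write all tables of a synthetic run to a directory
#'
#' Abundance, metadata and environment tables as TSV (rows = genes/factors,
#' columns = samples, first column = id); ground truth as JSON.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_synthetic <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_abundance(spec)
  meta <- generate_metadata(spec, sim$truth)
  env <- generate_env(spec, sim$truth$factors)
  write_tsv_matrix(sim$table, file.path(dir, "abundance.tsv"), "gene")
  write.table(meta$metadata, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (nrow(env) > 0)
    write_tsv_matrix(env, file.path(dir, "env.tsv"), "factor")
  truth <- sim$truth
  jsonlite::write_json(list(
    gene_cluster = as.list(truth$gene_cluster),
    hubs = as.list(truth$hubs),
    prevalence = truth$prevalence,
    negative_pairs = truth$negative_pairs,
    env_coupling = truth$env_coupling,
    withheld = as.list(meta$withheld)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
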