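test_that("latent factors realise the planted geometry exactly", {
  # independent clusters: exactly orthogonal in the sample
  spec <- synthetic_spec(n_clusters = 2, seed = 3)
  f <- generate_latent_factors(spec)
  expect_equal(nrow(f), 2)
  expect_lt(abs(cor(f[1, ], f[2, ])), 1e-10)

  # anti-correlated pair: correlation at most -0.9 by construction
  spec <- synthetic_spec(n_clusters = 2, negative_pairs = list(c(1, 2)),
                         seed = 3)
  f <- generate_latent_factors(spec)
  expect_lte(cor(f[1, ], f[2, ]), -0.9)

  # nested siblings share the parent: positive correlation, loading^2 exact
  spec <- synthetic_spec(n_clusters = 2,
                         nested_parents = list(list(clusters = c(1, 2),
                                                    loading = 0.9)),
                         seed = 3)
  f <- generate_latent_factors(spec)
  expect_gt(cor(f[1, ], f[2, ]), 0)
  expect_equal(cor(f[1, ], f[2, ]), 0.81, tolerance = 1e-10)
  expect_equal(cor(f[1, ], f["parent_1", ]), 0.9, tolerance = 1e-10)
})

test_that("independent factors stay uncorrelated over many seeds", {
  # at n = 45, |r| of two independent factors rarely approaches 0.5; with
  # the orthogonalised construction it is exactly 0
  r <- vapply(1:50, function(s) {
    f <- generate_latent_factors(synthetic_spec(n_clusters = 2, seed = s))
    abs(cor(f[1, ], f[2, ]))
  }, 0)
  expect_true(all(r < 0.5))
})

test_that("abundance generation plants loadings, hubs and prevalence", {
  spec <- synthetic_spec(n_clusters = 3, genes_per_cluster = 10,
                         n_background_genes = 5, frac_core = 1, seed = 11)
  sim <- generate_abundance(spec)
  expect_equal(dim(sim$table), c(35, 45))
  expect_true(all(sim$table >= 0))
  expect_false(anyDuplicated(rownames(sim$table)) > 0)
  # frac_core = 1: no masking anywhere
  expect_true(all(sim$table > 0))
  expect_true(all(sim$truth$prevalence$class == "core"))
  # exactly one hub per planted cluster
  expect_equal(length(sim$truth$hubs), 3)
  expect_true(all(sim$truth$hubs %in% rownames(sim$table)))

  # hub-member latent correlation (loading product 0.76) exceeds
  # member-member (0.64) on average across seeds
  gap <- vapply(1:25, function(s) {
    spec <- synthetic_spec(n_clusters = 1, genes_per_cluster = 10,
                           n_background_genes = 0, frac_core = 1, seed = s)
    sim <- generate_abundance(spec)
    rho <- cor(apply(sim$table, 1, rank))
    hub <- sim$truth$hubs[1]
    hm <- mean(rho[hub, setdiff(rownames(rho), hub)])
    mm <- rho[setdiff(rownames(rho), hub), setdiff(rownames(rho), hub)]
    hm - mean(mm[upper.tri(mm)])
  }, 0)
  expect_gt(mean(gap), 0)
  expect_gt(mean(gap > 0), 0.9)
})

test_that("two genes with loading 1 on one factor are rank-identical", {
  spec <- synthetic_spec(n_clusters = 1, genes_per_cluster = 2,
                         hub_loading = 1, member_loading = 1,
                         n_background_genes = 0, frac_core = 1, seed = 5)
  sim <- generate_abundance(spec)
  rho <- cor(sim$table[1, ], sim$table[2, ], method = "spearman")
  expect_equal(rho, 1)
})

test_that("prevalence bookkeeping matches ground truth exactly", {
  for (s in 1:5) {
    spec <- synthetic_spec(n_clusters = 3, genes_per_cluster = 8,
                           n_background_genes = 10, frac_core = 0.5,
                           n_excluded_genes = 6, seed = s)
    sim <- generate_abundance(spec)
    presence <- rowSums(sim$table > 0)
    tr <- sim$truth$prevalence
    expect_equal(unname(presence[tr$gene]), tr$presence)
    expect_true(all(presence[tr$gene[tr$class == "core"]] == 45))
    nc <- presence[tr$gene[tr$class == "noncore"]]
    expect_true(all(nc >= 25 & nc <= 44))
    expect_true(all(presence[tr$gene[tr$class == "excluded"]] < 25))
  }
})

test_that("identical seeds give bit-identical tables", {
  spec <- synthetic_spec(n_clusters = 4, n_excluded_genes = 5,
                         env_factors = 2, env_coupling = c(1L, NA), seed = 99)
  a <- generate_abundance(spec)
  b <- generate_abundance(spec)
  expect_identical(a$table, b$table)
  expect_identical(a$truth$prevalence, b$truth$prevalence)
  expect_identical(generate_env(spec, a$truth$factors),
                   generate_env(spec, b$truth$factors))
  expect_identical(generate_metadata(spec, a$truth)$metadata,
                   generate_metadata(spec, b$truth)$metadata)
})

test_that("metadata labels clusters and withholds DUF categories", {
  spec <- synthetic_spec(n_clusters = 3, genes_per_cluster = 10,
                         duf_fraction = 0.2, seed = 2)
  sim <- generate_abundance(spec)
  meta <- generate_metadata(spec, sim$truth)
  md <- meta$metadata
  # floor(0.2 * 10) = 2 DUF genes per cluster
  expect_equal(sum(md$is_duf), 6)
  expect_true(all(md$category[md$is_duf] == ""))
  # withheld truth equals the cluster's label
  for (g in names(meta$withheld)) {
    k <- sim$truth$gene_cluster[g]
    expect_equal(unname(meta$withheld[g]), unname(meta$cluster_labels[k]))
  }
  # background genes share one label
  bg <- md$gene[is.na(sim$truth$gene_cluster[md$gene])]
  expect_true(all(md$category[md$gene %in% bg] == "background"))

  # duf_fraction = 0: no DUF rows
  spec0 <- synthetic_spec(n_clusters = 3, duf_fraction = 0, seed = 2)
  sim0 <- generate_abundance(spec0)
  expect_equal(sum(generate_metadata(spec0, sim0$truth)$metadata$is_duf), 0)
})

test_that("environment factors couple to their clusters", {
  spec <- synthetic_spec(n_clusters = 2, env_factors = 2,
                         env_coupling = c(1L, NA), noise_sd = 1e-9, seed = 4)
  f <- generate_latent_factors(spec)
  env <- generate_env(spec, f)
  # coupling noise ~ 0: rank-identical to the cluster factor
  expect_equal(cor(env[1, ], f[1, ], method = "spearman"), 1)
  # uncoupled factor: orthogonalised factors make the null exact-ish
  expect_lt(abs(cor(env[2, ], f[1, ])), 0.5)
  # zero factors: empty table with the sample columns
  spec0 <- synthetic_spec(n_clusters = 2, env_factors = 0, seed = 4)
  env0 <- generate_env(spec0, f)
  expect_equal(dim(env0), c(0, 45))
})

test_that("spec validation rejects bad geometry", {
  expect_error(synthetic_spec(n_clusters = 0), "n_clusters")
  expect_error(synthetic_spec(hub_loading = 1.2), "loadings")
  expect_error(synthetic_spec(noncore_presence_range = c(25, 45)),
               "noncore presence")
  expect_error(synthetic_spec(negative_pairs = list(c(1, 9))), "cluster indices")
  expect_error(synthetic_spec(
    nested_parents = list(list(clusters = 1:2, loading = 1))), "parent")
})

test_that("synthetic tables round-trip through the writers", {
  dir <- withr::local_tempdir()
  spec <- synthetic_spec(n_clusters = 2, genes_per_cluster = 5,
                         n_background_genes = 3, env_factors = 1,
                         env_coupling = 1L, seed = 8)
  write_synthetic(spec, dir)
  ab <- read_abundance(file.path(dir, "abundance.tsv"))
  expect_equal(ab, generate_abundance(spec)$table, tolerance = 1e-12)
  md <- read_gene_metadata(file.path(dir, "metadata.tsv"))
  expect_equal(nrow(md), nrow(ab))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(length(truth$hubs), 2)
})
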