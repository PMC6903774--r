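test_that("pca eigenstructure satisfies the trace and reconstruction identities", {
  sim <- simulate_collection_like(seed = 14)
  pca <- pca_on_means(sim$data)
  expect_equal(sum(pca$eigenvalues), length(pca$traits), tolerance = 1e-10)
  expect_true(all(diff(pca$eigenvalues) <= 1e-10))
  # loadings * diag(eigenvalues) * loadings' reconstructs the correlation
  gm <- genotype_means(sim$data)
  recon <- pca$loadings %*% diag(pca$eigenvalues) %*% t(pca$loadings)
  expect_equal(recon, cor(as.matrix(gm[pca$traits])),
    tolerance = 1e-8, ignore_attr = TRUE
  )
  expect_equal(pca$n_retained, sum(pca$eigenvalues >= 1))
})

test_that("a perfectly duplicated trait concentrates variance on one axis", {
  df <- expand.grid(
    genotype = sprintf("g%02d", 1:15), year = 1:2, block = 1:2,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  set.seed(2)
  base <- stats::rnorm(15)
  df$a <- base[match(df$genotype, sprintf("g%02d", 1:15))]
  df$b <- 2 * df$a + 1
  pca <- pca_on_means(as_trial_data(df))
  expect_equal(pca$eigenvalues, c(2, 0), tolerance = 1e-10)
})

test_that("independent traits give near-unit eigenvalues at large n", {
  traits <- purrr::map_dfr(
    1:7, ~ trait_gen(paste0("t", .x), mu = 10, sigma2_g = 1)
  )
  sim <- simulate_trial(sim_config(2000, traits, years = 1, blocks = 1, seed = 8))
  pca <- pca_on_means(sim$data)
  expect_true(all(pca$eigenvalues > 0.9 & pca$eigenvalues < 1.1))
})

test_that("constant traits are dropped with a warning", {
  df <- expand.grid(
    genotype = sprintf("g%02d", 1:10), year = 1:2, block = 1:2,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  set.seed(3)
  vals <- stats::rnorm(10)
  df$a <- vals[match(df$genotype, sprintf("g%02d", 1:10))]
  df$b <- -vals[match(df$genotype, sprintf("g%02d", 1:10))]
  df$flat <- 5
  expect_warning(pca <- pca_on_means(as_trial_data(df)), "flat")
  expect_equal(pca$traits, c("a", "b"))
})

test_that("dendrogram cut behaves monotonically with its extremes", {
  sim <- simulate_collection_like(n_genotypes = 30, seed = 6)
  pca <- pca_on_means(sim$data)
  tiny <- ward_cluster(pca, cut_fraction = 1e-9)
  expect_equal(tiny$n_clusters, 30)
  one <- ward_cluster(pca, cut_fraction = 1)
  expect_equal(one$n_clusters, 1)
  fracs <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  sizes <- sapply(fracs, function(f) ward_cluster(pca, cut_fraction = f)$n_clusters)
  expect_true(all(diff(sizes) <= 0))
  fixed <- ward_cluster(pca, k = 4)
  expect_equal(fixed$n_clusters, 4)
  expect_error(ward_cluster(pca, cut_fraction = 0), "cut_fraction")
})

test_that("cluster ids are contiguous and invariant to genotype input order", {
  sim <- simulate_collection_like(n_genotypes = 40, seed = 23)
  pca <- pca_on_means(sim$data)
  cs <- ward_cluster(pca)
  expect_setequal(unique(cs$assignments$cluster), seq_len(cs$n_clusters))

  shuffled <- as_trial_data(
    as.data.frame(sim$data)[sample(nrow(sim$data)), ],
    traits = trial_traits(sim$data)
  )
  cs2 <- ward_cluster(pca_on_means(shuffled))
  merged <- dplyr::inner_join(
    cs$assignments, cs2$assignments,
    by = "genotype", suffix = c("_a", "_b")
  )
  expect_equal(merged$cluster_a, merged$cluster_b)
})

test_that("planted two-group structure is recovered exactly", {
  sim <- planted_two_groups(seed = 301)
  pca <- pca_on_means(sim$data)
  cs <- ward_cluster(pca, cut_fraction = 0.20)
  truth <- setNames(sim$genotypes$region, sim$genotypes$genotype)
  expect_equal(cs$n_clusters, 2)
  expect_equal(misassignments(cs, truth), 0)
})

test_that("cluster profiles expose means and nested F statistics", {
  sim <- planted_two_groups(seed = 302)
  cs <- ward_cluster(pca_on_means(sim$data), cut_fraction = 0.20)
  prof <- cluster_profile(sim$data, cs)
  expect_equal(sort(unique(prof$means$cluster)), seq_len(cs$n_clusters))
  # shifted traits separate the clusters decisively
  expect_true(all(prof$tests$statistic > stats::qf(0.999, 1, 38)))

  # a singleton cluster's mean is that genotype's mean
  gm <- genotype_means(sim$data)
  single <- ward_cluster(pca_on_means(sim$data), k = nrow(gm))
  prof1 <- cluster_profile(sim$data, single)
  joined <- dplyr::inner_join(
    dplyr::inner_join(single$assignments, gm, by = "genotype"),
    tidyr::pivot_wider(
      prof1$means[, c("cluster", "trait", "mean")],
      names_from = "trait", values_from = "mean"
    ),
    by = "cluster", suffix = c("", "_cl")
  )
  expect_equal(joined$t1, joined$t1_cl)

  # identical genotypes: undefined F, equal means
  df <- expand.grid(
    genotype = sprintf("g%02d", 1:8), year = 1:2, block = 1:2,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  df$a <- 1
  set.seed(4)
  df$b <- stats::rnorm(8)[match(df$genotype, sprintf("g%02d", 1:8))]
  df$c <- stats::rnorm(8)[match(df$genotype, sprintf("g%02d", 1:8))]
  suppressWarnings({
    ds <- as_trial_data(df)
    cs0 <- ward_cluster(pca_on_means(ds), k = 2)
    prof0 <- cluster_profile(ds, cs0, traits = "a")
  })
  expect_true(is.na(prof0$tests$statistic))
  expect_true(all(prof0$means$mean == 1))
})

test_that("newick export is well-formed and covers every genotype", {
  sim <- simulate_collection_like(n_genotypes = 12, seed = 2)
  cs <- ward_cluster(pca_on_means(sim$data))
  nwk <- dendrogram_newick(cs)
  expect_match(nwk, ";$")
  expect_equal(
    lengths(regmatches(nwk, gregexpr("\\(", nwk))),
    lengths(regmatches(nwk, gregexpr("\\)", nwk)))
  )
  for (g in cs$assignments$genotype) {
    expect_match(nwk, g, fixed = TRUE)
  }
})
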