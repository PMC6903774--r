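test_that("cross-products reduce to the variance decomposition on self-pairs", {
  sim <- simulate_trial(sim_config(
    12, trait_gen("y", mu = 5, sigma2_g = 2, sigma2_gy = 0.5, sigma2_e = 1),
    years = 3, blocks = 2, seed = 21
  ))
  cc <- cross_products_anova(sim$data, "y", "y")
  a <- anova_multiyear_rcbd(sim$data, "y")
  vd <- estimate_components(a)
  expect_equal(cc$cov_g, vd$sigma2_g, tolerance = 1e-10)
  expect_equal(cc$cov_gy, vd$sigma2_gy, tolerance = 1e-10)
  expect_equal(cc$cov_e, vd$sigma2_e, tolerance = 1e-10)
  expect_equal(cc$cov_p, vd$sigma2_p, tolerance = 1e-10)
})

test_that("cross-products are bilinear under affine transforms", {
  sim <- simulate_trial(sim_config(
    10, trait_gen("y", mu = 5, sigma2_g = 2, sigma2_gy = 0.5, sigma2_e = 1),
    years = 2, blocks = 2, seed = 22
  ))
  df <- as.data.frame(sim$data)
  df$z <- 3 * df$y + 7
  ds <- as_trial_data(df)
  cc <- cross_products_anova(ds, "y", "z")
  vd <- estimate_components(anova_multiyear_rcbd(ds, "y"))
  expect_equal(cc$cov_g, 3 * vd$sigma2_g, tolerance = 1e-9)
  expect_equal(cc$cov_e, 3 * vd$sigma2_e, tolerance = 1e-9)
  est <- correlation_from_components(
    cc, vd, estimate_components(anova_multiyear_rcbd(ds, "z"))
  )
  expect_equal(est$r_p, 1, tolerance = 1e-9)
  expect_equal(est$r_g, 1, tolerance = 1e-9)
})

test_that("cross-products match the brute-force oracle on small designs", {
  set.seed(5)
  for (g in 2:3) {
    grid <- expand.grid(
      genotype = paste0("g", 1:g), year = 1:2, block = 1:2,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    grid$x <- round(stats::rnorm(nrow(grid), 5, 2), 2)
    grid$z <- round(stats::rnorm(nrow(grid), 7, 3), 2)
    ds <- as_trial_data(grid)
    cc <- cross_products_anova(ds, "x", "z")
    oracle <- brute_force_scp(grid, "x", "z")
    df_g <- g - 1
    df_gy <- (g - 1) * 1
    df_e <- 2 * (g - 1) * 1
    mcp_e <- oracle["error"] / df_e
    mcp_gy <- oracle["genotype_x_year"] / df_gy
    mcp_g <- oracle["genotype"] / df_g
    expect_equal(cc$cov_e, unname(mcp_e), tolerance = 1e-9)
    expect_equal(cc$cov_gy, unname((mcp_gy - mcp_e) / 2), tolerance = 1e-9)
    expect_equal(cc$cov_g, unname((mcp_g - mcp_gy) / 4), tolerance = 1e-9)
  }
})

test_that("correlation matrices are symmetric with unit diagonal", {
  sim <- simulate_breeding_like(n_lines = 60, seed = 17)
  ct <- trait_correlations(sim$data, c("HT", "PH", "GY", "PC", "GC"))
  expect_equal(ct$r_p, t(ct$r_p))
  expect_equal(ct$r_g, t(ct$r_g))
  expect_equal(unname(diag(ct$r_p)), rep(1, 5))
  expect_equal(unname(diag(ct$r_g)), rep(1, 5))
  expect_true(all(abs(ct$r_p) <= 1 + 1e-9))
  td <- tidy(ct)
  expect_equal(nrow(td), choose(5, 2))
  expect_named(
    td, c("trait1", "trait2", "r_p", "p_p", "r_g", "p_g", "rg_out_of_range")
  )
})

test_that("genotypic correlations recover the generating correlation", {
  est <- sapply(1:12, function(s) {
    traits <- dplyr::bind_rows(
      trait_gen("a", mu = 10, sigma2_g = 4, sigma2_gy = 0.13, sigma2_e = 0.4),
      trait_gen("b", mu = 20, sigma2_g = 4, sigma2_gy = 0.13, sigma2_e = 0.4)
    )
    sim <- simulate_trial(sim_config(
      800, traits, years = 3, blocks = 3,
      gcorr = matrix(c(1, 0.9, 0.9, 1), 2), seed = 600 + s
    ))
    ct <- trait_correlations(sim$data)
    ct$r_g["a", "b"]
  })
  expect_gte(stats::median(est), 0.85)
  expect_lte(stats::median(est), 0.95)
})

test_that("independent traits show near-zero correlations", {
  traits <- dplyr::bind_rows(
    trait_gen("a", mu = 10, sigma2_g = 4, sigma2_gy = 1, sigma2_e = 2),
    trait_gen("b", mu = 20, sigma2_g = 9, sigma2_gy = 1, sigma2_e = 2)
  )
  sim <- simulate_trial(sim_config(800, traits, years = 3, blocks = 3, seed = 41))
  ct <- trait_correlations(sim$data)
  expect_lt(abs(ct$r_p["a", "b"]), 0.1)
  expect_lt(abs(ct$r_g["a", "b"]), 0.1)
})

test_that("genotypic correlations exceed phenotypic ones on average", {
  # with zero environmental correlation r_g is the undiluted association
  sims <- sapply(1:6, function(s) {
    traits <- dplyr::bind_rows(
      trait_gen("a", mu = 10, sigma2_g = 4, sigma2_gy = 1, sigma2_e = 3),
      trait_gen("b", mu = 20, sigma2_g = 4, sigma2_gy = 1, sigma2_e = 3)
    )
    sim <- simulate_trial(sim_config(
      300, traits, years = 3, blocks = 3,
      gcorr = matrix(c(1, 0.5, 0.5, 1), 2), seed = 700 + s
    ))
    ct <- trait_correlations(sim$data)
    c(abs(ct$r_g["a", "b"]), abs(ct$r_p["a", "b"]))
  })
  expect_gt(mean(sims[1, ]), mean(sims[2, ]))
})

test_that("component correlation of genotype means agrees with plain correlation", {
  sim <- simulate_breeding_like(n_lines = 490, seed = 19)
  ct <- trait_correlations(sim$data, c("PC", "GC"))
  gm <- genotype_means(sim$data, c("PC", "GC"))
  expect_equal(ct$r_p["PC", "GC"], cor(gm$PC, gm$GC), tolerance = 0.03)
})
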