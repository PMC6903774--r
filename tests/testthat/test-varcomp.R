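test_that("sums of squares match the brute-force cell-mean oracle", {
  # deterministic integer effect tables
  ds1 <- make_effect_dataset(
    g_eff = c(g1 = -2, g2 = 1, g3 = 1),
    y_eff = c(`1` = -1, `2` = 1),
    b_eff = c(`1:1` = 1, `1:2` = -1, `2:1` = 0, `2:2` = 0),
    gy_eff = c(
      `g1:1` = 1, `g2:1` = -1, `g3:1` = 0,
      `g1:2` = -1, `g2:2` = 1, `g3:2` = 0
    ),
    resid = c(1, -1, 0, 0, 0, 0, 2, -2, 0, 1, -1, 0)
  )
  # random datasets over all designs up to 3 genotypes x 3 years x 2 blocks
  set.seed(99)
  cases <- list(ds1)
  for (g in 2:3) {
    for (yy in 2:3) {
      grid <- expand.grid(
        genotype = paste0("g", 1:g), year = 1:yy, block = 1:2,
        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
      )
      grid$y <- round(stats::rnorm(nrow(grid), 10, 3), 3)
      cases <- c(cases, list(as_trial_data(grid)))
    }
  }
  for (ds in cases) {
    a <- anova_multiyear_rcbd(ds, "y")
    oracle <- brute_force_ss(as.data.frame(ds), "y")
    expect_equal(setNames(a$ss, a$source), oracle, tolerance = 1e-9)
    expect_equal(sum(a$df), nrow(ds) - 1)
  }
})

test_that("anova is translation-invariant and refuses bad designs", {
  ds <- make_effect_dataset(resid = stats::rnorm(12, sd = 0.5))
  a1 <- anova_multiyear_rcbd(ds, "y")
  shifted <- as.data.frame(ds)
  shifted$y <- shifted$y + 100
  a2 <- anova_multiyear_rcbd(as_trial_data(shifted), "y")
  expect_equal(a1$ms, a2$ms, tolerance = 1e-9)

  unbal <- suppressWarnings(as_trial_data(as.data.frame(ds)[-1, ]))
  expect_error(anova_multiyear_rcbd(unbal, "y"), "unbalanced")

  one_year <- make_effect_dataset(y_eff = c(`1` = 0))
  expect_error(anova_multiyear_rcbd(one_year, "y"), "at least 2 years")
})

test_that("null model: all mean squares estimate the residual variance", {
  set.seed(7)
  ms <- replicate(60, {
    grid <- expand.grid(
      genotype = paste0("g", 1:6), year = 1:3, block = 1:3,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    grid$y <- stats::rnorm(nrow(grid), 0, 2)
    anova_multiyear_rcbd(as_trial_data(grid), "y")$ms
  })
  expect_equal(rowMeans(ms), rep(4, 5), tolerance = 0.25)
})

test_that("component estimation follows the expected-mean-squares solve", {
  vd <- estimate_components(
    c(ms_genotype = 100, ms_gxy = 10, ms_error = 1), r = 3, y = 3
  )
  expect_equal(vd$sigma2_e, 1)
  expect_equal(vd$sigma2_gy, 3)
  expect_equal(vd$sigma2_g, 10)
  expect_equal(vd$sigma2_p, 10 + 1 + 1 / 9)
  expect_equal(vd$truncated, "")

  # negative solves clamp to zero with a flag
  clamped <- estimate_components(
    c(ms_genotype = 5, ms_gxy = 10, ms_error = 1), r = 3, y = 3
  )
  expect_equal(clamped$sigma2_g, 0)
  expect_match(clamped$truncated, "sigma2_g")
  expect_equal(heritability(clamped), 0)

  # degenerate: no interaction or error variance
  pure <- estimate_components(
    c(ms_genotype = 90, ms_gxy = 0, ms_error = 0), r = 3, y = 3
  )
  expect_equal(pure$sigma2_p, pure$sigma2_g)
  expect_equal(heritability(pure), 100)
})

test_that("heritability and CVs reproduce published-table arithmetic", {
  expect_equal(round(heritability(list(sigma2_g = 10.31, sigma2_p = 10.73)), 2), 96.09)
  expect_equal(round(heritability(list(sigma2_g = 0.60, sigma2_p = 0.88)), 2), 68.18)

  vd_gy <- tibble::tibble(trait = "GY", sigma2_g = 1.00, sigma2_p = 1.02)
  cv <- gcv_pcv(vd_gy, mu = 3.2)
  expect_equal(round(cv$gcv_percent, 2), 31.25)
  expect_equal(cv$gcv_class, "high")

  vd_ht <- tibble::tibble(trait = "HT", sigma2_g = 10.31, sigma2_p = 10.73)
  cv_ht <- gcv_pcv(vd_ht, mu = 29.9)
  expect_equal(round(cv_ht$pcv_percent, 2), 10.96)
  expect_equal(cv_ht$pcv_class, "moderate")

  zero <- gcv_pcv(tibble::tibble(trait = "z", sigma2_g = 0, sigma2_p = 0.5), mu = 2)
  expect_equal(zero$gcv_percent, 0)
  expect_equal(zero$gcv_class, "low")
  expect_error(gcv_pcv(vd_gy, mu = 0), "positive")
})

test_that("pcv never falls below gcv on estimated components", {
  sim <- simulate_breeding_like(n_lines = 90, seed = 6)
  vc <- variance_components(sim$data)
  expect_true(all(vc$pcv_percent >= vc$gcv_percent))
  expect_true(all(vc$h2b_percent >= 0 & vc$h2b_percent <= 100))
})

test_that("components are recovered from simulated data with known truth", {
  est <- t(sapply(1:30, function(s) {
    sim <- simulate_trial(sim_config(
      400,
      trait_gen("y", mu = 30, sigma2_g = 10.31, sigma2_y = 1, sigma2_gy = 0.63,
                sigma2_b = 0.2, sigma2_e = 1.89),
      years = 3, blocks = 3, seed = 1000 + s
    ))
    vd <- estimate_components(anova_multiyear_rcbd(sim$data, "y"))
    c(vd$sigma2_g, vd$sigma2_gy, vd$sigma2_e, heritability(vd))
  }))
  med <- apply(est, 2, stats::median)
  expect_equal(med[1], 10.31, tolerance = 0.05 * 10.31)
  expect_equal(med[2], 0.63, tolerance = 0.12 * 0.63)
  expect_equal(med[3], 1.89, tolerance = 0.05 * 1.89)
  expect_equal(med[4], 96.09, tolerance = 1)
})

test_that("tidy and glance expose the anova in broom shape", {
  ds <- make_effect_dataset(resid = stats::rnorm(12))
  a <- anova_multiyear_rcbd(ds, "y")
  td <- tidy(a)
  expect_named(td, c("source", "df", "ss", "ms", "statistic", "p.value"))
  gl <- glance(a)
  expect_equal(gl$g, 3)
  expect_equal(gl$statistic, td$statistic[td$source == "genotype"])
})
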