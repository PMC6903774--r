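test_that("dataset assembly infers the design and flags imbalance", {
  df <- expand.grid(
    genotype = c("g1", "g2"), year = 1:2, block = 1:2,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  df$yield <- 1:8
  ds <- as_trial_data(df)
  d <- trial_design(ds)
  expect_equal(d[c("r", "y", "g")], list(r = 2L, y = 2L, g = 2L))
  expect_true(d$balanced)

  expect_warning(as_trial_data(df[-1, ]), "unbalanced")
  expect_false(trial_design(suppressWarnings(as_trial_data(df[-1, ])))$balanced)

  expect_error(as_trial_data(rbind(df, df[1, ])), "duplicate")
  expect_error(
    as_trial_data(df[, -1]), "missing required column"
  )
})

test_that("disease scores outside [0, 9] are rejected", {
  df <- expand.grid(
    genotype = c("g1", "g2"), year = 1:2, block = 1:2,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  df$PM <- 10
  spec <- trait_spec("PM", merit_direction = "lower_better", kind = "disease_score")
  expect_error(as_trial_data(df, spec), "outside")
})

test_that("csv round-trip is identity on records", {
  sim <- simulate_collection_like(n_genotypes = 12, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(sim$data, path)
  back <- read_trial_csv(path, traits = trial_traits(sim$data))
  expect_equal(
    as.data.frame(back)[order(back$genotype, back$year, back$block), ],
    as.data.frame(sim$data)[order(sim$data$genotype, sim$data$year, sim$data$block), ],
    tolerance = 1e-12, ignore_attr = TRUE
  )
})

test_that("unknown trait columns in the spec are dropped with a warning", {
  df <- expand.grid(
    genotype = c("g1", "g2"), year = 1:2, block = 1:2,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  df$yield <- 1
  expect_warning(
    ds <- as_trial_data(df, trait_spec(c("yield", "ghost"))),
    "ghost"
  )
  expect_equal(trial_traits(ds)$trait, "yield")
})

test_that("genotype means average plot values and respect level", {
  ds <- make_effect_dataset(
    g_eff = c(g1 = 0, g2 = 0), y_eff = c(`1` = 0, `2` = 0),
    resid = c(4, 6, 0, 0, 0, 0, 2, 2), mu = 0
  )
  # g1 cells: rows with genotype g1 = 4, 0, 0, 2 -> mean 1.5
  gm <- genotype_means(ds, "y")
  expect_equal(gm$y[gm$genotype == "g1"], 1.5)

  # constant dataset: every genotype maps to the constant
  const <- make_effect_dataset(
    g_eff = c(g1 = 0, g2 = 0), y_eff = c(`1` = 0, `2` = 0), mu = 7
  )
  expect_true(all(genotype_means(const, "y")$y == 7))

  # per-year and across-year agree for a single year
  one_year <- make_effect_dataset(
    g_eff = c(g1 = 1, g2 = -1), y_eff = c(`1` = 0),
    resid = c(0.3, -0.1, 0.2, 0.4), mu = 5
  )
  expect_equal(
    genotype_means(one_year, "y", level = "per_year")$y,
    genotype_means(one_year, "y", level = "across_years")$y
  )
})

test_that("across-year means equal simulated genotypic values under zero noise", {
  cfg <- sim_config(
    8, trait_gen("y", mu = 12, sigma2_g = 4),
    years = 3, blocks = 2, seed = 11
  )
  sim <- simulate_trial(cfg)
  gm <- genotype_means(sim$data, "y")
  expect_equal(gm$y, sim$genotypes$y[match(gm$genotype, sim$genotypes$genotype)])
})

test_that("trait summaries match hand-computed dispersion and ignore row order", {
  ds <- make_effect_dataset(
    g_eff = c(g1 = -1, g2 = 1), y_eff = c(`1` = 0, `2` = 0), mu = 2
  )
  s <- summarize_traits(ds, "y")
  expect_equal(s$mean, 2)
  expect_equal(c(s$min, s$max), c(1, 3))
  # sd of {1, 3} = sqrt(2); cv = 100 * sqrt(2) / 2
  expect_equal(s$cv_percent, 100 * sqrt(2) / 2, tolerance = 1e-10)
  expect_equal(s$se, sqrt(2) / sqrt(2), tolerance = 1e-10)

  shuffled <- as_trial_data(as.data.frame(ds)[sample(nrow(ds)), ])
  expect_equal(summarize_traits(shuffled, "y"), s)

  # all genotype means equal -> cv 0
  const <- make_effect_dataset(
    g_eff = c(g1 = 0, g2 = 0), y_eff = c(`1` = 0, `2` = 0), mu = 3
  )
  expect_equal(summarize_traits(const, "y")$cv_percent, 0)
})

test_that("country labels collapse onto the four partitioning regions", {
  df <- expand.grid(
    genotype = c("g1", "g2", "g3"), year = 1:2, block = 1:2,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  df$region <- c("Iran", "Italy", "Atlantis")[match(df$genotype, c("g1", "g2", "g3"))]
  df$y <- 1
  ds <- assign_regions(as_trial_data(df), c(Iran = "Asia", Italy = "Europe"))
  expect_equal(
    unique(ds[c("genotype", "region")])$region,
    c("Asia", "Europe", "others")
  )
  expect_error(
    assign_regions(as_trial_data(df), c(Iran = "Narnia")),
    "unknown region"
  )
})
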