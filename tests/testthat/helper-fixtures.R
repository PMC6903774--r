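# Small deterministic fixtures and independent oracles shared by tests.

# A fully balanced dataset built from explicit effect tables, so every
# sum of squares can be recomputed from first principles.
make_effect_dataset <- function(g_eff = c(g1 = -2, g2 = 1, g3 = 1),
                                y_eff = c(`1` = -1, `2` = 1),
                                b_eff = NULL,
                                gy_eff = NULL,
                                resid = NULL,
                                blocks = 2,
                                mu = 10) {
  genotypes <- names(g_eff)
  years <- as.integer(names(y_eff))
  grid <- expand.grid(
    genotype = genotypes, year = years, block = seq_len(blocks),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  v <- mu + g_eff[grid$genotype] + y_eff[as.character(grid$year)]
  if (!is.null(b_eff)) {
    v <- v + b_eff[paste(grid$year, grid$block, sep = ":")]
  }
  if (!is.null(gy_eff)) {
    v <- v + gy_eff[paste(grid$genotype, grid$year, sep = ":")]
  }
  if (!is.null(resid)) {
    v <- v + resid
  }
  grid$y <- unname(v)
  as_trial_data(grid)
}

# Brute-force sums of squares from cell-mean definitions: every mean is
# recomputed by subsetting, one observation at a time. Independent of
# the package's closed-form implementation.
brute_force_ss <- function(df, trait) {
  v <- df[[trait]]
  g <- df$genotype
  yr <- df$year
  bl <- df$block
  grand <- mean(v)
  n_r <- length(unique(bl))
  n_y <- length(unique(yr))
  ss_g <- 0
  for (gi in unique(g)) {
    ss_g <- ss_g + n_r * n_y * (mean(v[g == gi]) - grand)^2
  }
  ss_y <- 0
  for (yj in unique(yr)) {
    ss_y <- ss_y + length(unique(g)) * n_r * (mean(v[yr == yj]) - grand)^2
  }
  ss_b <- 0
  for (yj in unique(yr)) {
    for (bk in unique(bl)) {
      ss_b <- ss_b + length(unique(g)) *
        (mean(v[yr == yj & bl == bk]) - mean(v[yr == yj]))^2
    }
  }
  ss_gy <- 0
  for (gi in unique(g)) {
    for (yj in unique(yr)) {
      ss_gy <- ss_gy + n_r * (mean(v[g == gi & yr == yj]) -
        mean(v[g == gi]) - mean(v[yr == yj]) + grand)^2
    }
  }
  ss_e <- 0
  for (i in seq_along(v)) {
    fitted <- mean(v[g == g[i] & yr == yr[i]]) +
      mean(v[yr == yr[i] & bl == bl[i]]) - mean(v[yr == yr[i]])
    ss_e <- ss_e + (v[i] - fitted)^2
  }
  c(
    genotype = ss_g, year = ss_y, block_in_year = ss_b,
    genotype_x_year = ss_gy, error = ss_e
  )
}

# Brute-force sums of cross-products by the same cell-mean definitions.
brute_force_scp <- function(df, trait1, trait2) {
  g <- df$genotype
  yr <- df$year
  bl <- df$block
  n_r <- length(unique(bl))
  n_y <- length(unique(yr))
  dev_g <- function(v, gi) mean(v[g == gi]) - mean(v)
  dev_gy <- function(v, gi, yj) {
    mean(v[g == gi & yr == yj]) - mean(v[g == gi]) - mean(v[yr == yj]) + mean(v)
  }
  x <- df[[trait1]]
  z <- df[[trait2]]
  scp_g <- 0
  for (gi in unique(g)) scp_g <- scp_g + n_r * n_y * dev_g(x, gi) * dev_g(z, gi)
  scp_gy <- 0
  for (gi in unique(g)) {
    for (yj in unique(yr)) {
      scp_gy <- scp_gy + n_r * dev_gy(x, gi, yj) * dev_gy(z, gi, yj)
    }
  }
  resid <- function(v, i) {
    v[i] - mean(v[g == g[i] & yr == yr[i]]) -
      mean(v[yr == yr[i] & bl == bl[i]]) + mean(v[yr == yr[i]])
  }
  scp_e <- 0
  for (i in seq_along(x)) scp_e <- scp_e + resid(x, i) * resid(z, i)
  c(genotype = scp_g, genotype_x_year = scp_gy, error = scp_e)
}

# One simulated two-group dataset with a planted mean separation, and the
# misassignment count of a cluster solution against the true groups:
# each cluster votes for its majority group; members outside the
# majority count as misassigned.
planted_two_groups <- function(seed, n_per_group = 20, shift = 6,
                               n_traits = 5) {
  traits <- purrr::map_dfr(seq_len(n_traits), function(k) {
    trait_gen(
      name = paste0("t", k), mu = 10, sigma2_g = 1, sigma2_gy = 0.2,
      sigma2_e = 0.5,
      region_shift = c(A = 0, B = shift)
    )
  })
  cfg <- sim_config(
    n_genotypes = 2 * n_per_group, traits = traits,
    years = 3, blocks = 3, regions = c(A = 0.5, B = 0.5), seed = seed
  )
  simulate_trial(cfg)
}

misassignments <- function(cs, truth) {
  truth <- truth[cs$assignments$genotype]
  cl <- cs$assignments$cluster
  bad <- 0
  for (k in unique(cl)) {
    members <- truth[cl == k]
    majority <- names(sort(table(members), decreasing = TRUE))[1]
    bad <- bad + sum(members != majority)
  }
  bad
}
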