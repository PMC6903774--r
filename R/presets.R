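# Collection preset: 77 accessions from 4 regions, 3 years x 3 blocks.
# The published between-accession CV describes across-year accession
# means, so (cv/100 * mu)^2 is taken as the phenotypic variance of a
# genotype mean; the published heritability splits it into sigma2_g =
# h2 * sigma2_p and a non-genetic remainder divided equally between the
# G-by-Y and residual contributions (sigma2_gy/y = sigma2_e/(r*y)),
# since neither is published separately.
collection_params <- function() {
  tibble(
    trait = c("HT", "PH", "GY", "SW", "TGW", "PC", "GC"),
    mu = c(33.0, 109.3, 2.8, 77.7, 54.0, 13.4, 10.2),
    cv = c(6.9, 7.3, 21.3, 4.8, 13.1, 5.4, 6.6),
    h2 = c(92.62, 85.37, 29.20, 97.68, 99.14, 85.35, 87.98) / 100,
    # relative strength of regional differentiation, largest for the
    # grain-size traits that separate regions most strongly
    gst_weight = c(0.12, 0.15, 0.08, 0.14, 0.27, 0.10, 0.08)
  )
}

breeding_rg_matrix <- function() {
  traits <- c("HT", "PH", "GY", "SW", "TGW", "PC", "GC", "PM", "STB", "YR", "LR")
  lower <- c(
    0.07,
    -0.34, -0.20,
    0.15, 0.61, -0.10,
    0.13, 0.41, 0.31, 0.46,
    0.07, 0.21, -0.09, 0.17, 0.00,
    0.15, 0.20, -0.08, 0.15, 0.03, 0.94,
    0.20, 0.03, -0.20, -0.05, -0.04, 0.17, 0.17,
    0.02, -0.10, 0.15, -0.10, 0.02, 0.09, 0.11, 0.56,
    0.22, 0.03, -0.35, 0.09, -0.08, -0.01, 0.01, 0.36, 0.14,
    0.08, -0.13, -0.51, -0.12, -0.25, -0.20, -0.21, 0.18, -0.06, 0.33
  )
  m <- diag(length(traits))
  m[lower.tri(m)] <- lower
  m <- m + t(m) - diag(length(traits))
  dimnames(m) <- list(traits, traits)
  # project to the nearest PSD correlation matrix if sampling noise in the
  # published lower triangle pushed an eigenvalue slightly below zero
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) < 0) {
    v <- pmax(e$values, 1e-6)
    m <- e$vectors %*% diag(v) %*% t(e$vectors)
    d <- sqrt(diag(m))
    m <- m / tcrossprod(d)
    dimnames(m) <- list(traits, traits)
  }
  m
}

# Breeding preset: sigma2_g and sigma2_p as published for the RIL
# population; the gap sigma2_p - sigma2_g split equally between the
# G-by-Y and residual contributions to the phenotypic variance of a
# genotype mean (sigma2_gy = 1.5 * gap, sigma2_e = 4.5 * gap for y = r = 3).
breeding_params <- function() {
  p <- tibble(
    trait = c("HT", "PH", "GY", "SW", "TGW", "PC", "GC", "PM", "STB", "YR", "LR"),
    mu = c(29.9, 100.0, 3.2, 49.6, 80.6, 15.6, 11.5, 2.0, 1.9, 0.9, 2.7),
    sigma2_g = c(10.31, 364.13, 1.00, 53.89, 3.57, 0.86, 0.83, 1.55, 0.60, 0.79, 3.30),
    sigma2_p = c(10.73, 370.73, 1.02, 70.45, 3.88, 1.00, 0.94, 1.84, 0.88, 1.05, 3.70)
  )
  gap <- pmax(p$sigma2_p - p$sigma2_g, 0)
  p$sigma2_gy <- 3 * gap / 2
  p$sigma2_e <- 9 * gap / 2
  p
}

#' Simulate a germplasm-collection-like trial
#'
#' Convenience preset emulating a 77-accession collection from four
#' regions of origin (Africa, Asia, Europe, others; weights matching the
#' reference collection's 9/49/12/7 split) grown for 3 years in 3 blocks.
#' Trait means and between-genotype CVs follow the reference collection;
#' regional mean shifts are proportional to each trait's relative
#' between-region differentiation, scaled by `region_sd` genotypic
#' standard deviations.
#'
#' @param n_genotypes Number of accessions (default 77).
#' @param region_sd Overall strength of regional differentiation, in
#'   genotypic-SD units for the most-differentiated trait (default 1);
#'   `0` removes all between-region structure.
#' @param years,blocks Design constants (default 3 and 3).
#' @param seed Integer seed.
#' @return A `sim_trial` (see [simulate_trial()]).
#' @export
simulate_collection_like <- function(n_genotypes = 77, region_sd = 1,
                                     years = 3, blocks = 3, seed = 1L) {
  par <- collection_params()
  regions <- c(Asia = 49 / 77, Europe = 12 / 77, Africa = 9 / 77, others = 7 / 77)
  # symmetric region offsets so the grand mean is unchanged
  offsets <- c(Asia = -0.5, Europe = 0.5, Africa = -1.5, others = 1.5)
  traits <- purrr::pmap_dfr(par, function(trait, mu, cv, h2, gst_weight) {
    sp <- (cv / 100 * mu)^2
    sg <- h2 * sp
    gap <- sp - sg
    shift_sd <- region_sd * sqrt(sg) * gst_weight / max(par$gst_weight)
    trait_gen(
      name = trait, mu = mu, sigma2_g = sg,
      sigma2_gy = years * gap / 2, sigma2_e = (years * blocks) * gap / 2,
      region_shift = offsets * shift_sd
    )
  })
  cfg <- sim_config(
    n_genotypes = n_genotypes, traits = traits, years = years,
    blocks = blocks, regions = regions, seed = seed
  )
  simulate_trial(cfg, trait_spec = wheat_trait_spec(include_disease = FALSE))
}

#' Simulate a breeding-population-like trial
#'
#' Convenience preset emulating an 800-genotype breeding population (790
#' recombinant inbred lines plus 10 parents, flagged in an `is_parent`
#' column) evaluated for 3 years in 3 blocks. Trait means, genotypic and
#' phenotypic variances match the reference RIL population; genotypic
#' effects across the 11 traits are drawn with the published genotypic
#' correlation structure. Disease scores are clipped to \[0, 9\].
#' The parents are ordinary draws from the same population — they carry
#' no separate parental means — so parent contrasts from this preset
#' exercise the bookkeeping, not the published parent values.
#'
#' @param n_lines Number of RILs (default 790).
#' @param n_parents Number of parent genotypes (default 10).
#' @param years,blocks Design constants (default 3 and 3).
#' @param seed Integer seed.
#' @return A `sim_trial`; `$data` carries `is_parent`.
#' @export
simulate_breeding_like <- function(n_lines = 790, n_parents = 10,
                                   years = 3, blocks = 3, seed = 1L) {
  par <- breeding_params()
  traits <- purrr::pmap_dfr(par, function(trait, mu, sigma2_g, sigma2_p,
                                          sigma2_gy, sigma2_e) {
    score <- trait %in% c("PM", "STB", "YR", "LR")
    trait_gen(
      name = trait, mu = mu, sigma2_g = sigma2_g,
      sigma2_gy = sigma2_gy, sigma2_e = sigma2_e,
      clip = if (score) c(0, 9)
    )
  })
  cfg <- sim_config(
    n_genotypes = n_lines + n_parents, traits = traits,
    years = years, blocks = blocks,
    gcorr = breeding_rg_matrix(), seed = seed
  )
  sim <- simulate_trial(cfg, trait_spec = wheat_trait_spec())
  parents <- utils::tail(sort(unique(sim$data$genotype)), n_parents)
  sim$data$is_parent <- sim$data$genotype %in% parents
  sim$genotypes$is_parent <- sim$genotypes$genotype %in% parents
  sim
}
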