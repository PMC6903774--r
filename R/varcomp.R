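#' Multi-year RCBD analysis of variance for one trait
#'
#' Fits the balanced fixed-effects decomposition of the model
#' \deqn{y_{ijk} = \mu + G_i + Y_j + B_{k(j)} + (GY)_{ij} + e_{ijk}}
#' (genotype, year, block nested in year, genotype-by-year, residual) by
#' the standard closed-form sums of squares for a randomized complete
#' block design repeated over years. Years are treated as environments:
#' the genotype F statistic uses the G-by-Y mean square as denominator,
#' while year, block and G-by-Y are tested against the residual.
#'
#' Requires a balanced dataset (every genotype observed in every
#' year x block cell); the expected-mean-squares algebra downstream
#' assumes balance, so unbalanced data are refused rather than silently
#' mis-estimated.
#'
#' @param ds A balanced `trial_df` with `y >= 2` years and `r >= 2`
#'   blocks.
#' @param trait Trait name.
#' @return An `rcbd_anova` object: a tibble with columns `source`
#'   (genotype, year, block_in_year, genotype_x_year, error), `df`,
#'   `ss`, `ms`, `statistic`, `p.value`, carrying `trait`, `r`, `y`,
#'   `g` and the grand `mean` as attributes.
#' @examples
#' sim <- simulate_trial(sim_config(
#'   20, trait_gen("y", 10, sigma2_g = 2, sigma2_gy = 0.5, sigma2_e = 1),
#'   years = 3, blocks = 3, seed = 5
#' ))
#' anova_multiyear_rcbd(sim$data, "y")
#' @export
anova_multiyear_rcbd <- function(ds, trait) {
  trait <- trait_cols(ds, trait)
  design <- trial_design(ds)
  if (!design$balanced) {
    cells <- tidyr::expand_grid(
      genotype = unique(ds$genotype),
      year = unique(ds$year), block = unique(ds$block)
    )
    have <- dplyr::semi_join(cells, as_tibble(as.data.frame(ds)),
      by = c("genotype", "year", "block")
    )
    miss <- dplyr::anti_join(cells, have, by = c("genotype", "year", "block"))
    abort(paste0(
      "unbalanced design: ", nrow(miss), " missing cell(s), e.g. ",
      paste(utils::head(
        sprintf("(%s, %s, %s)", miss$genotype, miss$year, miss$block), 3
      ), collapse = ", ")
    ))
  }
  if (design$y < 2 || design$r < 2) {
    abort("need at least 2 years and 2 blocks")
  }
  v <- ds[[trait]]
  if (anyNA(v)) {
    abort(paste0("trait '", trait, "' has missing plot values"))
  }
  g <- factor(ds$genotype)
  yr <- factor(ds$year)
  bl <- factor(paste(ds$year, ds$block, sep = ":"))
  n_g <- nlevels(g)
  n_y <- design$y
  n_r <- design$r

  grand <- mean(v)
  m_g <- tapply(v, g, mean)
  m_y <- tapply(v, yr, mean)
  m_yb <- tapply(v, bl, mean)
  m_gy <- tapply(v, list(g, yr), mean)

  ss_g <- n_r * n_y * sum((m_g - grand)^2)
  ss_y <- n_g * n_r * sum((m_y - grand)^2)
  ss_b <- n_g * sum((m_yb - m_y[sub(":.*", "", names(m_yb))])^2)
  ss_gy <- n_r * sum((sweep(sweep(m_gy, 1, m_g), 2, m_y) + grand)^2)
  fit <- v - m_gy[cbind(g, yr)] - m_yb[bl] + m_y[yr]
  ss_e <- sum(fit^2)

  df <- c(
    genotype = n_g - 1L,
    year = n_y - 1L,
    block_in_year = n_y * (n_r - 1L),
    genotype_x_year = (n_g - 1L) * (n_y - 1L),
    error = n_y * (n_g - 1L) * (n_r - 1L)
  )
  ss <- c(ss_g, ss_y, ss_b, ss_gy, ss_e)
  ms <- ss / df
  # mixed-model convention: genotype tested over G x Y, the rest over error
  f <- c(
    ms[1] / ms[4], ms[2] / ms[5], ms[3] / ms[5], ms[4] / ms[5], NA
  )
  fdf2 <- c(df[4], df[5], df[5], df[5], NA)
  p <- stats::pf(f, df, fdf2, lower.tail = FALSE)
  out <- tibble(
    source = names(df), df = unname(df), ss = unname(ss), ms = unname(ms),
    statistic = unname(f), p.value = unname(p)
  )
  structure(out,
    trait = trait, r = n_r, y = n_y, g = n_g, mean = grand,
    class = c("rcbd_anova", class(out))
  )
}

#' @export
print.rcbd_anova <- function(x, ...) {
  cat(sprintf(
    "# Multi-year RCBD ANOVA: %s (g = %d, y = %d, r = %d)\n",
    attr(x, "trait"), attr(x, "g"), attr(x, "y"), attr(x, "r")
  ))
  NextMethod()
}

#' Variance components from expected mean squares
#'
#' Solves the balanced expected-mean-squares equations of the multi-year
#' RCBD with genotypes random and years as environments:
#' \deqn{\sigma^2_e = MS_E,\quad
#'       \sigma^2_{gy} = (MS_{GY} - MS_E)/r,\quad
#'       \sigma^2_g = (MS_G - MS_{GY})/(r y)}
#' and forms the phenotypic variance of a genotype mean
#' \deqn{\sigma^2_p = \sigma^2_g + \sigma^2_{gy}/y + \sigma^2_e/(r y).}
#' Negative solutions (possible by sampling noise) are clamped to zero
#' and flagged in `truncated`.
#'
#' @param ms An `rcbd_anova`, or a named list/vector with `ms_genotype`,
#'   `ms_gxy`, `ms_error`.
#' @param r,y Design constants; taken from `ms` when it is an
#'   `rcbd_anova`.
#' @return A `variance_decomposition`: a one-row tibble with columns
#'   `trait`, `sigma2_g`, `sigma2_gy`, `sigma2_e`, `sigma2_p`, `r`, `y`,
#'   `truncated` (character, which components were clamped).
#' @examples
#' estimate_components(
#'   c(ms_genotype = 100, ms_gxy = 10, ms_error = 1), r = 3, y = 3
#' )
#' @export
estimate_components <- function(ms, r = NULL, y = NULL) {
  if (inherits(ms, "rcbd_anova")) {
    r <- r %||% attr(ms, "r")
    y <- y %||% attr(ms, "y")
    trait <- attr(ms, "trait")
    ms_g <- ms$ms[ms$source == "genotype"]
    ms_gy <- ms$ms[ms$source == "genotype_x_year"]
    ms_e <- ms$ms[ms$source == "error"]
  } else {
    ms <- as.list(ms)
    trait <- ms$trait %||% NA_character_
    ms_g <- ms$ms_genotype
    ms_gy <- ms$ms_gxy
    ms_e <- ms$ms_error
  }
  if (is.null(r) || is.null(y)) {
    abort("design constants r and y are required")
  }
  s_e <- ms_e
  s_gy <- (ms_gy - ms_e) / r
  s_g <- (ms_g - ms_gy) / (r * y)
  truncated <- character(0)
  if (s_gy < 0) {
    truncated <- c(truncated, "sigma2_gy")
    s_gy <- 0
  }
  if (s_g < 0) {
    truncated <- c(truncated, "sigma2_g")
    s_g <- 0
  }
  out <- tibble(
    trait = trait,
    sigma2_g = s_g, sigma2_gy = s_gy, sigma2_e = s_e,
    sigma2_p = s_g + s_gy / y + s_e / (r * y),
    r = as.integer(r), y = as.integer(y),
    truncated = paste(truncated, collapse = ",")
  )
  class(out) <- c("variance_decomposition", class(out))
  out
}

#' Broad-sense heritability
#'
#' \eqn{h^2_b = 100 \, \sigma^2_g / \sigma^2_p}, the percentage of the
#' phenotypic variance of a genotype mean attributable to genotypic
#' variance. Undefined (`NA`) when `sigma2_p` is zero.
#'
#' @param vd A `variance_decomposition` (or anything with `sigma2_g` and
#'   `sigma2_p` fields).
#' @return Heritability in percent, in \[0, 100\].
#' @examples
#' heritability(list(sigma2_g = 10.31, sigma2_p = 10.73))
#' @export
heritability <- function(vd) {
  if (vd$sigma2_p <= 0) {
    return(NA_real_)
  }
  100 * vd$sigma2_g / vd$sigma2_p
}

cv_class <- function(cv) {
  dplyr::case_when(
    is.na(cv) ~ NA_character_,
    cv <= 10 ~ "low",
    cv <= 20 ~ "moderate",
    TRUE ~ "high"
  )
}

h2_class <- function(h2) {
  dplyr::case_when(
    is.na(h2) ~ NA_character_,
    h2 >= 80 ~ "very high",
    h2 >= 60 ~ "moderately high",
    h2 >= 40 ~ "medium",
    TRUE ~ "low"
  )
}

#' Genotypic and phenotypic coefficients of variation
#'
#' \eqn{GCV = 100\sqrt{\sigma^2_g}/\mu}, \eqn{PCV =
#' 100\sqrt{\sigma^2_p}/\mu}, each classified into the conventional
#' low (0-10%), moderate (10-20%) and high (>20%) bands. PCV >= GCV
#' always, since the phenotypic variance contains the genotypic.
#'
#' @param vd A `variance_decomposition`.
#' @param mu Trait mean (must be positive).
#' @return A one-row tibble: `trait`, `gcv_percent`, `pcv_percent`,
#'   `gcv_class`, `pcv_class`.
#' @examples
#' vd <- estimate_components(
#'   c(ms_genotype = 100, ms_gxy = 10, ms_error = 1), r = 3, y = 3
#' )
#' gcv_pcv(vd, mu = 10)
#' @export
gcv_pcv <- function(vd, mu) {
  if (mu <= 0) {
    abort("mu must be positive for a coefficient of variation")
  }
  gcv <- 100 * sqrt(vd$sigma2_g) / mu
  pcv <- 100 * sqrt(vd$sigma2_p) / mu
  tibble(
    trait = vd$trait %||% NA_character_,
    gcv_percent = gcv, pcv_percent = pcv,
    gcv_class = cv_class(gcv), pcv_class = cv_class(pcv)
  )
}

#' Full variance-component table for several traits
#'
#' Runs [anova_multiyear_rcbd()], [estimate_components()],
#' [heritability()] and [gcv_pcv()] for each trait and assembles the
#' standard genetic-parameters table of a breeding-population report.
#'
#' @param ds A balanced `trial_df`.
#' @param traits Character vector of trait names; default all.
#' @return A tibble with one row per trait: `trait`, `mean`, `sigma2_g`,
#'   `sigma2_gy`, `sigma2_e`, `sigma2_p`, `gcv_percent`, `pcv_percent`,
#'   `gcv_class`, `pcv_class`, `h2b_percent`, `h2b_class`, `truncated`.
#' @examples
#' sim <- simulate_trial(sim_config(
#'   50, trait_gen("y", 10, sigma2_g = 4, sigma2_gy = 1, sigma2_e = 2),
#'   seed = 3
#' ))
#' variance_components(sim$data)
#' @export
variance_components <- function(ds, traits = NULL) {
  traits <- trait_cols(ds, traits)
  purrr::map_dfr(traits, function(tr) {
    aov_t <- anova_multiyear_rcbd(ds, tr)
    vd <- estimate_components(aov_t)
    mu <- attr(aov_t, "mean")
    cv <- gcv_pcv(vd, mu)
    tibble(
      trait = tr, mean = mu,
      sigma2_g = vd$sigma2_g, sigma2_gy = vd$sigma2_gy,
      sigma2_e = vd$sigma2_e, sigma2_p = vd$sigma2_p,
      gcv_percent = cv$gcv_percent, pcv_percent = cv$pcv_percent,
      gcv_class = cv$gcv_class, pcv_class = cv$pcv_class,
      h2b_percent = heritability(vd), h2b_class = h2_class(heritability(vd)),
      truncated = vd$truncated
    )
  })
}
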