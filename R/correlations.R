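#' Covariance components for a trait pair from mean cross-products
#'
#' The analysis-of-covariance analogue of [anova_multiyear_rcbd()]: sums
#' of cross-products between two traits are decomposed by the same
#' balanced design sources (genotype, G-by-Y, error) with the same
#' degrees of freedom, and covariance components are obtained by the
#' same expected-mean-squares solve:
#' \eqn{cov_e = MCP_E}, \eqn{cov_{gy} = (MCP_{GY} - MCP_E)/r},
#' \eqn{cov_g = (MCP_G - MCP_{GY})/(ry)}, and
#' \eqn{cov_p = cov_g + cov_{gy}/y + cov_e/(ry)}.
#' With `trait2 == trait1` this reproduces the trait's variance
#' decomposition (no clamping is applied to covariances, which may
#' legitimately be negative).
#'
#' @param ds A balanced `trial_df`.
#' @param trait1,trait2 Trait names.
#' @return A one-row tibble: `trait1`, `trait2`, `cov_g`, `cov_gy`,
#'   `cov_e`, `cov_p`, `r`, `y`.
#' @export
cross_products_anova <- function(ds, trait1, trait2) {
  trait1 <- trait_cols(ds, trait1)
  trait2 <- trait_cols(ds, trait2)
  design <- trial_design(ds)
  if (!design$balanced) {
    abort("unbalanced design: covariance components require balance")
  }
  x <- ds[[trait1]]
  z <- ds[[trait2]]
  if (anyNA(x) || anyNA(z)) {
    abort("missing plot values: covariance components require complete data")
  }
  g <- factor(ds$genotype)
  yr <- factor(ds$year)
  bl <- factor(paste(ds$year, ds$block, sep = ":"))
  n_g <- nlevels(g)
  n_y <- design$y
  n_r <- design$r

  dev <- function(v) {
    grand <- mean(v)
    m_g <- tapply(v, g, mean) - grand
    m_y <- tapply(v, yr, mean) - grand
    m_gy <- sweep(sweep(tapply(v, list(g, yr), mean) - grand, 1, m_g), 2, m_y)
    m_yb <- tapply(v, bl, mean)
    resid <- v - (tapply(v, list(g, yr), mean))[cbind(g, yr)] - m_yb[bl] +
      (tapply(v, yr, mean))[yr]
    list(g = m_g, gy = m_gy, resid = resid)
  }
  dx <- dev(x)
  dz <- dev(z)
  scp_g <- n_r * n_y * sum(dx$g * dz$g)
  scp_gy <- n_r * sum(dx$gy * dz$gy)
  scp_e <- sum(dx$resid * dz$resid)
  df_g <- n_g - 1
  df_gy <- (n_g - 1) * (n_y - 1)
  df_e <- n_y * (n_g - 1) * (n_r - 1)
  mcp_g <- scp_g / df_g
  mcp_gy <- scp_gy / df_gy
  mcp_e <- scp_e / df_e
  cov_e <- mcp_e
  cov_gy <- (mcp_gy - mcp_e) / n_r
  cov_g <- (mcp_g - mcp_gy) / (n_r * n_y)
  tibble(
    trait1 = trait1, trait2 = trait2,
    cov_g = cov_g, cov_gy = cov_gy, cov_e = cov_e,
    cov_p = cov_g + cov_gy / n_y + cov_e / (n_r * n_y),
    r = n_r, y = n_y
  )
}

#' Genotypic and phenotypic correlation for one trait pair
#'
#' \eqn{r_p = cov_p / \sqrt{\sigma^2_{p1}\sigma^2_{p2}}} and
#' \eqn{r_g = cov_g / \sqrt{\sigma^2_{g1}\sigma^2_{g2}}} from covariance
#' and variance components. A genotypic correlation estimate can fall
#' outside \[-1, 1\] by sampling noise; it is reported as computed with
#' `rg_out_of_range = TRUE`, never clamped. Zero genotypic variance in
#' either trait leaves `r_g` undefined.
#'
#' @param cc Output of [cross_products_anova()].
#' @param vd1,vd2 `variance_decomposition`s of the two traits.
#' @return A one-row tibble: `trait1`, `trait2`, `r_p`, `r_g`,
#'   `rg_out_of_range`.
#' @export
correlation_from_components <- function(cc, vd1, vd2) {
  r_p <- cc$cov_p / sqrt(vd1$sigma2_p * vd2$sigma2_p)
  r_g <- if (vd1$sigma2_g > 0 && vd2$sigma2_g > 0) {
    cc$cov_g / sqrt(vd1$sigma2_g * vd2$sigma2_g)
  } else {
    NA_real_
  }
  tibble(
    trait1 = cc$trait1, trait2 = cc$trait2,
    r_p = r_p, r_g = r_g,
    rg_out_of_range = isTRUE(abs(r_g) > 1)
  )
}

rp_significance <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t_stat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
}

#' Phenotypic and genotypic correlation matrices
#'
#' Computes [correlation_from_components()] for every trait pair. The
#' phenotypic correlations carry two-sided t-test p-values with
#' `df = g - 2`; the same approximation is applied to the genotypic
#' correlations and should be read as approximate (component-based
#' estimators have no exact small-sample test).
#'
#' @param ds A balanced `trial_df`.
#' @param traits Character vector of trait names; default all.
#' @return A `trait_correlations` object: list with `r_p` and `r_g`
#'   matrices (phenotypic above / genotypic below a unit diagonal are
#'   both stored in full), `p_p` and `p_g` p-value matrices, the flag
#'   matrix `rg_out_of_range`, and `n_genotypes`.
#' @examples
#' sim <- simulate_breeding_like(n_lines = 90, seed = 2)
#' ct <- trait_correlations(sim$data, c("PC", "GC", "GY"))
#' ct$r_g
#' @export
trait_correlations <- function(ds, traits = NULL) {
  traits <- trait_cols(ds, traits)
  n_t <- length(traits)
  vds <- lapply(traits, function(tr) estimate_components(anova_multiyear_rcbd(ds, tr)))
  names(vds) <- traits
  r_p <- diag(n_t)
  r_g <- diag(n_t)
  flag <- matrix(FALSE, n_t, n_t)
  dimnames(r_p) <- dimnames(r_g) <- dimnames(flag) <- list(traits, traits)
  for (a in seq_len(n_t - 1)) {
    for (b in seq((a + 1), n_t)) {
      cc <- cross_products_anova(ds, traits[a], traits[b])
      est <- correlation_from_components(cc, vds[[a]], vds[[b]])
      r_p[a, b] <- r_p[b, a] <- est$r_p
      r_g[a, b] <- r_g[b, a] <- est$r_g
      flag[a, b] <- flag[b, a] <- est$rg_out_of_range
    }
  }
  n_g <- trial_design(ds)$g
  structure(
    list(
      r_p = r_p, r_g = r_g,
      p_p = rp_significance(r_p, n_g), p_g = rp_significance(r_g, n_g),
      rg_out_of_range = flag, n_genotypes = n_g, traits = traits
    ),
    class = "trait_correlations"
  )
}

#' @export
print.trait_correlations <- function(x, digits = 2, ...) {
  cat(sprintf(
    "# Trait correlations (%d genotypes): phenotypic above, genotypic below diagonal\n",
    x$n_genotypes
  ))
  m <- x$r_p
  m[lower.tri(m)] <- x$r_g[lower.tri(m)]
  print(round(m, digits))
  invisible(x)
}
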