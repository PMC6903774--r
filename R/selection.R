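#' Standardized selection intensity for truncation selection
#'
#' The mean of a standard normal truncated to its upper tail of mass
#' `p`: \eqn{i = \phi(z_p)/p} with \eqn{z_p} the upper-`p` quantile and
#' \eqn{\phi} the standard normal density. This is the selection
#' differential, in phenotypic standard deviations, achieved by keeping
#' the best fraction `p` of a normally distributed population.
#'
#' @param p Selected proportion, in (0, 1).
#' @return The selection intensity `i` (dimensionless, > 0).
#' @examples
#' selection_intensity(0.05) # ~ 2.063
#' selection_intensity(0.5) # sqrt(2/pi)
#' @export
selection_intensity <- function(p) {
  if (any(p <= 0 | p >= 1)) {
    abort("selected proportion must be in (0, 1)")
  }
  dnorm(qnorm(p, lower.tail = FALSE)) / p
}

#' Predicted response to one cycle of truncation selection
#'
#' \eqn{R = h^2_b \, i \, \sqrt{\sigma^2_p}}: the expected change in the
#' population mean, in trait units, after selecting on genotype means
#' whose variance is `sigma2_p`.
#'
#' @param h2b Broad-sense heritability as a *fraction* in \[0, 1\].
#' @param i Selection intensity (see [selection_intensity()]).
#' @param sigma2_p Phenotypic variance of a genotype mean.
#' @return Predicted response `R` in trait units.
#' @examples
#' response_to_selection(0.9609, selection_intensity(0.05), 10.73)
#' @export
response_to_selection <- function(h2b, i, sigma2_p) {
  if (any(h2b < 0 | h2b > 1)) {
    abort("h2b must be a fraction in [0, 1]")
  }
  if (any(sigma2_p < 0)) {
    abort("sigma2_p must be >= 0")
  }
  h2b * i * sqrt(sigma2_p)
}

gain_class <- function(dg) {
  dplyr::case_when(
    is.na(dg) ~ NA_character_,
    dg < 10 ~ "low",
    dg <= 20 ~ "moderate",
    TRUE ~ "high"
  )
}

#' Genetic gain as a percentage of the mean
#'
#' \eqn{\Delta G = 100 R / \mu}, classified into the conventional
#' low (<10%), moderate (10-20%) and high (>20%) bands.
#'
#' @param R Response to selection, trait units.
#' @param mu Population mean (positive).
#' @return Gain percent.
#' @export
genetic_gain_percent <- function(R, mu) {
  if (any(mu <= 0)) {
    abort("mu must be positive")
  }
  100 * R / mu
}

#' Selection-response summary for every trait
#'
#' Joins the variance-component table with the truncation-selection
#' prediction: intensity `i` for the selected proportion `p`, response
#' `R` and genetic gain percent, plus the conventional magnitude classes
#' for heritability and gain.
#'
#' @param ds A balanced `trial_df`, or a precomputed
#'   [variance_components()] table.
#' @param traits Character vector of trait names; default all (ignored
#'   when `ds` is already a variance-component table).
#' @param p Selected proportion (default 0.05, i.e. the best 5%).
#' @return A tibble with one row per trait: the variance-component
#'   columns plus `i`, `R`, `delta_g_percent`, `gain_class`.
#' @examples
#' sim <- simulate_trial(sim_config(
#'   60, trait_gen("y", 10, sigma2_g = 4, sigma2_gy = 1, sigma2_e = 2),
#'   seed = 3
#' ))
#' selection_summary(sim$data, p = 0.05)
#' @export
selection_summary <- function(ds, traits = NULL, p = 0.05) {
  vc <- if (inherits(ds, "trial_df")) variance_components(ds, traits) else ds
  i <- selection_intensity(p)
  vc |>
    dplyr::mutate(
      i = i,
      R = response_to_selection(
        pmin(.data$h2b_percent / 100, 1), i, .data$sigma2_p
      ),
      delta_g_percent = genetic_gain_percent(.data$R, .data$mean),
      gain_class = gain_class(.data$delta_g_percent)
    )
}

#' Realized one-cycle gain on simulated data
#'
#' Selects the top fraction `p` of genotypes on their phenotypic means
#' and reports the mean *genotypic* value of the selected set minus the
#' population mean genotypic value — the realized analogue of the
#' predicted `R`, available when the generating truth is known.
#'
#' @param sim A `sim_trial`.
#' @param trait Trait name.
#' @param p Selected proportion.
#' @param lower_better Select the smallest values instead of the
#'   largest.
#' @return Realized gain in trait units (positive for a successful
#'   higher-better selection).
#' @export
realized_gain <- function(sim, trait, p = 0.05, lower_better = FALSE) {
  gm <- genotype_means(sim$data, trait)
  truth <- sim$genotypes[match(gm$genotype, sim$genotypes$genotype), ]
  n_sel <- max(1L, floor(p * nrow(gm)))
  ord <- order(gm[[trait]], decreasing = !lower_better)
  sel <- ord[seq_len(n_sel)]
  mean(truth[[trait]][sel]) - mean(truth[[trait]])
}
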