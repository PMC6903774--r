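#' Screening thresholds for superior genotypes
#'
#' For each trait the superiority threshold is the population mean of
#' the genotype means plus `k_sd` standard deviations for higher-better
#' traits, or minus `k_sd` SD for lower-better traits (heading time,
#' plant height, disease scores). The population here is the screened
#' genotype set (typically the breeding lines, excluding parents).
#'
#' @param gm Wide genotype-means tibble ([genotype_means()]).
#' @param traits Trait-spec tibble giving merit directions.
#' @param k_sd SD multiplier (default 1).
#' @return A tibble `trait`, `direction`, `mu`, `sd`, `threshold`.
#' @export
screen_rules <- function(gm, traits, k_sd = 1) {
  purrr::pmap_dfr(
    traits[c("trait", "merit_direction")],
    function(trait, merit_direction) {
      v <- gm[[trait]]
      v <- v[!is.na(v)]
      mu <- mean(v)
      s <- sd(v)
      tibble(
        trait = trait,
        direction = merit_direction,
        mu = mu, sd = s,
        threshold = if (merit_direction == "higher_better") {
          mu + k_sd * s
        } else {
          mu - k_sd * s
        }
      )
    }
  )
}

#' Identify superior genotypes per trait and across traits
#'
#' A genotype is superior for a trait when its across-year mean strictly
#' exceeds the mean-plus-`k_sd`-SD threshold (or falls strictly below
#' mean-minus-SD for lower-better traits); boundary values are excluded
#' by default, `strict = FALSE` includes them. Multi-trait superior
#' lines are genotypes superior for at least `k_traits` traits. For each
#' trait, `M` is the mean value of the multi-trait lines that are
#' superior for that trait, `PM` the parent mean, and the parent
#' comparison `100 * (M - PM) / PM`.
#'
#' Thresholds are computed from the screened population (parents
#' excluded when flagged); parents contribute only to `PM`. A trait with
#' zero SD yields an empty superior set with a warning.
#'
#' @param ds A `trial_df`; rows with `is_parent = TRUE` are treated as
#'   parents.
#' @param traits Character vector of trait names; default all.
#' @param k_sd SD multiplier for the threshold (default 1).
#' @param k_traits Minimum number of traits for a multi-trait superior
#'   line (default 6).
#' @param strict Exclude genotypes exactly at the threshold
#'   (default TRUE).
#' @param parents Optional character vector of parent genotype ids
#'   (overrides `is_parent`).
#' @return A `screen_result`: list with
#'   \describe{
#'     \item{per_trait}{tibble `trait`, `n_superior`, `mean_superior`,
#'       `M`, `PM`, `difference_percent`}
#'     \item{superior}{named list of per-trait superior genotype ids}
#'     \item{lines}{tibble of multi-trait superior lines: `genotype`,
#'       `n_traits_superior`, plus the line's mean per trait (NA where
#'       not superior)}
#'     \item{rules}{the thresholds used}
#'   }
#' @examples
#' sim <- simulate_breeding_like(n_lines = 100, seed = 4)
#' scr <- screen_genotypes(sim$data, k_traits = 4)
#' scr$per_trait
#' @export
screen_genotypes <- function(ds, traits = NULL, k_sd = 1, k_traits = 6,
                             strict = TRUE, parents = NULL) {
  trait_names <- trait_cols(ds, traits)
  spec <- trial_traits(ds)
  spec <- spec[spec$trait %in% trait_names, ]
  gm <- genotype_means(ds, trait_names)
  if (is.null(parents) && "is_parent" %in% names(gm)) {
    parents <- gm$genotype[gm$is_parent]
  }
  parents <- parents %||% character(0)
  pop <- gm[!gm$genotype %in% parents, ]
  par_means <- gm[gm$genotype %in% parents, ]
  rules <- screen_rules(pop, spec, k_sd = k_sd)

  superior <- purrr::pmap(
    rules[c("trait", "direction", "threshold", "sd")],
    function(trait, direction, threshold, sd) {
      if (sd == 0) {
        warn(paste0("trait '", trait, "' has zero SD: empty superior set"))
        return(character(0))
      }
      v <- pop[[trait]]
      keep <- if (direction == "higher_better") {
        if (strict) v > threshold else v >= threshold
      } else {
        if (strict) v < threshold else v <= threshold
      }
      pop$genotype[which(keep)]
    }
  )
  names(superior) <- rules$trait

  n_sup <- table(factor(unlist(superior), levels = pop$genotype))
  line_ids <- names(n_sup)[n_sup >= k_traits]
  lines <- tibble(
    genotype = line_ids,
    n_traits_superior = as.integer(n_sup[line_ids])
  )
  for (tr in rules$trait) {
    vals <- pop[[tr]][match(line_ids, pop$genotype)]
    vals[!line_ids %in% superior[[tr]]] <- NA_real_
    lines[[tr]] <- vals
  }

  per_trait <- purrr::map_dfr(rules$trait, function(tr) {
    sup <- superior[[tr]]
    line_vals <- lines[[tr]][!is.na(lines[[tr]])]
    m <- if (length(line_vals)) mean(line_vals) else NA_real_
    pm <- if (nrow(par_means)) mean(par_means[[tr]], na.rm = TRUE) else NA_real_
    tibble(
      trait = tr,
      n_superior = length(sup),
      mean_superior = if (length(sup)) mean(pop[[tr]][match(sup, pop$genotype)]) else NA_real_,
      M = m,
      PM = pm,
      difference_percent = if (!is.na(m) && !is.na(pm)) parent_comparison(m, pm) else NA_real_
    )
  })

  structure(
    list(per_trait = per_trait, superior = superior, lines = lines, rules = rules),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(
    "# Superior-genotype screen: %d multi-trait superior line(s)\n",
    nrow(x$lines)
  ))
  print(x$per_trait)
  invisible(x)
}

#' Percent difference of a superior-line mean from the parent mean
#'
#' \eqn{100 (M - PM) / PM}: positive when the selected lines beat the
#' parents on a higher-better trait, negative when they sit below the
#' parents (the desired direction for heading time, plant height and
#' disease scores). Undefined when `PM` is 0.
#'
#' @param M Mean of the superior lines for the trait.
#' @param PM Parent mean for the trait.
#' @return Percent difference.
#' @examples
#' parent_comparison(5.1, 3.1) # +64.5
#' @export
parent_comparison <- function(M, PM) {
  if (any(PM == 0)) {
    abort("parent mean is 0: percent difference undefined")
  }
  100 * (M - PM) / PM
}
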