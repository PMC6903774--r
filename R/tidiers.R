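#' Tidy a multi-year RCBD ANOVA table
#'
#' @param x An `rcbd_anova`.
#' @param ... Unused.
#' @return A tibble with one row per source: `source`, `df`, `ss`, `ms`,
#'   `statistic`, `p.value`.
#' @method tidy rcbd_anova
#' @export
tidy.rcbd_anova <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' One-row summary of a multi-year RCBD ANOVA
#'
#' @param x An `rcbd_anova`.
#' @param ... Unused.
#' @return A one-row tibble: `trait`, `g`, `y`, `r`, `mean`,
#'   `statistic` (genotype F over G-by-Y) and `p.value`.
#' @method glance rcbd_anova
#' @export
glance.rcbd_anova <- function(x, ...) {
  tibble(
    trait = attr(x, "trait"),
    g = attr(x, "g"), y = attr(x, "y"), r = attr(x, "r"),
    mean = attr(x, "mean"),
    statistic = x$statistic[x$source == "genotype"],
    p.value = x$p.value[x$source == "genotype"]
  )
}

#' Tidy a PCA of genotype means
#'
#' @param x A `trial_pca`.
#' @param matrix `"eigenvalues"` (one row per component),
#'   `"loadings"` (long trait x component table) or `"scores"` (long
#'   genotype x component table).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy trial_pca
#' @export
tidy.trial_pca <- function(x, matrix = c("eigenvalues", "loadings", "scores"),
                           ...) {
  matrix <- match.arg(matrix)
  pcs <- paste0("PC", seq_along(x$eigenvalues))
  switch(matrix,
    eigenvalues = tibble(
      component = pcs,
      eigenvalue = x$eigenvalues,
      proportion = x$proportion,
      cumulative = x$cumulative,
      retained = x$eigenvalues >= 1
    ),
    loadings = as_tibble(x$loadings, rownames = "trait") |>
      tidyr::pivot_longer(-"trait", names_to = "component", values_to = "loading"),
    scores = as_tibble(x$scores, rownames = "genotype") |>
      tidyr::pivot_longer(-"genotype", names_to = "component", values_to = "score")
  )
}

#' One-row summary of a PCA of genotype means
#'
#' @param x A `trial_pca`.
#' @param ... Unused.
#' @return A one-row tibble: `n_traits`, `n_genotypes`, `n_retained`,
#'   `cumulative_retained` (variance fraction carried by the retained
#'   components).
#' @method glance trial_pca
#' @export
glance.trial_pca <- function(x, ...) {
  tibble(
    n_traits = length(x$traits),
    n_genotypes = nrow(x$scores),
    n_retained = x$n_retained,
    cumulative_retained = x$cumulative[max(x$n_retained, 1L)]
  )
}

#' Tidy a Ward cluster solution
#'
#' @param x A `cluster_solution`.
#' @param ... Unused.
#' @return The assignments tibble (`genotype`, `cluster`).
#' @method tidy cluster_solution
#' @export
tidy.cluster_solution <- function(x, ...) {
  x$assignments
}

#' One-row summary of a Ward cluster solution
#'
#' @param x A `cluster_solution`.
#' @param ... Unused.
#' @return A one-row tibble: `n_genotypes`, `n_clusters`,
#'   `cut_fraction`, `cut_height`, `max_height`.
#' @method glance cluster_solution
#' @export
glance.cluster_solution <- function(x, ...) {
  tibble(
    n_genotypes = nrow(x$assignments),
    n_clusters = x$n_clusters,
    cut_fraction = x$cut_fraction,
    cut_height = x$cut_height,
    max_height = max(x$tree$height)
  )
}

#' Tidy a trait-correlation object into a long pair table
#'
#' @param x A `trait_correlations`.
#' @param ... Unused.
#' @return A tibble with one row per unordered trait pair: `trait1`,
#'   `trait2`, `r_p`, `p_p`, `r_g`, `p_g`, `rg_out_of_range`.
#' @method tidy trait_correlations
#' @export
tidy.trait_correlations <- function(x, ...) {
  traits <- x$traits
  pairs <- which(upper.tri(x$r_p), arr.ind = TRUE)
  tibble(
    trait1 = traits[pairs[, "row"]],
    trait2 = traits[pairs[, "col"]],
    r_p = x$r_p[pairs],
    p_p = x$p_p[pairs],
    r_g = x$r_g[pairs],
    p_g = x$p_g[pairs],
    rg_out_of_range = x$rg_out_of_range[pairs]
  )
}
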