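round_cols <- function(df, digits) {
  for (nm in intersect(names(digits), names(df))) {
    df[[nm]] <- round(df[[nm]], digits[[nm]])
  }
  df
}

write_report <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  readr::write_csv(df, path, progress = FALSE)
  path
}

#' Collection-evaluation workflow
#'
#' Runs the full evaluation chain for a germplasm collection with region
#' labels: descriptive trait summaries, within/between-region diversity
#' partition, trait correlations, PCA and Ward clustering — and writes
#' one CSV per table plus a JSON of full-precision results and the
#' parameter choices. Report cells are rounded for display (2 decimals
#' for diversity indices, 1 for means); the JSON keeps full precision.
#'
#' @param ds A `trial_df` (e.g. from [simulate_collection_like()] or
#'   [read_trial_csv()]).
#' @param out_dir Output directory, created if needed.
#' @param traits Character vector of trait names; default all.
#' @param cut_fraction Relative dendrogram cut height (default 0.20).
#' @param balanced_anova Also compute variance components (requires a
#'   balanced design).
#' @return Invisibly, a list with every computed table and the paths of
#'   the written files.
#' @examples
#' sim <- simulate_collection_like(n_genotypes = 40, seed = 9)
#' res <- run_collection_workflow(sim$data, out_dir = tempfile())
#' res$diversity
#' @export
run_collection_workflow <- function(ds, out_dir, traits = NULL,
                                    cut_fraction = 0.20,
                                    balanced_anova = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  traits <- trait_cols(ds, traits)

  summary_tbl <- summarize_traits(ds, traits)
  diversity <- if ("region" %in% names(ds)) {
    partition_diversity(ds, traits)
  } else {
    inform("no 'region' column: diversity partition skipped")
    NULL
  }
  correlations <- if (balanced_anova && trial_design(ds)$balanced) {
    trait_correlations(ds, traits)
  } else {
    NULL
  }
  pca <- pca_on_means(ds, traits)
  clusters <- ward_cluster(pca, cut_fraction = cut_fraction)
  profile <- cluster_profile(ds, clusters, traits)

  paths <- c(
    write_report(
      round_cols(summary_tbl, c(mean = 1, se = 2, min = 1, max = 1, cv_percent = 1)),
      out_dir, "trait_summary"
    ),
    if (!is.null(diversity)) {
      write_report(
        round_cols(
          as_tibble(as.data.frame(diversity)),
          c(ht = 2, hr = 2, hs = 2, gst = 2)
        ),
        out_dir, "diversity_partition"
      )
    },
    if (!is.null(correlations)) {
      write_report(tidy(correlations), out_dir, "trait_correlations")
    },
    write_report(tidy(pca), out_dir, "pca_eigenvalues"),
    write_report(tidy(pca, "loadings"), out_dir, "pca_loadings"),
    write_report(tidy(clusters), out_dir, "cluster_assignments"),
    write_report(
      round_cols(profile$means, c(mean = 1, sd = 2)),
      out_dir, "cluster_means"
    )
  )
  writeLines(dendrogram_newick(clusters), file.path(out_dir, "dendrogram.nwk"))

  full <- list(
    parameters = list(cut_fraction = cut_fraction, traits = traits),
    trait_summary = summary_tbl,
    diversity = if (!is.null(diversity)) as.data.frame(diversity),
    pca_eigenvalues = tidy(pca),
    cluster_assignments = tidy(clusters),
    cluster_sizes = profile$sizes
  )
  jsonlite::write_json(full, file.path(out_dir, "collection_results.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )

  invisible(list(
    trait_summary = summary_tbl, diversity = diversity,
    correlations = correlations, pca = pca, clusters = clusters,
    profile = profile, paths = paths
  ))
}

#' Breeding-population evaluation workflow
#'
#' Runs the evaluation chain for a breeding population: variance
#' components with heritability and CVs joined with the
#' truncation-selection prediction, genotypic/phenotypic correlations,
#' PCA + Ward clustering with per-cluster profiles, and the
#' superior-genotype screen against the flagged parents. Writes one CSV
#' per table plus a full-precision JSON.
#'
#' @param ds A balanced `trial_df`, with parents flagged in an
#'   `is_parent` column for the parent comparison.
#' @param out_dir Output directory, created if needed.
#' @param traits Character vector of trait names; default all.
#' @param p Selected proportion for the gain prediction (default 0.05).
#' @param cut_fraction Relative dendrogram cut height (default 0.20).
#' @param k_traits Multi-trait superior-line threshold (default 6).
#' @param k_sd SD multiplier for screening thresholds (default 1).
#' @return Invisibly, a list with every computed table and the written
#'   paths.
#' @examples
#' sim <- simulate_breeding_like(n_lines = 60, seed = 11)
#' res <- run_breeding_workflow(sim$data, out_dir = tempfile())
#' res$selection
#' @export
run_breeding_workflow <- function(ds, out_dir, traits = NULL, p = 0.05,
                                  cut_fraction = 0.20, k_traits = 6,
                                  k_sd = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  traits <- trait_cols(ds, traits)

  selection <- selection_summary(ds, traits, p = p)
  correlations <- trait_correlations(ds, traits)
  pca <- pca_on_means(ds, traits)
  clusters <- ward_cluster(pca, cut_fraction = cut_fraction)
  profile <- cluster_profile(ds, clusters, traits)
  n_parents <- if ("is_parent" %in% names(ds)) {
    dplyr::n_distinct(ds$genotype[ds$is_parent])
  } else {
    0L
  }
  screen <- if (n_parents >= 2) {
    screen_genotypes(ds, traits, k_sd = k_sd, k_traits = k_traits)
  } else {
    inform("fewer than 2 parents flagged: parent comparison skipped")
    screen_genotypes(ds, traits, k_sd = k_sd, k_traits = k_traits, parents = character(0))
  }

  paths <- c(
    write_report(
      round_cols(selection, c(
        mean = 1, gcv_percent = 2, pcv_percent = 2, h2b_percent = 2,
        i = 3, R = 2, delta_g_percent = 2
      )),
      out_dir, "genetic_parameters"
    ),
    write_report(tidy(correlations), out_dir, "trait_correlations"),
    write_report(tidy(pca), out_dir, "pca_eigenvalues"),
    write_report(tidy(clusters), out_dir, "cluster_assignments"),
    write_report(
      round_cols(profile$means, c(mean = 1, sd = 2)),
      out_dir, "cluster_means"
    ),
    write_report(
      round_cols(screen$per_trait, c(
        mean_superior = 1, M = 1, PM = 1, difference_percent = 1
      )),
      out_dir, "superior_genotypes"
    )
  )

  full <- list(
    parameters = list(
      p = p, i = selection_intensity(p), cut_fraction = cut_fraction,
      k_traits = k_traits, k_sd = k_sd, n_parents = n_parents
    ),
    genetic_parameters = selection,
    correlations = tidy(correlations),
    pca_eigenvalues = tidy(pca),
    cluster_sizes = profile$sizes,
    superior_per_trait = screen$per_trait,
    superior_lines = screen$lines
  )
  jsonlite::write_json(full, file.path(out_dir, "breeding_results.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )

  invisible(list(
    selection = selection, correlations = correlations, pca = pca,
    clusters = clusters, profile = profile, screen = screen, paths = paths
  ))
}
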