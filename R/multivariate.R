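#' Principal component analysis of standardized genotype means
#'
#' Eigen-decomposition of the trait correlation matrix of across-year
#' genotype means (each trait standardized to zero mean, unit SD over
#' genotypes). Eigenvalues therefore sum to the number of traits, and
#' components with eigenvalue >= 1 — those carrying more variance than a
#' single standardized trait — are retained for clustering. Constant
#' traits cannot be standardized and are dropped with a warning.
#'
#' @param ds A `trial_df`, or a wide genotype-means tibble from
#'   [genotype_means()].
#' @param traits Character vector of trait names; default all.
#' @return A `trial_pca`: list with `eigenvalues`, `proportion`,
#'   `cumulative`, `loadings` (traits x components), `scores`
#'   (genotypes x components, rownames = genotype ids), `n_retained`,
#'   `traits`.
#' @examples
#' sim <- simulate_collection_like(seed = 3)
#' pca <- pca_on_means(sim$data)
#' pca$eigenvalues
#' @export
pca_on_means <- function(ds, traits = NULL) {
  gm <- if (inherits(ds, "trial_df")) {
    genotype_means(ds, trait_cols(ds, traits))
  } else {
    ds
  }
  traits <- traits %||% setdiff(
    names(gm)[vapply(gm, is.numeric, logical(1))], c("year", "block")
  )
  x <- as.matrix(gm[traits])
  rownames(x) <- gm$genotype
  constant <- apply(x, 2, function(v) sd(v) == 0 || anyNA(v))
  if (any(constant)) {
    warn(paste0(
      "constant or incomplete trait(s) dropped from PCA: ",
      paste(traits[constant], collapse = ", ")
    ))
    x <- x[, !constant, drop = FALSE]
    traits <- traits[!constant]
  }
  if (ncol(x) < 2 || nrow(x) < 3) {
    abort("PCA needs at least 2 usable traits and 3 genotypes")
  }
  xs <- scale(x)
  eig <- eigen(cor(x), symmetric = TRUE)
  vals <- eig$values
  load <- eig$vectors
  # fix the sign of each component so the largest-|loading| trait loads
  # positively: makes output deterministic across LAPACK builds
  for (k in seq_along(vals)) {
    j <- which.max(abs(load[, k]))
    if (load[j, k] < 0) load[, k] <- -load[, k]
  }
  dimnames(load) <- list(traits, paste0("PC", seq_along(vals)))
  scores <- xs %*% load
  structure(
    list(
      eigenvalues = vals,
      proportion = vals / sum(vals),
      cumulative = cumsum(vals) / sum(vals),
      loadings = load,
      scores = scores,
      n_retained = sum(vals >= 1),
      traits = traits
    ),
    class = "trial_pca"
  )
}

#' @export
print.trial_pca <- function(x, ...) {
  cat(sprintf(
    "# PCA on genotype means: %d traits, %d genotypes, %d component(s) with eigenvalue >= 1\n",
    length(x$traits), nrow(x$scores), x$n_retained
  ))
  print(tibble(
    component = paste0("PC", seq_along(x$eigenvalues)),
    eigenvalue = x$eigenvalues,
    proportion = x$proportion,
    cumulative = x$cumulative
  ))
  invisible(x)
}

#' Ward clustering of genotypes on retained principal components
#'
#' Agglomerative clustering with Ward's minimum-variance criterion on
#' Euclidean distances between genotype scores on the retained
#' components (eigenvalue >= 1). The tree is cut at a *relative* height:
#' merges higher than `cut_fraction` times the maximum merge height are
#' undone, so `cut_fraction = 0.2` reproduces the usual "20% threshold"
#' dendrogram truncation; `k` overrides the fraction with a fixed
#' cluster count. Cluster ids are relabeled contiguously in order of
#' first appearance over the (sorted) genotype ids, which makes
#' assignments independent of input row order.
#'
#' @param pca A `trial_pca`, or a numeric score matrix with genotype
#'   rownames.
#' @param cut_fraction Relative cut height in (0, 1\]; default 0.20.
#' @param k Optional fixed number of clusters (overrides
#'   `cut_fraction`).
#' @param squared Use the classical minimum-variance criterion on
#'   squared Euclidean distances (`hclust` method `"ward.D"`, the
#'   default); `FALSE` switches to the un-squared `"ward.D2"` dialect.
#' @return A `cluster_solution`: list with `assignments` (tibble
#'   `genotype`, `cluster`), `tree` (the `hclust` object), `cut_height`,
#'   `cut_fraction`, `n_clusters`.
#' @examples
#' sim <- simulate_collection_like(seed = 3)
#' cs <- ward_cluster(pca_on_means(sim$data))
#' cs$n_clusters
#' @export
ward_cluster <- function(pca, cut_fraction = 0.20, k = NULL, squared = TRUE) {
  scores <- if (inherits(pca, "trial_pca")) {
    n_keep <- max(pca$n_retained, 1L)
    pca$scores[, seq_len(n_keep), drop = FALSE]
  } else {
    as.matrix(pca)
  }
  if (nrow(scores) < 2) {
    abort("clustering needs at least 2 genotypes")
  }
  if (is.null(k) && (cut_fraction <= 0 || cut_fraction > 1)) {
    abort("cut_fraction must be in (0, 1]")
  }
  ord <- order(rownames(scores))
  scores <- scores[ord, , drop = FALSE]
  d <- stats::dist(scores)
  tree <- stats::hclust(if (squared) d^2 else d,
    method = if (squared) "ward.D" else "ward.D2"
  )
  if (!is.null(k)) {
    raw <- stats::cutree(tree, k = k)
    cut_height <- NA_real_
  } else {
    cut_height <- cut_fraction * max(tree$height)
    raw <- stats::cutree(tree, h = cut_height)
  }
  # relabel in order of first appearance over sorted genotype ids
  relabel <- as.integer(factor(raw, levels = unique(raw)))
  structure(
    list(
      assignments = tibble(
        genotype = rownames(scores), cluster = relabel
      ),
      tree = tree,
      cut_height = cut_height,
      cut_fraction = if (is.null(k)) cut_fraction else NA_real_,
      n_clusters = length(unique(relabel))
    ),
    class = "cluster_solution"
  )
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf(
    "# Ward cluster solution: %d clusters over %d genotypes",
    x$n_clusters, nrow(x$assignments)
  ))
  if (!is.na(x$cut_fraction)) {
    cat(sprintf(" (cut at %.0f%% of max merge height)", 100 * x$cut_fraction))
  }
  cat("\n")
  print(dplyr::count(x$assignments, .data$cluster))
  invisible(x)
}

#' Export a dendrogram as nested Newick-style text
#'
#' Plain-text serialization of the clustering tree with merge heights as
#' branch lengths, readable by standard tree tools.
#'
#' @param cs A `cluster_solution`.
#' @return A single Newick string (terminated by `;`).
#' @export
dendrogram_newick <- function(cs) {
  tree <- cs$tree
  labs <- tree$labels
  build <- function(i) {
    h <- tree$height[i]
    parts <- vapply(tree$merge[i, ], function(m) {
      if (m < 0) {
        sprintf("%s:%g", labs[-m], h)
      } else {
        sprintf("%s:%g", build(m), h - tree$height[m])
      }
    }, character(1))
    paste0("(", parts[1], ",", parts[2], ")")
  }
  paste0(build(nrow(tree$merge)), ";")
}

#' Per-cluster trait means with nested F tests
#'
#' Profiles a cluster solution: the mean of each trait's genotype means
#' within each cluster, plus a fixed-effects nested F test per trait —
#' between-cluster mean square over the genotype-within-cluster mean
#' square, computed on genotype means. Singleton clusters contribute a
#' mean but no within-cluster degrees of freedom.
#'
#' @param ds A `trial_df`.
#' @param cs A `cluster_solution` over the same genotypes.
#' @param traits Character vector of trait names; default all.
#' @return A list: `means` (tibble cluster x trait, long), `tests`
#'   (tibble `trait`, `df_between`, `df_within`, `statistic`,
#'   `p.value`), `sizes`.
#' @export
cluster_profile <- function(ds, cs, traits = NULL) {
  traits <- trait_cols(ds, traits)
  gm <- genotype_means(ds, traits)
  joined <- dplyr::inner_join(gm, cs$assignments, by = "genotype")
  if (nrow(joined) < nrow(cs$assignments)) {
    abort("cluster assignments contain genotypes absent from the dataset")
  }
  means <- joined |>
    tidyr::pivot_longer(dplyr::all_of(traits), names_to = "trait") |>
    dplyr::group_by(.data$cluster, .data$trait) |>
    dplyr::summarise(
      n = dplyr::n(), mean = mean(.data$value), sd = sd(.data$value),
      .groups = "drop"
    )
  tests <- purrr::map_dfr(traits, function(tr) {
    v <- joined[[tr]]
    cl <- factor(joined$cluster)
    df_b <- nlevels(cl) - 1L
    df_w <- length(v) - nlevels(cl)
    grand <- mean(v)
    m_cl <- tapply(v, cl, mean)
    n_cl <- tabulate(cl)
    ss_b <- sum(n_cl * (m_cl - grand)^2)
    ss_w <- sum((v - m_cl[cl])^2)
    f <- if (df_w > 0 && ss_w > 0) (ss_b / df_b) / (ss_w / df_w) else NA_real_
    tibble(
      trait = tr, df_between = df_b, df_within = df_w,
      statistic = f,
      p.value = if (!is.na(f)) stats::pf(f, df_b, df_w, lower.tail = FALSE) else NA_real_
    )
  })
  list(
    means = means,
    tests = tests,
    sizes = dplyr::count(cs$assignments, .data$cluster)
  )
}
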