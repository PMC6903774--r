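#' Bin genotype means into five phenotypic classes
#'
#' Classic five-class binning of a quantitative trait around its mean:
#' class cut points at `mu - 2*sd`, `mu - sd`, `mu + sd`, `mu + 2*sd`.
#' The half-open convention used here assigns every value to exactly one
#' class: class 1 `v <= mu - 2*sd`; class 2 `mu - 2*sd < v <= mu - sd`;
#' class 3 `mu - sd < v < mu + sd`; class 4 `mu + sd <= v < mu + 2*sd`;
#' class 5 `v >= mu + 2*sd`. With `sd = 0` every value falls in class 3
#' (a warning is emitted).
#'
#' @param values Numeric vector of genotype means (names optional).
#' @param mu,sd Center and spread defining the cut points; defaults are
#'   the mean and SD of `values`. `sd` must be `>= 0`.
#' @return An integer vector of class labels in `1:5`, same length and
#'   names as `values`.
#' @examples
#' bin_into_classes(c(-3, 0, 3), mu = 0, sd = 1)
#' @export
bin_into_classes <- function(values, mu = mean(values), sd = stats::sd(values)) {
  if (sd < 0) {
    abort("sd must be >= 0")
  }
  if (sd == 0) {
    warn("sd is 0: all values assigned to class 3")
    return(setNames(rep(3L, length(values)), names(values)))
  }
  cls <- dplyr::case_when(
    values <= mu - 2 * sd ~ 1L,
    values <= mu - sd ~ 2L,
    values < mu + sd ~ 3L,
    values < mu + 2 * sd ~ 4L,
    TRUE ~ 5L
  )
  setNames(cls, names(values))
}

class_proportions <- function(classes, n_classes = 5L) {
  counts <- tabulate(classes, nbins = n_classes)
  counts / sum(counts)
}

#' Normalized Shannon-Weaver diversity index
#'
#' Computes \eqn{H' = -\sum_i p_i \ln p_i / \ln n} over the class
#' proportions `p`, with the convention \eqn{0 \ln 0 = 0}. Division by
#' `ln n` normalizes the index to \[0, 1\]: 0 for a monomorphic trait
#' (all entries in one class), 1 when entries are spread equally over
#' all `n` classes. By default `n` is the *defined* number of classes
#' (`length(p)`, 5 for the standard binning), keeping indices comparable
#' across traits; set `occupied_classes = TRUE` to normalize by the
#' number of non-empty classes instead.
#'
#' @param p Numeric vector of class proportions (sums to 1) or counts.
#' @param occupied_classes Normalize by occupied rather than defined
#'   class count.
#' @return The normalized index, a scalar in \[0, 1\].
#' @examples
#' shannon_weaver(rep(0.2, 5)) # 1: maximum diversity
#' shannon_weaver(c(1, 0, 0, 0, 0)) # 0: monomorphic
#' @export
shannon_weaver <- function(p, occupied_classes = FALSE) {
  if (any(p < 0)) {
    abort("proportions must be >= 0")
  }
  total <- sum(p)
  if (abs(total - 1) > 1e-8) {
    p <- p / total # accept raw counts
  }
  n <- if (occupied_classes) sum(p > 0) else length(p)
  if (n <= 1) {
    return(0)
  }
  pos <- p[p > 0]
  -sum(pos * log(pos)) / log(n)
}

#' Class frequencies for one trait, overall and per region
#'
#' Bins across-year genotype means with cut points from the
#' whole-collection mean and SD, then tabulates class proportions for the
#' whole collection and, if region labels are present, for each region
#' under the *same* cut points (a common classification is what makes
#' regional indices comparable with the total).
#'
#' @param ds A `trial_df`.
#' @param trait Trait name.
#' @return A tibble with columns `scope` (`"whole_collection"` or a
#'   region name), `class` (1-5), `count`, `proportion`.
#' @export
class_frequencies <- function(ds, trait) {
  trait <- trait_cols(ds, trait)
  gm <- genotype_means(ds, trait)
  v <- gm[[trait]]
  keep <- !is.na(v)
  v <- v[keep]
  cls <- bin_into_classes(v)
  tab <- function(cl, scope) {
    counts <- tabulate(cl, nbins = 5L)
    tibble(
      scope = scope, class = 1:5, count = counts,
      proportion = counts / sum(counts)
    )
  }
  out <- tab(cls, "whole_collection")
  if ("region" %in% names(gm)) {
    reg <- gm$region[keep]
    for (r in sort(unique(reg))) {
      out <- dplyr::bind_rows(out, tab(cls[reg == r], r))
    }
  }
  out
}

#' Partition phenotypic diversity within and between regions
#'
#' For each trait, computes the total normalized Shannon-Weaver index
#' `ht` from whole-collection class frequencies, the mean regional index
#' `hr` (each region's index normalized by `ln 5`, then averaged
#' unweighted over regions), the within-region proportion `hs = hr / ht`
#' and the between-region proportion `gst = (ht - hr) / ht`. Binning uses
#' whole-collection cut points throughout. `hs + gst = 1` whenever
#' `ht > 0`; when `ht = 0` both are undefined (`NA`). Small regions can
#' make `hr > ht`; the resulting negative `gst` is reported as computed
#' and flagged, never clamped.
#'
#' @param ds A `trial_df` with a `region` column.
#' @param traits Character vector of trait names; default all.
#' @return A `diversity_partition`: a tibble with columns `trait`, `ht`,
#'   `hr`, `hs`, `gst`, `negative_gst` (flag).
#' @examples
#' sim <- simulate_collection_like(seed = 7)
#' partition_diversity(sim$data)
#' @export
partition_diversity <- function(ds, traits = NULL) {
  if (!"region" %in% names(ds)) {
    abort("diversity partitioning needs a 'region' column")
  }
  traits <- trait_cols(ds, traits)
  out <- purrr::map_dfr(traits, function(tr) {
    freq <- class_frequencies(ds, tr)
    ht <- shannon_weaver(freq$proportion[freq$scope == "whole_collection"])
    regions <- setdiff(unique(freq$scope), "whole_collection")
    hr <- mean(vapply(
      regions,
      function(r) shannon_weaver(freq$proportion[freq$scope == r]),
      numeric(1)
    ))
    hs <- if (ht > 0) hr / ht else NA_real_
    gst <- if (ht > 0) (ht - hr) / ht else NA_real_
    tibble(
      trait = tr, ht = ht, hr = hr, hs = hs, gst = gst,
      negative_gst = isTRUE(gst < 0)
    )
  })
  class(out) <- c("diversity_partition", class(out))
  out
}

#' @export
print.diversity_partition <- function(x, ...) {
  cat("# Phenotypic diversity partition (normalized Shannon-Weaver)\n")
  NextMethod()
}
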