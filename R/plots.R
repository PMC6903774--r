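#' Scatter plot of genotype scores on two principal components
#'
#' @param object A `trial_pca`.
#' @param x_pc,y_pc Components to plot (defaults PC1 vs PC2).
#' @param clusters Optional `cluster_solution`; points are colored by
#'   cluster.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot trial_pca
#' @export
autoplot.trial_pca <- function(object, x_pc = 1, y_pc = 2, clusters = NULL,
                               ...) {
  df <- as_tibble(object$scores[, c(x_pc, y_pc), drop = FALSE],
    rownames = "genotype"
  )
  names(df)[2:3] <- c("x", "y")
  if (!is.null(clusters)) {
    df <- dplyr::left_join(df, clusters$assignments, by = "genotype")
    df$cluster <- factor(df$cluster)
  }
  lab <- function(k) {
    sprintf("PC%d (%.1f%%)", k, 100 * object$proportion[k])
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::labs(x = lab(x_pc), y = lab(y_pc)) +
    ggplot2::theme_minimal()
  if (!is.null(clusters)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$cluster))
  } else {
    p + ggplot2::geom_point()
  }
}

#' Bar chart of the within/between-region diversity split
#'
#' Stacked bars of the within-region (`hs`) and between-region (`gst`)
#' proportions of each trait's total diversity.
#'
#' @param object A `diversity_partition`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot diversity_partition
#' @export
autoplot.diversity_partition <- function(object, ...) {
  df <- as_tibble(as.data.frame(object)) |>
    tidyr::pivot_longer(c("hs", "gst"),
      names_to = "component", values_to = "proportion"
    ) |>
    dplyr::mutate(component = dplyr::recode(.data$component,
      hs = "within regions", gst = "between regions"
    ))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$trait, y = .data$proportion, fill = .data$component
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proportion of total diversity", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Dendrogram of a Ward cluster solution
#'
#' Segment-based ggplot dendrogram with the relative cut height drawn as
#' a dashed line.
#'
#' @param object A `cluster_solution`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cluster_solution
#' @export
autoplot.cluster_solution <- function(object, ...) {
  tree <- object$tree
  n <- length(tree$order)
  leaf_x <- setNames(seq_len(n), tree$order)
  node_x <- numeric(nrow(tree$merge))
  segs <- vector("list", nrow(tree$merge))
  xh <- function(m) {
    if (m < 0) c(leaf_x[[as.character(-m)]], 0) else c(node_x[m], tree$height[m])
  }
  for (i in seq_len(nrow(tree$merge))) {
    a <- xh(tree$merge[i, 1])
    b <- xh(tree$merge[i, 2])
    h <- tree$height[i]
    node_x[i] <- mean(c(a[1], b[1]))
    segs[[i]] <- tibble(
      x = c(a[1], b[1], a[1]),
      xend = c(a[1], b[1], b[1]),
      y = c(a[2], b[2], h),
      yend = c(h, h, h)
    )
  }
  df <- dplyr::bind_rows(segs)
  p <- ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$x, xend = .data$xend, y = .data$y, yend = .data$yend
    )) +
    ggplot2::labs(x = "genotype", y = "merge height") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_blank(),
      axis.ticks.x = ggplot2::element_blank()
    )
  if (!is.na(object$cut_height)) {
    p <- p + ggplot2::geom_hline(
      yintercept = object$cut_height, linetype = "dashed"
    )
  }
  p
}
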