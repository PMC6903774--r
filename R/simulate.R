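#' Per-trait generating parameters for trial simulation
#'
#' The simulator draws plot values from the additive model
#' \deqn{y_{ijk} = \mu + s_{region(i)} + g_i + y_j + (gy)_{ij} + b_{k(j)} + e_{ijk}}
#' with independent zero-mean normal effects: genotypic `sigma2_g`, year
#' `sigma2_y`, genotype-by-year `sigma2_gy`, block-within-year `sigma2_b`
#' and residual `sigma2_e` variances. `region_shift` adds a fixed offset
#' to every genotype from a region, which is what creates between-region
#' diversity downstream. `clip` truncates simulated values to a range
#' after all effects are added (used for 0-9 disease scores).
#'
#' @param name Trait name.
#' @param mu Grand mean, trait units.
#' @param sigma2_g,sigma2_y,sigma2_gy,sigma2_b,sigma2_e Variance
#'   components, all `>= 0`. Block effects are nested in year; `sigma2_b`
#'   defaults to 0.
#' @param region_shift Named numeric vector, region -> additive shift of
#'   the genotypic mean (default none).
#' @param clip Optional length-2 numeric `c(lo, hi)`.
#' @return A one-row tibble of generating parameters.
#' @export
trait_gen <- function(name, mu,
                      sigma2_g = 0, sigma2_y = 0, sigma2_gy = 0,
                      sigma2_b = 0, sigma2_e = 0,
                      region_shift = NULL, clip = NULL) {
  vars <- c(sigma2_g, sigma2_y, sigma2_gy, sigma2_b, sigma2_e)
  if (any(vars < 0)) {
    abort("variance components must be >= 0")
  }
  if (!is.null(clip) && (length(clip) != 2 || clip[1] >= clip[2])) {
    abort("clip must be c(lo, hi) with lo < hi")
  }
  tibble(
    trait = name, mu = mu,
    sigma2_g = sigma2_g, sigma2_y = sigma2_y, sigma2_gy = sigma2_gy,
    sigma2_b = sigma2_b, sigma2_e = sigma2_e,
    region_shift = list(region_shift), clip = list(clip)
  )
}

#' Simulation configuration for a multi-year RCBD trial
#'
#' @param n_genotypes Number of genotypes.
#' @param traits Tibble of per-trait parameters, rows from [trait_gen()].
#' @param years Number of years `y` (>= 1).
#' @param blocks Blocks per year `r` (>= 1).
#' @param regions Optional named numeric vector of region weights
#'   (must sum to 1); genotypes are assigned to regions in fixed
#'   proportions, largest weight first.
#' @param gcorr Optional genetic correlation matrix across traits
#'   (symmetric, unit diagonal, positive semi-definite); applied to the
#'   genotypic effects only — year, G-by-Y and residual effects stay
#'   independent across traits.
#' @param seed Integer seed; the same config always yields the same
#'   dataset.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genotypes, traits, years = 3, blocks = 3,
                       regions = NULL, gcorr = NULL, seed = 1L) {
  if (years < 1 || blocks < 1) {
    abort("years and blocks must be >= 1")
  }
  if (!is.null(regions)) {
    if (is.null(names(regions)) || abs(sum(regions) - 1) > 1e-8) {
      abort("regions must be a named vector of weights summing to 1")
    }
  }
  if (!is.null(gcorr)) {
    gcorr <- as.matrix(gcorr)
    nt <- nrow(traits)
    if (!isTRUE(all.equal(dim(gcorr), c(nt, nt)))) {
      abort("gcorr dimension must match the number of traits")
    }
    if (max(abs(gcorr - t(gcorr))) > 1e-8 || max(abs(diag(gcorr) - 1)) > 1e-8) {
      abort("gcorr must be symmetric with unit diagonal")
    }
    if (min(eigen(gcorr, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      abort("gcorr must be positive semi-definite")
    }
  }
  structure(
    list(
      n_genotypes = as.integer(n_genotypes), traits = traits,
      years = as.integer(years), blocks = as.integer(blocks),
      regions = regions, gcorr = gcorr, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# PSD square root via eigendecomposition; chol() would refuse the
# semi-definite boundary cases that valid correlation specs allow.
psd_root <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(m)) %*% t(e$vectors)
}

#' Simulate a multi-year RCBD trial with known ground truth
#'
#' Generates plot-level data under the additive random-effects model of
#' [trait_gen()] and returns both the dataset and the realized effects,
#' so estimators can be checked against the truth that generated the
#' data. Genotypic effects are drawn jointly across traits with
#' correlation `gcorr` (identity if absent); all other effects are
#' independent. Draws are genotype-major within trait, so appending a
#' trait never perturbs earlier traits' values.
#'
#' @param cfg A [sim_config()].
#' @param trait_spec Optional trait-spec tibble attached to the dataset;
#'   by default all traits are higher-better agronomic (traits with a
#'   `clip` of `c(0, 9)` become lower-better disease scores).
#' @return A list of class `sim_trial`:
#'   \describe{
#'     \item{data}{a `trial_df` of plot records}
#'     \item{genotypes}{tibble of realized genotypic values per trait
#'       (`mu + region shift + g_i`, before clipping) and the raw effects}
#'     \item{truth}{the generating parameters (the `cfg`)}
#'   }
#' @examples
#' cfg <- sim_config(10, trait_gen("y", mu = 5, sigma2_g = 1, sigma2_e = 0.5),
#'                   years = 2, blocks = 2, seed = 42)
#' sim <- simulate_trial(cfg)
#' head(sim$data)
#' @export
simulate_trial <- function(cfg, trait_spec = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  n_g <- cfg$n_genotypes
  n_y <- cfg$years
  n_r <- cfg$blocks
  traits <- cfg$traits
  n_t <- nrow(traits)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$seed)

  genotype <- sprintf("g%0*d", nchar(n_g), seq_len(n_g))
  region <- NULL
  if (!is.null(cfg$regions)) {
    w <- sort(cfg$regions, decreasing = TRUE)
    counts <- floor(w * n_g)
    rem <- n_g - sum(counts)
    if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
    region <- rep(names(counts), counts)
  }

  # joint genotypic effects: standard normals scaled per trait, mixed by
  # the PSD root of gcorr so trait k only depends on columns 1..k of Z
  Z <- matrix(stats::rnorm(n_g * n_t), n_g, n_t)
  if (!is.null(cfg$gcorr)) {
    Z <- Z %*% psd_root(cfg$gcorr)
  }
  g_eff <- sweep(Z, 2, sqrt(traits$sigma2_g), `*`)

  grid <- tidyr::expand_grid(
    genotype = genotype,
    year = seq_len(n_y),
    block = seq_len(n_r)
  )
  gi <- match(grid$genotype, genotype)
  yj <- grid$year
  cell_gy <- (gi - 1L) * n_y + yj
  cell_yb <- (yj - 1L) * n_r + grid$block

  out <- grid
  if (!is.null(region)) {
    out$region <- region[gi]
  }
  geno_tbl <- tibble(genotype = genotype)
  if (!is.null(region)) geno_tbl$region <- region

  for (k in seq_len(n_t)) {
    p <- traits[k, ]
    shift <- rep(0, n_g)
    rs <- p$region_shift[[1]]
    if (!is.null(rs) && !is.null(region)) {
      shift <- unname(ifelse(is.na(rs[region]), 0, rs[region]))
    }
    y_eff <- stats::rnorm(n_y, 0, sqrt(p$sigma2_y))
    gy_eff <- stats::rnorm(n_g * n_y, 0, sqrt(p$sigma2_gy))
    b_eff <- stats::rnorm(n_y * n_r, 0, sqrt(p$sigma2_b))
    e_eff <- stats::rnorm(nrow(grid), 0, sqrt(p$sigma2_e))
    geno_value <- p$mu + shift + g_eff[, k]
    v <- geno_value[gi] + y_eff[yj] + gy_eff[cell_gy] + b_eff[cell_yb] + e_eff
    cl <- p$clip[[1]]
    if (!is.null(cl)) {
      v <- pmin(pmax(v, cl[1]), cl[2])
    }
    out[[p$trait]] <- v
    geno_tbl[[p$trait]] <- geno_value
    geno_tbl[[paste0(".g_", p$trait)]] <- g_eff[, k]
  }

  if (is.null(trait_spec)) {
    is_score <- vapply(
      traits$clip, function(cl) !is.null(cl) && cl[1] == 0 && cl[2] == 9,
      logical(1)
    )
    trait_spec <- trait_spec(
      traits$trait,
      merit_direction = ifelse(is_score, "lower_better", "higher_better"),
      kind = ifelse(is_score, "disease_score", "agronomic")
    )
  }

  structure(
    list(
      data = as_trial_data(out, traits = trait_spec),
      genotypes = geno_tbl,
      truth = cfg
    ),
    class = "sim_trial"
  )
}

#' @export
print.sim_trial <- function(x, ...) {
  cat(sprintf(
    "<sim_trial> seed %d; %d genotypes, %d traits\n",
    x$truth$seed, x$truth$n_genotypes, nrow(x$truth$traits)
  ))
  print(x$data)
  invisible(x)
}

#' Read a simulation configuration from YAML
#'
#' The YAML mirrors [sim_config()]: top-level `n_genotypes`, `years`,
#' `blocks`, `seed`, optional `regions` (name: weight map), optional
#' `gcorr` (list of rows), and `traits`, a list of maps with the
#' [trait_gen()] fields.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  traits <- purrr::map_dfr(y$traits, function(tr) {
    trait_gen(
      name = tr$name, mu = tr$mu,
      sigma2_g = tr$sigma2_g %||% 0, sigma2_y = tr$sigma2_y %||% 0,
      sigma2_gy = tr$sigma2_gy %||% 0, sigma2_b = tr$sigma2_b %||% 0,
      sigma2_e = tr$sigma2_e %||% 0,
      region_shift = if (!is.null(tr$region_shift)) unlist(tr$region_shift),
      clip = if (!is.null(tr$clip)) unlist(tr$clip)
    )
  })
  gcorr <- if (!is.null(y$gcorr)) do.call(rbind, y$gcorr)
  sim_config(
    n_genotypes = y$n_genotypes, traits = traits,
    years = y$years %||% 3, blocks = y$blocks %||% 3,
    regions = if (!is.null(y$regions)) unlist(y$regions),
    gcorr = gcorr, seed = y$seed %||% 1L
  )
}
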