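#' Declare the traits measured in a trial
#'
#' A trait specification records, for each measured trait, its units, the
#' direction of merit (whether breeders want larger or smaller values) and
#' whether it is an ordinary agronomic measurement or a bounded 0-9 visual
#' disease score. The merit direction drives superior-genotype screening;
#' the kind drives validation (disease scores must lie in \[0, 9\]).
#'
#' @param name Character vector of trait names (unique).
#' @param units Character vector of measurement units (free text), recycled.
#' @param merit_direction `"higher_better"` or `"lower_better"`, recycled.
#'   Heading time, plant height and disease susceptibility scores are
#'   conventionally `"lower_better"`.
#' @param kind `"agronomic"` or `"disease_score"`, recycled.
#'
#' @return A tibble with columns `trait`, `units`, `merit_direction`,
#'   `kind`, one row per trait.
#' @examples
#' trait_spec(
#'   name = c("grain_yield", "heading_time"),
#'   units = c("t/ha", "days"),
#'   merit_direction = c("higher_better", "lower_better")
#' )
#' @export
trait_spec <- function(name,
                       units = "",
                       merit_direction = "higher_better",
                       kind = "agronomic") {
  merit_direction <- vapply(
    merit_direction, match.arg, "",
    choices = c("higher_better", "lower_better")
  )
  kind <- vapply(kind, match.arg, "", choices = c("agronomic", "disease_score"))
  if (anyDuplicated(name)) {
    abort("trait names must be unique")
  }
  tibble(
    trait = as.character(name),
    units = rep_len(as.character(units), length(name)),
    merit_direction = rep_len(unname(merit_direction), length(name)),
    kind = rep_len(unname(kind), length(name))
  )
}

#' Default trait specification for a wheat variety trial
#'
#' The eleven traits of the reference trial layout: seven agronomic traits
#' (heading time in days from April 1, plant height, grain yield, specific
#' weight, 1000-grain weight, protein and gluten content) plus four 0-9
#' disease susceptibility scores (powdery mildew, septoria tritici blotch,
#' yellow rust, leaf rust). Heading time, plant height and all disease
#' scores are lower-better.
#'
#' @param include_disease Include the four disease-score traits (used for
#'   breeding populations; the collection trial records only the seven
#'   agronomic traits).
#' @return A trait-spec tibble (see [trait_spec()]).
#' @export
wheat_trait_spec <- function(include_disease = TRUE) {
  agronomic <- trait_spec(
    name = c("HT", "PH", "GY", "SW", "TGW", "PC", "GC"),
    units = c("days", "cm", "t/ha", "kg/hl", "g", "%", "%"),
    merit_direction = c(
      "lower_better", "lower_better", "higher_better", "higher_better",
      "higher_better", "higher_better", "higher_better"
    ),
    kind = "agronomic"
  )
  if (!include_disease) {
    return(agronomic)
  }
  disease <- trait_spec(
    name = c("PM", "STB", "YR", "LR"),
    units = "score",
    merit_direction = "lower_better",
    kind = "disease_score"
  )
  dplyr::bind_rows(agronomic, disease)
}

id_cols <- function(ds) intersect(c("genotype", "region", "year", "block"), names(ds))

trait_cols <- function(ds, traits = NULL) {
  spec <- attr(ds, "traits")
  avail <- if (!is.null(spec)) {
    intersect(spec$trait, names(ds))
  } else {
    setdiff(names(ds), c(id_cols(ds), "is_parent"))
  }
  if (is.null(traits)) {
    return(avail)
  }
  missing <- setdiff(traits, avail)
  if (length(missing)) {
    abort(paste0("unknown trait(s): ", paste(missing, collapse = ", ")))
  }
  traits
}

check_balance <- function(df) {
  cells <- dplyr::count(df, .data$genotype, .data$year, .data$block)
  if (any(cells$n > 1)) {
    abort("duplicate (genotype, year, block) rows")
  }
  n_g <- dplyr::n_distinct(df$genotype)
  n_y <- dplyr::n_distinct(df$year)
  n_r <- dplyr::n_distinct(df$block)
  list(
    r = n_r, y = n_y, g = n_g,
    balanced = nrow(cells) == n_g * n_y * n_r
  )
}

#' Assemble a plot-level trial dataset
#'
#' Validates a long-format table of plot observations (one row per
#' genotype x year x block, one column per trait) and attaches trait
#' metadata and the inferred design constants: `r` blocks per year, `y`
#' years, and whether the design is balanced (every genotype observed in
#' all `y * r` cells). Variance-component estimation requires balance;
#' descriptive statistics tolerate missing cells.
#'
#' @param df Data frame with columns `genotype`, `year`, `block`, optional
#'   `region` and `is_parent`, and one numeric column per trait.
#' @param traits Trait-spec tibble ([trait_spec()]). If `NULL`, every
#'   non-identifier column is taken as a higher-better agronomic trait.
#' @return A `trial_df`: a tibble carrying `traits` and `design`
#'   attributes. The design attribute is a list with `r`, `y`, `g`,
#'   `balanced`.
#' @examples
#' df <- expand.grid(genotype = c("g1", "g2"), year = 1:2, block = 1:2)
#' df$yield <- rnorm(nrow(df), 3)
#' ds <- as_trial_data(df)
#' trial_design(ds)
#' @export
as_trial_data <- function(df, traits = NULL) {
  df <- as_tibble(df)
  required <- c("genotype", "year", "block")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")))
  }
  df$genotype <- as.character(df$genotype)
  df$year <- as.integer(df$year)
  df$block <- as.integer(df$block)
  if (is.null(traits)) {
    guess <- setdiff(names(df), c(required, "region", "is_parent"))
    guess <- guess[vapply(df[guess], is.numeric, logical(1))]
    traits <- trait_spec(guess)
  }
  known <- intersect(traits$trait, names(df))
  unknown <- setdiff(traits$trait, names(df))
  if (length(unknown)) {
    warn(paste0(
      "trait(s) in spec but not in data, dropped: ",
      paste(unknown, collapse = ", ")
    ))
    traits <- traits[traits$trait %in% known, ]
  }
  for (tr in known) {
    if (!is.numeric(df[[tr]])) {
      abort(paste0("trait column '", tr, "' is not numeric"))
    }
  }
  bad <- traits$trait[traits$kind == "disease_score"]
  for (tr in bad) {
    v <- df[[tr]]
    if (any(v < 0 | v > 9, na.rm = TRUE)) {
      abort(paste0("disease score '", tr, "' outside [0, 9]"))
    }
  }
  design <- check_balance(df)
  if (!design$balanced) {
    warn("design is unbalanced: variance-component estimation will refuse")
  }
  structure(
    df,
    traits = traits,
    design = design,
    class = c("trial_df", class(df))
  )
}

#' @export
print.trial_df <- function(x, ...) {
  d <- attr(x, "design")
  cat(sprintf(
    "<trial_df> %d genotypes x %d years x %d blocks (%s), %d traits\n",
    d$g, d$y, d$r, if (d$balanced) "balanced" else "UNBALANCED",
    nrow(attr(x, "traits"))
  ))
  NextMethod()
}

#' Design constants of a trial dataset
#'
#' @param ds A `trial_df`.
#' @return A list with `r` (blocks per year), `y` (years), `g`
#'   (genotypes) and `balanced`.
#' @export
trial_design <- function(ds) {
  attr(ds, "design") %||% check_balance(ds)
}

#' Trait metadata of a trial dataset
#'
#' @param ds A `trial_df`.
#' @return The trait-spec tibble attached to `ds`.
#' @export
trial_traits <- function(ds) {
  attr(ds, "traits")
}

#' Read a plot-level trial table from CSV
#'
#' Expects a UTF-8 CSV with a header row and one row per plot: columns
#' `genotype`, `year`, `block`, optional `region` and `is_parent`, and one
#' numeric column per trait. Empty cells are read as missing. Duplicate
#' (genotype, year, block) rows are a structural error; an unbalanced
#' design is flagged on the dataset but not fatal.
#'
#' @param path CSV file path.
#' @inheritParams as_trial_data
#' @return A `trial_df`.
#' @export
read_trial_csv <- function(path, traits = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_trial_data(df, traits = traits)
}

#' Write a trial dataset to CSV
#'
#' Inverse of [read_trial_csv()]: writes the plot-level long table so that
#' reading it back reproduces the records.
#'
#' @param ds A `trial_df`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(ds, path) {
  readr::write_csv(as_tibble(as.data.frame(ds)), path, progress = FALSE)
  invisible(path)
}

#' Map country labels onto partitioning regions
#'
#' Diversity partitioning uses four broad regions of origin (Africa, Asia,
#' Europe, others). Collections usually record country of provenance;
#' this collapses a country column through a user-supplied country-to-region
#' map. Unmapped or unknown origins go to `"others"`.
#'
#' @param ds A `trial_df` with a `region` column holding country labels.
#' @param country_map Named character vector, `country = region`; regions
#'   must be in `regions`.
#' @param regions Allowed region labels.
#' @return `ds` with `region` collapsed to the four regions.
#' @export
assign_regions <- function(ds, country_map,
                           regions = c("Africa", "Asia", "Europe", "others")) {
  if (!"region" %in% names(ds)) {
    abort("dataset has no 'region' column")
  }
  bad <- setdiff(unique(unname(country_map)), regions)
  if (length(bad)) {
    abort(paste0("country_map targets unknown region(s): ", paste(bad, collapse = ", ")))
  }
  mapped <- unname(country_map[ds$region])
  mapped[is.na(mapped)] <- "others"
  already <- ds$region %in% regions
  mapped[already] <- ds$region[already]
  ds$region <- mapped
  ds
}

#' Genotype means per trait
#'
#' Averages plot values to one value per genotype (and, optionally, per
#' year). Across-year means are computed as the mean of per-year means, so
#' a genotype missing a plot in one year is not over-weighted towards its
#' better-replicated years. Genotypes with no observations for a trait are
#' excluded with a warning. These means are the inputs to diversity
#' binning, PCA and genotype screening.
#'
#' @param ds A `trial_df`.
#' @param traits Character vector of trait names; default all.
#' @param level `"across_years"` (one row per genotype) or `"per_year"`.
#' @return A wide tibble: `genotype` (plus `region`/`is_parent` if
#'   present, plus `year` for `level = "per_year"`) and one column per
#'   trait.
#' @export
genotype_means <- function(ds, traits = NULL,
                           level = c("across_years", "per_year")) {
  level <- match.arg(level)
  traits <- trait_cols(ds, traits)
  df <- as_tibble(as.data.frame(ds))
  meta <- intersect(c("region", "is_parent"), names(df))
  per_year <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("genotype", meta, "year")))) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(traits), ~ mean(.x, na.rm = TRUE)),
      .groups = "drop"
    )
  out <- if (level == "per_year") {
    per_year
  } else {
    per_year |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c("genotype", meta)))) |>
      dplyr::summarise(
        dplyr::across(dplyr::all_of(traits), ~ mean(.x, na.rm = TRUE)),
        .groups = "drop"
      )
  }
  for (tr in traits) {
    out[[tr]][is.nan(out[[tr]])] <- NA_real_
  }
  dropped <- out$genotype[rowSums(is.na(out[traits])) == length(traits)]
  if (length(unique(dropped))) {
    warn(paste0(
      "genotype(s) with no observations excluded: ",
      paste(unique(dropped), collapse = ", ")
    ))
    out <- out[!out$genotype %in% dropped, ]
  }
  dplyr::arrange(out, .data$genotype)
}

#' Descriptive statistics over genotype means
#'
#' For each trait: mean, standard error, range and coefficient of
#' variation of the across-year genotype means. The CV (100 * SD / mean)
#' measures between-genotype dispersion, i.e. it is a diversity
#' descriptor, not a residual CV. With a single genotype the SE and CV are
#' undefined (`NA`); a zero mean leaves the CV undefined.
#'
#' @param ds A `trial_df`.
#' @param traits Character vector of trait names; default all.
#' @return A tibble with columns `trait`, `n`, `mean`, `se`, `min`,
#'   `max`, `cv_percent`.
#' @examples
#' ds <- as_trial_data(data.frame(
#'   genotype = rep(c("a", "b"), each = 2), year = 1, block = rep(1:2, 2),
#'   y = c(1, 1, 3, 3)
#' ))
#' summarize_traits(ds)
#' @export
summarize_traits <- function(ds, traits = NULL) {
  traits <- trait_cols(ds, traits)
  gm <- genotype_means(ds, traits)
  purrr::map_dfr(traits, function(tr) {
    v <- gm[[tr]]
    v <- v[!is.na(v)]
    n <- length(v)
    m <- if (n) mean(v) else NA_real_
    s <- if (n >= 2) sd(v) else NA_real_
    tibble(
      trait = tr,
      n = n,
      mean = m,
      se = if (n >= 2) s / sqrt(n) else NA_real_,
      min = if (n) min(v) else NA_real_,
      max = if (n) max(v) else NA_real_,
      cv_percent = if (n >= 2 && isTRUE(m != 0)) 100 * s / m else NA_real_
    )
  })
}
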