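#' Summarise developmental and reproductive endpoints per treatment
#'
#' Computes the bioassay endpoint table for each treatment (and dose, when a
#' `dose_uM` column is present): mean stage durations with standard errors,
#' adult longevity by sex, pupation and adult-emergence fractions, fecundity
#' (total eggs per reproducing female) and fertility (per-female hatch
#' fraction) when hatch totals are supplied.
#'
#' Definitions: a stage duration is the number of days an individual is
#' recorded in that stage, averaged over individuals that reached it. The
#' pupation fraction is individuals reaching the pupal stage over individuals
#' entering the cohort; the emergence fraction is adults eclosed over pupae
#' formed. Statistics whose denominator group is empty are reported as `NA`
#' (undefined), never as zero. Standard errors for means are `sd/sqrt(n)`;
#' for fractions they are binomial, `sqrt(p(1-p)/n)`.
#'
#' @inheritParams validate_cohort
#' @param hatch Optional tibble of per-individual hatch totals with columns
#'   `individual_id` and `eggs_hatched`, enabling the fertility statistic.
#' @param censored How to treat individuals whose record ends while they are
#'   still alive: `"exclude"` (default) drops them with a warning,
#'   `"as_dead"` keeps them and treats the record end as death.
#' @return A tibble with columns `treatment`, `dose_uM` (if present),
#'   `parameter`, `n`, `estimate`, `se`. Duration parameters are named
#'   `duration_<stage>`; the remaining parameters are `longevity_female`,
#'   `longevity_male`, `pupation`, `emergence`, `fecundity`, `fertility`.
#' @examples
#' cfg <- stage_config()
#' cohort <- simulate_cohort(simulation_config(n = 50), seed = 1)
#' summarize_endpoints(cohort, cfg)
#' @export
summarize_endpoints <- function(cohort,
                                stage_config = lifetabler::stage_config(),
                                hatch = NULL,
                                censored = c("exclude", "as_dead")) {
  cfg <- check_stage_config(stage_config)
  cohort <- validate_cohort(cohort, cfg)
  cohort <- resolve_censoring(cohort, cfg, censored)

  grp <- intersect(c("treatment", "dose_uM"), names(cohort))
  groups <- dplyr::distinct(cohort[grp])
  purrr::pmap_dfr(groups, function(...) {
    key <- tibble::tibble(...)
    sub <- dplyr::semi_join(cohort, key, by = grp)
    dplyr::bind_cols(key, endpoint_stats(sub, cfg, hatch))
  })
}

endpoint_stats <- function(sub, cfg, hatch) {
  adult_stages <- unique(c(cfg$adult_female, cfg$adult_male, cfg$reproductive))
  first_adult <- min(stage_index(cfg, adult_stages))
  pupal_stage <- if (first_adult > 1L) cfg$stages[first_adult - 1L] else NA

  per <- sub |>
    dplyr::filter(.data$stage != cfg$death) |>
    dplyr::group_by(.data$individual_id)

  days_in <- function(stg) {
    per |>
      dplyr::summarise(d = sum(.data$stage == stg), .groups = "drop") |>
      dplyr::filter(.data$d > 0L) |>
      dplyr::pull(.data$d)
  }
  mean_row <- function(name, x) {
    tibble::tibble(
      parameter = name, n = length(x),
      estimate = if (length(x)) mean(x) else NA_real_,
      se = if (length(x) > 1L) stats::sd(x) / sqrt(length(x))
           else if (length(x) == 1L) NA_real_ else NA_real_
    )
  }
  frac_row <- function(name, k, n) {
    p <- if (n > 0L) k / n else NA_real_
    tibble::tibble(
      parameter = name, n = n, estimate = p,
      se = if (n > 0L) sqrt(p * (1 - p) / n) else NA_real_
    )
  }

  rows <- purrr::map(setdiff(cfg$stages, adult_stages), function(stg) {
    mean_row(paste0("duration_", stg), days_in(stg))
  })
  if (!is.null(cfg$adult_female)) {
    rows <- c(rows, list(mean_row("longevity_female", days_in(cfg$adult_female))))
  }
  if (!is.null(cfg$adult_male)) {
    rows <- c(rows, list(mean_row("longevity_male", days_in(cfg$adult_male))))
  }

  n0 <- dplyr::n_distinct(sub$individual_id)
  reached <- function(stgs) {
    sub |>
      dplyr::filter(.data$stage %in% stgs) |>
      dplyr::pull(.data$individual_id) |>
      unique()
  }
  n_pupae <- if (is.na(pupal_stage)) NA_integer_ else length(reached(pupal_stage))
  n_adults <- length(reached(adult_stages))
  if (!is.na(pupal_stage)) {
    rows <- c(rows, list(frac_row("pupation", n_pupae, n0),
                         frac_row("emergence", n_adults, n_pupae)))
  }

  females <- reached(cfg$reproductive)
  eggs_tot <- sub |>
    dplyr::filter(.data$individual_id %in% females) |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(eggs = sum(.data$eggs), .groups = "drop")
  rows <- c(rows, list(mean_row("fecundity", eggs_tot$eggs)))

  if (!is.null(hatch)) {
    fert <- eggs_tot |>
      dplyr::inner_join(hatch, by = "individual_id") |>
      dplyr::filter(.data$eggs > 0L) |>
      dplyr::mutate(frac = .data$eggs_hatched / .data$eggs)
    rows <- c(rows, list(mean_row("fertility", fert$frac)))
  } else {
    rows <- c(rows, list(tibble::tibble(parameter = "fertility", n = 0L,
                                        estimate = NA_real_, se = NA_real_)))
  }
  dplyr::bind_rows(rows)
}
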