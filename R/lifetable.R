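#' Fit an age-stage two-sex life table to a single cohort
#'
#' Runs the full demographic pipeline on one cohort: builds the age-stage
#' survival and fecundity matrices, collapses them to `lx`/`mx` schedules,
#' and computes the net reproductive rate (R0), gross reproductive rate
#' (GRR), intrinsic rate of increase (r, Euler-Lotka bisection), finite rate
#' of increase (lambda = exp(r)), mean generation time (T = ln(R0)/r), and
#' the pre-oviposition periods (APOP, TPOP).
#'
#' The cohort must contain a single treatment; use [run_lifetable()] for
#' multi-treatment datasets. All quantities are kept at full precision;
#' rounding is a presentation concern only.
#'
#' @inheritParams summarize_endpoints
#' @param tol,max_iter Passed to [intrinsic_rate()].
#' @return An object of class `lifetable_fit`: a list with `matrices`
#'   (`age_stage_matrices`), `schedules` (`age_schedules` tibble),
#'   `estimates` (tibble of parameter/estimate rows), `n` (cohort size),
#'   and `treatment`.
#' @examples
#' cohort <- simulate_cohort(simulation_config(n = 100), seed = 1)
#' fit <- lifetable(cohort)
#' tidy(fit)
#' glance(fit)
#' @export
lifetable <- function(cohort, stage_config = lifetabler::stage_config(),
                      censored = c("exclude", "as_dead"),
                      tol = 1e-10, max_iter = 200L) {
  cfg <- check_stage_config(stage_config)
  cohort <- validate_cohort(cohort, cfg)
  cohort <- resolve_censoring(cohort, cfg, censored)
  if (dplyr::n_distinct(cohort$treatment) > 1L) {
    abort("Cohort contains multiple treatments; fit each separately or use run_lifetable().")
  }

  mats <- age_stage_core(cohort, cfg)
  sched <- age_schedules(mats)
  rr <- reproductive_rates(sched)
  est <- tibble::tibble(parameter = c("R0", "GRR"),
                        estimate = unname(rr))
  if (rr[["R0"]] > 0) {
    r <- as.numeric(intrinsic_rate(sched, tol = tol, max_iter = max_iter))
    est <- dplyr::bind_rows(
      est,
      tibble::tibble(parameter = "r", estimate = r),
      tibble::tibble(parameter = "lambda", estimate = exp(r)),
      tibble::tibble(parameter = "T",
                     estimate = if (r != 0) log(rr[["R0"]]) / r else NA_real_)
    )
  } else {
    est <- dplyr::bind_rows(
      est,
      tibble::tibble(parameter = c("r", "lambda", "T"), estimate = NA_real_))
  }
  per <- oviposition_per_female(cohort, cfg)
  mean_or_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  est <- dplyr::bind_rows(
    est,
    tibble::tibble(parameter = c("APOP", "TPOP"),
                   estimate = c(mean_or_na(per$apop), mean_or_na(per$tpop))))

  structure(
    list(matrices = mats, schedules = sched, estimates = est,
         n = mats$n, treatment = unique(cohort$treatment)),
    class = "lifetable_fit"
  )
}

#' @export
print.lifetable_fit <- function(x, digits = 2, ...) {
  cat(sprintf("<lifetable_fit> treatment '%s', n = %d, ages 0-%d\n",
              x$treatment, x$n, max(x$schedules$age)))
  est <- x$estimates
  cat(paste(sprintf("  %-7s %s", est$parameter,
                    formatC(est$estimate, digits = digits, format = "f")),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Tidy a fitted life table
#'
#' @param x A `lifetable_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `parameter` and `estimate` covering R0, GRR,
#'   r, lambda, T, APOP and TPOP.
#' @method tidy lifetable_fit
#' @export
tidy.lifetable_fit <- function(x, ...) {
  x$estimates
}

#' One-row summary of a fitted life table
#'
#' @param x A `lifetable_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `treatment`, `n`, `max_age`, and one column per
#'   demographic parameter.
#' @method glance lifetable_fit
#' @export
glance.lifetable_fit <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$estimates, names_from = "parameter",
                             values_from = "estimate")
  dplyr::bind_cols(
    tibble::tibble(treatment = x$treatment, n = x$n,
                   max_age = max(x$schedules$age)),
    wide
  )
}
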