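#' Build age-stage survival and fecundity matrices
#'
#' The age-stage survival matrix `S` holds `S[x, j]`, the proportion of the
#' initial cohort alive in stage `j` at age `x` days (ages are rows, from 0;
#' stages are columns in configured order). The age-stage fecundity matrix
#' `F` holds `f[x, j]`, the mean number of eggs laid at age `x` per individual
#' then in stage `j` (zero where no individual occupies the cell).
#'
#' @inheritParams summarize_endpoints
#' @return An object of class `age_stage_matrices`: a list with elements `S`
#'   and `F` (matrices, ages x stages), `n` (initial cohort size used as the
#'   denominator), `ages` and `stages`.
#' @examples
#' cohort <- simulate_cohort(simulation_config(n = 30), seed = 1)
#' m <- build_age_stage_matrices(cohort, stage_config())
#' m$S[1, ]   # day 0: whole cohort in the entry stage
#' @export
build_age_stage_matrices <- function(cohort,
                                     stage_config = lifetabler::stage_config(),
                                     censored = c("exclude", "as_dead")) {
  cfg <- check_stage_config(stage_config)
  cohort <- validate_cohort(cohort, cfg)
  cohort <- resolve_censoring(cohort, cfg, censored)
  age_stage_core(cohort, cfg)
}

# Counting core; assumes a validated, censor-resolved cohort.
age_stage_core <- function(cohort, cfg) {
  living <- dplyr::filter(cohort, .data$stage != cfg$death)
  n <- dplyr::n_distinct(cohort$individual_id)
  if (n < 1L) abort("Empty cohort.")
  max_age <- max(living$day)
  ages <- 0:max_age
  day_f <- factor(living$day, levels = ages)
  stage_f <- factor(living$stage, levels = cfg$stages)

  counts <- table(day_f, stage_f)
  eggs <- tapply(living$eggs, list(day_f, stage_f), sum, default = 0L)
  S <- unclass(counts) / n
  F <- ifelse(counts > 0, eggs / unclass(counts), 0)
  dimnames(S) <- dimnames(F) <- list(age = ages, stage = cfg$stages)

  structure(list(S = S, F = F, n = n, ages = ages, stages = cfg$stages),
            class = "age_stage_matrices")
}

#' @export
print.age_stage_matrices <- function(x, ...) {
  cat(sprintf("<age_stage_matrices> %d individuals, ages 0-%d, stages: %s\n",
              x$n, max(x$ages), paste(x$stages, collapse = ", ")))
  invisible(x)
}

#' Collapse age-stage matrices to age-specific schedules
#'
#' Computes the age-specific survival schedule `lx = sum_j S[x, j]` (the
#' probability of being alive at age `x`) and the age-specific fecundity
#' schedule `mx = sum_j S[x, j] f[x, j] / sum_j S[x, j]` (mean eggs per
#' surviving individual at age `x`). Ages where no individual survives have
#' `mx = 0` by convention, keeping downstream sums finite.
#'
#' @param mats An `age_stage_matrices` object from
#'   [build_age_stage_matrices()], or a cohort tibble (in which case
#'   `stage_config` is used to build the matrices first).
#' @inheritParams build_age_stage_matrices
#' @return A tibble of class `age_schedules` with columns `age`, `lx`, `mx`.
#' @examples
#' cohort <- simulate_cohort(simulation_config(n = 30), seed = 1)
#' sched <- age_schedules(build_age_stage_matrices(cohort, stage_config()))
#' head(sched)
#' @export
age_schedules <- function(mats, stage_config = lifetabler::stage_config(),
                          censored = c("exclude", "as_dead")) {
  if (is.data.frame(mats)) {
    mats <- build_age_stage_matrices(mats, stage_config, censored)
  }
  if (!inherits(mats, "age_stage_matrices")) {
    abort("`mats` must be an age_stage_matrices object or a cohort tibble.")
  }
  lx <- rowSums(mats$S)
  weighted <- rowSums(mats$S * mats$F)
  mx <- ifelse(lx > 0, weighted / lx, 0)
  new_age_schedules(mats$ages, unname(lx), unname(mx))
}

new_age_schedules <- function(age, lx, mx) {
  out <- tibble::tibble(age = as.integer(age), lx = lx, mx = mx)
  class(out) <- c("age_schedules", class(out))
  out
}

#' Construct age schedules from raw vectors
#'
#' Convenience constructor for analyses that start from an externally
#' computed survival/fecundity schedule rather than from cohort records.
#'
#' @param lx Numeric vector of age-specific survival, `lx[1]` at age 0;
#'   must start at 1 and be non-increasing within `[0, 1]`.
#' @param mx Numeric vector of age-specific fecundity, same length as `lx`,
#'   non-negative.
#' @return A tibble of class `age_schedules`.
#' @export
as_age_schedules <- function(lx, mx) {
  if (length(lx) != length(mx)) abort("`lx` and `mx` must have equal length.")
  if (length(lx) == 0L) abort("Schedules must have at least one age class.")
  if (any(mx < 0)) abort("`mx` must be non-negative.")
  if (any(lx < 0 | lx > 1)) abort("`lx` must lie in [0, 1].")
  if (any(diff(lx) > 1e-12)) abort("`lx` must be non-increasing.")
  new_age_schedules(seq_along(lx) - 1L, as.numeric(lx), as.numeric(mx))
}
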