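#' Net and gross reproductive rates
#'
#' The net reproductive rate `R0 = sum_x lx * mx` is the expected lifetime
#' offspring per individual entering the cohort; the gross reproductive rate
#' `GRR = sum_x mx` is the same sum ignoring mortality, so `GRR >= R0`
#' always. For matrices built from raw counts, `R0 * n` equals the total
#' number of eggs laid by the cohort exactly.
#'
#' @param sched An `age_schedules` tibble (columns `age`, `lx`, `mx`).
#' @return A named numeric vector with elements `R0` and `GRR`.
#' @examples
#' reproductive_rates(as_age_schedules(lx = c(1, 1), mx = c(0, 3)))
#' @export
reproductive_rates <- function(sched) {
  sched <- check_schedules(sched)
  c(R0 = sum(sched$lx * sched$mx), GRR = sum(sched$mx))
}

#' Intrinsic rate of increase by Euler-Lotka bisection
#'
#' Solves the discrete Euler-Lotka equation
#' `sum_x exp(-r (x + 1)) * lx * mx = 1` for the intrinsic rate of increase
#' `r` (per day), with ages indexed from 0. The left-hand side is strictly
#' decreasing in `r` whenever the net fecundity schedule has positive mass,
#' so the root is unique; it is found by bisection from an initial bracket
#' `[-1, 2]` per day, expanded geometrically if the residual does not change
#' sign across it.
#'
#' The exponent convention `exp(-r (x + 1))` with 0-indexed ages is the
#' standard one for two-sex life tables; the alternative `exp(-r x)` yields a
#' different `r` and is not used here.
#'
#' @inheritParams reproductive_rates
#' @param tol Convergence tolerance on the Euler-Lotka residual
#'   (`|lhs - 1|`). Default `1e-10`.
#' @param max_iter Maximum bisection iterations. Default 200.
#' @return The intrinsic rate `r` (numeric scalar) with attributes
#'   `residual` (achieved residual) and `iterations`.
#' @examples
#' # all net fecundity e at age 9: exp(-10 r) * e = 1  =>  r = 0.1
#' sched <- as_age_schedules(lx = c(rep(1, 10)), mx = c(rep(0, 9), exp(1)))
#' intrinsic_rate(sched)
#' @export
intrinsic_rate <- function(sched, tol = 1e-10, max_iter = 200L) {
  sched <- check_schedules(sched)
  euler_lotka_solve(sched$lx * sched$mx, tol = tol, max_iter = max_iter)
}

# Core solver on the net fecundity vector w[x] = lx*mx, x = 0, 1, ...
euler_lotka_solve <- function(w, tol = 1e-10, max_iter = 200L) {
  keep <- w > 0
  if (!any(keep)) abort("No reproduction (all lx*mx zero): r is undefined.")
  R0 <- sum(w)
  if (R0 == 1) {
    return(structure(0, residual = 0, iterations = 0L))
  }
  x1 <- which(keep) # age + 1 under 0-indexed ages
  w <- w[keep]
  resid <- function(r) sum(exp(-r * x1) * w) - 1

  lo <- -1; hi <- 2
  k <- 0L
  while (resid(hi) > 0 && k < 60L) { hi <- hi * 2; k <- k + 1L }
  while (resid(lo) < 0 && k < 120L) { lo <- lo * 2; k <- k + 1L }
  if (resid(hi) > 0 || resid(lo) < 0) {
    abort(sprintf(
      "Euler-Lotka bracket expansion failed: residual(%g) = %g, residual(%g) = %g.",
      lo, resid(lo), hi, resid(hi)))
  }
  it <- 0L
  mid <- (lo + hi) / 2
  fm <- resid(mid)
  while (abs(fm) >= tol && it < max_iter) {
    if (fm > 0) lo <- mid else hi <- mid
    mid <- (lo + hi) / 2
    fm <- resid(mid)
    it <- it + 1L
  }
  if (abs(fm) >= tol) {
    warn(sprintf(
      "Euler-Lotka bisection stopped after %d iterations with residual %g.",
      it, fm))
  }
  structure(mid, residual = fm, iterations = it)
}

#' Finite rate of increase and mean generation time
#'
#' The finite rate of increase is `lambda = exp(r)` (per-day multiplicative
#' growth factor); the mean generation time is `T = ln(R0) / r`, the time
#' over which a population growing at rate `r` multiplies by its net
#' reproductive rate.
#'
#' @param r Intrinsic rate of increase (per day).
#' @param R0 Net reproductive rate (> 0).
#' @return A named numeric vector with elements `lambda` and `T`.
#' @examples
#' derived_rates(r = log(2), R0 = exp(1))  # lambda = 2, T = 1/ln 2
#' @export
derived_rates <- function(r, R0) {
  r <- as.numeric(r)
  if (!is.finite(r)) abort("`r` must be finite.")
  if (r == 0) {
    abort("Mean generation time is undefined at r = 0 (lambda would be 1).")
  }
  if (R0 <= 0) abort("`R0` must be positive.")
  c(lambda = exp(r), T = log(R0) / r)
}

#' Pre-oviposition periods
#'
#' The adult pre-oviposition period (APOP) is the mean number of days between
#' adult emergence and the first egg; the total pre-oviposition period (TPOP)
#' is the mean age (days from cohort entry) at the first egg. Both are
#' averaged over females that laid at least one egg.
#'
#' @inheritParams summarize_endpoints
#' @return A tibble with one row per statistic (`APOP`, `TPOP`): columns
#'   `parameter`, `n` (reproducing females), `estimate`, `se`. If no female
#'   reproduces, estimates are `NA` and a warning is raised.
#' @export
oviposition_stats <- function(cohort,
                              stage_config = lifetabler::stage_config(),
                              censored = c("exclude", "as_dead")) {
  cfg <- check_stage_config(stage_config)
  cohort <- validate_cohort(cohort, cfg)
  cohort <- resolve_censoring(cohort, cfg, censored)
  per <- oviposition_per_female(cohort, cfg)
  stat <- function(name, x) {
    x <- x[!is.na(x)]
    tibble::tibble(
      parameter = name, n = length(x),
      estimate = if (length(x)) mean(x) else NA_real_,
      se = if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
    )
  }
  if (all(is.na(per$tpop))) {
    warn("No reproducing female: APOP/TPOP undefined.")
  }
  dplyr::bind_rows(stat("APOP", per$apop), stat("TPOP", per$tpop))
}

# First-egg ages per female; NA for individuals that never lay.
# Assumes rows sorted by (individual, day), as validate_cohort returns.
oviposition_per_female <- function(cohort, cfg) {
  x <- dplyr::arrange(cohort, .data$individual_id, .data$day)
  ids <- unique(x$individual_id)
  first_of <- function(rows) {
    keep <- rows[!duplicated(x$individual_id[rows])]
    out <- rep(NA_integer_, length(ids))
    out[match(x$individual_id[keep], ids)] <- x$day[keep]
    out
  }
  emergence <- first_of(which(x$stage == cfg$reproductive))
  first_egg <- first_of(which(x$eggs > 0L))
  tibble::tibble(
    individual_id = ids,
    emergence = emergence,
    first_egg = first_egg,
    apop = as.numeric(first_egg - emergence),
    tpop = as.numeric(first_egg)
  )
}

check_schedules <- function(sched) {
  if (inherits(sched, "age_schedules")) return(sched)
  if (is.data.frame(sched) && all(c("lx", "mx") %in% names(sched))) {
    return(new_age_schedules(seq_len(nrow(sched)) - 1L, sched$lx, sched$mx))
  }
  abort("`sched` must be an age_schedules tibble with columns lx and mx.")
}
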