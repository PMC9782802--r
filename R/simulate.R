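#' Configure a stage-structured cohort simulator
#'
#' Defines the generative model for synthetic individual life histories:
#' per-stage duration distributions (shifted, truncated negative binomial or
#' fixed), per-stage daily survival probabilities, metamorphosis completion
#' probabilities (pupation and eclosion), sex ratio at emergence, sex-specific
#' adult daily survival with a hard adult lifespan cap, and an age-dependent
#' daily fecundity curve for females. The same configuration drives both
#' stochastic simulation ([simulate_cohort()]) and exact expectation
#' ([expected_schedules()]), so simulated cohorts can be checked against
#' analytically known truth.
#'
#' Duration specifications are lists: `list(type = "fixed", days = k)` or
#' `list(type = "nbinom", min = a, mu = m, size = s, max = b)`, giving
#' `D = a + NegBinom(size, mu)` with the upper tail lumped at `b` (finite
#' support is required for exact expectations). The fecundity curve is
#' lognormal-shaped over adult age: zero during the pre-oviposition period,
#' then `peak * exp(-(log t - log peak_day)^2 / (2 sigma^2))` eggs/day in
#' expectation, where `t` is days since first possible oviposition. Daily egg
#' counts are Poisson around the curve (negative binomial if `dispersion` is
#' set); `list(type = "fixed", daily = c(...))` gives deterministic counts.
#'
#' @param n Cohort size (individuals enrolled at day 0).
#' @param stage_config A [stage_config()]; the simulator treats all stages
#'   before the adult stages as pre-adult, the last pre-adult stage as the
#'   pupa.
#' @param durations Named list of duration specs, one per pre-adult stage.
#' @param survival Named numeric vector of daily survival probabilities, one
#'   per pre-adult stage.
#' @param pupation Probability of completing the larva-to-pupa molt.
#' @param eclosion Probability of successful adult emergence from the pupa.
#' @param sex_ratio Probability an eclosing adult is female.
#' @param adult_survival Numeric vector `c(female = , male = )` of daily
#'   adult survival probabilities.
#' @param adult_max_days Hard cap on adult lifespan (days); death is recorded
#'   at the cap. Keeps all supports finite.
#' @param fecundity Fecundity curve spec (see Details).
#' @param treatment Treatment label stamped on simulated records.
#' @param dose_uM Dose in micromolar stamped on simulated records (`NA` for
#'   untreated).
#' @return An object of class `simulation_config`.
#' @seealso [config_control_like()], [config_treated_like()]
#' @export
simulation_config <- function(
    n = 60,
    stage_config = lifetabler::stage_config(),
    durations = list(
      L3 = list(type = "nbinom", min = 3, mu = 1.3, size = 8, max = 15),
      L4 = list(type = "nbinom", min = 3, mu = 1.3, size = 8, max = 15),
      L5 = list(type = "nbinom", min = 3, mu = 1.3, size = 8, max = 15),
      pupa = list(type = "nbinom", min = 12, mu = 3, size = 10, max = 30)
    ),
    survival = c(L3 = 0.998, L4 = 0.998, L5 = 0.998, pupa = 1.0),
    pupation = 0.97,
    eclosion = 0.97,
    sex_ratio = 0.5,
    adult_survival = c(female = 0.92, male = 0.87),
    adult_max_days = 30,
    fecundity = list(type = "lognormal", preovip = 3, peak = 260,
                     peak_day = 2.5, sigma = 0.35, dispersion = NULL),
    treatment = "control",
    dose_uM = NA_real_) {
  cfg <- check_stage_config(stage_config)
  adults <- unique(c(cfg$adult_female, cfg$adult_male))
  if (length(adults) == 0L) abort("Simulator requires sexed adult stages.")
  pre <- setdiff(cfg$stages, adults)
  if (!setequal(names(durations), pre)) {
    abort(sprintf("`durations` must name exactly the pre-adult stages: %s",
                  paste(pre, collapse = ", ")))
  }
  if (!setequal(names(survival), pre)) {
    abort("`survival` must name exactly the pre-adult stages.")
  }
  for (p in c(pupation, eclosion, sex_ratio, survival, adult_survival)) {
    if (any(p < 0 | p > 1)) abort("Probabilities must lie in [0, 1].")
  }
  if (n < 1) abort("`n` must be >= 1.")
  purrr::walk(durations, check_duration_spec)
  structure(
    list(n = as.integer(n), stage_config = cfg, pre_adult = pre,
         durations = durations, survival = survival,
         pupation = pupation, eclosion = eclosion, sex_ratio = sex_ratio,
         adult_survival = adult_survival,
         adult_max_days = as.integer(adult_max_days),
         fecundity = fecundity, treatment = treatment, dose_uM = dose_uM),
    class = "simulation_config"
  )
}

check_duration_spec <- function(d) {
  if (identical(d$type, "fixed")) {
    if (is.null(d$days) || d$days < 1) abort("Fixed durations must be >= 1 day.")
  } else if (identical(d$type, "nbinom")) {
    if (is.null(d$min) || d$min < 1) abort("Duration `min` must be >= 1 day.")
    if (is.null(d$max) || d$max < d$min) abort("Duration `max` must be >= `min`.")
    if (is.null(d$mu) || is.null(d$size)) abort("nbinom durations need `mu` and `size`.")
  } else {
    abort("Duration spec `type` must be 'fixed' or 'nbinom'.")
  }
  invisible(d)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("<simulation_config> n = %d, treatment '%s'\n", x$n, x$treatment))
  cat("  pre-adult stages:", paste(x$pre_adult, collapse = ", "), "\n")
  cat(sprintf("  pupation %.2f, eclosion %.2f, sex ratio %.2f\n",
              x$pupation, x$eclosion, x$sex_ratio))
  invisible(x)
}

#' Preset: untreated control-like rearing regime
#'
#' A configuration whose exact expected demography sits in the range reported
#' for untreated cohorts of a polyphagous noctuid reared on artificial diet
#' from the third instar: high pupation and emergence, roughly two-week
#' larval plus pupal development, several hundred eggs per female, net
#' reproductive rate near 180 and mean generation time near 33 days.
#'
#' @param n Cohort size.
#' @return A [simulation_config()].
#' @export
config_control_like <- function(n = 60) {
  simulation_config(n = n, treatment = "control")
}

#' Preset: high-dose-treated-like rearing regime
#'
#' Mirrors the qualitative contrast of a strongly growth-disrupting
#' treatment: shortened larval stadia, reduced emergence, shorter adult
#' lives and markedly lower fecundity, giving a much smaller net reproductive
#' rate and a shorter generation time than [config_control_like()].
#'
#' @param n Cohort size.
#' @param treatment Treatment label.
#' @param dose_uM Dose label in micromolar.
#' @return A [simulation_config()].
#' @export
config_treated_like <- function(n = 60, treatment = "treated_450uM",
                                dose_uM = 450) {
  simulation_config(
    n = n,
    durations = list(
      L3 = list(type = "nbinom", min = 1, mu = 0.3, size = 8, max = 8),
      L4 = list(type = "nbinom", min = 1, mu = 0.3, size = 8, max = 8),
      L5 = list(type = "nbinom", min = 1, mu = 0.3, size = 8, max = 8),
      pupa = list(type = "nbinom", min = 11, mu = 2, size = 10, max = 25)
    ),
    survival = c(L3 = 0.98, L4 = 0.98, L5 = 0.98, pupa = 1.0),
    pupation = 0.83, eclosion = 0.60,
    adult_survival = c(female = 0.88, male = 0.86),
    fecundity = list(type = "lognormal", preovip = 4, peak = 225,
                     peak_day = 2.5, sigma = 0.35, dispersion = NULL),
    treatment = treatment, dose_uM = dose_uM
  )
}

dur_sample <- function(d, n) {
  if (identical(d$type, "fixed")) rep.int(as.integer(d$days), n)
  else pmin.int(d$min + stats::rnbinom(n, size = d$size, mu = d$mu), d$max)
}

# pmf over support min..max with the upper tail lumped at max
dur_pmf <- function(d) {
  if (identical(d$type, "fixed")) {
    return(stats::setNames(1, d$days))
  }
  supp <- d$min:d$max
  p <- stats::dnbinom(supp - d$min, size = d$size, mu = d$mu)
  p[length(p)] <- 1 - sum(p[-length(p)])
  stats::setNames(p, supp)
}

# Expected eggs/day at adult age a = 0, 1, ..., adult_max_days - 1
fecundity_rate <- function(fec, adult_max_days) {
  a <- seq_len(adult_max_days) - 1L
  if (identical(fec$type, "fixed")) {
    r <- rep(0, adult_max_days)
    k <- min(length(fec$daily), adult_max_days)
    r[seq_len(k)] <- fec$daily[seq_len(k)]
    return(r)
  }
  t <- a - fec$preovip + 1
  r <- ifelse(t >= 1,
              fec$peak * exp(-(log(pmax(t, 1)) - log(fec$peak_day))^2 /
                               (2 * fec$sigma^2)),
              0)
  r
}

#' Simulate an individual-by-day cohort
#'
#' Draws one life history per individual under a [simulation_config()]:
#' stage durations are sampled per stage, survival is resolved by one
#' Bernoulli trial per individual-day, metamorphosis completion is resolved
#' at the larva-to-pupa and pupa-to-adult transitions, sex is assigned at
#' eclosion, and females lay daily egg counts drawn around the configured
#' fecundity curve. Every record ends with an explicit death row, so
#' simulated cohorts contain no censoring and always pass
#' [validate_cohort()].
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A validated cohort tibble (see [read_cohort()] for the format).
#' @examples
#' cohort <- simulate_cohort(simulation_config(n = 20), seed = 42)
#' dplyr::count(cohort, stage)
#' @export
simulate_cohort <- function(config, seed) {
  if (!inherits(config, "simulation_config")) {
    abort("`config` must be a simulation_config object.")
  }
  if (missing(seed)) abort("`seed` is required for reproducibility.")
  set.seed(seed)
  cfg <- config$stage_config
  pre <- config$pre_adult
  n_pre <- length(pre)
  rate <- fecundity_rate(config$fecundity, config$adult_max_days)
  fixed_eggs <- identical(config$fecundity$type, "fixed")
  disp <- config$fecundity$dispersion

  days_l <- vector("list", config$n)
  stage_l <- vector("list", config$n)
  eggs_l <- vector("list", config$n)

  for (i in seq_len(config$n)) {
    days <- integer(0); stages <- character(0); eggs <- integer(0)
    day <- 0L
    alive <- TRUE
    for (si in seq_len(n_pre)) {
      stg <- pre[si]
      D <- dur_sample(config$durations[[stg]], 1L)
      s <- config$survival[[stg]]
      died_on <- NA_integer_
      for (d in seq_len(D)) {
        days <- c(days, day); stages <- c(stages, stg); eggs <- c(eggs, 0L)
        day <- day + 1L
        if (stats::runif(1) > s) { died_on <- day; break }
      }
      if (!is.na(died_on)) { alive <- FALSE; break }
      # metamorphosis at stage exit: into the pupa, or out of it
      trans <- if (si == n_pre - 1L) config$pupation
               else if (si == n_pre) config$eclosion
               else 1
      if (stats::runif(1) > trans) { alive <- FALSE; break }
    }
    if (alive) {
      female <- stats::runif(1) < config$sex_ratio
      stg <- if (female) cfg$adult_female else cfg$adult_male
      s <- config$adult_survival[[if (female) "female" else "male"]]
      for (d in seq_len(config$adult_max_days)) {
        e <- 0L
        if (female && rate[d] > 0) {
          e <- if (fixed_eggs) as.integer(round(rate[d]))
               else if (is.null(disp)) stats::rpois(1, rate[d])
               else stats::rnbinom(1, size = disp, mu = rate[d])
        }
        days <- c(days, day); stages <- c(stages, stg); eggs <- c(eggs, e)
        day <- day + 1L
        if (stats::runif(1) > s) break
      }
    }
    days <- c(days, day); stages <- c(stages, cfg$death); eggs <- c(eggs, 0L)
    days_l[[i]] <- days; stage_l[[i]] <- stages; eggs_l[[i]] <- eggs
  }

  len <- lengths(days_l)
  width <- max(3L, nchar(as.character(config$n)))
  ids <- sprintf(paste0("%s_ind%0", width, "d"),
                 sanitize(config$treatment), seq_len(config$n))
  tibble::tibble(
    individual_id = rep(ids, len),
    treatment = config$treatment,
    dose_uM = config$dose_uM,
    day = unlist(days_l),
    stage = unlist(stage_l),
    eggs = unlist(eggs_l)
  )
}

#' Simulate per-female hatch totals
#'
#' Draws `eggs_hatched ~ Binomial(total eggs, hatch_prob)` per individual,
#' producing the sidecar table consumed by [summarize_endpoints()] for the
#' fertility statistic.
#'
#' @param cohort A cohort tibble.
#' @param hatch_prob Per-egg hatch probability.
#' @param seed Integer seed.
#' @return A tibble with columns `individual_id`, `eggs_hatched`.
#' @export
simulate_hatch_totals <- function(cohort, hatch_prob, seed) {
  if (hatch_prob < 0 || hatch_prob > 1) abort("`hatch_prob` must be in [0, 1].")
  set.seed(seed)
  cohort |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(eggs = sum(.data$eggs), .groups = "drop") |>
    dplyr::mutate(eggs_hatched = stats::rbinom(dplyr::n(), .data$eggs,
                                               hatch_prob)) |>
    dplyr::select("individual_id", "eggs_hatched")
}

#' Exact expected schedules and demographic truth for a simulator config
#'
#' Propagates the stage-duration/survival semi-Markov chain analytically
#' (discrete convolution over the finite duration supports) to obtain the
#' exact age-specific survival `lx`, fecundity `mx`, net and gross
#' reproductive rates, intrinsic rate `r` (solved from the exact schedule
#' with [intrinsic_rate()]), finite rate, mean generation time, and the
#' expected pre-oviposition periods. These are population expectations, not
#' simulation output, and serve as ground truth for parameter-recovery tests
#' of the whole pipeline.
#'
#' @param config A [simulation_config()]; all duration supports must be
#'   finite (the constructor enforces truncation).
#' @return A list with `schedules` (an `age_schedules` tibble), and numeric
#'   elements `R0`, `GRR`, `r`, `lambda`, `T`, `APOP`, `TPOP`,
#'   `p_reach_pupa`, `p_reach_adult`, `p_reproduce`.
#' @examples
#' truth <- expected_schedules(config_control_like())
#' truth$R0
#' @export
expected_schedules <- function(config) {
  if (!inherits(config, "simulation_config")) {
    abort("`config` must be a simulation_config object.")
  }
  cfg <- config$stage_config
  pre <- config$pre_adult
  n_pre <- length(pre)
  max_day <- sum(purrr::map_dbl(config$durations, function(d) {
    if (identical(d$type, "fixed")) d$days else d$max
  })) + config$adult_max_days + 1L
  horizon <- as.integer(max_day)

  # entry[x+1] = P(entering stage at day x); occupancy computed per stage
  entry <- numeric(horizon + 1L); entry[1] <- 1
  occ <- matrix(0, nrow = horizon + 1L, ncol = length(cfg$stages),
                dimnames = list(NULL, cfg$stages))

  for (si in seq_len(n_pre)) {
    stg <- pre[si]
    pmf <- dur_pmf(config$durations[[stg]])
    supp <- as.integer(names(pmf))
    s <- config$survival[[stg]]
    nxt <- numeric(horizon + 1L)
    for (xe in which(entry > 0) - 1L) {
      pe <- entry[xe + 1L]
      # occupancy on day xe + d, d = 0..max(supp)-1: P(D >= d+1) * s^d
      dmax <- max(supp)
      d <- 0:(dmax - 1L)
      pge <- vapply(d + 1L, function(v) sum(pmf[supp >= v]), numeric(1))
      idx <- xe + d + 1L
      ok <- idx <= horizon + 1L
      occ[idx[ok], stg] <- occ[idx[ok], stg] + pe * pge[ok] * s^d[ok]
      # transitions at day xe + D, having survived D days
      trans <- if (si == n_pre - 1L) config$pupation
               else if (si == n_pre) config$eclosion
               else 1
      tidx <- xe + supp + 1L
      ok <- tidx <= horizon + 1L
      nxt[tidx[ok]] <- nxt[tidx[ok]] + pe * pmf[ok] * s^supp[ok] * trans
    }
    entry <- nxt
  }

  adult_entry <- entry
  rate <- fecundity_rate(config$fecundity, config$adult_max_days)
  A <- config$adult_max_days
  eggs_at_age <- numeric(horizon + 1L)
  first_egg_num <- 0; first_egg_apop <- 0; p_repro <- 0
  for (sex in c("female", "male")) {
    share <- if (sex == "female") config$sex_ratio else 1 - config$sex_ratio
    if (share == 0) next
    stg <- if (sex == "female") cfg$adult_female else cfg$adult_male
    s <- config$adult_survival[[sex]]
    d <- 0:(A - 1L)
    occ_d <- s^d
    for (xe in which(adult_entry > 0) - 1L) {
      pe <- adult_entry[xe + 1L] * share
      idx <- xe + d + 1L
      ok <- idx <= horizon + 1L
      occ[idx[ok], stg] <- occ[idx[ok], stg] + pe * occ_d[ok]
      if (sex == "female") {
        eggs_at_age[idx[ok]] <- eggs_at_age[idx[ok]] + pe * occ_d[ok] * rate[d[ok] + 1L]
        # first-egg-age distribution: survive to adult day d, no egg before, egg at d
        if (!identical(config$fecundity$type, "fixed")) {
          p_none_before <- exp(-cumsum(c(0, rate[-A])))
          p_first <- occ_d * p_none_before * (1 - exp(-rate))
        } else {
          lays <- rate > 0
          p_first <- numeric(A)
          if (any(lays)) {
            f <- which(lays)[1]
            p_first[f] <- occ_d[f]
          }
        }
        p_repro <- p_repro + pe * sum(p_first)
        first_egg_num <- first_egg_num + pe * sum((xe + d) * p_first)
        first_egg_apop <- first_egg_apop + pe * sum(d * p_first)
      }
    }
  }

  lx <- rowSums(occ)
  last <- max(which(lx > 0))
  occ <- occ[seq_len(last), , drop = FALSE]
  lx <- lx[seq_len(last)]
  eggs_at_age <- eggs_at_age[seq_len(last)]
  mx <- ifelse(lx > 0, eggs_at_age / lx, 0)
  sched <- new_age_schedules(0:(last - 1L), lx, mx)

  R0 <- sum(eggs_at_age)
  GRR <- sum(mx)
  r <- if (R0 > 0) as.numeric(euler_lotka_solve(eggs_at_age)) else NA_real_
  p_pupa <- if (n_pre >= 2L) sum_entry_into(config, n_pre) else NA_real_

  list(
    schedules = sched, R0 = R0, GRR = GRR, r = r,
    lambda = if (is.na(r)) NA_real_ else exp(r),
    T = if (!is.na(r) && r != 0) log(R0) / r else NA_real_,
    APOP = if (p_repro > 0) first_egg_apop / p_repro else NA_real_,
    TPOP = if (p_repro > 0) first_egg_num / p_repro else NA_real_,
    p_reach_pupa = p_pupa,
    p_reach_adult = sum(adult_entry),
    p_reproduce = p_repro
  )
}

# P(entering pre-adult stage number `k`), by chain propagation without ages
sum_entry_into <- function(config, k) {
  p <- 1
  for (si in seq_len(k - 1L)) {
    stg <- config$pre_adult[si]
    pmf <- dur_pmf(config$durations[[stg]])
    supp <- as.integer(names(pmf))
    s <- config$survival[[stg]]
    p_surv <- sum(pmf * s^supp)
    trans <- if (si == length(config$pre_adult) - 1L) config$pupation
             else if (si == length(config$pre_adult)) config$eclosion
             else 1
    p <- p * p_surv * trans
  }
  p
}

#' Declare ground truth for a simulated dose-mortality experiment
#'
#' @param slope True probit slope (per log10 dose unit), > 0.
#' @param lc50 True median lethal concentration, > 0 (any concentration
#'   unit; the fitted LC values inherit it).
#' @param doses Dose levels tested.
#' @param n Number exposed per dose (scalar or per-dose vector).
#' @return An object of class `probit_truth`.
#' @export
probit_truth <- function(slope = 1, lc50 = 100,
                         doses = c(50, 150, 450), n = 60) {
  if (slope <= 0) abort("`slope` must be > 0.")
  if (lc50 <= 0) abort("`lc50` must be > 0.")
  if (any(doses <= 0)) abort("`doses` must be strictly positive.")
  n <- as.integer(rep(n, length.out = length(doses)))
  if (any(n < 1L)) abort("`n` must be >= 1 per dose.")
  structure(list(slope = slope, lc50 = lc50, doses = doses, n = n),
            class = "probit_truth")
}

#' Simulate a dose-mortality table with known probit truth
#'
#' Draws `dead ~ Binomial(n, pnorm(slope * (log10(dose) - log10(lc50))))`
#' at each dose, the exact generative model assumed by [fit_probit()].
#'
#' @param truth A [probit_truth()].
#' @param seed Integer seed.
#' @return A tibble with columns `dose`, `n`, `dead`.
#' @examples
#' simulate_dose_mortality(probit_truth(), seed = 1)
#' @export
simulate_dose_mortality <- function(truth, seed) {
  if (!inherits(truth, "probit_truth")) {
    abort("`truth` must be a probit_truth object.")
  }
  set.seed(seed)
  p <- stats::pnorm(truth$slope * (log10(truth$doses) - log10(truth$lc50)))
  tibble::tibble(
    dose = truth$doses, n = truth$n,
    dead = stats::rbinom(length(truth$doses), truth$n, p)
  )
}
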