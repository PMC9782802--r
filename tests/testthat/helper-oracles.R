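# Independent grid-scan root finder for the Euler-Lotka equation, used as an
# oracle against the bisection solver. Written as a direct scan of the
# residual, sharing no code with the package's solver.
grid_solve_r <- function(lxmx, coarse = 1e-3, fine = 1e-7) {
  x1 <- which(lxmx > 0)          # age + 1 for 0-indexed ages
  w <- lxmx[lxmx > 0]
  res <- function(r) vapply(r, function(ri) sum(exp(-ri * x1) * w) - 1,
                            numeric(1))
  lo <- -1; hi <- 2
  while (res(hi) > 0) hi <- hi * 2
  while (res(lo) < 0) lo <- lo * 2
  grid <- seq(lo, hi, by = coarse)
  v <- res(grid)
  k <- which(v[-1] <= 0 & v[-length(v)] > 0)[1]
  fine_grid <- seq(grid[k], grid[k + 1], by = fine)
  fv <- res(fine_grid)
  fine_grid[which.min(abs(fv))]
}

# Random fecundity schedule with guaranteed positive mass.
random_schedule <- function(max_age = 40) {
  surv <- runif(max_age, 0.8, 1)
  lx <- cumprod(c(1, surv))
  mx <- rep(0, max_age + 1)
  repro <- sample(5:max_age, size = sample(3:10, 1))
  mx[repro] <- runif(length(repro), 0, 30)
  as_age_schedules(lx, mx)
}

# Hand-build a small cohort tibble from per-individual stage/egg runs.
# spec: list(list(stages = c("L3","L3","L4"), eggs = c(0,0,0), died = TRUE))
build_cohort <- function(spec, treatment = "control") {
  rows <- purrr::imap_dfr(spec, function(ind, i) {
    stages <- ind$stages
    eggs <- ind$eggs %||% rep(0L, length(stages))
    died <- isTRUE(ind$died)
    if (died) {
      stages <- c(stages, "dead")
      eggs <- c(eggs, 0L)
    }
    tibble::tibble(
      individual_id = sprintf("i%02d", i),
      treatment = treatment,
      dose_uM = NA_real_,
      day = seq_along(stages) - 1L,
      stage = stages,
      eggs = as.integer(eggs)
    )
  })
  rows
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fully deterministic simulator configuration: fixed durations, no death
# before the adult cap, all-female cohort with a fixed egg schedule.
deterministic_config <- function(n = 10, daily_eggs = c(0, 0, 40, 60, 20),
                                 sex_ratio = 1, adult_max_days = 6) {
  simulation_config(
    n = n,
    durations = list(
      L3 = list(type = "fixed", days = 3),
      L4 = list(type = "fixed", days = 3),
      L5 = list(type = "fixed", days = 4),
      pupa = list(type = "fixed", days = 10)
    ),
    survival = c(L3 = 1, L4 = 1, L5 = 1, pupa = 1),
    pupation = 1, eclosion = 1, sex_ratio = sex_ratio,
    adult_survival = c(female = 1, male = 1),
    adult_max_days = adult_max_days,
    fecundity = list(type = "fixed", daily = daily_eggs)
  )
}
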