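cfg <- stage_config()

test_that("age-stage matrices are cohort proportions with entry normalised", {
  co <- build_cohort(list(
    list(stages = rep("L3", 3), died = TRUE),
    list(stages = rep("L3", 2), died = TRUE)
  ))
  m <- build_age_stage_matrices(co, cfg)
  expect_equal(unname(m$S[1, "L3"]), 1)

  # 4 individuals at day 5: one pupa, two L5, one already dead
  co4 <- build_cohort(list(
    list(stages = c("L3", "L4", "L4", "L5", "L5", "pupa", "pupa"), died = TRUE),
    list(stages = c("L3", "L3", "L4", "L4", "L5", "L5"), died = TRUE),
    list(stages = c("L3", "L3", "L4", "L5", "L5", "L5"), died = TRUE),
    list(stages = c("L3", "L4", "L4"), died = TRUE)
  ))
  m4 <- build_age_stage_matrices(co4, cfg)
  expect_equal(unname(m4$S[6, "pupa"]), 0.25)
  expect_equal(unname(m4$S[6, "L5"]), 0.5)
  # row sums non-increasing: survivorship can only fall
  expect_true(all(diff(rowSums(m4$S)) <= 1e-12))
})

test_that("lx and mx follow the age-stage summation rules", {
  S <- matrix(c(0.3, 0.2), nrow = 1,
              dimnames = list(age = 0, stage = c("a", "b")))
  F <- matrix(0, nrow = 1, ncol = 2, dimnames = dimnames(S))
  mats <- structure(list(S = S, F = F, n = 10, ages = 0, stages = c("a", "b")),
                    class = "age_stage_matrices")
  sched <- age_schedules(mats)
  expect_equal(sched$lx, 0.5)
  expect_equal(sched$mx, 0)

  F2 <- matrix(c(10, 0), nrow = 1, dimnames = dimnames(S))
  S2 <- matrix(c(0.4, 0.1), nrow = 1, dimnames = dimnames(S))
  mats2 <- structure(list(S = S2, F = F2, n = 10, ages = 0,
                          stages = c("a", "b")),
                     class = "age_stage_matrices")
  expect_equal(age_schedules(mats2)$mx, 0.4 * 10 / 0.5)

  # extinct age class: lx = 0 and mx = 0, not NaN
  S3 <- rbind(S2, c(0, 0))
  F3 <- rbind(F2, c(5, 5))
  mats3 <- structure(list(S = S3, F = F3, n = 10, ages = 0:1,
                          stages = c("a", "b")),
                     class = "age_stage_matrices")
  sched3 <- age_schedules(mats3)
  expect_equal(sched3$lx[2], 0)
  expect_equal(sched3$mx[2], 0)
})

test_that("reproductive rates are the schedule sums with GRR >= R0", {
  sched <- as_age_schedules(lx = c(1, 1), mx = c(0, 3))
  rr <- reproductive_rates(sched)
  expect_equal(unname(rr["R0"]), 3)
  expect_equal(unname(rr["GRR"]), 3)

  null <- reproductive_rates(as_age_schedules(lx = c(1, 0.5), mx = c(0, 0)))
  expect_equal(unname(null), c(0, 0))

  set.seed(42)
  for (i in 1:20) {
    rr <- reproductive_rates(random_schedule())
    expect_gte(rr[["GRR"]], rr[["R0"]])
  }
})

test_that("the Euler-Lotka solver recovers closed-form single-age roots", {
  # all net fecundity e at age 9: r solves exp(-10 r) e = 1, so r = 0.1
  sched <- as_age_schedules(lx = rep(1, 10), mx = c(rep(0, 9), exp(1)))
  r <- intrinsic_rate(sched)
  expect_equal(as.numeric(r), 0.1, tolerance = 1e-9)
  expect_lt(abs(attr(r, "residual")), 1e-10)

  # R0 = 1 gives r = 0 exactly
  one <- as_age_schedules(lx = rep(1, 6), mx = c(rep(0, 5), 1))
  expect_identical(as.numeric(intrinsic_rate(one)), 0)

  # general single-age law r = ln(R0)/(a + 1), T = a + 1
  set.seed(7)
  for (i in 1:25) {
    a <- sample(3:50, 1)
    R0 <- runif(1, 0.2, 40)
    mx <- rep(0, a + 1); mx[a + 1] <- R0
    r <- as.numeric(intrinsic_rate(as_age_schedules(rep(1, a + 1), mx)))
    expect_equal(r, log(R0) / (a + 1), tolerance = 1e-8)
    if (abs(log(R0)) > 1e-6) {
      expect_equal(unname(derived_rates(r, R0)["T"]), a + 1, tolerance = 1e-6)
    }
  }
})

test_that("bisection agrees with an independent fine-grid scan", {
  set.seed(2024)
  for (i in 1:20) {
    sched <- random_schedule(sample(20:60, 1))
    r_bis <- as.numeric(intrinsic_rate(sched))
    r_grid <- grid_solve_r(sched$lx * sched$mx)
    expect_lt(abs(r_bis - r_grid), 1e-6)
  }
})

test_that("degenerate schedules are rejected with clear errors", {
  dead <- as_age_schedules(lx = c(1, 0.5), mx = c(0, 0))
  expect_error(intrinsic_rate(dead), "undefined")
  expect_error(derived_rates(0, 10), "undefined")
  expect_error(derived_rates(0.1, 0), "positive")
})

test_that("derived rates satisfy their closed forms", {
  dr <- derived_rates(log(2), exp(1))
  expect_equal(unname(dr["lambda"]), 2)
  expect_equal(unname(dr["T"]), 1 / log(2))
  expect_equal(unname(derived_rates(1, exp(1))["T"]), 1)
})

test_that("pipeline identities hold on simulated cohorts", {
  for (seed in c(11, 53, 97)) {
    co <- simulate_cohort(config_control_like(n = 100), seed = seed)
    fit <- lifetable(co)
    est <- setNames(fit$estimates$estimate, fit$estimates$parameter)

    # R0 * N equals the total egg count exactly
    expect_equal(est[["R0"]] * fit$n, sum(co$eggs), tolerance = 1e-9)
    # lambda = e^r and T = ln(R0)/r to near machine precision
    expect_equal(est[["lambda"]], exp(est[["r"]]), tolerance = 1e-10)
    expect_equal(est[["T"]], log(est[["R0"]]) / est[["r"]],
                 tolerance = 1e-10)
    expect_gte(est[["GRR"]], est[["R0"]])
    # Euler-Lotka residual at the reported root
    w <- fit$schedules$lx * fit$schedules$mx
    resid <- sum(exp(-est[["r"]] * (fit$schedules$age + 1)) * w) - 1
    expect_lt(abs(resid), 1e-10)
  }
})

test_that("pre-oviposition periods follow their definitions", {
  co <- build_cohort(list(
    list(stages = c(rep("L3", 5), rep("L4", 5), rep("L5", 4), rep("pupa", 6),
                    rep("adult_female", 8)),
         eggs = c(rep(0, 24), 30, 20, 10, 0), died = TRUE),
    list(stages = c(rep("L3", 5), rep("L4", 5), rep("L5", 4), rep("pupa", 6),
                    rep("adult_male", 6)), died = TRUE)
  ))
  ovi <- oviposition_stats(co, cfg)
  # female emerges day 20, first egg day 24
  expect_equal(ovi$estimate[ovi$parameter == "APOP"], 4)
  expect_equal(ovi$estimate[ovi$parameter == "TPOP"], 24)
  expect_equal(ovi$n[ovi$parameter == "APOP"], 1L)
})
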