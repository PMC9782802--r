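cfg <- stage_config()

test_that("simulation is reproducible and always structurally valid", {
  c1 <- simulate_cohort(config_control_like(n = 40), seed = 7)
  c2 <- simulate_cohort(config_control_like(n = 40), seed = 7)
  expect_identical(c1, c2)
  c3 <- simulate_cohort(config_control_like(n = 40), seed = 8)
  expect_false(identical(c1, c3))

  for (seed in c(1, 2)) {
    for (conf in list(config_control_like(n = 50),
                      config_treated_like(n = 50))) {
      co <- simulate_cohort(conf, seed = seed)
      expect_silent(validate_cohort(co, cfg))
      fates <- cohort_fates(co, cfg)
      expect_true(all(fates$fate == "died"))   # no censoring by design
    }
  }
})

test_that("the deterministic limit is exactly computable", {
  config <- deterministic_config(n = 8, daily_eggs = c(0, 0, 40, 60, 20),
                                 sex_ratio = 1)
  co <- simulate_cohort(config, seed = 1)
  fit <- lifetable(co)
  est <- setNames(fit$estimates$estimate, fit$estimates$parameter)
  # every female lays exactly 120 eggs; all survive
  expect_equal(est[["R0"]], 120)
  ep <- summarize_endpoints(co, cfg)
  expect_true(all(ep$se[startsWith(ep$parameter, "duration")] == 0,
                  na.rm = TRUE))
  expect_equal(ep$estimate[ep$parameter == "fecundity"], 120)

  truth <- expected_schedules(config)
  expect_equal(truth$R0, 120)
  # lx is a step function: 1 while alive (ages 0..25), 0 after the adult cap
  expect_equal(truth$schedules$lx[1:26], rep(1, 26))
  expect_equal(est[["r"]], truth$r, tolerance = 1e-9)
})

test_that("R0 scales with the sex ratio when only females lay", {
  E <- sum(c(0, 0, 40, 60, 20))
  for (s in c(0.25, 0.5, 1)) {
    truth <- expected_schedules(deterministic_config(sex_ratio = s))
    expect_equal(truth$R0, s * E, tolerance = 1e-12)
  }
})

test_that("empirical age-stage survival matches the exact expectation", {
  config <- config_control_like(n = 8000)
  truth_occ <- expected_schedules(config)
  co <- simulate_cohort(config, seed = 1234)
  mats <- build_age_stage_matrices(co, cfg)
  sched <- age_schedules(mats)

  # compare lx cellwise at binomial resolution
  K <- min(nrow(sched), nrow(truth_occ$schedules))
  lx_true <- truth_occ$schedules$lx[1:K]
  lx_hat <- sched$lx[1:K]
  se <- sqrt(pmax(lx_true * (1 - lx_true), 1e-12) / config$n)
  z <- abs(lx_hat - lx_true) / se
  expect_gt(mean(z < 3), 0.985)
  expect_true(all(z < 6))

  # TPOP recovery within 3 SE of the exact expectation
  ovi <- oviposition_stats(co, cfg)
  tpop <- ovi[ovi$parameter == "TPOP", ]
  expect_lt(abs(tpop$estimate - truth_occ$TPOP), 3 * tpop$se)
})

test_that("the intrinsic rate is recovered at large cohort sizes", {
  config <- config_control_like(n = 100000)
  truth <- expected_schedules(config)
  co <- simulate_cohort(config, seed = 20240901)
  r_hat <- tidy(lifetable(co)) |>
    dplyr::filter(parameter == "r") |>
    dplyr::pull(estimate)
  expect_lt(abs(r_hat - truth$r), 0.005)
})

test_that("dose-mortality simulation honours its truth and seed", {
  tr <- probit_truth(slope = 1, lc50 = 100, doses = c(25, 100, 400), n = 200)
  d1 <- simulate_dose_mortality(tr, seed = 5)
  d2 <- simulate_dose_mortality(tr, seed = 5)
  expect_identical(d1, d2)
  # near-infinite slope: step mortality around the LC50
  step <- simulate_dose_mortality(
    probit_truth(slope = 100, lc50 = 100, doses = c(50, 90, 110, 200),
                 n = 500), seed = 6)
  expect_equal(step$dead[1:2], c(0L, 0L))
  expect_equal(step$dead[3:4], c(500L, 500L))
})

test_that("probit recovery from repeated simulated bioassays is unbiased", {
  tr <- probit_truth()      # slope 1, LC50 100, doses 50/150/450, n = 60
  set.seed(505)
  lc50s <- replicate(200, {
    d <- simulate_dose_mortality(tr, seed = sample.int(2^30, 1))
    f <- tryCatch(suppressWarnings(fit_probit(d)), error = function(e) NULL)
    if (is.null(f)) NA_real_ else f$lc$lc[f$lc$p == 0.5]
  })
  expect_lt(abs(stats::median(lc50s, na.rm = TRUE) / tr$lc50 - 1), 0.1)
})

test_that("hatch totals are binomial per female and reproducible", {
  co <- simulate_cohort(config_control_like(n = 30), seed = 3)
  h1 <- simulate_hatch_totals(co, 0.8, seed = 4)
  h2 <- simulate_hatch_totals(co, 0.8, seed = 4)
  expect_identical(h1, h2)
  eggs <- co |> dplyr::group_by(individual_id) |>
    dplyr::summarise(eggs = sum(eggs))
  merged <- dplyr::left_join(h1, eggs, by = "individual_id")
  expect_true(all(merged$eggs_hatched <= merged$eggs))
  expect_error(simulate_hatch_totals(co, 1.2, seed = 1), "\\[0, 1\\]")
})
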