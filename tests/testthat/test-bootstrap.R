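cfg <- stage_config()

test_that("a cohort of identical individuals bootstraps to zero SE", {
  co <- simulate_cohort(deterministic_config(n = 15), seed = 5)
  bt <- bootstrap_lifetable(co, B = 100, seed = 9)
  td <- tidy(bt)
  expect_true(all(td$se == 0))
  expect_true(all(td$conf_low == td$estimate & td$conf_high == td$estimate))
})

test_that("bootstrap results are bit-identical for a fixed seed", {
  co <- simulate_cohort(config_control_like(n = 50), seed = 21)
  b1 <- bootstrap_lifetable(co, B = 150, seed = 33)
  b2 <- bootstrap_lifetable(co, B = 150, seed = 33)
  expect_identical(b1$replicates, b2$replicates)
  expect_identical(tidy(b1), tidy(b2))
  b3 <- bootstrap_lifetable(co, B = 150, seed = 34)
  expect_false(identical(b1$replicates, b3$replicates))
})

test_that("bootstrap point estimates match the plain life-table fit", {
  co <- simulate_cohort(config_control_like(n = 80), seed = 61)
  bt <- bootstrap_lifetable(co, B = 10, seed = 2)
  fit <- tidy(lifetable(co))
  for (p in fit$parameter) {
    expect_equal(unname(bt$point[[p]]), fit$estimate[fit$parameter == p],
                 tolerance = 1e-12)
  }
})

test_that("replicate means converge to the point estimate for linear statistics", {
  co <- simulate_cohort(config_control_like(n = 120), seed = 71)
  bt <- bootstrap_lifetable(co, B = 2000, seed = 8,
                            parameters = c("R0", "APOP", "TPOP"))
  for (p in c("R0", "APOP", "TPOP")) {
    repl <- bt$replicates[, p]
    expect_lt(abs(mean(repl, na.rm = TRUE) - bt$point[[p]]),
              3 * stats::sd(repl, na.rm = TRUE) / sqrt(bt$B) + 1e-12)
  }
})

test_that("bootstrap SE of R0 tracks the sampling SD across cohorts", {
  n_cohorts <- 300
  r0s <- numeric(n_cohorts)
  ses <- numeric(10)
  for (i in seq_len(n_cohorts)) {
    co <- simulate_cohort(config_control_like(n = 200), seed = 5000 + i)
    if (i <= 10) {
      bt <- bootstrap_lifetable(co, B = 2000, seed = 6000 + i,
                                parameters = "R0")
      ses[i] <- bt$se[["R0"]]
      r0s[i] <- bt$point[["R0"]]
    } else {
      r0s[i] <- sum(co$eggs) / dplyr::n_distinct(co$individual_id)
    }
  }
  ratio <- mean(ses) / stats::sd(r0s)
  expect_lt(abs(ratio - 1), 0.2)
})

test_that("group comparison is null for identical cohorts and antisymmetric", {
  co <- simulate_cohort(config_control_like(n = 60), seed = 41)
  a <- bootstrap_lifetable(co, B = 300, seed = 1, parameters = "R0")
  b <- bootstrap_lifetable(co, B = 300, seed = 1, parameters = "R0")
  null_cmp <- compare_groups(a, b, "R0")
  expect_equal(null_cmp$difference, 0)
  expect_equal(null_cmp$p_value, 1)

  co2 <- simulate_cohort(config_treated_like(n = 60), seed = 42)
  c2 <- bootstrap_lifetable(co2, B = 300, seed = 2, parameters = "R0")
  ab <- compare_groups(a, c2, "R0")
  ba <- compare_groups(c2, a, "R0")
  expect_equal(ab$difference, -ba$difference)
  expect_equal(ab$conf_low, -ba$conf_high)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("well-separated cohorts yield intervals excluding zero", {
  a <- bootstrap_lifetable(
    simulate_cohort(config_control_like(n = 200), seed = 81),
    B = 2000, seed = 3, parameters = "R0")
  b <- bootstrap_lifetable(
    simulate_cohort(config_treated_like(n = 200), seed = 82),
    B = 2000, seed = 4, parameters = "R0")
  cmp <- compare_groups(a, b, "R0")
  expect_gt(cmp$conf_low, 0)
  expect_lt(cmp$p_value, 0.01)
})

test_that("undefined-parameter replicates are counted and can refuse comparison", {
  # tiny cohort where many resamples contain no reproducing female
  co <- build_cohort(list(
    list(stages = c(rep("L3", 3), rep("L4", 3), rep("L5", 3), rep("pupa", 5),
                    rep("adult_female", 3)),
         eggs = c(rep(0, 14), 10, 10, 0), died = TRUE),
    list(stages = c("L3", "L4"), died = TRUE),
    list(stages = c("L3", "L3", "L4"), died = TRUE)
  ))
  expect_message(
    bt <- bootstrap_lifetable(co, B = 200, seed = 10,
                              parameters = c("R0", "r")),
    "Undefined")
  expect_gt(bt$n_undefined[["r"]], 0)
  # guard: a group with mostly-undefined replicates refuses comparison
  broken <- bt
  broken$replicates[1:150, "r"] <- NA_real_
  expect_error(compare_groups(broken, bt, "r"), "refused")
})

test_that("the replicate-ANOVA compatibility path inflates df as documented", {
  a <- bootstrap_lifetable(
    simulate_cohort(config_control_like(n = 60), seed = 91),
    B = 500, seed = 5, parameters = "R0")
  b <- bootstrap_lifetable(
    simulate_cohort(config_treated_like(n = 60), seed = 92),
    B = 500, seed = 6, parameters = "R0")
  out <- anova_on_replicates(list(control = a, treated = b), "R0")
  expect_equal(out$df1, 1)
  expect_equal(out$df2, 2 * 500 - 2)
  expect_lt(out$p_value, 1e-10)
})
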