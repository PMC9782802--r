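exact_line_table <- function(alpha = -2, beta = 1, doses = c(10, 100, 1000),
                             n = 1000) {
  tibble::tibble(dose = doses, n = n,
                 dead = n * pnorm(alpha + beta * log10(doses)))
}

test_that("exact-line data recover the generating line with zero chi-square", {
  fit <- fit_probit(exact_line_table())
  expect_equal(unname(coef(fit)[["slope"]]), 1, tolerance = 1e-6)
  expect_equal(unname(coef(fit)[["intercept"]]), -2, tolerance = 1e-6)
  expect_lt(fit$chi2, 1e-8)
  expect_equal(fit$df, 1L)
  expect_equal(fit$heterogeneity, 1)
})

test_that("the glm scoring fit matches direct likelihood maximisation", {
  tab <- simulate_dose_mortality(probit_truth(slope = 1.2, lc50 = 120),
                                 seed = 314)
  fit <- suppressWarnings(fit_probit(tab))
  nll <- function(par) {
    p <- pnorm(par[1] + par[2] * log10(tab$dose))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(tab$dead * log(p) + (tab$n - tab$dead) * log(1 - p))
  }
  opt <- optim(c(0, 1), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(unname(coef(fit)), opt$par, tolerance = 1e-4)
})

test_that("lethal concentrations follow the closed-form ratio laws", {
  fit <- fit_probit(exact_line_table())
  lc <- lethal_concentration(fit, c(0.5, 0.9))
  expect_equal(lc$lc[1], 100, tolerance = 1e-5)
  # LC90/LC50 = 10^(qnorm(0.9)/beta) for any fit
  expect_equal(lc$lc[2] / lc$lc[1],
               10^(qnorm(0.9) / coef(fit)[["slope"]]), tolerance = 1e-6)
  # LCp strictly increasing in p for positive slope
  seqs <- lethal_concentration(fit, c(0.1, 0.3, 0.5, 0.7, 0.9))
  expect_true(all(diff(seqs$lc) > 0))
  expect_error(lethal_concentration(fit, 1.2), "between 0 and 1")
})

test_that("a zero covariance collapses fiducial limits to the point estimate", {
  fit <- fit_probit(exact_line_table())
  fit$vcov <- matrix(0, 2, 2)
  lc <- lethal_concentration(fit, 0.5)
  expect_equal(lc$conf_low, lc$lc)
  expect_equal(lc$conf_high, lc$lc)
  expect_equal(lc$g, 0)
})

test_that("doses rescale equivariantly without touching slope or fit", {
  tab <- simulate_dose_mortality(
    probit_truth(slope = 1, lc50 = 100, doses = c(20, 60, 120, 300, 800),
                 n = 100), seed = 9)
  f1 <- fit_probit(tab)
  tab2 <- dplyr::mutate(tab, dose = dose * 7.3)
  f2 <- fit_probit(tab2)
  expect_equal(coef(f2)[["slope"]], coef(f1)[["slope"]], tolerance = 1e-8)
  expect_equal(f2$chi2, f1$chi2, tolerance = 1e-8)
  expect_equal(f2$lc$lc, f1$lc$lc * 7.3, tolerance = 1e-6)
  expect_equal(f2$lc$conf_low, f1$lc$conf_low * 7.3, tolerance = 1e-6)
})

test_that("degenerate tables are rejected informatively", {
  expect_error(fit_probit(tibble::tibble(dose = 100, n = 60, dead = 30)),
               "two distinct doses")
  expect_error(
    fit_probit(tibble::tibble(dose = c(10, 100), n = 60, dead = c(0, 0))),
    "All-alive")
  expect_error(
    fit_probit(tibble::tibble(dose = c(10, 1000), n = 60, dead = c(0, 60))),
    "separation")
  expect_error(
    fit_probit(tibble::tibble(dose = c(-1, 10), n = 60, dead = c(1, 5))),
    "positive")
})

test_that("two-dose fits report the goodness of fit as undefined", {
  tab <- tibble::tibble(dose = c(50, 450), n = 100, dead = c(30, 70))
  fit <- fit_probit(tab)
  expect_true(is.na(fit$chi2))
  expect_true(is.na(fit$p_value))
  expect_equal(fit$df, 0L)
})

test_that("heterogeneity scaling widens limits when chi2/df > 1", {
  tab <- tibble::tibble(dose = c(10, 50, 100, 500), n = 100,
                        dead = c(12, 32, 62, 80))   # mild lack of fit
  fit <- fit_probit(tab)
  expect_gt(fit$heterogeneity, 1)
  unscaled <- fit
  unscaled$vcov <- fit$vcov_raw
  unscaled$crit <- qnorm(0.975)
  lc_h <- lethal_concentration(fit, 0.5)
  lc_0 <- lethal_concentration(unscaled, 0.5)
  expect_lt(lc_h$conf_low, lc_0$conf_low)
  expect_gt(lc_h$conf_high, lc_0$conf_high)
})

test_that("implied_slope inverts the LC-ratio identity", {
  expect_equal(implied_slope(100, 100 * 10^qnorm(0.9)), 1)
  fit <- fit_probit(exact_line_table(beta = 1.4))
  lc <- lethal_concentration(fit, c(0.5, 0.9))
  expect_equal(implied_slope(lc$lc[1], lc$lc[2]), 1.4, tolerance = 1e-6)
  expect_error(implied_slope(100, 50), "exceed")
})

test_that("Abbott correction rescales mortality before fitting", {
  tab <- exact_line_table()
  # add 20% control mortality on top: p' = c + (1-c) p
  cc <- 0.2
  tab$dead <- tab$n * (cc + (1 - cc) * (tab$dead / tab$n))
  fit <- fit_probit(tab, control_mortality = cc)
  expect_equal(unname(coef(fit)[["slope"]]), 1, tolerance = 1e-6)
  expect_equal(unname(coef(fit)[["intercept"]]), -2, tolerance = 1e-6)
})
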