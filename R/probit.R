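#' Fit a probit dose-response model
#'
#' Maximum-likelihood probit regression of binomial mortality on log10 dose:
#' `P(dead) = Phi(alpha + beta * log10(dose))`, fitted by iteratively
#' reweighted least squares. Reports the slope with standard error, Pearson
#' chi-square goodness of fit with `df = #doses - 2`, the heterogeneity
#' factor, and lethal concentrations (LC50, LC90 by default) with 95%
#' fiducial limits from Fieller's theorem.
#'
#' When the fit is over-dispersed (`chi2/df > 1`) the covariance matrix is
#' scaled by the heterogeneity factor `h = chi2/df` and fiducial limits use
#' t critical values on `df` degrees of freedom instead of normal ones, the
#' standard convention for bioassay probit analysis. Doses with 0% or 100%
#' observed mortality are retained; the likelihood handles them. No control
#' mortality correction is applied unless `control_mortality` is given, in
#' which case observed mortality is Abbott-corrected before fitting.
#'
#' @param table Data frame with columns `dose` (> 0), `n` (exposed, > 0) and
#'   `dead` (0 to `n`; real values are accepted for testing against exact
#'   expectations). At least two distinct doses are required.
#' @param p_levels Mortality quantiles at which to report lethal
#'   concentrations (default LC50 and LC90).
#' @param conf_level Coverage of the fiducial limits (default 0.95).
#' @param control_mortality Optional control mortality fraction in `[0, 1)`
#'   for Abbott's correction.
#' @return An object of class `probit_fit`: list with `coefficients`
#'   (`intercept`, `slope`), `vcov` (heterogeneity-scaled), `vcov_raw`,
#'   `chi2`, `df`, `p_value`, `heterogeneity`, `crit` (critical value used
#'   for limits), `lc` (tibble of lethal concentrations), `data`,
#'   `conf_level`.
#' @examples
#' # exact-line data: mortality on the probit line alpha = -2, beta = 1
#' d <- data.frame(dose = c(10, 100, 1000), n = 1000)
#' d$dead <- d$n * pnorm(log10(d$dose) - 2)
#' fit <- fit_probit(d)
#' coef(fit)
#' fit$lc
#' @export
fit_probit <- function(table, p_levels = c(0.5, 0.9), conf_level = 0.95,
                       control_mortality = NULL) {
  tab <- check_dose_table(table)
  if (!is.null(control_mortality)) {
    if (control_mortality < 0 || control_mortality >= 1) {
      abort("`control_mortality` must be in [0, 1).")
    }
    tab$dead <- pmax(0, (tab$dead / tab$n - control_mortality) /
                       (1 - control_mortality)) * tab$n
  }
  if (sum(tab$dead) == 0 || sum(tab$dead) == sum(tab$n)) {
    abort("All-alive or all-dead data: probit model cannot be fitted.")
  }
  if (all(tab$dead == 0 | tab$dead == tab$n)) {
    abort(paste0(
      "Complete separation: every dose shows 0% or 100% mortality, so the ",
      "slope is not finitely estimable. Consider intermediate doses."))
  }
  x <- log10(tab$dose)
  fit <- withCallingHandlers(
    stats::glm(cbind(dead, n - dead) ~ x,
               family = stats::binomial(link = "probit"),
               data = data.frame(dead = tab$dead, n = tab$n, x = x)),
    warning = function(w) {
      if (grepl("non-integer", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- unname(stats::coef(fit))
  if (!fit$converged || abs(beta[2]) > 50 || any(!is.finite(beta))) {
    abort(paste0(
      "Probit fit did not stabilise (likely complete separation): ",
      "mortality jumps from 0 to 1 between adjacent doses. ",
      "Consider intermediate doses."))
  }
  p_hat <- stats::pnorm(beta[1] + beta[2] * x)
  chi2 <- sum((tab$dead - tab$n * p_hat)^2 / (tab$n * p_hat * (1 - p_hat)))
  df <- length(unique(tab$dose)) - 2L
  V_raw <- unname(stats::vcov(fit))
  if (df >= 1L) {
    h <- max(1, chi2 / df)
    p_value <- stats::pchisq(chi2, df, lower.tail = FALSE)
  } else {
    h <- 1
    chi2 <- NA_real_
    p_value <- NA_real_
  }
  heterogeneous <- df >= 1L && h > 1
  V <- V_raw * h
  crit <- if (heterogeneous) stats::qt(1 - (1 - conf_level) / 2, df)
          else stats::qnorm(1 - (1 - conf_level) / 2)

  out <- structure(
    list(coefficients = c(intercept = beta[1], slope = beta[2]),
         vcov = V, vcov_raw = V_raw,
         chi2 = chi2, df = df, p_value = p_value,
         heterogeneity = h, heterogeneous = heterogeneous, crit = crit,
         data = tab, conf_level = conf_level),
    class = "probit_fit"
  )
  out$lc <- lethal_concentration(out, p_levels)
  out
}

check_dose_table <- function(table) {
  required <- c("dose", "n", "dead")
  missing <- setdiff(required, names(table))
  if (length(missing)) {
    abort(sprintf("Dose-mortality table is missing columns: %s",
                  paste(missing, collapse = ", ")))
  }
  tab <- tibble::as_tibble(table)[required]
  if (any(tab$dose <= 0)) abort("Doses must be strictly positive.")
  if (any(tab$n <= 0)) abort("`n` exposed must be positive.")
  if (any(tab$dead < 0 | tab$dead > tab$n)) {
    abort("`dead` must lie in [0, n] for every dose.")
  }
  if (length(unique(tab$dose)) < 2L) {
    abort("At least two distinct doses are required for fitting.")
  }
  tab
}

#' Lethal concentration with fiducial limits
#'
#' For a fitted probit model, the concentration killing a fraction `p` is
#' `LCp = 10^((qnorm(p) - alpha) / beta)`. Fiducial limits are obtained from
#' Fieller's theorem applied to the ratio `(qnorm(p) - alpha) / beta` using
#' the (heterogeneity-scaled) covariance of the coefficients; when
#' `g = crit^2 * var(beta) / beta^2 >= 1` the interval is unbounded and the
#' limits are reported as `NA` with `g` flagging the cause.
#'
#' @param fit A `probit_fit` object.
#' @param p Mortality fractions in (0, 1).
#' @return A tibble with columns `p`, `lc`, `conf_low`, `conf_high`, `g`.
#' @examples
#' d <- data.frame(dose = c(10, 100, 1000), n = 1000)
#' d$dead <- d$n * pnorm(log10(d$dose) - 2)
#' lethal_concentration(fit_probit(d), p = 0.5)   # LC50 = 100
#' @export
lethal_concentration <- function(fit, p) {
  if (!inherits(fit, "probit_fit")) abort("`fit` must be a probit_fit object.")
  if (any(p <= 0 | p >= 1)) abort("`p` must lie strictly between 0 and 1.")
  alpha <- fit$coefficients[["intercept"]]
  beta <- fit$coefficients[["slope"]]
  if (beta <= 0) {
    abort("Lethal concentrations require a positive fitted slope.")
  }
  V <- fit$vcov
  tcrit <- fit$crit
  purrr::map_dfr(p, function(pi) {
    zp <- stats::qnorm(pi)
    a <- zp - alpha
    b <- beta
    v_a <- V[1, 1]
    v_b <- V[2, 2]
    c_ab <- -V[1, 2]
    g <- tcrit^2 * v_b / b^2
    rho <- a / b
    if (g >= 1) {
      warn(sprintf(
        "g = %.3f >= 1 at p = %.2f: fiducial limits unbounded, reported NA.",
        g, pi))
      return(tibble::tibble(p = pi, lc = 10^rho,
                            conf_low = NA_real_, conf_high = NA_real_, g = g))
    }
    A <- b^2 - tcrit^2 * v_b
    Bq <- 2 * (tcrit^2 * c_ab - a * b)
    Cq <- a^2 - tcrit^2 * v_a
    disc <- Bq^2 - 4 * A * Cq
    if (disc < 0) disc <- 0
    roots <- sort((-Bq + c(-1, 1) * sqrt(disc)) / (2 * A))
    tibble::tibble(p = pi, lc = 10^rho,
                   conf_low = 10^roots[1], conf_high = 10^roots[2], g = g)
  })
}

#' @export
coef.probit_fit <- function(object, ...) object$coefficients

#' @export
vcov.probit_fit <- function(object, ...) object$vcov

#' @export
print.probit_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<probit_fit> %d doses, n = %g\n",
              nrow(x$data), sum(x$data$n)))
  cat(sprintf("  slope %.3f +/- %.3f, intercept %.3f\n",
              x$coefficients[["slope"]], sqrt(x$vcov[2, 2]),
              x$coefficients[["intercept"]]))
  if (!is.na(x$chi2)) {
    cat(sprintf("  chi2 = %.3f on %d df (p = %.3f), heterogeneity %.2f\n",
                x$chi2, x$df, x$p_value, x$heterogeneity))
  }
  lc <- x$lc
  for (i in seq_len(nrow(lc))) {
    cat(sprintf("  LC%g = %.4g (%.4g - %.4g)\n", 100 * lc$p[i], lc$lc[i],
                lc$conf_low[i], lc$conf_high[i]))
  }
  invisible(x)
}

#' Tidy probit coefficients
#'
#' @param x A `probit_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error` (from the
#'   heterogeneity-scaled covariance), `statistic`, `p.value`.
#' @method tidy probit_fit
#' @export
tidy.probit_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  z <- unname(x$coefficients) / se
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = unname(x$coefficients),
    std.error = se,
    statistic = z,
    p.value = 2 * stats::pnorm(-abs(z))
  )
}

#' One-row probit fit summary
#'
#' @param x A `probit_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_doses`, `n_total`, `slope`, `slope_se`,
#'   `chi2`, `df`, `p_value`, `heterogeneity`.
#' @method glance probit_fit
#' @export
glance.probit_fit <- function(x, ...) {
  tibble::tibble(
    n_doses = nrow(x$data), n_total = sum(x$data$n),
    slope = x$coefficients[["slope"]], slope_se = sqrt(x$vcov[2, 2]),
    chi2 = x$chi2, df = x$df, p_value = x$p_value,
    heterogeneity = x$heterogeneity
  )
}

#' Slope implied by a pair of lethal concentrations
#'
#' Under the probit model on log10 dose, `LCq = LCp * 10^((qnorm(q) -
#' qnorm(p)) / beta)`, so a published (LC50, LC90) pair implies
#' `beta = qnorm(0.9) / log10(LC90 / LC50)`. Useful as an internal
#' consistency check of published dose-response tables.
#'
#' @param lc50,lc90 Lethal concentrations for 50% and 90% mortality.
#' @return The implied probit slope.
#' @examples
#' implied_slope(100, 100 * 10^(qnorm(0.9)))  # slope 1
#' @export
implied_slope <- function(lc50, lc90) {
  if (any(lc90 <= lc50)) abort("LC90 must exceed LC50.")
  stats::qnorm(0.9) / log10(lc90 / lc50)
}
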