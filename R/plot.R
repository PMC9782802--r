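#' Plot age-specific survival and fecundity curves
#'
#' Draws `lx` (probability of being alive at age x) and `mx` (mean eggs per
#' surviving individual) against age in days, faceted on free y scales, the
#' standard way these schedules are displayed.
#'
#' @param object An `age_schedules` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot age_schedules
#' @export
autoplot.age_schedules <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), c("lx", "mx"),
                              names_to = "schedule", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$age, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~schedule, ncol = 1, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(lx = "age-specific survival (lx)",
                            mx = "age-specific fecundity (mx)"))) +
    ggplot2::labs(x = "age (days)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a fitted probit dose-response curve
#'
#' Observed mortality fractions against log10 dose with the fitted probit
#' curve and the lethal concentrations marked.
#'
#' @param object A `probit_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot probit_fit
#' @export
autoplot.probit_fit <- function(object, ...) {
  obs <- dplyr::mutate(object$data,
                       logdose = log10(.data$dose),
                       mortality = .data$dead / .data$n)
  a <- object$coefficients[["intercept"]]
  b <- object$coefficients[["slope"]]
  grid <- tibble::tibble(
    logdose = seq(min(obs$logdose) - 0.5, max(obs$logdose) + 0.5,
                  length.out = 200))
  grid$mortality <- stats::pnorm(a + b * grid$logdose)
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$logdose, y = .data$mortality)) +
    ggplot2::geom_line(data = grid) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), shape = 21) +
    ggplot2::geom_vline(xintercept = log10(object$lc$lc), linetype = 2,
                        colour = "grey50") +
    ggplot2::scale_size_area(max_size = 4, guide = "none") +
    ggplot2::labs(x = "log10 dose", y = "mortality fraction") +
    ggplot2::theme_minimal()
}

#' Plot bootstrap replicate distributions
#'
#' Histograms of the bootstrap replicates per demographic parameter with the
#' point estimate and percentile interval marked.
#'
#' @param object A `lifetable_boot` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lifetable_boot
#' @export
autoplot.lifetable_boot <- function(object, ...) {
  repl <- tibble::as_tibble(object$replicates) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "parameter",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  marks <- tidy(object)
  ggplot2::ggplot(repl, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = NA) +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$estimate)) +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$conf_low),
                        linetype = 2) +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$conf_high),
                        linetype = 2) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "replicates") +
    ggplot2::theme_minimal()
}
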