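#' Bootstrap demographic parameters by resampling individuals
#'
#' Resamples whole individuals with replacement (the exchangeable unit of a
#' rearing experiment), rebuilds the age-stage schedules for each replicate,
#' and recomputes every requested demographic parameter, yielding bootstrap
#' standard errors (SD of replicates) and percentile confidence intervals.
#'
#' Replicates where a parameter is undefined (for example `r` when a
#' resample contains no reproducing female, so R0 = 0) are recorded as `NA`,
#' counted, and excluded from the SE/CI for that parameter. Results are
#' deterministic for a fixed seed: all resampling indices are drawn up-front
#' from one stream, so the outcome does not depend on evaluation order.
#'
#' @inheritParams summarize_endpoints
#' @param B Number of bootstrap replicates (default 10000; studies often use
#'   100000, which this implementation supports but does not default to).
#' @param seed Integer seed (required).
#' @param parameters Which parameters to bootstrap, a subset of
#'   `c("R0", "GRR", "r", "lambda", "T", "APOP", "TPOP")`. Restricting to
#'   cheap parameters (R0, APOP, TPOP) uses a fully vectorised path.
#' @param conf_level Coverage of the percentile interval (default 0.95).
#' @return An object of class `lifetable_boot`: list with `point` (named
#'   vector of full-cohort estimates), `replicates` (B x parameters matrix),
#'   `se`, `ci` (2 x parameters), `n_undefined`, `B`, `n`, `seed`,
#'   `conf_level`, `treatment`.
#' @examples
#' cohort <- simulate_cohort(simulation_config(n = 40), seed = 1)
#' boot <- bootstrap_lifetable(cohort, B = 200, seed = 7)
#' tidy(boot)
#' @export
bootstrap_lifetable <- function(cohort,
                                stage_config = lifetabler::stage_config(),
                                B = 10000L, seed,
                                parameters = c("R0", "GRR", "r", "lambda",
                                               "T", "APOP", "TPOP"),
                                conf_level = 0.95,
                                censored = c("exclude", "as_dead")) {
  cfg <- check_stage_config(stage_config)
  if (missing(seed)) abort("`seed` is required for reproducibility.")
  B <- as.integer(B)
  if (B < 1L) abort("`B` must be >= 1.")
  parameters <- match.arg(parameters, several.ok = TRUE)
  cohort <- validate_cohort(cohort, cfg)
  cohort <- resolve_censoring(cohort, cfg, censored)

  pre <- boot_precompute(cohort, cfg)
  N <- pre$n

  set.seed(seed)
  idx <- matrix(sample.int(N, N * B, replace = TRUE), nrow = B, ncol = N)

  point <- boot_params(seq_len(N), pre, parameters)
  need_loop <- any(c("GRR", "r", "lambda", "T") %in% parameters)
  repl <- matrix(NA_real_, nrow = B, ncol = length(parameters),
                 dimnames = list(NULL, parameters))

  if ("R0" %in% parameters) {
    repl[, "R0"] <- rowMeans(matrix(pre$egg_tot[idx], nrow = B))
  }
  if ("APOP" %in% parameters) {
    repl[, "APOP"] <- rowMeans(matrix(pre$apop[idx], nrow = B), na.rm = TRUE)
  }
  if ("TPOP" %in% parameters) {
    repl[, "TPOP"] <- rowMeans(matrix(pre$tpop[idx], nrow = B), na.rm = TRUE)
  }
  if (need_loop) {
    for (b in seq_len(B)) {
      v <- boot_params(idx[b, ], pre,
                       intersect(parameters, c("GRR", "r", "lambda", "T")))
      repl[b, names(v)] <- v
    }
  }
  repl[is.nan(repl)] <- NA_real_

  alpha <- (1 - conf_level) / 2
  se <- apply(repl, 2, stats::sd, na.rm = TRUE)
  ci <- apply(repl, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE, names = FALSE)
  n_undef <- colSums(is.na(repl))
  if (any(n_undef > 0L)) {
    inform(sprintf(
      "Undefined in some replicates: %s",
      paste(sprintf("%s (%d/%d)", parameters[n_undef > 0L],
                    n_undef[n_undef > 0L], B), collapse = ", ")))
  }

  structure(
    list(point = point, replicates = repl, se = se, ci = ci,
         n_undefined = n_undef, B = B, n = N, seed = seed,
         conf_level = conf_level,
         treatment = unique(cohort$treatment)),
    class = "lifetable_boot"
  )
}

# Per-individual structures shared by all replicates.
boot_precompute <- function(cohort, cfg) {
  living <- dplyr::filter(cohort, .data$stage != cfg$death)
  ids <- sort(unique(cohort$individual_id))
  n <- length(ids)
  max_age <- max(living$day)
  A <- max_age + 1L
  row <- match(living$individual_id, ids)
  col <- living$day + 1L
  alive <- matrix(0L, nrow = n, ncol = A)
  alive[cbind(row, col)] <- 1L
  eggs <- matrix(0, nrow = n, ncol = A)
  eggs[cbind(row, col)] <- living$eggs
  ovi <- oviposition_per_female(cohort, cfg)
  ovi <- ovi[match(ids, ovi$individual_id), ]
  list(n = n, ages = A, alive = alive, eggs = eggs,
       egg_tot = rowSums(eggs), apop = ovi$apop, tpop = ovi$tpop)
}

# Demographic parameters for one resample (vector of row indices).
boot_params <- function(take, pre, parameters) {
  N <- length(take)
  out <- stats::setNames(rep(NA_real_, length(parameters)), parameters)
  ec <- colSums(pre$eggs[take, , drop = FALSE])
  R0 <- sum(ec) / N
  if ("R0" %in% parameters) out["R0"] <- R0
  if ("GRR" %in% parameters) {
    ac <- colSums(pre$alive[take, , drop = FALSE])
    out["GRR"] <- sum(ifelse(ac > 0, ec / ac, 0))
  }
  if (any(c("r", "lambda", "T") %in% parameters) && R0 > 0) {
    r <- as.numeric(euler_lotka_solve(ec / N))
    if ("r" %in% parameters) out["r"] <- r
    if ("lambda" %in% parameters) out["lambda"] <- exp(r)
    if ("T" %in% parameters && r != 0) out["T"] <- log(R0) / r
  }
  if ("APOP" %in% parameters) {
    a <- pre$apop[take]
    out["APOP"] <- if (all(is.na(a))) NA_real_ else mean(a, na.rm = TRUE)
  }
  if ("TPOP" %in% parameters) {
    t <- pre$tpop[take]
    out["TPOP"] <- if (all(is.na(t))) NA_real_ else mean(t, na.rm = TRUE)
  }
  out
}

#' @export
print.lifetable_boot <- function(x, digits = 3, ...) {
  cat(sprintf("<lifetable_boot> treatment '%s', n = %d, B = %d, seed = %d\n",
              x$treatment, x$n, x$B, x$seed))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy a bootstrap result
#'
#' @param x A `lifetable_boot` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `parameter`, `estimate`
#'   (full-cohort point estimate), `se` (SD of replicates), `conf_low`,
#'   `conf_high` (percentile interval), `n_undefined`.
#' @method tidy lifetable_boot
#' @export
tidy.lifetable_boot <- function(x, ...) {
  tibble::tibble(
    parameter = colnames(x$replicates),
    estimate = unname(x$point[colnames(x$replicates)]),
    se = unname(x$se),
    conf_low = x$ci[1, ],
    conf_high = x$ci[2, ],
    n_undefined = unname(x$n_undefined)
  )
}

#' One-row summary of a bootstrap run
#'
#' @param x A `lifetable_boot` object.
#' @param ... Unused.
#' @return A one-row tibble: `treatment`, `n`, `B`, `seed`, `conf_level`.
#' @method glance lifetable_boot
#' @export
glance.lifetable_boot <- function(x, ...) {
  tibble::tibble(treatment = x$treatment, n = x$n, B = x$B,
                 seed = x$seed, conf_level = x$conf_level)
}

#' Compare a demographic parameter between two bootstrapped cohorts
#'
#' Computes the difference in point estimates (`a` minus `b`) with a
#' percentile confidence interval and a two-sided bootstrap p-value from the
#' replicate differences `a_i - b_i` (the cohorts are independent, so pairing
#' replicates by index is an arbitrary but valid coupling).
#'
#' This percentile-difference comparison is the package's primary inferential
#' tool between treatments; treating bootstrap replicates as ANOVA samples
#' (see [anova_on_replicates()]) inflates the degrees of freedom and is
#' provided only for compatibility.
#'
#' @param a,b `lifetable_boot` objects with equal `B` containing `parameter`.
#' @param parameter Parameter name to compare, e.g. `"R0"`.
#' @param conf_level Coverage of the percentile interval.
#' @return A one-row tibble: `parameter`, `difference`, `conf_low`,
#'   `conf_high`, `p_value`, `B_used` (replicate pairs where both sides were
#'   defined).
#' @export
compare_groups <- function(a, b, parameter, conf_level = 0.95) {
  for (obj in list(a, b)) {
    if (!inherits(obj, "lifetable_boot")) {
      abort("`a` and `b` must be lifetable_boot objects.")
    }
    if (!parameter %in% colnames(obj$replicates)) {
      abort(sprintf("Parameter '%s' was not bootstrapped in both groups.",
                    parameter))
    }
  }
  if (a$B != b$B) abort("Both bootstrap runs must use the same B.")
  ra <- a$replicates[, parameter]
  rb <- b$replicates[, parameter]
  for (nm in c("a", "b")) {
    r <- if (nm == "a") ra else rb
    if (mean(is.na(r)) > 0.5) {
      abort(sprintf(
        "Parameter '%s' undefined in %.0f%% of group %s replicates; comparison refused.",
        parameter, 100 * mean(is.na(r)), nm))
    }
  }
  d <- ra - rb
  d <- d[!is.na(d)]
  alpha <- (1 - conf_level) / 2
  ci <- stats::quantile(d, c(alpha, 1 - alpha), names = FALSE)
  p <- min(1, 2 * min(mean(d <= 0), mean(d >= 0)))
  tibble::tibble(
    parameter = parameter,
    difference = unname(a$point[parameter] - b$point[parameter]),
    conf_low = ci[1], conf_high = ci[2],
    p_value = p, B_used = length(d)
  )
}

#' Compatibility: one-way ANOVA over bootstrap replicates
#'
#' Reproduces the convention of treating each bootstrap replicate as an
#' independent observation and running a one-way ANOVA across groups. With
#' B replicates per group the error degrees of freedom are inflated to
#' roughly `groups * B`, which makes the test anti-conservative (tiny
#' p-values regardless of effect size). Provided to reproduce published
#' table footnotes, not recommended for inference; use [compare_groups()].
#'
#' @param boots Named list of `lifetable_boot` objects (>= 2).
#' @param parameter Parameter name.
#' @return A one-row tibble: `parameter`, `statistic` (F), `df1`, `df2`,
#'   `p_value`.
#' @export
anova_on_replicates <- function(boots, parameter) {
  if (length(boots) < 2L) abort("Need at least two groups.")
  vals <- purrr::imap_dfr(boots, function(bt, nm) {
    tibble::tibble(group = nm, value = bt$replicates[, parameter])
  })
  vals <- dplyr::filter(vals, !is.na(.data$value))
  fit <- stats::aov(value ~ group, data = vals)
  s <- summary(fit)[[1]]
  tibble::tibble(
    parameter = parameter,
    statistic = s[["F value"]][1],
    df1 = s[["Df"]][1], df2 = s[["Df"]][2],
    p_value = s[["Pr(>F)"]][1]
  )
}
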