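#' Run the full life-table pipeline over a multi-treatment dataset
#'
#' Splits a cohort table by treatment, fits the life table, bootstraps every
#' demographic parameter, summarises bioassay endpoints, and writes a
#' publication-style report bundle: a demographic estimates TSV (one row per
#' treatment and parameter with bootstrap SE and percentile CI), an endpoint
#' summary TSV, one `lx`/`mx` curve TSV per treatment, and a run log
#' recording cohort sizes, the seed and B. All numeric computation is done at
#' full precision; `digits` only affects the estimates table written to disk.
#'
#' @param cohort A cohort tibble (possibly several treatments), or a path to
#'   a cohort CSV readable by [read_cohort()].
#' @inheritParams bootstrap_lifetable
#' @param out_dir Output directory (created if missing).
#' @param digits Display rounding for the estimates TSV (default 2).
#' @param hatch Optional hatch sidecar for fertility (see
#'   [summarize_endpoints()]).
#' @return Invisibly, a list with `fits`, `boots`, `endpoints` (tibble),
#'   `estimates` (tibble) and `files` (paths written).
#' @export
run_lifetable <- function(cohort,
                          stage_config = lifetabler::stage_config(),
                          B = 1000L, seed, out_dir,
                          digits = 2, hatch = NULL,
                          censored = c("exclude", "as_dead")) {
  cfg <- check_stage_config(stage_config)
  if (missing(seed)) abort("`seed` is required.")
  if (missing(out_dir)) abort("`out_dir` is required.")
  if (is.character(cohort) && length(cohort) == 1L) {
    cohort <- read_cohort(cohort, cfg)
  }
  cohort <- validate_cohort(cohort, cfg)
  cohort <- resolve_censoring(cohort, cfg, censored)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  treatments <- unique(cohort$treatment)
  files <- character(0)
  log_lines <- c(
    sprintf("lifetabler %s | R %s.%s",
            as.character(utils::packageVersion("lifetabler")),
            R.version$major, R.version$minor),
    sprintf("seed=%d B=%d treatments=%d", seed, B, length(treatments))
  )

  fits <- list(); boots <- list()
  for (i in seq_along(treatments)) {
    tr <- treatments[i]
    sub <- dplyr::filter(cohort, .data$treatment == tr)
    fits[[tr]] <- lifetable(sub, cfg, censored = "as_dead")
    boots[[tr]] <- bootstrap_lifetable(sub, cfg, B = B, seed = seed + i,
                                       censored = "as_dead")
    curve_file <- file.path(out_dir,
                            sprintf("lx_mx_curves_%s.tsv", sanitize(tr)))
    export_curves(fits[[tr]]$schedules, curve_file)
    files <- c(files, curve_file)
    log_lines <- c(log_lines, sprintf(
      "treatment=%s n=%d max_age=%d boot_seed=%d",
      tr, fits[[tr]]$n, max(fits[[tr]]$schedules$age), seed + i))
  }

  estimates <- purrr::imap_dfr(boots, function(bt, tr) {
    dplyr::mutate(tidy(bt), treatment = tr, .before = 1)
  })
  est_file <- file.path(out_dir, "estimates.tsv")
  est_out <- dplyr::mutate(estimates, dplyr::across(
    c("estimate", "se", "conf_low", "conf_high"), ~ round(.x, digits)))
  readr::write_tsv(est_out, est_file, progress = FALSE)

  endpoints <- summarize_endpoints(cohort, cfg, hatch = hatch,
                                   censored = "as_dead")
  end_file <- file.path(out_dir, "endpoints.tsv")
  readr::write_tsv(
    dplyr::mutate(endpoints, dplyr::across(
      c("estimate", "se"), ~ round(.x, digits))),
    end_file, progress = FALSE)

  log_file <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, log_file)
  files <- c(files, est_file, end_file, log_file)

  invisible(list(fits = fits, boots = boots, endpoints = endpoints,
                 estimates = estimates, files = files))
}

sanitize <- function(x) gsub("[^A-Za-z0-9_.-]+", "_", x)

#' Export lx/mx curves to TSV
#'
#' Writes the age-specific survival and fecundity schedules in the layout
#' used for survival/fecundity curve figures: columns `age_day`, `lx`, `mx`,
#' `lxmx`, one row per day of age, full precision.
#'
#' @param sched An `age_schedules` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_curves <- function(sched, path) {
  sched <- check_schedules(sched)
  out <- tibble::tibble(age_day = sched$age, lx = sched$lx, mx = sched$mx,
                        lxmx = sched$lx * sched$mx)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read back an exported curve file
#'
#' @param path Path written by [export_curves()].
#' @return An `age_schedules` tibble.
#' @export
read_curves <- function(path) {
  x <- readr::read_tsv(path, col_types = "iddd", progress = FALSE)
  new_age_schedules(x$age_day, x$lx, x$mx)
}
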