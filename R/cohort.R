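#' Read an individual-by-day cohort file
#'
#' Reads a long-format cohort CSV (one row per individual per day), validates
#' it against a stage configuration, and returns it with rows normalised to
#' (individual, day) order. The expected columns are `individual_id`,
#' `treatment`, `day`, `stage`, `eggs`, and optionally `dose_uM`.
#'
#' Days are 0-based and must be contiguous from 0 for every individual. An
#' observed death is recorded as a final row carrying the configured death
#' label; a record that simply ends on a living stage is treated as censored
#' (see [validate_cohort()]).
#'
#' @param path Path to a comma-separated, UTF-8, headered file.
#' @param stage_config A [stage_config()] describing the stage structure.
#' @return A validated cohort tibble ordered by (individual, day).
#' @seealso [write_cohort()], [validate_cohort()], [simulate_cohort()]
#' @examples
#' f <- system.file("extdata", "cohort_small.csv", package = "lifetabler")
#' read_cohort(f, stage_config())
#' @export
read_cohort <- function(path, stage_config = lifetabler::stage_config()) {
  check_stage_config(stage_config)
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  spec <- readr::cols(
    individual_id = readr::col_character(),
    treatment = readr::col_character(),
    day = readr::col_integer(),
    stage = readr::col_character(),
    eggs = readr::col_integer(),
    .default = readr::col_double()
  )
  x <- readr::read_csv(path, col_types = spec, progress = FALSE)
  required <- c("individual_id", "treatment", "day", "stage", "eggs")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort(sprintf("Cohort file %s is missing required columns: %s",
                  path, paste(missing, collapse = ", ")))
  }
  validate_cohort(x, stage_config)
}

#' Write a cohort tibble to CSV
#'
#' Writes the cohort in the normalised on-disk dialect read by
#' [read_cohort()]: comma-separated, UTF-8, header, rows ordered by
#' (individual, day). Writing then re-reading then re-writing is
#' byte-stable.
#'
#' @param cohort A cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  keep <- intersect(
    c("individual_id", "treatment", "dose_uM", "day", "stage", "eggs"),
    names(cohort)
  )
  out <- dplyr::arrange(cohort[keep], .data$individual_id, .data$day)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Validate a cohort tibble against a stage configuration
#'
#' Checks the structural invariants every downstream computation relies on:
#' known stage labels, unique (individual, day) pairs, day sequences that run
#' 0, 1, 2, ... without gaps, entry-stage start, forward-only stage
#' transitions, a death row only in terminal position, and eggs restricted to
#' days spent in the reproductive stage. Violations raise an error naming the
#' offending individual and day.
#'
#' @inheritParams write_cohort
#' @param stage_config A [stage_config()].
#' @return The cohort, ordered by (individual, day), invisibly valid.
#' @export
validate_cohort <- function(cohort, stage_config = lifetabler::stage_config()) {
  cfg <- check_stage_config(stage_config)
  required <- c("individual_id", "treatment", "day", "stage", "eggs")
  missing <- setdiff(required, names(cohort))
  if (length(missing)) {
    abort(sprintf("Cohort is missing required columns: %s",
                  paste(missing, collapse = ", ")))
  }
  x <- tibble::as_tibble(cohort)
  x$day <- as.integer(x$day)
  x$eggs <- as.integer(x$eggs)
  if (nrow(x) == 0L) abort("Cohort has no rows.")

  known <- c(cfg$stages, cfg$death)
  bad <- setdiff(unique(x$stage), known)
  if (length(bad)) {
    row1 <- which(x$stage %in% bad)[1]
    abort(sprintf(
      "Unknown stage label '%s' (first at individual '%s', day %d).",
      x$stage[row1], x$individual_id[row1], x$day[row1]))
  }
  if (anyNA(x$day) || any(x$day < 0L)) {
    abort("Column `day` must contain non-negative integers.")
  }
  if (anyNA(x$eggs) || any(x$eggs < 0L)) {
    abort("Column `eggs` must contain non-negative integers.")
  }

  x <- dplyr::arrange(x, .data$individual_id, .data$day)

  # all per-individual checks vectorised over the (id, day)-sorted rows
  n <- nrow(x)
  id <- x$individual_id
  first <- !duplicated(id)
  same_prev <- c(FALSE, id[-1] == id[-n])
  # ids are dataset-wide keys: one individual cannot span treatments
  changed <- same_prev & c(FALSE, x$treatment[-1] != x$treatment[-n])
  if (any(changed)) {
    abort(sprintf(
      "Individual '%s' appears under more than one treatment; ids must be unique across the dataset.",
      id[which(changed)[1]]))
  }
  dup <- same_prev & c(FALSE, x$day[-1] == x$day[-n])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(sprintf("Duplicated individual-day: individual '%s', day %d.",
                  x$individual_id[i], x$day[i]))
  }

  bad <- first & x$day != 0L
  if (any(bad)) {
    abort(sprintf("Individual '%s' does not start at day 0.",
                  id[which(bad)[1]]))
  }
  bad <- same_prev & c(0L, diff(x$day)) != 1L
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf("Day gap for individual '%s' before day %d.",
                  id[i], x$day[i]))
  }
  bad <- first & x$stage != cfg$entry
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf("Individual '%s' enters in stage '%s', expected '%s'.",
                  id[i], x$stage[i], cfg$entry))
  }
  is_death <- x$stage == cfg$death
  last <- c(id[-1] != id[-n], TRUE)
  bad <- is_death & !last
  if (any(bad)) {
    abort(sprintf(
      "Death label for individual '%s' must occur once, in final position.",
      id[which(bad)[1]]))
  }
  # transitions must move forward in stage order; death (index k+1) always ok
  sidx <- match(x$stage, cfg$stages)
  sidx[is_death] <- length(cfg$stages) + 1L
  bad <- same_prev & c(0L, diff(sidx)) < 0L
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf(
      "Stage reversal for individual '%s' at day %d ('%s' -> '%s').",
      id[i], x$day[i], x$stage[i - 1L], x$stage[i]))
  }
  if (!is.null(cfg$adult_female) && !is.null(cfg$adult_male)) {
    idf <- factor(id, levels = unique(id))
    both <- rowsum((x$stage == cfg$adult_female) + 0, idf) > 0 &
      rowsum((x$stage == cfg$adult_male) + 0, idf) > 0
    if (any(both)) {
      abort(sprintf("Individual '%s' occupies both adult sexes.",
                    rownames(both)[which(both)[1]]))
    }
  }
  laid <- x$eggs > 0L & x$stage != cfg$reproductive
  if (any(laid)) {
    i <- which(laid)[1]
    abort(sprintf(
      "Eggs recorded outside the reproductive stage: individual '%s', day %d, stage '%s'.",
      id[i], x$day[i], x$stage[i]))
  }
  x
}

#' Per-individual fate summary
#'
#' Classifies each individual as `died` (record ends with the death label) or
#' `censored` (record ends on a living stage), and reports its last observed
#' day and final stage.
#'
#' @inheritParams validate_cohort
#' @return A tibble with one row per individual: `individual_id`,
#'   `treatment`, `last_day`, `final_stage`, `fate`.
#' @export
cohort_fates <- function(cohort, stage_config = lifetabler::stage_config()) {
  cfg <- check_stage_config(stage_config)
  x <- dplyr::arrange(cohort, .data$individual_id, .data$day)
  last <- !duplicated(x$individual_id, fromLast = TRUE)
  tibble::tibble(
    individual_id = x$individual_id[last],
    treatment = x$treatment[last],
    last_day = x$day[last],
    final_stage = x$stage[last],
    fate = ifelse(x$stage[last] == cfg$death, "died", "censored")
  )
}

# Resolve censored individuals before demographic computation.
# "exclude" drops them with a warning; "as_dead" keeps them, treating the end
# of the record as the death day (covers escapes counted as deaths).
resolve_censoring <- function(cohort, cfg,
                              censored = c("exclude", "as_dead"),
                              quiet = FALSE) {
  censored <- match.arg(censored)
  fates <- cohort_fates(cohort, cfg)
  cens <- fates$individual_id[fates$fate == "censored"]
  if (length(cens) == 0L || censored == "as_dead") {
    return(cohort)
  }
  if (!quiet) {
    warn(sprintf(
      "Excluding %d censored individual(s) (record ends while alive): %s",
      length(cens),
      paste(utils::head(cens, 5L), collapse = ", ")))
  }
  out <- dplyr::filter(cohort, !.data$individual_id %in% cens)
  if (nrow(out) == 0L) abort("All individuals are censored; nothing to analyse.")
  out
}
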