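#' Define the developmental stage structure of a cohort
#'
#' A stage configuration declares the ordered living stages an individual can
#' pass through, which stage a cohort enters at, which stage reproduces, and
#' the label used to record an observed death. Every other function in the
#' package validates cohort records against a stage configuration.
#'
#' The default configuration matches a larval-enrolment bioassay: third-instar
#' larvae (`L3`) are enrolled at day 0 and develop through `L4`, `L5`, `pupa`
#' and a sexed adult stage. Egg-enrolled cohorts are supported by supplying a
#' different stage list with its own entry stage.
#'
#' @param stages Character vector of living stage labels in developmental
#'   order. The first element is the default entry stage.
#' @param entry Entry stage label; must be the first element of `stages`.
#' @param reproductive Label of the reproducing stage (eggs may only be laid
#'   on days spent in this stage). Must be one of `stages`.
#' @param adult_female,adult_male Labels of the sexed adult stages, or `NULL`
#'   if the stage list is unsexed. Used for sex-specific longevity summaries
#'   and by the cohort simulator.
#' @param death Terminal label recording an observed death. Must not collide
#'   with any living stage.
#'
#' @return An object of class `stage_config`: a named list with elements
#'   `stages`, `entry`, `reproductive`, `adult_female`, `adult_male`, `death`.
#' @examples
#' cfg <- stage_config()
#' cfg
#' stage_config(c("egg", "larva", "pupa", "adult"), reproductive = "adult")
#' @export
stage_config <- function(stages = c("L3", "L4", "L5", "pupa",
                                    "adult_female", "adult_male"),
                         entry = stages[1],
                         reproductive = if ("adult_female" %in% stages)
                           "adult_female" else stages[length(stages)],
                         adult_female = if ("adult_female" %in% stages)
                           "adult_female" else NULL,
                         adult_male = if ("adult_male" %in% stages)
                           "adult_male" else NULL,
                         death = "dead") {
  stages <- as.character(stages)
  if (length(stages) < 1L) abort("`stages` must name at least one stage.")
  if (anyDuplicated(stages)) {
    abort(paste0("Stage labels must be unique; duplicated: ",
                 paste(unique(stages[duplicated(stages)]), collapse = ", ")))
  }
  if (!identical(entry, stages[1])) {
    abort("`entry` must be the first stage in `stages`.")
  }
  if (!reproductive %in% stages) {
    abort(sprintf("Reproductive stage '%s' is not among the stages.",
                  reproductive))
  }
  for (lbl in c(adult_female, adult_male)) {
    if (!is.null(lbl) && !lbl %in% stages) {
      abort(sprintf("Adult stage '%s' is not among the stages.", lbl))
    }
  }
  if (death %in% stages) {
    abort(sprintf("Death label '%s' collides with a living stage.", death))
  }
  structure(
    list(stages = stages, entry = entry, reproductive = reproductive,
         adult_female = adult_female, adult_male = adult_male,
         death = death),
    class = "stage_config"
  )
}

#' @export
print.stage_config <- function(x, ...) {
  cat("<stage_config>\n")
  cat("  stages:      ", paste(x$stages, collapse = " -> "), "\n")
  cat("  entry:       ", x$entry, "\n")
  cat("  reproductive:", x$reproductive, "\n")
  if (!is.null(x$adult_female) || !is.null(x$adult_male)) {
    cat("  adults:      ",
        paste(c(x$adult_female, x$adult_male), collapse = ", "), "\n")
  }
  cat("  death label: ", x$death, "\n")
  invisible(x)
}

#' Read a stage configuration from a YAML file
#'
#' The file must contain a `stages` sequence and may override `entry`,
#' `reproductive`, `adult_female`, `adult_male` and `death`.
#'
#' @param path Path to a YAML file.
#' @return A [stage_config()] object.
#' @examples
#' f <- system.file("extdata", "stages_default.yaml", package = "lifetabler")
#' read_stage_config(f)
#' @export
read_stage_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  y <- yaml::read_yaml(path)
  if (is.null(y$stages)) abort("Stage config file must define `stages`.")
  args <- list(stages = unlist(y$stages))
  for (f in c("entry", "reproductive", "adult_female", "adult_male", "death")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  do.call(stage_config, args)
}

stage_index <- function(cfg, labels) {
  match(labels, cfg$stages)
}

is_stage_config <- function(x) inherits(x, "stage_config")

check_stage_config <- function(cfg) {
  if (!is_stage_config(cfg)) {
    abort("`stage_config` must be created with stage_config().")
  }
  invisible(cfg)
}
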