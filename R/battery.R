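#' Define a neuropsychological test battery
#'
#' A battery definition names the tests whose change scores feed the
#' reliable-change classifier and records, for each test, whether higher
#' raw scores mean better or worse performance. Time-based tests
#' (reaction time, trail-making style shifting tasks, interference and
#' scanning tasks) score "higher = worse"; accuracy- or recall-based
#' tests score "higher = better". The orientation is applied when change
#' scores are computed so that negative oriented change always means
#' deterioration, whatever the raw scale.
#'
#' @param tests Character vector of test names.
#' @param orientation Integer vector, same length as `tests`; `+1` if a
#'   higher raw score means better performance, `-1` if it means worse
#'   (e.g. completion times, reaction times).
#' @return An object of class `battery_def` with elements `tests` and
#'   `orientation` (named by test).
#' @examples
#' battery_def(c("recall", "rt"), c(1, -1))
#' @seealso [default_battery()] for the six-test battery used in POCD
#'   studies.
#' @export
battery_def <- function(tests, orientation) {
  if (!is.character(tests) || length(tests) < 1L) {
    stop("`tests` must be a non-empty character vector", call. = FALSE)
  }
  if (anyDuplicated(tests)) {
    stop("test names must be unique", call. = FALSE)
  }
  orientation <- as.integer(orientation)
  if (length(orientation) != length(tests) ||
      !all(orientation %in% c(-1L, 1L))) {
    stop("`orientation` must be +1/-1 for each test", call. = FALSE)
  }
  names(orientation) <- tests
  structure(list(tests = tests, orientation = orientation),
            class = "battery_def")
}

#' The default six-test POCD battery
#'
#' The battery used throughout this package: Visual Verbal Learning,
#' Concept Shifting Task, Stroop Color Word Test, Memory Scanning Task,
#' Letter-Digit Coding, and Reaction Time (four-boxes). Orientation is
#' an explicit modelling assumption, not something the battery scores
#' themselves encode: the time-based tasks (concept shifting, Stroop
#' interference, memory scanning, reaction time) are marked
#' "higher = worse"; verbal learning and letter-digit coding, scored as
#' correct responses, are "higher = better".
#'
#' @return A [battery_def()] with six tests.
#' @examples
#' default_battery()
#' @export
default_battery <- function() {
  battery_def(
    tests = c("vvl", "cst", "stroop", "mst", "ldc", "rt"),
    orientation = c(vvl = 1L, cst = -1L, stroop = -1L,
                    mst = -1L, ldc = 1L, rt = -1L)
  )
}

#' @export
print.battery_def <- function(x, ...) {
  cat("Neuropsychological battery:", length(x$tests), "tests\n")
  dir <- ifelse(x$orientation > 0, "higher = better", "higher = worse")
  for (i in seq_along(x$tests)) {
    cat(sprintf("  %-8s %s\n", x$tests[i], dir[i]))
  }
  invisible(x)
}

#' Read a battery definition from a YAML config
#'
#' The config must contain a `tests` mapping of test name to
#' orientation (`1` or `-1`), and may carry `z_threshold` and
#' `min_positive` overrides used by the classifier.
#'
#' @param path Path to a YAML file.
#' @return A list with `battery` (a [battery_def()]), `z_threshold`,
#'   and `min_positive` (the latter two `NULL` when absent).
#' @export
read_battery_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$tests)) {
    stop("battery config must have a `tests` mapping", call. = FALSE)
  }
  tests <- names(cfg$tests)
  orientation <- vapply(cfg$tests, function(v) as.integer(v), integer(1))
  list(
    battery = battery_def(tests, orientation),
    z_threshold = cfg$z_threshold,
    min_positive = cfg$min_positive
  )
}
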