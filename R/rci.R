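#' Deficit-oriented change score
#'
#' The change score is the follow-up score minus the baseline score,
#' multiplied by the test's orientation, so a negative value always
#' means deterioration: on a "higher = better" test a drop in score is
#' negative change, and on a "higher = worse" test (e.g. reaction time)
#' an increase is negative change.
#'
#' @param pre,post Baseline and follow-up raw scores; `NA` propagates.
#' @param orientation `+1` (higher = better) or `-1` (higher = worse).
#' @return `orientation * (post - pre)`.
#' @examples
#' change_score(50, 40, +1)     # -10: deterioration
#' change_score(400, 500, -1)   # -100: slower reaction time
#' @export
change_score <- function(pre, post, orientation) {
  if (!all(orientation %in% c(-1, 1))) {
    stop("`orientation` must be +1 or -1", call. = FALSE)
  }
  orientation * (post - pre)
}

intervals_known <- c("day7", "month3")

score_col <- function(test, timepoint) {
  paste0("score_", test, "_", timepoint)
}

# oriented change scores for one interval: rows = subjects, cols = tests
interval_changes <- function(cohort, battery, interval) {
  post_tp <- match.arg(interval, intervals_known)
  ch <- vapply(battery$tests, function(test) {
    pre <- cohort[[score_col(test, "baseline")]]
    post <- cohort[[score_col(test, post_tp)]]
    if (is.null(pre) || is.null(post)) {
      stop("cohort lacks score columns for test `", test,
           "` at interval ", post_tp, call. = FALSE)
    }
    change_score(pre, post, battery$orientation[[test]])
  }, numeric(nrow(cohort)))
  # vapply drops to a vector for single-subject cohorts
  matrix(ch, nrow = nrow(cohort),
         dimnames = list(NULL, battery$tests))
}

#' Calibrate expected change from the control group
#'
#' Controls take the battery at the same timepoints as patients but
#' undergo no surgery, so their change scores estimate the expected
#' change over time — practice effects plus retest noise. For every
#' test and interval this returns the mean and sample SD (n-1
#' denominator) of the controls' deficit-oriented change scores; these
#' are the reference distribution the reliable change index is scored
#' against.
#'
#' @param controls Cohort rows with `arm == "control"` (enforced).
#' @param battery A [battery_def()].
#' @param intervals Character vector of intervals to calibrate,
#'   subsets of `c("day7", "month3")`.
#' @return An object of class `control_change_stats`: a data frame with
#'   columns `test`, `interval`, `mean_change`, `sd_change`,
#'   `n_controls`.
#' @section Errors:
#' Fewer than 2 controls with complete scores for any test-interval, or
#' a zero change-score SD, abort calibration: the Z-score would be
#' undefined.
#' @export
fit_control_stats <- function(controls, battery,
                              intervals = intervals_known) {
  stopifnot(inherits(battery, "battery_def"))
  if (!all(controls$arm == "control")) {
    stop("`controls` must contain only control-arm subjects",
         call. = FALSE)
  }
  intervals <- match.arg(intervals, intervals_known, several.ok = TRUE)
  rows <- list()
  for (iv in intervals) {
    ch <- interval_changes(controls, battery, iv)
    for (j in seq_along(battery$tests)) {
      x <- ch[, j][!is.na(ch[, j])]
      if (length(x) < 2L) {
        stop(sprintf(
          "calibration error: fewer than 2 complete controls for test `%s`, interval %s",
          battery$tests[j], iv), call. = FALSE)
      }
      s <- stats::sd(x)
      if (s <= 0) {
        stop(sprintf(
          "calibration error: zero change-score SD for test `%s`, interval %s",
          battery$tests[j], iv), call. = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        test = battery$tests[j], interval = iv,
        mean_change = mean(x), sd_change = s, n_controls = length(x),
        stringsAsFactors = FALSE
      )
    }
  }
  structure(do.call(rbind, rows), class = c("control_change_stats",
                                            "data.frame"))
}

#' Reliable change index Z-score
#'
#' Standardizes a patient's deficit-oriented change score against the
#' control change distribution: `z = (delta - mean_change) / sd_change`.
#' A test is "positive" (reliable decline) when `z <= -z_threshold`,
#' i.e. the change is at least `z_threshold` control SDs below the
#' control mean after the practice effect has been subtracted.
#'
#' @param delta Deficit-oriented change score(s).
#' @param mean_change,sd_change Control calibration for the same test
#'   and interval; `sd_change` must be positive.
#' @return Z-score(s).
#' @examples
#' rci_z(-10, mean_change = 2, sd_change = 4)  # -3
#' @export
rci_z <- function(delta, mean_change, sd_change) {
  if (any(sd_change <= 0)) {
    stop("`sd_change` must be positive", call. = FALSE)
  }
  (delta - mean_change) / sd_change
}

#' Classify one subject from a vector of RCI Z-scores
#'
#' Counts tests with `z <= -z_threshold` ("positive" tests) among the
#' non-missing entries and declares POCD when the count reaches
#' `min_positive`. The threshold comparison is inclusive: a change
#' exactly 1.96 SD below the control mean counts as reliable decline.
#' By default every test must be present (patients unable to complete
#' the battery are unclassifiable, mirroring the usual exclusion rule);
#' `max_missing` relaxes this.
#'
#' @param z Numeric vector of RCI Z-scores, `NA` for missing tests.
#' @param z_threshold Positivity threshold in control-SD units
#'   (default 1.96).
#' @param min_positive Number of positive tests required for POCD
#'   (default 2).
#' @param max_missing Number of missing tests tolerated before the
#'   subject is flagged unclassifiable (default 0).
#' @return A list with `z`, `n_positive`, `pocd`, and `classifiable`;
#'   `pocd` is `NA` for unclassifiable subjects.
#' @examples
#' classify_subject(c(-2, -2.5, 0, 0, 0, 0))$pocd   # TRUE
#' classify_subject(c(-2, 0, 0, 0, 0, 0))$pocd      # FALSE
#' @export
classify_subject <- function(z, z_threshold = 1.96, min_positive = 2L,
                             max_missing = 0L) {
  if (z_threshold <= 0) stop("`z_threshold` must be positive",
                             call. = FALSE)
  n_missing <- sum(is.na(z))
  if (n_missing > max_missing) {
    return(list(z = z, n_positive = NA_integer_, pocd = NA,
                classifiable = FALSE))
  }
  n_positive <- sum(z <= -z_threshold, na.rm = TRUE)
  list(z = z, n_positive = as.integer(n_positive),
       pocd = n_positive >= min_positive, classifiable = TRUE)
}

#' Classify a cohort and report POCD incidence
#'
#' Runs the full reliable-change pipeline for one follow-up interval:
#' calibrates expected change from the controls (unless a prefitted
#' calibration is supplied), computes each patient's six Z-scores, and
#' applies the `z <= -1.96` / two-of-six rule. Incidence is the number
#' of POCD cases over the number of classifiable patients.
#'
#' @param cohort Cohort data frame (schema of [generate_cohort()]);
#'   both arms, or patients only if `control_stats` is given.
#' @param battery A [battery_def()].
#' @param interval `"day7"` or `"month3"`.
#' @param z_threshold,min_positive,max_missing Classification rule, see
#'   [classify_subject()].
#' @param control_stats Optional prefitted [fit_control_stats()]
#'   result.
#' @return An object of class `rci_result`: list with `outcomes` (data
#'   frame: `id`, `interval`, one `z_<test>` column per test,
#'   `n_positive`, `pocd`, `classifiable`), `incidence` (list with
#'   `n_pocd`, `n_classifiable`, `percent`, `label`), `control_stats`,
#'   and the rule parameters.
#' @examples
#' cohort <- generate_cohort(sim_config(seed = 3))
#' res <- classify_cohort(cohort, interval = "day7")
#' res$incidence$label
#' @export
classify_cohort <- function(cohort, battery = default_battery(),
                            interval = "day7", z_threshold = 1.96,
                            min_positive = 2L, max_missing = 0L,
                            control_stats = NULL) {
  interval <- match.arg(interval, intervals_known)
  patients <- cohort[cohort$arm == "patient", , drop = FALSE]
  if (is.null(control_stats)) {
    controls <- cohort[cohort$arm == "control", , drop = FALSE]
    control_stats <- fit_control_stats(controls, battery,
                                       intervals = interval)
  }
  cs <- control_stats[control_stats$interval == interval, , drop = FALSE]
  cs <- cs[match(battery$tests, cs$test), , drop = FALSE]
  if (anyNA(cs$test)) {
    stop("`control_stats` lacks calibration for some battery tests",
         call. = FALSE)
  }

  ch <- interval_changes(patients, battery, interval)
  z <- sweep(sweep(ch, 2L, cs$mean_change, "-"), 2L, cs$sd_change, "/")
  cls <- apply(z, 1L, classify_subject, z_threshold = z_threshold,
               min_positive = min_positive, max_missing = max_missing)
  n_positive <- vapply(cls, `[[`, integer(1), "n_positive")
  pocd <- vapply(cls, `[[`, logical(1), "pocd")
  classifiable <- vapply(cls, `[[`, logical(1), "classifiable")

  zdf <- as.data.frame(z)
  names(zdf) <- paste0("z_", battery$tests)
  outcomes <- cbind(
    data.frame(id = patients$id, interval = interval,
               stringsAsFactors = FALSE),
    zdf,
    data.frame(n_positive = n_positive, pocd = pocd,
               classifiable = classifiable)
  )
  rownames(outcomes) <- NULL

  n_cls <- sum(classifiable)
  n_pocd <- sum(pocd[classifiable])
  structure(list(
    outcomes = outcomes,
    incidence = incidence_summary(n_pocd, n_cls),
    control_stats = control_stats,
    interval = interval, z_threshold = z_threshold,
    min_positive = as.integer(min_positive)
  ), class = "rci_result")
}

#' Incidence as numerator, denominator and formatted percent
#'
#' Reports are formatted to one decimal place; the unrounded percentage
#' is kept alongside so no comparison ever runs on a rounded value.
#'
#' @param n_pocd,n_classifiable Counts.
#' @return List with `n_pocd`, `n_classifiable`, `percent` (unrounded),
#'   and `label` like `"29/99 (29.3%)"`.
#' @examples
#' incidence_summary(29, 99)$label
#' @export
incidence_summary <- function(n_pocd, n_classifiable) {
  pct <- if (n_classifiable > 0) 100 * n_pocd / n_classifiable else NA_real_
  list(
    n_pocd = as.integer(n_pocd),
    n_classifiable = as.integer(n_classifiable),
    percent = pct,
    label = if (is.na(pct)) {
      sprintf("%d/%d", n_pocd, n_classifiable)
    } else {
      sprintf("%d/%d (%.1f%%)", n_pocd, n_classifiable, pct)
    }
  )
}

#' @export
print.rci_result <- function(x, ...) {
  cat(sprintf(
    "RCI classification, interval %s (threshold %.2f SD, >= %d of %d tests)\n",
    x$interval, x$z_threshold, x$min_positive,
    sum(startsWith(names(x$outcomes), "z_"))))
  cat("  POCD incidence:", x$incidence$label, "\n")
  n_un <- sum(!x$outcomes$classifiable)
  if (n_un > 0) cat("  unclassifiable patients:", n_un, "\n")
  invisible(x)
}

#' Write per-subject RCI outcomes as TSV
#'
#' @param result An `rci_result` from [classify_cohort()], or its
#'   `outcomes` data frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_outcomes_tsv <- function(result, path) {
  outcomes <- if (inherits(result, "rci_result")) result$outcomes else result
  utils::write.table(outcomes, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
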