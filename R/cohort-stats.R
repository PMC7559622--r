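#' Two-sample t-test from summary statistics
#'
#' Independent two-sample t-test computed from group means, SDs and
#' sizes — the form needed when only summary tables are available.
#' The pooled variant uses
#' `sp^2 = ((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2)` on
#' `n1 + n2 - 2` degrees of freedom; the Welch variant uses unpooled
#' variances with Satterthwaite degrees of freedom. P-values are
#' two-sided.
#'
#' @param mean1,sd1,n1 First group: mean, SD (> 0), size (>= 2).
#' @param mean2,sd2,n2 Second group.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return List with `t`, `df`, `p`.
#' @examples
#' # recovery time at 3 months, POCD vs NO-POCD
#' t_test_from_summary(28.5, 7.4, 18, 24.8, 6.2, 81)$p  # ~0.03
#' @export
t_test_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2", call. = FALSE)
  if (sd1 <= 0 || sd2 <= 0) stop("SDs must be positive", call. = FALSE)
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Chi-square comparison of two proportions
#'
#' Pearson 2x2 chi-square (no continuity correction) on rows
#' `(k, n - k)` for the two groups; one degree of freedom.
#'
#' @param k1,n1 Events and size in group 1 (`0 <= k1 <= n1`).
#' @param k2,n2 Events and size in group 2.
#' @return List with `stat`, `df`, `p`, `expected`.
#' @examples
#' chi_square_from_counts(14, 29, 33, 70)$p  # hypertension row, ~0.91
#' @export
chi_square_from_counts <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("group sizes must be positive",
                               call. = FALSE)
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) {
    stop("event counts must satisfy 0 <= k <= n", call. = FALSE)
  }
  m <- rbind(g1 = c(event = k1, no_event = n1 - k1),
             g2 = c(event = k2, no_event = n2 - k2))
  chi_square_test(m)
}

#' Group-comparison summary table (demographics and clinical data)
#'
#' Builds the familiar "Table 1": for each variable, per-group
#' summaries (mean +/- SD for continuous, n (%) for categorical) of
#' POCD versus NO-POCD patients, with an independent t-test or
#' chi-square p-value. Multi-level categorical variables get a single
#' joint r x 2 chi-square p on all levels.
#'
#' @param cohort Cohort data frame (patients are selected from it).
#' @param classification An `rci_result` from [classify_cohort()] or
#'   its `outcomes` data frame; only classifiable patients enter.
#' @param variables Named character vector mapping cohort column names
#'   to `"continuous"` or `"categorical"`, e.g.
#'   `c(age = "continuous", sex = "categorical")`.
#' @param t_variant `"pooled"` (default) or `"welch"`, see
#'   [t_test_from_summary()].
#' @return Object of class `table1`: data frame with columns
#'   `variable`, `level` (`NA` for continuous), `pocd`, `no_pocd`
#'   (formatted summaries), `p` (repeated within a categorical block),
#'   plus numeric columns `n_pocd`, `n_no_pocd`.
#' @examples
#' cohort <- generate_cohort(sim_config(seed = 5))
#' cls <- classify_cohort(cohort, interval = "day7")
#' table1_report(cohort, cls,
#'               c(age = "continuous", sex = "categorical"))
#' @export
table1_report <- function(cohort, classification, variables,
                          t_variant = c("pooled", "welch")) {
  t_variant <- match.arg(t_variant)
  outcomes <- if (inherits(classification, "rci_result")) {
    classification$outcomes
  } else {
    classification
  }
  outcomes <- outcomes[outcomes$classifiable, , drop = FALSE]
  patients <- merge(cohort[cohort$arm == "patient", , drop = FALSE],
                    outcomes[, c("id", "pocd")], by = "id")
  grp <- patients$pocd
  n1 <- sum(grp)
  n2 <- sum(!grp)
  if (n1 == 0 || n2 == 0) {
    stop("both POCD and NO-POCD groups must be non-empty", call. = FALSE)
  }
  if (is.null(names(variables)) ||
      !all(variables %in% c("continuous", "categorical"))) {
    stop("`variables` must be a named vector of \"continuous\"/\"categorical\"",
         call. = FALSE)
  }
  rows <- list()
  for (v in names(variables)) {
    if (is.null(patients[[v]])) {
      stop("unknown cohort variable: ", v, call. = FALSE)
    }
    x <- patients[[v]]
    if (variables[[v]] == "continuous") {
      m1 <- mean(x[grp]); s1 <- stats::sd(x[grp])
      m2 <- mean(x[!grp]); s2 <- stats::sd(x[!grp])
      # a covariate constant in both groups carries no evidence
      p <- if (s1 == 0 && s2 == 0 && m1 == m2) 1 else {
        t_test_from_summary(m1, s1, n1, m2, s2, n2,
                            variant = t_variant)$p
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = NA_character_,
        pocd = sprintf("%.1f ± %.1f", m1, s1),
        no_pocd = sprintf("%.1f ± %.1f", m2, s2),
        p = p, n_pocd = n1, n_no_pocd = n2, stringsAsFactors = FALSE
      )
    } else {
      tab <- table(factor(x), grp)
      # joint r x 2 chi-square: one p for the whole block
      p <- if (nrow(tab) < 2) 1 else chi_square_test(unclass(tab))$p
      for (lev in rownames(tab)) {
        k1 <- tab[lev, "TRUE"]; k2 <- tab[lev, "FALSE"]
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = lev,
          pocd = sprintf("%d (%.1f)", k1, 100 * k1 / n1),
          no_pocd = sprintf("%d (%.1f)", k2, 100 * k2 / n2),
          p = p, n_pocd = n1, n_no_pocd = n2, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("table1", "data.frame"))
}

#' Write a group-comparison table as TSV
#'
#' P-values are displayed to two decimals, as such tables are usually
#' printed; the unrounded values remain in the returned object.
#'
#' @param table1 A [table1_report()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_table1_tsv <- function(table1, path) {
  out <- as.data.frame(table1)
  out$p <- sprintf("%.2f", out$p)
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
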