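#' Case-control genotype count table
#'
#' The hub of the association stage: a 2 (status) x 3 (genotype) table
#' of subject counts for a biallelic SNP, rows POCD / NO-POCD, columns
#' AA / AG / GG where G is the effect (here: putatively protective)
#' allele.
#'
#' @param pocd,no_pocd Integer vectors of length 3: counts of AA, AG,
#'   GG subjects among cases and non-cases.
#' @param timepoint Optional label (e.g. `"day7"`).
#' @return An object of class `genotype_table`: integer matrix with
#'   dimnames `status` x `genotype` and a `timepoint` attribute.
#' @examples
#' gt <- genotype_table(pocd = c(10, 16, 3), no_pocd = c(11, 39, 20),
#'                      timepoint = "day7")
#' allele_counts(gt)
#' @export
genotype_table <- function(pocd, no_pocd, timepoint = NULL) {
  for (v in list(pocd, no_pocd)) {
    if (length(v) != 3L || any(is.na(v)) || any(v < 0) ||
        any(v != round(v))) {
      stop("genotype counts must be 3 non-negative integers (AA, AG, GG)",
           call. = FALSE)
    }
  }
  m <- rbind(pocd = as.integer(pocd), no_pocd = as.integer(no_pocd))
  colnames(m) <- c("AA", "AG", "GG")
  names(dimnames(m)) <- c("status", "genotype")
  structure(m, timepoint = timepoint, class = c("genotype_table",
                                                class(m)))
}

#' Allele counts from a genotype table
#'
#' Each subject contributes two alleles: AA subjects contribute 2 A,
#' AG subjects 1 A and 1 G, GG subjects 2 G.
#'
#' @param table A [genotype_table()].
#' @return 2 x 2 integer matrix, rows POCD / NO-POCD, columns A / G.
#' @export
allele_counts <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  m <- unclass(table)
  out <- cbind(A = 2L * m[, "AA"] + m[, "AG"],
               G = 2L * m[, "GG"] + m[, "AG"])
  names(dimnames(out)) <- c("status", "allele")
  out
}

#' 2x2 exposure-by-status table
#'
#' Cell layout follows the epidemiological convention used throughout:
#' `a` exposed cases, `b` exposed non-cases, `c` unexposed cases, `d`
#' unexposed non-cases, so the odds ratio is `ad / bc`.
#'
#' @param a,b,c,d Non-negative counts.
#' @return Object of class `table2x2`.
#' @export
table2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("2x2 cells must be non-negative counts", call. = FALSE)
  }
  structure(as.list(cells), class = "table2x2")
}

as_matrix_2x2 <- function(t) {
  matrix(c(t$a, t$c, t$b, t$d), nrow = 2,
         dimnames = list(exposure = c("exposed", "unexposed"),
                         status = c("case", "noncase")))
}

#' Collapse a genotype table under a genetic model
#'
#' * dominant: G-carriers (AG + GG) exposed vs AA unexposed;
#' * recessive: GG exposed vs AA + AG unexposed;
#' * allelic: alleles are the units — each subject contributes two, so
#'   the table counts G vs A alleles by status.
#'
#' The additive model does not collapse to 2x2; see
#' [additive_trend_or()].
#'
#' @param table A [genotype_table()].
#' @param model `"dominant"`, `"recessive"` or `"allelic"`.
#' @return A [table2x2()].
#' @examples
#' gt <- genotype_table(c(10, 16, 3), c(11, 39, 20))
#' collapse_genotypes(gt, "dominant")   # a=19 b=59 c=10 d=11
#' @export
collapse_genotypes <- function(table,
                               model = c("dominant", "recessive",
                                         "allelic")) {
  stopifnot(inherits(table, "genotype_table"))
  model <- match.arg(model)
  m <- unclass(table)
  switch(model,
    dominant = table2x2(
      a = m["pocd", "AG"] + m["pocd", "GG"],
      b = m["no_pocd", "AG"] + m["no_pocd", "GG"],
      c = m["pocd", "AA"],
      d = m["no_pocd", "AA"]
    ),
    recessive = table2x2(
      a = m["pocd", "GG"],
      b = m["no_pocd", "GG"],
      c = m["pocd", "AA"] + m["pocd", "AG"],
      d = m["no_pocd", "AA"] + m["no_pocd", "AG"]
    ),
    allelic = {
      al <- allele_counts(table)
      table2x2(a = al["pocd", "G"], b = al["no_pocd", "G"],
               c = al["pocd", "A"], d = al["no_pocd", "A"])
    }
  )
}

or_result <- function(model, log_or, se_log_or, p,
                      correction_applied = FALSE) {
  structure(list(
    model = model,
    or_point = exp(log_or),
    log_or = log_or,
    se_log_or = se_log_or,
    ci95 = exp(log_or + c(-1, 1) * 1.96 * se_log_or),
    p = p,
    correction_applied = correction_applied
  ), class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("%s model: OR %s (95%% CI %s-%s), p = %.3g%s\n",
              x$model, format_or(x$or_point), format_or(x$ci95[1]),
              format_or(x$ci95[2]), x$p,
              if (x$correction_applied) " [Haldane +0.5]" else ""))
  invisible(x)
}

#' Odds ratio with Woolf confidence interval
#'
#' Point estimate `ad / bc`; the standard error of the log odds ratio
#' is Woolf's `sqrt(1/a + 1/b + 1/c + 1/d)` and the 95% interval is
#' `exp(log(OR) +/- 1.96 * SE)`. The p-value comes from the Pearson
#' chi-square on the 2x2 table without continuity correction, computed
#' on the original (uncorrected) counts. When any single cell is zero
#' the Haldane-Anscombe correction adds 0.5 to all four cells before
#' estimating the OR and SE, and the result is flagged; a whole zero
#' row or column leaves the odds ratio undefined and is an error.
#'
#' @param t A [table2x2()].
#' @param model Label carried into the result (default `"2x2"`).
#' @param haldane Apply the +0.5 correction when a cell is zero
#'   (default `TRUE`).
#' @return An `or_result`: list with `model`, `or_point`, `log_or`,
#'   `se_log_or`, `ci95`, `p`, `correction_applied`.
#' @examples
#' odds_ratio_2x2(table2x2(19, 59, 10, 11))  # dominant model, OR 0.35
#' @export
odds_ratio_2x2 <- function(t, model = "2x2", haldane = TRUE) {
  stopifnot(inherits(t, "table2x2"))
  cells <- c(t$a, t$b, t$c, t$d)
  if (t$a + t$b == 0 || t$c + t$d == 0 ||
      t$a + t$c == 0 || t$b + t$d == 0) {
    stop("odds ratio undefined: a whole row or column of the 2x2 table is zero",
         call. = FALSE)
  }
  corrected <- FALSE
  if (any(cells == 0)) {
    if (!haldane) {
      stop("zero cell in 2x2 table and Haldane correction disabled",
           call. = FALSE)
    }
    cells <- cells + 0.5
    corrected <- TRUE
  }
  log_or <- log(cells[1] * cells[4] / (cells[2] * cells[3]))
  se <- sqrt(sum(1 / cells))
  p <- suppressWarnings(
    stats::chisq.test(as_matrix_2x2(t), correct = FALSE)$p.value
  )
  or_result(model, log_or, se, p, correction_applied = corrected)
}

#' Per-allele (additive) odds ratio by grouped-binomial logistic MLE
#'
#' Fits `logit P(case) = b0 + b1 * g` where `g` in `{0, 1, 2}` counts
#' effect alleles, by Newton-Raphson on the grouped binomial
#' log-likelihood over the three genotype classes. The per-allele odds
#' ratio is `exp(b1)`; its Wald standard error comes from the observed
#' information at the maximum, the 95% CI is
#' `exp(b1 +/- 1.96 * SE)` and the p-value is the two-sided Wald test.
#' Convergence requires the Newton step to fall below 1e-10 (both
#' coordinates) within 50 iterations.
#'
#' @param table A [genotype_table()].
#' @return An `or_result` with `model = "additive"`.
#' @section Errors:
#' Fewer than two genotype classes with subjects make the slope
#' unidentifiable (rank deficiency); complete separation (fitted
#' probabilities driven to 0/1, diverging estimates) aborts with a
#' diagnostic rather than returning a sham estimate.
#' @examples
#' gt <- genotype_table(c(10, 16, 3), c(11, 39, 20))
#' additive_trend_or(gt)  # OR 0.41
#' @export
additive_trend_or <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  m <- unclass(table)
  y <- m["pocd", ]
  n <- colSums(m)
  keep <- n > 0
  if (sum(keep) < 2L) {
    stop("rank deficiency: need at least 2 genotype classes with subjects",
         call. = FALSE)
  }
  g <- (0:2)[keep]
  y <- y[keep]
  n <- n[keep]

  X <- unname(cbind(1, g))
  beta <- c(0, 0)
  for (iter in seq_len(50L)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- n * p * (1 - p)
    score <- drop(crossprod(X, y - n * p))
    info <- crossprod(X, X * w)
    if (!all(is.finite(info)) || abs(det(info)) < 1e-12) {
      stop("non-convergence: separation detected (fitted probabilities at 0/1; ",
           "observed information singular)", call. = FALSE)
    }
    delta <- solve(info, score)
    beta <- beta + delta
    if (!all(is.finite(beta)) || abs(beta[2]) > 30) {
      stop("non-convergence: separation detected (per-allele log-odds diverging, ",
           sprintf("|b1| > 30 at iteration %d)", iter), call. = FALSE)
    }
    if (max(abs(delta)) < 1e-10) {
      se <- sqrt(solve(info)[2, 2])
      z <- beta[2] / se
      p_wald <- 2 * stats::pnorm(-abs(z))
      return(or_result("additive", beta[2], se, p_wald))
    }
  }
  stop("non-convergence: Newton-Raphson did not reach tolerance in 50 iterations",
       call. = FALSE)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Estimates the allele frequency from the genotype counts, forms the
#' Hardy-Weinberg expected counts `n * (p^2, 2pq, q^2)` and compares
#' observed to expected by Pearson chi-square on 1 degree of freedom
#' (three genotype classes, minus one, minus one estimated allele
#' frequency).
#'
#' @param counts Length-3 vector of AA, AG, GG counts.
#' @return Object of class `hwe_result`: list with `chi2`, `df`, `p`,
#'   `observed`, `expected`, `allele_freq_g`.
#' @examples
#' hwe_chi_square(c(25, 50, 25))   # perfect HWE: chi2 = 0
#' hwe_chi_square(c(21, 55, 23))   # pooled patient genotypes: chi2 1.23
#' @export
hwe_chi_square <- function(counts) {
  if (length(counts) != 3L || any(is.na(counts)) || any(counts < 0)) {
    stop("`counts` must be 3 non-negative genotype counts (AA, AG, GG)",
         call. = FALSE)
  }
  n <- sum(counts)
  if (n == 0) stop("empty genotype sample", call. = FALSE)
  p_g <- (2 * counts[3] + counts[2]) / (2 * n)
  p_a <- 1 - p_g
  expected <- n * c(p_a^2, 2 * p_a * p_g, p_g^2)
  if (p_g == 0 || p_g == 1) {
    warning("monomorphic sample: HWE chi-square is degenerate (0 on 1 df)")
    chi2 <- 0
  } else {
    chi2 <- sum((counts - expected)^2 / expected)
  }
  structure(list(
    chi2 = chi2, df = 1L,
    p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
    observed = stats::setNames(as.numeric(counts), c("AA", "AG", "GG")),
    expected = stats::setNames(expected, c("AA", "AG", "GG")),
    allele_freq_g = p_g
  ), class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf(
    "HWE chi-square = %.3f, df = %d, p = %.3g (G-allele frequency %.3f)\n",
    x$chi2, x$df, x$p, x$allele_freq_g))
  invisible(x)
}

#' Pearson chi-square test for 2x2 or status-by-genotype tables
#'
#' Pearson chi-square without continuity correction by default (a Yates
#' flag is provided for 2x2 tables); degrees of freedom
#' `(rows - 1)(cols - 1)`. A warning is emitted when any expected cell
#' count falls below 5, where the chi-square approximation weakens.
#'
#' @param x A [table2x2()], [genotype_table()], or a plain count
#'   matrix.
#' @param yates Apply the continuity correction (2x2 only; default
#'   `FALSE`).
#' @return List with `stat`, `df`, `p`, `expected`.
#' @export
chi_square_test <- function(x, yates = FALSE) {
  m <- if (inherits(x, "table2x2")) {
    as_matrix_2x2(x)
  } else if (inherits(x, "genotype_table")) {
    unclass(x)
  } else {
    as.matrix(x)
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("chi-square undefined: zero marginal total", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = yates))
  if (any(res$expected < 5)) {
    warning("expected cell count below 5: chi-square approximation may be poor")
  }
  list(stat = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, expected = res$expected)
}

#' Format an odds ratio or CI bound the way association tables print
#'
#' Two decimal places, three below 0.1 (so 0.078 is not flattened to
#' 0.08). Display only — model code never rounds before comparing.
#'
#' @param x Numeric.
#' @return Character.
#' @export
format_or <- function(x) {
  ifelse(x < 0.1, sprintf("%.3f", x), sprintf("%.2f", x))
}

#' Full association report across models and timepoints
#'
#' Computes, for each supplied genotype table, the allelic, additive,
#' dominant and recessive odds ratios with 95% CIs and p-values, and
#' flags each model significant when its CI excludes 1. A model that
#' fails (e.g. separation) is reported as a row with `error` filled in
#' rather than aborting the rest of the report.
#'
#' @param ... Named [genotype_table()] objects, e.g.
#'   `day7 = gt7, month3 = gt3`.
#' @return Object of class `association_report`: data frame with
#'   columns `timepoint`, `model`, `or`, `ci_lo`, `ci_hi`, `p`,
#'   `significant`, `correction_applied`, `error`, and formatted
#'   display columns `or_fmt`, `ci_fmt`.
#' @examples
#' rep <- association_report(
#'   day7 = genotype_table(c(10, 16, 3), c(11, 39, 20)))
#' subset(rep, model == "dominant")$or_fmt
#' @export
association_report <- function(...) {
  tables <- list(...)
  if (length(tables) == 1L && is.list(tables[[1]]) &&
      !inherits(tables[[1]], "genotype_table")) {
    tables <- tables[[1]]
  }
  if (is.null(names(tables)) || any(names(tables) == "")) {
    stop("genotype tables must be named by timepoint", call. = FALSE)
  }
  models <- c("allelic", "additive", "dominant", "recessive")
  rows <- list()
  for (tp in names(tables)) {
    gt <- tables[[tp]]
    for (mod in models) {
      res <- tryCatch({
        if (mod == "additive") {
          additive_trend_or(gt)
        } else {
          odds_ratio_2x2(collapse_genotypes(gt, mod), model = mod)
        }
      }, error = function(e) e)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          timepoint = tp, model = mod, or = NA_real_, ci_lo = NA_real_,
          ci_hi = NA_real_, p = NA_real_, significant = NA,
          correction_applied = NA, error = conditionMessage(res),
          or_fmt = NA_character_, ci_fmt = NA_character_,
          stringsAsFactors = FALSE
        )
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          timepoint = tp, model = mod, or = res$or_point,
          ci_lo = res$ci95[1], ci_hi = res$ci95[2], p = res$p,
          significant = res$ci95[1] > 1 | res$ci95[2] < 1,
          correction_applied = res$correction_applied,
          error = NA_character_,
          or_fmt = format_or(res$or_point),
          ci_fmt = paste0(format_or(res$ci95[1]), "-",
                          format_or(res$ci95[2])),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("association_report", "data.frame"))
}

#' Consistency diagnostics for a genotype count table
#'
#' Published summary tables sometimes disagree with themselves; these
#' checks catch the two failure modes that matter for reanalysis:
#' genotype counts whose totals contradict the stated group sizes, and
#' allele counts that do not equal the counts implied by the genotypes
#' (2 x homozygote + heterozygote).
#'
#' @param table A [genotype_table()].
#' @param stated_sizes Optional named vector / list with `pocd` and
#'   `no_pocd` stated group sizes.
#' @param stated_alleles Optional 2x2 matrix of published allele counts
#'   (rows pocd / no_pocd, columns A / G) to verify against the
#'   genotype-implied counts.
#' @return Character vector of human-readable flags; empty when the
#'   table is internally consistent.
#' @examples
#' gt3m <- genotype_table(c(8, 12, 5), c(13, 43, 18))
#' check_genotype_table(gt3m, stated_sizes = c(pocd = 18, no_pocd = 81))
#' @export
check_genotype_table <- function(table, stated_sizes = NULL,
                                 stated_alleles = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  flags <- character(0)
  sums <- rowSums(unclass(table))
  if (!is.null(stated_sizes)) {
    for (grp in c("pocd", "no_pocd")) {
      if (!is.null(stated_sizes[[grp]]) &&
          stated_sizes[[grp]] != sums[[grp]]) {
        flags <- c(flags, sprintf(
          "%s genotype counts sum to %d but the stated group size is %d",
          grp, sums[[grp]], as.integer(stated_sizes[[grp]])))
      }
    }
  }
  if (!is.null(stated_alleles)) {
    implied <- allele_counts(table)
    if (!all(stated_alleles == implied)) {
      flags <- c(flags,
                 "stated allele counts differ from those implied by the genotype counts")
    }
  }
  flags
}

#' Write an association report (with HWE block) as TSV
#'
#' @param report An [association_report()].
#' @param path File path.
#' @param hwe Optional [hwe_chi_square()] result appended as comment
#'   lines.
#' @return `path`, invisibly.
#' @export
write_association_tsv <- function(report, path, hwe = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(hwe)) {
    writeLines(sprintf(
      "# HWE: chi2 = %.4f, df = %d, p = %.4f, G allele freq = %.4f",
      hwe$chi2, hwe$df, hwe$p, hwe$allele_freq_g), con)
  }
  utils::write.table(as.data.frame(report), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
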