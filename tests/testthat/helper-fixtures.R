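# Shared fixtures and independent oracles for the test suite.

# Published rs6265 genotype counts (AA, AG, GG) by POCD status.
counts_day7 <- function() {
  genotype_table(pocd = c(10, 16, 3), no_pocd = c(11, 39, 20),
                 timepoint = "day7")
}
counts_month3 <- function() {
  genotype_table(pocd = c(8, 12, 5), no_pocd = c(13, 43, 18),
                 timepoint = "month3")
}

# A two-test battery for hand-checkable cohorts.
mini_battery <- function() {
  battery_def(c("mem", "rt"), c(1L, -1L))
}

# Build a cohort data frame directly from score matrices.
# scores: named list tp -> matrix (subjects x tests).
make_cohort <- function(arm, scores, battery,
                        genotype = rep(1L, length(arm))) {
  n <- length(arm)
  out <- data.frame(
    id = sprintf("S%03d", seq_len(n)), arm = arm, genotype = genotype,
    age = rep(70, n), sex = rep("male", n),
    education_years = rep(5, n), stringsAsFactors = FALSE
  )
  for (tp in names(scores)) {
    m <- scores[[tp]]
    colnames(m) <- paste0("score_", battery$tests, "_", tp)
    out <- cbind(out, m)
  }
  out
}

# Random small cohort on a random battery, complete scores.
random_small_cohort <- function(n_tests = 6L, n_patients = 15L,
                                n_controls = 6L) {
  battery <- battery_def(paste0("t", seq_len(n_tests)),
                         sample(c(-1L, 1L), n_tests, replace = TRUE))
  n <- n_patients + n_controls
  arm <- rep(c("patient", "control"), c(n_patients, n_controls))
  scores <- list(
    baseline = matrix(rnorm(n * n_tests, 50, 10), n, n_tests),
    day7 = matrix(rnorm(n * n_tests, 48, 10), n, n_tests),
    month3 = matrix(rnorm(n * n_tests, 49, 10), n, n_tests)
  )
  list(cohort = make_cohort(arm, scores, battery), battery = battery)
}

# Brute-force reliable-change oracle: plain loops, every mean/SD/z
# re-derived from raw scores, independent of the package's vectorized
# path.
oracle_classify <- function(cohort, battery, interval,
                            z_threshold = 1.96, min_positive = 2L,
                            max_missing = 0L) {
  controls <- cohort[cohort$arm == "control", , drop = FALSE]
  patients <- cohort[cohort$arm == "patient", , drop = FALSE]
  n_tests <- length(battery$tests)
  means <- sds <- numeric(n_tests)
  for (j in seq_len(n_tests)) {
    deltas <- c()
    for (i in seq_len(nrow(controls))) {
      pre <- controls[i, paste0("score_", battery$tests[j], "_baseline")]
      post <- controls[i, paste0("score_", battery$tests[j], "_", interval)]
      d <- battery$orientation[[j]] * (post - pre)
      if (!is.na(d)) deltas <- c(deltas, d)
    }
    means[j] <- sum(deltas) / length(deltas)
    sds[j] <- sqrt(sum((deltas - means[j])^2) / (length(deltas) - 1))
  }
  pocd <- logical(nrow(patients))
  n_pos <- integer(nrow(patients))
  classifiable <- logical(nrow(patients))
  for (i in seq_len(nrow(patients))) {
    npos <- 0L
    nmiss <- 0L
    for (j in seq_len(n_tests)) {
      pre <- patients[i, paste0("score_", battery$tests[j], "_baseline")]
      post <- patients[i, paste0("score_", battery$tests[j], "_", interval)]
      if (is.na(pre) || is.na(post)) {
        nmiss <- nmiss + 1L
        next
      }
      z <- (battery$orientation[[j]] * (post - pre) - means[j]) / sds[j]
      if (z <= -z_threshold) npos <- npos + 1L
    }
    classifiable[i] <- nmiss <= max_missing
    n_pos[i] <- if (classifiable[i]) npos else NA_integer_
    pocd[i] <- if (classifiable[i]) npos >= min_positive else NA
  }
  list(pocd = pocd, n_positive = n_pos, classifiable = classifiable)
}

# Grouped-binomial log-likelihood for status ~ b0 + b1 * g.
grouped_loglik <- function(b0, b1, g, y, n) {
  eta <- b0 + b1 * g
  sum(y * eta - n * log1p(exp(eta)))
}

# Profile grid-search maximizer for the per-allele slope: for each b1
# on a 2001-point grid around `center`, the intercept is profiled out
# with optimize(); returns the grid b1 with maximal profile likelihood.
grid_search_slope <- function(table, center, halfwidth = 1e-3) {
  m <- unclass(table)
  y <- m["pocd", ]
  n <- colSums(m)
  keep <- n > 0
  g <- (0:2)[keep]; y <- y[keep]; n <- n[keep]
  grid <- seq(center - halfwidth, center + halfwidth, length.out = 2001L)
  prof <- vapply(grid, function(b1) {
    stats::optimize(function(b0) grouped_loglik(b0, b1, g, y, n),
                    interval = c(-20, 20), maximum = TRUE,
                    tol = 1e-12)$objective
  }, numeric(1))
  grid[which.max(prof)]
}

# Random 2x3 genotype table with all classes populated and mixed
# outcomes, so the additive MLE exists.
random_genotype_table <- function() {
  repeat {
    n <- sample(8:40, 3L, replace = TRUE)
    y <- vapply(n, function(ni) rbinom(1L, ni, runif(1, 0.15, 0.85)),
                integer(1))
    if (all(y > 0) && all(y < n)) {
      return(genotype_table(pocd = y, no_pocd = n - y))
    }
  }
}
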