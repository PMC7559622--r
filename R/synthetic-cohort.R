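#' Simulation configuration for a synthetic POCD cohort
#'
#' Bundles every knob of the cohort generator. The defaults emulate the
#' design the analysis assumes: 99 analysable surgical patients and 25
#' age- and gender-matched healthy controls; rs6265-style genotypes in
#' Hardy-Weinberg equilibrium at a G-allele frequency of 0.51 (the
#' pooled patient allele frequency, 101/198); a latent binary surgical
#' "insult" whose log-odds depend additively on G-allele count with a
#' protective per-allele log-odds ratio of -0.9; an intercept placed so
#' an AA-genotype patient has roughly a 48% insult risk (which, averaged
#' over the genotype distribution, yields an overall early-POCD risk
#' near 30%); and a six-test battery with practice effects.
#'
#' Battery scores are simulated on an arbitrary standardized scale
#' (baseline mean 50, between-subject SD 10): no raw score
#' distributions are published for this battery, and the reliable-change
#' arithmetic is scale-free, so the scale is a labelled stand-in.
#' `decline_magnitude` is expressed in units of the control change-score
#' SD (`noise_sd`), which is the scale the classifier thresholds on.
#'
#' @param n_patients,n_controls Non-negative subject counts.
#' @param p_g G-allele frequency in `[0, 1]`.
#' @param intercept_logit Baseline (genotype AA) log-odds of a surgical
#'   cognitive insult.
#' @param beta_per_g Additive log-odds change per G allele; negative
#'   values are protective.
#' @param practice_effect Numeric vector, length = number of battery
#'   tests: mean oriented score gain between baseline and each follow-up
#'   (the practice/learning effect, reached by day 7 and sustained).
#' @param decline_magnitude Mean oriented score drop inflicted on
#'   insulted patients, in control change-SD units.
#' @param noise_sd Residual SD of each test's change score (> 0).
#' @param rho Exchangeable correlation among the tests' change noise,
#'   in `[0, 1)`. The false-positive rate of the two-of-six rule depends
#'   on it, so it is explicit rather than hidden.
#' @param persistence Probability that an insulted patient's decline is
#'   still present at the 3-month assessment (default 0.6, so late
#'   incidence runs at roughly 60% of early incidence).
#' @param baseline_mean,baseline_sd Location and between-subject SD of
#'   the standardized baseline score scale.
#' @param battery A [battery_def()]; its size fixes the score matrix.
#' @param seed Integer RNG seed; identical seed + config reproduce the
#'   cohort bit for bit.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' cohort <- generate_cohort(cfg)
#' table(cohort$arm)
#' @export
sim_config <- function(n_patients = 99L,
                       n_controls = 25L,
                       p_g = 0.51,
                       intercept_logit = stats::qlogis(0.48),
                       beta_per_g = -0.9,
                       practice_effect = rep(2, 6L),
                       decline_magnitude = 3,
                       noise_sd = 4,
                       rho = 0.3,
                       persistence = 0.6,
                       baseline_mean = 50,
                       baseline_sd = 10,
                       battery = default_battery(),
                       seed = 1L) {
  stopifnot(inherits(battery, "battery_def"))
  n_tests <- length(battery$tests)
  if (!is.numeric(p_g) || length(p_g) != 1L || is.na(p_g) ||
      p_g < 0 || p_g > 1) {
    stop("`p_g` must be a single value in [0, 1]", call. = FALSE)
  }
  if (n_patients < 0 || n_controls < 0) {
    stop("subject counts must be non-negative", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    stop("`noise_sd` must be positive", call. = FALSE)
  }
  if (rho < 0 || rho >= 1) {
    stop("`rho` must be in [0, 1)", call. = FALSE)
  }
  if (persistence < 0 || persistence > 1) {
    stop("`persistence` must be a probability", call. = FALSE)
  }
  if (length(practice_effect) == 1L) {
    practice_effect <- rep(practice_effect, n_tests)
  }
  if (length(practice_effect) != n_tests) {
    stop("`practice_effect` must have one entry per battery test",
         call. = FALSE)
  }
  structure(list(
    n_patients = as.integer(n_patients),
    n_controls = as.integer(n_controls),
    p_g = p_g,
    intercept_logit = intercept_logit,
    beta_per_g = beta_per_g,
    practice_effect = practice_effect,
    decline_magnitude = decline_magnitude,
    noise_sd = noise_sd,
    rho = rho,
    persistence = persistence,
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    battery = battery,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Sample genotypes under Hardy-Weinberg equilibrium
#'
#' Each subject draws two alleles independently with `P(G) = p_g`; the
#' returned code is the G-allele count, so genotype frequencies follow
#' the Hardy-Weinberg proportions ((1-p)^2, 2p(1-p), p^2) for AA/AG/GG.
#'
#' @param n Number of subjects.
#' @param p_g G-allele frequency in `[0, 1]`.
#' @param seed Optional integer seed; when `NULL` the current RNG
#'   stream is used (as when called from [generate_cohort()]).
#' @return Integer vector of G-allele counts in `{0, 1, 2}`.
#' @examples
#' table(sample_genotypes(1000, 0.51, seed = 7))
#' @export
sample_genotypes <- function(n, p_g, seed = NULL) {
  if (!is.numeric(p_g) || length(p_g) != 1L || is.na(p_g) ||
      p_g < 0 || p_g > 1) {
    stop("`p_g` must be a single value in [0, 1]", call. = FALSE)
  }
  if (n < 0) stop("`n` must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  stats::rbinom(n, size = 2L, prob = p_g)
}

# Correlated N(0, sd^2) noise, exchangeable correlation rho across tests.
corr_noise <- function(n, n_tests, sd, rho) {
  R <- matrix(rho, n_tests, n_tests)
  diag(R) <- 1
  z <- matrix(stats::rnorm(n * n_tests), n, n_tests)
  z %*% chol(R) * sd
}

#' Generate a synthetic cohort with known ground truth
#'
#' Simulates genotypes, demographics, a latent surgical insult and a
#' full battery-score matrix (baseline, day 7, month 3) for patients
#' and controls. Controls never receive an insult; each patient's
#' latent insult is Bernoulli with
#' `logit^-1(intercept_logit + beta_per_g * g)` where `g` is the
#' G-allele count. Follow-up scores are baseline plus the practice
#' effect, minus `decline_magnitude * noise_sd` for insulted subjects,
#' plus correlated residual noise; at month 3 the decline applies only
#' to insulted patients whose deficit persists. The latent labels are
#' recorded (`truth_insult`, `truth_insult_m3`) so recovery of the
#' generative parameters can be checked downstream.
#'
#' Tests with orientation "higher = worse" are stored as
#' `100 - latent` so that every raw scale stays positive while the
#' oriented change behaves identically across tests.
#'
#' @param config A [sim_config()].
#' @param scores If `FALSE`, skip score simulation and return only
#'   genotypes, demographics and truth labels — convenient for large
#'   calibration studies of the association stage where battery scores
#'   are irrelevant.
#' @return A data frame, one row per subject, with columns `id`, `arm`
#'   (`"patient"`/`"control"`), `genotype` (0/1/2 G alleles), `age`,
#'   `sex`, `education_years`, `truth_insult`, `truth_insult_m3`, and
#'   (when `scores = TRUE`) `score_<test>_<timepoint>` for every
#'   battery test at `baseline`, `day7`, `month3`.
#' @examples
#' cohort <- generate_cohort(sim_config(seed = 42))
#' mean(cohort$truth_insult[cohort$arm == "patient"])
#' @export
generate_cohort <- function(config, scores = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_pat <- config$n_patients
  n_ctl <- config$n_controls
  n <- n_pat + n_ctl
  battery <- config$battery
  n_tests <- length(battery$tests)

  arm <- rep(c("patient", "control"), c(n_pat, n_ctl))
  id <- sprintf("%s%03d", ifelse(arm == "patient", "P", "C"),
                c(seq_len(n_pat), seq_len(n_ctl)))
  genotype <- sample_genotypes(n, config$p_g)

  # decorative demographics, matched across arms by construction
  age <- pmax(60, round(stats::rnorm(n, 72, 4.5)))
  sex <- ifelse(stats::runif(n) < 0.8, "male", "female")
  education_years <- pmax(0, round(stats::rnorm(n, 5, 2)))

  eta <- config$intercept_logit + config$beta_per_g * genotype
  insult <- arm == "patient" & stats::runif(n) < stats::plogis(eta)
  insult_m3 <- insult & stats::runif(n) < config$persistence

  out <- data.frame(
    id = id, arm = arm, genotype = genotype, age = age, sex = sex,
    education_years = education_years,
    truth_insult = insult, truth_insult_m3 = insult_m3,
    stringsAsFactors = FALSE
  )
  if (!scores) {
    return(out)
  }

  drop <- config$decline_magnitude * config$noise_sd
  base_lat <- config$baseline_mean +
    corr_noise(n, n_tests, config$baseline_sd, config$rho)
  pe <- matrix(config$practice_effect, n, n_tests, byrow = TRUE)
  d7_lat <- base_lat + pe - drop * insult +
    corr_noise(n, n_tests, config$noise_sd, config$rho)
  m3_lat <- base_lat + pe - drop * insult_m3 +
    corr_noise(n, n_tests, config$noise_sd, config$rho)

  flip <- matrix(battery$orientation, n, n_tests, byrow = TRUE)
  to_raw <- function(lat) ifelse(flip > 0, lat, 100 - lat)
  mats <- list(baseline = to_raw(base_lat), day7 = to_raw(d7_lat),
               month3 = to_raw(m3_lat))
  for (tp in names(mats)) {
    m <- mats[[tp]]
    colnames(m) <- paste0("score_", battery$tests, "_", tp)
    out <- cbind(out, m)
  }
  out
}

#' Write / read the cohort CSV
#'
#' The on-disk schema consumed by the classifier: one row per subject
#' with `id`, `arm`, `genotype`, demographics and
#' `score_<test>_<timepoint>` columns, plain UTF-8 CSV with a header
#' row. Truth columns, when present, round-trip too.
#'
#' @param cohort A cohort data frame from [generate_cohort()] or of the
#'   same schema.
#' @param path File path.
#' @return `write_cohort_csv` returns `path` invisibly;
#'   `read_cohort_csv` returns the cohort data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
  required <- c("id", "arm", "genotype")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols)) {
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_arm <- !cohort$arm %in% c("patient", "control")
  if (any(bad_arm)) {
    stop(sprintf("invalid `arm` value at data line %d of %s",
                 which(bad_arm)[1], path), call. = FALSE)
  }
  bad_gt <- !is.na(cohort$genotype) & !cohort$genotype %in% 0:2
  if (any(bad_gt)) {
    stop(sprintf("invalid genotype code at data line %d of %s",
                 which(bad_gt)[1], path), call. = FALSE)
  }
  cohort
}
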