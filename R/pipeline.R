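#' Configuration for an end-to-end pipeline run
#'
#' Collects every input path, threshold and option of the
#' simulate -> classify -> associate -> report pipeline so a run is
#' fully described by one object; the object (plus the seed) is echoed
#' into a JSON run manifest next to the outputs, which makes any run
#' reproducible from its artifact directory alone.
#'
#' @param out_dir Output directory (created if needed).
#' @param cohort_path Path to an existing cohort CSV, or `NULL` to
#'   simulate one.
#' @param simulate A [sim_config()] used when `cohort_path` is `NULL`.
#' @param battery A [battery_def()].
#' @param z_threshold,min_positive,max_missing Classifier rule.
#' @param t_variant t-test variant for the group-comparison table.
#' @param variables Named kind vector for [table1_report()].
#' @param yates Continuity-correct the chi-square tests (default
#'   `FALSE`).
#' @param haldane Apply the Haldane zero-cell policy (default `TRUE`).
#' @param seed Integer seed recorded in the manifest; when simulating,
#'   it overrides the seed inside `simulate`.
#' @param verbose Log stage progress to standard error.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            cohort_path = NULL,
                            simulate = sim_config(),
                            battery = default_battery(),
                            z_threshold = 1.96,
                            min_positive = 2L,
                            max_missing = 0L,
                            t_variant = "pooled",
                            variables = c(age = "continuous",
                                          sex = "categorical",
                                          education_years = "continuous"),
                            yates = FALSE,
                            haldane = TRUE,
                            seed = 1L,
                            verbose = TRUE) {
  structure(list(
    out_dir = out_dir, cohort_path = cohort_path, simulate = simulate,
    battery = battery, z_threshold = z_threshold,
    min_positive = as.integer(min_positive),
    max_missing = as.integer(max_missing),
    t_variant = t_variant, variables = variables, yates = yates,
    haldane = haldane, seed = as.integer(seed), verbose = verbose
  ), class = "pipeline_config")
}

log_stage <- function(verbose, ...) {
  if (verbose) message("[pocdassoc] ", ...)
}

# genotype_table from classified subjects at one interval
tabulate_genotypes <- function(patients, outcomes) {
  merged <- merge(patients[, c("id", "genotype")],
                  outcomes[outcomes$classifiable, c("id", "pocd")],
                  by = "id")
  merged <- merged[!is.na(merged$genotype), , drop = FALSE]
  cnt <- function(flag) {
    vapply(0:2, function(g) sum(merged$pocd == flag &
                                  merged$genotype == g), integer(1))
  }
  genotype_table(pocd = cnt(TRUE), no_pocd = cnt(FALSE))
}

#' Run the full POCD analysis pipeline
#'
#' Executes, in order: cohort simulation (when no cohort file is
#' given), RCI classification at day 7 and month 3, genotype
#' association under all four genetic models with an HWE diagnostic on
#' the pooled patient genotypes, and the group-comparison table. Every
#' stage writes a plain-text artifact into `config$out_dir`, and a
#' `manifest.json` records the configuration, seed and MD5 checksums
#' of all outputs. Identical configuration and inputs produce
#' byte-identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `artifacts` (named file paths),
#'   `incidence` (per interval), `association` (the report),
#'   `hwe`, and `cohort`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()

  if (is.null(config$cohort_path)) {
    log_stage(config$verbose, "simulate: seed ", config$seed)
    simcfg <- config$simulate
    simcfg$seed <- config$seed
    cohort <- generate_cohort(simcfg)
    artifacts$cohort <- file.path(config$out_dir, "cohort.csv")
    write_cohort_csv(cohort, artifacts$cohort)
  } else {
    log_stage(config$verbose, "load cohort: ", config$cohort_path)
    cohort <- read_cohort_csv(config$cohort_path)
  }
  if (nrow(cohort) == 0 || !any(cohort$arm == "patient")) {
    stop("cohort contains no patients", call. = FALSE)
  }

  patients <- cohort[cohort$arm == "patient", , drop = FALSE]
  incidence <- list()
  outcomes_by_iv <- list()
  for (iv in c("day7", "month3")) {
    log_stage(config$verbose, "classify: ", iv)
    res <- classify_cohort(cohort, battery = config$battery,
                           interval = iv,
                           z_threshold = config$z_threshold,
                           min_positive = config$min_positive,
                           max_missing = config$max_missing)
    outcomes_by_iv[[iv]] <- res$outcomes
    incidence[[iv]] <- res$incidence
    artifacts[[paste0("outcomes_", iv)]] <-
      file.path(config$out_dir, paste0("outcomes_", iv, ".tsv"))
    write_outcomes_tsv(res, artifacts[[paste0("outcomes_", iv)]])
  }

  log_stage(config$verbose, "associate")
  tables <- lapply(outcomes_by_iv, tabulate_genotypes,
                   patients = patients)
  report <- association_report(tables)
  pooled <- colSums(unclass(tables$day7))
  hwe <- hwe_chi_square(pooled)
  artifacts$association <- file.path(config$out_dir, "association.tsv")
  write_association_tsv(report, artifacts$association, hwe = hwe)

  log_stage(config$verbose, "table1")
  for (iv in c("day7", "month3")) {
    t1 <- table1_report(cohort, outcomes_by_iv[[iv]], config$variables,
                        t_variant = config$t_variant)
    artifacts[[paste0("table1_", iv)]] <-
      file.path(config$out_dir, paste0("table1_", iv, ".tsv"))
    write_table1_tsv(t1, artifacts[[paste0("table1_", iv)]])
  }

  log_stage(config$verbose, "incidence + manifest")
  artifacts$incidence <- file.path(config$out_dir, "incidence.tsv")
  inc_df <- data.frame(
    interval = names(incidence),
    n_pocd = vapply(incidence, `[[`, integer(1), "n_pocd"),
    n_classifiable = vapply(incidence, `[[`, integer(1),
                            "n_classifiable"),
    percent = sprintf("%.1f",
                      vapply(incidence, `[[`, numeric(1), "percent")),
    stringsAsFactors = FALSE
  )
  utils::write.table(inc_df, artifacts$incidence, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_manifest(config, artifacts)

  invisible(list(artifacts = artifacts, incidence = incidence,
                 association = report, hwe = hwe, cohort = cohort))
}

write_manifest <- function(config, artifacts) {
  files <- unlist(artifacts)
  cfg <- config
  cfg$battery <- list(tests = cfg$battery$tests,
                      orientation = as.list(cfg$battery$orientation))
  cfg$simulate <- if (is.null(cfg$cohort_path)) {
    sim <- unclass(cfg$simulate)
    sim$battery <- NULL
    sim
  }
  manifest <- list(
    package = "pocdassoc",
    config = cfg[setdiff(names(cfg), c("out_dir", "verbose"))],
    seed = config$seed,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(files)), basename(files)))
  )
  path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
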