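test_that("genotype tables collapse correctly under each model", {
  gt <- counts_day7()
  d <- collapse_genotypes(gt, "dominant")
  expect_equal(unlist(d[c("a", "b", "c", "d")]),
               c(a = 19, b = 59, c = 10, d = 11))
  r <- collapse_genotypes(gt, "recessive")
  expect_equal(unlist(r[c("a", "b", "c", "d")]),
               c(a = 3, b = 20, c = 26, d = 50))
  al <- collapse_genotypes(gt, "allelic")
  expect_equal(unlist(al[c("a", "b", "c", "d")]),
               c(a = 22, b = 79, c = 36, d = 61))
  # allele counts match the published allele columns at both timepoints
  expect_equal(unname(allele_counts(counts_month3())),
               rbind(c(28, 22), c(69, 79)))
})

test_that("Woolf odds ratios reproduce hand-checked values", {
  dom <- odds_ratio_2x2(table2x2(19, 59, 10, 11))
  expect_equal(dom$or_point, 19 * 11 / (59 * 10))
  expect_equal(format_or(dom$or_point), "0.35")
  expect_equal(format_or(dom$ci95[1]), "0.13")
  expect_equal(format_or(dom$ci95[2]), "0.96")
  rec <- odds_ratio_2x2(table2x2(3, 20, 26, 50))
  expect_equal(format_or(rec$or_point), "0.29")
  expect_equal(format_or(rec$ci95[1]), "0.078")
  expect_equal(format_or(rec$ci95[2]), "1.06")
  # balanced table: OR 1, CI symmetric about 1 in log space
  bal <- odds_ratio_2x2(table2x2(7, 7, 7, 7))
  expect_equal(bal$or_point, 1)
  expect_equal(log(bal$ci95[1]), -log(bal$ci95[2]))
})

test_that("Haldane policy handles zero cells; empty margins error", {
  z <- odds_ratio_2x2(table2x2(0, 10, 5, 5))
  expect_true(z$correction_applied)
  expect_equal(z$or_point, 0.5 * 5.5 / (10.5 * 5.5))
  clean <- odds_ratio_2x2(table2x2(19, 59, 10, 11))
  expect_false(clean$correction_applied)
  expect_error(odds_ratio_2x2(table2x2(0, 0, 5, 5)), "row or column")
  expect_error(odds_ratio_2x2(table2x2(0, 5, 0, 5)), "row or column")
  expect_error(odds_ratio_2x2(table2x2(0, 10, 5, 5), haldane = FALSE),
               "Haldane")
})

test_that("Woolf CI width identity holds exactly", {
  set.seed(41)
  tabs <- c(list(collapse_genotypes(counts_day7(), "dominant"),
                 collapse_genotypes(counts_month3(), "recessive")),
            lapply(1:10, function(i) {
              cells <- sample(1:60, 4, replace = TRUE)
              table2x2(cells[1], cells[2], cells[3], cells[4])
            }))
  for (t in tabs) {
    res <- odds_ratio_2x2(t)
    expect_equal(log(res$ci95[2]) - log(res$ci95[1]),
                 2 * 1.96 * res$se_log_or, tolerance = 1e-12)
    expect_true(res$ci95[1] <= res$or_point &&
                  res$or_point <= res$ci95[2])
  }
})

test_that("exposure-swap and status-swap antisymmetries hold", {
  set.seed(42)
  for (i in 1:20) {
    cells <- sample(1:60, 4, replace = TRUE)
    t0 <- table2x2(cells[1], cells[2], cells[3], cells[4])
    res <- odds_ratio_2x2(t0)
    # swapping exposed/unexposed inverts the OR and reflects the CI
    swap_exp <- odds_ratio_2x2(table2x2(t0$c, t0$d, t0$a, t0$b))
    expect_equal(swap_exp$or_point, 1 / res$or_point, tolerance = 1e-12)
    expect_equal(swap_exp$ci95, rev(1 / res$ci95), tolerance = 1e-12)
    expect_equal(swap_exp$p, res$p, tolerance = 1e-12)
    # swapping case/non-case status does the same
    swap_st <- odds_ratio_2x2(table2x2(t0$b, t0$a, t0$d, t0$c))
    expect_equal(swap_st$or_point, 1 / res$or_point, tolerance = 1e-12)
  }
})

test_that("additive MLE reproduces published value and matches glm", {
  add <- additive_trend_or(counts_day7())
  expect_equal(format_or(add$or_point), "0.41")
  expect_equal(format_or(add$ci95[1]), "0.20")
  expect_equal(format_or(add$ci95[2]), "0.84")
  # independent route: R's IRLS logistic fit on the grouped counts
  set.seed(43)
  for (i in 1:20) {
    gt <- random_genotype_table()
    m <- unclass(gt)
    fit <- glm(cbind(m["pocd", ], m["no_pocd", ]) ~ c(0, 1, 2),
               family = binomial)
    mine <- additive_trend_or(gt)
    # glm's IRLS stops on a looser deviance criterion than the
    # Newton-Raphson parameter tolerance here, so compare at 1e-5
    expect_equal(mine$log_or, unname(coef(fit)[2]), tolerance = 1e-5)
    expect_equal(mine$se_log_or,
                 unname(summary(fit)$coefficients[2, 2]),
                 tolerance = 1e-5)
  }
})

test_that("additive slope maximizes the likelihood (grid-search oracle)", {
  set.seed(44)
  for (i in 1:10) {
    gt <- random_genotype_table()
    mine <- additive_trend_or(gt)
    grid_best <- grid_search_slope(gt, mine$log_or)
    expect_lt(abs(grid_best - mine$log_or), 1.5e-6)
  }
})

test_that("additive model handles flat, degenerate and separated tables", {
  # identical case fraction in every genotype class: no trend
  flat <- additive_trend_or(genotype_table(c(5, 10, 15), c(5, 10, 15)))
  expect_equal(flat$or_point, 1, tolerance = 1e-9)
  # one empty genotype class: MLE equals the closed-form 2x2 OR on the
  # remaining classes (saturated two-group model), with g recoded 0/1
  two <- genotype_table(c(8, 12, 0), c(10, 30, 0))
  mine <- additive_trend_or(two)
  expect_equal(mine$or_point, (12 * 10) / (30 * 8), tolerance = 1e-9)
  # a GG-only class still spans two allele copies: slope halves
  gap <- genotype_table(c(8, 0, 12), c(10, 0, 30))
  expect_equal(additive_trend_or(gap)$log_or,
               log((12 * 10) / (30 * 8)) / 2, tolerance = 1e-9)
  # single populated class: slope unidentifiable
  expect_error(additive_trend_or(genotype_table(c(5, 0, 0), c(5, 0, 0))),
               "rank deficiency")
  # complete separation: monotone 0 -> 1 case fractions
  expect_error(additive_trend_or(genotype_table(c(0, 0, 8), c(9, 11, 0))),
               "separation")
})

test_that("HWE chi-square matches closed-form expectations", {
  # perfect equilibrium at p = 0.5
  expect_equal(hwe_chi_square(c(25, 50, 25))$chi2, 0)
  # maximal disequilibrium at p = 0.5: chi2 equals n
  res <- hwe_chi_square(c(50, 0, 50))
  expect_equal(res$chi2, 100)
  # pooled patient genotypes: frozen hand computation
  pooled <- hwe_chi_square(c(21, 55, 23))
  expect_equal(pooled$chi2, 1.232223, tolerance = 1e-6)
  expect_equal(pooled$p, 0.2669752, tolerance = 1e-6)
  expect_equal(pooled$allele_freq_g, 101 / 198)
  # expected counts preserve the sample size
  expect_equal(sum(pooled$expected), 99)
  expect_warning(hwe_chi_square(c(10, 0, 0)), "monomorphic")
  expect_error(hwe_chi_square(c(0, 0, 0)), "empty")
})

test_that("Pearson chi-square wrapper covers 2x2 and 2x3 tables", {
  null22 <- chi_square_test(table2x2(10, 10, 10, 10))
  expect_equal(null22$stat, 0)
  expect_equal(null22$p, 1)
  dom <- chi_square_test(collapse_genotypes(counts_day7(), "dominant"))
  expect_lt(dom$p, 0.05)
  expect_equal(chi_square_test(counts_day7())$df, 2)
  expect_error(chi_square_test(rbind(c(0, 0), c(3, 4))), "marginal")
  expect_warning(chi_square_test(table2x2(2, 3, 3, 2)), "below 5")
  # oracle: direct Pearson formula on a random 2x2
  set.seed(45)
  m <- matrix(sample(5:40, 4), 2)
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  expect_equal(suppressWarnings(chi_square_test(m)$stat),
               sum((m - e)^2 / e), tolerance = 1e-12)
})

test_that("association report covers all models and flags significance", {
  rep <- association_report(day7 = counts_day7(),
                            month3 = counts_month3())
  expect_equal(nrow(rep), 8L)
  d7 <- rep[rep$timepoint == "day7", ]
  expect_true(d7$significant[d7$model == "additive"])
  expect_true(d7$significant[d7$model == "dominant"])
  expect_false(d7$significant[d7$model == "recessive"])
  expect_false(any(rep$significant[rep$timepoint == "month3"]))
  # a failing model yields an error row without sinking the report
  sep <- genotype_table(c(0, 0, 8), c(9, 11, 0))
  rep2 <- association_report(day7 = sep)
  expect_true(is.na(rep2$or[rep2$model == "additive"]))
  expect_match(rep2$error[rep2$model == "additive"], "separation")
  expect_false(anyNA(rep2$or[rep2$model == "dominant"]))
})

test_that("count-table diagnostics flag internal inconsistencies", {
  # 3-month genotype counts sum to 25/74, not the stated 18/81
  flags <- check_genotype_table(counts_month3(),
                                stated_sizes = c(pocd = 18, no_pocd = 81))
  expect_length(flags, 2L)
  expect_match(flags[1], "sum to 25")
  # the 7-day table is consistent with its stated sizes and alleles
  expect_length(check_genotype_table(
    counts_day7(), stated_sizes = c(pocd = 29, no_pocd = 70),
    stated_alleles = rbind(c(36, 22), c(61, 79))), 0L)
  expect_match(check_genotype_table(
    counts_day7(), stated_alleles = rbind(c(36, 23), c(61, 78))),
    "allele counts differ")
})
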