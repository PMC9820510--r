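test_that("concordance bookkeeping reproduces the published tallies", {
  cs <- concordance_summary(ctdna_fixture("table2"))
  expect_equal(cs$n, 61L)
  expect_equal(cs$caller_detected, 13L)
  expect_equal(cs$overall_detected, 18L)
  expect_equal(cs$caller_fraction, 13 / 61)
  expect_equal(cs$overall_fraction, 18 / 61)
  expect_equal(round(100 * cs$caller_fraction, 2), 21.31)

  two <- data.frame(caller_detected = c(TRUE, FALSE),
                    manual_detected = c(FALSE, FALSE))
  expect_equal(concordance_summary(two)$caller_fraction, 0.5)
  allno <- data.frame(caller_detected = rep(FALSE, 4),
                      manual_detected = rep(FALSE, 4))
  expect_equal(concordance_summary(allno)$overall_detected, 0L)
  expect_warning(e <- concordance_summary(allno[0, ]), "empty")
  expect_true(is.na(e$caller_fraction))
})

test_that("tumor yield and naive-mode bookkeeping match the published counts", {
  ty <- tumor_yield(ctdna_fixture("table2"))
  expect_equal(ty$n_mutated, 40L)
  expect_equal(round(100 * ty$fraction, 2), 56.34)

  np <- naive_positivity(ctdna_fixture("table2"), ctdna_fixture("table3"))
  expect_equal(np$n_positive, 25L)
  expect_equal(round(100 * np$fraction, 2), 33.78)
  expect_equal(np$plasma_only_mutations, 16L)
  expect_equal(np$plasma_only_patients, 8L)
})

test_that("gene spectra carry the published counts and sum to one", {
  tb2 <- ctdna_fixture("table2")
  gs <- gene_spectrum(tb2)
  expect_equal(gs$n[gs$gene == "PIK3CA"], 33L)
  expect_equal(gs$n[gs$gene == "TP53"], 12L)
  expect_equal(gs$n[gs$gene == "GATA3"], 4L)
  expect_equal(sum(gs$fraction), 1, tolerance = 1e-12)
  expect_true(all(diff(gs$n) <= 0))

  pd <- plasma_detected_variants(tb2, ctdna_fixture("table3"))
  gp <- gene_spectrum(pd)
  expect_equal(gp$n[gp$gene == "TP53"], 13L)
  expect_equal(sum(gp$fraction), 1, tolerance = 1e-12)
  expect_equal(nrow(gene_spectrum(pd[0, ])), 0L)
})

test_that("Clopper-Pearson intervals are exact and well-behaved", {
  ci <- clopper_pearson_ci(19, 22)
  expect_equal(round(100 * ci[["lower"]], 2), 65.09)
  expect_equal(round(100 * ci[["upper"]], 2), 97.09)
  expect_equal(clopper_pearson_ci(0, 10)[["lower"]], 0)
  expect_equal(clopper_pearson_ci(10, 10)[["upper"]], 1)
  expect_error(clopper_pearson_ci(5, 4), "k <= n")

  # cross-check against the exact binomial test's interval
  for (kn in list(c(19, 22), c(23, 74), c(3, 22), c(0, 7), c(12, 12))) {
    ci1 <- clopper_pearson_ci(kn[1], kn[2])
    ci2 <- as.numeric(stats::binom.test(kn[1], kn[2])$conf.int)
    expect_equal(unname(ci1), ci2, tolerance = 1e-9)
  }

  # contains k/n; width shrinks with n at fixed k/n
  widths <- vapply(c(10, 40, 160, 640), function(n) {
    k <- 0.25 * n
    ci <- clopper_pearson_ci(k, n)
    expect_gte(0.25, ci[["lower"]]); expect_lte(0.25, ci[["upper"]])
    ci[["upper"]] - ci[["lower"]]
  }, 0)
  expect_true(all(diff(widths) < 0))
})

test_that("diagnostic metrics reproduce the published operating characteristics", {
  dm <- diagnostic_metrics(confusion_counts(tp = 23, fn = 51, fp = 3,
                                            tn = 19))
  est <- function(m) dm$estimate[dm$metric == m]
  expect_equal(round(100 * est("sensitivity"), 2), 31.08)
  expect_equal(round(100 * est("specificity"), 2), 86.36)
  expect_equal(round(100 * est("ppv"), 2), 88.46)
  lo <- function(m) dm$lower[dm$metric == m]
  hi <- function(m) dm$upper[dm$metric == m]
  expect_equal(round(100 * c(lo("sensitivity"), hi("sensitivity")), 2),
               c(20.83, 42.90))
  expect_equal(round(100 * c(lo("specificity"), hi("specificity")), 2),
               c(65.09, 97.09))

  # degenerate tables stay defined
  d0 <- suppressWarnings(diagnostic_metrics(confusion_counts(0, 5, 0, 7)))
  expect_equal(d0$estimate[d0$metric == "sensitivity"], 0)
  expect_equal(d0$estimate[d0$metric == "specificity"], 1)
  expect_true(is.na(d0$estimate[d0$metric == "ppv"]))
})

test_that("diagnostic metrics agree with caret's confusion matrix", {
  skip_if_not_installed("caret")
  pred <- factor(c(rep("pos", 23), rep("neg", 51), rep("pos", 3),
                   rep("neg", 19)), levels = c("pos", "neg"))
  truth <- factor(c(rep("pos", 74), rep("neg", 22)), levels = c("pos", "neg"))
  cm <- caret::confusionMatrix(pred, truth, positive = "pos")
  dm <- diagnostic_metrics(confusion_counts(23, 51, 3, 19))
  expect_equal(dm$estimate[dm$metric == "sensitivity"],
               unname(cm$byClass["Sensitivity"]), tolerance = 1e-12)
  expect_equal(dm$estimate[dm$metric == "specificity"],
               unname(cm$byClass["Specificity"]), tolerance = 1e-12)
  expect_equal(dm$estimate[dm$metric == "ppv"],
               unname(cm$byClass["Pos Pred Value"]), tolerance = 1e-12)
})

test_that("positivity table links detections to roles and flags unknown samples", {
  sheet <- data.frame(
    sample_id = c("p1", "p2", "p3", "c1", "c2"),
    role = c("plasma_case", "plasma_case", "plasma_case",
             "plasma_control", "plasma_control"),
    stage = c(1L, 2L, 3L, NA, NA),
    stringsAsFactors = FALSE
  )
  det <- data.frame(
    sample_id = c("p1", "p1", "p3", "c2"),
    gene = c("TP53", "PIK3CA", "GATA3", "ERBB2"),
    vaf = c(0.002, 0.01, 3e-4, 5e-4),
    passed = c(TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  pt <- positivity_table(det, sheet)
  expect_equal(sum(pt$cohort$ctdna_positive), 3L)
  expect_equal(pt$confusion$tp, 2L)
  expect_equal(pt$confusion$fn, 1L)
  expect_equal(pt$confusion$fp, 1L)
  expect_equal(pt$confusion$tn, 1L)
  p1 <- pt$cohort[pt$cohort$sample_id == "p1", ]
  expect_equal(p1$n_plasma_mutations, 2L)
  expect_equal(p1$median_vaf, 0.006)
  expect_true(p1$tp53_in_plasma)
  # no detections -> all negative
  pt0 <- positivity_table(det[0, ], sheet)
  expect_equal(sum(pt0$cohort$ctdna_positive), 0L)
  # unknown sample errors
  bad <- det; bad$sample_id[1] <- "ghost"
  expect_error(positivity_table(bad, sheet), "ghost")
})

test_that("per-stage sensitivity groups cases and keeps exact intervals", {
  cohort <- data.frame(
    sample_id = sprintf("s%02d", 1:32),
    role = "plasma_case",
    stage = rep(c(1L, 2L, 3L), c(14, 9, 9)),
    ctdna_positive = c(rep(c(TRUE, FALSE), c(3, 11)),
                       rep(c(TRUE, FALSE), c(2, 7)),
                       rep(c(TRUE, FALSE), c(4, 5))),
    stringsAsFactors = FALSE
  )
  ps <- per_stage_sensitivity(cohort)
  expect_equal(nrow(ps), 3L)
  expect_equal(round(100 * ps$sensitivity[ps$stage == 3], 2), 44.44)
  expect_true(all(ps$lower <= ps$sensitivity & ps$sensitivity <= ps$upper))
  one <- per_stage_sensitivity(cohort[cohort$stage == 2, ])
  expect_equal(nrow(one), 1L)
})

test_that("association screen picks tests by type and expected counts", {
  set.seed(11)
  n <- 120
  cohort <- data.frame(
    ctdna_positive = c(rep(TRUE, 40), rep(FALSE, 80)),
    median_vaf = stats::rlnorm(n, meanlog = -6),
    n_plasma_mutations = stats::rpois(n, 1),
    tp53_in_plasma = stats::runif(n) < 0.1,
    grade = sample(c("low", "high"), n, replace = TRUE),
    relapse = stats::runif(n) < 0.5,
    constant_cov = "x",
    stringsAsFactors = FALSE
  )
  scr <- association_screen(cohort, covariates = c("grade", "relapse",
                                                   "constant_cov"))
  expect_true(all(c("metric", "covariate", "test", "p_value", "p_bh") %in%
                    names(scr)))
  # numeric metric x 2-level covariate -> Wilcoxon
  expect_equal(scr$test[scr$metric == "median_vaf" &
                          scr$covariate == "grade"], "wilcoxon")
  # binary x binary with large counts -> chi-square
  expect_equal(scr$test[scr$metric == "ctdna_positive" &
                          scr$covariate == "relapse"], "chi_square")
  # constant covariate skipped with a reason
  sk <- scr[scr$covariate == "constant_cov", ]
  expect_true(all(!is.na(sk$skipped_reason)))
  # small expected cells -> Fisher
  rare <- cohort
  rare$rare_cov <- c(rep(TRUE, 4), rep(FALSE, n - 4))
  scr2 <- association_screen(rare, metrics = "ctdna_positive",
                             covariates = "rare_cov")
  expect_equal(scr2$test, "fisher")
  # a 2x2 Fisher p equals brute-force enumeration (expected cells < 5)
  tiny <- data.frame(
    ctdna_positive = rep(c(TRUE, FALSE), c(10, 12)),
    g = c(rep("a", 9), rep("b", 1), rep("a", 3), rep("b", 9)),
    stringsAsFactors = FALSE
  )
  scr_tiny <- association_screen(tiny, metrics = "ctdna_positive",
                                 covariates = "g")
  expect_equal(scr_tiny$test, "fisher")
  expect_equal(scr_tiny$p_value, enum_fisher_p(9, 1, 3, 9, "two.sided"),
               tolerance = 1e-9)
  # identical VAF distributions across groups are not flagged
  null <- data.frame(median_vaf = rep(stats::rlnorm(60, -6), 2),
                     g = rep(c("a", "b"), each = 60),
                     stringsAsFactors = FALSE)
  p_null <- association_screen(null, metrics = "median_vaf",
                               covariates = "g")$p_value
  expect_gt(p_null, 0.5)
})

test_that("association screen detects a built-in grade effect with good power", {
  # grade shifts log median VAF by 0.75 SD; n = 200, 500 replicates
  set.seed(77)
  hits <- logical(500)
  for (i in seq_len(500)) {
    grade <- sample(c("low", "high"), 200, replace = TRUE)
    vaf <- stats::rlnorm(200, meanlog = -7 + 0.75 * (grade == "high"))
    cohort <- data.frame(median_vaf = vaf, grade = grade,
                         stringsAsFactors = FALSE)
    hits[i] <- association_screen(cohort, metrics = "median_vaf",
                                  covariates = "grade")$p_value < 0.05
  }
  expect_gte(mean(hits), 0.8)
})

test_that("association screen p-values are super-uniform under the null", {
  set.seed(31)
  rej <- logical(1000)
  for (i in seq_len(1000)) {
    cohort <- data.frame(
      ctdna_positive = stats::runif(60) < 0.3,
      g = sample(c("a", "b"), 60, replace = TRUE),
      stringsAsFactors = FALSE
    )
    p <- association_screen(cohort, metrics = "ctdna_positive",
                            covariates = "g")$p_value
    rej[i] <- !is.na(p) && p < 0.05
  }
  expect_lte(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))
})
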