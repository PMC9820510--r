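test_that("site interrogation echoes pileup counts and coordinates", {
  panel <- toy_panel(0L, 20000L)
  sites <- data.frame(chrom = "chrT", pos = 10000L, ref = "A", alt = "T",
                      vaf = 2e-4, stringsAsFactors = FALSE)
  cfg <- sim_config(seed = 91, panel = panel, sites = sites,
                    consensus_depth = 10000L, read_length = 10L,
                    family_lambda = 2)
  sim <- simulate_read_families(cfg)
  pile <- build_pileup(call_consensus_reads(group_reads_by_umi(sim$reads)),
                       panel)
  si <- interrogate_site(pile, list(chrom = "chrT", pos = 10001L,
                                    ref = "A", alt = "T"), panel = panel)
  expect_equal(si$alt_count, sim$truth$n_alt_fragments)
  expect_equal(length(unique(si$coords)), sim$truth$n_distinct_coords)
  expect_gt(si$ref_count, 9000L)
  # a site with no alt evidence
  si0 <- interrogate_site(pile, list(chrom = "chrT", pos = 9001L,
                                     ref = "A", alt = "G"))
  expect_equal(si0$alt_count, 0L)
  # outside the panel is an error
  expect_error(interrogate_site(pile, list(chrom = "chrT", pos = 30001L,
                                           ref = "A", alt = "T"),
                                panel = panel), "outside")
})

test_that("indel allele tokens are counted as alt support", {
  panel <- toy_panel(0L, 2000L)
  sites <- data.frame(chrom = "chrT", pos = 1000L, ref = "A", alt = "delCA",
                      vaf = 0.05, stringsAsFactors = FALSE)
  cfg <- sim_config(seed = 14, panel = panel, sites = sites,
                    consensus_depth = 300L, read_length = 10L)
  sim <- simulate_read_families(cfg)
  pile <- build_pileup(call_consensus_reads(group_reads_by_umi(sim$reads)),
                       panel)
  si <- interrogate_site(pile, list(chrom = "chrT", pos = 1001L,
                                    ref = "A", alt = "delCA"))
  expect_equal(si$alt_count, sim$truth$n_alt_fragments)
  expect_gt(si$alt_count, 0L)
})

test_that("the coordinate rule needs two reads at two distinct coordinates", {
  expect_true(coordinate_support_rule(make_interrogation(2, 100,
                                                         coords = c(5, 9))))
  expect_false(coordinate_support_rule(make_interrogation(3, 100,
                                                          coords = c(5, 5, 5))))
  expect_false(coordinate_support_rule(make_interrogation(1, 100, coords = 5)))
})

test_that("control pooling sums counts over the selected pool", {
  ctrls <- list(make_interrogation(0, 1000), make_interrogation(1, 900),
                make_interrogation(0, 1100))
  pooled <- pool_control_counts(ctrls)
  expect_equal(pooled$alt, 1L)
  expect_equal(pooled$ref, 3000L)
  expect_equal(pooled$pool, "healthy_only")
  # patient plasmas excluded unless requested; mutated patients always out
  pat <- make_interrogation(2, 500); attr(pat, "role") <- "patient"
  mut <- make_interrogation(9, 100); attr(mut, "role") <- "patient"
  attr(mut, "mutated") <- TRUE
  pooled2 <- pool_control_counts(c(ctrls, list(pat, mut)))
  expect_equal(pooled2$alt, 1L)
  pooled3 <- pool_control_counts(c(ctrls, list(pat, mut)),
                                 include_negative_patients = TRUE)
  expect_equal(pooled3$alt, 3L)
  expect_equal(pooled3$ref, 3500L)
  expect_equal(pooled3$pool, "healthy_plus_negative_patients")
  # single control is the identity; empty pool errors
  expect_equal(pool_control_counts(ctrls[2])$alt, 1L)
  expect_error(pool_control_counts(list()), "empty")
})

test_that("Fisher rescue p-values match brute-force hypergeometric enumeration", {
  # exhaustive over all small tables
  for (a in 0:4) for (b in 0:4) for (c_ in 0:4) for (d in 0:4) {
    if (a + b == 0 || c_ + d == 0 || a + c_ == 0) next
    res <- fisher_rescue_test(make_interrogation(a, b),
                              list(alt = c_, ref = d))
    expect_equal(res$p_value, enum_fisher_p(a, b, c_, d, "greater"),
                 tolerance = 1e-10,
                 label = sprintf("table %d,%d,%d,%d", a, b, c_, d))
  }
  # random tables with margins up to 50, both sidednesses
  set.seed(99)
  for (i in 1:200) {
    a <- sample(0:25, 1); b <- sample(0:25, 1)
    c_ <- sample(0:25, 1); d <- sample(0:25, 1)
    if (a + b == 0 || c_ + d == 0 || a + c_ == 0) next
    for (sided in c("greater", "two.sided")) {
      res <- fisher_rescue_test(make_interrogation(a, b),
                                list(alt = c_, ref = d), sided = sided)
      expect_equal(res$p_value, enum_fisher_p(a, b, c_, d, sided),
                   tolerance = 1e-8,
                   label = sprintf("%s %d,%d,%d,%d", sided, a, b, c_, d))
    }
  }
})

test_that("rescue decisions combine significance with coordinate support", {
  # strong enrichment at distinct coordinates is rescued
  strong <- fisher_rescue_test(make_interrogation(5, 9995, coords = 1:5),
                               list(alt = 0, ref = 200000))
  expect_lt(strong$p_value, 1e-6)
  expect_true(strong$passed)
  # zero alt evidence: p = 1, not rescued
  none <- fisher_rescue_test(make_interrogation(0, 10000, coords = integer(0)),
                             list(alt = 0, ref = 50000))
  expect_equal(none$p_value, 1)
  expect_false(none$passed)
  # matched proportions are not significant
  same <- fisher_rescue_test(make_interrogation(2, 9998, coords = 1:2),
                             list(alt = 400, ref = 1999600))
  expect_gt(same$p_value, 0.5)
  expect_false(same$passed)
  # significance without coordinate support is not rescued
  onecoord <- fisher_rescue_test(make_interrogation(5, 9995,
                                                    coords = rep(7L, 5)),
                                 list(alt = 0, ref = 200000))
  expect_lt(onecoord$p_value, 1e-6)
  expect_false(onecoord$passed)
  # a p-value just above alpha (e.g. the 0.053 case) is not rescued
  p_target <- enum_fisher_p(2, 998, 1, 4999, "greater")
  res <- fisher_rescue_test(make_interrogation(2, 998, coords = 1:2),
                            list(alt = 1, ref = 4999))
  expect_equal(res$p_value, p_target)
  expect_identical(res$passed, res$p_value < 0.05)
})

test_that("p-values are monotone in alt count and in clean-control pooling", {
  prev <- 1
  for (a in 0:6) {
    p <- fisher_rescue_test(make_interrogation(a, 1000 - a),
                            list(alt = 2, ref = 5000))$p_value
    expect_lte(p, prev + 1e-12)
    prev <- p
  }
  # adding mutation-free controls never increases the p-value
  p1 <- fisher_rescue_test(make_interrogation(3, 997),
                           list(alt = 1, ref = 2000))$p_value
  p2 <- fisher_rescue_test(make_interrogation(3, 997),
                           list(alt = 1, ref = 6000))$p_value
  expect_lte(p2, p1 + 1e-12)
})

test_that("rescue accounting on the concordance fixture finds 5 rescues in 4 patients", {
  acc <- rescue_accounting(ctdna_fixture("table2"))
  expect_equal(acc$n_rescued, 5L)
  expect_equal(acc$n_patients, 4L)
  expect_setequal(unique(acc$rows$sample), c("002MS", "015MS", "079MS",
                                             "107MS"))
  expect_setequal(unique(acc$rows$gene), c("TP53", "GATA3"))
})

test_that("rescue pass over simulated data recovers a shed caller-missed variant", {
  panel <- toy_panel(0L, 60000L)
  tumor_variants <- data.frame(chrom = "chrT", pos = 10001L, ref = "A",
                               alt = "T", gene = "SYNTH",
                               stringsAsFactors = FALSE)
  sites <- data.frame(chrom = "chrT", pos = 10000L, ref = "A", alt = "T",
                      vaf = 3e-3, stringsAsFactors = FALSE)
  mk <- function(seed, vaf) {
    s <- sites; s$vaf <- vaf
    cfg <- sim_config(seed = seed, panel = panel, sites = s,
                      consensus_depth = 2000L, read_length = 10L,
                      family_lambda = 2)
    sim <- simulate_read_families(cfg)
    build_pileup(call_consensus_reads(group_reads_by_umi(sim$reads)), panel)
  }
  plasma <- mk(21, 3e-3)
  ctrls <- list(c1 = mk(22, 0), c2 = mk(23, 0), c3 = mk(24, 0))
  rep <- rescue_pass(tumor_variants, plasma, ctrls, panel = panel)
  expect_equal(nrow(rep), 1L)
  expect_true(rep$passed)
  expect_lt(rep$p_value, 0.05)
  expect_equal(rep$pool, "healthy_only")
  # empty tumor set -> empty result
  expect_equal(nrow(rescue_pass(tumor_variants[0, ], plasma, ctrls)), 0L)
})

test_that("the rescue screen holds its nominal type-I level under the null", {
  # site-level null: sample and pooled controls share the same
  # post-consensus error rate; the one-sided Fisher screen at alpha 0.05
  # must reject at most 5% (+3 SE) of sites
  set.seed(123)
  n_sites <- 2000L
  e <- 5e-4                 # residual post-consensus error rate
  alpha <- 0.05
  rej <- logical(n_sites)
  for (i in seq_len(n_sites)) {
    a <- stats::rbinom(1, 1000, e)
    c_ <- stats::rbinom(1, 3000, e)
    res <- fisher_rescue_test(
      make_interrogation(a, 1000 - a, coords = seq_len(max(a, 1))),
      list(alt = c_, ref = 3000 - c_), alpha = alpha)
    rej[i] <- res$p_value < alpha
  }
  bound <- alpha + 3 * sqrt(alpha * (1 - alpha) / n_sites)
  expect_lte(mean(rej), bound)
})
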