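## Cohort bookkeeping and statistics: tumor-plasma concordance, diagnostic
## performance with exact binomial confidence intervals, gene spectra,
## per-stage sensitivity and clinicopathological association screens.

#' Tumor-plasma concordance summary
#'
#' Counts, over a tumor/plasma concordance table, how many tumor
#' mutations were rediscovered in plasma by the automatic caller and
#' overall (caller or manual rescue).
#'
#' @param table2 A `data.frame` with logical `caller_detected` and
#'   `manual_detected` columns (the `table2` dialect).
#' @return A list: `n` (tumor mutations), `caller_detected`,
#'   `overall_detected`, `caller_fraction`, `overall_fraction`.
#'   Fractions are `NA` (flagged by a warning) on empty input.
#' @examples
#' concordance_summary(ctdna_fixture("table2"))  # 13/61 caller, 18/61 overall
#' @export
concordance_summary <- function(table2) {
  stopifnot(all(c("caller_detected", "manual_detected") %in% names(table2)))
  n <- nrow(table2)
  caller <- sum(table2$caller_detected)
  overall <- sum(table2$caller_detected | table2$manual_detected)
  if (n == 0L) {
    warning("empty concordance table: fractions undefined")
    return(list(n = 0L, caller_detected = 0L, overall_detected = 0L,
                caller_fraction = NA_real_, overall_fraction = NA_real_))
  }
  list(n = n, caller_detected = caller, overall_detected = overall,
       caller_fraction = caller / n, overall_fraction = overall / n)
}

#' Tumor mutation yield
#'
#' Fraction of sequenced tumors in which at least one somatic mutation
#' survived the stringent tumor filter.
#'
#' @param table2 The tumor mutation table (`sample` column).
#' @param n_tumors Number of tumors sequenced (default 71).
#' @return A list: `n_mutated`, `n_tumors`, `fraction`.
#' @export
tumor_yield <- function(table2, n_tumors = 71L) {
  n_mut <- length(unique(table2$sample))
  if (n_mut > n_tumors) stop("more mutated samples than sequenced tumors")
  list(n_mutated = n_mut, n_tumors = n_tumors, fraction = n_mut / n_tumors)
}

#' Tumor-naive positivity bookkeeping
#'
#' Combines the tumor-informed concordance table and the plasma-only
#' table into the tumor-naive (plasma positivity) summary: distinct
#' plasma-positive individuals, mutations seen only in plasma, and
#' patients whose plasma carried mutations while their tumor biopsy
#' carried none (rows whose tumor-mutation flag is not affirmative,
#' including the one tumor with no recorded flag, count as
#' plasma-only patients).
#'
#' @param table2,table3 The two detection tables (fixture dialects).
#' @param n_plasma Number of patient plasmas sequenced (default 74).
#' @return A list: `n_positive`, `n_plasma`, `fraction`,
#'   `plasma_only_mutations`, `plasma_only_patients`.
#' @export
naive_positivity <- function(table2, table3, n_plasma = 74L) {
  pos2 <- unique(table2$sample[table2$caller_detected | table2$manual_detected])
  pos3 <- unique(table3$sample)
  positives <- union(pos2, pos3)
  if (length(positives) > n_plasma) {
    stop("more positive samples than sequenced plasmas")
  }
  only <- table3$sample[is.na(table3$any_mutation_in_tumor) |
                          !table3$any_mutation_in_tumor]
  list(
    n_positive = length(positives),
    n_plasma = n_plasma,
    fraction = length(positives) / n_plasma,
    plasma_only_mutations = nrow(table3),
    plasma_only_patients = length(unique(only))
  )
}

#' Plasma-detected variant set
#'
#' All plasma-detected mutations across both pipeline modes: concordant
#' tumor mutations rediscovered in plasma (caller or rescue) plus the
#' plasma-only detections.
#'
#' @param table2,table3 The two detection tables.
#' @return A `data.frame`: `sample`, `gene`, `nt_change`, `vaf`
#'   (plasma fraction), `source` (`tumor_informed`/`plasma_only`).
#' @export
plasma_detected_variants <- function(table2, table3) {
  det2 <- table2[table2$caller_detected | table2$manual_detected, ,
                 drop = FALSE]
  rbind(
    data.frame(sample = det2$sample, gene = det2$gene,
               nt_change = det2$nt_change, vaf = det2$plasma_vaf,
               source = "tumor_informed", stringsAsFactors = FALSE),
    data.frame(sample = table3$sample, gene = table3$gene,
               nt_change = table3$nt_change, vaf = table3$vaf,
               source = "plasma_only", stringsAsFactors = FALSE)
  )
}

#' Per-gene mutation spectrum
#'
#' @param variants A `data.frame` with a `gene` column.
#' @return A `data.frame` (`gene`, `n`, `fraction`) in descending count
#'   order; fractions sum to 1. Empty input yields an empty table.
#' @export
gene_spectrum <- function(variants) {
  stopifnot("gene" %in% names(variants))
  if (!nrow(variants)) {
    return(data.frame(gene = character(), n = integer(), fraction = numeric(),
                      stringsAsFactors = FALSE))
  }
  tab <- sort(table(variants$gene), decreasing = TRUE)
  data.frame(gene = names(tab), n = as.integer(tab),
             fraction = as.integer(tab) / nrow(variants),
             stringsAsFactors = FALSE)
}

#' Confusion counts
#'
#' @param tp,fn,fp,tn Non-negative integers; `tp + fn` is the number of
#'   cases and `fp + tn` the number of controls.
#' @return A list of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  vals <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(is.na(vals)) || any(vals < 0)) {
    stop("confusion counts must be non-negative")
  }
  structure(list(tp = as.integer(tp), fn = as.integer(fn),
                 fp = as.integer(fp), tn = as.integer(tn)),
            class = "confusion_counts")
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Computed from beta-distribution quantiles: the lower bound is the
#' `alpha/2` quantile of `Beta(k, n - k + 1)` (0 when `k = 0`), the
#' upper the `1 - alpha/2` quantile of `Beta(k + 1, n - k)` (1 when
#' `k = n`). The interval always contains `k/n`.
#'
#' @param k Successes, `0 <= k <= n`.
#' @param n Trials, `n >= 1`.
#' @param level Confidence level (default 0.95).
#' @return `c(lower, upper)` as fractions.
#' @examples
#' clopper_pearson_ci(19, 22)  # c(0.6509, 0.9709) to 4 decimals
#' @export
clopper_pearson_ci <- function(k, n, level = 0.95) {
  if (any(is.na(c(k, n))) || n < 1L || k < 0L || k > n) {
    stop("require 0 <= k <= n with n >= 1")
  }
  alpha <- 1 - level
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Diagnostic metrics with exact confidence intervals
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)` and positive
#' predictive value `tp/(tp+fp)`, each with an exact Clopper-Pearson
#' interval. A metric with a zero denominator is reported as `NA`
#' rather than failing.
#'
#' @param counts A [confusion_counts()] object.
#' @param ci_level Confidence level (default 0.95).
#' @return A `data.frame`: `metric`, `estimate`, `lower`, `upper`, `k`,
#'   `n` (all proportions as fractions).
#' @export
diagnostic_metrics <- function(counts, ci_level = 0.95) {
  stopifnot(inherits(counts, "confusion_counts"))
  one <- function(metric, k, n) {
    if (n == 0L) {
      warning(metric, " undefined: zero denominator")
      return(data.frame(metric = metric, estimate = NA_real_,
                        lower = NA_real_, upper = NA_real_, k = k, n = n,
                        stringsAsFactors = FALSE))
    }
    ci <- clopper_pearson_ci(k, n, ci_level)
    data.frame(metric = metric, estimate = k / n,
               lower = ci[["lower"]], upper = ci[["upper"]], k = k, n = n,
               stringsAsFactors = FALSE)
  }
  rbind(
    one("sensitivity", counts$tp, counts$tp + counts$fn),
    one("specificity", counts$tn, counts$tn + counts$fp),
    one("ppv", counts$tp, counts$tp + counts$fp)
  )
}

#' Per-sample positivity table and confusion counts
#'
#' Collapses passing detections to per-sample ctDNA positivity with the
#' summary covariates used in cohort analyses (mutation count, median
#' VAF among detected mutations, TP53 involvement), and tallies the
#' confusion counts against sample roles.
#'
#' @param detections A detection `data.frame` with `sample_id`, `passed`,
#'   and optionally `vaf` and `gene`.
#' @param sheet A sample sheet (see [read_sample_sheet()]); every
#'   detection's sample must appear in it.
#' @return A list: `cohort` (per-sample table with `ctdna_positive`,
#'   `n_plasma_mutations`, `median_vaf`, `tp53_in_plasma`, and any sheet
#'   covariates) and `confusion` ([confusion_counts()]).
#' @export
positivity_table <- function(detections, sheet) {
  sheet <- validate_sample_sheet(sheet)
  plasma <- sheet[sheet$role %in% c("plasma_case", "plasma_control"), ,
                  drop = FALSE]
  if (nrow(detections)) {
    unknown <- setdiff(unique(detections$sample_id), sheet$sample_id)
    if (length(unknown)) {
      stop("detections reference samples absent from the sheet: ",
           paste(unknown, collapse = ", "))
    }
  }
  per_sample <- function(s) {
    d <- detections[nrow(detections) > 0 & detections$sample_id == s &
                      detections$passed, , drop = FALSE]
    vafs <- if ("vaf" %in% names(d)) d$vaf else numeric(0)
    genes <- if ("gene" %in% names(d)) d$gene else character(0)
    data.frame(
      sample_id = s,
      ctdna_positive = nrow(d) > 0L,
      n_plasma_mutations = nrow(d),
      median_vaf = if (nrow(d)) stats::median(vafs, na.rm = TRUE) else NA_real_,
      tp53_in_plasma = any(genes == "TP53", na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  }
  cohort <- do.call(rbind, lapply(plasma$sample_id, per_sample))
  cohort <- merge(cohort, plasma, by = "sample_id", sort = FALSE)
  is_case <- cohort$role == "plasma_case"
  counts <- confusion_counts(
    tp = sum(cohort$ctdna_positive & is_case),
    fn = sum(!cohort$ctdna_positive & is_case),
    fp = sum(cohort$ctdna_positive & !is_case),
    tn = sum(!cohort$ctdna_positive & !is_case)
  )
  list(cohort = cohort, confusion = counts)
}

#' Per-stage sensitivity
#'
#' Sensitivity (fraction of ctDNA-positive cases) within each disease
#' stage group, with exact Clopper-Pearson intervals. Groups with no
#' cases are skipped with a warning.
#'
#' @param cohort A per-sample cohort table (cases only are used:
#'   `role == "plasma_case"` when a role column is present) with
#'   logical `ctdna_positive` and the stage covariate.
#' @param stage_col Name of the stage column (default `"stage"`).
#' @param ci_level Confidence level.
#' @return A `data.frame`: `stage`, `k`, `n`, `sensitivity`, `lower`,
#'   `upper`.
#' @export
per_stage_sensitivity <- function(cohort, stage_col = "stage",
                                  ci_level = 0.95) {
  if (!stage_col %in% names(cohort)) {
    stop("stage covariate '", stage_col, "' absent from cohort table")
  }
  cases <- if ("role" %in% names(cohort)) {
    cohort[cohort$role == "plasma_case", , drop = FALSE]
  } else {
    cohort
  }
  stages <- sort(unique(cases[[stage_col]]))
  rows <- lapply(stages, function(s) {
    g <- cases[!is.na(cases[[stage_col]]) & cases[[stage_col]] == s, ,
               drop = FALSE]
    if (!nrow(g)) {
      warning("stage group ", s, " has no cases; skipped")
      return(NULL)
    }
    k <- sum(g$ctdna_positive)
    n <- nrow(g)
    ci <- clopper_pearson_ci(k, n, ci_level)
    data.frame(stage = s, k = k, n = n, sensitivity = k / n,
               lower = ci[["lower"]], upper = ci[["upper"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

expected_cell_min <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  min(e)
}

#' Clinicopathological association screen
#'
#' Tests each plasma-derived metric against each covariate. Test choice:
#' categorical x categorical uses Fisher's exact test when any expected
#' cell count is below 5, the chi-square test otherwise; a continuous
#' metric against a 2-level covariate uses the Wilcoxon rank-sum test
#' (Kruskal-Wallis for more levels). Constant metrics or covariates are
#' skipped with a reason. No multiplicity correction enters the decision
#' column; Benjamini-Hochberg adjusted p-values are supplementary.
#'
#' @param cohort A per-sample cohort table.
#' @param metrics Metric column names (default the four plasma metrics:
#'   positivity, mutation count, median VAF, TP53 involvement).
#' @param covariates Covariate column names.
#' @param alpha Significance threshold for the `significant` column
#'   (default 0.05).
#' @return A `data.frame`: `metric`, `covariate`, `test`, `p_value`,
#'   `p_bh`, `direction`, `significant`, `skipped_reason`.
#' @export
association_screen <- function(cohort,
                               metrics = c("ctdna_positive",
                                           "n_plasma_mutations",
                                           "median_vaf", "tp53_in_plasma"),
                               covariates, alpha = 0.05) {
  metrics <- intersect(metrics, names(cohort))
  covariates <- intersect(covariates, names(cohort))
  if (!length(metrics) || !length(covariates)) {
    stop("no usable metric/covariate columns in cohort table")
  }
  one <- function(m, v) {
    base <- data.frame(metric = m, covariate = v, test = NA_character_,
                       p_value = NA_real_, direction = NA_real_,
                       skipped_reason = NA_character_,
                       stringsAsFactors = FALSE)
    x <- cohort[[m]]; y <- cohort[[v]]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
      base$skipped_reason <- "constant metric or covariate"
      return(base)
    }
    metric_categorical <- is.logical(x) || is.character(x) || is.factor(x)
    if (metric_categorical) {
      tab <- table(x, y)
      if (expected_cell_min(tab) < 5) {
        ft <- stats::fisher.test(tab)
        base$test <- "fisher"
        base$p_value <- ft$p.value
        base$direction <- if (all(dim(tab) == 2L)) {
          log((tab[2, 2] + 0.5) * (tab[1, 1] + 0.5) /
                ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5)))
        } else NA_real_
      } else {
        ct <- stats::chisq.test(tab)
        base$test <- "chi_square"
        base$p_value <- ct$p.value
        base$direction <- NA_real_
      }
    } else {
      yf <- factor(y)
      if (nlevels(yf) == 2L) {
        wt <- stats::wilcox.test(x ~ yf, exact = FALSE)
        base$test <- "wilcoxon"
        base$p_value <- wt$p.value
        meds <- tapply(x, yf, stats::median)
        base$direction <- unname(meds[2L] - meds[1L])
      } else {
        kt <- stats::kruskal.test(x, yf)
        base$test <- "kruskal_wallis"
        base$p_value <- kt$p.value
        base$direction <- NA_real_
      }
    }
    base
  }
  grid <- expand.grid(metric = metrics, covariate = covariates,
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, Map(one, grid$metric, grid$covariate))
  out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  rownames(out) <- NULL
  out[, c("metric", "covariate", "test", "p_value", "p_bh", "direction",
          "significant", "skipped_reason")]
}
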