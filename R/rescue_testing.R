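## The exploratory "rescue" path: tumor-known sites missed by the caller
## are interrogated directly in the plasma pileup, required to show
## variant reads at two or more distinct genomic coordinates, and accepted
## via a Fisher exact test of their allele counts against the pooled
## counts of control plasmas (the programmatic equivalent of manual
## inspection in a genome browser).

#' Interrogate a variant site in a consensus pileup
#'
#' Returns the variant- and wild-type-supporting consensus fragment
#' counts at the site, plus the distinct fragment start coordinates
#' carrying the variant allele.
#'
#' @param pileup A [build_pileup()] result (plasma, family-size minimum 1).
#' @param variant A list or one-row `data.frame` with `chrom`, `pos`
#'   (1-based), `ref`, `alt` (base or indel/splice allele token).
#' @param panel Optional panel regions; when supplied, a site outside
#'   the panel is an error.
#' @return A list of class `site_interrogation`: `chrom`, `pos`, `ref`,
#'   `alt`, `alt_count`, `ref_count`, `depth`, `coords` (integer vector
#'   of distinct supporting fragment starts).
#' @export
interrogate_site <- function(pileup, variant, panel = NULL) {
  stopifnot(inherits(pileup, "pileup"))
  v <- as.list(variant)
  pos0 <- as.integer(v$pos) - 1L
  if (!is.null(panel)) {
    if (is.na(panel_region_index(v$chrom, pos0, panel))) {
      stop("site ", v$chrom, ":", v$pos, " is outside the capture panel")
    }
  }
  al <- pileup$alleles
  sel <- al$chrom == v$chrom & al$pos == pos0
  alt_count <- sum(al$count[sel & al$allele == v$alt])
  ref_count <- sum(al$count[sel & al$allele == v$ref])
  depth <- sum(al$count[sel])
  sup <- pileup$support
  j <- which(sup$chrom == v$chrom & sup$pos == pos0 & sup$allele == v$alt)
  coords <- if (length(j)) parse_coords(sup$coords[j[1L]]) else integer(0)
  structure(list(chrom = v$chrom, pos = as.integer(v$pos), ref = v$ref,
                 alt = v$alt, alt_count = as.integer(alt_count),
                 ref_count = as.integer(ref_count),
                 depth = as.integer(depth), coords = coords),
            class = "site_interrogation")
}

#' Coordinate support rule for rescued variants
#'
#' A variant passes to the statistical step only if it is found in at
#' least two reads aligned at at least two different genomic
#' coordinates.
#'
#' @param interrogation A [interrogate_site()] result.
#' @return Logical.
#' @export
coordinate_support_rule <- function(interrogation) {
  interrogation$alt_count >= 2L &&
    length(unique(interrogation$coords)) >= 2L
}

#' Pool control allele counts at a site
#'
#' Element-wise sums of variant and wild-type counts over the selected
#' control pool: healthy plasma controls always; plasma samples from
#' patients negative for the specific mutation optionally (the mixed
#' pool; the healthy-only pool is the default elsewhere because patient
#' plasmas add background noise).
#'
#' @param interrogations A list of [interrogate_site()] results, each
#'   optionally carrying attributes `role` (`"healthy"` or `"patient"`)
#'   and `mutated` (patients positive for this mutation are always
#'   excluded).
#' @param include_negative_patients Include mutation-negative patient
#'   plasmas in the pool (default `FALSE`).
#' @return A list: `alt`, `ref`, `n_pooled`, `pool`
#'   (`"healthy_only"` or `"healthy_plus_negative_patients"`).
#' @export
pool_control_counts <- function(interrogations,
                                include_negative_patients = FALSE) {
  if (!length(interrogations)) stop("empty control pool")
  keep <- vapply(interrogations, function(x) {
    role <- attr(x, "role") %||% "healthy"
    mutated <- isTRUE(attr(x, "mutated"))
    if (mutated) return(FALSE)
    role == "healthy" || include_negative_patients
  }, logical(1))
  if (!any(keep)) stop("empty control pool after role selection")
  sel <- interrogations[keep]
  list(
    alt = sum(vapply(sel, `[[`, 0L, "alt_count")),
    ref = sum(vapply(sel, `[[`, 0L, "ref_count")),
    n_pooled = length(sel),
    pool = if (include_negative_patients) "healthy_plus_negative_patients"
           else "healthy_only"
  )
}

#' Fisher exact rescue test against pooled controls
#'
#' Tests the 2x2 table (sample alt, sample ref; pooled control alt,
#' pooled control ref) with Fisher's exact (hypergeometric) test. The
#' default alternative is one-sided enrichment of the variant allele in
#' the case sample. A variant is rescued iff `p < alpha` AND the
#' coordinate support rule holds.
#'
#' @param sample A [interrogate_site()] result for the case plasma.
#' @param pooled_controls A [pool_control_counts()] result (or a list
#'   with `alt` and `ref`).
#' @param alpha Significance threshold (default 0.05).
#' @param sided `"greater"` (one-sided, default) or `"two.sided"`.
#' @return A list of class `rescue_result`: `p_value`, `passed`,
#'   `coord_ok`, `alt`, `ref`, `pooled_alt`, `pooled_ref`, `pool`.
#' @export
fisher_rescue_test <- function(sample, pooled_controls, alpha = 0.05,
                               sided = c("greater", "two.sided")) {
  sided <- match.arg(sided)
  a <- sample$alt_count; b <- sample$ref_count
  c_ <- pooled_controls$alt; d <- pooled_controls$ref
  stopifnot(a >= 0, b >= 0, c_ >= 0, d >= 0)
  if (a + b + c_ + d == 0 || a + c_ == 0) {
    p <- 1                                     # no variant evidence anywhere
  } else {
    tab <- matrix(c(a, c_, b, d), nrow = 2L,
                  dimnames = list(c("sample", "controls"), c("alt", "ref")))
    p <- stats::fisher.test(tab, alternative = sided)$p.value
  }
  coord_ok <- coordinate_support_rule(sample)
  structure(list(
    p_value = p,
    passed = (p < alpha) && coord_ok,
    coord_ok = coord_ok,
    alt = a, ref = b, pooled_alt = c_, pooled_ref = d,
    pool = pooled_controls$pool %||% NA_character_,
    alpha = alpha, sided = sided
  ), class = "rescue_result")
}

#' @export
print.rescue_result <- function(x, ...) {
  cat(sprintf("rescue: alt %d/%d vs pooled %d/%d, p = %.4g, %s\n",
              x$alt, x$alt + x$ref, x$pooled_alt,
              x$pooled_alt + x$pooled_ref, x$p_value,
              if (x$passed) "rescued" else "not rescued"))
  invisible(x)
}

#' Rescue pass over caller-missed tumor variants
#'
#' For each tumor-known variant missed by the caller path, interrogates
#' the plasma pileup, applies the coordinate support rule, pools control
#' counts and runs the Fisher rescue test. No multiple-testing correction
#' is applied to the decision; a Benjamini-Hochberg column is emitted as
#' supplementary output only.
#'
#' @param tumor_variants A `data.frame` of variants (`chrom`, `pos`
#'   1-based, `ref`, `alt`) from the paired tumor's stringent set.
#' @param plasma_pileup The case plasma [build_pileup()] (family-size
#'   minimum 1).
#' @param control_pileups A named list of control [build_pileup()]s;
#'   names are sample ids. Optional attribute `role` per element
#'   (`"healthy"`/`"patient"`).
#' @param panel Optional panel for site validation.
#' @param include_negative_patients Pool choice, see
#'   [pool_control_counts()].
#' @param alpha,sided See [fisher_rescue_test()].
#' @return A `data.frame`, one row per interrogated variant, in input
#'   order: counts, `p_value`, `p_bh`, `coord_ok`, `passed`, `pool`.
#' @export
rescue_pass <- function(tumor_variants, plasma_pileup, control_pileups,
                        panel = NULL, include_negative_patients = FALSE,
                        alpha = 0.05, sided = c("greater", "two.sided")) {
  sided <- match.arg(sided)
  if (!nrow(tumor_variants)) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), alt_count = integer(),
                      ref_count = integer(), vaf = numeric(),
                      pooled_alt = integer(), pooled_ref = integer(),
                      p_value = numeric(), p_bh = numeric(),
                      coord_ok = logical(), passed = logical(),
                      pool = character(), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(tumor_variants)), function(i) {
    v <- tumor_variants[i, , drop = FALSE]
    si <- interrogate_site(plasma_pileup, v, panel = panel)
    ctrl <- lapply(control_pileups, function(pu) {
      ci <- interrogate_site(pu, v, panel = panel)
      attr(ci, "role") <- attr(pu, "role") %||% "healthy"
      ci
    })
    pooled <- pool_control_counts(ctrl, include_negative_patients)
    res <- fisher_rescue_test(si, pooled, alpha = alpha, sided = sided)
    data.frame(
      chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
      alt_count = si$alt_count, ref_count = si$ref_count,
      vaf = if (si$depth > 0) si$alt_count / si$depth else NA_real_,
      pooled_alt = res$pooled_alt, pooled_ref = res$pooled_ref,
      p_value = res$p_value, coord_ok = res$coord_ok,
      passed = res$passed, pool = pooled$pool,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out[, c("chrom", "pos", "ref", "alt", "alt_count", "ref_count", "vaf",
          "pooled_alt", "pooled_ref", "p_value", "p_bh", "coord_ok",
          "passed", "pool")]
}

#' Rescue accounting on a concordance table
#'
#' Tallies the manual-inspection rescue path on a tumor/plasma
#' concordance table (rows carrying caller and manual detection flags):
#' how many caller-missed mutations were rescued and in how many
#' distinct patients.
#'
#' @param table2 A `data.frame` in the `table2` dialect of
#'   [read_variant_table()].
#' @return A list: `n_rescued`, `n_patients`, `rows` (the rescued rows).
#' @export
rescue_accounting <- function(table2) {
  stopifnot(all(c("sample", "caller_detected", "manual_detected") %in%
                  names(table2)))
  rescued <- table2[!table2$caller_detected & table2$manual_detected, ,
                    drop = FALSE]
  list(n_rescued = nrow(rescued),
       n_patients = length(unique(rescued$sample)),
       rows = rescued)
}
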