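## Pileup construction over the capture panel, VAF computation, the
## frequency-based candidate caller (standing in for an external somatic
## caller: externally produced VCFs are accepted interchangeably by the
## downstream filters), and the per-region coverage QC rule.

## Vectorized panel membership for 0-based positions against 0-based
## half-open regions. Returns the region row index, or NA outside.
panel_region_index <- function(chrom, pos, panel) {
  out <- rep(NA_integer_, length(pos))
  for (cr in unique(chrom)) {
    rows <- which(panel$chrom == cr)
    if (!length(rows)) next
    o <- order(panel$start[rows])
    rows <- rows[o]
    starts <- panel$start[rows]
    ends <- panel$end[rows]
    sel <- which(chrom == cr)
    i <- findInterval(pos[sel], starts)
    inside <- i >= 1L & pos[sel] < ends[pmax(i, 1L)]
    out[sel[inside]] <- rows[i[inside]]
  }
  out
}

#' Build an allele-resolved pileup over panel regions
#'
#' Expands consensus reads to per-position allele counts, restricted to
#' the capture panel. `N` bases are excluded from all counts. Each
#' fragment contributes at most one count per position (duplicate
#' per-fragment covers, e.g. unclipped mate overlaps, are collapsed to
#' the higher-quality base; run [clip_overlap()] first to resolve
#' disagreements explicitly). Fragments carrying an indel/splice allele
#' token (`allele_tag` at `tag_pos`) contribute that token, rather than
#' their base, at the tagged position.
#'
#' @param consensus Consensus reads from [call_consensus_reads()]
#'   (optionally filtered and clipped).
#' @param panel Panel regions from [read_panel_bed()].
#' @param ref Reference alleles: a single base applied everywhere
#'   (synthetic references), or a `data.frame` with `chrom`, `pos`
#'   (0-based) and `ref`.
#' @return An object of class `pileup`: a list with
#'   * `sites`: per-position `chrom`, `pos` (0-based), `ref`, `depth`;
#'   * `alleles`: per-(position, allele) fragment `count` and `is_ref`;
#'   * `support`: for each non-reference allele, the number (`n_coords`)
#'     and comma-joined set (`coords`) of distinct supporting fragment
#'     start coordinates.
#' @export
build_pileup <- function(consensus, panel, ref = "A") {
  if (!nrow(panel)) stop("panel must contain at least one region")
  empty <- function() {
    structure(list(
      sites = data.frame(chrom = character(), pos = integer(),
                         ref = character(), depth = integer()),
      alleles = data.frame(chrom = character(), pos = integer(),
                           allele = character(), count = integer(),
                           is_ref = logical()),
      support = data.frame(chrom = character(), pos = integer(),
                           allele = character(), n_coords = integer(),
                           coords = character())
    ), class = "pileup")
  }
  if (!nrow(consensus)) return(empty())
  dt <- data.table::as.data.table(consensus)
  if (!"allele_tag" %in% names(dt)) dt[, allele_tag := NA_character_]
  if (!"tag_pos" %in% names(dt)) dt[, tag_pos := NA_integer_]
  lens <- nchar(dt$bases)
  long <- data.table::data.table(
    family_id = rep(dt$family_id, lens),
    chrom = rep(dt$chrom, lens),
    frag_start = rep(dt$frag_start, lens),
    refpos = rep(dt$pos, lens) + (sequence(lens) - 1L),
    base = unlist(strsplit(dt$bases, "", fixed = TRUE), use.names = FALSE),
    qual = utf8ToInt(paste(dt$quals, collapse = "")) - 33L,
    allele_tag = rep(dt$allele_tag, lens),
    tag_pos = rep(dt$tag_pos, lens)
  )
  long[!is.na(allele_tag) & refpos == tag_pos, base := allele_tag]
  long <- long[base != "N"]
  if (!nrow(long)) return(empty())
  long <- long[!is.na(panel_region_index(chrom, refpos, panel))]
  if (!nrow(long)) return(empty())
  ## one count per fragment per position: keep the best-quality cover
  data.table::setorder(long, chrom, refpos, family_id, -qual)
  long <- unique(long, by = c("chrom", "refpos", "family_id"))

  alleles <- long[, .(count = .N), by = .(chrom, pos = refpos, allele = base)]
  if (is.character(ref) && length(ref) == 1L) {
    alleles[, ref_allele := ref]
  } else {
    refdt <- data.table::as.data.table(ref)
    stopifnot(all(c("chrom", "pos", "ref") %in% names(refdt)))
    alleles[refdt, ref_allele := i.ref, on = c("chrom", "pos")]
    alleles[is.na(ref_allele), ref_allele := "N"]
  }
  alleles[, is_ref := allele == ref_allele]
  sites <- alleles[, .(ref = ref_allele[1L], depth = sum(count)),
                   by = .(chrom, pos)]
  sup <- long[, .(allele = base, frag_start), by = .(chrom, pos = refpos)]
  sup <- merge(sup, alleles[is_ref == FALSE, .(chrom, pos, allele)],
               by = c("chrom", "pos", "allele"))
  support <- if (nrow(sup)) {
    sup[, .(n_coords = data.table::uniqueN(frag_start),
            coords = paste(sort(unique(frag_start)), collapse = ",")),
        by = .(chrom, pos, allele)]
  } else {
    data.table::data.table(chrom = character(), pos = integer(),
                           allele = character(), n_coords = integer(),
                           coords = character())
  }
  data.table::setorder(sites, chrom, pos)
  data.table::setorder(alleles, chrom, pos, allele)
  data.table::setorder(support, chrom, pos, allele)
  structure(list(
    sites = as.data.frame(sites),
    alleles = as.data.frame(alleles[, .(chrom, pos, allele, count, is_ref)]),
    support = as.data.frame(support)
  ), class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat("pileup over", nrow(x$sites), "panel positions;",
      sum(!x$alleles$is_ref), "non-reference alleles observed\n")
  invisible(x)
}

#' Compute a variant allele frequency
#'
#' `alt_count / depth`, as a fraction. Zero depth yields `NA` (an explicit
#' undefined marker) with a warning, never a silent `0/0`.
#'
#' @param alt_count Non-negative count(s) of variant-supporting fragments.
#' @param depth Total fragment depth(s), `depth >= alt_count`.
#' @return Numeric VAF fraction(s) in `[0, 1]`, `NA` where depth is 0.
#' @examples
#' compute_vaf(3, 10003)   # 0.0003 = 0.03%: 3 mutant molecules in 10,000 wild-type
#' @export
compute_vaf <- function(alt_count, depth) {
  alt_count <- as.numeric(alt_count)
  depth <- as.numeric(depth)
  if (any(alt_count < 0, na.rm = TRUE)) stop("alt_count must be >= 0")
  if (any(alt_count > depth, na.rm = TRUE)) {
    stop("alt_count exceeds depth")
  }
  out <- ifelse(depth == 0, NA_real_, alt_count / depth)
  if (any(depth == 0, na.rm = TRUE)) {
    warning("VAF undefined at zero depth; returning NA")
  }
  out
}

#' Call candidate variants from a pileup
#'
#' A frequency-based candidate caller: one candidate per (site,
#' non-reference allele) supported by at least `min_alt_fragments`
#' consensus fragments, in deterministic `(chrom, pos, alt)` order.
#' Downstream stringent filters are caller-agnostic, so externally
#' produced VCFs can be used instead.
#'
#' @param pileup A [build_pileup()] result.
#' @param min_alt_fragments Minimum supporting consensus fragments
#'   (default 1).
#' @return A `data.frame` of candidates: `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `alt_count`, `depth`, `vaf`, `n_coords`, `coords`.
#' @export
call_candidates <- function(pileup, min_alt_fragments = 1L) {
  stopifnot(inherits(pileup, "pileup"))
  alt <- pileup$alleles[!pileup$alleles$is_ref &
                          pileup$alleles$count >= min_alt_fragments, ,
                        drop = FALSE]
  if (!nrow(alt)) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), alt_count = integer(),
                      depth = integer(), vaf = numeric(),
                      n_coords = integer(), coords = character(),
                      stringsAsFactors = FALSE))
  }
  sites <- pileup$sites
  key_site <- paste(sites$chrom, sites$pos)
  i <- match(paste(alt$chrom, alt$pos), key_site)
  sup <- pileup$support
  j <- match(paste(alt$chrom, alt$pos, alt$allele),
             paste(sup$chrom, sup$pos, sup$allele))
  out <- data.frame(
    chrom = alt$chrom,
    pos = alt$pos + 1L,          # report 1-based
    ref = sites$ref[i],
    alt = alt$allele,
    alt_count = alt$count,
    depth = sites$depth[i],
    vaf = compute_vaf(alt$count, sites$depth[i]),
    n_coords = ifelse(is.na(j), 0L, sup$n_coords[j]),
    coords = ifelse(is.na(j), "", sup$coords[j]),
    stringsAsFactors = FALSE
  )
  out[order(out$chrom, out$pos, out$alt), , drop = FALSE]
}

#' Per-region coverage QC
#'
#' A region is flagged low-coverage iff strictly more than
#' `max_low_fraction` of its bases have consensus depth below
#' `min_depth` (boundary rule: a region with exactly the threshold
#' fraction of low bases passes). Panel bases never covered by any
#' consensus read count as depth 0.
#'
#' @param pileup A [build_pileup()] result.
#' @param panel Panel regions.
#' @param min_depth Depth threshold (default 100).
#' @param max_low_fraction Tolerated fraction of low-depth bases
#'   (default 0.10).
#' @return A list with `regions` (per-region `label`, `n_bases`,
#'   `low_fraction`, `flagged`) and `median_depth` (median per-base depth
#'   over all panel bases).
#' @export
region_coverage_qc <- function(pileup, panel, min_depth = 100L,
                               max_low_fraction = 0.10) {
  stopifnot(inherits(pileup, "pileup"))
  if (!nrow(panel)) stop("panel must contain at least one region")
  sites <- pileup$sites
  ridx <- if (nrow(sites)) {
    panel_region_index(sites$chrom, sites$pos, panel)
  } else {
    integer(0)
  }
  n_bases <- panel$end - panel$start
  n_low <- integer(nrow(panel))
  n_cov <- integer(nrow(panel))
  for (r in seq_len(nrow(panel))) {
    d <- sites$depth[which(ridx == r)]
    n_cov[r] <- length(d)
    n_low[r] <- sum(d < min_depth) + (n_bases[r] - length(d))
  }
  low_fraction <- n_low / n_bases
  regions <- data.frame(
    chrom = panel$chrom, start = panel$start, end = panel$end,
    label = if ("label" %in% names(panel)) panel$label else NA_character_,
    n_bases = n_bases,
    low_fraction = low_fraction,
    flagged = low_fraction > max_low_fraction,   # strict
    stringsAsFactors = FALSE
  )
  covered_depths <- sites$depth[!is.na(ridx)]
  all_depths <- c(covered_depths, rep(0L, sum(n_bases) - length(covered_depths)))
  list(regions = regions, median_depth = stats::median(all_depths))
}
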