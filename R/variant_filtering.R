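## The two stringent filtration modes: tumor-informed reference-set
## construction (VAF threshold + database membership) and plasma
## tumor-naive detection (exonic + COSMIC + TCGA-breast membership +
## duplex read support, with no VAF floor).

#' Annotation flags for a variant
#'
#' @param in_cosmic,in_tcga_bc,in_tcga_all,exonic Logical flags.
#' @param gene Gene symbol (optional).
#' @return A one-row `data.frame` of flags.
#' @export
annotation_flags <- function(in_cosmic = FALSE, in_tcga_bc = FALSE,
                             in_tcga_all = FALSE, exonic = FALSE,
                             gene = NA_character_) {
  stopifnot(is.logical(in_cosmic), is.logical(in_tcga_bc),
            is.logical(in_tcga_all), is.logical(exonic))
  data.frame(gene = gene, in_cosmic = in_cosmic, in_tcga_bc = in_tcga_bc,
             in_tcga_all = in_tcga_all, exonic = exonic,
             stringsAsFactors = FALSE)
}

#' Tumor stringent filter
#'
#' A tumor variant passes iff its VAF strictly exceeds the
#' tissue-specific threshold (0.05 for fresh-frozen, 0.2 for FFPE, whose
#' fixation artifacts inflate low-VAF calls) AND the variant is present
#' in at least one of the COSMIC / TCGA databases.
#'
#' @param vaf Variant allele frequency as a fraction.
#' @param flags [annotation_flags()] for the variant.
#' @param tissue_prep `"fresh_frozen"` or `"FFPE"`; plasma samples use
#'   [plasma_stringent_filter()] instead and are rejected here.
#' @return A list with `passed` (logical) and `fail_reasons`
#'   (character vector, empty when passed).
#' @export
tumor_stringent_filter <- function(vaf, flags, tissue_prep) {
  if (!tissue_prep %in% c("fresh_frozen", "FFPE")) {
    stop("tumor_stringent_filter applies to tumor tissue only ",
         "(tissue_prep 'fresh_frozen' or 'FFPE'), got: ", tissue_prep)
  }
  threshold <- if (tissue_prep == "FFPE") 0.2 else 0.05
  reasons <- character(0)
  if (!(vaf > threshold)) {               # strict >
    reasons <- c(reasons, sprintf("vaf_below_threshold(%g<=%g)", vaf, threshold))
  }
  db_ok <- isTRUE(flags$in_cosmic) || isTRUE(flags$in_tcga_bc) ||
    isTRUE(flags$in_tcga_all)
  if (!db_ok) reasons <- c(reasons, "not_in_databases")
  list(passed = length(reasons) == 0L, fail_reasons = reasons)
}

#' Duplex support check
#'
#' "Duplex configuration" in the operational sense used here: the variant
#' is supported by at least two fragments whose alignments start at
#' different genomic coordinates. Two reads sharing one start coordinate
#' do not qualify.
#'
#' @param supporting_coords Vector (or comma-joined string) of fragment
#'   start coordinates carrying the variant allele.
#' @return `TRUE` iff at least two distinct coordinates are present.
#' @export
duplex_support_check <- function(supporting_coords) {
  coords <- parse_coords(supporting_coords)
  length(unique(coords)) >= 2L
}

parse_coords <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!nzchar(x)) return(integer(0))
    return(as.integer(strsplit(x, ",", fixed = TRUE)[[1L]]))
  }
  x[!is.na(x)]
}

#' Plasma stringent (tumor-naive) filter
#'
#' Applied to candidates from plasma processed at a family-size minimum
#' of 1 with no VAF threshold. A variant is considered shed by a tumor
#' iff it (i) affects an exonic region, (ii) is annotated in both COSMIC
#' and the TCGA breast-cancer set (membership in the pan-cancer TCGA set
#' is recorded, and additionally required when `require_tcga_all =
#' TRUE`), and (iii) has duplex support: variant reads aligned at two or
#' more distinct genomic coordinates. Splice-site variants count as
#' exonic by default (`treat_splice_as_exonic`), since the filtration is
#' meant to keep protein-affecting database variants.
#'
#' @param variant A list or one-row `data.frame` with at least `vaf`;
#'   `chrom`, `pos`, `ref`, `alt`, `class`, `sample_id` are carried
#'   through when present.
#' @param flags [annotation_flags()] for the variant.
#' @param supporting_coords Distinct fragment start coordinates carrying
#'   the variant allele (vector or comma-joined string).
#' @param require_tcga_all Additionally require pan-cancer TCGA
#'   membership (default `FALSE`).
#' @param treat_splice_as_exonic Count `class == "splice"` variants as
#'   satisfying the exonic criterion (default `TRUE`).
#' @return A one-row `data.frame` (a detection result): variant fields,
#'   `vaf`, `method = "caller_stringent"`, `duplex_coord_count`, the
#'   flags, `passed` and `fail_reasons` (semicolon-joined; empty when
#'   passed).
#' @export
plasma_stringent_filter <- function(variant, flags, supporting_coords,
                                    require_tcga_all = FALSE,
                                    treat_splice_as_exonic = TRUE) {
  v <- as.list(variant)
  coords <- parse_coords(supporting_coords)
  reasons <- character(0)
  splice_ok <- treat_splice_as_exonic && identical(v$class, "splice")
  if (!(isTRUE(flags$exonic) || splice_ok)) reasons <- c(reasons, "not_exonic")
  if (!isTRUE(flags$in_cosmic)) reasons <- c(reasons, "not_in_cosmic")
  if (!isTRUE(flags$in_tcga_bc)) reasons <- c(reasons, "not_in_tcga_bc")
  if (require_tcga_all && !isTRUE(flags$in_tcga_all)) {
    reasons <- c(reasons, "not_in_tcga_all")
  }
  if (!duplex_support_check(coords)) reasons <- c(reasons, "duplex")
  ## no VAF condition: detection reaches arbitrarily low fractions
  data.frame(
    chrom = v$chrom %||% NA_character_,
    pos = v$pos %||% NA_integer_,
    ref = v$ref %||% NA_character_,
    alt = v$alt %||% NA_character_,
    gene = flags$gene %||% NA_character_,
    sample_id = v$sample_id %||% NA_character_,
    vaf = v$vaf %||% NA_real_,
    method = "caller_stringent",
    duplex_coord_count = length(unique(coords)),
    in_cosmic = isTRUE(flags$in_cosmic),
    in_tcga_bc = isTRUE(flags$in_tcga_bc),
    in_tcga_all = isTRUE(flags$in_tcga_all),
    exonic = isTRUE(flags$exonic),
    passed = length(reasons) == 0L,
    fail_reasons = paste(reasons, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Control positivity screen
#'
#' Controls are processed with the identical plasma pipeline as cases;
#' this op tabulates, per control sample, whether at least one detection
#' passed.
#'
#' @param detections A detection `data.frame` (rows for control samples)
#'   with `sample_id` and `passed` columns; may be empty.
#' @param control_ids All control sample ids (so detection-free controls
#'   are counted as negative).
#' @return A list with `table` (per-control `sample_id`,
#'   `n_passing`, `positive`) and `n_positive`.
#' @export
apply_control_screen <- function(detections, control_ids) {
  if (!length(control_ids)) stop("no control samples supplied")
  n_passing <- vapply(control_ids, function(s) {
    if (!nrow(detections)) 0L
    else sum(detections$sample_id == s & detections$passed)
  }, 0L)
  tab <- data.frame(sample_id = control_ids,
                    n_passing = unname(n_passing),
                    positive = unname(n_passing) > 0L,
                    stringsAsFactors = FALSE)
  list(table = tab, n_positive = sum(tab$positive))
}
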