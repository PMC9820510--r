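## Readers/writers for the external formats the pipeline touches:
## BED capture panels, VCF 4.2 site lists, annotation flag tables,
## sample sheets and the packaged study-table fixtures.

#' Read a capture panel BED file
#'
#' Panel regions are interpreted BED-style: 0-based, half-open
#' `[start, end)`. Regions are returned in file order.
#'
#' @param path Path to a tab-separated BED file with at least 3 columns
#'   (chrom, start, end); a 4th column is taken as the region label
#'   (gene/exon tag).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `label`.
#' @examples
#' bed <- system.file("extdata", "panel_33genes.bed", package = "ctdnaflow")
#' panel <- read_panel_bed(bed)
#' head(panel)
#' @export
read_panel_bed <- function(path) {
  if (!file.exists(path)) stop("panel BED file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), label = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("malformed BED line %d: expected at least 3 tab-separated columns",
                 lineno[which(nf < 3L)[1L]]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end   <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop(sprintf("malformed BED line %d: non-numeric coordinates",
                 lineno[which(is.na(start) | is.na(end))[1L]]))
  }
  if (any(!nzchar(chrom))) {
    stop(sprintf("malformed BED line %d: empty chromosome name",
                 lineno[which(!nzchar(chrom))[1L]]))
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop(sprintf("invalid region at line %d: start (%d) must be < end (%d)",
                 lineno[bad[1L]], start[bad[1L]], end[bad[1L]]))
  }
  label <- vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_, "")
  data.frame(chrom = chrom, start = start, end = end, label = label,
             stringsAsFactors = FALSE)
}

#' Write a panel back to BED
#'
#' Inverse of [read_panel_bed()]; coordinates are preserved exactly.
#'
#' @param panel A panel `data.frame` (`chrom`, `start`, `end`, `label`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_bed <- function(panel, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(panel)))
  out <- panel[, intersect(c("chrom", "start", "end", "label"), names(panel))]
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE, na = ".")
  invisible(path)
}

#' Read a variant annotation database
#'
#' Loads a flat-file annotation table emulating COSMIC / TCGA-breast /
#' TCGA-pan-cancer membership flags, keyed by `(chrom, pos, ref, alt)`
#' with 1-based positions. Lookups are total: variants absent from the
#' table return all-`FALSE` flags (see [annotation_lookup()]).
#'
#' @param path Tab-separated file with header columns `chrom`, `pos`,
#'   `ref`, `alt`, `gene`, `in_cosmic`, `in_tcga_bc`, `in_tcga_all`,
#'   `exonic` (flags as 0/1 or logical).
#' @return An object of class `annotation_db`.
#' @export
read_annotation_db <- function(path) {
  if (!file.exists(path)) stop("annotation database not found: ", path)
  db <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = "chrom"))
  required <- c("chrom", "pos", "ref", "alt", "in_cosmic", "in_tcga_bc",
                "in_tcga_all", "exonic")
  missing <- setdiff(required, names(db))
  if (length(missing)) {
    stop("annotation database lacks required columns: ",
         paste(missing, collapse = ", "))
  }
  if (!"gene" %in% names(db)) db[, gene := NA_character_]
  for (fl in c("in_cosmic", "in_tcga_bc", "in_tcga_all", "exonic")) {
    data.table::set(db, j = fl, value = as.logical(db[[fl]]))
  }
  annotation_db(db)
}

#' Construct an annotation database from a flag table
#'
#' @param flags A `data.frame` with columns `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `gene`, and logical `in_cosmic`, `in_tcga_bc`,
#'   `in_tcga_all`, `exonic`.
#' @return An object of class `annotation_db`.
#' @export
annotation_db <- function(flags) {
  db <- data.table::as.data.table(flags)
  db[, key_ := paste(chrom, pos, ref, alt, sep = ":")]
  if (anyDuplicated(db$key_)) {
    dups <- db[, .N, by = .(key_, in_cosmic, in_tcga_bc, in_tcga_all, exonic)]
    conflicting <- dups[, .N, by = key_][N > 1L]
    if (nrow(conflicting)) {
      stop("duplicate annotation key with conflicting flags: ",
           conflicting$key_[1L])
    }
    db <- unique(db, by = "key_")
  }
  data.table::setkey(db, key_)
  structure(list(table = db), class = "annotation_db")
}

#' @export
print.annotation_db <- function(x, ...) {
  cat("annotation_db with", nrow(x$table), "keyed variants\n")
  invisible(x)
}

#' Look up annotation flags for variants
#'
#' Total lookup: every query returns a record; unlisted variants get
#' all-`FALSE` flags and an `NA` gene symbol.
#'
#' @param db An `annotation_db`.
#' @param chrom,pos,ref,alt Vectors describing the variants (1-based `pos`).
#' @return A `data.frame` with one row per query: `gene`, `in_cosmic`,
#'   `in_tcga_bc`, `in_tcga_all`, `exonic`.
#' @export
annotation_lookup <- function(db, chrom, pos, ref, alt) {
  stopifnot(inherits(db, "annotation_db"))
  key <- paste(chrom, pos, ref, alt, sep = ":")
  hit <- db$table[J(key), on = "key_"]
  out <- data.frame(
    gene        = hit$gene,
    in_cosmic   = !is.na(hit$in_cosmic)   & hit$in_cosmic,
    in_tcga_bc  = !is.na(hit$in_tcga_bc)  & hit$in_tcga_bc,
    in_tcga_all = !is.na(hit$in_tcga_all) & hit$in_tcga_all,
    exonic      = !is.na(hit$exonic)      & hit$exonic,
    stringsAsFactors = FALSE
  )
  out
}

variant_class <- function(nt_change, aa_change) {
  cls <- rep("substitution", length(nt_change))
  cls[grepl("del|ins|dup", nt_change)] <- "indel"
  cls[grepl("splice", aa_change)] <- "splice"
  cls
}

#' Read a variant list (VCF or study-table dialect)
#'
#' Supports three dialects:
#' * `"vcf"`: minimal VCF 4.2 sites (CHROM POS ID REF ALT QUAL FILTER INFO),
#'   read via \pkg{vcfR}; records with ALT `"."` are skipped with a warning.
#'   INFO keys `VAF`, `METHOD` and `DUPLEX` are parsed when present.
#' * `"table2"`: the tumor/plasma concordance table (sample, gene,
#'   nucleotide change, amino-acid change, tumor VAF \%, caller/manual
#'   detection flags, plasma VAF \%).
#' * `"table3"`: the plasma-only detection table.
#'
#' Percent VAF columns are stored as printed in the source tables and
#' converted to fractions on load (`vaf`, `tumor_vaf`, `plasma_vaf`).
#'
#' @param path Input file.
#' @param dialect One of `"vcf"`, `"table2"`, `"table3"`.
#' @return A `data.frame` of normalized variants with 1-based positions
#'   (VCF) or HGVS-keyed rows (table dialects), carrying a `class` column
#'   (`substitution`/`indel`/`splice`) for the table dialects.
#' @export
read_variant_table <- function(path, dialect = c("vcf", "table2", "table3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("variant file not found: ", path)
  switch(dialect,
    vcf = read_variants_vcf(path),
    table2 = read_variants_table2(path),
    table3 = read_variants_table3(path)
  )
}

read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), vaf = numeric(), method = character(),
                      duplex_coord_count = integer(), stringsAsFactors = FALSE))
  }
  drop <- is.na(fix$ALT) | fix$ALT == "."
  if (any(drop)) {
    warning(sum(drop), " VCF record(s) with missing ALT skipped")
    fix <- fix[!drop, , drop = FALSE]
  }
  info_get <- function(info, key) {
    pat <- paste0("(^|;)", key, "=[^;]*")
    m <- regexpr(pat, info)
    out <- rep(NA_character_, length(info))
    out[m > 0L] <- sub(paste0("^;?", key, "="), "", regmatches(info, m))
    out
  }
  info <- fix$INFO %||% rep(NA_character_, nrow(fix))
  vaf <- suppressWarnings(as.numeric(info_get(info, "VAF")))
  method <- info_get(info, "METHOD")
  duplex <- suppressWarnings(as.integer(info_get(info, "DUPLEX")))
  bad_vaf <- !is.na(vaf) & (vaf < 0 | vaf > 1)
  if (any(bad_vaf)) stop("VAF outside [0, 1] in VCF INFO field")
  data.frame(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    vaf = vaf,
    method = method,
    duplex_coord_count = duplex,
    stringsAsFactors = FALSE
  )
}

read_variants_table2 <- function(path) {
  tb <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   na.strings = c("-", ""), colClasses = "character")
  required <- c("sample", "gene", "nt_change", "aa_change", "tumor_vaf_pct",
                "caller_detected", "manual_detected", "plasma_vaf_pct")
  missing <- setdiff(required, names(tb))
  if (length(missing)) {
    stop("unknown tumor/plasma table dialect; missing columns: ",
         paste(missing, collapse = ", "))
  }
  tumor_pct <- suppressWarnings(as.numeric(tb$tumor_vaf_pct))
  plasma_pct <- suppressWarnings(as.numeric(tb$plasma_vaf_pct))
  if (any(is.na(tumor_pct) & !is.na(tb$tumor_vaf_pct))) {
    stop("non-numeric tumor VAF in table")
  }
  if (any(is.na(plasma_pct) & !is.na(tb$plasma_vaf_pct))) {
    stop("non-numeric plasma VAF in table")
  }
  data.frame(
    sample = tb$sample,
    gene = tb$gene,
    nt_change = tb$nt_change,
    aa_change = tb$aa_change,
    tumor_vaf = tumor_pct / 100,
    caller_detected = tb$caller_detected == "Y",
    manual_detected = tb$manual_detected == "Y",
    plasma_vaf = plasma_pct / 100,
    class = variant_class(tb$nt_change, tb$aa_change),
    stringsAsFactors = FALSE
  )
}

read_variants_table3 <- function(path) {
  tb <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   na.strings = c("-", ""), colClasses = "character")
  required <- c("sample", "gene", "nt_change", "aa_change", "vaf_pct",
                "in_databases", "tumor_sequenced", "any_mutation_in_tumor")
  missing <- setdiff(required, names(tb))
  if (length(missing)) {
    stop("unknown plasma-only table dialect; missing columns: ",
         paste(missing, collapse = ", "))
  }
  pct <- suppressWarnings(as.numeric(tb$vaf_pct))
  if (any(is.na(pct) & !is.na(tb$vaf_pct))) stop("non-numeric VAF in table")
  data.frame(
    sample = tb$sample,
    gene = tb$gene,
    nt_change = tb$nt_change,
    aa_change = tb$aa_change,
    vaf = pct / 100,
    in_databases = tb$in_databases == "Y",
    tumor_sequenced = tb$tumor_sequenced == "Y",
    any_mutation_in_tumor = ifelse(is.na(tb$any_mutation_in_tumor), NA,
                                   tb$any_mutation_in_tumor == "Y"),
    class = variant_class(tb$nt_change, tb$aa_change),
    stringsAsFactors = FALSE
  )
}

#' Write detections as a minimal VCF 4.2 file
#'
#' Emits one site record per detection with INFO keys `VAF` (fraction),
#' `METHOD` (`caller`/`rescue`) and `DUPLEX` (count of distinct supporting
#' fragment coordinates). Positions are written 1-based. The output
#' round-trips through `read_variant_table(..., dialect = "vcf")` on the
#' key fields.
#'
#' @param detections A `data.frame` with columns `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `vaf`, `method`, `duplex_coord_count`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_detections_vcf <- function(detections, path) {
  required <- c("chrom", "pos", "ref", "alt", "vaf", "method",
                "duplex_coord_count")
  missing <- setdiff(required, names(detections))
  if (length(missing)) {
    stop("detections lack required fields: ", paste(missing, collapse = ", "))
  }
  if (nrow(detections) && (anyNA(detections$chrom) || any(!nzchar(detections$chrom)))) {
    stop("unsortable contigs: missing chromosome names")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ctdnaflow",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele frequency (fraction)\">",
    "##INFO=<ID=METHOD,Number=1,Type=String,Description=\"Detection path: caller or rescue\">",
    "##INFO=<ID=DUPLEX,Number=1,Type=Integer,Description=\"Distinct supporting fragment start coordinates\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- character(0)
  if (nrow(detections)) {
    ord <- order(detections$chrom, detections$pos, detections$alt)
    d <- detections[ord, , drop = FALSE]
    info <- sprintf("VAF=%.6g;METHOD=%s;DUPLEX=%d",
                    d$vaf, d$method, as.integer(d$duplex_coord_count))
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                    d$chrom, as.integer(d$pos), d$ref, d$alt, info)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a sample sheet CSV
#'
#' Sample sheets link plasma/tumor/control samples and carry
#' clinicopathological covariates. Required columns: `sample_id`, `role`
#' (one of `tumor`, `plasma_case`, `plasma_control`); optional:
#' `tissue_prep` (`fresh_frozen`, `FFPE`, `plasma`), `link` (paired
#' sample id), plus free covariate columns (stage, grade, ER, ...).
#'
#' @param path CSV file path.
#' @return A `data.frame`; `sample_id` is checked for uniqueness.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_sheet(sheet)
}

validate_sample_sheet <- function(sheet) {
  if (!all(c("sample_id", "role") %in% names(sheet))) {
    stop("sample sheet requires columns sample_id and role")
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicate sample_id in sample sheet: ",
         sheet$sample_id[duplicated(sheet$sample_id)][1L])
  }
  ok_roles <- c("tumor", "plasma_case", "plasma_control")
  if (!all(sheet$role %in% ok_roles)) {
    stop("invalid role(s): ", paste(setdiff(unique(sheet$role), ok_roles),
                                    collapse = ", "))
  }
  sheet
}
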