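## Reads-on-disk formats: a plain TSV of the tagged-read model, and a
## minimal SAM-dialect (gapless alignments, UMI in a configurable tag,
## fragment coordinates and mate/orientation in auxiliary tags).

#' Write tagged reads as TSV
#'
#' @param reads A tagged-read `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_tsv <- function(reads, path) {
  validate_tagged_reads(reads)
  cols <- c("read_id", "umi", "chrom", "frag_start", "frag_end", "orient",
            "mate", "pos", "bases", "quals")
  extra <- intersect(c("allele_tag", "tag_pos"), names(reads))
  write.table(reads[, c(cols, extra)], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read tagged reads from TSV
#'
#' @param path Input path (written by [write_reads_tsv()]).
#' @return A tagged-read `data.frame`.
#' @export
read_reads_tsv <- function(path) {
  reads <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                      colClasses = c(umi = "character", bases = "character",
                                     quals = "character",
                                     chrom = "character"))
  validate_tagged_reads(reads)
}

#' Write tagged reads as a minimal SAM dialect
#'
#' Gapless alignments only: CIGAR is always `<length>M`, POS is 1-based,
#' the UMI goes to `umi_tag` (default `RX`), and fragment coordinates,
#' orientation and mate are carried in the auxiliary tags `XS`/`XE`
#' (0-based fragment start/end), `XO` and `XM`. Indel/splice allele
#' tokens use `XT`/`XP`.
#'
#' @param reads A tagged-read `data.frame`.
#' @param path Output path.
#' @param umi_tag Two-letter tag holding the UMI (default `"RX"`).
#' @return `path`, invisibly.
#' @export
write_reads_sam <- function(reads, path, umi_tag = "RX") {
  validate_tagged_reads(reads)
  chroms <- unique(reads$chrom)
  maxend <- vapply(chroms, function(cr) {
    max(reads$pos[reads$chrom == cr] + nchar(reads$bases[reads$chrom == cr]))
  }, 0)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", chroms, as.integer(maxend + 1000L)))
  flag <- ifelse(reads$mate == "read1", 64L, 128L) +
    ifelse(reads$orient == "F2R1", 16L, 0L)
  tags <- sprintf("%s:Z:%s\tXS:i:%d\tXE:i:%d\tXO:Z:%s\tXM:Z:%s",
                  umi_tag, reads$umi, reads$frag_start, reads$frag_end,
                  reads$orient, reads$mate)
  if ("allele_tag" %in% names(reads)) {
    has <- !is.na(reads$allele_tag)
    tags[has] <- paste0(tags[has],
                        sprintf("\tXT:Z:%s\tXP:i:%d",
                                reads$allele_tag[has],
                                as.integer(reads$tag_pos[has])))
  }
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\t%s",
                  reads$read_id, flag, reads$chrom, reads$pos + 1L,
                  nchar(reads$bases), reads$bases, reads$quals, tags)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read tagged reads from the minimal SAM dialect
#'
#' Counterpart of [write_reads_sam()]. Alignments must be gapless
#' (CIGAR `<length>M`); the reader emits reference-positioned base
#' vectors, as the consensus engine requires.
#'
#' @param path Input SAM path.
#' @param umi_tag Tag holding the UMI (default `"RX"`).
#' @return A tagged-read `data.frame`.
#' @export
read_tagged_sam <- function(path, umi_tag = "RX") {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(tagged_reads(character(0), character(0), character(0),
                        integer(0), integer(0), bases = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(fields, `[[`, "", i)
  cigar <- get(6L)
  if (any(!grepl("^[0-9]+M$", cigar))) {
    stop("only gapless alignments (CIGAR <n>M) are supported by this dialect")
  }
  tag_val <- function(prefix) {
    vapply(fields, function(f) {
      hit <- f[startsWith(f, prefix)]
      if (length(hit)) sub(prefix, "", hit[1L], fixed = TRUE) else NA_character_
    }, "")
  }
  flag <- as.integer(get(2L))
  reads <- data.frame(
    read_id = get(1L),
    umi = tag_val(paste0(umi_tag, ":Z:")),
    chrom = get(3L),
    frag_start = as.integer(tag_val("XS:i:")),
    frag_end = as.integer(tag_val("XE:i:")),
    orient = ifelse(is.na(tag_val("XO:Z:")),
                    ifelse(bitwAnd(flag, 16L) > 0L, "F2R1", "F1R2"),
                    tag_val("XO:Z:")),
    mate = ifelse(is.na(tag_val("XM:Z:")),
                  ifelse(bitwAnd(flag, 128L) > 0L, "read2", "read1"),
                  tag_val("XM:Z:")),
    pos = as.integer(get(4L)) - 1L,
    bases = get(10L),
    quals = get(11L),
    stringsAsFactors = FALSE
  )
  xt <- tag_val("XT:Z:")
  if (any(!is.na(xt))) {
    reads$allele_tag <- xt
    reads$tag_pos <- as.integer(tag_val("XP:i:"))
  }
  if (anyNA(reads$umi)) stop("missing UMI tag ", umi_tag, " on some records")
  if (anyNA(reads$frag_start) || anyNA(reads$frag_end)) {
    ## fall back to alignment span when fragment tags are absent
    reads$frag_start[is.na(reads$frag_start)] <- reads$pos[is.na(reads$frag_start)]
    miss <- is.na(reads$frag_end)
    reads$frag_end[miss] <- reads$pos[miss] + nchar(reads$bases[miss])
  }
  validate_tagged_reads(reads)
}
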