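## UMI family grouping, molecular consensus calling, consensus filtering and
## mate-overlap clipping. Reads are modeled as gapless aligned base vectors
## positioned on the reference (the SAM reader / simulator emit
## reference-positioned bases); indels enter the pipeline at the variant
## level, not inside the read model.

#' Construct a table of UMI-tagged reads
#'
#' The read model used throughout the package: each read carries a UMI
#' barcode, fragment (insert) coordinates (0-based half-open), a strand
#' orientation (`F1R2`/`F2R1`), a mate tag, and gapless aligned bases with
#' Phred+33 qualities starting at reference position `pos` (0-based).
#'
#' @param read_id,umi,chrom Character vectors.
#' @param frag_start,frag_end Integer fragment coordinates, `frag_start < frag_end`.
#' @param orient `"F1R2"` or `"F2R1"`.
#' @param mate `"read1"` or `"read2"`.
#' @param pos 0-based reference position of the first aligned base.
#' @param bases Aligned base strings over `A`,`C`,`G`,`T`,`N`.
#' @param quals Phred+33 quality strings (same length as `bases`), or a
#'   single integer Phred score applied to every base.
#' @return A `data.frame` of tagged reads.
#' @export
tagged_reads <- function(read_id, umi, chrom, frag_start, frag_end,
                         orient = "F1R2", mate = "read1", pos = frag_start,
                         bases, quals = 37L) {
  n <- max(length(read_id), length(umi), length(chrom), length(frag_start),
           length(bases))
  if (is.numeric(quals)) {
    q <- as.integer(quals)
    if (length(q) == 1L) {
      quals <- strrep(intToUtf8(min(93L, max(0L, q)) + 33L), nchar(bases))
    } else {
      quals <- int_to_phred(list(q))[[1L]]
    }
  }
  reads <- data.frame(
    read_id = rep_len(as.character(read_id), n),
    umi = rep_len(as.character(umi), n),
    chrom = rep_len(as.character(chrom), n),
    frag_start = rep_len(as.integer(frag_start), n),
    frag_end = rep_len(as.integer(frag_end), n),
    orient = rep_len(orient, n),
    mate = rep_len(mate, n),
    pos = rep_len(as.integer(pos), n),
    bases = bases,
    quals = rep_len(quals, n),
    stringsAsFactors = FALSE
  )
  validate_tagged_reads(reads)
}

validate_tagged_reads <- function(reads) {
  required <- c("read_id", "umi", "chrom", "frag_start", "frag_end",
                "orient", "mate", "pos", "bases", "quals")
  missing <- setdiff(required, names(reads))
  if (length(missing)) {
    stop("tagged reads lack required fields: ", paste(missing, collapse = ", "))
  }
  if (!nrow(reads)) return(reads)
  if (any(!nzchar(reads$umi))) stop("empty UMI barcode")
  if (any(reads$frag_start >= reads$frag_end)) {
    stop("fragment start must be < fragment end")
  }
  if (any(nchar(reads$bases) != nchar(reads$quals))) {
    stop("aligned bases and base qualities differ in length")
  }
  if (!all(reads$orient %in% c("F1R2", "F2R1"))) {
    stop("orientation must be F1R2 or F2R1")
  }
  if (!all(reads$mate %in% c("read1", "read2"))) {
    stop("mate must be read1 or read2")
  }
  reads
}

#' Group UMI-tagged reads into molecular families
#'
#' Two reads belong to the same family iff their UMI strings are
#' byte-identical (Identity strategy: degenerate barcodes are not
#' edit-distance clustered) AND their fragment coordinates and strand
#' orientation match. The family key therefore is
#' `(umi, chrom, frag_start, frag_end, orient)`.
#'
#' @param reads A tagged-read `data.frame` (see [tagged_reads()]).
#' @param strategy UMI matching strategy; only `"identity"` is supported.
#' @return `reads` with an added integer `family_id` column (a partition:
#'   every read gets exactly one family). The per-family summary is
#'   attached as attribute `"families"`.
#' @export
group_reads_by_umi <- function(reads, strategy = "identity") {
  strategy <- match.arg(strategy, "identity")
  reads <- validate_tagged_reads(as.data.frame(reads))
  key <- paste(reads$umi, reads$chrom, reads$frag_start, reads$frag_end,
               reads$orient, sep = "\r")
  reads$family_id <- match(key, unique(key))
  fam <- if (nrow(reads)) {
    dt <- data.table::as.data.table(reads)
    as.data.frame(dt[, .(umi = umi[1L], chrom = chrom[1L],
                         frag_start = frag_start[1L], frag_end = frag_end[1L],
                         orient = orient[1L], size = .N),
                     by = family_id])
  } else {
    data.frame(family_id = integer(), umi = character(), chrom = character(),
               frag_start = integer(), frag_end = integer(),
               orient = character(), size = integer())
  }
  attr(reads, "families") <- fam
  reads
}

## Per-position consensus vote over a member x position base matrix.
## Columns are independent: callers may stack positions of many families
## side by side. Rules: a base qualifies if its quality >= min_base_quality
## and it is not N; the consensus base is the unique most frequent
## qualifying base (tie or nothing qualifying -> N); consensus quality is
## the quality sum of agreeing bases minus the sum of disagreeing ones,
## floored at 2 and capped at 60; positions whose consensus quality falls
## below min_base_quality are masked to N.
consensus_core <- function(M, Q, min_base_quality = 30L) {
  if (!is.matrix(M)) M <- matrix(M, nrow = 1L)
  if (!is.matrix(Q)) Q <- matrix(Q, nrow = 1L)
  stopifnot(identical(dim(M), dim(Q)))
  P <- ncol(M)
  n <- nrow(M)
  ok <- (Q >= min_base_quality) & (M != "N")
  alphabet <- c("A", "C", "G", "T")
  cnt <- matrix(0L, 4L, P)
  qsm <- matrix(0, 4L, P)
  for (i in 1:4) {
    mb <- (M == alphabet[i]) & ok
    cnt[i, ] <- .colSums(mb, n, P)
    qsm[i, ] <- .colSums(Q * mb, n, P)
  }
  maxc <- pmax(cnt[1L, ], cnt[2L, ], cnt[3L, ], cnt[4L, ])
  ntop <- (cnt[1L, ] == maxc) + (cnt[2L, ] == maxc) +
          (cnt[3L, ] == maxc) + (cnt[4L, ] == maxc)
  win <- max.col(t(cnt), ties.method = "first")
  qw <- qsm[cbind(win, seq_len(P))]
  qtot <- qsm[1L, ] + qsm[2L, ] + qsm[3L, ] + qsm[4L, ]
  cq <- pmin(60, pmax(2, qw - (qtot - qw)))
  base <- alphabet[win]
  masked <- maxc == 0L | ntop > 1L | cq < min_base_quality
  base[masked] <- "N"
  cq[masked] <- 2
  list(base = base, qual = as.integer(round(cq)))
}

collapse_rows <- function(mat) {
  ## row-wise paste of a character matrix, vectorized across rows
  if (!nrow(mat)) return(character())
  if (ncol(mat) == 1L) return(mat[, 1L])
  do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
}

#' Call molecular consensus reads for every UMI family
#'
#' Per family (and mate), performs a base-quality aware per-position vote:
#' the consensus base is the unique most frequent member base with quality
#' at or above `min_base_quality`; ties and positions with no qualifying
#' base become `N`. Consensus quality is the sum of agreeing base
#' qualities minus the sum of disagreeing ones, floored at 2, capped at
#' 60; positions whose consensus quality ends up below
#' `min_base_quality` are masked to `N`.
#'
#' @param reads Tagged reads; grouped with [group_reads_by_umi()] first if
#'   no `family_id` column is present.
#' @param min_base_quality Minimum Phred base quality for a member base to
#'   qualify, and for a consensus position to survive unmasked (default 30).
#' @return A consensus-read `data.frame`: one row per `(family_id, mate)`
#'   with `bases`, `quals` (Phred+33, capped at 60), `family_size`
#'   (contributing read count) and the family key columns.
#' @export
call_consensus_reads <- function(reads, min_base_quality = 30L) {
  if (!"family_id" %in% names(reads)) reads <- group_reads_by_umi(reads)
  dt <- data.table::as.data.table(reads)
  if (!nrow(dt)) {
    return(data.frame(family_id = integer(), umi = character(),
                      chrom = character(), frag_start = integer(),
                      frag_end = integer(), orient = character(),
                      mate = character(), pos = integer(),
                      bases = character(), quals = character(),
                      family_size = integer(), allele_tag = character(),
                      tag_pos = integer(), stringsAsFactors = FALSE))
  }
  if (!"allele_tag" %in% names(dt)) dt[, allele_tag := NA_character_]
  if (!"tag_pos" %in% names(dt)) dt[, tag_pos := NA_integer_]
  dt[, len := nchar(bases)]
  if (any(dt$len != nchar(dt$quals))) {
    stop("aligned bases and base qualities differ in length")
  }
  data.table::setorder(dt, family_id, mate)
  dt[, gid := data.table::rleid(family_id, mate)]
  grp <- dt[, .(family_id = family_id[1L], umi = umi[1L], chrom = chrom[1L],
                frag_start = frag_start[1L], frag_end = frag_end[1L],
                orient = orient[1L], mate = mate[1L], pos = pos[1L],
                n = .N, len = len[1L],
                ragged = (max(pos) != min(pos)) || (max(len) != min(len)),
                allele_tag = allele_tag[1L], tag_pos = tag_pos[1L]),
            by = gid]
  if (any(grp$ragged)) {
    stop("ragged member reads within a family: members must share aligned start and length")
  }
  res_bases <- character(nrow(grp))
  res_quals <- character(nrow(grp))
  batches <- unique(grp[, .(n, len)])
  for (b in seq_len(nrow(batches))) {
    s <- batches$n[b]
    L <- batches$len[b]
    gids <- grp[n == s & len == L, gid]
    sub <- dt[gid %in% gids]
    nf <- length(gids)
    bv <- unlist(strsplit(sub$bases, "", fixed = TRUE), use.names = FALSE)
    qv <- utf8ToInt(paste(sub$quals, collapse = "")) - 33L
    arrB <- array(bv, dim = c(L, s, nf))
    arrQ <- array(qv, dim = c(L, s, nf))
    mB <- aperm(arrB, c(2L, 1L, 3L)); dim(mB) <- c(s, L * nf)
    mQ <- aperm(arrQ, c(2L, 1L, 3L)); dim(mQ) <- c(s, L * nf)
    cc <- consensus_core(mB, mQ, min_base_quality)
    bmat <- matrix(cc$base, nrow = L)
    qmat <- matrix(intToUtf8(cc$qual + 33L, multiple = TRUE), nrow = L)
    idx <- match(gids, grp$gid)
    res_bases[idx] <- collapse_rows(t(bmat))
    res_quals[idx] <- collapse_rows(t(qmat))
  }
  data.frame(
    family_id = grp$family_id, umi = grp$umi, chrom = grp$chrom,
    frag_start = grp$frag_start, frag_end = grp$frag_end,
    orient = grp$orient, mate = grp$mate, pos = grp$pos,
    bases = res_bases, quals = res_quals, family_size = grp$n,
    allele_tag = grp$allele_tag, tag_pos = grp$tag_pos,
    stringsAsFactors = FALSE
  )
}

#' Call the consensus read of a single family
#'
#' Convenience wrapper around [call_consensus_reads()] for one family.
#'
#' @param family A tagged-read `data.frame` whose rows all share one
#'   family key.
#' @param min_base_quality See [call_consensus_reads()].
#' @return A one-row (per mate) consensus `data.frame`.
#' @export
call_consensus_read <- function(family, min_base_quality = 30L) {
  if (!nrow(family)) stop("empty read family")
  key <- unique(paste(family$umi, family$chrom, family$frag_start,
                      family$frag_end, family$orient))
  if (length(key) != 1L) {
    stop("reads do not share a single family key")
  }
  family$family_id <- 1L
  call_consensus_reads(family, min_base_quality)
}

#' Filter consensus reads by family size
#'
#' Tumor samples use a minimum of 3 contributing reads per family; plasma
#' samples a minimum of 1 (which is the identity filter).
#'
#' @param consensus Consensus reads from [call_consensus_reads()].
#' @param min_family_size Minimum contributing read count (>= 1).
#' @return The consensus reads with `family_size >= min_family_size`.
#' @export
filter_consensus_reads <- function(consensus, min_family_size) {
  min_family_size <- as.integer(min_family_size)
  if (is.na(min_family_size) || min_family_size < 1L) {
    stop("min_family_size must be an integer >= 1")
  }
  consensus[consensus$family_size >= min_family_size, , drop = FALSE]
}

#' Clip overlapping mate pairs of consensus reads
#'
#' For families with both mates, reference positions covered by both are
#' retained on exactly one mate — the one with the higher mean consensus
#' quality over the overlap (tie: read1) — and masked to `N` on the other,
#' so downstream pileups count each fragment once per position.
#'
#' @param consensus Consensus reads (any mix of families; families with a
#'   single mate pass through unchanged).
#' @return The consensus reads with overlaps masked.
#' @export
clip_overlap <- function(consensus) {
  if (!nrow(consensus)) return(consensus)
  split_idx <- split(seq_len(nrow(consensus)), consensus$family_id)
  for (idx in split_idx) {
    if (length(idx) != 2L) next
    m1 <- idx[consensus$mate[idx] == "read1"]
    m2 <- idx[consensus$mate[idx] == "read2"]
    if (length(m1) != 1L || length(m2) != 1L) next
    if (consensus$chrom[m1] != consensus$chrom[m2]) {
      stop("mates of family ", consensus$family_id[m1],
           " align to different chromosomes")
    }
    s1 <- consensus$pos[m1]; e1 <- s1 + nchar(consensus$bases[m1])
    s2 <- consensus$pos[m2]; e2 <- s2 + nchar(consensus$bases[m2])
    lo <- max(s1, s2); hi <- min(e1, e2)
    if (lo >= hi) next
    q1 <- utf8ToInt(consensus$quals[m1]) - 33L
    q2 <- utf8ToInt(consensus$quals[m2]) - 33L
    r1 <- (lo - s1 + 1L):(hi - s1)
    r2 <- (lo - s2 + 1L):(hi - s2)
    keep1 <- mean(q1[r1]) >= mean(q2[r2])  # tie -> read1
    loser <- if (keep1) m2 else m1
    rng <- if (keep1) r2 else r1
    b <- strsplit(consensus$bases[loser], "", fixed = TRUE)[[1L]]
    q <- if (keep1) q2 else q1
    b[rng] <- "N"
    q[rng] <- 2L
    consensus$bases[loser] <- paste(b, collapse = "")
    consensus$quals[loser] <- intToUtf8(q + 33L, multiple = FALSE)
  }
  consensus
}
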