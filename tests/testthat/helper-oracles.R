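# Independent oracles and small builders used across the suite.

# Brute-force Fisher exact p-value by enumerating the hypergeometric
# distribution of the 2x2 table [a, b; c, d] (rows: sample/controls,
# columns: alt/ref) with fixed margins. Independent of stats::fisher.test
# and of the package implementation.
enum_fisher_p <- function(a, b, c_, d, sided = c("greater", "two.sided")) {
  sided <- match.arg(sided)
  m <- a + c_          # alt margin
  n2 <- b + d          # ref margin
  k <- a + b           # sample row margin
  lo <- max(0, k - n2)
  hi <- min(k, m)
  xs <- lo:hi
  logp <- lchoose(m, xs) + lchoose(n2, k - xs)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(xs == a)
  if (sided == "greater") {
    sum(p[xs >= a])
  } else {
    sum(p[p <= p[obs] * (1 + 1e-7)])
  }
}

# A toy panel: one small synthetic contig region.
toy_panel <- function(start = 0L, end = 10000L, chrom = "chrT") {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             label = "TOY", stringsAsFactors = FALSE)
}

# Build one read family: n copies of `bases` sharing a UMI and fragment.
make_family <- function(bases, quals = 37L, umi = "ACGTACGTAA",
                        chrom = "chrT", frag_start = 100L,
                        frag_end = frag_start + nchar(bases[1L]),
                        pos = frag_start, orient = "F1R2", mate = "read1") {
  tagged_reads(
    read_id = sprintf("r%d", seq_along(bases)),
    umi = umi, chrom = chrom, frag_start = frag_start, frag_end = frag_end,
    orient = orient, mate = mate, pos = pos, bases = bases, quals = quals
  )
}

# A minimal interrogation object for direct rescue-test calls.
make_interrogation <- function(alt, ref, coords = seq_len(alt),
                               chrom = "chrT", pos = 101L) {
  structure(list(chrom = chrom, pos = pos, ref = "A", alt = "T",
                 alt_count = as.integer(alt), ref_count = as.integer(ref),
                 depth = as.integer(alt + ref),
                 coords = as.integer(coords)),
            class = "site_interrogation")
}
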