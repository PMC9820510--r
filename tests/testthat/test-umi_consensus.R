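test_that("grouping partitions reads by exact UMI and fragment key", {
  r1 <- make_family(c("ACGT", "ACGT"), umi = "ACGTAAGG")
  gr <- group_reads_by_umi(r1)
  expect_equal(length(unique(gr$family_id)), 1L)
  expect_equal(attr(gr, "families")$size, 2L)

  # one barcode mismatch keeps families apart under the identity strategy
  r2 <- rbind(make_family("ACGT", umi = "ACGTAAGG"),
              make_family("ACGT", umi = "ACGTAAGC"))
  expect_equal(length(unique(group_reads_by_umi(r2)$family_id)), 2L)

  # the key includes fragment coordinates
  r3 <- rbind(make_family("ACGT", umi = "ACGTAAGG", frag_start = 100L),
              make_family("ACGT", umi = "ACGTAAGG", frag_start = 101L))
  expect_equal(length(unique(group_reads_by_umi(r3)$family_id)), 2L)

  expect_equal(nrow(group_reads_by_umi(r1[0, ])), 0L)
})

test_that("grouping is a partition over random read sets", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 200L
    reads <- tagged_reads(
      read_id = sprintf("r%d", seq_len(n)),
      umi = sample(c("AAAA", "CCCC", "GGGG", "TTTT"), n, replace = TRUE),
      chrom = "chrT",
      frag_start = sample(100:104, n, replace = TRUE),
      frag_end = 200L,
      orient = sample(c("F1R2", "F2R1"), n, replace = TRUE),
      bases = strrep("A", 10L), quals = 37L
    )
    gr <- group_reads_by_umi(reads)
    expect_false(anyNA(gr$family_id))
    fam <- attr(gr, "families")
    expect_equal(sum(fam$size), n)
    expect_equal(sort(unique(gr$family_id)), fam$family_id[order(fam$family_id)])
  }
})

test_that("consensus follows unanimity, tie and majority rules", {
  # unanimity: consensus equals the read, no N
  cons <- call_consensus_read(make_family(rep("ACGTT", 3)))
  expect_equal(cons$bases, "ACGTT")
  expect_equal(cons$family_size, 3L)

  # equal-quality disagreement at one position -> N
  cons2 <- call_consensus_read(make_family(c("ACGTT", "ACATT")))
  expect_equal(cons2$bases, "ACNTT")

  # consensus quality cap: agreeing qualities sum above 60 are clamped
  q <- utf8ToInt(cons$quals) - 33L
  expect_true(all(q <= 60L))
})

test_that("majority restores the true base over all 2-vs-1 error splits", {
  # enumeration oracle: for every position and every erroneous base, a
  # 3-read family with one error must restore the majority base whenever
  # >= 2 qualifying reads agree
  truth <- "ACGT"
  for (p in 1:4) {
    for (wrong in setdiff(c("A", "C", "G", "T"), substring(truth, p, p))) {
      b <- strsplit(truth, "")[[1]]
      b[p] <- wrong
      bad <- paste(b, collapse = "")
      cons <- call_consensus_read(make_family(c(truth, truth, bad)))
      expect_equal(cons$bases, truth,
                   label = sprintf("pos %d err %s", p, wrong))
    }
  }
})

test_that("low-quality bases neither vote nor rescue a position", {
  # the single qualifying base wins; but a lone sub-threshold base gives N
  fam <- make_family(c("AAAA", "AAAA"))
  lowq <- make_family("CCCC", quals = 10L)
  lowq$read_id <- "r9"
  cons <- call_consensus_read(rbind(fam, lowq))
  expect_equal(cons$bases, "AAAA")
  expect_equal(cons$family_size, 3L)

  only_low <- call_consensus_read(make_family("AAAA", quals = 10L))
  expect_equal(only_low$bases, "NNNN")
})

test_that("ragged families are rejected", {
  fam <- rbind(make_family("ACGT", frag_start = 100L, frag_end = 140L),
               make_family("ACGTA", frag_start = 100L, frag_end = 140L))
  fam$read_id <- c("a", "b")
  expect_error(call_consensus_reads(group_reads_by_umi(fam)), "ragged")
})

test_that("family-size filtering keeps exactly the large-enough families", {
  reads <- rbind(make_family(rep("AAAA", 2), umi = "AAAAAAAAAA"),
                 make_family(rep("CCCC", 3), umi = "CCCCCCCCCC",
                             frag_start = 300L))
  cons <- call_consensus_reads(group_reads_by_umi(reads))
  expect_equal(nrow(filter_consensus_reads(cons, 3L)), 1L)
  expect_equal(filter_consensus_reads(cons, 3L)$family_size, 3L)
  # minimum 1 is the identity
  expect_equal(filter_consensus_reads(cons, 1L), cons)
  expect_error(filter_consensus_reads(cons, 0L), "must be")
})

test_that("overlap clipping masks shared positions on exactly one mate", {
  pair <- rbind(
    make_family(strrep("A", 30), frag_start = 100L, frag_end = 140L,
                pos = 100L, mate = "read1"),
    make_family(strrep("A", 30), frag_start = 100L, frag_end = 140L,
                pos = 110L, mate = "read2")
  )
  pair$read_id <- c("m1", "m2")
  cons <- call_consensus_reads(group_reads_by_umi(pair))
  clipped <- clip_overlap(cons)
  # overlap is [110, 130): 20 bp; position-set oracle
  covered <- function(row) {
    b <- strsplit(clipped$bases[row], "")[[1]]
    (clipped$pos[row] + which(b != "N")) - 1L
  }
  pos1 <- covered(which(clipped$mate == "read1"))
  pos2 <- covered(which(clipped$mate == "read2"))
  expect_length(intersect(pos1, pos2), 0L)
  expect_setequal(union(pos1, pos2), 100:139)

  # disjoint mates unchanged
  disj <- rbind(
    make_family(strrep("A", 10), frag_start = 100L, frag_end = 130L,
                pos = 100L, mate = "read1"),
    make_family(strrep("A", 10), frag_start = 100L, frag_end = 130L,
                pos = 120L, mate = "read2")
  )
  disj$read_id <- c("d1", "d2")
  cd <- call_consensus_reads(group_reads_by_umi(disj))
  expect_equal(clip_overlap(cd)$bases, cd$bases)

  # fully nested mate is fully masked
  nest <- rbind(
    make_family(strrep("A", 40), frag_start = 100L, frag_end = 140L,
                pos = 100L, mate = "read1"),
    make_family(strrep("A", 10), frag_start = 100L, frag_end = 140L,
                pos = 110L, mate = "read2")
  )
  nest$read_id <- c("n1", "n2")
  cn <- clip_overlap(call_consensus_reads(group_reads_by_umi(nest)))
  inner <- cn$bases[cn$mate == "read2"]
  expect_equal(inner, strrep("N", 10))

  # different chromosomes are an error
  bad <- rbind(
    make_family("AAAA", mate = "read1"),
    make_family("AAAA", mate = "read2", chrom = "chrZ")
  )
  bad$read_id <- c("x1", "x2")
  bad$family_id <- 1L
  cb <- suppressWarnings(call_consensus_reads(bad))
  expect_error(clip_overlap(cb), "different chromosomes")
})

test_that("after clipping, a fragment is counted once per position in pileups", {
  pair <- rbind(
    make_family(strrep("A", 30), frag_start = 100L, frag_end = 140L,
                pos = 100L, mate = "read1"),
    make_family(strrep("A", 30), frag_start = 100L, frag_end = 140L,
                pos = 110L, mate = "read2")
  )
  pair$read_id <- c("m1", "m2")
  cons <- clip_overlap(call_consensus_reads(group_reads_by_umi(pair)))
  pile <- build_pileup(cons, toy_panel())
  expect_true(all(pile$sites$depth == 1L))
})
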