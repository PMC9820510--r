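---
title: "Ultrasensitive ctDNA detection: models, parameters and design choices"
author: "ctdnaflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ultrasensitive ctDNA detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdnaflow)
```

## The problem

Circulating tumor DNA (ctDNA) is the small tumor-derived fraction of
cell-free DNA in plasma. In localized breast cancer that fraction can sit
at or below one mutant molecule per several thousand wild-type molecules
— far beneath the raw error rate of short-read sequencing (~1e-3 per
base). Detecting it requires (a) suppressing sequencing errors
physically, by collapsing reads that derive from the same original
molecule, and (b) suppressing the residual background statistically, by
demanding database membership, independent fragment support, and — for
tumor-known sites — a significant excess over the allele counts observed
in control plasmas.

`ctdnaflow` implements that full chain: UMI family grouping and
molecular consensus calling, panel-restricted pileup and candidate
calling, two stringent filtration modes (tumor-informed and
tumor-naive), a Fisher exact "rescue" test against pooled controls,
cohort-level diagnostics with exact binomial intervals, and a seeded
synthetic read generator with a known truth table.

## The read model and consensus calling

Reads are gapless aligned base vectors positioned on the reference,
each carrying a UMI barcode, fragment (insert) coordinates and a strand
orientation. Soft-clipping and CIGAR interpretation are the reader's
job: `read_tagged_sam()` accepts only gapless records by contract.
Insertions and deletions are deliberately kept out of the base vector —
callers notoriously disagree on indel evidence at the read level — and
instead travel as *allele tokens* (`allele_tag`/`tag_pos`) attached to
whole fragments, entering pileups as single-token alleles at the
variant's leftmost reference position.

**Family key.** Two reads belong to one molecular family iff their UMIs
are byte-identical *and* their fragment coordinates and orientation
match. Identity matching (rather than edit-distance clustering) is the
appropriate strategy for fully degenerate barcodes, where collisions
between distinct molecules are made vanishingly rare by the coordinate
component of the key; it also never merges true distinct molecules that
happen to carry near-identical barcodes.

**Consensus vote.** Per position, member bases with quality below
`min_base_quality` (default Phred 30) are excluded; the consensus base
is the unique most frequent qualifying base. Ties become `N` — a
deliberate, conservative choice over any deterministic-but-arbitrary
tie-break, since a position with balanced evidence carries no usable
information at 0.03% VAF. The consensus quality is the sum of agreeing
qualities minus the sum of disagreeing ones, floored at 2 and capped at
60; positions whose consensus quality falls below the threshold are
masked to `N`. This agree-minus-disagree score is a simplified stand-in
for a full error-model posterior; it preserves the two properties the
pipeline relies on (unanimous families saturate the cap, conflicted
positions fall below threshold) without modelling per-cycle error
profiles.

**Family-size minima.** Tumor tissue, where DNA is plentiful, uses a
minimum of 3 contributing reads per family, so every consensus base has
real redundancy behind it. Plasma, where input molecules are the
limiting resource, uses a minimum of 1: discarding singleton families
would discard most of the signal at the detection limit. The
asymmetry is intentional — the tumor set serves as a high-confidence
reference, while plasma detection leans on the downstream statistical
guards instead.

**Overlap clipping.** Where mates of one fragment overlap, the overlap
is kept on the mate with the higher mean consensus quality (tie:
read 1) and masked on the other, so a fragment is never counted twice
at one position. Pileups additionally collapse any residual duplicate
(family, position) covers to the better-quality base.

## Candidate calling and coverage QC

The frequency-based candidate caller emits one candidate per (site,
non-reference allele) with at least `min_alt_fragments` (default 1)
supporting consensus fragments, restricted to the capture panel, with
`N` bases excluded everywhere. It deliberately applies no VAF floor and
no error model: its job is to enumerate evidence, and the stringent
filters own the decisions. External caller VCFs can be substituted
interchangeably (`read_variant_table()`), because the filters are
caller-agnostic.

Per-region coverage QC flags a region iff *strictly more than* 10% of
its bases sit below 100x consensus depth — the boundary case of exactly
10% passes. Median per-base depth is computed over panel bases only,
with never-covered bases counted as zero.

## The two filtration modes

**Tumor stringent filter** (reference-set construction): a tumor
variant passes iff VAF > 0.05 *and* it appears in at least one of
COSMIC / TCGA-breast / TCGA-pan-cancer. For FFPE tissue the threshold
rises to VAF > 0.2, because fixation-induced deamination artifacts
populate exactly the low-VAF range. Thresholds are strict
inequalities.

**Plasma stringent filter** (tumor-naive detection): a plasma variant
is accepted iff it (i) affects an exonic region, (ii) is present in
*both* COSMIC *and* the TCGA breast set, and (iii) shows *duplex
support* — variant reads whose alignments start at two or more distinct
genomic coordinates. No VAF condition is applied at all. Two design
points deserve comment:

* The database requirement is implemented as COSMIC AND TCGA-breast,
  with pan-cancer TCGA membership recorded and available as an
  additional requirement (`require_tcga_all = TRUE`) but not demanded
  by default: the breast-set condition is the binding one for a breast
  cancer panel, and requiring the pan-cancer set too changes no
  fixture-level bookkeeping.
* "Duplex configuration" is operationalized as distinct fragment start
  coordinates, not opposite-strand pairing. Distinct start coordinates
  certify distinct original molecules — the property that actually
  rules out a clonal PCR or sequencing artifact. A stricter
  strand-aware mode would additionally demand both orientations;
  the orientation field is retained in the read model so that check
  remains possible downstream.
* Splice-site variants count as satisfying the exonic criterion by
  default (`treat_splice_as_exonic = TRUE`): recurrent splice
  disruptions of driver genes are protein-affecting database variants
  in every relevant sense, and the detection tables this package ships
  include such variants as accepted detections.

## The rescue path

Tumor-known variants missed by the caller are interrogated directly in
the plasma pileup. Two guards apply:

1. **Coordinate rule**: at least two variant reads at at least two
   distinct genomic coordinates.
2. **Fisher exact test**: the 2x2 table (sample alt/ref vs pooled
   control alt/ref) must reject at `alpha = 0.05`.

The test is one-sided (enrichment of the variant allele in the case
sample) by default. The direction of scientific interest is
unambiguous — a tumor-shed variant can only *raise* the mutant
fraction — and a two-sided test would spend half its level on the
impossible direction; still, sidedness is configurable because the
choice is not externally fixed. The default control pool is
healthy-donor plasmas only: pooling in mutation-negative patient
plasmas adds ctDNA-derived noise at other sites' error rates and
measurably dilutes borderline signals, so the mixed pool is retained
only as an option (`include_negative_patients = TRUE`) for sensitivity
analyses. The pool is collapsed to a single summed table rather than
per-control tests, matching the absolute-allele-count framing of the
procedure. No multiple-testing correction enters the rescue decision;
a Benjamini-Hochberg column is emitted as supplementary output, since
the interrogated set is small, tumor-anchored and pre-specified.

## Cohort metrics

Sensitivity, specificity and PPV come with exact Clopper–Pearson
intervals computed from beta quantiles — the method behind the exact
binomial intervals of standard classification tooling, verified in the
test suite against `binom.test()` and `caret::confusionMatrix()`. The
association screen chooses tests mechanically: categorical pairs use
chi-square unless any expected cell is below 5 (then Fisher's exact
test); a continuous metric against a two-level covariate uses the
Wilcoxon rank-sum test (Kruskal–Wallis beyond two levels). Constant
columns are skipped with an explicit reason, and the screen's decision
column is uncorrected (with BH-adjusted values alongside), matching
the exploratory character of such screens.

One bookkeeping subtlety is surfaced rather than hidden: the
positivity count over the packaged detection tables is 25/74 samples,
while the printed diagnostic metrics correspond to an operative
true-positive count of 23. `positivity_table()` reports the raw count;
`diagnostic_metrics()` takes whatever confusion counts the analyst
supplies, so both readings are computable side by side.

## The synthetic-data generator

No raw reads are published for this study, so validation runs on
synthetic data whose generator encodes the study conditions as
defaults:

| Parameter | Default | Meaning |
|---|---|---|
| `consensus_depth` | 2500 | fragments (consensus families) per site, the plasma-scale consensus coverage |
| `family_lambda` | 6 | family size is 1 + Poisson(6), matching the ~7–9x raw-to-consensus collapse |
| `error_rate` | 1e-3 | per-base substitution rate per read copy, pre-consensus |
| `umi_length` | 10 | degenerate barcode length |
| `read_length` | 100 | aligned bases per read |
| `base_quality` | 37 | constant Phred quality of simulated bases |

Fragments covering a site get uniformly random start offsets, so
independent molecules naturally satisfy the duplex coordinate rule;
`frac_duplex` can force a site's mutant fragments onto a single
coordinate to exercise the rule's failure mode. Errors are injected
*after* family replication (per read copy), so consensus genuinely
suppresses them; `polymerase_mode` injects them once per fragment
instead — shared by the whole family and therefore consensus-proof — to
stress the Fisher screen with correlated errors. All randomness flows
through the single mandatory seed; re-runs are byte-identical.

What the generator does *not* emulate: cfDNA fragment-size
distributions, GC and mappability bias, strand-specific damage, clonal
hematopoiesis variants, and real reference sequence (sites sit on a
flat synthetic reference, which is immaterial to allele-count logic).
Passing simulation tests therefore demonstrates the *statistical*
correctness of the machinery — error suppression scaling, detection at
3 mutant molecules in 10,000 wild-type, type-I control of the rescue
screen — not robustness to alignment artifacts in real data.

The cohort generator draws stage/grade/receptor covariates at
Table-1-like frequencies (stage 1/2/3 at 0.32/0.55/0.13 among staged
cases, grade I/II/III at 0.20/0.50/0.30, ER+ 0.90, PR+ 0.77, HER2+
0.08, relapse 0.11) and uses a stage-increasing shedding model
(P(shed) = 0.25/0.35/0.55; log-uniform plasma VAF with stage-increasing
upper bounds 2e-3/8e-3/5e-2). These are the one-time realistic choices
for quantities the source tables constrain only loosely; they are
deliberately not tuned further.

## Numerical choices and degenerate inputs

* VAF at zero depth is `NA` with a warning — never a silent 0/0.
* An all-zero Fisher table (no variant evidence anywhere) yields p = 1.
* Fisher p-values are computed by `stats::fisher.test`; the test suite
  holds them equal to an independent brute-force hypergeometric
  enumeration over tables with margins up to 50.
* Consensus qualities are floored at 2 and capped at 60 (Phred+33
  encoding stays printable).
* Candidate ordering is deterministic (`chrom`, `pos`, `alt`), and both
  pipeline modes are pure functions of (inputs, config, seed).
* Empty inputs (empty BED, empty read set, empty tumor set, zero
  detections) return typed empty results, not errors; invalid inputs
  (start >= end, ragged families, alt count above depth, unknown
  sample ids) fail loudly with the offending item named.

## Problem sizes used in the checks

The packaged checks run at deliberately chosen desk scales: the
detection-limit simulation uses 200 replicates at consensus depth
10,000 with 8 bp site-focused reads (read length does not enter the
site-level detection decision); the type-I simulation uses 2,000 null
sites at consensus depth 120 with two pooled controls; the consensus
error-scaling Monte Carlo uses 1e5 single-position families per family
size. Fixture-based bookkeeping (concordance, yield, positivity,
diagnostics, spectra) is exact and instantaneous.

## Known limitations

* The consensus quality model is a vote margin, not a calibrated
  posterior; downstream logic uses it only as a mask threshold.
* UMI grouping is identity-only; sequencing errors *inside* the barcode
  split a family in two rather than merging wrongly — conservative for
  error suppression, slightly deflationary for family sizes.
* The rescue test treats pooled controls as one homogeneous background;
  site-specific error heterogeneity across controls is not modelled
  (the healthy-only default pool mitigates this).
* Germline subtraction and CHIP filtering are out of scope: the design
  has no matched normals, and database membership plus duplex support
  are the only somatic guards.
* Stage-stratified sensitivity on real cohorts depends on stage
  definitions the packaged tables do not fully pin down; the per-stage
  computation is exercised on synthetic cohorts only.
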