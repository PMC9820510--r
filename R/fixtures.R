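## Packaged study-table fixtures: the cohort characteristics table, the
## tumor/plasma concordance table, the plasma-only detection table and the
## 33-gene capture panel. Row and sample counts are validated at load so a
## corrupted fixture fails loudly rather than skewing downstream bookkeeping.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "ctdnaflow")
  if (!nzchar(p)) stop("packaged fixture not found: ", file)
  p
}

#' Load a packaged study fixture
#'
#' @param name One of:
#' * `"table1"`: cohort clinicopathological characteristics
#'   (characteristic, level, n, percent).
#' * `"table2"`: the 61 tumor mutations of 40 patients with their plasma
#'   caller/manual detection flags and VAFs.
#' * `"table3"`: the 16 plasma-only mutations of 14 patients.
#' * `"panel"`: the 33-gene capture panel (BED, gene-level intervals).
#' * `"annotation"`: a small demonstration annotation flag table.
#'
#' Percent columns are converted to fractions on load; gene symbols carry
#' no typographic markup. Expected shapes (61 rows / 40 samples for
#' `table2`; 16 rows / 14 samples for `table3`; 33 regions for `panel`)
#' are asserted at load time.
#'
#' @return A `data.frame` (or `annotation_db` for `"annotation"`).
#' @examples
#' tb2 <- ctdna_fixture("table2")
#' nrow(tb2)  # 61
#' @export
ctdna_fixture <- function(name = c("table1", "table2", "table3", "panel",
                                   "annotation")) {
  name <- match.arg(name)
  switch(name,
    table1 = {
      tb <- read.delim(fixture_path("table1_cohort.tsv"), sep = "\t",
                       stringsAsFactors = FALSE)
      tb
    },
    table2 = {
      tb <- read_variant_table(fixture_path("table2_tumor_plasma.tsv"),
                               dialect = "table2")
      if (nrow(tb) != 61L || length(unique(tb$sample)) != 40L) {
        stop("tumor/plasma fixture is corrupted: expected 61 rows over 40 samples, got ",
             nrow(tb), " rows over ", length(unique(tb$sample)), " samples")
      }
      tb
    },
    table3 = {
      tb <- read_variant_table(fixture_path("table3_plasma_only.tsv"),
                               dialect = "table3")
      if (nrow(tb) != 16L || length(unique(tb$sample)) != 14L) {
        stop("plasma-only fixture is corrupted: expected 16 rows over 14 samples, got ",
             nrow(tb), " rows over ", length(unique(tb$sample)), " samples")
      }
      tb
    },
    panel = {
      panel <- read_panel_bed(fixture_path("panel_33genes.bed"))
      if (nrow(panel) != 33L) {
        stop("panel fixture is corrupted: expected 33 regions, got ", nrow(panel))
      }
      panel
    },
    annotation = read_annotation_db(fixture_path("annotation_demo.tsv"))
  )
}

#' Build the study-scale sample sheet from the packaged fixtures
#'
#' Reconstructs a 74-case / 22-control plasma sample sheet. Case ids come
#' from the packaged detection tables where known; the remaining case ids
#' (patients without any reported mutation) and all control ids are
#' synthetic placeholders, since the study published no per-sample
#' identifiers beyond the mutated ones.
#'
#' @param n_cases Number of sequenced case plasmas (default 74).
#' @param n_controls Number of sequenced control plasmas (default 22).
#' @return A sample-sheet `data.frame` with columns `sample_id`, `role`,
#'   `tissue_prep`.
#' @export
fixture_sample_sheet <- function(n_cases = 74L, n_controls = 22L) {
  tb2 <- ctdna_fixture("table2")
  tb3 <- ctdna_fixture("table3")
  known <- sort(unique(c(tb2$sample, tb3$sample)))
  if (length(known) > n_cases) {
    stop("more known case ids than n_cases")
  }
  fill <- sprintf("synthetic_case_%02d", seq_len(n_cases - length(known)))
  controls <- sprintf("synthetic_control_%02d", seq_len(n_controls))
  data.frame(
    sample_id = c(known, fill, controls),
    role = c(rep("plasma_case", n_cases), rep("plasma_control", n_controls)),
    tissue_prep = "plasma",
    stringsAsFactors = FALSE
  )
}
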