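## End-to-end orchestration of the two published analysis modes.
## Tumor-informed: build the stringent tumor reference set, rediscover
## it in plasma via the caller path, and rescue caller-missed variants
## with the Fisher screen. Non-informed: plasma-only detection under the
## database/duplex criteria, identical for cases and controls. Every
## dropped variant is retained with its fail reasons so the
## bookkeeping is auditable.

#' Pipeline run configuration
#'
#' Mode-consistent defaults: family-size minimum 3 for tumor consensus
#' and 1 for plasma; consensus base quality 30; no VAF floor in plasma.
#'
#' @param mode `"tumor_informed"` or `"non_informed"`.
#' @param min_family_size_tumor,min_family_size_plasma Family-size
#'   minima (defaults 3 and 1).
#' @param min_base_quality Consensus base quality threshold (default 30).
#' @param tissue_prep Tumor tissue preparation for the tumor filter.
#' @param require_tcga_all Plasma filter option.
#' @param include_negative_patients Rescue pool option.
#' @param alpha,sided Fisher rescue parameters.
#' @param min_alt_fragments Candidate caller support minimum.
#' @param ref Reference allele model passed to [build_pileup()].
#' @param seed Optional seed recorded for provenance.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("tumor_informed", "non_informed"),
                       min_family_size_tumor = 3L,
                       min_family_size_plasma = 1L,
                       min_base_quality = 30L,
                       tissue_prep = "fresh_frozen",
                       require_tcga_all = FALSE,
                       include_negative_patients = FALSE,
                       alpha = 0.05, sided = "greater",
                       min_alt_fragments = 1L, ref = "A", seed = NULL) {
  mode <- match.arg(mode)
  structure(list(
    mode = mode,
    min_family_size_tumor = as.integer(min_family_size_tumor),
    min_family_size_plasma = as.integer(min_family_size_plasma),
    min_base_quality = as.integer(min_base_quality),
    tissue_prep = tissue_prep,
    require_tcga_all = isTRUE(require_tcga_all),
    include_negative_patients = isTRUE(include_negative_patients),
    alpha = alpha, sided = sided,
    min_alt_fragments = as.integer(min_alt_fragments),
    ref = ref, seed = seed,
    version = as.character(utils::packageVersion("ctdnaflow"))
  ), class = "run_config")
}

#' Serialize a run configuration
#'
#' Flat `key = value` lines, embedded as comment headers in every output
#' file for provenance.
#'
#' @param config A [run_config()].
#' @return Character vector of lines.
#' @export
serialize_run_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  vals <- vapply(config, function(v) {
    if (is.null(v)) "NULL" else paste(format(v), collapse = ",")
  }, "")
  sprintf("%s = %s", names(vals), vals)
}

#' Write a detections table with embedded provenance
#'
#' @param detections A detection `data.frame`.
#' @param path Output path.
#' @param config The [run_config()] of the run.
#' @return `path`, invisibly.
#' @export
write_detections_tsv <- function(detections, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", serialize_run_config(config)), con)
  write.table(detections, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

consensus_pileup <- function(reads, panel, min_family_size,
                             min_base_quality, ref) {
  grouped <- group_reads_by_umi(reads)
  cons <- call_consensus_reads(grouped, min_base_quality)
  cons <- filter_consensus_reads(cons, min_family_size)
  cons <- clip_overlap(cons)
  build_pileup(cons, panel, ref = ref)
}

match_variant_keys <- function(a, b) {
  match(paste(a$chrom, a$pos, a$ref, a$alt),
        paste(b$chrom, b$pos, b$ref, b$alt))
}

#' Run the tumor-informed analysis mode
#'
#' Stage order: tumor consensus (family-size minimum 3) -> candidate
#' calling -> tumor stringent filter (the tumor reference set); plasma
#' consensus (minimum 1) -> candidate calling -> caller-path detections
#' (tumor variants rediscovered by the caller); Fisher rescue pass over
#' the caller-missed tumor variants against the control plasmas; merged
#' detections tagged by method; concordance summary.
#'
#' @param tumor_reads Tagged reads of the tumor sample.
#' @param plasma_reads Tagged reads of the paired case plasma.
#' @param control_reads A named list of control plasma read tables.
#' @param annotation An `annotation_db`.
#' @param panel Panel regions.
#' @param config A [run_config()] (`mode = "tumor_informed"`).
#' @return A list: `tumor_variants` (the stringent set, with filter
#'   outcomes for dropped candidates), `detections` (caller + rescued,
#'   with `method`), `rescue` (full rescue report), `concordance`
#'   (caller and overall detected / tumor set size), `config`.
#' @export
run_tumor_informed <- function(tumor_reads, plasma_reads, control_reads,
                               annotation, panel,
                               config = run_config("tumor_informed")) {
  stopifnot(inherits(config, "run_config"))
  t_pile <- consensus_pileup(tumor_reads, panel,
                             config$min_family_size_tumor,
                             config$min_base_quality, config$ref)
  t_cand <- call_candidates(t_pile, config$min_alt_fragments)
  t_flags <- annotation_lookup(annotation, t_cand$chrom, t_cand$pos,
                               t_cand$ref, t_cand$alt)
  t_keep <- logical(nrow(t_cand))
  t_reasons <- character(nrow(t_cand))
  for (i in seq_len(nrow(t_cand))) {
    res <- tumor_stringent_filter(t_cand$vaf[i], t_flags[i, ],
                                  config$tissue_prep)
    t_keep[i] <- res$passed
    t_reasons[i] <- paste(res$fail_reasons, collapse = ";")
  }
  tumor_all <- cbind(t_cand, gene = t_flags$gene, passed = t_keep,
                     fail_reasons = t_reasons)
  tumor_set <- tumor_all[t_keep, , drop = FALSE]

  p_pile <- consensus_pileup(plasma_reads, panel,
                             config$min_family_size_plasma,
                             config$min_base_quality, config$ref)
  p_cand <- call_candidates(p_pile, config$min_alt_fragments)
  hit <- match_variant_keys(tumor_set, p_cand)
  caller_det <- if (nrow(tumor_set)) {
    found <- !is.na(hit)
    data.frame(
      chrom = tumor_set$chrom[found], pos = tumor_set$pos[found],
      ref = tumor_set$ref[found], alt = tumor_set$alt[found],
      gene = tumor_set$gene[found],
      vaf = p_cand$vaf[hit[found]],
      duplex_coord_count = p_cand$n_coords[hit[found]],
      method = if (any(found)) "caller" else character(0),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame()
  }

  missed <- tumor_set[is.na(hit), , drop = FALSE]
  ctrl_piles <- lapply(control_reads, function(r) {
    consensus_pileup(r, panel, config$min_family_size_plasma,
                     config$min_base_quality, config$ref)
  })
  rescue <- rescue_pass(missed, p_pile, ctrl_piles, panel = panel,
                        include_negative_patients =
                          config$include_negative_patients,
                        alpha = config$alpha, sided = config$sided)
  r <- rescue[rescue$passed, , drop = FALSE]
  rescued_det <- if (nrow(r)) {
    data.frame(
      chrom = r$chrom, pos = r$pos, ref = r$ref, alt = r$alt,
      gene = missed$gene[match_variant_keys(r, missed)],
      vaf = r$vaf,
      duplex_coord_count = vapply(match_variant_keys(r, missed), function(i) {
        si <- interrogate_site(p_pile, missed[i, , drop = FALSE])
        length(unique(si$coords))
      }, 0L),
      method = "rescue",
      stringsAsFactors = FALSE
    )
  } else {
    data.frame()
  }
  detections <- rbind(caller_det, rescued_det)
  n_tumor <- nrow(tumor_set)
  concordance <- list(
    n = n_tumor,
    caller_detected = nrow(caller_det),
    overall_detected = nrow(detections),
    caller_fraction = if (n_tumor) nrow(caller_det) / n_tumor else NA_real_,
    overall_fraction = if (n_tumor) nrow(detections) / n_tumor else NA_real_
  )
  list(tumor_variants = tumor_all, tumor_set = tumor_set,
       detections = detections, rescue = rescue,
       concordance = concordance, config = config)
}

#' Run the non-tumor-informed analysis mode
#'
#' Somatic information from solid biopsies is disregarded by
#' construction: the interface takes plasma samples only. Every sample
#' (cases and controls alike) goes through consensus at family-size
#' minimum 1, candidate calling with no VAF threshold, and the plasma
#' stringent filter (exonic + COSMIC + TCGA-breast + duplex support).
#'
#' @param plasma_samples Named list of case plasma read tables.
#' @param control_samples Named list of control plasma read tables.
#' @param annotation An `annotation_db`.
#' @param panel Panel regions.
#' @param sheet Optional sample sheet with covariates; built from the
#'   sample names when `NULL`.
#' @param config A [run_config()] (`mode = "non_informed"`).
#' @return A list: `detections` (all candidates with filter outcomes),
#'   `cohort` (per-sample positivity table), `confusion`, `metrics`
#'   (diagnostics with exact CIs), `control_screen`, `config`.
#' @export
run_non_informed <- function(plasma_samples, control_samples, annotation,
                             panel, sheet = NULL,
                             config = run_config("non_informed")) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(sheet)) {
    sheet <- data.frame(
      sample_id = c(names(plasma_samples), names(control_samples)),
      role = c(rep("plasma_case", length(plasma_samples)),
               rep("plasma_control", length(control_samples))),
      tissue_prep = "plasma",
      stringsAsFactors = FALSE
    )
  }
  all_samples <- c(plasma_samples, control_samples)
  det_rows <- list()
  for (sid in names(all_samples)) {
    pile <- consensus_pileup(all_samples[[sid]], panel,
                             config$min_family_size_plasma,
                             config$min_base_quality, config$ref)
    cand <- call_candidates(pile, config$min_alt_fragments)
    if (!nrow(cand)) next
    flags <- annotation_lookup(annotation, cand$chrom, cand$pos,
                               cand$ref, cand$alt)
    rows <- lapply(seq_len(nrow(cand)), function(i) {
      v <- list(chrom = cand$chrom[i], pos = cand$pos[i], ref = cand$ref[i],
                alt = cand$alt[i], vaf = cand$vaf[i], sample_id = sid,
                class = if (nchar(cand$alt[i]) > 1L) "indel" else "substitution")
      plasma_stringent_filter(v, flags[i, ], cand$coords[i],
                              require_tcga_all = config$require_tcga_all)
    })
    det_rows[[sid]] <- do.call(rbind, rows)
  }
  detections <- if (length(det_rows)) {
    do.call(rbind, c(det_rows, make.row.names = FALSE))
  } else {
    data.frame(sample_id = character(), gene = character(), vaf = numeric(),
               passed = logical(), stringsAsFactors = FALSE)
  }
  pt <- positivity_table(detections, sheet)
  metrics <- suppressWarnings(diagnostic_metrics(pt$confusion))
  screen <- if (length(control_samples)) {
    apply_control_screen(detections, names(control_samples))
  } else {
    NULL
  }
  list(detections = detections, cohort = pt$cohort,
       confusion = pt$confusion, metrics = metrics,
       control_screen = screen, config = config)
}
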