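## Seeded synthetic-data generator: UMI-tagged read families over a
## capture panel with a known truth table. The generator emulates the
## study conditions of ultra-deep hybrid-capture sequencing: a target
## consensus depth around 2,000-2,500x, read families of size
## 1 + Poisson(lambda) (lambda = 6 approximates the observed ~7-9x
## raw-to-consensus collapse), a pre-consensus per-base error rate of
## 1e-3, 10-nt degenerate UMIs, and spiked variants down to 3 mutant
## molecules in 10,000 wild-type (0.03% VAF). The reference is a
## synthetic flat sequence (one base per site's neighbourhood), which is
## immaterial to the allele-count logic downstream.

#' Simulation configuration
#'
#' @param seed Mandatory integer seed; every stochastic call flows
#'   through it.
#' @param panel Panel regions ([read_panel_bed()]).
#' @param sites A `data.frame` of interrogated sites: `chrom`, `pos`
#'   (0-based), `ref` (single base), `alt` (alternate base, an
#'   indel/splice allele token, or `NA` for background sites), `vaf`
#'   (truth fraction, 0 for background). See [sim_sites()].
#' @param consensus_depth Fragments (consensus families) per site
#'   (default 2500, the study-scale plasma consensus coverage).
#' @param family_lambda Family sizes are `1 + Poisson(family_lambda)`
#'   (default 6).
#' @param error_rate Pre-consensus per-base substitution error rate per
#'   read copy (default 1e-3).
#' @param umi_length UMI barcode length (default 10).
#' @param read_length Aligned read length in bp (default 100).
#' @param base_quality Constant Phred base quality of simulated reads
#'   (default 37).
#' @param frac_duplex Probability that a spiked site's mutant fragments
#'   keep their independently drawn start coordinates; with probability
#'   `1 - frac_duplex` all mutant fragments of the site are collapsed
#'   onto a single coordinate (duplex-ineligible support, for testing
#'   the coordinate rule). Default 1.
#' @param polymerase_mode If `TRUE`, errors are injected once per
#'   fragment (shared by the whole family, hence consensus-proof) rather
#'   than per read copy; a stress mode for the Fisher screen. Default
#'   `FALSE`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed, panel, sites, consensus_depth = 2500L,
                       family_lambda = 6, error_rate = 1e-3,
                       umi_length = 10L, read_length = 100L,
                       base_quality = 37L, frac_duplex = 1,
                       polymerase_mode = FALSE) {
  if (missing(seed) || is.na(seed)) stop("a seed is mandatory")
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt", "vaf") %in% names(sites)))
  vafs <- sites$vaf
  if (any(is.na(vafs) & !is.na(sites$alt))) stop("spiked sites need a vaf")
  if (any(vafs < 0 | vafs > 1, na.rm = TRUE)) stop("truth vaf must be in [0, 1]")
  outside <- is.na(panel_region_index(sites$chrom, sites$pos, panel))
  if (any(outside & !is.na(sites$alt) & sites$vaf > 0)) {
    stop("spiked site outside the capture panel: ",
         paste(sites$chrom[outside], sites$pos[outside], collapse = ", ")[1L])
  }
  structure(list(seed = as.integer(seed), panel = panel, sites = sites,
                 consensus_depth = as.integer(consensus_depth),
                 family_lambda = family_lambda, error_rate = error_rate,
                 umi_length = as.integer(umi_length),
                 read_length = as.integer(read_length),
                 base_quality = as.integer(base_quality),
                 frac_duplex = frac_duplex,
                 polymerase_mode = isTRUE(polymerase_mode)),
            class = "sim_config")
}

#' Place interrogation sites on a panel
#'
#' Deterministically spreads `n_sites` sites over the panel regions
#' (round-robin over regions, stepping within each region), leaving a
#' read-length margin from region edges.
#'
#' @param panel Panel regions.
#' @param n_sites Number of sites.
#' @param ref Reference base at each site (default `"A"`).
#' @param alt Alternate allele(s): recycled; `NA` for background sites.
#' @param vaf Truth VAF(s): recycled (default 0).
#' @param margin Margin from region edges in bp (default 200).
#' @param step Within-region spacing in bp (default 211).
#' @return A site `data.frame` for [sim_config()].
#' @export
sim_sites <- function(panel, n_sites, ref = "A", alt = NA_character_,
                      vaf = 0, margin = 200L, step = 211L) {
  stopifnot(nrow(panel) >= 1L, n_sites >= 1L)
  nreg <- nrow(panel)
  i <- seq_len(n_sites)
  r <- ((i - 1L) %% nreg) + 1L
  k <- (i - 1L) %/% nreg
  width <- panel$end[r] - panel$start[r]
  usable <- pmax(width - 2L * margin, 1L)
  pos <- panel$start[r] + margin + (k * step) %% usable
  data.frame(chrom = panel$chrom[r], pos = as.integer(pos),
             ref = rep_len(ref, n_sites), alt = rep_len(alt, n_sites),
             vaf = rep_len(vaf, n_sites), stringsAsFactors = FALSE)
}

random_umis <- function(n, len) {
  if (!n) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  collapse_rows(m)
}

is_base_allele <- function(alt) {
  !is.na(alt) & alt %in% c("A", "C", "G", "T")
}

#' Simulate UMI-tagged read families with a truth table
#'
#' For each site, draws `consensus_depth` fragments covering the site
#' with uniformly random start offsets, marks each fragment mutant with
#' probability equal to the site's truth VAF, assigns a random UMI,
#' expands the fragment into a family of `1 + Poisson(lambda)` read
#' copies, and perturbs every base with the per-base error rate
#' (per copy by default; per fragment in `polymerase_mode`). Mutant
#' fragments carry the alternate base at the spiked position, or an
#' allele token (`allele_tag`/`tag_pos` columns) for indel/splice
#' alleles. Output is byte-identical for a fixed config.
#'
#' @param config A [sim_config()].
#' @return A list: `reads` (tagged reads), `truth` (per spiked site:
#'   `truth_vaf`, `n_alt_fragments`, `n_distinct_coords`, `coords`),
#'   `sites`, `config`.
#' @export
simulate_read_families <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sites <- config$sites
  ns <- nrow(sites)
  depth <- config$consensus_depth
  L <- config$read_length
  nf <- ns * depth
  site_idx <- rep(seq_len(ns), each = depth)

  offset <- sample.int(L, nf, replace = TRUE) - 1L
  start <- sites$pos[site_idx] - offset
  vaf <- ifelse(is.na(sites$vaf), 0, sites$vaf)
  mutant <- stats::runif(nf) < vaf[site_idx]

  ## optionally collapse a site's mutant fragments onto one coordinate
  if (config$frac_duplex < 1) {
    spiked <- which(!is.na(sites$alt) & vaf > 0)
    collapse <- spiked[stats::runif(length(spiked)) >= config$frac_duplex]
    for (s in collapse) {
      idx <- which(site_idx == s & mutant)
      if (length(idx) > 1L) start[idx] <- start[idx[1L]]
    }
  }
  frag_end <- start + L
  umi <- random_umis(nf, config$umi_length)
  orient <- sample(c("F1R2", "F2R1"), nf, replace = TRUE)
  fam_size <- 1L + stats::rpois(nf, config$family_lambda)

  R <- sum(fam_size)
  frag_of_read <- rep(seq_len(nf), fam_size)
  site_of_read <- site_idx[frag_of_read]

  ## true fragment sequence: the site's flat reference base, with the
  ## alternate base substituted at the spiked position of mutant fragments
  M <- matrix(rep(sites$ref[site_of_read], each = L), nrow = L)
  sub_mut <- mutant[frag_of_read] & is_base_allele(sites$alt)[site_of_read]
  if (any(sub_mut)) {
    rowpos <- sites$pos[site_of_read] - start[frag_of_read] + 1L
    cols <- which(sub_mut)
    M[cbind(rowpos[cols], cols)] <- sites$alt[site_of_read][cols]
  }

  ## sequencing errors
  e <- config$error_rate
  if (e > 0) {
    alphabet <- c("A", "C", "G", "T")
    if (config$polymerase_mode) {
      err_f <- which(matrix(stats::runif(nf * L), nrow = L) < e)
      ## replicate fragment-level errors to every copy
      if (length(err_f)) {
        fr <- ((err_f - 1L) %/% L) + 1L   # fragment index
        rw <- ((err_f - 1L) %% L) + 1L
        shift <- sample.int(3L, length(err_f), replace = TRUE)
        cur <- match(M[cbind(rw, match(fr, frag_of_read))], alphabet)
        newb <- alphabet[((cur - 1L + shift) %% 4L) + 1L]
        for (j in seq_along(err_f)) {
          cols <- which(frag_of_read == fr[j])
          M[rw[j], cols] <- newb[j]
        }
      }
    } else {
      err <- which(stats::runif(L * R) < e)
      if (length(err)) {
        cur <- match(M[err], alphabet)
        shift <- sample.int(3L, length(err), replace = TRUE)
        M[err] <- alphabet[((cur - 1L + shift) %% 4L) + 1L]
      }
    }
  }

  bases <- collapse_rows(t(M))
  qchar <- intToUtf8(min(93L, config$base_quality) + 33L)
  reads <- data.frame(
    read_id = sprintf("s%d_f%d_c%d", site_of_read, frag_of_read,
                      sequence(fam_size)),
    umi = umi[frag_of_read],
    chrom = sites$chrom[site_of_read],
    frag_start = start[frag_of_read],
    frag_end = frag_end[frag_of_read],
    orient = orient[frag_of_read],
    mate = "read1",
    pos = start[frag_of_read],
    bases = bases,
    quals = strrep(qchar, L),
    stringsAsFactors = FALSE
  )
  ## indel/splice alleles travel as tokens, not inside the base vector
  tok <- mutant[frag_of_read] & !is.na(sites$alt)[site_of_read] &
    !is_base_allele(sites$alt)[site_of_read]
  if (any(tok)) {
    reads$allele_tag <- ifelse(tok, sites$alt[site_of_read], NA_character_)
    reads$tag_pos <- ifelse(tok, sites$pos[site_of_read], NA_integer_)
  }

  spiked <- which(!is.na(sites$alt))
  truth <- data.frame(
    chrom = sites$chrom[spiked], pos = sites$pos[spiked],
    ref = sites$ref[spiked], alt = sites$alt[spiked],
    truth_vaf = vaf[spiked],
    n_alt_fragments = vapply(spiked, function(s) sum(mutant & site_idx == s), 0L),
    n_distinct_coords = vapply(spiked, function(s) {
      length(unique(start[mutant & site_idx == s]))
    }, 0L),
    coords = vapply(spiked, function(s) {
      paste(sort(unique(start[mutant & site_idx == s])), collapse = ",")
    }, ""),
    stringsAsFactors = FALSE
  )
  list(reads = reads, truth = truth, sites = sites, config = config)
}

#' Simulate one sample (tumor, case plasma or control plasma)
#'
#' Role-specific spiking: tumors carry 1 or more clonal variants at VAFs
#' drawn uniformly in 0.03-0.8 (the tumor VAF range of the study
#' tables); case plasmas carry the paired tumor's variants at
#' log-uniform VAFs in 1e-4 to 5e-2; control plasmas spike nothing but
#' are sequenced over the same sites.
#'
#' @param seed Integer seed.
#' @param role `"tumor"`, `"plasma_case"` or `"plasma_control"`.
#' @param panel Panel regions.
#' @param sites Background sites (see [sim_sites()]); spiked variants
#'   are placed on the first rows for tumors.
#' @param sample_id Sample identifier.
#' @param paired_truth For `plasma_case`: the paired tumor's truth table
#'   (`chrom`, `pos`, `ref`, `alt` at minimum). Required.
#' @param n_variants Number of tumor variants to spike (tumor role).
#' @param plasma_vaf Optional fixed plasma VAF(s) for the paired
#'   variants; drawn log-uniformly when `NULL`.
#' @param ... Further [sim_config()] overrides (`consensus_depth`,
#'   `read_length`, ...).
#' @return A list: `reads`, `truth`, `sheet_row`, `sites`.
#' @export
simulate_sample <- function(seed, role = c("tumor", "plasma_case",
                                           "plasma_control"),
                            panel, sites, sample_id = role,
                            paired_truth = NULL, n_variants = 2L,
                            plasma_vaf = NULL, ...) {
  role <- match.arg(role)
  set.seed(seed)
  sites$alt <- rep_len(NA_character_, nrow(sites))
  sites$vaf <- 0
  if (role == "tumor") {
    n_variants <- min(n_variants, nrow(sites))
    alts <- vapply(seq_len(n_variants), function(i) {
      sample(setdiff(c("A", "C", "G", "T"), sites$ref[i]), 1L)
    }, "")
    sites$alt[seq_len(n_variants)] <- alts
    sites$vaf[seq_len(n_variants)] <- stats::runif(n_variants, 0.03, 0.8)
  } else if (role == "plasma_case") {
    if (is.null(paired_truth) || !nrow(paired_truth)) {
      stop("plasma_case requires the paired tumor's truth table")
    }
    key <- paste(sites$chrom, sites$pos)
    i <- match(paste(paired_truth$chrom, paired_truth$pos), key)
    if (anyNA(i)) stop("paired tumor variants must lie on the sample's sites")
    vafs <- if (is.null(plasma_vaf)) {
      10^stats::runif(nrow(paired_truth), log10(1e-4), log10(5e-2))
    } else {
      rep_len(plasma_vaf, nrow(paired_truth))
    }
    sites$ref[i] <- paired_truth$ref
    sites$alt[i] <- paired_truth$alt
    sites$vaf[i] <- vafs
  }
  cfg <- sim_config(seed = seed + 1L, panel = panel, sites = sites, ...)
  sim <- simulate_read_families(cfg)
  tissue <- if (role == "tumor") "fresh_frozen" else "plasma"
  sim$sheet_row <- data.frame(sample_id = sample_id, role = role,
                              tissue_prep = tissue, stringsAsFactors = FALSE)
  sim
}

#' Default clinicopathological covariate model
#'
#' Draws Table-1-like covariates: stage 1/2/3 with probabilities
#' 0.32/0.55/0.13, grade I/II/III with 0.20/0.50/0.30, ER+ 0.90,
#' PR+ 0.77, HER2+ 0.08, relapse 0.11, symptomatic 0.62.
#'
#' @param n Number of cases.
#' @return A covariate `data.frame`.
#' @export
default_covariate_model <- function(n) {
  data.frame(
    stage = sample(1:3, n, replace = TRUE, prob = c(0.32, 0.55, 0.13)),
    grade = sample(c("I", "II", "III"), n, replace = TRUE,
                   prob = c(0.20, 0.50, 0.30)),
    er_positive = stats::runif(n) < 0.90,
    pr_positive = stats::runif(n) < 0.77,
    her2_positive = stats::runif(n) < 0.08,
    relapse = stats::runif(n) < 0.11,
    symptomatic = stats::runif(n) < 0.62,
    stringsAsFactors = FALSE
  )
}

#' Default stage-dependent shedding model
#'
#' Shedding probability and plasma VAF range both increase with disease
#' stage: P(shed) = 0.25/0.35/0.55 and log-uniform VAF upper bounds
#' 2e-3/8e-3/5e-2 for stages 1/2/3 (lower bound 1e-4 throughout).
#'
#' @param stage Integer stage (1-3).
#' @return A list: `p_shed`, `vaf_lo`, `vaf_hi`.
#' @export
default_shedding_model <- function(stage) {
  stage <- pmin(pmax(as.integer(stage), 1L), 3L)
  list(p_shed = c(0.25, 0.35, 0.55)[stage],
       vaf_lo = 1e-4,
       vaf_hi = c(2e-3, 8e-3, 5e-2)[stage])
}

#' Simulate a full case/control cohort bundle
#'
#' Draws covariates per case, spikes tumor variants, decides shedding
#' per variant from the stage-dependent shedding model, and simulates
#' case and control plasma reads over shared interrogation sites, plus
#' an annotation database flagging every spiked variant as
#' COSMIC/TCGA-listed and exonic (the panel targets recurrent exonic
#' drivers). Supports end-to-end runs of both pipeline modes.
#'
#' @param n_cases,n_controls Cohort sizes (study scale: 74 and 22).
#' @param panel Panel regions.
#' @param seed Integer seed.
#' @param shedding_model Function `stage -> list(p_shed, vaf_lo, vaf_hi)`.
#' @param covariate_model Function `n -> covariate data.frame`.
#' @param n_sites Shared interrogation sites per sample.
#' @param n_variants_per_case Tumor variants spiked per case.
#' @param ... [sim_config()] overrides (e.g. `consensus_depth`,
#'   `read_length`) applied to every sample.
#' @return A list: `sheet` (sample sheet with covariates), `samples`
#'   (named list of read tables), `truth` (per-case spiked variants with
#'   `shed` flag and plasma VAF), `annotation` (an `annotation_db`),
#'   `sites`.
#' @export
simulate_cohort <- function(n_cases = 74L, n_controls = 22L, panel, seed,
                            shedding_model = default_shedding_model,
                            covariate_model = default_covariate_model,
                            n_sites = 4L, n_variants_per_case = 2L, ...) {
  set.seed(seed)
  covs <- covariate_model(n_cases)
  sites0 <- sim_sites(panel, n_sites)
  case_ids <- sprintf("case_%03d", seq_len(n_cases))
  control_ids <- sprintf("control_%03d", seq_len(n_controls))
  seeds <- sample.int(.Machine$integer.max - 2L, n_cases + n_controls)

  samples <- list()
  truth_rows <- list()
  for (i in seq_len(n_cases)) {
    sid <- case_ids[i]
    stage <- covs$stage[i]
    nv <- min(n_variants_per_case, nrow(sites0))
    sites <- sites0
    alts <- vapply(seq_len(nv), function(j) {
      sample(setdiff(c("A", "C", "G", "T"), sites$ref[j]), 1L)
    }, "")
    shed_par <- shedding_model(stage)
    shed <- stats::runif(nv) < shed_par$p_shed
    vafs <- ifelse(shed,
                   10^stats::runif(nv, log10(shed_par$vaf_lo),
                                   log10(shed_par$vaf_hi)),
                   0)
    sites$alt[seq_len(nv)] <- alts
    sites$vaf[seq_len(nv)] <- vafs
    cfg <- sim_config(seed = seeds[i], panel = panel, sites = sites, ...)
    sim <- simulate_read_families(cfg)
    samples[[sid]] <- sim$reads
    truth_rows[[sid]] <- data.frame(
      sample_id = sid, chrom = sites$chrom[seq_len(nv)],
      pos = sites$pos[seq_len(nv)], ref = sites$ref[seq_len(nv)],
      alt = alts, shed = shed, plasma_vaf = vafs,
      stringsAsFactors = FALSE
    )
  }
  for (j in seq_len(n_controls)) {
    sid <- control_ids[j]
    cfg <- sim_config(seed = seeds[n_cases + j], panel = panel,
                      sites = sites0, ...)
    samples[[sid]] <- simulate_read_families(cfg)$reads
  }
  truth <- do.call(rbind, truth_rows)
  ann_rows <- unique(truth[, c("chrom", "pos", "ref", "alt")])
  annotation <- annotation_db(data.frame(
    chrom = ann_rows$chrom, pos = ann_rows$pos + 1L,  # db is 1-based
    ref = ann_rows$ref, alt = ann_rows$alt, gene = "SYNTH",
    in_cosmic = TRUE, in_tcga_bc = TRUE, in_tcga_all = TRUE, exonic = TRUE,
    stringsAsFactors = FALSE
  ))
  sheet <- rbind(
    cbind(data.frame(sample_id = case_ids, role = "plasma_case",
                     tissue_prep = "plasma", stringsAsFactors = FALSE), covs),
    data.frame(sample_id = control_ids, role = "plasma_control",
               tissue_prep = "plasma", stage = NA_integer_,
               grade = NA_character_, er_positive = NA, pr_positive = NA,
               her2_positive = NA, relapse = NA, symptomatic = NA,
               stringsAsFactors = FALSE)
  )
  list(sheet = sheet, samples = samples, truth = truth,
       annotation = annotation, sites = sites0)
}
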