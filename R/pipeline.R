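# Deterministic per-subject sub-seed derived from a master seed.
subject_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

# Genomic DNA contamination dilutes the tumour-derived proportion of
# amplifiable template and adds off-target high-molecular-weight reads.
# `gdna_template_efficiency` is the amplification efficiency of gDNA
# template relative to cfDNA; `offtarget_scale` converts contamination into
# the off-target read fraction.
contamination_effects <- function(gdna, gdna_template_efficiency = 0.5,
                                  offtarget_scale = 0.6) {
  list(theta_dilution = 1 / (1 + gdna_template_efficiency * gdna),
       offtarget_fraction = min(0.85, offtarget_scale * gdna / (1 + gdna)))
}

#' Simulate reads and run alignment + methylation calling for a cohort
#'
#' For every subject, bisulfite read pairs are simulated (tumour fraction
#' diluted and off-target reads added according to the subject's gDNA
#' contamination), merged, aligned to the panel and methylation-called.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param panel An `amplicon_panel`.
#' @param params Baseline [read_sim_params()]; per-subject tumour fraction,
#'   background methylation, off-target fraction and seed are derived from
#'   the cohort truth and `seed`.
#' @param seed Master seed for the per-subject read simulations.
#' @param apply_contamination Model gDNA dilution/off-target effects
#'   (default TRUE).
#' @return A list: `pcts` (sample x region summary rows), `qc` (per-sample
#'   mapping QC), `truth_pct` (per sample x region truth percentage of
#'   fully methylated fragments).
#' @export
run_cohort_pipeline <- function(cohort, panel, params = read_sim_params(),
                                seed = 1L, apply_contamination = TRUE) {
  subjects <- cohort$subjects
  pcts <- list(); qc <- list(); truth <- list()
  for (i in seq_len(nrow(subjects))) {
    subj <- subjects[i, ]
    eff <- if (apply_contamination) {
      contamination_effects(subj$gdna_contamination_truth)
    } else {
      list(theta_dilution = 1, offtarget_fraction = params$offtarget_gdna_read_fraction)
    }
    p <- params
    p$offtarget_gdna_read_fraction <- eff$offtarget_fraction
    p$seed <- subject_seed(seed, i)
    subj_eff <- subj
    subj_eff$tumor_fraction_truth <- subj$tumor_fraction_truth * eff$theta_dilution
    reads <- simulate_reads(subj_eff, panel, p)
    res <- align_call_sample(reads$r1, reads$r2, panel,
                             sample_id = subj$subject_id,
                             q1 = reads$q1, q2 = reads$q2)
    pcts[[i]] <- res$summaries
    qc[[i]] <- data.frame(sample_id = subj$subject_id,
                          n_pairs_total = res$qc$n_pairs_total,
                          n_pairs_mapped = res$qc$n_pairs_mapped,
                          mapping_rate = res$qc$mapping_rate,
                          passed = res$qc$passed,
                          stringsAsFactors = FALSE)
    tt <- reads$truth[reads$truth$region_id != "offtarget", ]
    truth[[i]] <- do.call(rbind, lapply(split(tt, tt$region_id), function(d) {
      data.frame(sample_id = subj$subject_id, region_id = d$region_id[1],
                 truth_pct = 100 * mean(d$fully_methylated),
                 stringsAsFactors = FALSE)
    }))
  }
  list(pcts = do.call(rbind, pcts),
       qc = do.call(rbind, qc),
       truth_pct = do.call(rbind, truth))
}

# Default evaluation strata for the diagnostic scenario.
diagnostic_strata <- function() {
  list(all = list(),
       high_risk = list(risk = "high"),
       ca125_negative = list(ca125_negative = TRUE))
}

# Default evaluation strata for the early-detection scenario.
early_detection_strata <- function() {
  list(all = list(),
       lower_contamination = list(contamination = "lower"),
       higher_contamination = list(contamination = "higher"),
       high_risk = list(risk = "high"),
       high_risk_lower_contamination = list(risk = "high", contamination = "lower"),
       high_risk_lower_contamination_1yr = list(risk = "high",
                                                contamination = "lower",
                                                max_days_to_diagnosis = 365),
       brca_carriers = list(brca = c("BRCA1", "BRCA2")))
}

#' Diagnostic scenario: calibrate thresholds and evaluate on the same cohort
#'
#' Calibrates per-region thresholds at the target specificity on the
#' cohort's QC-passing samples, scores every sample (WID-cfOC, CA125 with
#' temporal imputation, combined), and evaluates sensitivity/specificity in
#' the diagnostic strata.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param pipeline_out Output of [run_cohort_pipeline()] on the same cohort.
#' @param target_specificity Default 0.97.
#' @param level CI level, default 0.95.
#' @param strata Named stratum list (default [diagnostic_strata] set).
#' @return A list: `thresholds`, `scores`, `estimates`, `stage_table`, `qc`.
#' @export
run_diagnostic <- function(cohort, pipeline_out, target_specificity = 0.97,
                           level = 0.95, strata = diagnostic_strata()) {
  subjects <- cohort$subjects
  qc_passed <- stats::setNames(pipeline_out$qc$passed, pipeline_out$qc$sample_id)
  keep <- pipeline_out$pcts$sample_id %in% names(qc_passed)[qc_passed]
  pcts <- pipeline_out$pcts[keep, ]
  is_case <- stats::setNames(subjects$group == "cancer", subjects$subject_id)
  thresholds <- calibrate_threshold_set(pcts, is_case, target_specificity,
                                        calibration_set_id = "diagnostic")
  scores <- score_cohort(pipeline_out$pcts, thresholds, subjects,
                         ca125 = cohort$ca125, qc_passed = qc_passed)
  estimates <- evaluate_strata(subjects, scores, strata = strata, level = level)
  list(thresholds = thresholds, scores = scores, estimates = estimates,
       stage_table = stage_detection_table(subjects, scores, "wid_cfoc"),
       qc = pipeline_out$qc)
}

#' Early-detection scenario: apply transferred thresholds
#'
#' Scores the early-detection cohort with thresholds calibrated elsewhere
#' (no recalibration), computes the cfDNA/gDNA contamination median split
#' within this cohort, and evaluates the stratified diagnostics (all /
#' lower / higher contamination, high-risk, <1 year to diagnosis, BRCA).
#'
#' @param cohort Output of [simulate_cohort()].
#' @param pipeline_out Output of [run_cohort_pipeline()] on the same cohort.
#' @param thresholds A `threshold_set` from the diagnostic calibration.
#' @param profiles Named list of `fragment_profile` objects (names = sample
#'   ids); NULL skips contamination-stratified outputs with a warning.
#' @param level CI level, default 0.95.
#' @param strata Named stratum list (default [early_detection_strata] set).
#' @return A list: `scores`, `contamination`, `estimates`, `stage_table`,
#'   `qc`.
#' @export
run_early_detection <- function(cohort, pipeline_out, thresholds,
                                profiles = NULL, level = 0.95,
                                strata = early_detection_strata()) {
  subjects <- cohort$subjects
  qc_passed <- stats::setNames(pipeline_out$qc$passed, pipeline_out$qc$sample_id)
  scores <- score_cohort(pipeline_out$pcts, thresholds, subjects,
                         ca125 = cohort$ca125, qc_passed = qc_passed)
  contamination <- NULL
  if (is.null(profiles)) {
    warning("no fragment profiles supplied: contamination strata skipped")
    strata <- strata[!vapply(strata, function(s) !is.null(s$contamination), logical(1))]
  } else {
    calls <- do.call(rbind, lapply(names(profiles), function(sid) {
      cfdna_gdna_ratio(profiles[[sid]], sample_id = sid)
    }))
    contamination <- stratify_by_median(calls)
  }
  estimates <- evaluate_strata(subjects, scores, contamination,
                               strata = strata, level = level)
  list(scores = scores, contamination = contamination, estimates = estimates,
       stage_table = stage_detection_table(subjects, scores, "wid_cfoc"),
       qc = pipeline_out$qc)
}

#' Write a full synthetic study to disk
#'
#' Generates the amplicon panel, both cohorts, per-sample FASTQ pairs,
#' fragment-size profiles and sample sheets, and writes everything under
#' `out_dir` (FASTA, BED, gzipped FASTQ, TSV, JSON truth tables) together
#' with a manifest of MD5 hashes. Deterministic for a fixed seed.
#'
#' @param out_dir Output directory (created; refuses to overwrite an
#'   existing manifest unless `force = TRUE`).
#' @param seed Master seed.
#' @param designs Named list of cohort designs (defaults: the diagnostic
#'   and early-detection designs).
#' @param panel_args Arguments to [make_reference_panel()].
#' @param params Baseline [read_sim_params()].
#' @param force Overwrite existing outputs.
#' @return Invisibly, the manifest as a named character vector of hashes.
#' @export
run_simulation <- function(out_dir, seed,
                           designs = list(diagnostic = cohort_design_diagnostic(),
                                          early_detection = cohort_design_early_detection()),
                           panel_args = list(n_regions = 3, region_length_bp = 150,
                                             n_cpgs_per_region = 6),
                           params = read_sim_params(),
                           force = FALSE) {
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !force) {
    stop("outputs already exist in '", out_dir, "' (use force = TRUE)")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  panel <- do.call(make_reference_panel, c(panel_args, list(seed = seed)))
  write_panel(panel, file.path(out_dir, "panel.fasta"),
              file.path(out_dir, "panel.bed"))
  files <- c(file.path(out_dir, "panel.fasta"), file.path(out_dir, "panel.bed"))
  set_offset <- 0L
  for (set_name in names(designs)) {
    cohort <- simulate_cohort(designs[[set_name]], seed = subject_seed(seed, set_offset))
    subjects <- cohort$subjects
    sheet_path <- file.path(out_dir, paste0(set_name, "_samples.tsv"))
    write_tsv(subjects[, c("subject_id", "group", "grade", "stage",
                           "brca_status", "sample_date", "diagnosis_date")],
              sheet_path)
    ca_path <- file.path(out_dir, paste0(set_name, "_ca125.tsv"))
    write_tsv(cohort$ca125, ca_path)
    files <- c(files, sheet_path, ca_path)
    profiles <- list()
    truth_all <- list()
    for (i in seq_len(nrow(subjects))) {
      subj <- subjects[i, ]
      eff <- contamination_effects(subj$gdna_contamination_truth)
      p <- params
      p$offtarget_gdna_read_fraction <- eff$offtarget_fraction
      p$seed <- subject_seed(seed, set_offset + i)
      subj_eff <- subj
      subj_eff$tumor_fraction_truth <- subj$tumor_fraction_truth * eff$theta_dilution
      reads <- simulate_reads(subj_eff, panel, p)
      r1p <- file.path(out_dir, paste0(subj$subject_id, "_R1.fastq.gz"))
      r2p <- file.path(out_dir, paste0(subj$subject_id, "_R2.fastq.gz"))
      write_fastq_pair(reads, r1p, r2p)
      files <- c(files, r1p, r2p)
      profiles[[subj$subject_id]] <-
        simulate_fragment_profile(subj$gdna_contamination_truth,
                                  seed = subject_seed(seed, set_offset + i))
      truth_all[[subj$subject_id]] <- reads$truth
    }
    prof_path <- file.path(out_dir, paste0(set_name, "_profiles.tsv"))
    write_fragment_profiles(profiles, prof_path)
    truth_path <- file.path(out_dir, paste0(set_name, "_truth.json"))
    jsonlite::write_json(truth_all, truth_path, dataframe = "columns")
    files <- c(files, prof_path, truth_path)
    set_offset <- set_offset + nrow(subjects) + 1000L
  }
  hashes <- tools::md5sum(files)
  names(hashes) <- basename(files)
  jsonlite::write_json(as.list(hashes), manifest_path, auto_unbox = TRUE)
  invisible(hashes)
}

#' Align and call a sample from FASTQ files
#'
#' File-based entry to [align_call_sample()].
#'
#' @param r1_path,r2_path FASTQ paths.
#' @param panel An `amplicon_panel` (or use [read_panel()]).
#' @param sample_id Sample label.
#' @param ... Passed to [align_call_sample()].
#' @return See [align_call_sample()].
#' @export
align_call_fastq <- function(r1_path, r2_path, panel, sample_id = "sample", ...) {
  reads <- read_fastq_pair(r1_path, r2_path)
  align_call_sample(reads$r1, reads$r2, panel, sample_id = sample_id,
                    q1 = reads$q1, q2 = reads$q2, ...)
}
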