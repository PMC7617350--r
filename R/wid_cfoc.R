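#' Calibrate a per-region fully-methylated-read threshold
#'
#' A sample is called positive in a region when its percentage of fully
#' methylated reads is strictly above the region threshold. Candidate
#' thresholds are the sorted unique observed values (controls and cases);
#' the candidate whose control specificity is closest to the target is
#' chosen, ties on |specificity - target| broken toward the higher
#' specificity, remaining ties toward the lower threshold. With n controls
#' the achievable specificities are k/n, so a 41-control calibration set
#' operates at 40/41 = 97.6% when a separating threshold exists.
#'
#' @param control_pcts Finite nonnegative control values (>= 1 required).
#' @param case_pcts Case values (used only to report achieved sensitivity;
#'   may be empty).
#' @param target_specificity Default 0.97.
#' @return A list: `threshold_pct`, `achieved_specificity`,
#'   `achieved_sensitivity` (NA without cases).
#' @export
calibrate_threshold <- function(control_pcts, case_pcts = numeric(0),
                                target_specificity = 0.97) {
  control_pcts <- control_pcts[!is.na(control_pcts)]
  case_pcts <- case_pcts[!is.na(case_pcts)]
  if (length(control_pcts) == 0L) stop("calibration requires at least one control value")
  if (any(!is.finite(control_pcts)) || any(control_pcts < 0)) {
    stop("control values must be finite and >= 0")
  }
  cand <- sort(unique(c(control_pcts, case_pcts)))
  spec <- vapply(cand, function(t) mean(control_pcts <= t), numeric(1))
  d <- abs(spec - target_specificity)
  # closest to target; ties toward higher specificity, then lower threshold
  ord <- order(d, -spec, cand)
  best <- ord[1]
  list(threshold_pct = cand[best],
       achieved_specificity = spec[best],
       achieved_sensitivity = if (length(case_pcts) > 0) {
         mean(case_pcts > cand[best])
       } else {
         NA_real_
       })
}

#' Calibrate thresholds for every panel region
#'
#' @param pcts Data frame with sample_id, region_id, pct_fully_methylated.
#' @param is_case Named logical vector (names = sample_id), TRUE for cancer.
#' @param target_specificity Default 0.97.
#' @param calibration_set_id Label stored with the threshold set.
#' @return A `threshold_set` data frame: region_id, threshold_pct,
#'   achieved_specificity, achieved_sensitivity; attributes
#'   `target_specificity`, `calibration_set_id`.
#' @export
calibrate_threshold_set <- function(pcts, is_case, target_specificity = 0.97,
                                    calibration_set_id = "calibration") {
  rows <- lapply(unique(pcts$region_id), function(rid) {
    d <- pcts[pcts$region_id == rid, ]
    case <- is_case[d$sample_id]
    th <- calibrate_threshold(d$pct_fully_methylated[!case],
                              d$pct_fully_methylated[case],
                              target_specificity)
    data.frame(region_id = rid, threshold_pct = th$threshold_pct,
               achieved_specificity = th$achieved_specificity,
               achieved_sensitivity = th$achieved_sensitivity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "target_specificity") <- target_specificity
  attr(out, "calibration_set_id") <- calibration_set_id
  class(out) <- c("threshold_set", "data.frame")
  out
}

#' Compute the WID-cfOC call for one sample
#'
#' Positive iff any region with a defined percentage is strictly above its
#' threshold; a value equal to the threshold is negative. Regions without
#' amplification (undefined percentage) are skipped; a sample undefined in
#' every region is negative by absence of signal and flagged.
#'
#' @param region_pcts Named numeric vector (names = region_id; NA allowed).
#' @param thresholds A `threshold_set` covering every defined region.
#' @return A list: `wid_cfoc_positive`, `all_undefined` flag.
#' @export
score_sample <- function(region_pcts, thresholds) {
  defined <- names(region_pcts)[!is.na(region_pcts)]
  missing_th <- setdiff(defined, thresholds$region_id)
  if (length(missing_th) > 0L) {
    stop("no threshold configured for region(s): ",
         paste(missing_th, collapse = ", "))
  }
  if (length(defined) == 0L) {
    return(list(wid_cfoc_positive = FALSE, all_undefined = TRUE))
  }
  th <- stats::setNames(thresholds$threshold_pct, thresholds$region_id)
  list(wid_cfoc_positive = any(region_pcts[defined] > th[defined]),
       all_undefined = FALSE)
}

#' Classify a CA125 measurement
#'
#' Values of 35 U/mL or more are abnormal (positive).
#'
#' @param value CA125 in U/mL (>= 0).
#' @return `"positive"` or `"negative"`.
#' @export
ca125_classify <- function(value) {
  if (any(value < 0, na.rm = TRUE)) stop("CA125 values must be >= 0")
  ifelse(value >= 35, "positive", "negative")
}

#' Infer CA125 status at the index sample date
#'
#' A measurement on the index date is classified directly. Otherwise: a
#' positive result before the index date carries forward as positive; a
#' negative result after the index date carries back as negative. A negative
#' result only before the index date, a positive result only after it, or no
#' measurement at all leaves the status unknowable and the sample is
#' excluded from CA125 analyses.
#'
#' @param measurements Data frame with `date` and `value` (may be empty).
#' @param index_date The cfDNA sampling date.
#' @return `"positive"`, `"negative"` or `"excluded"`.
#' @export
ca125_impute <- function(measurements, index_date) {
  if (is.null(measurements) || nrow(measurements) == 0L) return("excluded")
  at <- measurements[measurements$date == index_date, ]
  if (nrow(at) > 0L) return(ca125_classify(at$value[which.max(at$date)]))
  before <- measurements[measurements$date < index_date, ]
  if (nrow(before) > 0L) {
    nearest <- before$value[which.max(as.numeric(before$date))]
    if (ca125_classify(nearest) == "positive") return("positive")
    return("excluded")  # negative before the index date: status unknowable
  }
  after <- measurements[measurements$date > index_date, ]
  nearest <- after$value[which.min(as.numeric(after$date))]
  if (ca125_classify(nearest) == "negative") return("negative")
  "excluded"  # positive after the index date: status unknowable
}

#' Combine the WID-cfOC and CA125 calls
#'
#' The combined marker is positive when either component is positive;
#' samples with excluded CA125 are excluded from combined analyses.
#'
#' @param wid_positive Logical WID-cfOC call.
#' @param ca125_status `"positive"`, `"negative"` or `"excluded"`.
#' @return `"positive"`, `"negative"` or `"excluded"`.
#' @export
combined_score <- function(wid_positive, ca125_status) {
  ifelse(ca125_status == "excluded", "excluded",
         ifelse(wid_positive | ca125_status == "positive",
                "positive", "negative"))
}

#' Score every sample of a cohort
#'
#' Applies [score_sample()], [ca125_impute()] and [combined_score()] across
#' a cohort. QC-failed samples are dropped with their IDs recorded in
#' attribute `"excluded_qc"`.
#'
#' @param pcts Data frame: sample_id, region_id, pct_fully_methylated.
#' @param thresholds A `threshold_set`.
#' @param subjects Cohort `subjects` data frame (needs subject_id,
#'   sample_date).
#' @param ca125 Long-format CA125 history (subject_id, date, value), or NULL.
#' @param qc_passed Optional named logical vector of per-sample QC results.
#' @return Data frame: sample_id, one `pct_<region>` column per region,
#'   wid_cfoc_positive, all_regions_undefined, ca125_status, combined.
#' @export
score_cohort <- function(pcts, thresholds, subjects, ca125 = NULL,
                         qc_passed = NULL) {
  ids <- unique(pcts$sample_id)
  excluded_qc <- character(0)
  if (!is.null(qc_passed)) {
    excluded_qc <- ids[!qc_passed[ids]]
    ids <- ids[qc_passed[ids]]
  }
  rows <- lapply(ids, function(sid) {
    d <- pcts[pcts$sample_id == sid, ]
    v <- stats::setNames(d$pct_fully_methylated, d$region_id)
    sc <- score_sample(v, thresholds)
    subj <- subjects[subjects$subject_id == sid, ]
    ca_status <- if (is.null(ca125) || nrow(subj) == 0L) {
      "excluded"
    } else {
      ca125_impute(ca125[ca125$subject_id == sid, , drop = FALSE],
                   subj$sample_date[1])
    }
    out <- data.frame(sample_id = sid, stringsAsFactors = FALSE)
    for (rid in thresholds$region_id) {
      out[[paste0("pct_", rid)]] <- if (rid %in% names(v)) v[[rid]] else NA_real_
    }
    out$wid_cfoc_positive <- sc$wid_cfoc_positive
    out$all_regions_undefined <- sc$all_undefined
    out$ca125_status <- ca_status
    out$combined <- combined_score(sc$wid_cfoc_positive, ca_status)
    out
  })
  out <- do.call(rbind, rows)
  attr(out, "excluded_qc") <- excluded_qc
  out
}

#' Write / read a threshold set as JSON
#'
#' @param thresholds A `threshold_set`.
#' @param path File path.
#' @return `read_threshold_set` returns a `threshold_set`.
#' @export
write_threshold_set <- function(thresholds, path) {
  obj <- list(target_specificity = attr(thresholds, "target_specificity"),
              calibration_set_id = attr(thresholds, "calibration_set_id"),
              regions = as.data.frame(thresholds))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_threshold_set
#' @export
read_threshold_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- obj$regions
  attr(out, "target_specificity") <- obj$target_specificity
  attr(out, "calibration_set_id") <- obj$calibration_set_id
  class(out) <- c("threshold_set", "data.frame")
  out
}
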