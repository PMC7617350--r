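#' Exact Clopper-Pearson binomial confidence interval
#'
#' Exact two-sided interval from beta-distribution quantiles: the lower
#' bound is the alpha/2 quantile of Beta(x, n - x + 1) (0 when x = 0), the
#' upper bound the 1 - alpha/2 quantile of Beta(x + 1, n - x) (1 when
#' x = n). Coverage is conservative (at least the nominal level).
#'
#' @param x Successes (0 <= x <= n).
#' @param n Trials (>= 1).
#' @param level Confidence level, default 0.95.
#' @return Numeric vector `c(lower, upper)` on the proportion scale.
#' @export
clopper_pearson <- function(x, n, level = 0.95) {
  if (n < 1L || x < 0L || x > n) stop("require 0 <= x <= n and n >= 1")
  alpha <- 1 - level
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

# One DiagnosticEstimate row.
diag_estimate <- function(stratum, marker, metric, x, n, level) {
  if (n == 0L) {
    return(data.frame(stratum = stratum, marker = marker, metric = metric,
                      x = 0L, n = 0L, point = NA_real_,
                      ci_lower = NA_real_, ci_upper = NA_real_,
                      stringsAsFactors = FALSE))
  }
  ci <- clopper_pearson(x, n, level)
  data.frame(stratum = stratum, marker = marker, metric = metric,
             x = x, n = n, point = x / n,
             ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
             stringsAsFactors = FALSE)
}

#' Sensitivity and specificity with exact confidence intervals
#'
#' Sensitivity is TP/(TP+FN) over case-labelled samples, specificity
#' TN/(TN+FP) over control-labelled samples, each with a Clopper-Pearson
#' interval. Excluded (NA) predictions are dropped; the number dropped is
#' recorded in attribute `"n_excluded"`. A side without samples yields an
#' undefined (NA) estimate rather than an error.
#'
#' @param predictions Logical vector (TRUE = test positive; NA = excluded).
#' @param truth_labels Logical vector (TRUE = case).
#' @param level Confidence level, default 0.95.
#' @param stratum,marker Labels carried into the output.
#' @return Two-row data frame (sensitivity, specificity) with x, n, point,
#'   ci_lower, ci_upper.
#' @export
sens_spec <- function(predictions, truth_labels, level = 0.95,
                      stratum = "all", marker = "test") {
  stopifnot(length(predictions) == length(truth_labels))
  keep <- !is.na(predictions)
  n_excluded <- sum(!keep)
  p <- predictions[keep]
  y <- truth_labels[keep]
  out <- rbind(
    diag_estimate(stratum, marker, "sensitivity", sum(p & y), sum(y), level),
    diag_estimate(stratum, marker, "specificity", sum(!p & !y), sum(!y), level)
  )
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Empirical ROC curve and AUC
#'
#' Standard empirical ROC with tied scores grouped (one operating point per
#' distinct score; positivity means score strictly above the threshold,
#' matching the score's positivity rule). The AUC equals the normalized
#' Mann-Whitney U statistic: the fraction of case-control pairs in which
#' the case scores higher, counting ties as 1/2.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Logical (TRUE = case); both classes must be present.
#' @return A list: `points` (data frame threshold/fpr/tpr) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("ROC requires at least one case and one control")
  thr <- c(-Inf, sort(unique(scores)))
  points <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) mean(scores[!labels] > t), numeric(1)),
    tpr = vapply(thr, function(t) mean(scores[labels] > t), numeric(1))
  )
  r <- rank(scores)  # midranks handle ties as 1/2
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(points = points[order(points$fpr, points$tpr), ], auc = auc)
}

#' Paired-difference t confidence interval
#'
#' The standard paired-t interval for the mean of per-subject difference
#' scores: delta +/- t(alpha/2, N-1) * S_D / sqrt(N), with S_D the sample
#' standard deviation of the differences. Set `sd_is_se = TRUE` to treat
#' S_D as a pre-computed standard error (the sqrt(N) division is then
#' skipped).
#'
#' @param diff_scores Numeric vector of per-subject differences (N >= 2).
#' @param level Confidence level, default 0.95.
#' @param sd_is_se Interpret the dispersion term as a standard error.
#' @return A list: delta, sd, n, t_crit, lower, upper.
#' @export
paired_difference_ci <- function(diff_scores, level = 0.95, sd_is_se = FALSE) {
  n <- length(diff_scores)
  if (n < 2L) stop("need at least 2 difference scores")
  delta <- mean(diff_scores)
  s <- stats::sd(diff_scores)
  t_crit <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  half <- t_crit * if (sd_is_se) s else s / sqrt(n)
  list(delta = delta, sd = s, n = n, t_crit = t_crit,
       lower = delta - half, upper = delta + half)
}

#' Day/night paired concordance split by signal level
#'
#' Pearson correlation between paired (e.g. diurnal/nocturnal)
#' fully-methylated-read percentages, computed separately for pairs whose
#' mean value is above the split and at or below it; also counts discordant
#' positive/negative calls across `call_threshold`. Strata with fewer than
#' 3 pairs, or with a constant member, yield an undefined correlation.
#'
#' @param day_values,night_values Equal-length paired numeric vectors.
#' @param split_at Signal split in percent fully methylated reads
#'   (default 1).
#' @param call_threshold Positivity threshold used for the discordance
#'   count (default `split_at`).
#' @return A list: r_above, r_below, n_above, n_below, n_discordant.
#' @export
paired_concordance <- function(day_values, night_values, split_at = 1.0,
                               call_threshold = split_at) {
  stopifnot(length(day_values) == length(night_values))
  m <- (day_values + night_values) / 2
  strat_cor <- function(idx) {
    if (sum(idx) < 3L) return(NA_real_)
    d <- day_values[idx]; n <- night_values[idx]
    if (stats::sd(d) == 0 || stats::sd(n) == 0) return(NA_real_)
    stats::cor(d, n)
  }
  list(r_above = strat_cor(m > split_at),
       r_below = strat_cor(m <= split_at),
       n_above = sum(m > split_at),
       n_below = sum(m <= split_at),
       n_discordant = sum((day_values > call_threshold) !=
                            (night_values > call_threshold)))
}

# Resolve one stratum specification into the sample ids it contains.
# Case-only clauses (risk, stage, max_days_to_diagnosis) restrict cases and
# leave controls untouched; shared clauses (contamination, brca,
# ca125_negative) restrict both sides.
resolve_stratum <- function(spec, subjects, scores, contamination = NULL) {
  keep <- rep(TRUE, nrow(subjects))
  is_case <- subjects$group == "cancer"
  if (!is.null(spec$risk)) {
    hr <- subjects$grade %in% c("2", "3")
    sel <- if (spec$risk == "high") hr else !hr
    keep <- keep & (!is_case | sel)
  }
  if (!is.null(spec$stage)) {
    keep <- keep & (!is_case | subjects$stage %in% spec$stage)
  }
  if (!is.null(spec$max_days_to_diagnosis)) {
    keep <- keep & (!is_case |
                      (!is.na(subjects$days_to_diagnosis) &
                         subjects$days_to_diagnosis >= 0 &
                         subjects$days_to_diagnosis < spec$max_days_to_diagnosis))
  }
  if (!is.null(spec$brca)) {
    keep <- keep & subjects$brca_status %in% spec$brca
  }
  if (!is.null(spec$contamination)) {
    if (is.null(contamination)) stop("stratum needs contamination data, none supplied")
    grp <- stats::setNames(contamination$group, contamination$sample_id)
    want <- paste0(spec$contamination, "_contamination")
    keep <- keep & !is.na(grp[subjects$subject_id]) &
      grp[subjects$subject_id] == want
  }
  if (isTRUE(spec$ca125_negative)) {
    st <- stats::setNames(scores$ca125_status, scores$sample_id)
    keep <- keep & !is.na(st[subjects$subject_id]) &
      st[subjects$subject_id] == "negative"
  }
  unknown <- setdiff(names(spec), c("risk", "stage", "max_days_to_diagnosis",
                                    "brca", "contamination", "ca125_negative"))
  if (length(unknown) > 0L) {
    stop("unknown stratum key(s): ", paste(unknown, collapse = ", "))
  }
  subjects$subject_id[keep]
}

#' Stratified diagnostic evaluation of all three markers
#'
#' For every named stratum specification, computes sensitivity and
#' specificity with exact confidence intervals for the WID-cfOC score,
#' CA125 and the combined score. Case-only filters (risk class, stage, time
#' to diagnosis) restrict the case side only; contamination group, BRCA
#' status and the CA125-negative subset restrict both sides. Excluded
#' samples (CA125 unknowable) are dropped per marker with counts logged in
#' attribute `"n_excluded"`. Empty strata yield NA rows, not errors.
#'
#' @param subjects Cohort subjects data frame.
#' @param scores Output of [score_cohort()].
#' @param contamination Optional stratified contamination calls (from
#'   [stratify_by_median()]).
#' @param strata Named list of stratum specifications, e.g.
#'   `list(all = list(), high_risk = list(risk = "high"))`.
#' @param level Confidence level, default 0.95.
#' @return Data frame of estimates: stratum, marker, metric, x, n, point,
#'   ci_lower, ci_upper.
#' @export
evaluate_strata <- function(subjects, scores, contamination = NULL,
                            strata = list(all = list()), level = 0.95) {
  joined <- merge(subjects, scores, by.x = "subject_id", by.y = "sample_id")
  excl <- integer(0)
  out <- do.call(rbind, lapply(names(strata), function(sname) {
    ids <- resolve_stratum(strata[[sname]], subjects, scores, contamination)
    d <- joined[joined$subject_id %in% ids, ]
    truth <- d$group == "cancer"
    markers <- list(
      wid_cfoc = d$wid_cfoc_positive,
      ca125 = ifelse(d$ca125_status == "excluded", NA,
                     d$ca125_status == "positive"),
      combined = ifelse(d$combined == "excluded", NA, d$combined == "positive")
    )
    do.call(rbind, lapply(names(markers), function(mk) {
      est <- sens_spec(markers[[mk]], truth, level,
                       stratum = sname, marker = mk)
      excl[[paste(sname, mk, sep = ".")]] <<- attr(est, "n_excluded")
      est
    }))
  }))
  rownames(out) <- NULL
  attr(out, "n_excluded") <- excl
  out
}

#' Stage-stratified detection counts
#'
#' Detected/total cancer counts per tumour stage for one marker.
#'
#' @param subjects Cohort subjects data frame.
#' @param scores Output of [score_cohort()].
#' @param marker `"wid_cfoc"`, `"ca125"` or `"combined"`.
#' @return Data frame: stage, n_detected, n_total.
#' @export
stage_detection_table <- function(subjects, scores, marker = "wid_cfoc") {
  d <- merge(subjects[subjects$group == "cancer", ], scores,
             by.x = "subject_id", by.y = "sample_id")
  pos <- switch(marker,
                wid_cfoc = d$wid_cfoc_positive,
                ca125 = d$ca125_status == "positive",
                combined = d$combined == "positive",
                stop("unknown marker: ", marker))
  stages <- c("I", "II", "III", "IV", "unknown")
  data.frame(stage = stages,
             n_detected = vapply(stages, function(s) sum(pos[d$stage == s]), integer(1)),
             n_total = vapply(stages, function(s) sum(d$stage == s), integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
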