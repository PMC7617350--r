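#' Quantify genomic-DNA contamination as a cfDNA/gDNA mass ratio
#'
#' Integrates the fragment-size profile mass over a cell-free DNA window and
#' a high-molecular-weight genomic DNA window (bins assigned by midpoint)
#' and returns their ratio. A sample with no gDNA mass gets an infinite
#' ratio, flagged, which sorts above every finite ratio in the median split.
#'
#' @param profile A `fragment_profile` (see [simulate_fragment_profile()]),
#'   or a list with `bin_edges` and `mass`.
#' @param sample_id Sample label.
#' @param cf_window_bp cfDNA window, default c(50, 700).
#' @param gdna_window_bp gDNA window, default c(700, Inf).
#' @return A one-row data frame: sample_id, cfdna_mass, gdna_mass, ratio,
#'   infinite_flag.
#' @export
cfdna_gdna_ratio <- function(profile, sample_id = "sample",
                             cf_window_bp = c(50, 700),
                             gdna_window_bp = c(700, Inf)) {
  if (max(cf_window_bp) > min(gdna_window_bp) &&
      max(gdna_window_bp) > min(cf_window_bp)) {
    stop("cfDNA and gDNA windows must be disjoint")
  }
  edges <- profile$bin_edges
  mass <- profile$mass
  stopifnot(length(mass) == length(edges) - 1L)
  if (sum(mass) <= 0) stop("invalid profile: total mass must be positive")
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  cf <- sum(mass[mid >= cf_window_bp[1] & mid < cf_window_bp[2]])
  g <- sum(mass[mid >= gdna_window_bp[1] & mid < gdna_window_bp[2]])
  data.frame(sample_id = sample_id, cfdna_mass = cf, gdna_mass = g,
             ratio = if (g > 0) cf / g else Inf,
             infinite_flag = g == 0,
             stringsAsFactors = FALSE)
}

#' Stratify samples by the cohort-median cfDNA/gDNA ratio
#'
#' The cohort median is computed over all ratios (infinite ratios sort above
#' every finite value); samples with ratio at or below the median form the
#' higher-contamination group, samples above it the lower-contamination
#' group. For an even cohort the median is the midpoint of the central order
#' statistics.
#'
#' @param calls Data frame from [cfdna_gdna_ratio()] rows (needs `ratio`).
#' @return `calls` with a `group` column
#'   (`higher_contamination`/`lower_contamination`) and the cohort median in
#'   attribute `"cohort_median"` and column `cohort_median`.
#' @export
stratify_by_median <- function(calls) {
  if (nrow(calls) < 2L) stop("need at least 2 samples to stratify")
  med <- stats::median(calls$ratio)
  calls$group <- ifelse(calls$ratio <= med, "higher_contamination",
                        "lower_contamination")
  calls$cohort_median <- med
  attr(calls, "cohort_median") <- med
  calls
}
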