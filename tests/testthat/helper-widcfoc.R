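# Shared fixtures and independent oracles for the test suite.

tiny_panel <- function(seed = 101L, n_cpgs = 6L, len = 150L) {
  make_reference_panel(3, len, n_cpgs, seed = seed)
}

# Independent brute-force aligner: scores every region x offset placement in
# the reduced alphabet with plain character loops; deliberately written
# without reusing the package's alignment internals.
brute_force_align <- function(fragment, panel, max_mismatch_rate = 0.1) {
  lf <- nchar(fragment)
  best_region <- NA_character_
  best_offset <- NA_integer_
  best_mm <- Inf
  for (region in panel) {
    ref <- region$ref_seq
    if (region$conversion_mode == "C2T") {
      ref <- gsub("C", "T", ref, fixed = TRUE)
      frag <- gsub("C", "T", fragment, fixed = TRUE)
    } else {
      ref <- gsub("G", "A", ref, fixed = TRUE)
      frag <- gsub("G", "A", fragment, fixed = TRUE)
    }
    lr <- nchar(ref)
    if (lf > lr) next
    fc <- strsplit(frag, "")[[1]]
    rc <- strsplit(ref, "")[[1]]
    for (off in 0:(lr - lf)) {
      mm <- 0L
      for (j in seq_len(lf)) {
        if (rc[off + j] != fc[j]) mm <- mm + 1L
      }
      if (mm < best_mm) {
        best_mm <- mm
        best_region <- region$region_id
        best_offset <- off
      }
    }
  }
  list(region_id = best_region, offset = best_offset,
       mismatches = if (is.finite(best_mm)) as.integer(best_mm) else NA_integer_,
       mapped = is.finite(best_mm) && best_mm / lf <= max_mismatch_rate)
}

# Brute-force AUC: fraction of case-control pairs where the case scores
# higher, ties counted 1/2.
brute_force_auc <- function(scores, labels) {
  cases <- scores[labels]
  controls <- scores[!labels]
  tot <- 0
  for (a in cases) {
    for (b in controls) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
  }
  tot / (length(cases) * length(controls))
}

# Exact sensitivity/specificity counts on the subset where a marker call is
# defined; used for the OR-dominance set inclusions.
marker_counts <- function(positive, truth) {
  keep <- !is.na(positive)
  list(tp = sum(positive[keep] & truth[keep]),
       cases = sum(truth[keep]),
       tn = sum(!positive[keep] & !truth[keep]),
       controls = sum(!truth[keep]))
}
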