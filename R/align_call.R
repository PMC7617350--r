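#' Reduce a sequence to the three-letter bisulfite alphabet
#'
#' Bisulfite conversion collapses methylation information into C/T (top
#' strand) or G/A (bottom strand) ambiguity; matching is therefore done in a
#' reduced alphabet: mode `"C2T"` maps every C to T, mode `"G2A"` maps every
#' G to A. Other bases are unchanged. Idempotent.
#'
#' @param seq A/C/G/T/N string (or vector of strings).
#' @param mode `"C2T"` or `"G2A"`.
#' @return The reduced sequence(s).
#' @export
reduce_alphabet <- function(seq, mode) {
  switch(mode,
         C2T = chartr("C", "T", seq),
         G2A = chartr("G", "A", seq),
         stop("unknown conversion mode: ", mode))
}

#' Merge a read pair into a fragment sequence
#'
#' R2 is reverse-complemented, then the overlap between the R1 suffix and
#' the reverse-complemented R2 prefix is searched from the largest possible
#' overlap downwards; the first shift reaching `min_identity` within an
#' overlap of at least `min_overlap` bases is accepted. At disagreeing
#' overlap positions the base with the higher quality wins; ties become N.
#' Pairs with no acceptable overlap are returned as two sub-reads of one
#' fragment (the gap between them is of unknown length).
#'
#' @param r1_seq,r2_seq Mate sequences; `r2_seq` in sequencing orientation.
#' @param q1,q2 Optional Phred+33 quality strings (equal qualities assumed
#'   when absent, so every disagreement becomes N).
#' @param min_overlap Minimum acceptable overlap in bp (default 20).
#' @param min_identity Minimum fraction of agreeing bases in the overlap
#'   (default 0.9).
#' @return A list: `seqs` (length 1 if merged, 2 sub-reads otherwise),
#'   `merged` (logical), and `shift` (0-based start of the
#'   reverse-complemented R2 on the fragment; NA when unmerged).
#' @export
merge_pair <- function(r1_seq, r2_seq, q1 = NULL, q2 = NULL,
                       min_overlap = 20L, min_identity = 0.9) {
  if (nchar(r1_seq) == 0L || nchar(r2_seq) == 0L) {
    stop("both mates must be non-empty")
  }
  rc2 <- revcomp(r2_seq)
  qc2 <- if (!is.null(q2)) intToUtf8(rev(utf8ToInt(q2))) else NULL
  n1 <- nchar(r1_seq)
  n2 <- nchar(rc2)
  a <- strsplit(r1_seq, "", fixed = TRUE)[[1]]
  b <- strsplit(rc2, "", fixed = TRUE)[[1]]
  qa <- if (!is.null(q1)) utf8ToInt(q1) else rep(0L, n1)
  qb <- if (!is.null(qc2)) utf8ToInt(qc2) else rep(0L, n2)
  # shift s: rc2 starts at 0-based position s on the fragment; overlap with
  # r1 is positions (s+1)..min(n1, s+n2) — search the largest overlap first
  for (s in 0:(n1 - min_overlap)) {
    ov <- min(n1, s + n2) - s
    if (ov < min_overlap) break
    ia <- (s + 1L):(s + ov)
    ib <- 1L:ov
    match <- a[ia] == b[ib]
    if (mean(match) >= min_identity) {
      cons <- a[ia]
      dis <- which(!match)
      if (length(dis) > 0L) {
        take_b <- qb[ib[dis]] > qa[ia[dis]]
        tie <- qb[ib[dis]] == qa[ia[dis]]
        cons[dis[take_b]] <- b[ib[dis[take_b]]]
        cons[dis[tie]] <- "N"
      }
      frag <- paste(c(a[seq_len(s)], cons,
                      if (s + n2 > n1) b[(ov + 1L):n2]), collapse = "")
      return(list(seqs = frag, merged = TRUE, shift = s))
    }
  }
  list(seqs = c(r1_seq, rc2), merged = FALSE, shift = NA_integer_)
}

#' Align one fragment to the amplicon panel
#'
#' Ungapped alignment in the reduced bisulfite alphabet: the fragment and
#' every reference are reduced per the region's conversion mode, every
#' region x offset placement is scored by mismatch count, and the best
#' placement wins; ties are broken toward the lower region index, then the
#' lower offset. A fragment maps iff its best mismatch rate is at most
#' `max_mismatch_rate`.
#'
#' @param fragment DNA string.
#' @param panel An `amplicon_panel`.
#' @param max_mismatch_rate Maximum mismatches / fragment length
#'   (default 0.1).
#' @return A list: `region_id`, `offset` (0-based), `mismatches`, `mapped`.
#' @export
align_fragment <- function(fragment, panel, max_mismatch_rate = 0.1) {
  if (length(panel) == 0L) stop("panel must be non-empty")
  lf <- nchar(fragment)
  best <- list(region_id = NA_character_, offset = NA_integer_,
               mismatches = NA_integer_, mapped = FALSE)
  best_mm <- Inf
  for (region in panel) {
    red_ref <- reduce_alphabet(region$ref_seq, region$conversion_mode)
    red_frag <- reduce_alphabet(fragment, region$conversion_mode)
    lr <- nchar(red_ref)
    if (lf > lr) next
    fr <- charToRaw(red_frag)
    rr <- charToRaw(red_ref)
    for (off in 0:(lr - lf)) {
      mm <- sum(rr[(off + 1L):(off + lf)] != fr)
      if (mm < best_mm) {
        best_mm <- mm
        best <- list(region_id = region$region_id, offset = off,
                     mismatches = as.integer(mm), mapped = FALSE)
      }
    }
  }
  if (is.finite(best_mm) && best_mm / lf <= max_mismatch_rate) {
    best$mapped <- TRUE
  }
  best
}

#' Mapping-rate quality control for one sample
#'
#' Samples with a mapping rate below 2% are excluded; a rate of exactly 2%
#' passes (the exclusion rule is strict).
#'
#' @param n_pairs_mapped Number of read pairs mapped to the panel.
#' @param n_pairs_total Total read pairs (> 0).
#' @param min_mapping_rate Pass threshold (default 0.02).
#' @return A `sample_qc` list: `n_pairs_total`, `n_pairs_mapped`,
#'   `mapping_rate`, `passed`.
#' @export
compute_mapping_rate <- function(n_pairs_mapped, n_pairs_total,
                                 min_mapping_rate = 0.02) {
  if (n_pairs_total <= 0L) stop("invalid sample: no read pairs")
  rate <- n_pairs_mapped / n_pairs_total
  structure(list(n_pairs_total = n_pairs_total,
                 n_pairs_mapped = n_pairs_mapped,
                 mapping_rate = rate,
                 passed = rate >= min_mapping_rate),
            class = "sample_qc")
}

#' Call per-CpG methylation states for one aligned fragment
#'
#' For each region CpG covered by the fragment, the original (unreduced)
#' fragment base at the CpG cytosine position is read: C means methylated,
#' T unmethylated, anything else (including N from mate disagreement) is
#' ambiguous. In `G2A` mode the guanine of the dinucleotide is read instead
#' (G methylated, A unmethylated). CpGs outside the aligned span are
#' uncovered. A read is fully methylated iff every region CpG is covered and
#' methylated; ambiguous counts as not methylated.
#'
#' @param alignment Result of [align_fragment()]; must be mapped.
#' @param fragment The original (unreduced) fragment sequence.
#' @param region The matching `amplicon_region`.
#' @return A list: `cpg_states` (character vector over region CpGs with
#'   values methylated/unmethylated/ambiguous/uncovered), `fully_methylated`,
#'   `n_covered`.
#' @export
call_read_methylation <- function(alignment, fragment, region) {
  if (!isTRUE(alignment$mapped)) {
    stop("contract violation: methylation can only be called on mapped fragments")
  }
  if (!identical(alignment$region_id, region$region_id)) {
    stop("alignment and region disagree")
  }
  off <- alignment$offset
  lf <- nchar(fragment)
  # position of the informative base of each CpG on the reference
  info_pos <- if (region$conversion_mode == "C2T") {
    region$cpg_positions
  } else {
    region$cpg_positions + 1L
  }
  meth_base <- if (region$conversion_mode == "C2T") "C" else "G"
  unmeth_base <- if (region$conversion_mode == "C2T") "T" else "A"
  states <- rep("uncovered", length(info_pos))
  covered <- info_pos >= off & info_pos < off + lf
  if (any(covered)) {
    bases <- substring(fragment, info_pos[covered] - off + 1L,
                       info_pos[covered] - off + 1L)
    states[covered] <- ifelse(bases == meth_base, "methylated",
                              ifelse(bases == unmeth_base, "unmethylated",
                                     "ambiguous"))
  }
  list(cpg_states = states,
       fully_methylated = all(states == "methylated"),
       n_covered = sum(covered))
}

# Combine per-sub-read CpG state vectors of one fragment: a definite call
# wins over uncovered/ambiguous; conflicting definite calls become ambiguous.
combine_cpg_states <- function(states_list) {
  Reduce(function(x, y) {
    out <- x
    for (i in seq_along(x)) {
      a <- x[i]; b <- y[i]
      out[i] <- if (a == b) a
      else if (a == "uncovered") b
      else if (b == "uncovered") a
      else if (a == "ambiguous") b
      else if (b == "ambiguous") a
      else "ambiguous"  # methylated vs unmethylated conflict
    }
    out
  }, states_list)
}

#' Summarize fully-methylated-read calls for one sample and region
#'
#' @param fully_methylated Logical vector, one element per read mapped to
#'   the region.
#' @param sample_id,region_id Labels.
#' @return A one-row data frame: sample_id, region_id, n_reads_mapped,
#'   n_fully_methylated, pct_fully_methylated (NA with
#'   `no_amplification = TRUE` when no reads mapped).
#' @export
summarize_region <- function(fully_methylated, sample_id, region_id) {
  n <- length(fully_methylated)
  x <- sum(fully_methylated)
  data.frame(sample_id = sample_id, region_id = region_id,
             n_reads_mapped = n, n_fully_methylated = x,
             pct_fully_methylated = if (n > 0) 100 * x / n else NA_real_,
             no_amplification = n == 0L,
             stringsAsFactors = FALSE)
}

#' Align, QC and methylation-call one sample's read pairs
#'
#' Merges each pair, aligns the merged fragment (or each sub-read of an
#' unmerged pair) to the panel, applies the mapping-rate QC, calls per-read
#' CpG methylation, and computes the per-region percentage of fully
#' methylated reads. Beyond the mapping-rate QC no read filtering is
#' applied: every mapped read enters its region's denominator.
#'
#' @param r1,r2 Character vectors of mate sequences (R2 in sequencing
#'   orientation).
#' @param panel An `amplicon_panel`.
#' @param sample_id Sample label.
#' @param q1,q2 Optional quality strings.
#' @param max_mismatch_rate Aligner threshold (default 0.1).
#' @param min_mapping_rate QC threshold (default 0.02).
#' @param min_overlap Pair-merge minimum overlap (default 20).
#' @return A list: `summaries` (one row per region), `qc` (`sample_qc`),
#'   and `calls` (per mapped pair: read index, region_id, fully_methylated,
#'   n_covered, all_covered).
#' @export
align_call_sample <- function(r1, r2, panel, sample_id = "sample",
                              q1 = NULL, q2 = NULL,
                              max_mismatch_rate = 0.1, min_mapping_rate = 0.02,
                              min_overlap = 20L) {
  stopifnot(length(r1) == length(r2))
  n <- length(r1)
  if (n == 0L) stop("invalid sample: no read pairs")
  region_ids <- vapply(panel, `[[`, character(1), "region_id")
  regions_by_id <- stats::setNames(panel, region_ids)
  res_region <- character(n)
  res_full <- logical(n)
  res_ncov <- integer(n)
  res_allcov <- logical(n)
  for (i in seq_len(n)) {
    mp <- merge_pair(r1[i], r2[i],
                     q1 = if (!is.null(q1)) q1[i] else NULL,
                     q2 = if (!is.null(q2)) q2[i] else NULL,
                     min_overlap = min_overlap)
    alns <- lapply(mp$seqs, align_fragment, panel = panel,
                   max_mismatch_rate = max_mismatch_rate)
    mapped <- vapply(alns, `[[`, logical(1), "mapped")
    if (!any(mapped)) {
      res_region[i] <- NA_character_
      next
    }
    # pair's region: the mapped piece with the lowest mismatch rate
    rates <- vapply(alns, function(a) {
      if (a$mapped) a$mismatches else Inf
    }, numeric(1)) / nchar(mp$seqs)
    region_id <- alns[[which.min(rates)]]$region_id
    region <- regions_by_id[[region_id]]
    use <- which(mapped & vapply(alns, `[[`, character(1), "region_id") == region_id)
    states <- combine_cpg_states(lapply(use, function(j) {
      call_read_methylation(alns[[j]], mp$seqs[j], region)$cpg_states
    }))
    res_region[i] <- region_id
    res_full[i] <- all(states == "methylated")
    res_ncov[i] <- sum(states != "uncovered")
    res_allcov[i] <- !any(states == "uncovered")
  }
  calls <- data.frame(pair_index = seq_len(n), region_id = res_region,
                      fully_methylated = res_full, n_cpgs_covered = res_ncov,
                      all_cpgs_covered = res_allcov,
                      stringsAsFactors = FALSE)
  qc <- compute_mapping_rate(sum(!is.na(res_region)), n,
                             min_mapping_rate = min_mapping_rate)
  summaries <- do.call(rbind, lapply(region_ids, function(rid) {
    summarize_region(res_full[!is.na(res_region) & res_region == rid],
                     sample_id, rid)
  }))
  rownames(summaries) <- NULL
  list(summaries = summaries, qc = qc, calls = calls)
}
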