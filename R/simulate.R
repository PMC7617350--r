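#' Construct an amplicon target region
#'
#' An amplicon region is one multiplex-PCR target: a reference sequence, the
#' ordered 0-based offsets of the C of each CpG dinucleotide, and the
#' bisulfite conversion mode of the sequenced strand (`"C2T"` for the
#' original-top strand, `"G2A"` for the original-bottom strand).
#'
#' @param region_id Region label, e.g. `"EFC144"`.
#' @param ref_seq Uppercase DNA string (A/C/G/T).
#' @param cpg_positions Strictly increasing integer vector of 0-based offsets
#'   of the C of each CpG; `ref_seq[p..p+1]` must be `"CG"` for each.
#' @param conversion_mode `"C2T"` (default) or `"G2A"`.
#' @param genomic_label Free-text gene tag (e.g. `"ZNF154"`).
#' @return An object of class `amplicon_region`.
#' @export
amplicon_region <- function(region_id, ref_seq, cpg_positions,
                            conversion_mode = c("C2T", "G2A"),
                            genomic_label = NA_character_) {
  conversion_mode <- match.arg(conversion_mode)
  ref_seq <- toupper(ref_seq)
  cpg_positions <- as.integer(cpg_positions)
  if (length(cpg_positions) < 1L) {
    stop("a region must contain at least one CpG")
  }
  if (is.unsorted(cpg_positions, strictly = TRUE)) {
    stop("'cpg_positions' must be strictly increasing")
  }
  dinucs <- substring(ref_seq, cpg_positions + 1L, cpg_positions + 2L)
  if (!all(dinucs == "CG")) {
    stop("every CpG position must point at a CG dinucleotide in 'ref_seq'")
  }
  structure(
    list(region_id = region_id, ref_seq = ref_seq,
         cpg_positions = cpg_positions, conversion_mode = conversion_mode,
         genomic_label = genomic_label),
    class = "amplicon_region"
  )
}

#' @export
print.amplicon_region <- function(x, ...) {
  cat(sprintf("<amplicon_region> %s (%s): %d bp, %d CpGs, mode %s\n",
              x$region_id, x$genomic_label, nchar(x$ref_seq),
              length(x$cpg_positions), x$conversion_mode))
  invisible(x)
}

#' Generate a synthetic amplicon reference panel
#'
#' Builds `n_regions` synthetic amplicons in which CpG dinucleotides are
#' placed at randomly chosen non-overlapping positions and no CG dinucleotide
#' occurs anywhere else, so CpG coordinates are unambiguously recoverable
#' from the sequence alone. The panel stands in for a real target panel and
#' is drop-in replaceable with user FASTA+BED via [read_panel()].
#'
#' @param n_regions Number of amplicons.
#' @param region_length_bp Length of each amplicon in bp.
#' @param n_cpgs_per_region CpGs per amplicon (>= 1).
#' @param seed Integer seed; output is byte-identical for a fixed seed.
#' @param region_ids Optional character vector of region labels; defaults to
#'   `EFC144`, `EFC204`, `EFC228` when `n_regions == 3`, else `R1..Rn`.
#' @param genomic_labels Optional gene tags (defaults mirror the assay's
#'   target genes for a 3-region panel).
#' @return A list of [amplicon_region()] objects, class `amplicon_panel`.
#' @export
make_reference_panel <- function(n_regions, region_length_bp, n_cpgs_per_region,
                                 seed, region_ids = NULL, genomic_labels = NULL) {
  if (n_regions < 1L) stop("'n_regions' must be >= 1")
  if (n_cpgs_per_region < 1L) stop("'n_cpgs_per_region' must be >= 1")
  if (region_length_bp < 2L * n_cpgs_per_region + 10L) {
    stop("infeasible CpG placement: need region_length_bp >= 2*n_cpgs_per_region + 10")
  }
  if (is.null(region_ids)) {
    region_ids <- if (n_regions == 3L) {
      c("EFC144", "EFC204", "EFC228")
    } else {
      sprintf("R%d", seq_len(n_regions))
    }
  }
  if (is.null(genomic_labels)) {
    genomic_labels <- if (n_regions == 3L) {
      c("ZNF154", "C2CD4D", "WNT6")
    } else {
      rep(NA_character_, n_regions)
    }
  }
  with_seed(seed, {
    panel <- lapply(seq_len(n_regions), function(i) {
      L <- region_length_bp
      k <- n_cpgs_per_region
      # non-overlapping CpG placement: sample k sorted values with min gap 2
      # (classical spacing transform), keeping the dinucleotide inside [0, L).
      base_pos <- sort(sample.int(L - 1L - 2L * (k - 1L), k))
      pos <- base_pos - 1L + 2L * (seq_len(k) - 1L)  # 0-based C offsets
      chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      chars[pos + 1L] <- "C"
      chars[pos + 2L] <- "G"
      # remove accidental CG dinucleotides outside the designated sites;
      # designated bases are never part of an accidental CG, so mutating the
      # offending C is safe and cannot create a new CG.
      repeat {
        cg_at <- which(chars[-L] == "C" & chars[-1L] == "G")  # 1-based C index
        cg_at <- setdiff(cg_at, pos + 1L)
        if (length(cg_at) == 0L) break
        chars[cg_at] <- "T"
      }
      amplicon_region(region_ids[i], paste(chars, collapse = ""), pos,
                      conversion_mode = "C2T",
                      genomic_label = genomic_labels[i])
    })
    structure(panel, class = "amplicon_panel")
  })
}

#' Default cohort design mirroring the diagnostic case-control set
#'
#' Sixty-eight subjects: 41 controls (4 healthy volunteers, 37 benign pelvic
#' pathology) and 27 ovarian cancers with the published grade/stage mixture
#' (20 grade-2/3 "high-risk" cancers). CA125 is log-normal per group,
#' calibrated so group medians match the published cohort (controls 14 U/mL,
#' cases 152 U/mL); blood sampling happens around clinical diagnosis.
#'
#' @return A design list accepted by [simulate_cohort()].
#' @export
cohort_design_diagnostic <- function() {
  list(
    set_id = "diagnostic",
    n_controls = 41L,
    n_cases = 27L,
    control_mix = c(control_healthy = 4L, control_benign = 37L),
    case_grades = c("1" = 5L, "2" = 1L, "3" = 19L, "unknown" = 2L),
    case_stages = c(I = 3L, II = 1L, III = 10L, IV = 7L, unknown = 6L),
    brca_cases = c(unknown = 27L),
    brca_controls = c(unknown = 41L),
    ca125_meanlog = c(control = log(14), case = log(152)),
    ca125_sdlog = c(control = 0.58, case = 1.45),
    # CA125 availability: at-index measurements for 39/41 controls, 24/27
    # cases; the rest have no measurement.
    ca125_n_at_index = c(control = 39L, case = 24L),
    ca125_n_before = c(control = 0L, case = 0L),
    ca125_n_after = c(control = 0L, case = 0L),
    # tumour fraction of case cfDNA (log-normal; high-risk sheds more)
    tumor_fraction = list(highrisk_meanlog = log(0.04), lowrisk_meanlog = log(0.002),
                          sdlog = 1.3, decay_days = Inf),
    # subject-level background per-CpG methylation probability
    background_meth = list(meanlog = log(0.12), sdlog = 0.6, cap = 0.5),
    # cfDNA-tube samples: minimal white-blood-cell lysis
    gdna_contamination = list(meanlog = log(0.05), sdlog = 0.5),
    sample_date_origin = as.Date("2020-03-01"),
    # diagnostic sampling occurs within weeks of clinical diagnosis
    days_to_diagnosis_range = c(-28L, 14L)
  )
}

#' Default cohort design mirroring the early-detection (screening) set
#'
#' Fifty-eight subjects: 29 matched cancer-free controls and 29 ovarian
#' cancers sampled before diagnosis, with the published grade/stage/BRCA
#' mixture (27 high-risk cancers), CA125 medians of 12 (controls) and
#' 34 U/mL (cases), heavier genomic-DNA contamination typical of long-stored
#' archival plasma, and tumour fractions that decay with time to diagnosis.
#'
#' @return A design list accepted by [simulate_cohort()].
#' @export
cohort_design_early_detection <- function() {
  list(
    set_id = "early_detection",
    n_controls = 29L,
    n_cases = 29L,
    control_mix = c(control_healthy = 29L),
    case_grades = c("1" = 1L, "3" = 27L, "unknown" = 1L),
    case_stages = c(I = 7L, II = 2L, III = 15L, IV = 2L, unknown = 3L),
    brca_cases = c(BRCA1 = 17L, BRCA2 = 5L, wildtype = 6L, unknown = 1L),
    brca_controls = c(BRCA1 = 18L, BRCA2 = 6L, wildtype = 4L, unknown = 1L),
    ca125_meanlog = c(control = log(12), case = log(34)),
    ca125_sdlog = c(control = 0.35, case = 1.1),
    # at-index CA125 for 22 controls / 24 cases; the remainder only have a
    # measurement before or after the index sample, or none at all
    ca125_n_at_index = c(control = 22L, case = 24L),
    ca125_n_before = c(control = 3L, case = 2L),
    ca125_n_after = c(control = 3L, case = 3L),
    tumor_fraction = list(highrisk_meanlog = log(0.008), lowrisk_meanlog = log(0.001),
                          sdlog = 1.3, decay_days = 400),
    background_meth = list(meanlog = log(0.12), sdlog = 0.6, cap = 0.5),
    # archival EDTA samples: substantial leukocyte lysis
    gdna_contamination = list(meanlog = log(1.2), sdlog = 0.9),
    sample_date_origin = as.Date("2009-06-01"),
    # sampling predates diagnosis by one month to four years
    days_to_diagnosis_range = c(30L, 1460L)
  )
}

#' Simulate a case-control cohort
#'
#' Draws subjects, CA125 histories and simulation ground truth (tumour
#' fraction, subject-level background methylation, gDNA contamination) from a
#' design list such as [cohort_design_diagnostic()]. Group sizes, grade,
#' stage and BRCA mixtures match the design exactly; continuous quantities
#' are drawn from the design's distributions.
#'
#' @param design Design list (see [cohort_design_diagnostic()]).
#' @param seed Integer seed.
#' @return A list with `subjects` (one row per subject) and `ca125`
#'   (long-format measurement history: subject_id, date, value).
#' @export
simulate_cohort <- function(design, seed) {
  if (design$n_controls < 0L || design$n_cases < 0L) {
    stop("group counts must be nonnegative")
  }
  stopifnot(sum(design$control_mix) == design$n_controls,
            sum(design$case_grades) == design$n_cases,
            sum(design$case_stages) == design$n_cases)
  with_seed(seed, {
    n <- design$n_controls + design$n_cases
    subject_id <- sprintf("%s_S%03d", design$set_id, seq_len(n))
    is_case <- c(rep(FALSE, design$n_controls), rep(TRUE, design$n_cases))
    group <- c(rep(names(design$control_mix), design$control_mix),
               rep("cancer", design$n_cases))
    grade <- c(rep("unknown", design$n_controls),
               sample(rep(names(design$case_grades), design$case_grades)))
    stage <- c(rep("unknown", design$n_controls),
               sample(rep(names(design$case_stages), design$case_stages)))
    brca <- c(sample(rep(names(design$brca_controls), design$brca_controls)),
              sample(rep(names(design$brca_cases), design$brca_cases)))
    sample_date <- design$sample_date_origin + sample.int(365L, n, replace = TRUE)
    dtd <- ifelse(is_case,
                  round(runif(n, design$days_to_diagnosis_range[1],
                              design$days_to_diagnosis_range[2])), NA_real_)
    diagnosis_date <- sample_date + dtd

    # tumour fraction: 0 for controls; cases draw by risk class, attenuated
    # exponentially with time to diagnosis (early lesions shed less cfDNA)
    tf <- design$tumor_fraction
    high_risk <- grade %in% c("2", "3")
    meanlog <- ifelse(high_risk, tf$highrisk_meanlog, tf$lowrisk_meanlog)
    theta <- ifelse(is_case,
                    pmin(1, rlnorm(n, meanlog, tf$sdlog) *
                           exp(-pmax(dtd, 0) / tf$decay_days)), 0)
    theta[is.na(theta)] <- 0

    bm <- design$background_meth
    m_b <- pmin(bm$cap, rlnorm(n, bm$meanlog, bm$sdlog))
    gc <- design$gdna_contamination
    gdna <- rlnorm(n, gc$meanlog, gc$sdlog)

    subjects <- data.frame(
      subject_id = subject_id, group = group,
      histology = ifelse(is_case, "ovarian carcinoma",
                         ifelse(group == "control_healthy", "none", "benign pelvic pathology")),
      grade = grade, stage = stage, brca_status = brca,
      sample_date = sample_date, diagnosis_date = diagnosis_date,
      days_to_diagnosis = dtd,
      tumor_fraction_truth = theta,
      background_meth_truth = m_b,
      gdna_contamination_truth = gdna,
      stringsAsFactors = FALSE
    )

    # CA125 histories: availability pattern per design, values log-normal per
    # group so group medians match the design's exp(meanlog)
    ca125 <- do.call(rbind, lapply(c(control = FALSE, case = TRUE)[c(1, 2)], function(case_side) {
      idx <- which(is_case == case_side)
      key <- if (case_side) "case" else "control"
      n_at <- design$ca125_n_at_index[[key]]
      n_bef <- design$ca125_n_before[[key]]
      n_aft <- design$ca125_n_after[[key]]
      stopifnot(n_at + n_bef + n_aft <= length(idx))
      pattern <- rep("none", length(idx))
      pattern[seq_len(n_at + n_bef + n_aft)] <-
        rep(c("at_index", "before", "after"), c(n_at, n_bef, n_aft))
      pattern <- sample(pattern)
      keep <- pattern != "none"
      if (!any(keep)) return(NULL)
      offs <- integer(length(idx))
      offs[pattern == "before"] <- -sample(30:365, sum(pattern == "before"), replace = TRUE)
      offs[pattern == "after"] <- sample(30:365, sum(pattern == "after"), replace = TRUE)
      vals <- rlnorm(length(idx), design$ca125_meanlog[[key]], design$ca125_sdlog[[key]])
      data.frame(subject_id = subject_id[idx][keep],
                 date = sample_date[idx][keep] + offs[keep],
                 value = round(vals[keep], 1),
                 stringsAsFactors = FALSE)
    }))
    rownames(ca125) <- NULL
    list(subjects = subjects, ca125 = ca125)
  })
}

#' Default read-simulation parameters
#'
#' @param depth_per_region On-target fragments per region (default 300).
#' @param read_length Read length in bp (default 150).
#' @param tumor_fraction Probability a fragment is tumour-derived.
#' @param tumor_cpg_meth_prob Per-CpG methylation probability of tumour
#'   fragments (default 1).
#' @param background_cpg_meth_prob Per-CpG methylation probability of
#'   background fragments (default 0.01).
#' @param conversion_rate Probability an unmethylated C reads as T
#'   (default 0.995).
#' @param overconversion_rate Probability a methylated C reads as T
#'   (default 0.005).
#' @param seq_error_rate Per-base uniform substitution error (default 0.001).
#' @param offtarget_gdna_read_fraction Fraction of all emitted read pairs
#'   that are off-target genomic DNA (default 0).
#' @param seed Integer seed.
#' @return A `read_sim_params` list.
#' @export
read_sim_params <- function(depth_per_region = 300L, read_length = 150L,
                            tumor_fraction = 0, tumor_cpg_meth_prob = 1,
                            background_cpg_meth_prob = 0.01,
                            conversion_rate = 0.995, overconversion_rate = 0.005,
                            seq_error_rate = 0.001,
                            offtarget_gdna_read_fraction = 0, seed = 1L) {
  p <- list(depth_per_region = as.integer(depth_per_region),
            read_length = as.integer(read_length),
            tumor_fraction = tumor_fraction,
            tumor_cpg_meth_prob = tumor_cpg_meth_prob,
            background_cpg_meth_prob = background_cpg_meth_prob,
            conversion_rate = conversion_rate,
            overconversion_rate = overconversion_rate,
            seq_error_rate = seq_error_rate,
            offtarget_gdna_read_fraction = offtarget_gdna_read_fraction,
            seed = as.integer(seed))
  probs <- unlist(p[c("tumor_fraction", "tumor_cpg_meth_prob",
                      "background_cpg_meth_prob", "conversion_rate",
                      "overconversion_rate", "seq_error_rate",
                      "offtarget_gdna_read_fraction")])
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (p$depth_per_region < 0L) stop("'depth_per_region' must be >= 0")
  structure(p, class = "read_sim_params")
}

#' Apply the bisulfite conversion model to one fragment
#'
#' Unmethylated cytosines read as T with probability `c` (conversion);
#' methylated cytosines read as T with probability `o` (over-conversion).
#' Cytosines outside CpG offsets are always treated as unmethylated. Non-C
#' bases are unchanged. Uses the current RNG stream.
#'
#' @param fragment_seq DNA string.
#' @param cpg_states Logical vector, TRUE = methylated, aligned to
#'   `cpg_offsets`.
#' @param cpg_offsets 0-based offsets of CpG cytosines within the fragment.
#' @param c Conversion rate for unmethylated C.
#' @param o Over-conversion rate for methylated C.
#' @return The converted sequence.
#' @export
bisulfite_convert <- function(fragment_seq, cpg_states, cpg_offsets, c, o) {
  stopifnot(length(cpg_states) == length(cpg_offsets))
  chars <- strsplit(fragment_seq, "", fixed = TRUE)[[1]]
  if (length(cpg_offsets) > 0 &&
      (min(cpg_offsets) < 0 || max(cpg_offsets) >= length(chars))) {
    stop("'cpg_offsets' must lie within the fragment")
  }
  c_idx <- which(chars == "C")
  if (length(c_idx) == 0L) return(fragment_seq)
  meth <- c_idx %in% (cpg_offsets[cpg_states] + 1L)
  p_convert <- ifelse(meth, o, c)
  flip <- runif(length(c_idx)) < p_convert
  chars[c_idx[flip]] <- "T"
  paste(chars, collapse = "")
}

# Substitute each base with a uniformly random different base at rate `rate`.
apply_seq_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit) > 0L) {
    for (i in hit) {
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
    }
    seq <- paste(chars, collapse = "")
  }
  seq
}

#' Simulate paired-end bisulfite reads for one subject
#'
#' For each panel region, `depth_per_region` amplicon fragments are drawn;
#' each is tumour-derived with probability `tumor_fraction`, CpG methylation
#' states are drawn per fragment (tumour vs background per-CpG
#' probabilities), bisulfite conversion and uniform sequencing errors are
#' applied, and a full-length read pair is emitted (R2 in sequencing
#' orientation). Off-target genomic-DNA read pairs — bisulfite-converted
#' uniform-random long fragments — are added so they make up
#' `offtarget_gdna_read_fraction` of all pairs.
#'
#' @param subject One-row data frame (or list) with at least
#'   `subject_id`; `tumor_fraction_truth` and `background_meth_truth`
#'   override the corresponding `params` entries when present.
#' @param panel An `amplicon_panel`.
#' @param params A [read_sim_params()] object.
#' @return A list with `r1`, `r2` (character vectors of read sequences),
#'   `q1`, `q2` (Phred+33 quality strings), and `truth` — a per-fragment data
#'   frame (read_id, region_id, origin, n_cpgs_methylated, fully_methylated).
#' @export
simulate_reads <- function(subject, panel, params) {
  stopifnot(inherits(params, "read_sim_params"))
  sid <- subject$subject_id %||% "sample"
  theta <- subject$tumor_fraction_truth %||% params$tumor_fraction
  m_b <- subject$background_meth_truth %||% params$background_cpg_meth_prob
  m_t <- params$tumor_cpg_meth_prob
  rl <- params$read_length
  depth <- params$depth_per_region
  if (depth == 0L) {
    warning("zero depth requested: emitting empty read set")
    return(list(r1 = character(0), r2 = character(0),
                q1 = character(0), q2 = character(0),
                truth = data.frame(read_id = character(0), region_id = character(0),
                                   origin = character(0), n_cpgs_methylated = integer(0),
                                   fully_methylated = logical(0))))
  }
  with_seed(params$seed, {
    per_region <- lapply(panel, function(region) {
      L <- nchar(region$ref_seq)
      k <- length(region$cpg_positions)
      is_tumor <- runif(depth) < theta
      r1 <- r2 <- character(depth)
      n_meth <- integer(depth)
      for (i in seq_len(depth)) {
        p_meth <- if (is_tumor[i]) m_t else m_b
        states <- runif(k) < p_meth
        frag <- bisulfite_convert(region$ref_seq, states, region$cpg_positions,
                                  params$conversion_rate, params$overconversion_rate)
        r1[i] <- apply_seq_errors(substr(frag, 1L, min(rl, L)), params$seq_error_rate)
        r2[i] <- apply_seq_errors(revcomp(substr(frag, max(1L, L - rl + 1L), L)),
                                  params$seq_error_rate)
        n_meth[i] <- sum(states)
      }
      list(r1 = r1, r2 = r2,
           truth = data.frame(
             read_id = sprintf("%s_%s_f%05d", sid, region$region_id, seq_len(depth)),
             region_id = region$region_id,
             origin = ifelse(is_tumor, "tumor", "background"),
             n_cpgs_methylated = n_meth,
             fully_methylated = n_meth == k,
             stringsAsFactors = FALSE))
    })
    r1 <- unlist(lapply(per_region, `[[`, "r1"))
    r2 <- unlist(lapply(per_region, `[[`, "r2"))
    truth <- do.call(rbind, lapply(per_region, `[[`, "truth"))
    n_on <- length(r1)
    f <- params$offtarget_gdna_read_fraction
    n_off <- if (f > 0) round(f / (1 - f) * n_on) else 0L
    if (n_off > 0L) {
      o1 <- o2 <- character(n_off)
      for (j in seq_len(n_off)) {
        # high-molecular-weight gDNA: long random fragment, fully
        # bisulfite-converted (no methylation signal), mates don't overlap
        frag <- rand_dna(1L, 2L * rl + 200L)
        frag <- bisulfite_convert(frag, logical(0), integer(0),
                                  params$conversion_rate, params$overconversion_rate)
        o1[j] <- apply_seq_errors(substr(frag, 1L, rl), params$seq_error_rate)
        o2[j] <- apply_seq_errors(revcomp(substr(frag, nchar(frag) - rl + 1L, nchar(frag))),
                                  params$seq_error_rate)
      }
      r1 <- c(r1, o1)
      r2 <- c(r2, o2)
      truth <- rbind(truth, data.frame(
        read_id = sprintf("%s_offtarget_f%05d", sid, seq_len(n_off)),
        region_id = "offtarget", origin = "offtarget",
        n_cpgs_methylated = 0L, fully_methylated = FALSE,
        stringsAsFactors = FALSE))
    }
    q1 <- strrep("F", nchar(r1))
    q2 <- strrep("F", nchar(r2))
    list(r1 = r1, r2 = r2, q1 = q1, q2 = q2, truth = truth)
  })
}

#' Simulate a capillary-electrophoresis fragment-size profile
#'
#' A two-component mixture: a cell-free DNA mononucleosome component centred
#' at 167 bp with unit mass, and a high-molecular-weight genomic-DNA
#' component above 700 bp whose mass equals `gdna_contamination_truth`
#' (relative units). Mild multiplicative bin noise makes profiles
#' sample-like; output is deterministic for a fixed seed.
#'
#' @param gdna_contamination_truth Nonnegative gDNA:cfDNA mass ratio.
#' @param seed Integer seed.
#' @param scale Overall mass scale (fluorescence-like units).
#' @param noise_sd Standard deviation of log-normal per-bin noise.
#' @return A `fragment_profile` list with `bin_edges` (bp) and `mass`.
#' @export
simulate_fragment_profile <- function(gdna_contamination_truth, seed,
                                      scale = 100, noise_sd = 0.02) {
  if (gdna_contamination_truth < 0) stop("contamination must be >= 0")
  edges <- c(seq(50, 700, by = 25), seq(1000, 10000, by = 300))
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  cf_w <- ifelse(mid < 700, dnorm(mid, 167, 20), 0)
  cf_w <- cf_w / sum(cf_w)
  g_w <- ifelse(mid > 700, dnorm(mid, 6000, 1800), 0)
  g_w <- g_w / sum(g_w)
  with_seed(seed, {
    noise <- rlnorm(length(mid), 0, noise_sd)
    mass <- (cf_w * scale + g_w * scale * gdna_contamination_truth) * noise
    structure(list(bin_edges = edges, mass = mass), class = "fragment_profile")
  })
}
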