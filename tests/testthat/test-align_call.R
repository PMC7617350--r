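test_that("alphabet reduction collapses the converted base and is idempotent", {
  expect_identical(reduce_alphabet("ACGT", "C2T"), "ATGT")
  expect_identical(reduce_alphabet("ACGT", "G2A"), "ACAT")
  s <- "ACGTNCCGG"
  expect_identical(reduce_alphabet(reduce_alphabet(s, "C2T"), "C2T"),
                   reduce_alphabet(s, "C2T"))
  expect_error(reduce_alphabet("ACGT", "X2Y"), "unknown")
})

test_that("pair merging reconstructs the fragment and flags disagreements", {
  frag <- "ACGTACGTACGTACGTACGTACGT"
  m <- merge_pair(frag, revcomp(frag))
  expect_true(m$merged)
  expect_identical(m$seqs, frag)
  expect_equal(m$shift, 0)
  # one disagreeing base, equal qualities: the tie rule yields N
  r1 <- frag
  r2chars <- strsplit(frag, "")[[1]]
  r2chars[5] <- "T"
  r2 <- revcomp(paste(r2chars, collapse = ""))
  q <- strrep("F", nchar(frag))
  m <- merge_pair(r1, r2, q, q)
  expect_identical(substr(m$seqs, 5, 5), "N")
  # higher quality wins
  q2 <- paste0(strrep("F", nchar(frag) - 5), "I", strrep("F", 4))
  m <- merge_pair(r1, r2, q, q2)
  expect_identical(substr(m$seqs, 5, 5), "T")
  expect_error(merge_pair("", "ACGT"), "non-empty")
})

test_that("a short amplicon read pair merges into the full-length fragment", {
  panel <- tiny_panel()
  subj <- list(subject_id = "s", tumor_fraction_truth = 1)
  p <- read_sim_params(depth_per_region = 5, tumor_fraction = 1,
                       conversion_rate = 1, overconversion_rate = 0,
                       seq_error_rate = 0, seed = 3)
  reads <- simulate_reads(subj, panel, p)
  for (i in seq_along(reads$r1)) {
    m <- merge_pair(reads$r1[i], reads$r2[i])
    expect_true(m$merged)
    expect_equal(nchar(m$seqs), 150)
  }
})

test_that("pairs without overlap are processed as two sub-reads of one fragment", {
  panel <- make_reference_panel(1, 380, 8, seed = 5)
  region <- panel[[1]]
  # error-free fully methylated fragment spanning the whole amplicon
  frag <- bisulfite_convert(region$ref_seq, rep(TRUE, 8), region$cpg_positions,
                            c = 1, o = 0)
  r1 <- substr(frag, 1, 150)
  r2 <- revcomp(substr(frag, 231, 380))
  m <- merge_pair(r1, r2)
  expect_false(m$merged)
  expect_length(m$seqs, 2)
  res <- align_call_sample(r1, r2, panel, "s")
  expect_equal(res$qc$n_pairs_mapped, 1)
  call <- res$calls[1, ]
  # CpGs falling in the unsequenced middle stay uncovered, so the read can
  # never count as fully methylated
  mid_cpgs <- sum(region$cpg_positions >= 150 & region$cpg_positions < 230)
  expect_equal(call$n_cpgs_covered, 8 - mid_cpgs)
  if (mid_cpgs > 0) {
    expect_false(call$all_cpgs_covered)
    expect_false(call$fully_methylated)
  }
})

test_that("alignment maps converted copies and rejects random sequence", {
  panel <- tiny_panel()
  frag <- chartr("C", "T", panel[[2]]$ref_seq)
  a <- align_fragment(frag, panel)
  expect_true(a$mapped)
  expect_identical(a$region_id, "EFC204")
  expect_equal(a$offset, 0)
  expect_equal(a$mismatches, 0)
  set.seed(8)
  for (i in 1:20) {
    r <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = "")
    expect_false(align_fragment(r, panel)$mapped)
  }
  expect_error(align_fragment("ACGT", structure(list(), class = "amplicon_panel")),
               "non-empty")
})

test_that("alignment matches the brute-force scorer including offsets", {
  panel <- make_reference_panel(3, 120, 5, seed = 21)
  set.seed(22)
  for (i in 1:60) {
    region <- panel[[sample(3, 1)]]
    off <- sample(0:40, 1)
    len <- sample(60:(120 - off), 1)
    frag <- substr(chartr("C", "T", region$ref_seq), off + 1, off + len)
    ch <- strsplit(frag, "")[[1]]
    hit <- runif(length(ch)) < 0.02
    ch[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
    frag <- paste(ch, collapse = "")
    got <- align_fragment(frag, panel)
    want <- brute_force_align(frag, panel)
    expect_identical(got[c("region_id", "offset", "mismatches", "mapped")], want)
  }
})

test_that("mapping-rate QC applies the strict below-2% exclusion", {
  qc <- compute_mapping_rate(19, 1000)
  expect_equal(qc$mapping_rate, 0.019)
  expect_false(qc$passed)
  qc <- compute_mapping_rate(20, 1000)
  expect_equal(qc$mapping_rate, 0.02)
  expect_true(qc$passed)
  expect_true(compute_mapping_rate(1000, 1000)$passed)
  expect_error(compute_mapping_rate(0, 0), "invalid sample")
})

test_that("read-level methylation calls follow the C/T readout and coverage rule", {
  panel <- tiny_panel()
  region <- panel[[1]]
  meth_frag <- bisulfite_convert(region$ref_seq, rep(TRUE, 6),
                                 region$cpg_positions, c = 1, o = 0)
  aln <- align_fragment(meth_frag, panel)
  call <- call_read_methylation(aln, meth_frag, region)
  expect_true(all(call$cpg_states == "methylated"))
  expect_true(call$fully_methylated)
  # one unmethylated CpG
  states <- rep(TRUE, 6); states[3] <- FALSE
  frag <- bisulfite_convert(region$ref_seq, states, region$cpg_positions,
                            c = 1, o = 0)
  call <- call_read_methylation(align_fragment(frag, panel), frag, region)
  expect_identical(call$cpg_states[3], "unmethylated")
  expect_false(call$fully_methylated)
  # partial coverage: fragment starting after the first CpG
  start <- region$cpg_positions[1] + 2L
  part <- substr(meth_frag, start + 1L, 150)
  aln <- align_fragment(part, panel)
  call <- call_read_methylation(aln, part, region)
  expect_identical(call$cpg_states[1], "uncovered")
  expect_equal(call$n_covered, 5)
  expect_false(call$fully_methylated)
  # N at a CpG is ambiguous, not methylated
  nfrag <- meth_frag
  substr(nfrag, region$cpg_positions[2] + 1L, region$cpg_positions[2] + 1L) <- "N"
  call <- call_read_methylation(align_fragment(nfrag, panel), nfrag, region)
  expect_identical(call$cpg_states[2], "ambiguous")
  expect_false(call$fully_methylated)
  expect_error(call_read_methylation(list(mapped = FALSE), meth_frag, region),
               "contract")
})

test_that("methylation calling works symmetrically on the G2A strand", {
  region <- amplicon_region("r1", "AACGTTACGTAACGTT", c(2L, 7L, 12L),
                            conversion_mode = "G2A")
  panel <- structure(list(region), class = "amplicon_panel")
  # bottom-strand chemistry: unmethylated CpG guanines read as A
  frag <- "AACGTTACATAACGTT"  # CpG 2 converted
  aln <- align_fragment(frag, panel)
  expect_true(aln$mapped)
  call <- call_read_methylation(aln, frag, region)
  expect_identical(call$cpg_states, c("methylated", "unmethylated", "methylated"))
  expect_false(call$fully_methylated)
})

test_that("region summaries compute the fully-methylated percentage", {
  s <- summarize_region(c(rep(TRUE, 2), rep(FALSE, 98)), "s", "r")
  expect_equal(s$pct_fully_methylated, 2.0)
  s <- summarize_region(rep(FALSE, 100), "s", "r")
  expect_equal(s$pct_fully_methylated, 0.0)
  s <- summarize_region(logical(0), "s", "r")
  expect_true(is.na(s$pct_fully_methylated))
  expect_true(s$no_amplification)
})

test_that("every pair is partitioned and no filtering occurs beyond mapping QC", {
  panel <- tiny_panel()
  subj <- list(subject_id = "s", tumor_fraction_truth = 0.2)
  p <- read_sim_params(depth_per_region = 30, tumor_fraction = 0.2,
                       offtarget_gdna_read_fraction = 0.15, seed = 13)
  reads <- simulate_reads(subj, panel, p)
  res <- align_call_sample(reads$r1, reads$r2, panel, "s",
                           q1 = reads$q1, q2 = reads$q2)
  expect_equal(sum(res$summaries$n_reads_mapped), res$qc$n_pairs_mapped)
  expect_equal(res$qc$n_pairs_total, length(reads$r1))
  expect_equal(sum(is.na(res$calls$region_id)) + res$qc$n_pairs_mapped,
               res$qc$n_pairs_total)
})

test_that("error-free simulation round-trips exactly through the pipeline", {
  panel <- tiny_panel()
  subj <- list(subject_id = "s", tumor_fraction_truth = 0.1,
               background_meth_truth = 0.05)
  p <- read_sim_params(depth_per_region = 120, tumor_fraction = 0.1,
                       conversion_rate = 1, overconversion_rate = 0,
                       seq_error_rate = 0, seed = 31)
  reads <- simulate_reads(subj, panel, p)
  res <- align_call_sample(reads$r1, reads$r2, panel, "s",
                           q1 = reads$q1, q2 = reads$q2)
  truth <- reads$truth
  for (rid in c("EFC144", "EFC204", "EFC228")) {
    trow <- truth[truth$region_id == rid, ]
    srow <- res$summaries[res$summaries$region_id == rid, ]
    expect_identical(srow$n_reads_mapped, nrow(trow))
    expect_identical(srow$n_fully_methylated, sum(trow$fully_methylated))
    expect_equal(srow$pct_fully_methylated, 100 * mean(trow$fully_methylated))
  }
})
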