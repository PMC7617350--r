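#' Write an amplicon panel as FASTA + BED
#'
#' The FASTA holds one record per amplicon; the BED (0-based half-open)
#' holds the region spans on a synthetic coordinate frame (one "chromosome"
#' per region, span = the amplicon), with the gene tag in the name column.
#'
#' @param panel An `amplicon_panel`.
#' @param fasta_path,bed_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_panel <- function(panel, fasta_path, bed_path) {
  seqs <- Biostrings::DNAStringSet(vapply(panel, `[[`, character(1), "ref_seq"))
  names(seqs) <- vapply(panel, `[[`, character(1), "region_id")
  Biostrings::writeXStringSet(seqs, fasta_path)
  gr <- GenomicRanges::GRanges(
    seqnames = names(seqs),
    ranges = IRanges::IRanges(start = 1L, width = Biostrings::width(seqs)),
    name = vapply(panel, function(r) {
      if (is.na(r$genomic_label)) r$region_id else r$genomic_label
    }, character(1))
  )
  rtracklayer::export(gr, bed_path, format = "BED")
  invisible(c(fasta = fasta_path, bed = bed_path))
}

#' Read an amplicon panel from FASTA (+ optional BED)
#'
#' CpG positions are recovered by scanning each reference for CG
#' dinucleotides — valid both for panels written by
#' [make_reference_panel()] (which guarantees no stray CG) and for real
#' amplicon references, where every CG is a CpG site.
#'
#' @param fasta_path Panel FASTA.
#' @param bed_path Optional BED; its name column supplies gene tags.
#' @param conversion_mode Conversion mode applied to all regions.
#' @return An `amplicon_panel`.
#' @export
read_panel <- function(fasta_path, bed_path = NULL, conversion_mode = "C2T") {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  labels <- stats::setNames(rep(NA_character_, length(seqs)), names(seqs))
  if (!is.null(bed_path)) {
    gr <- rtracklayer::import(bed_path, format = "BED")
    labels[as.character(GenomicRanges::seqnames(gr))] <- gr$name
  }
  panel <- lapply(seq_along(seqs), function(i) {
    s <- as.character(seqs[[i]])
    pos <- as.integer(Biostrings::start(
      Biostrings::matchPattern("CG", Biostrings::DNAString(s)))) - 1L
    amplicon_region(names(seqs)[i], s, pos, conversion_mode,
                    genomic_label = labels[[names(seqs)[i]]])
  })
  structure(panel, class = "amplicon_panel")
}

#' Write a simulated read set as a gzipped FASTQ pair
#'
#' @param reads Output of [simulate_reads()].
#' @param r1_path,r2_path Output paths (`.fastq.gz` recommended).
#' @return Invisibly, the two paths.
#' @export
write_fastq_pair <- function(reads, r1_path, r2_path) {
  write_one <- function(seqs, quals, ids, path) {
    # the constructor warns about dropped (empty) metadata columns
    x <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(seqs),
      Biostrings::PhredQuality(quals)))
    names(x) <- ids
    Biostrings::writeQualityScaledXStringSet(
      x, path, compress = grepl("\\.gz$", path))
  }
  ids <- reads$truth$read_id
  write_one(reads$r1, reads$q1, ids, r1_path)
  write_one(reads$r2, reads$q2, ids, r2_path)
  invisible(c(r1 = r1_path, r2 = r2_path))
}

#' Read a FASTQ pair into the in-memory read-set form
#'
#' @param r1_path,r2_path FASTQ paths (gzipped or plain).
#' @return A list with `r1`, `r2`, `q1`, `q2`, `read_ids`.
#' @export
read_fastq_pair <- function(r1_path, r2_path) {
  read_one <- function(path) {
    # the reader warns about dropped (empty) metadata columns
    x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
    list(seq = as.character(x), qual = as.character(Biostrings::quality(x)),
         ids = names(x))
  }
  a <- read_one(r1_path)
  b <- read_one(r2_path)
  list(r1 = unname(a$seq), r2 = unname(b$seq),
       q1 = unname(a$qual), q2 = unname(b$qual),
       read_ids = sub(" .*$", "", a$ids))
}

#' Write / read fragment-size profiles as TSV
#'
#' Long format: sample_id, bin_start, bin_end, mass.
#'
#' @param profiles Named list of `fragment_profile` objects (names =
#'   sample ids).
#' @param path TSV path.
#' @return `read_fragment_profiles` returns the named list back.
#' @export
write_fragment_profiles <- function(profiles, path) {
  rows <- do.call(rbind, lapply(names(profiles), function(sid) {
    p <- profiles[[sid]]
    data.frame(sample_id = sid,
               bin_start = p$bin_edges[-length(p$bin_edges)],
               bin_end = p$bin_edges[-1],
               mass = p$mass, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fragment_profiles
#' @export
read_fragment_profiles <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(split(d, d$sample_id), function(x) {
    structure(list(bin_edges = c(x$bin_start, x$bin_end[nrow(x)]),
                   mass = x$mass), class = "fragment_profile")
  })
  out[unique(d$sample_id)]
}

# Plain TSV writers for cohort tables.
write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
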