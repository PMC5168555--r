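#' Strand-specific read coverage of intron terminal bases
#'
#' For each single-base terminal-base window, counts the filtered reads
#' on the sense strand with at least one aligned block containing the
#' base. Transreads never contribute to the coverage of their own
#' junction: the N gap excludes the intronic bases by construction, so a
#' read is either spliced evidence (transread) or pre-mRNA evidence
#' (terminal-base coverage) at a given junction, never both.
#'
#' @param aln A `spliced_alignments` object.
#' @param terminal_bases Table from [intron_terminal_bases()].
#' @param strandedness `"forward"` if reads align on the transcript
#'   strand, `"reverse"` if on its reverse complement (typical dUTP
#'   protocols). No default: this must match the library preparation
#'   protocol or every count is wrong.
#' @return `terminal_bases` with an integer `count` column appended.
#' @export
terminal_base_coverage <- function(aln, terminal_bases, strandedness) {
  stopifnot(inherits(aln, "spliced_alignments"))
  strandedness <- match.arg(strandedness, c("forward", "reverse"))

  missing_chrom <- setdiff(unique(terminal_bases$chrom), aln$seqnames)
  if (length(missing_chrom) > 0L) {
    warning(sprintf(
      "%d terminal base chromosome(s) absent from the alignment header (%s); counts set to 0",
      length(missing_chrom), paste(utils::head(missing_chrom, 3L), collapse = ", ")
    ))
  }

  tb_gr <- terminal_bases_granges(terminal_bases)
  if (strandedness == "reverse") {
    GenomicRanges::strand(tb_gr) <- flip_strand(as.character(GenomicRanges::strand(tb_gr)))
  }
  b <- aln$blocks
  bl_gr <- GenomicRanges::GRanges(
    seqnames = b$chrom,
    ranges = IRanges::IRanges(start = b$start + 1L, end = b$end),
    strand = b$strand
  )
  # blocks of one read are disjoint, so one overlap = one read; the
  # seqlevel-mismatch warning for absent chromosomes was raised above
  counts <- suppressWarnings(
    GenomicRanges::countOverlaps(tb_gr, bl_gr, ignore.strand = FALSE)
  )
  dplyr::mutate(terminal_bases, count = as.integer(counts))
}

flip_strand <- function(s) {
  ifelse(s == "+", "-", ifelse(s == "-", "+", s))
}

#' Combine per-sample terminal-base coverage into wide tables
#'
#' @param coverage_by_sample Named list of tibbles from
#'   [terminal_base_coverage()], all on the same terminal-base set.
#' @return A wide tibble: terminal-base columns plus one count column per
#'   sample.
#' @export
coverage_count_table <- function(coverage_by_sample) {
  stopifnot(length(coverage_by_sample) > 0L,
            !is.null(names(coverage_by_sample)))
  long <- dplyr::bind_rows(coverage_by_sample, .id = "sample")
  long |>
    tidyr::pivot_wider(
      id_cols = c("intron_id", "chrom", "pos", "strand", "which_end", "gene_id"),
      names_from = "sample", values_from = "count", values_fill = 0L
    ) |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Write terminal-base coverage tables as CSV
#'
#' Produces `introns_known_5ss.bed.counts.csv` and
#' `introns_known_3ss.bed.counts.csv` in `dir`.
#'
#' @param coverage5,coverage3 Wide tables from [coverage_count_table()]
#'   for the 5' and 3' terminal bases.
#' @param dir Output directory (created if missing).
#' @return Paths of the written files, invisibly.
#' @export
write_coverage_counts <- function(coverage5, coverage3, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p5 <- file.path(dir, "introns_known_5ss.bed.counts.csv")
  p3 <- file.path(dir, "introns_known_3ss.bed.counts.csv")
  write_csv_na(coverage5, p5)
  write_csv_na(coverage3, p3)
  invisible(c(five_prime = p5, three_prime = p3))
}
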