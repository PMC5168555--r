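#' Detect splice junctions (transreads) from gapped alignments
#'
#' Every N gap of every filtered read whose length lies within the intron
#' length bounds and whose flanking aligned blocks each contribute at
#' least `min_anchor` reference bases counts as one transread observation
#' for that junction. A read with several qualifying gaps supports each of
#' them independently.
#'
#' @param aln A `spliced_alignments` object from [read_alignments()].
#' @param min_intron,max_intron Acceptable intronic gap lengths in nt
#'   (defaults 20 and 10000, the yeast-appropriate bounds).
#' @param min_anchor Minimum aligned reference bases in each flanking
#'   block (default 8). Junction counts are anchor-sensitive; keep this
#'   consistent across compared samples.
#' @return A tibble with one row per junction: `chrom`, `start`, `end`
#'   (0-based half-open intronic gap), `transread_count`,
#'   `max_left_anchor`, `max_right_anchor`. Junctions with no qualifying
#'   read are absent. Attribute `skipped_gaps` counts non-qualifying gaps.
#' @export
extract_junctions <- function(aln, min_intron = 20L, max_intron = 10000L,
                              min_anchor = 8L) {
  stopifnot(inherits(aln, "spliced_alignments"),
            min_intron >= 1L, min_anchor >= 1L, max_intron >= min_intron)
  g <- aln$gaps
  len <- g$end - g$start
  qual <- len >= min_intron & len <= max_intron &
    g$left_anchor >= min_anchor & g$right_anchor >= min_anchor
  if (!any(qual)) {
    out <- tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      transread_count = integer(), max_left_anchor = integer(),
      max_right_anchor = integer()
    )
    attr(out, "skipped_gaps") <- sum(!qual)
    return(out)
  }
  out <- g[qual, , drop = FALSE] |>
    dplyr::group_by(.data$chrom, .data$start, .data$end) |>
    dplyr::summarise(
      transread_count = dplyr::n(),
      max_left_anchor = max(.data$left_anchor),
      max_right_anchor = max(.data$right_anchor),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$start, .data$end)
  attr(out, "skipped_gaps") <- sum(!qual)
  out
}

#' Classify junctions as known or novel against annotated introns
#'
#' A junction exactly matching an annotated intron's coordinates is
#' `known` (strand copied from the intron). Otherwise, a match of only the
#' donor boundary gives `novel_acceptor`, only the acceptor boundary
#' `novel_donor`, both boundaries (necessarily of different introns)
#' `novel_pair`, and neither `novel`. Donor/acceptor sides are
#' strand-aware: the donor boundary of a `+` intron is its start
#' coordinate, of a `-` intron its end coordinate. A junction matching
#' annotated introns on both strands at identical coordinates is flagged
#' `ambiguous` and excluded from the known set with a warning.
#'
#' @param junctions Junction tibble from [extract_junctions()].
#' @param introns Intron table from [parse_gene_annotation()].
#' @return `junctions` with `strand`, `annotation_class`, `gene_id` and
#'   `intron_id` columns filled (NA gene/intron for non-known classes;
#'   strand `"*"` when unknown).
#' @export
annotate_junctions <- function(junctions, introns) {
  if (nrow(junctions) == 0L) {
    return(dplyr::mutate(junctions, strand = character(),
                         annotation_class = character(),
                         gene_id = character(), intron_id = character()))
  }
  jkey <- paste(junctions$chrom, junctions$start, junctions$end)
  ikey <- paste(introns$chrom, introns$start, introns$end)

  n_strands <- vapply(jkey, function(k) {
    length(unique(introns$strand[ikey == k]))
  }, integer(1L), USE.NAMES = FALSE)
  ambiguous <- n_strands > 1L
  if (any(ambiguous)) {
    warning(sprintf(
      "%d junction(s) match annotated introns on both strands; excluded from the known set",
      sum(ambiguous)
    ))
  }

  hit <- match(jkey, ikey)
  known <- !is.na(hit) & !ambiguous

  plus <- introns$strand == "+"
  donor_start <- paste(introns$chrom[plus], introns$start[plus])    # + donors
  donor_end <- paste(introns$chrom[!plus], introns$end[!plus])      # - donors
  acc_end <- paste(introns$chrom[plus], introns$end[plus])          # + acceptors
  acc_start <- paste(introns$chrom[!plus], introns$start[!plus])    # - acceptors

  js <- paste(junctions$chrom, junctions$start)
  je <- paste(junctions$chrom, junctions$end)
  donor_hit <- js %in% donor_start | je %in% donor_end
  acc_hit <- je %in% acc_end | js %in% acc_start

  cls <- rep("novel", nrow(junctions))
  cls[donor_hit & !acc_hit] <- "novel_acceptor"
  cls[!donor_hit & acc_hit] <- "novel_donor"
  cls[donor_hit & acc_hit] <- "novel_pair"
  cls[known] <- "known"
  cls[ambiguous] <- "ambiguous"

  strand <- rep("*", nrow(junctions))
  strand[known] <- introns$strand[hit[known]]
  # one-sided matches inherit strand when all matched boundaries agree
  side_strand <- vapply(seq_len(nrow(junctions)), function(i) {
    if (known[i] || ambiguous[i]) return(NA_character_)
    s <- character()
    if (js[i] %in% donor_start || je[i] %in% acc_end) s <- c(s, "+")
    if (je[i] %in% donor_end || js[i] %in% acc_start) s <- c(s, "-")
    if (length(unique(s)) == 1L) unique(s) else NA_character_
  }, character(1L))
  strand[!is.na(side_strand)] <- side_strand[!is.na(side_strand)]

  dplyr::mutate(
    junctions,
    strand = strand,
    annotation_class = cls,
    gene_id = ifelse(known, introns$gene_id[hit], NA_character_),
    intron_id = ifelse(known, introns$intron_id[hit], NA_character_)
  )
}

#' Combine per-sample junction counts into known/novel tables
#'
#' @param junctions_by_sample Named list (one annotated junction tibble
#'   per sample, from [extract_junctions()] + [annotate_junctions()]).
#' @param introns Intron table used for annotation.
#' @return List of two wide tibbles, `known` and `novel`, one count
#'   column per sample (0 where a junction was not observed in that
#'   sample); junctions with zero transreads in every sample are absent.
#' @export
junction_count_table <- function(junctions_by_sample, introns) {
  stopifnot(length(junctions_by_sample) > 0L,
            !is.null(names(junctions_by_sample)))
  long <- dplyr::bind_rows(
    lapply(junctions_by_sample, function(j) {
      j[, c("chrom", "start", "end", "strand", "annotation_class",
            "gene_id", "intron_id", "transread_count")]
    }),
    .id = "sample"
  )
  wide <- long |>
    tidyr::pivot_wider(
      id_cols = c("chrom", "start", "end", "strand", "annotation_class",
                  "gene_id", "intron_id"),
      names_from = "sample", values_from = "transread_count",
      values_fill = 0L
    ) |>
    dplyr::arrange(.data$chrom, .data$start, .data$end)
  # guarantee one column per declared sample even if it saw no junctions
  for (s in names(junctions_by_sample)) {
    if (!s %in% names(wide)) wide[[s]] <- integer(nrow(wide))
  }
  known <- wide |>
    dplyr::filter(.data$annotation_class == "known") |>
    dplyr::select(-"annotation_class") |>
    dplyr::relocate("intron_id", "chrom", "start", "end", "strand", "gene_id")
  novel <- wide |>
    dplyr::filter(.data$annotation_class != "known") |>
    dplyr::select(-"gene_id", -"intron_id") |>
    dplyr::relocate("chrom", "start", "end", "strand", "annotation_class")
  list(known = known, novel = novel)
}

#' Write junction count tables as CSV
#'
#' Produces `splice_junctions_coverage.known.csv` and
#' `splice_junctions_coverage.novel.csv` in `dir`.
#'
#' @param tables List from [junction_count_table()].
#' @param dir Output directory (created if missing).
#' @return Paths of the written files, invisibly.
#' @export
write_junction_counts <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  known_path <- file.path(dir, "splice_junctions_coverage.known.csv")
  novel_path <- file.path(dir, "splice_junctions_coverage.novel.csv")
  write_csv_na(tables$known, known_path)
  write_csv_na(tables$novel, novel_path)
  invisible(c(known = known_path, novel = novel_path))
}

# CSV dialect used for all outputs: comma, header, literal NA, no quoting
# unless needed.
write_csv_na <- function(x, path) {
  readr::write_csv(x, path, na = "NA")
  invisible(path)
}
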