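#' Derive known introns from a GTF annotation
#'
#' Reads exon features from a GTF file (1-based inclusive coordinates,
#' `gene_id`/`transcript_id` attributes) and infers introns as the gaps
#' between consecutive exons of each multi-exon transcript. Explicit
#' `intron` features, if present, are ignored: exon features are the
#' universal currency across GTF producers. Coordinates are converted to
#' the 0-based half-open convention used throughout the package.
#'
#' Introns identical in (chrom, start, end, strand) across transcripts are
#' merged into a single record listing all supporting transcripts; the
#' reported `gene_id` is that of the lexicographically first supporting
#' transcript.
#'
#' @param gtf_file Path to a GTF file.
#' @return A tibble with one row per unique intron: `chrom`, `start`
#'   (0-based inclusive), `end` (0-based exclusive), `strand` (`+`/`-`),
#'   `gene_id`, `transcript_ids` (comma-separated), `intron_id`
#'   (`chrom:start-end(strand)` key).
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(c(
#'   "chrI\tx\texon\t1\t100\t.\t+\t.\tgene_id \"g1\"; transcript_id \"t1\";",
#'   "chrI\tx\texon\t201\t300\t.\t+\t.\tgene_id \"g1\"; transcript_id \"t1\";"
#' ), gtf)
#' parse_gene_annotation(gtf)
#' @export
parse_gene_annotation <- function(gtf_file) {
  stopifnot(is.character(gtf_file), length(gtf_file) == 1L, file.exists(gtf_file))
  validate_gtf_lines(gtf_file)

  gr <- rtracklayer::import(gtf_file, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) {
    return(empty_intron_table())
  }
  if (is.null(gr$gene_id) || is.null(gr$transcript_id)) {
    stop("GTF exon features must carry gene_id and transcript_id attributes")
  }

  exons <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    # GTF is 1-based inclusive; internal convention is 0-based half-open
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id)
  )

  bad_strand <- !exons$strand %in% c("+", "-")
  if (any(bad_strand)) {
    warning(sprintf(
      "skipping %d exon(s) without a +/- strand", sum(bad_strand)
    ))
    exons <- exons[!bad_strand, , drop = FALSE]
  }

  per_tx <- split(exons, exons$transcript_id)
  introns_list <- lapply(names(per_tx), function(tx) {
    ex <- per_tx[[tx]]
    if (length(unique(ex$chrom)) > 1L || length(unique(ex$strand)) > 1L) {
      warning(sprintf(
        "transcript '%s' has exons on multiple chromosomes/strands; skipped", tx
      ))
      return(NULL)
    }
    if (nrow(ex) < 2L) return(NULL)
    ex <- ex[order(ex$start), , drop = FALSE]
    tibble::tibble(
      chrom = ex$chrom[1L],
      start = ex$end[-nrow(ex)],
      end = ex$start[-1L],
      strand = ex$strand[1L],
      gene_id = ex$gene_id[1L],
      transcript_id = tx
    )
  })
  introns <- dplyr::bind_rows(introns_list)
  if (nrow(introns) == 0L) {
    return(empty_intron_table())
  }
  if (any(introns$end - introns$start < 1L)) {
    bad <- introns[introns$end - introns$start < 1L, ]
    warning(sprintf(
      "dropping %d zero-length intron(s) from overlapping/adjacent exons", nrow(bad)
    ))
    introns <- introns[introns$end - introns$start >= 1L, , drop = FALSE]
  }

  introns |>
    dplyr::arrange(.data$transcript_id) |>
    dplyr::group_by(.data$chrom, .data$start, .data$end, .data$strand) |>
    dplyr::summarise(
      gene_id = .data$gene_id[1L],
      transcript_ids = paste(sort(unique(.data$transcript_id)), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$start, .data$end) |>
    dplyr::mutate(intron_id = intron_key(.data$chrom, .data$start, .data$end, .data$strand)) |>
    dplyr::relocate("intron_id")
}

intron_key <- function(chrom, start, end, strand) {
  sprintf("%s:%d-%d(%s)", chrom, start, end, strand)
}

empty_intron_table <- function() {
  tibble::tibble(
    intron_id = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), gene_id = character(),
    transcript_ids = character()
  )
}

# Cheap structural check so malformed lines fail with a line number instead
# of an opaque import error. Tab-field count and numeric coordinates only.
validate_gtf_lines <- function(gtf_file) {
  lines <- readLines(gtf_file, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L) {
      stop(sprintf("malformed GTF line %d: expected 9 tab-separated fields, got %d",
                   i, length(f)))
    }
    if (is.na(suppressWarnings(as.integer(f[4L]))) ||
        is.na(suppressWarnings(as.integer(f[5L])))) {
      stop(sprintf("malformed GTF line %d: non-numeric coordinates", i))
    }
  }
  invisible(TRUE)
}

#' Strand-aware 5' and 3' terminal bases of introns
#'
#' For each intron, emits the single first (5', donor side) and last
#' (3', acceptor side) intronic base. On the `+` strand the 5' base is the
#' intron start and the 3' base is `end - 1`; on the `-` strand the
#' assignment is mirrored. These single-base windows are the denominators
#' of the splicing-efficiency ratio: a read covering the 5' terminal base
#' is direct pre-mRNA evidence at the donor site.
#'
#' @param introns Intron table from [parse_gene_annotation()].
#' @return A tibble with two rows per intron: `chrom`, `pos` (0-based
#'   single-base coordinate), `strand`, `which_end` (`five_prime` /
#'   `three_prime`), `intron_id`, `gene_id`.
#' @export
intron_terminal_bases <- function(introns) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(introns)))
  if (nrow(introns) > 0L) {
    stopifnot(all(introns$strand %in% c("+", "-")),
              all(introns$end - introns$start >= 1L))
  }
  plus <- introns$strand == "+"
  five <- tibble::tibble(
    chrom = introns$chrom,
    pos = ifelse(plus, introns$start, introns$end - 1L),
    strand = introns$strand,
    which_end = "five_prime",
    intron_id = introns$intron_id,
    gene_id = introns$gene_id
  )
  three <- tibble::tibble(
    chrom = introns$chrom,
    pos = ifelse(plus, introns$end - 1L, introns$start),
    strand = introns$strand,
    which_end = "three_prime",
    intron_id = introns$intron_id,
    gene_id = introns$gene_id
  )
  out <- dplyr::bind_rows(five, three)
  out$pos <- as.integer(out$pos)
  out
}

#' Write terminal bases as a BED6 file
#'
#' Single-base BED intervals (0-based half-open), name = intron key,
#' score = 0, strand column set.
#'
#' @param terminal_bases Table from [intron_terminal_bases()], usually
#'   filtered to one `which_end`.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_terminal_bed <- function(terminal_bases, path) {
  gr <- terminal_bases_granges(terminal_bases)
  names(gr) <- terminal_bases$intron_id
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# GRanges view (1-based internally to Bioconductor) of single-base windows
terminal_bases_granges <- function(terminal_bases) {
  GenomicRanges::GRanges(
    seqnames = terminal_bases$chrom,
    ranges = IRanges::IRanges(start = terminal_bases$pos + 1L, width = 1L),
    strand = terminal_bases$strand
  )
}

#' Read a single-base BED6 file back into a terminal-base table
#'
#' @param path BED file written by [write_terminal_bed()].
#' @param which_end Label to attach (`"five_prime"` or `"three_prime"`).
#' @return Terminal-base tibble (without `gene_id`).
#' @export
read_terminal_bed <- function(path, which_end) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = GenomicRanges::start(gr) - 1L,
    strand = as.character(GenomicRanges::strand(gr)),
    which_end = which_end,
    intron_id = if (!is.null(gr$name)) gr$name else NA_character_
  )
}
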