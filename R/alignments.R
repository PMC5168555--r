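#' Decompose a CIGAR string into reference blocks and N gaps
#'
#' Splits one alignment into the 0-based half-open reference intervals it
#' covers. `M`, `=`, `X` and `D` operations extend the current block
#' (a deletion stays inside its block), `N` closes the block and records a
#' gap, and `I`/`S`/`H`/`P` consume no reference. This is the split-read
#' semantics used everywhere downstream: a junction-spanning read covers
#' its anchors but none of the gapped (intronic) bases.
#'
#' @param cigar A single CIGAR string.
#' @param pos 0-based leftmost reference coordinate of the alignment.
#' @return A list with integer matrices `blocks` and `gaps`, each with
#'   columns `start`, `end` (0-based half-open).
#' @examples
#' aligned_blocks("20M60N80M", 0)
#' @export
aligned_blocks <- function(cigar, pos) {
  stopifnot(length(cigar) == 1L, length(pos) == 1L, pos >= 0)
  dec <- decompose_cigars(cigar, as.integer(pos))
  if (dec$malformed[1L]) {
    stop(sprintf("malformed CIGAR '%s': %s", cigar, dec$reason[1L]))
  }
  b <- dec$blocks[[1L]]
  g <- dec$gaps[[1L]]
  list(
    blocks = matrix(c(IRanges::start(b) - 1L, IRanges::end(b)),
                    ncol = 2L, dimnames = list(NULL, c("start", "end"))),
    gaps = matrix(c(IRanges::start(g) - 1L, IRanges::end(g)),
                  ncol = 2L, dimnames = list(NULL, c("start", "end")))
  )
}

# Vectorised CIGAR decomposition. pos is 0-based; returned IRanges are
# 1-based (Bioconductor convention), converted at the tibble boundary.
decompose_cigars <- function(cigar, pos) {
  n <- length(cigar)
  valid <- grepl("^([0-9]+[MIDNSHP=X])+$", cigar)
  reason <- ifelse(valid, "", "unparsable CIGAR")

  blocks <- rep(list(IRanges::IRanges()), n)
  gaps <- rep(list(IRanges::IRanges()), n)

  if (any(valid)) {
    iok <- which(valid)
    ops <- GenomicAlignments::explodeCigarOps(cigar[iok])
    # reference-consuming ops only; N at either edge has no anchoring block
    edge_n <- vapply(ops, function(o) {
      o <- o[o %in% c("M", "=", "X", "D", "N")]
      length(o) == 0L || o[1L] == "N" || o[length(o)] == "N"
    }, logical(1L))
    reason[iok[edge_n]] <- "N gap at alignment edge"
    valid[iok[edge_n]] <- FALSE

    idx <- iok[!edge_n]
    if (length(idx) > 0L) {
      rl <- GenomicAlignments::extractAlignmentRangesOnReference(
        cigar[idx], pos = pos[idx] + 1L, drop.D.ranges = FALSE
      )
      # insertions/clips between two N ops leave a zero-width "block";
      # it cannot anchor anything, so drop it and merge the flanking gaps
      blocks[idx] <- lapply(as.list(rl), function(b) {
        b[IRanges::width(b) > 0L]
      })
      gaps[idx] <- lapply(blocks[idx], function(b) {
        k <- length(b)
        if (k < 2L) return(IRanges::IRanges())
        IRanges::IRanges(start = IRanges::end(b)[-k] + 1L,
                         end = IRanges::start(b)[-1L] - 1L)
      })
    }
  }
  list(blocks = blocks, gaps = gaps, malformed = !valid, reason = reason)
}

#' Read raw alignment records from SAM or BAM
#'
#' Plain-text SAM input is converted to BAM on the fly (in a temporary
#' directory) so both formats flow through the same reader. No filtering
#' is applied here; see [filter_alignments()].
#'
#' @param path A SAM (`.sam`) or BAM file. SAM input must carry `@SQ`
#'   header lines.
#' @return A tibble of raw records (`read_id`, `flag`, `chrom`, `pos`
#'   0-based, `mapq`, `cigar`, `strand`) with the header reference names
#'   in attribute `seqnames`.
#' @export
read_sam_records <- function(path) {
  stopifnot(file.exists(path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "strand")
  )
  x <- Rsamtools::scanBam(bam, param = param)[[1L]]
  out <- tibble::tibble(
    read_id = x$qname,
    flag = as.integer(x$flag),
    chrom = as.character(x$rname),
    pos = as.integer(x$pos) - 1L,
    mapq = as.integer(x$mapq),
    cigar = x$cigar,
    strand = as.character(x$strand)
  )
  attr(out, "seqnames") <- names(hdr$targets)
  out
}

#' Filter alignments and decompose them into blocks and gaps
#'
#' Applies the uniqueness filter: unmapped, secondary (0x100) and
#' supplementary (0x800) records are dropped, then records with
#' `mapq < min_mapq` are dropped. Duplicates are kept (no 0x400
#' handling). Survivors are decomposed into reference blocks split on N
#' gaps; records with unparsable CIGARs or an N gap at an alignment edge
#' are skipped with a warning and counted.
#'
#' @param records Raw record tibble from [read_sam_records()].
#' @param min_mapq Minimum mapping quality to keep (default 10, the
#'   threshold for unambiguous single-locus alignment).
#' @return A `spliced_alignments` object: list with tibbles `reads`
#'   (`read_id`, `chrom`, `pos`, `mapq`, `strand`, `flag`), `blocks` and
#'   `gaps` (both keyed by `read` = row index into `reads`; `gaps` also
#'   carries `left_anchor`/`right_anchor`, the widths of the flanking
#'   blocks), the header `seqnames`, and a `dropped` counter list.
#' @export
filter_alignments <- function(records, min_mapq = 10L) {
  stopifnot(is.data.frame(records), min_mapq >= 0)
  flag <- records$flag
  unmapped <- bitwAnd(flag, 0x4L) != 0L | is.na(records$pos)
  secondary <- bitwAnd(flag, 0x100L) != 0L
  supplementary <- bitwAnd(flag, 0x800L) != 0L
  drop_class <- !unmapped & !secondary & !supplementary
  low_mapq <- drop_class & records$mapq < min_mapq
  keep <- drop_class & !low_mapq

  kept <- records[keep, , drop = FALSE]
  dec <- decompose_cigars(kept$cigar, kept$pos)
  if (any(dec$malformed)) {
    bad <- which(dec$malformed)
    warning(sprintf(
      "skipped %d record(s) with malformed CIGAR (e.g. read '%s': %s)",
      length(bad), kept$read_id[bad[1L]], dec$reason[bad[1L]]
    ))
    kept <- kept[!dec$malformed, , drop = FALSE]
    dec$blocks <- dec$blocks[!dec$malformed]
    dec$gaps <- dec$gaps[!dec$malformed]
  }

  reads <- tibble::tibble(
    read_id = kept$read_id,
    chrom = kept$chrom,
    pos = kept$pos,
    mapq = kept$mapq,
    strand = ifelse(bitwAnd(kept$flag, 0x10L) != 0L, "-", "+"),
    flag = kept$flag
  )

  nb <- lengths(dec$blocks)
  bl <- unlist_iranges(dec$blocks)
  blocks <- tibble::tibble(
    read = rep.int(seq_len(nrow(reads)), nb),
    chrom = rep.int(reads$chrom, nb),
    start = bl$start,
    end = bl$end,
    strand = rep.int(reads$strand, nb)
  )

  ng <- lengths(dec$gaps)
  gl <- unlist_iranges(dec$gaps)
  gap_read <- rep.int(seq_len(nrow(reads)), ng)
  # gap i of a read is flanked by its blocks i and i+1
  gap_ord <- sequence(ng)
  widths <- blocks$end - blocks$start
  block_offset <- c(0L, cumsum(nb))[gap_read]
  gaps <- tibble::tibble(
    read = gap_read,
    chrom = rep.int(reads$chrom, ng),
    start = gl$start,
    end = gl$end,
    strand = rep.int(reads$strand, ng),
    left_anchor = widths[block_offset + gap_ord],
    right_anchor = widths[block_offset + gap_ord + 1L]
  )

  structure(list(
    reads = reads, blocks = blocks, gaps = gaps,
    seqnames = attr(records, "seqnames"),
    dropped = list(
      unmapped = sum(unmapped), secondary = sum(secondary & !unmapped),
      supplementary = sum(supplementary & !unmapped & !secondary),
      low_mapq = sum(low_mapq), malformed_cigar = sum(dec$malformed)
    )
  ), class = "spliced_alignments")
}

unlist_iranges <- function(lst) {
  ir <- unlist(IRanges::IRangesList(lst), use.names = FALSE)
  list(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Read and filter a SAM/BAM file in one step
#'
#' @inheritParams read_sam_records
#' @inheritParams filter_alignments
#' @return A `spliced_alignments` object; see [filter_alignments()].
#' @export
read_alignments <- function(path, min_mapq = 10L) {
  filter_alignments(read_sam_records(path), min_mapq = min_mapq)
}

#' @export
print.spliced_alignments <- function(x, ...) {
  cat(sprintf(
    "<spliced_alignments> %d reads (%d blocks, %d gapped junction observations)\n",
    nrow(x$reads), nrow(x$blocks), nrow(x$gaps)
  ))
  d <- x$dropped
  cat(sprintf(
    "  dropped: %d unmapped, %d secondary, %d supplementary, %d low MAPQ, %d malformed\n",
    d$unmapped, d$secondary, d$supplementary, d$low_mapq, d$malformed_cigar
  ))
  invisible(x)
}
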