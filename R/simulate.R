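#' Specification for a simulated spliced RNA-seq dataset
#'
#' Describes a set of intron-containing genes, each on its own
#' chromosome, with a known per-gene spliced fraction. Reads are drawn
#' error-free with uniform start positions from the spliced isoform
#' (fraction `spliced_fraction` of per-base depth) or the unspliced
#' pre-mRNA (the remainder); reads crossing an exon-exon junction receive
#' an N-gapped CIGAR with the exact intron length. Genes have two exons
#' by default, the typical budding-yeast structure; set `n_introns > 1`
#' for multi-gap read tests.
#'
#' @param n_genes Number of genes (one chromosome each).
#' @param exon_length Exon length in nt (recycled per gene; all exons of
#'   a gene share it).
#' @param intron_length Intron length in nt (recycled per gene).
#' @param spliced_fraction Per-gene probability `p` that a read comes
#'   from the spliced isoform (recycled; 0 <= p <= 1).
#' @param strand Per-gene strand (recycled; default alternates `+`/`-`).
#' @param read_length Read length in nt.
#' @param depth Mean per-base read coverage over the gene's two templates
#'   combined (so the per-start-position sampling rate is `depth/L`).
#' @param strandedness Protocol emulated: `"forward"` (reads on the
#'   transcript strand) or `"reverse"`.
#' @param mapq MAPQ assigned to regular reads (default 60, kept by the
#'   filter).
#' @param decoy_fraction Fraction of reads emitted with `decoy_mapq`
#'   instead, to exercise the MAPQ filter (default 0).
#' @param decoy_mapq MAPQ of decoy reads (default 3, below the filter).
#' @param n_introns Introns per gene (recycled; default 1).
#' @return A `sim_spec` object.
#' @export
sim_spec <- function(n_genes = 20L, exon_length = 150L, intron_length = 100L,
                     spliced_fraction = 0.5, strand = NULL,
                     read_length = 100L, depth = 500,
                     strandedness = c("forward", "reverse"),
                     mapq = 60L, decoy_fraction = 0, decoy_mapq = 3L,
                     n_introns = 1L) {
  strandedness <- match.arg(strandedness)
  stopifnot(n_genes >= 1L, read_length >= 1L, depth > 0,
            all(spliced_fraction >= 0), all(spliced_fraction <= 1),
            all(exon_length >= 1L), all(intron_length >= 1L),
            all(n_introns >= 1L), decoy_fraction >= 0, decoy_fraction <= 1)
  if (is.null(strand)) strand <- rep_len(c("+", "-"), n_genes)
  genes <- tibble::tibble(
    gene_id = sprintf("gene%d", seq_len(n_genes)),
    chrom = sprintf("sim%d", seq_len(n_genes)),
    strand = rep_len(strand, n_genes),
    spliced_fraction = rep_len(spliced_fraction, n_genes),
    exon_length = rep_len(as.integer(exon_length), n_genes),
    intron_length = rep_len(as.integer(intron_length), n_genes),
    n_introns = rep_len(as.integer(n_introns), n_genes)
  )
  spliced_len <- (genes$n_introns + 1L) * genes$exon_length
  if (any(read_length > spliced_len)) {
    stop("read length exceeds spliced transcript length for at least one gene")
  }
  structure(list(
    genes = genes, read_length = as.integer(read_length), depth = depth,
    strandedness = strandedness, mapq = as.integer(mapq),
    decoy_fraction = decoy_fraction, decoy_mapq = as.integer(decoy_mapq)
  ), class = "sim_spec")
}

#' Simulate a spliced RNA-seq dataset as FASTA + GTF + SAM
#'
#' Deterministic given `seed`: running twice with the same spec and seed
#' produces byte-identical files. The genome carries canonical GT..AG
#' splice motifs (strand-aware) for realism; no downstream computation
#' reads the sequence. A truth table of per-gene spliced fractions is
#' written alongside.
#'
#' @param spec A [sim_spec()] object.
#' @param seed Integer RNG seed.
#' @param dir Output directory (created if missing).
#' @return A list with paths `fasta`, `gtf`, `sam`, `truth` and the truth
#'   tibble (`genes` with realized read counts).
#' @export
simulate_dataset <- function(spec, seed, dir) {
  stopifnot(inherits(spec, "sim_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(as.integer(seed))

  L <- spec$read_length
  genes <- spec$genes
  chrom_seqs <- character(nrow(genes))
  gtf_lines <- character()
  sam_records <- vector("list", nrow(genes))
  n_spliced <- integer(nrow(genes))
  n_unspliced <- integer(nrow(genes))

  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    E <- rep(g$exon_length, g$n_introns + 1L)
    I <- rep(g$intron_length, g$n_introns)
    glen <- sum(E) + sum(I)
    # 0-based exon starts on the reference
    exon_starts <- cumsum(c(0L, E[-length(E)] + I))
    intron_starts <- exon_starts[-length(exon_starts)] + E[-length(E)]

    seq_chars <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)
    for (k in seq_along(intron_starts)) {
      s <- intron_starts[k]
      e <- s + I[k]
      if (g$strand == "+") {
        seq_chars[(s + 1):(s + 2)] <- c("G", "T")
        seq_chars[(e - 1):e] <- c("A", "G")
      } else {
        seq_chars[(s + 1):(s + 2)] <- c("C", "T")
        seq_chars[(e - 1):e] <- c("A", "C")
      }
    }
    chrom_seqs[i] <- paste(seq_chars, collapse = "")

    gtf_lines <- c(gtf_lines, sprintf(
      "%s\tspliceff_sim\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"tx%d\";",
      g$chrom, exon_starts + 1L, exon_starts + E, g$strand, g$gene_id, i
    ))

    p <- g$spliced_fraction
    rate <- spec$depth / L
    n_s <- stats::rpois(1L, rate * p * (sum(E) - L + 1L))
    n_u <- stats::rpois(1L, rate * (1 - p) * (glen - L + 1L))
    n_spliced[i] <- n_s
    n_unspliced[i] <- n_u

    sense <- if (spec$strandedness == "forward") g$strand else flip_strand(g$strand)
    flag <- if (sense == "-") 16L else 0L

    recs <- character(n_s + n_u)
    if (n_s > 0L) {
      offs <- sample.int(sum(E) - L + 1L, n_s, replace = TRUE) - 1L
      for (r in seq_len(n_s)) {
        ali <- spliced_read_alignment(offs[r], L, E, I, exon_starts)
        recs[r] <- sam_line(
          sprintf("%s_s%05d", g$gene_id, r), flag, g$chrom, ali$pos + 1L,
          spec$mapq, ali$cigar,
          spliced_read_seq(chrom_seqs[i], ali$pos, ali$cigar)
        )
      }
    }
    if (n_u > 0L) {
      starts <- sample.int(glen - L + 1L, n_u, replace = TRUE) - 1L
      cig <- sprintf("%dM", L)
      for (r in seq_len(n_u)) {
        recs[n_s + r] <- sam_line(
          sprintf("%s_u%05d", g$gene_id, r), flag, g$chrom, starts[r] + 1L,
          spec$mapq, cig,
          substr(chrom_seqs[i], starts[r] + 1L, starts[r] + L)
        )
      }
    }
    sam_records[[i]] <- recs
  }

  # decoy low-MAPQ reads exercise the uniqueness filter
  all_records <- unlist(sam_records)
  if (spec$decoy_fraction > 0 && length(all_records) > 0L) {
    decoy <- stats::runif(length(all_records)) < spec$decoy_fraction
    if (any(decoy)) {
      f <- strsplit(all_records[decoy], "\t", fixed = TRUE)
      all_records[decoy] <- vapply(f, function(x) {
        x[5L] <- as.character(spec$decoy_mapq)
        paste(x, collapse = "\t")
      }, character(1L))
    }
  }

  fasta_path <- file.path(dir, "genome.fasta")
  genome <- Biostrings::DNAStringSet(chrom_seqs)
  names(genome) <- genes$chrom
  Biostrings::writeXStringSet(genome, fasta_path)

  gtf_path <- file.path(dir, "annotation.gtf")
  writeLines(gtf_lines, gtf_path)

  sam_path <- file.path(dir, "reads.sam")
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", genes$chrom, nchar(chrom_seqs))
  )
  writeLines(c(header, all_records), sam_path)

  truth <- dplyr::mutate(genes, n_spliced_reads = n_spliced,
                         n_unspliced_reads = n_unspliced)
  truth_path <- file.path(dir, "truth.csv")
  write_csv_na(truth, truth_path)

  list(fasta = fasta_path, gtf = gtf_path, sam = sam_path,
       truth = truth_path, genes = truth)
}

# Map a 0-based offset on the spliced transcript to a reference position
# and CIGAR (N ops for every crossed intron).
spliced_read_alignment <- function(offset, read_length, E, I, exon_starts) {
  cum <- cumsum(c(0L, E))
  j <- findInterval(offset, cum, rightmost.closed = FALSE)  # exon index
  within <- offset - cum[j]
  pos <- exon_starts[j] + within
  remaining <- read_length
  parts <- character()
  k <- j
  while (remaining > 0L) {
    avail <- E[k] - if (k == j) within else 0L
    m <- min(remaining, avail)
    parts <- c(parts, sprintf("%dM", m))
    remaining <- remaining - m
    if (remaining > 0L) {
      parts <- c(parts, sprintf("%dN", I[k]))
      k <- k + 1L
    }
  }
  list(pos = pos, cigar = paste(parts, collapse = ""))
}

# Reference-forward sequence of an aligned read (exonic pieces only)
spliced_read_seq <- function(chrom_seq, pos, cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1L]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]]
  at <- pos
  pieces <- character()
  for (q in seq_along(ops)) {
    if (ops[q] == "M") {
      pieces <- c(pieces, substr(chrom_seq, at + 1L, at + lens[q]))
      at <- at + lens[q]
    } else if (ops[q] == "N") {
      at <- at + lens[q]
    }
  }
  paste(pieces, collapse = "")
}

sam_line <- function(qname, flag, chrom, pos1, mapq, cigar, seq) {
  paste(qname, flag, chrom, pos1, mapq, cigar, "*", 0L, 0L,
        seq, strrep("I", nchar(seq)), sep = "\t")
}

#' Closed-form expected splicing efficiency under uniform sampling
#'
#' With per-start-position sampling at equal rate on both templates
#' (fraction `p` spliced), the expected transread count at a junction is
#' proportional to `p * (L - 2a + 1)` (start positions giving both
#' anchors) and the expected terminal-base coverage to `(1 - p) * L`
#' (start positions covering one base), so the expected efficiency is
#' `p * (L - 2a + 1) / ((1 - p) * L)`; undefined for `p = 1` (no
#' pre-mRNA reads).
#'
#' @param p Spliced fraction(s), in `[0, 1]`.
#' @param read_length Read length L.
#' @param min_anchor Anchor requirement a used for junction counting;
#'   must satisfy `L > 2a`.
#' @return Numeric vector of expected efficiencies (`NA` where `p = 1`).
#' @examples
#' expected_efficiency(0.9, 100, 8)  # 7.65
#' @export
expected_efficiency <- function(p, read_length, min_anchor) {
  stopifnot(all(p >= 0), all(p <= 1), read_length > 2 * min_anchor)
  ifelse(p == 1, NA_real_,
         p * (read_length - 2 * min_anchor + 1) / ((1 - p) * read_length))
}
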