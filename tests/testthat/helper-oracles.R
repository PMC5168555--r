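# Brute-force oracles, written independently of the package internals:
# SAM text is re-parsed here with base R and every CIGAR is walked
# base by base.

# Per-base CIGAR walk -> covered reference positions and N gaps (0-based)
oracle_walk <- function(cigar, pos) {
  m <- regmatches(cigar, gregexpr("[0-9]+|[MIDNSHP=X]", cigar))[[1L]]
  lens <- as.integer(m[c(TRUE, FALSE)])
  ops <- m[c(FALSE, TRUE)]
  ref_ops <- ops[ops %in% c("M", "=", "X", "D", "N")]
  if (length(ref_ops) == 0L || ref_ops[1L] == "N" ||
      ref_ops[length(ref_ops)] == "N") {
    return(NULL)  # malformed: N gap at alignment edge
  }
  covered <- integer(0)
  at <- pos
  for (i in seq_along(ops)) {
    n <- lens[i]
    if (ops[i] %in% c("M", "=", "X", "D")) {
      covered <- c(covered, seq.int(at, at + n - 1L))
      at <- at + n
    } else if (ops[i] == "N") {
      at <- at + n
    }
  }
  covered <- sort(unique(covered))
  breaks <- which(diff(covered) > 1L)
  starts <- covered[c(1L, breaks + 1L)]
  ends <- covered[c(breaks, length(covered))] + 1L
  # the only uncovered reference space inside an alignment comes from N,
  # so gaps are exactly the complement between consecutive blocks
  gaps <- if (length(starts) > 1L) {
    cbind(start = ends[-length(ends)], end = starts[-1L])
  } else {
    matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  }
  list(blocks = cbind(start = starts, end = ends), gaps = gaps)
}

# Filter + count junctions and terminal-base coverage straight from SAM text
oracle_sam_counts <- function(sam_path, terminal_bases, strandedness,
                              min_mapq = 10L, min_intron = 20L,
                              max_intron = 10000L, min_anchor = 8L) {
  lines <- readLines(sam_path)
  body <- lines[!startsWith(lines, "@")]
  tb_key <- paste(terminal_bases$chrom, terminal_bases$pos,
                  terminal_bases$which_end)
  cov <- stats::setNames(integer(length(tb_key)), tb_key)
  want_strand <- if (strandedness == "forward") terminal_bases$strand else
    ifelse(terminal_bases$strand == "+", "-", "+")
  junc <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    flag <- as.integer(f[2L])
    if (bitwAnd(flag, 0x4L) != 0L || bitwAnd(flag, 0x100L) != 0L ||
        bitwAnd(flag, 0x800L) != 0L) next
    if (as.integer(f[5L]) < min_mapq) next
    w <- oracle_walk(f[6L], as.integer(f[4L]) - 1L)
    if (is.null(w)) next
    chrom <- f[3L]
    rstrand <- if (bitwAnd(flag, 0x10L) != 0L) "-" else "+"
    # junction support: gap length within bounds, flanking blocks >= anchor
    if (nrow(w$gaps) > 0L) {
      for (gi in seq_len(nrow(w$gaps))) {
        gs <- w$gaps[gi, 1L]; ge <- w$gaps[gi, 2L]
        len <- ge - gs
        left <- w$blocks[w$blocks[, "end"] == gs, , drop = FALSE]
        right <- w$blocks[w$blocks[, "start"] == ge, , drop = FALSE]
        if (nrow(left) != 1L || nrow(right) != 1L) next
        if (len >= min_intron && len <= max_intron &&
            (left[, "end"] - left[, "start"]) >= min_anchor &&
            (right[, "end"] - right[, "start"]) >= min_anchor) {
          key <- paste(chrom, gs, ge)
          junc[[key]] <- (junc[[key]] %||% 0L) + 1L
        }
      }
    }
    # terminal-base coverage: sense strand, any block containing the base
    idx <- which(terminal_bases$chrom == chrom & want_strand == rstrand)
    for (t in idx) {
      p <- terminal_bases$pos[t]
      if (any(w$blocks[, "start"] <= p & p < w$blocks[, "end"])) {
        cov[t] <- cov[t] + 1L
      }
    }
  }
  list(junctions = junc, coverage = cov)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-built SAM files for unit fixtures
make_sam <- function(records, seqlens) {
  path <- tempfile(fileext = ".sam")
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens), seqlens))
  writeLines(c(header, records), path)
  path
}

sam_record <- function(qname, flag, chrom, pos1, mapq, cigar) {
  qlen <- cigar_query_length(cigar)
  paste(qname, flag, chrom, pos1, mapq, cigar, "*", 0, 0,
        strrep("A", qlen), strrep("I", qlen), sep = "\t")
}

cigar_query_length <- function(cigar) {
  m <- regmatches(cigar, gregexpr("[0-9]+|[MIDNSHP=X]", cigar))[[1L]]
  lens <- as.integer(m[c(TRUE, FALSE)])
  ops <- m[c(FALSE, TRUE)]
  sum(lens[ops %in% c("M", "I", "S", "=", "X")])
}

# Enumeration oracle for the closed-form expected efficiency: walk every
# read start position on both templates of a two-exon gene and count
# transread-eligible starts versus terminal-base-covering starts.
enumerate_expected_efficiency <- function(p, exon_len, intron_len,
                                          read_length, min_anchor) {
  e <- exon_len; L <- read_length; a <- min_anchor
  n_trans <- 0L
  for (o in 0:(2L * e - L)) {
    left <- e - o
    right <- o + L - e
    if (left >= a && right >= a && left >= 1L && right >= 1L) {
      n_trans <- n_trans + 1L
    }
  }
  # unspliced template; 5' terminal base sits at genomic offset e
  n_cov <- 0L
  for (o in 0:(2L * e + intron_len - L)) {
    if (o <= e && e <= o + L - 1L) n_cov <- n_cov + 1L
  }
  if (p == 1) return(NA_real_)
  (p * n_trans) / ((1 - p) * n_cov)
}

# Minimal GTF writer for annotation fixtures: exons as (chrom, start1, end1,
# strand, gene, tx) rows, 1-based inclusive
make_gtf <- function(exons) {
  path <- tempfile(fileext = ".gtf")
  writeLines(sprintf(
    "%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    exons$chrom, exons$start1, exons$end1, exons$strand,
    exons$gene, exons$tx
  ), path)
  path
}
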