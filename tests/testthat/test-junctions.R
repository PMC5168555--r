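make_aln <- function(records, seqlens = c(chrI = 100000)) {
  read_alignments(make_sam(records, seqlens))
}

test_that("qualifying N gaps are counted as transreads with anchor and length rules", {
  aln <- make_aln(c(
    sam_record("r1", 0, "chrI", 1, 60, "20M60N80M"),   # junction [20,80)
    sam_record("r2", 0, "chrI", 1, 60, "20M60N80M"),   # same junction
    sam_record("r3", 0, "chrI", 6, 60, "15M15N85M"),   # gap 15 < min_intron
    sam_record("r4", 0, "chrI", 16, 60, "5M60N95M"),   # left anchor 5 < 8
    sam_record("r5", 0, "chrI", 1, 60, "100M")         # no gap
  ))
  j <- extract_junctions(aln, min_intron = 20, max_intron = 10000, min_anchor = 8)
  expect_equal(nrow(j), 1L)
  expect_equal(j$start, 20L)
  expect_equal(j$end, 80L)
  expect_equal(j$transread_count, 2L)
  expect_equal(j$max_left_anchor, 20L)
  expect_equal(j$max_right_anchor, 80L)
  expect_equal(attr(j, "skipped_gaps"), 2L)
})

test_that("a read with several qualifying gaps supports every junction independently", {
  aln <- make_aln(c(
    sam_record("r1", 0, "chrI", 1, 60, "20M50N30M40N20M")
  ))
  j <- extract_junctions(aln)
  expect_equal(nrow(j), 2L)
  expect_equal(j$start, c(20L, 100L))
  expect_equal(j$end, c(70L, 140L))
  expect_equal(j$transread_count, c(1L, 1L))
  # conservation of evidence: total count equals qualifying (read, gap) pairs
  expect_equal(sum(j$transread_count), nrow(aln$gaps) - attr(j, "skipped_gaps"))
})

test_that("junction counting is invariant under read order permutation", {
  set.seed(7)
  recs <- vapply(1:40, function(i) {
    sam_record(sprintf("r%d", i), 0, "chrI", sample(200, 1), 60,
               sample(c("20M60N80M", "30M100N70M", "100M"), 1))
  }, character(1))
  j1 <- extract_junctions(make_aln(recs))
  j2 <- extract_junctions(make_aln(sample(recs)))
  expect_equal(j1, j2, ignore_attr = TRUE)
})

test_that("junctions are classified against annotated introns", {
  introns <- tibble::tibble(
    intron_id = c("i1", "i2"), chrom = "chrI",
    start = c(100L, 300L), end = c(200L, 350L),
    strand = c("+", "+"), gene_id = c("g1", "g2"), transcript_ids = "t"
  )
  junctions <- tibble::tibble(
    chrom = "chrI",
    start = c(100L, 100L, 120L, 100L, 400L),
    end = c(200L, 250L, 200L, 350L, 500L),
    transread_count = 1L, max_left_anchor = 10L, max_right_anchor = 10L
  )
  ann <- annotate_junctions(junctions, introns)
  expect_equal(ann$annotation_class,
               c("known", "novel_acceptor", "novel_donor", "novel_pair", "novel"))
  expect_equal(ann$strand, c("+", "+", "+", "+", "*"))
  expect_equal(ann$gene_id[1], "g1")
  expect_equal(ann$intron_id[1], "i1")
  expect_true(all(is.na(ann$gene_id[-1])))
})

test_that("junctions matching introns on both strands are ambiguous, not known", {
  introns <- tibble::tibble(
    intron_id = c("p", "m"), chrom = "chrI",
    start = 100L, end = 200L, strand = c("+", "-"),
    gene_id = c("gp", "gm"), transcript_ids = "t"
  )
  junctions <- tibble::tibble(
    chrom = "chrI", start = 100L, end = 200L,
    transread_count = 3L, max_left_anchor = 10L, max_right_anchor = 10L
  )
  expect_warning(ann <- annotate_junctions(junctions, introns), "both strands")
  expect_equal(ann$annotation_class, "ambiguous")
})

test_that("known and novel junction tables partition counts across samples", {
  introns <- tibble::tibble(
    intron_id = "i1", chrom = "chrI", start = 100L, end = 200L,
    strand = "+", gene_id = "g1", transcript_ids = "t"
  )
  j_of <- function(starts, ends, counts) {
    annotate_junctions(tibble::tibble(
      chrom = "chrI", start = starts, end = ends,
      transread_count = counts, max_left_anchor = 10L, max_right_anchor = 10L
    ), introns)
  }
  tables <- junction_count_table(
    list(s1 = j_of(c(100L, 400L), c(200L, 500L), c(3L, 2L)),
         s2 = j_of(100L, 200L, 7L)),
    introns
  )
  expect_equal(nrow(tables$known), 1L)
  expect_equal(tables$known$s1, 3L)
  expect_equal(tables$known$s2, 7L)
  expect_equal(nrow(tables$novel), 1L)
  expect_equal(tables$novel$s1, 2L)
  expect_equal(tables$novel$s2, 0L)

  dir <- tempfile()
  paths <- write_junction_counts(tables, dir)
  known <- readr::read_csv(paths[["known"]], show_col_types = FALSE)
  expect_equal(known$s1, 3)
  expect_equal(known$s2, 7)
})

test_that("samples with no detected junctions still yield a header-only known table", {
  introns <- tibble::tibble(
    intron_id = "i1", chrom = "chrI", start = 100L, end = 200L,
    strand = "+", gene_id = "g1", transcript_ids = "t"
  )
  empty <- annotate_junctions(tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    transread_count = integer(), max_left_anchor = integer(),
    max_right_anchor = integer()
  ), introns)
  tables <- junction_count_table(list(s1 = empty), introns)
  expect_equal(nrow(tables$known), 0L)
  dir <- tempfile()
  paths <- write_junction_counts(tables, dir)
  lines <- readLines(paths[["known"]])
  expect_length(lines, 1L)  # header only
})
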