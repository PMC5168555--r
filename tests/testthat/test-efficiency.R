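test_that("efficiency is the transread/coverage ratio with an inclusive 5-read confidence rule", {
  e <- splicing_efficiency(
    transread_count = c(10L, 5L, 9L, 0L, 7L),
    terminal_coverage = c(10L, 5L, 4L, 50L, 0L)
  )
  expect_equal(e$efficiency, c(1, 1, 2.25, 0, NA))
  expect_equal(e$confident, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_error(splicing_efficiency(-1L, 5L), "non-negative")
})

test_that("zero-denominator efficiency is NA and never confident, even at high transreads", {
  e <- splicing_efficiency(1000L, 0L)
  expect_true(is.na(e$efficiency))
  expect_false(e$confident)
})

test_that("pooling sums raw counts so replicates can jointly reach confidence", {
  counts <- tibble::tibble(intron_id = c("a", "b"), r1 = c(3L, 2L), r2 = c(4L, 1L))
  pooled <- pool_samples(counts, list(wt = c("r1", "r2")))
  expect_equal(pooled$wt, c(7L, 3L))
  # single-sample group is the identity
  pooled1 <- pool_samples(counts, list(g = "r1"))
  expect_equal(pooled1$g, counts$r1)
  expect_error(pool_samples(counts, list(bad = character())), "empty")
  expect_error(pool_samples(counts, list(bad = "nope")), "unknown")

  # (4,3) and (3,9) replicates: neither confident alone, pooled (7,12) is
  t_pool <- pool_samples(tibble::tibble(r1 = 4L, r2 = 3L), list(g = c("r1", "r2")))
  c_pool <- pool_samples(tibble::tibble(r1 = 3L, r2 = 9L), list(g = c("r1", "r2")))
  expect_false(splicing_efficiency(4L, 3L)$confident)
  expect_true(splicing_efficiency(t_pool$g, c_pool$g)$confident)
})

test_that("relative efficiency is defined only for confident pairs with positive reference", {
  eff <- function(t, c) splicing_efficiency(t, c)
  expect_equal(relative_efficiency(eff(5L, 10L), eff(10L, 20L))$relative_efficiency, 1)
  expect_equal(relative_efficiency(eff(1L, 10L), eff(9L, 10L))$relative_efficiency,
               NA_real_)  # test not confident
  expect_equal(relative_efficiency(eff(10L, 10L), eff(9L, 4L))$relative_efficiency,
               NA_real_)  # reference not confident
  expect_equal(relative_efficiency(eff(10L, 10L), eff(0L, 10L))$relative_efficiency,
               NA_real_)  # reference zero... and not confident either
  expect_equal(
    relative_efficiency(eff(5L, 50L), eff(45L, 50L))$relative_efficiency,
    (5 / 50) / (45 / 50)
  )
  a <- dplyr::mutate(eff(5L, 10L), intron_id = "x")
  b <- dplyr::mutate(eff(5L, 10L), intron_id = "y")
  expect_error(relative_efficiency(a, b), "disagree")
})

test_that("relative efficiency of a sample against itself is 1 wherever confident", {
  set.seed(31)
  e <- splicing_efficiency(sample(0:30, 50, TRUE), sample(0:30, 50, TRUE))
  rel <- relative_efficiency(e, e)$relative_efficiency
  defined <- e$confident & e$efficiency > 0
  expect_true(all(rel[defined] == 1))
  expect_true(all(is.na(rel[!defined])))
})

test_that("efficiencies are invariant under scaling all counts of a sample", {
  set.seed(32)
  t0 <- sample(0:40, 30, TRUE)
  c0 <- sample(1:40, 30, TRUE)
  e1 <- splicing_efficiency(t0, c0)
  e7 <- splicing_efficiency(7L * t0, 7L * c0)
  expect_equal(e7$efficiency, e1$efficiency)
})

test_that("efficiency records join junction counts with site-matched coverage", {
  known <- tibble::tibble(
    intron_id = c("i1", "i2"), chrom = "chrI", start = c(10L, 60L),
    end = c(40L, 90L), strand = "+", gene_id = c("g1", "g2"),
    s1 = c(10L, 3L)
  )
  cov5 <- tibble::tibble(
    intron_id = c("i1", "i2"), chrom = "chrI", pos = c(10L, 60L),
    strand = "+", which_end = "five_prime", gene_id = c("g1", "g2"),
    s1 = c(20L, 2L)
  )
  recs <- efficiency_records(known, cov5, "five_prime")
  expect_equal(recs$efficiency, c(0.5, 1.5))
  expect_equal(recs$confident, c(TRUE, FALSE))
  expect_equal(recs$sample, c("s1", "s1"))

  dir <- tempfile()
  write_efficiency_tables(recs, recs, dir)
  conf <- readr::read_csv(file.path(dir, "splicing_efficiency_5ss_conf.csv"),
                          show_col_types = FALSE)
  all_ <- readr::read_csv(file.path(dir, "splicing_efficiency_5ss_all.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(conf), 1L)
  expect_equal(nrow(all_), 2L)
  expect_equal(conf$intron_id, "i1")
})

test_that("no confident records yields a header-only _conf file", {
  recs <- dplyr::bind_cols(
    tibble::tibble(intron_id = "i1", chrom = "chrI", start = 1L, end = 30L,
                   strand = "+", gene_id = "g", which_end = "five_prime",
                   sample = "s1"),
    splicing_efficiency(2L, 2L)
  )
  dir <- tempfile()
  write_efficiency_tables(recs, recs, dir)
  expect_length(readLines(file.path(dir, "splicing_efficiency_5ss_conf.csv")), 1L)
})

test_that("scatterplots mark confidence, handle empty input, and show impairment below the diagonal", {
  set.seed(33)
  n <- 15
  ref_t <- sample(10:60, n, TRUE)
  ref_c <- sample(10:60, n, TRUE)
  test_e <- splicing_efficiency(as.integer(floor(ref_t / 2)), ref_c)
  ref_e <- splicing_efficiency(ref_t, ref_c)
  pair <- tibble::tibble(
    efficiency_test = test_e$efficiency,
    efficiency_reference = ref_e$efficiency,
    confident = test_e$confident & ref_e$confident
  )
  path <- tempfile(fileext = ".pdf")
  p <- efficiency_scatterplot(pair, "5ss", "mut", "wt", path)
  expect_true(file.exists(path))
  # halving every transread count displaces all points below the diagonal
  expect_true(all(pair$efficiency_test <= pair$efficiency_reference))
  expect_true(all(pair$efficiency_test[pair$efficiency_test > 0] <
                    pair$efficiency_reference[pair$efficiency_test > 0]))

  empty <- pair[0, ]
  path2 <- tempfile(fileext = ".pdf")
  expect_warning(efficiency_scatterplot(empty, "5ss", "a", "b", path2),
                 "no plottable points")
  expect_true(file.exists(path2))
})
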