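#' Splicing efficiency with confidence flag
#'
#' Efficiency at one splice site is the ratio of transreads (spliced
#' mRNA evidence) to reads covering the intron terminal base (pre-mRNA
#' evidence). A value is confident when both counts reach their
#' thresholds (default 5 reads each, inclusive); a zero denominator gives
#' `NA`, never infinity, and can never be confident.
#'
#' @param transread_count,terminal_coverage Non-negative integer count
#'   vectors (recycled to common length).
#' @param min_transreads,min_coverage Confidence thresholds (default 5).
#' @return A tibble with `transread_count`, `terminal_coverage`,
#'   `efficiency` and `confident`.
#' @examples
#' splicing_efficiency(c(10, 5, 9, 0, 7), c(10, 5, 4, 50, 0))
#' @export
splicing_efficiency <- function(transread_count, terminal_coverage,
                                min_transreads = 5L, min_coverage = 5L) {
  if (any(transread_count < 0, na.rm = TRUE) ||
      any(terminal_coverage < 0, na.rm = TRUE)) {
    stop("counts must be non-negative")
  }
  n <- max(length(transread_count), length(terminal_coverage))
  transread_count <- rep_len(transread_count, n)
  terminal_coverage <- rep_len(terminal_coverage, n)
  eff <- ifelse(terminal_coverage > 0,
                transread_count / terminal_coverage, NA_real_)
  tibble::tibble(
    transread_count = as.integer(transread_count),
    terminal_coverage = as.integer(terminal_coverage),
    efficiency = eff,
    confident = transread_count >= min_transreads &
      terminal_coverage >= min_coverage
  )
}

#' Pool raw counts across replicates of a group
#'
#' Sums count columns element-wise across the samples of each group
#' before any ratio is computed; pooling raw counts (rather than
#' averaging per-replicate ratios) keeps the estimate well-defined at low
#' coverage and matches computing the efficiency ratio on pooled data.
#'
#' @param counts A wide count table with one column per sample.
#' @param groups Named list: group name -> character vector of sample
#'   column names.
#' @return `counts` with one additional integer column per group.
#' @export
pool_samples <- function(counts, groups) {
  stopifnot(is.list(groups))
  for (g in names(groups)) {
    members <- groups[[g]]
    if (length(members) == 0L) stop(sprintf("group '%s' is empty", g))
    missing <- setdiff(members, names(counts))
    if (length(missing) > 0L) {
      stop(sprintf("group '%s' references unknown sample(s): %s",
                   g, paste(missing, collapse = ", ")))
    }
    counts[[g]] <- as.integer(rowSums(as.matrix(counts[, members, drop = FALSE])))
  }
  counts
}

#' Relative splicing efficiency of a test sample over a reference
#'
#' The ratio test/reference at one intron and site, defined only when
#' both records are confident and the reference efficiency is positive;
#' otherwise `NA`.
#'
#' @param test,reference Tibbles of efficiency records (as produced by
#'   [splicing_efficiency()], optionally carrying `intron_id` and
#'   `which_end` key columns) aligned row by row; keys, when present,
#'   must match exactly.
#' @return A tibble with the key columns (if any), per-member
#'   efficiencies and `relative_efficiency`.
#' @export
relative_efficiency <- function(test, reference) {
  stopifnot(nrow(test) == nrow(reference))
  for (key in c("intron_id", "which_end")) {
    if (key %in% names(test) && key %in% names(reference) &&
        !identical(test[[key]], reference[[key]])) {
      stop(sprintf("test and reference records disagree on '%s'", key))
    }
  }
  rel <- ifelse(
    test$confident & reference$confident & reference$efficiency > 0,
    test$efficiency / reference$efficiency,
    NA_real_
  )
  out <- test[, intersect(c("intron_id", "which_end"), names(test)), drop = FALSE]
  out$efficiency_test <- test$efficiency
  out$efficiency_reference <- reference$efficiency
  out$relative_efficiency <- rel
  tibble::as_tibble(out)
}

#' Build long-format efficiency records for one splice site
#'
#' Joins the known-junction transread counts with the matching
#' terminal-base coverage and computes efficiency for every sample or
#' group column. Only introns with detected transreads (present in the
#' known junction table) are reported.
#'
#' @param known_counts Known junction wide table ([junction_count_table()]),
#'   possibly extended by [pool_samples()].
#' @param coverage Wide coverage table for the matching site
#'   ([coverage_count_table()], same pooling applied).
#' @param which_end `"five_prime"` or `"three_prime"`.
#' @param columns Sample/group columns to compute (default: all count
#'   columns shared by the two tables).
#' @param min_transreads,min_coverage Confidence thresholds.
#' @return A long tibble: intron metadata, `which_end`, `sample`,
#'   `transread_count`, `terminal_coverage`, `efficiency`, `confident`.
#' @export
efficiency_records <- function(known_counts, coverage, which_end,
                               columns = NULL,
                               min_transreads = 5L, min_coverage = 5L) {
  which_end <- match.arg(which_end, c("five_prime", "three_prime"))
  meta <- c("intron_id", "chrom", "start", "end", "strand", "gene_id")
  cov_meta <- c("intron_id", "chrom", "pos", "strand", "which_end", "gene_id")
  if (is.null(columns)) {
    columns <- intersect(setdiff(names(known_counts), meta),
                         setdiff(names(coverage), cov_meta))
  }
  cov <- coverage[coverage$which_end == which_end, , drop = FALSE]
  hit <- match(known_counts$intron_id, cov$intron_id)
  if (any(is.na(hit))) {
    stop("known junctions without a matching terminal base; annotation mismatch")
  }
  recs <- lapply(columns, function(s) {
    e <- splicing_efficiency(known_counts[[s]], cov[[s]][hit],
                             min_transreads, min_coverage)
    dplyr::bind_cols(
      known_counts[, meta, drop = FALSE],
      tibble::tibble(which_end = which_end, sample = s),
      e
    )
  })
  dplyr::bind_rows(recs)
}

#' Write efficiency tables as CSV
#'
#' For each splice site, writes a `_conf` table containing only the
#' confident records and a companion `_all` table carrying every record
#' with its confidence flag
#' (`splicing_efficiency_5ss_conf.csv` / `_all.csv`, likewise `3ss`).
#'
#' @param records5,records3 Long record tables from
#'   [efficiency_records()] for the 5' and 3' sites.
#' @param dir Output directory (created if missing).
#' @return Paths of the written files, invisibly.
#' @export
write_efficiency_tables <- function(records5, records3, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (site in c("5ss", "3ss")) {
    recs <- if (site == "5ss") records5 else records3
    conf <- file.path(dir, sprintf("splicing_efficiency_%s_conf.csv", site))
    all_ <- file.path(dir, sprintf("splicing_efficiency_%s_all.csv", site))
    write_csv_na(recs[recs$confident, , drop = FALSE], conf)
    write_csv_na(recs, all_)
    paths <- c(paths, conf, all_)
  }
  invisible(paths)
}

#' Write relative-efficiency tables as CSV
#'
#' Writes `relative_splicing_efficiency_5ss_conf.csv` and `_3ss_conf.csv`;
#' only rows with a defined relative efficiency (both members confident)
#' are included.
#'
#' @param relative5,relative3 Tables with a `relative_efficiency` column
#'   (one row per intron and pair; a `pair_id` column identifies the
#'   comparison).
#' @param dir Output directory (created if missing).
#' @return Paths of the written files, invisibly.
#' @export
write_relative_tables <- function(relative5, relative3, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p5 <- file.path(dir, "relative_splicing_efficiency_5ss_conf.csv")
  p3 <- file.path(dir, "relative_splicing_efficiency_3ss_conf.csv")
  write_csv_na(relative5[!is.na(relative5$relative_efficiency), , drop = FALSE], p5)
  write_csv_na(relative3[!is.na(relative3$relative_efficiency), , drop = FALSE], p3)
  invisible(c(five_prime = p5, three_prime = p3))
}

#' Scatterplot of reference versus test splicing efficiency
#'
#' One point per intron for one sample pair and splice site: reference
#' efficiency on x, test on y, log10-log10 axes. Confident points (both
#' members confident) are filled, low-confidence points open.
#' Non-positive or undefined efficiencies cannot be placed on log axes
#' and are excluded; their number is reported in the plot caption.
#'
#' @param pair_records Tibble with columns `efficiency_test`,
#'   `efficiency_reference` and `confident` (both members confident).
#' @param site Label for the splice site (`"5ss"`/`"3ss"`), used in the
#'   title.
#' @param test_label,ref_label Axis labels.
#' @param path Output PDF path.
#' @return The ggplot object, invisibly; the PDF is written as a side
#'   effect (an empty plot with a warning if nothing is plottable).
#' @export
efficiency_scatterplot <- function(pair_records, site, test_label, ref_label,
                                   path) {
  ok <- !is.na(pair_records$efficiency_test) &
    !is.na(pair_records$efficiency_reference) &
    pair_records$efficiency_test > 0 &
    pair_records$efficiency_reference > 0
  n_excluded <- sum(!ok)
  d <- pair_records[ok, , drop = FALSE]
  if (nrow(d) == 0L) {
    warning("no plottable points; writing an empty plot")
  }
  d$confident <- factor(d$confident, levels = c("TRUE", "FALSE"))
  p <- ggplot2::ggplot(
    d, ggplot2::aes(x = .data$efficiency_reference, y = .data$efficiency_test,
                    shape = .data$confident)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(size = 1.8, alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_shape_manual(
      values = c(`TRUE` = 16, `FALSE` = 1),
      labels = c(`TRUE` = "confident", `FALSE` = "low coverage"),
      name = NULL, drop = FALSE
    ) +
    ggplot2::labs(
      title = sprintf("Splicing efficiency, %s", site),
      x = sprintf("%s efficiency", ref_label),
      y = sprintf("%s efficiency", test_label),
      caption = sprintf("%d intron(s) with zero/undefined efficiency not shown",
                        n_excluded)
    ) +
    ggplot2::theme_bw()
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  # rendering chatter (e.g. empty-scale notes on an empty plot) is not a
  # user-facing condition
  suppressMessages(suppressWarnings(
    ggplot2::ggsave(path, p, width = 5, height = 5)
  ))
  invisible(p)
}
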