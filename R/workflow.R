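#' Run the complete splicing-efficiency workflow
#'
#' Executes annotation parsing, alignment filtering, junction detection,
#' terminal-base coverage, efficiency calculation, pooling, pairwise
#' relative efficiencies and plotting for every configured sample, and
#' writes the standard output folders:
#'
#' * `introns/` — terminal-base BED files and their per-sample coverage
#'   counts (`introns_known_5ss.bed`, `introns_known_5ss.bed.counts.csv`,
#'   likewise `3ss`);
#' * `transreads/` — known/novel junction count tables
#'   (`splice_junctions_coverage.known.csv`, `.novel.csv`);
#' * `efficiency/` — per-sample/group efficiencies
#'   (`splicing_efficiency_5ss_conf.csv` + `_all`, likewise `3ss`) and
#'   pairwise relative efficiencies
#'   (`relative_splicing_efficiency_5ss_conf.csv`, likewise `3ss`);
#' * `images/` — reference-vs-test efficiency scatterplots (PDF), one per
#'   pair and site.
#'
#' Only introns with at least one detected transread in at least one
#' sample appear in the junction and efficiency tables.
#'
#' @param config A [splice_workflow_config()] object.
#' @param output_dir Root output directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the computed tables: `introns`,
#'   `terminal_bases`, `junctions` (known/novel wide tables), `coverage5`
#'   / `coverage3`, `efficiency5` / `efficiency3` (long records over
#'   samples and groups), and `relative5` / `relative3`.
#' @export
run_splicing_workflow <- function(config, output_dir, quiet = FALSE) {
  stopifnot(inherits(config, "splice_workflow_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  introns <- parse_gene_annotation(config$gtf)
  say("annotation: %d unique introns", nrow(introns))
  tb <- intron_terminal_bases(introns)
  introns_dir <- file.path(output_dir, "introns")
  dir.create(introns_dir, recursive = TRUE, showWarnings = FALSE)
  write_terminal_bed(tb[tb$which_end == "five_prime", ],
                     file.path(introns_dir, "introns_known_5ss.bed"))
  write_terminal_bed(tb[tb$which_end == "three_prime", ],
                     file.path(introns_dir, "introns_known_3ss.bed"))

  junc_by_sample <- list()
  cov5_by_sample <- list()
  cov3_by_sample <- list()
  for (s in names(config$samples)) {
    aln <- read_alignments(config$samples[[s]], min_mapq = config$min_mapq)
    say("sample %s: %d reads kept (%d low-MAPQ, %d unmapped dropped)",
        s, nrow(aln$reads), aln$dropped$low_mapq, aln$dropped$unmapped)
    j <- extract_junctions(aln, min_intron = config$min_intron,
                           max_intron = config$max_intron,
                           min_anchor = config$min_anchor)
    junc_by_sample[[s]] <- annotate_junctions(j, introns)
    say("sample %s: %d junctions (%d known)", s, nrow(junc_by_sample[[s]]),
        sum(junc_by_sample[[s]]$annotation_class == "known"))
    cov <- terminal_base_coverage(aln, tb, config$strandedness)
    cov5_by_sample[[s]] <- cov[cov$which_end == "five_prime", ]
    cov3_by_sample[[s]] <- cov[cov$which_end == "three_prime", ]
  }

  junctions <- junction_count_table(junc_by_sample, introns)
  write_junction_counts(junctions, file.path(output_dir, "transreads"))
  coverage5 <- coverage_count_table(cov5_by_sample)
  coverage3 <- coverage_count_table(cov3_by_sample)
  write_coverage_counts(coverage5, coverage3, introns_dir)

  known <- pool_samples(junctions$known, config$sample_groups)
  coverage5 <- pool_samples(coverage5, config$sample_groups)
  coverage3 <- pool_samples(coverage3, config$sample_groups)
  units <- c(names(config$samples), names(config$sample_groups))

  eff5 <- efficiency_records(known, coverage5, "five_prime", columns = units,
                             min_transreads = config$min_transreads,
                             min_coverage = config$min_coverage)
  eff3 <- efficiency_records(known, coverage3, "three_prime", columns = units,
                             min_transreads = config$min_transreads,
                             min_coverage = config$min_coverage)
  eff_dir <- file.path(output_dir, "efficiency")
  write_efficiency_tables(eff5, eff3, eff_dir)

  rel5 <- list()
  rel3 <- list()
  for (pair in config$sample_pairs) {
    pair_id <- sprintf("%s_vs_%s", pair[[1L]], pair[[2L]])
    for (site in c("five_prime", "three_prime")) {
      eff <- if (site == "five_prime") eff5 else eff3
      test <- eff[eff$sample == pair[[1L]], , drop = FALSE]
      ref <- eff[eff$sample == pair[[2L]], , drop = FALSE]
      rel <- relative_efficiency(test, ref)
      rel <- dplyr::mutate(rel, pair_id = pair_id, .before = 1L)
      rel$gene_id <- test$gene_id
      if (site == "five_prime") rel5[[pair_id]] <- rel else rel3[[pair_id]] <- rel

      plot_rec <- tibble::tibble(
        efficiency_test = test$efficiency,
        efficiency_reference = ref$efficiency,
        confident = test$confident & ref$confident
      )
      efficiency_scatterplot(
        plot_rec, site = if (site == "five_prime") "5ss" else "3ss",
        test_label = pair[[1L]], ref_label = pair[[2L]],
        path = file.path(output_dir, "images", sprintf(
          "%s_%s.pdf", pair_id, if (site == "five_prime") "5ss" else "3ss"))
      )
    }
  }
  rel5 <- dplyr::bind_rows(rel5)
  rel3 <- dplyr::bind_rows(rel3)
  if (length(config$sample_pairs) > 0L) {
    write_relative_tables(rel5, rel3, eff_dir)
  }

  invisible(list(
    introns = introns, terminal_bases = tb, junctions = junctions,
    coverage5 = coverage5, coverage3 = coverage3,
    efficiency5 = eff5, efficiency3 = eff3,
    relative5 = rel5, relative3 = rel3
  ))
}
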