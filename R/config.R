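#' Workflow configuration
#'
#' Bundles sample paths, library strandedness, filtering thresholds,
#' replicate groups and comparison pairs for a full run. Strandedness has
#' no default: it must be stated explicitly because a value that does not
#' match the library protocol silently corrupts every count.
#'
#' @param gtf Path to the genome annotation (GTF).
#' @param samples Named character vector: sample name -> SAM/BAM path.
#' @param strandedness `"forward"` or `"reverse"` (see
#'   [terminal_base_coverage()]).
#' @param min_mapq Minimum MAPQ to keep a read (default 10).
#' @param min_intron,max_intron Intronic gap length bounds in nt
#'   (defaults 20 and 10000).
#' @param min_anchor Minimum junction anchor in nt (default 8).
#' @param min_transreads,min_coverage Confidence thresholds (default 5
#'   reads each).
#' @param sample_groups Named list: group name -> character vector of
#'   sample names whose raw counts are pooled (e.g. replicates of one
#'   genotype).
#' @param sample_pairs List of `c(test, reference)` character pairs, each
#'   naming a declared sample or group, compared as relative
#'   efficiencies.
#' @return A `splice_workflow_config` object.
#' @export
splice_workflow_config <- function(gtf, samples, strandedness,
                                   min_mapq = 10L, min_intron = 20L,
                                   max_intron = 10000L, min_anchor = 8L,
                                   min_transreads = 5L, min_coverage = 5L,
                                   sample_groups = list(),
                                   sample_pairs = list()) {
  strandedness <- match.arg(strandedness, c("forward", "reverse"))
  stopifnot(
    is.character(samples), length(samples) > 0L,
    !is.null(names(samples)), all(nzchar(names(samples))),
    min_mapq >= 0L, min_intron >= 1L, max_intron >= min_intron,
    min_anchor >= 1L, min_transreads >= 0L, min_coverage >= 0L
  )
  known_units <- c(names(samples), names(sample_groups))
  for (g in names(sample_groups)) {
    bad <- setdiff(sample_groups[[g]], names(samples))
    if (length(bad) > 0L) {
      stop(sprintf("group '%s' references undeclared sample(s): %s",
                   g, paste(bad, collapse = ", ")))
    }
  }
  for (p in sample_pairs) {
    if (length(p) != 2L || !all(p %in% known_units)) {
      stop("each sample pair must be c(test, reference) over declared samples/groups")
    }
  }
  structure(list(
    gtf = gtf, samples = samples, strandedness = strandedness,
    min_mapq = as.integer(min_mapq), min_intron = as.integer(min_intron),
    max_intron = as.integer(max_intron), min_anchor = as.integer(min_anchor),
    min_transreads = as.integer(min_transreads),
    min_coverage = as.integer(min_coverage),
    sample_groups = sample_groups, sample_pairs = sample_pairs
  ), class = "splice_workflow_config")
}

#' Read a workflow configuration from YAML
#'
#' Expected keys mirror the arguments of [splice_workflow_config()];
#' `samples` is a mapping of sample name to path, `sample_groups` a
#' mapping of group name to a list of sample names, and `sample_pairs` a
#' list of two-element `[test, reference]` lists.
#'
#' @param path YAML file path.
#' @param overrides Named list of scalar settings that take precedence
#'   over the file (used by the command-line interface flags).
#' @return A `splice_workflow_config` object.
#' @export
read_workflow_config <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  for (k in names(overrides)) y[[k]] <- overrides[[k]]
  scalars <- c("min_mapq", "min_intron", "max_intron", "min_anchor",
               "min_transreads", "min_coverage")
  args <- list(
    gtf = y$gtf,
    samples = unlist(y$samples),
    strandedness = y$strandedness,
    sample_groups = lapply(y$sample_groups %||% list(), unlist),
    sample_pairs = lapply(y$sample_pairs %||% list(), unlist)
  )
  for (k in scalars) if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(splice_workflow_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
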