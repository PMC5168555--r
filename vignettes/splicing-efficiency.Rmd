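---
title: "Measuring splicing efficiency from strand-specific RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring splicing efficiency from strand-specific RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceff)
```

## The measurement

Budding yeast has a compact transcriptome in which only a minority of
genes carry introns, usually a single one, yet those genes are so highly
expressed that roughly a third of all mRNA molecules are spliced.
Splicing efficiency — how completely a given intron is removed — is the
quantity of interest when studying spliceosome mutants or condition-
dependent splicing regulation, and it can be estimated genome-wide from
ordinary strand-specific RNA-seq.

`spliceff` estimates splicing efficiency per intron and per splice site
as a ratio of two read counts taken at single-base resolution:

* **transreads** — reads whose alignment spans an exon–exon junction
  with an N-gapped CIGAR. By construction a transread covers at least
  the last base of the upstream exon and the first base of the
  downstream exon, and it can only derive from a spliced mRNA molecule;
* **terminal-base coverage** — reads (on the sense strand, with split
  alignment blocks honoured) covering the single first base of the
  intron (5′ splice site) or the single last base (3′ splice site).
  Those bases exist only in unspliced pre-mRNA.

For each intron,

$$
\mathrm{Efficiency}_{5'} = \frac{\text{transread count}}
     {\text{coverage of the first intronic base}},
\qquad
\mathrm{Efficiency}_{3'} = \frac{\text{transread count}}
     {\text{coverage of the last intronic base}} .
$$

The two sites reflect the two catalytic steps of splicing, and the
single-base denominator makes the estimate comparable to an RT-qPCR
assay with primers across the exon–intron boundary. It also makes the
ratio insensitive to library size: both counts come from the same
sample, so any global scaling cancels (this invariance is asserted in
the test suite). Because only a single base is counted, introns hosting
stable nested ncRNAs (e.g. snoRNAs), whose excised introns persist and
would inflate whole-intron read counts, bias this estimator less than
window-based alternatives — though the terminal bases themselves are
still part of the excised lariat.

The estimator is a ratio of counts, not a fraction: values above 1 are
legitimate (spliced mRNA more abundant than pre-mRNA at that junction,
the common case for efficiently spliced genes).

## Pipeline stages and their parameters

1. **Annotation** (`parse_gene_annotation`). Introns are inferred as the
   gaps between consecutive exons of each multi-exon transcript in the
   GTF; explicit intron features are ignored because exon features are
   the one universal representation across annotation sources. Introns
   identical in coordinates and strand across transcripts collapse into
   one record. Internally everything is 0-based half-open; GTF is
   converted on read and BED written natively, so there is exactly one
   coordinate convention in the code. No intron length filter is
   applied at this stage — length bounds belong to junction detection.
2. **Alignment filtering** (`read_alignments`, default
   `min_mapq = 10`). Unmapped, secondary and supplementary records are
   dropped, then reads below the MAPQ threshold. MAPQ ≥ 10 plus
   primary-only is our operational reading of "aligned unambiguously to
   a single locus"; duplicates are deliberately kept, as no
   deduplication is part of the method. Reads are treated as single-end
   regardless of mate flags.
3. **Junction detection** (`extract_junctions`, defaults
   `min_intron = 20`, `max_intron = 10000`, `min_anchor = 8`). Every N
   gap with an in-range length whose two flanking blocks each align at
   least `min_anchor` reference bases counts as one transread for that
   junction; a read with several qualifying gaps supports each junction
   independently. The intron length bounds are the values appropriate
   for yeast; the 8 nt anchor matches the default of widely used
   junction-extraction tools, and because counts are anchor-sensitive
   the same value must be used for samples that will be compared.
4. **Annotation of junctions** (`annotate_junctions`). `known` requires
   an exact donor–acceptor coordinate match to one annotated intron —
   the strictest reading; junctions matching only one annotated
   boundary are `novel_donor`/`novel_acceptor`, two boundaries of
   different introns `novel_pair`. A junction matching introns on both
   strands at identical coordinates is `ambiguous` and excluded from
   the known set, since its strand (and hence sense-counting) is
   undecidable from single-end data.
5. **Terminal-base coverage** (`terminal_base_coverage`). Counts
   sense-strand reads with an aligned block containing the base.
   `strandedness` (`forward`/`reverse`) has **no default**: it encodes
   the library protocol, and a silently wrong value corrupts every
   denominator. Split-read semantics guarantee that a transread never
   counts towards the terminal-base coverage of its own junction — the
   gap excludes those bases — so numerator and denominator partition
   the evidence. Deletions (D) remain inside a block, so a base spanned
   by a small deletion still counts as covered.
6. **Efficiency, confidence, pooling, comparison**
   (`splicing_efficiency`, `pool_samples`, `relative_efficiency`).
   A value is *confident* when transreads ≥ 5 **and** terminal coverage
   ≥ 5 (inclusive); the `_conf` output tables contain exactly the
   confident records, the `_all` tables everything with the flag. Both
   thresholds are configurable. A zero denominator yields `NA`, never
   infinity — such a site fails the coverage threshold anyway, and NA
   keeps the CSVs numerically clean. Replicates of a genotype are
   pooled by summing raw counts *before* the ratio is taken: averaging
   per-replicate ratios would be undefined or unstable exactly where
   counts are low, whereas the pooled ratio is the efficiency of the
   pooled data. Relative efficiency (test/reference, e.g. mutant over
   wild type) is reported only where both members are confident and the
   reference is positive.

Scatterplots are drawn on log10–log10 axes with confident points filled
and low-confidence points open. Zero or undefined efficiencies cannot
be placed on log axes; they are excluded rather than nudged with
pseudocounts — a pseudocount would silently change reported values —
and their number is stated in the plot caption.

## The simulator

`sim_spec()`/`simulate_dataset()` generate a synthetic genome, GTF and
SAM with known ground truth, so every stage of the pipeline is testable
without downloads. Each gene sits on its own chromosome with two exons
(configurably more), canonical GT..AG motifs at the intron boundaries,
and a spliced fraction *p*. Reads are error-free, uniformly started,
and strand-faithful to the declared protocol: each start position on
the spliced transcript emits reads at rate `depth × p / L`, each
position on the unspliced pre-mRNA at rate `depth × (1 − p) / L`
(Poisson counts), so `depth` is the mean per-base coverage summed over
the two isoforms. A configurable fraction of decoy reads carries low
MAPQ to exercise the filter.

Under this sampling, a junction with anchor requirement *a* collects
transreads from exactly `L − 2a + 1` start positions and a terminal
base is covered from exactly `L` positions, giving the closed form

$$
E[\widehat{\mathrm{eff}}] \;=\; \frac{p\,(L - 2a + 1)}{(1-p)\,L},
$$

implemented as `expected_efficiency()` and verified in the tests by
exhaustive enumeration of every start position on both templates. This
is the package's parameter-recovery oracle: the pipeline estimate must
fall within 3 binomial standard errors (delta-method on the two Poisson
counts) of the closed form for every simulated gene.

What the simulator does *not* emulate: sequencing errors and indels
(the pipeline never inspects base identities), non-uniform coverage
along transcripts (3′ bias, mappability), overlapping genes and
antisense transcription, multi-mapping reads (decoys model only the
MAPQ outcome), and partial splicing intermediates. Passing the
recovery tests therefore demonstrates correctness of the counting and
the estimator under ideal sampling, not robustness to real-library
artefacts; the confidence threshold and the strandedness warning exist
precisely because real data are messier.

## Numerical and degenerate-input choices

* Coordinates: 0-based half-open internally; GTF (+1-based inclusive)
  converted on read; BED written natively; a base at a block's `end` is
  *not* covered.
* A length-1 intron places both terminal bases on the same coordinate;
  both sites then share a denominator.
* Insertions or clips sandwiched between two N operations would create
  a zero-length "block"; it can anchor nothing, so it is dropped and
  the two gaps merge. An alignment whose first or last
  reference-consuming operation is N has no flanking anchor at all and
  is flagged malformed and skipped (with a counter), as are unparsable
  CIGARs.
* Overlapping introns sharing a terminal-base coordinate are counted
  independently and report the same coverage value — the contract is
  per-intron.
* Junction tables report only junctions with at least one observed
  transread in at least one sample; efficiency tables inherit that row
  set (a gene with no junction evidence anywhere has no efficiency
  row).

## Validation problem sizes

The shipped test-suite and acceptance script validate on: 50 small
simulated samples (two-three genes, ~50–150 reads each, mixed strands,
protocols, decoys and multi-intron genes) checked *exactly* against an
independent brute-force re-count that re-parses the SAM text and walks
every CIGAR base by base; and a 20-gene simulation at 500× depth with
spliced fractions cycling through 0.1–0.9 (read length 100, anchor 8,
150 nt exons, 100 nt introns) for parameter recovery at both splice
sites and for a paired mutant-versus-wild-type comparison with the test
sample's spliced fractions halved. These sizes give every gene
comfortably more than the 5-read confidence minimum while keeping the
whole validation desk-scale.

## Known limitations

* Single-end semantics only; paired-end data should be reduced to one
  read per fragment upstream (e.g. use read 1 only).
* No significance testing on relative efficiencies — the output is the
  ratio table and the scatterplots; replicate concordance is the
  intended reliability check.
* The `known` class requires exact junction coordinates; annotation
  inaccuracies at either boundary demote a junction to a novel class.
* No normalisation across samples beyond the ratio's internal
  cancellation; comparing *absolute* efficiencies across libraries of
  very different quality remains the user's risk.
* Alternative splicing is handled only as far as coordinate
  deduplication — appropriate for budding yeast, where it is rare, but
  not for organisms with pervasive isoform complexity.
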