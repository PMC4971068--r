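---
title: "Measuring genome plasticity along a clonal polyploid filament"
author: "filoplast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring genome plasticity along a clonal polyploid filament}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model

A filament of a giant sulfur bacterium is a chain of clonal cells, each
highly polyploid (tens of thousands of genome copies per cell). Cutting
one filament into consecutive segments and sequencing each segment
independently gives two complementary views of genomic plasticity:

* the **consensus** view: each segment assembly collapses the reads of
  ~30 cells into one sequence; differences between segment assemblies are
  fixed (or nearly fixed) differences between groups of cells;
* the **within-segment** view: at individual positions a minority allele
  can be carried by an appreciable fraction of the reads, reflecting
  heterogeneity among the genome copies of the segment's cells. We call
  such positions intrasegmental sequence heterogeneity (ISH) events.

`filoplast` implements both measurements plus the supporting machinery
(fragment ANI, summary tables) and a simulator that generates complete
synthetic filaments with known ground truth. This vignette records the
model, the parameters that matter, and the design decisions taken where
the procedure was genuinely open.

## Pairwise assembly comparison

Two segment assemblies of one filament are expected to be > 99.9%
identical, which permits a light-weight anchored alignment instead of a
general-purpose whole-genome aligner:

1. **Anchors.** All k-mers (default k = 21) occurring exactly once in
   each sequence are matched; hits advancing along one diagonal with
   start distance at most k are merged into maximal exact matches.
   Windows containing non-ACGT characters never seed anchors. Requiring
   two-sided uniqueness makes false anchors vanishingly rare at
   bacterial genome sizes, at the cost of occasional coverage gaps where
   a k-mer happens to recur (about one chance 21-mer collision per
   3 Mbp genome).
2. **Chaining.** The highest-total-length subset of anchors with
   strictly increasing start coordinates in both sequences is selected
   by a weighted longest-increasing-subsequence dynamic program.
   Consecutive anchors may overlap by up to 32 bp — maximal exact
   matches legitimately overlap around indels in micro-repeat context —
   and such overlaps are trimmed from the later anchor, preserving
   exactness. Ties are resolved toward the smaller total gap span, then
   the leftmost query coordinate, so output is deterministic.
3. **Gap alignment.** Inter-anchor gaps (and the flanks) are aligned
   globally within a band (default half-width 256, automatically widened
   to cover the gap-pair length difference) under match +1, mismatch −1,
   gap open −2, gap extend −1. The scoring scheme is a package choice;
   any scheme consistent with near-identity alignment works, and
   equivalence tests against an unbanded full dynamic program pin the
   behaviour. A gap exceeding 20 kbp on either side is flagged
   structurally divergent and excluded from variant calling rather than
   forced through an alignment.
4. **Calls.** Each mismatch column is one SNP. A run of r gap columns
   counts as r single-nucleotide indel events (the events this analysis
   is restricted to); a one-event-per-run mode exists but is off by
   default, since whether a published pipeline counted runs or bases is
   generally unknowable. Insertions are recorded at the target position
   of the base they follow; deletions at the deleted base. Columns
   pairing an N never yield calls; denominators remain whole assembly
   lengths.

Counts are partitioned by membership of the call position in the
**query** assembly's merged CDS intervals, and all six densities
(total/CDS/nCDS × SNP/indel) are `1e5 * count / length` with the query
assembly's total, CDS and nCDS lengths as denominators. The query-side
convention is not arbitrary: it is the only denominator choice that
reproduces the bundled published table's printed cells from its printed
counts (e.g. 132 SNPs against the 3,217,969 bp query gives 4.10/100 kbp,
and 86 against 3,239,714 gives 2.65). Coordinates are 0-based half-open
internally; GFF3 input is converted on read and reports are 1-based.

Rounding (half-up, 2 decimals for rates, 1 for summary means) is applied
only at serialization; aggregation always uses full precision. The
bundled published table has one internally inconsistent row (the
reference-segment-1 indels-in-CDS row, whose count row duplicates
segment 3's); the package recomputes from counts and reports the
difference rather than silently preferring either version.

## ISH calling and co-localization

The caller consumes per-position allele counts (contig, 1-based
position, reference base, depth, A/C/G/T/ins/del counts — a dialect any
mpileup post-processor can emit). For every column with depth at or
above the coverage floor the consensus is the majority base, ties
resolved to the lexicographically smallest base for determinism; every
non-consensus allele whose read fraction reaches the frequency threshold
yields one event. Defaults follow the standard operating point for
several-hundred-fold libraries: **coverage ≥ 100** (read heterogeneity
is only robust above ~30×, so the floor is constrained to ≥ 31) and
**variant frequency ≥ 0.25**. Frequency is per allele (variant reads /
depth), so a column can yield at most three SNV events plus an insertion
and a deletion event. No strand-bias, base-quality or mapping-quality
filters are applied — real-data users should pre-filter their pileups
accordingly.

Sites are keyed by (contig, position, event class, variant allele) and a
site is **co-localized** when every segment carries a matching event.
Requiring the variant allele to match makes co-localization
well-defined; a looser present-in-≥2-segments fraction is reported
alongside, as is the event-level fraction (shared-by-all events per
segment over mean events per segment), which is the quantity usually
quoted when "a third of events recur in all segments".

## Fragment ANI

Average nucleotide identity uses the classical fragment procedure:
consecutive non-overlapping 1,020 bp windows (a trailing window is kept
if ≥ 100 bp), each placed on the other genome by the same
anchor-chain-align machinery, contributing its percent identity over
aligned columns when it reaches 30% identity over at least 70% of its
length. Fragments contribute unweighted; one-way ANI is the mean over
retained fragments and two-way ANI the mean of the two directions.
These constants are the cited method's, not fitted values. At the
divergences relevant here (a few SNPs per 100 kbp) two-way ANI sits at
99.98–100%, so the measure mainly serves as a sanity check that
assemblies are near-clonal.

## The simulator

The generator emulates the study conditions: a single ~3.2 Mbp, ~34%
G+C genome that is ~88% coding; six segments; per-position Poisson
coverage around 380× (the library means range from ~220 to ~470);
per-base sequencing error 0.005. Structure and rates:

* **Reference.** Random sequence; gene lengths ~ Gamma(shape 4, mean
  1 kbp), intergenic gaps ~ Poisson with mean chosen so coding fraction
  meets the target; a deterministic end-correction lands the fraction
  within ±0.02 (±0.005 in practice at megabase sizes).
* **Consensus divergence.** Substitutions and single-nucleotide indels
  are placed i.i.d. uniformly within each compartment at
  compartment-specific per-bp rates — the simplest null consistent with
  the observed absence of positional directionality. Defaults
  (SNP 1.8×10⁻⁵/bp CDS, 4.25×10⁻⁵/bp nCDS; indel 1×10⁻⁶ and 2×10⁻⁵) are
  half the segment-pair densities of the published table's segments 1–4
  block, because each segment mutates independently from the common
  reference and pairwise divergence is the sum of two branches.
  Configurations implying > 10% divergence are rejected — the anchored
  aligner assumes near-clonality. The CDS annotation is carried through
  the indels so each segment assembly has consistent coordinates.
* **ISH.** Distinct sites are planted on the framework coordinates; a
  fraction (default 1/3) is present with identical position and variant
  allele in every segment, the rest are private to one segment each.
  The distinct-site count is solved from the per-segment event rate
  (default 7×10⁻⁴/bp, ~2,260 events per segment at 3.2 Mbp). True
  variant frequencies are drawn per site and segment from U(0.25, 0.5):
  only the calling threshold is known, not the real frequency spectrum,
  so the spectrum is a free modelling choice kept wide. Within-cell
  copy number is unknown and deliberately not modelled; frequency is a
  free parameter rather than a function of ploidy.
* **Pileups.** Each segment library is simulated against the framework
  (reference) coordinates: the co-localization analysis needs a single
  coordinate system, and mapping per-segment consensus coordinates
  through indels would add machinery the analysis never uses. Fixed
  consensus differences are consequently *not* injected into pileups —
  consensus-level divergence is the assembly-comparison module's
  subject. At ISH sites the variant count is Binomial(depth, true
  frequency); elsewhere non-reference reads arise only from sequencing
  error, split evenly over the three other bases. Insertion/deletion
  read counts are emitted (as zeros): the generator plants SNV
  heterogeneity only, while the caller's indel path is exercised by
  hand-built pileups in the tests.
* **Reproducibility.** One seed drives everything; per-stage and
  per-segment sub-seeds are derived by fixed offsets, and all outputs
  (FASTA, GFF3, pileup TSV, truth TSV, config JSON) are byte-identical
  across runs. No read-level FASTQ, mapping step, amplification-bias or
  contamination model is included.

### What recovery experiments can and cannot show

Two detection effects are intrinsic to thresholded calling and matter
when interpreting recovery rates:

* a site with true frequency *f* at the calling threshold is detected
  with probability ≈ 0.5 (the binomial sample straddles 0.25), so
  end-to-end sensitivity under the default U(0.25, 0.5) spectrum is
  ~0.9, not 1;
* a site with *f* near 0.5 can flip consensus and variant in a given
  segment (variant reads exceed reference reads, probability up to ~0.5
  at f = 0.5), after which its event key carries the other allele and
  legitimately fails to match across segments. For co-localized sites
  this deflates the shared-by-all fraction by roughly (1 − q)⁶ with q
  the per-segment flip probability — at U(0.3, 0.5) and 380× that is
  ~0.76, enough to pull a planted site fraction of 1/3 down to ~0.24 in
  the called events.

Recovery experiments in the tests and the acceptance script therefore
draw truth frequencies from [0.30, 0.45] — clear of both boundaries — so
that they measure the pipeline, not the unavoidable threshold
statistics. Generator defaults stay at the wide spectrum, and the
worked example in the README shows the resulting (expected) gap between
planted and recovered co-localized fractions. Passing tests on
simulated data demonstrate internal correctness of the machinery; they
do not validate mapping artefacts, strand bias, quality miscalibration
or amplification chimeras, none of which the simulator models.

## Summary statistics

The block matrix (one block per reference segment, ten rows in the
published order) is assembled at full precision; gap cells for missing
pairs stay `NA`, never 0, and self-comparisons are zero by construction.
Subset summaries report the sample (n−1) standard deviation — this is
the convention that reproduces the published "4.2 ± 1" (population sd
gives 0.9). The "segments 1–4" subset takes all 12 ordered off-diagonal
pairs within the subset; the "segments 5–6 involved" subset takes all 18
ordered pairs with 5 or 6 on either side, the reading of "among each
other and to all other segments" that reproduces the published 19.2.
Whether published means were computed from rounded cells or full
precision is unknowable; both agree to the printed precision here
(asserted as an invariant), and the package computes from full precision
except when explicitly summarizing the bundled printed cells.

## Problem sizes

The test suite and the acceptance script exercise the pipeline at the
sizes the statistics require rather than maximal ones: exact-recovery
and ANI properties at the full 3.2 Mbp genome scale, oracle equivalence
on 200 pairs up to 5 kbp, co-localization recovery at ~2,000 sites on a
1 Mbp genome, rate-ratio and ISH/SNP-ratio properties on 0.4–0.5 Mbp
genomes over five seeds, and one full six-segment end-to-end run at
1 Mbp. The analysis scripts use a 0.5 Mbp genome, enough for every
qualitative conclusion while keeping each script in the tens of seconds.

## Known limitations

* No rearrangement or inversion detection: the anchored chain is
  colinear by construction, and genuinely divergent regions are excluded
  and reported, not resolved.
* Contig pairing between fragmented assemblies is reciprocal-best by
  shared anchor length; for the simulated single-contig genomes this is
  trivial, and heavily fragmented real assemblies may need external
  scaffolding first.
* The ISH caller reproduces exactly two published thresholds; the
  variant model behind any particular published count (quality
  weighting, indel representation) is tool-specific and not emulated.
* ANI fragments are placed by unique-k-mer seeding; genomes so repetitive
  that fragments lack unique 21-mers would lose fragments to the
  unalignable class (reported in the fragment counts).
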