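---
title: "Inferring PAMs, array orientation and strand bias from CRISPR spacer targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring PAMs, array orientation and strand bias from CRISPR spacer targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacerscope)
```

## The problem

CRISPR arrays store fragments of past invaders (spacers) between near-identical
repeats. When a spacer is matched back to a database sequence, the matched locus
(the protospacer) carries information the array itself does not: the
protospacer adjacent motif (PAM) required by DNA-targeting effector complexes,
the transcription orientation of the array (because the PAM sits 5' of the
protospacer for type I/IV/V systems and 3' for type II), and whether the crRNA
targets the coding or the template strand of a gene -- which decides whether it
can also base-pair the mRNA. Aggregated over many spacers, these signals
characterise whole repeat families and reveal genomes in which a single array
serves effector complexes of two different subtypes ("multi-effector
compatible" arrays).

`spacerscope` implements this analysis as a reusable pipeline: hit finding and
filtering, repeat clustering, flank profiling with GC-corrected information
content, orientation and PAM calling, exact binomial strand-bias tests, and
compatibility classification -- together with a synthetic-data generator that
plants every one of these signals so the pipeline can be scored against ground
truth.

## Matching and filtering

Spacers are matched on both strands with an exact 10-mer seed, ungapped
extension along the seed diagonal, and a banded (band 3) gapped refinement
where enough mismatches remain to hide an indel. The quality metric is the
**matched fraction**: identities divided by the full spacer length, which
penalises both mismatches and partial coverage in one number. No e-value is
computed; nothing downstream uses one. Pre-computed hits in the extended
tabular format (`qseqid ... bitscore qlen nident`) can be ingested instead of
the internal matcher.

Filtering proceeds in the published two steps: hits with matched fraction
above 0.90 are kept outright; hits above 0.80 are additionally kept when the
same subject already received a step-1 hit from a *different* spacer of the
same genus. By construction step 2 can never add a subject absent from step 1
(the no-new-contigs property, asserted in the tests). Spacers shorter than
27 nt are removed entirely.

Hits inside CRISPR arrays are recognised by aligning the spacer's repeat
against the 23-nt flanks of the hit, in both orientations, and flagging more
than 13 identical positions. The alignment scores match +1, mismatch 0 and 3
per gapped position, with **free end gaps**. The end-gap choice is a design
decision this package takes deliberately: a 23-nt flank lying inside a ~30-nt
repeat aligns flush only when end gaps are free (23 identities), whereas with
penalised end gaps the identity-maximising dynamics of a zero-cost mismatch
push random pairs over 13 identities roughly 20% of the time, which would make
the threshold useless. With free end gaps the measured null rate is ~1.5% per
orientation at GC 0.5 (~3% testing both orientations, higher at extreme GC),
and planted array hits are recognised essentially always.

## Repeat clusters and subtypes

Repeats are clustered greedily at 90% global identity with equal length
required; repeats are sorted by descending abundance (ties lexicographic) so
the partition is canonical and independent of input order. Repeats are
clustered in their stored orientation -- orientation correction happens later,
per cluster, not per repeat. Subtypes come either from the spacer table or
from reference repeats at a 74% identity threshold (both orientations tried;
ties resolved towards higher identity then lexicographic label).

All global alignments use the same published scoring scheme. The identity
count reported for an alignment is the maximum across score-co-optimal
alignments, with deterministic tie-breaks (more identities, then shorter
alignment); this removes the dependence on which co-optimal traceback an
external library happens to return. The dynamic programs are validated
against `Biostrings::pairwiseAlignment` scores exactly, and against brute-force
enumeration on tiny strings, in the test suite.

## Flank profiles and GC-corrected information content

For each spacer, the flanks of all its kept hits are collapsed into a
**consensus flank** (per-position plurality, N on ties, N observations
excluded), so a spacer with many redundant database hits counts once. Within a
cluster, identical (upstream, downstream) consensus pairs are further
collapsed into one *unique protospacer* -- the deduplicating reading of that
term, guarding against one protospacer deposited in many records.

Position-wise conservation is measured as relative entropy against a
background derived from the cluster's mean spacer GC
(`p_A = p_T = (1-GC)/2`, `p_C = p_G = GC/2`):

$$\mathrm{IC}_j = \sum_b f_{bj}\,\log_2\!\frac{f_{bj}}{p_b}$$

with $0\log 0 \equiv 0$. This is the "expected occurrences" correction stated
with the method, not uniform-background entropy; it is what keeps false PAM
signals flat in high- and low-GC organisms. No small-sample correction is
applied -- the median-ratio thresholds below already normalise the noise
floor. The **median IC** pools all positions of both 23-nt flanks, including
eventual PAM positions, reading the method's description literally.

## Orientation and PAM calls

A flank side *qualifies* for orientation when at least two positions exceed
0.3 bits **and** 5x the median IC. The orientation is *forward* when the
qualifying (or better-scoring) side is the subtype's mechanistic PAM side
(upstream for I/IV/V, downstream for II), *reverse* when it is the opposite
side -- the cluster's stored sequences are then flipped and profiles rebuilt --
and *undetermined* with fewer than 10 unique protospacers or no qualifying
side. Type III and unassigned clusters have no usable PAM side; their
externally supplied orientation passes through unchanged.

PAM positions are flagged at 0.5 bits **and** 10x the median IC; a call
requires at least 10 unique protospacers and at least 2 flagged positions.
(A figure caption in the source material quotes 0.4 bits where the methods
text says 0.5; the methods value is the default and `pam_bits_min` is one
config field away.) The motif spans from the most distal flagged position to
the protospacer edge, unflagged interior positions rendered N. Flagged
positions become IUPAC characters via a documented approximation: the smallest
base set, filled in descending frequency, reaching cumulative frequency 0.8.
At 90% adherence this renders the planted base; a position drifting below 0.8
picks up a second base (e.g. W for a weak A/T mix), which is the behaviour one
sees in published degenerate motifs such as AWG.

`compare_repeat_pam()` then asks whether the repeat base occupying the same
position relative to the spacer is contained in the called PAM character's
IUPAC set -- the systematic mismatch between repeat ends and PAMs (and its
exceptions at the -1 position) is one of the analyses this enables. A helper
detects the conserved crRNA 5'-handle motif ATTGAAAC near repeat 3' ends
(<=1 mismatch within the last 10 nt by default).

## Strand bias

"Targeting strand X" is anchored to base-pairing: the crRNA hybridises X, so a
**coding**-strand call means the crRNA can also base-pair the mRNA. Concretely,
let s be the subject strand matching the spacer in its transcribed orientation
(the hit strand, flipped for reverse-oriented clusters); the call is coding
exactly when s is the ORF's template strand. The protospacer must lie fully
inside exactly one ORF; boundary-straddling, intergenic and
overlapping-gene cases are undetermined rather than double-counted. One call
is made per spacer, on its primary target (nucleotide-database subjects
preferred over metagenomes, then longest subject, then lexicographic id). ORFs
come from a GFF3 annotation when available, otherwise from a simple six-frame
scanner (starts ATG/GTG/TTG, length >= 90 nt, longest frame per stop).

Group summaries use the exact two-sided binomial test at p0 = 0.5 (minimum
likelihood definition, delegated to `stats::binom.test` and cross-checked
against exhaustive enumeration to 1e-12), flagged at alpha = 0.01.

## Multi-effector compatibility

Arrays link to cas gene clusters of the same genome within 25 kb edge-to-edge
distance. Three organisations are recognised: **category 1**, two
DNA-targeting subtypes whose (distinct) repeat clusters carry the same PAM;
**category 2**, a DNA- and an RNA-targeting subtype with distinct repeat
clusters and the same PAM; **category 3**, cas clusters of two subtypes linked
to a single repeat cluster with no other arrays linked to those cas clusters.
"Same PAM" is exact string equality after trimming flanking N; IUPAC
near-matches are surfaced in a separate column but never drive a category,
because no fuzzy-matching rule is given with the method. When a genome
satisfies several categories the most-shared one wins (3 > 2 > 1) -- an
implementation choice surfaced in the evidence field.

## The synthetic universe

`generate_universe()` plants, per cluster: a repeat (with the ATTGAAAC handle
for type I/III), a subtype-specific 3-nt PAM at 90% adherence on the
mechanistic side, an orientation (a quarter of PAM-bearing clusters stored
reverse-complemented), and per-spacer strand classes at subtype-specific
coding fractions (0.65/0.55/0.50/0.43 for III-B/I-B/II-A/I-E, mirroring
reported biases). Each spacer receives one protospacer context inside an ORF
on its own contig; additional hits are near-copies of that context (0.5%
divergence), emulating redundant database records -- which is precisely the
redundancy the per-spacer consensus step exists to remove. Decoy spacers get
targets at 2/4/6 substitutions (matched fractions 0.94/0.875/0.81) to
exercise both filter steps; dedicated contigs pair an exact hit with a weak
same-genus hit so step 2 actually fires; repeat-spacer-repeat cassettes
exercise the array-hit test. Flank backgrounds are i.i.d. at the target GC.

What the generator does *not* emulate: dinucleotide or codon-usage structure
beyond stop-codon avoidance, phylogenetic correlation between genera, mobile
genetic element realism, indel divergence between database copies, and
strain-specific type II PAM diversity. Passing tests therefore demonstrate
correctness of the inference machinery under the stated noise model, not
performance on real databases.

Default problem sizes -- 20 clusters x 30 spacers end to end, 200 clusters for
the recovery experiments, 400 calls per group for strand-bias recovery, 1000
pairs for the array-test null -- were chosen as the smallest cohorts at which
the planted effects are comfortably identifiable (e.g. binomial
sd ~ 0.025 at n = 400 against the +-0.06 recovery band).

## Numerical choices and edge cases

* Ambiguity codes other than N are normalised to N on input (profile counting
  is over ACGT); truly invalid characters are row-level errors.
* Coordinates are 0-based half-open on the subject plus strand everywhere
  internally; tabular formats convert at the boundary and round-trip exactly.
* Flanks beyond contig edges are N-padded to full length; N never matches in
  any alignment or count.
* Consensus ties are N; IC of an all-N column is 0.
* Overlapping hits of one spacer (>= 50% of the shorter interval) collapse to
  the best fraction before any "unique protospacer" counting.
* With both flank sides qualifying for orientation, the larger summed IC over
  qualifying positions wins; equal sums resolve to the subtype's PAM side
  (forward).
* Clusters with a realised PAM adherence well below the planted 0.9 (a low
  binomial draw) can fall under the 10x-median gate -- one such cluster exists
  in the default end-to-end universe, which is why the end-to-end test asserts
  recovery of >= 90% while the 200-cluster experiment achieves 99%.

## Limitations

The internal matcher approximates a permissive blastn-style search but does
not reproduce its HSP statistics; the ingestion path is the fidelity route for
real searches. Orientation and PAM calls inherit the method's gates (>= 10
unique protospacers), so sparsely targeted clusters stay undetermined by
design. Type II PAMs are called per repeat cluster; strain-level splitting is
possible via per-genome grouping of profiles but PAM-interacting-domain
analysis is out of scope. Replication-orientation confounders of strand bias
and transcriptome-based orientation validation are likewise out of scope.
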