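---
title: "Local-haplotype SV calling: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local-haplotype SV calling: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

haplosv calls and jointly genotypes structural variants (SVs; events of at
least 50 bp) from mapped high-accuracy long reads. Its organizing idea is
that every SV is represented by its *local haplotype* — the assembled
alternate-allele sequence plus flanking anchors — and that this haplotype,
not an individual read signature, is the unit that is merged across
samples, realigned to the reference, and genotyped. This document explains
the model behind each stage, the tunable parameters and why their defaults
were chosen, what the synthetic-data generator does and does not emulate,
and the numerical choices and limitations a user should know about.

## Pipeline overview

Discovery runs per sample:

1. **Signatures.** Every primary/supplementary alignment is scanned for
   SV-associated evidence: CIGAR insertion/deletion runs of at least
   `min_signature_size` (default 35 bp — deliberately below the 50 bp SV
   threshold so that events fragmented by the aligner into smaller nearby
   runs still seed candidates; the definitive 50 bp filter is applied
   after refinement), terminal soft clips of at least `min_clip_size`
   (default 200 bp; shorter clips are mostly noise), and split-read
   junctions derived from adjacent segments of one read ordered along the
   read, with breakend orientations derived from strand and segment
   order. Nearby same-kind indel runs of one read separated by at most
   `max_gap` (50 bp, the typical aligner fragmentation scale) are merged
   first.

2. **Clustering.** Single-linkage clustering per contig: indel signatures
   link when they are the same kind, within `max_dist` (500 bp) and with
   size ratio at least `size_ratio` (0.5); junction signatures link when
   both breakends agree in orientation and position within `max_dist`.
   Clusters with fewer than `min_cluster_support` (2) distinct reads are
   dropped. Single linkage can chain distinct nearby events, but this is
   recoverable: the assembly step separates haplotypes again. Soft clips
   never seed clusters; they only corroborate existing ones.

3. **Assembly.** For each indel cluster, the query subsequences of
   supporting reads projecting onto the cluster span padded by `flank`
   (500 bp — long enough for confident realignment anchors, short enough
   to stay local) are extracted. Segments are partitioned into allele
   groups by complete-linkage clustering on edit-distance ratio with
   `split_threshold` 0.05 (diploid separation: two alleles differing by
   more than 5% of their length never share a group), and each group is
   collapsed by a star alignment: the median-length segment is the
   backbone, every other segment is globally aligned to it with affine
   gaps, and each backbone column and insertion slot is decided by
   majority vote with ties resolved toward the backbone. With independent
   ~1% read errors and at least a handful of segments this removes
   essentially all singleton errors; the engine satisfies the natural
   contract (identical inputs reproduce themselves; the count never
   exceeds `max_haplotypes`, default 2 under the diploid assumption). At
   most `max_consensus_reads` (6) segments, chosen evenly across the
   length distribution, enter the star alignment of one group; support is
   still counted over all members. This cap bounds the quadratic
   alignment cost on deep clusters without hurting the vote.

4. **Refinement.** Each consensus haplotype is globally realigned to its
   reference anchor window (match 1, mismatch −4, gap open 6, gap extend
   1 — extension cheap relative to mismatch so a single large indel
   aligns as one gap run). Haplotypes whose flank identity over the
   terminal 200 alignment columns falls below 0.9 are dropped as
   low-confidence. Every gap run of at least 50 bp becomes a
   sequence-resolved DEL/INS record.

   **Breakpoint canonicalization and microhomology.** A junction inside
   repetitive sequence has a whole interval of equivalent placements.
   haplosv computes the maximal left and right shifts that preserve the
   alternate sequence (for insertions, rotating the inserted sequence
   accordingly), reports the interval length as HOMLEN with the
   homologous sequence at the leftmost placement (HOMSEQ), and always
   places records at the leftmost (canonical) position, matching VCF
   normalization practice. Because the placement interval of a tandem
   duplication can exceed the assembly flank, canonicalization is re-run
   on a reference window padded by the event size, which is always wide
   enough to contain the full equivalence interval. Homology and
   untemplated junction insertion are mutually exclusive annotations;
   mixed junctions resolve in favor of maximal homology.

   **Type refinement.** An insertion whose sequence matches the adjacent
   reference segment with identity at least `min_identity` (0.9, over at
   least 80% of its length) is reclassified as a tandem duplication;
   dispersed duplications deliberately remain INS. Split-junction
   clusters become BND records by taking the modal junction coordinates —
   a linear CIGAR cannot represent an inversion, so junction breakpoints
   come from the (exact) split-alignment coordinates rather than from
   consensus realignment. Two intra-contig BNDs with inverted
   orientations (both-left and both-right) nesting within `pair_tol`
   (1 kb) and spanning at most `max_span` (2 Mb) are joined into one INV
   event; the component breakpoints are retained in the output under a
   shared EVENT id.

## Joint genotyping

Haplotypes from all samples whose reference footprints lie within
`max_merge_dist` (500 bp) are compared by sequence; an edit-distance ratio
of at most 1 − `merge_similarity` (default similarity 0.99, i.e. 1%)
makes two haplotypes the same allele with pooled support. Comparing
haplotype *sequences* rather than per-sample call coordinates avoids
alignment-dependent representation artifacts in merging. Allele indices
are assigned by descending total support with ties broken by sequence
order, so numbering is reproducible. Inversions, which carry no assembled
sequence, merge by coordinates instead.

**Read scoring.** At genotyping time all local reads vote (MAPQ threshold
0, versus 10 at discovery — noisy mappings should not seed candidates but
may still carry allele information). Each read's query segment over the
locus is compared to each allele sequence by edit distance. Small loci
(footprint and length change at most `max_direct` = 2 kb) are scored on
one full-span window; larger events are scored on junction-local windows
(600 bp crossing each junction) extracted in query space, which makes the
cost independent of event size and — crucially for inversions — works for
split-aligned reads that no single alignment record carries end-to-end.
A read votes through every junction window it spans; a single junction
suffices, because each junction is independently discriminative and
requiring the full event span would bias allele depths against long
alternate alleles (reference-supporting reads would need only a few
hundred spanning bases while alternate-supporting reads would need the
whole event). A read is assigned to the best allele only when its margin
over the runner-up is at least `min_score_margin` (10 edits); ambiguous
reads are suppressed rather than miscounted.

**Genotype model.** Given per-allele assigned-read counts, a read drawn
from haplotype $h$ supports allele $h$ with probability $1-\varepsilon$
and any other allele with probability $\varepsilon/(K-1)$
($\varepsilon = 0.05$ by default, $K$ = number of alleles including the
reference). A diploid genotype mixes its two haplotypes equally, so for a
biallelic site the per-read alternate-support probabilities are
$\varepsilon$, $1/2$, and $1-\varepsilon$ for hom-ref, het and hom-alt.
The genotype likelihood is the product over assigned reads (binomial
kernel; constant factors cancel), the prior is uniform, and

$$\mathrm{GQ} = \lfloor -10 \log_{10}(1 - P(\hat g \mid \text{reads}))
\rfloor,$$

floored for determinism and capped at 999. Worked values: 10 reference
reads and no alternate reads give GQ 27; a 6:6 split gives a heterozygous
call with GQ 40. With no assignable reads the genotype is missing (./.,
GQ 0). The model uses hard read assignment plus a binomial mixture rather
than per-read alignment-score likelihoods; with the margin rule
suppressing ambiguous reads the two agree in practice and the hard
version is exactly testable against a closed-form oracle.

**Depth refinement.** For DEL/DUP candidates of at least
`min_depth_event_size` (5 kb), the mean binned depth (bin 1 kb, raw — no
GC or mappability normalization) inside the event is divided by the mean
over `depth_flank` (5 kb) on each side. The expected ratio is
$1 \mp 0.5 \times \text{dosage}$ (DEL/DUP). Within `tol` (0.25) of its
own expectation the record is flagged depth-supported; failing its own
expectation but matching the opposite type's flips the type. Depth only
annotates or reclassifies existing breakpoint candidates; it never
rescues candidates on its own. Note the scale dependence of this
evidence: coverage fluctuates at the read-length correlation scale, so
the ratio of a 10-60 kb event at 30x has a standard deviation around
0.07 even with generous flanks, tightening only for events several-fold
longer than a read. The 0.25 tolerance reflects this; depth ratios on
events near 10 kb should be read as corroboration, not as precise copy
number.

**Phasing.** Two heterozygous loci of one sample are phased when they
share read-to-allele assignments (or derive from one assembled haplotype
pair): reads supporting both alternates are cis evidence, reads
supporting one alternate and the other reference are trans. Conflicting
evidence leaves the pair unphased. Phased genotypes share a PS id (the
position of the leftmost locus of the set) and ordered GT.

## The synthetic-data generator

`simulate_dataset()` builds, deterministically from one seed: a uniform
random reference with tandem-repeat arrays planted at a configurable
fraction of future small DEL/INS sites (units 2-10 bp — so repeat-placed
events have non-trivial microhomology, computed into the truth table with
the same sliding-placement definition the caller is tested against);
diploid genomes with non-overlapping planted DEL/INS/DUP/INV events of
at least 50 bp spaced at least 2 kb apart; and long reads (Normal length,
default mean 15 kb, sd 3 kb, truncated to [1 kb, 30 kb]) at a target
fold-coverage with ~1% errors (75% substitutions, 25% indels of 1-3 bp).
The default event plan holds 20 events spanning the 50-499, 500-4999 and
>= 5000 bp size strata. Pedigree mode draws four founder haplotypes and
transmits one haplotype per parent per child by a seeded coin flip,
giving known inheritance and genotypes for the concordance module.

Alignments are constructed by lifting read coordinates through the known
haplotype-to-reference block map rather than by running a mapper: DEL and
INS (and tandem DUP, as an insertion at the end of the first copy) appear
as single CIGAR runs; inversions produce split records with SA tags whose
junctions sit exactly at the planted breakpoints; injected errors appear
as small sequence changes and 1-3 bp CIGAR indels. This keeps every test
hermetic and the truth exact, at the cost of realism: real aligners
fragment and shift events in repeats, misplace reads in segmental
duplications, produce reference-biased soft clips, and HiFi errors
concentrate in homopolymers. Reads are also emitted in reference-forward
orientation (BAM stores strand-normalized sequence anyway, so downstream
code is unaffected, but the strand flag distribution is not realistic),
and translocations are not planted — the breakend machinery is exercised
through inversion junctions only. Passing tests on these data therefore
demonstrate correctness of the method's own logic (coordinates, models,
merging, genotypes), not robustness to mapper artifacts.

## Numerical and design choices

* All internal coordinates are 0-based half-open; conversion to 1-based
  happens only in the VCF writer (left-anchor base included in REF/ALT
  for sequence-resolved records). DEL/INS below `symbolic_threshold`
  (10 kb) are sequence-resolved; larger DELs and all DUP/INV are symbolic
  with END. Inversions are written both as one symbolic INV and as their
  component BND records (bracket notation, reciprocal MATEIDs, shared
  EVENT), and consumers may drop either view.
* Co-optimal alignments resolve to the leftmost gap placement; records
  are canonicalized leftmost, so equivalent alignments yield identical
  output.
* Ties in consensus voting prefer the backbone symbol; allele numbering
  ties break by sequence order; genotype ties resolve to the first
  genotype in enumeration order. Every stochastic step in the simulator
  derives from the single config seed. The caller itself is
  deterministic: reruns are byte-identical.
* Unpaired BND records (junction clusters that do not form an inversion)
  are discovered and archived but not genotyped or emitted in the VCF;
  with translocations out of the simulator's scope there is no test
  surface for their genotypes, and emitting unvalidated records seemed
  worse than omitting them.
* Degenerate inputs: an empty region yields an empty, valid VCF; a locus
  with no assignable reads is ./.; a depth ratio with empty flanks or a
  sub-bin event is reported missing and leaves the candidate unannotated.

## Problem sizes used in the test suite

The packaged tests run the full pipeline on a 1 Mb contig at 30x with the
20-event default plan (the recovery and VCF-validity checks share one
run), a 400 kb contig at 15x and 30x for the coverage-titration property,
and smaller 60-200 kb contigs for module-level properties; oracle
equivalences use 100-200 randomized instances each. These sizes were
chosen so the whole suite exercises every stage, including consensus of
multi-kilobase insertions, while remaining a desk-scale computation.

## Known limitations

* Dispersed duplications are reported as insertions; nested/complex
  multi-SV structures beyond the inversion pairing rule are not resolved.
* No base-quality awareness anywhere (assembly, scoring, genotyping).
* Depth is raw; GC or mappability correction is a hook for future work.
* Genotyping of events much longer than the read length loses power
  because few reads span both flanks; junction windows mitigate but do
  not remove this.
* The concordance module evaluates genotypes against a pedigree; it
  never edits them, and deriving inheritance vectors from data is out of
  scope (MODE B accepts an externally supplied map).
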