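---
title: "Models and design of clonesv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of clonesv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`clonesv` analyses structural variants (SVs) in clonally expanded cell
populations. A clone grown from a single progenitor cell carries that
cell's somatic variants heterozygously in every cell, so a mosaic SV shows
up at ~50% allele fraction in ordinary 30× short-read sequencing of the
clone, while being essentially absent (below one part in a few hundred)
from the bulk tissue. This vignette describes the models implemented, the
parameters that matter, the synthetic data the package uses to verify
itself, and the design decisions taken where the methodology left choices
open.

## The discovery model

Candidate breakpoints come from three classes of *abnormal reads*: reads
with more than `soft_clip_min` (30) soft-clipped bases, pairs whose insert
size exceeds the proper-pair mean by more than `discordance_sds` (3)
standard deviations, and pairs whose mates map to different contigs. The
insert-size discordance criterion has no canonical cutoff; the 3-SD
operationalization is this package's choice and is configurable.

Soft-clip junction positions on the same contig and side are merged within
`cluster_tolerance` (10 bp, single linkage; candidate position = lower
median). Two candidate clusters are joined into a typed junction when each
clipped sequence matches the partner locus at `clip_match_identity` (90%)
or better: right-clip + left-clip on one contig in forward order is a
deletion junction, in backward order a tandem duplication, same-side pairs
are inversion-type junctions, and inter-contig pairs are breakends. When
only one side of a junction survives the `min_split_support` floor (3
reads), the clipped consensus is realigned to the whole reference to
recover the partner locus; clips matching nowhere stay one-sided breakends.
`min_split_support = 3` suppresses singleton-error junctions at 30× and is
deliberately conservative; it is not taken from the original callers, whose
internals are not reproduced.

Somatic filtering follows the clone-to-clone design: each case call is
compared against every other clone, and a comparison votes the call somatic
iff the control shows zero supporting abnormal reads at the breakpoints.
"Consistently made" is operationalized as votes in at least
`recurrence_fraction` (80%) of the informative (non-carrier) comparisons —
again a package choice, since no canonical fraction exists. Calls sharing breakpoints across clones are reported once with
their carrier list; calls present in every clone are treated as
germline-like and dropped. Spanned calls of one type merge at 50%
reciprocal overlap (of *both* lengths; merging is applied to a fixpoint and
is idempotent), and same-sample calls within `adjacency` (1000 bp) of each
other group single-linkage into complex-SV groups.

## Replication-model resolution

Abnormal reads (plus their mates) around every breakpoint of a group are
assembled per locus by greedy overlap–layout–consensus: repeatedly merge
the pair with the longest suffix/prefix overlap (anchored on a terminal
12-mer, at most `max_mismatch` = 2 mismatches), ties broken by the
lexicographically smallest merged sequence; the consensus is a per-column
majority vote. OLC rather than a de Bruijn graph because read counts per
locus are tens, and determinism matters more than scalability here.

Contigs are aligned to the reference by exact 15-mer seeding on both
strands, same-diagonal run merging, and exact-match extension. The
simulator's error model is substitution-only, so ungapped alignment is
exact for data in scope; for real indel-rich data a gapped extender would
be needed (a known limitation). The maximum-weight chain of alignments
tiling the contig (weighted interval scheduling; weight = aligned length ×
identity; contig overlaps up to the microhomology allowance permitted) is
selected exactly by dynamic programming — verified in the tests against
brute-force enumeration of all compatible subsets.

Each adjacency between chained alignments is a junction. Its position is
refined to the minimum-mismatch split point between the two alignment
diagonals, leftmost on ties after preferring the cut with maximal junction
microhomology. This refinement is what keeps junction coordinates exact
when a germline SNP or a consensus error sits within a few bases of the
junction — without it, a single mismatched base next to the junction
shifts the recovered breakpoint.

Junctions pooled across contigs (each junction also contributes its
mirror, since a contig may assemble in either orientation) are then walked
from the left anchor flank: starting on the forward strand upstream of the
event, repeatedly jump through the nearest unconsumed junction ahead of
the current oriented position, until the walk returns to the anchor
forward strand and runs out of junctions. The walk needs only junctions,
never segment interiors, so inserted segments of any size are reconstructed
in full even though their interiors attract no abnormal reads. All
terminating walks from all candidate anchor neighborhoods are enumerated
(bounded depth-first search), and the chain whose reconstructed allele
explains the most junction-informative (clipped) reads end-to-end wins;
co-optimal alternatives are returned rather than discarded. The reported
*explanation score* is the fraction of all abnormal reads in the
neighborhood aligning end-to-end to the reconstructed allele with at most
2 mismatches; calls are retained only when the score strictly exceeds 0.8.
The definition of this score is this package's own.

From the final chain the model derives: deletions (sub-spans of the
replaced region covered zero times), duplications (total copy count ≥ 2
within the neighborhood of the replaced span), inversions (reverse-
orientation segments), insertions (segments from other contigs or outside
the neighborhood), template switches (junctions where replication did not
continue contiguously; a junction with microhomology still counts), switch
jump distances, and the absolute size |replaced reference length −
alternate length|. The absolute size is invariant to the ±microhomology
ambiguity of junction placement, which is why it is recovered exactly while
breakpoints are only guaranteed to ±(MH+2).

Microhomology at a junction is reported as the maximum of the two
homology conventions (the m bases ending at the donor breakpoint equal
those ending at the acceptor breakpoint, or the m bases after the donor
equal the acceptor's first m); junctions are left-aligned and the
convention used by any particular rearrangement mechanism is not
observable, so the maximum is the defensible summary.

A deletion and a duplication with reciprocally matching breakpoints
(within the cluster tolerance) are fused into a single extrachromosomal
circular DNA event: the circle excised from the deleted region explains
both signals at once. Conversely, a group containing an inversion-type
junction *without* its opposite-orientation companion, adjacent to a
duplication, matches the classic fold-back chimera of multiple
displacement amplification and is flagged as an artifact; fully reciprocal
patterns are never flagged.

## Genotyping

The pseudoreference is the resolved alternate allele flanked by `flank`
(2000) bp of reference. Homozygous SNPs in it are reverted to the
reference base (a site counts homozygous at panel alternate-allele
frequency ≥ 0.9 — a numeric rule this package had to fix), so reads never map to the SV allele merely because of shared
homozygous differences from the reference; heterozygous sites are left
untouched. A read supports the allele only if its best ungapped alignment
beats the other allele by `map_margin` (5) score units *and* crosses an
allele-diagnostic position (a junction for ALT, a replaced-span edge for
REF); flank reads fit both alleles and count for neither, which keeps
denominators honest. Allele fraction is ALT/(ALT+REF); a sample with zero
ALT reads receives the upper bound 0.5/N from the capacity N observed in a
true carrier — the extrapolation "what allele fraction would one
supporting read correspond to".

Clonality: a call is subclonal iff its allele fraction is significantly
below 0.5 (one-sided exact binomial test, α = 0.01) or a heterozygous SNP
inside a deleted region still shows both alleles in the carrier's reads
(two surviving haplotypes are incompatible with a clonal deletion).

The read-depth post-filter consumes binned (200 bp) normalized copy
numbers (per-sample mean normalized to 2.0) and applies the
threshold criteria verbatim; every failure reports the violated clause. The
duplication tissue clause is conventionally quoted in a direction
inconsistent with the deletion logic; the default here is the
mirror-consistent reading (tissue ≤ 2.4), with
`dup_tissue_reading = "printed"` available for the literal one.

## Timing and statistics

Two clones sharing an SV diverged from a common ancestor; SNVs unique to
each clone accumulated after the divergence. With N₁ and N₂ unique SNVs
and a rate r per day per progenitor, divergence time = mean(N₁, N₂)/r days
(default r = 5.1). Weeks are reported raw and rounded half-up; the origin
of the shared event is harvest age minus the divergence.

ddPCR: droplet occupancy is Poisson, so the concentration per channel is
λ = −ln(1 − k/n) for k positive of n droplets; allele fraction is
λ_var/λ_ref. The 95% CI takes the Wilson binomial interval of each
channel's positive fraction, transforms it through λ, and combines the two
channels as independent errors on the log-ratio scale. Input-mass
sensitivity: `input_ng` × 1000 / `pg_per_genome` genome equivalents; the
minimal detectable fraction is the reciprocal. The default 10 pg per
diploid genome reproduces the standard 40 ng → 4000 genomes arithmetic;
the textbook value is ~6.6 pg and both are configurable.

The incidence comparison uses the exact two-sided Fisher test in the
standard minimum-likelihood convention (probabilities ≤ the observed
table's, within the customary 1+10⁻⁷ tolerance). For 4 of 41 versus 0 of
36 this gives p = 0.1184; other software conventions can differ in the
fourth digit, and no attempt is made to match any particular one.

Discovery sensitivity is estimated exactly as designed: the truth set is
the 50%-reciprocal intersection of two independent bulk call sets, and
each clone's sensitivity is the fraction of truth entries recovered
reciprocally among its calls. The tests verify the estimator against an
independent interval-arithmetic oracle on every simulation.

## The synthetic-data generator

The generator exists so that every stage is verifiable without external
data, and its defaults are the study conditions: clones sequenced at 30×
coverage; clonal SVs at cell fraction 1 (allele fraction 0.5) and
subclonal ones at lower fractions; complex alleles built from 1–5 oriented
reference segments of 50–2000 bp (inter-chromosomal segments allowed)
replacing a span at an anchor; 2–4 bp junction microhomologies;
clone-private SNVs at allele fraction 0.5 placed outside SV spans (so
timing and genotyping tests stay independent); heterozygous and homozygous
germline SNPs at ~10⁻³–10⁻⁴ per base; 150-bp paired reads with
normal(400, 50) inserts truncated at the read length; uniform substitution
errors at 0.1% and no indel errors (read length and insert geometry are
conventional values and configurable).

Microhomology is *realized*, not just annotated: for a requested length m
the m reference bases immediately upstream of each acceptor breakpoint (in
acceptor orientation) are set equal to the donor's last m emitted bases,
and one guard base beyond the homology on each side is forced to mismatch.
The edits precede read simulation, so the genome, the reads and the
microhomology operator are mutually consistent and the recovered length is
exactly m — the implant verifies every junction after editing and rejects
contradictory edit sets. Because the edits touch only acceptor flanks, the
alternate sequence and the truth breakpoints are exact by construction.

Reads are sampled from explicit haplotypes (haplotype 1: heterozygous SNP
alternates; haplotype 2: private SNVs in all cells, plus the SV in the
carrier fraction) and projected onto the reference: a read inside one
segment maps contiguously; a junction-crossing read is anchored to the
side holding most of it — as an aligner maximizing its score would — and
the remainder is soft-clipped, so clip length always equals the bases on
the far side of the junction and both junction sides produce clip
clusters. MDA chimeras are emitted as fold-back templates (forward
approach, inverted re-priming within tens of bases) next to a short
tandem-duplicated span, in one sample only and absent from all truth
files. Circular DNA reads come from a doubled circular template whose
wrap-around fragments create the duplication-like junction reciprocal to
the deletion.

What the generator does **not** model: aligner mismapping and mapping-
quality structure, PCR duplicates, GC-coverage bias, indel errors, repeat-
driven ambiguity (genomes are random sequence, so essentially repeat-free)
and MDA amplification curves beyond the chimera junctions. Passing tests
therefore demonstrate the correctness of the algorithms under clean
mapping, not performance on repeat-rich real genomes.

## Problem sizes and numerical choices

The test-suite simulations use 2 × 100 kb genomes at 30× for the 20
round-trip replicates, a 2 × 60 kb six-sample brain for genotyping, a
250 kb genome for the MDA/eccDNA scenarios and an 870 kb genome with 100
implanted deletions for the sensitivity estimate — sizes chosen so the
whole suite, including these end-to-end checks, runs in minutes on one CPU
while every rate they estimate is still binomially meaningful. Tie-breaks
are deterministic throughout (lower median for cluster positions,
lexicographic for assembly merges, leftmost-with-maximal-microhomology for
junction cuts), so identical seeds give byte-identical outputs. Internal
coordinates are 1-based inclusive (the R/Bioconductor convention; IRanges
does the interval arithmetic), converted to each format's convention at
the VCF/BED boundary.

## Known limitations

- Chains that traverse the same junction more than once (e.g. triple
  tandem repeats through one junction) are reconstructed parsimoniously as
  a single traversal.
- The walk assumes both anchor flanks are reachable; alleles whose
  junctions were not all observed resolve to partial models with low
  explanation scores rather than failing loudly per junction.
- Ungapped contig alignment: exact for the substitution-only error model,
  inappropriate for indel-rich data.
- Reported microhomology is capped at `max_mh` (20) bases and measured on
  the reference, so sample-private variation inside a homology tract is
  invisible to it.
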