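---
title: "Methods: detecting endogenous caulimovirid elements with evehunter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting endogenous caulimovirid elements with evehunter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(evehunter)
```

## The problem

Caulimoviridae are the only plant viruses with double-stranded DNA
genomes (roughly 7--10 kb). Although integration is not part of their
replication cycle, fragments and full copies are frequently captured in
plant genomes, where they decay by substitution, indels, truncation and
rearrangement, and frequently occur as tandem concatemers in integration
hotspots. The two practical difficulties in finding them are (i) decay —
old elements keep only patchy similarity to any modern reference — and
(ii) confusion with LTR retrotransposons (*Gypsy*, *Copia*), which share
homologous reverse transcriptase (RT) and RNase H domains and are far
more abundant. `evehunter` addresses both with a two-branch design:
a repeat-level branch (A) that reconstructs consensus elements and
annotates the genome, and an RT-level branch (B) that classifies
individual RT loci phylogenetically, including single-copy elements that
branch A cannot see.

## Branch A

**Step 1 — sub-genome construction.** The genome is searched in
six-frame translation against a library of caulimovirid genome
sequences (mode `txnt_vs_txnt`). Overlapping hit spans are merged per
chromosome; spans that merely touch are contiguous sequence and merge
too (all internal coordinates are 0-based half-open; only the GFF3
writer converts to 1-based inclusive). Each merged locus is extracted
and compared, again in six frames, against the "baits" library — a
protein set mixing caulimovirid proteins with retroelement RT/RNase H —
and kept only when its single best-scoring bait is caulimovirid.
Ties are broken deterministically: higher score, longer alignment,
caulimovirid class, lexicographic bait id. Loci with no bait hit at all
are discarded as unclassifiable. Surviving loci separated by at most
`merge_gap_bp` (5000; the threshold is inclusive) merge into one
presumed integration event, are extended by `extension_bp` (2000) per
side, re-merged if extension makes them overlap, and extracted as the
sub-genome. The enrichment is what later allows an aggressive 85%
identity threshold for repeat discovery.

**Step 2 — grouping and consensus.** De novo repeat discovery on the
sub-genome is a defined single-linkage span-graph procedure (the
published workflow treats this stage as a black box with stated
thresholds; a defined equivalent keeps the contract testable). All
segment pairs are searched at the nucleotide level; hits with >= 85%
identity and >= 100 aligned columns are admitted, excluding only the
trivial self-identity diagonal — off-diagonal self hits are real signal
(internal tandem structure). Each hit contributes its query-side and
subject-side span as a graph node; nodes on the same segment with
>= 80% mutual overlap are fused; components with >= `hsp_min` (5)
member spans become families. Up to `group_cap` (20) members, longest
first, are star-aligned to the longest member with free end gaps,
trying both orientations per member (planted and real elements occur on
both strands). The consensus calls the modal residue per backbone
column among the members whose aligned span covers the column; columns
where fewer than half of the covering members have a residue are
dropped, and exact ties emit the IUPAC ambiguity code. Counting
occupancy only over covering members means a fragment does not vote
against columns it never reached — terminal gaps are absence of
evidence, not evidence of absence. Insertions relative to the backbone
are not added, so the consensus has no gap characters and is at most
backbone-length.

**Step 3 — characterisation.** Domains are detected with bundled
consensus-pattern profiles (one representative sequence per domain,
scored by local BLOSUM62 alignment against all six frames, per-profile
cutoffs calibrated so that random 7 kb sequence fires < 5% of the
time; a seeded calibration test ships with the package). The profile
set covers RT core (including the YxDD motif), RNase H, aspartyl
protease, movement protein and the Gag-like CCHC zinc finger, plus the
TE-specific integrase and transposase. Only integrase and transposase
trigger chimera removal: the zinc finger is carried by caulimovirids
themselves and is classed as shared. Best-hit comparison against the
baits gives a provisional genus; single-linkage clustering links two
records when a global alignment reaches `-S` (90%) identity and `-L`
(0.9) coverage of both sequences (the both-sequence rule mirrors the
classic clustering tool's length-coverage default and is switchable to
`either`/`shorter`). Selection keeps caulimovirid-classified records;
with `-bl` supplementation it additionally keeps their cluster
co-members. Redundancy is deliberately not removed — structural
variants and bipartite genome components are wanted in the library.
Records >= 2 kb are self-compared: an off-diagonal hit of >= 1 kb at
>= 90% identity flags a concatemer, and the diagonal offset estimates
the monomer length; monomerisation is left to the analyst, as the
annotation step does not require it.

**Step 4 — annotation.** The selected library is searched against the
genome (>= 70% identity, >= 80 bp); overlapping annotations from the
same library sequence merge, different library sequences stay separate,
and coverage is the union of annotated bases over genome length
(double-annotated bases count once, so coverage is invariant under
splitting annotations).

## Branch B

RT probes are searched against the translated genome; hits grow by
`rt_flank_bp` (120) to bridge alignment breaks and merge. Each locus is
translated in the frame of its best-scoring hit, split at stops, and
stop-free products >= `min_protein_aa` (200) survive a competitive
best-hit filter against the mixed RT library (same tie-breaking as the
bait filter; candidates with no hit are dropped). Greedy centroid
clustering at `rt_cluster_identity_pct` (80%) — longest first, each
sequence joining the first centroid within the threshold — dereplicates
the candidates; by construction all centroid pairs end below the
threshold. Representatives pass the iterative align/trim selection
(initial alignment plus `trim_rounds_initial` = 2 rounds), are merged
with the genus-labelled reference panel (references are exempt from
trim removal — losing them would break classification), realigned
through `trim_rounds_final` = 4 rounds, curated to conserved blocks,
and used for the phylogeny.

The alignment stack is built in: a progressive aligner with a 3-mer
count-distance guide order agglomerated by neighbour joining and
BLOSUM62 profile-profile merges (affine gaps, open -10 / extend -1);
`trim_msa` drops columns with > 80% gaps then sequences occupying
< 50% of the remaining columns; `select_blocks` keeps maximal runs of
>= 5 columns with <= 50% gaps and modal residue frequency >= 50%.
Distances are p-distances over mutually non-gap columns with the Kimura
protein correction d = -ln(1 - p - p^2/5), capped at d = 10 for
p >= 0.85. Trees are neighbour joining with deterministic tie-breaking
and negative branch lengths clamped to zero; maximum-likelihood
inference was deliberately replaced by NJ plus bootstrap because genus
assignment consumes only topology and support, and a config-gated hook
allows an external engine to be substituted. Support values come from
column bootstrap (default 100 replicates, seeded); a candidate is
assigned the genus of the smallest clade (after rooting on a single
outgroup leaf, which stays valid even when the outgroups are not
monophyletic in the estimate) that contains it and at least one
reference at >= `support_threshold` (70), and only when that clade's
references carry one genus.

## The synthetic genome generator

`make_ancestors()` builds ancestral genomes from the bundled domain
profiles: each viral ancestor is 7.5 kb and gene-dense, with a
Gag-Pol-like polyprotein (movement protein, protease, RT, RNase H, zinc
finger separated by linkers plus ~1200 aa of genus-specific filler)
reverse-translated with random codons; per-genus divergence from the
profile consensus is 18%, giving realistic ~65% cross-genus amino-acid
identity in the conserved domains. The Gypsy-like decoy carries
RT core, RNase H and integrase. The matching bait library, RT panel
(one RT per genus plus retroelement outgroups) and probe set are
emitted alongside, so detector and fixtures share no hidden state
beyond the profiles themselves.

`plant_elements()` inserts decayed copies into an i.i.d. background
(default GC 0.36, a typical plant genome value): per-site substitutions
at the requested divergence, indels at 10% of the substitution rate
with geometric lengths (mean 2), fragments as uniform 20-60% sub-spans,
tandems as concatenated copies mutated as one element, both strands,
non-overlapping insertion points, and an exact truth table.

The standard benchmark (`default_copy_plan()`) gives each of three
viral ancestors ten full copies at 5-15% divergence in a burst-plus-tail
age structure — a recent integration cohort at 5-7.5% and an older tail
at 10-15% — plus five fragments at 8%; the first ancestor gets one
triple tandem at 5%, and thirty decoy copies at 10% provide the false-
positive load. The cohort structure is both the standard demography of
an EVE family (integration bursts) and a feasibility requirement: with
single-linkage at 85% identity, two copies at divergences d1 and d2
share roughly 1 - (d1 + d2) identity, so at least five copies must fall
within a ~7-8 point band for any family to reach the `hsp_min`
threshold at all; uniformly spaced ages cannot satisfy the stated
thresholds.

What the generator does not emulate: isochores and real repeat
background, site-rate heterogeneity, codon models, nested insertions.
Passing tests demonstrate the detection contracts under uniform decay,
not performance on real genomes.

## Numerical and scale choices

The search engine uses exact 11-mer seeds for DNA (match +1, mismatch
-2, gap open -5, extend -2, one-hit triggering) and 4-mer BLOSUM62
neighbourhood seeds for proteins (neighbourhood score >= 12 enumerated
best-first and capped at 64 words per position, two-hit triggering in a
40-residue window, gap open -11, extend -1). Ungapped X-drop extension
(raw-score trigger 30 nt / 40 aa) is followed by adaptive-band gapped
X-drop extension (band cap 192 nt / 128 aa) that propagates match and
column counts through the dynamic programme, so reported identities are
exact for the reported path without a traceback. Significance is a raw
score plus identity floor (40 and 60% for DNA, 50 and 30% for protein)
rather than an E-value: deterministic, database-size independent, and
directly testable. Because a fixed raw score does not scale with search
space, the pipeline configuration raises the protein-mode floor to 80
for genome-scale stages (`eve_config()$search_aa`): at megabase sizes,
score-50 chance hits otherwise seed spurious background loci, and the
empty-background property of step 1 would not hold. Hits nearly contained in a better hit are dropped
only when their diagonal ranges overlap, which preserves the
off-diagonal self-alignments of tandem arrays that the concatemer
detector and the grouping stage rely on. Translated searches pool the
six frame strings into one subject separated by 64 X residues (more
than the gapped X-drop can cross) so the k-mer index and seed
enumeration are paid once.

Problem sizes used by the shipped tests: the benchmark genome is a 2 Mb
background carrying ~440 kb of planted elements; end-to-end branch A
runs in a few minutes on one CPU, and the oracle suites (interval
bitmap, clustering closure, quadratic DP, codon table, additive-matrix
NJ recovery) use hundreds to a thousand random cases each.

## Known limitations

* Consensus building does not insert columns absent from the backbone,
  so insertions private to non-backbone members are lost.
* A single planted tandem cannot seed a concatemeric consensus: the
  grouping rule fuses spans only at 80% mutual overlap, so the two-unit
  spans contributed by a tandem's off-diagonal self-alignment form
  their own two-node component and never reach consensus building.
  Concatemer consensi do arise when tandem arrays recur in a family;
  `flag_concatemers()` detects constructed and natural tandems either
  way.
* At >= 5% nucleotide divergence the prescribed decay model (stops and
  frameshifts included) leaves very few 200-aa stop-free RT products,
  so branch B on the standard benchmark recovers at most a handful of
  heavily decayed candidates; its contracts are exercised on younger
  landscapes (2-3% divergence) where intact RT ORFs survive, which is
  also the regime in which real RT mining succeeds.
* The NJ + bootstrap stand-in ignores rate heterogeneity and model
  selection; genus assignment therefore leans on clear reference
  coverage of each genus.
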