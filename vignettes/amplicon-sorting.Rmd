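---
title: "Sorting long amplicon reads without a reference: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sorting long amplicon reads without a reference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampsort)
```

## The problem

Nanopore sequencing of amplicons (COI, 18S, ITS spacers, ...) produces
thousands of full-length reads per locus, but each read carries 5-15%
errors. Without a reference database, turning such a pool into one accurate
sequence per species requires (i) deciding which reads come from the same
locus, (ii) deciding which reads within a locus come from the same species,
and (iii) averaging away the random read errors in a consensus. `ampsort`
does all three with a single primitive: global edit-distance similarity.

## The similarity measure

For sequences $a$, $b$ the package uses

$$ \mathrm{sim}(a,b) = 100\left(1 - \frac{D(a,b)}{\max(|a|,|b|)}\right), $$

where $D$ is the unit-cost global (Needleman-Wunsch) edit distance, computed
with a bit-parallel Myers algorithm (exact, checked against a quadratic DP in
the tests). Normalising by the longer length makes the similarity thresholds
and the relative length gates mutually consistent: sequences differing by
more than 5% in length cannot exceed 95% similarity, so the 5% read gate and
the 80% edge floor never disagree. Alignment is end-to-end because amplicons
of one primer pair are full-length products and the length gate has already
removed fragments. Similarity is carried as a float and compared with `>=`;
no rounding. `N` is scored as a mismatch against everything, and reads
containing other ambiguity codes are rejected at load time rather than
silently down-weighted.

Amplicon pools contain both strands. Same-strand similarity is computed
first; only when it falls below 50% is the reverse complement tried
(`rc_trigger`). Two random 700-mers score about 48% +/- 1.5 under this
metric, so a true opposite-strand pair usually (not always) falls below the
trigger; occasional missed pairs are rescued later, when reads are compared
against species consensuses. This behaviour is deliberate - the trigger
exists to halve the cost of the all-pairs stage, not to be a perfect strand
classifier.

## Stage 1: gene groups

Reads are sampled (default 10,000; all reads when fewer than 1,000) in
batches of 1,000 - in file order by default, or uniformly with replacement
across batches in random mode (duplicates within a batch are collapsed, so
sampling N from N touches ~63% of reads, matching the with-replacement
expectation $1-(1-1/N)^N$). Within each batch every pair passing the 5%
length gate is scored and pairs at >= 80% similarity are retained. Each read
keeps only its best match; overlapping best pairs are merged into connected
components (gene groups). Because strand islands or batch boundaries can
split one locus into several components, each group then builds a consensus
from 50 random members, and groups whose consensuses are >= 60% similar
within an 8% length gate are fused, transitively, to a fixed point.

Orientation bookkeeping is not specified by the algorithm's published
description and is this package's choice: the smallest serial in a component
defines the group strand, and each member's orientation is composed along
the best-pair edges by breadth-first traversal (conflicting assignments are
resolved by first visit; at >= 80% similarity, genuinely conflicting strand
evidence is vanishingly rare).

## Stage 2: species groups

Within a gene group, edges at >= 93% similarity (`species_seed_sim`) seed
species groups as connected components. Then a threshold falls from 95% to
85% in 1% steps; at each level, every still-unassigned read is compared to
every species consensus within a 5% length gate and joins its best match if
it reaches the threshold, with at most 3 passes per level (a pass adding
nothing ends the level early; a global cycle counter increments every pass).
Every second cycle, species consensuses within an 8% length gate that are
>= 96% similar (`species_merge_sim`) cause their groups to merge. Consensuses
are rebuilt (from at most 200 sampled members) whenever a group gains or
merges, so assignment is always against the current best estimate.

Two design points the published description leaves open, decided here:

* "every other cycle" is counted on a global pass counter across the whole
  loop (first merge opportunity is cycle 2, i.e. after two assignment
  passes), not per threshold level;
* the in-loop consensus rebuild uses the same 200-read cap as the final
  consensus - the cap is specified only for the final consensus, but an
  uncapped in-loop rebuild would make the loop quadratic in group size for
  no measurable accuracy gain;
* unassigned reads are re-examined at every level, so a read that misses the
  95% bar can join at 92% against a consensus that has meanwhile improved;
* a gene group whose edges never reach 93% produces zero species groups and
  emits only a "unique sequences" file.

These thresholds interact with read quality in a way worth spelling out.
At ~5% read error, two same-species reads sit near 90.5% +/- 1.4 similarity,
so only the cleanest read pairs (a few percent) seed species groups, and the
bulk of reads join via the falling threshold against an already-accurate
consensus (read-vs-consensus similarity is ~95%). This also sets the
separation limit: species whose true sequences are >= 96% identical produce
consensuses that the merge step averages together, while pairs at <= 95%
stay apart - with cleaner reads one can raise `species_seed_sim` to 94 and
`species_merge_sim` to 98 and separate a 97%-identical pair.

## Consensus construction

The consensus algorithm is this package's own (the original tool's is
unpublished; matching it is explicitly not a goal - only the accuracy
contract is). It is a star alignment with one refinement round: sample at
most 200 reads, take the read whose length is closest to the sample median
as backbone (extreme lengths make bad references), align every read to the
backbone with a banded global DP (the band grows and the alignment is redone
whenever the distance does not fit, so the alignment is always optimal),
vote per backbone column, and repeat once with the round-1 consensus as
backbone. A gap plurality deletes a column; an insertion needs a strict
majority of reads inserting at that junction (most frequent segment, ties to
the lexicographically smallest). The strict insertion rule avoids consensus
inflation from nanopore's rarer insertion errors and, together with
deletion-heavy homopolymer errors, reproduces the characteristic slight
homopolymer underestimation of nanopore consensuses. Ties between bases go
alphabetically; base beats gap at equal counts. One consequence of the
deterministic tie-breaking is that strand equivariance (consensus of flipped
reads = flipped consensus) is exact up to alignment ties - identical in
practice, and exactly identical for error-free input.

## The read simulator

The simulator provides ground truth for every claim the tests make. A
reference is i.i.d. DNA at a chosen GC; related species are made by
`mutate_to_identity()`, which applies 90% substitutions / 10% single-base
indels and verifies the realised identity with the package's own metric to
+/- 0.5. Reads corrupt the reference per base (defaults 2% substitution, 1%
insertion, 2% deletion ~ 95% read identity, emulating high-accuracy
basecalled nanopore reads), with the deletion rate doubled inside
homopolymer runs of length >= 3 - one interpretable parameter reproducing
nanopore's dominant residual error mode. Reads are reverse-complemented with
probability 0.5 by default and carry flat qualities consistent with the
total error rate (the sorter ignores qualities, so finer quality modelling
would be cosmetic). Pools allocate reads multinomially across species and
interleave them randomly; serials in the truth table match load order.

What the simulator does *not* model: chimeras, adapter/primer remnants,
quality heterogeneity along the read, and context-dependent (non-homopolymer)
error hotspots. A green test therefore establishes that the algorithm and
thresholds behave as designed on reads with realistic error magnitude and
composition - not that any particular wet-lab library will reach the same
numbers.

## Determinism and parallelism

All sampling flows from one seed (`rng_seed`), set once at the start of a
run. Worker processes (`n_workers`) parallelise only the pairwise scoring
loop, which consumes no randomness and is reassembled in canonical order, so
results are byte-identical across worker counts; gene-group sorting is kept
serial because its consensus subsampling consumes RNG and forking it would
tie results to the scheduling. Batched mode with one batch is exactly
equivalent to all-vs-all on the same reads.

## Degenerate inputs and numerical choices

* Empty post-filter input is a fatal error naming the length window.
* A batch of one read produces no edges; reads without edges join no gene
  group and are reported as ungrouped.
* Tie-breaks are all deterministic: best match to the smaller serial,
  assignment to the lower species id, consensus votes as above.
* Thresholds are compared with `>=` on unrounded floats; length gates are
  strict `<` (a pair at exactly 8% length difference is not compared).
* Temporary-file spilling of the original tool is not replicated; all state
  is in memory (desk-scale target - the contract is identical results, not
  identical I/O behaviour).

## Scaling choices in the validation suite

The acceptance script runs the full stated scales for the separation ladder
(500 reads per species at the 5% HAC-like error model) and the
single-species accuracy check (1,000 reads). The minority-recovery check
mirrors a pooled-barcode experiment performed on quality-filtered (Q12)
reads, so its 10,000-read pool uses a ~3% total error model; this matters at
low depth - with homogeneous 5% error a ~45-read minority often has no read
pair above the 93% seed threshold at all, because the i.i.d. simulator lacks
the per-read quality spread whose clean tail supplies seeds in real data.
Its all-vs-all stage runs on a 3,000-read subsample (5,000 would triple the
alignment count past a 20-minute single-CPU budget; the 1.5% minority still
contributes ~45 reads). The testthat suite re-runs the same designs at
reduced pool sizes purely for runtime; error models, thresholds and the
abundance profile are identical between suite and script.

## Known limitations

* The separation limit (~95-96%) is a property of the threshold set and read
  quality, not of the implementation; closely related species are averaged.
* Low-read "redundant" species groups can survive alongside the main group
  (reads sharing a chance error pattern); they are recognisable by their low
  member counts in the consensus headers.
* Homopolymer runs may be underestimated by ~1 bp at high depth; polishing
  with signal-level tools is out of scope.
* FASTQ consensus records are emitted only in the FASTA summary (a consensus
  has no meaningful per-base qualities).
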