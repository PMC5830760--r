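---
title: "radasm: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{radasm: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`radasm` assembles overlapping paired-end RAD (RPE) loci from multiple
individuals: forward reads are anchored at an SbfI cut site, reverse
reads are staggered by random shearing over roughly 200–700 bp
downstream.  This vignette explains the models the package implements,
the parameters that matter, what the synthetic data do and do not
emulate, and the design choices made where the design was genuinely
open.  It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Clustering model

Forward reads of one individual are grouped into *stacks* of exactly
identical sequences.  Stacks of depth at least `min_depth` (default 5)
are *primary*; a graph with edges between primary stacks at Hamming
distance at most `m` is built, and its connected components are the
individual's loci.  Hamming (not edit) distance is appropriate because
RPE forward reads share one length and are anchored base-for-base at
the cut site; the package deliberately performs no gapped comparison
anywhere (a documented limitation for indel-polymorphic real data).

Two repeat guards act before and after graphing:

* *lumberjack removal* (`removal = TRUE`): stacks deeper than
  mean + 2 sd of primary-stack depths are deleted, the classical rule
  for repetitive pile-ups; their reads are reported as unassigned.
* *component-size flagging* (`max_stacks`, default 3): components with
  more primary stacks than a diploid plausibly explains are flagged
  repetitive and excluded from the catalog.  This replaces the
  "deleveraging" of stack-based RAD tools, whose exact algorithm is
  version-internal; flagging-and-excluding mirrors its purpose (keeping
  likely paralogues out of downstream assembly) with transparent
  semantics.

The locus consensus is the depth-weighted per-column majority over its
primary stacks; ties break to the alphabetically smallest base so
results are order-independent.  Secondary (shallow) stacks join the
unique locus within `m` of the consensus; ambiguous or unmatched stacks
stay unassigned and never add haplotypes.

## Threshold selection

*Within individuals* the package scans `m` over `m_range` (default
1–10) and picks the value maximizing the number of two-haplotype loci,
breaking ties by fewer one-haplotype loci, then by smaller `m`.  The
two objectives are stated without a combining rule in the protocol this
package follows; the lexicographic order implements "maximize two-allele
loci and simultaneously minimize one-allele loci" deterministically and
reduces to the smallest scanned `m` on homozygous data.

*Across individuals* the locus sets are merged sequentially into a
catalog at each `n` in `n_range` (default 1–8), recording how many new
catalog loci each successive individual founds.  With `delta(n)` the
mean increment over individuals 2..k, the chosen `n` is the smallest
value from which the curve has *settled*: every consecutive relative
drop `(delta(n') - delta(n'+1)) / delta(n')` for `n' >= n` in the range
stays below `tau` (default 0.05), with `delta = 0` qualifying outright.
A first-qualifying-single-drop rule was rejected because it fires on
flat leading segments of curves that subsequently collapse, which is
not what a visual inflection reader would choose.  When no `n`
qualifies the range maximum is returned with a warning.

This warning is the expected behaviour on the package's own synthetic
data: with no paralogues and essentially no per-individual locus
dropout, the increment curve is a floor-less Poisson-like tail whose
relative drop per step is roughly constant (0.3–0.6 in the scaled
runs), so no inflection exists inside the range.  Real datasets have a
floor of genuinely novel loci per individual, which is what makes their
inflection visible.  A green threshold-recovery test on synthetic data
therefore establishes the within-individual rule only; the
across-individual optimum on idealized data is reported but lands at
the range maximum, and users should read the emitted curve (the
package exposes it) rather than trust a single number.

## Catalog and data reduction

Catalog merging is sequential and founder-anchored: an incoming locus
joins the first catalog locus (lowest id) whose consensus is within `n`
mismatches, else founds a new locus whose consensus is its own.  The
founder consensus is never updated, trading a small amount of
over-splitting for determinism and order-stability; loci from one
individual never merge with each other, so a single individual's
catalog is exactly its locus set.

Reverse reads are pooled per catalog locus through the membership map.
Pools above `max_reads` (default 400) are uniformly subsampled with a
seed derived stably from the run seed and the locus id, so results do
not depend on scheduling; pools below `min_reads` (default 10) skip
assembly and emit the forward consensus, flagged `consensus_only`, so
no catalog locus silently disappears.  Pools contain post-filter reads
only.

## Two-step greedy OLC assembly

Reads are assembled by a greedy overlap–layout–consensus procedure:
all pairwise best ungapped suffix–prefix overlaps (length at least
`min_overlap`, mismatch fraction at most `max_mismatch_rate`) and
containments are scored `matches - mismatch_penalty * mismatches`; the
best-scoring overlap is merged (ties: longer overlap, fewer mismatches,
smaller index pair), the merged consensus is recomputed as the
depth-weighted per-column majority, and the process repeats.  Exact
duplicate reads are collapsed to one weighted member first; a merge
that leaves the absorbing contig's consensus and frame unchanged
provably invalidates no other stored overlap and skips recomputation (a
pure speed optimization).

Per locus, step 1 assembles the reverse-complemented second reads alone
(all assembly happens in genome-forward orientation); step 2
re-assembles the step-1 contigs together with the forward consensus.
If the final contig containing the consensus absorbed at least one
step-1 contig, the locus assembled through; otherwise the consensus and
the longest step-1 contig are concatenated with exactly ten `N`s, the
conventional marker for an unsequenced gap of unknown true length.
Contigs that joined neither are dropped and counted in the report —
emitting one contig per locus is the contract.  The minimum final
contig length (default 125 bp) is applied after padding; at the default
read length the filter is vacuous for two-step contigs and guards only
degenerate custom configurations.

Defaults `min_overlap = 20`, `max_mismatch_rate = 0.06`,
`mismatch_penalty = 2` suit 125 bp reads at 1% error with percent-scale
polymorphism: 0.06 is roughly twice the error rate plus the expected
heterozygous divergence, so true overlaps between alleles survive while
random 25%-identity overlaps are rejected.  All are exposed.

## Simulator: what it emulates, what it does not

`simulate_radseq` plants `n_loci` SbfI sites in a uniform-random
genome, spaced so loci can never overlap, and re-rolls accidental
background occurrences so the digest finds exactly the planted sites.
Each site yields one 700 bp truth locus on the + strand starting at
the remnant (`--bidirectional` adds the opposite-strand locus;
single-direction is the default because the expected library footprint
arithmetic, sites times span, presumes one locus per site).

Individuals follow the wgsim-family diploid mutation model: each base
beyond the 6 bp remnant is a mutation with probability `het` (default
0.02); one third of mutations are homozygous (both haplotypes carry the
same non-reference base), two thirds heterozygous (one random haplotype
carries it) — the split hard-coded in wgsim, from which the protocol's
simulator descends.  `het` is thus the mutation-rate dial of that
family, realizing a per-base heterozygosity of about 0.013.  The
alternative reading of "heterozygosity 0.02" (realized het-site rate
0.02, mutation rate 0.03–0.04) was evaluated and rejected because its
consequences contradict the published outcomes this design reproduces
(catalog duplication around 1%, proper-pair rates near 99%): at
mutation rate 0.03–0.04 the cross-individual consensus divergence
over-splits the catalog several-fold more and drags the proper-pair
rate well below the published values.  Mutations never fall in the
remnant: a disrupted recognition site would not have been cut and
sequenced at all, and allele dropout is out of scope.

Pairs are drawn per locus and insert size (ladder 200–700 by 50,
Poisson mean `depth_per_step = 10` per step — the standard shotgun
count model for a stated mean depth); the forward read copies the first
125 haplotype bases, the reverse read is the reverse complement of the
insert's last 125; substitution errors hit each base with probability
`err = 0.01` (no indels, matching the SNP-style polymorphism model);
qualities are uniform Q40.  Ground truth (locus, individual, insert,
haplotype) travels in the read id.

Not emulated: indels and structural variation, quality-profiled errors,
adapter read-through, paralogues and repeat families, missing loci and
allele dropout, and insert-size jitter around the ladder values.  A
green test on this generator therefore establishes the pipeline's
arithmetic and its behaviour under error and SNP-scale polymorphism —
not robustness to repeats or indels.

## Evaluation

N50 is the length of the shortest contig in the smallest set of longest
contigs reaching half the total length; `N`s count toward length.  The
re-mapper seeds with exact 21-mers on both strands and scores
full-read-length ungapped identity (overhangs and `N` columns count as
mismatches); a read maps at identity at least `min_identity` (default
0.9, tolerant of error plus polymorphism on 125 bp reads), ties
breaking to the lowest contig id, then leftmost position, then forward
strand.  A pair is proper when both mates hit one contig in
forward/reverse orientation with the plus-strand 5' end not past the
minus-strand 3' end and an inferred insert inside `insert_range`
(default 100–1000 bp; spacer `N`s count toward the insert, as for a
padded reference).  The fixed insert window is an explicit
approximation of an aligner's learned insert distribution.  Mapping
mates independently (no pairing rescue) makes the proper-pair rate
slightly conservative when near-duplicate contigs exist.

Truth identity aligns each contig (padded contigs: the segments on
either side of the ten-`N` spacer, separately, so spacer columns are
never scored) to the truth locus chosen by majority vote of its member
reads' labels, and reports percent of non-`N` bases matching; a contig
is "matched" at 80% or more.

## Numerical and degenerate-input choices

* All randomness flows through seeds derived stably from the run seed
  and a stage/locus label, below 2^31; user RNG state is restored.
* Consensus ties break to the alphabetically smallest base; catalog
  ties to the lowest catalog id; assembly ties by score, length,
  mismatches, then smallest index pair.  Fixed input order plus these
  rules make every stage deterministic, and per-locus assembly tasks
  share no state, so thread count never changes results.
* Empty inputs error early (`build_stacks`, `greedy_assemble`,
  `contig_stats`, `map_read_pairs` on no contigs); a locus read set
  that is empty or under `min_reads` is routed around assembly rather
  than erroring mid-pipeline.
* The window quality filter drops whole pairs rather than truncating
  reads (uniform read length is load-bearing for stacking); window
  length is `max(1, round(window_frac * read_length))` per mate.

## Known limitations

Ungapped comparison throughout (no indel alleles); no genotype calling;
no SAM/BAM emission; the across-individual optimum is not meaningful on
idealized no-dropout data (see above); catalog consensus is not updated
on merge, so heavily polymorphic loci can split into near-duplicate
catalog entries — downstream mapping resolves ties deterministically
but pair placement across near-duplicates remains conservative.
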