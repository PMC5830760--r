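# radasm

Local de novo assembly of overlapping paired-end RAD-seq loci from
multiple individuals, in R.

## The problem

In original-protocol paired-end RAD sequencing (RPE), forward reads all
begin at a restriction-enzyme cut site (here SbfI, recognition site
`CCTGCAGG`, leaving the remnant `TGCAGG` at read starts), while reverse
reads end at random sonication breakpoints staggered over a few hundred
bp downstream.  Each cut site therefore defines a *RAD locus* whose
forward reads stack exactly and whose reverse reads tile the locus at
non-uniform depth.  Assembling one contig per locus from many
individuals is hard: polymorphism between individuals, sequencing error,
and the uneven reverse-read coverage confuse whole-genome assemblers.

`radasm` implements the clustering-then-local-assembly strategy for this
design:

1. **Threshold optimization.** Forward reads of one individual are
   clustered at every mismatch threshold *m* in a range; the optimum
   maximizes the number of loci with two haplotypes while minimizing
   one-haplotype loci (a diploid carries at most two alleles per locus).
   Across individuals, locus sets are merged into a catalog at each
   threshold *n*, and the optimum is the inflection of the
   new-loci-per-individual curve.
2. **Clustering.** Identical forward reads pile into stacks (minimum
   depth 5); stacks within *m* mismatches form loci (connected
   components); over-deep "lumberjack" stacks (depth > mean + 2 sd) and
   over-merged components (> 3 stacks) are removed or flagged as likely
   repeats.  Loci merge across individuals into a catalog at *n*
   mismatches against the founder consensus.
3. **Read sorting with data reduction.** Reverse reads are pooled per
   catalog locus (minimum 10, maximum 400 per locus; larger pools are
   seeded-subsampled).
4. **Two-step assembly.** Per locus, reverse reads are assembled by a
   greedy ungapped overlap-layout-consensus assembler; the resulting
   contigs are then re-assembled together with the forward-read
   consensus.  If they do not overlap the consensus, the longest contig
   is joined to it with exactly ten `N`s marking the unsequenced gap.
5. **Evaluation.** N50 / mean / total length; re-mapping of the
   assembly-input pairs with a k-mer-seeded ungapped mapper and the
   standard proper-pair rule (same contig, forward/reverse orientation,
   insert within range); and, for simulations, contig identity against
   the ground truth.

A diploid RAD-seq simulator (in-silico SbfI digest, wgsim-style
mutation model, insert-size ladder 200–700 bp, per-base error rate 0.01,
ground-truth labels in read ids) generates the package's test bed.

## Worked example

```r
library(radasm)
res <- run_pipeline(rad_config(n_loci = 30L, n_individuals = 4L, seed = 5L))
res$thresholds$m_opt   # chosen within-individual mismatch threshold
res$metrics
```

On this 30-locus, 4-individual simulation the pipeline printed
(`m_opt` = 5):

```
  n_clusters n50 mean_len total_cov total_mapped_pct proper_paired_pct
1         30 700      702     21060         99.89852          99.79705
  n_pairs_mapped_input identical_clusters_pct mean_identity_pct
1                10840                    100          99.67302
```

30 contigs for 30 planted loci, N50 at the full 700 bp locus span,
99.8% of the assembly-input read pairs re-mapping as proper pairs, and
every contig matching its true locus at a mean identity of 99.7%
despite the 1% read error rate.  At the full scaled replication
(200 loci, 12 individuals, seed 1) the within-individual optimization
picks m = 6 and the pipeline reports 97.5% proper pairs and 99.7% mean
identity.

## Command line

```sh
inst/cli/radasm simulate  --n-loci 200 --n-individuals 12 --seed 1 --out-dir sim/
inst/cli/radasm preprocess --in1 r1.fq.gz --in2 r2.fq.gz --out-prefix clean \
                           --window-frac 0.1 --score-limit 13 --remnant TGCAGG
inst/cli/radasm run --out-dir run1/ --n-loci 200 --threads 4
```

`run` writes per-stage outputs plus `manifest.json`; deleting a stage's
outputs and re-running resumes from what is still on disk.
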