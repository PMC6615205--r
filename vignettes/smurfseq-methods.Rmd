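---
title: "Copy-number profiling with concatenated-fragment long reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number profiling with concatenated-fragment long reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smurfseq)
```

## The problem

Read-counting applications such as copy-number variation (CNV) profiling do
not need long reads; they need many independently mapped molecules.  A
nanopore flowcell, however, spends its capacity more efficiently on long
molecules.  The SMURF-seq idea resolves this tension: genomic DNA is cut
into short restriction fragments, the fragments are re-ligated at random
into artificial long molecules (~6-8 kb), and each sequenced read is then
*split computationally* back into its constituent fragments, each aligning
to its own location in the genome.  One read yields ~25-30 countable
fragments.

This package implements the computational side of that design as a
desk-scale, fully testable toolkit: a simulator that produces
concatenated-fragment reads with exact per-fragment truth, a split-read
mapper, truth-based mapper evaluation, and the read-count CNV pipeline
(equal-mappability bins, bad-bin masking, LOWESS GC correction, circular
binary segmentation, event calling), plus profile comparison utilities.

## Simulation model

### Genomes and truth

`generate_genome()` draws i.i.d. bases at a target GC fraction (or a linear
GC gradient per chromosome, used to exercise GC correction).  Copy-number
truth is planted with `plant_cnv()` as integer copy numbers on half-open
intervals; unspecified regions are diploid (CN 2).  All coordinates in the
package are 0-based half-open; 1-based coordinates appear only inside
FASTA/SAM writers, following those formats.

An i.i.d. genome deliberately lacks repeats, satellite arrays, chromatin
or replication-timing structure.  Consequently almost every position is
uniquely mappable and there are no genuinely "bad" genomic regions; tests
that exercise masking and multi-mapping plant their own duplications and
count spikes.  Passing tests on this substrate demonstrate the
correctness of the machinery, not robustness to every artifact of real
genomes.

### Digestion

`digest_genome()` scans the forward strand for exact occurrences of the
recognition site (overlapping occurrences included) and cuts at the
enzyme's offset; fragments are the intervals between consecutive cuts,
including both chromosome-end pieces (genome-wide these end pieces are a
negligible fraction of all inter-site distances, so summary statistics
include them).  The built-in enzymes, SaqAI (T^TAA) and Hin1II (CATG^),
both have palindromic sites, so forward-strand scanning finds every cut
site; enzymes with non-palindromic sites would require double-strand
scanning and are not supported.  N runs never match a site, so they are
never cut.  On an i.i.d. GC-0.5 genome a 4-bp site occurs every 4^4 = 256
bp on average, and observed mean fragment lengths track that expectation.

### Reads and the error model

`sample_fragments()` draws digest fragments with replacement, with
probability proportional to the planted copy number at the fragment
midpoint — this is what couples the read data to the CNV truth.  Strand is
Bernoulli(1/2) per fragment, reflecting random ligation orientation.
`concatenate_fragments()` packs fragments, in sampled order, into reads:
a read closes when the next fragment would exceed the target length
(default 6,750 bp), because ligation never splits a molecule; read lengths
therefore spread by about one fragment.

`apply_errors()` is a per-base process: deletion with `del_rate`,
otherwise emission with substitution probability `sub_rate` and a single
inserted random base after it with probability `ins_rate`.  The defaults
(0.05/0.03/0.04) give ~12% edit load, in the range of R9-era nanopore
reads.  The model has no homopolymer structure, no quality strings and no
adapter/barcode sequence; it stresses the mapper with indel-rich noise,
nothing more.  Truth intervals are re-mapped through the error process, so
evaluation always works in final read coordinates.

`splice_from_reads()` reproduces the alternative simulation route — cutting
random substrings out of longer origin-bearing reads — with the fragment
length distribution exposed as a parameter, since no single distribution
is canonical for that protocol.

## The split mapper

Mapping uses seed-and-extend with the scoring regime chosen for
concatenated-fragment nanopore reads: match +4, mismatch −10, gap open 6,
gap extend 3 (a length-k gap costs 6 + 3k), 12-bp exact seeds, chains of
at least 12 seed-covered bases, and a reporting floor of 120 — exactly a
perfect 30-bp match.  Reverse-strand hits are found by looking up the
reverse complement of each read k-mer, and '-' chains are processed in
reverse-complemented read coordinates so that chaining and extension are
strand-agnostic.

Seeds are clustered by diagonal within a 100-bp band and ordered along the
read; read-coordinate gaps above 150 bp split a chain (at 12% error the
probability of a 150-bp seed desert inside a real fragment is negligible).
Each chain is extended outward from its longest exact run by a banded
(±25 diagonal) affine-gap dynamic program with an x-drop of 100 and full
traceback, so every report carries a CIGAR whose re-scored path equals the
reported score exactly; on fragments of a few hundred bases the result
matches an unbanded Smith–Waterman.  Overlapping fragment reports are
resolved greedily by score (overlaps above 20% of the shorter are
dropped); ties break deterministically to the lowest (chromosome, start).
A fragment is `is_unique` only when its score strictly exceeds every
competing placement covering at least half the same read interval — the
CNV pipeline counts only such fragments.

Two consequences of *local*, score-determined extension are worth knowing.
First, fragment boundaries can overshoot by a few bases into the adjacent
ligated fragment whenever the reference happens to continue with matching
bases; with restriction fragments this is partly systematic, because a
fragment ends exactly where the genome continues with the recognition-site
bases that the next fragment may also begin with, so median slips of ~3 bp
are expected and harmless for counting.  Second, fragments shorter than
30 bp can never reach the reporting floor; they are invisible to the
mapper by design, which is why mapper benchmarks here (as in practice)
restrict to fragments of at least 100 bp.  Spurious single-seed chains
(a random 200-bp read against a 100-kb genome produces two to four) are
likewise eliminated by the floor.

## Mapper evaluation

`evaluate_mapping()` scores any fragment table against simulation truth at
two levels.  Fragment level: one-to-one greedy matching on reciprocal
reference-interval overlap (default 50%, the usual structural-variant
convention), same read, chromosome and strand required; precision =
matched/predicted, recall = matched/truth.  Base level: precision and
recall of the multiset of reference positions covered per read, which
penalizes boundary error and misplacement alike.  With zero predictions,
precision is reported as 1 alongside an explicit `zero_predictions` flag.
Greedy matching at reciprocal-50% equals optimal bipartite matching on
the small per-read instances that occur here (verified against an
exhaustive oracle in the tests).

## The CNV pipeline

1. **Mappability and bins.** A position is uniquely mappable iff its
   40-mer (configurable, 20-64 bp) occurs exactly once in the genome
   counting both strands.  `make_bins()` sweeps the genome accumulating
   mappable positions and closes a bin at `ceiling(total/n_bins)`; bins
   never cross chromosomes, the last bin of a chromosome absorbs the
   remainder (masked from the start if it deviates >10% from target).
   Equal mappability equalizes expected counts under uniform coverage, so
   variable physical width is the point, not a defect.
2. **Counting.** Only unique fragments count, assigned by reference
   midpoint so boundary-straddling fragments count exactly once.
3. **Bad-bin masking.** Iterative upper-outlier rule: mask bins above
   `median + 5·MAD` of the unmasked counts, recompute, repeat to a fixed
   point.  A multiplicative guard (`min_fold = 3`) restricts masking to
   bins at least 3× the median: at realistic depth the MAD of the counts
   is of order sqrt(depth), far below genuine copy-number signal, and
   without the guard an ordinary 2× amplification would be masked as an
   artifact.  Both knobs are exposed; the rule is a stand-in for
   reference-sample-derived bad-bin lists and should not be expected to
   reproduce any external pipeline bin for bin.
4. **GC correction.** `stats::lowess` (tricube local linear regression,
   span 0.3, 3 robustness iterations) of raw count on GC over unmasked
   bins; the fit is subtracted and the counts re-centered at the grand
   mean, floored at zero.  Local linear fits reproduce an exactly linear
   bias exactly; the span is wide enough not to absorb segment-scale CNV
   signal.  Constant GC degenerates to the identity with a warning.
5. **Ratios.** Corrected counts divided by their unmasked mean, so
   unmasked ratios average exactly 1.  With a genome whose average copy
   number is 2 this puts neutral bins at ratio 1; in heavily aberrant
   genomes the mean shifts, as it does in any mean-normalized profile.
   Sex chromosomes are not special-cased in synthetic genomes.
6. **Segmentation.** From-scratch circular binary segmentation: per
   chromosome and per current segment, the arc (i, j] of the circularized
   ratio sequence maximizing |mean(arc) − mean(rest)| / (s·sqrt(1/k +
   1/(n−k))) is tested by permutation; p-values use (1 + #exceed)/(n_perm
   + 1), which keeps the type-I rate at or below alpha, and permutation
   stops early once p < alpha is impossible.  Accepted splits produce up
   to three children, searched recursively in deterministic order with a
   seeded generator.  Because s is permutation-invariant it cancels from
   the test.  Note the granularity limit of permutation tests: for a 4+4
   step the best circular arc arises by chance in ~8/70 permutations, so
   no effect size can reach p < 0.11 on 8 bins; short segments therefore
   require a looser alpha, while 50-bin steps split comfortably at the
   default alpha = 0.01.
7. **Spurious-segment removal.** Segments shorter than 5 bins, or closer
   than 0.1 in mean ratio to a neighbor, merge into the neighbor with the
   closer mean, iterated to a fixed point (each merge reduces the segment
   count, so termination is immediate).  These two thresholds are
   parameterized concretizations of common post-CBS filters, flagged as
   such.
8. **Event calling.** A bin's state comes solely from its segment mean:
   amplified at ≥ 1.25, deleted at ≤ 0.8, boundaries inclusive, neutral
   otherwise.  Masked bins carry `NA`.

`cnv_profile()` composes the stages and records every parameter and seed
in the returned object; `plot()` draws bin ratios with the segment means
overlaid.

## Comparison utilities

`correlate_profiles()` computes the Pearson correlation of paired bin
ratios, excluding bins masked in either profile.  `compare_events()`
treats a non-neutral bin state as an event and, by default, requires
state agreement (an amplification called where the reference is deleted
counts as both a false positive and a miss); `ignore_direction = TRUE`
recovers the looser convention.  The full 3×3 confusion table is emitted
so the metrics can be recomputed exactly.  `downsample_fragments()`
subsamples at read granularity by default — whole reads with all their
fragments — matching how concatenated-fragment data is actually thinned.

## Problem sizes and determinism

The shipped tests and the acceptance script run the pipeline at the sizes
the analysis is designed around: 10 Mb single-chromosome genomes, ~6,000
reads of ~19-25 fragments each for mapper benchmarks, 10^6 counted
fragments over 500 equal-mappability bins (~2,000 fragments per bin,
comparable per-bin depth to a 5,000-bin whole-genome profile), CBS
permutation tests with 1,000 permutations, and 1,000-run null batteries
for type-I control.  Every stochastic step takes an explicit seed —
genome generation, sampling, the error model, CBS permutations,
downsampling — and repeated runs are byte-identical.

## Known limitations

- The i.i.d. genome understates multi-mapping; the mapper's uniqueness
  logic is exercised by planted duplications only.
- The error model has no homopolymer or quality structure; recall under
  real basecaller error may differ from the simulated 12% regime.
- The seed index holds 4^k buckets in memory (k ≤ 13), sized for
  desk-scale genomes (up to a few hundred Mb), not for a full human
  genome; externally produced SAM can be ingested instead.
- Bad-bin masking and spurious-segment removal are parameterized
  stand-ins for published filters whose exact rules are not public.
- Integer copy-number calling with ploidy/purity estimation is out of
  scope; the pipeline stops at ratio-scale segment means and
  amplified/neutral/deleted states.
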