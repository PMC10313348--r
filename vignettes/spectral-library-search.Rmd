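---
title: "Partitioned fragment-ion indexing and spectral library search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioned fragment-ion indexing and spectral library search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragidx)
```

## The problem

Spectral library search identifies peptides by comparing each experimental
MS/MS spectrum against reference spectra with known peptide annotations --
increasingly, libraries *predicted* for every peptide of a sequence
database. For metaproteome-scale search spaces such libraries hold millions
of spectra and cannot be held in memory, and naive pairwise comparison is
far too slow. `fragidx` addresses both constraints with an inverted
fragment-ion index that scores all candidates of a query simultaneously,
and a partitioning scheme that bounds memory by a fraction of the library.

## Index data structures

**Precursor index.** Every library spectrum receives a dense 32-bit id in
read order. Ids are ranked by (charge, precursor m/z), ties broken by id so
the ordering is deterministic, and the inverse permutation `rank_of` is
precomputed by a linear scan. A precursor tolerance constraint then becomes
a contiguous *rank window* found by binary search inside the matching
charge block.

**Fragment index.** Each preprocessed peak is stored as a triplet
(fragment m/z, intensity, parent id) in half-open m/z bins of width $B$
(default 0.2 Da, the fragment tolerance). Within a bin, entries are sorted
by the parent's rank, so the entries relevant to one query peak and one
candidate window form a contiguous run: scoring is a batched multiply-add
of intensity products into a per-rank accumulator.

**Partitions.** The fragment index is split by non-overlapping precursor
m/z intervals; each partition carries the full bin range and is an
independently loadable fragment index for the library subset whose
precursors fall in its interval. The split points are placed at precursor
m/z *quantiles* (equal spectrum counts per partition) rather than at
equal-width intervals: precursor masses are far from uniformly distributed,
and the equal-count rule balances both file sizes and search work
regardless of the mass distribution. A query only touches the partitions
its tolerance window intersects, so peak memory is bounded by the largest
single partition plus the precursor index.

**On-disk format.** Fragment entries are little-endian float32/uint32
records grouped by bin, with a JSON manifest (configuration, boundaries,
counts, checksums). Because rescoring needs full-precision peaks and ion
series labels, each partition also carries a float64 "spectra" sidecar with
the complete preprocessed reference peaks; reconstructing them from the
float32 triplets would inject ~1e-4 Da rounding into the Gaussian rescoring
and break the package's 1e-6 equivalence guarantee between indexed and
exhaustive search.

**Two-phase construction.** The library is streamed twice, never held in
memory: a first pass collects only precursor records (fixing the precursor
index and the partition boundaries), a second pass preprocesses each
spectrum and appends its fragments to the owning partition's spill file.
A finalize step rewrites each spill with every bin's entries sorted by
parent rank -- a full rewrite rather than in-place patching, which is
simpler and crash-safe. If boundaries are supplied in the configuration
the first pass result is used only for the precursor table.

## Preprocessing

Raw intensities are square rooted (dominant peaks otherwise overwhelm the
dot product) and scaled to unit Euclidean norm, so a perfect binned match
scores 1. The transform is applied exactly once per spectrum -- it is not
idempotent -- and symmetrically to queries and references, since the
scoring formula treats both sides' intensities as comparable weights.
An optional top-$k$ in window-$w$ noise filter is available but off by
default everywhere. Fragments outside the indexed m/z range (default
[0, 2000) Da) are dropped from the *index* with a counter in the manifest,
while the rescoring sidecar keeps the full spectrum.

## Scoring model

Candidates pre-ranked by the accumulated binned dot product are rescored
by resolving the binning. With $k$ over reference peaks and $l$ over query
peaks:

$$\mathrm{similarity}(Q,R)=\sum_k \max_l\; I_l I_k\, \varphi(mz_l, mz_k),
\qquad
\varphi(x,\mu)=\exp\!\left(-\tfrac12\left(\tfrac{x-\mu}{\sigma}\right)^2\right)$$

$$\mathrm{bias}(Q,R)=\frac{\sum_k \left(\max_l I_l I_k \varphi\right)^2}
                          {\mathrm{similarity}(Q,R)}$$

The Gaussian spread $\sigma$ models the fragment tolerance and defaults to
the bin width $B$. $\varphi$ is truncated to exactly zero beyond 5$\sigma$
(contributions below $e^{-12.5}\approx 4\times10^{-6}$), which lets the
implementation evaluate the max per reference peak over a sorted m/z window
(`findInterval`) in $O(|R|\log|Q|)$ while remaining equal to the quadratic
double loop to well below 1e-9. When the similarity is zero the bias is
defined as 1, so the *bias-adjusted similarity*
$\mathrm{similarity}\cdot(1-\mathrm{bias})$ of a non-match is 0; the bias
penalizes matches carried by a single dominant peak pair.

**Reflection score.** Predicted references carry only b/y ions, so real
but unpredicted ion types in the query would unfairly depress a correct
match. The reflection variant removes query peaks with no reference peak
within the truncation radius, renormalizes the surviving intensities to
unit norm, and reapplies the same formulas. Renormalization is the design
choice that makes a clean sub-spectrum score exactly 1 against its
prediction; without it the reflection score would still scale with the
fraction of explained intensity, defeating its purpose. With no matched
peak all reflection components are 0. The **final ranking score** is the
arithmetic mean of the plain and reflection bias-adjusted similarities --
the reflection score alone can be gamed by matching a few small annotated
peaks, the plain score alone punishes unpredicted ions, and the average is
robust to both failure modes.

**Auxiliary features** (rescoring features only, never the ranking score):
a log-hyperscore $\ln N_b! + \ln N_y! + \ln N_{other}! + \ln(1+\sum I_lI_k)$
over matched reference peaks by ion series (log-factorials via
`lgamma`); an f-value $0.6\,dot_1 - 0.4\,(dot_1 - dot_2)$ from the binned
dot products of the top two matches ($dot_2 = 0$ without a runner-up, the
same convention as `delta_final`); shared peak count; the standard
deviation of matched-fragment m/z differences; absolute precursor m/z
difference; peptide length. The exact constants of the hyperscore and
f-value are conventions borrowed from the database-search and
spectral-search literature; since they are consumed only as Percolator
features, downstream results are insensitive to the choice.

## Search

Queries are scheduled to every partition whose precursor interval
intersects their tolerance window (10 ppm default, applied on m/z to match
the index ordering; a query at a partition boundary is searched in both
neighbours and the best-scoring instance survives the merge). A query with
unknown charge (0) searches every charge block. Per partition, the top
`n_rescore` accumulator candidates (default 50 per query per partition;
`Inf` rescores the whole window) are rescored, results are merged across
partitions, deduplicated per library spectrum, and the top X by final
score are emitted with contiguous ranks. Ties at the cut are broken by
higher shared peak count, then lower library id, so results are fully
deterministic and independent of processing order. Queries without any
candidate are reported as an explicit marker row (`rank == 0`) rather than
silently dropped.

Because query peaks match only their own bin during accumulation, a peak
jittered across a bin edge contributes nothing to the accumulator; the
Gaussian rescoring recovers such cross-bin matches. With `n_rescore = Inf`
the indexed search is *exactly* equivalent (rank-1 identity, scores to
1e-6) to exhaustive scoring of all in-tolerance candidates
(`oracle_search()`); with a finite `n_rescore` rare borderline queries
could differ, which is why the equivalence tests pin the full window.

## Target-decoy validation

Target and decoy libraries are searched separately and competed per query;
an exact score tie keeps the target (ties are counted in an attribute so
the effect is auditable). The FDR at threshold $t$ is
$N_{decoy}(t)/N_{target}(t)$ -- as printed, without the +1 correction,
which is available behind a flag -- and q-values are the monotonized
cumulative minimum. The entrapment estimate
$N_{trap}(t)/N_{target}(t)\cdot R$ uses $R$ = (all target peptides,
entrapment included) / (entrapment peptides), matching a construction in
which the entrapment organisms are appended to the target database. A
target PSM counts as entrapment when its peptide occurs in the entrapment
set and not among true-target peptides. True FDR against a ground-truth
map compares modified sequences as exact strings (I/L distinct).

When the tests compare the entrapment estimate with the target-decoy
estimate at the 1% acceptance threshold, both counts are small Poisson
variables estimating the same false-hit rate $\lambda$
($N_{decoy}\sim\mathrm{Pois}(\lambda)$,
$N_{trap}\sim\mathrm{Pois}(\lambda/R)$). The agreement band is therefore
$3\sqrt{\hat\lambda (R+1)}/N_{target}$ with the pooled, pseudocounted
$\hat\lambda = (N_{decoy} + R\,N_{trap})/2 + 1/2$; a fixed absolute band
would be either vacuous or flaky at these counts.

## The synthetic-data generator

The generator emulates the predicted-library workflow end to end: random
proteomes (K/R frequency ~4.5% each, so tryptic peptides average ~11
residues), tryptic digestion (cleave after K/R, not before P, up to two
missed cleavages), peptides of length 7-30, charges 2-4 restricted to
precursor m/z 400-1500, and a b/y-ion "predictor" whose intensities follow
a smooth position-dependent bell profile hashed deterministically from
(peptide, charge) -- distinct peptides get distinct patterns and every
artifact is byte-reproducible from (config, seed). Cysteine is fixed
carbamidomethylated. Decoys are pseudo-reversed (C-terminal residue kept,
mass preserved, collisions reshuffled deterministically or dropped).
The entrapment set is a second, disjoint proteome appended to the targets
with its own decoys; queries are drawn only from non-entrapment targets
(plus "foreign" peptides absent from every library), mirroring a study
design in which query spectra cannot originate from the entrapment
organisms.

Query noise defaults -- m/z jitter 0.02 Da, intensity CV 0.2, 10% peak
dropout, 5 contaminant peaks, precursor jitter within 5 ppm (half the
search tolerance) -- were chosen once so that rank-1 recovery is high but
not saturated, leaving the FDR machinery real discrimination work. The
default study condition is 2000 target + 2000 decoy spectra and 500
queries with 10% foreign; the test suite exercises ten seeds of it and the
examples use scaled-down variants (300-400 spectra) where full scale adds
nothing.

**What the generator does not emulate** -- and hence what passing tests do
*not* demonstrate about real data: learned, instrument-specific
fragmentation intensities (the bell profile is a stand-in); retention
time; isotope envelopes and co-isolation chimeras; non-b/y ion series,
neutral losses and realistic noise structure; charge-state errors; shared
peptides between proteins. Conclusions about absolute identification rates
on real runs require real libraries and runs; the synthetic conditions
validate the *algorithms* (index equivalence, partition invariance, FDR
calibration), not instrument realism.

## Numerical and degenerate-input choices

* Bins and intervals are half-open everywhere; a value exactly at a
  boundary belongs to the upper bin/partition.
* Fewer distinct precursor m/z values than requested partitions degrade
  gracefully to fewer non-empty partitions with a warning; empty
  partitions are valid and searchable.
* Duplicate m/z within a spectrum are merged by intensity summation at
  construction, keeping the max-per-reference-peak scoring well behaved;
  zero-intensity peaks are dropped at parse time.
* An all-zero spectrum is an error at preprocessing ("empty spectrum").
* Spectra are preprocessed exactly once, by `build_index()` for libraries
  and by `search_run()`/`oracle_search()` for queries.
* `threads` in the CLI is accepted as a hint and ignored; the
  implementation is single-threaded and results are by construction
  independent of any worker count.

## Limitations

mzML/mzXML input, open-modification (mass-offset) search, peptide-level
FDR, memory-mapped partition loading and built-in SVM rescoring are out of
scope; Percolator integration stops at writing its pin-tab input file.
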