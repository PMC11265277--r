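---
title: "Synteny similarity and 16S matrix augmentation: models, conventions, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synteny similarity and 16S matrix augmentation: models, conventions, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synscale)
```

## The model

A bacterial genome is reduced to its ordered gene list; a genome pair is a
pair of such linear graphs joined by cross edges, one per orthologous gene
pair. The synteny similarity asks: *do the orthologs sit in consistent
relative positions in the two genomes?*

The gene at position $r$ of genome $X$ has rank $\mathrm{rank}_X = r$
(1-based, over the full gene order). For ortholog pairs $i$ and $j$ the
arrangement contributes the cosine

$$
\cos(u, v), \qquad
u = (\mathrm{rank}_A(i),\, \mathrm{rank}_A(j)), \quad
v = (\mathrm{rank}_B(i),\, \mathrm{rank}_B(j)),
$$

and the arrangement's score is the mean over all $\binom{n}{2}$
combinations. Because bacterial chromosomes are circular while flat files
are linear, the measure does not trust the deposited origin: each ortholog
pair in turn becomes a *pivot*, both gene orders are circularly rotated so
the pivot genes take rank 1, and the $n + 1$ arrangement scores (original
plus $n$ pivots) are reduced by their **median**. The median is what makes
the measure rotation-invariant: for a pure rotation every pivot arrangement
aligns the two orders perfectly (score 1), so the median is 1 no matter how
poorly the arbitrary deposited origins agree. Even-length score vectors use
the midpoint of the central pair.

Assumptions worth stating: ranks are positive, so every cosine is in
$(0, 1]$ and the measure cannot return 0 for a scored pair (0 is reserved
for "no data"); strand and gene orientation are ignored; the ortholog
mapping must be one-to-one (see below); pairs with fewer than two orthologs
are not scored and appear as missing entries in the matrix.

## Augmentation

With $D_{16S}$ the 16S distance matrix and $D_{syn}$ the synteny distance
matrix ($1 -$ similarity, applied verbatim so missing similarities become
distance 1), the augmented matrix is

$$
M = \mathrm{minmax}\!\left(D_{16S} \cdot \mathrm{Cov}(D_{syn})\right),
$$

min–max normalized over **all** entries (diagonal included), then
symmetrized as $(M + M^\top)/2$, then the diagonal forced to 0. The order
matters and was a genuinely open choice:

* The product of two symmetric matrices is not symmetric in general, so a
  symmetric result requires an explicit convention. Averaging with the
  transpose is the least-committal one; the pre-symmetrization maximum
  asymmetry is recorded in the `max_asymmetry` attribute so users can see
  how much the convention mattered.
* Forcing the diagonal to zero *last* guarantees the diagonal reads
  "complete similarity" regardless of what the normalization did to it.
* A constant (degenerate) input yields `max == min`; the normalization then
  returns the all-zero matrix rather than dividing by zero.

Covariance treats columns as variables with the unbiased $n-1$ denominator
(`unbiased = FALSE` switches to $n$); this is the mainstream numerical
default and changes nothing downstream of the min–max step except scale.

## Conventions where the design was open

* **Cosine vector construction.** The default `genome-vectors` mode pairs
  within-genome rank vectors across genomes, which is invariant to
  uniformly rescaling one genome's ranks — the property that makes
  "relative position" meaningful when genomes have different gene counts.
  The alternative `ortholog-vectors` mode (pairing each ortholog's
  $(\mathrm{rank}_A, \mathrm{rank}_B)$ point with another ortholog's) is a
  config switch; it lacks the scale invariance and is provided for
  comparison, not as the default.
* **Within-arrangement statistic.** Mean by default, median by option. The
  tests exercise both against the brute-force enumerator.
* **Rank scope.** Ranks run over the full gene order by default; the
  `rank_scope = "ortholog-genes"` option re-ranks over the orthologous
  genes only.
* **One-to-one canonicalization.** BLAST-style hit tables are many-to-many;
  pivots need one partner per gene. Hits are accepted greedily in order of
  decreasing identity, ties broken by longer aligned length (equivalently,
  smallest difference from the longest alignment in the tie group), then
  lexicographic gene ids — deterministic regardless of input row order.
* **Multiple 16S copies.** A genome can carry several unique 16S genes; the
  gene-set distance aggregates all cross-pair sketch distances by mean
  (default) or min. No claim is made about which aggregation upstream tools
  use.
* **Missing entries.** Sparse matrices encode "no data" as 0 with a
  `zero_is_missing` flag. Clustering and KNN construction need a defined
  dissimilarity everywhere, so missing distances are filled with the
  maximal distance 1 — a documented, deliberately pessimistic choice that
  pushes data-free genomes to the periphery rather than guessing.
* **Thr / Rem reductions.** `Thr` keeps entries with similarity strictly
  greater than 82 % (the reporting floor common to ANI tools; strict ">"
  by construction, configurable). `Rem` keeps the entries lying on the
  non-zero support of a reference matrix, typically ANI.
* **DeltaCon similarity.** The bounded transform $1/(1+d)$ of the Matusita
  distance between fast-belief-propagation affinity matrices
  $S = (I + \varepsilon^2 D - \varepsilon A)^{-1}$, with
  $\varepsilon = 1/(1 + \max \mathrm{degree})$ by default. The unbounded
  alternative $1/d$ is undefined at $d = 0$ and was rejected. Affinities
  are computed on the unweighted KNN edge set by default (weighted behind a
  flag). Node attribution is the row-wise root-Euclidean distance between
  affinity matrices; edge attribution assigns each changed edge the sum of
  its endpoints' attributions, signed by gain/loss.
* **Cluster cutoff.** Interpreted as the requested number of flat clusters
  (`cutree` on the complete-linkage dendrogram), matching an integer sweep
  axis; silhouette is reported only where defined ($2 \le c \le n-1$), and
  members of singleton clusters score 0 by the usual convention. The Rand
  score is the plain (unadjusted) pair-counting index on $[0, 1]$.

## Sketching

The MinHash module is a self-contained bottom-$s$ sketch over canonical
$k$-mers (lexicographic minimum of a $k$-mer and its reverse complement;
$k$-mers containing N are skipped) with a single seeded 64-bit hash
(FNV-1a over the 2-bit bases, splitmix64 finalizer, truncated to 53 bits so
hashes are exact doubles). Defaults $k = 21$, $s = 1000$ follow common
whole-genome sketching practice. The Jaccard estimate merges both sketches
and counts shared hashes among the bottom $s$ of the union — exact whenever
the union has at most $s$ distinct $k$-mers, which the tests verify against
a naive set-based oracle. The Mash-style distance
$d = -\tfrac{1}{k}\ln\tfrac{2j}{1+j}$ diverges at $j = 0$ and is clamped to
1 there (and capped at 1 generally) so distance matrices stay in $[0, 1]$.

## The simulator and what passing tests mean

`simulate_corpus()` emulates exactly the structure the measure targets:
group-wise ancestors with ordered genes, descendants derived by circular
rotations (which the measure should ignore), block transpositions and
segment reversals (which it should penalize), independent per-gene ortholog
retention (so the ortholog count between two genomes is
Binomial($G$, retention²), a property the tests check by goodness of fit),
and i.i.d. per-site substitution for the sketch arm. Defaults — 3 groups,
30 genomes, 30 genes of 900 bp, retention 0.9, one rotation plus one
transposition per descendant, 1 % substitution — describe a corpus where
group structure is present but not trivial.

It deliberately does **not** emulate: horizontal gene transfer, indels,
gene duplication or paralogy, unequal gene lengths, rearrangement hotspots,
or between-group orthology. Passing the recovery tests therefore shows the
machinery is correct and sensitive in the intended direction; it does not
show that real corpora cluster this cleanly — real ortholog sets are
noisier, and real between-genus pairs are not perfectly orthology-free.

## Problem sizes and numerical tolerances

The test suite and the acceptance script run at sizes chosen to make every
check exhaustive or statistically stable while staying quick on a laptop:
brute-force oracle agreement on genome pairs of up to 6 genes (tolerance
1e-12, the enumerator being an independent implementation); 20-seed
recovery runs on 30-genome corpora; 50 replicates per transposition level;
DeltaCon affinity versus dense inversion on graphs of up to 20 nodes
(tolerance 1e-8); silhouette versus an independent textbook implementation
(tolerance 1e-9). Matrix TSV output uses `%.12g`, making round-trips
byte-stable and lossless to 12 significant digits.

## Known limitations

* The measure needs annotated gene orders and precomputed ortholog hits; it
  does not discover synteny blocks from raw sequence.
* With very few orthologs ($n = 2, 3$) the median runs over 3–4
  arrangements and is accordingly coarse.
* Synteny coverage sums aligned block lengths; without block coordinates,
  physically overlapping blocks cannot be merged and coverage is capped at
  1 rather than union-corrected.
* GenBank parsing covers the feature-table subset the pipeline needs (CDS
  and rRNA, simple and `complement()` locations, `join()` reduced to its
  span); exotic location operators are out of scope.
* Girvan–Newman recomputes exact edge betweenness after every removal —
  fine for a few hundred genomes, not for thousands.
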