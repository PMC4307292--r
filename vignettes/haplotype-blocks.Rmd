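---
title: "Diversity-based haplotype blocks and tagSNP selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity-based haplotype blocks and tagSNP selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapblockr)
```

## The model

The input is a phased, biallelic haplotype matrix: $m$ haplotype rows
(phased chromosome copies) over $n$ SNP columns, each cell the major
allele (0), the minor allele (1), or missing. A *block* is a contiguous
marker interval $[j, k]$, and a *segmentation* is a set of non-overlapping
blocks; it is *full* when it covers every column.

Within an interval, two rows are **compatible** when their alleles agree at
every locus where both are observed. A row is **ambiguous** when it is
compatible with two rows that are themselves incompatible — with complete
data this cannot happen, so ambiguity is purely a consequence of missing
genotypes. Among the unambiguous rows, a row is **common** when at least
one other unambiguous row is compatible with it, and **singleton**
otherwise. Writing $U = C + S$ for the unambiguous, common and singleton
counts, the diversity of the interval is

$$\delta = 1 - C/U = S/U,$$

the fraction of unambiguous haplotypes that appear only once. Equivalently
$1 - \delta$ is the *coverage* of the interval by common haplotypes, and
the conventional criterion that at least $\alpha = 80\%$ of haplotypes be
represented more than once is exactly the feasibility condition
$\delta \le D$ with $D = 1 - \alpha = 0.2$. With complete data $\delta$ is
monotone under interval nesting: widening a block can only increase its
diversity. With missing data monotonicity can fail, and the implementation
treats it as an optimisation hint, never as a correctness assumption
(every candidate block the sweep reports is verified against the limit
directly).

A compact worked example: the eight rows formed by six distinct five-locus
strings plus two duplicates give $U = 8$ unambiguous rows of which the two
duplicated classes ($C = 4$ rows) are common, so
$\delta = 1 - 4/8 = 0.5$.

## Block partitioning

Feasible blocks are those with $\delta \le D$ and width at most $W$ SNPs.
Preprocessing computes the **good-partner table**: for each locus $i$,
$L[i]$ is the leftmost start such that $[L[i], i]$ is feasible ($NA$ when
even the single column fails the limit, which can happen for strict $D$).
With complete data a two-pointer sweep fills the table in one pass; with
missing data each window is scanned and verified explicitly.

Two objectives are solved by dynamic programming over this table:

* **longest-k**: maximise the total number of SNPs covered by at most $k$
  disjoint feasible blocks, via
  $f(k, j) = \max\{f(k, j-1),\; f(k-1, L[j]-1) + j - L[j] + 1\}$.
  Only the widest feasible block ending at $j$ is considered: under a
  monotone diversity function a narrower last block never covers more.
  Traceback prefers the skip branch on ties, which deterministically
  yields the solution with the fewest blocks.
* **min-blocks** (the pipeline default): cover *all* loci with the fewest
  feasible blocks. Here the widest-last-block shortcut is not valid —
  full coverage changes the trade-off — so every feasible start in
  $[L[j], j]$ is considered for the final block, with per-start
  feasibility looked up from the score table rather than assumed from
  monotonicity. Ties are broken toward the widest last block.

Both DPs are linear-time in $n$ (times $k$ or $W$) once interval scores
are available; scoring dominates, at roughly $O(n \cdot W \cdot m)$ for
complete data via successive partition refinement, and an incremental
pairwise-compatibility update when data are missing (compatibility only
shrinks as an interval grows, so pairs are removed monotonically).

## TagSNP selection

Within a block, the common haplotypes fall into compatibility classes
(for complete data: identical substrings with multiplicity at least two).
A tagSNP set is a locus subset whose joint allele patterns distinguish
every pair of classes; the package returns the lexicographically first
set of minimum size $\gamma$. The search enumerates
$\gamma$-combinations of the block's loci in lexicographic order starting
from the information-theoretic floor $\gamma_0 = \lceil \log_2 k \rceil$
for $k$ classes — sets below the floor cannot work, and starting there
changes nothing but the constant factor. Classes are summarised by their
consensus string (per-locus majority over the class, missing ignored);
for complete data this is the class's shared string. Two consensus
patterns count as distinguished only where both are observed, so with
heavily missing data a block can have no distinguishing set at all, which
is reported as an error rather than an arbitrary choice. `max_gamma`
(default `min(20, width)`) bounds the search; past it the enumeration
aborts with a clear error instead of running indefinitely.

## Chunked map/reduce scoring

Interval scoring decomposes by block start index: the start space
$1..n$ is split into contiguous ranges balanced to within one index, one
per worker, and each worker emits $\langle(\mathrm{start},
\mathrm{end}), \delta\rangle$ for every interval starting in its range
with width at most $W$. The merged stream is consumed by a single
sequential reduce that rebuilds the good-partner table and runs the DP.
Because each worker is pure and the interval space is partitioned
exactly, the output is identical — byte for byte in the written reports —
for every pool size, which the test suite asserts directly. The pool is
an in-process `parallel::mclapply` fork pool; a failed chunk is retried
once on the parent before the run errors out. Scores are merged in
memory: at the scales this package targets (up to a few tens of
thousands of loci at $W \le 500$) the dense $n \times W$ score table is
at most a few hundred MB, so no on-disk spill path is provided.

## The synthetic generator

`simulate_haplotypes()` emulates the structure the method is built for:
planted block boundaries; a few founder haplotypes per block copied by
each row with skewed frequencies, drawn independently per block; whole-row
singleton noise within a block; and uniform random missingness applied
last. Defaults are three founders at frequencies $(0.6, 0.3, 0.1)$ —
so the top founders cover well over 80% of rows and the $\alpha = 80\%$
criterion is informative — with 5% singleton noise and 2% missing cells.
The generator is deterministic given a seed, and returns the planted
truth (boundaries, founders, assignments, noised rows) for recovery
scoring.

What it does **not** emulate: linkage-disequilibrium decay within blocks,
recombination hot-spot placement, allele-frequency spectra from
population genetics, or correlated missingness. Tests that pass on this
generator therefore validate the combinatorial machinery — scoring,
optimality, equivalence of the parallel decomposition — not the biological
fidelity of any particular block call on real data.

## Numerical and design choices

* $\delta$ with $U = 0$ (every row ambiguous) is defined as 0 rather than
  undefined, so fully ambiguous intervals cannot poison feasibility with a
  division error; the classification counts still expose the situation.
* Major/minor coding when reading nucleotide data is per-column by
  observed frequency; frequency ties code the lexicographically smaller
  nucleotide as 0. This makes the coding deterministic where the
  convention is otherwise underdetermined.
* The common-SNP (MAF) filter exists but defaults to off, because any
  cutoff is a study choice that should be explicit in the run manifest.
* 1-based inclusive intervals everywhere in the API; 0-based half-open
  only at the BED boundary.
* Feasibility of reported blocks is re-verified post hoc
  (`verify_segmentation()`) independently of the sweep that found them.
* Unphased VCF genotypes are rejected, not phased or imputed.
* The "max blocks" summary figure is defined here, explicitly, as the
  largest number of blocks intersecting any 1 Mb window (only when
  base-pair positions are available); other definitions in circulation
  are not discoverable from output tables alone.

## Problem sizes used by the test-suite experiments

Optimality is proven by brute-force enumeration, which is only tractable
at small sizes: the DP-versus-enumeration experiments run hundreds of
instances at $m \le 12$, $n \le 20$ with $k \in \{1,2,3\}$ and
$D \in \{0, 0.2, 0.5\}$; tagSNP minimality is checked against exhaustive
subset search on blocks of up to 12 loci and 8 classes. Parallel
equivalence is exercised at chromosome-arm-like scale — up to
$120 \times 5000$ with $W \in \{300, 500\}$ and pools of 1, 2, 4 and 8
workers — where exhaustive verification is impossible but byte-identity
across pool sizes is exact. These sizes are the package's choice of
where enumeration remains an oracle and where scale is demonstrated.

## Known limitations

* **Planted boundaries need not be diversity boundaries.** With three
  founders per block at frequencies $(0.6, 0.3, 0.1)$ and $m = 30$ rows,
  the concatenation of two adjacent planted blocks has nine
  founder-pair haplotypes whose largest classes still cover roughly 83%
  of rows; its measured diversity (typically $\approx 0.17$) stays below
  $D = 0.2$. The minimum-block objective then merges planted blocks —
  correctly, by its own definition — and boundary recovery against the
  planted truth sits near 30–35% rather than near 100%. Recovering such
  boundaries requires either rarer founders, smaller samples, a stricter
  $D$, or a width cap near the planted width; the package reports the
  recovery rate honestly instead of tuning the experiment to flatter it.
* Diversity scoring is quadratic in $m$ per interval extension under
  missing data; matrices with thousands of rows and heavy missingness
  will be slow.
* The dense score table keeps $n \times W$ doubles in memory; for a full
  chromosome at $n \approx 10^5$ and $W = 500$ plan for several hundred
  MB or score in chunks via `map_score_chunk()` yourself.
* TagSNP selection is exact and therefore exponential in the worst case;
  `max_gamma` exists to fail fast rather than hang.
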