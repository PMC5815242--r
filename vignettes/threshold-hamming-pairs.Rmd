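---
title: "Threshold Hamming-distance pairs for typing profiles: method and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold Hamming-distance pairs for typing profiles: method and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hammingpairs)
```

## The problem

Sequence-based typing abstracts a bacterial genome to an *allelic profile*: a
vector of categorical allele identifiers, one per locus (seven loci for
classical MLST, hundreds to thousands for cgMLST/wgMLST). Distance-based
phylogenetic analyses of such data start from pairwise Hamming distances
$H(u, v)$ — the number of loci at which two profiles differ — and computing
the full $d \times d$ matrix for $d$ profiles of length $m$ costs
$\Theta(m d^2)$, which is prohibitive for modern typing databases.

Methods built on the clonal-expansion model, goeBURST foremost, never need
the full matrix: they only consume the *truncated* distance matrix
$\{(u, v) : H(u, v) \le k\}$ for a threshold $k$. This package computes that
truncated matrix in average-case $O(md)$ time on uniform data, and applies it
to goeBURST forest inference and to $k$-closest queries against an indexed
profile database.

## The algorithm

**Indexing.** The $d$ profiles are concatenated row-major into one integer
string $s$ of length $n = md$, with no separator symbols. We build its suffix
array (prefix-doubling construction), the LCP array (Kasai's algorithm), and
a sparse-table RMQ over the LCP array, so the longest common extension (LCE)
of any two suffixes is one range-minimum query after $O(n \log n)$
preprocessing. One index serves all thresholds and both use cases.

**Pigeonhole filtering.** For a threshold $k$ with $0 < k < m$, profiles are
conceptually split into aligned, non-overlapping blocks of length
$\mathcal{L} = \lfloor m/(k+1) \rfloor$. Two profiles within distance $k$
have at most $k$ mismatching positions, which can spoil at most $k$ of the
$k + 1$ leading blocks — so they must agree verbatim on at least one aligned
block. Candidate enumeration therefore only considers pairs sharing an
aligned block, via either of two strategies:

* **LCP clusters** (`strategy = "lcp"`): one scan of the LCP array
  maintaining maximal runs of suffix-array positions whose adjacent LCP is at
  least $\mathcal{L}$; all members of a run share a length-$\mathcal{L}$
  prefix. Aligned members are grouped by block ordinal and all unordered
  profile pairs per group are emitted.
* **SA binary search** (`strategy = "binary"`): for each block of each
  profile, two binary searches locate the suffix-array interval of suffixes
  prefixed by that block; aligned matches at the same ordinal are emitted.

Both streams are supersets of the true answer and are proven equal as
*distinct pair sets* by a property test. Candidates are deduplicated on the
unordered pair before verification, since a close pair can share several
blocks and verification dominates the per-candidate cost.

**Verification.** Each surviving pair is verified by kangaroo jumps: from the
current offset, jump over the LCE of the two suffixes (clipped at the profile
end, see below), count one mismatch, advance one position, and stop once
$k + 1$ mismatches are reached. The cap makes each verification $O(k)$; a
result of at most $k$ is the exact distance, and running to $k + 1$ (one LCE
probe past the $k$-th mismatch) cleanly separates $H = k$, which is reported,
from $H > k$, which is not.

**Admissibility.** On profiles whose symbols are i.i.d. uniform over an
alphabet of size $\sigma$, the expected number of verified candidates is at
most $\mathcal{B} d / \sigma^{\mathcal{L}}$ with
$\mathcal{B} = d \lfloor m/\mathcal{L} \rfloor$ total blocks, and the whole
pipeline runs in $O(md)$ expected time whenever

$$k < \frac{(m - k - 1)\,\log \sigma}{\log md}.$$

`maxAdmissibleK(m, d, sigma)` returns the largest such integer $k$ (the
inequality is a ratio of logarithms, hence base-invariant);
`simplifiedKBound(m)` is the closed form $\lfloor m / (2 \log_2 m) \rfloor$
for the square binary regime $d = m$, $\sigma = 2$ — base 2 is the natural
reading there since it evaluates to 170 at $m = 4096$, and the closed form
majorizes the exact scan (property-tested for $m$ up to $2^{16}$).

## Design choices

**No separators in the concatenation.** The complexity accounting uses
$n = md$ exactly, so nothing is inserted between profiles. The price is that
suffix comparisons and LCEs can run across a profile boundary; every
downstream consumer clips extensions at offset $m$. Block matches cannot
cross a boundary because an accepted aligned start at in-profile offset
$\ell$ must satisfy $\ell + \mathcal{L} \le m$ — the same guard that excludes
a trailing aligned start whose block would overrun the profile. Without the
guard, a "block" straddling two profiles could be matched; with it, the block
ordinals range over all $\lfloor m/\mathcal{L} \rfloor \ge k + 1$ in-profile
blocks, a superset of the $k + 1$ leading blocks that the pigeonhole argument
needs, so completeness is preserved and the filter is only ever stricter
per ordinal.

**Suffix array construction.** Prefix doubling with comparison sort
($O(n \log^2 n)$) rather than a linear-time construction: the guarantee that
matters downstream is correctness of SA/LCP (checked exactly against a
brute-force suffix sort on a thousand random strings), and at the problem
sizes this package targets the construction is a small fraction of total
time. The RMQ is a sparse table — constant-time queries after linearithmic
preprocessing.

**Global token encoding.** Allele tokens are mapped to integers by global
first-occurrence order across the whole table, not per locus. Hamming
distance compares aligned positions for equality only, so any injective
per-table encoding preserves every distance (property-tested against raw
token comparison); per-locus disjoint alphabets would only sharpen the
filter and are deliberately not used. Missing-allele codes (`"0"`, `"-"`)
are ordinary categories: two profiles both missing a locus match there. A
query profile's unseen alleles are encoded as fresh symbols beyond the
database alphabet, which can match nothing — the natural semantics for a
novel allele.

**goeBURST total order.** Links are sorted by: distance ascending; then SLV
count of the endpoints (max, then min) descending; then DLV and TLV
likewise; then isolate frequency (max, then min) descending; then profile id
rank (max, then min) ascending. The published goeBURST description fixes the
criteria list (distance, SLVs, DLVs, TLVs, frequency, identifier) but not
every direction or the endpoint aggregation; the comparator above is this
package's frozen specification of those open details. Because the trailing
id-rank pair is unique per unordered edge the order is strict, so the Kruskal
construction is deterministic and the forest unique. Distance-0 links
(duplicate profiles) are valid and joined first. SLV/DLV/TLV counts are
derived from the truncated matrix at the user's $k$; when $k < 3$ the
unavailable counts are zero by construction, and `lvK = max(k, 3)` requests a
second (cheap, same index) enumeration at the larger threshold instead.

**Query path.** Database querying uses suffix-array binary search per block
of the query — $O(m \log n)$ search plus $O(m)$ naive verification per
candidate row (the query itself is not indexed, so LCE against it is not
available). The index is immutable per build; adding profiles means
rebuilding, which `writeIndex`/`readIndex` make cheap to amortize.

## The synthetic generator

`randomProfiles(d, m, sigma, seed)` draws i.i.d. uniform symbols — exactly
the statistical model of the average-case analysis — and
`plantPair(profiles, i, j, h, seed)` copies row $i$ into row $j$ and mutates
exactly $h$ distinct positions to different symbols, giving ground-truth
pairs for completeness tests. Generation is deterministic per seed and
isolated from the caller's RNG state.

What the generator does *not* emulate matters for interpreting the tests:
real typing databases are strongly clustered (clonal complexes), with locus
alleles far from uniform and far from independent. On such data the filter
still returns the exact truncated matrix — correctness never depends on the
distribution — but candidate counts exceed the uniform-model expectation,
and thresholds well below `maxAdmissibleK` can already favor the naive
strategy. Passing the uniform-model scaling tests therefore validates the
average-case analysis, not wall-clock superiority on any particular real
dataset; no heuristic strategy chooser is implemented, only the explicit
`strategy` flag.

## Verification strategy and problem sizes

The test suite checks, among others: exact equality of SA/LCP with a
brute-force suffix sort (1000 random strings, $n \le 200$, $\sigma \in \{2,
4, 26\}$) and of LCE with direct scans ($10^4$ queries); equality of all
three `closestPairs` strategies with an independent all-pairs R oracle on
200 random instances ($d \le 50$, $m \le 64$, $\sigma \in \{2, 4, 20\}$);
completeness on 100 planted pairs at $h = k$; `hammingCapped =
min(k, H)` on $10^4$ random row pairs; forest acyclicity, weight-equality
with a generic MSF oracle (igraph), and component nesting across thresholds
on random instances; and query equivalence with a linear scan on 500 draws.
The uniform-model scaling check runs $m \in \{256, 512\}$,
$d \in \{250, 500, 1000, 2000\}$ at $k = \lfloor m/(2\log_2 m)\rfloor$ over
ten seeds and compares verified-candidate counts with the
$\mathcal{B} d / \sigma^{\mathcal{L}}$ expectation; these sizes keep the
whole suite in the minutes range on one CPU while leaving the asymptotic
regime clearly visible.

One caveat the scaling data make explicit: the *count* of block-sharing
pairs on uniform data is itself proportional to
$\lfloor m/\mathcal{L}\rfloor \binom{d}{2} / \sigma^{\mathcal{L}}$ — tiny,
but quadratic in $d$, with a doubling ratio near 4. It is the total running
time, dominated by the $O(md)$ indexing term, that grows linearly in $d$
under the admissibility condition; a sub-quadratic trend should not be
expected of the candidate count alone, and the suite's measurements bear
this out.

## Limitations

* Distances are observed $p$-distances; no evolutionary-model correction is
  applied (most corrections are monotone in $H$, so threshold semantics
  carry over, but corrected values are out of scope).
* The index is static; no dynamic insertion.
* The hybrid naive/indexed strategy chooser suggested by the clustered
  behavior of real data is not implemented.
* `ProfileSet` requires complete, equal-length profiles; locus absence must
  be encoded as a token, not as missing cells.
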