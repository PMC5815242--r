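# hammingpairs

Fast truncated Hamming-distance computation for microbial typing profiles,
with goeBURST forest inference and database querying built on top.

## The problem

MLST, cgMLST and wgMLST abstract bacterial genomes into **allelic
profiles**: equal-length vectors of categorical allele identifiers, one per
locus. Distance-based analyses of typing databases start from the pairwise
Hamming distance H(u, v) — the number of loci at which two profiles differ —
and the full d × d matrix costs Θ(m d²) for d profiles of length m, which is
painful once databases hold thousands of profiles with thousands of loci.

Clonal-complex methods such as goeBURST only ever need the **truncated
distance matrix**: the pairs with H(u, v) ≤ k. `hammingpairs` computes
exactly that set in average-case O(m d) time on uniform data:

1. concatenate all profiles into one integer string and index it with a
   suffix array, LCP array and constant-time RMQ structure;
2. filter candidate pairs by the pigeonhole principle — split profiles into
   aligned blocks of length L = ⌊m/(k+1)⌋; two profiles within distance k
   must share at least one aligned block verbatim — using either one scan of
   the LCP array (`"lcp"`) or per-block binary search in the suffix array
   (`"binary"`);
3. verify each deduplicated candidate in O(k) by "kangaroo" jumps: repeated
   longest-common-extension queries, one mismatch counted per jump, stopping
   past k mismatches.

The average-case guarantee holds whenever
k < (m − k − 1)·log σ / log(md) (`maxAdmissibleK()`); in the square binary
regime d = m, σ = 2 the closed form ⌊m/(2 log₂ m)⌋ (`simplifiedKBound()`)
bounds it from above — 170 at m = 4096.

Use cases shipped on top of the truncated matrix:

* **goeBURST minimum spanning forest** (`goeburstForest()`): Kruskal's
  greedy construction over the threshold graph under the goeBURST total
  order on links (distance, then SLV/DLV/TLV counts, isolate frequency,
  profile id); components are clonal complexes.
* **Database queries** (`queryProfile()`, `classifyProfile()`): all indexed
  profiles within distance k of a new profile, and closest-match
  classification with a `"new"` sentinel.
* **Synthetic instances** (`randomProfiles()`, `plantPair()`): uniform
  i.i.d. profiles — the model of the average-case analysis — with optional
  planted pairs at an exact distance.

## Worked example

```r
library(hammingpairs)

# 500 uniform binary profiles with 64 loci, plus two planted close pairs
ps <- randomProfiles(d = 500, m = 64, sigma = 2, seed = 42)
ps <- plantPair(ps, 10, 20, h = 2, seed = 43)
ps <- plantPair(ps, 10, 30, h = 1, seed = 44)

td <- closestPairs(ps, k = 3)
td
#> TruncatedDistance: 3 pairs with H <= 3 (22 candidates, 17 verified)
pairsTable(td)
#>    i  j h
#> 1 10 20 2
#> 2 10 30 1
#> 3 20 30 3
```

Out of the 124,750 possible pairs, the block filter enumerated 22 candidate
emissions (17 distinct pairs verified) and found exactly the three pairs
within distance 3: the planted ones, plus rows 20 and 30 which are close to
each other through their common template row 10.

```r
f <- goeburstForest(ps, k = 3)
forestEdges(f)
#>    i  j h
#> 1 10 30 1
#> 2 10 20 2   # edges in acceptance order: distance 1 before distance 2
```

The forest links the trio with two edges (the distance-3 edge would close a
cycle and is rejected), leaving 498 components: the 497 singletons plus this
clonal complex.

```r
idx <- buildConcatIndex(ps)
u <- alleleMatrix(ps)[20, ]; u[1:2] <- 1L - u[1:2]   # a 2-mutation variant
queryProfile(idx, ps, u, k = 4)
#>   row  id h
#> 1  20 P20 2
#> 2  10 P10 4
```

A command-line interface wrapping the same functions lives at
`inst/scripts/profilepairs.R`:

```sh
Rscript inst/scripts/profilepairs.R synth --d 500 --m 64 --sigma 2 \
    --seed 42 --output profiles.tsv
Rscript inst/scripts/profilepairs.R pairs --input profiles.tsv --k 3 \
    --strategy lcp --output pairs.tsv
Rscript inst/scripts/profilepairs.R goeburst --input profiles.tsv --k 3 \
    --output forest.tsv
```

Profile tables are plain TSV (id column, then one column per locus), the
standard layout of typing databases.

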