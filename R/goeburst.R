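#' Locus-variant counts per profile
#'
#' From a truncated distance set, counts for every profile its single,
#' double and triple locus variants (SLV/DLV/TLV): the number of other
#' profiles at Hamming distance exactly 1, 2 and 3. Under the goeBURST
#' model a founder genotype diversifies first into SLVs, then DLVs and
#' TLVs, so profiles with many close variants are preferred as link
#' endpoints when distances tie. Counts at distances above the k the pair
#' set was computed at are zero by construction (compute the pair set at
#' \code{max(k, 3)} for full counts).
#'
#' @param pairs a \linkS4class{TruncatedDistance}.
#' @param d number of profiles.
#' @param freq integer vector of isolate frequencies (default all 1).
#' @return data.frame with columns \code{slv}, \code{dlv}, \code{tlv},
#'   \code{freq}, \code{idRank} (input order, the final tie-break).
#' @export
lvCounts <- function(pairs, d, freq = rep(1L, d)) {
  p <- pairsTable(pairs)
  count_at <- function(h) {
    idx <- c(p$i[p$h == h], p$j[p$h == h])
    tabulate(idx, nbins = d)
  }
  data.frame(slv = count_at(1L), dlv = count_at(2L), tlv = count_at(3L),
             freq = as.integer(freq), idRank = seq_len(d))
}

# lexicographic sort keys of the goeBURST total order on links; lower key
# row = earlier link. Columns: distance asc; endpoint SLV (max then min)
# desc; DLV, TLV likewise; frequency (max then min) desc; id rank (max then
# min) asc. The trailing id-rank pair is unique per unordered edge, so the
# order is strict.
edgeKeys <- function(i, j, h, lv) {
  cbind(h,
        -pmax(lv$slv[i], lv$slv[j]), -pmin(lv$slv[i], lv$slv[j]),
        -pmax(lv$dlv[i], lv$dlv[j]), -pmin(lv$dlv[i], lv$dlv[j]),
        -pmax(lv$tlv[i], lv$tlv[j]), -pmin(lv$tlv[i], lv$tlv[j]),
        -pmax(lv$freq[i], lv$freq[j]), -pmin(lv$freq[i], lv$freq[j]),
        pmax(lv$idRank[i], lv$idRank[j]), pmin(lv$idRank[i], lv$idRank[j]))
}

#' goeBURST total order on links
#'
#' Strict comparator deciding which of two candidate links is joined first:
#' smaller Hamming distance first; then higher endpoint SLV counts (max,
#' then min endpoint), then DLV, then TLV; then higher isolate frequency;
#' finally lower profile id rank. Pairs at distance delta are always joined
#' before pairs at distance delta + 1.
#'
#' @param e1,e2 edges as length-3 vectors or 1-row data.frames
#'   \code{(i, j, h)} with 1-based endpoint rows.
#' @param lv locus-variant table from \code{\link{lvCounts}}.
#' @return logical: does \code{e1} strictly precede \code{e2}?
#' @export
edgeLess <- function(e1, e2, lv) {
  e1 <- as.integer(unlist(e1)[1:3]); e2 <- as.integer(unlist(e2)[1:3])
  k1 <- edgeKeys(e1[1], e1[2], e1[3], lv)
  k2 <- edgeKeys(e2[1], e2[2], e2[3], lv)
  diffs <- which(k1 != k2)
  if (!length(diffs)) return(FALSE)
  k1[diffs[1]] < k2[diffs[1]]
}

#' goeBURST minimum spanning forest of the threshold graph
#'
#' Builds the graph whose vertices are the profiles and whose edges are all
#' pairs at Hamming distance at most k, then grows a spanning forest
#' greedily: starting from singleton trees, links are considered in the
#' goeBURST total order (\code{\link{edgeLess}}) and accepted whenever they
#' join two different trees, exactly as in Kruskal's algorithm on a graphic
#' matroid. The strict total order makes the forest unique; its connected
#' components are the clonal complexes at threshold k. Duplicate profiles
#' (distance 0) are valid links and are joined first.
#'
#' @param profiles a \linkS4class{ProfileSet} (isolate frequencies feed the
#'   tie-break order).
#' @param k maximum Hamming distance, 0 < k < m.
#' @param lvK threshold used for the SLV/DLV/TLV counts; defaults to k.
#'   Pass \code{max(k, 3)} to obtain full tie-break counts when k < 3 (the
#'   index is simply queried a second time at the larger threshold).
#' @param strategy pair-enumeration strategy, see \code{\link{closestPairs}}.
#' @return a \linkS4class{GoeBurstForest}.
#' @examples
#' ps <- ProfileSet(rbind(c(0L,0L,0L), c(0L,0L,1L), c(0L,1L,1L)))
#' forestEdges(goeburstForest(ps, k = 2))
#' @export
goeburstForest <- function(profiles, k, lvK = k,
                           strategy = c("lcp", "binary", "naive")) {
  strategy <- match.arg(strategy)
  d <- profileCount(profiles)
  idx <- if (strategy == "naive") NULL else buildConcatIndex(profiles)
  td <- closestPairs(profiles, k, strategy, index = idx)
  lvK <- as.integer(lvK)
  lvSource <- if (lvK > td@k) {
    closestPairs(profiles, lvK, strategy, index = idx)
  } else {
    td
  }
  lv <- lvCounts(lvSource, d, isolateFreq(profiles))
  p <- pairsTable(td)
  uf <- seq_len(d)
  find <- function(x) {
    while (uf[x] != x) {
      uf[x] <<- uf[uf[x]]
      x <- uf[x]
    }
    x
  }
  acc_i <- integer(0); acc_j <- integer(0); acc_h <- integer(0)
  if (nrow(p)) {
    keys <- edgeKeys(p$i, p$j, p$h, lv)
    ord <- do.call(order, c(lapply(seq_len(ncol(keys)), function(c) keys[, c]),
                            list(method = "radix")))
    for (e in ord) {
      ri <- find(p$i[e]); rj <- find(p$j[e])
      if (ri != rj) {
        uf[ri] <- rj
        acc_i <- c(acc_i, p$i[e]); acc_j <- c(acc_j, p$j[e])
        acc_h <- c(acc_h, p$h[e])
      }
    }
  }
  roots <- vapply(seq_len(d), find, integer(1))
  comp <- match(roots, unique(roots))
  new("GoeBurstForest",
      edges = data.frame(i = acc_i, j = acc_j, h = acc_h),
      components = comp, ids = profileIds(profiles), k = td@k)
}
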