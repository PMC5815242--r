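#' Pigeonhole block scheme for a Hamming threshold
#'
#' For profiles of length m and a maximum Hamming distance k (0 < k < m),
#' blocks have length L = floor(m / (k + 1)). Any two profiles within
#' distance k must agree verbatim on at least one of the k + 1 leading
#' aligned blocks; the filters use all floor(m / L) >= k + 1 aligned
#' in-profile blocks.
#'
#' @param m profile length.
#' @param k maximum Hamming distance, 0 < k < m.
#' @param d profile count used for the total block count B (default 1).
#' @return a \linkS4class{BlockScheme}.
#' @examples
#' blockScheme(4096, 170)   # L = 23
#' @export
blockScheme <- function(m, k, d = 1L) {
  m <- as.integer(m); k <- as.integer(k)
  if (is.na(k) || k <= 0L || k >= m)
    stopParameter("threshold must satisfy 0 < k < m (got k = %d, m = %d)",
                  k, m)
  L <- m %/% (k + 1L)
  bpp <- m %/% L
  new("BlockScheme", k = k, L = L, blocksPerProfile = bpp,
      B = as.numeric(d) * bpp, m = m)
}

#' Capped Hamming distance between two indexed profiles
#'
#' Kangaroo verification: starting at offset 0, repeatedly jump over the
#' longest common extension of the two suffixes (clipped at the profile
#' end), count one mismatch, and advance; stops as soon as the count
#' reaches k. Returns min(k, H), so a return value below k is the exact
#' distance; each call costs O(k) RMQs.
#'
#' @param index a \linkS4class{ConcatIndex}.
#' @param pi,pj 1-based profile row indices, \code{pi != pj}.
#' @param k cap.
#' @return integer, \code{min(k, H(pi, pj))}.
#' @export
hammingCapped <- function(index, pi, pj, k) {
  d <- index@d
  pi <- as.integer(pi); pj <- as.integer(pj)
  if (pi < 1L || pj < 1L || pi > d || pj > d)
    stopBounds("profile rows must lie in [1, %d]", d)
  if (pi == pj) stopBounds("rows must be distinct")
  cpp_hd_capped(index@lcp, index@rmq, index@isa, length(index@s),
                index@m, pi - 1L, pj - 1L, as.integer(k))
}

#' Enumerate candidate pairs sharing an aligned block
#'
#' Two interchangeable strategies over the same index. \code{"lcp"} scans
#' the LCP array once, maintaining maximal runs of suffix-array positions
#' whose adjacent LCP values are at least L; within a run it groups aligned
#' suffix starts by block ordinal and emits all unordered profile pairs per
#' group. \code{"binary"} instead binary-searches the suffix array for the
#' interval of suffixes prefixed by each block of each profile and emits
#' the aligned matches. Both are complete: every pair within distance k
#' shares at least one aligned block and is emitted for at least one
#' ordinal. The stream may contain duplicates (a close pair can share
#' several blocks); \code{\link{closestPairs}} deduplicates before
#' verification.
#'
#' @param index a \linkS4class{ConcatIndex}.
#' @param scheme a \linkS4class{BlockScheme} built for the same m.
#' @param strategy \code{"lcp"} or \code{"binary"}.
#' @return data.frame with 1-based columns \code{i}, \code{j} (i < j) and
#'   the 0-based block ordinal \code{t} of the shared block.
#' @export
candidatePairs <- function(index, scheme, strategy = c("lcp", "binary")) {
  strategy <- match.arg(strategy)
  if (scheme@m != index@m)
    stopInput("scheme (m = %d) does not match index (m = %d)",
              scheme@m, index@m)
  raw <- switch(strategy,
    lcp = cpp_candidates_lcp(index@sa, index@lcp, index@m, index@d,
                             scheme@L),
    binary = cpp_candidates_binary(index@s, index@sa, index@m, index@d,
                                   scheme@L)
  )
  data.frame(i = raw[, 1] + 1L, j = raw[, 2] + 1L, t = raw[, 3])
}

#' All profile pairs within Hamming distance k
#'
#' Computes the truncated distance matrix: the exact set of unordered pairs
#' (i, j), i < j, with H(i, j) <= k, together with their distances. The
#' indexed strategies (\code{"lcp"}, \code{"binary"}) enumerate candidates
#' through the pigeonhole block filter, deduplicate them on (i, j), and
#' verify each survivor by kangaroo jumps capped at k + 1 mismatches — one
#' LCE probe past the k-th mismatch distinguishes H = k from H > k.
#' \code{"naive"} compares all pairs positionwise with early exit and is
#' the exact oracle the indexed strategies are validated against.
#'
#' @param profiles a \linkS4class{ProfileSet}.
#' @param k maximum Hamming distance, 0 < k < m.
#' @param strategy \code{"lcp"} (default), \code{"binary"} or \code{"naive"}.
#' @param index optional prebuilt \linkS4class{ConcatIndex} for
#'   \code{profiles}, to amortize indexing across calls.
#' @return a \linkS4class{TruncatedDistance}.
#' @examples
#' ps <- ProfileSet(rbind(c(0L,1L,0L,1L), c(0L,1L,1L,1L), c(1L,1L,1L,1L)))
#' pairsTable(closestPairs(ps, k = 1))
#' @export
closestPairs <- function(profiles, k, strategy = c("lcp", "binary", "naive"),
                         index = NULL) {
  strategy <- match.arg(strategy)
  m <- profileLength(profiles)
  k <- as.integer(k)
  if (is.na(k) || k <= 0L || k >= m)
    stopParameter("threshold must satisfy 0 < k < m (got k = %d, m = %d)",
                  k, m)
  if (strategy == "naive") {
    res <- cpp_naive_pairs(alleleMatrix(profiles), k)
    npairs <- length(res$i)
    tot <- profileCount(profiles) * (profileCount(profiles) - 1) / 2
    return(new("TruncatedDistance",
               pairs = data.frame(i = res$i + 1L, j = res$j + 1L, h = res$h),
               k = k, ids = profileIds(profiles),
               nCandidates = as.integer(tot), nVerified = as.integer(tot)))
  }
  if (is.null(index)) index <- buildConcatIndex(profiles)
  scheme <- blockScheme(m, k, profileCount(profiles))
  cand <- candidatePairs(index, scheme, strategy)
  res <- cpp_verify_candidates(cand$i - 1L, cand$j - 1L, index@lcp,
                               index@rmq, index@isa, length(index@s),
                               m, index@d, k)
  ord <- order(res$i, res$j)
  new("TruncatedDistance",
      pairs = data.frame(i = res$i[ord] + 1L, j = res$j[ord] + 1L,
                         h = res$h[ord]),
      k = k, ids = profileIds(profiles),
      nCandidates = nrow(cand), nVerified = res$n_verified)
}
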