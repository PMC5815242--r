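#' Query an indexed profile database for all matches within distance k
#'
#' Finds every indexed profile within Hamming distance k of an external
#' profile u of the same length. Each aligned block of u is located in the
#' suffix array by binary search; matches occurring at the same block
#' ordinal inside an indexed profile become candidate rows, which are
#' deduplicated and verified by direct positionwise comparison against u in
#' O(m). The same pigeonhole argument as for pair enumeration makes the
#' filter complete: any indexed profile within distance k shares at least
#' one aligned block with u.
#'
#' @param index a \linkS4class{ConcatIndex} built from \code{profiles}.
#' @param profiles the indexed \linkS4class{ProfileSet}.
#' @param u integer vector of length m using the same encoding as
#'   \code{profiles} (see \code{\link{encodeProfile}}; unseen alleles get
#'   fresh symbols that can match nothing), or a character vector of raw
#'   tokens, encoded automatically.
#' @param k maximum Hamming distance, 0 < k < m.
#' @return data.frame with columns \code{row} (1-based indexed row),
#'   \code{id} and \code{h}, sorted by (distance, row); zero rows when
#'   nothing is within k.
#' @examples
#' ps <- ProfileSet(rbind(c(0L,1L,0L,1L), c(0L,1L,1L,1L), c(1L,1L,1L,1L)))
#' idx <- buildConcatIndex(ps)
#' queryProfile(idx, ps, c(0L,1L,0L,0L), k = 1)
#' @export
queryProfile <- function(index, profiles, u, k) {
  m <- profileLength(profiles)
  if (is.character(u)) u <- encodeProfile(profiles, u)
  u <- as.integer(u)
  if (length(u) != m)
    stopInput("query has %d loci, database has %d", length(u), m)
  k <- as.integer(k)
  if (is.na(k) || k <= 0L || k >= m)
    stopParameter("threshold must satisfy 0 < k < m (got k = %d, m = %d)",
                  k, m)
  scheme <- blockScheme(m, k, profileCount(profiles))
  res <- cpp_query(index@s, index@sa, alleleMatrix(profiles), u, k,
                   scheme@L)
  row <- res$row + 1L
  ord <- order(res$h, row)
  data.frame(row = row[ord], id = profileIds(profiles)[row[ord]],
             h = res$h[ord])
}

#' Classify a new profile against an indexed, labelled database
#'
#' Convenience wrapper over \code{\link{queryProfile}}: if at least one
#' indexed profile lies within distance k, the query inherits the label of
#' the closest match (ties broken by lower row index); otherwise the
#' sentinel \code{"new"} is returned, signalling that a new classification
#' should be assigned.
#'
#' @inheritParams queryProfile
#' @param labels character vector of per-row class labels, length d.
#' @return a single label, or \code{"new"}.
#' @export
classifyProfile <- function(index, profiles, u, k, labels) {
  if (length(labels) != profileCount(profiles))
    stopInput("need one label per indexed profile")
  hits <- queryProfile(index, profiles, u, k)
  if (!nrow(hits)) return("new")
  as.character(labels[hits$row[1]])  # sorted by (h, row): closest, lowest row
}
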