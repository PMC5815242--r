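#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib hammingpairs, .registration = TRUE
NULL

#' ProfileSet: a set of equal-length typing profiles over an integer alphabet
#'
#' Holds d allelic profiles (or other categorical sequences) of length m,
#' integer-encoded over the alphabet \{0, ..., sigma-1\}. The encoding maps
#' raw allele tokens to integers by global first-occurrence order, so
#' identical tokens at different loci share one symbol; Hamming distance only
#' tests positionwise equality, so this encoding preserves all distances.
#'
#' @slot ids character vector of d unique profile identifiers.
#' @slot profiles integer matrix, d rows (profiles) by m columns (loci),
#'   entries in \[0, sigma).
#' @slot sigma integer, alphabet size (number of distinct encoded tokens).
#' @slot freq integer vector of per-profile isolate frequencies (>= 1),
#'   used by the goeBURST tie-break order.
#' @slot encoding character vector of length sigma giving the raw token for
#'   each integer code (code q is \code{encoding[q + 1]}); may be empty for
#'   natively integer data.
#'
#' @export
setClass("ProfileSet",
  representation(
    ids = "character",
    profiles = "matrix",
    sigma = "integer",
    freq = "integer",
    encoding = "character"
  )
)

setValidity("ProfileSet", function(object) {
  p <- object@profiles
  if (!is.integer(p)) return("profiles must be an integer matrix")
  if (nrow(p) < 1L || ncol(p) < 1L) return("need d >= 1 and m >= 1")
  if (length(object@ids) != nrow(p)) return("ids length must equal row count")
  if (anyDuplicated(object@ids)) return("profile ids must be unique")
  if (anyNA(p)) return("profiles must not contain NA")
  if (min(p) < 0L || max(p) >= object@sigma)
    return("all entries must lie in [0, sigma)")
  if (length(object@freq) != nrow(p)) return("freq length must equal row count")
  if (any(object@freq < 1L)) return("all frequencies must be >= 1")
  if (length(object@encoding) &&
      length(object@encoding) != object@sigma)
    return("encoding must have length sigma (or 0)")
  TRUE
})

#' ConcatIndex: suffix array / LCP / RMQ index of concatenated profiles
#'
#' The d profiles are concatenated row-major into one integer string s of
#' length n = m * d, with no separator symbols. Suffix comparisons may
#' therefore run across profile boundaries; every consumer caps longest
#' common extensions at the profile end. Positions in the low-level API
#' (\code{\link{lce}}, \code{\link{alignedBlock}}) are 0-based, following
#' suffix-array convention.
#'
#' @slot s integer vector of length n: the concatenated string.
#' @slot sa suffix array, a 0-based permutation of \code{0:(n-1)} sorting all
#'   suffixes lexicographically (a suffix that is a proper prefix of another
#'   sorts first).
#' @slot lcp integer vector, \code{lcp[i + 1]} (i >= 1) is the longest common
#'   prefix length of the suffixes at SA ranks i-1 and i; rank-0 entry is 0.
#' @slot isa inverse suffix array (0-based ranks).
#' @slot rmq sparse table of range-minimum indices over the LCP array.
#' @slot m integer, profile length.
#' @slot d integer, profile count.
#'
#' @export
setClass("ConcatIndex",
  representation(
    s = "integer", sa = "integer", lcp = "integer", isa = "integer",
    rmq = "matrix", m = "integer", d = "integer"
  )
)

setValidity("ConcatIndex", function(object) {
  n <- length(object@s)
  if (n != object@m * object@d) return("length(s) must equal m * d")
  if (length(object@sa) != n || length(object@lcp) != n ||
      length(object@isa) != n) return("sa, lcp, isa must have length n")
  if (!all(sort(object@sa) == 0:(n - 1))) return("sa must be a permutation")
  if (!all(object@isa[object@sa + 1L] == 0:(n - 1)))
    return("isa must invert sa")
  TRUE
})

#' BlockScheme: the pigeonhole block partition for a threshold k
#'
#' Length-m profiles are split into non-overlapping aligned blocks of length
#' L = floor(m / (k + 1)). Two profiles within Hamming distance k must agree
#' verbatim on at least one aligned block (pigeonhole over the k+1 leading
#' blocks); the candidate filters use all floor(m / L) >= k + 1 aligned
#' in-profile blocks, a superset that preserves completeness.
#'
#' @slot k integer, maximum Hamming distance (0 < k < m).
#' @slot L integer, block length.
#' @slot blocksPerProfile integer, floor(m / L).
#' @slot B numeric, total block count d * floor(m / L).
#' @slot m integer, profile length.
#'
#' @export
setClass("BlockScheme",
  representation(k = "integer", L = "integer", blocksPerProfile = "integer",
                 B = "numeric", m = "integer")
)

setValidity("BlockScheme", function(object) {
  if (object@k <= 0L || object@k >= object@m) return("need 0 < k < m")
  if (object@L < 1L) return("block length must be >= 1")
  if (object@blocksPerProfile < object@k + 1L)
    return("must have at least k + 1 blocks per profile")
  if ((object@k + 1L) * object@L > object@m) return("(k+1) * L must be <= m")
  TRUE
})

#' TruncatedDistance: all profile pairs within Hamming distance k
#'
#' The truncated distance matrix: the set of unordered row pairs (i, j),
#' i < j, with their exact Hamming distance h <= k. Row indices are 1-based.
#' Enumeration statistics (raw candidate emissions before deduplication and
#' distinct pairs actually verified) are retained for diagnostics.
#'
#' @slot pairs data.frame with integer columns \code{i}, \code{j}, \code{h}.
#' @slot k integer threshold the set was computed at.
#' @slot ids character vector of all profile ids (length d), so pair tables
#'   can be written without the originating \linkS4class{ProfileSet}.
#' @slot nCandidates integer, candidate emissions before deduplication
#'   (equals the verified count for the naive strategy).
#' @slot nVerified integer, distinct pairs submitted to verification.
#'
#' @export
setClass("TruncatedDistance",
  representation(pairs = "data.frame", k = "integer", ids = "character",
                 nCandidates = "integer", nVerified = "integer")
)

setValidity("TruncatedDistance", function(object) {
  p <- object@pairs
  if (!all(c("i", "j", "h") %in% names(p)))
    return("pairs must have columns i, j, h")
  if (nrow(p)) {
    if (any(p$i >= p$j)) return("pairs must satisfy i < j")
    if (any(p$h > object@k) || any(p$h < 0L))
      return("all stored distances must lie in [0, k]")
    if (anyDuplicated(p[, c("i", "j")])) return("duplicate (i, j) pair")
  }
  TRUE
})

#' GoeBurstForest: goeBURST minimum spanning forest of the threshold graph
#'
#' Edges accepted by the Kruskal-style greedy construction over the
#' truncated distance graph, in acceptance order, together with the
#' union-find component labelling (clonal complexes). Row indices are
#' 1-based; component labels are 1..c in order of first appearance.
#'
#' @slot edges data.frame with integer columns \code{i}, \code{j}, \code{h},
#'   in acceptance (total) order.
#' @slot components integer vector of length d: component label per profile.
#' @slot ids character vector of profile ids.
#' @slot k integer threshold used.
#'
#' @export
setClass("GoeBurstForest",
  representation(edges = "data.frame", components = "integer",
                 ids = "character", k = "integer")
)

setValidity("GoeBurstForest", function(object) {
  d <- length(object@components)
  if (length(object@ids) != d) return("ids and components lengths differ")
  if (nrow(object@edges) != d - length(unique(object@components)))
    return("edge count must equal d - number of components")
  TRUE
})
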