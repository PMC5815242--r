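#' Build the suffix-array index of a concatenated ProfileSet
#'
#' Concatenates the d profiles row-major into one integer string s of length
#' n = m * d (no separators) and builds the suffix array (prefix-doubling
#' construction), the LCP array (Kasai's algorithm), the inverse suffix
#' array and a sparse-table RMQ over the LCP array giving constant-time
#' range minima after O(n log n) preprocessing. One index serves every
#' downstream step: candidate enumeration, kangaroo verification and
#' database querying, for any threshold k.
#'
#' @param profiles a \linkS4class{ProfileSet}.
#' @return a \linkS4class{ConcatIndex}.
#' @examples
#' ps <- ProfileSet(rbind(c(0L, 1L), c(1L, 0L)))
#' idx <- buildConcatIndex(ps)
#' suffixArray(idx)   # 0-based suffix start positions in sorted order
#' @export
buildConcatIndex <- function(profiles) {
  if (!is(profiles, "ProfileSet")) stopInput("profiles must be a ProfileSet")
  mat <- alleleMatrix(profiles)
  s <- as.integer(t(mat))
  sa <- cpp_build_sa(s)
  lcp <- cpp_build_lcp(s, sa)
  isa <- integer(length(s))
  isa[sa + 1L] <- seq_along(s) - 1L
  rmq <- cpp_build_rmq(lcp)
  new("ConcatIndex", s = s, sa = sa, lcp = lcp, isa = isa, rmq = rmq,
      m = ncol(mat), d = nrow(mat))
}

#' Longest common extension of two suffixes
#'
#' Length of the longest common prefix of the suffixes starting at 0-based
#' positions i and j of the concatenated string, answered as the minimum of
#' the LCP array over the open-left rank interval via one RMQ;
#' \code{lce(idx, i, i)} is \code{n - i}. Extensions may run across profile
#' boundaries — callers comparing profiles cap the result at the profile
#' end (as \code{\link{hammingCapped}} does).
#'
#' @param index a \linkS4class{ConcatIndex}.
#' @param i,j 0-based suffix start positions in \code{[0, n)}.
#' @return integer extension length.
#' @export
lce <- function(index, i, j) {
  n <- length(index@s)
  i <- as.integer(i); j <- as.integer(j)
  if (i < 0L || j < 0L || i >= n || j >= n)
    stopBounds("suffix positions must lie in [0, %d)", n)
  cpp_lce(index@lcp, index@rmq, index@isa, n, i, j)
}

#' Block ordinal of an aligned suffix position
#'
#' With l = i mod m the offset of position i inside its profile, returns the
#' block ordinal l / L when l is a multiple of the block length L and the
#' block fits inside the profile (l + L <= m), and -1 otherwise. The fit
#' guard excludes a trailing aligned start whose block would overrun the
#' profile end, so accepted block matches can never cross the separator-free
#' concatenation boundary.
#'
#' @param index a \linkS4class{ConcatIndex} (only m is used).
#' @param i 0-based position in \code{[0, n)}.
#' @param L block length, \code{1 <= L <= m}.
#' @return integer block ordinal, or -1 if not aligned.
#' @export
alignedBlock <- function(index, i, L) {
  n <- length(index@s)
  i <- as.integer(i); L <- as.integer(L)
  if (i < 0L || i >= n) stopBounds("position must lie in [0, %d)", n)
  if (L < 1L || L > index@m) stopParameter("need 1 <= L <= m")
  cpp_aligned(i, index@m, L)
}

#' Serialize / load a ConcatIndex
#'
#' Writes a versioned container holding the concatenated string, suffix
#' array, LCP array and dimensions; the RMQ sparse table is rebuilt on load.
#' Useful when one database index serves many queries or thresholds.
#'
#' @param index a \linkS4class{ConcatIndex}.
#' @param path file path.
#' @return \code{writeIndex}: invisibly, \code{path}; \code{readIndex}: a
#'   \linkS4class{ConcatIndex}.
#' @export
writeIndex <- function(index, path) {
  ok <- tryCatch({
    saveRDS(list(format = "hammingpairs-index", version = 1L,
                 s = index@s, sa = index@sa, lcp = index@lcp,
                 m = index@m, d = index@d),
            path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stopIO("cannot write index '%s'", path)
  invisible(path)
}

#' @rdname writeIndex
#' @export
readIndex <- function(path) {
  if (!file.exists(path)) stopIO("cannot read index '%s'", path)
  obj <- readRDS(path)
  if (!identical(obj$format, "hammingpairs-index"))
    stopFormat("'%s' is not a serialized index", path)
  isa <- integer(length(obj$s))
  isa[obj$sa + 1L] <- seq_along(obj$s) - 1L
  new("ConcatIndex", s = obj$s, sa = obj$sa, lcp = obj$lcp, isa = isa,
      rmq = cpp_build_rmq(obj$lcp), m = obj$m, d = obj$d)
}
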