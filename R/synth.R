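#' Uniform i.i.d. synthetic profiles
#'
#' Draws d profiles of length m whose symbols are independent and uniform
#' over an alphabet of size sigma — the statistical model under which the
#' average-case admissibility bound (\code{\link{maxAdmissibleK}}) holds.
#' Generation is deterministic per seed (a local RNG state is used, so the
#' caller's RNG is untouched).
#'
#' @param d profile count, >= 1.
#' @param m profile length, >= 1.
#' @param sigma alphabet size, >= 2.
#' @param seed integer seed.
#' @return a \linkS4class{ProfileSet} with ids \code{"P1"..."Pd"}.
#' @examples
#' ps <- randomProfiles(5, 8, 2, seed = 1)
#' alleleMatrix(ps)
#' @export
randomProfiles <- function(d, m, sigma, seed) {
  d <- as.integer(d); m <- as.integer(m); sigma <- as.integer(sigma)
  if (d < 1L || m < 1L) stopParameter("need d >= 1 and m >= 1")
  if (sigma < 2L) stopParameter("alphabet size must be > 1 (got %d)", sigma)
  mat <- withLocalSeed(seed, {
    matrix(sample.int(sigma, d * m, replace = TRUE) - 1L,
           nrow = d, ncol = m, byrow = TRUE)
  })
  ProfileSet(mat, sigma = sigma)
}

# evaluate expr under a seeded, isolated RNG state
withLocalSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Plant a pair at an exact Hamming distance
#'
#' Overwrites row j with a copy of row i mutated at exactly h uniformly
#' chosen positions, each to a different symbol, so that H(i, j) = h
#' exactly. Used to validate the completeness of the pigeonhole filter on
#' pairs known to be within threshold.
#'
#' @param profiles a \linkS4class{ProfileSet} with sigma >= 2.
#' @param i,j distinct 1-based rows.
#' @param h exact target distance, 0 <= h <= m.
#' @param seed integer seed for the mutated positions and symbols.
#' @return the modified \linkS4class{ProfileSet}.
#' @export
plantPair <- function(profiles, i, j, h, seed) {
  m <- profileLength(profiles)
  h <- as.integer(h); i <- as.integer(i); j <- as.integer(j)
  if (h < 0L || h > m) stopParameter("need 0 <= h <= m (got h = %d)", h)
  if (i == j) stopParameter("rows must be distinct")
  mat <- alleleMatrix(profiles)
  row <- mat[i, ]
  withLocalSeed(seed, {
    pos <- sample.int(m, h)
    for (p in pos) {
      row[p] <- (row[p] + sample.int(profiles@sigma - 1L, 1L)) %% profiles@sigma
    }
  })
  mat[j, ] <- row
  initialize(profiles, profiles = mat)
}

#' Largest admissible threshold for average-case linear time
#'
#' The block-filter pair enumeration runs in O(m d) time on average over
#' uniform i.i.d. profiles whenever k < (m - k - 1) * log(sigma) / log(m d)
#' (the ratio of logs makes the base irrelevant). Returns the largest
#' integer k in \code{[1, m - 1]} satisfying the inequality, or 0 when no
#' k does.
#'
#' @param m profile length, >= 2.
#' @param d profile count, >= 1.
#' @param sigma alphabet size, >= 2.
#' @return integer, the largest admissible k (0 if none).
#' @examples
#' maxAdmissibleK(4096, 4096, 2)
#' @export
maxAdmissibleK <- function(m, d, sigma) {
  m <- as.integer(m)
  if (m < 2L || d < 1L || sigma < 2L)
    stopParameter("need m >= 2, d >= 1, sigma >= 2")
  ks <- seq_len(m - 1L)
  ok <- ks < (m - ks - 1) * log(sigma) / log(as.numeric(m) * d)
  if (!any(ok)) 0L else max(ks[ok])
}

#' Simplified admissibility bound for square binary instances
#'
#' Closed-form upper bound floor(m / (2 log2 m)) on the admissible
#' threshold in the binary, d = m regime; for m = 4096 it evaluates to 170.
#'
#' @param m profile length, >= 2.
#' @return integer bound.
#' @examples
#' simplifiedKBound(4096)
#' @export
simplifiedKBound <- function(m) {
  m <- as.integer(m)
  if (m < 2L) stopParameter("need m >= 2")
  as.integer(m %/% (2 * log2(m)))
}
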