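#' @name accessors
#' @title Accessors for hammingpairs classes
#'
#' @description Slot accessors: \code{profileIds}, \code{alleleMatrix},
#' \code{profileCount} (d), \code{profileLength} (m), \code{alphabetSize}
#' (sigma), \code{isolateFreq}, \code{suffixArray}, \code{lcpArray},
#' \code{pairsTable}, \code{candidateCount}, \code{verifiedCount},
#' \code{forestEdges}, \code{forestComponents}.
#'
#' @param x a \linkS4class{ProfileSet}, \linkS4class{ConcatIndex},
#'   \linkS4class{TruncatedDistance} or \linkS4class{GoeBurstForest}.
#' @param value replacement value.
#' @return the corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("profileIds", function(x) standardGeneric("profileIds"))
#' @rdname accessors
#' @export
setGeneric("alleleMatrix", function(x) standardGeneric("alleleMatrix"))
#' @rdname accessors
#' @export
setGeneric("profileCount", function(x) standardGeneric("profileCount"))
#' @rdname accessors
#' @export
setGeneric("profileLength", function(x) standardGeneric("profileLength"))
#' @rdname accessors
#' @export
setGeneric("alphabetSize", function(x) standardGeneric("alphabetSize"))
#' @rdname accessors
#' @export
setGeneric("isolateFreq", function(x) standardGeneric("isolateFreq"))
#' @rdname accessors
#' @export
setGeneric("isolateFreq<-", function(x, value) standardGeneric("isolateFreq<-"))
#' @rdname accessors
#' @export
setGeneric("suffixArray", function(x) standardGeneric("suffixArray"))
#' @rdname accessors
#' @export
setGeneric("lcpArray", function(x) standardGeneric("lcpArray"))
#' @rdname accessors
#' @export
setGeneric("pairsTable", function(x) standardGeneric("pairsTable"))
#' @rdname accessors
#' @export
setGeneric("candidateCount", function(x) standardGeneric("candidateCount"))
#' @rdname accessors
#' @export
setGeneric("verifiedCount", function(x) standardGeneric("verifiedCount"))
#' @rdname accessors
#' @export
setGeneric("forestEdges", function(x) standardGeneric("forestEdges"))
#' @rdname accessors
#' @export
setGeneric("forestComponents", function(x) standardGeneric("forestComponents"))

#' @rdname accessors
#' @export
setMethod("profileIds", "ProfileSet", function(x) x@ids)
#' @rdname accessors
#' @export
setMethod("alleleMatrix", "ProfileSet", function(x) x@profiles)
#' @rdname accessors
#' @export
setMethod("profileCount", "ProfileSet", function(x) nrow(x@profiles))
#' @rdname accessors
#' @export
setMethod("profileLength", "ProfileSet", function(x) ncol(x@profiles))
#' @rdname accessors
#' @export
setMethod("alphabetSize", "ProfileSet", function(x) x@sigma)
#' @rdname accessors
#' @export
setMethod("isolateFreq", "ProfileSet", function(x) x@freq)
#' @rdname accessors
#' @export
setMethod("isolateFreq<-", "ProfileSet", function(x, value) {
  x@freq <- as.integer(value)
  validObject(x)
  x
})
#' @rdname accessors
#' @export
setMethod("profileCount", "ConcatIndex", function(x) x@d)
#' @rdname accessors
#' @export
setMethod("profileLength", "ConcatIndex", function(x) x@m)
#' @rdname accessors
#' @export
setMethod("suffixArray", "ConcatIndex", function(x) x@sa)
#' @rdname accessors
#' @export
setMethod("lcpArray", "ConcatIndex", function(x) x@lcp)
#' @rdname accessors
#' @export
setMethod("pairsTable", "TruncatedDistance", function(x) x@pairs)
#' @rdname accessors
#' @export
setMethod("candidateCount", "TruncatedDistance", function(x) x@nCandidates)
#' @rdname accessors
#' @export
setMethod("verifiedCount", "TruncatedDistance", function(x) x@nVerified)
#' @rdname accessors
#' @export
setMethod("forestEdges", "GoeBurstForest", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("forestComponents", "GoeBurstForest", function(x) x@components)

setMethod("show", "ProfileSet", function(object) {
  cat(sprintf("ProfileSet: %d profiles x %d loci, alphabet size %d\n",
              nrow(object@profiles), ncol(object@profiles), object@sigma))
  cat("  ids: ", paste(utils::head(object@ids, 5), collapse = ", "),
      if (length(object@ids) > 5) ", ..." else "", "\n", sep = "")
})

setMethod("show", "ConcatIndex", function(object) {
  cat(sprintf("ConcatIndex: n = %d (m = %d, d = %d), sparse-table RMQ\n",
              length(object@s), object@m, object@d))
})

setMethod("show", "BlockScheme", function(object) {
  cat(sprintf(
    "BlockScheme: k = %d, block length L = %d, %d blocks/profile, B = %g\n",
    object@k, object@L, object@blocksPerProfile, object@B))
})

setMethod("show", "TruncatedDistance", function(object) {
  cat(sprintf(
    "TruncatedDistance: %d pairs with H <= %d (%d candidates, %d verified)\n",
    nrow(object@pairs), object@k, object@nCandidates, object@nVerified))
})

setMethod("show", "GoeBurstForest", function(object) {
  cat(sprintf("GoeBurstForest: %d edges, %d components, k = %d\n",
              nrow(object@edges), length(unique(object@components)),
              object@k))
})
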