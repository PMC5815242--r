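#' Construct a ProfileSet from an integer matrix
#'
#' Low-level constructor for data that is already integer-encoded. Use
#' \code{\link{readProfiles}} for tabular allele tokens.
#'
#' @param profiles integer matrix, d profiles by m loci, entries in
#'   \code{[0, sigma)}.
#' @param ids character vector of d unique identifiers; defaults to
#'   \code{"P1"..."Pd"}.
#' @param sigma alphabet size; defaults to \code{max(profiles) + 1}.
#' @param freq per-profile isolate frequencies (integer >= 1).
#' @param encoding raw tokens per integer code (optional).
#' @return a \linkS4class{ProfileSet}.
#' @export
ProfileSet <- function(profiles, ids = NULL, sigma = NULL, freq = NULL,
                       encoding = character()) {
  profiles <- as.matrix(profiles)
  storage.mode(profiles) <- "integer"
  if (is.null(ids)) ids <- paste0("P", seq_len(nrow(profiles)))
  if (is.null(sigma)) sigma <- max(profiles) + 1L
  if (is.null(freq)) freq <- rep(1L, nrow(profiles))
  new("ProfileSet", ids = as.character(ids), profiles = profiles,
      sigma = as.integer(sigma), freq = as.integer(freq),
      encoding = as.character(encoding))
}

# global first-occurrence encoding of a character token matrix (row-major
# scan, so identical tokens at any locus share one integer symbol)
encodeTokens <- function(tokens) {
  lev <- unique(as.vector(t(tokens)))
  codes <- matrix(match(t(tokens), lev) - 1L,
                  nrow = nrow(tokens), byrow = TRUE)
  list(codes = codes, encoding = lev)
}

#' Read a typing-profile table
#'
#' Reads a tab-separated profile table in the layout used by typing
#' databases: one row per profile, an identifier column (e.g. the sequence
#' type, ST) and one column per locus holding categorical allele tokens.
#' Tokens are mapped to an integer alphabet by global first-occurrence
#' order; since Hamming distance only compares aligned positions for
#' equality, the encoding preserves every pairwise distance. Missing-allele
#' codes (e.g. \code{"0"} or \code{"-"}) are ordinary categories: two
#' profiles both missing a locus match there.
#'
#' @param path path to the TSV file.
#' @param hasHeader logical; whether the first row names the loci.
#' @param idColumn column holding the profile identifier (ordinal or, with a
#'   header, a column name).
#' @param freqPath optional path to a two-column TSV \code{id <TAB> frequency}
#'   assigning isolate frequencies; profiles absent from it keep frequency 1.
#' @return a \linkS4class{ProfileSet}.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("ST\tL1\tL2\tL3", "A\t1\t2\t1", "B\t1\t2\t2"), tf)
#' ps <- readProfiles(tf)
#' alleleMatrix(ps)
#' @export
readProfiles <- function(path, hasHeader = TRUE, idColumn = 1L,
                         freqPath = NULL) {
  if (!file.exists(path)) stopIO("cannot read profile table '%s'", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (hasHeader && length(lines)) {
    header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
    lines <- lines[-1]
  } else {
    header <- NULL
  }
  if (!length(lines)) stopInput("empty profile table '%s'", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (length(unique(ncols)) != 1L) {
    bad <- which(ncols != ncols[[1]])[[1]]
    stopFormat("ragged row %d in '%s': %d fields, expected %d",
               bad + as.integer(hasHeader), path, ncols[[bad]], ncols[[1]])
  }
  if (ncols[[1]] < 2L)
    stopFormat("profile table '%s' needs an id column plus >= 1 locus", path)
  if (is.character(idColumn)) {
    if (is.null(header)) stopInput("idColumn by name requires a header")
    idc <- match(idColumn, header)
    if (is.na(idc)) stopInput("no column named '%s'", idColumn)
  } else {
    idc <- as.integer(idColumn)
  }
  tab <- do.call(rbind, fields)
  ids <- tab[, idc]
  if (anyDuplicated(ids))
    stopIdentifier("duplicate profile identifier '%s'",
                   ids[duplicated(ids)][[1]])
  enc <- encodeTokens(tab[, -idc, drop = FALSE])
  freq <- rep(1L, length(ids))
  if (!is.null(freqPath)) {
    if (!file.exists(freqPath)) stopIO("cannot read frequencies '%s'", freqPath)
    ft <- utils::read.table(freqPath, sep = "\t", header = FALSE,
                            colClasses = c("character", "integer"))
    hit <- match(ft[[1]], ids)
    freq[hit[!is.na(hit)]] <- ft[[2]][!is.na(hit)]
  }
  ProfileSet(enc$codes, ids = ids, sigma = length(enc$encoding),
             freq = freq, encoding = enc$encoding)
}

#' Write a ProfileSet back to a TSV profile table
#'
#' Writes the table in the same layout \code{\link{readProfiles}} reads
#' (identifier column then locus columns), using the original raw tokens
#' when the set carries an encoding and the integer codes otherwise, so that
#' read-write-read round-trips reproduce the encoded matrix and ids exactly.
#'
#' @param profiles a \linkS4class{ProfileSet}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeProfiles <- function(profiles, path) {
  m <- profileLength(profiles)
  codes <- alleleMatrix(profiles)
  toks <- if (length(profiles@encoding)) {
    matrix(profiles@encoding[codes + 1L], nrow = nrow(codes))
  } else {
    matrix(as.character(codes), nrow = nrow(codes))
  }
  header <- paste(c("ID", paste0("L", seq_len(m))), collapse = "\t")
  body <- vapply(seq_len(nrow(codes)), function(r) {
    paste(c(profileIds(profiles)[r], toks[r, ]), collapse = "\t")
  }, character(1))
  ok <- tryCatch({
    writeLines(c(header, body), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stopIO("cannot write profile table '%s'", path)
  invisible(path)
}

#' Write a truncated distance pair list
#'
#' Emits one tab-separated row \code{id_i id_j distance} per pair with the
#' lower row index first, sorted by (distance, id_i, id_j), under a header
#' line. The file is round-trippable via \code{\link{readPairs}}.
#'
#' @param pairs a \linkS4class{TruncatedDistance}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writePairs <- function(pairs, path) {
  p <- pairsTable(pairs)
  ids <- pairs@ids
  rows <- character(0)
  if (nrow(p)) {
    id_i <- ids[p$i]
    id_j <- ids[p$j]
    ord <- order(p$h, id_i, id_j, method = "radix")
    rows <- paste(id_i[ord], id_j[ord], p$h[ord], sep = "\t")
  }
  ok <- tryCatch({
    writeLines(c("id_i\tid_j\tdistance", rows), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stopIO("cannot write pair list '%s'", path)
  invisible(path)
}

#' Read a pair list written by [writePairs()]
#'
#' @param path path to the TSV pair list.
#' @return data.frame with columns \code{id_i}, \code{id_j}, \code{distance}.
#' @export
readPairs <- function(path) {
  if (!file.exists(path)) stopIO("cannot read pair list '%s'", path)
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "character", "integer"))
}

#' Write a goeBURST forest edge list
#'
#' Edges are written as \code{id_i id_j distance} rows in the greedy
#' acceptance order, which is the goeBURST total order restricted to
#' accepted links. Optionally writes a companion component-membership table.
#'
#' @param forest a \linkS4class{GoeBurstForest}.
#' @param path output path for the edge list.
#' @param componentsPath optional output path for an \code{id component} TSV.
#' @return invisibly, \code{path}.
#' @export
writeForest <- function(forest, path, componentsPath = NULL) {
  e <- forestEdges(forest)
  ids <- forest@ids
  rows <- if (nrow(e)) paste(ids[e$i], ids[e$j], e$h, sep = "\t") else character(0)
  ok <- tryCatch({
    writeLines(c("id_i\tid_j\tdistance", rows), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stopIO("cannot write forest '%s'", path)
  if (!is.null(componentsPath)) {
    writeLines(c("id\tcomponent",
                 paste(ids, forestComponents(forest), sep = "\t")),
               componentsPath)
  }
  invisible(path)
}

#' Encode an external profile with a ProfileSet's token encoding
#'
#' Maps raw allele tokens of a query profile onto the integer alphabet of an
#' indexed database. Tokens never seen in the database are assigned fresh
#' symbols at and beyond sigma, which can match nothing in the index — the
#' natural semantics for a novel allele.
#'
#' @param profiles a \linkS4class{ProfileSet} carrying an encoding.
#' @param tokens character (or coercible) vector of m allele tokens.
#' @return integer vector of length m.
#' @export
encodeProfile <- function(profiles, tokens) {
  tokens <- as.character(tokens)
  if (length(tokens) != profileLength(profiles))
    stopInput("query has %d loci, database has %d",
              length(tokens), profileLength(profiles))
  if (!length(profiles@encoding))
    stopInput("ProfileSet carries no token encoding; pass integer codes")
  code <- match(tokens, profiles@encoding) - 1L
  novel <- is.na(code)
  if (any(novel))
    code[novel] <- profiles@sigma - 1L + match(tokens[novel],
                                               unique(tokens[novel]))
  code
}
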