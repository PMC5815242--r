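# Independent brute-force oracles the indexed implementations are checked
# against. These stay deliberately naive: string-sort suffix ordering,
# positionwise scans, and an all-pairs R loop.

# 0-based suffix array by sorting fixed-width string renderings of every
# suffix; the space separator sorts below all digits, so a suffix that is a
# proper prefix of another sorts first.
bruteSuffixArray <- function(s) {
  n <- length(s)
  keys <- vapply(seq_len(n), function(i) {
    paste(sprintf("%05d", s[i:n]), collapse = " ")
  }, character(1))
  order(keys, method = "radix") - 1L
}

# adjacent-suffix longest-common-prefix scan (0-based sa)
bruteLCP <- function(s, sa) {
  n <- length(s)
  lcp <- integer(n)
  for (r in 2:n) {
    a <- sa[r - 1] + 1L
    b <- sa[r] + 1L
    l <- 0L
    while (a + l <= n && b + l <= n && s[a + l] == s[b + l]) l <- l + 1L
    lcp[r] <- l
  }
  lcp
}

# direct character-scan longest common extension (0-based positions)
bruteLCE <- function(s, i, j) {
  n <- length(s)
  l <- 0L
  while (i + l < n && j + l < n && s[i + l + 1L] == s[j + l + 1L]) l <- l + 1L
  l
}

naiveHamming <- function(a, b) sum(a != b)

# all-pairs truncated distance table, pure R
naivePairsR <- function(mat, k) {
  d <- nrow(mat)
  out <- list()
  for (i in seq_len(d - 1)) {
    for (j in (i + 1):d) {
      h <- sum(mat[i, ] != mat[j, ])
      if (h <= k) out[[length(out) + 1L]] <- c(i, j, h)
    }
  }
  if (!length(out)) {
    return(data.frame(i = integer(0), j = integer(0), h = integer(0)))
  }
  m <- do.call(rbind, out)
  data.frame(i = m[, 1], j = m[, 2], h = m[, 3])
}

# random character token table for I/O round trips
randomTokenTable <- function(d, m, tokens) {
  matrix(sample(tokens, d * m, replace = TRUE), nrow = d)
}

writeProfileTSV <- function(path, ids, tokens, locusNames = NULL) {
  if (is.null(locusNames)) locusNames <- paste0("L", seq_len(ncol(tokens)))
  lines <- c(paste(c("ST", locusNames), collapse = "\t"),
             vapply(seq_along(ids), function(r) {
               paste(c(ids[r], tokens[r, ]), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  path
}

expect_same_pairs <- function(a, b) {
  rownames(a) <- NULL
  rownames(b) <- NULL
  expect_equal(a[order(a$i, a$j), , drop = FALSE],
               b[order(b$i, b$j), , drop = FALSE],
               ignore_attr = TRUE)
}
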