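test_that("block scheme fields follow the floor rules and guard k", {
  s <- blockScheme(4096, 170)
  expect_equal(s@L, 23L)
  s2 <- blockScheme(4, 1)
  expect_equal(s2@L, 2L)
  expect_equal(s2@blocksPerProfile, 2L)
  s3 <- blockScheme(7, 2)
  expect_equal(s3@L, 2L)
  expect_equal(s3@blocksPerProfile, 3L)
  expect_true((s3@k + 1L) * s3@L <= 7L)
  expect_error(blockScheme(4, 0), class = "hpParameterError")
  expect_error(blockScheme(4, 4), class = "hpParameterError")
})

test_that("capped Hamming distance is min(k, H) and exact below the cap", {
  ps <- ProfileSet(rbind(c(0L, 1L, 0L, 1L),   # abab
                         c(0L, 1L, 1L, 1L),   # abbb
                         c(1L, 1L, 1L, 1L)))  # bbbb
  idx <- buildConcatIndex(ps)
  expect_equal(hammingCapped(idx, 1, 2, 2), 1L)
  expect_equal(hammingCapped(idx, 1, 3, 1), 1L)  # true H = 2, capped at 1
  expect_error(hammingCapped(idx, 2, 2, 3), class = "hpBoundsError")
  expect_error(hammingCapped(idx, 0, 1, 2), class = "hpBoundsError")
  # distinct rows with identical content: distance 0 at any cap
  dup <- buildConcatIndex(ProfileSet(rbind(c(0L, 1L, 0L), c(0L, 1L, 0L))))
  expect_equal(hammingCapped(dup, 1, 2, 2), 0L)

  withr::local_seed(21)
  for (rep in 1:30) {
    ps <- randomProfiles(sample(2:8, 1), sample(4:20, 1),
                         sample(c(2L, 4L), 1), seed = rep)
    idx <- buildConcatIndex(ps)
    mat <- alleleMatrix(ps)
    for (q in 1:20) {
      ij <- sample.int(profileCount(ps), 2)
      k <- sample.int(profileLength(ps) - 1L, 1)
      h <- naiveHamming(mat[ij[1], ], mat[ij[2], ])
      got <- hammingCapped(idx, ij[1], ij[2], k)
      expect_equal(got, min(k, h))
      if (got < k) expect_equal(got, h)
    }
  }
})

test_that("candidate enumeration finds exactly the hand-enumerated blocks", {
  ps <- ProfileSet(rbind(c(0L, 1L, 0L, 1L), c(0L, 1L, 1L, 1L),
                         c(1L, 1L, 1L, 1L)))
  idx <- buildConcatIndex(ps)
  scheme <- blockScheme(4, 1)
  for (strat in c("lcp", "binary")) {
    cand <- candidatePairs(idx, scheme, strat)
    got <- unique(cand[, c("i", "j")])
    expect_same_pairs(got, data.frame(i = c(1L, 2L), j = c(2L, 3L)))
    # (1,3) never emitted: no shared aligned block
    expect_false(any(cand$i == 1L & cand$j == 3L))
  }
  # block-0 match "ab" at t = 0, block-1 match "bb" at t = 1
  candLcp <- candidatePairs(idx, scheme, "lcp")
  expect_equal(candLcp$t[candLcp$i == 1L], 0L)
  expect_equal(candLcp$t[candLcp$i == 2L & candLcp$j == 3L], 1L)
})

test_that("degenerate inputs give empty or complete candidate streams", {
  # all-distinct symbols everywhere: no repeated aligned block
  ps <- ProfileSet(matrix(0:11, nrow = 3, byrow = TRUE), sigma = 12L)
  idx <- buildConcatIndex(ps)
  for (strat in c("lcp", "binary")) {
    expect_equal(nrow(candidatePairs(idx, blockScheme(4, 1), strat)), 0L)
  }
  # d identical profiles: every unordered pair emitted
  psId <- ProfileSet(matrix(rep(c(0L, 1L, 0L, 1L), 5), nrow = 5,
                            byrow = TRUE))
  idxId <- buildConcatIndex(psId)
  for (strat in c("lcp", "binary")) {
    cand <- candidatePairs(idxId, blockScheme(4, 1), strat)
    expect_equal(nrow(unique(cand[, c("i", "j")])), choose(5, 2))
  }
  # single profile: empty stream
  one <- buildConcatIndex(ProfileSet(matrix(c(0L, 1L, 0L, 1L), 1)))
  expect_equal(nrow(candidatePairs(one, blockScheme(4, 1), "binary")), 0L)
  # two profiles differing everywhere
  dis <- buildConcatIndex(ProfileSet(rbind(c(0L, 0L, 0L, 0L),
                                           c(1L, 1L, 1L, 1L))))
  expect_equal(nrow(candidatePairs(dis, blockScheme(4, 2), "lcp")), 0L)
})

test_that("the two candidate strategies emit the same distinct pair set", {
  withr::local_seed(22)
  for (rep in 1:40) {
    ps <- randomProfiles(sample(2:25, 1), sample(4:32, 1),
                         sample(c(2L, 4L), 1), seed = 100 + rep)
    idx <- buildConcatIndex(ps)
    k <- sample.int(profileLength(ps) - 1L, 1)
    scheme <- blockScheme(profileLength(ps), k, profileCount(ps))
    a <- unique(candidatePairs(idx, scheme, "lcp")[, c("i", "j")])
    b <- unique(candidatePairs(idx, scheme, "binary")[, c("i", "j")])
    expect_same_pairs(a, b)
  }
})

test_that("closestPairs returns the exact truncated distance set", {
  ps <- ProfileSet(rbind(c(0L, 1L, 0L, 1L), c(0L, 1L, 1L, 1L),
                         c(1L, 1L, 1L, 1L)))
  expect_equal(pairsTable(closestPairs(ps, 1)),
               data.frame(i = c(1L, 2L), j = c(2L, 3L), h = c(1L, 1L)))
  expect_equal(pairsTable(closestPairs(ps, 2)),
               data.frame(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L),
                          h = c(1L, 2L, 1L)))
  # identical rows at any threshold: all pairs at distance 0
  psId <- ProfileSet(matrix(rep(0:3, 4), nrow = 4, byrow = TRUE), sigma = 4L)
  td <- closestPairs(psId, 3)
  expect_equal(nrow(pairsTable(td)), choose(4, 2))
  expect_true(all(pairsTable(td)$h == 0L))
  expect_error(closestPairs(ps, 0), class = "hpParameterError")
  expect_error(closestPairs(ps, 4), class = "hpParameterError")
})

test_that("all three strategies agree with the R oracle on random instances", {
  withr::local_seed(23)
  for (rep in 1:40) {
    sigma <- sample(c(2L, 4L, 20L), 1)
    ps <- randomProfiles(sample(2:30, 1), sample(4:48, 1), sigma,
                         seed = 200 + rep)
    k <- sample.int(profileLength(ps) - 1L, 1)
    expected <- naivePairsR(alleleMatrix(ps), k)
    for (strat in c("lcp", "binary", "naive")) {
      expect_same_pairs(pairsTable(closestPairs(ps, k, strat)), expected)
    }
  }
})

test_that("the pair set is monotone in the threshold", {
  withr::local_seed(24)
  for (rep in 1:15) {
    ps <- randomProfiles(sample(3:20, 1), sample(6:24, 1), 2L,
                         seed = 300 + rep)
    m <- profileLength(ps)
    ks <- sort(sample.int(m - 1L, 2))
    if (ks[1] == ks[2]) next
    small <- pairsTable(closestPairs(ps, ks[1]))
    large <- pairsTable(closestPairs(ps, ks[2]))
    keys <- function(p) paste(p$i, p$j, p$h)
    expect_true(all(keys(small) %in% keys(large)))
  }
})

test_that("planted pairs at h = k survive filtering with exact distance", {
  withr::local_seed(25)
  for (rep in 1:25) {
    d <- sample(4:20, 1)
    m <- sample(8:32, 1)
    k <- sample.int(m %/% 2, 1)
    ps <- randomProfiles(d, m, 2L, seed = 400 + rep)
    ij <- sample.int(d, 2)
    ps <- plantPair(ps, ij[1], ij[2], k, seed = 500 + rep)
    lo <- min(ij); hi <- max(ij)
    idx <- buildConcatIndex(ps)
    scheme <- blockScheme(m, k, d)
    for (strat in c("lcp", "binary")) {
      cand <- candidatePairs(idx, scheme, strat)
      expect_true(any(cand$i == lo & cand$j == hi))
    }
    p <- pairsTable(closestPairs(ps, k, index = idx))
    expect_equal(p$h[p$i == lo & p$j == hi], k)
  }
})
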