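# chain fixture: p1 - p2 at H=1, p2 - p3 at H=1, p1 - p3 at H=2
chainProfiles <- function() {
  ProfileSet(rbind(c(0L, 0L, 0L), c(0L, 0L, 1L), c(0L, 1L, 1L)))
}

test_that("locus-variant counts are tallied from the pair set", {
  td <- closestPairs(chainProfiles(), 2)
  lv <- lvCounts(td, 3)
  expect_equal(lv$slv, c(1L, 2L, 1L))
  expect_equal(lv$dlv, c(1L, 0L, 1L))
  expect_equal(lv$tlv, c(0L, 0L, 0L))
  expect_equal(lv$idRank, 1:3)

  # empty pair set -> all zeros
  far <- ProfileSet(rbind(c(0L, 0L, 0L), c(1L, 1L, 1L)))
  lv0 <- lvCounts(closestPairs(far, 1), 2)
  expect_true(all(lv0$slv == 0L & lv0$dlv == 0L & lv0$tlv == 0L))

  # identical profiles pair at H=0, which is not an SLV
  dup <- ProfileSet(matrix(rep(c(0L, 1L), 3), nrow = 3, byrow = TRUE))
  lvDup <- lvCounts(closestPairs(dup, 1), 3)
  expect_true(all(lvDup$slv == 0L))
})

test_that("the link order prefers small distance, then high variant counts", {
  lv <- data.frame(slv = c(3L, 2L, 3L, 2L), dlv = 0L, tlv = 0L,
                   freq = 1L, idRank = 1:4)
  # distance dominates
  expect_true(edgeLess(c(1, 2, 1), c(3, 4, 2), lv))
  expect_false(edgeLess(c(3, 4, 2), c(1, 2, 1), lv))
  # equal distance: higher max-endpoint SLV first
  expect_true(edgeLess(c(1, 3, 1), c(2, 4, 1), lv))   # slv {3,3} vs {2,2}
  # all keys equal except id ranks: lower rank pair first; never a tie
  lvEq <- data.frame(slv = 1L, dlv = 0L, tlv = 0L, freq = 1L, idRank = 1:4)
  expect_true(edgeLess(c(1, 2, 1), c(3, 4, 1), lvEq))
  expect_true(xor(edgeLess(c(1, 3, 1), c(2, 3, 1), lvEq),
                  edgeLess(c(2, 3, 1), c(1, 3, 1), lvEq)))
  # higher frequency preferred when variant counts tie
  lvF <- data.frame(slv = 1L, dlv = 0L, tlv = 0L, freq = c(9L, 1L, 1L, 1L),
                    idRank = 1:4)
  expect_true(edgeLess(c(1, 2, 1), c(3, 4, 1), lvF))
})

test_that("the greedy forest joins the chain and rejects the cycle edge", {
  f <- goeburstForest(chainProfiles(), 2)
  e <- forestEdges(f)
  expect_equal(nrow(e), 2L)
  expect_true(all(e$h == 1L))
  expect_false(any(e$h == 2L))  # the (1,3) edge would close a cycle
  expect_equal(length(unique(forestComponents(f))), 1L)

  # single profile: empty forest, one component
  f1 <- goeburstForest(ProfileSet(matrix(c(0L, 1L), 1)), 1)
  expect_equal(nrow(forestEdges(f1)), 0L)
  expect_equal(forestComponents(f1), 1L)

  # two profiles at exactly H = k: one edge
  f2 <- goeburstForest(ProfileSet(rbind(c(0L, 0L, 0L), c(0L, 1L, 1L))), 2)
  expect_equal(forestEdges(f2)$h, 2L)
  expect_equal(length(unique(forestComponents(f2))), 1L)
})

test_that("forests are acyclic with |edges| = d - #components (replay)", {
  withr::local_seed(31)
  for (rep in 1:20) {
    ps <- randomProfiles(sample(4:25, 1), sample(4:16, 1), 2L,
                         seed = 600 + rep)
    k <- sample.int(profileLength(ps) - 1L, 1)
    f <- goeburstForest(ps, k)
    e <- forestEdges(f)
    # independent union-find replay: every accepted edge joins two trees
    parent <- seq_len(profileCount(ps))
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (r in seq_len(nrow(e))) {
      ri <- find(e$i[r]); rj <- find(e$j[r])
      expect_true(ri != rj)
      parent[ri] <- rj
    }
    expect_equal(nrow(e),
                 profileCount(ps) - length(unique(forestComponents(f))))
    expect_true(all(e$h <= k))
  }
})

test_that("forest weight equals a generic MSF oracle on the threshold graph", {
  skip_if_not_installed("igraph")
  withr::local_seed(32)
  for (rep in 1:15) {
    ps <- randomProfiles(sample(4:20, 1), sample(4:12, 1), 2L,
                         seed = 700 + rep)
    k <- sample.int(profileLength(ps) - 1L, 1)
    td <- closestPairs(ps, k)
    f <- goeburstForest(ps, k)
    p <- pairsTable(td)
    if (!nrow(p)) {
      expect_equal(nrow(forestEdges(f)), 0L)
      next
    }
    g <- igraph::graph_from_data_frame(
      data.frame(from = p$i, to = p$j, weight = p$h + 1), directed = FALSE,
      vertices = data.frame(name = seq_len(profileCount(ps))))
    msf <- igraph::mst(g)
    expect_equal(sum(forestEdges(f)$h + 1),
                 sum(igraph::E(msf)$weight))
  }
})

test_that("components at a smaller threshold refine those at a larger one", {
  withr::local_seed(33)
  for (rep in 1:50) {
    ps <- randomProfiles(sample(4:20, 1), sample(5:14, 1), 2L,
                         seed = 800 + rep)
    m <- profileLength(ps)
    ks <- sort(sample.int(m - 1L, 2))
    if (ks[1] == ks[2]) next
    c1 <- forestComponents(goeburstForest(ps, ks[1]))
    c2 <- forestComponents(goeburstForest(ps, ks[2]))
    # each k1-component must sit inside a single k2-component
    for (comp in unique(c1)) {
      expect_equal(length(unique(c2[c1 == comp])), 1L)
    }
  }
})

test_that("lvK recomputes tie-break counts at a larger threshold", {
  ps <- ProfileSet(rbind(c(0L, 0L, 0L, 0L, 0L), c(0L, 0L, 0L, 0L, 1L),
                         c(0L, 0L, 0L, 1L, 1L)))
  f <- goeburstForest(ps, 1, lvK = 3)
  expect_equal(nrow(forestEdges(f)), 2L)  # same chain, counts at k = 3
  expect_equal(length(unique(forestComponents(f))), 1L)
})
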