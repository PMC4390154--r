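test_that("hypergeometric pmf reproduces hand-enumerated values", {
  expect_equal(hypergeomPMF(10, 3, 4, 2), 63 / 210)
  expect_equal(hypergeomPMF(10, 0, 4, 0), 1)       # no seeds: zero links certain
  expect_equal(hypergeomPMF(10, 3, 4, 0), choose(7, 4) / choose(10, 4))
  # combinatorially impossible: more non-seed links than non-seed nodes
  expect_equal(hypergeomPMF(10, 8, 5, 1), 0)
})

test_that("pmf normalizes to 1 over its support", {
  for (N in c(5, 17, 30, 60)) {
    for (s0 in unique(c(1, N %/% 3, N - 1))) {
      for (k in unique(c(1, N %/% 2, N - 1))) {
        total <- sum(hypergeomPMF(N, s0, k, 0:min(k, s0)))
        expect_equal(total, 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("connectivity p-value matches hand sums and the tail oracle", {
  expect_equal(connectivityPValue(10, 3, 4, 2), 70 / 210)
  expect_equal(connectivityPValue(10, 3, 3, 3), 1 / 120)
  expect_identical(connectivityPValue(10, 3, 4, 0), 1)
  # independent oracle: stats::phyper upper tail
  set.seed(20)
  for (i in 1:200) {
    N <- sample(4:60, 1); s0 <- sample(1:(N - 1), 1); k <- sample(1:(N - 1), 1)
    ks <- sample(0:min(k, s0), 1)
    expect_equal(connectivityPValue(N, s0, k, ks),
                 phyper(ks - 1, s0, N - s0, k, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("log-space evaluation is stable for extreme tails", {
  lp <- connectivityPValue(13460, 45, 100, 45, log.p = TRUE)
  expect_true(is.finite(lp))
  expect_lt(lp / log(10), -30)  # representable far below 1e-30
})

test_that("parameter bound violations name the violated bound", {
  expect_error(connectivityPValue(10, 11, 2, 1), "s0")
  expect_error(connectivityPValue(10, 3, 10, 1), "k must not exceed")
  expect_error(connectivityPValue(10, 3, 4, 4), "min\\(k, s0\\)")
  expect_error(weightedPValue(10, 3, 4, 2, alpha = 0.5), "alpha")
})

test_that("p-value is monotone: decreasing in ks, increasing in k", {
  # the dominance lemma behind candidate pruning; the tail saturates at 1
  # once the observed count is forced (k > N - s0 style pigeonhole cases),
  # so strictness is required only below saturation
  for (N in c(12, 25, 40)) {
    s0 <- N %/% 3
    for (k in 2:(N - 1)) {
      p <- connectivityPValue(rep(N, min(k, s0)), s0, k, seq_len(min(k, s0)))
      expect_true(all(diff(p) <= 0))
      expect_true(all(diff(p[p < 1 - 1e-9]) < 0))
    }
    for (ks in 1:3) {
      kk <- ks:(N - 1)
      p <- connectivityPValue(rep(N, length(kk)), s0, kk, ks)
      expect_true(all(diff(p) >= 0))
      expect_true(all(diff(p[p < 1 - 1e-9]) > 0))
    }
  }
})

test_that("alpha = 1 weighting is the identity", {
  set.seed(4)
  for (i in 1:50) {
    N <- sample(6:40, 1); s0 <- sample(1:(N - 2), 1); k <- sample(1:(N - 1), 1)
    ks <- sample(0:min(k, s0), 1)
    expect_equal(weightedPValue(N, s0, k, ks, alpha = 1),
                 connectivityPValue(N, s0, k, ks))
  }
  expect_identical(weightedPValue(20, 5, 4, 0, alpha = 3), 1)
})

test_that("integer alpha equals the plain p-value on the duplicated graph", {
  for (alpha in 2:3) {
    for (seed in 1:10) {
      net <- gnpNet(25, 0.2, seed)
      seeds <- withr::with_seed(seed, sample(nodeNames(net), 4))
      dup <- duplicatedGraph(net, seeds, alpha)
      dupSeeds <- c(seeds, unlist(lapply(seeds, function(s)
        paste0(s, "_dup", seq_len(alpha - 1)))))
      cands <- setdiff(nodeNames(net), seeds)
      for (v in head(cands, 8)) {
        k <- igraph::degree(asIgraph(net), v)
        ks <- sum(igraph::neighbors(asIgraph(net), v)$name %in% seeds)
        if (ks == 0) next
        kDup <- igraph::degree(dup, v)
        ksDup <- sum(igraph::neighbors(dup, v)$name %in% dupSeeds)
        expect_equal(
          weightedPValue(numNodes(net), length(seeds), k, ks, alpha = alpha),
          connectivityPValue(igraph::vcount(dup), length(dupSeeds), kDup, ksDup),
          tolerance = 1e-12)
      }
    }
  }
})

test_that("candidate ranking obeys the dominance relations", {
  # equal k, ks 3 vs 1: the ks = 3 candidate ranks first; equal ks, k 10 vs 50:
  # the k = 10 candidate ranks first.  Star-built toy graphs realize both.
  edges <- rbind(
    data.frame(a = c("s1", "s2", "s3"), b = "X"),          # X: ks 3, k 6
    data.frame(a = "X", b = c("f1", "f2", "f3")),
    data.frame(a = "s1", b = "Y"),                         # Y: ks 1, k 6
    data.frame(a = "Y", b = c("f4", "f5", "f6", "f7", "f8")))
  net <- Interactome(edges)
  rc <- rankCandidates(net, c("s1", "s2", "s3"))
  expect_identical(rc$k[rc$gene == "X"], rc$k[rc$gene == "Y"])
  expect_identical(rc$gene[1], "X")
  chain <- Interactome(rbind(
    data.frame(a = "s1", b = c("P", "Q")),
    data.frame(a = "P", b = sprintf("p%02d", 1:9)),
    data.frame(a = "Q", b = sprintf("q%02d", 1:49))))
  rc2 <- rankCandidates(chain, "s1")
  expect_lt(which(rc2$gene == "P"), which(rc2$gene == "Q"))
})

test_that("full ranking equals the exhaustive phyper oracle, including ties", {
  for (seed in 1:40) {
    net <- gnpNet(50, 0.12, seed)
    module <- withr::with_seed(seed * 7, sample(nodeNames(net), 6))
    got <- rankCandidates(net, module)
    want <- oracleRanking(net, module)
    expect_identical(got$gene, want$gene)
    expect_equal(got$pValue, want$pValue, tolerance = 1e-10)
  }
})
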