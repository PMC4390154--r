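test_that("GMT files parse, report errors with line numbers, and round-trip", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("T1\tfirst term\tA\tB\tC", "T2\tsecond term\tB\tC\tD"), path)
  ann <- loadGMT(path)
  expect_setequal(termNames(ann), c("T1", "T2"))
  expect_setequal(termGenes(ann, "T2"), c("B", "C", "D"))
  expect_setequal(annotationBackground(ann), c("A", "B", "C", "D"))
  out <- withr::local_tempfile(fileext = ".gmt")
  writeGMT(ann, out)
  ann2 <- loadGMT(out)
  expect_identical(ann2@terms, ann@terms)
  expect_identical(ann2@background, ann@background)
  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("T1\tdesc\tA", "T2\tno-genes"), bad)
  expect_error(loadGMT(bad), "line 2")
  empty <- withr::local_tempfile(fileext = ".gmt")
  writeLines(character(), empty)
  expect_length(termNames(loadGMT(empty)), 0)
})

test_that("seed enrichment matches the hand-computed hypergeometric tail", {
  seeds <- sprintf("s%02d", 1:10)
  bg <- c(seeds, sprintf("b%03d", 1:990))
  terms <- list(hit = c(seeds, sprintf("b%03d", 1:10)),   # all 10 seeds, 20 genes
                miss = sprintf("b%03d", 101:120))         # disjoint from seeds
  ann <- new("AnnotationCollection", terms = terms,
             descriptions = c(hit = "", miss = ""), background = bg)
  sig <- enrichSeedTerms(ann, seeds, alphaLevel = 0.05)
  expect_identical(as.character(sig), "hit")
  tab <- attr(sig, "tests")
  pHand <- phyper(10 - 1, 20, 980, 10, lower.tail = FALSE)
  expect_equal(tab$p[tab$term == "hit"], pHand, tolerance = 1e-10)
  expect_equal(tab$p[tab$term == "miss"], 1)
  expect_equal(tab$pBonferroni, pmin(1, 2 * tab$p))
})

test_that("enrichment degenerate cases behave", {
  ann <- new("AnnotationCollection", terms = list(),
             descriptions = character(), background = c("A", "B"))
  expect_length(enrichSeedTerms(ann, "A"), 0)
  expect_error(enrichSeedTerms(ann, "Z"), "background")
})

test_that("one-sided Fisher p equals the exact tail sum on small tables", {
  # cross-check the 2x2 testing route against direct hypergeometric tails
  for (n in c(20, 35, 50)) {
    for (i in 1:10) {
      set.seed(n + i)
      nTerm <- sample(2:(n - 2), 1); nSeed <- sample(2:(n - 2), 1)
      a <- sample(0:min(nTerm, nSeed), 1)
      tab <- matrix(c(a, nSeed - a, nTerm - a, n - nSeed - nTerm + a), 2)
      if (any(tab < 0)) next
      expect_equal(fisher.test(tab, alternative = "greater")$p.value,
                   phyper(a - 1, nTerm, n - nTerm, nSeed, lower.tail = FALSE),
                   tolerance = 1e-12)
    }
  }
})

test_that("synthetic annotations respect coverage, noise and the seed", {
  net <- syntheticInteractome(300, 3, rngSeed = 14)
  module <- nodeNames(net)[1:40]
  pure <- makeSyntheticAnnotations(net, module, nTerms = 6, coverage = 1,
                                   noise = 0, rngSeed = 5)
  expect_true(all(unlist(pure@terms) %in% module))
  a <- makeSyntheticAnnotations(net, module, nTerms = 6, rngSeed = 9)
  b <- makeSyntheticAnnotations(net, module, nTerms = 6, rngSeed = 9)
  expect_identical(a@terms, b@terms)
})

test_that("pure-noise annotations are not enriched in the seeds", {
  net <- syntheticInteractome(500, 3, rngSeed = 25)
  module <- nodeNames(net)[1:40]
  ann <- makeSyntheticAnnotations(net, module, nTerms = 40, noise = 1,
                                  termSize = 25, rngSeed = 6)
  sig <- enrichSeedTerms(ann, module[1:20], alphaLevel = 0.05)
  expect_length(sig, 0)
})

test_that("planted annotation structure is recovered by the sliding window", {
  fx <- plantedCliqueInteractome(nNodes = 400, nEdges = 800, cliqueSize = 20,
                                 rngSeed = 41)
  seeds <- fx$clique[1:10]
  rk <- quietly(runDiamond(fx$net, seeds, nIterations = 60))
  ann <- makeSyntheticAnnotations(fx$net, fx$clique, nTerms = 10, noise = 0.05,
                                  termSize = 15, rngSeed = 3)
  sig <- enrichSeedTerms(ann, seeds)
  expect_gt(length(sig), 0)
  vr <- validateRanking(rk, sig, ann, window = 10)
  tab <- vr@table
  # clique members dominate the first iterations and are the true positives
  early <- tab$tp[tab$gene %in% fx$clique]
  expect_gt(mean(early), 0.5)
  expect_true(all(tab$windowP > 0 & tab$windowP <= 1))
  # windows packed with TPs are more significant than TP-free windows
  if (any(tab$tp) && any(!tab$tp))
    expect_lt(min(tab$windowP[tab$tp]), max(tab$windowP[!tab$tp]))
  # unannotated genes are never flagged
  expect_false(any(tab$tp[!tab$gene %in% unlist(ann@terms)]))
})

test_that("empty significant-term sets flag nothing and warn", {
  genes <- sprintf("g%02d", 1:10)
  ann <- new("AnnotationCollection", terms = list(T1 = genes[1:3]),
             descriptions = c(T1 = ""), background = genes)
  expect_warning(vr <- validateRanking(genes, character(), ann), "no significant")
  expect_false(any(vr@table$tp))
  expect_identical(vr@table$windowP, rep(1, 10))
})
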