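test_that("a forced move agglomerates the only candidate", {
  net <- pathNet(3)  # A - B - C
  rk <- runDiamond(net, "A", nIterations = 1)
  expect_identical(rankedGenes(rk), "B")
  tab <- rankingTable(rk)
  expect_identical(tab$seedLinks, 1L)
})

test_that("the candidate with more seed links wins at equal degree", {
  net <- Interactome(rbind(
    data.frame(a = c("s1", "s2"), b = "X"),
    data.frame(a = "X", b = "f1"),
    data.frame(a = "s1", b = "Y"),
    data.frame(a = "Y", b = c("f2", "f3"))))
  rk <- runDiamond(net, c("s1", "s2"), nIterations = 1)
  expect_identical(rankedGenes(rk), "X")
  # the recorded p equals the direct computation
  tab <- rankingTable(rk)
  expect_equal(tab$pValue, connectivityPValue(numNodes(net), 2, 3, 2))
})

test_that("two runs with identical inputs produce identical rankings", {
  net <- gnpNet(120, 0.06, 31)
  seeds <- nodeNames(net)[1:8]
  a <- quietly(runDiamond(net, seeds, nIterations = 40))
  b <- quietly(runDiamond(net, seeds, nIterations = 40))
  expect_identical(rankingTable(a), rankingTable(b))
})

test_that("module grows by one per iteration and never re-adds members", {
  net <- gnpNet(100, 0.08, 13)
  seeds <- nodeNames(net)[1:5]
  rk <- quietly(runDiamond(net, seeds, nIterations = 30))
  tab <- rankingTable(rk)
  expect_identical(tab$iteration, seq_len(nrow(tab)))
  expect_identical(anyDuplicated(tab$gene), 0L)
  expect_length(intersect(tab$gene, seeds), 0)
})

test_that("every agglomerated gene was adjacent to the module at its turn", {
  net <- gnpNet(80, 0.07, 17)
  seeds <- nodeNames(net)[1:6]
  rk <- quietly(runDiamond(net, seeds, nIterations = 25))
  module <- seeds
  g <- asIgraph(net)
  for (gene in rankedGenes(rk)) {
    nb <- igraph::neighbors(g, gene)$name
    expect_gt(length(intersect(nb, module)), 0)
    module <- c(module, gene)
  }
})

test_that("each step picks the oracle argmin over all candidates", {
  for (seed in 1:5) {
    net <- gnpNet(60, 0.1, seed + 100)
    module <- nodeNames(net)[1:5]
    rk <- quietly(runDiamond(net, module, nIterations = 10))
    for (gene in rankedGenes(rk)) {
      expect_identical(gene, oracleRanking(net, module)$gene[1])
      module <- c(module, gene)
    }
  }
})

test_that("candidate exhaustion stops early with a warning", {
  net <- pathNet(3)
  expect_warning(rk <- runDiamond(net, "A", nIterations = 10), "exhausted")
  expect_identical(rankedGenes(rk), c("B", "C"))
})

test_that("seeds off the network raise a precondition error", {
  net <- pathNet(3)
  expect_error(quietly(runDiamond(net, "nope")), "no seed maps")
})

test_that("planted clique members are recovered first", {
  fx <- plantedCliqueInteractome(nNodes = 500, nEdges = 1000, cliqueSize = 20,
                                 rngSeed = 5)
  seeds <- fx$clique[1:10]
  rk <- runDiamond(fx$net, seeds, nIterations = 10)
  expect_true(all(rankedGenes(rk) %in% fx$clique))
})

test_that("weighted runs bias early picks toward seed neighbors", {
  fx <- plantedCliqueInteractome(nNodes = 300, nEdges = 600, cliqueSize = 15,
                                 rngSeed = 9)
  seeds <- fx$clique[1:7]
  rk1 <- runDiamond(fx$net, seeds, nIterations = 20, alpha = 1)
  rk10 <- runDiamond(fx$net, seeds, nIterations = 20, alpha = 10)
  g <- asIgraph(fx$net)
  firstOrder <- function(genes) mean(vapply(genes, function(v)
    any(igraph::neighbors(g, v)$name %in% seeds), logical(1)))
  expect_gte(firstOrder(rankedGenes(rk10)), firstOrder(rankedGenes(rk1)))
})

test_that("moduleLCC reports integrated seeds", {
  # two seed clusters joined through a connector that growth will add
  net <- Interactome(rbind(
    data.frame(a = c("s1", "s2", "s1"), b = c("s2", "s3", "s3")),  # seed triangle
    data.frame(a = c("s4", "C", "C", "C"), b = c("C", "s1", "s2", "s3"))))
  seeds <- c("s1", "s2", "s3", "s4")
  rk <- quietly(runDiamond(net, seeds, nIterations = 1))
  expect_identical(rankedGenes(rk), "C")
  base <- moduleLCC(net, seeds, rk, topN = 0)
  expect_identical(base$size, 3L)
  expect_identical(base$integratedSeeds, 0L)
  grown <- moduleLCC(net, seeds, rk, topN = 1)
  expect_identical(grown$size, 5L)
  expect_identical(grown$integratedSeeds, 1L)   # s4 joined through C
  expect_error(moduleLCC(net, seeds, rk, topN = 5), "exceeds")
})

test_that("fully connected seeds integrate nothing at any depth", {
  fx <- plantedCliqueInteractome(nNodes = 200, nEdges = 400, cliqueSize = 10,
                                 rngSeed = 2)
  rk <- runDiamond(fx$net, fx$clique, nIterations = 15)
  for (n in c(0, 5, 15))
    expect_identical(moduleLCC(fx$net, fx$clique, rk, n)$integratedSeeds, 0L)
})

test_that("rankings serialize with the documented column schema", {
  net <- gnpNet(50, 0.1, 3)
  rk <- quietly(runDiamond(net, nodeNames(net)[1:4], nIterations = 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeRanking(rk, path)
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_named(tab, c("iteration", "gene", "degree_k", "seed_links_ks", "p_value"))
  expect_equal(tab$p_value, rankingTable(rk)$pValue, tolerance = 1e-5)
})
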