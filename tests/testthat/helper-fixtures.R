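# Shared fixtures and independent oracles, built in code at test time.

# small named graphs -----------------------------------------------------------

triangleNet <- function() {
  Interactome(data.frame(a = c("A", "B", "C"), b = c("B", "C", "A")))
}

pathNet <- function(n = 4) {
  ids <- LETTERS[seq_len(n)]
  Interactome(data.frame(a = ids[-n], b = ids[-1]))
}

# Erdos-Renyi test graph with guaranteed character names.
gnpNet <- function(n, p, seed) {
  g <- withr::with_seed(seed, igraph::sample_gnp(n, p))
  igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
  Interactome(g)
}

# oracles ----------------------------------------------------------------------

# Exhaustive candidate ranking: every neighbor of the module scored with
# stats::phyper (an implementation-independent path), ordered by p-value
# with the package's documented tie rule (higher ks, lower k, identifier).
oracleRanking <- function(net, module) {
  g <- asIgraph(net)
  nms <- nodeNames(net)
  module <- intersect(module, nms)
  nbrs <- setdiff(unique(unlist(lapply(
    module, function(m) igraph::neighbors(g, m)$name))), module)
  if (!length(nbrs)) return(data.frame(gene = character(), k = integer(),
                                       ks = integer(), pValue = numeric()))
  k <- as.integer(igraph::degree(g, nbrs))
  ks <- vapply(nbrs, function(v)
    sum(igraph::neighbors(g, v)$name %in% module), integer(1))
  p <- phyper(ks - 1, length(module), numNodes(net) - length(module), k,
              lower.tail = FALSE)
  ord <- order(p, -ks, k, nbrs, method = "radix")
  data.frame(gene = nbrs[ord], k = k[ord], ks = ks[ord], pValue = p[ord])
}

# Brute-force local modularity by classifying every edge.
oracleModularity <- function(net, community) {
  el <- igraph::as_edgelist(asIgraph(net))
  inC <- matrix(el %in% community, ncol = 2)
  boundary <- unique(c(el[inC[, 1] & !inC[, 2], 1], el[!inC[, 1] & inC[, 2], 2]))
  if (!length(boundary)) return(1)
  touchB <- el[, 1] %in% boundary | el[, 2] %in% boundary
  sum(touchB & inC[, 1] & inC[, 2]) / sum(touchB)
}

# Materialize the seed-duplication construction behind the alpha weighting:
# each seed gains (alpha - 1) copies wired to all its neighbors.
duplicatedGraph <- function(net, seeds, alpha) {
  stopifnot(alpha == round(alpha), alpha >= 1)
  g <- asIgraph(net)
  for (s in seeds) {
    nb <- igraph::neighbors(g, s)$name
    for (r in seq_len(alpha - 1)) {
      copy <- paste0(s, "_dup", r)
      g <- igraph::add_vertices(g, 1, name = copy)
      g <- igraph::add_edges(g, as.vector(rbind(copy, nb)))
    }
  }
  g
}

quietly <- function(expr) suppressMessages(suppressWarnings(expr))
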