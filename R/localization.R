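# Localization statistics: LCC size, LCC significance, local modularity.

# LCC size of the subgraph induced by integer vertex indices.
.lccSizeIdx <- function(g, idx) {
  if (!length(idx)) return(0L)
  comp <- igraph::components(igraph::induced_subgraph(g, idx))
  as.integer(max(comp$csize))
}

#' Size of the largest connected component induced by a node set
#'
#' Identifiers absent from the network are ignored.
#'
#' @param net an [Interactome-class].
#' @param nodeSet character vector of identifiers.
#' @return non-negative integer.
#' @examples
#' tri <- Interactome(data.frame(a = c("A", "B", "C"), b = c("B", "C", "A")))
#' lccSize(tri, c("A", "B", "C"))
#' @export
lccSize <- function(net, nodeSet) {
  stopifnot(is(net, "Interactome"))
  idx <- which(nodeNames(net) %in% nodeSet)
  .lccSizeIdx(asIgraph(net), idx)
}

#' Significance of seed-set agglomeration in the network
#'
#' Compares the observed LCC size of the seed set against LCC sizes of
#' \code{nRandom} node sets of the same cardinality drawn uniformly (without
#' degree matching) from the network.  Reports the z-score and the
#' upper-tail empirical p-value with the (r+1)/(n+1) correction, so a
#' never-exceeded observation yields p = 1/(nRandom+1) rather than 0.
#'
#' @param net an [Interactome-class].
#' @param seeds a [SeedSet-class] or character vector of identifiers.
#' @param nRandom number of random replicates (>= 100; default 1e5).
#' @param rngSeed optional integer seed for reproducible draws.
#' @return an [LCCStats-class].  When the null distribution is degenerate
#'   (sd = 0, e.g. the seed set is the whole network) the z-score is NA and
#'   the \code{degenerate} flag is set.
#' @export
lccSignificance <- function(net, seeds, nRandom = 1e5, rngSeed = NULL) {
  stopifnot(is(net, "Interactome"))
  seeds <- .asSeedSet(net, seeds)
  s0 <- seedCount(seeds)
  if (s0 < 1) .stopf("lccSignificance: seed set is empty after mapping")
  nRandom <- as.integer(nRandom)
  if (nRandom < 100) .stopf("lccSignificance: nRandom must be >= 100")
  g <- asIgraph(net)
  obs <- lccSize(net, seedNames(seeds))
  N <- numNodes(net)
  rand <- .withSeed(rngSeed, {
    vapply(seq_len(nRandom),
           function(i) .lccSizeIdx(g, sample.int(N, s0)), integer(1))
  })
  mu <- mean(rand); sdv <- sd(rand)
  degen <- !is.finite(sdv) || sdv == 0
  z <- if (degen) NA_real_ else (obs - mu) / sdv
  p <- (sum(rand >= obs) + 1) / (nRandom + 1)
  new("LCCStats", lccSize = obs, zScore = z, empiricalP = p,
      nRandom = nRandom, randomMean = mu, randomSD = if (degen) 0 else sdv,
      degenerate = degen,
      rngSeed = if (is.null(rngSeed)) NA_integer_ else as.integer(rngSeed))
}

setMethod("show", "LCCStats", function(object) {
  cat(sprintf("LCC significance: size %d | z = %s | empirical p %s %.3g (%d draws)%s\n",
              object@lccSize,
              if (is.na(object@zScore)) "NA (degenerate null)"
              else sprintf("%.2f", object@zScore),
              if (object@empiricalP <= 1 / object@nRandom) "<" else "=",
              object@empiricalP, object@nRandom,
              if (object@degenerate) " [degenerate]" else ""))
})

#' Local modularity R of a candidate community
#'
#' The boundary B consists of community members with at least one edge to a
#' non-member.  R is the number of edges incident to B whose other endpoint
#' is also in the community, divided by the total number of edges incident
#' to B (edges with both endpoints in B counted once).  An empty boundary
#' (fully separated community) yields R = 1 by convention.
#'
#' @param net an [Interactome-class].
#' @param community non-empty character vector of member identifiers, all in
#'   the network.
#' @return a [ModularityResult-class].
#' @examples
#' path4 <- Interactome(data.frame(a = c("A", "B", "C"), b = c("B", "C", "D")))
#' localModularity(path4, c("A", "B"))  # R = 0.5
#' @export
localModularity <- function(net, community) {
  stopifnot(is(net, "Interactome"))
  community <- unique(as.character(community))
  if (!length(community)) .stopf("localModularity: community is empty")
  if (!all(community %in% nodeNames(net)))
    .stopf("localModularity: %d community member(s) not in the network",
           sum(!community %in% nodeNames(net)))
  g <- asIgraph(net)
  el <- igraph::as_edgelist(g)
  inC1 <- el[, 1] %in% community
  inC2 <- el[, 2] %in% community
  # boundary: community nodes with >=1 edge leaving the community
  leaving <- c(el[inC1 & !inC2, 1], el[!inC1 & inC2, 2])
  boundary <- unique(leaving)
  if (!length(boundary))
    return(new("ModularityResult", R = 1, boundarySize = 0L,
               communitySize = length(community)))
  inB1 <- el[, 1] %in% boundary
  inB2 <- el[, 2] %in% boundary
  incident <- inB1 | inB2
  inside <- incident & inC1 & inC2
  new("ModularityResult", R = sum(inside) / sum(incident),
      boundarySize = length(boundary), communitySize = length(community))
}

setMethod("show", "ModularityResult", function(object) {
  cat(sprintf("Local modularity R = %.4f (community %d, boundary %d)\n",
              object@R, object@communitySize, object@boundarySize))
})

#' Localization statistics for a corpus of disease gene sets
#'
#' Convenience driver reproducing, for every disease in an association
#' table, the per-disease localization summary: number of associated genes
#' on the network, LCC size, LCC z-score and empirical p-value, and local
#' modularity R of the mapped gene set.
#'
#' @param net an [Interactome-class].
#' @param diseases named list of identifier vectors (see [loadSeedTable()]).
#' @param nRandom random replicates per disease for the LCC null.
#' @param rngSeed integer seed; per-disease sub-seeds are derived from it.
#' @return data.frame with one row per disease: disease, nGenes (mapped),
#'   nUnmapped, lcc, zScore, empiricalP, modularityR.
#' @export
diseaseCorpusStats <- function(net, diseases, nRandom = 1e4, rngSeed = NULL) {
  stopifnot(is(net, "Interactome"), is.list(diseases))
  rows <- lapply(seq_along(diseases), function(i) {
    nm <- names(diseases)[i]
    ss <- seedSet(net, diseases[[i]], name = nm)
    if (seedCount(ss) < 1)
      return(data.frame(disease = nm, nGenes = 0L, nUnmapped = length(unmappedNames(ss)),
                        lcc = 0L, zScore = NA_real_, empiricalP = NA_real_,
                        modularityR = NA_real_))
    sub <- if (is.null(rngSeed)) NULL else (as.integer(rngSeed) + i) %% .Machine$integer.max
    st <- lccSignificance(net, ss, nRandom = nRandom, rngSeed = sub)
    mr <- localModularity(net, seedNames(ss))
    data.frame(disease = nm, nGenes = seedCount(ss),
               nUnmapped = length(unmappedNames(ss)),
               lcc = st@lccSize, zScore = st@zScore, empiricalP = st@empiricalP,
               modularityR = mr@R)
  })
  do.call(rbind, rows)
}
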