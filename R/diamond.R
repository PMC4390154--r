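# The module-growth iteration: repeatedly agglomerate the candidate with
# the most significant number of connections to the current module.

# Core engine on integer vertex indices.  Maintains, incrementally, each
# node's link count into the module (ks) and into the weighted original
# seeds (ksw); at every iteration only a dominance-pruned shortlist of
# candidates needs an exact p-value (for fixed ks the lowest k dominates),
# which keeps each step O(#candidates + s log s).
.diamondEngine <- function(g, seedIdx, nIterations, alpha = 1) {
  N <- igraph::vcount(g)
  nms <- igraph::V(g)$name
  adj <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
  deg <- as.integer(igraph::degree(g))
  inMod <- logical(N)
  inMod[seedIdx] <- TRUE
  ks <- integer(N); ksw <- integer(N)
  for (s in seedIdx) {
    nb <- adj[[s]]
    ks[nb] <- ks[nb] + 1L
    ksw[nb] <- ksw[nb] + 1L
  }
  s0 <- length(seedIdx)
  Nw <- N + (alpha - 1) * s0
  out <- vector("list", nIterations)
  nDone <- 0L
  for (it in seq_len(nIterations)) {
    cand <- which(!inMod & ks > 0L)
    if (!length(cand)) {
      warning(sprintf("candidate pool exhausted after %d iteration(s)", nDone),
              call. = FALSE)
      break
    }
    sEff <- alpha * s0 + (it - 1L)
    kEff <- deg[cand] + (alpha - 1) * ksw[cand]
    ksEff <- ks[cand] + (alpha - 1) * ksw[cand]
    # dominance pruning: per distinct ksEff, only the minimal kEff can win
    grp <- match(ksEff, sort(unique(ksEff)))
    kMin <- vapply(split(kEff, grp), min, numeric(1))
    ksU <- vapply(split(ksEff, grp), `[[`, numeric(1), 1L)
    lp <- vapply(seq_along(ksU),
                 function(j) .lpval(Nw, sEff, kMin[j], ksU[j]), numeric(1))
    j <- .orderCandidates(lp, ksU, kMin, rep("", length(lp)))[1]
    hit <- cand[ksEff == ksU[j] & kEff == kMin[j]]
    win <- hit[order(nms[hit], method = "radix")][1]
    out[[it]] <- list(gene = nms[win], degree = deg[win], seedLinks = ks[win],
                      pValue = exp(lp[j]))
    nDone <- it
    inMod[win] <- TRUE
    nb <- adj[[win]]
    ks[nb] <- ks[nb] + 1L
  }
  out <- out[seq_len(nDone)]
  data.frame(iteration = seq_len(nDone),
             gene = vapply(out, `[[`, "", "gene"),
             degree = vapply(out, `[[`, 0L, "degree"),
             seedLinks = vapply(out, `[[`, 0L, "seedLinks"),
             pValue = vapply(out, `[[`, 0, "pValue"))
}

#' Grow a disease module by connectivity significance
#'
#' Starting from the seed proteins, each iteration (i) computes the
#' connectivity p-value of every protein adjacent to the current module,
#' (ii) ranks the candidates by p-value, (iii) agglomerates the most
#' significant one (ties broken by higher \code{ks}, then lower \code{k},
#' then lexicographic identifier), and (iv) repeats with the enlarged
#' module, pulling in one protein per iteration.  The output order is the
#' module-relevance ranking of the agglomerated proteins.  The loop is
#' fully deterministic.
#'
#' With \code{alpha > 1} the original seeds count \code{alpha}-fold
#' (see [weightedPValue()]); proteins agglomerated during the iteration
#' always carry weight 1.
#'
#' @param net an [Interactome-class].
#' @param seeds a [SeedSet-class] or character vector of seed identifiers.
#' @param nIterations iteration budget (default 200, the module-size
#'   plateau observed across disease corpora).  The run stops early, with a
#'   warning, if the candidate pool is exhausted (module = whole component).
#' @param alpha seed weight >= 1 (default 1, the unweighted algorithm).
#' @return a [DiamondRanking-class].
#' @examples
#' net <- Interactome(data.frame(a = c("A", "B"), b = c("B", "C")))
#' runDiamond(net, "A", nIterations = 2)
#' @export
runDiamond <- function(net, seeds, nIterations = 200, alpha = 1) {
  stopifnot(is(net, "Interactome"))
  seeds <- .asSeedSet(net, seeds)
  if (seedCount(seeds) < 1)
    .stopf("runDiamond: no seed maps onto the network")
  nIterations <- as.integer(nIterations)
  if (nIterations < 1) .stopf("runDiamond: nIterations must be >= 1")
  if (alpha < 1) .stopf("runDiamond: alpha must be >= 1")
  seedIdx <- which(nodeNames(net) %in% seedNames(seeds))
  entries <- .diamondEngine(asIgraph(net), seedIdx, nIterations, alpha)
  new("DiamondRanking", entries = entries, seeds = seeds,
      nIterations = nIterations, alpha = as.numeric(alpha))
}

#' Accessors for DiamondRanking objects
#'
#' \code{rankingTable} returns the per-iteration data.frame,
#' \code{rankedGenes} just the ordered gene identifiers.
#'
#' @param x a [DiamondRanking-class].
#' @name DiamondRanking-accessors
#' @aliases rankingTable rankedGenes
NULL

#' @rdname DiamondRanking-accessors
#' @export
setMethod("rankingTable", "DiamondRanking", function(x) x@entries)

#' @rdname DiamondRanking-accessors
#' @export
setMethod("rankedGenes", "DiamondRanking", function(x) x@entries$gene)

setMethod("show", "DiamondRanking", function(object) {
  cat(sprintf("DiamondRanking: %d agglomerated gene(s) from %d seed(s) (alpha = %g)\n",
              nrow(object@entries), seedCount(object@seeds), object@alpha))
  if (nrow(object@entries))
    print(head(object@entries, 5), row.names = FALSE)
})

#' Largest connected component of seeds plus top-ranked genes
#'
#' Takes the subgraph induced by the seeds together with the first
#' \code{topN} ranked genes and returns its largest connected component,
#' along with the number of seeds inside it that were *not* part of the
#' seed-only LCC — i.e. previously disconnected seed proteins integrated
#' into the module by the agglomerated connectors.
#'
#' @param net an [Interactome-class].
#' @param seeds a [SeedSet-class] or character vector.
#' @param ranking a [DiamondRanking-class] (or character vector of ranked
#'   genes).
#' @param topN how many ranked genes to include (0 = seed-only LCC).
#' @return list with elements \code{members} (identifiers in the LCC),
#'   \code{size}, and \code{integratedSeeds} (count of newly connected
#'   seeds).
#' @export
moduleLCC <- function(net, seeds, ranking, topN) {
  stopifnot(is(net, "Interactome"))
  seeds <- .asSeedSet(net, seeds)
  genes <- if (is(ranking, "DiamondRanking")) rankedGenes(ranking) else as.character(ranking)
  topN <- as.integer(topN)
  if (topN > length(genes))
    .stopf("moduleLCC: topN (%d) exceeds ranking length (%d)", topN, length(genes))
  g <- asIgraph(net)
  nms <- nodeNames(net)
  seedIdx <- which(nms %in% seedNames(seeds))
  # seed-only LCC membership
  subSeed <- igraph::induced_subgraph(g, seedIdx)
  seedLCC <- character()
  if (igraph::vcount(subSeed) > 0) {
    comp <- igraph::components(subSeed)
    seedLCC <- igraph::V(subSeed)$name[comp$membership == which.max(comp$csize)]
  }
  nodes <- union(seedNames(seeds), genes[seq_len(topN)])
  idx <- which(nms %in% nodes)
  sub <- igraph::induced_subgraph(g, idx)
  comp <- igraph::components(sub)
  members <- igraph::V(sub)$name[comp$membership == which.max(comp$csize)]
  integrated <- setdiff(intersect(members, seedNames(seeds)), seedLCC)
  list(members = members, size = length(members),
       integratedSeeds = length(integrated))
}

#' Write a ranking to TSV
#'
#' Columns: iteration, gene, degree_k, seed_links_ks, p_value (scientific
#' notation, 6 significant digits).
#'
#' @param x a [DiamondRanking-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeRanking <- function(x, path) {
  stopifnot(is(x, "DiamondRanking"))
  e <- x@entries
  out <- data.frame(iteration = e$iteration, gene = e$gene, degree_k = e$degree,
                    seed_links_ks = e$seedLinks,
                    p_value = formatC(e$pValue, digits = 5, format = "e"))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
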