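# Network noise models (link pruning, degree-preserving partial rewiring)
# and leave-one-seed-out robustness of the module ranking.

#' Prune a fraction of links
#'
#' Removes \code{floor(f * E)} uniformly chosen edges, modelling network
#' incompleteness.  The node set is unchanged; nodes isolated by the
#' removal are retained.
#'
#' @param net an [Interactome-class].
#' @param f fraction of links to remove, in \[0, 1\].
#' @param rngSeed integer seed.
#' @return an [Interactome-class] with the same nodes.
#' @export
pruneNetwork <- function(net, f, rngSeed = NULL) {
  stopifnot(is(net, "Interactome"))
  if (f < 0 || f > 1) .stopf("pruneNetwork: f must be in [0, 1]")
  m <- floor(f * numEdges(net))
  if (m == 0) return(net)
  g <- asIgraph(net)
  drop <- .withSeed(rngSeed, sample.int(igraph::ecount(g), m))
  new("Interactome", graph = igraph::delete_edges(g, drop))
}

#' Partially rewire a fraction of links, preserving all degrees
#'
#' Selects \code{floor(f * E)} edges, splits them into stubs, and re-pairs
#' the stubs uniformly at random (the configuration model restricted to the
#' selected links).  Pairings that would create a self-loop or duplicate an
#' existing edge are re-drawn; after \code{retryBudget} re-shuffles the
#' remaining conflicts are resolved by double-edge swaps against already
#' accepted pairs, so the result is always a simple graph with exactly the
#' input degree sequence.  This models interaction noise: selected links
#' are destroyed and the same number of new ones created elsewhere.
#'
#' @param net an [Interactome-class].
#' @param f fraction of links to rewire, in \[0, 1\].
#' @param rngSeed integer seed.
#' @param retryBudget full re-shuffles of conflicted stubs before falling
#'   back to double-edge swaps (default 100).
#' @return an [Interactome-class] with identical degree sequence.
#' @export
rewireNetwork <- function(net, f, rngSeed = NULL, retryBudget = 100) {
  stopifnot(is(net, "Interactome"))
  if (f < 0 || f > 1) .stopf("rewireNetwork: f must be in [0, 1]")
  m <- floor(f * numEdges(net))
  if (m == 0) return(net)
  g <- asIgraph(net)
  el <- igraph::as_edgelist(g, names = FALSE)
  .withSeed(rngSeed, {
    sel <- sample.int(nrow(el), m)
    kept <- el[-sel, , drop = FALSE]
    keptKeys <- .edgeKey(kept[, 1], kept[, 2])
    stubs <- as.vector(t(el[sel, , drop = FALSE]))
    accepted <- matrix(integer(), ncol = 2)
    tries <- 0L
    while (length(stubs) && tries <= retryBudget) {
      perm <- sample(stubs)
      a <- perm[seq(1, length(perm), by = 2)]
      b <- perm[seq(2, length(perm), by = 2)]
      keys <- .edgeKey(a, b)
      ok <- a != b & !keys %in% keptKeys & !duplicated(keys) &
            !keys %in% .edgeKey(accepted[, 1], accepted[, 2])
      accepted <- rbind(accepted, cbind(a[ok], b[ok]))
      stubs <- c(rbind(a[!ok], b[!ok]))
      tries <- tries + 1L
    }
    if (length(stubs)) {
      .msg(sprintf("rewireNetwork: %d stub(s) unresolved after %d re-shuffles; falling back to double-edge swaps",
                   length(stubs), retryBudget))
      accepted <- .swapFallback(stubs, accepted, keptKeys)
    }
    newEl <- rbind(kept, accepted)
    g2 <- igraph::make_empty_graph(n = igraph::vcount(g), directed = FALSE)
    igraph::V(g2)$name <- igraph::V(g)$name
    g2 <- igraph::add_edges(g2, t(newEl))
    new("Interactome", graph = g2)
  })
}

# Resolve leftover stubs by swapping endpoints with accepted pairs; each
# swap keeps both degrees intact.  Guaranteed to terminate: if no valid
# swap exists after many attempts we re-try with a different partner, and
# as a last resort pair the stubs directly even against a conflict is never
# needed because a swap partner always exists in graphs with enough
# accepted pairs; for pathological tiny graphs we error out.
.swapFallback <- function(stubs, accepted, keptKeys, maxAttempts = 10000L) {
  pairKey <- function(m) .edgeKey(m[, 1], m[, 2])
  while (length(stubs)) {
    x <- stubs[1]; y <- stubs[2]
    placed <- FALSE
    key <- .edgeKey(x, y)
    if (x != y && !key %in% keptKeys && !key %in% pairKey(accepted)) {
      accepted <- rbind(accepted, c(x, y))
      stubs <- stubs[-c(1, 2)]
      next
    }
    att <- 0L
    while (!placed && att < maxAttempts && nrow(accepted) > 0) {
      att <- att + 1L
      j <- sample.int(nrow(accepted), 1)
      a <- accepted[j, 1]; b <- accepted[j, 2]
      for (cand in list(c(x, a, y, b), c(x, b, y, a))) {
        k1 <- .edgeKey(cand[1], cand[2]); k2 <- .edgeKey(cand[3], cand[4])
        others <- pairKey(accepted[-j, , drop = FALSE])
        if (cand[1] != cand[2] && cand[3] != cand[4] && k1 != k2 &&
            !k1 %in% keptKeys && !k2 %in% keptKeys &&
            !k1 %in% others && !k2 %in% others) {
          accepted <- rbind(accepted[-j, , drop = FALSE],
                            c(cand[1], cand[2]), c(cand[3], cand[4]))
          placed <- TRUE
          break
        }
      }
    }
    if (!placed)
      .stopf("rewireNetwork: unable to re-pair stubs without violating simplicity")
    stubs <- stubs[-c(1, 2)]
  }
  accepted
}

#' Leave-one-seed-out robustness of the module ranking
#'
#' Reruns the module growth once per seed with that seed removed, and
#' compares each perturbed ranking to the original: the deviation at
#' iteration t is \code{1 - |top-t(original) intersect top-t(perturbed)|/t},
#' and the persistence is the fraction of iterations with deviation > 0.
#' Seeds whose removal causes persistent deviation are structurally
#' crucial; they tend to have far higher degree than the network average.
#'
#' @param net an [Interactome-class].
#' @param seeds a [SeedSet-class] or character vector with >= 2 mapped
#'   seeds.
#' @param nIterations growth budget per run (default 200).
#' @param alpha seed weight >= 1.
#' @return list with \code{summary}, a data.frame (removedSeed, degree,
#'   persistence, maxDeviation), and \code{curves}, a named list of
#'   per-seed data.frames (iteration, deviation).
#' @export
nMinusOne <- function(net, seeds, nIterations = 200, alpha = 1) {
  stopifnot(is(net, "Interactome"))
  seeds <- .asSeedSet(net, seeds)
  if (seedCount(seeds) < 2)
    .stopf("nMinusOne: need at least 2 mapped seeds")
  suppress <- function(expr) withCallingHandlers(expr,
    warning = function(w) invokeRestart("muffleWarning"))
  original <- suppress(runDiamond(net, seeds, nIterations, alpha))
  orig <- rankedGenes(original)
  deg <- nodeDegrees(net)
  members <- seedNames(seeds)
  curves <- list()
  rows <- lapply(members, function(s) {
    pert <- suppress(runDiamond(net, setdiff(members, s), nIterations, alpha))
    dev <- deviationCurve(orig, rankedGenes(pert))
    curves[[s]] <<- dev
    data.frame(removedSeed = s, degree = as.integer(deg[[s]]),
               persistence = mean(dev$deviation > 0),
               maxDeviation = max(dev$deviation))
  })
  list(summary = do.call(rbind, rows), curves = curves)
}

#' Deviation curve between two rankings
#'
#' \code{deviation(t) = 1 - |top-t(a) intersect top-t(b)| / t} for
#' t = 1..min(length(a), length(b)).  Identical rankings give deviation 0
#' everywhere.
#'
#' @param a,b character vectors of ranked identifiers.
#' @return data.frame with columns iteration, deviation.
#' @export
deviationCurve <- function(a, b) {
  n <- min(length(a), length(b))
  a <- a[seq_len(n)]; b <- b[seq_len(n)]
  pos <- match(a, b)
  dev <- vapply(seq_len(n), function(t) {
    1 - sum(!is.na(pos[seq_len(t)]) & pos[seq_len(t)] <= t) / t
  }, numeric(1))
  data.frame(iteration = seq_len(n), deviation = dev)
}

#' Ranking overlap under network perturbation
#'
#' Runs module growth on the original network and on a perturbed copy and
#' reports, per iteration, the overlap (shared proteins in the top-t sets)
#' as a fraction of t.  At f = 0 the overlap is 1 everywhere.
#'
#' @param net an [Interactome-class].
#' @param perturbed a perturbed [Interactome-class] (see [pruneNetwork()],
#'   [rewireNetwork()]).
#' @param seeds a [SeedSet-class] or character vector.
#' @param nIterations growth budget.
#' @param alpha seed weight.
#' @return data.frame with columns iteration, overlap.
#' @export
perturbationOverlap <- function(net, perturbed, seeds, nIterations = 200, alpha = 1) {
  suppress <- function(expr) withCallingHandlers(expr,
    warning = function(w) invokeRestart("muffleWarning"))
  seeds <- .asSeedSet(net, seeds)
  a <- rankedGenes(suppress(runDiamond(net, seeds, nIterations, alpha)))
  bSeeds <- intersect(seedNames(seeds), nodeNames(perturbed))
  b <- rankedGenes(suppress(runDiamond(perturbed, bSeeds, nIterations, alpha)))
  dev <- deviationCurve(a, b)
  data.frame(iteration = dev$iteration, overlap = 1 - dev$deviation)
}
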