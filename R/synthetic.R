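# Synthetic fixtures: background networks, planted modules, and recovery
# experiments measuring how well module growth re-discovers hidden members.

#' Synthetic background networks
#'
#' `syntheticInteractome()` generates a scale-free background network by
#' preferential attachment, emulating the heavy-tailed degree distribution
#' of real interactomes.  `randomInteractome()` generates an Erdos-Renyi
#' G(n, m) graph, useful as an unstructured null background.  Node
#' identifiers are zero-padded strings ("g0001", ...).
#'
#' @param nNodes number of nodes.
#' @param edgesPerNode preferential-attachment edges added per node
#'   (default 10, giving mean degree near 20 — the density of consolidated
#'   human interactome maps).
#' @param nEdges edge count for the G(n, m) variant.
#' @param rngSeed integer seed for reproducible generation.
#' @return an [Interactome-class].
#' @export
syntheticInteractome <- function(nNodes = 5000, edgesPerNode = 10, rngSeed = NULL) {
  g <- .withSeed(rngSeed, igraph::sample_pa(nNodes, m = edgesPerNode, directed = FALSE))
  igraph::V(g)$name <- .geneNames(nNodes)
  Interactome(g)
}

#' @rdname syntheticInteractome
#' @export
randomInteractome <- function(nNodes, nEdges, rngSeed = NULL) {
  g <- .withSeed(rngSeed, igraph::sample_gnm(nNodes, nEdges))
  igraph::V(g)$name <- .geneNames(nNodes)
  Interactome(g)
}

.geneNames <- function(n) {
  sprintf("g%0*d", nchar(as.character(n)), seq_len(n))
}

#' Plant a clique into a sparse random background
#'
#' Wires a fully connected clique over \code{cliqueSize} randomly chosen
#' nodes of a sparse G(n, m) background, a controlled fixture whose module
#' membership is known exactly.
#'
#' @param nNodes background node count (default 500).
#' @param nEdges background edge count (default 1000, mean degree 4).
#' @param cliqueSize clique order (default 20).
#' @param rngSeed integer seed.
#' @return list with elements \code{net} (an [Interactome-class]) and
#'   \code{clique} (character vector of planted members).
#' @export
plantedCliqueInteractome <- function(nNodes = 500, nEdges = 1000, cliqueSize = 20,
                                     rngSeed = NULL) {
  .withSeed(rngSeed, {
    g <- igraph::sample_gnm(nNodes, nEdges)
    igraph::V(g)$name <- .geneNames(nNodes)
    members <- sample(igraph::V(g)$name, cliqueSize)
    pairs <- t(combn(members, 2))
    g <- igraph::add_edges(g, t(pairs))
    list(net = Interactome(igraph::simplify(g)), clique = sort(members))
  })
}

#' Build a shell module: radius-2 neighborhood of a start node
#'
#' Members are the start node together with all its first and second
#' neighbors (the breadth-first ball of radius 2).
#'
#' @param net an [Interactome-class].
#' @param start identifier of the start node.
#' @return a [SyntheticModule-class].
#' @export
makeShellModule <- function(net, start) {
  stopifnot(is(net, "Interactome"))
  start <- as.character(start)
  if (!start %in% nodeNames(net))
    .stopf("makeShellModule: start node '%s' not in the network", start)
  ball <- igraph::ego(asIgraph(net), order = 2, nodes = start)[[1]]
  new("SyntheticModule", members = sort(ball$name), method = "shell",
      startNode = start, targetSize = NA_integer_, rngSeed = NA_integer_)
}

#' Build a connectivity-significance module
#'
#' Grows from a single start node by the same lowest-p-value rule as
#' [runDiamond()] until the module reaches \code{targetSize} nodes,
#' producing planted modules with connectivity patterns similar to real
#' disease proteins.  The default target size of 200 reflects the putative
#' size of a complete disease module.
#'
#' @param net an [Interactome-class].
#' @param start identifier of the start node.
#' @param targetSize desired module size (default 200).  If the start
#'   node's component is smaller, the full component is returned with a
#'   warning.
#' @return a [SyntheticModule-class].
#' @export
makeConnectivityModule <- function(net, start, targetSize = 200) {
  stopifnot(is(net, "Interactome"))
  start <- as.character(start)
  if (!start %in% nodeNames(net))
    .stopf("makeConnectivityModule: start node '%s' not in the network", start)
  targetSize <- as.integer(targetSize)
  if (targetSize < 1) .stopf("makeConnectivityModule: targetSize must be >= 1")
  members <- start
  if (targetSize > 1) {
    rk <- withCallingHandlers(
      runDiamond(net, start, nIterations = targetSize - 1L),
      warning = function(w) {
        warning(sprintf("makeConnectivityModule: component of '%s' smaller than targetSize %d; returning the full component",
                        start, targetSize), call. = FALSE)
        invokeRestart("muffleWarning")
      })
    members <- c(start, rankedGenes(rk))
  }
  new("SyntheticModule", members = sort(members), method = "connectivity",
      startNode = start, targetSize = targetSize, rngSeed = NA_integer_)
}

#' Sample a planted module with a random start node
#'
#' Picks a start node uniformly among nodes whose connected component can
#' host the target size, then delegates to [makeShellModule()] or
#' [makeConnectivityModule()].
#'
#' @param net an [Interactome-class].
#' @param method "connectivity" or "shell".
#' @param targetSize module size for connectivity modules (default 200).
#' @param rngSeed integer seed.
#' @return a [SyntheticModule-class].
#' @export
sampleModule <- function(net, method = c("connectivity", "shell"),
                         targetSize = 200, rngSeed = NULL) {
  method <- match.arg(method)
  g <- asIgraph(net)
  comp <- igraph::components(g)
  eligible <- which(comp$csize[comp$membership] >= if (method == "connectivity") targetSize else 1)
  if (!length(eligible))
    .stopf("sampleModule: no component can host targetSize %d", targetSize)
  start <- .withSeed(rngSeed, nodeNames(net)[sample(eligible, 1)])
  mod <- if (method == "shell") makeShellModule(net, start)
         else makeConnectivityModule(net, start, targetSize)
  mod@rngSeed <- if (is.null(rngSeed)) NA_integer_ else as.integer(rngSeed)
  mod
}

#' @rdname SyntheticModule-accessors
#' @param x a [SyntheticModule-class].
#' @export
setMethod("moduleMembers", "SyntheticModule", function(x) x@members)

setMethod("show", "SyntheticModule", function(object) {
  cat(sprintf("SyntheticModule (%s): %d member(s), start '%s'\n",
              object@method, length(object@members), object@startNode))
})

#' Recovery experiment: hide module members and re-discover them
#'
#' Removes \code{floor(removeFraction * |members|)} uniformly chosen
#' members of a module (always keeping at least one and removing at least
#' one), runs module growth from the kept members, and records recall —
#' recovered hidden members over total hidden — after every iteration.
#'
#' For disease seed sets (the real-data variant), pass the member
#' identifiers as \code{module}; with \code{restrictToLCC = TRUE} the
#' removal pool is restricted to members of the seed LCC, mirroring the
#' observation that recall is higher when associations are removed from
#' connected seed proteins.
#'
#' @param net an [Interactome-class].
#' @param module a [SyntheticModule-class], [SeedSet-class], or character
#'   vector of member identifiers.
#' @param removeFraction fraction of members to hide, in (0, 1).
#' @param nIterations growth budget (default: number of removed members,
#'   capped at 2x; see Details in the vignette).
#' @param rngSeed integer seed governing the removal draw.
#' @param restrictToLCC restrict removal to the module's LCC members.
#' @return a [RecoveryExperiment-class].
#' @export
runRecovery <- function(net, module, removeFraction, nIterations = NULL,
                        rngSeed = NULL, restrictToLCC = FALSE) {
  stopifnot(is(net, "Interactome"))
  members <- if (is(module, "SyntheticModule")) moduleMembers(module)
             else if (is(module, "SeedSet")) seedNames(module)
             else unique(as.character(module))
  members <- intersect(members, nodeNames(net))
  if (removeFraction <= 0 || removeFraction >= 1)
    .stopf("runRecovery: removeFraction must be in (0, 1)")
  nRemove <- floor(removeFraction * length(members))
  if (nRemove < 1 || nRemove >= length(members))
    .stopf("runRecovery: removal of %d node(s) from %d leaves no usable split",
           nRemove, length(members))
  pool <- members
  if (restrictToLCC) {
    g <- asIgraph(net)
    idx <- which(nodeNames(net) %in% members)
    sub <- igraph::induced_subgraph(g, idx)
    comp <- igraph::components(sub)
    lcc <- igraph::V(sub)$name[comp$membership == which.max(comp$csize)]
    if (length(lcc) > nRemove) pool <- lcc
  }
  removed <- .withSeed(rngSeed, sample(pool, nRemove))
  kept <- setdiff(members, removed)
  if (is.null(nIterations)) nIterations <- 2L * nRemove
  rk <- withCallingHandlers(
    runDiamond(net, kept, nIterations = nIterations),
    warning = function(w) invokeRestart("muffleWarning"))
  genes <- rankedGenes(rk)
  recall <- cumsum(genes %in% removed) / length(removed)
  new("RecoveryExperiment", removed = sort(removed), keptSeeds = sort(kept),
      recallCurve = data.frame(iteration = seq_along(genes), recall = recall),
      rngSeed = if (is.null(rngSeed)) NA_integer_ else as.integer(rngSeed))
}

#' Recall at a given iteration
#'
#' @param x a [RecoveryExperiment-class].
#' @param iteration iteration index; values beyond the recorded curve
#'   return the final recall.
#' @return recall fraction in \[0, 1\].
#' @export
recallAt <- function(x, iteration) {
  stopifnot(is(x, "RecoveryExperiment"))
  rc <- x@recallCurve
  if (!nrow(rc)) return(0)
  rc$recall[pmin(pmax(iteration, 1L), nrow(rc))]
}

setMethod("show", "RecoveryExperiment", function(object) {
  final <- if (nrow(object@recallCurve)) object@recallCurve$recall[nrow(object@recallCurve)] else 0
  cat(sprintf("RecoveryExperiment: %d kept seed(s), %d removed, final recall %.2f over %d iteration(s)\n",
              length(object@keptSeeds), length(object@removed), final,
              nrow(object@recallCurve)))
})

#' Write a recovery curve to TSV with a JSON configuration sidecar
#'
#' @param x a [RecoveryExperiment-class].
#' @param path output TSV (columns iteration, recall); the configuration is
#'   written alongside as \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
writeRecovery <- function(x, path) {
  stopifnot(is(x, "RecoveryExperiment"))
  write.table(x@recallCurve, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- list(removed = x@removed, keptSeeds = x@keptSeeds,
              rngSeed = if (is.na(x@rngSeed)) NULL else x@rngSeed)
  jsonlite::write_json(cfg, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
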