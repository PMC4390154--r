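#' @import methods
#' @importFrom stats fisher.test median p.adjust quantile runif sd setNames
#' @importFrom utils combn head packageVersion read.table write.table
NULL

setOldClass("igraph")

#' Interactome: an undirected simple protein-interaction network
#'
#' Thin S4 wrapper around an [igraph::igraph] object that guarantees the
#' invariants all statistics in this package rely on: the graph is
#' undirected, simple (no self-loops, no multi-edges) and every node carries
#' a character name.  Identifiers are opaque strings; no gene-identifier
#' translation is performed.
#'
#' @slot graph the underlying \code{igraph} object.
#' @seealso [loadEdgeList()], [Interactome()], [numNodes()], [lccSize()]
#' @export
setClass("Interactome", representation(graph = "igraph"), validity = function(object) {
  g <- object@graph
  msgs <- character()
  if (igraph::is_directed(g))
    msgs <- c(msgs, "graph must be undirected")
  if (igraph::any_loop(g))
    msgs <- c(msgs, "graph must not contain self-loops")
  if (igraph::any_multiple(g))
    msgs <- c(msgs, "graph must not contain duplicate edges")
  if (igraph::vcount(g) > 0 &&
      (is.null(igraph::V(g)$name) || anyNA(igraph::V(g)$name)))
    msgs <- c(msgs, "every node must carry a character name")
  if (length(msgs)) msgs else TRUE
})

#' SeedSet: seed proteins mapped onto an interactome
#'
#' Records which of the requested identifiers are present in the network
#' (\code{members}) and which were not found (\code{unmapped}).  All module
#' statistics operate on the mapped members only; the initial seed count
#' \eqn{s_0} is \code{length(members)}.
#'
#' @slot name label for the seed set (e.g. a disease name).
#' @slot members identifiers present in the network.
#' @slot unmapped requested identifiers absent from the network.
#' @seealso [seedSet()]
#' @export
setClass("SeedSet",
  representation(name = "character", members = "character", unmapped = "character"),
  validity = function(object) {
    if (anyDuplicated(object@members))
      return("seed members must be unique")
    if (length(intersect(object@members, object@unmapped)))
      return("members and unmapped must be disjoint")
    TRUE
  })

#' LCCStats: significance of seed-set agglomeration
#'
#' Size of the largest connected component (LCC) induced by a seed set,
#' compared against LCC sizes of uniformly drawn random node sets of the
#' same cardinality.
#'
#' @slot lccSize observed LCC size.
#' @slot zScore (observed - random mean) / random sd; \code{NA} when the
#'   null distribution is degenerate (sd = 0).
#' @slot empiricalP upper-tail empirical p-value with the (r+1)/(n+1)
#'   correction, so a never-exceeded observation reports p < 1/(n+1)
#'   rather than 0.
#' @slot nRandom number of random replicates.
#' @slot randomMean,randomSD moments of the null LCC-size distribution.
#' @slot degenerate TRUE when the null sd was zero.
#' @slot rngSeed seed used for the random draws (NA if none supplied).
#' @export
setClass("LCCStats", representation(
  lccSize = "integer", zScore = "numeric", empiricalP = "numeric",
  nRandom = "integer", randomMean = "numeric", randomSD = "numeric",
  degenerate = "logical", rngSeed = "integer"))

#' ModularityResult: local modularity R of a candidate community
#'
#' The boundary B of a community C holds the members with at least one link
#' leaving C.  R is the fraction of edges incident to B that stay inside C;
#' R = 1 for a fully separated community (empty boundary), R near 0 for a
#' randomly scattered one.
#'
#' @slot R local modularity in \[0, 1\].
#' @slot boundarySize number of boundary nodes.
#' @slot communitySize number of community members.
#' @export
setClass("ModularityResult", representation(
  R = "numeric", boundarySize = "integer", communitySize = "integer"),
  validity = function(object) {
    if (object@R < 0 || object@R > 1) return("R must lie in [0,1]")
    TRUE
  })

#' DiamondRanking: ordered output of the module-growth iteration
#'
#' One row per iteration: the agglomerated gene, its degree \code{k}, its
#' number of links to the module at the time of addition \code{ks}, and its
#' connectivity p-value.  The order is the module-relevance ranking.
#'
#' @slot entries data.frame with columns iteration, gene, degree, seedLinks,
#'   pValue.
#' @slot seeds the [SeedSet-class] the run started from.
#' @slot nIterations requested iteration budget.
#' @slot alpha seed weight used (1 = unweighted).
#' @seealso [runDiamond()], [rankingTable()], [moduleLCC()]
#' @export
setClass("DiamondRanking", representation(
  entries = "data.frame", seeds = "SeedSet",
  nIterations = "integer", alpha = "numeric"),
  validity = function(object) {
    e <- object@entries
    need <- c("iteration", "gene", "degree", "seedLinks", "pValue")
    if (!all(need %in% names(e)))
      return(paste("entries must have columns", paste(need, collapse = ", ")))
    if (nrow(e)) {
      if (!identical(as.integer(e$iteration), seq_len(nrow(e))))
        return("iterations must be consecutive from 1")
      if (anyDuplicated(e$gene))
        return("no gene may appear twice")
      if (length(intersect(e$gene, object@seeds@members)))
        return("no seed may appear as an entry")
    }
    TRUE
  })

#' SyntheticModule: a planted connected node set
#'
#' Built either as the radius-2 neighborhood shell of a start node or by
#' connectivity-significance growth to a target size; used for recovery
#' benchmarks where a fraction of the members is hidden and re-discovered.
#'
#' @slot members module members (induce a connected subgraph).
#' @slot method "shell" or "connectivity".
#' @slot startNode the node the construction started from.
#' @slot targetSize requested size (NA for shell modules).
#' @slot rngSeed seed used to pick the start node (NA if supplied directly).
#' @seealso [makeShellModule()], [makeConnectivityModule()], [runRecovery()]
#' @export
setClass("SyntheticModule", representation(
  members = "character", method = "character", startNode = "character",
  targetSize = "integer", rngSeed = "integer"),
  validity = function(object) {
    if (!object@method %in% c("shell", "connectivity"))
      return("method must be 'shell' or 'connectivity'")
    if (!object@startNode %in% object@members)
      return("startNode must be a member")
    TRUE
  })

#' RecoveryExperiment: recall of removed module members
#'
#' A fraction of a (synthetic or disease) module is hidden, the remainder
#' seeds a module-growth run, and recall — the fraction of hidden members
#' recovered — is recorded after every iteration.
#'
#' @slot removed identifiers whose association was hidden.
#' @slot keptSeeds identifiers used as seeds.
#' @slot recallCurve data.frame with columns iteration, recall
#'   (non-decreasing, in \[0, 1\]).
#' @slot rngSeed seed governing the random removal.
#' @export
setClass("RecoveryExperiment", representation(
  removed = "character", keptSeeds = "character",
  recallCurve = "data.frame", rngSeed = "integer"),
  validity = function(object) {
    if (length(intersect(object@removed, object@keptSeeds)))
      return("removed and kept seeds must be disjoint")
    rc <- object@recallCurve$recall
    if (length(rc) && (any(rc < 0 | rc > 1) || is.unsorted(rc)))
      return("recall curve must be non-decreasing within [0,1]")
    TRUE
  })

#' AnnotationCollection: gene-set annotations (GMT)
#'
#' A mapping from term identifiers to gene sets over a background universe,
#' as read from a tab-separated GMT file (term, description, member genes).
#'
#' @slot terms named list of character vectors (term -> genes).
#' @slot descriptions named character vector of term descriptions.
#' @slot background universe of annotated genes.
#' @seealso [loadGMT()], [enrichSeedTerms()], [makeSyntheticAnnotations()]
#' @export
setClass("AnnotationCollection", representation(
  terms = "list", descriptions = "character", background = "character"),
  validity = function(object) {
    if (length(object@terms) && is.null(names(object@terms)))
      return("terms must be named")
    if (!all(unlist(object@terms, use.names = FALSE) %in% object@background))
      return("every annotated gene must be in the background")
    TRUE
  })

#' ValidationResult: annotation-based validation of a ranking
#'
#' @slot significantTerms terms enriched in the seed set.
#' @slot table data.frame with columns iteration, gene, tp, windowP.
#' @slot seedTpRate fraction of seed genes annotated with a significant term.
#' @slot window sliding-window width used.
#' @seealso [validateRanking()]
#' @export
setClass("ValidationResult", representation(
  significantTerms = "character", table = "data.frame",
  seedTpRate = "numeric", window = "integer"))
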