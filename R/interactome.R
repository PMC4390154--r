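#' Construct an Interactome
#'
#' Builds an [Interactome-class] from an \code{igraph} object or from a
#' two-column data.frame/matrix of edges.  Self-loops and duplicate edges
#' are dropped (with a message reporting how many), edge direction is
#' discarded, and isolated nodes listed in \code{nodes} are retained.
#'
#' @param x an \code{igraph} object or a two-column edge table whose columns
#'   are coerced to character identifiers.
#' @param nodes optional character vector of node identifiers to include
#'   even if they carry no edge.
#' @return an [Interactome-class].
#' @examples
#' net <- Interactome(data.frame(a = c("A", "B"), b = c("B", "C")))
#' numNodes(net)
#' @export
Interactome <- function(x, nodes = NULL) {
  if (igraph::is_igraph(x)) {
    g <- x
    if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
    if (igraph::vcount(g) > 0 && is.null(igraph::V(g)$name))
      igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    nSelf <- sum(igraph::which_loop(g))
    nDup <- sum(igraph::count_multiple(g) > 1) # edges participating in a multiple
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
    if (nSelf > 0 || nDup > 0)
      .msg(sprintf("dropped %d self-loop(s) and collapsed duplicate edges (%d edges involved)",
                   nSelf, nDup))
  } else {
    x <- as.data.frame(x)
    if (ncol(x) < 2) .stopf("edge table must have at least two columns")
    a <- as.character(x[[1]]); b <- as.character(x[[2]])
    keep <- a != b
    nSelf <- sum(!keep)
    a <- a[keep]; b <- b[keep]
    key <- .edgeKey(a, b)
    first <- !duplicated(key)
    nDup <- sum(!first)
    if (nSelf > 0 || nDup > 0)
      .msg(sprintf("dropped %d self-loop(s) and %d duplicate edge line(s)", nSelf, nDup))
    a <- a[first]; b <- b[first]
    ids <- unique(c(a, b, nodes))
    g <- igraph::graph_from_data_frame(data.frame(from = a, to = b),
                                       directed = FALSE,
                                       vertices = data.frame(name = ids))
  }
  if (!is.null(nodes)) {
    missing <- setdiff(nodes, igraph::V(g)$name)
    if (length(missing)) g <- igraph::add_vertices(g, length(missing), name = missing)
  }
  new("Interactome", graph = g)
}

#' Read an interaction network from a delimited edge list
#'
#' Expects one interaction per line with at least two identifier columns;
#' lines starting with \code{#} are ignored, extra columns are ignored.
#' The resulting graph is undirected and simple: duplicate lines (in either
#' orientation) and self-loops are dropped and their counts reported.
#'
#' @param path path to the edge-list file.
#' @param delimiter field separator, default tab.
#' @return an [Interactome-class].
#' @export
loadEdgeList <- function(path, delimiter = "\t") {
  if (!file.exists(path)) .stopf("cannot read edge list: '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(Interactome(data.frame(a = character(), b = character())))
  parts <- strsplit(lines, delimiter, fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2))
    .stopf("parse error at line %d: expected at least 2 columns, found %d",
           lineNo[which(nf < 2)[1]], nf[which(nf < 2)[1]])
  Interactome(data.frame(a = vapply(parts, `[[`, "", 1L),
                         b = vapply(parts, `[[`, "", 2L)))
}

#' Write an interactome as a two-column TSV edge list
#'
#' @param net an [Interactome-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeEdgeList <- function(net, path) {
  el <- igraph::as_edgelist(asIgraph(net))
  write.table(el, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Accessors for Interactome objects
#'
#' \code{numNodes}/\code{numEdges} return the node and edge counts,
#' \code{nodeNames} the identifiers, \code{nodeDegrees} a named integer
#' vector of degrees, and \code{asIgraph} the underlying \code{igraph}.
#'
#' @param x an [Interactome-class].
#' @name Interactome-accessors
#' @aliases numNodes numEdges nodeNames nodeDegrees asIgraph
NULL

#' @rdname Interactome-accessors
#' @export
setMethod("numNodes", "Interactome", function(x) as.integer(igraph::vcount(x@graph)))

#' @rdname Interactome-accessors
#' @export
setMethod("numEdges", "Interactome", function(x) as.integer(igraph::ecount(x@graph)))

#' @rdname Interactome-accessors
#' @export
setMethod("nodeNames", "Interactome", function(x) igraph::V(x@graph)$name)

#' @rdname Interactome-accessors
#' @export
setMethod("nodeDegrees", "Interactome", function(x) {
  d <- igraph::degree(x@graph)
  setNames(as.integer(d), igraph::V(x@graph)$name)
})

#' @rdname Interactome-accessors
#' @export
setMethod("asIgraph", "Interactome", function(x) x@graph)

setMethod("show", "Interactome", function(object) {
  cat(sprintf("Interactome: %d proteins, %d interactions (mean degree %.1f)\n",
              numNodes(object), numEdges(object),
              if (numNodes(object)) 2 * numEdges(object) / numNodes(object) else 0))
})

#' Map seed identifiers onto an interactome
#'
#' @param net an [Interactome-class].
#' @param ids character vector of protein identifiers (duplicates removed).
#' @param name label for the set.
#' @return a [SeedSet-class]; identifiers absent from the network are kept
#'   in the \code{unmapped} slot and reported via a message.
#' @examples
#' net <- Interactome(data.frame(a = "A", b = "B"))
#' seedSet(net, c("A", "Z"))
#' @export
seedSet <- function(net, ids, name = "seeds") {
  stopifnot(is(net, "Interactome"))
  ids <- unique(as.character(ids))
  present <- ids %in% nodeNames(net)
  if (any(!present))
    .msg(sprintf("seed set '%s': %d of %d identifiers not in the network",
                 name, sum(!present), length(ids)))
  new("SeedSet", name = name, members = ids[present], unmapped = ids[!present])
}

#' Accessors for SeedSet objects
#' @param x a [SeedSet-class].
#' @name SeedSet-accessors
#' @aliases seedNames seedCount unmappedNames
NULL

#' @rdname SeedSet-accessors
#' @export
setMethod("seedNames", "SeedSet", function(x) x@members)

#' @rdname SeedSet-accessors
#' @export
setMethod("seedCount", "SeedSet", function(x) length(x@members))

#' @rdname SeedSet-accessors
#' @export
setMethod("unmappedNames", "SeedSet", function(x) x@unmapped)

setMethod("show", "SeedSet", function(object) {
  cat(sprintf("SeedSet '%s': %d mapped seed(s), %d unmapped\n",
              object@name, length(object@members), length(object@unmapped)))
})

# Coerce seeds given as a character vector.
.asSeedSet <- function(net, seeds, name = "seeds") {
  if (is(seeds, "SeedSet")) seeds else seedSet(net, seeds, name = name)
}

#' Read disease-gene association tables
#'
#' Accepts either a two-column TSV (disease_name, gene_id; one pair per
#' line, optional header detected when the first line's second field is
#' "gene_id") or a single-column plain list of identifiers for one set.
#'
#' @param path path to the table.
#' @param delimiter field separator, default tab.
#' @return a named list of character vectors (disease -> gene identifiers).
#' @export
loadSeedTable <- function(path, delimiter = "\t") {
  if (!file.exists(path)) .stopf("cannot read seed table: '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) return(list())
  parts <- strsplit(lines, delimiter, fixed = TRUE)
  nf <- lengths(parts)
  if (all(nf == 1)) {
    return(list(seeds = unique(trimws(vapply(parts, `[[`, "", 1L)))))
  }
  if (any(nf < 2))
    .stopf("parse error at line %d of '%s': expected 2 columns", which(nf < 2)[1], path)
  disease <- vapply(parts, `[[`, "", 1L)
  gene <- vapply(parts, `[[`, "", 2L)
  if (tolower(gene[1]) %in% c("gene_id", "gene")) {
    disease <- disease[-1]; gene <- gene[-1]
  }
  lapply(split(gene, disease), unique)
}
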