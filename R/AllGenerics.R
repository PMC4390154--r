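#' @rdname Interactome-accessors
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname Interactome-accessors
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname Interactome-accessors
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' @rdname Interactome-accessors
#' @export
setGeneric("nodeDegrees", function(x) standardGeneric("nodeDegrees"))

#' @rdname Interactome-accessors
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @rdname SeedSet-accessors
#' @export
setGeneric("seedNames", function(x) standardGeneric("seedNames"))

#' @rdname SeedSet-accessors
#' @export
setGeneric("seedCount", function(x) standardGeneric("seedCount"))

#' @rdname SeedSet-accessors
#' @export
setGeneric("unmappedNames", function(x) standardGeneric("unmappedNames"))

#' @rdname DiamondRanking-accessors
#' @export
setGeneric("rankingTable", function(x) standardGeneric("rankingTable"))

#' @rdname DiamondRanking-accessors
#' @export
setGeneric("rankedGenes", function(x) standardGeneric("rankedGenes"))

#' @rdname SyntheticModule-accessors
#' @export
setGeneric("moduleMembers", function(x) standardGeneric("moduleMembers"))

#' @rdname AnnotationCollection-accessors
#' @export
setGeneric("termNames", function(x) standardGeneric("termNames"))

#' @rdname AnnotationCollection-accessors
#' @export
setGeneric("termGenes", function(x, term) standardGeneric("termGenes"))

#' @rdname AnnotationCollection-accessors
#' @export
setGeneric("annotationBackground", function(x) standardGeneric("annotationBackground"))
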