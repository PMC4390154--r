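# Annotation-based validation: seed-term enrichment, true-positive flags
# for ranked candidates, and sliding-window significance.

#' Read a gene-set collection in GMT format
#'
#' One term per line: term identifier, description, then member genes,
#' tab-separated.  Unless an explicit \code{background} is supplied, the
#' background universe is the union of all annotated genes.
#'
#' @param path path to the GMT file.
#' @param background optional character vector defining the universe.
#' @return an [AnnotationCollection-class].
#' @export
loadGMT <- function(path, background = NULL) {
  if (!file.exists(path)) .stopf("cannot read GMT: '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(new("AnnotationCollection", terms = list(),
               descriptions = character(), background = as.character(background %||% character())))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3))
    .stopf("parse error at line %d: GMT lines need term, description and >= 1 gene",
           which(nf < 3)[1])
  terms <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(terms) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(terms)))
    .stopf("duplicate term identifier '%s'", names(terms)[duplicated(names(terms))][1])
  desc <- setNames(vapply(parts, `[[`, "", 2L), names(terms))
  bg <- if (is.null(background)) unique(unlist(terms, use.names = FALSE))
        else unique(as.character(background))
  new("AnnotationCollection", terms = terms, descriptions = desc, background = bg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a gene-set collection in GMT format
#'
#' @param ann an [AnnotationCollection-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGMT <- function(ann, path) {
  stopifnot(is(ann, "AnnotationCollection"))
  lines <- vapply(names(ann@terms), function(tm) {
    d <- if (tm %in% names(ann@descriptions)) ann@descriptions[[tm]] else ""
    paste(c(tm, d, ann@terms[[tm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Accessors for AnnotationCollection objects
#' @param x an [AnnotationCollection-class].
#' @param term a term identifier.
#' @name AnnotationCollection-accessors
#' @aliases termNames termGenes annotationBackground
NULL

#' @rdname AnnotationCollection-accessors
#' @export
setMethod("termNames", "AnnotationCollection", function(x) names(x@terms))

#' @rdname AnnotationCollection-accessors
#' @export
setMethod("termGenes", "AnnotationCollection", function(x, term) {
  if (!term %in% names(x@terms)) .stopf("unknown term '%s'", term)
  x@terms[[term]]
})

#' @rdname AnnotationCollection-accessors
#' @export
setMethod("annotationBackground", "AnnotationCollection", function(x) x@background)

setMethod("show", "AnnotationCollection", function(object) {
  cat(sprintf("AnnotationCollection: %d term(s) over %d background gene(s)\n",
              length(object@terms), length(object@background)))
})

#' Terms enriched within a seed set
#'
#' One-sided (enrichment) Fisher's exact test per term on the 2x2 table
#' seed/non-seed x annotated/not, over the collection's background
#' universe, with Bonferroni correction across the tested terms.
#'
#' @param ann an [AnnotationCollection-class].
#' @param seeds a [SeedSet-class] or character vector; members outside the
#'   background are dropped (the universe is the annotation background).
#' @param alphaLevel corrected significance threshold (default 0.05).
#' @return character vector of significant term identifiers; the full test
#'   table (term, overlap, p, pBonferroni) is attached as
#'   \code{attr(, "tests")}.
#' @export
enrichSeedTerms <- function(ann, seeds, alphaLevel = 0.05) {
  stopifnot(is(ann, "AnnotationCollection"))
  seedIds <- if (is(seeds, "SeedSet")) seedNames(seeds) else unique(as.character(seeds))
  seedIds <- intersect(seedIds, ann@background)
  if (!length(seedIds)) .stopf("enrichSeedTerms: no seed is in the annotation background")
  if (!length(ann@terms)) {
    out <- character()
    attr(out, "tests") <- data.frame(term = character(), overlap = integer(),
                                     p = numeric(), pBonferroni = numeric())
    return(out)
  }
  nBg <- length(ann@background)
  nSeed <- length(seedIds)
  tests <- lapply(names(ann@terms), function(tm) {
    genes <- ann@terms[[tm]]
    a <- length(intersect(genes, seedIds))
    tab <- matrix(c(a, nSeed - a,
                    length(genes) - a, nBg - nSeed - (length(genes) - a)), 2)
    p <- fisher.test(tab, alternative = "greater")$p.value
    data.frame(term = tm, overlap = a, p = p)
  })
  tab <- do.call(rbind, tests)
  tab$pBonferroni <- p.adjust(tab$p, method = "bonferroni")
  sig <- tab$term[tab$pBonferroni < alphaLevel]
  attr(sig, "tests") <- tab
  sig
}

#' Validate a ranking against seed-enriched annotations
#'
#' Flags each ranked gene as a true positive (TP) iff it is annotated with
#' at least one seed-enriched term, then scans the ranking with a sliding
#' window (width = the number of seed genes by default, so window counts
#' remain comparable across iterations): at iteration i the TPs among the
#' ranked genes in \code{[i - window/2, i + window/2]} (truncated at the
#' ends; seeds excluded) are tested against the background annotation rate
#' with a one-sided Fisher's exact test.
#'
#' @param ranking a [DiamondRanking-class] or character vector of ranked
#'   genes.
#' @param significantTerms term identifiers from [enrichSeedTerms()]; if
#'   empty, all flags are FALSE and all window p-values 1 (with a warning).
#' @param ann an [AnnotationCollection-class].
#' @param window window width (default: seed count when \code{ranking} is a
#'   [DiamondRanking-class], else 20).
#' @return a [ValidationResult-class].
#' @export
validateRanking <- function(ranking, significantTerms, ann, window = NULL) {
  stopifnot(is(ann, "AnnotationCollection"))
  if (is(ranking, "DiamondRanking")) {
    genes <- rankedGenes(ranking)
    seedIds <- seedNames(ranking@seeds)
    if (is.null(window)) window <- max(1L, seedCount(ranking@seeds))
  } else {
    genes <- as.character(ranking)
    seedIds <- character()
    if (is.null(window)) window <- 20L
  }
  window <- as.integer(window)
  if (window < 1) .stopf("validateRanking: window must be >= 1")
  tpGenes <- unique(unlist(ann@terms[intersect(significantTerms, names(ann@terms))],
                           use.names = FALSE))
  if (!length(significantTerms)) {
    warning("validateRanking: no significant terms; all flags FALSE", call. = FALSE)
    tab <- data.frame(iteration = seq_along(genes), gene = genes,
                      tp = FALSE, windowP = 1)
    return(new("ValidationResult", significantTerms = character(), table = tab,
               seedTpRate = NA_real_, window = window))
  }
  tp <- genes %in% tpGenes
  nBg <- length(ann@background)
  nBgTP <- length(intersect(tpGenes, ann@background))
  half <- window %/% 2
  windowP <- vapply(seq_along(genes), function(i) {
    lo <- max(1L, i - half); hi <- min(length(genes), i + half)
    size <- hi - lo + 1L
    hits <- sum(tp[lo:hi])
    tab <- matrix(c(hits, size - hits,
                    nBgTP - hits, nBg - size - (nBgTP - hits)), 2)
    fisher.test(tab, alternative = "greater")$p.value
  }, numeric(1))
  seedRate <- if (length(seedIds)) mean(seedIds %in% tpGenes) else NA_real_
  new("ValidationResult", significantTerms = as.character(significantTerms),
      table = data.frame(iteration = seq_along(genes), gene = genes,
                         tp = tp, windowP = windowP),
      seedTpRate = seedRate, window = window)
}

setMethod("show", "ValidationResult", function(object) {
  cat(sprintf("ValidationResult: %d significant term(s), %d/%d ranked genes TP (window %d)\n",
              length(object@significantTerms), sum(object@table$tp),
              nrow(object@table), object@window))
})

#' Generate a synthetic annotation collection around a module
#'
#' Builds \code{nTerms} gene sets that preferentially cover a module:
#' each term member is drawn from a covered subset of the module (a
#' fraction \code{coverage} of its members, fixed per collection) with
#' probability \code{1 - noise}, and uniformly from the whole network
#' otherwise.  \code{noise = 0, coverage = 1} yields terms fully inside the
#' module; \code{noise = 1} makes membership independent of the module.
#'
#' @param net an [Interactome-class] (defines the background universe).
#' @param module character vector of module member identifiers.
#' @param nTerms number of terms (default 20).
#' @param coverage fraction of the module eligible for term membership.
#' @param noise probability that a member is drawn uniformly instead.
#' @param termSize gene count per term (default 25; recycled).
#' @param rngSeed integer seed for reproducible generation.
#' @return an [AnnotationCollection-class] with background = all network
#'   nodes.
#' @export
makeSyntheticAnnotations <- function(net, module, nTerms = 20, coverage = 1,
                                     noise = 0.1, termSize = 25, rngSeed = NULL) {
  stopifnot(is(net, "Interactome"))
  module <- intersect(unique(as.character(module)), nodeNames(net))
  if (!length(module)) .stopf("makeSyntheticAnnotations: empty module")
  if (coverage <= 0 || coverage > 1) .stopf("coverage must be in (0, 1]")
  if (noise < 0 || noise > 1) .stopf("noise must be in [0, 1]")
  bg <- nodeNames(net)
  sizes <- rep_len(as.integer(termSize), nTerms)
  .withSeed(rngSeed, {
    pool <- sample(module, max(1L, round(coverage * length(module))))
    terms <- lapply(seq_len(nTerms), function(i) {
      fromPool <- runif(sizes[i]) >= noise
      unique(c(sample(pool, sum(fromPool), replace = TRUE),
               sample(bg, sum(!fromPool), replace = TRUE)))
    })
    names(terms) <- sprintf("T%03d", seq_len(nTerms))
    new("AnnotationCollection", terms = terms,
        descriptions = setNames(rep("synthetic term", nTerms), names(terms)),
        background = bg)
  })
}
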