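# Hypergeometric connectivity significance, its seed-weighted
# generalization, and candidate ranking with dominance pruning.
#
# All probability work is carried out in log-space: connectivity p-values
# on real networks reach 1e-23 and below, far past where naive products of
# binomial ratios underflow.  Parameters are allowed to be real-valued so
# that the seed-weighting transform (which scales counts by alpha) reuses
# the same code path; binomial coefficients generalize through log-gamma.

# log C(n, k) for real n and real k >= 0; -Inf where the coefficient is 0.
.lchooseGen <- function(n, k) {
  len <- max(length(n), length(k))
  n <- rep_len(n, len); k <- rep_len(k, len)
  out <- rep(-Inf, len)
  ok <- k >= -1e-9 & n - k >= -1e-9
  if (any(ok))
    out[ok] <- lgamma(n[ok] + 1) - lgamma(k[ok] + 1) - lgamma(n[ok] - k[ok] + 1)
  out
}

.checkQuery <- function(N, s0, k, ks) {
  if (any(N < 1)) .stopf("connectivity query: N must be >= 1")
  if (any(s0 < 0)) .stopf("connectivity query: s0 must be >= 0")
  if (any(s0 > N)) .stopf("connectivity query: s0 must not exceed N")
  if (any(k < 0)) .stopf("connectivity query: k must be >= 0")
  if (any(k > N - 1 + 1e-9)) .stopf("connectivity query: k must not exceed N - 1")
  if (any(ks < 0)) .stopf("connectivity query: ks must be >= 0")
  if (any(ks > pmin(k, s0) + 1e-9))
    .stopf("connectivity query: ks must not exceed min(k, s0)")
}

# log pmf of observing exactly ks seed links; scalar core, real-valued args.
.lpmf <- function(N, s0, k, ks) {
  .lchooseGen(s0, ks) + .lchooseGen(N - s0, k - ks) - .lchooseGen(N, k)
}

#' Hypergeometric probability of a seed-link count
#'
#' Probability that a node of degree \code{k} has exactly \code{ks} links to
#' a set of \code{s0} seed nodes placed at random in a network of \code{N}
#' nodes: \eqn{C(s_0,k_s)\,C(N-s_0,k-k_s)/C(N,k)}.  Evaluated in log-space;
#' combinatorially impossible configurations (e.g. \eqn{k-k_s > N-s_0})
#' return 0.  Arguments recycle to a common length.
#'
#' @param N network node count.
#' @param s0 seed count (may be real-valued under seed weighting).
#' @param k node degree.
#' @param ks links to seeds; must satisfy \code{0 <= ks <= min(k, s0)}.
#' @param log.p return log-probabilities.
#' @return numeric vector of probabilities.
#' @examples
#' hypergeomPMF(10, 3, 4, 2)  # 63/210
#' @export
hypergeomPMF <- function(N, s0, k, ks, log.p = FALSE) {
  n <- max(length(N), length(s0), length(k), length(ks))
  N <- rep_len(as.numeric(N), n); s0 <- rep_len(as.numeric(s0), n)
  k <- rep_len(as.numeric(k), n); ks <- rep_len(as.numeric(ks), n)
  .checkQuery(N, s0, k, ks)
  lp <- .lpmf(N, s0, k, ks)
  if (log.p) lp else exp(lp)
}

# scalar log p-value: upper tail from ks to min(k, s0) in unit steps.
.lpval <- function(N, s0, k, ks) {
  if (ks <= 0) return(0)
  # pigeonhole saturation: a degree-k node must hit >= k - (N - s0) seeds,
  # so the tail covers the whole support and equals 1 exactly
  if (ks <= k - (N - s0) + 1e-9) return(0)
  top <- min(k, s0)
  m <- floor(top - ks + 1e-9)
  if (m < 0) return(-Inf)
  ki <- ks + 0:m
  lp <- .logSumExp(.lpmf(N, s0, k, ki))
  min(lp, 0)
}

#' Connectivity p-value of a candidate node
#'
#' Cumulative hypergeometric probability of the observed or any higher
#' number of links to the seed set:
#' \eqn{\sum_{k_i = k_s}^{\min(k, s_0)} p(k, k_i)}.  Stable down to values
#' around 1e-30 and below thanks to log-space summation.  \code{ks = 0}
#' yields exactly 1.  Arguments recycle.
#'
#' @inheritParams hypergeomPMF
#' @return numeric vector of upper-tail probabilities in (0, 1].
#' @examples
#' connectivityPValue(10, 3, 4, 2)  # 1/3
#' connectivityPValue(10, 3, 3, 3)  # 1/120
#' @export
connectivityPValue <- function(N, s0, k, ks, log.p = FALSE) {
  n <- max(length(N), length(s0), length(k), length(ks))
  N <- rep_len(as.numeric(N), n); s0 <- rep_len(as.numeric(s0), n)
  k <- rep_len(as.numeric(k), n); ks <- rep_len(as.numeric(ks), n)
  .checkQuery(N, s0, k, ks)
  lp <- vapply(seq_len(n), function(i) .lpval(N[i], s0[i], k[i], ks[i]), numeric(1))
  if (log.p) lp else exp(lp)
}

#' Seed-weighted connectivity p-value
#'
#' Generalizes the connectivity p-value by giving the original seed
#' proteins a weight \code{alpha >= 1}; links to them count \code{alpha}
#' times.  Implemented as the seed-duplication transform — each weighted
#' seed is (virtually) replicated \code{alpha - 1} times together with its
#' interactions:
#' \deqn{N' = N + (\alpha-1)s_0,\quad s' = \alpha s_0 + s_{agg},\quad
#'       k' = k + (\alpha-1)k_w,\quad k_s' = k_s + (\alpha-1)k_w}
#' where \code{s0} counts the weighted (original) seeds, \code{sAgg} the
#' unweighted nodes agglomerated later, \code{ks} the candidate's links to
#' all current module members and \code{ksw} those to weighted seeds only.
#' For integer \code{alpha} this equals the plain connectivity p-value on
#' the explicitly duplicated graph; real \code{alpha} interpolates through
#' log-gamma binomial coefficients.  \code{alpha = 1} reduces to
#' [connectivityPValue()].
#'
#' @param N network node count (before duplication).
#' @param s0 number of weighted seed proteins.
#' @param k candidate degree.
#' @param ks candidate links to the module (weighted seeds + agglomerated).
#' @param alpha seed weight, >= 1.
#' @param ksw candidate links to weighted seeds only (default: \code{ks}).
#' @param sAgg number of unweighted agglomerated module members (default 0).
#' @param log.p return log-probabilities.
#' @return numeric vector of probabilities.
#' @export
weightedPValue <- function(N, s0, k, ks, alpha = 1, ksw = ks, sAgg = 0, log.p = FALSE) {
  if (any(alpha < 1)) .stopf("weightedPValue: alpha must be >= 1")
  n <- max(length(N), length(s0), length(k), length(ks), length(ksw), length(sAgg))
  N <- rep_len(as.numeric(N), n); s0 <- rep_len(as.numeric(s0), n)
  k <- rep_len(as.numeric(k), n); ks <- rep_len(as.numeric(ks), n)
  ksw <- rep_len(as.numeric(ksw), n); sAgg <- rep_len(as.numeric(sAgg), n)
  alpha <- rep_len(as.numeric(alpha), n)
  if (any(ksw > ks + 1e-9))
    .stopf("weightedPValue: ksw must not exceed ks")
  connectivityPValue(N + (alpha - 1) * s0,
                     alpha * s0 + sAgg,
                     k + (alpha - 1) * ksw,
                     ks + (alpha - 1) * ksw, log.p = log.p)
}

# ---- candidate scoring ------------------------------------------------------

# Internal: candidate statistics for a module on integer vertex indices.
# Returns indices, degree k, module links ks, weighted-seed links ksw.
.candidateStats <- function(g, moduleIdx, weightedIdx) {
  inMod <- logical(igraph::vcount(g))
  inMod[moduleIdx] <- TRUE
  el <- igraph::as_edgelist(g, names = FALSE)
  m1 <- inMod[el[, 1]]; m2 <- inMod[el[, 2]]
  w <- logical(igraph::vcount(g)); w[weightedIdx] <- TRUE
  # half-edges from a non-module endpoint into the module
  from <- c(el[!m1 & m2, 1], el[m1 & !m2, 2])
  to <- c(el[!m1 & m2, 2], el[m1 & !m2, 1])
  if (!length(from))
    return(list(idx = integer(), k = integer(), ks = integer(), ksw = integer()))
  ks <- table(factor(from, levels = sort(unique(from))))
  idx <- as.integer(names(ks))
  ksw <- vapply(split(w[to], factor(from, levels = sort(unique(from)))), sum, numeric(1))
  list(idx = idx, k = as.integer(igraph::degree(g, idx)),
       ks = as.integer(ks), ksw = as.integer(ksw))
}

# Deterministic candidate ordering given scores; ties on p broken by
# higher ks, then lower k, then lexicographic identifier.
.orderCandidates <- function(logp, ks, k, gene) {
  order(logp, -ks, k, gene, method = "radix")
}

#' Rank module neighbors by connectivity significance
#'
#' Computes, for every node outside \code{module} with at least one link
#' into it, the (optionally seed-weighted) connectivity p-value, and
#' returns the candidates ordered by ascending p-value.  Ties are broken
#' deterministically: higher \code{ks}, then lower \code{k}, then
#' lexicographic identifier.  The module-growth loop ([runDiamond()]) picks
#' its next node through a dominance-pruned shortlist (within equal
#' \code{ks} only the lowest \code{k} needs an exact p-value); the order
#' returned here is identical to that selection rule, exhaustively applied.
#'
#' @param net an [Interactome-class].
#' @param module non-empty character vector: current module members.
#' @param alpha seed weight >= 1.
#' @param weightedSeeds members carrying weight \code{alpha} (default: the
#'   whole \code{module}); remaining members count with weight 1.
#' @return data.frame with columns gene, k, ks, pValue, ordered by rank.
#' @export
rankCandidates <- function(net, module, alpha = 1, weightedSeeds = module) {
  stopifnot(is(net, "Interactome"))
  module <- unique(as.character(module))
  if (!length(module)) .stopf("rankCandidates: module is empty")
  g <- asIgraph(net)
  nms <- nodeNames(net)
  moduleIdx <- which(nms %in% module)
  weightedIdx <- which(nms %in% weightedSeeds)
  st <- .candidateStats(g, moduleIdx, weightedIdx)
  if (!length(st$idx))
    return(data.frame(gene = character(), k = integer(), ks = integer(),
                      pValue = numeric()))
  s0 <- length(weightedIdx)
  sAgg <- length(moduleIdx) - s0
  lp <- weightedPValue(numNodes(net), s0, st$k, st$ks, alpha = alpha,
                       ksw = st$ksw, sAgg = sAgg, log.p = TRUE)
  ord <- .orderCandidates(lp, st$ks + (alpha - 1) * st$ksw,
                          st$k + (alpha - 1) * st$ksw, nms[st$idx])
  data.frame(gene = nms[st$idx][ord], k = st$k[ord], ks = st$ks[ord],
             pValue = exp(lp[ord]))
}
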