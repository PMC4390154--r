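# Random walk with restart: the diffusion baseline for gene prioritization.

#' Random-walk-with-restart visit frequencies
#'
#' Stationary distribution of a walker that at each step moves to a uniform
#' random neighbor and, with probability \code{restart}, teleports back to
#' a uniformly chosen seed: the fixed point of
#' \deqn{p = r\,u + (1-r)\,W p}
#' with \code{W} the column-normalized adjacency matrix and \code{u}
#' uniform over the seeds.  Computed deterministically by power iteration
#' to an L1 residual below \code{tolerance} (equivalent to simulating the
#' walker to convergence, but reproducible and fast).  Walkers at
#' degree-zero nodes teleport back to the seeds.  Scores sum to 1.
#'
#' @param net an [Interactome-class].
#' @param seeds a [SeedSet-class] or character vector with >= 1 mapped seed.
#' @param restart restart probability r in (0, 1); default 0.4.
#' @param tolerance L1 convergence threshold (default 1e-10).
#' @param maxSteps iteration cap (default 10000); exceeded -> error
#'   reporting the residual.
#' @return named numeric vector of visit frequencies over all nodes.
#' @examples
#' net <- Interactome(data.frame(a = "A", b = "B"))
#' rwrScores(net, "A")  # A: 0.625, B: 0.375
#' @export
rwrScores <- function(net, seeds, restart = 0.4, tolerance = 1e-10,
                      maxSteps = 10000) {
  stopifnot(is(net, "Interactome"))
  if (restart <= 0 || restart >= 1) .stopf("rwrScores: restart must be in (0, 1)")
  seeds <- .asSeedSet(net, seeds)
  if (seedCount(seeds) < 1) .stopf("rwrScores: no seed maps onto the network")
  g <- asIgraph(net)
  nms <- nodeNames(net)
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  degs <- Matrix::colSums(A)
  inv <- ifelse(degs > 0, 1 / degs, 0)
  W <- A %*% Matrix::Diagonal(x = inv)
  u <- numeric(length(nms))
  u[nms %in% seedNames(seeds)] <- 1 / seedCount(seeds)
  dangling <- degs == 0
  p <- u
  for (step in seq_len(maxSteps)) {
    lost <- if (any(dangling)) sum(p[dangling]) else 0
    pNew <- restart * u + (1 - restart) * (as.numeric(W %*% p) + lost * u)
    res <- sum(abs(pNew - p))
    p <- pNew
    if (res < tolerance) {
      p <- p / sum(p)
      return(setNames(p, nms))
    }
  }
  .stopf("rwrScores: no convergence within %d steps (L1 residual %.3g)",
         maxSteps, res)
}

#' Rank non-seed genes by visit frequency
#'
#' @param scores named numeric vector from [rwrScores()].
#' @param seeds a [SeedSet-class] or character vector of seed identifiers
#'   to exclude from the ranking.
#' @return character vector of non-seed genes by descending score, ties
#'   broken lexicographically.  If every non-seed score is zero (seeds
#'   disconnected from the rest), the order is lexicographic and a warning
#'   is emitted.
#' @export
rwrRank <- function(scores, seeds) {
  seedIds <- if (is(seeds, "SeedSet")) seedNames(seeds) else as.character(seeds)
  s <- scores[setdiff(names(scores), seedIds)]
  if (length(s) && all(s == 0))
    warning("rwrRank: all non-seed scores are zero; returning lexicographic order",
            call. = FALSE)
  names(s)[order(-s, names(s), method = "radix")]
}
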