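# Internal helpers shared across the package.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# state; `seed = NULL` means "use the current RNG stream".
.withSeed <- function(seed, expr) {
  if (is.null(seed)) {
    expr
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

# log(sum(exp(x))) without overflow/underflow; x may contain -Inf.
.logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

.msg <- function(...) message("diamondR: ", ...)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Canonical undirected edge key, used for duplicate detection.
.edgeKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}
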