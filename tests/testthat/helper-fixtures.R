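# Shared fixtures, all built in code at test time.

suppressPackageStartupMessages({
  library(Biostrings)
  library(GenomicRanges)
})

randomRna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                               collapse = "")

# GRanges of genes at given starts (for cluster chaining tests)
genesAt <- function(starts, width = 70, scaffold = "scf1",
                    ids = sprintf("g%02d", seq_along(starts))) {
  GenomicRanges::GRanges(scaffold,
                         IRanges::IRanges(starts, starts + width - 1),
                         gene_id = ids, provenance = "novel")
}

# brute-force average-rank Spearman for two vectors
spearmanOracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# brute-force step-up BH
bhOracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# brute-force median-of-ratios
sizeFactorOracle <- function(cnt) {
  ok <- apply(cnt, 1, function(x) all(x > 0))
  ref <- apply(cnt[ok, , drop = FALSE], 1, function(x) prod(x)^(1 / length(x)))
  vapply(seq_len(ncol(cnt)), function(j)
    median(cnt[ok, j] / ref), numeric(1))
}

# adjusted Rand index between two label vectors
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# default count simulation shared by coexpression/DE tests (cached)
defaultSim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulateCounts(simConfig())
    cache
  }
})
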