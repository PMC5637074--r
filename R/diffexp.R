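#' Median-of-ratios size factors
#'
#' The per-library scale is the median, over genes with nonzero counts
#' in every library, of the ratio between the library's count and the
#' gene's geometric mean across libraries. Multiplying one library by a
#' constant multiplies its factor by that constant (given a stable
#' reference gene set).
#'
#' @param counts integer matrix or \linkS4class{MirnaExperiment}.
#' @return named numeric vector of positive size factors.
#' @export
#' @examples
#' sizeFactorsMedianRatios(cbind(A = c(10, 100), B = c(20, 200)))
sizeFactorsMedianRatios <- function(counts) {
  cnt <- if (is(counts, "MirnaExperiment")) counts(counts) else counts
  ok <- rowSums(cnt == 0) == 0
  if (!any(ok))
    stop("no gene with nonzero counts in all libraries; ",
         "size factors are undefined")
  ref <- exp(rowMeans(log(cnt[ok, , drop = FALSE])))
  apply(cnt[ok, , drop = FALSE], 2, function(x) stats::median(x / ref))
}

#' Method-of-moments NB dispersion with conservative shrinkage
#'
#' For each gene the raw moment estimate is
#' \eqn{\hat\alpha = \max(0, (s^2 - \bar\mu) / \overline{\mu^2})}, where
#' \eqn{s^2} is the mean within-condition sample variance of normalized
#' counts and the mean terms average over conditions. Raw estimates are
#' then shrunk halfway toward the across-gene mean dispersion and
#' floored at that mean: with two replicates per condition the gene-wise
#' moment estimate is extremely noisy, and genes whose replicates are
#' accidentally concordant would otherwise get near-zero dispersion and
#' inflate the Wald false-positive rate; the floor keeps the test
#' calibrated while the halfway shrinkage from above preserves signal
#' for genuinely overdispersed genes.
#'
#' @param counts integer matrix or \linkS4class{MirnaExperiment}.
#' @param sizeFactors per-library size factors
#'   (default [sizeFactorsMedianRatios()]).
#' @param conditions per-library condition labels (taken from the
#'   experiment's stages when omitted).
#' @return data.frame with \code{raw} and \code{dispersion} per gene.
#' @export
estimateDispersion <- function(counts, sizeFactors = NULL,
                               conditions = NULL) {
  if (is(counts, "MirnaExperiment")) {
    if (is.null(conditions)) conditions <- stageOf(counts)
    counts <- counts(counts)
  }
  if (is.null(conditions)) stop("conditions are required for a plain matrix")
  if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMedianRatios(counts)
  nrep <- table(conditions)
  if (any(nrep < 2))
    stop("each condition needs >= 2 replicates; pool replicate libraries ",
         "before estimating dispersion otherwise")
  nc <- sweep(counts, 2, sizeFactors, "/")
  conds <- unique(conditions)
  mns <- sapply(conds, function(cd)
    rowMeans(nc[, conditions == cd, drop = FALSE]))
  vrs <- sapply(conds, function(cd)
    apply(nc[, conditions == cd, drop = FALSE], 1, stats::var))
  mns <- matrix(mns, nrow = nrow(counts)); vrs <- matrix(vrs, nrow = nrow(counts))
  s2 <- rowMeans(vrs)
  mubar <- rowMeans(mns)
  mu2 <- rowMeans(mns^2)
  raw <- ifelse(mu2 > 0, pmax(0, (s2 - mubar) / mu2), 0)
  abar <- mean(raw)
  data.frame(raw = raw, dispersion = pmax((raw + abar) / 2, abar),
             row.names = rownames(counts))
}

#' Negative-binomial Wald test for one stage transition
#'
#' Compares the normalized mean expression of two stages. The log2 fold
#' change uses a 0.5 pseudocount for stability at two replicates; its
#' standard error propagates the NB variance
#' \eqn{\mu + \alpha \mu^2} of each replicate mean to the log2 scale,
#' and the Wald statistic is referred to a standard normal (two-sided).
#' Genes with zero counts in all libraries of both stages are excluded.
#'
#' @param counts matrix or \linkS4class{MirnaExperiment}.
#' @param sizeFactors per-library size factors.
#' @param dispersions per-gene dispersion (vector, or
#'   [estimateDispersion()] output).
#' @param conditions per-library labels (experiment stages by default).
#' @param transition length-2 character: \code{c(stageA, stageB)}; fold
#'   changes are B over A.
#' @param pseudocount added to both normalized means (default 0.5).
#' @return data.frame: \code{gene_id}, \code{baseMeanA},
#'   \code{baseMeanB}, \code{log2FoldChange}, \code{lfcSE}, \code{stat},
#'   \code{pvalue}, \code{padj}, \code{significant} (BH q < 0.05).
#' @export
nbWaldTest <- function(counts, sizeFactors = NULL, dispersions = NULL,
                       conditions = NULL, transition, pseudocount = 0.5) {
  if (is(counts, "MirnaExperiment")) {
    if (is.null(conditions)) conditions <- stageOf(counts)
    counts <- counts(counts)
  }
  stopifnot(length(transition) == 2)
  missing_st <- setdiff(transition, conditions)
  if (length(missing_st))
    stop("unknown stage: ", paste(missing_st, collapse = ", "))
  if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMedianRatios(counts)
  if (is.null(dispersions))
    dispersions <- estimateDispersion(counts, sizeFactors, conditions)
  a <- if (is.data.frame(dispersions)) dispersions$dispersion else dispersions
  ia <- which(conditions == transition[1])
  ib <- which(conditions == transition[2])
  keep <- rowSums(counts[, c(ia, ib), drop = FALSE]) > 0
  cnt <- counts[keep, , drop = FALSE]
  a <- a[keep]
  nc <- sweep(cnt, 2, sizeFactors, "/")
  mA <- rowMeans(nc[, ia, drop = FALSE])
  mB <- rowMeans(nc[, ib, drop = FALSE])
  l2fc <- log2((mB + pseudocount) / (mA + pseudocount))
  # Var(mean_l K_l / s_l) = n^-2 sum_l (mu / s_l + alpha mu^2)
  varA <- (mA * sum(1 / sizeFactors[ia]) + a * mA^2 * length(ia)) /
    length(ia)^2
  varB <- (mB * sum(1 / sizeFactors[ib]) + a * mB^2 * length(ib)) /
    length(ib)^2
  se <- sqrt(varA / (mA + pseudocount)^2 + varB / (mB + pseudocount)^2) /
    log(2)
  stat <- ifelse(se > 0, l2fc / se, 0)
  p <- 2 * stats::pnorm(-abs(stat))
  q <- bhAdjust(p)
  data.frame(gene_id = rownames(cnt), baseMeanA = mA, baseMeanB = mB,
             log2FoldChange = l2fc, lfcSE = se, stat = stat, pvalue = p,
             padj = q, significant = q < 0.05, row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment via [stats::p.adjust()], with input
#' validation. Adjusted values are monotone in the sorted p-values and
#' never smaller than the raw p-value.
#'
#' @param p numeric vector of p-values in \code{[0, 1]}.
#' @return vector of q-values, same order as the input.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential expression across all adjacent stage transitions
#'
#' Runs [nbWaldTest()] for every consecutive pair of
#' \code{orderedStages} with shared size factors and dispersions.
#'
#' @param experiment a \linkS4class{MirnaExperiment}.
#' @param orderedStages stage order (default [bgStages()] intersected
#'   with the stages present).
#' @param pseudocount see [nbWaldTest()].
#' @return named list of per-transition result data.frames
#'   (names \code{"A->B"}).
#' @export
diffexpAllTransitions <- function(experiment, orderedStages = NULL,
                                  pseudocount = 0.5) {
  stopifnot(is(experiment, "MirnaExperiment"))
  st <- stageOf(experiment)
  if (is.null(orderedStages)) orderedStages <- intersect(bgStages(), st)
  sf <- sizeFactorsMedianRatios(experiment)
  disp <- estimateDispersion(counts(experiment), sf, st)
  out <- list()
  for (i in seq_len(length(orderedStages) - 1)) {
    tr <- c(orderedStages[i], orderedStages[i + 1])
    out[[paste(tr, collapse = "->")]] <-
      nbWaldTest(counts(experiment), sf, disp, st, tr,
                 pseudocount = pseudocount)
  }
  out
}

#' Per-transition counts of significant changes
#'
#' @param results named list of [nbWaldTest()] results (see
#'   [diffexpAllTransitions()]); names define the transition order
#'   unless \code{orderedStages} is given.
#' @param orderedStages optional stage order used to order rows.
#' @return data.frame with \code{transition}, \code{n_up},
#'   \code{n_down} (significant genes with positive / negative log2
#'   fold change).
#' @export
transitionSummary <- function(results, orderedStages = NULL) {
  nm <- names(results)
  if (!is.null(orderedStages)) {
    want <- paste(orderedStages[-length(orderedStages)],
                  orderedStages[-1], sep = "->")
    nm <- want[want %in% nm]
  }
  rows <- lapply(nm, function(tr) {
    r <- results[[tr]]
    data.frame(transition = tr,
               n_up = sum(r$significant & r$log2FoldChange > 0),
               n_down = sum(r$significant & r$log2FoldChange < 0))
  })
  do.call(rbind, rows)
}
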