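#' Percent of embryonic development
#'
#' Converts hours after oviposition into percent of total embryogenesis
#' (default 18 days = 432 h at 29 degrees C), the common axis used to
#' align embryonic stages across species with different absolute
#' developmental tempos.
#'
#' @param hoursAO hours after oviposition (0 <= hoursAO <= totalHours).
#' @param totalHours total embryogenesis duration in hours (default 432).
#' @param decimals rounding, in decimal places (default 2).
#' @return numeric percentage(s).
#' @export
#' @examples
#' percentDevelopment(8)              # 1.85
#' percentDevelopment(144, decimals = 0)  # 33
percentDevelopment <- function(hoursAO, totalHours = 432, decimals = 2) {
  if (any(totalHours <= 0)) stop("totalHours must be positive")
  if (any(hoursAO < 0)) stop("hoursAO must be non-negative")
  if (any(hoursAO > totalHours))
    stop("hoursAO exceeds the total embryogenesis duration")
  round(100 * hoursAO / totalHours, decimals)
}

#' Orthologous-family expression table across species
#'
#' Retains exactly the families with nonzero expression in every
#' species and binds the per-species library columns into one matrix.
#'
#' @param tables named list (one element per species) of family x
#'   library matrices with family rownames.
#' @return matrix (shared families x all libraries) with a
#'   \code{"species"} attribute mapping columns to species.
#' @export
sharedFamilyTable <- function(tables) {
  if (length(tables) < 2) stop("need at least 2 species")
  present <- lapply(tables, function(tb)
    rownames(tb)[rowSums(tb != 0) > 0])
  shared <- Reduce(intersect, present)
  if (!length(shared)) stop("no family is present in every species")
  shared <- sort(shared)
  out <- do.call(cbind, lapply(tables, function(tb)
    tb[shared, , drop = FALSE]))
  attr(out, "species") <- rep(names(tables),
                              vapply(tables, ncol, 0L))
  out
}

#' Relative family abundance per library
#'
#' @param familyTable matrix, families x libraries, column totals > 0.
#' @return matrix of proportions; columns sum to 1.
#' @export
relativeAbundance <- function(familyTable) {
  tot <- colSums(familyTable)
  if (any(tot == 0))
    stop("library with zero total: ",
         paste(colnames(familyTable)[tot == 0], collapse = ", "))
  sweep(familyTable, 2, tot, "/")
}

# the abundance transform used before clustering / PCA: proportions are
# heavy-tailed, so work on log10 of per-million values
logAbundance <- function(rel) log10(rel * 1e6 + 1)

#' Hierarchical clustering of libraries by family abundance
#'
#' Average-linkage agglomerative clustering on correlation distance
#' (1 - Pearson) between log-transformed relative abundances,
#' log10(p * 1e6 + 1). Libraries are ordered by name first so the result
#' is invariant to input order.
#'
#' @param relAbundance [relativeAbundance()] matrix.
#' @param linkage linkage method for [stats::hclust()]
#'   (default "average").
#' @param distance \code{"pearson"} (1 - correlation, default) or
#'   \code{"euclidean"} on the log scale.
#' @return list with \code{hclust}, the \code{dist} used, and
#'   \code{cut}, a function of k returning flat cluster labels.
#' @export
hclusterLibraries <- function(relAbundance, linkage = "average",
                              distance = c("pearson", "euclidean")) {
  if (ncol(relAbundance) < 2) stop("need at least 2 libraries")
  distance <- match.arg(distance)
  relAbundance <- relAbundance[, order(colnames(relAbundance)),
                               drop = FALSE]
  lx <- logAbundance(relAbundance)
  d <- if (distance == "pearson") stats::as.dist(1 - stats::cor(lx))
       else stats::dist(t(lx))
  fit <- stats::hclust(d, method = linkage)
  list(hclust = fit, dist = d,
       cut = function(k) stats::cutree(fit, k = k))
}

#' Write a library dendrogram as Newick
#'
#' @param clustering [hclusterLibraries()] result (or an hclust).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeDendrogramNewick <- function(clustering, path) {
  fit <- if (inherits(clustering, "hclust")) clustering
         else clustering$hclust
  ape::write.tree(ape::as.phylo(fit), file = path)
  invisible(path)
}

#' PCA of family abundances with driver families
#'
#' Principal component analysis of the column-centred log-transformed
#' proportions (libraries as observations, families as variables). The
#' "drivers" of the separation are operationalized as the families with
#' the largest absolute loadings on PC1, then PC2. PC signs are fixed by
#' orienting each component so the first library's score is
#' non-negative.
#'
#' @param relAbundance [relativeAbundance()] matrix.
#' @param nDrivers how many driver families to report (default 3).
#' @return list with \code{scores} (libraries x PCs), \code{loadings}
#'   (families x PCs), \code{varExplained} and \code{drivers}.
#' @export
pcaDrivers <- function(relAbundance, nDrivers = 3) {
  if (ncol(relAbundance) < 2 || nrow(relAbundance) < 2)
    stop("need at least 2 libraries and 2 families")
  x <- t(logAbundance(relAbundance))
  if (all(apply(x, 2, stats::sd) == 0))
    stop("degenerate input: no family varies between libraries")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  for (j in seq_len(ncol(pc$x))) {
    if (pc$x[1, j] < 0) {
      pc$x[, j] <- -pc$x[, j]
      pc$rotation[, j] <- -pc$rotation[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  rank1 <- order(-abs(pc$rotation[, 1]))
  cand <- rownames(pc$rotation)[rank1]
  if (ncol(pc$rotation) >= 2) {
    rank2 <- order(-abs(pc$rotation[, 2]))
    cand <- c(cand[seq_len(min(nDrivers, length(cand)))],
              rownames(pc$rotation)[rank2])
  }
  drivers <- utils::head(unique(cand), nDrivers)
  list(scores = pc$x, loadings = pc$rotation,
       varExplained = ve, drivers = drivers)
}
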