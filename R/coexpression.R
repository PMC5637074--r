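#' Stage-mean expression profiles
#'
#' Averages replicate CPM per stage, giving each gene an 11-point stage
#' profile. Correlations downstream are computed on these stage means
#' rather than on the 22 individual libraries: the module metagenes are
#' drawn over stages, and averaging suppresses replicate noise at the
#' design's n = 2.
#'
#' @param cpm CPM matrix (genes x libraries) or a
#'   \linkS4class{MirnaExperiment} carrying a \code{"cpm"} assay.
#' @param design data.frame with \code{library} and \code{stage}
#'   (defaults to the experiment's design).
#' @param stageOrder stage order of the output columns.
#' @return matrix, genes x stages.
#' @export
stageMeans <- function(cpm, design = NULL, stageOrder = NULL) {
  if (is(cpm, "MirnaExperiment")) {
    if (is.null(design)) design <- designOf(cpm)
    cpm <- SummarizedExperiment::assay(cpm, "cpm")
  }
  if (is.null(design)) stop("a design table is required for a plain matrix")
  if (is.null(stageOrder)) stageOrder <- intersect(bgStages(), design$stage)
  missing_st <- setdiff(stageOrder, design$stage)
  if (length(missing_st))
    stop("stage without libraries: ", paste(missing_st, collapse = ", "))
  out <- sapply(stageOrder, function(s) {
    libs <- design$library[design$stage == s]
    rowMeans(cpm[, libs, drop = FALSE])
  })
  out <- matrix(out, nrow = nrow(cpm),
                dimnames = list(rownames(cpm), stageOrder))
  out
}

#' Tie-corrected Spearman correlation matrix
#'
#' Average-rank Spearman correlation between all gene pairs, the
#' rank-based measure reported to model RNA-seq coexpression best.
#' Genes with constant profiles have undefined rank correlation; their
#' correlations are set to 0 (diagonal stays 1) with a warning rather
#' than propagating NaN.
#'
#' @param profiles matrix, genes x stages (see [stageMeans()]).
#' @return symmetric genes x genes matrix with unit diagonal.
#' @export
spearmanMatrix <- function(profiles) {
  if (ncol(profiles) < 3) stop("need at least 3 stages")
  const <- apply(profiles, 1, function(x) length(unique(x)) == 1)
  rho <- suppressWarnings(stats::cor(t(profiles), method = "spearman"))
  if (any(const)) {
    warning(sum(const), " constant profile(s); their correlations set to 0")
    rho[const, ] <- 0
    rho[, const] <- 0
  }
  diag(rho) <- 1
  rho
}

#' Build the thresholded coexpression network
#'
#' Edges connect gene pairs whose Spearman rho strictly exceeds the
#' threshold ("higher than 0.9"); anti-correlated pairs are never
#' connected (no absolute value).
#'
#' @param rho correlation matrix from [spearmanMatrix()].
#' @param threshold edge cut-off in (0, 1), default 0.9.
#' @return an [igraph::graph] with vertex names and edge attribute
#'   \code{rho}.
#' @export
buildNetwork <- function(rho, threshold = 0.9) {
  stopifnot(threshold > 0, threshold < 1)
  adj <- rho > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  e <- igraph::as_edgelist(g)
  igraph::E(g)$rho <- rho[cbind(match(e[, 1], rownames(rho)),
                                match(e[, 2], rownames(rho)))]
  g
}

# connected components of size >= minSize, largest first, deterministic
componentModules <- function(graph, minSize, prefix = "M") {
  memb <- igraph::components(graph)$membership
  sizes <- table(memb)
  keep <- names(sizes)[sizes >= minSize]
  if (!length(keep))
    return(S4Vectors::DataFrame(gene_id = character(), module = character()))
  # order by size desc, ties by smallest member name
  first_member <- vapply(keep, function(k)
    min(names(memb)[memb == k]), "")
  ord <- order(-as.integer(sizes[keep]), first_member)
  keep <- keep[ord]
  rows <- lapply(seq_along(keep), function(i) {
    ids <- sort(names(memb)[memb == keep[i]])
    S4Vectors::DataFrame(gene_id = ids,
                         module = rep(paste0(prefix, i), length(ids)))
  })
  do.call(rbind, rows)
}

#' Extract coexpression modules
#'
#' Modules are the connected components of the thresholded network with
#' at least \code{minSize} members (smaller components are treated as
#' noise), ordered by decreasing size with deterministic identifiers
#' \code{M1, M2, ...}.
#'
#' @param network [buildNetwork()] result.
#' @param minSize minimum module size (default 3).
#' @return \code{DataFrame} with \code{gene_id} and \code{module}.
#' @export
findModules <- function(network, minSize = 3) {
  componentModules(network, minSize)
}

#' Split the largest module into submodules
#'
#' Re-thresholds the correlations inside the largest module at the
#' stricter cut-off (default 0.925) and reports the resulting connected
#' components as submodules (ids \code{M1.1, M1.2, ...}).
#'
#' @param network [buildNetwork()] result.
#' @param rho the full Spearman matrix.
#' @param subThreshold stricter cut-off, default 0.925.
#' @param minSize minimum submodule size (default 3).
#' @return \code{DataFrame} with \code{gene_id} and \code{submodule}.
#' @export
splitLargest <- function(network, rho, subThreshold = 0.925, minSize = 3) {
  mods <- findModules(network, minSize)
  if (nrow(mods) == 0) stop("no modules found")
  big <- mods$gene_id[mods$module == mods$module[1]]
  sub <- buildNetwork(rho[big, big, drop = FALSE], subThreshold)
  out <- componentModules(sub, minSize, prefix = paste0(mods$module[1], "."))
  colnames(out)[colnames(out) == "module"] <- "submodule"
  out
}

#' SVD metagene of a module
#'
#' Member profiles are z-scored across stages (so the first singular
#' vector captures profile shape, not magnitude), the member-by-stage
#' matrix is decomposed by SVD and the first right singular vector,
#' oriented to correlate positively with the per-stage mean of the raw
#' member profiles and scaled to unit Euclidean norm, is the module's
#' characteristic expression pattern.
#'
#' @param moduleProfiles matrix, member genes x stages (>= 2 members).
#' @param standardize z-score rows first (default TRUE; set FALSE for a
#'   raw-CPM decomposition).
#' @return unit-norm numeric vector, one value per stage.
#' @export
metagene <- function(moduleProfiles, standardize = TRUE) {
  if (nrow(moduleProfiles) < 2) stop("a module needs >= 2 genes")
  sds <- apply(moduleProfiles, 1, stats::sd)
  if (all(sds == 0)) stop("degenerate module: all profiles constant")
  x <- moduleProfiles
  if (standardize) {
    if (any(sds == 0)) {
      warning(sum(sds == 0), " constant profile(s) dropped from metagene")
      x <- x[sds > 0, , drop = FALSE]
    }
    x <- t(scale(t(x)))
  }
  v <- svd(x)$v[, 1]
  ref <- colMeans(moduleProfiles)
  orient <- sum(v * (ref - mean(ref)))
  if (orient == 0) orient <- sum(v)
  if (orient < 0) v <- -v
  v <- v / sqrt(sum(v^2))
  stats::setNames(v, colnames(moduleProfiles))
}

#' Full coexpression analysis
#'
#' Convenience wrapper: stage means are correlated ([spearmanMatrix()]),
#' thresholded into a network, modules and the largest module's
#' submodules extracted, and a metagene computed for each.
#'
#' @param cpm CPM matrix or \linkS4class{MirnaExperiment} with a
#'   \code{"cpm"} assay.
#' @param design design table (see [stageMeans()]).
#' @param threshold,subThreshold the two correlation cut-offs.
#' @param minSize minimum module size.
#' @return a \linkS4class{CoexpressionResult}.
#' @export
coexpressionAnalysis <- function(cpm, design = NULL, threshold = 0.9,
                                 subThreshold = 0.925, minSize = 3) {
  prof <- stageMeans(cpm, design)
  rho <- spearmanMatrix(prof)
  net <- buildNetwork(rho, threshold)
  mods <- findModules(net, minSize)
  subs <- if (nrow(mods)) splitLargest(net, rho, subThreshold, minSize)
          else S4Vectors::DataFrame(gene_id = character(),
                                    submodule = character())
  groups <- c(split(mods$gene_id, mods$module),
              split(subs$gene_id, subs$submodule))
  mg <- t(vapply(groups, function(ids)
    metagene(prof[ids, , drop = FALSE]), numeric(ncol(prof))))
  new("CoexpressionResult", rho = rho, graph = net, modules = mods,
      submodules = subs,
      metagenes = if (length(groups)) mg else matrix(0, 0, ncol(prof)),
      threshold = threshold, subThreshold = subThreshold)
}

#' Coefficient of variation of stage profiles
#'
#' CV = sample standard deviation / mean over the stage means. Genes
#' with zero mean are excluded with a warning.
#'
#' @param profiles matrix, genes x stages.
#' @return named numeric vector of CVs.
#' @export
expressionCV <- function(profiles) {
  mns <- rowMeans(profiles)
  if (any(mns == 0)) {
    warning(sum(mns == 0), " zero-mean gene(s) excluded from CV")
    profiles <- profiles[mns > 0, , drop = FALSE]
    mns <- mns[mns > 0]
  }
  sds <- apply(profiles, 1, stats::sd)
  stats::setNames(sds / mns, rownames(profiles))
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch test with Welch-Satterthwaite degrees of freedom,
#' used to compare expression-variation (CV) distributions between gene
#' groups (e.g. lineage-specific versus conserved miRNAs).
#'
#' @param x,y numeric vectors (each n >= 2).
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
welchTest <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 values")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = length(x) + length(y) - 2,
                                        p = 1))
    stop("zero variance in both groups with unequal means")
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Export a coexpression network as GraphML
#'
#' @param network [buildNetwork()] result or a
#'   \linkS4class{CoexpressionResult}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeNetworkGraphML <- function(network, path) {
  if (is(network, "CoexpressionResult")) network <- coexNetwork(network)
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}
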