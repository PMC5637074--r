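#' @importFrom BiocGenerics counts
#' @export
setMethod("counts", "MirnaExperiment", function(object, ...)
  SummarizedExperiment::assay(object, "counts"))

#' Stage labels of the libraries
#' @param x a \code{MirnaExperiment}.
#' @return character vector, one stage per library.
#' @export
stageOf <- function(x) {
  stopifnot(is(x, "MirnaExperiment"))
  as.character(SummarizedExperiment::colData(x)$stage)
}

#' Library design table
#' @param x a \code{MirnaExperiment}.
#' @return data.frame with \code{library}, \code{stage}, \code{replicate}.
#' @export
designOf <- function(x) {
  stopifnot(is(x, "MirnaExperiment"))
  cd <- SummarizedExperiment::colData(x)
  data.frame(library = colnames(x), stage = as.character(cd$stage),
             replicate = as.integer(cd$replicate))
}

#' Catalog accessors
#'
#' \code{catalogGenes()} and \code{catalogMatures()} return the precursor
#' and arm loci; \code{matureSequences()} returns arm sequences (all arms,
#' or only \code{role == "mature"} ones); \code{provenanceOf()} returns
#' the per-gene provenance labels.
#'
#' @param x a \code{MirnaCatalog}.
#' @param role arm roles to keep (\code{matureSequences}).
#' @return See individual descriptions.
#' @name catalog-accessors
NULL

#' @rdname catalog-accessors
#' @export
catalogGenes <- function(x) { stopifnot(is(x, "MirnaCatalog")); x@genes }

#' @rdname catalog-accessors
#' @export
catalogMatures <- function(x) { stopifnot(is(x, "MirnaCatalog")); x@matures }

#' @rdname catalog-accessors
#' @export
matureSequences <- function(x, role = c("mature", "star")) {
  stopifnot(is(x, "MirnaCatalog"))
  role <- match.arg(role, several.ok = TRUE)
  keep <- x@matures$mature_id[x@matures$role %in% role]
  if (!length(keep)) return(Biostrings::RNAStringSet())
  x@matureSeq[keep]
}

#' @rdname catalog-accessors
#' @export
provenanceOf <- function(x) {
  stopifnot(is(x, "MirnaCatalog"))
  stats::setNames(x@genes$provenance, x@genes$gene_id)
}

#' @rdname catalog-accessors
#' @export
precursorSequences <- function(x) { stopifnot(is(x, "MirnaCatalog")); x@precursorSeq }

#' Ground-truth accessors
#' @param x a \code{SimTruth}.
#' @return \code{truthGenes()}: per-gene DataFrame; \code{truthProfile()}:
#'   true mean CPM matrix; \code{truthReads()}: per-read DataFrame.
#' @name truth-accessors
NULL

#' @rdname truth-accessors
#' @export
truthGenes <- function(x) { stopifnot(is(x, "SimTruth")); x@geneInfo }

#' @rdname truth-accessors
#' @export
truthProfile <- function(x) { stopifnot(is(x, "SimTruth")); x@meanProfile }

#' @rdname truth-accessors
#' @export
truthReads <- function(x) { stopifnot(is(x, "SimTruth")); x@reads }

#' Tail-modification profile table
#' @param x a \code{TailModProfile}.
#' @return \code{DataFrame}, one row per library.
#' @export
tailTable <- function(x) { stopifnot(is(x, "TailModProfile")); x@table }

#' Coexpression result accessors
#' @param x a \code{CoexpressionResult}.
#' @return \code{moduleMembers()}/\code{submoduleMembers()}: membership
#'   DataFrames; \code{metagenes()}: matrix of unit-norm stage profiles;
#'   \code{coexNetwork()}: the igraph network; \code{coexRho()}: the
#'   Spearman matrix.
#' @name coex-accessors
NULL

#' @rdname coex-accessors
#' @export
moduleMembers <- function(x) { stopifnot(is(x, "CoexpressionResult")); x@modules }

#' @rdname coex-accessors
#' @export
submoduleMembers <- function(x) { stopifnot(is(x, "CoexpressionResult")); x@submodules }

#' @rdname coex-accessors
#' @export
metagenes <- function(x) { stopifnot(is(x, "CoexpressionResult")); x@metagenes }

#' @rdname coex-accessors
#' @export
coexNetwork <- function(x) { stopifnot(is(x, "CoexpressionResult")); x@graph }

#' @rdname coex-accessors
#' @export
coexRho <- function(x) { stopifnot(is(x, "CoexpressionResult")); x@rho }

setMethod("show", "MirnaCatalog", function(object) {
  prov <- table(factor(object@genes$provenance,
                       c("conserved", "previous", "novel")))
  cat("MirnaCatalog with", length(object@genes), "genes (",
      paste(names(prov), as.integer(prov), collapse = ", "), ")\n")
  cat("  arms:", sum(object@matures$role == "mature"), "mature,",
      sum(object@matures$role == "star"), "star\n")
  cat("  scaffolds:",
      paste(unique(as.character(GenomicRanges::seqnames(object@genes))),
            collapse = ", "), "\n")
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth for", nrow(object@geneInfo), "genes")
  if (nrow(object@geneInfo)) {
    tw <- table(object@geneInfo$wave)
    cat(" (waves: ", paste(names(tw), as.integer(tw), sep = "=",
                           collapse = ", "), ")", sep = "")
  }
  cat("\n")
  if (nrow(object@reads))
    cat("  read-level truth:", nrow(object@reads), "reads\n")
})

setMethod("show", "TailModProfile", function(object) {
  cat("TailModProfile over", nrow(object@table), "libraries\n")
  if (nrow(object@table)) {
    f <- object@table$frequency
    cat(sprintf("  modified-read frequency: %.3f-%.3f\n",
                min(f, na.rm = TRUE), max(f, na.rm = TRUE)))
  }
})

setMethod("show", "CoexpressionResult", function(object) {
  nmod <- length(unique(object@modules$module))
  cat("CoexpressionResult:", nmod, "modules at rho >", object@threshold,
      "\n")
  if (nrow(object@submodules))
    cat("  largest module split into",
        length(unique(object@submodules$submodule)),
        "submodules at rho >", object@subThreshold, "\n")
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", sum(object@nGenesPerWave), "wave genes +",
      object@nBackgroundGenes, "background; dispersion",
      object@dispersion, "; seed", object@seed, "\n")
})
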