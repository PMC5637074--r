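#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Biostrings RNAStringSet
NULL

#' MirnaExperiment: stage-resolved miRNA count container
#'
#' A thin subclass of [SummarizedExperiment::SummarizedExperiment] holding
#' a genes-by-libraries integer count matrix (assay \code{"counts"}) with
#' mandatory \code{stage} and \code{replicate} columns in \code{colData}.
#'
#' @slot ... inherited from \code{SummarizedExperiment}.
#' @aliases MirnaExperiment-class
#' @exportClass MirnaExperiment
setClass("MirnaExperiment", contains = "SummarizedExperiment")

setValidity("MirnaExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  cd <- SummarizedExperiment::colData(object)
  for (col in c("stage", "replicate"))
    if (!col %in% colnames(cd))
      msg <- c(msg, sprintf("colData column '%s' is required", col))
  if ("counts" %in% SummarizedExperiment::assayNames(object)) {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MirnaExperiment
#'
#' @param counts integer matrix, genes in rows, libraries in columns.
#'   Column names are library identifiers (e.g. \code{"ED2_rep1"}).
#' @param stage character vector, one stage label per library.
#' @param replicate integer vector, replicate index per library.
#' @param rowData optional \code{DataFrame} of per-gene annotation.
#' @return A \code{MirnaExperiment}.
#' @export
#' @examples
#' m <- matrix(rpois(8, 10), 2, 4,
#'             dimnames = list(c("g1", "g2"),
#'                             c("NFE_rep1", "NFE_rep2", "ED0_rep1", "ED0_rep2")))
#' MirnaExperiment(m, stage = rep(c("NFE", "ED0"), each = 2),
#'                 replicate = rep(1:2, 2))
MirnaExperiment <- function(counts, stage, replicate, rowData = NULL) {
  stopifnot(is.matrix(counts), length(stage) == ncol(counts),
            length(replicate) == ncol(counts))
  cd <- S4Vectors::DataFrame(stage = as.character(stage),
                             replicate = as.integer(replicate),
                             row.names = colnames(counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd,
    rowData = if (is.null(rowData)) S4Vectors::DataFrame(row.names = rownames(counts)) else rowData)
  new("MirnaExperiment", se)
}

#' MirnaCatalog: the miRNA gene catalog
#'
#' Holds precursor hairpin loci, their mature and star arms and the arm
#' sequences. Coordinates are 1-based closed genomic intervals
#' ([GenomicRanges::GRanges]), the native convention of both Bioconductor
#' and GFF3.
#'
#' @slot genes \code{GRanges} of precursor loci with metadata columns
#'   \code{gene_id} and \code{provenance}
#'   (\code{conserved}/\code{previous}/\code{novel}).
#' @slot matures \code{GRanges} of arm loci (nested inside their
#'   precursor) with \code{mature_id}, \code{gene_id}, \code{arm}
#'   (\code{"5p"}/\code{"3p"}) and \code{role}
#'   (\code{"mature"}/\code{"star"}).
#' @slot matureSeq \code{RNAStringSet} of arm sequences, named by
#'   \code{mature_id}.
#' @slot precursorSeq \code{RNAStringSet} of hairpin sequences, named by
#'   \code{gene_id}.
#' @aliases MirnaCatalog-class
#' @exportClass MirnaCatalog
setClass("MirnaCatalog",
  representation(genes = "GRanges", matures = "GRanges",
                 matureSeq = "RNAStringSet", precursorSeq = "RNAStringSet"))

setValidity("MirnaCatalog", function(object) {
  msg <- character()
  g <- object@genes
  m <- object@matures
  need_g <- c("gene_id", "provenance")
  need_m <- c("mature_id", "gene_id", "arm", "role")
  if (!all(need_g %in% colnames(S4Vectors::mcols(g))))
    msg <- c(msg, "genes must carry gene_id and provenance")
  if (!all(need_m %in% colnames(S4Vectors::mcols(m))))
    msg <- c(msg, "matures must carry mature_id, gene_id, arm, role")
  if (length(msg)) return(msg)
  bad_prov <- setdiff(unique(g$provenance), c("conserved", "previous", "novel"))
  if (length(bad_prov))
    msg <- c(msg, paste("unknown provenance label:", paste(bad_prov, collapse = ", ")))
  idx <- match(m$gene_id, g$gene_id)
  if (anyNA(idx)) {
    msg <- c(msg, "every arm must reference a catalogued gene")
  } else if (length(m)) {
    nested <- GenomicRanges::start(m) >= GenomicRanges::start(g)[idx] &
      GenomicRanges::end(m) <= GenomicRanges::end(g)[idx] &
      as.character(GenomicRanges::seqnames(m)) ==
        as.character(GenomicRanges::seqnames(g))[idx]
    if (!all(nested)) msg <- c(msg, "arm intervals must nest inside their precursor")
  }
  if (length(object@matureSeq) &&
      !setequal(names(object@matureSeq), m$mature_id))
    msg <- c(msg, "matureSeq names must match mature_id")
  if (length(msg)) msg else TRUE
})

#' SimTruth: ground truth of a synthetic data set
#'
#' @slot geneInfo \code{DataFrame} with one row per simulated gene:
#'   \code{gene_id}, \code{wave}, \code{provenance}, \code{scale}.
#' @slot meanProfile numeric matrix (genes x 11 stages) of true mean
#'   expression on the CPM scale.
#' @slot reads \code{DataFrame} of per-read truth (gene, templated length,
#'   appended tail and its class) when reads were simulated; empty
#'   otherwise.
#' @slot params list echoing the generator parameters.
#' @aliases SimTruth-class
#' @exportClass SimTruth
setClass("SimTruth",
  representation(geneInfo = "DataFrame", meanProfile = "matrix",
                 reads = "DataFrame", params = "list"))

setValidity("SimTruth", function(object) {
  gi <- object@geneInfo
  if (!all(c("gene_id", "wave", "provenance") %in% colnames(gi)))
    return("geneInfo must carry gene_id, wave and provenance")
  if (anyDuplicated(gi$gene_id))
    return("each gene must appear exactly once")
  TRUE
})

#' TailModProfile: per-library 3'-end modification summary
#'
#' @slot table \code{DataFrame} with columns \code{library},
#'   \code{stage}, \code{n_assigned}, \code{n_modified}, \code{frequency},
#'   \code{frac_A}, \code{frac_U}, \code{frac_other}.
#' @aliases TailModProfile-class
#' @exportClass TailModProfile
setClass("TailModProfile", representation(table = "DataFrame"))

setValidity("TailModProfile", function(object) {
  tb <- object@table
  need <- c("library", "n_assigned", "n_modified", "frequency",
            "frac_A", "frac_U", "frac_other")
  if (!all(need %in% colnames(tb)))
    return(paste("missing columns:", paste(setdiff(need, colnames(tb)), collapse = ", ")))
  if (nrow(tb) && any(tb$frequency < 0 | tb$frequency > 1, na.rm = TRUE))
    return("frequency must lie in [0, 1]")
  TRUE
})

#' CoexpressionResult: thresholded Spearman network and its modules
#'
#' @slot rho symmetric gene-by-gene Spearman correlation matrix.
#' @slot graph \code{igraph} network (edges where rho exceeds the
#'   threshold, with edge attribute \code{rho}).
#' @slot modules \code{DataFrame} (\code{gene_id}, \code{module}).
#' @slot submodules \code{DataFrame} (\code{gene_id}, \code{submodule})
#'   for members of the largest module.
#' @slot metagenes numeric matrix, one unit-norm 11-stage metagene per row
#'   (modules, then submodules).
#' @slot threshold,subThreshold the two correlation cut-offs used.
#' @aliases CoexpressionResult-class
#' @exportClass CoexpressionResult
setClass("CoexpressionResult",
  representation(rho = "matrix", graph = "ANY", modules = "DataFrame",
                 submodules = "DataFrame", metagenes = "matrix",
                 threshold = "numeric", subThreshold = "numeric"))

#' SimConfig: parameters of the synthetic small-RNA generator
#'
#' Defaults encode the reference study's design: 11 stages times 2
#' replicates; 157 genes split into five expression waves plus
#' background; catalog provenance quotas of 88 conserved, 11 previously
#' known and 58 novel genes; 3'-tail modification rates of 20% at
#' ED0--ED1 versus 9% elsewhere (the reported ranges are 15--26% and
#' 7--11%); tail composition 50% adenylation, 25% uridylation, 25% other;
#' and a 22-nt miRNA / 28-nt piRNA read-length mixture.
#'
#' @slot nGenesPerWave named integer-ish vector, genes per wave.
#' @slot nBackgroundGenes genes with unstructured random profiles.
#' @slot provenanceCounts quotas for conserved/previous/novel labels.
#' @slot dispersion negative-binomial dispersion alpha (>= 0; 0 gives
#'   Poisson counts). Default 0.05, typical of replicate libraries built
#'   from pooled individuals.
#' @slot baseline additive mean offset (CPM scale) for all genes.
#' @slot libSizeMean expected reads per library for the count simulator.
#' @slot sizeFactorSdLog log-normal sd of per-library depth jitter.
#' @slot readsPerLibrary reads per library for the read-level simulator.
#' @slot tailmodRateByStage named per-stage fraction of miRNA reads
#'   carrying a nontemplated 3' tail.
#' @slot tailComposition fractions of modified reads that are adenylated
#'   (\code{A}), uridylated (\code{U}) or \code{other}; sums to 1.
#' @slot pirnaFractionByStage named per-stage fraction of 28-nt
#'   piRNA-like decoy reads (not stated quantitatively in the source
#'   study; defaults peak at ED0--ED1 where the relative amount of miRNA
#'   reads is minimal).
#' @slot seed integer RNG seed; all generator draws derive from it.
#' @aliases SimConfig-class
#' @exportClass SimConfig
setClass("SimConfig",
  representation(nGenesPerWave = "numeric", nBackgroundGenes = "numeric",
                 provenanceCounts = "numeric", dispersion = "numeric",
                 baseline = "numeric", libSizeMean = "numeric",
                 sizeFactorSdLog = "numeric", readsPerLibrary = "numeric",
                 tailmodRateByStage = "numeric", tailComposition = "numeric",
                 pirnaFractionByStage = "numeric", seed = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character()
  frac_ok <- function(x) all(x >= 0 & x <= 1)
  if (any(object@nGenesPerWave < 0) || object@nBackgroundGenes < 0)
    msg <- c(msg, "gene counts must be non-negative")
  if (is.null(names(object@nGenesPerWave)))
    msg <- c(msg, "nGenesPerWave must be named by wave")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  if (!frac_ok(object@tailmodRateByStage))
    msg <- c(msg, "tail modification rates must lie in [0, 1]")
  if (!frac_ok(object@pirnaFractionByStage))
    msg <- c(msg, "piRNA fractions must lie in [0, 1]")
  if (!setequal(names(object@tailComposition), c("A", "U", "other")) ||
      abs(sum(object@tailComposition) - 1) > 1e-9)
    msg <- c(msg, "tailComposition must be named A/U/other and sum to 1")
  for (nm in c("tailmodRateByStage", "pirnaFractionByStage")) {
    v <- slot(object, nm)
    if (!all(bgStages() %in% names(v)))
      msg <- c(msg, sprintf("%s must name all 11 stages", nm))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' All arguments default to the reference study conditions; see
#' \linkS4class{SimConfig} for their meaning.
#'
#' @param nGenesPerWave named vector of genes per wave.
#' @param nBackgroundGenes count of unstructured background genes.
#' @param provenanceCounts named quotas (conserved/previous/novel).
#' @param dispersion NB dispersion alpha.
#' @param baseline additive CPM offset.
#' @param libSizeMean expected library size (counts).
#' @param sizeFactorSdLog log-normal sd of library depth jitter.
#' @param readsPerLibrary reads per library for `simulateReads()`.
#' @param tailmodRateByStage per-stage tail-modification fraction.
#' @param tailComposition named fractions A/U/other, summing to 1.
#' @param pirnaFractionByStage per-stage piRNA decoy fraction.
#' @param seed integer RNG seed.
#' @return A validated \code{SimConfig}.
#' @export
#' @examples
#' simConfig(dispersion = 0)
simConfig <- function(nGenesPerWave = c(A1 = 25, A2 = 30, B = 22, C = 30,
                                        maternal = 20),
                      nBackgroundGenes = 30,
                      provenanceCounts = c(conserved = 88, previous = 11,
                                           novel = 58),
                      dispersion = 0.05,
                      baseline = 0,
                      libSizeMean = 1e6,
                      sizeFactorSdLog = 0.15,
                      readsPerLibrary = 2e4,
                      tailmodRateByStage = NULL,
                      tailComposition = c(A = 0.5, U = 0.25, other = 0.25),
                      pirnaFractionByStage = NULL,
                      seed = 20171011) {
  st <- bgStages()
  if (is.null(tailmodRateByStage)) {
    tailmodRateByStage <- stats::setNames(rep(0.09, 11), st)
    tailmodRateByStage[c("ED0", "ED1")] <- 0.20
  }
  if (is.null(pirnaFractionByStage)) {
    pirnaFractionByStage <- stats::setNames(rep(0.20, 11), st)
    pirnaFractionByStage[c("NFE", "ED0", "ED1", "ED2", "ED6")] <-
      c(0.30, 0.45, 0.40, 0.30, 0.25)
  }
  new("SimConfig", nGenesPerWave = nGenesPerWave,
      nBackgroundGenes = nBackgroundGenes,
      provenanceCounts = provenanceCounts, dispersion = dispersion,
      baseline = baseline, libSizeMean = libSizeMean,
      sizeFactorSdLog = sizeFactorSdLog, readsPerLibrary = readsPerLibrary,
      tailmodRateByStage = tailmodRateByStage,
      tailComposition = tailComposition,
      pirnaFractionByStage = pirnaFractionByStage, seed = seed)
}
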