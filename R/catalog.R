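#' Seed sequence of a mature miRNA
#'
#' The seed is the 7-mer at positions 2--8 (1-based) of the mature
#' sequence, the primary determinant of target recognition and the basis
#' for family grouping.
#'
#' @param x mature sequence(s): character vector or
#'   [Biostrings::RNAStringSet]; T and U are treated as equivalent.
#' @return character vector of 7-mer seeds (RNA alphabet).
#' @export
#' @examples
#' seedOf("UAAGGCACGCGGUGAAUGCCA")   # "AAGGCAC"
seedOf <- function(x) {
  if (is(x, "XStringSet")) x <- stats::setNames(as.character(x), names(x))
  x <- toupper(x)
  if (any(nchar(x) < 8))
    stop("mature sequences must be at least 8 nt long")
  gsub("T", "U", substr(x, 2, 8))
}

#' Group mature miRNAs into seed families
#'
#' Partitions matures by exact seed identity. Families are named after
#' their lexicographically smallest member id, making the grouping
#' deterministic, and returned sorted by family id.
#'
#' @param matures named character vector or [Biostrings::RNAStringSet]
#'   of mature sequences (names are mature ids).
#' @return \code{DataFrame} with \code{family_id}, \code{seed},
#'   \code{n_members} and a \code{members} [IRanges::CharacterList].
#' @export
groupFamilies <- function(matures) {
  if (is(matures, "XStringSet"))
    matures <- stats::setNames(as.character(matures), names(matures))
  if (length(matures) == 0)
    return(S4Vectors::DataFrame(family_id = character(), seed = character(),
                                n_members = integer(),
                                members = IRanges::CharacterList()))
  if (is.null(names(matures)) || anyDuplicated(names(matures)))
    stop("matures must carry unique names")
  seeds <- seedOf(matures)
  groups <- split(names(matures), seeds)
  groups <- lapply(groups, sort)
  fam_id <- vapply(groups, `[`, "", 1)
  ord <- order(fam_id)
  S4Vectors::DataFrame(
    family_id = unname(fam_id[ord]), seed = names(groups)[ord],
    n_members = unname(lengths(groups)[ord]),
    members = IRanges::CharacterList(unname(groups[ord])))
}

#' Detect genomic miRNA clusters by single-linkage chaining
#'
#' Genes on the same scaffold are chained when consecutive precursor
#' starts are within \code{linkageGapBp}; chains with at least two
#' members are reported as clusters. Strand agreement is not required.
#'
#' @param genes a \linkS4class{MirnaCatalog} or a
#'   [GenomicRanges::GRanges] with a \code{gene_id} metadata column.
#' @param linkageGapBp linkage threshold in bp (default 10 kb).
#' @return \code{DataFrame} with \code{cluster_id}, \code{scaffold},
#'   \code{n_genes}, \code{span_bp} and a \code{members} CharacterList,
#'   ordered by scaffold and position.
#' @export
findClusters <- function(genes, linkageGapBp = 10000) {
  if (is(genes, "MirnaCatalog")) genes <- catalogGenes(genes)
  stopifnot(is(genes, "GRanges"))
  if (!"gene_id" %in% colnames(S4Vectors::mcols(genes)))
    stop("genes must carry a gene_id column")
  empty <- S4Vectors::DataFrame(cluster_id = character(),
                                scaffold = character(), n_genes = integer(),
                                span_bp = integer(),
                                members = IRanges::CharacterList())
  if (length(genes) == 0) return(empty)
  ord <- order(as.character(GenomicRanges::seqnames(genes)),
               GenomicRanges::start(genes), genes$gene_id)
  genes <- genes[ord]
  sc <- as.character(GenomicRanges::seqnames(genes))
  st <- GenomicRanges::start(genes)
  en <- GenomicRanges::end(genes)
  newchain <- c(TRUE, sc[-1] != sc[-length(sc)] |
                  diff(st) > linkageGapBp)
  chain <- cumsum(newchain)
  rows <- list()
  for (ch in unique(chain)) {
    i <- which(chain == ch)
    if (length(i) < 2) next
    rows[[length(rows) + 1]] <- list(
      scaffold = sc[i[1]], n = length(i),
      span = max(en[i]) - min(st[i]) + 1L,
      members = genes$gene_id[i])
  }
  if (!length(rows)) return(empty)
  S4Vectors::DataFrame(
    cluster_id = sprintf("cl%d", seq_along(rows)),
    scaffold = vapply(rows, `[[`, "", "scaffold"),
    n_genes = vapply(rows, `[[`, 0L, "n"),
    span_bp = vapply(rows, `[[`, 0L, "span"),
    members = IRanges::CharacterList(lapply(rows, `[[`, "members")))
}

# Watson-Crick (+ G:U wobble) complementarity test on RNA characters
pairsWith <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
  (a == "G" & b == "C") | (a == "C" & b == "G") |
  (a == "G" & b == "U") | (a == "U" & b == "G")
}

#' 3' overhang lengths of a mature:star duplex
#'
#' Determines the duplex register by maximizing base-pair complementarity
#' between the two arms on the hairpin (antiparallel pairing
#' \eqn{x \leftrightarrow r - x}), then reports the 3' overhang length at
#' each duplex end from coordinate arithmetic: at the open (precursor
#' basal) end the 3' arm's 3' terminus overhangs the 5' arm's 5'
#' terminus, and at the loop-proximal end vice versa. Dicer/Drosha
#' processing leaves 2-nt overhangs at both ends of a canonical duplex.
#'
#' @param mature,star lists with \code{start}/\code{end} positions of the
#'   two arms, 1-based within the precursor (order irrelevant; the
#'   leftmost arm is taken as the 5' arm).
#' @param precursor precursor sequence ([Biostrings::RNAString] or
#'   character) used to score complementarity.
#' @return named numeric \code{c(open = , loop = )} overhang lengths in
#'   nt (negative values denote recessed, not overhanging, ends).
#' @export
#' @examples
#' toy <- makeToyAnnotation(1, seed = 7)
#' g <- catalogGenes(toy$catalog); m <- catalogMatures(toy$catalog)
duplexOverhang <- function(mature, star, precursor) {
  a <- c(start = as.integer(mature$start), end = as.integer(mature$end))
  b <- c(start = as.integer(star$start), end = as.integer(star$end))
  if (a["start"] > b["start"]) { tmp <- a; a <- b; b <- tmp }
  if (a["end"] >= b["start"]) stop("arms overlap on the precursor")
  pc <- strsplit(toupper(gsub("T", "U", as.character(precursor))), "")[[1]]
  if (b["end"] > length(pc)) stop("arms exceed the precursor")
  best_r <- NA_integer_; best_score <- -1L
  for (r in (a["start"] + b["start"]):(a["end"] + b["end"])) {
    x <- a["start"]:a["end"]
    y <- r - x
    keep <- y >= b["start"] & y <= b["end"]
    if (!any(keep)) next
    score <- sum(pairsWith(pc[x[keep]], pc[y[keep]]))
    if (score > best_score) { best_score <- score; best_r <- r }
  }
  r <- best_r
  c(open = unname(b["end"] - (r - a["start"])),
    loop = unname(a["end"] - (r - b["start"])))
}

#' Filter candidate hairpins by miRNA biogenesis criteria
#'
#' Applies the configurable evidence filters used to promote hairpin
#' candidates to bona-fide miRNA genes: a minimum mature-arm read count,
#' star-arm read support, a 2-nt 3' duplex overhang at both ends (within
#' tolerance) and 5' homogeneity (the fraction of mature-arm reads
#' sharing the modal 5' end). The exact thresholds of the original
#' prediction filters are deliberately configuration, with the defaults
#' below.
#'
#' @param candidates data.frame with columns \code{candidate_id},
#'   \code{mature_reads}, \code{star_reads}, \code{modal5p_fraction},
#'   \code{overhang_open}, \code{overhang_loop}.
#' @param minMatureReads minimum mature-arm read count (default 10).
#' @param requireStar require at least one star-arm read (default TRUE).
#' @param overhangTarget,overhangTol required 3' overhang and tolerance
#'   (default 2 +/- 1 nt at both duplex ends).
#' @param minFivePrimeHomogeneity minimum modal 5'-end fraction
#'   (default 0.9).
#' @return list with \code{accepted} and \code{rejected} data.frames;
#'   \code{rejected} carries a \code{reasons} column
#'   (semicolon-separated).
#' @export
biogenesisFilter <- function(candidates, minMatureReads = 10,
                             requireStar = TRUE, overhangTarget = 2,
                             overhangTol = 1,
                             minFivePrimeHomogeneity = 0.9) {
  need <- c("candidate_id", "mature_reads", "star_reads",
            "modal5p_fraction", "overhang_open", "overhang_loop")
  if (!is.data.frame(candidates) || !all(need %in% colnames(candidates)))
    stop("malformed evidence: need columns ", paste(need, collapse = ", "))
  if (any(candidates$mature_reads < 0 | candidates$star_reads < 0))
    stop("malformed evidence: read counts must be non-negative")
  reasons <- vector("list", nrow(candidates))
  add <- function(which, why) {
    for (i in which) reasons[[i]] <<- c(reasons[[i]], why)
  }
  add(which(candidates$mature_reads < minMatureReads),
      sprintf("mature reads < %d", minMatureReads))
  if (requireStar) add(which(candidates$star_reads < 1), "no star support")
  off <- abs(candidates$overhang_open - overhangTarget) > overhangTol |
    abs(candidates$overhang_loop - overhangTarget) > overhangTol
  add(which(off), sprintf("3' overhang outside %d +/- %d nt",
                          overhangTarget, overhangTol))
  add(which(candidates$modal5p_fraction < minFivePrimeHomogeneity),
      sprintf("5' homogeneity < %.2f", minFivePrimeHomogeneity))
  ok <- lengths(reasons) == 0
  rejected <- candidates[!ok, , drop = FALSE]
  rejected$reasons <- vapply(reasons[!ok], paste, "", collapse = "; ")
  list(accepted = candidates[ok, , drop = FALSE], rejected = rejected)
}

#' Summarize a miRNA catalog
#'
#' Bookkeeping totals: genes and matures by provenance, distinct mature
#' sequences, seed families and genomic clusters (computed on the fly
#' unless supplied).
#'
#' @param catalog a \linkS4class{MirnaCatalog}.
#' @param families optional precomputed [groupFamilies()] result.
#' @param clusters optional precomputed [findClusters()] result.
#' @return named list of integer totals.
#' @export
catalogSummary <- function(catalog, families = NULL, clusters = NULL) {
  stopifnot(is(catalog, "MirnaCatalog"))
  g <- catalogGenes(catalog)
  m <- catalogMatures(catalog)
  mat <- m[m$role == "mature"]
  prov_gene <- table(factor(g$provenance, c("conserved", "previous", "novel")))
  prov_mat <- table(factor(g$provenance[match(mat$gene_id, g$gene_id)],
                           c("conserved", "previous", "novel")))
  seqs <- matureSequences(catalog, "mature")
  if (is.null(families) && length(seqs))
    families <- groupFamilies(seqs)
  if (is.null(clusters)) clusters <- findClusters(g)
  list(
    n_genes = length(g),
    genes_conserved = as.integer(prov_gene["conserved"]),
    genes_previous = as.integer(prov_gene["previous"]),
    genes_novel = as.integer(prov_gene["novel"]),
    n_matures = length(mat),
    matures_conserved = as.integer(prov_mat["conserved"]),
    matures_previous = as.integer(prov_mat["previous"]),
    matures_novel = as.integer(prov_mat["novel"]),
    n_distinct_mature_seqs = length(unique(as.character(seqs))),
    n_families = if (is.null(families)) 0L else nrow(families),
    n_clusters = nrow(clusters))
}

#' Write / read a miRNA catalog as GFF3
#'
#' Serializes precursors as \code{miRNA_primary_transcript} features and
#' arms as \code{miRNA} features with \code{ID}/\code{Derives_from}
#' attributes (1-based closed coordinates, the miRBase dialect); arm
#' role and gene provenance travel in \code{role} and \code{provenance}
#' attributes. \code{readCatalogGff3()} reconstructs the catalog,
#' extracting arm and precursor sequences from the genome.
#'
#' @param catalog a \linkS4class{MirnaCatalog}.
#' @param path GFF3 file path.
#' @param genome [Biostrings::DNAStringSet] to re-extract sequences from.
#' @return \code{writeCatalogGff3()}: the path, invisibly;
#'   \code{readCatalogGff3()}: a \linkS4class{MirnaCatalog}.
#' @export
writeCatalogGff3 <- function(catalog, path) {
  stopifnot(is(catalog, "MirnaCatalog"))
  g <- catalogGenes(catalog)
  m <- catalogMatures(catalog)
  gg <- GenomicRanges::GRanges(GenomicRanges::seqnames(g),
                               IRanges::IRanges(GenomicRanges::start(g),
                                                GenomicRanges::end(g)),
                               strand = GenomicRanges::strand(g))
  gg$source <- "mirwaves"
  gg$type <- "miRNA_primary_transcript"
  gg$ID <- g$gene_id
  gg$Name <- g$gene_id
  gg$provenance <- g$provenance
  mm <- GenomicRanges::GRanges(GenomicRanges::seqnames(m),
                               IRanges::IRanges(GenomicRanges::start(m),
                                                GenomicRanges::end(m)),
                               strand = GenomicRanges::strand(m))
  mm$source <- "mirwaves"
  mm$type <- "miRNA"
  mm$ID <- m$mature_id
  mm$Name <- m$mature_id
  mm$Derives_from <- m$gene_id
  mm$arm <- m$arm
  mm$role <- m$role
  gr <- suppressWarnings(c(gg, mm))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname writeCatalogGff3
#' @export
readCatalogGff3 <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "gff3")
  gg <- gr[gr$type == "miRNA_primary_transcript"]
  mm <- gr[gr$type == "miRNA"]
  genes <- GenomicRanges::granges(gg)
  genes$gene_id <- gg$ID
  genes$provenance <- if (!is.null(gg$provenance)) as.character(gg$provenance)
                      else rep("novel", length(gg))
  matures <- GenomicRanges::granges(mm)
  matures$mature_id <- mm$ID
  matures$gene_id <- as.character(mm$Derives_from)
  matures$arm <- as.character(mm$arm)
  matures$role <- as.character(mm$role)
  matureSeq <- Biostrings::RNAStringSet(stats::setNames(
    gsub("T", "U", senseSeq(genome, matures)), matures$mature_id))
  precursorSeq <- Biostrings::RNAStringSet(stats::setNames(
    gsub("T", "U", senseSeq(genome, genes)), genes$gene_id))
  out <- new("MirnaCatalog", genes = genes, matures = matures,
             matureSeq = matureSeq, precursorSeq = precursorSeq)
  validObject(out)
  out
}

#' Export a catalog as JSON
#'
#' Portable catalog dump (genes with coordinates and provenance, arms
#' with sequences) for downstream tools.
#'
#' @param catalog a \linkS4class{MirnaCatalog}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeCatalogJson <- function(catalog, path) {
  g <- catalogGenes(catalog)
  m <- catalogMatures(catalog)
  obj <- list(
    genes = data.frame(
      gene_id = g$gene_id,
      scaffold = as.character(GenomicRanges::seqnames(g)),
      start = GenomicRanges::start(g), end = GenomicRanges::end(g),
      strand = as.character(GenomicRanges::strand(g)),
      provenance = g$provenance),
    arms = data.frame(
      mature_id = m$mature_id, gene_id = m$gene_id, arm = m$arm,
      role = m$role, start = GenomicRanges::start(m),
      end = GenomicRanges::end(m),
      sequence = as.character(catalog@matureSeq[m$mature_id])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
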