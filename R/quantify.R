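#' Size-select reads
#'
#' Retains reads whose length is within \code{[minLen, maxLen]}
#' (inclusive), the 16--29 nt window that captures both the ~22-nt miRNA
#' and ~28-nt piRNA peaks while discarding degradation products.
#'
#' @param reads [Biostrings::DNAStringSet] (or character vector).
#' @param minLen,maxLen inclusive length bounds (defaults 16 and 29).
#' @return the retained reads, same container as the input.
#' @export
sizeSelect <- function(reads, minLen = 16, maxLen = 29) {
  stopifnot(minLen <= maxLen)
  w <- if (is(reads, "XStringSet")) Biostrings::width(reads) else nchar(reads)
  reads[w >= minLen & w <= maxLen]
}

#' Classify a candidate 3' tail
#'
#' Totals over all (tail, downstream) pairs: an empty tail is
#' \code{unmodified}; a tail equal to the genomic continuation is a
#' \code{templated_extension} (the read simply extends past the annotated
#' 3' boundary and is not evidence of enzymatic tailing); otherwise an
#' all-A tail is an \code{adenylation}, an all-U tail a
#' \code{uridylation}, anything else \code{other}.
#'
#' @param tail character vector of candidate tails (may be \code{""}).
#' @param downstream genomic sequence downstream of the templated 3' end
#'   (at least as long as the tail; recycled).
#' @return character vector of classes.
#' @export
#' @examples
#' classifyTail(c("", "AA", "AU"), c("GG", "AAG", "GG"))
classifyTail <- function(tail, downstream) {
  n <- max(length(tail), length(downstream))
  tail <- toupper(gsub("T", "U", rep_len(as.character(tail), n)))
  downstream <- toupper(gsub("T", "U", rep_len(as.character(downstream), n)))
  out <- rep("other", n)
  out[tail == ""] <- "unmodified"
  templ <- tail != "" & tail == substr(downstream, 1, nchar(tail))
  out[templ] <- "templated_extension"
  rest <- tail != "" & !templ
  out[rest & grepl("^A+$", tail)] <- "adenylation"
  out[rest & grepl("^U+$", tail)] <- "uridylation"
  out
}

# templated reference strings for every (arm, 5' shift): the genomic
# sequence starting at the shifted 5' end, running maxRefLen nt
# downstream but clipped at the precursor boundary.
buildReferences <- function(catalog, genome, maxShift = 2, maxRefLen = 40) {
  m <- catalogMatures(catalog)
  g <- catalogGenes(catalog)
  gi <- match(m$gene_id, g$gene_id)
  refs <- list()
  for (o in -maxShift:maxShift) {
    plus <- as.character(GenomicRanges::strand(m)) != "-"
    s5 <- ifelse(plus, GenomicRanges::start(m) + o, GenomicRanges::end(m) - o)
    start <- ifelse(plus, s5, pmax(s5 - maxRefLen + 1,
                                   GenomicRanges::start(g)[gi]))
    end <- ifelse(plus, pmin(s5 + maxRefLen - 1,
                             GenomicRanges::end(g)[gi]), s5)
    ok <- start <= end &
      start >= GenomicRanges::start(g)[gi] & end <= GenomicRanges::end(g)[gi]
    if (!any(ok)) next
    rg <- GenomicRanges::GRanges(GenomicRanges::seqnames(m)[ok],
                                 IRanges::IRanges(start[ok], end[ok]),
                                 strand = GenomicRanges::strand(m)[ok])
    refs[[length(refs) + 1]] <- data.frame(
      mature_id = m$mature_id[ok], gene_id = m$gene_id[ok], shift = o,
      annotated_len = GenomicRanges::width(m)[ok] - o,
      ref = senseSeq(genome, rg), stringsAsFactors = FALSE)
  }
  do.call(rbind, refs)
}

# length of the common prefix of two strings
lcpLen <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  n <- min(length(ra), length(rb))
  if (n == 0) return(0L)
  neq <- which(ra[seq_len(n)] != rb[seq_len(n)])
  if (length(neq)) neq[1] - 1L else n
}

#' Assign small-RNA reads to catalogued miRNAs
#'
#' A read is assigned to an annotated arm when its longest
#' genome-templated prefix aligns exactly (no mismatches) inside the
#' precursor with the read 5' end within \code{maxShift} nt of the
#' annotated 5' end, and the nontemplated residual 3' suffix is at most
#' \code{maxTail} nt. The residual relative to the annotated 3' boundary
#' is recorded: nontemplated bases as the candidate \code{tail}
#' (classified with [classifyTail()]), templated bases beyond the
#' boundary as \code{templated_overhang}. Reads matching k > 1 distinct
#' arms contribute weight 1/k to each.
#'
#' @param reads named [Biostrings::DNAStringSet] (or character vector)
#'   for one library.
#' @param catalog a \linkS4class{MirnaCatalog}.
#' @param genome matching [Biostrings::DNAStringSet].
#' @param maxShift 5'-end tolerance in nt (default 2).
#' @param maxTail maximum nontemplated 3' suffix in nt (default 5).
#' @param minTemplated minimum templated prefix length (default 16).
#' @return list with \code{assignments} (data.frame: \code{read_id},
#'   \code{mature_id}, \code{gene_id}, \code{weight}, \code{shift},
#'   \code{templated_len}, \code{templated_overhang}, \code{tail},
#'   \code{downstream}, \code{tail_class}) and \code{unassigned}
#'   (character vector of read ids).
#' @export
assignReads <- function(reads, catalog, genome, maxShift = 2, maxTail = 5,
                        minTemplated = 16) {
  if (is(reads, "XStringSet"))
    reads <- stats::setNames(as.character(reads), names(reads))
  if (is.null(names(reads))) names(reads) <- sprintf("read%06d", seq_along(reads))
  # verify catalog/genome consistency up front
  m <- catalogMatures(catalog)
  stored <- as.character(catalog@matureSeq[m$mature_id])
  genomic <- gsub("T", "U", senseSeq(genome, m))
  bad <- which(stored != genomic)
  if (length(bad))
    stop("catalog/genome inconsistency at feature ", m$mature_id[bad[1]])

  refs <- buildReferences(catalog, genome, maxShift = maxShift)
  refs$key <- substr(refs$ref, 1, minTemplated)
  refmap <- split(seq_len(nrow(refs)), refs$key)

  seqs <- toupper(gsub("U", "T", unname(reads)))
  uq <- unique(seqs)
  keys <- substr(uq, 1, minTemplated)
  hit_rows <- vector("list", length(uq))
  for (i in seq_along(uq)) {
    cand <- refmap[[keys[i]]]
    if (is.null(cand)) next
    s <- uq[i]
    best <- list()
    for (j in cand) {
      lcp <- lcpLen(s, refs$ref[j])
      tail_len <- nchar(s) - lcp
      if (lcp < minTemplated || tail_len > maxTail) next
      mid <- refs$mature_id[j]
      prev <- best[[mid]]
      if (is.null(prev) || lcp > prev$lcp) {
        ann <- refs$annotated_len[j]
        best[[mid]] <- list(
          j = j, lcp = lcp,
          tail = substr(s, lcp + 1, nchar(s)),
          downstream = substr(refs$ref[j], lcp + 1, lcp + tail_len + 2),
          overhang = max(0L, lcp - ann))
      }
    }
    if (length(best)) hit_rows[[i]] <- best
  }
  rows <- list()
  for (i in seq_along(uq)) {
    best <- hit_rows[[i]]
    if (is.null(best)) next
    k <- length(best)
    for (mid in names(best)) {
      h <- best[[mid]]
      rows[[length(rows) + 1]] <- data.frame(
        seq = uq[i], mature_id = mid, gene_id = refs$gene_id[h$j],
        weight = 1 / k, shift = refs$shift[h$j], templated_len = h$lcp,
        templated_overhang = h$overhang,
        tail = gsub("T", "U", h$tail),
        downstream = gsub("T", "U", h$downstream),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(list(assignments = data.frame(read_id = character(),
                  mature_id = character(), gene_id = character(),
                  weight = numeric(), shift = integer(),
                  templated_len = integer(), templated_overhang = integer(),
                  tail = character(), downstream = character(),
                  tail_class = character()),
                unassigned = names(reads)))
  }
  per_uq <- do.call(rbind, rows)
  idx <- match(seqs, uq)
  expand <- split(seq_along(seqs), idx)
  asn_list <- lapply(seq_len(nrow(per_uq)), function(r) {
    reads_i <- expand[[as.character(match(per_uq$seq[r], uq))]]
    if (is.null(reads_i)) return(NULL)
    cbind(data.frame(read_id = names(reads)[reads_i],
                     stringsAsFactors = FALSE),
          per_uq[rep(r, length(reads_i)), -1, drop = FALSE])
  })
  asn <- do.call(rbind, asn_list)
  rownames(asn) <- NULL
  asn$tail_class <- classifyTail(asn$tail, asn$downstream)
  assigned_ids <- unique(asn$read_id)
  list(assignments = asn,
       unassigned = setdiff(names(reads), assigned_ids))
}

#' Per-library 3'-modification profile
#'
#' Aggregates classified assignments into the per-library frequency of
#' 3'-modified reads and the composition (adenylation / uridylation /
#' other) of the modified fraction. Templated extensions count as
#' unmodified unless \code{countTemplatedExtensions = TRUE} (both
#' readings of "reads surpassing the annotated 3' boundary" are
#' supported).
#'
#' @param assignments either one [assignReads()] \code{assignments}
#'   data.frame or a named list of them (one per library).
#' @param countTemplatedExtensions logical; see above.
#' @param stage optional named vector mapping library to stage.
#' @return a \linkS4class{TailModProfile}.
#' @export
tailmodProfile <- function(assignments, countTemplatedExtensions = FALSE,
                           stage = NULL) {
  if (is.data.frame(assignments)) assignments <- list(library = assignments)
  rows <- lapply(names(assignments), function(lib) {
    a <- assignments[[lib]]
    n_assigned <- sum(a$weight)
    modcls <- c("adenylation", "uridylation", "other")
    is_mod <- a$tail_class %in% modcls
    if (countTemplatedExtensions)
      is_mod <- is_mod | (a$tail_class == "templated_extension") |
        (a$templated_overhang > 0)
    n_mod <- sum(a$weight[is_mod])
    wA <- sum(a$weight[is_mod & a$tail_class == "adenylation"])
    wU <- sum(a$weight[is_mod & a$tail_class == "uridylation"])
    wO <- n_mod - wA - wU
    S4Vectors::DataFrame(
      library = lib,
      stage = if (!is.null(stage)) unname(stage[lib]) else NA_character_,
      n_assigned = n_assigned, n_modified = n_mod,
      frequency = if (n_assigned > 0) n_mod / n_assigned else NA_real_,
      frac_A = if (n_mod > 0) wA / n_mod else NA_real_,
      frac_U = if (n_mod > 0) wU / n_mod else NA_real_,
      frac_other = if (n_mod > 0) wO / n_mod else NA_real_)
  })
  new("TailModProfile", table = do.call(rbind, rows))
}

#' Counts-per-million normalization
#'
#' \code{cpm[g, l] = counts[g, l] * 1e6 / sum_g counts[g, l]}. The
#' denominator is the miRNA-assigned total of the library (not the raw
#' sequencing depth), so piRNA-like decoys cannot distort stage
#' comparisons.
#'
#' @param x count matrix or \linkS4class{MirnaExperiment}.
#' @return matrix of CPM values (or the experiment with a \code{"cpm"}
#'   assay added).
#' @export
cpmNormalize <- function(x) {
  cnt <- if (is(x, "MirnaExperiment")) counts(x) else x
  tot <- colSums(cnt)
  if (any(tot == 0))
    stop("library with zero assigned reads: ",
         paste(colnames(cnt)[tot == 0], collapse = ", "))
  cpm <- sweep(cnt, 2, tot, "/") * 1e6
  if (is(x, "MirnaExperiment")) {
    SummarizedExperiment::assay(x, "cpm") <- cpm
    x
  } else cpm
}

#' Family-level expression
#'
#' The expression of a family is the sum of the CPM of its member
#' miRNAs; summing over a full partition restores each library's column
#' total.
#'
#' @param cpm CPM matrix with member ids as rownames.
#' @param families [groupFamilies()] result (or any DataFrame/data.frame
#'   with \code{family_id} and a \code{members} list column).
#' @return matrix, families x libraries.
#' @export
familyExpression <- function(cpm, families) {
  memb <- as.list(families$members)
  missing <- setdiff(unlist(memb), rownames(cpm))
  if (length(missing))
    stop("family member(s) absent from the matrix: ",
         paste(utils::head(missing, 3), collapse = ", "))
  out <- t(vapply(memb, function(ids)
    colSums(cpm[ids, , drop = FALSE]), numeric(ncol(cpm))))
  # vapply collapses the library dimension for single-library matrices
  if (ncol(cpm) == 1) out <- matrix(out, ncol = 1)
  dimnames(out) <- list(families$family_id, colnames(cpm))
  out
}

#' Read-length distribution with peak detection
#'
#' Histogram of read lengths within the configured bounds plus its local
#' maxima. The reference libraries show two prominent peaks, at 22 nt
#' (miRNAs) and 28 nt (piRNAs).
#'
#' @param reads [Biostrings::DNAStringSet] or character vector.
#' @param minLen,maxLen histogram bounds (defaults 16 and 29).
#' @return list with \code{histogram} (named integer vector over
#'   \code{minLen:maxLen}) and \code{peaks} (integer vector of lengths
#'   at local maxima).
#' @export
lengthDistribution <- function(reads, minLen = 16, maxLen = 29) {
  w <- if (is(reads, "XStringSet")) Biostrings::width(reads) else nchar(reads)
  w <- w[w >= minLen & w <= maxLen]
  h <- table(factor(w, levels = minLen:maxLen))
  h <- stats::setNames(as.integer(h), names(h))
  n <- length(h)
  left <- c(-Inf, h[-n])
  right <- c(h[-1], -Inf)
  peaks <- as.integer(names(h))[h > left & h >= right & h > 0]
  list(histogram = h, peaks = peaks)
}

#' FASTQ output / input for simulated libraries
#'
#' Writes each library as a phred+33 FASTQ with constant quality;
#' \code{readFastqReads()} loads one back as a
#' [Biostrings::DNAStringSet].
#'
#' @param reads named list of [Biostrings::DNAStringSet] (as returned in
#'   [simulateReads()]'s \code{reads}).
#' @param dir output directory (created if needed).
#' @param path a FASTQ path.
#' @return \code{writeFastqLibraries()}: the written paths, invisibly.
#' @export
writeFastqLibraries <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (lib in names(reads)) {
    p <- file.path(dir, paste0(lib, ".fastq"))
    rs <- reads[[lib]]
    qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(rs)))
    Biostrings::writeXStringSet(rs, p, format = "fastq", qualities = qual)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname writeFastqLibraries
#' @export
readFastqReads <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}

#' Count matrix from read assignments
#'
#' Sums assignment weights per gene and library. With equal fractional
#' splitting of multi-matching reads the per-read weights sum to 1, so
#' column totals equal the number of assigned reads.
#'
#' @param assignments named list (library -> [assignReads()]
#'   \code{assignments} data.frame).
#' @param geneIds optional gene universe for the row set (defaults to
#'   the genes observed).
#' @param byMature count per arm (\code{mature_id}) instead of per gene.
#' @return numeric matrix, genes (or arms) x libraries.
#' @export
countsFromAssignments <- function(assignments, geneIds = NULL,
                                  byMature = FALSE) {
  if (is.data.frame(assignments)) assignments <- list(library = assignments)
  key <- if (byMature) "mature_id" else "gene_id"
  if (is.null(geneIds))
    geneIds <- sort(unique(unlist(lapply(assignments, function(a) a[[key]]))))
  out <- matrix(0, length(geneIds), length(assignments),
                dimnames = list(geneIds, names(assignments)))
  for (lib in names(assignments)) {
    a <- assignments[[lib]]
    s <- tapply(a$weight, a[[key]], sum)
    out[names(s), lib] <- as.numeric(s)
  }
  out
}
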