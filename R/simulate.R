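#' Simulate a stage-resolved miRNA count matrix
#'
#' Draws a genes-by-22-libraries (11 stages x 2 replicates) count matrix
#' under the wave model: each wave gene's stage mean is
#' \code{scale * template(stage) + baseline}, background genes get
#' unstructured random profiles, per-stage means are rescaled so each
#' library's expected depth equals \code{libSizeMean} times a log-normal
#' per-library size factor, and replicate counts are negative-binomial
#' (Poisson when \code{dispersion == 0}).
#'
#' Provenance labels are assigned deterministically from the catalog
#' quotas: novel labels fill the embryo-restricted waves (A1, B, then A2)
#' first, previously-known labels continue in A2, and conserved labels
#' cover the broadly expressed waves (maternal, C) and the background.
#'
#' @param config a [simConfig()] object.
#' @param templates named list of wave templates
#'   (default [waveTemplates()]); every wave named in
#'   \code{config@nGenesPerWave} must be present.
#' @return list with elements \code{experiment} (a
#'   \linkS4class{MirnaExperiment}) and \code{truth} (a
#'   \linkS4class{SimTruth}).
#' @export
#' @examples
#' sim <- simulateCounts(simConfig(libSizeMean = 1e5))
#' dim(counts(sim$experiment))
simulateCounts <- function(config = simConfig(),
                           templates = waveTemplates()) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  nper <- config@nGenesPerWave
  if (length(nper) == 0 || sum(nper) == 0)
    stop("at least one wave with genes is required")
  missing_tpl <- setdiff(names(nper)[nper > 0], names(templates))
  if (length(missing_tpl))
    stop("no template for wave(s): ", paste(missing_tpl, collapse = ", "))
  st <- bgStages()
  withSeed(config@seed, {
    # order waves embryo-first so provenance quotas land on the right waves
    wave_order <- intersect(c("A1", "B", "A2", "maternal", "C"), names(nper))
    wave_order <- c(wave_order, setdiff(names(nper), wave_order))
    waves <- rep(wave_order, nper[wave_order])
    nbg <- config@nBackgroundGenes
    n <- length(waves) + nbg
    gene_id <- sprintf("bge-sim-%03d", seq_len(n))
    wave <- c(waves, rep("background", nbg))

    prof <- matrix(0, n, 11, dimnames = list(gene_id, st))
    for (i in seq_along(waves)) prof[i, ] <- templates[[waves[i]]]
    if (nbg > 0) for (i in (length(waves) + 1):n) {
      v <- exp(stats::rnorm(11, 0, 1.5))
      prof[i, ] <- v / max(v)
    }
    scale <- exp(stats::rnorm(n, log(300), 0.4))
    if (nbg > 0)
      scale[(length(waves) + 1):n] <- exp(stats::rnorm(nbg, log(150), 0.8))

    quota <- config@provenanceCounts
    quota <- round(quota / sum(quota) * n)
    quota[1] <- n - sum(quota[-1])
    prov_pool <- rep(c("novel", "previous", "conserved"),
                     c(quota["novel"], quota["previous"], quota["conserved"]))
    provenance <- prov_pool[seq_len(n)]

    mu <- prof * scale + config@baseline
    stage_tot <- colSums(mu)
    if (any(stage_tot == 0))
      stop("a stage has zero total mean expression; adjust templates")
    libs <- paste0(rep(st, each = 2), "_rep", 1:2)
    cnt <- matrix(0L, n, 22, dimnames = list(gene_id, libs))
    sf <- exp(stats::rnorm(22, 0, config@sizeFactorSdLog))
    names(sf) <- libs
    for (s in seq_len(11)) for (r in 1:2) {
      j <- (s - 1) * 2 + r
      m <- mu[, s] / stage_tot[s] * config@libSizeMean * sf[j]
      cnt[, j] <- if (config@dispersion == 0) stats::rpois(n, m)
                  else stats::rnbinom(n, mu = m, size = 1 / config@dispersion)
    }
    exp_cpm <- sweep(mu, 2, stage_tot, "/") * 1e6
    truth <- new("SimTruth",
      geneInfo = S4Vectors::DataFrame(gene_id = gene_id, wave = wave,
                                      provenance = provenance,
                                      scale = scale, row.names = gene_id),
      meanProfile = exp_cpm,
      reads = S4Vectors::DataFrame(),
      params = list(config = config, sizeFactors = sf))
    expmt <- MirnaExperiment(cnt, stage = rep(st, each = 2),
                             replicate = rep(1:2, 11),
                             rowData = S4Vectors::DataFrame(
                               wave = wave, provenance = provenance,
                               row.names = gene_id))
    list(experiment = expmt, truth = truth)
  })
}

BASES <- c("A", "C", "G", "T")

randomDna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Build a toy genome with embedded miRNA hairpins
#'
#' Generates a single random scaffold containing \code{nPrecursors}
#' hairpin precursors (~55--80 nt). Each precursor carries a 5p and a 3p
#' arm (21--23 nt) whose duplex has the canonical 2-nt 3' overhang at
#' both ends; one arm is labelled mature and the other star. When
#' \code{nClusters > 0} the precursors are distributed evenly over the
#' clusters and placed with start-to-start gaps below \code{gapKb};
#' otherwise (or between clusters) loci are separated widely enough that
#' default linkage chaining never joins them.
#'
#' The two genomic bases immediately downstream of every arm's 3' end are
#' fixed to \code{"GC"}, so a nontemplated adenine or uridine tail always
#' mismatches the genome at position +1; templated-extension ambiguity is
#' exercised by dedicated fixtures instead of the generator.
#'
#' @param nPrecursors number of hairpin loci (>= 1).
#' @param nClusters number of genomic clusters (0 for all-singleton
#'   layout; requires \code{nPrecursors >= 2 * nClusters}).
#' @param gapKb upper bound (kb) on within-cluster start-to-start gaps.
#' @param seed integer RNG seed.
#' @return list with \code{genome} (named [Biostrings::DNAStringSet]) and
#'   \code{catalog} (a \linkS4class{MirnaCatalog}).
#' @export
#' @examples
#' toy <- makeToyAnnotation(4, nClusters = 1, gapKb = 8)
#' toy$catalog
makeToyAnnotation <- function(nPrecursors, nClusters = 0, gapKb = 8,
                              seed = 20171011) {
  if (nPrecursors < 1 || nClusters < 0)
    stop("invalid parameter: counts must be non-negative and nPrecursors >= 1")
  if (nClusters > 0 && nPrecursors < 2 * nClusters)
    stop("invalid parameter: need at least 2 precursors per cluster")
  withSeed(seed, {
    gap_bp <- gapKb * 1000
    wide <- max(25000, 3 * gap_bp)

    # cluster assignment: even split; 0 clusters means all singletons
    if (nClusters > 0) {
      sizes <- rep(nPrecursors %/% nClusters, nClusters)
      extra <- nPrecursors %% nClusters
      if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
      groups <- rep(seq_len(nClusters), sizes)
    } else {
      groups <- seq_len(nPrecursors)
    }

    starts <- integer(nPrecursors)
    pos <- 10000L
    for (i in seq_len(nPrecursors)) {
      if (i > 1) {
        same <- groups[i] == groups[i - 1]
        step <- if (same) sample(1000:(gap_bp - 1), 1) else wide
        pos <- pos + as.integer(step)
      }
      starts[i] <- pos
    }

    gene_id <- sprintf("bge-mir-toy-%02d", seq_len(nPrecursors))
    rec <- vector("list", nPrecursors)
    for (i in seq_len(nPrecursors)) {
      # mature arms are modally 22 nt
      L <- sample(21:23, 1, prob = c(0.15, 0.7, 0.15))
      arm5 <- randomDna(L)
      arm3 <- paste0(revcompChar(substr(arm5, 1, L - 2)), randomDna(2))
      loop <- paste0("GC", randomDna(sample(10:16, 1)))
      f5 <- randomDna(sample(3:8, 1))
      f3 <- paste0("GC", randomDna(sample(1:6, 1)))
      prec <- paste0(f5, arm5, loop, arm3, f3)
      off5 <- nchar(f5)
      rec[[i]] <- list(
        prec = prec, len = nchar(prec),
        arm5 = c(start = off5 + 1, end = off5 + L),
        arm3 = c(start = off5 + L + nchar(loop) + 1,
                 end = off5 + L + nchar(loop) + nchar(arm3)),
        matureArm = sample(c("5p", "3p"), 1),
        strand = sample(c("+", "-"), 1, prob = c(0.8, 0.2)))
    }

    glen <- max(starts + vapply(rec, `[[`, 0L, "len")) + 10000L
    genome_chars <- strsplit(randomDna(glen), "")[[1]]
    g_start <- starts
    g_end <- starts + vapply(rec, `[[`, 0L, "len") - 1L
    for (i in seq_len(nPrecursors)) {
      seqi <- if (rec[[i]]$strand == "+") rec[[i]]$prec else revcompChar(rec[[i]]$prec)
      genome_chars[g_start[i]:g_end[i]] <- strsplit(seqi, "")[[1]]
    }
    genome <- Biostrings::DNAStringSet(paste(genome_chars, collapse = ""))
    names(genome) <- "scaffold_1"

    # arm intervals in genomic coordinates (sense intervals on `strand`)
    toGenomic <- function(i, iv) {
      if (rec[[i]]$strand == "+") {
        c(g_start[i] + iv["start"] - 1L, g_start[i] + iv["end"] - 1L)
      } else {
        c(g_end[i] - iv["end"] + 1L, g_end[i] - iv["start"] + 1L)
      }
    }
    mat_rows <- list()
    for (i in seq_len(nPrecursors)) {
      for (arm in c("5p", "3p")) {
        iv <- toGenomic(i, rec[[i]][[paste0("arm", substr(arm, 1, 1), "")]])
        role <- if (rec[[i]]$matureArm == arm) "mature" else "star"
        suffix <- if (role == "star") paste0("-", arm, "*") else paste0("-", arm)
        within <- rec[[i]][[if (arm == "5p") "arm5" else "arm3"]]
        seq_rna <- gsub("T", "U",
                        substr(rec[[i]]$prec, within["start"], within["end"]))
        mat_rows[[length(mat_rows) + 1]] <- data.frame(
          mature_id = paste0(gene_id[i], suffix), gene_id = gene_id[i],
          arm = arm, role = role, start = iv[1], end = iv[2],
          strand = rec[[i]]$strand, seq = seq_rna,
          stringsAsFactors = FALSE)
      }
    }
    md <- do.call(rbind, mat_rows)

    genes <- GenomicRanges::GRanges("scaffold_1",
      IRanges::IRanges(g_start, g_end),
      strand = vapply(rec, `[[`, "", "strand"),
      gene_id = gene_id, provenance = rep("novel", nPrecursors))
    matures <- GenomicRanges::GRanges("scaffold_1",
      IRanges::IRanges(md$start, md$end), strand = md$strand,
      mature_id = md$mature_id, gene_id = md$gene_id,
      arm = md$arm, role = md$role)
    matureSeq <- Biostrings::RNAStringSet(stats::setNames(md$seq, md$mature_id))
    precursorSeq <- Biostrings::RNAStringSet(stats::setNames(
      gsub("T", "U", vapply(rec, `[[`, "", "prec")), gene_id))
    catalog <- new("MirnaCatalog", genes = genes, matures = matures,
                   matureSeq = matureSeq, precursorSeq = precursorSeq)
    validObject(catalog)
    list(genome = genome, catalog = catalog)
  })
}

# sense-strand genomic sequence of GRanges loci, as DNA character
senseSeq <- function(genome, gr) {
  sc <- as.character(GenomicRanges::seqnames(gr))
  bad <- setdiff(unique(sc), names(genome))
  if (length(bad))
    stop("unknown scaffold reference: ", paste(bad, collapse = ", "))
  out <- character(length(gr))
  for (i in seq_along(gr)) {
    s <- Biostrings::subseq(genome[[sc[i]]],
                            GenomicRanges::start(gr)[i],
                            GenomicRanges::end(gr)[i])
    if (as.character(GenomicRanges::strand(gr))[i] == "-")
      s <- Biostrings::reverseComplement(s)
    out[i] <- as.character(s)
  }
  out
}

#' Simulate small-RNA reads per library
#'
#' Emits, for each of the 22 libraries, a mixture of miRNA-derived reads
#' (sampled from the catalog's mature arms, lengths centred at 22 nt via
#' templated 3' trimming/extension) and 28-nt random piRNA-like decoys at
#' the configured per-stage fraction. A per-stage fraction of miRNA reads
#' carries a nontemplated 3' tail of 1--3 nt whose composition follows
#' \code{config@tailComposition}; tails always mismatch the genomic base
#' at position +1 (tailed reads keep the exact annotated 3' boundary, so
#' the \code{"GC"} guard bases built by [makeToyAnnotation()] apply).
#'
#' @param config a [simConfig()] object (uses \code{readsPerLibrary},
#'   \code{tailmodRateByStage}, \code{tailComposition},
#'   \code{pirnaFractionByStage} and \code{seed}).
#' @param catalog a \linkS4class{MirnaCatalog}.
#' @param genome the matching [Biostrings::DNAStringSet].
#' @param stages stages to simulate (default all 11).
#' @return list with \code{reads} (named list of
#'   [Biostrings::DNAStringSet], one per library) and \code{truth}
#'   (a \linkS4class{SimTruth} carrying the per-read record).
#' @export
simulateReads <- function(config, catalog, genome,
                          stages = bgStages()) {
  stopifnot(is(config, "SimConfig"), is(catalog, "MirnaCatalog"))
  validObject(config)
  m <- catalogMatures(catalog)
  m <- m[m$role == "mature"]
  if (length(m) == 0) stop("catalog has no mature arms")
  genomic <- gsub("T", "U", senseSeq(genome, m))
  stored <- as.character(matureSequences(catalog, "mature")[m$mature_id])
  bad <- which(genomic != stored)
  if (length(bad))
    stop("annotation/genome mismatch for feature ", m$mature_id[bad[1]])

  # downstream templated bases (sense orientation), 3 nt past the 3' end
  down <- GenomicRanges::flank(m, width = 3, start = FALSE)
  down_seq <- senseSeq(genome, down)

  mat_seq_dna <- gsub("U", "T", stored)
  withSeed(config@seed, {
    scale <- exp(stats::rnorm(length(m), log(100), 0.7))
    pgene <- scale / sum(scale)
    reads <- list()
    truth_rows <- list()
    for (stg in stages) for (r in 1:2) {
      lib <- paste0(stg, "_rep", r)
      n <- config@readsPerLibrary
      n_pi <- stats::rbinom(1, n, config@pirnaFractionByStage[[stg]])
      n_mi <- n - n_pi
      gi <- sample(seq_along(m), n_mi, replace = TRUE, prob = pgene)
      tailed <- stats::runif(n_mi) < config@tailmodRateByStage[[stg]]
      delta <- ifelse(tailed, 0L,
                      sample(c(-1L, 0L, 1L), n_mi, replace = TRUE,
                             prob = c(0.2, 0.6, 0.2)))
      base_seq <- mat_seq_dna[gi]
      Lm <- nchar(base_seq)
      tseq <- substr(paste0(base_seq, substr(down_seq[gi], 1, 1)),
                     1, Lm + delta)
      tail <- character(n_mi)
      cls <- rep("unmodified", n_mi)
      if (any(tailed)) {
        idx <- which(tailed)
        k <- sample(1:3, length(idx), replace = TRUE, prob = c(0.6, 0.3, 0.1))
        tc <- config@tailComposition
        cl <- sample(c("adenylation", "uridylation", "other"), length(idx),
                     replace = TRUE, prob = tc[c("A", "U", "other")])
        for (j in seq_along(idx)) {
          i2 <- idx[j]
          dn1 <- substr(down_seq[gi[i2]], 1, 1)
          tail[i2] <- switch(cl[j],
            adenylation = strrep("A", k[j]),
            uridylation = strrep("T", k[j]),
            other = {
              first <- setdiff(c("C", "G"), dn1)[1]
              paste0(first, if (k[j] > 1) randomDna(k[j] - 1) else "")
            })
          cls[i2] <- cl[j]
        }
        # an 'other' tail that happens to be all-A/all-T reads as A/U-tailing
        allA <- cls == "other" & grepl("^A+$", tail)
        allT <- cls == "other" & grepl("^T+$", tail)
        cls[allA] <- "adenylation"
        cls[allT] <- "uridylation"
      }
      mi_seq <- paste0(tseq, tail)
      pi_seq <- vapply(sample(27:29, n_pi, replace = TRUE,
                              prob = c(0.25, 0.5, 0.25)),
                       randomDna, "")
      all_seq <- c(mi_seq, pi_seq)
      ids <- sprintf("%s_read%06d", lib, seq_len(n))
      rs <- Biostrings::DNAStringSet(all_seq)
      names(rs) <- ids
      reads[[lib]] <- rs
      truth_rows[[lib]] <- S4Vectors::DataFrame(
        library = lib, read_id = ids,
        gene_id = c(m$gene_id[gi], rep(NA_character_, n_pi)),
        mature_id = c(m$mature_id[gi], rep(NA_character_, n_pi)),
        templated_len = c(nchar(tseq), rep(NA_integer_, n_pi)),
        tail = c(gsub("T", "U", tail), rep(NA_character_, n_pi)),
        tail_class = c(cls, rep(NA_character_, n_pi)))
    }
    truth <- new("SimTruth",
      geneInfo = S4Vectors::DataFrame(
        gene_id = unique(m$gene_id),
        wave = rep("background", length(unique(m$gene_id))),
        provenance = rep("novel", length(unique(m$gene_id))),
        row.names = unique(m$gene_id)),
      meanProfile = matrix(0, 0, 11),
      reads = do.call(rbind, truth_rows),
      params = list(config = config))
    list(reads = reads, truth = truth)
  })
}

#' Synthetic cross-species family-expression tables
#'
#' Builds family-level CPM-sum tables for four "species" non-fertilized
#' egg libraries shaped like the reference comparison: the two short
#' germ-band-like species (\code{bge}, \code{tca}) are enriched in
#' MIR-276- and MIR-279-like families and carry let-7-cluster expression,
#' while the two long germ-band-like species (\code{dme}, \code{dvi}) are
#' enriched in a MIR-92-like family; \code{bge} additionally carries a
#' highly expressed MIR-bg5-like family.
#'
#' @param nShared number of undifferentiated shared families added on top
#'   of the discriminating ones.
#' @param seed integer RNG seed.
#' @return named list of one-column matrices (families x library), one
#'   per species, rownames = family ids.
#' @export
simulateSpeciesTables <- function(nShared = 20, seed = 20171011) {
  withSeed(seed, {
    fam <- c("MIR-276", "MIR-279", "MIR-92", "MIR-bg5", "let-7",
             sprintf("FAM-%02d", seq_len(nShared)))
    base <- exp(stats::rnorm(length(fam), log(2000), 0.6))
    names(base) <- fam
    species <- c("bge", "tca", "dme", "dvi")
    short_gb <- c("bge", "tca")
    out <- list()
    for (sp in species) {
      v <- base * exp(stats::rnorm(length(fam), 0, 0.15))
      if (sp %in% short_gb) {
        v[c("MIR-276", "MIR-279")] <- v[c("MIR-276", "MIR-279")] * 40
        v["let-7"] <- v["let-7"] * 8
        v["MIR-92"] <- v["MIR-92"] / 10
      } else {
        v["MIR-92"] <- v["MIR-92"] * 40
        v[c("MIR-276", "MIR-279")] <- v[c("MIR-276", "MIR-279")] / 10
        v["let-7"] <- v["let-7"] / 8
      }
      v["MIR-bg5"] <- if (sp == "bge") v["MIR-bg5"] * 25 else v["MIR-bg5"] / 50
      out[[sp]] <- matrix(v, ncol = 1,
                          dimnames = list(fam, paste0(sp, "_NFE")))
    }
    out
  })
}

randomRnaVec <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = ""), "")
}

#' Synthetic catalog with the reference bookkeeping structure
#'
#' Builds a \linkS4class{MirnaCatalog} whose provenance, duplication,
#' family and cluster structure mirrors the reference repertoire:
#' 88 conserved genes, 11 previously known genes, 63 lineage-specific
#' novel genes carrying 54 distinct mature sequences (three triplet and
#' three pair duplications) that group into 48 seed families, plus a
#' 4-gene MIR-309-like family sharing one seed and clustered on one
#' scaffold. 43 of the 63 novel genes are placed in nine genomic
#' clusters of 2--12 genes spanning under ~70 kb; all remaining genes
#' are isolated loci.
#'
#' @param seed integer RNG seed.
#' @return a \linkS4class{MirnaCatalog}.
#' @export
simulateCatalog <- function(seed = 20171011) {
  withSeed(seed, {
    matlen <- 22L
    distinct_seed <- function(n, existing = character()) {
      out <- character(0)
      while (length(out) < n) {
        cand <- unique(randomRnaVec(n - length(out), 7))
        cand <- setdiff(cand, c(existing, out))
        out <- c(out, cand)
      }
      out
    }
    mature_from_seed <- function(sd7) {
      paste0(randomRnaVec(1, 1), sd7,
             randomRnaVec(1, matlen - 8))
    }

    cons_seeds <- distinct_seed(88)
    prev_seeds <- distinct_seed(11, cons_seeds)
    nov_seeds <- distinct_seed(48, c(cons_seeds, prev_seeds))
    mir309_seed <- distinct_seed(1, c(cons_seeds, prev_seeds, nov_seeds))

    cons_seq <- vapply(cons_seeds, mature_from_seed, "")
    prev_seq <- vapply(prev_seeds, mature_from_seed, "")
    # 48 novel families -> 54 distinct matures (6 families of 2)
    nov_seq <- c(vapply(nov_seeds, mature_from_seed, ""),
                 vapply(nov_seeds[1:6], mature_from_seed, ""))
    # 54 distinct matures -> 63 genes (3 triplets + 3 pairs share a mature)
    nov_gene_seq <- c(nov_seq, rep(nov_seq[1:3], each = 2),
                      nov_seq[4:6])
    stopifnot(length(nov_gene_seq) == 63,
              length(unique(nov_gene_seq)) == 54)
    mir309_seq <- vapply(rep(mir309_seed, 4), mature_from_seed, "")

    seqs <- c(cons_seq, prev_seq, nov_gene_seq, mir309_seq)
    prov <- c(rep("conserved", 88), rep("previous", 11),
              rep("novel", 63 + 4))
    n <- length(seqs)
    gene_id <- sprintf("bge-mir-%03d", seq_len(n))
    gene_id[(n - 3):n] <- sprintf("bge-mir-309-%d", 1:4)

    # genomic layout: novel genes 100..142 (43 of the 63) go into nine
    # clusters of 2-12 genes; the MIR-309-like genes form a tenth
    cl_sizes <- c(12, 8, 6, 5, 4, 2, 2, 2, 2)
    novel_idx <- 100:162
    clustered <- novel_idx[seq_len(sum(cl_sizes))]
    cluster_of <- integer(n)
    cluster_of[clustered] <- rep(seq_along(cl_sizes), cl_sizes)
    cluster_of[(n - 3):n] <- 10L

    scaffold <- sprintf("scaffold_%03d", seq_len(n))
    start <- rep(5000L, n)
    for (cl in 1:10) {
      i <- which(cluster_of == cl)
      scaffold[i] <- sprintf("scaffold_cl%02d", cl)
      gaps <- sample(3000:6000, length(i) - 1, replace = TRUE)
      start[i] <- 5000L + c(0L, cumsum(gaps))
    }
    singles <- which(cluster_of == 0)
    scaffold[singles] <- sprintf("scaffold_%03d", seq_along(singles))

    flank5 <- sample(5:12, n, replace = TRUE)
    preclen <- flank5 + matlen + sample(30:40, n, replace = TRUE)
    prec_seq <- vapply(seq_len(n), function(i) {
      before <- randomRnaVec(1, flank5[i])
      after <- randomRnaVec(1, preclen[i] - flank5[i] - matlen)
      paste0(before, seqs[i], after)
    }, "")

    genes <- GenomicRanges::GRanges(scaffold,
      IRanges::IRanges(start, start + preclen - 1L), strand = "+",
      gene_id = gene_id, provenance = prov)
    matures <- GenomicRanges::GRanges(scaffold,
      IRanges::IRanges(start + flank5, start + flank5 + matlen - 1L),
      strand = "+", mature_id = paste0(gene_id, "-5p"),
      gene_id = gene_id, arm = "5p", role = "mature")
    out <- new("MirnaCatalog", genes = genes, matures = matures,
               matureSeq = Biostrings::RNAStringSet(
                 stats::setNames(seqs, paste0(gene_id, "-5p"))),
               precursorSeq = Biostrings::RNAStringSet(
                 stats::setNames(prec_seq, gene_id)))
    validObject(out)
    out
  })
}

#' Synthetic candidate-hairpin evidence for the biogenesis funnel
#'
#' Builds a table of candidate evidence in which exactly \code{nPass}
#' candidates satisfy every default [biogenesisFilter()] criterion and
#' the rest violate at least one (too few mature reads, missing star
#' support, aberrant duplex overhangs or heterogeneous 5' ends),
#' emulating the shape of a prediction funnel in which a few dozen
#' bona-fide genes emerge from a few hundred hairpin candidates.
#'
#' @param nCandidates total candidates (default 264).
#' @param nPass candidates built to pass (default 67).
#' @param seed integer RNG seed.
#' @return data.frame of [biogenesisFilter()] evidence columns.
#' @export
simulateCandidateEvidence <- function(nCandidates = 264, nPass = 67,
                                      seed = 20171011) {
  stopifnot(nPass <= nCandidates)
  withSeed(seed, {
    n <- nCandidates
    ev <- data.frame(
      candidate_id = sprintf("cand-%03d", seq_len(n)),
      mature_reads = sample(10:2000, n, replace = TRUE),
      star_reads = sample(1:100, n, replace = TRUE),
      modal5p_fraction = stats::runif(n, 0.9, 1),
      overhang_open = sample(1:3, n, replace = TRUE),
      overhang_loop = sample(1:3, n, replace = TRUE))
    fail <- seq_len(n) > nPass
    modes <- c("reads", "star", "overhang", "homog")
    pick <- sample(modes, n, replace = TRUE)
    for (i in which(fail)) {
      how <- pick[i]
      if (how == "reads") ev$mature_reads[i] <- sample(0:9, 1)
      if (how == "star") ev$star_reads[i] <- 0L
      if (how == "overhang") ev$overhang_open[i] <- sample(c(-1, 4:8), 1)
      if (how == "homog") ev$modal5p_fraction[i] <- stats::runif(1, 0.3, 0.89)
    }
    ev[sample(n), , drop = FALSE]
  })
}
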