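test_that("count simulation is deterministic and respects the design", {
  cfg <- simConfig(libSizeMean = 2e5)
  s1 <- simulateCounts(cfg)
  s2 <- simulateCounts(cfg)
  expect_identical(counts(s1$experiment), counts(s2$experiment))
  expect_identical(as.data.frame(truthGenes(s1$truth)),
                   as.data.frame(truthGenes(s2$truth)))

  expmt <- s1$experiment
  expect_equal(dim(counts(expmt)), c(157, 22))
  expect_equal(stageOf(expmt), rep(bgStages(), each = 2))
  # provenance quotas mirror the catalog
  expect_equal(as.vector(table(truthGenes(s1$truth)$provenance)[
    c("conserved", "previous", "novel")]), c(88, 11, 58))
  # every gene has exactly one wave and one provenance label
  gi <- truthGenes(s1$truth)
  expect_false(anyNA(gi$wave))
  expect_false(anyNA(gi$provenance))
})

test_that("library sizes concentrate around libSizeMean", {
  cfg <- simConfig(libSizeMean = 1e5, sizeFactorSdLog = 0.05, seed = 11)
  sim <- simulateCounts(cfg)
  tot <- colSums(counts(sim$experiment))
  # dominant variance source is the log-normal depth jitter
  sd_tot <- 1e5 * sqrt(exp(0.05^2) - 1) + sqrt(1e5)
  expect_true(all(abs(tot - 1e5) < 4 * sd_tot))
})

test_that("degenerate noise settings give Poisson counts on the template", {
  cfg <- simConfig(dispersion = 0, baseline = 0, sizeFactorSdLog = 0,
                   libSizeMean = 1e6, seed = 5)
  sim <- simulateCounts(cfg)
  gi <- truthGenes(sim$truth)
  bgenes <- gi$gene_id[gi$wave == "B"]
  tplB <- waveTemplates()$B
  off <- names(tplB)[tplB == 0]
  off_libs <- paste0(rep(off, each = 2), "_rep", 1:2)
  expect_true(all(counts(sim$experiment)[bgenes, off_libs] == 0))

  # empirical stage means converge to the true template at deep coverage
  cpm <- cpmNormalize(counts(sim$experiment))
  sm <- stageMeans(cpm, designOf(sim$experiment))
  truth <- truthProfile(sim$truth)
  big <- truth > 200   # relative error bound needs non-tiny means
  relerr <- abs(sm[big] - truth[big]) / truth[big]
  expect_lt(stats::median(relerr), 0.02)
})

test_that("toy annotation lays out precursors and clusters as requested", {
  toy <- makeToyAnnotation(4, nClusters = 1, gapKb = 8, seed = 3)
  expect_equal(length(catalogGenes(toy$catalog)), 4)
  cl <- findClusters(toy$catalog, linkageGapBp = 10000)
  expect_equal(nrow(cl), 1)
  expect_gte(max(cl$n_genes), 2)

  one <- makeToyAnnotation(1, nClusters = 0, seed = 3)
  expect_equal(length(catalogGenes(one$catalog)), 1)
  expect_equal(nrow(findClusters(one$catalog)), 0)

  # 12 genes chained < 7 kb apart form one long cluster
  chain <- makeToyAnnotation(12, nClusters = 1, gapKb = 7, seed = 3)
  cl12 <- findClusters(chain$catalog, linkageGapBp = 10000)
  expect_equal(cl12$n_genes, 12L)
  expect_gt(cl12$span_bp, 12000)
  expect_lt(cl12$span_bp, 90000)

  expect_error(makeToyAnnotation(-1), "invalid parameter")
  expect_error(makeToyAnnotation(3, nClusters = 2), "invalid parameter")
})

test_that("toy hairpins have canonical 2-nt 3' duplex overhangs", {
  toy <- makeToyAnnotation(5, seed = 9)
  g <- catalogGenes(toy$catalog)
  m <- catalogMatures(toy$catalog)
  for (gid in g$gene_id) {
    arms <- m[m$gene_id == gid]
    prec <- precursorSequences(toy$catalog)[[gid]]
    gs <- GenomicRanges::start(g)[g$gene_id == gid]
    ge <- GenomicRanges::end(g)[g$gene_id == gid]
    minus <- as.character(GenomicRanges::strand(g))[g$gene_id == gid] == "-"
    # arm intervals relative to the (sense) precursor
    rel <- lapply(seq_along(arms), function(i) {
      if (minus) list(start = ge - GenomicRanges::end(arms)[i] + 1,
                      end = ge - GenomicRanges::start(arms)[i] + 1)
      else list(start = GenomicRanges::start(arms)[i] - gs + 1,
                end = GenomicRanges::end(arms)[i] - gs + 1)
    })
    ord <- order(vapply(rel, `[[`, 0, "start"))
    ov <- duplexOverhang(rel[[ord[1]]], rel[[ord[2]]], prec)
    expect_equal(unname(ov), c(2, 2))
  }
})

test_that("GFF3 catalog output round-trips through the reader", {
  toy <- makeToyAnnotation(6, nClusters = 1, gapKb = 8, seed = 21)
  path <- tempfile(fileext = ".gff3")
  writeCatalogGff3(toy$catalog, path)
  back <- readCatalogGff3(path, toy$genome)
  expect_equal(GenomicRanges::start(catalogGenes(back)),
               GenomicRanges::start(catalogGenes(toy$catalog)))
  expect_equal(GenomicRanges::end(catalogMatures(back)),
               GenomicRanges::end(catalogMatures(toy$catalog)))
  expect_equal(sort(names(matureSequences(back))),
               sort(names(matureSequences(toy$catalog))))
  expect_identical(
    as.character(matureSequences(back)[names(matureSequences(toy$catalog))]),
    as.character(matureSequences(toy$catalog)))
})

test_that("read simulation is deterministic, traceable, honest about rates", {
  toy <- makeToyAnnotation(6, seed = 2)
  cfg <- simConfig(readsPerLibrary = 2000, seed = 77)
  r1 <- simulateReads(cfg, toy$catalog, toy$genome, stages = c("ED0", "N3"))
  r2 <- simulateReads(cfg, toy$catalog, toy$genome, stages = c("ED0", "N3"))
  expect_identical(lapply(r1$reads, as.character),
                   lapply(r2$reads, as.character))

  tr <- truthReads(r1$truth)
  expect_equal(nrow(tr), 4 * 2000)
  mi <- tr[!is.na(tr$gene_id), ]
  # every miRNA read is traceable to gene, templated length and tail
  expect_false(anyNA(mi$templated_len))
  expect_false(anyNA(mi$tail))

  # zero modification rate -> no tails anywhere
  cfg0 <- simConfig(readsPerLibrary = 1000,
                    tailmodRateByStage = stats::setNames(rep(0, 11), bgStages()))
  r0 <- simulateReads(cfg0, toy$catalog, toy$genome, stages = "ED2")
  tr0 <- truthReads(r0$truth)
  expect_true(all(tr0$tail[!is.na(tr0$tail)] == ""))

  # mismatched genome is refused with the offending feature named
  genome_bad <- toy$genome
  sq <- as.character(genome_bad[[1]])
  m <- catalogMatures(toy$catalog)
  gs <- GenomicRanges::start(m[m$role == "mature"])[1]
  substr(sq, gs + 3, gs + 3) <- setdiff(c("A", "C", "G", "T"),
                                        substr(sq, gs + 3, gs + 3))[1]
  genome_bad[[1]] <- Biostrings::DNAString(sq)
  expect_error(simulateReads(cfg, toy$catalog, genome_bad, stages = "ED0"),
               "mismatch")
})

test_that("simulated read lengths peak at 22 nt with a 28-nt decoy peak", {
  toy <- makeToyAnnotation(8, seed = 4)
  cfg <- simConfig(readsPerLibrary = 8000, seed = 12)
  rr <- simulateReads(cfg, toy$catalog, toy$genome, stages = "NFE")
  ld <- lengthDistribution(rr$reads[["NFE_rep1"]])
  expect_true(22 %in% ld$peaks)
  expect_true(28 %in% ld$peaks)
})

test_that("synthetic catalog reproduces the repertoire bookkeeping", {
  ctl <- simulateCatalog(seed = 1)
  s <- catalogSummary(ctl)
  expect_equal(s$n_genes, 166)
  expect_equal(s$genes_conserved, 88)
  expect_equal(s$genes_previous, 11)
  expect_equal(s$genes_novel, 67)
  expect_equal(s$n_distinct_mature_seqs, 157)
  expect_equal(s$n_clusters, 10)
  # duplicated matures: distinct sequences < gene count among novel genes
  nov <- catalogGenes(ctl)$gene_id[catalogGenes(ctl)$provenance == "novel"]
  seqs <- as.character(matureSequences(ctl, "mature")[paste0(nov, "-5p")])
  expect_lt(length(unique(seqs)), length(nov))
})
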