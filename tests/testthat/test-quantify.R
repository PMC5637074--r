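# tiny hand-built catalog: one plus-strand gene whose mature is followed
# by a chosen downstream genomic context (for templated-extension cases)
miniCatalog <- function(downstream = "AAG") {
  mature <- "TGAGGTAGTAGGTTGTATAGTT"          # 22 nt
  prec <- paste0("CCACC", mature, downstream, "CCTTGAGG")
  genome_seq <- paste0(strrep("T", 50), prec, strrep("G", 50))
  genome <- Biostrings::DNAStringSet(genome_seq)
  names(genome) <- "scf1"
  gs <- 51L
  genes <- GenomicRanges::GRanges("scf1",
    IRanges::IRanges(gs, gs + nchar(prec) - 1L), strand = "+",
    gene_id = "mini-1", provenance = "novel")
  ms <- gs + 5L
  matures <- GenomicRanges::GRanges("scf1",
    IRanges::IRanges(ms, ms + 21L), strand = "+",
    mature_id = "mini-1-5p", gene_id = "mini-1", arm = "5p",
    role = "mature")
  ctl <- new("MirnaCatalog", genes = genes, matures = matures,
             matureSeq = Biostrings::RNAStringSet(
               c("mini-1-5p" = gsub("T", "U", mature))),
             precursorSeq = Biostrings::RNAStringSet(
               c("mini-1" = gsub("T", "U", prec))))
  list(catalog = ctl, genome = genome, mature = mature)
}

test_that("sizeSelect keeps the inclusive 16-29 nt window", {
  reads <- Biostrings::DNAStringSet(vapply(c(15, 16, 29, 30), function(n)
    strrep("A", n), ""))
  names(reads) <- paste0("r", 1:4)
  kept <- sizeSelect(reads)
  expect_equal(sort(Biostrings::width(kept)), c(16, 29))
  expect_equal(length(sizeSelect(Biostrings::DNAStringSet())), 0)
  # multiset identity against a direct comprehension
  set.seed(1)
  lens <- sample(10:35, 200, replace = TRUE)
  rd <- vapply(lens, function(n) randomRna(n), "")
  expect_equal(sort(nchar(sizeSelect(rd, 18, 26))),
               sort(lens[lens >= 18 & lens <= 26]))
})

test_that("classifyTail is total and matches an exhaustive rule oracle", {
  expect_equal(classifyTail("", "GG"), "unmodified")
  expect_equal(classifyTail("AA", "AAG"), "templated_extension")
  expect_equal(classifyTail("AU", "GG"), "other")

  nt <- c("A", "C", "G", "U")
  tails <- c("", nt, as.vector(outer(nt, nt, paste0)))
  downs <- c("AA", "AU", "GC", "UU", "CG", "GA")
  oracle <- function(tl, dn) {
    if (tl == "") return("unmodified")
    if (tl == substr(dn, 1, nchar(tl))) return("templated_extension")
    if (all(strsplit(tl, "")[[1]] == "A")) return("adenylation")
    if (all(strsplit(tl, "")[[1]] == "U")) return("uridylation")
    "other"
  }
  for (dn in downs) {
    got <- classifyTail(tails, dn)
    want <- vapply(tails, oracle, "", dn = dn)
    expect_equal(got, unname(want))
    # totality: exactly one class per pair
    expect_true(all(got %in% c("unmodified", "templated_extension",
                               "adenylation", "uridylation", "other")))
  }
})

test_that("assignReads anchors reads and records residual tails", {
  mc <- miniCatalog(downstream = "GTG")
  r <- assignReads(stats::setNames(mc$mature, "exact"),
                   mc$catalog, mc$genome)
  expect_equal(nrow(r$assignments), 1)
  expect_equal(r$assignments$tail, "")
  expect_equal(r$assignments$tail_class, "unmodified")

  # nontemplated AA over downstream G... is recorded as a tail
  r2 <- assignReads(stats::setNames(paste0(mc$mature, "AA"), "tailed"),
                    mc$catalog, mc$genome)
  expect_equal(r2$assignments$tail, "AA")
  expect_equal(r2$assignments$tail_class, "adenylation")

  # a templated extension is absorbed into the prefix but remembered
  mt <- miniCatalog(downstream = "AAG")
  r3 <- assignReads(stats::setNames(paste0(mt$mature, "AA"), "templ"),
                    mt$catalog, mt$genome)
  expect_equal(r3$assignments$tail, "")
  expect_equal(r3$assignments$templated_overhang, 2L)

  # 5' shifts within 2 nt are tolerated, larger are not
  shifted <- substr(mc$mature, 3, 22)
  r4 <- assignReads(stats::setNames(shifted, "s2"), mc$catalog, mc$genome)
  expect_equal(r4$assignments$shift, 2L)
  # reads from elsewhere stay unassigned
  r5 <- assignReads(stats::setNames(randomRna(22), "noise"),
                    mc$catalog, mc$genome)
  expect_equal(nrow(r5$assignments), 0)
  expect_equal(r5$unassigned, "noise")
})

test_that("assignment recovers simulated reads against the truth table", {
  toy <- makeToyAnnotation(8, seed = 6)
  cfg <- simConfig(readsPerLibrary = 4000, seed = 8)
  rr <- simulateReads(cfg, toy$catalog, toy$genome, stages = "ED1")
  lib <- "ED1_rep1"
  asn <- assignReads(rr$reads[[lib]], toy$catalog, toy$genome)
  tr <- truthReads(rr$truth)
  tr <- tr[tr$library == lib & !is.na(tr$gene_id), ]
  hit <- match(tr$read_id, asn$assignments$read_id)
  expect_gte(mean(!is.na(hit)), 0.99)
  ok <- !is.na(hit)
  expect_gte(mean(asn$assignments$gene_id[hit[ok]] == tr$gene_id[ok]), 0.99)
  # per-read fractional weights sum to one
  w <- tapply(asn$assignments$weight, asn$assignments$read_id, sum)
  expect_true(all(abs(w - 1) < 1e-12))
  # recovered tails match the planted ones
  both <- merge(as.data.frame(tr), asn$assignments, by = "read_id")
  expect_gte(mean(both$tail.x == both$tail.y), 0.99)
})

test_that("tailmodProfile recovers planted rates and composition", {
  toy <- makeToyAnnotation(8, seed = 16)
  cfg <- simConfig(readsPerLibrary = 12000, seed = 17)
  rr <- simulateReads(cfg, toy$catalog, toy$genome, stages = c("ED0", "N5"))
  asn <- lapply(rr$reads, function(r)
    assignReads(sizeSelect(r), toy$catalog, toy$genome)$assignments)
  prof <- as.data.frame(tailTable(tailmodProfile(asn)))
  ed0 <- prof[prof$library == "ED0_rep1", ]
  expect_lt(abs(ed0$frequency - 0.20), 0.02)
  expect_lt(abs(ed0$frac_A - 0.50), 0.04)
  expect_lt(abs(ed0$frac_U - 0.25), 0.04)
  # the early-embryo peak ordering survives quantification
  n5 <- prof[prof$library == "N5_rep1", ]
  expect_lt(abs(n5$frequency - 0.09), 0.02)
  expect_gt(ed0$frequency, n5$frequency)

  # all-unmodified assignments -> frequency exactly 0
  unmod <- data.frame(read_id = "r1", mature_id = "m", gene_id = "g",
                      weight = 1, shift = 0L, templated_len = 22L,
                      templated_overhang = 0L, tail = "",
                      downstream = "GC", tail_class = "unmodified")
  expect_equal(tailTable(tailmodProfile(unmod))$frequency, 0)

  # templated extensions count as modified only behind the flag
  templ <- transform(unmod, templated_overhang = 2L,
                     tail_class = "templated_extension")
  expect_equal(tailTable(tailmodProfile(templ))$frequency, 0)
  expect_equal(tailTable(tailmodProfile(templ,
    countTemplatedExtensions = TRUE))$frequency, 1)
})

test_that("CPM normalization conserves column sums and scale invariance", {
  set.seed(3)
  m <- matrix(rpois(80, 50), 20, 4,
              dimnames = list(paste0("g", 1:20), paste0("L", 1:4)))
  cpm <- cpmNormalize(m)
  expect_equal(unname(colSums(cpm)), rep(1e6, 4))
  expect_equal(cpmNormalize(m * 2)[, 2], cpm[, 2])
  expect_equal(cpm, sweep(m, 2, colSums(m), "/") * 1e6, tolerance = 1e-9)

  single <- matrix(c(0, 7, 0), 3, 1,
                   dimnames = list(c("a", "b", "c"), "L1"))
  expect_equal(unname(cpmNormalize(single)["b", 1]), 1e6)
  zero <- matrix(0, 2, 1, dimnames = list(NULL, "empty_lib"))
  expect_error(cpmNormalize(zero), "empty_lib")
})

test_that("familyExpression sums member CPM and respects partitions", {
  set.seed(4)
  cpm <- cpmNormalize(matrix(rpois(60, 100), 15, 4,
                             dimnames = list(paste0("g", 1:15),
                                             paste0("L", 1:4))))
  singles <- S4Vectors::DataFrame(
    family_id = rownames(cpm),
    members = IRanges::CharacterList(as.list(rownames(cpm))))
  expect_equal(unname(familyExpression(cpm, singles)),
               unname(cpm[singles$family_id, ]))

  all_in_one <- S4Vectors::DataFrame(
    family_id = "F", members = IRanges::CharacterList(list(rownames(cpm))))
  expect_equal(unname(familyExpression(cpm, all_in_one)[1, ]),
               rep(1e6, 4))

  # random partition against a group-sum oracle
  grp <- sample(rep(1:4, length.out = 15))
  fams <- S4Vectors::DataFrame(
    family_id = paste0("F", 1:4),
    members = IRanges::CharacterList(split(rownames(cpm), grp)))
  fe <- familyExpression(cpm, fams)
  expect_equal(unname(fe), unname(rowsum(cpm, grp)), tolerance = 1e-12)

  bad <- S4Vectors::DataFrame(family_id = "F",
                              members = IRanges::CharacterList(list("nope")))
  expect_error(familyExpression(cpm, bad), "absent")
})

test_that("length histograms count every in-bounds read with peaks", {
  reads <- c(strrep("A", 20), strrep("C", 20), strrep("G", 20))
  ld <- lengthDistribution(reads)
  expect_equal(ld$peaks, 20)
  expect_equal(sum(ld$histogram), 3)
  set.seed(5)
  lens <- sample(16:29, 500, replace = TRUE)
  ld2 <- lengthDistribution(vapply(lens, function(n) strrep("A", n), ""))
  expect_equal(unname(ld2$histogram),
               as.integer(table(factor(lens, 16:29))))
})

test_that("FASTQ libraries round-trip through Biostrings", {
  toy <- makeToyAnnotation(3, seed = 1)
  rr <- simulateReads(simConfig(readsPerLibrary = 200), toy$catalog,
                      toy$genome, stages = "ED6")
  dir <- tempfile()
  writeFastqLibraries(rr$reads, dir)
  back <- readFastqReads(file.path(dir, "ED6_rep2.fastq"))
  expect_equal(as.character(back), as.character(rr$reads[["ED6_rep2"]]),
               ignore_attr = TRUE)
  expect_equal(length(back), 200)
})
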