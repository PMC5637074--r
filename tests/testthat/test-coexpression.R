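test_that("stageMeans averages replicates per stage", {
  cpm <- matrix(c(10, 30, 5, 7), 1, 4,
                dimnames = list("g1", c("NFE_rep1", "NFE_rep2",
                                        "ED0_rep1", "ED0_rep2")))
  des <- data.frame(library = colnames(cpm),
                    stage = rep(c("NFE", "ED0"), each = 2))
  sm <- stageMeans(cpm, des)
  expect_equal(unname(sm["g1", ]), c(20, 6))

  set.seed(6)
  big <- matrix(rpois(22 * 10, 100), 10, 22,
                dimnames = list(paste0("g", 1:10),
                                paste0(rep(bgStages(), each = 2),
                                       "_rep", 1:2)))
  desb <- data.frame(library = colnames(big),
                     stage = rep(bgStages(), each = 2))
  smb <- stageMeans(big, desb)
  for (s in bgStages())
    expect_equal(unname(smb[, s]),
                 unname(rowMeans(big[, desb$stage == s])))
  expect_error(stageMeans(big, desb[-(1:2), ], stageOrder = bgStages()),
               "NFE")
})

test_that("spearmanMatrix is tie-corrected and handles constant profiles", {
  x <- 1:11
  expect_equal(spearmanMatrix(rbind(a = x, b = 2 * x))["a", "b"], 1)
  expect_equal(spearmanMatrix(rbind(a = x, b = rev(x)))["a", "b"], -1)
  set.seed(12)
  for (rep in 1:20) {
    m <- rbind(a = sample(0:4, 11, replace = TRUE),
               b = sample(0:4, 11, replace = TRUE))
    if (length(unique(m["a", ])) == 1 || length(unique(m["b", ])) == 1) next
    expect_equal(spearmanMatrix(m)["a", "b"],
                 spearmanOracle(m["a", ], m["b", ]), tolerance = 1e-12)
  }
  # invariance under strictly monotone transforms
  m <- rbind(a = rpois(11, 50) + runif(11), b = rpois(11, 50) + runif(11))
  expect_equal(spearmanMatrix(m)["a", "b"],
               spearmanMatrix(rbind(a = log(m["a", ]), b = m["b", ]^3))["a", "b"])
  expect_warning(rr <- spearmanMatrix(rbind(a = rep(2, 11), b = x)),
                 "constant")
  expect_equal(rr["a", "b"], 0)
  expect_equal(diag(rr), c(a = 1, b = 1))
})

test_that("network edges require rho strictly above the threshold", {
  rho <- matrix(c(1, 0.9, 0.95,
                  0.9, 1, 0.2,
                  0.95, 0.2, 1), 3, 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  g <- buildNetwork(rho, 0.9)
  el <- igraph::as_edgelist(g)
  expect_equal(nrow(el), 1)          # rho exactly 0.9 makes no edge
  expect_setequal(as.vector(el), c("a", "c"))
  expect_equal(igraph::E(g)$rho, 0.95)

  set.seed(18)
  n <- 12
  r <- matrix(runif(n * n, -1, 1), n, n)
  r <- (r + t(r)) / 2; diag(r) <- 1
  dimnames(r) <- list(paste0("g", 1:n), paste0("g", 1:n))
  gg <- buildNetwork(r, 0.3)
  want <- which(r > 0.3 & upper.tri(r), arr.ind = TRUE)
  expect_equal(igraph::ecount(gg), nrow(want))
})

test_that("modules are size-ordered components above the minimum size", {
  rho <- diag(12)
  dimnames(rho) <- list(paste0("g", 1:12), paste0("g", 1:12))
  rho[1:5, 1:5] <- 0.95; rho[6:10, 6:10] <- 0.95; diag(rho) <- 1
  g <- buildNetwork(rho, 0.9)
  mods <- findModules(g)
  expect_equal(length(unique(mods$module)), 2)
  expect_equal(as.vector(table(mods$module)), c(5, 5))
  expect_equal(nrow(findModules(buildNetwork(diag(5) + 0, 0.9))), 0)
})

test_that("splitLargest re-thresholds the largest module", {
  # two sub-blocks correlated 0.91 across, > 0.925 within
  rho <- matrix(0.1, 8, 8)
  rho[1:3, 1:3] <- 0.96
  rho[4:6, 4:6] <- 0.96
  rho[1:3, 4:6] <- 0.91; rho[4:6, 1:3] <- 0.91
  rho[7:8, 7:8] <- 0.99
  diag(rho) <- 1
  dimnames(rho) <- list(paste0("g", 1:8), paste0("g", 1:8))
  net <- buildNetwork(rho, 0.9)
  mods <- findModules(net, minSize = 2)
  expect_equal(length(unique(mods$module)), 2)
  subs <- splitLargest(net, rho, 0.925, minSize = 2)
  expect_equal(length(unique(subs$submodule)), 2)
  expect_true(all(subs$gene_id %in% mods$gene_id[mods$module == "M1"]))

  # an internally homogeneous module stays whole
  rho2 <- matrix(0.95, 4, 4); diag(rho2) <- 1
  dimnames(rho2) <- list(letters[1:4], letters[1:4])
  net2 <- buildNetwork(rho2, 0.9)
  subs2 <- splitLargest(net2, rho2, 0.925)
  expect_equal(length(unique(subs2$submodule)), 1)
  expect_setequal(subs2$gene_id, letters[1:4])
  expect_error(splitLargest(buildNetwork(diag(3) + 0, 0.9), diag(3)),
               "no modules")
})

test_that("metagene matches SVD oracle, orientation and rank-1 exactness", {
  v <- c(0.1, 1, 0.7, 0.4, 0.15, 0.05, 0.02, 0.01, 0.05, 0.1, 0.2)
  mod <- outer(c(2, 5, 9), v)
  colnames(mod) <- bgStages()
  mg <- metagene(mod, standardize = FALSE)
  expect_equal(unname(mg), v / sqrt(sum(v^2)), tolerance = 1e-12)

  set.seed(23)
  m <- matrix(rexp(5 * 11), 5, 11, dimnames = list(NULL, bgStages()))
  mg2 <- metagene(m)
  expect_equal(sqrt(sum(mg2^2)), 1, tolerance = 1e-12)
  z <- t(scale(t(m)))
  vor <- svd(z)$v[, 1]
  expect_gte(abs(sum(mg2 * vor)), 0.9999)
  # orientation: positive correlation with the mean member profile
  expect_gt(stats::cor(mg2, colMeans(m)), 0)
  # invariant to member order (orientation handles the sign)
  expect_equal(metagene(m[sample(5), ]), mg2)
  expect_error(metagene(matrix(3, 4, 11)), "degenerate")
})

test_that("the four planted waves are recovered end to end", {
  sim <- defaultSim()
  cpm <- cpmNormalize(counts(sim$experiment))
  coex <- coexpressionAnalysis(cpm, designOf(sim$experiment))
  mods <- moduleMembers(coex)
  expect_equal(length(unique(mods$module)), 4)

  gi <- truthGenes(sim$truth)
  truth_label <- ifelse(gi$wave %in% c("A1", "A2"), "A", gi$wave)
  truth_label[truth_label == "background"] <- "none"
  found <- stats::setNames(rep("none", nrow(gi)), gi$gene_id)
  found[mods$gene_id] <- mods$module
  expect_gte(ari(truth_label, found[gi$gene_id]), 0.9)

  # wave-B module metagene peaks at the ED2 spike
  prof <- stageMeans(cpm, designOf(sim$experiment))
  bmod <- names(which.max(table(found[gi$gene_id[gi$wave == "B"]])))
  mgB <- metagenes(coex)[bmod, ]
  expect_equal(names(which.max(mgB)), "ED2")
})

test_that("expression CV follows the sample-sd convention", {
  expect_equal(unname(expressionCV(matrix(7, 1, 11))), 0)
  prof <- matrix(c(rep(0, 10), 5), 1, 11, dimnames = list("g", NULL))
  expect_equal(unname(expressionCV(prof)), sqrt(11), tolerance = 1e-12)
  set.seed(25)
  m <- matrix(rexp(44), 4, 11, dimnames = list(paste0("g", 1:4), NULL))
  expect_equal(unname(expressionCV(m)),
               unname(apply(m, 1, sd) / rowMeans(m)), tolerance = 1e-12)
  m[1, ] <- 0
  expect_warning(cv <- expressionCV(m), "zero-mean")
  expect_equal(length(cv), 3)
})

test_that("Welch's t-test matches the closed-form computation", {
  x <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6)
  y <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2)
  w <- welchTest(x, y)
  sx <- var(x) / length(x); sy <- var(y) / length(y)
  t_hand <- (mean(x) - mean(y)) / sqrt(sx + sy)
  df_hand <- (sx + sy)^2 /
    (sx^2 / (length(x) - 1) + sy^2 / (length(y) - 1))
  expect_equal(w$t, t_hand, tolerance = 1e-10)
  expect_equal(w$df, df_hand, tolerance = 1e-10)
  expect_equal(w$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-10)

  z <- c(1.2, 3.4, 2.2, 4.1)
  same <- welchTest(z, z)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(welchTest(1, z), "at least 2")
})

test_that("lineage-specific genes show higher expression variation", {
  sim <- defaultSim()
  cpm <- cpmNormalize(counts(sim$experiment))
  prof <- stageMeans(cpm, designOf(sim$experiment))
  cv <- expressionCV(prof)
  gi <- truthGenes(sim$truth)
  novel <- cv[gi$gene_id[gi$provenance == "novel"]]
  conserved <- cv[gi$gene_id[gi$provenance == "conserved"]]
  expect_gt(mean(novel, na.rm = TRUE), mean(conserved, na.rm = TRUE))
  w <- welchTest(novel[!is.na(novel)], conserved[!is.na(conserved)])
  expect_lt(w$p, 0.01)
})
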