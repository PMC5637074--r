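defaultRunConfig <- function() {
  list(
    seed = 20171011,
    annotation = list(nPrecursors = 12, nClusters = 2, gapKb = 8),
    simulation = list(dispersion = 0.05, libSizeMean = 1e6,
                      readsPerLibrary = 5000,
                      readStages = c("NFE", "ED0", "ED1", "N1")),
    quantify = list(minLen = 16, maxLen = 29,
                    countTemplatedExtensions = FALSE),
    diffexp = list(pseudocount = 0.5),
    network = list(threshold = 0.9, subThreshold = 0.925, minSize = 3),
    comparative = list(enabled = TRUE, nSharedFamilies = 20))
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults, rejects unknown keys and range-violating values, and
#' returns the effective configuration with deterministically ordered
#' keys. Normalization is idempotent:
#' \code{validateConfig(validateConfig(x))} equals
#' \code{validateConfig(x)}.
#'
#' @param config named list (possibly nested, possibly empty).
#' @return the normalized configuration list.
#' @export
#' @examples
#' cfg <- validateConfig(list(network = list(threshold = 0.85)))
#' cfg$network$threshold
validateConfig <- function(config = list()) {
  if (!is.list(config)) stop("config must be a list")
  def <- defaultRunConfig()
  errs <- character()
  unknown_top <- setdiff(names(config), names(def))
  if (length(unknown_top))
    errs <- c(errs, paste("unknown key(s):",
                          paste(unknown_top, collapse = ", ")))
  out <- def
  for (k in intersect(names(config), names(def))) {
    if (is.list(def[[k]])) {
      if (!is.list(config[[k]])) {
        errs <- c(errs, sprintf("'%s' must be a list", k))
        next
      }
      bad <- setdiff(names(config[[k]]), names(def[[k]]))
      if (length(bad))
        errs <- c(errs, sprintf("unknown key(s) under '%s': %s", k,
                                paste(bad, collapse = ", ")))
      for (k2 in intersect(names(config[[k]]), names(def[[k]])))
        out[[k]][[k2]] <- config[[k]][[k2]]
    } else {
      out[[k]] <- config[[k]]
    }
  }
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(is.numeric(out$seed) && length(out$seed) == 1 && out$seed >= 0 &&
        out$seed == round(out$seed), "seed must be a non-negative integer")
  for (th in c("threshold", "subThreshold"))
    chk(is.numeric(out$network[[th]]) && out$network[[th]] > 0 &&
          out$network[[th]] < 1,
        sprintf("network.%s must lie in (0, 1)", th))
  chk(out$network$minSize >= 1, "network.minSize must be >= 1")
  chk(out$quantify$minLen <= out$quantify$maxLen,
      "quantify.minLen must not exceed maxLen")
  chk(out$annotation$nPrecursors >= 1, "annotation.nPrecursors must be >= 1")
  chk(out$annotation$nClusters >= 0, "annotation.nClusters must be >= 0")
  chk(length(out$simulation$readStages) >= 1 &&
        all(out$simulation$readStages %in% bgStages()),
      "simulation.readStages must be a non-empty subset of bgStages()")
  chk(out$simulation$dispersion >= 0, "simulation.dispersion must be >= 0")
  if (length(errs)) stop(paste(errs, collapse = "\n"))
  # deterministic key order
  out <- out[names(def)]
  for (k in names(out)) if (is.list(out[[k]])) out[[k]] <- out[[k]][names(def[[k]])]
  out
}

writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline on synthetic data
#'
#' Orchestrates the stages in dependency order: toy annotation and
#' genome, read simulation and quantification (size selection,
#' assignment, tail-modification profile, length histogram) for the
#' configured stages, count-level simulation with CPM normalization,
#' differential expression over all adjacent transitions, coexpression
#' modules with metagenes, and the cross-species family comparison.
#' Every output is a plain-text table under \code{outdir}, and a
#' \code{manifest.json} records parameters, package version and the md5
#' checksum of every output so reruns with the same configuration can
#' be verified byte-identical.
#'
#' If a stage fails, previously written outputs are kept, a
#' \code{failed/<stage>} marker is created and the error names the
#' failing stage.
#'
#' @param config a [validateConfig()]-acceptable list.
#' @param outdir run directory (created; must not already contain a
#'   manifest).
#' @return invisibly, the manifest as a list.
#' @export
runPipeline <- function(config = list(), outdir) {
  cfg <- validateConfig(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "run.log")
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), paste0(...))
    cat(line, "\n", file = logfile, append = TRUE, sep = "")
    message(line)
  }
  current_stage <- "setup"
  run_stage <- function(name, expr) {
    current_stage <<- name
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    logmsg(sprintf("stage %-12s done in %.1fs", name,
                   proc.time()[["elapsed"]] - t0))
    res
  }
  tryCatch({
    jsonlite::write_json(cfg, file.path(outdir, "config.json"),
                         auto_unbox = TRUE, digits = NA)

    toy <- run_stage("annotation", {
      toy <- makeToyAnnotation(cfg$annotation$nPrecursors,
                               cfg$annotation$nClusters,
                               cfg$annotation$gapKb, seed = cfg$seed)
      Biostrings::writeXStringSet(toy$genome,
                                  file.path(outdir, "genome.fa"))
      writeCatalogGff3(toy$catalog, file.path(outdir, "annotation.gff3"))
      writeCatalogJson(toy$catalog, file.path(outdir, "catalog.json"))
      cl <- findClusters(toy$catalog)
      writeTsv(data.frame(cluster_id = cl$cluster_id,
                          scaffold = cl$scaffold, n_genes = cl$n_genes,
                          span_bp = cl$span_bp,
                          members = vapply(as.list(cl$members), paste, "",
                                           collapse = ",")),
               file.path(outdir, "clusters.tsv"))
      toy
    })

    sc <- simConfig(seed = cfg$seed,
                    dispersion = cfg$simulation$dispersion,
                    libSizeMean = cfg$simulation$libSizeMean,
                    readsPerLibrary = cfg$simulation$readsPerLibrary)

    asn <- run_stage("reads", {
      rr <- simulateReads(sc, toy$catalog, toy$genome,
                          stages = cfg$simulation$readStages)
      writeFastqLibraries(rr$reads, file.path(outdir, "fastq"))
      sel <- lapply(rr$reads, sizeSelect, minLen = cfg$quantify$minLen,
                    maxLen = cfg$quantify$maxLen)
      hist_rows <- do.call(rbind, lapply(names(sel), function(lib) {
        h <- lengthDistribution(sel[[lib]], cfg$quantify$minLen,
                                cfg$quantify$maxLen)$histogram
        data.frame(library = lib, length = as.integer(names(h)),
                   reads = h, row.names = NULL)
      }))
      writeTsv(hist_rows, file.path(outdir, "length_hist.tsv"))
      lapply(sel, assignReads, catalog = toy$catalog, genome = toy$genome)
    })

    run_stage("tailmod", {
      asn_tabs <- lapply(asn, `[[`, "assignments")
      stage_map <- stats::setNames(sub("_rep[12]$", "", names(asn_tabs)),
                                   names(asn_tabs))
      prof <- tailmodProfile(asn_tabs,
                             countTemplatedExtensions =
                               cfg$quantify$countTemplatedExtensions,
                             stage = stage_map)
      writeTsv(as.data.frame(tailTable(prof)),
               file.path(outdir, "tail_profile.tsv"))
      rc <- countsFromAssignments(asn_tabs,
                                  geneIds = catalogGenes(toy$catalog)$gene_id)
      writeTsv(data.frame(gene_id = rownames(rc), rc,
                          check.names = FALSE),
               file.path(outdir, "read_counts.tsv"))
    })

    sim <- run_stage("counts", {
      sim <- simulateCounts(sc)
      cnt <- counts(sim$experiment)
      writeTsv(data.frame(gene_id = rownames(cnt), cnt,
                          check.names = FALSE),
               file.path(outdir, "counts.tsv"))
      cpm <- cpmNormalize(cnt)
      writeTsv(data.frame(gene_id = rownames(cpm), cpm,
                          check.names = FALSE),
               file.path(outdir, "cpm.tsv"))
      sim
    })

    run_stage("diffexp", {
      res <- diffexpAllTransitions(sim$experiment,
                                   pseudocount = cfg$diffexp$pseudocount)
      for (tr in names(res))
        writeTsv(res[[tr]], file.path(outdir,
                 paste0("de_", gsub("->", "_to_", tr, fixed = TRUE), ".tsv")))
      writeTsv(transitionSummary(res),
               file.path(outdir, "de_summary.tsv"))
    })

    coex <- run_stage("network", {
      cpm <- cpmNormalize(counts(sim$experiment))
      coex <- coexpressionAnalysis(cpm, designOf(sim$experiment),
                                   threshold = cfg$network$threshold,
                                   subThreshold = cfg$network$subThreshold,
                                   minSize = cfg$network$minSize)
      el <- igraph::as_edgelist(coexNetwork(coex))
      writeTsv(data.frame(gene_a = el[, 1], gene_b = el[, 2],
                          rho = igraph::E(coexNetwork(coex))$rho),
               file.path(outdir, "network_edges.tsv"))
      writeNetworkGraphML(coex, file.path(outdir, "network.graphml"))
      writeTsv(as.data.frame(moduleMembers(coex)),
               file.path(outdir, "modules.tsv"))
      writeTsv(as.data.frame(submoduleMembers(coex)),
               file.path(outdir, "submodules.tsv"))
      mg <- metagenes(coex)
      writeTsv(data.frame(module = rownames(mg), mg, check.names = FALSE),
               file.path(outdir, "metagenes.tsv"))
      prof <- stageMeans(cpm, designOf(sim$experiment))
      cv <- expressionCV(prof)
      writeTsv(data.frame(gene_id = names(cv), cv = cv,
                          provenance = truthGenes(sim$truth)[names(cv),
                                                             "provenance"]),
               file.path(outdir, "cv_report.tsv"))
      coex
    })

    if (cfg$comparative$enabled) run_stage("comparative", {
      tabs <- simulateSpeciesTables(cfg$comparative$nSharedFamilies,
                                    seed = cfg$seed)
      shared <- sharedFamilyTable(tabs)
      writeTsv(data.frame(family = rownames(shared), shared,
                          check.names = FALSE),
               file.path(outdir, "shared_families.tsv"))
      rel <- relativeAbundance(shared)
      hc <- hclusterLibraries(rel)
      writeDendrogramNewick(hc, file.path(outdir, "libraries.nwk"))
      pca <- pcaDrivers(rel)
      writeTsv(data.frame(library = rownames(pca$scores), pca$scores,
                          check.names = FALSE),
               file.path(outdir, "pca_scores.tsv"))
      writeTsv(data.frame(family = rownames(pca$loadings), pca$loadings,
                          check.names = FALSE),
               file.path(outdir, "pca_loadings.tsv"))
      writeLines(pca$drivers, file.path(outdir, "pca_drivers.txt"))
    })

    run_stage("manifest", {
      outs <- setdiff(list.files(outdir, recursive = TRUE),
                      c("manifest.json", "run.log"))
      sums <- tools::md5sum(file.path(outdir, outs))
      manifest <- list(
        package = "mirwaves",
        version = as.character(utils::packageVersion("mirwaves")),
        parameters = cfg,
        modules = length(unique(moduleMembers(coex)$module)),
        outputs = lapply(stats::setNames(seq_along(outs), outs),
                         function(i) unname(sums[i])))
      jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      manifest
    })
  }, error = function(e) {
    dir.create(file.path(outdir, "failed"), showWarnings = FALSE)
    file.create(file.path(outdir, "failed", current_stage))
    stop(sprintf("pipeline stage '%s' failed: %s", current_stage,
                 conditionMessage(e)), call. = FALSE)
  }) -> manifest
  invisible(manifest)
}
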