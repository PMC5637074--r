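#' Developmental stage order of the cockroach small-RNA design
#'
#' The eleven stages profiled in the reference design, in chronological
#' order: a non-fertilized egg (NFE), five embryonic time points (ED0, ED1,
#' ED2, ED6 and ED13; days after oviposition out of an 18-day
#' embryogenesis), four nymphal instars (N1, N3, N5, N6) and the adult
#' female. Every stage-indexed vector in the package follows this order.
#'
#' @return Character vector of the 11 stage labels.
#' @export
#' @examples
#' bgStages()
bgStages <- function() {
  c("NFE", "ED0", "ED1", "ED2", "ED6", "ED13",
    "N1", "N3", "N5", "N6", "Adult")
}

#' Canonical co-expression wave templates
#'
#' Peak-normalized stage-intensity templates for the five expression waves
#' the synthetic generator plants: \code{A1} (predominantly ED0--ED1),
#' \code{A2} (expressed between ED0 and ED6, peaking at ED1), \code{B}
#' (acute spike at ED2), \code{C} (post-embryonic) and \code{maternal}
#' (loaded in the non-fertilized egg, cleared during embryogenesis, and
#' re-expressed in the adult female ovary). Stages at which a wave is off
#' are exact zeros, mirroring the absence of counts for stage-restricted
#' miRNAs.
#'
#' The non-zero values of \code{A1} and \code{A2} share one value multiset
#' with permuted stage ranks, so that genes of different sub-waves
#' correlate (Spearman) between the 0.9 network cut-off and the 0.925
#' submodule cut-off, while genes within a sub-wave correlate above 0.925.
#' Adjacent template values are separated by roughly two-fold steps so
#' that replicate-level counting noise rarely permutes stage ranks.
#'
#' @return Named list of five numeric vectors of length 11 (stage order
#'   \code{bgStages()}), each with maximum 1.
#' @seealso [simulateCounts()]
#' @export
#' @examples
#' sapply(waveTemplates(), max)
waveTemplates <- function() {
  tpl <- list(
    A1       = c(0.13, 1, 0.62, 0.36, 0.05, 0, 0, 0, 0, 0, 0),
    A2       = c(0.05, 0.13, 1, 0.62, 0.36, 0, 0, 0, 0, 0, 0),
    B        = c(0, 0.05, 0.25, 1, 0.45, 0.10, 0, 0, 0, 0, 0),
    C        = c(0, 0, 0, 0, 0.06, 0.13, 0.27, 0.55, 1, 0.80, 0.40),
    maternal = c(1, 0.45, 0.20, 0.08, 0, 0, 0, 0, 0, 0.05, 0.60)
  )
  lapply(tpl, function(v) { names(v) <- bgStages(); v })
}

# Run code with a private RNG stream, restoring the caller's .Random.seed.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
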