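---
title: "Methods: developmental miRNA expression waves"
author: "mirwaves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: developmental miRNA expression waves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirwaves)
```

# The analysis

`mirwaves` implements a stage-resolved small-RNA expression analysis for
hemimetabolan insect development, organized around the 11-stage design
of the German cockroach *Blattella germanica*: a non-fertilized egg
(NFE), five embryonic days (ED0, ED1, ED2, ED6, ED13 of an 18-day
embryogenesis at 29 °C), four nymphal instars (N1, N3, N5, N6) and the
adult female, each profiled in two replicate libraries. The pipeline
covers five analysis layers:

1. **Catalog** — housing the miRNA gene repertoire: precursor hairpins
   with mature/star arms, seed-based family grouping, genomic cluster
   detection, and configurable biogenesis filtering of hairpin
   candidates.
2. **Quantification** — size selection (16–29 nt), exact templated
   assignment of reads to annotated matures, counts-per-million (CPM)
   normalization, family-level expression, read-length histograms, and
   3′-end nontemplated tail (adenylation/uridylation) profiling.
3. **Differential expression** — stage-to-adjacent-stage
   negative-binomial Wald tests with median-of-ratios normalization and
   Benjamini–Hochberg FDR control.
4. **Coexpression** — a Spearman-threshold network whose connected
   components are the expression waves, with SVD metagenes and a
   conserved-versus-novel expression-variation comparison.
5. **Comparative** — cross-species family-level tables, hierarchical
   clustering, PCA with "driver" families, and the percent-of-development
   staging model that aligns embryos across species.

Because the original sequencing libraries are not redistributable at
package scale, every analysis layer is exercised against a first-class
synthetic-data generator whose defaults encode the study conditions.
The generator is tested code, not a fixture: parameter-recovery tests
quantify how faithfully each analysis layer reconstructs what the
generator planted.

# The synthetic-data model

## Expression waves

`simulateCounts()` plants five coexpression waves
(`waveTemplates()`), each a peak-normalized 11-stage intensity
template:

* **A1** — predominantly ED0–ED1 (early zygotic);
* **A2** — ED0–ED6, peaking at ED1–ED2 (mid-embryonic);
* **B** — an acute spike at ED2;
* **C** — post-embryonic (nymphs and adult);
* **maternal** — loaded in the NFE, cleared during embryogenesis, and
  re-expressed in the adult female (maternal loading for the next
  generation).

A gene of wave $w$ with scale $s_g$ has stage mean
$\mu_g(t) = s_g \cdot \mathrm{template}_w(t)$; stage means are rescaled
so each library's expected depth equals `libSizeMean` times a
log-normal per-library size factor (sdlog 0.15), and replicate counts
are negative binomial with dispersion $\alpha$ (default 0.05, typical
of replicate libraries prepared from pooled individuals; $\alpha = 0$
gives Poisson counts). The default gene complement is 157 genes —
25 A1, 30 A2, 22 B, 30 C, 20 maternal and 30 unstructured background
genes — with provenance quotas of 88 conserved, 11 previously known
and 58 novel genes assigned embryo-first, so that novel labels land on
the embryo-restricted waves and conserved labels on the broadly
expressed ones. That assignment reproduces the empirical pattern that
lineage-specific miRNAs are embryo-biased and therefore show a higher
coefficient of variation across development than conserved miRNAs.

Two numerical choices in the templates matter and were made once, by
construction:

* Stages at which a wave is off are **exact zeros**. Stage-restricted
  miRNAs yield no counts outside their window; the resulting shared
  tie-blocks are what make within-wave rank correlations high and
  stable at $n = 11$ stages.
* The non-zero values of A1 and A2 share one value multiset with
  permuted stage ranks, placing the between-subwave Spearman
  correlation at $\approx 0.913$ — between the 0.9 network cut-off and
  the 0.925 submodule cut-off — while within-subwave correlations sit
  near 1. Adjacent template values are separated by roughly two-fold
  steps so replicate noise rarely permutes stage ranks. This is what
  lets the network analysis recover one large early-embryonic module
  that splits into the two planted subwaves, the topology the analysis
  is designed to detect.

## Reads, tails and decoys

`simulateReads()` emits per-library FASTQ-ready reads: miRNA reads
sampled from catalog matures (lengths modally 22 nt via templated 3′
trimming/extension) mixed with random 28-nt piRNA-like decoys at a
per-stage fraction. A per-stage fraction of miRNA reads carries a
nontemplated 3′ tail of 1–3 nt. Default stage rates are 20% at ED0 and
ED1 versus 9% at all other stages (the reported ranges are 15–26% and
7–11%), and tail composition is 50% adenylation, 25% uridylation, 25%
other — the adenylation excess being the degradation signal associated
with maternal miRNA clearance at the maternal-to-zygotic transition.

The generator guarantees that tails mismatch the genome at position
+1: `makeToyAnnotation()` fixes the two bases downstream of every arm
to `GC`, so poly-A and poly-U tails are unambiguously nontemplated,
and tailed reads keep the exact annotated 3′ boundary. Ambiguity
between tailing and templated extension is exercised by dedicated
fixtures instead of the generator. Per-stage piRNA fractions are not
reported quantitatively anywhere we could anchor them, so they are
free parameters; the defaults (45% at ED0 declining to 20%
post-embryonically) encode the observation that the relative amount of
miRNA reads is minimal exactly when tailing peaks.

What the generator does **not** emulate: sequencing errors, adapter
read-through, mismatch-tolerant alignment, isomiR 5′ heterogeneity
beyond the ±2 nt assignment tolerance, and real piRNA biology. Passing
recovery tests therefore demonstrate the correctness of the analysis
logic under the stated statistical model, not robustness to every
artifact of real libraries.

# Analysis choices

## Quantification

Reads are assigned when their longest genome-templated prefix matches
exactly inside a precursor with the 5′ end within ±2 nt of an
annotated mature 5′ end; the nontemplated residual (≤5 nt) is the
candidate tail. Multi-matching reads are split fractionally (1/k to
each of k arms), so per-read weights always sum to 1. A residual that
equals the genomic continuation is a *templated extension* and counts
as unmodified by default — calling it a modification would over-count
tailing whenever the downstream genomic base happens to be an A — but
`tailmodProfile(countTemplatedExtensions = TRUE)` provides the other
reading of "reads surpassing the annotated 3′ boundary".

CPM uses the miRNA-assigned total as denominator, not raw depth:
piRNA-like reads vary strongly by stage and would otherwise distort
stage comparisons. Family expression is the sum of member CPM, so a
full partition conserves each library's $10^6$ total.

## Differential expression

The negative-binomial machinery is implemented explicitly rather than
delegated, as the package's re-implementation contract:
median-of-ratios size factors; method-of-moments dispersion on
normalized counts; a Wald test on the log2 ratio of normalized stage
means with a 0.5 pseudocount, with the NB variance
$\mu + \alpha\mu^2$ propagated to the log2 scale; and step-up BH
adjustment (via `stats::p.adjust`, with the step-up construction
verified against a brute-force oracle in the tests). Significance is
declared at adjusted $q < 0.05$.

The dispersion shrinkage needs one word of justification. With two
replicates per stage the gene-wise moment estimate is extremely noisy,
and genes whose replicates are accidentally concordant get near-zero
dispersion estimates that inflate the Wald false-positive rate: plain
halfway shrinkage toward the across-gene mean left the null
type-I error at ~0.087 in our calibration simulations. The estimator
therefore shrinks halfway from above but floors at the across-gene
mean, $\alpha_g = \max\{(\hat\alpha_g + \bar\alpha)/2,\ \bar\alpha\}$,
which calibrates the null rejection rate at 0.05 (observed 0.036–0.066
over repeated null simulations at $\alpha = 0.1$, 1000 genes, 2 + 2
replicates) while retaining per-gene signal for genuinely
overdispersed genes. This is deliberately simpler than the empirical
Bayes trend machinery of the established packages; those remain the
cross-check, not the implementation.

## Coexpression

Correlations are tie-corrected Spearman over the 11 **stage means**
(replicates averaged), not the 22 libraries: metagenes are drawn over
stages, and averaging suppresses replicate noise at $n = 2$. Edges
require rho **strictly** above the cut-off ("higher than 0.9"), with
no absolute value — anti-correlated genes are not coexpressed. Modules
are connected components with at least 3 members (the study reports
only four large modules; dyads are noise), ordered by size; the
largest is re-thresholded at 0.925 to resolve submodules. Genes with
constant profiles get rho 0 against everything, with a warning, rather
than propagating NaN.

The metagene is the first right singular vector of the member × stage
matrix after per-gene z-scoring (shape, not magnitude; a raw-CPM
decomposition is available via `standardize = FALSE`), oriented to
correlate positively with the mean member profile and scaled to unit
norm. The CV comparison uses the sample (n − 1) standard deviation
over stage means and Welch's unequal-variance t-test.

## Catalog

The seed is the 7-mer at mature positions 2–8, the dominant convention;
families are exact-seed partitions named after their lexicographically
smallest member. Genomic clusters are single-linkage chains of
precursor starts within 10 kb (configurable), strand-agnostic —
chaining is what lets clusters span tens of kb while the pairwise gap
stays below the threshold. Duplex overhangs are computed from arm
coordinates after fixing the pairing register by maximal
complementarity (Watson–Crick plus G:U wobble); no secondary-structure
prediction is attempted. The biogenesis filter's thresholds (≥10
mature reads, star support required, 2 ± 1 nt 3′ overhangs, ≥0.9 5′
homogeneity) are explicit configuration: the original prediction
filters delegate their exact values to prior work, so the package
states its defaults rather than claiming fidelity to unpublished
cut-offs.

Coordinates are 1-based closed genomic intervals (`GRanges`)
throughout — the native convention of both Bioconductor and GFF3 —
rather than converting through a 0-based internal representation.

## Comparative layer

The staging model converts hours after oviposition to percent of total
embryogenesis (432 h default). Note one bookkeeping subtlety: 48 h of
432 is 11% at integer precision, which is what the model reports for
ED2. Abundance tables are intersected to families present in every
species, converted to per-library proportions, and transformed as
$\log_{10}(p \cdot 10^6 + 1)$ before clustering and PCA — proportions
are heavy-tailed and the comparison should weigh presence patterns,
not single dominant families. Clustering uses average linkage on
1 − Pearson distance (both flags); "driver" families are
operationalized as the largest-|loading| families on PC1 then PC2,
with signs fixed so the first library scores non-negatively.

# Reproducibility and problem sizes

Every stochastic operation takes an explicit seed (default 20171011)
and restores the caller's RNG state; identical configurations produce
byte-identical outputs, which `runPipeline()` verifies by recording
md5 checksums of every written table in its manifest. The test-suite
problem sizes — 157 genes × 22 libraries for recovery tests, 2,000–
12,000 reads per library for read-level tests, 500–1,000 genes for
statistical calibration, 100,000 reads for tail-rate recovery — were
chosen so each contract is tested at the precision it claims (e.g.
binomial error ±0.02 needs ~10^5 reads) while the whole suite stays
fast on one CPU.

# Known limitations

* Assignment is exact-match on templated prefixes; it is intended for
  the package's toy genomes and clean simulated reads, not for
  error-containing reads against large genomes (use a dedicated
  aligner upstream in that setting).
* The DE model has no covariates and no likelihood-ratio alternative;
  with two replicates its guarantees are statistical (calibration
  bands), not exact.
* Module recovery guarantees hold under the generator's correlation
  structure; real data with intermediate correlation topologies can
  produce chained components that no threshold separates cleanly.
* Family orthology across species is input metadata; no homology
  inference is performed.
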