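---
title: "Testing acoustic traits for phylogenetic signal: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing acoustic traits for phylogenetic signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(callphylo)
```

## The question and the model

Vocalizations of non-vocal-learning taxa are presumed largely genetically
determined, so acoustic similarity between species should track
phylogenetic relatedness. `callphylo` operationalizes that question as a
pipeline: extract low-level acoustic descriptors from recordings, remove
the allometric effect of body size, and test the residuals for
phylogenetic signal under several statistics and relatedness models, so
that a conclusion does not hinge on any single methodological choice.

The evolutionary reference model throughout is Brownian motion (BM): trait
variance accumulates linearly along branches, which induces the tip
covariance matrix `C` with `C[i,j]` equal to the branch length from the
root to the most recent common ancestor of tips i and j. `C` enters three
times: as the error covariance of the PGLS size-correction, as the
relatedness model of Blomberg's K, and (through its lambda-diluted form)
as the generator of synthetic traits.

## Acoustic descriptors

Recordings are analyzed at their native sampling rate in frames of 40 ms
with a 20 ms hop (frame counts follow `floor((n - win)/hop) + 1`); the
window length also sets the FFT size, so the bin width is `rate/win` (25 Hz
at 44.1 kHz). Choices the short-time analysis needs that a verbal
definition of the descriptors does not fix:

* **Window function.** A Hann window precedes each FFT (the common default
  in music-information-retrieval toolchains). RMS is computed on the raw,
  unwindowed frame.
* **Silence.** All frames enter CVA — envelope variation is exactly the
  measurand. Frames with RMS below 1e-6 are excluded from DF, SI and TON,
  whose definitions (argmax, peak structure, flatness) are meaningless on
  silence; SF uses all consecutive pairs.
* **SI partials.** Partials are spectral peaks: local maxima within 40 dB
  of the frame maximum. The sum of squared differences between adjoining
  partials (with an implicit trailing zero) is normalized by the summed
  squared partial amplitudes, making SI gain-invariant: a lone partial
  scores 1, an equal comb of many partials tends to 0. The raw,
  unnormalized sum is available via `normalized = FALSE`.
* **TON floor.** Power bins are floored at 1e-12 times the frame maximum
  before the geometric mean, so flatness is defined on frames with exact
  spectral zeros.
* **Gain.** CVA, DF, TON and normalized SI are invariant to a global gain;
  SF is the one deliberately gain-sensitive descriptor (it scales
  linearly), which matters if recordings are not level-normalized.

Species values average each descriptor over the species' one or two
recordings on the linear scale; DF, SF, SI, TON and snout-vent length are
then log10-transformed (CVA, already a ratio, is not). Averaging before
the log keeps the species value an unbiased mean of recording-level
measurements; because all downstream statistics are location-scale
invariant, the base of the logarithm is irrelevant (asserted to 1e-10 in
the tests).

## Size correction

Each trait is regressed on log SVL by generalized least squares with error
covariance `C` (lambda fixed at 1, pure BM — no lambda estimation), and
the **ordinary-scale** residuals `y - X beta` are carried forward, the
construction standard for phylogenetic size-correction; whitened residuals
`L^-1 (y - X beta)` are available for sensitivity analysis via
`residuals(fit, type = "whitened")`. `C` is inverted through its Cholesky
factor and failure is surfaced as an error rather than silently
pseudo-inverted. Per-clade analyses refit the regression on the
clade-pruned tree (clades under 3 species are skipped with a warning), and
residuals are standardized to mean 0, sd 1 **within each analysis group**
before multivariate distances, so every trait gets equal weight at the
scale the group actually spans.

## Signal statistics and inference

* **Moran's I** uses centered residuals and a zero-diagonal nonnegative
  weight matrix; its null expectation is `-1/(n-1)` and the reported
  standard deviate uses the randomization (permutation-moment) variance,
  not the normality variance. Pairwise genetic distances become weights by
  reciprocal distance with row standardization (`inverse_squared` and
  `rank` schemes are available); zero distances are replaced by half the
  smallest positive distance before inversion. Abouheif proximities are
  used directly as weights with their diagonal dropped.
* **Geary's C** has null expectation 1 with positive autocorrelation
  pushing C below 1, so its Monte-Carlo p-value is lower-tailed.
* **Blomberg's K** is the observed MSE0/MSE ratio about the phylogenetic
  mean, scaled by its BM expectation `(tr(C) - n/(1'C^-1 1))/(n-1)`; on a
  star phylogeny the ratio equals its expectation for *any* trait vector,
  so K = 1 identically (a sharp correctness check used in the tests).
* **Mantel r** is the Pearson correlation of strict lower triangles;
  permutations relabel taxa (simultaneous row/column shuffles). Because r
  is invariant to positive affine maps of matrix entries, Abouheif
  proximities enter the Mantel as `max_offdiag(A) - A`, which only flips
  the correlation sign relative to using proximities directly.

All Monte-Carlo p-values use the add-one convention
`p = (1 + #extreme)/(1 + n_perm)` with 10,000 permutations by default, and
count permutation values within `1e-9 * (1 + |stat|)` of the observed
statistic as extreme: tree symmetries (e.g. swapping the tips of a cherry)
produce exactly tied permutation statistics, and the tolerance keeps the
tie-counting conservative rather than at the mercy of floating-point
summation order. Sidedness: upper tail for Moran, K and Mantel, lower for
Geary. Every result records its seed and permutation count.

## Stepwise multivariate selection

The forward search starts from the single trait with the highest Mantel r
(an empty start is a degenerate special case of no information; the best
single trait is the natural anchor when the comparison rule needs an
incumbent). At each step the candidate giving the largest enlarged-model r
is compared against a bootstrap sample of the incumbent's coefficient:
`ceiling(0.9 n)` taxa drawn **without replacement** (with-replacement
draws would create zero self-distances that corrupt a distance matrix),
10,000 iterations, acceptance when the challenger exceeds 95% of the
sample. Bootstrap seeds derive deterministically from the master seed,
the step index and the candidate's position in the caller's list, so the
selection is reproducible and independent of candidate ordering. Ties in
r break lexicographically by the caller's candidate order. The search is
run on the whole sample only; clades then evaluate the whole-sample-
selected subset (small clades would overfit a per-clade search).

## The synthetic-data generator

The generator emulates the statistical shape of a comparative bioacoustic
study — about 90 species in four clades, one or two recordings per
species — with known ground truth:

* **Trees**: forward Yule simulation conditioned on the tip count; while k
  lineages exist the next split waits an Exp(k * birth) time, so the
  expected root height is `sum_{k=2}^{n} 1/(k * birth)` (checked against
  this closed form). Clade labels come from cutting the ultrametric tree
  into its basal subtrees.
* **Traits**: multivariate-normal tips with covariance
  `sigma2 * C(lambda)`, where lambda multiplies the off-diagonal of `C` —
  chosen over additive white noise because it maps directly onto the
  covariance used by K and PGLS; lambda = 1 is pure BM, 0 is
  phylogeny-free noise. Dominant frequency is allometric
  (`logDF = 4.8 - 1.0 logSVL + e`, the inverse size-frequency relation at
  realistic anuran scales: root SVL 50 mm, about 1.25 kHz); the other four
  traits carry signal without size dependence. The signal dial applies to
  log SVL as well: a fully signal-free null study should contain *no*
  phylogenetically structured character, otherwise the size-correction
  step (whose covariance model no longer matches any data) injects
  covariate structure into every residual and the null is not a null.
* **Sequences**: Jukes-Cantor evolution site by site, root uniform,
  substitution probability `(3/4)(1 - exp(-4d/3))` per branch; the study
  tree is rescaled to a root height of 0.25 substitutions/site, a
  plausible mitochondrial-marker depth, before sequence simulation.
* **Audio**: a harmonic stack with per-harmonic rolloff, sinusoidal
  amplitude modulation and additive white noise. Ground truth travels with
  each recording: expected DF = f0 and expected CVA = depth/sqrt(2). The
  envelope-variation identity holds when the analysis window is short
  relative to the modulation period; the bundled fixtures use 2 Hz
  modulation so the 40 ms window attenuates the envelope by about 1%.
  The generator does not attempt realistic anuran call synthesis
  (no pulse trains, formants, or frequency modulation).

All generators are seed-deterministic. Problem sizes used in the test
suite — 500 replicates for the Brownian K calibration, 2,000 for type-I
rates at 50 tips, 200 for slope recovery at 64 tips and for the null end
of the 90-tip study contrast, 25 for its power end, 10 seeded replicates
per stepwise scenario — were chosen to keep Monte-Carlo error a small
fraction of each assertion's tolerance band.

## What the synthetic tests do and do not show

Passing on synthetic data demonstrates that the estimators, their null
distributions and the pipeline's plumbing are correct under the generating
model. Real recordings differ in ways the generator deliberately omits:
background noise and other callers, within-species call variation sampled
by only one or two recordings, non-Brownian trait evolution, and trees
estimated with error. The statistics' robustness to those violations is a
property of the methods, not something these tests certify.

## Known limitations

* **Signal tests on regression residuals are not exact.** PGLS residuals
  are a projection of the data; permuting them treats them as exchangeable,
  which they are not. The distortion is negligible when the BM covariance
  is approximately right, but in a fully phylogeny-free world the GLS
  slope is estimated with very large error (two orders of magnitude above
  OLS variance on 90-tip Yule trees in our measurements), and the
  projection systematically deflates residual variance on short-branch
  (cherry) tips. Upper-tail Blomberg's K reads that deflation as positive
  signal: in our 90-tip null simulations K rejected at roughly 0.10-0.13
  at a nominal 0.05, while Moran's I on Abouheif proximities stayed near
  nominal, and K on raw (unregressed) traits is exact. Conclusions that
  rest on a marginal K significance after size-correction should be
  checked against the Moran and Mantel results.
* Branch lengths are taken as given; lambda is fixed at 1 in the PGLS and
  no rate heterogeneity or OU alternatives are fitted.
* MEGA-style composite-likelihood distances are not implemented; the
  pipeline accepts any externally computed distance matrix in their place
  (`genetic_distance` argument of `run_analysis()`).
* No multiple-testing correction is applied across the results table, by
  design; the stars encode raw permutation p-values (p < 0.05, 0.01,
  0.001).

## A minimal end-to-end run

```{r example, eval = FALSE}
study <- simulate_study(n_species = 30, n_clades = 2, seq_length = 300,
                        audio = TRUE, seed = 42)
dir <- tempfile(); write_study(study, dir)

md <- read.delim(file.path(dir, "metadata.tsv"))
recs <- lapply(seq_len(nrow(md)), function(i)
  read_wav(md$wav_paths[i], species_id = md$species_id[i]))
traits <- species_trait_table(recs, md)

out <- run_analysis(traits,
                    tree = read_tree(file.path(dir, "tree.nwk")),
                    alignment = read_fasta(file.path(dir, "alignment.fasta")),
                    n_perm = 999, n_boot = 1000, seed = 1)
head(out$results)
out$stepwise$abouheif
```
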