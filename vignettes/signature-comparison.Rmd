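---
title: "Comparing microglial population signatures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing microglial population signatures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microsig)
```

This vignette is the package's account of its science: the models it fits,
the conventions and tunable parameters behind each module, what the
synthetic-data generators do and do not emulate, and the design choices made
where more than one defensible option existed.

## The signature-comparison model

A population signature is a vector of gene-level expression summaries on a
shared panel. We use log2 fold change versus each study's own control as the
attribute, because fold changes are comparable across platforms (microarray
intensities and RNA-seq counts live on different absolute scales) and because
published microglial subtype signatures are themselves reported as
differential expression against a homeostatic baseline. `build_signature()`
projects a differential-expression table onto a gene panel;
`align_gene_panels()` harmonises collections from different studies by
case-insensitive symbol intersection (mouse symbols are capitalised
inconsistently across supplementary tables). Genes absent from any collection
are dropped rather than zero-filled: dropping loses information but never
fabricates agreement, whereas imputed zeros systematically shrink cosines
between otherwise-similar profiles.

Two population-by-population matrices summarise the collection. The distance
matrix has entries

$$d_{i,j} = \sqrt{\textstyle\sum_k (i_k - j_k)^2},$$

and the cross-correlation matrix has entries

$$c_{i,j} = \lvert\cos\theta\rvert
          = \frac{\lvert \mathbf{i}\cdot\mathbf{j}\rvert}
                 {\lVert\mathbf{i}\rVert\,\lVert\mathbf{j}\rVert} \in [0,1],$$

so 0 is total absence of relationship and 1 is equivalence up to scale. The
modulus is part of the statistic's definition here, which means a profile and
its mirror image (coherently opposite regulation) score as maximally similar.
We keep that form as the default because it is the statistic this pipeline is
defined around, and expose `correlation_matrix(sig, signed = TRUE)` as a
sensitivity check; with log2-fold-change signatures, strongly anti-correlated
population pairs are biologically informative and worth noticing before
trusting an unsigned similarity. A population with a zero-magnitude vector
has no direction, so it is an error rather than a silent zero row. For unit
vectors with non-negative cosine the two summaries are linked by
$d^2 = 2(1-\cos\theta)$, a consistency relation the test suite checks.

### Multidimensional scaling

`classical_mds()` implements the Torgerson procedure: double-centre
$-\tfrac12 d^2$, eigendecompose, and take coordinates from the top-$k$
non-negative eigenvalues (negative eigenvalues — non-Euclidean residue —
contribute zero variance rather than imaginary axes). Eigenvectors are
sign-ambiguous, so each axis is oriented to make its largest-magnitude
coordinate positive; this makes embeddings bit-reproducible without
affecting any distance. The goodness-of-fit summary is
$\mathrm{stress} = \sqrt{\sum_{ij}(d_{ij}-\hat d_{ij})^2 / \sum_{ij} d_{ij}^2}$
over reconstructed distances; it is 0 (to 1e-9) exactly when the
configuration is Euclidean-embeddable in $k$ dimensions, which the tests
exercise with planar point sets and the 3-4-5 right triangle. An all-zero
distance matrix embeds as a single point with stress 0 by convention.

### Clustering

`hierarchical_cluster()` uses average linkage on the Euclidean distance
matrix. No linkage is canonical for this problem; average linkage is the
common default for expression profiles and is what the planted-block
recovery property is calibrated against. Labels are sorted lexicographically
before agglomeration so that merge order cannot depend on input order —
`hclust` is deterministic given its input, and sorting makes the input
canonical, which is the tie-break rule. Dendrograms export as Newick via
`ape`.

## Differential expression

`deg_table()` compares test against reference samples per gene and applies
the significance filter q < 0.05 and |signed fold| > 1.5 (both strict, as
thresholds of this form are conventionally printed). The signed fold is
$2^{\mathrm{lfc}}$ for positive log2 fold changes and $-2^{-\mathrm{lfc}}$
for negative ones — the array-software convention under which "fold change
greater than 1.5" reads |fold| > 1.5. Multiple testing uses
Benjamini–Hochberg step-up, the standard choice when only "FDR/q-value" is
specified.

The default test is limma's moderated t. At three samples per condition a
per-gene Welch test has roughly four degrees of freedom, and no threshold
tuning can rescue its power: in our simulations at fold 4 and
$\sigma = 0.25$ log2 units it recovers under half of the planted genes,
while the moderated t — which shrinks per-gene variances toward a common
prior and is the de facto standard for small-n array studies — recovers
essentially all of them at a realised false-discovery proportion near the
nominal 5% and stays calibrated under the null (raw p < 0.05 rate ≈ 0.05).
`welch_t_per_gene()` (and a pooled-variance mode) remains available via
`method =` for designs where its assumptions are preferred, with documented
conventions at zero variance: equal means give p = 1, unequal means the
p = 0 limit, reported via a message.

The ranking metric for enrichment is $\mathrm{sign}(\mathrm{lfc})\cdot
(-\log_{10} p)$ with ties broken by gene name and p = 0 clipped at 300
(beyond double-precision underflow there is no information left to rank on).

## Pre-ranked enrichment

`enrichment_score()` is the weighted running-sum statistic: walking the
ranked list, genes in the set add their $|score|^{w}$ (normalised so hits
total 1; $w = 1$ by default, $w = 0$ gives the analytically checkable
unweighted walk) and genes outside subtract $1/(N - N_\mathrm{hit})$. The
enrichment score is the signed extremum of the walk; a set equal to the
whole universe has an empty complement and scores 0 by convention.

The null in `permutation_nes()` resamples random gene sets of equal size
from the ranked universe — a gene-set (not phenotype) permutation, because
the pipeline operates on a pre-ranked list and phenotype permutation is
near-degenerate at 3 vs 3. The NES divides the observed score by the mean
|null score| of matching sign. The permutation p-value is two-sided on
magnitude, $p = (1 + \#\{|es^\ast| \ge |es|\})/(1 + B)$: a one-sided p
conditioned on the observed sign would reject at double the nominal rate
under the null (both 5% tails qualify), while the magnitude form is
calibrated — the suite verifies an empirical rate of p ≤ 0.05 within
[0.03, 0.08] over 400 null draws — and preserves the floor
$p \ge 1/(B+1)$ attained by strongly planted sets. Fewer than five
same-sign null draws flags the NES as unstable. Since the extrema of the
walk occur only at (or just before) hit positions, null scores are computed
from hit positions alone, making 999 permutations cheap.

## Comparative-Ct qPCR

`ddct_fold_change()` is the standard Livak workflow: technical replicates
are averaged per (gene, animal); $\Delta Ct = Ct_\mathrm{target} -
Ct_\mathrm{reference}$ per animal; $\Delta\Delta Ct$ subtracts the
calibrator-group mean; the reported fold is $2^{-\overline{\Delta\Delta
Ct}}$ over the test group — the fold of group means rather than the mean of
per-animal folds, which keeps the calibrator's geometric-mean fold at
exactly 1. Amplification efficiency is fixed at perfect doubling; no
efficiencies are estimated. Significance is an unpaired two-sided Student
t-test on per-animal $\Delta Ct$ values (not on folds), where the normality
assumption is defensible. Running the pipeline with the target equal to the
reference yields fold 1 and p = 1 exactly, and adding any constant to every
Ct leaves all folds unchanged; both are tested invariants.

## What the generators emulate

`simulate_expression_study()` draws per-gene baselines
$\mathcal N(7, 1.5^2)$ on the log2 scale and adds independent
$\mathcal N(0, \sigma^2)$ noise, with planted genes shifted by
$\log_2(\mathrm{fold})$ in the test condition. The default design is three
samples per condition — each notionally a pool of three biological
replicates, which is why a noise level of $\sigma = 0.25$ log2 units
(typical for averaged variance-stabilised array intensities) is the default;
the true per-animal variance would be larger. Additive Gaussian noise on the
log2 scale keeps every downstream expectation in closed form, which the
zero-noise exactness tests rely on.

`simulate_signature_collection()` realises block correlation by mixing three
exactly orthonormal components (QR-orthogonalised Gaussian vectors): a
shared vector with weight $\sqrt{B}$, a block vector with weight
$\sqrt{W-B}$, and a population vector with weight $\sqrt{1-W}$, giving
noise-free cosines of exactly $W$ within and $B$ between blocks — the
closed form makes a numeric solve for the mixing weights unnecessary.
Gaussian measurement noise of sd 0.1 per gene attenuates cosines by
$\approx 1/(1+0.1^2)$, so the defaults ($W = 0.9$, $B = 0.2$, $n' = 500$)
produce empirical within-block cosines near 0.89 and between-block near
0.20. The demo collection's two blocks (PAM/ATM/CD11c/AQP4_AC/AQP4_CC vs
APP/Aged/DAM1/DAM2/MGnD/LDAM) encode the expected neurodevelopment vs
disease/ageing split.

`simulate_qpcr_plate()` places the reference gene at 10 cycles and targets
at 25 (WT), lowers KO target Cts by $\log_2(\mathrm{fold})$, adds a
per-animal loading shift (sd 0.5 cycles, identical across an animal's
genes — it cancels exactly in $\Delta Ct$, making the normalisation path
load-bearing rather than decorative) and technical noise of 0.3 cycles per
well, in triplicate for six animals per group. All Cts are validated to lie
in (0, 40).

What the generators do **not** emulate: probe-level effects and RMA
preprocessing, batch effects, correlated genes within the expression study
(noise is independent across genes, so the BH calibration results say
nothing about correlation-robustness), count overdispersion of RNA-seq
signatures, and qPCR efficiency differences. Passing tests therefore
demonstrate the pipeline's correctness and calibration under its stated
model, not robustness to every artefact of real data.

## Numerical choices and reproducibility

All comparisons in code and tests use explicit tolerances of 1e-9 or looser;
nothing asserts agreement beyond what double precision supports. Cosines are
clamped to their theoretical range before the diagonal is pinned to 1.
Every stochastic entry point takes an integer seed, derives a per-component
substream (so adding a generator to a workflow cannot perturb another's
output), and restores the caller's RNG state. The pipeline driver writes a
JSON manifest with the package version, a configuration hash, the seed and
MD5 hashes of every output; determinism is asserted by rerunning the shipped
demo configuration and comparing hashes.

Problem sizes used by the validation suite — 1000 random signature sets for
the metric axioms, 100 instances per brute-force oracle comparison, 100
simulated studies each for null calibration and power, 400 null enrichment
runs, 500 qPCR recovery runs, 20 seeds for block recovery — were chosen so
the whole suite completes in well under a minute while leaving Monte-Carlo
margins far from each acceptance band's edges.

## Known limitations

- The unsigned cosine cannot distinguish coherent activation from coherent
  repression; use `signed = TRUE` alongside it.
- Fold-change signatures inherit each source study's control condition; if
  controls differ biologically, cross-study cosines conflate that
  difference with subtype identity. No cross-platform normalisation beyond
  the shared-panel fold-change convention is attempted.
- The moderated-t default assumes roughly exchangeable per-gene variances;
  grossly heteroscedastic spike-ins would favour the Welch mode.
- Gene-set permutation treats genes as exchangeable under the null;
  inter-gene correlation in real data typically inflates enrichment scores
  relative to this null.
- With two groups of three pooled samples, the DE results quantify
  pool-level, not animal-level, variability.
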