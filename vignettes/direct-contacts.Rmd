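---
title: "Predicting direct subunit contacts from CF-MS elution profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting direct subunit contacts from CF-MS elution profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfcontact)
```

## The problem

Co-fractionation / mass spectrometry (CF-MS) separates native protein
complexes along biochemical gradients and quantifies every detectable
protein in every collected fraction, yielding an elution profile per
protein. Correlation between elution profiles identifies which proteins
belong to the same complex, but it cannot tell *directly contacting*
subunits from subunits that merely co-reside: in a chain A–B–C where A
binds B and B binds C, the profiles of A and C correlate through their
shared intermediate even though A and C never touch. `cfcontact`
implements a sparse conditional-dependence approach that removes such
transitive associations: two proteins are predicted to contact when they
remain associated after conditioning on all other observed proteins.

## The model

### Compositional treatment

MS quantitation is relative: each fraction's abundances carry only
proportional information, so each column of the $d \times n$ elution
matrix is treated as a composition. Exact zeros (proteins not identified
in a fraction) receive a pseudocount of 1 **before** closure — adding a
constant to already-normalized proportions would be dimensionally
incoherent — and each fraction is then normalized to sum to 1. Naive
covariances of compositions are biased negative by the unit-sum
constraint, so profiles pass through the centered log-ratio (CLR)
transform,
$$\mathrm{clr}(x)_i = \log \frac{x_i}{g(x)},$$
with $g(x)$ the geometric mean of the fraction, mapping compositions to a
zero-sum hyperplane. In the sparse high-dimensional regime the CLR
covariance $\Gamma$ approximates the covariance of the unobserved
absolute abundances, which is what makes the downstream graphical model
meaningful.

To relax distributional assumptions of the regressions, each protein row
is optionally (and by default) passed through a nonparanormal (Gaussian
copula) transform: ranks are mapped to a Winsorized empirical CDF
(bound $\delta = 1/(4 n^{1/4}\sqrt{\pi \log n})$), Gaussianized with
$\Phi^{-1}$, and rescaled to unit sample variance. Whether the copula
should replace or follow the CLR step is not dictated by theory; the
package applies it to CLR rows by default and exposes
`copula_order = "copula_then_clr"` for the alternative composition.

### Neighborhood selection on the covariance

Direct contacts are modeled as the nonzero off-diagonal entries of the
precision matrix $\Theta = \Sigma^{-1}$. With $d \gg$ the effective
sample size this is estimated by node-wise lasso: for every protein $j$,
$$\hat g_j = \arg\min_{g,\; g_j = 0}\;
  \tfrac{1}{2} g^\top \Gamma g - \Gamma_{\cdot j}^\top g
  + \lambda \lVert g \rVert_1 ,$$
solved by cyclic coordinate descent with soft-thresholding directly on
the Gram matrix $\Gamma$ (compiled code; no design matrix is formed, so
subsampled refits are cheap). The per-node neighborhoods are merged with
the OR rule — an edge is present if either endpoint selected the other —
which asymptotically recovers the support of $\Theta$.

Numerical choices: convergence is declared when the largest coefficient
change in a sweep falls below `tol = 1e-4` (at most `max_iter = 1000`
sweeps, with a warning naming unconverged columns); $\Gamma$'s diagonal
provides the curvature; zero-variance proteins keep zero coefficients;
"nonzero" means exactly nonzero because soft-thresholding produces exact
zeros. The $\lambda$-path holds `K = 30` values, log-spaced from
$\lambda_{\max} = \max_{i \ne j} |\Gamma_{ij}|$ (the smallest value
yielding an empty graph) down to `min_ratio = 0.01` of it; linear spacing
is available. Fits are warm-started along the path, which changes
nothing beyond `tol` but speeds the subsampling loop.

### Stability scoring (StARS)

A single fit at one $\lambda$ is fragile; the package follows the
Stability Approach to Regularization Selection. `N = 20` subsamples of
$b = \lfloor 10\sqrt{n} \rfloor$ fractions are drawn without replacement,
the *entire* compositional pipeline (closure, CLR, copula, covariance) is
recomputed inside each subsample — subsetting a precomputed $\Gamma$
would understate the variability — and the lasso path is refit. The edge
frequency $P_{ij}(\lambda) \in \{0, 1/N, \dots, 1\}$ across subsamples is
the package's *contact probability*. Total graph instability is
$$D(\lambda) = \binom{d}{2}^{-1} \sum_{i<j} 2 P_{ij}(1 - P_{ij})
  \in [0, 0.5],$$
monotonized by a running maximum from the most-regularized end.

Two selection rules are provided. The unsupervised rule picks the
least-regularized $\lambda$ whose monotonized instability stays below
$\beta$, with the conservative default $\beta = 0.005$ (standard StARS
uses 0.1). The semi-supervised rule ranks edges by $P(\lambda)$ for every
$\lambda$, scores them against a structure-derived benchmark, and picks
the $\lambda$ maximizing AUPR, breaking ties toward the sparser
(more conservative) $\lambda$. Edge frequencies are reported at the
selected $\lambda$ only; an alternative would aggregate across the path,
but per-$\lambda$ frequencies are what make individual probabilities
interpretable (e.g. 0.85 = present in 17 of 20 subsamples). Ranked
output breaks probability ties lexicographically by pair id so results
are byte-reproducible.

### Co-complex filtering

Conditional dependence can reflect associations other than physical
contact, so predictions are restricted to pairs that co-occur in at
least one cataloged complex with $\ge 5$ unique subunits
(`min_subunits = 5`, i.e. "larger than 4"). Pairs whose members share
only small complexes, or appear only in *different* complexes, are
dropped.

## The correlation baseline

The comparison method mirrors standard CF-MS practice: profiles are
divided by each protein's number of theoretical tryptic peptides
(cleave after K/R unless followed by P, no missed cleavages, minimum
fragment length 1 — all exposed as arguments since MS-observable length
bounds such as 6–50 aa are a defensible variant), each fraction is
z-scored (sample sd, $d - 1$), and Pearson correlations are computed for
all pairs. Zero-variance profiles get correlation 0 rather than NaN so
rankings stay total.

## Evaluation

The benchmark labels within-complex pairs as contacting when their
buried interface area exceeds 0 Å², complexes with fewer than 5 mapped
subunits are excluded, cross-complex pairs are never emitted, and
subunits without an ortholog mapping are dropped. AUPR is average
precision (step-wise, not trapezoidal), with tied scores handled as
blocks whose members all receive the block-end precision — deterministic
and order-free. Benchmark positives that a predictor never scored count
as false negatives at every cutoff; dropping them would inflate recall.
The random baseline is positives / total pairs.

Crosslink enrichment compares the observed overlap between predictions
and an inter-protein crosslink set against a permutation null: each of
1000 trials draws the same number of distinct random pairs from the
crosslink dataset's protein universe (the matched-count reading of
"random pairs from the crosslinking dataset"; a flagged alternative
would resample proteins instead), and
$z = (\text{observed} - \text{null mean}) / \text{null sd}$.

## The synthetic test bed

Real CF-MS compendia are far beyond desk scale, so validation uses a
generative model with known contact graphs. Per experiment, every
contact of every complex independently dissociates with probability
`p_break`; the connected components of what remains are the eluting
species. Each species receives a Gaussian elution peak (uniform center,
width 1–3 fractions, log-normal intensity), abundances are the sum over
species containing the protein times multiplicative log-normal noise
(`dispersion = 0.25`), values under a detection floor of $10^{-5}$ of
the experiment maximum (a typical MS dynamic range) are zeroed, and a
further 20% of positive measurements drop out to exact 0. Independent
edge removal plus connected components is the essential choice: it
guarantees direct neighbors co-occur in subassemblies more often than
indirect pairs, the precise signal conditional dependence exploits;
random subsets would destroy the direct/indirect distinction.

Two heterogeneity mechanisms reproduce how real compendia behave.
Each complex draws a per-experiment expression probability from
`p_present_range = c(0.15, 0.85)` — compendia pool different cell types
and lysis conditions, so a complex is routinely absent from entire
experiments — and a median abundance from a log-normal with
`complex_scale_sdlog = 2`. Under these settings per-complex observation
depth spans roughly 50–400 nonzero fractions out of 2000, matching the
order-of-magnitude spread reported for real data. These mechanisms are
also what make the marginal-correlation baseline genuinely confounded:
shared presence/absence patterns correlate *every* pair of co-complex
subunits, direct or not, while conditioning removes the shared
component.

The default scenario — 5 chain complexes of 5 subunits, 40 experiments
of 50 fractions — runs the full pipeline in seconds and is the problem
size used throughout the test suite; the Gaussian support-recovery
checks use $d = 4$, $n = 20000$. What passing these tests does *not*
show: robustness to shared peptides, ion suppression, RNA-scaffolded
complexes (a documented failure mode of interface benchmarks), or
between-complex peak collisions, none of which the generator models.

## Worked example

```{r example, eval = FALSE}
truth <- synthetic_truth(seed = 1)
ds <- generate_dataset(truth)
run <- predict_contacts(ds$elution, catalog = truth_catalog(truth),
                        benchmark = ds$benchmark, mode = "aupr", seed = 1)
run
pr <- precision_recall_curve(
  data.frame(protein_a = run$predictions$protein_a,
             protein_b = run$predictions$protein_b,
             score = run$predictions$probability),
  ds$benchmark)
pr
plot(pr)
plot_instability(run)
```

## Known limitations

* Contact probabilities are relative to the chosen $\lambda$; comparing
  probabilities across runs with different selections is not meaningful.
* The copula insertion point (before vs after CLR) is an open modeling
  choice; both are implemented, the default follows the package's own
  validation.
* Proteins absent from an experiment are zero-filled on concatenation;
  dropping them instead is defensible but would change the
  compositional geometry, so the zero-fill matches the
  missing-equals-zero convention used everywhere else.
* The benchmark treats any positive interface area as a contact; very
  small crystallographic interfaces may not be biologically meaningful
  contacts.
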