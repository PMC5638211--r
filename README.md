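# cfcontact

Direct protein–protein contact prediction from co-fractionation / mass
spectrometry (CF-MS) elution profiles.

## What problem this solves

CF-MS experiments separate native protein complexes along biochemical
gradients and quantify every detectable protein in every collected
fraction. Correlating the resulting elution profiles reveals which
proteins share a complex, but not which subunits physically touch: in a
chain A–B–C, the profiles of A and C correlate through B even though A
and C never contact. `cfcontact` is for proteomics and structural
systems-biology researchers who want contact-level resolution out of
co-elution data — constraints for structural modeling of complexes
without solved structures.

The package treats each fraction as compositional data (pseudocount,
closure, centered log-ratio transform, optional nonparanormal copula),
then learns a sparse conditional-dependence graph by neighborhood
selection: for every protein $j$ it solves the covariance-parameterized
lasso

$$\hat g_j = \arg\min_{g,\;g_j=0}\ \tfrac12 g^\top \Gamma g
  - \Gamma_{\cdot j}^\top g + \lambda\lVert g\rVert_1,$$

merges neighborhoods with the OR rule, and scores every edge by its
StARS stability: the frequency $P_{ij}(\lambda)$ with which the edge
appears across $N = 20$ refits on random subsamples of
$\lfloor 10\sqrt{n}\rfloor$ fractions. Those frequencies, at a $\lambda$
chosen either by the instability threshold $\beta = 0.005$ or by
maximizing benchmark AUPR, are reported as contact probabilities,
restricted to pairs co-resident in a known complex with at least five
subunits. The package also ships the standard Pearson co-elution
baseline (tryptic-peptide normalization, fraction-wise z-scores),
precision–recall benchmarking against structure-derived interface
contacts, crosslink-overlap enrichment z-scores, and a synthetic CF-MS
simulator with known contact graphs.

## Worked example

```r
library(cfcontact)

truth <- synthetic_truth(seed = 1)        # 5 chain complexes of 5 subunits
ds    <- generate_dataset(truth)          # 40 experiments x 50 fractions
ds$elution
#> elution_matrix: 25 proteins x 2000 fractions (40 experiment(s))
#> nonzero values: 7044 (14.1%)

run <- predict_contacts(ds$elution, catalog = truth_catalog(truth),
                        benchmark = ds$benchmark, mode = "aupr", seed = 1)
run
#> contact_run: 40 predictions at lambda = 0.4167 (aupr selection)
#> top predictions:
#>   protein_a protein_b probability
#> 1     C2_P1     C2_P2           1
#> 2     C2_P2     C2_P3           1
#> 3     C2_P4     C2_P5           1
#> 4     C3_P2     C3_P3           1
#> 5     C3_P3     C3_P4           1

pr <- precision_recall_curve(
  data.frame(protein_a = run$predictions$protein_a,
             protein_b = run$predictions$protein_b,
             score     = run$predictions$probability),
  ds$benchmark)
pr
#> pr_result: AUPR = 0.9486 (20 positives, 30 negatives, 40 scored; random baseline 0.4000)
```

A probability of 1 means the edge appeared in all 20 subsample refits at
the selected regularization — the strongest possible stability support
for a direct contact. The AUPR of 0.9486 against the generating contact
graph (random baseline 0.40) shows the ranking places true chain edges
above within-complex non-contacts. Overlap with an independent contact
measurement is scored by a permutation z:

```r
xl <- ds$benchmark[ds$benchmark$label, c("protein_a", "protein_b")]
crosslink_overlap_zscore(run$predictions, xl, trials = 1000, seed = 1)
#> enrichment_result: observed overlap 20, null 2.70 +/- 1.51 over 1000 trials -> z = 11.46
```

A command-line front end over the same functions (commands `simulate`,
`predict`, `correlate`, `evaluate`) is installed at
`system.file("cli", "cfcontact.R", package = "cfcontact")`.

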