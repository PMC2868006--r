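# triadKDE

Sequence-only protein–protein interaction (PPI) prediction under class
imbalance: permutation-significance features over conjoint triads, a
relaxed variable kernel density estimator (RVKDE) classifier, and the
dataset-construction and evaluation machinery needed to study predictors
at positive-to-negative ratios from 1:1 to 1:15 and beyond.

## What it computes

**Features.** The 20 amino acids are reduced to 7 physicochemical groups
(1 = {A,G,V}, 2 = {I,L,F,P}, 3 = {Y,M,T,S}, 4 = {H,N,Q,W}, 5 = {R,K},
6 = {D,E}, 7 = {C}); a protein is scanned with an overlapping 3-residue
window, giving counts *o<sub>i</sub>* for the 7³ = 343 grouped triads.
Because raw counts mostly reflect amino-acid composition, each count is
replaced by its *permutation significance*

&nbsp;&nbsp;&nbsp;&nbsp;*s<sub>i</sub>* = Pr(*X<sub>i</sub>* < *o<sub>i</sub>*)
= (1/*n*) #{ *j* : *x<sub>ij</sub>* < *o<sub>i</sub>* },

the probability that a composition-preserving shuffle of the sequence
shows strictly fewer occurrences of triad *i* than observed (one minus the
permutation p-value; *n* = 10,000 shuffles by default).  A protein pair is
the concatenation of its two 343-vectors in lexicographic identifier
order — 686 dimensions instead of the 2·20³ = 16,000 an ungrouped encoding
would need.

**Classifier.** One kernel density estimate per class with per-sample
bandwidths σ<sub>i</sub> = β·(V<sub>m</sub>(R(s<sub>i</sub>))/ks)<sup>1/m</sup>,
where R(s<sub>i</sub>) is the distance to the ks-th nearest other training
sample and V<sub>m</sub> the m-ball volume (computed in log space).  A
query pair **v** is assigned to the class maximising
|S<sub>j</sub>|<sup>α</sup>·f̂<sub>j</sub>(**v**), with the density sum
truncated to the query's *kt* nearest training samples; ties go to the
non-interacting class.

**Evaluation.** Precision, sensitivity, specificity, accuracy and
F-measure = 2TP/(2TP+FP+FN); trivial baselines (random, all-negative,
all-positive); precision–sensitivity curves with grouped ties; mean ± sd
aggregation over repeated dataset draws.  Ratio-controlled datasets draw
|neg| = r·|pos| negatives uniformly from the n(n+1)/2 − m non-interaction
pairs, pairwise disjoint across ratios and repetitions.

A synthetic generator (`syntheticConfig()`, `generateProteome()`,
`generateNetwork()`) produces proteomes with natural group composition and
networks whose interactions concentrate on proteins orderly enriched in a
motif triad set — signal the significance encoding can see but plain
composition cannot — so the whole pipeline is testable without external
interaction databases.

## Worked example

```r
library(triadKDE)

## significance encoding of one sequence: which triads occur more often
## than its own composition predicts?
s <- significanceVector("MKVLAAGLLALLAVSQA", nPermutations = 10000, seed = 1)
round(s[s > 0.5], 3)
#>   113   122   134   211   212   221   341   351   512
#> 0.621 0.940 0.943 0.750 0.517 0.942 0.943 0.939 0.860

## end-to-end imbalance sweep on synthetic data: 300 proteins, 400
## interactions, fully motif-determined network, ratios 1:1 .. 1:15
cfg <- syntheticConfig(seed = 1)
report <- ratioBenchmark(cfg, seed = 1)

round(metricByRatio(report, "f_measure", "rvkde"), 3)
#>     1     3     7    15
#> 0.786 0.585 0.453 0.328

round(metricByRatio(report, "accuracy", "opportunistic_neg"), 3)
#>     1     3     7    15
#> 0.500 0.750 0.875 0.938
```

The two trends are the point: the model's F-measure degrades as the
negative class grows (the problem genuinely hardens), while the
all-negative baseline's *accuracy* climbs to 15/16 = 93.8% without
predicting a single interaction — which is why F-measure, not accuracy, is
the objective under imbalance.

A command-line wrapper covering the same pipeline
(`simulate`, `build-data`, `encode`, `train`, `predict`, `evaluate`,
`benchmark`) is installed at `system.file("cli", "triadkde", package =
"triadKDE")`.

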