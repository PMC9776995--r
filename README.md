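# rcccpred

Sequence-based three-class prediction of renal clear cell carcinoma (RCCC)
driver genes from DNA mutations.

## What it does, and for whom

Given reference gene sequences (FASTA) and a catalog of single-nucleotide
substitutions (CSV: gene, 1-based position, reference base, alternate base,
class label), the package builds a labeled benchmark of *mutated*
sequences, summarizes each sequence as a six-value moment feature vector,
trains a three-class classifier — RCCC driver vs. other tumor driver vs.
unknown/non-driver — and evaluates it under four protocols. It is aimed at
computational biologists who want a self-contained, reproducible pipeline
from a mutation catalog to validated classification metrics, with a
synthetic-data generator so everything is testable offline.

## The method in brief

Each sequence (A=1, C=2, G=3, T=4, other=0) fills a square matrix
$\beta_{xy}$ of side $n = \lceil\sqrt L\rceil$, row-major, zero-padded.
Layer 1 computes three moment families up to combined order 3
(10 values each):

- raw: $R_{ab} = \sum_{x,y} x^a y^b \beta_{xy}$
- central: $C_{ab} = \sum_{x,y}(x-\bar e)^a (y-\bar d)^b \beta_{xy}$,
  centroid $(\bar e,\bar d) = (R_{10}/R_{00}, R_{01}/R_{00})$
- Hahn: $H_{ab} = \sum_{x,y}\hat h_a(x)\hat h_b(y)\beta_{xy}$ with
  orthonormal discrete Hahn polynomials $\hat h_q$ ($\alpha=\beta=0$)

Layer 2 pools the 30 values $v$ into the feature vector
$[M_1, M_2, M_3, M_4, \mathrm{Min}, \mathrm{Max}]$, where $M_1$ is the
mean and $M_p = \frac1m\sum_j (v_j - \bar v)^p$ for $p = 2,3,4$.

The final classifier is histogram gradient boosting; plain gradient
boosting, random forest, decision tree, Gaussian naive Bayes, and a
feed-forward neural net (max 3000 iterations, early stopping) form the
comparison suite. Evaluation maps the three classes one-vs-rest and
reports specificity, sensitivity, accuracy, and MCC per class and macro,
plus ROC/AUC, under self-consistency, stratified 10-fold CV, jackknife
(leave-one-out), and a stratified 70:30 independent split.

## Worked example

```r
library(rcccpred)

ds    <- gen_separable_dataset(n_per_class = 100, delta = 0.9,
                               length_range = c(900, 900), seed = 1)
feats <- extract_feature_table(ds)
round(extract_features(ds$sequence[1]), 3)
#>           M1           M2           M3           M4          Min          Max
#> 8.818540e+05 4.796948e+12 2.448454e+19 1.554963e+26 -1.534007e+04 7.682170e+06

sc <- self_consistency(feats, train_config("hist_gradient_boosting", seed = 1))
report_summary(sc)
#>                 class Specificity Sensitivity Accuracy MCC
#> 1 kidney_tumor_driver           1           1        1   1
#> 2  other_tumor_driver           1           1        1   1
#> 3             unknown           1           1        1   1
#> 4               macro           1           1        1   1

cv <- kfold_cv(feats, k = 10, config = train_config(seed = 1), seed = 1)
report_summary(cv)
#>                 class Specificity Sensitivity  Accuracy       MCC
#> 1 kidney_tumor_driver       1.000        0.99 0.9966667 0.9925093
#> 2  other_tumor_driver       0.995        0.99 0.9933333 0.9850000
#> 3             unknown       0.990        0.99 0.9900000 0.9775835
#> 4               macro       0.995        0.99 0.9900000 0.9850309
```

The first table is the self-consistency (training-set) check on a strongly
separated synthetic dataset: the final model memorizes it perfectly, all
four metrics 1.00. The second is genuine out-of-fold performance under
10-fold CV — macro accuracy 0.99 here, with per-class one-vs-rest metrics
in the columns. On real catalog-derived data these numbers measure the
pipeline; on synthetic data they confirm the machinery (see the methods
vignette for what a green synthetic run does and does not establish).

## Command line

```sh
rccc-pred synth --mode dataset --n 100 --delta 0.9 --seed 1 --out-dir fixtures/
rccc-pred build-dataset --references ref.fasta --catalog catalog.csv \
          --threshold 0.7 --out samples.fasta --labels labels.csv
rccc-pred extract-features --sequences samples.fasta --labels labels.csv \
          --out features.csv
rccc-pred train --features features.csv --algorithm hist_gradient_boosting \
          --seed 1 --out model.bin
rccc-pred predict --model model.bin --features features.csv --out pred.csv
rccc-pred evaluate --features features.csv --protocol cv --k 10 --seed 1 \
          --out report.json
```

`rccc-pred` is the installed `inst/bin/rccc-pred` wrapper (equivalently:
`Rscript -e 'rcccpred::parse_and_dispatch(commandArgs(TRUE))' ...`).
Exit codes: 0 success, 1 contract/format error, 2 usage error.

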