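# swtcnn

Prognostic risk stratification of tumor gene-expression profiles with a
stationary wavelet transform, a one-convolutional-layer classifier, and a Cox
proportional-hazards gene signature.

## What it does, and for whom

Given an FPKM-like expression matrix (genes × samples) and a clinical table
(overall-survival days, vital status, tumor stage), the package predicts a
binary prognostic endpoint — advanced stage, or death within three years —
**without filtering genes beforehand**, and then works backwards from the
trained network to score every gene's importance and build a compact survival
signature. It is aimed at computational-biology users who want the full
protocol (repeated random splits, wavelet selection, top-*n* tuning,
KM/log-rank reporting) reproducible on their own cohorts, plus a synthetic
cohort generator so every stage is testable without any data download.

The pipeline, in the field's usual notation:

1. Each sample's profile (length *p*) is decomposed by the **stationary
   (undecimated) wavelet transform**; the approximation bands cA₁…cA₃ form a
   *p* × 3 input. Twelve wavelet functions are supported (db1–sym6).
2. A CNN with one convolutional layer (64 filters, kernel 8, relu), one
   max-pooling layer (window 8, ceiling padding: 26,270 positions → 3,284
   features), a 32-unit dense layer and a 2-unit softmax is trained with
   RMSprop on binary cross-entropy.
3. The post-pooling activations, averaged over filter channels, give the
   representative feature matrix **X** (features × samples). Gene scores are
   the row means of **B = Y·Xᵀ(X·Xᵀ)⁻¹** (pseudoinverse when X·Xᵀ is
   singular), with **Y** the genes × samples expression matrix.
4. The top-*n* genes (n tuned over 100…1000) pass univariate then
   multivariate Cox selection (Wald p < 0.05, Efron ties, ridge fallback);
   the signature's linear predictor **risk score = Σ βᵢxᵢ**, thresholded at a
   training-set Youden-J ROC cutoff, assigns high/low risk groups compared by
   Kaplan–Meier curves and the log-rank test.

SVM (RBF, grid-searched), random-forest and logistic-regression baselines
behind the classical t-test + fold-change filter are included for protocol
parity.

## Worked example

```r
library(swtcnn)

sim <- simulate_cohort(sim_config(n_samples = 300, n_genes = 1000,
                                  n_prognostic = 20, beta = 2, seed = 42))
cfg <- pipeline_config(wavelet = "db3", cnn = cnn_config(epochs = 25),
                       top_n = "auto", seed = 42)
res <- run_pipeline(sim$expression, sim$clinical, cfg)
res
#> SWT-CNN risk-stratification pipeline (endpoint survival3y)
#>   wavelet db3, top-n 900 -> 26 signature gene(s) [standard]
#>   validation AUC: SWT-CNN 0.5, risk score 0.643
#>   log-rank chisq 7.37 (p = 0.00662)
```

Reading the output: from a simulated 300-patient cohort with 20 planted
prognostic genes, the tuner kept the top 900 scored genes, the Cox stage
retained a 26-gene signature (7 of them truly planted), and on the held-out
30% the risk score reaches AUC 0.643 for the 3-year endpoint while the
all-gene classifier sits at chance; the risk groups' survival curves separate
at log-rank p ≈ 0.007. The gene-score table and per-patient risk table are in
`res$scores` and `res$risk_table`:

```r
head(res$scores, 3)
#>   gene_id     score rank
#> 1  g00930 0.6320210    1
#> 2  g00283 0.1788649    2
#> 3  g00899 0.1693524    3
```

Lower-level entry points mirror each stage: `decompose_cohort()`,
`swt_cnn()` / `train_cnn()`, `extract_representative_features()`,
`score_matrix()` / `gene_scores()`, `univariate_cox()` /
`multivariate_cox()`, `risk_score()`, `choose_cutoff_roc()`, `stratify()`,
`km_logrank()`, `auc()`, `run_benchmark()`. A thin command-line front end
(`inst/cli/swtcnn.R`) exposes `simulate` and `pipeline` subcommands.

The methods vignette (`vignettes/swtcnn-methods.Rmd`) documents the model,
the numerical conventions, the simulator's assumptions, and — measured on the
package's own runs — which claims reproduce on synthetic cohorts and which do
not (the least-squares gene ranking is magnitude-dominated; the Cox stage
supplies the prognostic power).

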