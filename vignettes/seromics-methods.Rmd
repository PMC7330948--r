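---
title: "Methods: autoantibody seromics screening and committee ANN classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: autoantibody seromics screening and committee ANN classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seromics)
```

## Scope and model

`seromics` implements a three-phase serum autoantibody (AAb) biomarker
pipeline for hepatocellular carcinoma (HCC) detection: protein-array signal
quantification, two-stage marker screening, consensus predictor selection by
cross-validated stepwise logistic regression, and a committee-vote
feedforward neural network evaluated against and in combination with serum
alpha-fetoprotein (AFP). Because no serum cohort of this kind is publicly
deposited, the package ships a synthetic seromics cohort generator as
first-class, tested code; every downstream stage runs identically on real
spot tables in the same simplified tab-delimited dialect.

## Signal quantification

The quantitative readout of a spot is its signal-to-noise ratio,

$$\mathrm{SNR} = \frac{\text{median foreground intensity}}
                      {\text{median background intensity}},$$

and a protein's value on one array is the arithmetic mean over its duplicate
spots. The mean is a deliberate choice: duplicate spots on these arrays are
printed adjacently and agree closely (squared correlation near 0.99 in
practice), so any symmetric combiner gives nearly the same answer; the mean
is unbiased under the log-normal spot noise model and keeps the combiner
linear.

Cross-array normalization defaults to quantile normalization within a phase
and channel (delegated to `limma::normalizeQuantiles`), with per-sample
median scaling and no normalization available through the same interface for
sensitivity analysis. Quantile normalization maps every array onto the
cross-array mean quantile profile, so an array and any positively rescaled
copy of it receive identical normalized values, and within-array rank order
is preserved. Which span the original study normalized over (array, phase,
cohort) is not recoverable from its description; this package normalizes
within phase and records the choice in the signal matrix's provenance
sidecar rather than claiming fidelity on that point.

Screening and modeling read the IgG channel by default. Arrays are scanned
in two channels (IgG and IgM), and the generator simulates both, but IgG is
the conventional seromics readout and the focused-array analysis this
package mirrors reports a single signal per protein; IgM is retained in all
I/O for users who want it.

## Marker screening

Two filters mirror the study phases:

* **Discovery filter** (HCC vs healthy): Welch t-test `p <= 0.05`, linear
  fold change of group means `>= 1.2`, and positive ratio `>= 10%`. A case
  is seropositive for a protein when its signal strictly exceeds the healthy
  mean plus twice the healthy sample SD; the positive ratio is the fraction
  of seropositive cases. Zero-variance controls degrade the threshold to the
  control mean, with a warning rather than a failure.
* **Test-phase filter** (run separately for HCC vs healthy and HCC vs
  cirrhotic): `p < 0.05` (strict), fold change `>= 1.2`, and sensitivity
  `> 15%` (strict) at specificity `>= 90%`. The sensitivity criterion scans
  candidate thresholds at the observed values and takes the smallest
  threshold whose specificity reaches the floor. Each protein is labeled by
  the comparisons it passes (`healthy_only`, `cirrhotic_only`, `both`).

The discovery filter uses a non-strict p-value bound and the test-phase
filter a strict one; both are implemented exactly as stated in the source
criteria, without harmonizing them. Welch's unequal-variance t-test is used
because nothing justifies assuming equal group variances; fold change is the
ratio of arithmetic group means on the normalized linear SNR scale; and the
positive-ratio denominator is the number of HCC samples. No multiple-testing
correction enters either filter's pass decision — the screens are
intentionally permissive funnels ahead of supervised selection — but a
Benjamini–Hochberg column is reported for information.

## Consensus panel selection

Predictor selection runs stepwise logistic regression inside stratified
10-fold cross-validation. For each fold, the test-phase criteria are
re-applied to the ~90% training portion (HCC vs pooled controls by default,
matching the classifier's target; the two-comparison variant is a switch),
and the surviving candidates enter a bidirectional stepwise search from the
intercept-only model. Markers selected in **every** fold form the consensus
panel, which is refit as a single logistic model on the full phase.

The stepwise score is BIC by default, with AIC one argument away. BIC is the
choice consistent with the selection behaviour this module promises and
tests: on pure-noise candidates the procedure should usually return the
intercept-only model, and with one informative marker among nine noise
columns it should rarely admit more than two extras. AIC's entry threshold
(chi-squared exceeding 2, about a 16% null entry rate per candidate) cannot
deliver either property; BIC's `log(n)` penalty does, and parsimony is the
point of a 55-to-7 reduction.

Numerical details: candidate columns are standardized to training mean/SD
(parameters stored for reuse) and processed in ascending protein-ID order,
which makes the search deterministic; a duplicated column can never enter
twice because it adds no deviance. Final coefficients are refit by
iteratively reweighted least squares with an L2 penalty of `1e-8 * n` on the
slopes — far below any statistical consequence, but it keeps coefficients
finite under perfect separation, which strong markers do produce.

Fold construction deals each class cyclically over the folds starting from
the least-filled one, so total fold sizes differ by at most one (576 samples
give six folds of 58 and four of 57 — exact equality is impossible) and
per-fold class composition matches the cohort to within one sample.
Whether the original analysis stratified its folds is unstated; stratified
is the default here because it protects small classes, and it is a flag.

## Committee neural network

The hidden-layer width follows the sizing rule

$$N_h = \frac{4n^2 + 3}{n^2 - 8},$$

rounded half-up, where $n$ is the number of input predictors; at $n = 7$
this gives $199/41 \approx 4.85 \to 5$, i.e. the 7-5-2 architecture. The
rule is only defined for $n \ge 3$ and the package refuses smaller inputs
(the pipeline falls back to an explicit width when a selected panel is
narrower).

Each member network is a fully connected one-hidden-layer perceptron:
logistic-sigmoid hidden units and a two-node softmax output whose HCC node
probability is "the output" of the member. The two-node output with scalar
0/1 votes is reconciled exactly this way: control node vs HCC node under
softmax, vote = HCC-node probability. Training is full-batch gradient
backpropagation on cross-entropy (learning rate 0.05, at most 500 epochs by
default). For each of 50 repeats, an independent stratified 10-fold plan is
drawn; each fold's ~10% portion serves as verification set for early
stopping only (patience 20 epochs, best-verification weights restored,
never any weight update from it), while the remaining ~90% trains the
network — 500 members in all. None of the activation, epoch, learning-rate
or early-stopping settings are fixed by the source description; all are
explicit, documented defaults in `network_spec()`.

The committee vote is the arithmetic mean of all member outputs, classified
as HCC when strictly above 0.5 (ties to control). Out-of-fold votes —
each sample predicted only by the networks whose verification fold held
it — are recorded for unbiased in-phase evaluation. Blind prediction
applies the frozen committee, including the training phase's
standardization, to a disjoint cohort; shared sample IDs abort the call.
Whether the original committee was trained against pooled controls or
healthy controls only is not fully explicit; pooled controls is the default
(it is the headline comparison) and the labels are caller-supplied.

Committees serialize to JSON at full floating-point precision (architecture,
weights, standardization, fold/repeat provenance, seeds), so a restored
model reproduces blind votes.

## Evaluation

AUC is computed by the Mann–Whitney pair-counting definition (ties count
half) via the rank formula. AFP is called positive strictly above 400 ng/mL,
and a case is AFP-negative strictly below 20 ng/mL; both tie rules are
documented and tested. The AFP+ANN combination is not defined in the source
material; here it is a two-variable logistic combiner over
`(log1p(AFP), vote)` fitted on training-phase data and applied frozen to
validation (an OR-of-positives rule would be the obvious alternative and is
easy to evaluate from the same reports). `stratified_report()` reproduces
the tables' shape: case strata (all, AFP-negative, HBsAg+/-, BCLC 0/A, B,
C) crossed with detectors (AFP, ANN, AFP+ANN) and control sets
(healthy+cirrhotic, healthy, cirrhotic); strata restrict cases only, and
empty strata keep their rows with NA metrics. The operating thresholds
behind the originally printed specificities are unknowable from the text;
this package reports the vote threshold's operating point alongside the
full ROC coordinates rather than guessing.

## Synthetic cohort generator

The generator emulates the statistical structure the analysis assumes,
starting at spot medians (no image simulation):

* **Background** medians are Gamma(4, scale 150): strictly positive and
  right-skewed like scanner backgrounds.
* **Latent log-SNR** for protein *p* in sample *i* is
  `baseline_p + effect + noise`, with protein baselines N(0, 0.3²),
  biological noise N(0, 0.5²), and duplicate-spot technical noise N(0,
  0.05²) on the log scale; foreground = background × SNR. Log-normal SNR
  matches the positivity and skew of real arrays.
* **Informative proteins** (`n_informative` of `n_proteins`) receive a mean
  log-SNR shift of `effect_size` in HCC and `effect_size * cirrhosis_leak`
  in cirrhotic samples, on the IgG channel only (see the channel note
  above). The default leak of 0.25 reflects that cirrhosis shares part of
  the HCC autoantibody response, which is why HCC-vs-cirrhotic
  discrimination is the harder comparison.
* **AFP** in HCC is a two-component log-normal mixture calibrated in closed
  form to two targets: 30% of cases above the 400 ng/mL cutoff and 40%
  AFP-negative (< 20 ng/mL) — a single log-normal cannot satisfy both.
  Cirrhotic and healthy AFP are single low log-normals (medians 10 and 4
  ng/mL; the cirrhotic tail allows occasional false positives).
* **Metadata**: 72% of HCC samples HBsAg-positive (roughly the 70% of an
  HBV-endemic cohort), BCLC stages drawn as 0/A/B/C with probabilities
  0.10/0.35/0.25/0.30, stages NA outside HCC.
* **Default group sizes** are the test-phase cohort (282 HCC / 130
  cirrhotic / 164 healthy); the validation-phase profile (279/119/179) is
  the pipeline's default second cohort.
* **Reproducibility**: every sample owns an RNG stream keyed by (master
  seed, phase, group, within-group index), so enlarging one group, or
  adding a phase, never perturbs existing samples; protein-level content is
  keyed by the master seed alone and is therefore shared across phases of
  one study.

Replicate scans of a single serum sample share one latent profile and
differ by per-protein array noise. The noise SD is calibrated in closed
form against a target pairwise Pearson correlation of the linear-scale
profiles (for log-normal signals, $r = (e^v - 1)/(e^{v + \tau^2} - 1)$ with
latent log-variance $v$; duplicate-averaged spot noise is folded into
$\tau^2$), defaulting to the 0.95 reproducibility level of repeated
focused arrays.

What the generator does **not** emulate: spatial artifacts and gridding
errors, batch/site effects, inter-protein correlation (planted effects are
independent given group), non-specific binding that correlates across
samples, and any coupling between tumor stage and marker level. Passing
tests therefore demonstrate that the pipeline's statistics and bookkeeping
behave as specified under the assumed data model — not that the published
cohort's AUCs are reproducible, which they are not from desk scale (the
serum data are not deposited; the printed 0.894/0.902 AUCs serve as
documentation anchors only).

## Verification problem sizes

The test suite checks the analytic anchors exactly (hidden sizing rule,
worked examples of the positive ratio, sensitivity-at-specificity and AUC;
committee cardinality from the fold plans) and the statistical behaviour at
moderate scale chosen to keep the suite fast while leaving clear margins:
null-filter calibration over 100 seeds of 200-protein, 50-per-group
cohorts; 7-marker consensus recovery over 20 seeds of 60-protein,
250-per-group cohorts; and the committee's out-of-fold AUC against the
closed-form Gaussian oracle $\Phi(\lVert\delta\rVert/\sqrt{2})$ over 10
seeds of 7-marker cohorts (10 folds × 5 repeats per committee).

The recovery check plants a log-scale shift of 0.5 per marker
(fold-change-equivalent ≈ 1.65, combined 7-marker AUC ≈ 0.95 — the
discrimination regime the published panel occupies). This choice is
deliberate, and its boundaries are worth knowing:

* At much **smaller** effects (fold change near the 1.2 screening floor),
  quantile normalization compresses realized fold changes and markers drop
  out of individual folds at the filter stage, shrinking the all-folds
  intersection.
* At much **larger** effects (log shift above ~1), training folds become
  perfectly separable by a subset of the markers; stepwise selection then
  stops early (zero deviance leaves nothing for additional terms to
  explain), different folds credit different subsets, and the consensus
  intersection again loses true markers. This is intrinsic to stepwise
  selection under separation, not an implementation artifact; a consensus
  over near-redundant strong markers is not identifiable.

## Known limitations

* The consensus-intersection rule is brittle when candidate markers are
  individually borderline or collectively redundant (see above);
  `require_folds` relaxes the all-folds requirement when that matters.
* Plain gradient descent is deliberate fidelity to the described training
  rule, not a performance choice; very small committees on hard problems
  may undertrain within the default epoch budget.
* The AFP+ANN combiner, operating thresholds, normalization span, channel
  choice, and fold stratification are all points the source description
  leaves open; each is an explicit, recorded default here, and none should
  be read as a claim about the original study's internals.
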