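---
title: "Methods: interpretable PHQ-8 severity assessment from interview text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interpretable PHQ-8 severity assessment from interview text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phqlm)
```

## The model

`phqlm` implements a two-stage framework for assessing depression severity
from semi-structured clinical interview transcripts of the DAIC-WOZ family
(a participant conversing with the virtual interviewer "Ellie").

**Stage 1 — prompt-based feature extraction.** Each transcript is rendered
as `Speaker: text` lines and inserted into a fixed prompt template together
with one of 23 questions; a scoring backend (a large instruction-tuned
language model in production, the deterministic mock backend in testing)
answers each question with an integer score from 0 ("Not at all") to 10
("Extremely"). The questions span three domains with established links to
depression:

* **Clinical symptoms (Q1–Q8)** — one question per PHQ-8 item / DSM-5
  criterion of major depressive disorder (anhedonia, depressed mood, sleep
  disturbance, fatigue, appetite change, worthlessness, poor concentration,
  psychomotor disturbance).
* **Linguistic patterns (Q9–Q13)** — positive and negative sentiment,
  self- vs other-focused language, present- vs past/future-focused
  language, and emotion differentiation.
* **Cognitive distortions (Q14–Q23)** — the ten distortion types of the
  Cognitive Distortion Scale (mindreading, catastrophizing, all-or-nothing
  thinking, emotional reasoning, labeling, mental filter,
  overgeneralization, personalization, should statements, minimizing the
  positive).

**Stage 2 — linear severity regression.** The resulting participants × 23
score matrix predicts the PHQ-8 total (0–24) through multiple linear
regression. Predictors are z-scored with *training-set* means and SDs
(sample SD, $n-1$ convention), so coefficients are standardized betas and
directly comparable across features:

$$\hat y_i = \beta_0 + \sum_{j=1}^{23} \beta_j \, z_{ij}, \qquad
  z_{ij} = \frac{x_{ij} - \bar x_j^{\text{train}}}{s_j^{\text{train}}}.$$

Performance is summarized by MAE (primary), RMSE, and $R^2 = 1 -
SS_{res}/SS_{tot}$ computed with the evaluation-set mean — a genuine
coefficient of determination that can go negative, not a squared
correlation. Predictions are raw regression output by default; a `clip`
option limits them to the 0–24 scale.

## Interpretability statistics

* **Structure coefficients** — the Pearson correlation between each
  feature's raw values and the model prediction over held-out rows. Under
  the multicollinearity typical of symptom batteries they remain readable
  where partial regression weights do not. Standardization leaves them
  unchanged, so raw feature values are used.
* **Standardized univariate betas** — per-feature simple regressions of
  the outcome on the z-scored feature; the slope equals
  $\mathrm{cor}(x, y)\,\mathrm{sd}(y)$.
* **Ablation importance** — $\Delta MAE_j$: the test-set MAE of the model
  refit without feature $j$ minus the full model's. Refitting (not
  coefficient-zeroing) is used, because zeroing a z-scored coefficient does
  not correspond to any fitted model. These fits use an SVD minimum-norm
  fallback so exactly collinear designs (e.g. a duplicated feature, whose
  removal is free) are handled rather than rejected.

All three are reported with percentile bootstrap 95% CIs (2.5/97.5
quantiles of the resample distribution, default $B = 10{,}000$) and a
sign-based two-sided p-value with add-one continuity correction,
$p = \min\!\big(1,\ 2\min(\#\{\theta^* \le 0\}+1, \#\{\theta^* \ge 0\}+1)/(B+1)\big)$.
The literature this framework follows states only that p-values come "via
bootstrap"; the sign-based percentile rule is this package's explicit
choice, and a normal-approximation alternative was deliberately not mixed
in. For test-set statistics the bootstrap resamples *evaluation* rows with
the train-fitted model held fixed. P-values are adjusted across each
feature set with the Benjamini–Hochberg step-up procedure
($q_{(i)} = \min_{j\ge i} p_{(j)} m / j$, capped at 1).

## Construct validity

Extracted features are checked against external references where any
exist: Q1–Q8 against their PHQ-8 item scores, Q9–Q12 against lexicon-based
text metrics, via Spearman correlation (average ranks; two-sided p from
the t approximation, appropriate under the heavy ties of 0–10 integer
scores) with BH-FDR across the 12 linked features. Emotion differentiation
and the distortions have no reference metric and are skipped. Validity is
computed on training participants only.

The shipped lexicon is a compact open word list: pronoun and tense marker
classes are closed-class and intended to be faithful; the positive and
negative tone lists are a small curated approximation of commercial
sentiment dictionaries and are documented as heuristic. Tone rates are
matched tokens per 100 tokens; the self-focus ratio is the first-person
share of all matched pronouns; the present-focus ratio is the
present-marker share of all matched tense markers. Zero-denominator ratios
are flagged `NA`, never silently 0. Per-document normalization conventions
differ across tools; "per 100 tokens" is this package's stated choice.

## Decoding configuration and parsing

The deterministic preset emulates greedy decoding (`top_p = 0`,
`temperature = 1e-4`). The generation cap is `max_new_tokens = 4` rather
than 1: under some tokenizations the two-character answer `"10"` needs two
tokens, and a cap of 1 would truncate it; strict parsing (a bare base-10
integer in 0–10, anything else a typed error) preserves the single-score
intent. The stochastic preset (`top_p = 0.8`, `temperature = 0.7`) allows
response variability across repeated runs; `repeat_extraction()` runs it
with distinct seeds to obtain MAE distributions. Retries after a parse
failure are only meaningful under stochastic decoding (greedy decoding
would reproduce the same completion), so the deterministic preset fails a
cell after one attempt and the stochastic preset retries up to 3 times.
Failed cells are recorded in a failure report, never imputed. An on-disk
cache keyed by (participant text, question, backend, decoding config)
makes reruns incremental.

Whether interviewer turns belong in the prompt body is not externally
settled; because the template frames the text as the full interview, both
parties are rendered (`Ellie:` / `Participant:` lines), and the rendering
is deterministic byte-for-byte.

## Model variants

* **RBF-SVR** (`family = "svr_rbf"`): $\varepsilon$-SVR on the z-scored
  features. Only the cost $C$ is tuned — by leave-one-out cross-validation
  on the training rows, minimizing MAE, ties to the smallest $C$ — over a
  16-point log-spaced grid $2^{-5} \ldots 2^{10}$. Defaults
  $\varepsilon = 0.1$ and $\gamma = 1/(d \cdot \text{pooled variance})$
  are stated, not silent; the underlying quadratic-program solver is
  deterministic, so selection is reproducible. Fold models re-estimate the
  standardizer, so no held-out row leaks into its own fold.
* **Stacking** (`family = "stacking"`): one OLS base model per feature
  category; their leave-one-out out-of-fold training predictions form the
  design of an OLS-with-intercept meta-model (the meta-learner family is
  an open choice; OLS keeps the ensemble linear and inspectable). Base
  models are refit on the full training set for prediction.

## Synthetic cohorts and the mock backend

`generate_cohort()` draws integer severities from a discretized
right-skewed Beta(1.6, 3.2) over 0–24 (screening-cohort shaped: most mass
below 10), allocates PHQ-8 items to sum to the total by assigning points
one at a time to items with remaining capacity (cap 3 — always feasible,
unlike naive multinomial rejection), and generates each question's score
as $\mathrm{round}(\mathrm{clip}(b_q + \lambda_q \cdot 10 s/24 +
\varepsilon,\ 0, 10))$ with noise SD $\sigma = 1.5$ and within-category
equicorrelation $\rho = 0.3$ by default. Reverse-keyed questions
(positive sentiment, present focus, emotion differentiation) get negative
loadings and baseline $b_q = 10$. The "strong" preset (loadings 0.9
clinical / 0.8 distortions / 0.5–0.9 linguistic) defines the study
conditions used by the acceptance checks; the "null" preset zeroes all
loadings for calibration tests.

`generate_transcripts()` plants, in each participant's turns, exactly as
many copies of each question's cue token (`q2cue`, …) as the ground-truth
feature value, plus lexicon tokens (tone words, pronouns, tense markers)
in proportion to the Q9–Q12 values, severity-independent control cues and
a noisy severity-graded direct-severity cue. The mock backend parses the
prompt it receives, maps the question text back to its id, counts that
question's cue token in participant lines, and returns
$\min(\text{count}, 10)$ — deterministic given the prompt, with seeded ±1
jitter under the stochastic preset.

What passing tests on this generator do show: the statistics, the
train/test hygiene, the end-to-end plumbing, and the qualitative ordering
of prompting strategies are correct by construction and recoverable.
What they do not show: anything about real interview language,
transcription noise, or how a particular language model scores real
transcripts — the generator makes no attempt at linguistic realism, and
its cue-counting backend is a test double, not a language model.

## Numerical choices and degenerate inputs

* OLS is solved by QR; rank deficiency is an error naming the collinear
  features, except in ablation where the SVD pseudo-inverse path is
  intended and documented.
* Zero-variance features are rejected at standardization by name.
* Constant features on an evaluation set make the structure coefficient
  undefined: flagged `NA` with a warning, never coerced to 0.
* Bootstrap resamples on which a statistic is undefined are dropped and
  counted; a result with more than 1% undefined draws is flagged.
* Report rows are ordered by absolute estimate, ties broken by original
  question order.
* BH q-values are computed by `stats::p.adjust`; the test suite holds
  them to the step-up definition to within one floating-point ulp
  (the two differ only in the association order of `p·m/j`).

## Problem sizes used in the checks

The packaged checks run the full pipeline at the reference scale
(140 train / 46 + 86 test participants, 23 questions), verify oracle
equivalence on 100 random small instances, parameter recovery on a
synthetic cohort of $n = 1000$ with noise SD 2 (test MAE approaching
$\sigma\sqrt{2/\pi}$), bootstrap-coverage calibration with 500
replications of $n = 140$ at $B = 500$ (chosen to mirror the training-set
scale), and null calibration over 200 seeded cohorts at $B = 199$.
Bootstrap defaults are $B = 10{,}000$ in production use; the reports in
the automated checks use smaller $B$ (stated alongside each result).

## Known limitations

* The control question bank ships placeholder texts on the documented
  non-clinical themes; users with the original control items should
  substitute them via `read_question_set()`.
* The tone lexicon is approximate; validity checks against it measure
  agreement with a stand-in, not with a commercial dictionary.
* PHQ-8 item allocation in the generator is exchangeable across items;
  real item profiles are not.
* The in-sample nesting guarantee of OLS applies to RMSE (sum of squares),
  not MAE; category-restricted models are compared to the full model on
  RMSE in the invariants.

## A worked example

```{r example, eval = FALSE}
cohort <- generate_cohort(cohort_spec(272, seed = 1, preset = "strong"))
transcripts <- generate_transcripts(cohort, seed = 2)
fm <- extract_features(transcripts, question_set("depression23"))
ids <- rownames(fm)
train <- ids[1:140]; test <- ids[141:272]
y <- cohort$labels$phq8_total
model <- severity_model(fm[train, ], y[match(train, ids)])
evaluate_predictions(predict(model, fm[test, ]), y[match(test, ids)])
coefficient_report("structure", model = model, x_test = fm[test, ],
                   questions = question_set("depression23"),
                   B = 2000, seed = 3)
```
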