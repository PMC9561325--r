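---
title: "DeepMPM: model, training protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DeepMPM: model, training protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the model implemented by `deepmpm`, the choices made
where the design was genuinely open, the synthetic data it is validated on,
and what those validations do and do not establish.

## The prediction problem

The input is a longitudinal coded EHR: each patient has an ordered sequence
of hospital visits, each visit carrying a set of ICD-9 diagnosis codes, a
set of DRG codes (used as the treatment/intervention summary), an admission
type, and admission/discharge timestamps. The target is in-hospital death,
recorded on the final visit of a deceased patient. The model predicts, after
every visit, the probability that the patient's record ends in in-hospital
death, using only the visits observed so far, and exposes attention weights
that say *which* visits and *which* code dimensions drove the prediction.

## Model

**Encoding.** Visit $t$ is a pair of multi-hot vectors
$x_t \in \{0,1\}^{|D|}$ (diagnoses) and $p_t \in \{0,1\}^{|L|}$ (DRGs).
A one-layer ReLU encoder embeds each into $\mathbb{R}^d$:
$X_t = \mathrm{ReLU}(W_{x} x_t + b_x)$, $P_t = \mathrm{ReLU}(W_{p} p_t + b_p)$,
with $d = 32$ by default. The weight matrices can be initialised by an
intra-visit skip-gram with negative sampling (the context of a code is the
other codes of the same visit), then fine-tuned end-to-end; whether the
original system pretrained or learned the encoder purely end-to-end is not
determinable, so both are supported (`pretrain` flag), with
pretrain-then-fine-tune as the default pipeline.

**Care-LSTM.** Both attention branches run a modified LSTM over the visit
sequence whose gates receive clinically meaningful side inputs:

* input gate $i_t = \frac{1}{m_t}\,\sigma(W_i X_t + U_i h_{t-1} + b_i)$,
  where $m_t = 1$ for emergency-group admissions (EMERGENCY, URGENT) and
  $m_t = 2$ for the non-emergency group (ELECTIVE, NEWBORN) — emergency
  records are weighted more heavily;
* forget gate receives the previous visit's treatment embedding $P_{t-1}$
  and a three-scale view of the gap since the previous discharge,
  $q_t = [\Delta/60, \Delta/180, \Delta/365]$ (days);
* output gate receives the current treatment embedding $P_t$;
* the candidate cell keeps the standard form
  $\tilde C_t = \tanh(W_c X_t + U_c h_{t-1} + b_c)$ — only the gates carry
  the extra inputs.

Two notes. First, the surrounding description of the time scales mentions
360 days while the defining expression divides by 365; the equation is
followed (the divisors are configurable via `scales`). Second, whether the
candidate-cell weights were shared with a standard-LSTM implementation
cannot be determined; the standard form above is used.

**Two-level attention.** The visit-level branch produces scalar scores
$W_\alpha^\top g_t + b_\alpha$ from its Care-LSTM states $g_t$, normalised
by a softmax **across the visits of the patient** — a per-visit softmax of a
scalar would be identically 1 and carry no information, so the
across-visits reading is the only meaningful one. The variable-level branch
produces $\beta_t = \tanh(W_\beta e_t + b_\beta) \in [-1,1]^d$ from its own
(unshared) Care-LSTM; negative entries are read as suppression between
diseases and treatments, positive as synergy. A harmonic recency weight
$r_t = [m_t + \ln(1+\Delta_{t:T})]^{-1}$ (natural log; $\Delta_{t:T}$ = days
from visit $t$'s admission to the last visible discharge) down-weights
non-emergency and long-ago visits. The combined weight is
$w_t = r_t \odot (\alpha_t + \beta_t)/2$ with the scalar $\alpha_t$
broadcast across $d$; the ablated variant (`ablate_beta`) uses
$w_t = r_t \alpha_t$.

**Pooling and head.** The health-status vector is the elementwise weighted
average $\bar h = \sum_t w_t \odot X_t \,/\, \sum_t w_t$, followed by a
two-class softmax head; the second class probability is the death risk.

**Per-prefix predictions.** The training loss averages a per-visit binary
cross-entropy over each patient's visits, which requires a prediction
$\hat y_i$ *per visit*; the only reading under which those are well defined
is a prefix forward pass: the attention softmax, harmonic weights, pooling
and head are recomputed on visits $1..i$ for each $i$. Consequently
$\Delta_{t:T}$ inside a prefix is measured to the discharge of visit $i$,
not of the eventual last visit — otherwise the prediction at visit $i$
would depend on the future, violating the prefix property that the tests
assert. The total loss is the mean over patients of the per-patient mean
over prefixes, plus an elastic-net penalty
$10^{-4}(\sum|\theta| + \sum \theta^2)$ over the weight matrices (biases
excluded).

## Numerical choices

* **Pooling denominator.** Because $\alpha_t + \beta_t$ can be negative,
  $\sum_t w_t$ can cancel arbitrarily close to zero in any dimension. The
  denominator keeps its sign but its magnitude is floored via
  $s + \varepsilon\,\mathrm{sign}(s)$ with $\varepsilon = 10^{-8}$.
* **Clamped head input.** Even with the floor, a near-cancelled denominator
  yields pooled entries of order $10^{6}$; the head therefore sees
  $\bar h$ clamped to $[-10, 10]$ (the reported health-status vector is the
  exact weighted average). Without this, a handful of near-singular
  denominators saturate the risk output and their gradients dominate every
  mini-batch.
* **Elementwise gradient clipping** at $\pm 5$ per entry (config
  `grad_clip`), the usual recurrent-network safeguard, for the same reason.
* **Zero-initialised variable-level projection.** $W_\beta = 0$,
  $b_\beta = 0$ at initialisation, so the fresh model's combined weights
  are proportional to $r_t\alpha_t$ — identical to the ablated model, since
  the pooled average is invariant to the overall weight scale — and the
  variable-level attention grows from zero only where the data support it.
  With a random $\beta$ the sign cancellations above dominate early
  training and the full model reliably underperforms its own ablation.
* **Probability clipping** to $[10^{-7}, 1-10^{-7}]$ inside the loss; the
  training gradient uses the exact softmax cross-entropy form.
* **First-visit conventions.** $\Delta_{0:1} = 0$ (no prior discharge) and
  $P_0 = 0$ (no prior treatment); overlapping admissions (negative raw
  gaps) clamp to 0 days; day differences are floors of elapsed time.
* **Initial LSTM state** is zeros; all other weights are Glorot-uniform
  draws from the configured seed.

## Training protocol

Defaults follow the published protocol: mini-batches of 80 patients, 100
epochs, Adadelta with decay $\rho = 0.1$ (unusual for Adadelta but honoured
as printed; configurable), L1+L2 coefficients $10^{-4}$, dropout with keep
probability 0.8 applied to $\bar h$ at train time (the most common placement
when the location is unstated), and the slanted triangular learning rate
with `cut_frac` 0.1 and `ratio` 32: linear rise from
$\eta_{\max}/\mathrm{ratio}$ to $\eta_{\max}$ over the first 10% of
iterations, linear decay back afterwards. The protocol's iteration count of
100 is read as 100 epochs, with the schedule's total $T$ equal to epochs ×
batches per epoch. The Adadelta proposal step is multiplied by the
scheduled rate.

Two protocol-adjacent constants are deliberately scale-dependent. The
published protocol pairs $\eta_{\max} = 0.1$ with roughly $9{,}400$
iterations (7,491 patients); the desk-scale experiments in this package run
a few hundred iterations, where Adadelta's accumulators never leave their
warm-up regime at that rate and the training loss barely moves. The
experiment configurations therefore use $\eta_{\max} = 1$ with 15 epochs.
Second, Adadelta's stability constant $\varepsilon$ — an implementation
constant no protocol prints — sets the magnitude of the optimiser's first
steps ($\sqrt{\varepsilon}$ before the rate multiplier) and hence how many
iterations the warm-up consumes; the package default is $10^{-3}$, suited
to short schedules. Both were chosen by watching the *training* loss reach
its minimum (with $\rho = 0.1$ the optimiser behaves like sign-SGD with a
slowly ratcheting step size, and running far past the loss minimum lets
that noise floor grow, so the schedule stops near it); the schedule shape
and every other protocol constant are unchanged. Alternatives were
compared on training loss: standard Adadelta decay ($\rho = 0.95$) and
Adam both converge less reliably here than the printed $\rho = 0.1$ once
$\varepsilon$ is set appropriately.

**Evaluation** is at the patient level: the final-prefix (full-sequence)
risk, thresholded at 0.5 for the confusion matrix (no threshold is
specified; 0.5 is the natural choice for a balanced cohort), with AUC by
the rank (Mann–Whitney) formulation. Cross-validation is stratified by the
death label and split at the patient level, so no patient's prefixes leak
across folds; fold metrics are reported as mean ± sd (labelled as sd: the
published tables do not say whether their ± is sd or sem). Hard positive
examples are deceased patients misclassified in strictly more than half of
their test appearances across repeated cross-validation.

## Synthetic cohorts

The generator (`synth_config()` / `generate_cohort()`) emulates the
statistical structure the model assumes, at desk scale:

* visit counts: truncated geometric on $[2, 10]$ with mean 2.57 — the
  mean visits per patient of the cleaned MIMIC-III mortality cohort this
  model family targets;
* code sets: ~8 distinct diagnosis codes per visit from a 100-code
  vocabulary and ~2 DRG codes from 50 — the same visit-level density
  profile as that cohort (12.97 codes of 931 and 2.23 of 1,406), scaled
  down so that experiments run in minutes;
* comorbidity structure: four disjoint 20-code blocks; each patient has a
  primary block from which 80% of code draws come, producing the
  within-block co-occurrence the skip-gram and correlation analyses target;
* gaps: log-normal (meanlog 4, sdlog 1; median ≈ 55 days) — long-tailed
  across the 60/180/365-day scales the forget gate resolves;
* admission types: emergency group with probability 0.7;
* death: a Bernoulli on the final visit with
  $\mathrm{logit} = \mathrm{baseline} + \mathrm{effect} \times k$, where
  $k$ is the number of distinct lethal codes (8 designated codes) across
  the patient's visits. Patients belong to a high-burden subgroup
  (probability 0.5, per-visit lethal-code prevalence 0.25) or a low-burden
  one (prevalence 0.02) — the patient-level heterogeneity in chronic
  disease burden that real cohorts show, and what gives the lethal-code
  count enough dispersion for the signal-recovery experiments to have a
  well-separated optimum. Defaults (baseline −2.5, effect 1.5) put the
  marginal death rate near the balanced positive/negative ratio of the
  originally reported cohort. Death truncates the sequence: no visits follow it.

What the generator does **not** emulate: real ICD-9/DRG semantics or
frequencies (codes are abstract tokens), seasonal or age structure,
censoring, code-set correlation between diagnoses and treatments, or
measurement noise in timestamps. Passing the signal-recovery tests
therefore shows that the implementation can extract a known multi-visit
code signal through the full pipeline — not that it attains any particular
performance on real EHR.

## Experiment sizes

The test-suite experiments use cohorts of 2,000 patients (500 held out),
embedding dimension 32 and hidden size 64 as in the published protocol, 15
epochs at $\eta_{\max}=1$, and three generator seeds for the
signal-recovery average; smaller cohorts and dimensions are used for purely
mechanical checks. The skip-gram pretraining runs 3 epochs with 5 negative
samples per pair.

## Interpretability conventions

The per-patient report (`deepmpm_explain()`) lists each visit's
$\alpha$-weight and, for each active code, a score projecting $\beta_t$
onto the code's embedding column, $\sum_j \beta_{t,j} W_{x}[j, c]$,
normalised within the visit by the sum of absolute scores. How the
published reports mapped the $d$-dimensional $\beta_t$ back to individual
codes is unspecified; this projection is a reporting convention of this
package, not a fidelity claim. Code–code correlation matrices
(`deepmpm_correlations()`) are Pearson correlations between embedding
columns — the only reading consistent with "correlation coefficients of
the weight matrices".

ICD-9 codes are truncated to their first 3 characters by default
(`truncate_cohort_codes()`), as in the published preprocessing; the length
is configurable because the published case-study tables print full-length
codes, which the 3-character rule cannot reproduce — the two statements are
left unreconciled there, and both behaviours are supported here.

## Known limitations

* Pure-R training: a 2,000-patient, 30-epoch run takes a few minutes; the
  implementation is not meant for cohorts of $10^5$+ patients.
* The per-visit labels make the prefix predictions hazard-like (the
  probability that *this* visit is the fatal one), so well-calibrated
  prefix risks sit well below the eventual death rate; patient-level
  ranking (AUC) is unaffected, but the 0.5 threshold is conservative for
  recall.
* With $\rho = 0.1$, Adadelta behaves close to sign-SGD with a slowly
  ratcheting step size; very long schedules can destabilise late in
  training. The experiment configurations were chosen inside the stable
  range of that regime.
* The correlation matrices are over embedding columns; codes that never
  co-occur with anything informative keep near-random columns and noisy
  correlations.
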