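---
title: "Models and methods behind rtcit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rtcit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtcit)
```

## The paradigm and what the package computes

The reaction-time Concealed Information Test (RT-CIT) infers recognition
from response slowing. A participant classifies serially presented items as
"familiar" or "unfamiliar". Probes (self-relevant items, e.g. the
participant's own name) must be denied with the "unfamiliar" button, among
matched irrelevant items; targets are learned items requiring the rare
"familiar" response; in the Go/No-go variant two additional no-go items
require withholding any response, giving a behavioural index of response
inhibition (the commission rate). The diagnostic quantity is the **RT-CIT
effect**: a participant's mean probe RT minus mean irrelevant RT. Its
standardised form, **dCIT**, divides the effect by the SD of the
participant's irrelevant-trial RTs.

`rtcit` implements the full analysis chain for this paradigm — a calibrated
trial-level simulator, the preregistered-style exclusion rules,
questionnaire scoring (LSRP psychopathy and BIS-11 impulsivity),
detection-efficiency estimation by bootstrap ROC against a simulated naive
group, and the default Bayes factors used to quantify evidence for and
against the focal association between the RT-CIT effect and secondary
psychopathy.

## The trial schedule

The default design presents 14 distinct items (2 probes, 8 irrelevants, 2
targets, 2 no-go), each 6 times per block, in 4 blocks: 84 trials per block,
336 per session, with an inter-stimulus interval drawn uniformly from
{250, 500, 750} ms, a 1500 ms stimulus window and an 800 ms response
deadline. Item order is random subject to a hard no-immediate-repetition
constraint. `generate_schedule()` enforces it by shuffling each block and
repairing any adjacent duplicate through a random swap that creates no new
adjacency, falling back to a full reshuffle; at the default density
(6 repetitions of 14 items) the repair almost always succeeds in a handful
of swaps, and the residual ordering bias of this scheme is negligible for
every quantity the package computes (no analysis depends on serial
position). The block boundary is treated as contiguous: the last item of one
block may not open the next. A design whose most frequent item exceeds the
available gaps is rejected as infeasible.

## The reaction-time model

The study-level summaries this simulator is calibrated to are
participant-level means; trial-level RT distributions are not part of those
summaries, so the within-subject law is a modelling convention. We use the
**ex-Gaussian** (Gaussian plus exponential) distribution, the standard
convolution model for simple RTs: right-skewed, with mean `mu + tau` and
variance `sigma^2 + tau^2`.

Per participant:

* the mean irrelevant RT, `mu + tau`, is drawn
  Normal(477.47, 33.28) ms (between subjects);
* the within-subject SD `sqrt(sigma^2 + tau^2)` defaults to 100 ms, split
  evenly between the two components (`tau = 100/sqrt(2)`). The 100 ms value
  is a typical magnitude for speeded binary classification and is the single
  calibration constant linking the millisecond CIT effect to the
  standardised dCIT (and hence to the detection-efficiency results below);
  it is exposed as `within_sd_irrelevant_ms`;
* probes receive an additive slowing drawn Normal(54.91, 32.43) ms between
  subjects — the RT-CIT effect. Under the default configuration this shift
  is **independent of all latent traits**, encoding the null hypothesis of
  no association between the CIT effect and secondary psychopathy;
* targets receive an additive slowing of Normal(55, 25) ms. No group-level
  target summary constrains this choice; targets only need to be slower and
  noisier than irrelevants, and nothing downstream consumes target RTs;
* latencies beyond the 1500 ms stimulus window become omissions; wrong-button
  presses occur with probability 0.04 on go trials; no-go commissions follow
  a logit link on (negated) inhibition capacity centred on a mean commission
  rate of 14.99/48, giving a realistic between-subject spread of no-go error
  counts. Commission latencies are drawn from the go distribution but are
  never used in RT summaries — no-go trials are scored for errors only.

One consequence worth stating explicitly: the 32.43 ms between-subject SD of
the probe shift is taken from an *observed* study-level summary, which
already contains trial-sampling noise. Adding fresh trial noise on top means
the simulated cohort's observed effect SD is slightly larger (~36 ms), so
the realised one-sample effect size is ~1.5 rather than the latent
54.91/32.43 = 1.69. We kept the printed value as the generator default
because it is the documented study condition and because the detection
analysis that matters (the dCIT ROC) takes the printed distribution
directly; the modest attenuation of the whole-pipeline d is a known and
accepted property of the simulator, bounded in the test suite.

## Questionnaire items and reliability calibration

Latent primary psychopathy, secondary psychopathy, impulsivity and
inhibition capacity are multivariate standard normal. Their correlations
default to the **disattenuated** target scale correlations: to make two
scored scales with reliabilities `a1`, `a2` correlate at `rho`, the latent
traits must correlate at `rho / sqrt(a1 * a2)` (0.709 for
secondary-impulsivity from a 0.516 target with alphas 0.63 and 0.84).
Inhibition is uncorrelated with the other traits by default, reflecting the
small and unreliable no-go-error correlations in this literature.

Each Likert item is a thresholded noisy copy of its latent trait:
`y = loading * z + noise`, cut at three thresholds into 1–4. Two numerical
choices matter:

* **Thresholds** are unit-spaced and shifted so the discretised normal hits
  the scale's per-item mean (1.77 primary, 1.90 secondary, 2.10 BIS-11).
* **Loadings** are solved so the *discretised* items reach the target
  Cronbach's alpha. Coarse 4-category discretisation attenuates
  correlations by roughly 12% here; we invert the exact correlation
  function of two thresholded bivariate normals (a one-dimensional normal
  integral, solved by root-finding) rather than using a linear attenuation
  approximation, which left a visible downward bias in the recovered
  scale-level correlation. Because within-scale and cross-scale item
  correlations attenuate by the same mechanism, the scored-scale correlation
  then lands on `latent_r * sqrt(a1 * a2)` — the calibration target — without
  any further adjustment.

Post-test ratings (probe/irrelevant significance on 1–9, motivation and felt
impulsivity on 1–10) are round-and-clip normals with the configured means
and SDs. Clipping pulls extreme means (e.g. 8.58 on a 9-point scale)
slightly inward; tests compare against the round-and-clip distribution's own
mean.

What the generator does **not** emulate: practice phases, feedback-driven
speeding, sequential trial dependencies, speed–accuracy trade-offs,
countermeasures, and item-content effects. Passing tests therefore show that
the analysis chain recovers the structure this generator encodes, not that
it is robust to every property of real RT data.

## Exclusion rules

Trial level, applied to go trials only: a press faster than 150 ms, slower
than 800 ms, or with the wrong button excludes that trial from RT summaries
(one reason per trial, in that order of precedence). Omissions are retained
rows but contribute to no RT summary. No-go trials are never filtered.

Participant level: exclusion for an incomplete session (< 336 trials) or a
go-trial error rate of at least 50% on any single stimulus type. Whether
omissions count as errors for the 50% rule is not decidable from study-level
descriptions that gloss errors as wrong presses; we count them (both
invalidate a go trial) and expose `count_omissions = FALSE` for the stricter
wrong-press-only reading. Reasons are evaluated in a fixed order (incomplete
first, then probe, irrelevant, target rates), so the reported reason is
deterministic. The commission-rate denominator is the designed 48 no-go
trials, not the retained count, and the irrelevant-RT SD is the sample
(n−1) SD of retained trials.

## Detection efficiency: the simulated-naive ROC

Real naive (unknowledgeable) participants are not needed: their expected
dCIT is 0, and its sampling SD is taken from the variance of a standardised
mean difference,

    SD = sqrt( ((N-1)/(N-3)) * (4/N) * (1 + delta^2/8) ),

with `delta = 0` for naive participants (`naive_sd(86)` = 0.2183 — verified
in tests against the Monte-Carlo SD of a null two-group Cohen's d). `N`
defaults to the knowledgeable sample size but is exposed, since "total
sample size" admits more than one reading. Each of 1000 bootstrap
repetitions draws a fresh Normal(0, SD) naive group of the knowledgeable
group's size and computes the rank-based (Mann–Whitney) AUC with half credit
for ties; the estimate is the mean of the 1000 AUCs with a percentile
(2.5/97.5) interval — the interval method is a package choice, as is holding
the knowledgeable scores fixed across repetitions (an optional flag also
resamples them). With knowledgeable dCITs distributed as
Normal(54.91, 32.43)/100, the closed form `pnorm(mu / sqrt(sigma^2 + SD^2))`
gives 0.920, and the bootstrap reproduces it.

## Bayes factors

Both Bayes factors are computed from summary statistics (t or r, plus n), so
published values are reproducible without raw data.

**One-sample t (JZS).** A Cauchy prior with scale `sqrt(2)/2` on the
standardised effect against the point null. The two-sided factor is
evaluated by adaptive quadrature over the inverse-gamma mixing variable — an
integrand that is a bounded likelihood ratio, stable even at t near 40 —
and the directional factors by integrating the noncentral-t marginal over a
half-Cauchy. The two routes are mutually consistent (the two-sided factor is
the average of the two directional ones) and that identity, a Monte-Carlo
prior-average oracle, and doubled-resolution stability to 1e-6 are all
enforced in tests. Directional tests reproduce published values for
preregistered directional hypotheses; `two.sided` is the function default.

**Correlation.** A stretched symmetric beta prior of width 1 (uniform on
(−1, 1)) against the point null, two-sided, using the exact reduced
likelihood of a sample correlation (with its Gauss hypergeometric factor
summed to machine precision) integrated over the prior. At r = 0.038,
n = 86 this gives BF01 = 6.99. Published values from specific software
versions can differ from the exact quadrature by up to ~3% at large |r|; we
implement the exact expression rather than emulate any particular version.

`sequential_bf()` recomputes the correlation BF on growing prefixes of the
data, tracing the evidential flow; under independence the trajectory drifts
toward the null, which the test suite checks across study-sized subsamples.

Cohen's d confidence intervals use the normal approximation
`SE = sqrt(1/n + d^2/(2n))` by default (the convention that matches
published intervals in this literature), with a noncentral-t inversion
behind `ci = "nct"`. The Bonferroni threshold is `alpha / m`.

## Problem sizes and reproducibility

The package's own verification uses cohorts of 5000 simulated participants
for calibration-recovery checks (alpha and scale-correlation targets, the
null association), 86 — the study-scale cohort — for pipeline-level checks,
and 1000 bootstrap repetitions for detection efficiency; these sizes give
Monte-Carlo error comfortably inside the asserted tolerances while keeping a
full test run under a minute. `run_pipeline()` derives independent per-stage
substreams from one master seed, so re-running with the same configuration
is byte-identical and toggling one stage does not perturb another's draws;
every report bundle records the master seed, the stage seeds, the package
version and per-stage counts.

## Known limitations

* The generator's probe-shift SD conflates latent and trial-level variance
  (see above); whole-pipeline standardised effects are mildly attenuated
  relative to the latent calibration.
* Scored-scale correlations are recovered through a linear-loading graded
  response mechanism; real item response processes (varying loadings,
  reversed wording, acquiescence) are not modelled, and the reverse-key maps
  of the real instruments must be supplied by the user for real data.
* The no-repeat scheduler is repair-based, not an exact uniform sampler over
  admissible sequences; its bias is irrelevant here but would matter for
  serial-position analyses.
* The paired ratings contrast can only be reproduced from summary
  statistics up to the unprinted difference SD; the simulator draws probe
  and irrelevant ratings independently, which makes the simulated paired t
  conservative relative to positively correlated real ratings.
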