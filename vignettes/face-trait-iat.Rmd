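---
title: "Scoring face-trait IATs and testing single cases against norms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring face-trait IATs and testing single cases against norms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faceiat)
```

## The problem this package addresses

Developmental prosopagnosia (DP) is a lifelong impairment in recognising
face identity. Whether people with DP can nonetheless form *implicit*
trait impressions from faces — for example automatically associating
composite faces with extraversion-related words — is a question about
the separability of identity recognition from social-evaluative face
processing. The standard instrument is the Implicit Association Task
(IAT): participants categorise faces and trait words under congruent and
incongruent response mappings, and the latency cost of the incongruent
mapping indexes the strength of the implicit association.

Answering the question requires a chain of methods, each of which this
package implements as tested, reusable code:

1. **trial-level scoring** of IAT sessions into D-scores,
2. **single-case inference** comparing each DP participant's D against a
   normative control sample,
3. **group-level inference** (frequentist and Bayesian) on the DP cohort,
4. **screening-battery scoring** for the diagnostic criteria that define
   the cohort in the first place, and
5. a **session simulator** so every stage is testable end to end without
   access to any participant data.

## The D-score algorithm

Sessions follow the standard seven-block IAT design (`iat_block_design()`):
blocks 1, 2 and 5 are single-category practice blocks, blocks 3/4 carry the
congruent pairing (20 and 40 trials) and blocks 6/7 the incongruent pairing
(20 and 40 trials). Counterbalancing swaps only the presentation order, not
the block labels, so scoring is identical for both orders.

`compute_d()` implements the improved scoring algorithm on the four test
blocks. Writing \(\bar{x}_b\) for the mean latency of block \(b\) and
\(s_{36}, s_{47}\) for the sample SDs pooled over all trials of blocks
\(3 \cup 6\) and \(4 \cup 7\) respectively,

\[
D = \frac{1}{2}\left(
  \frac{\bar{x}_6 - \bar{x}_3}{s_{36}} +
  \frac{\bar{x}_7 - \bar{x}_4}{s_{47}}
\right),
\]

so positive \(D\) means faster responding under the congruent pairing.
Before scoring, trials slower than 10,000 ms are removed (trial-level
rule, strict `>`), and a participant is flagged for exclusion when
strictly more than 10% of the remaining trials are faster than 300 ms.

Two error-trial treatments are provided:

* **reference** — block means are computed over correct trials only, and
  each error trial then contributes its block's correct-trial mean plus a
  fixed 600 ms penalty;
* **error_penalty** (default) — every trial contributes its full latency
  from stimulus onset to the final *corrected* response, so errors carry
  their own implicit time penalty. This is the variant used by the online
  task this package models, where a wrong keypress must be corrected
  before the next trial begins.

On error-free data the two variants agree exactly, and the test suite
asserts this, along with antisymmetry under relabelling the pairings and
invariance of \(D\) under shifting or rescaling all latencies.

Three readings were genuinely open and are fixed here as package
conventions:

* the pooled SDs use the *n − 1* sample-SD over all retained trials of
  the block pair, with error trials contributing their variant-specific
  values (the replaced value under `reference`, the corrected-response
  latency under `error_penalty`);
* "correct latencies" means the first-keypress latency of trials whose
  first response was correct;
* slow-trial removal precedes the fast-fraction computation, so the 10%
  denominator is the retained trial count.

Degenerate inputs (a zero pooled SD, a missing test block, a block with
fewer than two usable trials) raise errors rather than returning
infinities.

## Single-case inference

`crawford_t()` implements the modified t-test for comparing one case
score \(x\) against a control sample summarised by \((\bar{x}_c, s_c,
n_c)\):

\[
t = \frac{x - \bar{x}_c}{s_c\sqrt{(n_c+1)/n_c}}, \qquad df = n_c - 1 .
\]

Treating the controls as a sample rather than a population gives correct
Type I error control when the normative sample is modest; as
\(n_c \to \infty\) the statistic converges to the z-score, which the
suite verifies at \(n_c = 10^6\). The percentile rank — the estimated
proportion of the control population scoring below the case — is the
Student-t CDF at \(t\), reported as a point estimate without interval
limits. Both tails are reported: the printed case table uses the
two-tailed p, while deficit screening (`count_below_norm()`) uses the
one-tailed, deficit-direction p at \(\alpha = 0.05\) together with the
requirement \(t < 0\); the headline "no case below the normative range"
holds on the packaged case table under either reading.

The packaged fixtures `dp_case_dscores()` (36 case D-scores) and
`combined_norms()` (mean 0.082, SD 0.405, N = 180) reproduce the
published case analysis. Only the elevated case (participant 4) and the
zero-deficit count are treated as consistency targets: most printed
per-case t values in the source table are not reproducible from the
combined norms (they plausibly reflect unpublished age-matched
subsamples), so the fixture serves single-case arithmetic, not
t-column regression.

## Group-level inference

`one_sample_test()` wraps the standard one-sample t-test against zero,
adding Cohen's \(d = \bar{x}/s = t/\sqrt{n}\) (an exact identity the
suite checks to \(10^{-12}\)) and the t-based confidence interval;
`one_sample_from_summary()` reconstructs the same result from printed
summary statistics.

`jzs_bf10()` computes the default Bayes factor for the one-sample design
by integrating the Jeffreys–Zellner–Siow marginal likelihood over a
Cauchy(0, r) effect-size prior. The integral over the mixing parameter
\(g\) is evaluated adaptively on the log-\(g\) axis — the integrand is
heavy-tailed in \(g\), and the log transform makes the mass compact —
in log space, with relative tolerance \(10^{-8}\). The default prior
scale \(r = \sqrt{2}/2 \approx 0.707\) is the common "medium" default
of standard Bayes-factor software; the source analysis does not state
its prior, and with this default the published Bayes factor is
recovered within rounding. The suite cross-checks the quadrature
against an independent brute-force trapezoid grid to four significant
digits.

`sequential_bf()` recomputes the Bayes factor after each accumulated
participant in presentation order, matching the usual
accumulation-by-participant reading of sequential analyses; no
reordering is applied. `spearman_rho()` provides the rank correlation
(average ranks for ties) with the t-approximation p-value — adequate at
the cohort sizes targeted here, and no exact permutation p is offered.

## Screening battery

The screening module scores the diagnostic battery that defines a DP
cohort:

* `pi20_score()` — 20 Likert items, five reverse-keyed (\(v \to 6-v\)),
  bands mild 65–74, moderate 75–84, severe 85–100, `"none"` below 65.
  The instrument's reverse-keyed positions are configurable; the package
  default (items 3, 8, 11, 15, 19) is a convention, and all arithmetic
  is position-agnostic. The honest attainable range of the total is 20
  to 100 (the floor requires answering the reverse-keyed items
  "strongly disagree"), which the suite pins by corner enumeration.
* `cfpt_trial_score()` — deviation-sum scoring of a six-face sorting
  trial: the sum over faces of absolute positional displacement. A full
  reversal scores 18, the per-trial maximum (verified by exhaustive
  enumeration over all 720 arrangements), giving 144 over the eight
  upright trials; 0 is perfect.
* `fft_adjusted_percent()` — percent correct with celebrities unknown to
  the participant removed from the denominator.
* `aq_excluded()` — exclusion at AQ ≥ 32. The source description is
  ambiguous between "≥ 32" and "> 32"; the ≥ reading is adopted because
  the retained-sample maximum AQ of 31 and the 51 − 15 = 36 arithmetic
  both require it.
* `dp_classify()` — a task is impaired beyond 2 control SDs in the
  deficit direction, and DP classification requires at least two
  impaired objective tasks. Because a *high* CFPT deviation score is bad,
  the 2-SD rule is mirrored to mean + 2·SD for CFPT; CFMT and FFT use
  mean − 2·SD. Plain z-style cutoffs against the control mean are used
  here, as the screening rule is stated, not Crawford t.

## The session simulator

`generate_session()` draws latencies from a lognormal distribution —
the standard right-skewed phenomenology of reaction times — with median
`base_latency_ms` (default 800 ms) and log-scale spread `latency_sigma`
(default 0.25). The congruency effect is a shift of the log-latency
location on congruent test blocks, so `congruency_effect_ms` is the
median latency reduction in milliseconds and remains interpretable on
the ms scale. Error trials keep their first-keypress latency and add
`error_correction_extra_ms` (default 400 ms) for the corrective
response; anticipatory responses replace the base draw with a uniform
draw on 100–299 ms, guaranteeing they engage the fast-trial rule.
Participant \(i\) uses seed `seed + i`, so cohorts are reproducible and
any single session can be regenerated in isolation.

The default congruency effect of 17 ms was calibrated once, by repeated
simulation, so that the default 180-participant cohort's mean D is close
to 0.082, the published control-sample mean for this task; the suite
checks the calibration within ±0.05 and verifies that mean D is zero
(within Monte-Carlo error) at a null effect and increases monotonically
over effects of 0/50/100/150 ms, at 500 sessions per level.

What the generator does *not* emulate: between-participant variation in
association strength (every simulated participant shares one
congruency effect, so the simulated between-person SD of D, about 0.19,
is smaller than the 0.405 of the real control sample), sequential
effects such as practice or fatigue within a session, latency
autocorrelation, and any stimulus-level structure. Passing tests
therefore demonstrate the correctness of the scoring and inference
machinery under a clean generative model, not distributional fidelity
to any empirical RT dataset.

## Pipeline and problem sizes

`run_score()`, `run_singlecase()`, `run_group()` and `run_screen()`
orchestrate the full chain from trial CSVs (or simulation parameters) to
the fixed-decimal case table, with every participant-level exclusion
logged with its rule, full-precision sidecars next to each rounded
output, and file-level determinism under a fixed seed — the suite
asserts byte-identical reruns. A thin command-line wrapper over these
functions ships in `inst/cli/faceiat.R`.

The test suite's simulation sizes — 500 sessions per calibration level,
1,000 samples for CI coverage, 2,000 for Type-I calibration — were
chosen as the smallest sizes at which the asserted tolerance bands are
comfortably stable across seeds; the whole suite runs in under a
minute on one core.

## Known limitations

* The simulator's homogeneous effect size (above) limits it to
  mean-level calibration; do not use it to emulate control-sample
  variances.
* Percentile ranks are point estimates; no credible or confidence
  limits on abnormality are computed.
* The Spearman p-value is asymptotic; with heavy ties at small n an
  exact method would differ.
* No alternative D-algorithm family (log-transformed or windsorised
  variants) is provided, and screening norms for the battery tasks are
  not shipped — callers supply their own `normative_sample` per task.
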