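---
title: "Comparing direct and indirect recognition sensitivities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing direct and indirect recognition sensitivities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itasense)
options(itasense.verbose = FALSE)
```

## The model

`itasense` tests whether an indirect, RT-based measure of recognition is
more sensitive than participants' explicit reports — an Indirect Task
Advantage (ITA). Everything rests on the equal-variance Gaussian
signal-detection model: on each trial a latent recognition signal is drawn
from one of two unit-separation-scaled normal distributions, and sensitivity
is

$$d' = \Phi^{-1}(\mathrm{HR}) - \Phi^{-1}(\mathrm{FA}).$$

For the direct task, HR and FA are the observed old/new response rates
(`dprime_from_rates()`). For the search task, recognition is only expressed
through RTs: the *true* indirect sensitivity is the RT effect divided by the
trial-level RT standard deviation, $d' = \Delta/\sigma_\varepsilon$. Two
estimators recover it:

**Median-split ideal observer (trial data).** Each participant's selected
search trials are classified against their own pooled median RT:
faster-than-median trials are predicted "repeated", the rest "new"
(`indirect_dprime_from_trials()`). The per-participant median, rather than a
grand median, prevents overall-speed differences from washing out the split;
pooling conditions and blocks gives the observer a stable criterion. The
split is the optimal linear rule for log-normal RTs, so the resulting d'
upper-bounds the recognition sensitivity the RTs can carry — if even this
ideal observer shows no advantage over the explicit reports, no real
observer will.

**Noncentral-t estimator (reported statistics).** When only a paired
$t$-statistic is available, $\hat d' = t \cdot c_{N,K,q^2}$ with

$$c_{N,K,q^2} = \sqrt{\tfrac{q^2 + 4/K}{N}}\sqrt{\tfrac{2}{N-1}}
\frac{\Gamma\!\left(\tfrac{N-1}{2}\right)}{\Gamma\!\left(\tfrac{N-2}{2}\right)}$$

(`estimator_constant()`, log-gamma arithmetic so $N$ in the thousands is
safe). The constant inverts the mean of the noncentral t distribution, so
the estimator is exactly unbiased for the true $\Delta/\sigma_\varepsilon$
— the acceptance suite verifies $|\mathrm{bias}| < 3$ MC SEs over $10^4$
replicates at $d' \in \{0, 0.1, 0.3\}$.

**The variance ratio $q^2$.** The standard error inside a paired $t$ mixes
trial-level noise with genuine between-subject variation of true effects,
$SE = \sqrt{(\sigma^2_\mathrm{effect} + \tfrac{4}{K}\sigma^2_\varepsilon)/N}$.
$q^2 = \sigma^2_\mathrm{effect}/\sigma^2_\varepsilon$ resolves that
underdetermination. With trial data it is estimated by
`estimate_q2()`: trial variance pooled over participant-by-condition cells
(df-weighted), between-subject variance by subtracting the noise
contribution from $N\,SE^2$. The numerator is unbiased only if negative
estimates are allowed, so `q2_hat` is reported unclamped; it is clamped to 0
(with a logged warning path) only where it feeds the constant, which
requires $q^2 \ge 0$. For summary-only studies the default assumption is
`q2 = 0.09` ($q = 0.3$, i.e. true individual sensitivities spread with SD
0.3) — a deliberately *high* value, since larger $q^2$ inflates the indirect
estimate and therefore favours finding an ITA; 0.0225 and 0.25 are the
conventional sensitivity alternates.

## The comparison

$d'_\mathrm{difference} = d'_\mathrm{indirect} - d'_\mathrm{direct}$ is
tested three ways:

* paired one-sample t test across participants (trial mode) or a
  quadrature-combined SE assuming task independence (summary mode, where
  pairing is unavailable);
* the CI decision rule: an ITA is declared only when the *lower* 95% bound
  exceeds 0;
* a one-sided JZS Bayes factor (`jzs_bf_one_sided()`): point null against
  $\delta \sim \mathrm{Cauchy}(0, 1/\sqrt2)$ truncated to positive effects,
  computed by adaptive quadrature of the noncentral-t likelihood over the
  truncated prior. Integrating over $\delta$ with R's noncentral-t density
  is mathematically identical to integrating the JZS variance-mixing
  variable, and accurate to far better than the 2-decimal reporting
  precision. Cut-offs 1/3 and 3 map BFs to "against / inconclusive / for".

**Individual ITAs.** `individual_ita_tests()` replaces low-correlation
arguments (which are confounded by unreliability, learning-rate variability
and nonlinearity) with per-participant tests: search trials are resampled
with replacement within condition (median and classification recomputed each
time), recognition responses likewise, the bootstrap SD serves as SE, and
`difference / SE` is referred one-sidedly to a t distribution with
(total trials − 2) df. The summary proportion carries a Clopper–Pearson CI
(conservative; Wilson available).

## Standard errors: conventions and a documented divergence

Two SE conventions are this package's own choices:

* SE of the summary-based $\hat d'$: $c \cdot \mathrm{SD}$ of a noncentral t
  with $\nu = N-1$ and noncentrality solved from the mean relation
  $\hat\delta = t/b(\nu)$. For the worked example this yields 0.112 and a
  combined difference SE of 0.18 ($t = 0.73$), whereas the original
  reanalysis, using a supplement-derived formula, prints
  $SE_\mathrm{difference} = 0.20$, $t(13) = 0.66$, $p = .52$,
  CI $[-0.29, 0.55]$. Those three printed values are therefore documented
  but never asserted; every other headline number (0.091, 0.24, 0.11, 0.13,
  BF 0.47 at the printed $t = 0.66$) is reproduced exactly.
* SE of a d' from counts: the binomial delta method at the (corrected)
  rates. Tests pin it against parametric-bootstrap oracles (within 5% at
  per-side counts of ~28).

## Analysis policies (benefit of the doubt)

All defaults lean *toward* finding an ITA, so a null result is conservative:

* `epochs = "last"`: late trials carry the largest effect against the
  smallest RT spread. Filtering happens first; the median is then computed
  on the selected trials only. (A running median is deliberately not
  offered.)
* Ties classify as "new" — deterministic and documented; with continuous RTs
  ties are measure-zero.
* Error trials are excluded by default when a `correct` flag exists, kept
  otherwise; no RT trimming by default (optional `rt_range`). Every filter
  is logged (`options(itasense.verbose = TRUE)`).
* Extreme rates use the log-linear correction (+0.5 to all four cells) by
  default: standard, bias-bounded, and keeps d' defined. The raw-count mode
  (`correction = "none"`) errors loudly instead of guessing.

## The simulation world

`simulation_config()` states a single canonical world rather than exposing
dials to chase results: 14 participants, 48 search trials per condition,
12 + 12 recognition trials, a 50 ms effect over 400 ms trial noise
(d' = 0.125), between-subject SD 120 ms (q² = 0.09), and a 2500 ms baseline.
Per participant $i$: $\Delta_i \sim N(\Delta, \sigma^2_\mathrm{effect})$,
search latents $N(\mp\Delta_i/2, \sigma^2_\varepsilon)$ emitted either
additively (Gaussian mode, d' exact by construction; the baseline must
exceed $5\sigma_\varepsilon$ so RTs stay positive — validated, never
clamped) or exponentiated (log-normal mode, honouring real RT shape; the
median split is optimal either way). Recognition evidence is
$N(\pm d_i/2, 1)$ with $d_i = \Delta_i/\sigma_\varepsilon$ against a
per-participant criterion $N(0, \mathrm{criterion\_sd}^2)$ — the
evidence-plus-criterion recipe for binary responses is this package's
choice, as no canonical generative recipe exists for the recognition task.
Under `single_source` the *same* $d_i$ drives both tasks, so the expected
sensitivity difference is exactly zero: the generative null against which
both the group test and the individual bootstrap test are shown to reject at
≈5% (2000-unit calibrations in the acceptance suite). `dual_source` adds
`indirect_extra_dprime` to the search task only, creating a true ITA for
power studies. A two-phase `learning_onset_epoch` option exists to emulate
learning-curve confounds; fitting learning dynamics is out of scope.

What a green test does **not** establish: the generator draws i.i.d. trials
with a stationary effect, Gaussian/log-normal noise, no sequential
dependencies, no display-specific (learned vs. not-learned) structure, no
response bias drift, and balanced designs. Real data violate several of
these; the estimators' behaviour under such violations is untested here.

## Numerical choices

* Inverse normal, gamma and noncentral-t functions come from R's stats
  library; gamma ratios are computed in log space.
* BF quadrature: `integrate()` at `rel.tol = 1e-8`; the ~1e-8 accuracy
  warnings of the noncentral-t density are suppressed as immaterial.
* Degenerate inputs: all-equal RTs classify everything "new", giving
  HR = FA and d' = 0 after correction; a participant emptied by filtering
  or missing a response cell raises an error naming them; `N < 3` is
  rejected by the constant, `N < 4` by its SE (the t variance needs
  df > 2).
* Bootstrap reproducibility: per-participant RNG streams derived from one
  master seed, so results don't depend on participant order or parallel
  chunking.

## Known limitations

* The summary-mode difference SE assumes independence between tasks;
  trial-mode pairing is preferred whenever raw data exist.
* Only binary recognition tasks are supported (quadrant/target-generation
  tasks need a different linking model), and only RT-based indirect
  measures are implemented, though any trial-level scalar would slot into
  the same median-split machinery.
* `q^2` cannot be estimated from reported statistics alone; summary-mode
  conclusions inherit the stated `q2` assumption.
* No meta-analytic pooling across studies is offered: the benefit-of-the-
  doubt biases would accumulate, and each study should carry its own
  evidence.
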