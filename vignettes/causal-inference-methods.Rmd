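---
title: "Bayesian causal inference for audio-visual perception: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian causal inference for audio-visual perception: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avci)
```

## The scientific problem

When a flash and a beep occur in close spatial and temporal register, an
observer must decide - implicitly or explicitly - whether they arose from a
single physical event or from two. If one cause is assumed, the optimal
strategy is to fuse the two sensory estimates weighted by their
reliabilities; if two causes are assumed, each cue should be localized on
its own. `avci` implements the full modeling stack for this problem:
forced-fusion (maximum-likelihood integration) predictions, a hierarchical
causal-inference ideal observer for implicit localization and explicit
common-cause reports, the descriptive psychometric layer used around it,
maximum-likelihood fitting with AIC and explainable-variance model
comparison, and a synthetic-observer simulator that reproduces the trial
schedules of five behavioral experiments so the whole pipeline can be
exercised and validated without any external data.

## The generative model

On a trial with true cue locations $\epsilon_a$, $\epsilon_v$ (degrees,
rightward positive), the observer receives noisy measurements

$$X_a \sim \mathcal N(\epsilon_a, \sigma_a^2), \qquad
  X_v \sim \mathcal N(\epsilon_v, \sigma_v^2),$$

with one $\sigma_v$ per visual reliability level (the stimulus size
manipulation). The observer's prior over source locations has two parts: a
*natural* Gaussian prior per modality,
$\mathcal N(\mu_a, \sigma_{ap}^2)\,\mathcal N(\mu_v, \sigma_{vp}^2)$, and a
*causal-structure* component: with prior probability $p_\mathrm{common}$
both cues share one location ($C=1$, enforced by a delta function),
otherwise the locations are independent ($C=2$).

Both marginal likelihoods are Gaussian-analytic. Writing
$\mathcal N(x;\mu,\sigma^2)$ for the normal density,

$$p(X_a, X_v \mid C=2) =
  \mathcal N(X_a; \mu_a, \sigma_a^2+\sigma_{ap}^2)\,
  \mathcal N(X_v; \mu_v, \sigma_v^2+\sigma_{vp}^2),$$

and for $C=1$ the product of the two sensory likelihoods and the fused
natural prior integrates to

$$p(X_a, X_v \mid C=1) =
  \mathcal N(X_a; X_v, \sigma_a^2+\sigma_v^2)\,
  \mathcal N(m_1; m_p, v_1+v_p),$$

where $(m_1, v_1)$ is the inverse-variance fusion of the two measurements
and $(m_p, v_p)$ the fusion of the two natural priors; the
$\mathcal N(\mu_a; \mu_v, \sigma_{ap}^2+\sigma_{vp}^2)$ normalizer of the
fused prior is divided out. `likelihood_common()` and
`likelihood_separate()` expose these closed forms; the test suite holds
them to a dense-grid integration oracle at relative error below $10^{-4}$.

**Implicit task.** The observer reports the side of the *auditory* source.
Within each causal structure the task prior restricts the (auditory) source
to a half-line; the resulting posterior masses are Gaussian CDFs with
truncated-prior normalizers, combined with a Bernoulli response prior
$p_\mathrm{choice}$, and finally mixed across structures with the cause
posterior $p(C=1 \mid X_a, X_v)$. The response is the category with the
larger posterior (`implicit_decision()`). A point of ambiguity in the
source formulation is whether the choice prior applies before or after
marginalizing the cause variable; `avci` applies the Bernoulli prior to the
category *within each causal branch* and then mixes branches by the cause
posterior. The alternative (a single prior applied after mixing) differs
only through the branch normalizers; the dense-grid oracle in
`tests/testthat/helper-oracles.R` pins down exactly the implemented
reading.

**Explicit task.** The observer reports "common source" when
$L_1\, q > L_2\,(1-q)$, with $q$ (`p_combined`) a single estimable mixture
of $p_\mathrm{common}$, the explicit choice bias, and a task-learning
weight $\alpha_\mathrm{task}$. The three components are not separately
identifiable from explicit reports; `p_combined_from_components()`
evaluates the surface for forward exploration, and the decision is
equivalently a criterion $t$ on the cause posterior with
$q = (1-t)p_c / ((1-t)p_c + t(1-p_c))$ (`p_combined_from_criterion()`).
Deriving the mixture from the category-prior formulation gives, with
$B = p_c(1-p_\mathrm{ch}) + p_\mathrm{ch}(1-p_c)$,

$$q = \frac{p_c\,(2p_\mathrm{ch}-1) + \alpha B}
           {(2p_c-1)(2p_\mathrm{ch}-1) + 2\alpha B},$$

clipped to $[0,1]$. Two limits anchor it: at $\alpha=1$ the report category
coincides with the cause variable, so $q = p_\mathrm{ch}$ exactly; at
$\alpha=0$ the report is unrelated to the cause and the decision degenerates
to the side of the choice prior. Both are asserted in the tests by
comparison with a direct numerical evaluation of the underlying decision
rule.

**Lapses.** After the deterministic decision, with probability
`lapse_rate` the response is replaced by a coin flip that lands on the
positive code (right / common / synchronous) with probability
`lapse_bias`. The generator accepts any lapse rate in $[0,1]$ (degenerate
observers are useful test fixtures); model fits bound it at $0.5$, beyond
which the lapse mixture and the decision rule become mutually
unidentifiable.

## Response probabilities: quadrature design

Model fitting needs $P(\text{response} \mid \epsilon_a, \epsilon_v)$, the
decision rule marginalized over sensory noise. A tensor-product
Gauss-Hermite rule applied directly to the *decision indicator* converges
poorly - the integrand is discontinuous along the decision boundary, and at
order 61 per dimension the error is still several binomial standard errors
of a $10^5$-draw Monte Carlo. `avci` therefore integrates the auditory
dimension in closed form:

* *implicit rule*: at a fixed visual measurement the posterior margin is
  monotone in $X_a$, so the decision region is a half-line whose boundary
  is located by vectorized bisection (tolerance $10^{-4}\sigma_a$, well
  below any quantity of interest) and whose mass is one Gaussian tail;
* *explicit rule*: the log-likelihood ratio is an exact quadratic in
  $X_a$, so the "common" region is a root interval and its mass a
  difference of Gaussian CDFs;
* *unisensory rule*: the decision is a fixed criterion on the measurement
  axis, found once per parameter set, making the response probability a
  single exact Gaussian mass.

Only the visual dimension is left to Gauss-Hermite quadrature (default
order 61 for reported quantities; fitting uses lower orders, see below).
The result matches Monte-Carlo simulation within sampling error everywhere
the test suite looks, and makes the likelihood smooth in the parameters -
important because the optimizer is derivative-free.

## Fitting

`fit_subject()` maximizes the binomial trial likelihood over an
unconstrained transform of the free parameters (log for SDs, logit for
probabilities, logit of rate$/0.5$ for the lapse rate) with seeded
multi-start Nelder-Mead; ties between converged starts break by lowest
negative log-likelihood, then smallest parameter norm. The default free set
follows the tasks present in the data: sensory noise for the observed
modalities and reliabilities (anchored by the unisensory trials of the
joint design), `p_common` and `p_choice_implicit` for implicit audio-visual
data, `p_combined` for explicit data, and the two lapse parameters.
Natural-prior parameters default to fixed broad values
($\mu = 0$, $\sigma_{\cdot p} = 30^\circ$) because, at single-experiment
trial counts, they trade off almost freely against the common-cause prior;
they can be freed through `fit_config(free = ...)`.

Model variants mirror the alternative internal models: forced fusion
(`alt_A`, $p_\mathrm{common} = 1$), no fusion (`alt_B`,
$p_\mathrm{common} = 0$ - the "always two causes" observer), no lapse bias
(`alt_C`), and choice-parameters-only (`alt_D`, everything except lapse
rate, lapse bias and - for implicit data - `p_choice` held at reference
values, typically a control-group fit). Comparison uses
$\mathrm{AIC} = 2k + 2\,\mathrm{NLL}$ (`compare_models()`); goodness of fit
uses explainable variance explained,

$$\mathrm{EVE} = 1 -
  \frac{\mathrm{MSE}_\mathrm{model} - \bar v}{\mathrm{Var}_\mathrm{data} - \bar v},
  \qquad \bar v = \overline{\hat p(1-\hat p)/n},$$

computed on per-condition proportions and reported clipped to at most 1. A
saturated model scores 1, the grand-mean model 0 in expectation, and data
whose variance does not exceed the binomial noise floor is flagged
undefined rather than scored. Confidence intervals are seeded percentile
bootstraps (trials within subject; whole subjects within a cohort), in
place of posterior quantiles from a sampling-based fit - a deliberate
design choice for reproducibility; the bootstrap's 68% coverage is itself
checked by simulation in the test suite.

One behavior worth knowing: on data generated by a forced-fusion observer,
the full model's $\hat p_\mathrm{common}$ must travel to the $1$ boundary,
which on the logit scale is infinitely far. With a finite iteration budget
the estimate approaches but does not reach the boundary, so the full
model's AIC can sit more than the nominal one-parameter penalty above the
fusion variant's. The boundary-consistency tests therefore fix the nuisance
parameters when asserting the boundary pull.

## The synthetic cohort

`make_cohort()` draws per-subject parameters from truncated normal
distributions (`cohort_spec()`) and simulates the requested experiments.
The defaults encode the study conditions the package is built around:

* sensory noise - visual thresholds $1.10$, $4.76$, $13.96^\circ$ for
  high/medium/low reliability (group means of the unisensory fits), with
  auditory noise matching the medium visual level (the design matched
  them); the medium patch size varied across subjects, represented here as
  between-subject spread in $\sigma_{v,\mathrm{med}}$ (SD $1^\circ$), a
  free choice since no distribution is reported;
* inference - control-like $p_\mathrm{common}$ centered at $0.25$ and an
  ASD-like group at $0.75$, the three-fold elevation reported for the
  implicit task; explicit `p_combined` $0.60$ vs $0.40$, encoding the
  compensatory reversal;
* synchrony curves - amplitude/width $0.98/171.68$ ms (control-like) vs
  $0.83/363$ ms (ASD-like), the reference group Gaussian parameters, used as
  generative values for the temporal experiment, which is modeled
  descriptively throughout (a Gaussian synchrony probability plus lapse)
  because the main-text analysis of that experiment is descriptive;
* choice - $p_\mathrm{choice}$ near $0.5$, lapse rate $\approx 0.03$.

Trial schedules reproduce the reference designs exactly: 1680 trials for the
unisensory + fusion experiment (the design's location list names 15
visual positions but its counts require 14; the generator uses the
7 symmetric pairs, whose total matches every stated subtotal), 1512 and
1323 for the implicit and explicit spatial tasks, 23 temporal disparities
$\times$ 25 for the synchrony task, and the 130-condition heading /
object-motion factorial (schedule only - that experiment's observer model
is out of scope). Disparity is auditory minus visual throughout; in the
fusion experiment cues straddle the mean location at $\pm\Delta/2$, in the
spatial causal-inference experiments the auditory cue sits on a speaker and
the visual cue at speaker $-\Delta$.

What the generator does *not* emulate: apparatus timing, the
subject-specific medium patch diameter (only its noise consequence),
session/block structure, learning or fatigue, and any response-time
information. Passing tests therefore establish that the *pipeline*
recovers what it simulates under the model's own assumptions - not that
the model is true of any human observer.

## Numerical choices

* Likelihoods and posteriors in log space; posterior ratios through
  stable log-sum-exp forms; response probabilities floored at $10^{-9}$
  inside the likelihood.
* Exact decision ties break toward the positive code (+1 / common) -
  measure-zero events under continuous noise.
* Gauss-Hermite order: 61 for reported response probabilities; 7-9 inside
  iterative fits (the semi-analytic inner integral keeps even low orders
  accurate to $\sim 10^{-3}$ in the cell probabilities).
* Psychometric fits: bounded L-BFGS-B with 10 seeded starts, tolerance
  $10^{-8}$; degenerate data (all responses identical) returns an explicit
  flag instead of runaway estimates. The descriptive Gaussian curve is
  least squares on proportions (matching its descriptive use), with the
  $R^2<0.5$ flat-report flag mirroring the subject screening rule.
* $R^2$ for screening is $1-\mathrm{RSS}/\mathrm{TSS}$ on per-condition
  proportions, keeping the $0.50$ exclusion threshold interpretable.

## Problem sizes used by the tests and acceptance script

Simulation-backed checks run at deliberately chosen sizes: parameter
recovery uses 20 replicates (tests; 12 in the acceptance script) of the
full joint design at reference trial counts with all eight default
parameters free; cohort group contrasts use 10 (tests; 8 script)
replicates of 3+3-subject cohorts fit as aggregates; AIC comparisons use
10 causal-inference seeds and 8 high-fusion seeds (8 and 6 in the script)
with all sensory parameters free, exactly as the alternative-model
analysis prescribes.
These sizes keep each study's Monte-Carlo error well inside the asserted
margins while remaining small enough to re-run routinely; the frozen
thresholds in the tests were computed from the same seeded oracles the
assertions use.

## Known limitations

* The temporal experiment is generated and analyzed descriptively; no
  temporal ideal observer is included.
* The heading / object-motion experiment contributes only its schedule.
* `p_combined` is the only estimable explicit-task inference parameter;
  fits never attempt to split it into its components.
* Aggregate fits share one $\sigma_v$ per reliability across subjects;
  heterogeneous cohorts therefore absorb between-subject sensory variance
  into the choice and lapse parameters.
* With priors fixed at their defaults, strongly non-central natural priors
  in the generating observer would bias $\hat p_\mathrm{common}$; freeing
  the prior parameters is supported but slow at desk scale.
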