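---
title: "Partially hidden two-state modelling of Minimal Disease Activity"
author: "mdahmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partially hidden two-state modelling of Minimal Disease Activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdahmm)
```

## The composite outcome and when it can be decided

Minimal Disease Activity (MDA) in psoriatic arthritis is defined by an
m-of-n rule: at least 5 of 7 criteria satisfied, where the criteria are
inclusive cutpoints on eight clinical variables (the skin criterion is an
OR of two of them: PASI ≤ 1 *or* body surface area ≤ 3%).  With
components missing, the composite is decided exactly when certainty is
possible: ≥ 5 criteria observed-and-satisfied gives MDA, and ≥ 3
observed-and-failed gives No-MDA, because 5 satisfied criteria are then
unattainable.  The two rules are mutually exclusive (counts cannot exceed
7) and exhaust the certain cases; everything else is indeterminate.

Two decisions here were genuinely open and are package conventions:

* **Partial observation of the OR criterion.**  If only PASI is recorded
  and exceeds its cutpoint, the unrecorded BSA could still satisfy the
  criterion, so the criterion is *undecided*, not failed.  Failure
  requires both components observed and both failing.  "Observed" in the
  determinability tabulation likewise means *decidable*.
* **Recorded precision.**  Criteria compare the values as recorded; the
  rounding of VAS scores to integers (and the ×100 integer coding of HAQ
  and PASI) belongs to the emission model only.

Both `m_required` and every cutpoint are configurable
(`mda_criteria()`); the shipped defaults are the standard definition.

## The model

The MDA process is a time-homogeneous continuous-time Markov chain on
{No-MDA, MDA} with intensities
$\lambda_{\text{No}\to\text{MDA}}(x) = \lambda_{01} e^{x\beta}$ and
$\lambda_{\text{MDA}\to\text{No}}(x) = \lambda_{02} e^{x\gamma}$, time in
**years** throughout.  Covariates are held constant over each inter-visit
interval at their value at the interval's start — the usual panel-data
convention; in the shipped examples they are baseline indicators, so this
is exact.

At each visit the eight defining variables are modelled conditionally
independently given the state: the two patient VAS scores, rounded
half-to-even to 0–10, as Binomial(10, $p_{kr}$); the remaining variables
(integers once HAQ and PASI are multiplied by 100) as negative binomial
with size $n_k$ *shared across states* and state-specific success
probability $p_{kr}$ — the sharing follows the way the parameters are
indexed, and a per-state size is a one-line change if wanted.  The mean
convention is $n(1-p)/p$, so $p$ near 1 means low counts; degenerate
limits are avoided by clipping probabilities to $[10^{-8}, 1-10^{-8}]$.
BSA is included as the eighth variable and modelled as a negative
binomial on integer percent, consistent with the treatment of the other
count-like bounded scores.

Missing components are assumed missing at random given the observed ones
(plausible here because much of the missingness is a fixed
administration schedule), so a visit's emission factor multiplies the
observed components only, and a fully missing visit contributes factor 1.
Missingness indicators are deliberately **not** modelled.

The likelihood sums, per patient, over all latent state paths consistent
with the observed determinations:
$$\sum_{\{S\}} \Pr(S_1\mid f)\, f(y_1\mid S_1)
  \prod_{j>1} \Pr(S_j \mid S_{j-1})\, f(y_j \mid S_j).$$
A determinable visit acts purely as a path constraint — its emission
factor is still included, but the determination itself is never counted
as an extra data term, which would double-count the outcomes it was
computed from.  The initial distribution $f$ is estimated on the logit
scale by default and can be fixed (`fix_f`).  The complete-case
comparator is the standard panel likelihood over determinable visits
only, conditioned on each patient's first determinable state; dropping is
at visit level, not patient level.

## Evaluation and fitting

The forward recursion propagates a 2-vector through interval transition
matrices and emission factors, zeroing the component excluded by a known
determination, and rescales at every visit (log-sum accumulation), so
underflow cannot occur on realistic series.  For the two-state chain,
$P(t)$ uses the closed form
$P_{12}(t) = \frac{\lambda_1}{\lambda_1+\lambda_2}(1-e^{-(\lambda_1+\lambda_2)t})$;
the general matrix exponential is retained for the four-phase model and
as a cross-check (the two agree to $10^{-12}$ in the test suite, and the
forward value matches brute-force path enumeration to $10^{-10}$).

Maximisation is BFGS (`stats::optim`) on an unconstrained working scale
(log rates and sizes, logit probabilities, identity for β and γ), with
numerically differenced gradients, a numerical Hessian for the
asymptotic covariance, and multiple jittered starts (default 3) as a
guard against local optima.  Starting values: rates from a complete-case
fit, emission parameters from state-stratified moments on determinable
visits, β = γ = 0.  Latent-state labels are anchored by the determinable
visits (state 2 ≡ MDA); fitting the partially hidden model to data with
no determinable visit is refused rather than risking label switching.
Standard errors for derived quantities (mean sojourns $1/\hat\lambda$,
intensity ratios $e^{\hat\beta}$) use the delta method on the log scale.

## Sustained-MDA summaries

Expected time in a state over $[0,T]$ and expected numbers of entries
have closed forms (integrated occupancy probabilities; entries = rate ×
time in the source state).  Sustained quantities — time and spell counts
restricted to MDA sojourns of full duration ≥ 1 year — do not, and are
estimated by simulating alternating exponential sojourns for (by
default) 100,000 patients over a 10-year horizon.  Conventions, chosen to
keep the summary internally consistent:

* a spell counts if it **starts** before the horizon; the initial No-MDA
  spell is included in its count (a switch in the code if not wanted);
* spell classification (short/long) uses the **full** sojourn length —a
  sojourn in progress at the horizon is followed to its end (the overrun
  rule) — while all *time* totals are truncated at the horizon;
* "time in sustained MDA" is the within-horizon time beyond the first
  threshold-year of each MDA sojourn, which makes it numerically equal
  to "time in later years of MDA" and lets short + long = total and
  first-year + later-years = total hold on every run (asserted in the
  tests).

Confidence intervals are parametric bootstrap: draw parameter vectors
from the asymptotic normal on the working scale (default 1000 draws),
recompute the summary per draw (closed forms where available, reduced
simulation sizes otherwise), and take percentile intervals.  Group
comparisons reuse the same random-number stream per group (common random
numbers), which sharpens the ratio and odds-ratio estimates of the
relative-prognosis table; visit probabilities are compared as odds
ratios, which can look extreme when the probabilities are near 1 even
though the absolute differences are small.

The truncation matters: expected time in MDA over 10 years is *not* the
mean sojourn times the expected number of entries (the tests assert the
inequality), which is why the simulation machinery exists at all.

## Phase-type robustness check

To probe the Markov (exponential-sojourn) assumption, each state is
split into two latent phases — progression a→b within a state, exit from
either phase to phase a of the other state — giving a four-phase hidden
Markov model with 6 rates whose macro-state sojourns are phase-type.  It
is fitted to the determinable visits only (an indeterminate visit is a
validation error in this path), conditioning on the first observation in
phase a; with the progression rates at zero it reduces *exactly* to the
two-state complete-case likelihood, so the likelihood gain is a direct
nesting diagnostic (non-negative up to optimiser tolerance, asserted on
every fit pair).  Phase labels are fixed by the entry-phase-a convention.
The forward step is evaluated for all patients at once through one
eigendecomposition of the 4×4 generator per likelihood call, falling
back to the matrix exponential near defective generators; numerically
invalid transition matrices are rejected outright, and log rates are
bounded to ±12 so the optimiser cannot wander into overflow.

## The synthetic cohort generator

`cohort_design()` emulates the observation structure of a large PsA
clinic cohort: 856 patients, visit gaps uniform on 0.5–1 years,
exponential follow-up with median 3 years capped at 10 (median ≈ 5–6
visits), HAQ and the patient global VAS on a deterministic
every-other-visit schedule with a random phase (≈ 50% missing), the
other six variables missing independently at 15%, and baseline
covariates with clinic-like prevalences.  Masks are drawn before any
outcome value is generated, so missingness is at random by construction.

The true parameters are **synthetic**, not estimates from any data: mean
sojourns of 2.3 (No-MDA) and 4.5 (MDA) years with f = (0.45, 0.55), and
emission parameters giving plausible marginal distributions, chosen once
so that the determinable-visit mix is about 39% MDA / 23% No-MDA / 38%
indeterminate — the realistic regime for this design.  One deliberate
mismatch: simulated negative-binomial draws are capped at each variable's
clinical maximum (e.g. HAQ ≤ 3) while the likelihood uses the untruncated
pmf; the affected mass is far below $10^{-3}$ and invisible to the fits.

Passing the recovery tests on these cohorts shows the estimator is
consistent and the intervals calibrated *under the model's own
assumptions* with this observation structure.  It does not establish
robustness to informative visit times, missingness that depends on the
unobserved values, residual dependence between outcomes given the state,
or non-Markov dynamics — only the phase-type check addresses the last of
these, and only on determinable visits.

## Problem sizes and numerical conventions

The shipped tests use cohorts of 20–600 patients, simulations of
3·10⁴–10⁵ histories, bootstrap runs of 50–300 draws, and a 100-replicate
coverage study of the closed-form bootstrap — sizes at which Monte-Carlo
error (±3 standard errors) is well below the effects being checked while
the whole suite stays interactive.  The acceptance script simulates
100,000 histories per parameter set.  Ties at criterion cutpoints are
inclusive; rounding is half-to-even (R's `round`); probabilities are
clipped at $10^{-8}$; a singular observed information matrix yields point
estimates with a warning rather than an error; optimiser non-convergence
is flagged on the result, not raised.

## Known limitations

Time-homogeneous intensities only (no piecewise-constant extension);
no modelling of missingness indicators; conditional independence of the
outcomes given the state is an approximation; the phase-type check is
confined to fully determinable sequences; and fitted values for any real
clinic cohort are outside the package's scope — the package provides the
machinery, synthetic evidence of its correctness, and reproduction of
published-scale summary tables from their sojourn inputs.
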