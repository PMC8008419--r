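---
title: "Surrogate-assisted sample size determination: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-assisted sample size determination: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssdopt)
```

## The problem

Choosing a sample size for a complex trial is rarely a one-dimensional
search. A cluster randomised trial trades the number of clusters against
the number of participants; a multilevel trial with therapists and doctors
adds an allocation ratio and a nominal test level. The operating
characteristics (OCs) that constrain these choices — power and type I
error — often have no closed form and must be estimated by simulating the
trial and its analysis, which makes every candidate design expensive to
assess. `ssdopt` treats this as constrained multi-objective optimisation
over a bounded design box $X$:

$$\min_{x \in X} \; f_i(x), \quad i = 1,\dots,B, \qquad
  \text{s.t.} \; g_j(x) = \mathrm{OC}_j(x) - \tau_j \le 0,$$

where the objectives $f_i$ (totals of participants, clusters, therapists,
doctors) are cheap and deterministic, while each constraint OC must be
estimated by Monte Carlo. Because objectives conflict, the solution is not
a single design but an *approximation set*: mutually nondominated,
currently-feasible designs approximating the Pareto set. Its quality is
the dominated hypervolume $H(A)$ with respect to a reference point worse
than any plausible design.

## Monte Carlo error model

An OC estimate from $N$ binary replicates is unbiased with standard error
$\omega = \sqrt{\hat p(1-\hat p)/N}$. The estimate is treated as the true
value plus $N(0, \omega^2)$ noise. Two numerical choices:

* $\hat p$ is clipped to $[0.5/N,\, 1 - 0.5/N]$ before computing
  $\omega$, so a run with 0 or $N$ successes still carries strictly
  positive noise — an estimate of exactly 0 is an artefact of finite
  $N$, not certainty, and the surrogate's noise diagonal must stay
  positive definite.
* Every evaluation consumes a numbered substream of a single root seed
  (`rng_stream()`), so a checkpointed run resumed mid-way replays the
  remaining stream and reproduces an uninterrupted run exactly. This is a
  shipped test, not an aspiration.

## The Gaussian process surrogate

Each constraint OC is modelled by Gaussian process regression with the
squared-exponential kernel
$k(x, x') = \sigma \exp\{-\sum_j (x_j - x_j')^2 / \lambda_j^2\}$ and a
*fixed* heteroscedastic noise diagonal $\Delta_{ii} = \omega_{(i)}^2$ —
the known Monte Carlo variances, not an estimated nugget. Hyperparameters
$(\sigma, \lambda_1, \dots, \lambda_D)$ maximise the log marginal
likelihood.

Design choices worth knowing:

* **Input scaling.** Raw parameters span wildly different ranges
  (e.g. $n \in [100, 500]$ vs $a \in [0.05, 0.2]$); inputs are affinely
  mapped to the unit box before the kernel sees them, so length-scales are
  comparable across dimensions.
* **Centred targets.** The zero-mean formulas are applied to residuals
  about the empirical target mean, stored as an offset and added back at
  prediction. Raw OCs live near their thresholds, far from zero, and a
  literal zero prior mean would distort extrapolation.
* **Hyperparameter search.** Optimisation runs over $\log \sigma \in
  [\log 10^{-6}, 0]$ and $\log \lambda_j \in [\log 0.01, \log 10]$
  (unit-box scale), L-BFGS-B with an analytic gradient from 10 starts (a
  quasi-random design plus a median-distance heuristic); the contract is
  "best of starts". If every start fails, median-heuristic length-scales
  are used with a warning.
* **Jitter.** Factorisation first tries the noise diagonal alone, then
  adds jitter $10^{-8}$ growing tenfold to $10^{-4}$ only on failure;
  failure beyond that names the offending hyperparameters.

OC probabilities are modelled on their natural scale, untransformed. Near
0 or 1 a logit-type transform could stabilise variance, but thresholds of
interest (0.1, 0.2) sit comfortably inside the range and the heteroscedastic
noise already encodes the boundary shrinkage.

## Feasibility and acquisition

A design is *deemed feasible* when the upper $p$-quantile of each
constraint's predictive distribution is non-positive:
$q(x) = m + \Phi^{-1}(p)\, s \le 0$. The quantile level defaults to
$p = 0.9$ — conservative but not extreme; it is configurable and logged,
and fixed for a whole run.

Before spending $N$ replicates on a candidate, the post-evaluation
quantile $q_+$ is itself uncertain; it is normal with

$$m_+ = m + \Phi^{-1}(p) \sqrt{\frac{\omega^2 s^2}{\omega^2 + s^2}},
\qquad
s_+^2 = \frac{(s^2)^2}{\omega^2 + s^2},$$

where $\omega$ is the planned evaluation's error, computed from the GP
mean of the OC clipped to $[0.001, 0.999]$. Two limits pin this down and
are shipped as tests to $10^{-10}$: a perfect evaluation
($\omega \to 0$) gives $q_+ \sim N(m, s^2)$; an uninformative one
($\omega \to \infty$) leaves $q_+ = q(x)$ with certainty. The acquisition
function multiplies the hypervolume gain of the candidate's (deterministic)
objective vector by the probability the candidate will be deemed feasible
after evaluation:

$$EI(x) = \left[H(A \cup \{f(x)\}) - H(A)\right]
  \prod_{j=1}^{C} \Phi(-m_{j,+} / s_{j,+}).$$

One subtlety: the "more samples help" intuition holds only for designs
whose mean is feasible but whose quantile is not yet — information then
pulls the quantile down towards the mean. For a design already deemed
feasible, information can only put that status at risk, so the
confirmation probability *decreases* towards $\Phi(-m/s)$ as $N$ grows.
Both regimes are tested.

$EI$ is maximised by particle swarm over the continuous box (swarm 40,
200 iterations, inertia 0.7298, cognitive/social weights 1.49618,
reflecting bounds; all configurable). PSO is used because the EI surface
is multi-modal and gradient-free search is robust to its plateaus; when
EI is zero everywhere the swarm visited (e.g. all mass already explored),
the search falls back to the visited point with the highest product of
feasibility probabilities and flags the fallback in the log.

## Hypervolume computation

Exact, for two and three objectives: the 2-D case is the sorted staircase
sum; the 3-D case sweeps slices of the third objective, each slice a 2-D
staircase — chosen over inclusion–exclusion for numerical robustness at
the few hundred points a run can accumulate. Four or more objectives are
explicitly unsupported. Ties: a candidate equal in all objectives to a
member is treated as dominated, keeping sets minimal; objective-space
duplicates keep the first-evaluated design, and the log retains the rest.
The default reference point is the per-objective maximum over the box
corners times 1.1; any point worse than all candidate designs gives the
same rankings.

## The optimisation loop

`run_ego()` evaluates a Sobol initial design of $E$ points (default ten
per dimension, capped at the iteration count so the initial phase uses at
most half the budget), then iterates: fit one GP per constraint to all
data so far, maximise EI, round integer dimensions half-up, evaluate, and
refresh the approximation set by recomputing every design's feasibility
quantile under the current GPs — new data can evict a design that
previously looked feasible. A proposal that rounds onto an
already-evaluated design pools its replicates with the old ones
(successes and $N$ add; the noise entry shrinks), so budget is conserved
exactly at $(E + \text{iterations}) \times N \times C$ simulator draws.

The Sobol generator is built from the Joe–Kuo direction-number tables
(dimensions up to 10) with a seed-driven random digital shift; the shift
preserves the dyadic balance property (tested: 8 points always place 2 in
each quadrant) while giving independent replications. Collisions after
integer rounding are replaced by subsequent sequence elements.

Termination is a fixed iteration count — the natural budget notion when
each iteration costs $N \times C$ simulated trials. Checkpoints (plain
JSON: archive, log, substream counter, GP hyperparameters, embedded
config) are written after every evaluation, and `resume_ego()` /
`ssd-opt resume` continue a run bit-reproducibly, so "more iterations"
is always available after inspecting a trajectory.

The comparator, `run_fixed_design()`, evaluates one Sobol batch,
discards designs whose Monte Carlo interval (default two-sided 95%,
$z = 1.96$) is not entirely below the nominal threshold, and returns the
nondominated survivors.

`ego_diagnostics()` reports, for each post-initial evaluation, the
standardised prediction error
$(\hat y - m) / \sqrt{s^2 + \omega^2}$ of the surrogate that proposed the
point; values beyond $\pm 3$ flag a surrogate that should not be trusted
without refitting or rescaling.

## Built-in problems

**Cluster randomised trial.** Outcome
$y_{ij} = \beta_0 + \beta_1 t_i + u_j + e_i$ with
$u_j \sim N(0, \sigma_B^2 = 0.05)$, $e_i \sim N(0, \sigma_W^2 = 0.95)$,
analysed by a one-sided two-sample t-test on cluster means at
$\alpha = 0.025$; design parameters $k \in [10, 100]$ clusters and
$n \in [100, 500]$ participants per arm; objectives $(2n, 2k)$; type II
error constrained at 0.1. Cluster means have variance
$\sigma_B^2 + \sigma_W^2 / m$ with $m = n/k$, so power is a noncentral-t
tail probability — a closed form that makes this problem the package's
truth oracle: `cluster_true_pareto()` scans all 91 × 401 integer designs
exhaustively. The default effect is $\delta = 0.3$; with total variance 1
this is a standardised difference, a conventional "small-to-moderate"
effect in this setting, and it is a configuration field everywhere. The
simulator balances cluster sizes when $k \nmid n$ (sizes differ by at
most one), which the equal-$m$ closed form ignores; the discrepancy is
far below Monte Carlo resolution at the tested designs.

**Two-endpoint multilevel trial.** Two correlated continuous endpoints;
therapists partially nested (intervention arm only, random effect on the
treatment indicator), doctors crossed with arms; bivariate therapist,
doctor and residual effects with marginal variances
$\sigma_T^2 = 0.19$, $\sigma_D^2 = 0.37$, $\sigma_W^2 = 3.29$ and
cross-endpoint correlations 0.9; effects 1.10 per endpoint under the
alternative. Intervention patients are assigned round-robin to therapists
and round-robin to doctors (cross-classified); control patients
round-robin to doctors; $n_0 = \mathrm{round}(r\, n_1)$. Each endpoint is
analysed with its own univariate mixed model — deliberately misspecified
by ignoring the cross-endpoint correlation, which is exactly the
situation that forces simulation-based power assessment — and the trial
is positive if either endpoint's one-sided likelihood ratio test rejects
at the nominal level $a$ (a `"both"` rule is available as a
configuration switch). That decision rule inflates the familywise type I
error into $[a, 2a]$, which is why $a$ is itself a design parameter,
constrained at 0.2 while power is constrained at 90%.

The mixed-model fitter maximises the marginal Gaussian likelihood with
fixed effects and the residual variance profiled out by generalised least
squares; the two variance ratios are searched on the log scale by
Nelder–Mead from three starts. The random-effects structure has rank
$k + j$, so all quadratic forms go through the Woodbury identity on a
$(k+j) \times (k+j)$ system — one pass of cross-products over the data,
then each likelihood evaluation is effectively free. ML rather than REML
because the likelihood ratio test compares maximised likelihoods across
nested mean structures. The one-sided p-value uses the signed-root
equivalence: half the two-sided $\chi^2_1$ p-value when the effect
estimate is beneficial, else one minus half. Non-convergence after all
restarts is recorded as a non-rejection with a flag (conservative for
power, anti-conservative for size; it essentially never triggers in the
tested regimes). The fitter matches `lme4` ML fits to numerical precision
on identical datasets — shipped as a cross-check test, with `lme4` never
in the computational path.

A caution the tests made explicit: ML variance components are biased low
when a component is informed by few clusters. At the example's
$k = 10$ therapists the therapist variance is underestimated by roughly
30% on average (identically so by `lme4`); recovery within 15% holds once
the design is large in the cluster counts as well (e.g. 30 therapists and
doctors). This is a property of the estimator, not a defect of either
implementation.

## What the generators do and do not emulate

The built-in simulators generate exactly the model the OCs are defined
on: Gaussian effects at every level, balanced round-robin allocation, no
attrition, known nuisance variances, and a point MCID. Passing tests
therefore demonstrate that the optimiser solves the stated design problem
efficiently; they say nothing about misspecified variance components,
missing data, unbalanced accrual or uncertainty in the MCID — for those,
the user supplies a simulator that generates them, which is the point of
the simulator contract (any `function(design, hypothesis)` returning a
0/1 reject indicator plugs in).

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` rerun the full pipeline at
sizes chosen to exercise every code path while remaining comfortable to
run routinely: the method comparison uses the study conditions of the
analytic example (initial design 20, 30 iterations, $N = 100$ per
evaluation, 50-point fixed designs) over 10–20 independent seeds;
calibration checks use $N = 10^4$ replicates for the cluster trial and
$N$ in the hundreds-to-thousands for the multilevel trial at small
designs. Distributional summaries (median hypervolumes, set sizes,
validity proportions) are reproduced directionally — EGO above fixed
design at equal budget — rather than numerically, since reference
distributions depend on an effect size that is a free parameter here.

## Known limitations

* Hypervolume (and therefore EI) is exact only for 2–3 objectives.
* One evaluation per iteration; no batch acquisition or look-ahead.
* No variance reduction across designs (no common random numbers); each
  evaluation is an independent binomial experiment by design, which is
  what the noise model assumes.
* The GP is stationary and very smooth; OC surfaces with kinks (e.g.
  induced by discrete analysis switches inside the simulator) will be
  tracked only through the noise term.
* Constraint adjustment mid-run is supported only via checkpoint, edit,
  resume; there is no interactive loop.
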