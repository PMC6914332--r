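---
title: "Gaze-weighted linear accumulator modelling with glamr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaze-weighted linear accumulator modelling with glamr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

glamr implements the gaze-weighted linear accumulator model (GLAM) of
multi-alternative value-based choice. The model takes, per trial, the item
values $r_i$ (e.g. liking ratings), the fractions $g_i \in [0,1]$ of total
trial time the decision maker spent fixating each item, and the observed
outcome (chosen item, response time), and describes the joint distribution
of choices and response times as a linear stochastic race.

Three transformations build the race inputs:

1. **Gaze-weighted average absolute signal.** While an item is fixated its
   value signal is $r_i$; while any other item is fixated the signal is
   discounted by the gaze bias $\gamma \le 1$. Averaged over the trial,
   $\bar A_i = g_i r_i + (1 - g_i)\,\gamma\, r_i$. With $\gamma = 1$ gaze
   has no influence at all; with $\gamma < 0$ evidence is actively lost
   while an item is unattended.
2. **Relative signal.** $R^*_i = \bar A_i - \max_{j \ne i} \bar A_j$, the
   difference to the item's best competitor. Exactly one item has
   $R^*_i \ge 0$ (ties excepted).
3. **Logistic scaling.** $R_i = 1 / (1 + e^{-\tau R^*_i}) \in (0, 1)$ with
   sensitivity $\tau \ge 0$, so the representation is most sensitive to
   differences near zero. $\tau = 0$ erases all value information
   ($R_i = 0.5$ for every item).

Each item then drives an independent linear accumulator with drift
$v R_i$, Gaussian increment noise with standard deviation $\sigma$, and
absorbing boundary $b$. To keep the model identified $b$ is fixed at 1.
The first-passage time of a single accumulator is inverse-Gaussian (Wald)
with mean $\mu_i = b / (v R_i)$ and shape $\lambda = b^2 / \sigma^2$; the
joint density that item $i$ wins at time $t$ multiplies its first-passage
density by every competitor's survival probability,
$p_i(t) = f_i(t) \prod_{j \ne i} (1 - F_j(t))$.

Finally, a fixed-rate contaminant process absorbs lapses and accidental
button presses: with probability $\varepsilon$ (default 0.05, settable but
never estimated) the response is uniform over the $N$ items and over the
subject's empirically observed RT interval,
$u_s(t) = 1 / (N (\max \mathrm{rt}_s - \min \mathrm{rt}_s))$. The trial
likelihood is the mixture
$l_i(t) = (1 - \varepsilon)\, p_i(t) + \varepsilon\, u_s(t)$. Note that
$u_s$ is a density on the observed RT interval only; outside it the
contaminant contributes nothing.

## Parameters, priors and model kinds

| parameter | meaning | support used for estimation |
|---|---|---|
| $v$ | drift scaling (boundary units / s) | $U(0, 4)$ |
| $\gamma$ | gaze bias weight (unitless) | $U(-2, 1)$ |
| $\sigma$ | accumulation noise s.d. (boundary units / $\sqrt{s}$) | $U(0, 4)$ |
| $\tau$ | logistic sensitivity (1 / value unit) | $U(0, 10)$ |

`glam_model()` builds three estimation variants. *Individual* fits an
independent parameter set per subject under the uniform priors above;
*pooled* shares one set across all subjects. *Hierarchical* draws each
subject's parameter from a truncated normal group distribution
$\theta_s \sim \mathcal{TN}(\mu_\theta, \sigma_\theta)$ (truncated to the
uniform support above), with weakly informative truncated-normal
hyperpriors $\mathcal{N}(M, f \cdot SD)$ on $\mu_\theta$ and
$\sigma_\theta$, bounded between sensible limits. The default locations
and base scales (for $v_\mu$: $M = 0.63$, $SD = 0.26$ on $[0,2]$, and so
on; see `glam_priors()`) summarize group-level estimates published for
four empirical datasets; the vagueness factor $f$ (default 10) widens them
so they stay weakly informative. Location and scale are the
*pre-truncation* mean and standard deviation — the conventional reading of
the $\mathcal{N}(M, f \cdot SD)$ notation; the post-truncation moments
differ and are what the prior-predictive tests check against analytically.

`depends_on` splits a parameter by the levels of a factor column. A factor
is treated as between-subject exactly when every subject exhibits a single
level; otherwise it is within-subject and each subject receives one
parameter per level it exhibits. In hierarchical models the split is at
the group level (one $\mu_\theta, \sigma_\theta$ pair per level). `fixed`
removes a parameter from sampling; for individual models a per-subject
vector of fixed values is accepted. The common no-gaze-bias variant is
`fixed = list(gamma = 1)`; with $\gamma = 1$ the likelihood is exactly
invariant to permutations of the gaze vector (the implementation
short-circuits the gaze arithmetic in this case so the invariance holds in
floating point, not just algebraically).

## Estimation

**MCMC (default).** Adaptive random-walk Metropolis, updating one scalar
parameter at a time. Proposal scales adapt toward a 0.44 acceptance rate
in windows of 50 iterations during the tuning phase (damped over windows)
and are frozen before the retained draws, so the kept chain satisfies
detailed balance. Hierarchical models use the same scheme as
Metropolis-within-Gibbs over subject-level parameters and group-level
means/standard deviations; subject-level likelihoods are cached so one
sweep costs one likelihood evaluation per subject-parameter. Chains start
from jittered prior mid-range draws (individual/pooled) or jittered
hyperprior locations (hierarchical) — dispersed enough for split-$\hat R$
to be meaningful, reproducible under a seed. Convergence is summarized by
split-$\hat R$ and an autocorrelation-based effective sample size (Geyer
initial-positive-sequence truncation); we recommend the usual
$\hat R < 1.05$ screen, which `glam_cli fit` enforces by exit status.

**Variational approximation.** `fit_vi()` fits a mean-field Gaussian on
logit-transformed (box-unconstrained) parameters by stochastic gradient
ascent on the ELBO (Adam, reparameterization gradients; the
log-posterior gradient is taken by central finite differences, which is
cheap in these few-dimensional spaces). It is fast but ignores posterior
correlations and is flagged approximate; MCMC is recommended for final
analyses. It covers individual and pooled kinds; hierarchical models are
MCMC-only.

**Point estimates.** The MAP reported by `extract_estimates()` is the mode
of a Gaussian-kernel density estimate of the marginal samples (512-point
grid), a robust convention for sample-based mode reporting; intervals are
95% highest-posterior-density intervals computed as the shortest
contiguous interval over the sorted samples (unimodality assumed).
Degenerate posteriors (all draws equal, e.g. under per-subject fixing)
return that value with a zero-width interval.

## Model comparison and contrasts

`compare_models()` computes WAIC or PSIS-LOO from the pointwise (one
trial = one unit) log-likelihood matrix, on the deviance scale where lower
is better, with standard errors from the pointwise spread and the
difference-to-best standard error from paired pointwise differences.
Model weights are Akaike-style, $w_m \propto \exp(-\tfrac12 \Delta_m)$,
normalized per subject — one standard convention among several; the
comparison table (model, WAIC, pWAIC, dWAIC, weight, SE, dSE, var_warn)
flags pointwise variances above 0.4 as unreliable. PSIS-LOO smooths the
importance-weight tails with a generalized Pareto fit
(profile-likelihood estimator) and flags tail shapes $\hat k > 0.7$.
WAIC is cross-checked in the test suite against the defining
$-2(\mathrm{lppd} - \sum_i \mathrm{var}_i)$ formula computed
independently.

`compare_parameters()` contrasts posterior samples between factor levels:
group-level means for hierarchical fits, per-subject level parameters for
individual fits. Each row reports the mean difference, the fraction of
posterior mass above zero (ties split, so a self-contrast reports exactly
0.5), and the 95% HPD of the difference.

## The synthetic cohort generator

`simulate_group()` is the package's data engine for power analyses,
recovery studies and the test suite. It emulates a liking-rating choice
task: item values i.i.d. uniform on the integers 1–10 (the scale on which
comparable parameter estimates are conventionally obtained), and gaze
vectors drawn from a symmetric Dirichlet(1), *independent of the values*.
Per-subject parameters are either supplied, drawn from truncated normals
centred on published group-level estimates (the default population:
$v \sim \mathcal{TN}(0.63, 0.26)$, $\gamma \sim \mathcal{TN}(0.12, 0.35)$,
$\sigma \sim \mathcal{TN}(0.27, 0.05)$,
$\tau \sim \mathcal{TN}(1.03, 0.62)$, truncated to the uniform supports),
or — for hierarchical cohorts — drawn from user-specified group means and
standard deviations. Choices and RTs come from the exact race sampler:
one inverse-Gaussian variate per accumulator (Michael–Schucany–Haas
transformation, implemented in the cancellation-free small-root form so
extreme means cannot round to non-positive times) and the argmin wins.
This is exact because the racers are independent; a discrete-time Euler
simulation of the accumulator equation is kept only as an independent
oracle in the tests. Contaminant trials are injected at rate
$\varepsilon$; since no empirical RTs exist yet, their uniform RT interval
is the race component's own 1st–99th percentile range, obtained from the
closed-form race RT distribution $1 - \prod_i (1 - F_i(t))$ by
root-finding.

What the generator does *not* emulate: fixation sequences (only trial-level
gaze fractions), gaze that depends on value (empirically, gaze and value
are correlated), value-rating noise, or non-stationarity across a session.
Passing recovery tests on generated data therefore shows the estimation
machinery is sound under the model's own assumptions — not that the model
is correct for any particular empirical dataset, which should be checked
per dataset with `parameter_recovery()` and posterior predictions.

## Numerical choices

- All densities are evaluated in log space. The inverse-Gaussian CDF is
  computed in its standard two-term normal-CDF form with the
  $e^{2\lambda/\mu}\Phi(\cdot)$ product evaluated as
  $\exp(2\lambda/\mu + \log\Phi(\cdot))$ — the combined exponent is
  provably non-positive, so it cannot overflow; the CDF is validated
  against quadrature of the density to $10^{-6}$ in the tests.
- Survival factors $1 - F_j(t)$ are floored at $10^{-300}$ before taking
  logs; drifts are floored at $10^{-10}$ (relevant only when $\tau R^*$
  underflows the logistic).
- Exact ties in $\max_{j\ne i}$ need no special handling: $R^* = 0$ maps
  to $R = 0.5$.
- No RT censoring is applied during fitting; $p_i(t)$ is defined for all
  $t > 0$.
- The mixture log-likelihood uses log-sum-exp; a non-finite intermediate
  raises an error naming the trial and parameter values rather than
  propagating NaNs into the sampler.

## Study sizes used in the test suite

The suite exercises the full workflows at sizes chosen to keep the
statistical checks sharp while remaining desk-scale: parameter recovery
with 10 subjects × 300 trials × 3 items (2000 tune + 2000 draws, 2
chains; ≥ 90% of subject×parameter cells must cover the generating value),
model recovery with 6 subjects of which 2 have $\gamma = 1$ (≥ 5/6
correctly classified by WAIC), and a hierarchical three-group contrast
with 5/10/15 subjects × 50 trials and group $\gamma$ means of 0.7 / 0.1 /
−0.5 (all pairwise group-level $\gamma_\mu$ HPDs exclude zero; $v_\mu$,
$\sigma_\mu$, $\tau_\mu$ HPDs include zero). Sampler agreement checks run
at $10^5$ analytic draws and $10^4$ Euler draws with step
$\Delta = 10^{-3}$.

## Known limitations

- Fixation-sequence (scanpath) modelling is out of scope; only trial-level
  gaze fractions enter the likelihood.
- $\varepsilon$ is fixed, never estimated, and the contaminant interval is
  per-subject empirical (observed RT range); pooled alternatives are not
  offered.
- The hierarchy is centred; for very small groups with tight group
  standard deviations, mixing can be slow — increase `tune`/`draws`.
- Metropolis sampling needs more draws than gradient-based samplers for
  the same effective sample size; the defaults reflect that.
- `predict()` uses MAP plug-in estimates (posterior predictive averaging
  over draws is not implemented); with several condition-dependent
  factors, predictions condition on the first factor only.
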