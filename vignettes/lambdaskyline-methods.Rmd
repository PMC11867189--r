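---
title: "Multiple-merger coalescent skyline inference: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple-merger coalescent skyline inference: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lambdaskyline)
```

## The model

`lambdaskyline` infers a time-varying effective population size $N_e(t)$ and
the multiple-merger intensity of the coalescent process from a single rooted,
timed, possibly multifurcating genealogy.  Standard skyline methods assume
Kingman's coalescent, in which exactly two lineages merge at a time.  In
populations with sweepstakes reproduction (many marine species), strong
selection, or superspreading transmission (several viral epidemics), the
offspring distribution is heavy-tailed and genealogies contain true
multifurcations.  The $\Lambda$-coalescent covers this regime: a finite
measure $\Lambda$ on $[0,1]$ generates the rate at which any specific set of
$k$ of $b$ extant lineages merges,

$$\lambda_{b,k} = \int_0^1 x^{k-2} (1-x)^{b-k}\, \Lambda(dx),
  \qquad 2 \le k \le b,$$

with total event rate $\lambda_b = \sum_{k=2}^{b} \binom{b}{k}
\lambda_{b,k}$ and block-size distribution $P(X = k) = \binom{b}{k}
\lambda_{b,k} / \lambda_b$ at an event.  The point mass at 0 gives Kingman's
coalescent, the point mass at 1 the star coalescent, and
$\Lambda = \mathrm{Beta}(2-\alpha, \alpha)$ the Beta-coalescent with
$\alpha \in (0,2]$: $\alpha \to 2$ recovers Kingman, $\alpha = 1$ is the
Bolthausen–Sznitman coalescent, and smaller $\alpha$ means larger mergers.
The rates satisfy the consistency identity
$\lambda_{b,k} = \lambda_{b+1,k} + \lambda_{b+1,k+1}$, which the test suite
verifies across all measure families.

With serially sampled tips (counts $n_\ell$ at times $s_\ell$, time 0 the
most recent tip and increasing into the past), coalescent times $t_k$ and
block sizes $m_k$, and the lineage-count step function
$A(t) = \sum_\ell n_\ell 1(s_\ell < t) - \sum_k (m_k - 1) 1(t_k < t)$, the
log-likelihood is

$$\ell = \sum_{k=1}^{K} \left[\log \binom{A(t_k)}{m_k} +
  \log \lambda_{A(t_k), m_k} - \log N_e(t_k)\right]
  - \int_0^\infty \frac{\lambda_{A(u)}}{N_e(u)}\, du .$$

$N_e(t)$ is modelled as piecewise constant, $N_e(t) = e^{\gamma_d}$ on the
cell $(x_d, x_{d+1}]$ of a regular grid of $D$ points spanning $[0,
t_{\mathrm{MRCA}}]$ ($D = 100$ by default), with an intrinsic first-order
Gaussian Markov random field prior on $\gamma$: penalty
$\frac{\tau}{2}\sum_d (\gamma_{d+1}-\gamma_d)^2$, precision
$\tau \sim \mathrm{Gamma}(0.001, 0.001)$, and a uniform prior on
$\alpha \in (0,2]$.

## Estimation methods

**Block-size pseudo-likelihood MLE** (`estimate_alpha_blocksize`).  The
topology-only pseudo-likelihood $\prod_k P(X = m_k \mid A(t_k), \alpha)$
depends on block sizes and lineage counts but not on times or $N_e$, so
$\alpha$ can be estimated from tree shape alone.  Maximization uses a
0.005-step grid on $(0,2]$ followed by golden-section refinement; boundary
maxima (e.g. all-binary trees, whose pseudo-likelihood increases
monotonically toward the Kingman limit) are flagged.

**Laplace skyline fit** (`fit_ne_given_alpha`).  Given $\alpha$, the
conditional posterior of $\gamma$ is log-concave (diagonal likelihood
Hessian $-T_d e^{-\gamma_d}$, where $T_d$ is the integrated hazard
coefficient of cell $d$), so a damped Newton iteration finds the mode and a
Gaussian approximation supplies pointwise bands.  The precision $\tau$ is
integrated numerically: the Laplace-approximate marginal of $\log\tau$ is
maximized, a 31-point grid spanning $\pm 4$ log units around the maximizer
is weighted by the marginal times the Jacobian, and pointwise medians and
2.5/97.5 percentiles are read off the resulting Gaussian mixture by
root-finding on its CDF.  This replaces the integrated nested Laplace
approximation used by earlier binary-coalescent skyline software with an
explicit, dependency-free, testable approximation of the same family; the
replicate-level acceptance tolerances absorb the difference.

**Hybrid estimator** (`estimate_hybrid`).  Initializes $\alpha$ at the
block-size MLE, then alternates a Laplace fit (taking the posterior median
trajectory) with full-likelihood maximization of $\alpha$ at that fixed
trajectory until $|\Delta\alpha| < 10^{-3}$ (at most 20 iterations).  The
inner $\alpha$ update uses the full likelihood rather than the
pseudo-likelihood, since times carry some information once $N_e$ is pinned.

**MCMC** (`run_mcmc`).  A Metropolis-within-Gibbs sampler with three blocks:

1. $\tau \mid \gamma$ is conjugate,
   $\mathrm{Gamma}(0.001 + \tfrac{D-2}{2},\ 0.001 + \tfrac12 \sum_d
   \Delta\gamma_d^2)$, and is drawn exactly.  (An alternative design updates
   $\tau$ jointly with $\gamma$ inside the Hamiltonian flight on the log
   scale; the exact conjugate draw is simpler, correct, and mixes at least
   as well, so it was adopted.)
2. $\gamma \mid \tau, \alpha$ by split Hamiltonian Monte Carlo: the Gaussian
   prior part of the dynamics is solved exactly in the eigenbasis of the
   RW1 structure matrix (harmonic rotation with frequencies
   $\sqrt{\tau \lambda_i}$; the null eigenvector moves freely), and only the
   likelihood force enters the leapfrog half-kicks.  10 leapfrog steps per
   update; the step size is adapted multiplicatively toward 70% acceptance
   during burn-in and then frozen.  None of these tuning constants come from
   external reference; they are declared package defaults.
3. $\alpha \mid \gamma$ from its discretized full conditional: the
   likelihood is evaluated at the 400 midpoints of the intervals
   $I_m = ((m-1)\cdot 0.005,\ m \cdot 0.005]$, which exactly tile $(0,2]$
   (a naive reading of $[0.005m, 0.005(m+1)]$, $m = 1..400$, would overshoot
   2); the Riemann sum normalizes, an interval is sampled, and $\alpha$ is
   drawn uniformly within it.  A cached table of log total rates on the
   400-point grid for all lineage counts up to $n$ makes this update O($n$)
   per iteration.

Defaults are 20,000 iterations with 10% burn-in; the desk-scale studies and
acceptance runs use 5,000 (noted where they do).  Point summaries are
pointwise posterior medians and 2.5/97.5 percentiles of $e^{\gamma_d}$, and
the posterior median of $\alpha$.

## Numerical choices

* All rates are computed in log space via `lbeta`/`lchoose`; the Beta
  normalizer $B(2-\alpha,\alpha)$ diverges at $\alpha = 2$, so
  `beta_measure(2)` is defined to *be* the Kingman measure and values near 2
  are stable because the normalizer cancels in ratios.
* The exponent integral of the likelihood is computed exactly over the
  change-point partition (sampling times, coalescent times, grid
  boundaries): since $N_e$ is exactly piecewise constant, the Riemann sum
  of earlier implementations is replaced by its exact limit.  A
  `riemann = TRUE` flag restores the grid-cell Riemann scheme (freezing
  $A$ at each cell midpoint) for comparability.
* Grid cells follow the prior's indicator convention $(x_d, x_{d+1}]$; an
  event falling exactly on a boundary belongs to the left cell, and times
  past the last grid point use the last cell's value (tail extension), so
  numerical jitter cannot leave the likelihood undefined.
* Exact ties between event times (measure-zero under the continuous model,
  but possible in rounded input trees) are perturbed pastward by $10^{-9}$
  with a warning.  Multifurcations in input Newick are recognized by
  collapsing internal branches shorter than `collapse_tol` ($10^{-8}$ by
  default, user-settable because maximum-likelihood tree software encodes
  polytomies as near-zero branches).
* Intervals where $A(t) < 2$ (possible under heterochronous sampling when
  all early samples have coalesced) contribute nothing to the hazard and
  are guarded explicitly.

## The simulator and what a green test establishes

`simulate_genealogy` draws waiting times by analytic inversion of the
cumulative hazard $\lambda_A \int du/N_e(u)$ across the cells of a
piecewise-constant $N_e$ — no thinning, exact given the cells.  Continuous
trajectories are discretized at 2,000 cells per horizon chunk (step 0.005
for the built-in trajectories), auto-extended until the MRCA; the
discretization bias on $1/N_e$ is below $10^{-5}$ relative for the built-in
trajectories.  Crossing a sampling time discards the pending waiting time
and redraws, which is exact by memorylessness.  Block sizes are drawn from
the block-size pmf and the merging lineages chosen uniformly, so simulator
output follows the same model the likelihood evaluates — the calibration
tests (hazard-transform KS, block-size chi-square, special-case means)
check the sampling machinery, not the model.

The built-in study world matches the simulation design used throughout the
tests: $\alpha \in \{1, 1.5, 1.8\}$, $n \in \{20, 50, 100\}$ tips, three
trajectories (constant $N_e = 100$; exponential growth $1000 e^{-t}$;
boom–bust $1000 e^{-|t-1|}$) and three sampling schedules (isochronous;
two times with a 50/50 split; four times with a 50/30/10/10 split).  The
spacing between sampling times is not pinned down by that design; 0.2
time units is the package default, and results pool schedules because they
differ little.  Synthetic genealogies are exactly Beta-coalescent draws:
green tests establish correctness of the algorithms under the model, not
robustness to misspecified or misestimated input trees (estimated
genealogies with collapsed near-zero branches are accepted, but their
estimation error is outside the model).

Two empirical notes from validating the simulator.  The tree-averaged block
size *increases* with the number of tips at fixed $\alpha$ (larger samples
spend time in larger-$A$ states with heavier block-size laws); verbal
accounts sometimes state the opposite, which does not reproduce here.
And the TMRCA itself barely separates $\alpha$ values, because the final
pairwise phase has rate $\lambda_2 = 1$ for every $\alpha$; the
"longer genealogies for smaller $\alpha$" effect is strong and monotone in
the total branch length, which is what the property test asserts.

## Metrics and identifiability

Skyline accuracy is summarized at the grid cells by coverage of the 95%
band and by bias/deviance/MSE of $\log \hat N_e - \log N_e$.  The log scale
is a deliberate choice: the skyline is modelled and plotted on the log
scale, and natural-scale MSE magnitudes reported elsewhere are not
reproducible without their exact metric definitions — quantitative
comparisons therefore use coverage only, which is scale-free.

Under a *constant* $N_e$, $\alpha$ and the level of $N_e$ are nearly
confounded in the time part of the likelihood (rescaling all total rates
and $N_e$ together is exact invariance; across lineage counts the rate
ratios vary slowly in $\alpha$), so time information adds little to the
topology information about $\alpha$ — the hybrid estimate stays close to
the block-size MLE there, and joint estimates rely on topology.  With
non-constant trajectories the MCMC's joint treatment pays off, which is the
pattern the reduced study reruns assert.

## Known limitations

* The exact boundary correction applied to the RW1 precision matrix varies
  across skyline implementations; free RW1 boundaries (first/last diagonal
  entries 1) are used here and documented.
* The Laplace fit conditions each band on a Gaussian at each $\tau$ grid
  value; heavy-tailed conditional posteriors (very sparse data) are
  summarized optimistically compared to MCMC.
* No inference from sequences: the genealogy is taken as known, and
  genealogical uncertainty is not propagated.
* $\Xi$-coalescents (simultaneous multiple mergers), measures mixing an
  atom at 0 with a continuous part, second-order random-walk priors and
  non-regular grids are out of scope.
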