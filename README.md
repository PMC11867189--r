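# lambdaskyline

Joint Bayesian nonparametric inference of the effective population size
trajectory *N<sub>e</sub>(t)* and the Beta-coalescent parameter *α* from a
single rooted, timed, possibly **multifurcating** genealogy.

Classical skyline methods assume Kingman's coalescent, where lineages merge
strictly two at a time. In populations with sweepstakes reproduction (many
marine species such as sardines and oysters), superspreading epidemics, or
strong selection, the offspring distribution is heavy-tailed and genealogies
contain true multifurcations. The Λ-coalescent handles this: a finite
measure Λ on [0,1] generates the rate at which any specific *k* of *b*
lineages merge,

    λ_{b,k} = ∫₀¹ x^{k−2} (1−x)^{b−k} Λ(dx),    2 ≤ k ≤ b,

with Λ = δ₀ giving Kingman, Λ = δ₁ the star coalescent, and
Λ = Beta(2−α, α) the Beta-coalescent for α ∈ (0,2] (α → 2 is Kingman,
α = 1 is Bolthausen–Sznitman; smaller α means bigger mergers). The package
provides, for serially sampled multifurcating genealogies under any such
measure:

* the merger-rate algebra (`merger_rate`, `total_rate`, `block_size_pmf`,
  `rate_table`) computed stably in log space;
* the heterochronous variable-*N<sub>e</sub>* coalescent likelihood, its
  topology-only (block-size) pseudo-likelihood, and its gradient in the
  log-skyline values (`loglik`, `topology_loglik`, `loglik_grad_gamma`);
* a piecewise-constant skyline *N<sub>e</sub>(t)* on a regular grid with an
  intrinsic first-order GMRF (random-walk) prior;
* three estimators: the block-size pseudo-likelihood MLE of α
  (`estimate_alpha_blocksize`), a hybrid iterative Laplace estimator
  (`estimate_hybrid`), and a Metropolis-within-Gibbs sampler with split
  Hamiltonian Monte Carlo for the latent field and a discretized conditional
  for α (`run_mcmc`);
* an exact backward-in-time simulator for any Λ measure, variable
  *N<sub>e</sub>(t)* and heterochronous sampling (`simulate_genealogy`), and
  a simulation-study driver (`run_study`).

Input genealogies are Newick trees with branch lengths (`read_newick`);
internal branches shorter than a tolerance are collapsed into
multifurcations, as maximum-likelihood tree software encodes polytomies as
near-zero branches.

## Worked example

Simulate a Beta(α = 1.5) genealogy of 50 tips under exponential growth
*N<sub>e</sub>(t)* = 1000 e<sup>−t</sup>, then estimate α and the skyline:

```r
library(lambdaskyline)

sim <- simulate_genealogy(beta_measure(1.5), "exponential", 50, seed = 1)
sim$data
#> <coal_data> n = 50 tips at 1 sampling time(s), K = 35 events, TMRCA = 6.885

est <- estimate_alpha_blocksize(sim$data)
sprintf("block-size MLE alpha: %.3f", est$alpha)
#> "block-size MLE alpha: 1.476"

fit <- fit_ne_given_alpha(sim$data, alpha = est$alpha, D = 100)
fit
#> <posterior_result> method = laplace, alpha = 1.4758, D = 100 grid points
#>   Ne(t) median range: [0.785, 510]

mc <- run_mcmc(sim$data, D = 100, iterations = 5000, seed = 2)
mc$result
#> <posterior_result> method = mcmc, alpha = 1.4627, D = 100 grid points
#>   Ne(t) median range: [0.884, 779]

ne_metrics(mc$result, function(t) 1000 * exp(-t))
#> coverage 1.00, bias 0.080, deviance 0.376, mse 0.206
```

The genealogy has 35 coalescent events among 50 tips (14 multifurcations —
an all-binary tree would have 49). The block-size MLE recovers α from tree
shape alone; the MCMC posterior median (1.463) agrees and additionally
returns pointwise 95% credible bands for *N<sub>e</sub>(t)* whose median
trajectory tracks the 1000 e<sup>−t</sup> truth (coverage 1.00 at the 99
grid cells; errors are on the log scale).

A command-line interface wraps the same operations:

```sh
Rscript -e 'lambdaskyline::cli_main()' simulate --alpha 1.5 --n 50 \
    --ne exponential --seed 1 --out simdir
Rscript -e 'lambdaskyline::cli_main()' infer --tree simdir/tree_001.nwk \
    --method mcmc --iterations 20000 --out inferdir
```

Each run writes its outputs (Newick / TSV trajectories / JSON results /
CSV traces) with a JSON manifest recording the full configuration and seed.

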