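---
title: "Reconstructing stochastic temporal networks from diffusive arrival times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing stochastic temporal networks from diffusive arrival times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stnrec)
```

## The model

A *stochastic temporal network* (STN) is a null model for temporally
resolved contact data.  It keeps two ingredients of a temporal network and
deliberately discards everything else:

1. the **time-aggregated directed graph** `G` — which ordered pairs of nodes
   interact at all, and
2. one **inter-event-time (IET) distribution** `rho_uv` per link — the law
   of the gaps between successive activations of that link, with the
   activation sequences of different links mutually independent renewal
   processes.

Information spreads on such a network in SI (susceptible–infected) fashion:
a node that becomes informed at time `t_u` transmits along each outgoing
link at that link's next activation.  Because the informing instant is
unrelated to the link's own renewal clock, the residual wait until that
next activation does not follow `rho` itself but its *length-biased*
transform (the inspection paradox),

    psi(tau) = S_rho(tau) / mu,

where `S_rho` is the IET survival function and `mu` its mean
(`length_biased_wtd()`).  `psi` is the *waiting-time distribution* (WTD)
and is the object the estimator below works with.  Two consequences worth
keeping in mind: for exponential IETs the transform is the identity
(memorylessness), and for a deterministic IET at `Delta` the wait is
uniform on `[0, Delta]`.

The observable data are *diffusive arrival times* (DATs): for each of `C`
independent cascades, the first instant `t_v` at which each node `v` was
informed, with `t_source = 0`.  The inverse problem is to recover `(G,
psi)` from the arrival times alone — the individual transmission events and
the spreading trees are latent.

## Likelihood

For one cascade, each informed non-source node `v` was informed first by
exactly one in-neighbour.  With independent renewal links this is a
competing-risks situation: every in-neighbour `u` with `t_u < t_v` raced to
inform `v`, the winner produced an exact waiting time equal to the
time-difference-of-arrival (TDOA) `d_uv = t_v - t_u`, and every loser's
waiting time is right-censored at its own `d_uv` (it had not fired by
`t_v`).  Summing over the unknown winner gives the per-node contribution

    log sum_u lambda_uv(d_uv)  +  sum_u log S_uv(d_uv),

with `S` the WTD survival function and `lambda = psi / S` the hazard, and
the cascade log-likelihood is the sum over non-source nodes
(`cascade_loglik()`).  Links whose endpoints are ordered the other way
contribute nothing; a node with no eligible in-neighbour at all makes the
graph incompatible with the cascade (`-Inf`).

The posterior probability that `u` was the winner — the **branching
coefficient** — follows from the superposition of the independent risk
processes as the hazard share

    beta_uv = lambda_uv(d_uv) / sum_w lambda_wv(d_wv)

(`branching_coefficients()`).  These weights drive both inference steps
below, and their per-node entropy

    H = - sum_v sum_u beta_uv log beta_uv

is the entropy of the spreading-tree posterior, which factorises over
per-node parent choices under dyadic independence
(`inferential_complexity()`).  We report `H / (N - 1)` as a per-node
*relative* complexity; cascades that pin down their tree exactly have
`H = 0`.

## Topology inference

Rather than a single maximum-likelihood graph (a hard submodular
optimisation), `gibbs_sample()` integrates over graph configurations with
likelihood weights.  The sampler state is the indicator vector of the
*candidate links* — ordered pairs with `t_u < t_v` in at least one cascade;
all other pairs are likelihood-neutral and fixed absent
(`candidate_links()`).  Sweeping candidates in a fixed shuffled order, each
indicator is resampled from its full conditional

    P(present | rest) = 1 / (1 + exp(-Delta_add)),

where `Delta_add` is the add-direction marginal gain of the link — the
likelihood difference of the flip, computed incrementally by touching only
the head node's terms (`marginal_gain()`).  We use heat-bath (full
conditional) resampling rather than a Metropolis flip: both are legitimate
Gibbs readings of a flip-with-acceptance-probability scheme, heat-bath is
parameter-free, and the sampler is verified against exhaustive enumeration
of the posterior on small instances.  The chain starts from the
all-candidates-present graph, which always has finite likelihood (every
node keeps its true parent among the candidates); a state whose removal
move would strand a node is automatically repaired because such a move has
`Delta_add = +Inf` and the link is forced present.

Defaults are `burn_in = 10` sweeps, `lag = 10`, `M = 200` retained samples;
one retained sample per full sweep.  The per-link presence frequency over
retained samples is the ranking score for precision–recall evaluation, and
thresholding at 0.5 (majority vote) gives the working graph between
alternation rounds.

## Waiting-time estimation

Given a graph, each eligible pair (link x cascade with `t_u < t_v`) is one
partially observed waiting time: an exact observation with probability
`beta_uv` and a right-censored one (`tau > d_uv`) with probability
`1 - beta_uv`.  The estimator is the *redistribute-to-the-right* imputation
iterated to self-consistency (`redistribute_update()`, `estimate_wtds()`):
with the current density estimate, each pair contributes

* a **branch atom** of mass `beta_uv` at `d_uv`, convolved with a Gaussian
  kernel of bandwidth `h` (default `0.05`; a Dirac option keeps exact atoms
  for small tests), and
* a **chord term** of mass `1 - beta_uv`, distributed as the current
  density truncated to `(d_uv, Inf)` and renormalised by `S(d_uv)`.

The kernel touches only the atom component — the chord component is already
smooth.  All updates in a sweep use the previous iterate (synchronous
updates), iteration stops when the Kolmogorov–Smirnov divergence between
successive survival functions drops below `eps` (default `1e-3`), and a
hit of the iteration cap flags non-convergence instead of failing.  On a
tree every `beta = 1` and a single update *is* kernel density estimation of
the TDOAs, independent of the starting guess — a useful exactness check.
The first guess is exponential (following the recommended initialisation),
with its mean set to the mean observed TDOA; the default is data-driven
because no universally good fixed scale exists.

Pooling is `"shared"` by default (one density for all links — the
homogeneous population assumption used in all benchmark inference here);
`"per-link"` mode estimates each link separately on a common grid, for
heterogeneous small networks.  `bootstrap_bands()` provides parametric
bootstrap percentile bands: cascades are resimulated from the fitted model
with the observed sources held fixed (the design is data, not noise) and
the estimator is re-run per replicate.

## Numerical representation

Densities live on equidistant half-open bins `[left, right)` over
`[0, tau_max]`, piecewise constant, with a single *tail atom* holding any
mass beyond the grid, so survival values never go negative.  Survival is
evaluated exactly as the right-tail bin sum (`S(0) = 1`), the hazard is
piecewise constant, and `psi = lambda * S` holds on-grid to `1e-9` by
construction.  Two guards keep log-likelihoods finite: survival values are
floored at `1e-12` inside logs, hazards are capped at `1e12`.  Estimation
grids default to `tau_max = 1.5 x` the largest observed TDOA; benchmark
densities are discretised out to a high quantile of their family.  Exact
arrival ties (`t_u = t_v`) are measure-zero in the continuous model and are
treated as non-informative: such a pair is excluded both as branch and as
censor.

Cascade simulation exploits the SI equivalence: one waiting time per link
per cascade plus single-source shortest paths equals the first-arrival
process of the broadcast, which is exact for renewal links under the
length-biased first-wait law.  Shortest paths for all cascades are computed
by repeated edge relaxation vectorised across cascades, which beats
per-cascade Dijkstra calls at these problem sizes.

## The coordinate-ascent driver

`reconstruct()` alternates Gibbs topology inference and density estimation,
starting from the exponential first guess, taking the posterior-mode
(majority-vote) graph between rounds, and stopping when that graph repeats
— a discrete fixpoint is testable for equality, unlike a likelihood
tolerance.  If the mode graph is empty the driver falls back to the top-`k`
ranking (`k` = expected link count, default `n`).  Supplying the true
density reduces round one bit-for-bit to the standalone topology path;
supplying the true graph reduces the driver to the standalone estimator —
both identities are tested.  The per-round total log-likelihood trace
(`total_loglik_trace()`) warns when the objective drops, the signature of
the positive feedback loop in which topology and density errors amplify
each other.

## What the synthetic benchmarks do and do not show

`generate_benchmark()` crosses Erdős–Rényi, ring-lattice, and scale-free
topologies (each undirected tie doubled into two directed links sharing one
density) with truncated-Gaussian, exponential, uniform, Pareto, and
log-normal waiting-time families.  The headline accuracy experiment uses
an Erdős–Rényi graph with `N = 100`, mean degree 6, truncated-Gaussian
waits of mean 2 and sd 0.5, `C = 100` cascades (relative sample size
`C/N = 1`), and the true density supplied to the sampler.  Density-recovery
experiments use the 8-node / 16-link ring lattice with `C = 2000` cascades
and `h = 1e-3` (a scaled-down version of the reference setting of
`C = 10^4`), and check that the Kolmogorov–Smirnov error to the truth falls
below 0.05 and decreases with `C` over `{200, 2000, 20000}`.  The
complexity-difficulty scan runs seven waiting-time families of increasing
dispersion on a 25-node Erdős–Rényi graph, three replicates per sample-size
grid point; these sizes are chosen to make the full suite run in minutes
while leaving the qualitative conclusions intact.

The generator draws from exactly the model the estimator assumes:
independent renewal links, complete cascades, no event durations, no
recovery.  Passing benchmarks therefore demonstrates correctness of the
inference machinery, not robustness to model misspecification.  Real
contact data have cross-dyad correlations (schedules, group meetings) that
this first-order null model ignores by design, and heavy-tailed empirical
waiting times push the equidistant-bin estimator towards many parameters
and slow convergence.  Those regimes — higher-order STNs, subdistributed
waits with recovery mass, sparsity-prior MAP variants — are out of scope
here.

## Known limitations

* `gibbs_sample()` supports a single shared density; per-link densities are
  supported in estimation (fixed graph) but not in topology inference.
* Kernel mass smoothed below `tau = 0` is clipped and renormalised rather
  than reflected; with the default `h` this affects at most the first
  couple of bins, and the scaled experiments use `h` below the bin width.
* Window-truncated (partial) cascades are accepted by the replay path and
  the file formats, but the likelihood treats only nodes with observed
  arrivals; systematically missing nodes are not modelled.
* The bootstrap quantifies sampling variability under the fitted model; it
  does not see model misspecification.
```
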