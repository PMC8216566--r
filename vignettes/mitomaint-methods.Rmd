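---
title: "Modeling mitochondrial maintenance in neuronal axons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling mitochondrial maintenance in neuronal axons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Neurons station mitochondria at discrete, metabolically demanding sites along
axons that can be centimeters long, while the protein content that keeps a
mitochondrion functional ("health") is synthesized almost entirely in the cell
body and turns over on a timescale of days. Keeping distal outposts healthy
therefore requires continuous long-range transport, and a trade-off: mitochondria
parked at demand sites serve local metabolism but age in place, while motile
mitochondria carry fresh material but serve no site. `mitomaint` implements two
quantitative mechanisms for the exchange between these pools:

* **CoG ("Changing of the Guard")** — whole mitochondria interchange: a motile
  mitochondrion passing a demand site stops with probability $p_s$; a stationary
  one re-enters the motile pool at rate $k_w$, with its direction chosen
  uniformly.
* **SS ("Space Station")** — permanent residents: $S$ mitochondria are stationed
  at each site forever, and material is exchanged through transient
  fusion/fission ("kiss-and-run") events, each passage fusing with each resident
  in turn with probability $p_f$ and fully equilibrating the two health values.

The domain is a segment of length $L$ with $n$ point-like demand sites at
$x_i = i\,L/(n+1)$. Motile mitochondria move processively at speed $v$,
reflect from the distal end (anterograde becomes retrograde), and are removed
and recycled when they return to the soma at $x = 0$, where new mitochondria
with health 1 are produced at rate $k_p$. Health decays exponentially at rate
$k_d$ in every state.

## Dimensionless control parameters

After rescaling lengths by $L$ and times by $L/v$, steady-state health depends
on three groups (`derive_params()` / `params_from_targets()` convert in both
directions):

| group | meaning | default study value |
|---|---|---|
| $\hat k_d = k_d L/v$ | decay accrued traversing the domain once | 0.06 (1 cm axon) – 0.6 (10 cm), using $k_d = (4\,\mathrm{d})^{-1}$, $v = 0.5\,\mu$m/s |
| $f_s = nS/M$ | fraction of the population that is stationary | scanned; 0.53 in the mitophagy studies |
| $N_s = 2\hat p_s n$ | expected stops/exchanges of a protein per round trip | scanned; 2 in the mitophagy studies |

Here $\hat p_s$ is the per-site probability that a *protein* transfers into the
stationary pool: $\hat p_s = p_s$ for CoG and $\hat p_s = 1-(1-p_f/2)^S$ for SS
(each of $S$ independent fusion chances moves a protein with probability
$p_f/2$). Because even $p_f = 1$ leaves a protein a 50% chance per fusion of
staying with its motile carrier, the SS mechanism caps $\hat p_s$ at
$1 - 2^{-S}$; `params_from_targets()` rejects targets beyond the cap rather
than silently truncating. The motile density is $\rho = 2k_p/v$ and the SS
effective restart rate is $\hat k_w = p_f v \rho / 2$.

For SS configurations the per-site count must be an integer, so
$S = \operatorname{round}(f_s M / n)$ and the realized fraction $nS/M$ is
reported alongside the request (attribute `realized_f_s`). At the standard
mitophagy conditions ($M = 300$, $n = 10$, $f_s = 0.53$, i.e. 15.9 per site)
this rounds to $S = 16$.

Site positions are strictly interior with equal gaps including both boundary
segments. Placing the last site *at* the domain end would confound distal-site
health with the reflecting boundary; the interior choice keeps all sites
geometrically equivalent. Site coordinates affect distal-site health only
weakly (the gap is $1/(n+1)$ of the domain).

## Mean-field steady state

`solve_cog()` and `solve_ss()` assemble one linear system per configuration and
solve it densely (systems are at most a few hundred unknowns; LU is exact to
machine precision and the assembled residual is checked to $10^{-10}$ in the
tests). The ingredients:

* motile health densities $H^\pm(x)$ decay exponentially,
  $e^{-k_d \Delta x/v}$, along the direction of motion across each inter-site
  interval — anterograde falls with distance from the soma and retrograde
  falls toward it;
* at each site the outgoing flux equals the non-stopping passage plus the flux
  restarted from the stationary pool,
  $vH^\pm(x_i^\pm) = vH^\pm(x_i^\mp)(1-p_s) + \tfrac12 k_w H_i$;
* stationary balance
  $(k_d + k_w)H_i = v p_s\,[H^+(x_i^-) + H^-(x_i^+)] + r f_s M/n$, the last
  term being the optional local-translation source;
* boundary conditions $H^+(L) = H^-(L)$ and $vH^+(0) = k_p$.

For SS, each of the $S$ residents at a site is resolved individually
($H_{i,j}$), with fusion jump conditions
$H^\pm_{i,j} = (1-p_f/2) H^\pm_{i,j\mp1} + (p_f\rho/4) H_{i,j}$ and balance
$(v\rho p_f/2 + k_d)H_{i,j} = (vp_f/2)[H^+_{i,j-1} + H^-_{i,j+1}]$. Residents
sit at a point, so there is no decay between consecutive residents of one
site. The full per-resident system is solved; the small-$p_f$ approximation
that maps SS onto CoG is *not* used by the solver (it is exercised only as a
test of the claim that the two models coincide at $S = 1$ under
$p_s \to p_f/2$, $k_w \to \hat k_w$, which holds to machine precision).

Degenerate systems are refused explicitly rather than returned as garbage:
$k_d = k_w = 0$ with $p_s > 0$ (CoG) and $k_d = 0$ with $p_f = 0$ (SS) have no
unique steady state, and $k_w = 0$ with $p_s > 0$ has no finite stationary
population.

Normalized metrics divide site health by mitochondria per site:
$\hat H_i = H_i / (M/n)$. These are invariant under rescaling $M$ (equivalently
$k_p$), which the tests verify over a 10× range. Two reference populations
matter once mitophagy is on: the *realized* total (fixed-content reading) and
the zero-mitophagy population $M^{(0)}$ (fixed-production reading,
$\hat H^{(0)}_i = H_i/[M^{(0)}/n]$).

## Stochastic agent simulation

`run_cog()` / `run_ss()` simulate discrete mitochondria with a fixed time step
(defaults $\Delta t = 10^{-3}$, $10^5$ steps, i.e. 100 domain-traversal times,
100 iterations), in nondimensional units $L = v = 1$. The per-step rule order
is fixed and documented: **move → stop/fuse → restart → decay → engulf →
produce**. Within a step:

1. motile agents advance $\pm v\Delta t$; anterograde agents reaching $L$ fold
   back ($x \to 2L - x$) as retrograde; retrograde agents reaching 0 are
   removed (or relaunched with health 1 in the fixed-$M$ recycling variant);
2. an agent whose step crossed a site stops there with probability $p_s$
   (CoG), or attempts fusion with each resident in positional order (SS;
   anterograde proximal-first, retrograde distal-first), each success
   averaging the two health values;
3. stationary agents restart with probability $1-e^{-k_w\Delta t}$, direction
   equiprobable; a restarted agent is not re-evaluated at its own site until
   it has left it (otherwise restarting retrograde from site $i$ would face an
   immediate, $\Delta t$-dependent re-capture);
4. all health decays by $e^{-k_d\Delta t}$;
5. with mitophagy ($\phi > 0$), any non-engulfed agent with health below
   $\phi$ becomes engulfed: it moves retrograde only, never stops or fuses,
   is excluded from all health statistics, but still counts toward the
   population $M$; an engulfed SS resident leaves a vacant slot, filled by
   the next non-engulfed motile agent to cross the site (it stops with
   probability 1 and becomes a permanent resident);
6. a new agent (health 1, anterograde, at $x=0$) is born with probability
   $1-e^{-k_p\Delta t}$ — at most one per step, so the realized influx
   saturates below $k_p \Delta t$ when $k_p \Delta t$ is not small; this is a
   property of the discrete production rule itself, and normalized health
   metrics are unaffected because agents do not interact through production.

An agent that stops during a step does not draw a restart in that same step.
The chosen order is one of several defensible $O(\Delta t)$ variants; the test
suite checks that halving $\Delta t$ leaves steady-state means within sampling
error.

SS residents are initialized with health 1 (their relaxation to steady state
is covered by the burn-in; the alternative of initializing at the mean-field
value only shortens burn-in). A burn-in check in the tests verifies that the
last 10% of steps is trend-free and that the realized population matches the
steady-state density prediction.

**Implementation.** The kernel (C++ via Rcpp) exploits two exact
reformulations of these rules. Health decay is uniform, so health is stored
as $h = \mathrm{health}\cdot e^{+k_d t}$; decay costs nothing per step, fusion
averages remain valid, and the engulfment test compares $h$ against a global
threshold $\phi e^{k_d t}$ (this bounds usable runs to
$k_d \Delta t \cdot \mathrm{steps} < 600$; the wrapper enforces it). Second,
between site crossings, boundary hits and threshold crossings nothing happens
to an agent, and stationary waits are geometric; each agent therefore carries
the precomputed step of its next event, with event steps computed as the first
step at which the per-step rule would fire. The realized distributions are
exactly those of a naive per-step loop; only the RNG consumption order
differs. One RNG stream is derived per iteration from
`(seed, iteration index)`, making ensembles reproducible and independent of
execution order; identical inputs reproduce results bit for bit.

**Measurement.** Each iteration contributes its final-step snapshot; ensemble
statistics are means/SDs across iterations (no time averaging). Normalization
is per iteration: $\hat H$ uses that iteration's realized total $M$ (fixed
content), $\hat H^{(0)}$ uses the configured reference $M$ (fixed
production). The variability statistic $\sigma_H/\langle H\rangle$ is, by
default, the across-iteration SD of per-region health averaged over regions,
divided by the grand mean per-region health; the alternative pooling (SD of
the region-averaged health) is available via `variability(mode = "pooled")`,
since either reading of "standard deviation in health per region" is
defensible. For SS ensembles the residents can be stationed uniformly
(exactly $S$ per site, the default) or scattered over the sites uniformly at
random per iteration (`ss_placement = "random"`), which perturbs the
per-site counts without changing their total.

## What the simulations emulate — and what they do not

The simulator *is* the data generator for this package: all analyses run on
synthetic ensembles under the study conditions above. It emulates processive
bidirectional transport with stochastic stopping/fusion, somal production,
exponential protein decay, threshold mitophagy with instantaneous engulfment,
and fixed or production-limited population size. It does **not** represent:
transient pausing or reversals of motile mitochondria, spatially or
activity-dependent decay rates, delays in autophagosome arrival, branched
axonal geometries, partial (non-equilibrating) fusion, or discreteness of the
health variable itself. Agreement of tests with this generator therefore
validates the implementation and the model's internal claims, not the
biological fidelity of those simplifications.

## Parameter sweeps and optimization

`sweep_landscape()` evaluates either engine over grids of
$(f_s, N_s, \phi)$; infeasible SS cells (beyond the $\hat p_s$ cap) are
recorded as `NA` rows with the reason, never dropped. Grid points are
stateless, independent evaluations (each stochastic cell reseeds from the
configured seed), so any evaluation order gives identical tables.
`sweep_optimize()` takes the grid argmax and, for the stochastic engine,
re-evaluates it with independent replicate ensembles to attach a standard
error. Default grids are $f_s \in \{0.05,\dots,0.95\}$ (10 points),
$N_s$ log-spaced on $[0.2, 20]$ (10 points), matching the ranges over which
the optima move as $\hat k_d$ varies.

Mitophagy comparisons use the fixed-content reading (normalize by realized
$M$) by default, which the fixed-$M$ recycling variant reproduces directly —
the tests cross-validate the two. The fixed-production reading
(`normalization = "per_M0"`) shows the complementary behavior: with $k_p$
held fixed, engulfment drains the population and CoG health falls
monotonically with $\phi$.

`translation_enhancement()` quantifies distal protein synthesis in the CoG
mean-field model: stationary mitochondria gain health at rate
$r = \alpha v/(2L)$ each, a fraction $\alpha$ of the maximal somal supply per
mitochondrion. Enhancement ratios $H_{i,t}/H_i$ grow with site index —
distal sites, whose soma-derived supply has decayed most, benefit most. The
SS mean-field system does not include a translation term (translation into
permanently stationed residents would also feed back into the motile pool
through fusion, a coupling we have not modeled); `solve_ss()` rejects
$\alpha > 0$ explicitly. In the stochastic engine translation is a
deterministic per-step increment $r\,\Delta t$ to each stationary agent,
disabled by default.

## Problem sizes in the tests and the acceptance script

The full study protocol (10×10 transport grids × 100 iterations × 10
replicates per mitophagy threshold) is the package's reference but not what
the routine checks run. `scripts/acceptance.R` uses, as this package's
standing choices: fine deterministic grids for the mean-field optima
($f_s$ step 0.02, 60-point log grid in $N_s$, $n = 30$); for the mitophagy
health gains, the study protocol that pins the stationary fraction at
$f_s(\phi{=}0) = 0.53$ and optimizes over the exchange frequency $N_s$ at
each threshold; for the freely-optimized fold-increase bounds, coarse 5×5
$(f_s, N_s)$ grids per threshold. Stochastic scans run 50-iteration
ensembles of $4\times10^4$-step runs (40 traversal times, comfortably past
the slowest relaxation at $\hat k_d = 0.6$), with $10^5$-step runs where
slow decay ($\hat k_d = 0.06$, relaxation time $\approx 17$) or the
fixed-production protocol requires them, and common random numbers across
thresholds so gain ratios do not accumulate independent cell noise. The
test suite runs further-reduced analogues of the same protocols. Ensemble
SEMs are reported throughout so the sampling resolution of each number is
visible.

Two readings of the "average health improvement under mitophagy" are
possible: the average-health objective maximized over the transport grid at
the optimal threshold, or the average health evaluated at the transport
parameters that maximize *distal* health. The package reports the latter —
the gain in $\langle\hat H\rangle$ at the distal-optimal $(N_s, \phi)$
relative to the distal-optimal cell at $\phi = 0$ — which is the quantity
that accompanies a distal-health-first optimization; the former is available
directly from the landscape tables.

## Known limitations

* Mean-field mitophagy is not available: engulfment is triggered by
  individual discrete health values, which has no closed per-site
  description; mitophagy runs through the stochastic engine only.
* The dense mean-field assembly is comfortable to $nS$ of a few thousand
  unknowns; very large $n \cdot S$ would want a banded solver.
* With $k_p\Delta t \gtrsim 0.1$ the one-birth-per-step production rule
  visibly saturates the realized population below its nominal target;
  normalized health metrics are unaffected.
* Single decay rate, identical for motile and stationary states; no
  health-dependent transport arrest other than threshold engulfment.
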