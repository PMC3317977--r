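---
title: "Methods: time-dependent Poisson random field inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-dependent Poisson random field inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdprf)
```

## The model

`tdprf` estimates selection, mutation and divergence-time parameters from
DOHRS tables: per-locus counts of fixed **D**ifferences between two species'
samples, sites polymorphic in **O**ne sample, and sites polymorphic in
bot**H** samples, split into **R**eplacement and **S**ilent site classes.
Under the Poisson random field (PRF) assumption — free recombination between
sites, so mutant frequencies form a Poisson point process — the six counts of
a locus are independent Poisson variables.  Unlike the classical equilibrium
PRF treatment, the two daughter species are *not* assumed to have returned to
mutation–selection–drift equilibrium after the split: the six means depend
explicitly on the scaled divergence time $t$.

All parameters are scaled by the haploid effective population size $N_e$:
time is measured in units of $N_e$ generations, the selection coefficient is
$\gamma = N_e s$, and the per-locus mutation rates are $\theta = 2 N_e \mu$
(silent: $\theta_s$, replacement: $\theta_r$).  Derived allele frequency $x$
follows the Wright–Fisher diffusion with generator

$$L u = \tfrac12 x(1-x)\,u'' + \gamma\, x(1-x)\, u',$$

whose backward solution $u(t,x) = E_x[f(X_t)]$ gives the expectation of any
sampling functional $f$ after $t$ time units.  Under this scaling the
fixation probability from frequency $p$ is
$(1-e^{-2\gamma p})/(1-e^{-2\gamma})$, the neutral equilibrium frequency
spectrum is $\theta/x$, and the equilibrium spectrum under selection is

$$f(x) = \theta\,
  \frac{1-e^{-2\gamma(1-x)}}{(1-e^{-2\gamma})\,x(1-x)}.$$

These three closed forms are used throughout the test suite as oracles for
the numerical machinery; they jointly pin down the scaling convention (for
instance, the neutral spectrum integrates against the polymorphism sampling
probability to Watterson's $\theta \sum_{i<n} 1/i$, which the quadrature
reproduces to $10^{-7}$ relative error).

### The six Poisson means

Each mean is the sum of two contributions.

*Legacy polymorphisms.*  Sites segregating at frequency $y$ when the species
split carried the equilibrium spectrum $\theta g_\gamma(y)$.  Both daughter
species inherit $y$ and then evolve independently, so for sample sizes $m$
and $n$ the legacy part of, e.g., the fixed-difference mean is
$$\theta \int_0^1 g_\gamma(y)\,
  \big[a_m(t,y)\,b_n(t,y) + b_m(t,y)\,a_n(t,y)\big]\,dy,$$
where $a_k(t,y) = E_y[X_t^k]$ (sample monomorphic derived) and
$b_k(t,y) = E_y[(1-X_t)^k]$ (monomorphic ancestral) come from the backward
equation.  The polymorphic classes use
$p_k = 1 - a_k - b_k$: "polymorphic in one sample" pairs $p$ with $1-p$ in
the two species, "polymorphic in both" multiplies $p_m p_n$.  Sites
monomorphic for the same allele in both samples are invisible and counted
nowhere.

*New mutations.*  After the split each species receives mutations at rate
$\theta/2$ per unit time at vanishing frequency.  A mutation of age $s$
contributes through the slope at the origin
$v_f(s) = \partial_y E_y[f(X_s)]\big|_{y=0}$, giving
$\tfrac{\theta}{2}\int_0^t v_f(s)\,ds$ per species.  New mutations can fix in
a sample (fixed differences) or segregate (polymorphic in one sample); they
can never be polymorphic in both species.  As $t \to \infty$ the influx
integrand for the fixed class approaches the classical fixation-rate
constant $2\gamma/(1-e^{-2\gamma})$, so the expected fixed count grows
asymptotically linearly and the ratio of slopes at $\pm\gamma$ is exactly
$e^{2\gamma}$ — both used as acceptance oracles.

Every mean is linear in its $\theta$; the package therefore caches *unit*
functionals per $(\gamma, k, t)$ and rescales, which is also what makes the
mutation-rate updates in the sampler conjugate.

## Numerics

**Crank–Nicolson solver.**  The backward equation is discretised on a
sinh-stretched grid (default 400 interior nodes, stretching 6) that
concentrates nodes near the absorbing endpoints, where sampling polynomials
like $x^{15}$ have boundary layers.  Both diffusion and drift coefficients
vanish at $x \in \{0, 1\}$, so boundary values stay frozen at the payoff —
this matches the absorbing-endpoint expectation semantics and needs no
artificial boundary condition.  Time stepping is Crank–Nicolson
(second-order, unconditionally stable; default $\Delta t = 10^{-3}$), with a
few damped backward-Euler start-up steps only for discontinuous payoffs
(absorption indicators).  All intermediate time levels are retained: one
solve serves every divergence time up to its horizon, and the new-mutation
time integrals reuse the level values via the trapezoid rule.  The
origin slope $v_f(s)$ is obtained by quadratic extrapolation through the two
grid nodes nearest 0 (the payoffs involved vanish at the origin).

The test suite verifies: exact preservation of constants; the neutral
martingale $u(t,x) = x$; eigenfunction decay of $x(1-x)$ at the discrete
generator's own eigenvalue; the semigroup property; an observed convergence
order $\ge 1.8$ under refinement; the discrete maximum principle; and
self-adjointness of the neutral generator under the discrete speed measure.

**Quadrature.**  Frequency-space integrands inherit the integrable $1/x$
singularity of the spectrum at 0.  Integrals are computed with Gauss–
Legendre panels after the substitution $x = e^{-u}$ on $(\varepsilon, 1/2)$
(default $\varepsilon = 10^{-8}$, three panels in $u$) plus one plain panel
on $[1/2, 1]$; the substitution turns $dx/x$ into $du$ and makes the
integrands smooth.  The truncation below $\varepsilon$ contributes
$O(\varepsilon)$ to every integrand used here.  Default order is 24 nodes
per panel (96 total); the reduced MCMC profile uses 12.

## The hierarchical model and sampler

Per locus $i$: $\gamma_i \sim N(\mu_\gamma, \sigma^2)$ (replacement sites
share one selection coefficient within a locus; silent sites are neutral),
$\theta_{s,i}, \theta_{r,i} \sim$ Gamma priors, and globally
$(\mu_\gamma, \sigma^2)$ carries the conjugate normal–inverse-gamma prior
($\sigma^2 \sim \mathrm{InvGamma}(a_0, b_0)$,
$\mu_\gamma \mid \sigma^2 \sim N(\mu_0, \sigma^2/\kappa_0)$) and
$t \sim U(0, t_{\max})$.  The hyperparameters are small so the priors stay
weak: $\kappa_0$ and the $\theta$ shapes/rates default to $0.01$, and
$t_{\max} = 20$; all are configurable.  Whether the prior variance of
$\mu_\gamma$ scales with $\sigma^2$ was an open choice; the scaled (fully
conjugate) form was adopted because it is the standard construction and
makes the hyper-block update exact.

The $\sigma^2$ hyperparameters deserve one paragraph.  The
$\mathrm{InvGamma}(\epsilon, \epsilon)$ limit often written down as
"uninformative" is nothing of the sort: its mass concentrates near
$\sigma^2 \approx \epsilon$, so it actively rewards collapsing the
selection hierarchy onto its mean — a well-documented pathology of
variance-component priors.  A direct numerical check of this package's own
posterior (integrating the per-locus $\gamma$ likelihoods against the
hierarchy on a grid, no MCMC involved) shows the $\epsilon = 0.01$ prior
pulling the bulk of the $\sigma^2$ posterior one to two orders of magnitude
below the generating value at the default study size.  The package
therefore defaults to $a_0 = b_0 = 0.5$ — a unit scaled-inverse-$\chi^2$
with a single prior degree of freedom, still weak across the plausible
range $\sigma^2 \in (10^{-1}, 10^{1})$ but free of the collapse spike.
Both choices remain available through `hyper_parameters()`.

The sampler is Metropolis-within-Gibbs:

* $(\mu_\gamma, \sigma^2)$ — exact normal–inverse-gamma Gibbs draw;
* each $\gamma_i$ — Gaussian random walk on the three replacement counts
  plus the population prior;
* each $\theta$ — **exact conjugate gamma Gibbs draw**.  Because the six
  means are linear in $\theta$ with cached unit coefficients, the full
  conditional is Gamma(shape $+ \sum k$, rate $+ \sum$ unit means).  A
  log-scale random-walk update (with Jacobian) is also provided in
  `metropolis_step()`, but the Gibbs draw is exact and solver-free, so it is
  what `run_mcmc()` uses;
* $t$ — Gaussian random walk reflected into $(0, t_{\max})$;
* two *group moves* through the $(\mu_\gamma, \sigma^2, \gamma)$ funnel,
  every other iteration: a scaling move
  $\gamma_i' = \mu_\gamma + c(\gamma_i - \mu_\gamma)$,
  $\sigma^{2\prime} = c^2 \sigma^2$ with the $(L+2)\log c$ Jacobian, and a
  translation move shifting $\mu_\gamma$ and all $\gamma_i$ jointly.

The group moves matter.  The centred hierarchy with an
$\mathrm{InvGamma}(0.01, 0.01)$ prior places substantial posterior mass at
small $\sigma^2$ (per-locus likelihoods for $\gamma_i$ are informative but
not sharp — three replacement counts with a free $\theta_r$), and single-site
updates deadlock there: every individual $\gamma_i$ move away from
$\mu_\gamma$ pays an enormous prior penalty.  The deterministic
rescaling/translation proposals let the chain traverse between the
concentrated and dispersed regimes, so the reported credible intervals
reflect both.  In addition, the first third of burn-in floors $\sigma^2$ at 1
so the $\gamma_i$ first migrate to their likelihood positions before the
hierarchy may shrink them; the floor is released well before any draw is
retained, so the post-burn-in kernel is exact.

Proposal scales adapt toward 20–50% acceptance during burn-in only and are
frozen afterwards.  Chains start from overdispersed draws (numerically
bounded: the nearly improper Gamma(0.01, 0.01) priors produce starting
values like $10^{-40}$ that no floating-point likelihood survives, so
initial draws are clipped to wide finite boxes; $t$ starts uniformly across
many posterior standard deviations).  Convergence is monitored with the
Gelman–Rubin statistic on every parameter; `cmd_fit()` logs a warning, not
an error, when some $\hat R \ge 1.1$.

Default chain settings (4 chains, 20,000 burn-in, 10,000 samples retained at
thinning 10) mirror the reference analysis scale.  The bundled tests and the
acceptance script use the reduced profile (61 grid nodes,
$\Delta t = 0.01$, 12-node panels, 2 chains, 1,200–1,500 burn-in and
retained draws), chosen so the whole study re-runs on one CPU in minutes;
the reduced numerics bias the six means by $\lesssim 3\%$ relative to the
default grid, well inside the recovery tolerances checked.

## The simulator and what it does (not) emulate

`simulate_dohrs()` reproduces the model's own data-generating process: fixed
global $(t, \mu_\gamma, \sigma^2)$; per locus
$\gamma_i \sim N(\mu_\gamma, \sigma^2)$, $\theta$s from continuous uniform
ranges, sample sizes from discrete uniform ranges; six Poisson draws from
the computed means.  Defaults: 30 loci, $t = 1$, $\mu_\gamma = 1$,
$\sigma^2 = 4$, $\theta_s \in [1, 20]$, $\theta_r \in [0.5, 10]$,
$m, n \in \{5, \dots, 15\}$.  The $\theta$ and sample-size ranges are
plausible for multi-kilobase *Drosophila* coding loci surveyed in samples of
a dozen alleles; $t = 1$ ($N_e$ generations) sits in the middle of the
divergence scale the method targets, and $\mu_\gamma = 1$, $\sigma = 2$ give
mostly weak positive selection with a realistic minority of deleterious
loci.  These are package choices, documented here once, and configurable.

Because the simulator *is* the model, parameter recovery on simulated data
checks the numerics, the sampler and identifiability — not robustness to
linkage, demography, population-size change, or misclassified sites, none of
which the generator emulates.  Per-locus substreams are derived
deterministically from the design seed, so locus $i$ is reproducible even
when `n_loci` changes.

## Degenerate inputs, tie-breaks, numerical floors

* Every Poisson mean is floored at $10^{-12}$ before entering a
  log-likelihood, so extreme parameter proposals return $-\infty$-ish values
  instead of `NaN`.
* Samples of size 1 cannot be polymorphic: the payoff $p_1 \equiv 0$ makes
  the shared-polymorphism mean vanish identically, and the data validator
  rejects tables violating it.
* Out-of-support states get $-\infty$ log prior, never an exception.
* The spectrum shape is evaluated in an `expm1`/`log1p` form that is stable
  for $|\gamma|$ in the hundreds; the $|\gamma| < 10^{-9}$ neighbourhood
  switches to the neutral limit $1/x$.
* Cache keys quantise $\gamma$ at $10^{-6}$; the LRU cache never evicts the
  neutral (silent-class) entries shared by all loci.

## Known limitations

* The within-locus fixed-effect assumption (one $\gamma$ per locus) is the
  model's, not a numerical choice; random-effects variants are out of scope.
* $\sigma^2$ is weakly identified at the default study size (30 loci,
  moderate counts): its posterior mixes mass near 0 with mass at the
  generating value, which is why interval coverage — not point recovery of
  $\sigma^2$ — is the meaningful simulation check.
* The equal-and-constant population size, no-migration assumptions are baked
  into the diffusion; applying the method to populations with strong
  demography will bias $t$ and $\gamma$ in ways the simulator cannot reveal.
* Divergence-time conversion to years (`scaled_time_to_years()`) is a pure
  unit change and inherits whatever $N_e$ and generation time the user
  supplies.
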