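# tdprf

Time-dependent Poisson random field (PRF) inference of selection and
divergence for two recently diverged species.

## The problem

McDonald–Kreitman-style data summarise aligned coding sequences from two
species as counts of fixed differences and polymorphisms at silent and
amino-acid-replacement sites.  Classical PRF estimators of selection assume
that each daughter species returned to mutation–selection–drift equilibrium
immediately after the split — an assumption that is known to bias
divergence-time estimates.  `tdprf` implements the time-dependent
alternative: the species split is an explicit model parameter, sites that
were already polymorphic at the split ("legacy polymorphisms") are
propagated through the Wright–Fisher diffusion, and mutations arising after
the split enter through a time-integrated influx.

The data unit is the **DOHRS table**: per locus, the number of fixed
**D**ifferences, sites polymorphic in **O**ne sample, and sites polymorphic
in bot**H** samples, for **R**eplacement and **S**ilent sites, plus the two
sample sizes — nine columns of tab-separated text.

## The model

With all parameters scaled by the haploid effective size `N_e` (time in
`N_e` generations, `γ = N_e s`, `θ = 2 N_e μ`), allele frequencies follow
the diffusion with generator

    L u = ½ x(1−x) u″ + γ x(1−x) u′

and the six DOHRS counts of a locus are independent Poisson variables whose
means combine (i) the equilibrium spectrum
`θ (1−e^{−2γ(1−x)}) / ((1−e^{−2γ}) x(1−x))` carried through the backward
equation for time `t` independently in the two species, and (ii) a
new-mutation influx of rate `θ/2` per species per unit time.  A hierarchical
Bayesian layer ties loci together: `γ_i ~ N(μ_γ, σ²)` across loci with a
normal–inverse-gamma prior on `(μ_γ, σ²)`, gamma priors on each `θ`, and a
uniform prior on `t`.  Posteriors are sampled by Metropolis-within-Gibbs
MCMC (exact conjugate updates for `(μ_γ, σ²)` and every `θ`; random-walk
updates for each `γ_i` and `t`; deterministic group moves through the
hierarchy's funnel), with Gelman–Rubin convergence monitoring.

The backward equation is solved by a Crank–Nicolson scheme on a
boundary-concentrated grid; spectrum integrals use Gauss–Legendre panels
under the substitution `x = e^{−u}` that removes the `1/x` endpoint
singularity.  See `vignettes/tdprf-methods.Rmd` for the full account.

## Worked example

```r
library(tdprf)

# reduced-accuracy numerics: fine for a demonstration
ctx <- prf_context(n_grid = 61, dt = 0.01, quad_order = 12,
                   cache_max = 1500, gamma_quantum = 0.01)

# one locus: silent rate 5, replacement rate 2, selection +2,
# 8 and 11 sequences, divergence time 0.8
lam <- expected_counts(locus_parameters(5, 2, 2, 8, 11), t = 0.8, ctx)
lam
#> Expected DOHRS counts (Poisson means):
#>     fixed_s  poly_one_s poly_both_s     fixed_r  poly_one_r poly_both_r
#>    1.058538   23.395724    1.950514    1.079243   13.627178    1.185019
```

At this young divergence time most variation is still polymorphism: the
silent class expects ~23 sites polymorphic in one sample against only ~1
fixed difference.  Per unit mutation rate the positively selected
replacement class fixes 2.5 times faster (1.08/2 = 0.54 vs 1.06/5 = 0.21)
and carries legacy variants shifted toward intermediate frequencies, hence
relatively more shared polymorphism (0.59 vs 0.39 per unit rate).

Simulate a 30-gene study and re-estimate everything:

```r
des <- simulation_design(n_loci = 30, t = 1, mu_gamma = 1, sigma2 = 4, seed = 1)
ds  <- simulate_dohrs(des, ctx)
fit <- run_mcmc(ds, hyper_parameters(t_max = 10),
                chain_settings(n_chains = 2, burn_in = 1500, thin = 1,
                               n_retained = 1500, seed = 2), ctx)
sm  <- summarize_fit(fit)
subset(sm, parameter == "t")
#>  parameter    median      q2.5    q97.5     rhat
#>          t 0.9419467 0.8868163 1.001925 1.016712
recovery_report(sm, attr(ds, "truth"))
#>  t_rel_error t_covered gamma_ci_coverage theta_median_rel_error max_rhat
#>   0.05805326      TRUE         0.9666667              0.1202161 1.038905
```

The posterior median of the scaled divergence time lands within 6% of the
generating value 1 and its 95% interval covers it; 97% of the per-locus
selection intervals cover their true coefficients, and the mutation-rate
medians sit within ~12% of truth (the error is dominated by Poisson noise
at low-rate loci).  Convert scaled time to years with, e.g.,
`scaled_time_to_years(0.94, N_e = 2e6, generations_per_year = 10)`.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/exec/tdprf simulate --out dohrs.tsv --seed 1 --quick
Rscript inst/exec/tdprf fit --data dohrs.tsv --out fitdir --quick
Rscript inst/exec/tdprf summarize --out fitdir --truth dohrs.tsv.truth.tsv
```

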