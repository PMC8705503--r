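# rnahit

Can a high-fidelity replicator be found in RNA sequence space by random
drift? `rnahit` is an R package for studying that question at the sequence
level: it simulates, exactly, a replicating population of fixed-length RNA
sequences on fitness/similarity/fidelity landscapes over Hamming space, and
analyses the first-passage ("hitting") times of replicator emergence and
establishment. It is aimed at researchers in molecular evolution and
stochastic chemical kinetics who want a tested, reproducible testbed for
replicator-search dynamics.

## The model in brief

Sequences live in `E = {A,U,G,C}^n`. The core reaction network, simulated
with the Gillespie stochastic simulation algorithm, is

* duplex formation  `x + xc -> {x,xc}`, propensity `kds N(x) N(xc)`,
* dissociation  `{x,xc} -> x + xc`, propensity `kss` per duplex,
* template-directed polymerization  `x + y -> x + y + y*c`, propensity
  `a f(x) s(x,y) N(x)(N(y) - I(x=y))` per ordered pair,

optionally extended by single-strand decay, surface ("clay")
oligomerization/polymerization, and vesicle compartmentalization. The
landscapes are anchored on a high-fidelity set `R`:
`f(x) = exp(-k H(x,R))` (tent; a linear form is also provided),
`s(x,y) = exp(-l S(x,y))` with the complement-invariant distance
`S(x,y) = min(h(x,y), h(x,yc))`, and per-site copying fidelity
`p(x) = exp(-m H(x,R))`. Copying errors are iid across sites, so the
offspring of template `y` lands in the Hamming level set `H_i(yc)` with
binomial probability `C(n,i) (1-p)^i p^(n-i)`, uniformly within it.

On top of the simulator the package provides: online/replay detectors for
the hitting times `tau_rep`, `tau_R`, `tau_min`, `tau_v` with right
censoring; the sweep protocols over `(n, k, kdecay, fclay, p)`; a
Weibull proportional-hazards likelihood
(`R(t|theta) = exp(-(t/beta)^alpha e^{gamma.theta})`) with closed-form
moments; HDMR variance-based sensitivity indices `S_u = Var(f_u)/Var(y)`;
and a mean-field mass-action ODE reduction whose fixed point at unit
high-fidelity concentration is verified and classified by its Jacobian
spectrum.

## Worked example

A single high-curvature run at `n = 3`: random singleton `R`, ten random
initial strands, tent landscapes with terminus 0.01, stopped when the
high-fidelity volume fraction reaches 25%.

```r
library(rnahit)
set.seed(5)
R  <- build_manifold(n = 3, q = 0)          # random singleton
k  <- curvature_from_terminus(0.01, 3)      # ~1.535
ls <- landscape(R, k = k, l = k, a = 10)
x0 <- init_population(3, 10, R, avoid_R = TRUE)
tr <- simulate_population(ls, x0, reaction_rates(), budget = 5000,
                          v = 0.25, seed = 42)
tr
#> SSA trajectory: n = 3 , I = 10 , 107 events in 0.8032 time units ( hit )
#>   hits: tau_rep = 0.03777, tau_R = 0.6387, tau_min = 0.7052, tau_v = 0.8032
```

Reading: the first replication happens almost immediately (`tau_rep`), the
high-fidelity sequence is discovered after most of the run (`tau_R`), its
concentration dips to a minimum shortly after (`tau_min`, the period the
replicator exists alone), and 25% of the population is high-fidelity 107
reactions in (`tau_v`) — the rapid end-of-run takeover characteristic of
sharply curved landscapes. With a flat landscape (terminus 0.1, same
protocol) the run censors at 5000 reactions without hitting.

The parameter-sweep / survival / sensitivity pipeline:

```r
sweep <- run_core_sweep(seed = 1)           # 100 runs, ~40 s
sum(!sweep$censored)
#> [1] 61                                    # finite hitting times

fit_sweep_survival(sweep, covariates = c("n", "k"))
#> Weibull proportional-hazards fit ( 61 events / 100 observations )
#>   shape alpha = 2.5701  scale beta = 323.31
#>       coef        se        p
#> n 3.511346 0.4545983 1.13e-14
#> k 1.481664 0.2862073 2.26e-07

classify_hitting(sweep)$S[c("terminus", "n")]
#>   terminus          n
#> 0.75830181 0.02040732                     # curvature dominates hitting
regress_hitting_time(sweep)$S[c("n", "terminus")]
#>          n   terminus
#> 0.65938620 0.02745174                     # dimension dominates time-to-hit
```

Both covariates increase the hazard (hitting) significantly, but the
variance decomposition splits the roles: landscape curvature controls
*whether* the replicator is found, sequence dimension controls *how long*
it takes when it is found.

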