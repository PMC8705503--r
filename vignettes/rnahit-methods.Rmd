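---
title: "Modelling replicator emergence: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling replicator emergence: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`rnahit` simulates a well-mixed population of fixed-length RNA sequences,
`x` in `E = {A,U,G,C}^n`, that can base-pair, dissociate, and copy one
another by template-directed polymerization. The question it is built to
study is a search problem: starting from random sequences, how long until a
designated *high-fidelity replicator* (a set `R` of sequences with maximal
replicative fitness and perfect per-site copying) is found and established
in the population?

Three reactions make up the core network, with mass-action propensities
over the molecule counts `N(.)`:

* duplex formation `x + xc -> {x,xc}` at rate `kds N(x) N(xc)` per
  unordered complementary pair (complementation is element-wise A-U / C-G,
  so `h(x, xc) = n` always);
* duplex dissociation `{x,xc} -> x + xc` at `kss` per duplex molecule;
* polymerization `x + y -> x + y + y*c` in which polymerase `x` copies
  template `y` into a mutated complement `y*c`, at rate
  `k_rep(x, y) = a f(x) s(x, y)` per ordered pair of distinct molecules.

Fitness `f`, similarity `s` and per-site fidelity `p` are landscapes over
Hamming distance: the *tent* form `exp(-k H(x, R))` with curvature `k`, or
an affine (*linear*) form interpolating from 1 on `R` to a terminus value at
distance `n`. Similarity uses the complement-invariant distance
`S(x, y) = min(h(x,y), h(x,yc))`, an ansatz that sequence proximity stands
in for spatial proximity of replicating foci. Copying errors are iid across
positions: each site emits the complement-correct base with probability
`p(x)` and otherwise one of the three alternatives uniformly, which is the
unique per-site model whose offspring distribution is uniform within each
Hamming level set and binomial across them
(`h(yc, y*c) ~ Binomial(n, 1 - p)`).

Optional channels extend the network: first-order decay of single strands
(duplexes are treated as stable), a zero-order surface ("clay")
oligomerization emitting a uniformly random sequence, first-order clay
polymerization with constant fidelity, and vesiculation (below).

Trajectories are sampled exactly with the Gillespie stochastic simulation
algorithm: waiting times are exponential in the total propensity, channels
fire proportionally to theirs, and every event updates the counting measure
incrementally. Propensity sums run over the occupied species only; the
similarity row-sum `w = S N` is maintained incrementally so one event costs
`O(4^n)` vector work rather than `O(16^n)`.

# Hitting times and censoring

Four first-passage times are detected online and by log replay:
`tau_rep` (first growth beyond the initial population size `I`), `tau_R`
(first appearance of a member of `R`, free or inside a duplex), `tau_min`
(the running minimum of the volume fraction after `tau_R` — the period the
replicator exists without amplification), and `tau_v` (volume fraction
`V(t) = N(X_R)/K` first reaching `v`). A run that exhausts its reaction
budget is right-censored at its end time, and censored runs enter the
survival likelihood through their survival term only.

Two readings in the definitions were fixed by choice and are configurable:
the indicator in the `tau_R` condition is read as "at least one member of
R present" (not "exactly one"), and `tau_min` reports the *last* attainment
of the running minimum (`first = TRUE` gives the first). A high-fidelity
sequence locked inside a duplex counts as present: the duplex contains the
information.

# Experiment protocols and the generator defaults

The experiment drivers define the study conditions rather than exposing
every knob as a dial:

* **Core sweep** (`run_core_sweep`): `n` in {3, 4} crossed with tent
  curvatures `k = l = -log(i)/n` for terminus grid
  `i` in {0.1, 0.05, 0.01, 0.005, 0.001}; fidelity curvature
  `m = -log(0.25)/n` so the least-fit sequences copy at random chance;
  `kss = kds = 1`; `I = 10` initial single strands; a random singleton `R`
  and one initial population per dimension, shared across curvature cells;
  10 replicates per cell, budget 5000 reactions, `tau_v` at `v = 0.1`. The
  replication scale `a` is calibrated per cell so the initial replicative
  mass is exactly 10, making times comparable across cells.
* **Expanded sweep** (`run_expanded_sweep`): adds decay `kdecay ~ U(0,1)`,
  clay fraction `fclay ~ U(0,1)` and clay fidelity `p ~ U(0,1)`, 24 iid
  draws per grid cell (a product design with uniform marginals; the layout
  within cells is this package's choice), `kclay_o = 1`, and the initial
  polymerization mass 20 split as `(1 - fclay) 20` RNA vs `fclay 20` clay.

Both sweeps draw the initial population disjoint from `R`. The protocols
only state that constraint explicitly for the expanded sweep, but without
it a draw of `X0` touching a singleton `R` makes `tau_v(0.1)` hit trivially
at time zero with `I = 10`; the disjoint initialization is the
non-degenerate reading and is applied uniformly.

What the generator does *not* emulate: finite nucleotide pools, explicit
diffusion, sequence-length change, or empirical polymerase landscapes.
Passing tests therefore show that the search-and-establishment dynamics
behave as modelled — not that any particular wet chemistry does.

# Survival analysis

Censored hitting times are fitted with a Weibull proportional-hazards
model: survival `R(t|theta) = exp(-(t/beta)^alpha e^{gamma.theta})`. The
likelihood is maximized over `(log alpha, log beta, gamma)` with BFGS;
Wald standard errors come from the observed information, delta-method
transformed for `alpha` and `beta`. Closed-form moments
(`E tau = beta e^{-gamma.theta/alpha} Gamma(1 + 1/alpha)`) are verified
against adaptive quadrature to 1e-6 relative error, and the whole fit is
cross-checked in the test suite against an independent accelerated-failure-
time fit (`survival::survreg`) through the AFT-to-PH reparameterization.
Covariates enter on their natural scales by default (`standardize = TRUE`
z-scores them). Ties need no special handling in a parametric likelihood.

# HDMR sensitivity analysis

The input-output maps — the per-run hitting indicator and the hitting time
on the finite-hit subsample — are decomposed as
`f0 + sum_i f_i + sum_{i<j} f_ij` with variance shares
`S_u = Var(f_u)/Var(y)`. Bases are orthonormal under the design's product
measure: full orthonormal polynomial contrasts for gridded inputs (`n` and
the curvature grid level) and shifted Legendre polynomials up to degree 3
for continuous inputs on their sampling domains. Coding the curvature input
by its grid level makes the indices invariant to any monotone recoding
(curvature vs terminus), which avoids an ambiguity in how that parameter
is scaled.

Two numerical choices matter on conditioned data. First, the least-squares
projection is solved by minimum-norm truncated SVD: after restricting to
finite hits some basis directions are exactly aliased (whole grid cells can
lose all observations), and a pivoted-QR solve can return enormous
coefficients on near-dependent column subsets. Second, component variances
are computed under the *sample* measure (on balanced designs this equals
the sum of squared coefficients under the product measure). Under the
product measure, a grid level retained by only two finite runs would carry
a fifth of the weight of that input; sample weighting keeps such levels
from dominating the variance shares. The classifier is fitted by
squared-error HDMR on the 0/1 indicator, so its indices decompose the
hitting probability on the same scale as the regressor's.

The regressor's conditioning on hits is deliberate and inherited from the
construction it reproduces: it estimates how long hits take given that
they occur, and the selection changes the roles of the inputs (curvature
decides *whether*, dimension decides *how fast*).

At the desk scale used by the tests (a 240-run reduction of the 2400-run
clay-and-decay experiment), the regressor's first-order indices are noisy:
the monotone effects of `fclay` and `kdecay` on the mean hitting time are
clearly visible in cell means, but scarce finite hits at flat-landscape
cells can hand the curvature input a larger index than either. The
full-size experiment is the appropriate scale for those indices.

# Mean-field ODE and stability

The mass-action reduction assigns one concentration per single-strand
sequence and per canonical duplex (`3 * 4^n / 2` coordinates). Duplex
formation and dissociation translate directly; polymerization keeps the
stochastic self-pair exclusion, `a f(x) s(x,y) [x]([y] - I(x=y))`, with
offspring distributed by the exact mutation kernel. The exclusion term is
load-bearing: with it, the state concentrating unit mass on a singleton
high-fidelity sequence annihilates every pair propensity and is an exact
zero of the field; without it the pair `(x, x)` would produce `xc` at rate
`a` there. At that state the Jacobian (central differences, dense
eigensolver) has no zero eigenvalue and a positive real eigenvalue — the
fixed point is unstable, and from any richer initial condition the total
concentration grows without bound, which the test suite confirms by
integration (`deSolve`). Any single-molecule vertex is likewise a zero of
the field under this reconstruction, so uniqueness is not asserted; the
analysis verifies the stated fixed point and its instability. Fixed points
are located by Newton iteration from a perturbed start rather than asserted,
with the residual reported.

# Compartmentalization

Vesiculation forms intervals on a 1-D projection `[-T, T]` of the reaction
volume, at rate `kmic` per single strand, centred on a random molecule;
an interval that would partially overlap an existing one is rejected
(vesicles nest or are disjoint, never cross). Replication is restricted to
molecule pairs sharing the same innermost vesicle region, so the total
replicative mass is bounded by the well-mixed value and strictly below it
as soon as occupied vesicles are disjoint — the trade-off between
compartmentalization and replicative mass. Unspecified spatial details are
fixed as: initial positions uniform on `[-T, T]`, offspring inherit the
template's position, vesicle width constant. This simulator tracks
individual molecules and is intended for small populations; the count-based
simulator covers the well-mixed case.

# Numerical and reproducibility choices

* Sequences are base-4 integers (A=0, U=1, G=2, C=3); complementation is a
  single XOR. Dense per-landscape tables (fitness, fidelity, similarity
  matrix, Hamming matrix) are precomputed for `n <= 5`; full-space
  enumeration guards at `n <= 8`.
* Image measures `mu = nu Q` are computed by grouping polymerase species
  over the at most `n + 1` distinct fidelity values, turning the
  `16^n x 4^n` kernel into a handful of `4^n x 4^n` products; a dense
  brute-force oracle checks this on toy states.
* One seeded RNG drives a run; replicate `i` of a sweep uses
  `base_seed + i`. Identical (config, seed) pairs reproduce event logs
  bit-for-bit, which the I/O tests assert.
* Problem sizes in the test suite: sweeps at their protocol sizes (100
  runs; 240 runs for the reduced clay-and-decay design), kernel oracles at
  `n <= 3`, the ODE analysis at `n = 2` (24 coordinates), Monte Carlo
  checks at 1e4-1e5 draws.

# Known limitations

Sequence length is fixed and small; the landscape tables are dense, so the
simulator is not meant for `n` beyond about 5-6. First-order rate
conventions count molecules (not unique species), the stronger mass-action
reading. Clay oligomerization emits uniform sequences — a maximum-entropy
choice where no law is specified. The HDMR explained-variance figures
depend on the estimator described above, and parameter recovery on
conditioned subsamples is approximate by construction.
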