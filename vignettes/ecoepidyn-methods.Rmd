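---
title: "Methods: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

`ecoepidyn` implements a four-variable eco-epidemiological system:
susceptible prey $S$, infected prey $I$, predator $P$, and a behavioural
cooperation level $x \in [0,1]$:

$$\frac{dS}{dt} = \Big[r - bS - cI - \frac{\beta(x) I}{a+S}
  - \frac{\alpha_1 P}{\sigma+S}\Big] S, \qquad
\frac{dI}{dt} = \Big[\frac{\beta(x) S}{a+S} - \frac{\alpha_2 P}{d+I}
  - \mu\Big] I,$$

$$\frac{dP}{dt} = \Big[\Big(\frac{c_1\alpha_1 S}{\sigma+S}
  + \frac{c_2\alpha_2 I}{d+I}\Big)\frac{P}{\theta+P} - m\Big] P, \qquad
\frac{dx}{dt} = x(1-x)\,G(S,I,P).$$

Assumptions worth making explicit:

* **Saturated incidence.** The infection force is $\beta(x) I/(a+S)$:
  per-capita transmission declines as the susceptible pool grows,
  representing behavioural inhibition. $a$ is its half-saturation
  constant.
* **Holling type-II predation** on both prey classes, with separate
  attack rates ($\alpha_1, \alpha_2$), half-saturations ($\sigma, d$) and
  conversion efficiencies ($c_1, c_2$).
* **Weak Allee effect on the predator.** The mate-finding probability
  $P/(\theta+P)$ multiplies the predator's *growth* term only. It is 0 at
  zero density, increasing, and saturates at 1. Two exactness contracts
  are enforced and tested: $\theta = 0$ reduces the factor to exactly 1
  (the Allee-free model is recovered without roundoff), and the $0/0$
  corner $P = \theta = 0$ is defined as 1 — the factor only ever
  multiplies a term already carrying a factor of $P$, so any finite
  convention yields the correct product 0, and 1 preserves the
  $\theta \to 0$ limit.
* **Behaviour modulates transmission linearly**, $\beta(x) =
  \beta_0(1 - e x)$, floored at 0 (the floor can only activate for
  $e x > 1$, outside the recommended $e \in [0,1]$; a warning is emitted).
* **Replicator dynamics** keep $x$ in $[0,1]$: the factor $x(1-x)$
  vanishes at both boundary strategies, so $[0,1]$ is invariant — as is
  every coordinate face $S=0$, $I=0$, $P=0$ (each bracket carries its own
  population factor). These face invariances are asserted over randomised
  parameter draws in the test suite.

### The payoff gain $G$ and its readings

The payoff gain of cooperating is genuinely ambiguous in the source
formulation, so it is isolated behind `strategy_gain()` with three
switchable readings: `literal` (default) $G = -C_S S + I + C_P P$,
`pooled` $G = -C_S(S+I) + C_P P$, and `ratio` $G = -C_S/(S+I) + C_P P$
(guarded near $S+I=0$). The literal reading is the default because it
matches the component-wise description of the formulation and because its
qualitative predictions along $C_S$ (higher cost of cooperating with a
large susceptible pool suppresses cooperation, raising infection and
oscillation) are the ones the downstream scan scenarios exhibit. The
`ratio` reading can drive $S+I$ toward zero and is numerically the most
delicate (see *Underflow absorption* below).

Under any of the three readings, the direction of the predator-survival
pattern in the $(C_S, e)$ plane is the same: predator persistence at high
transmission requires sustained infection, sustained infection requires
low cooperation, and low cooperation is delivered by *high* $C_S$. This
is a structural property of the model worth knowing before interpreting
two-parameter scans.

## Parameters

All rates are per unit time; densities are in arbitrary biomass units.
The defaults of `model_params()` are the canonical scenario set used by
every preset: $a=0.3636$, $b=1$, $\alpha_1=0.01$, $\sigma=15$, $c=0.01$,
$r=1$, $\alpha_2=0.05$, $d=0.5$, $\mu=0.4$, $c_1=2$, $c_2=1$, $e=1$,
$m=0.01$, $\theta=0$, with $\beta_0=0.95$ and $C_S = C_P = 0.5$. One
widely copied transcription of this set reads "$e=15$" where every other
statement of it reads "$\sigma=15,\ e=1$"; the registry adopts the latter
and records the former as a transcription erratum in the preset notes.
Presets for the dynamic-strategy and bifurcation scenarios that do not
state $\beta_0$ adopt $\beta_0 = 0.95$ for continuity with the
fixed-strategy ladder; this is flagged as an adopted (not quoted) value
in their notes.

The initial condition is $(S,I,P)(0) = (0.99, 0.01, 0.01)$ throughout;
dynamic-strategy runs start from the uninformative interior point
$x(0) = 0.5$ (the formulation leaves $x(0)$ open; an interior point is
required for replicator dynamics to move at all, and 0.5 encodes no prior
toward either strategy). Both are overridable.

## Numerical choices

* **Integration.** `deSolve::lsoda` (adaptive, `rtol = 1e-8`,
  `atol = 1e-10`) by default; classical RK4 with a fixed internal step
  (`dt_fixed = 1e-3`) as a cross-check integrator. The two agree to
  better than $10^{-5}$ relative on the oscillatory ladder scenario over
  200 time units (tested). The right-hand side is compiled C; a pure-R
  reference implementation is tested to agree exactly, and an
  independently re-derived RHS (different algebraic arrangement) agrees
  to $10^{-12}$ relative on 1000 random states.
* **Chunked clamping.** Integration proceeds in 50-time-unit segments.
  Between segments, components below 0 are clamped to 0 (logged as an
  event when the excursion exceeds `abs_tol`), $x$ is clamped into
  $[0,1]$, and components below the absorption floor $10^{-30}$ are set
  to exactly 0. The floor is 22 orders of magnitude below the extinction
  threshold, so it cannot affect any extinction call; it exists because a
  compartment decaying exponentially toward $10^{-130}$ and beyond drags
  the step-size controller into failure (observed with the `ratio`
  payoff reading), while a face-absorbed 0 is exact and smooth.
* **Extinction calls.** `detect_extinction()` reports the first time a
  compartment dips below `extinction_eps` ($10^{-8}$) and whether it
  stayed below. The operational `extinct` flag uses a terminal-suffix
  rule — below `eps` from some time through the end, with that stretch
  covering at least 5% of the horizon — because deep relaxation-cycle
  troughs can pierce `eps` transiently and rebound, and a trough that
  happens to sit at the very end of a window must not be called
  extinction.
* **Equilibria.** Damped Newton (analytic Jacobian, step-halving line
  search, residual tolerance $10^{-10}$) from a deterministic
  $10 \times 10 \times 10$ multi-start grid over $[0, r/b]^3$ — $r/b$ is
  the disease-free carrying capacity, a natural a-priori seed box. Ten
  seeds per axis suffice here: the equilibrium set is unchanged under a
  doubled grid (tested); the closed-form axial states are always seeded
  exactly. Duplicates merge at distance $10^{-6}$; solutions with
  negative components are discarded.
* **Stability labels.** Eigenvalues within $10^{-7}$ of the imaginary
  axis yield `non_hyperbolic` rather than a guess — threshold scans
  probe exactly these boundaries.
* **Attractor classification.** Extinction labels take precedence; then
  post-transient amplitude below `point_tol` ($10^{-4}$) means
  `stable_point`; then a largest Lyapunov exponent above `chaos_tol`
  (0.005) means `chaotic`; otherwise the number of distinct
  peak-value clusters (relative tolerance $10^{-3}$) separates
  `limit_cycle` from `period_doubled`. The Lyapunov estimate is the
  standard two-trajectory Benettin procedure: a companion orbit offset by
  $10^{-8}$, renormalised every 1 time unit over the post-transient
  window; `chaos_tol` separates the cycle-neutral direction (whose
  finite-horizon estimate hovers near 0) from genuine exponential
  divergence at desk-scale horizons.
* **Horizons.** The solver default is `t_end = 500` with the transient
  cut at `t_end/2`. The model's relaxation cycles have periods around
  250 time units, so scans and classification runs in the tests and the
  acceptance script use `t_end = 2000`–2500 (several full periods after
  the transient); near-threshold runs need the longer horizon because
  weakly damped foci decay on $10^3$-unit timescales.

## The bifurcation structure along the frozen strategy

With behaviour frozen ($dx/dt = 0$), raising $x$ simply lowers
$\beta(x) = 0.95(1-x)$. Three critical points line up along $x$ (all
computed by the package, all under the default parameter set):

1. **Interior Hopf, $x \approx 0.3624$** (`hopf_threshold()`): the
   coexistence equilibrium's complex pair crosses the imaginary axis.
   For $x$ just above it the equilibrium is a *weakly* stable focus
   ($|\mathrm{Re}\,\lambda| \lesssim 2\times10^{-3}$), so perturbations
   decay on thousand-unit timescales and any finite-horizon diagram
   still shows oscillation dots there.
2. **Predator-loss transcritical, $x \approx 0.4185$**
   (`invasion_threshold()`): the predator's invasion eigenvalue at the
   predator-free endemic state crosses zero; simultaneously the interior
   equilibrium's $P^\*$ component reaches 0 and its leading eigenvalue
   touches zero. Beyond it the attractor is a strongly damped boundary
   state, so the oscillations collapse *visibly* here — this, not the
   weak Hopf, is the flip a simulation scan resolves, and the two agree
   within one grid step (tested, and recomputed by
   `scripts/acceptance.R`).
3. **Infection loss, $x \approx 0.4259$**: $\beta(x)$ falls below the
   invasion value $\mu(a+K)/K$ at carrying capacity $K = r/b$ and the
   disease disappears, leaving the disease-free, predator-free state.

The same geometry read along $\beta_0$ at $x = 0$ explains the
transmission ladder: below $\beta_0 \approx 0.545$ the infection cannot
invade at all (no coexistence equilibrium exists — the stable state is
disease-free); the interior Hopf sits at $\beta_0 \approx 0.6057$; at
$\beta_0 = 0.6$ the coexistence equilibrium is therefore weakly *stable*
and the sustained-looking oscillations there are slowly decaying
transients; by $\beta_0 = 0.8$ the equilibrium is genuinely unstable and
the attractor is a relaxation cycle.

Two further structural properties of the model deserve emphasis because
they are easy to mispredict:

* **Any positive $\theta$ dooms a rare predator.** The mate-finding
  factor vanishes at $P = 0$, so the predator's invasion eigenvalue is
  identically $-m$ for $\theta > 0$: a predator reduced to rarity cannot
  re-invade. In simulations from the standard initial condition,
  $\theta = 0.3$–$0.5$ at high transmission drives the *predator* to
  extinction while the infection persists on a healthy prey–infection
  cycle; a weak Allee effect here removes the predator, not the disease.
* **Predator survival in the $(C_S, e)$ plane sits at high $C_S$** (or
  low $e$), by the cooperation–infection–predation chain described
  above.

## What the scenario battery does and does not show

The preset registry encodes the full scenario battery (transmission
ladder, Allee sweeps, frozen- and dynamic-strategy bifurcation scans,
two-parameter outcome diagrams) so every experiment and test is
self-contained and deterministic: no field data enters anywhere. Passing
tests therefore demonstrate internal correctness — the implemented
equations, Jacobian, solver, equilibrium finder and classifiers agree
with each other and with independent oracles (finite differences,
re-derived RHS, cross-integrator checks, perturbed-simulation stability
concordance) — not that the model describes any particular ecological
community. The model itself omits space, stochasticity, age structure
and delays; its parameters are abstract, and the behavioural-cost
coefficients are theoretical controls rather than measured quantities.

## Known limitations

* Peak-cluster counting classifies a cycle with a multi-humped profile
  (the infected-prey pulse has two local maxima per period) as
  `period_doubled`; the `oscillatory` flag and amplitude columns are the
  robust quantities for scan-level decisions.
* The Lyapunov estimate at desk horizons has a resolution of roughly
  $\pm$`chaos_tol`; weakly damped foci and true cycles both produce
  small-magnitude values.
* `hopf_threshold()` tracks one interior branch by continuation; systems
  with multiple interior equilibria would need the multi-start finder at
  each bisection step instead.
* Near-threshold regime labels depend on the horizon: a weakly damped
  focus looks oscillatory until `t_end` is several multiples of
  $1/|\mathrm{Re}\,\lambda|$. Doubling the horizon and transient leaves
  every regime label in the tested scans unchanged, but labels within
  one grid step of a threshold are intrinsically horizon-sensitive.
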