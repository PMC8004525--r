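---
title: "Methods: equilibria, bifurcations and randomized ensembles in the fox-cottontail-hare model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: equilibria, bifurcations and randomized ensembles in the fox-cottontail-hare model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperpred)
```

## The model and its assumptions

`hyperpred` analyses the three-species system

$$
\begin{aligned}
\dot V &= V\,(r - c_{VV} V - m + e a S + e b L)\\
\dot S &= S\,(s - c_{SS} S - n - a V)\\
\dot L &= L\,(u - c_{LL} L - p - b V)
\end{aligned}
$$

for fox ($V$), invasive Eastern cottontail ($S$) and native European hare
($L$) densities in individuals per km², with time in years. Three
modelling commitments are baked in and not configurable:

* **Bilinear (Holling type I) predation.** Fox densities in the study
  region are of order 1–2.5 per km² and lagomorph densities stay below
  ~110 per km², well inside the linear range of a saturating response;
  feeding saturation is therefore omitted. There is deliberately no
  satiation option: adding one would change the bifurcation structure
  (saturating responses admit Hopf bifurcations, which this model
  provably lacks).
* **No direct prey–prey competition.** The two lagomorphs select
  different macro- and microhabitats; the $(S,L)$ and $(L,S)$ Jacobian
  entries are structurally zero. Their interaction is purely *apparent*,
  mediated by the shared predator.
* **Separate reproduction and mortality.** Field-derived rates can have
  negative net growth ($r<m$), which a single logistic "growth rate"
  cannot express; extinction regimes are first-class outcomes here.

## Parameters and their provenance

The twelve rates live in an `hp_params` object. The reference set is
derived from life-history quantities by three one-line conversions:

* mortality = 1 / mean lifespan (exponential survival): lifespans 3.5 y
  (fox), 1.25 y (cottontail — the ~15-month mean, not the 5-y maximum
  lifespan, since the conversion needs the mean) and 5.5 y (hare);
* reproduction = log of the observed annual multiplication factor
  (solution of $P(1) = k\,P(0)$ under exponential growth): factors 3,
  4.5 and 5;
* competition = (reproduction − mortality) / carrying capacity, which
  pins the single-species equilibrium at the field capacity: 1 fox,
  100 cottontails, 30 hares per km².

The conversion coefficient defaults to $e = 0.91$, the measured
digestibility of lagomorph prey for foxes (reported values for rabbits
and hares are close enough to share one number). The hunting rates $a$
and $b$ carry no field estimate and are left `NA` in the reference set;
every scenario must set them explicitly. All values are stored as exact
expressions (`log(3)`, `2/7`, ...) and evaluated lazily, so printed
5-digit decimals are roundings of exact quantities; tests compare at five
significant digits.

```{r}
reference_params(a = 0.2, b = 0.5)
```

## Equilibria, margins, and the attractor

All eight equilibria (one per subset of surviving species) have closed
forms, implemented in `equilibria()`. Every feasibility and stability
condition is exposed as a *margin* — left minus right of the inequality
in its "satisfied" orientation — so downstream code can root-find on
them directly. Three conventions matter:

* **Strict inequalities, boundaries flagged.** A margin of exactly zero
  classifies as infeasible/unstable and sets a `boundary` flag. The
  closed-form conditions mix strict and non-strict inequalities at
  measure-zero parameter sets; the bifurcation machinery owns those
  boundaries, and `classify_attractor()` raises a classification error
  rather than guessing.
* **Stability of infeasible candidates is still computed** (it is needed
  to draw exchange diagrams), but the closed-form verdicts are
  eigenvalue-exact only at feasible candidates: their Routh–Hurwitz
  reductions assume nonnegative populations. Tests cross-validate
  verdicts against numerically computed Jacobian eigenvalues at feasible
  candidates on 1000 random parameter sets.
* **Coexistence is unconditionally stable when feasible**; its
  "stability margins" are the three Routh–Hurwitz quantities, reported
  numerically.

Local stability implies global stability for this system, and
bistability is impossible, so the unique feasible-and-stable candidate is
*the* long-run state. The regime taxonomy (`regime_case()`) reproduces
the same answer from the sign pattern of the net rates
$(r-m,\,s-n,\,u-p)$ plus four threshold comparisons
($k_1, k_2, h_2, g_2$) on the competition coefficients; the package
derives these comparisons from the stability margins themselves. Two
regimes deserve a note: in $(-,+,-)$ the cottontails-only state is
stable for *large* $c_{SS} > h_2$ (low competition means a cottontail
density high enough to sustain invading foxes), and in $(-,+,+)$
coexistence is possible even though foxes cannot persist on either prey
alone — the two prey jointly sustain them.

Global stability is certified by a quadratic Lyapunov form whose matrix
(`lyapunov_matrix()`) is equilibrium-independent. The weights default to
$(1, e, e)$: this choice cancels both off-diagonal entries exactly,
leaving a manifestly negative-definite diagonal form, which is the
simplest certificate the structure admits. Other positive weights are
accepted and checked via leading principal minors.

## Transcritical thresholds and their classification

Equilibria exchange stability only through transcritical bifurcations:
the quadratic vector field has identically vanishing third derivatives
(no pitchforks), and the Lyapunov structure excludes purely imaginary
eigenvalues (no Hopf, hence no sustained oscillations). The admissible
exchanges form a 12-arc graph (`exchange_graph()`): two equilibria are
joined exactly when their surviving-species sets differ by one species,
whose density crosses zero at the exchange.

`threshold_solve()` locates a threshold as the root of the exchanged
species' population *numerator* in the larger equilibrium — a polynomial
of degree at most two in any single parameter. The polynomial
coefficients are recovered exactly from three evaluations (divided
differences), the roots come from the stable quadratic formula, and a
bisection root (tolerance $10^{-12}$) cross-checks every root where the
margin changes sign. Quadratic margins with two roots in the bracket
produce two points: these are the re-entrant coexistence windows. At each
root, a zero eigenvalue of *both* Jacobians is verified, and the
transcritical coincidence — feasibility boundary of the larger
equilibrium ≡ stability boundary of the smaller — holds to $10^{-9}$
between two independently coded margins.

Classification uses the Sotomayor scalars with one refinement. The
boundary equilibrium moves with the bifurcation parameter, so the raw
scalar $w^{\mathsf T}(D F_\mu\, v)$ vanishes spuriously whenever the
parameter does not appear in the critical species' equation (e.g. the
coexistence/foxes-cottontails exchange swept in $a$). The package
therefore evaluates the transversality in coordinates that pin the
persisting equilibrium at the origin,
$w^{\mathsf T}\!\left(DF_\mu v + D^2F(\mathrm d x_0/\mathrm d\mu,\, v)\right)$,
which equals the crossing speed of the critical eigenvalue up to the
positive factor $w \cdot v$. Null eigenvectors are normalized to unit
length with first nonzero component positive, so the reported scalars
are reproducible to sign. The pitchfork scalar is returned as an exact
zero.

With the reference rates, the interesting transitions happen at hunting
rates below about one (the calibrated fox-only density of 1 fox per km²
makes larger hunting rates collapse one or both prey immediately). The
package's reference sections, each verified by both the closed-form
margins and grid classification:

```{r}
sweep_attractor("a", c(0.02, 0.4), n_grid = 151,
                params = reference_params(b = 0.3))
sweep_attractor("b", c(0.02, 1), n_grid = 151,
                params = reference_params(a = 0.2))
sweep_attractor("b", c(0.2, 1), n_grid = 151,
                params = reference_params(a = 0.3))
```

The first two show re-entrant coexistence (both roots of a quadratic
margin); the third is the invasion-relevant chain — alien-free system,
then coexistence, then hare extinction — obtained here by increasing the
hunting pressure on hares. `sweep_attractor()` grids the attractor,
localizes each label change with `threshold_solve()`, and recovers
windows narrower than the grid step by trying common neighbours in the
exchange graph.

## Numerical integration choices

* `simulate_dynamics()` uses `deSolve`'s lsoda (adaptive,
  stiff-capable) in linear state space with `rtol = 1e-8`,
  `atol = 1e-10`. The extinction faces are invariant analytically;
  numerically, undershoots larger than $-10^{-9}$ abort (integrator
  misuse) and smaller ones are clamped to zero. Effective extinctions
  (density `< 1e-6` for more than 10 y) are logged per species.
* The default horizon is 500 y with a 50-y convergence window and
  tolerance $10^{-8}$ on both state drift and the right-hand side: the
  slowest reference net rate is ~0.3/y, so transients decay well inside
  that horizon.
* The steady-state engines behind ensembles and the global-stability
  checks (`integrate_to_steady()`, fixed-horizon recording) integrate
  the strictly positive components in **log space**. Damped
  predator–prey overshoot can take a density through values of order
  $e^{-100}$: in linear space those underflow onto the absorbing
  extinction face and strand the trajectory on an unstable boundary
  state, while log-space integration controls *relative* error at every
  magnitude and carries the trough through. Components starting at
  exactly zero stay zero, respecting face invariance. Runs that have not
  met the criterion keep doubling their horizon up to `t_max = 64000` y
  (slow convergence happens only near bifurcation boundaries, where a
  jittered draw can land).
* Halving the integrator tolerances changes final states by less than
  $10^{-7}$ (tested), and long runs show no residual oscillation
  (peak-to-peak below $10^{-5}$ over the final 20 %).

## The randomized ensemble: what it emulates

`run_ensemble()` reproduces the randomized steady-state study behind the
hyperpredation conclusion: `n = 500` parameter sets, each entry drawn
uniformly within ±9 % of its reference value, hunting rates
`a = 0.2, b = 0.5`, initial state $(V,S,L) = (0.4, 1, 3)$ per km². All
twelve rates are jittered by default; because it is ambiguous whether
hunting rates belong to the jittered set, `jitter_hunting = FALSE`
freezes them without disturbing the random stream. Two shipped configs
(`inst/extdata/ensemble_draw*.yaml`) differ only by seed, mirroring two
independent random draws of the same study. A fixed seed makes records,
bins and slopes bit-identical across reruns.

Steady states are harvested in one of two modes:

* `mode = "converged"` (default): integrate until the steady-state
  criterion holds. Extinct species then sit at exactly zero, and the
  regression stage's log floor (`1e-6`, configurable) excludes those
  records, tallying them per bin. Under the study conditions the
  reference attractor is the hares-extinct state `E3` (the coexistence
  candidate has a negative hare component), so most high-cottontail
  records carry $L = 0$ and drop out: the surviving-hare slopes do not
  turn negative.
* `mode = "fixed_horizon"`: record the state at 500 y regardless of
  convergence. A hare population on its way to extinction is then
  captured at a small positive density (resolved by the log-space
  integrator), and the per-bin regressions of $\ln L$ on $V$ show the
  signature the field data motivated: slopes near zero or positive in
  low-cottontail bins, turning strongly negative as cottontail density
  rises. This mode is the package's reading of how endpoint data from a
  finite simulation campaign behave; the trend is reported
  (`slope_trend()`), not asserted numerically, because its strength
  depends on the draw.

Each record cross-checks the integrated steady state against the
closed-form populations of the classified attractor (`cf_dev`,
typically below $10^{-9}$ in converged mode). Binning uses
open-left/closed-right intervals — the edges (1,3], (3,5], (5,7],
(7,9], (9,11], (11,13] by default; membership of a record exactly on an
edge is a measure-zero convention, fixed as "lower bin". The per-bin
ordinary least squares is implemented from the normal equations
(slope, intercept and slope standard error), with `lm()` serving as an
independent oracle in the tests and synthetic known-line groups
providing parameter-recovery checks.

### What the generator does *not* emulate

The ensemble varies rates deterministically around one reference
ecology. It has no demographic or environmental stochasticity, no
observation error, no spatial structure, and no year effects — all
present in real count data. Passing tests therefore show that the
*model* produces the apparent-competition signature under parameter
uncertainty, not that field data of this shape must arise from
hyperpredation.

## Problem sizes used by the tests

The shipped suite validates eigenvalue agreement and attractor
uniqueness on 1000 well-separated random parameter sets, global
convergence on 50 sets × 20 random starts, the full 500-run ensemble
twice (bit-identical rerun), and the sweep sections above at 151 grid
points; the whole suite runs in a few minutes on one core. These sizes
are the package's reference study conditions, chosen to match the
analyses they reproduce.

## Known limitations

* Boundary parameter sets (any margin exactly zero) are deliberately
  unclassified; use the bifurcation tools there.
* `sweep_attractor()` cannot see a re-entrant window that lies strictly
  between two grid points *and* returns to the same label on both sides;
  increase `n_grid` when hunting for narrow windows.
* The Sotomayor machinery assumes a simple zero eigenvalue; codimension-2
  points (two margins vanishing together) report `degenerate` and are
  not unfolded.
* Regression standard errors assume independent homoscedastic residuals
  within a bin; ensemble records violate this mildly since all runs share
  the reference ecology.
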