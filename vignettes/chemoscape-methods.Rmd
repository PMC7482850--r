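---
title: "Chemostat resource competition under metabolic trade-offs: models and methods"
author: "chemoscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemostat resource competition under metabolic trade-offs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemoscape)
```

## The modelling framework

chemoscape simulates competition among microbial metabolic strategies in a
chemostat. A strategy is a point $\vec\alpha$ on the allocation simplex: each
component is the fraction of the cell's internal resource budget (enzymes,
transporters) allocated to one metabolic function, and an exact trade-off is
assumed, $\sum_j \alpha_j = 1$. The chemical environment is the vector
$\vec c$ of extracellular metabolite concentrations. A metabolic model maps
$(\vec c, \vec\alpha)$ to a growth rate $g(\vec c, \vec\alpha) \ge 0$ and an
impact flux $I_i(\vec c, \vec\alpha)$ per unit cell volume (negative
components are secretion). Populations and environment are coupled by the
chemostat equations

$$\frac{dm_\sigma}{dt} = m_\sigma\,(g(\vec c, \vec\alpha_\sigma) - d),
\qquad
\frac{dc_i}{dt} = d\,(c_{i,\mathrm{supply}} - c_i)
  - \sum_\sigma \frac{m_\sigma}{r}\, I_i(\vec c, \vec\alpha_\sigma),$$

with dilution rate $d$, supply vector $\vec c_\mathrm{supply}$ and biomass
per cell volume $r$ (default 1). All quantities are dimensionless model
units: rates in units of the maximal uptake rate, concentrations in units of
the Monod constants. At a steady state every surviving species grows at
exactly $d$.

Two nullclines organise all of the geometry. Setting $dm_\sigma/dt = 0$
gives the *growth contour* (the zero-net-growth isocline) of a strategy: the
level set $g(\vec c, \vec\alpha) = d$ in chemical space. Setting
$dc_i/dt = 0$ for a single resident gives the *flux-balance curve*: the
one-parameter family of environments indexed by the resident's biomass. The
single-species steady state is their intersection.

## The five bundled metabolic models

All import steps use Monod kinetics $c/(K + c)$ with defaults $v = K = 1$
and unit yields, chosen as the standard saturating form; every constant can
be overridden through `make_model(params = )`, and per-nutrient constants
may be vectors for asymmetric variants.

**`substitutable`** ($p$ nutrients, $p$ functions). Growth is additive,
$g = \sum_i w_i v_i \alpha_i\, c_i/(K_i + c_i)$, and impact is the uptake
flux. Because $g$ is linear in $\vec\alpha$ at fixed $\vec c$, the
maximizing strategy is a vertex of the simplex (all-or-none specialist), and
with the exact trade-off all growth contours at a given $d$ share the common
point where every Monod term equals $d$ — the geometric origin of the flat
fitness landscape and unlimited coexistence.

**`essential`** (2 nutrients, 2 functions). Growth follows the law of the
minimum, $g = \min_i(v_i \alpha_i c_i/(K_i + c_i))$. Impact equals the full
transporter uptake even for the non-limiting nutrient (luxurious uptake).
This choice is deliberate: it makes each resident deplete the nutrient it
over-imports, creating a self-favouring environment, which is what produces
bistable pairs and the ascending chain of invasion. Growth-matched
consumption would remove the bistability.

**`substitutable_assim`** (3 nutrients, 6 functions). Each nutrient is
processed by a serial import/assimilation bottleneck,
$g = \sum_i w_i \min(\alpha_{\mathrm{imp},i} v\, c_i/(K + c_i),\;
\alpha_{\mathrm{as},i} v_\mathrm{as})$, with impact equal to the import flux
(imports in excess of assimilation capacity are wasted). The wasteful-import
channel is what allows a species to suppress a competitor's nutrient without
profiting from it, the ingredient for cyclic (rock–paper–scissors)
invasion.

**`interconvert`** (2 nutrients, 4 functions:
$\alpha_a, \alpha_b, \alpha_{ab}, \alpha_{ba}$). Both nutrients passively
diffuse across the membrane at rate $D$, can be imported actively, and can
be enzymatically interconverted inside the cell ($\alpha_{ab}$ converts
internal $b$ into $a$ at rate $v_c \alpha_{ab} x_b$, and vice versa). Both
internal pools are essential: $g = v_g \min(x_a, x_b)$, and growth drains
$y$ units of each pool per unit of growth flux. The drain is a deliberate
design choice: with a purely catalytic growth term, any conversion-free
strategy re-exports by diffusion exactly what it imports and has zero net
impact at quasi-steady state, so residents could never shape their medium.
Defaults $v_c = 1$, $D = 0.2$, $v_g = y = 1$ produce the three
maximizing-strategy sectors (importer wedge around the diagonal flanked by
the two converter sectors); larger $D$ blurs the importer wedge by making
passive influx too generous.

**`secretion`** (chemicals $S$ and $I_\mathrm{ext}$; 4 functions:
$\alpha_{ATP1}, \alpha_{ATP2}, \alpha_\mathrm{exp}, \alpha_\mathrm{imp}$).
A single substrate $S$ is processed through a two-step energy pathway with a
dual-role intermediate. The first reaction
$J_1 = \alpha_{ATP1} v_1 \frac{c_S}{K_S + c_S}\frac{K_\mathrm{inh}}{K_\mathrm{inh} + x}$
produces the internal intermediate $x$ and is product-inhibited by it; the
second reaction $J_2 = \alpha_{ATP2} v_2 x/(K_I + x)$ consumes it; export
($\alpha_\mathrm{exp} v_e\, x/(K_e + x)$) dumps it into the medium, where it
can be re-imported ($\alpha_\mathrm{imp} v_m\, c_I/(K_m + c_I)$). Growth is
total ATP production $w_1 J_1 + w_2 J_2$; the impact on $S$ is $J_1$ and on
$I_\mathrm{ext}$ is import minus export. Defaults
$v_1 = 5, v_2 = 1, v_e = 6, v_m = 2, K_\mathrm{inh} = 0.1$ (all other
constants 1) make strong inhibition plus efficient export favour *polluters*
($\alpha_{ATP1}+\alpha_\mathrm{exp}$) at high $S$, *cleaners*
($\alpha_{ATP2}+\alpha_\mathrm{imp}$) at high $I_\mathrm{ext}$, and
*generalists* ($\alpha_{ATP1}+\alpha_{ATP2}$) in between — the three classes
the class map reports. With these stand-in constants the maximal-contour
discontinuity at both $d = 0.4$ and $d = 0.6$ is polluter/cleaner; which
classes flank the high-dilution kink is sensitive to the kinetic constants,
so fixtures assert class counts and kink existence rather than the flanking
identities.

### Quasi-steady internal states

For the two internal-state models the intracellular pools are solved
algebraically at every evaluation rather than co-integrated, keeping $g$ and
$I$ pure functions of $(\vec c, \vec\alpha)$ as the geometric machinery
requires. The interconversion balance is piecewise-linear in the pools (the
$\min$ picks the limiting one); both branches are solved in closed form and
the self-consistent branch kept. The secretion balance reduces to a
quadratic when $K_I = K_e$ (the default) and is otherwise bracketed and
bisected, followed by a short Newton polish to a residual below $10^{-10}$.
Strategies whose saturated consumption plus export cannot match their influx
have no finite balance point; they are flagged `diverged` and evaluated at
their limiting fluxes (fully inhibited first reaction, saturated second
reaction). Tests verify the algebraic states against long-time integration
of the explicit intracellular ODE.

## Geometry in chemical space

`growth_contour()` and `maximal_growth_contour()` extract level sets on a
log-spaced grid (concentrations span decades) by marching squares
(`grDevices::contourLines`), then refine every vertex by bisection along the
grid axis with the larger local gradient until the residual $|g - d|$ is
below $10^{-7}$ (reported tolerance $10^{-6}$). Log spacing plus
axis-aligned bisection is robust for the kinked, min-type growth functions,
where curvature-based refinement fails.

`maximizing_strategy()` returns the simplex argmax of $g(\vec c, \cdot)$.
It is analytic for the substitutable model (best vertex), the essential
model (allocation equalising the two Monod terms), and the serial-bottleneck
model (all budget on the best nutrient, split so import equals assimilation
capacity). For the internal-state models every two-component face of the
simplex is maximised by golden-section search, all vertices are evaluated,
and a multi-start Nelder–Mead over a softmax chart of the full simplex
guards against interior optima (`interior = FALSE` restricts to the faces,
used for dense grid scans; the full search is validated against a
$\sim 10^4$-point barycentric brute force in the tests). Ties within
$10^{-9}$ set a degeneracy flag.

The *maximal growth contour* is the $d$-level set of the envelope
$g_{\max}(\vec c)$. Each refined point carries its maximizing strategy and a
class label — the sorted set of strategy components above the activity
threshold $10^{-6}$. A discontinuity is a class change between adjacent
contour points, localised by bisection along the connecting segment to an
arc resolution of $10^{-4}$; this label-based definition matches the
slope-kink definition for these models and is far more robust numerically.
`supply_line()` exposes the ray of supply points
$\vec c_0 + \frac{m}{r d} \vec I(\vec c_0, \vec\alpha)$ for which a strategy
recreates the anchor environment $\vec c_0$, and `in_supply_cone()` tests
membership of the cone spanned by two such rays at a discontinuity — the
supply region of evolutionarily stable coexistence. `c_opt()` intersects
the maximal contour with the flux-balance relation evaluated with the local
maximizing strategy, by minimising the spread of the per-nutrient implied
biomasses along the contour polyline.

Contours are restricted to two-dimensional chemical spaces; the 10-nutrient
analyses need only pointwise growth and argmax evaluations, which work in
any dimension.

## Dynamics and steady states

`simulate_chemostat()` integrates the community with `deSolve::lsoda`
(relative tolerance $10^{-8}$, absolute $10^{-10}$), in blocks so that
species crossing the extinction threshold $10^{-9}$ are clamped to zero and
logged as events; fluxes are evaluated at clamped nonnegative
concentrations, so concentrations cannot escape the positive orthant.
`steady_state()` integrates in growing chunks until the derivative norm
$\max|dy/dt|$ falls below $10^{-8}$, then applies a damped Newton polish to
the algebraic system (growth $= d$ per survivor, mass balance per nutrient),
typically reaching residuals near $10^{-12}$; systems that never settle —
limit cycles — are reported as non-converged results, not errors.
`simulate_chain()` couples $k_\mathrm{tot}$ identical vessels through a
discrete Laplacian on both biomasses and chemicals at leakage rate $l$ (the
legend of the linked-chemostat setup says medium *and* cells are exchanged,
so both leak at the same rate), with no-flux boundaries — a finite chain;
periodic boundaries would destroy the spatial gradient the setup is meant to
exhibit.

## Evolutionary procedures

The rule of invasion evaluates an invader's growth rate in the resident
community's steady-state environment; invasion succeeds when it exceeds
$d$ by more than the strictness margin $10^{-9}$ (so a resident never
counts as invading itself). Invaders introduced dynamically start at
biomass $10^{-6}$ — a concrete stand-in for "infinitesimally small".
`chain_of_invasion()` iterates replacement by the best response (the
maximizing strategy of the resident's environment) until the resident is
within $10^{-6}$ of the maximizing strategy of its own environment — the
non-invasible strategy; the replacement reading follows the single-resident
narrative of the essential-nutrient story. `greedy_assembly()` instead
accumulates: it adds the opportunist whenever $g_{\max} - d$ exceeds the
margin $10^{-6}$ at the community steady state, prunes extinctions, and
terminates when the landscape is flat at the top. `invasion_graph()`
classifies all ordered pairs into mutual / bistable / one-way motifs and
reports directed 3-cycles.

## The fixture library and what it does and does not emulate

The bundled scenarios (`fixture_names()`) encode the study conditions used
throughout the tests: the substitutable Red/Blue pair ($\alpha_a = 0.6$ vs
$0.2$, $d = 0.5$, symmetric supply 4), the essential Red/Blue pair
($\alpha_a = 0.65$ vs $0.35$, $d = 0.25$, symmetric supply 10), 10-nutrient
assembly ($d = 0.5$, uniform supply 5), the interconversion cartel at
$d = 0.2$, the secretion model at $d = 0.4$ and $0.6$ supplied only with S,
a 20-vessel chain at $l = 1$, and the rock–paper–scissors trio. The chain
scenario uses fast uptake kinetics ($v = 10$, $d = 2.5$): leakage exchanges
cells as well as medium, so the opposed biomass gradient is a stable steady
state only when local competitive exclusion is fast relative to the leakage
rate; at the default kinetic scale the gradient is merely a long transient
before one species takes the whole chain. The trio was
designed so that species $i$ allocates $0.275$ import $+$ $0.275$
assimilation to nutrient $i$ and $0.45$ wasteful import to nutrient $i+1$
at $d = 0.2$ and supply 10: this sits just above the Hopf boundary of the
symmetric coexistence point, giving a genuine stable limit cycle (stationary
peak-to-peak amplitude, biomass bounded well away from extinction) together
with the directed invasion 3-cycle. Larger waste fractions collapse the
cycle heteroclinically to extinctions; smaller ones damp to coexistence.

These are deterministic, dimensionless, spatially idealised models with
stand-in kinetic constants. Passing tests show that the implementation
reproduces the qualitative phenomena the framework predicts — mutual
invasion and landscape flattening, bistability and ascending invasion
chains, maximizing-class sectors and coexistence at contour kinks, cyclic
invasion with sustained oscillation, spatial gradients in linked chains —
not that any particular organism's kinetics are captured. Demographic noise,
mutation, non-exact trade-offs and time-varying supply are out of scope; the
extinction threshold is the only (deterministic) stand-in for stochastic
extinction.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: zero concentrations give zero
fluxes; the essential model's argmax at an all-zero environment returns the
balanced allocation with a degeneracy flag; empty contours are results, not
errors; washout steady states return the supply environment with an empty
survivor set. The test suite and acceptance script use deliberately modest
problem sizes — class maps at $17^2$ grids, maximal contours at
$25$–$41$-point resolutions, 100 randomized invasion cases, brute-force
argmax checks on $\sim 10^4$-point simplex grids, a 20-vessel chain run to
$t = 2000$, and the oscillator run to $t = 6000$ — which keep every
qualitative and quantitative check sharp while running on a single CPU in
minutes. Resolutions and horizons are arguments everywhere, so any analysis
can be rerun at higher fidelity.

## Known limitations

- The kinetic constants are package defaults, not fitted to any organism;
  conclusions that depend on exact parameter values (e.g. which classes
  flank a particular high-dilution kink, the intermediate $\alpha$ values
  visited by a chain of invasion) should be treated as parameterization-
  dependent.
- The cartel coexistence at a contour discontinuity is an ESS, not a global
  attractor of two-species dynamics: from arbitrary two-species initial
  conditions the community can settle into an (invasible) monoculture;
  the cartel is reached when a richer set of maximizing strategies competes,
  which is how the tests exercise it.
- Contour extraction is 2-D only; higher-dimensional geometry is pointwise.
- `steady_state()` distinguishes fixed points from non-convergence by a
  derivative-norm criterion with a time cap; extremely slow transients near
  degenerate (neutral) directions can require raising the cap.
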