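# chemoscape

Chemostat resource-competition models with exact metabolic trade-offs: a
simulator and strategy-evaluation toolkit for microbial ecology and
evolution.

Microbes allocate a limited internal budget (enzymes, transporters) across
metabolic functions, and they do not merely respond to their chemical
environment — they create it, by consuming and secreting metabolites in the
shared medium. chemoscape implements this feedback loop in the standard
chemostat setting and provides the geometric and evolutionary machinery to
ask which allocation strategies win, coexist, or are evolutionarily stable,
and how the answer depends on the supply condition and dilution rate. It is
aimed at theoretical ecologists and systems biologists studying
consumer-resource models, adaptive dynamics, and microbial community
assembly.

## The model

A strategy is a point on the allocation simplex, $\sum_j \alpha_j = 1$
(exact trade-off). Each metabolic model maps an environment $\vec c$ and a
strategy $\vec\alpha$ to a growth rate $g(\vec c,\vec\alpha)$ and an impact
flux $\vec I(\vec c,\vec\alpha)$ (consumption; negative = secretion), and
the chemostat closes the loop:

$$\dot m_\sigma = m_\sigma\,(g(\vec c,\vec\alpha_\sigma) - d), \qquad
\dot c_i = d\,(c_{i,\mathrm{supply}} - c_i)
 - \textstyle\sum_\sigma (m_\sigma/r)\, I_i(\vec c,\vec\alpha_\sigma).$$

Five models ship with the package: substitutable nutrients (additive
growth), substitutable nutrients with a serial import/assimilation
bottleneck, essential nutrients (law of the minimum), internal
interconversion of two essential nutrients, and a secretion model with a
dual-role intermediate (polluter / cleaner / generalist ecology).

On top of the dynamics sit the evaluation tools:

- **growth contours** (zero-net-growth isoclines) $g(\vec c,\vec\alpha)=d$
  and **flux-balance curves** in chemical space; their intersection is the
  resident's steady state;
- the **rule of invasion**: an invader establishes iff the resident's
  steady-state environment lies inside the invader's invasion zone
  ($g > d$), giving environment-dependent **fitness landscapes**;
- **maximizing strategies** $\vec\alpha_{\max}(\vec c)$ and the **maximal
  growth contour** (the envelope $g_{\max}(\vec c)=d$) with class labels and
  slope discontinuities — the places where evolutionarily stable coexistence
  lives — plus **supply lines** and supply cones;
- evolutionary procedures: **chain of invasion** (best-response replacement
  to the non-invasible strategy), **greedy opportunist assembly**,
  **pairwise invasion graphs**, and **linked-chemostat chains** for spatial
  coexistence.

## Worked example

Two species competing for two substitutable nutrients, Red ($\alpha_a=0.6$)
and Blue ($\alpha_a=0.2$), at dilution rate $d = 0.5$ and symmetric supply:

```r
library(chemoscape)

sub   <- make_model("substitutable")
setup <- chemostat_setup(d = 0.5, c_supply = c(4, 4))
red   <- c(0.6, 0.4); blue <- c(0.2, 0.8)

invasion_graph(sub, setup, list(red, blue))
#> <invasion_graph> 2 strategies, 2 invasion edges
#> mutual
#>      1

steady_state(setup, sub, list(red, blue),
             community_state(c(0.01, 0.01), setup$c_supply))
#> <chemostat_steady_state> converged
#>   survivors: 1, 2
#>   environment: 1, 1
#>   residual (max |dy/dt|): 2.22e-16
```

Each species invades the environment the other creates (`mutual`), so they
coexist — at the common intersection of all growth contours, $c_a=c_b=1$
(where each Monod term equals $d$). In that co-created environment the
fitness landscape is flat: every strategy grows at exactly the dilution
rate, which is why this model supports unlimited coexistence.

```r
fitness_landscape(sub, c(1, 1), seq(0, 1, 0.1), d = 0.5)
#> <fitness_landscape> 11 strategies at c = (1, 1)
#>   g in [0.5, 0.5], flatness = 0
```

The essential-nutrient model behaves oppositely — each species builds an
environment hostile to its competitor. Iterated replacement by the fastest
strategy walks to the balanced allocation:

```r
ess <- make_model("essential")
chain_of_invasion(ess, chemostat_setup(0.25, c(10, 10)), c(0.35, 0.65))
#> <invasion_chain> 51 residents, converged to a non-invasible strategy
#>   ESS: (0.499995, 0.500005)
```

Bundled scenarios reproduce the package's reference setups
(`fixture_names()`); `run_scenario(fixture("fig2_coexist"), "out/")` writes
tidy CSV tables, a JSON summary and a run manifest. A thin command-line
wrapper lives at `inst/cli/chemoscape.R`:

```sh
Rscript inst/cli/chemoscape.R fixture s4_rps --out out/rps
```

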