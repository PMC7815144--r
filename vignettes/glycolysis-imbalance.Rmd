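---
title: "Eco-evolutionary dynamics of a core glycolysis pathway"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eco-evolutionary dynamics of a core glycolysis pathway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycosim)
```

## The model

`glycosim` simulates populations of yeast-like cells whose metabolism is a
four-reaction core of glycolysis. Each cell carries three dynamical
metabolite concentrations — the lumped intermediate FBP
(fructose-1,6-bisphosphate), ATP, and cytosolic inorganic phosphate
$P_i$ — plus a volume $V$ and a health variable $H$.

The reactions are:

* **Upper glycolysis (UG)**: two-substrate Michaelis–Menten kinetics in
  external glucose and ATP, with allosteric inhibition by ATP
  ($K_{i,\mathrm{atp}}$). UG invests 2 ATP and produces 1 FBP per glucose.
  The inhibition makes the UG flux unimodal in ATP, with a maximum at
  $\sqrt{K_{M,\mathrm{atp}} K_{i,\mathrm{atp}}} \approx 0.55$ mM — the
  source of the trade-off between a high ATP level and fast uptake.
* **Lower glycolysis (LG)**: three-substrate Michaelis–Menten kinetics in
  FBP, ADP and $P_i$, producing 4 ATP per FBP. ADP is never stored; it is
  derived from the conserved pool $a_{tot} = \mathrm{ATP} + \mathrm{ADP}$.
* **ATPase demand**: first-order consumption $k_{atp}\,[\mathrm{ATP}]$,
  standing for everything the cell spends energy on.
* **Phosphate transport**: $k_p([P_i]_{vac} - [P_i])$ between a buffered
  vacuolar store and the cytosol. The vacuolar concentration is an
  instantaneous function of the total phosphate already imported,
  $P_{tot} = P_i + 2\,\mathrm{FBP} + \mathrm{ATP}$, dropping to half at
  $K_{vac} = 250$ mM with a sharpness exponent $m = 4$. This caps how much
  FBP a cell can accumulate before the store runs dry.

Metabolites are additionally diluted at the fractional growth rate $V'/V$.
The stoichiometry guarantees $\mathrm{d}P_{tot}/\mathrm{d}t = v_p -
P_{tot}\,V'/V$ exactly; the test suite asserts this identity on random
states.

This "turbo design" — ATP investment upstream, net ATP gain downstream —
is bistable: a *balanced* steady state (moderate FBP, high ATP, UG and LG
fluxes equal up to growth dilution) coexists with a self-sustaining
*imbalanced* regime in which UG outruns LG, FBP accumulates, and ATP and
cytosolic phosphate stay low. Which attractor a cell reaches depends on
its phosphate availability during pathway start-up.

## Growth, health and cost

The ATPase flux is budgeted as $v_{atp} = v_{atp,e} + v_{atp,m} +
v_{atp,g}$: expression cost, general maintenance (0 by default), and
growth flux. The four rate constants $(v_{max,up}, v_{max,lo}, k_{atp},
k_p)$ are proportional to enzyme expression levels and constitute the
evolvable genotype; their expression cost is by default
$v_{atp,e} = k_e \sum_x (w_x x)^4$ (weights 1, rate constants scaled by
the unit concentration 1 mM), normalized so the reference genotype
$(10, 10, 10, 0.3)$ costs 5 mM/min. An alternative power-of-sum variant
is available as `costModel("power_of_sum")`.

A cell at maximal health grows at $V'/V = u_g\,v_{atp,g}$ when
$v_{atp,g} > 0$; under an energy deficit health falls at
$-u_d\,v_{atp,g}$, and a recovering cell first refills health at
$u_g\,v_{atp,g}$ before growing. The constants are calibrated against two
anchor observations of the reference genotype at 2 mM glucose: the
balanced state (ATPase flux 12.7 mM/min) doubles the volume in
$\tau_g = 90$ min, and the imbalanced state (0.46 mM/min) kills the cell
in $\tau_d = 420$ min. `u_d` is stored with its literal negative sign so
the health equation can be written exactly as calibrated. At division
(volume $\ge 2V_c$), one daughter draws a fresh volume
$U(0.5, 1.5)\,V_c$, the other takes the complement; both draw individual
$H_{max} \sim U(0.9, 1.1)$ (this desynchronizes clonal lineages) and
inherit metabolite concentrations unchanged. Each genotype parameter of
each daughter mutates with probability $\mu = 0.01$ by a multiplicative
log-normal factor ($\sigma = 0.1$). We mutate *both* daughters — the
procedure is described per daughter cell, and a per-daughter reading is
the simplest consistent one; a `mutate_both_daughters = FALSE` switch
restores the one-daughter variant.

## Environments

Two chamber models are implemented:

* **Chemostat**: glucose obeys $[\mathrm{Glc}]' = -\sum_i v_{up,i}
  V_i/V_{ch} + D([\mathrm{Glc}]_0 - [\mathrm{Glc}])$, so cells compete for
  the resource, and each cell is washed out at per-capita rate $D$. All
  cells and the chamber glucose are integrated as one coupled system per
  demographic interval — the uptake sum couples every cell to every other,
  and operator splitting would miss within-interval feedback.
* **NCG** ("no competition for glucose"): the limiting case of a large,
  fast-flushed chamber. Cells do not affect glucose, which follows
  $D([\mathrm{Glc}]_0 - [\mathrm{Glc}])$ in closed form (piecewise
  exponential between supply switches); population size is instead
  regulated by space competition, with total loss rate $d N^2$. Here each
  cell is an independent ODE system, integrated separately.

Supply schedules are constant, square waves of equal ON/OFF duration, or
pulse trains (1 min pulses of 300 mM into a slow chemostat). Pulse-train
OFF durations may vary cycle to cycle (normal with CV 5 %, truncated at a
1 min floor — the truncation rule is our choice; only the CV is
prescribed). The realized schedule is drawn once from a dedicated RNG
stream and cached, so cycle boundaries used by the statistics come from
the generator, never from inferring switches in the glucose trace.

## Numerical scheme

All per-cell dynamics use an adaptive Dormand–Prince 5(4) pair with
per-family tolerances (metabolites: atol $10^{-5}$ mM, rtol $10^{-5}$;
volume: atol $10^{-17}$ L; health: atol $10^{-2}$). After each accepted
step, a metabolite concentration in $(-(atol_c + |c|\,rtol_c),\, 0)$ is
projected to zero; any more negative value rejects the step, which is
retried at half the size. Kinetic rates additionally clamp transiently
negative inputs to zero, but the projection is the authoritative
non-negativity mechanism. Health is clipped into $[0, H_{max}]$ at step
boundaries; the growth gate treats $H \ge H_{max} - 10^{-12}$ as "at
maximal health" so that clipping and gating agree. Integration runs in
intervals of $\Delta t_p = 5$ min during which the population composition
is frozen; demographic events are applied between intervals in a fixed
order — death ($H \le 0$), division (every cell at $V \ge 2V_c$; mutation
only within the mutation-on segment), washout (binomial with the exact
exponential survival probability $1 - e^{-r\Delta t_p}$), tracked-set
refresh. Death precedes division so dead cells cannot reproduce; washout
after division matches a continuous-outflow reading. Division is checked
only at interval boundaries, so cells can overshoot $2V_c$ slightly;
volume is conserved exactly at the split.

Step-size underflow (below $10^{-10}$ min) raises an error naming the
offending cell. The cross-check suite integrates the same right-hand side
with `deSolve::ode45` at tight tolerances and agrees to a few parts in
$10^5$, consistent with the requested accuracy.

## Protocol, calibration and RNG discipline

A run has three segments: mutation off (establishment from standing
variation drawn $U(0.1P, 10P)$ around the reference genotype — most random
genotypes are unviable, and this segment lets a viable population form),
mutation on, mutation off (purge). Because the equilibrium population
size depends on the evolving strategies, a mutation-free pre-simulation
of the establishment segment first measures the steady-state size $N_p$
(mean over its final quarter — "steady state" is not otherwise specified,
and the final quarter is insensitive to the initial transient), then
rescales $V_{ch} = V_{ch,0} N^*/N_p$ (chemostat) or $d = d_0 N_p/N^*$
(NCG) to hit the target size $N^*$.

All randomness derives from one seed through four named streams
(initialization, schedule, demography, mutation), so a run is bit
reproducible and, e.g., the supply schedule does not shift when the
population grows. We use one shared mutation stream rather than per-cell
streams; with demography and mutation already separated, per-cell streams
would add bookkeeping without changing any statistic computed here.

## Balancedness statistics

* `balancednessCov`: covariance of external glucose and intracellular ATP
  over an integral number of supply cycles (positive = balanced).
* `balancednessPhase`: mean ATP in ON phases minus mean ATP in OFF phases
  — sharper under NCG square waves, where the chamber switches abruptly.
  Averaging is over time samples within labeled phases (not per-phase
  means), which weights phases by their realized duration.
* `isBalancedTrajectory`: at constant glucose a balanced cell satisfies
  $v_{up} = v_{lo} + \mathrm{FBP}\,V'/V$ at steady state; a trajectory is
  balanced if the identity holds within 0.1 % relative error for more
  than 10 % of the simulated time (samples with $v_{up} = 0$ fall back to
  the absolute metabolite tolerance).
* `genotypicBalancedness`: the largest glucose concentration on the grid
  2.00, 1.95, ..., 0.05 mM at which 100 trajectories of 300 min, started
  from normally perturbed initial metabolites (CV 6 %, truncated at zero
  and at $a_{tot}$; means FBP 2, ATP 1, $P_i$ 10 mM, or an observed
  evolved state), are all balanced. These single-cell scans run at fixed
  glucose with growth and health active but no environmental feedback.
  All initial draws are made up front, indexed by grid level, so the scan
  order cannot change the result.
* `reproductionRate`: the cycle-averaged $V'/V$, recomputed from the
  gated growth flux $u_g v_{atp,g}$ so that division discontinuities in
  the volume trace never enter.

## Worked example

A reference-genotype cell at constant 2 mM glucose from the standard
start settles into the balanced state; a phosphate-poor start tips the
same genotype into the imbalanced regime:

```{r example}
fp <- balancedFixedPoint(referenceGenotype(), glc = 2)
round(fp$state, 3)
balancedAtpaseFlux()        # ~12.6 mM/min at the fixed point
volumeDoublingTime()        # ~91 min
imbalancedAtpasePlateau()   # ~0.49 mM/min from a phosphate-poor start
timeToDeath(growthFlux(0.46, 5))  # 420 min by calibration
```

## Desk-scale study conditions

The full study conditions (target size $N^* = 10^4$, mutation-on segment
of $4.9 \times 10^5$ min) are far beyond an interactive session, so the
shipped tests replicate the qualitative findings at a reduced scale,
chosen once:

* evolution runs: $N^* = 500$, $N_0 = 10^4$, segments 0–3000–52000–62000
  min (establishment kept at 3000 min so that the calibration
  pre-simulation reaches its steady state; mutation-on shortened about
  10-fold; purge 10000 min), provisional $d_0 = 10^{-5}$/min so the
  provisional equilibrium is reachable within the establishment segment;
* competition runs: the built-in balanced/imbalanced genotype pair, a
  pulsed chemostat at $N \approx 1000$ (calibrated from a 5000 min mixed
  pre-simulation), 300 supply cycles.

At this scale the suite reproduces the directional results: fast square
waves (period 40 min) select imbalanced strategies (negative phase
balancedness) and slow ones (200 min) balanced strategies; competing
genotypes started at balanced fractions 0.2 and 0.8 converge to a common
interior mixture; and scarcer constant glucose selects a larger
$v_{max,up} - v_{max,lo}$ expression gap. What passes at desk scale shows
direction and mechanism, not effect sizes: smaller populations have more
demographic noise, shorter mutation-on segments leave genotypes farther
from their evolutionary attractor, and catastrophe statistics (rare at
full scale) are not assessed quantitatively here.

## Known limitations

The pathway is a four-reaction caricature: no trehalose cycling, glycerol
branch, hexokinase regulation or reversible LG, so quantitative yeast
predictions are out of scope. The analytic fitness comparison of balanced
versus imbalanced strategies in fluctuating environments is likewise not
implemented; the simulator addresses those questions empirically. The
catastrophe detector (`catastropheEvents`) is a reporting heuristic of
this package, not a derived statistic. CSV outputs print doubles with 17
significant digits so files round-trip exactly.
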