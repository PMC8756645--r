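---
title: "Methods: dynamic FBA, expression integration, and flux-bound evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic FBA, expression integration, and flux-bound evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoflux)
```

This vignette is the package's own account of the science it implements:
the models, the tunable parameters and why their defaults are what they
are, what the synthetic fixtures do and do not emulate, and the numerical
and design choices that were genuinely open.

## Constraint-based core

A metabolic model is a stoichiometric matrix $S$ (metabolites × reactions)
with flux bounds $lb \le v \le ub$. Flux balance analysis (FBA) solves

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0, \; lb \le v \le ub,$$

on the package's dense two-phase simplex (written in C++ for the solve
volume the evolutionary algorithm generates; at the bundled model sizes a
solve takes well under a millisecond). Two conventions matter downstream:

* **Exchange reactions** touch exactly one metabolite; negative flux is
  uptake, positive is secretion. Biomass flux is reported in h⁻¹, all
  other fluxes in mmol gDW⁻¹ h⁻¹; no unit conversion is performed.
* **Degenerate optima are expected.** Only objective values are uniquely
  determined; every check in this package compares objective values or
  flux-variability (FVA) intervals, never a single interior flux of one
  solve, because the vertex an LP lands on is solver-specific.

All bounds are finite; nominally unbounded fluxes use ±1000
(`default_bound()`), the usual convention of constraint-based models.
Feasibility tolerance is 10⁻⁹ at the solver, and mass balance of optimal
states is asserted at 10⁻⁶ in tests (standard LP scaling).

## Dynamic FBA of a mixed-sugar batch

`simulate_batch()` couples repeated FBA solves to Euler updates of the
external pools:

$$C \leftarrow C + v\,X\,\Delta t, \qquad X \leftarrow X\,(1 + \mu \Delta t),$$

with concentrations in mM, biomass $X$ in g/L, and
mmol gDW⁻¹ h⁻¹ × g/L × h = mM. The substrate kinetics (all defaults in
`kinetic_parameters()`) describe phosphate-limited citrate fermentation of
a glucose/xylose feedstock:

| parameter | default | meaning |
|---|---|---|
| `v_pe_max`, `k_pe` | 0.15, 0.0333 mM | external phosphate uptake (Michaelis–Menten) |
| `v_p_max`, `k_p` | 0.06, 20 mM | internal phosphate-store consumption |
| `g_passive_coeff` | 0.0027 | passive glucose uptake per mM |
| `v_g2_max`, `k_g2`, `k_i2` | 0.08, 0.26 mM, 933 mM | glucose carrier with product inhibition |
| `x_passive_coeff` | 0.00027 | passive xylose uptake per mM |
| `v_x2_max`, `k_x2` | 0.18, 3.33 mM | xylose carrier |
| `glucose_gate` | 5 mM | xylose carrier off while glucose exceeds this |
| `v_cit_cap`, `cap_delay`, `start_time` | 0.12, 32 h, 10 h | scheduled product-output cap |

Design choices that the kinetics alone do not fix:

* **Product inhibition form.** The glucose carrier is multiplied by
  $1/(1+[\mathrm{CIT}]/K_{i2})$ — the simplest single-constant inhibition
  consistent with naming an inhibition constant. The term is isolated in
  `uptake_bounds()` so alternative forms can be substituted.
* **Two-pool phosphate.** While external phosphate remains, uptake runs
  *at* capacity (luxury uptake) and the equality constraint pushes the
  surplus out through the store exchange, filling the store; once the
  external pool is below 10⁻⁶ mM the store becomes consumable at its own
  Michaelis–Menten rate. This reproduces the two-phase physiology —
  biomass growth first, then phosphate-limited production sustained by the
  store — and matches a growth-phase solution in which the external
  phosphate flux sits near its maximum while the store exchange is
  positive.
* **Per-step objective.** The LP objective within a step is lexicographic:
  maximise growth, then maximise product at the fixed growth optimum.
  This reproduces growth-then-product phasing without a dedicated
  regulatory model and is the natural greedy counterpart of the two-phase
  physiology.
* **Pool depletion.** Every uptake capacity is clipped to
  $C/(X\,\Delta t)$, so a step can empty a pool exactly but never
  overshoot into negative concentrations; flooring at zero is only a
  numerical guard.
* **Step size.** Default $\Delta t = 0.01$ h. The integrator is first
  order; the acceptance checks run the bundled scenario at
  $\Delta t = 0.02$ versus $0.01$ and observe endpoint shifts of ~0.002%,
  far below the 1% criterion, because the dynamics between the discrete
  switching events (phosphate depletion, glucose gate, cap onset) are
  smooth.

The simulation clock starts at `start_time` (10 h after inoculation) and
the product cap activates at `start_time + cap_delay` (42 h) in
constrained runs.

## Expression integration

Transcript–reaction associations are boolean AND/OR trees. Reaction-level
TPM is computed recursively: `OR` sums its children (isoenzymes add
capacity), `AND` takes the minimum (complex subunits limit capacity).
Three thresholds drive the calls, all exposed as arguments:

* **Silencing:** reactions with reaction-level TPM strictly below 1 are
  switched off (both bounds to zero). The rule is strict `<`, so exactly
  1 TPM stays open.
* **Significance:** a reaction-level call requires |log2FC| > 0.7 and at
  least one associated transcript with q < 0.01. Transcript q-values are
  combined by minimum — the least surprising lift from transcript-level
  statistics to a reaction-level call; a combination rule is needed
  because significance testing happens per transcript.
* **Eligibility for mutation:** reaction-level fold change ≥ 2 in either
  the first-to-second or second-to-third timepoint comparison (union by
  default; an intersection mode is available as a config switch). The
  union reading is used because target evidence can legitimately come
  from a single transition (e.g. events specific to the sugar switch).
  When the two comparisons disagree in direction, the larger |log2FC|
  wins and an exact tie makes the reaction ineligible — a deterministic
  rule for a case the thresholds alone leave open.

Reaction-level log2 fold changes use a pseudocount of 0.5 TPM on both
sides (configurable) to keep ratios defined at zero expression; a
transcript absent from a profile counts as 0 TPM with a warning, the
conservative reading consistent with the silencing rule.

## Evolution of flux bounds

The evolutionary algorithm searches over *mutation sets*: per-reaction
replacements of flux bounds, restricted to expression-eligible reactions.

**Fitness.** An individual is scored by solving the model with the
non-product tracked exchanges (internal phosphate, glucose, xylose,
biomass) pinned to their target fluxes and the product maximised, then

$$F = -\log_{10} \sum_i \left(f_{t,i} - f_{a,i}\right)^2$$

over the five tracked exchanges. The expression diverges at a perfect
fit, so $F$ is capped at 12 (any finite cap above the capture threshold 6
works; 12 corresponds to summed squared deviations of 10⁻¹²). Infeasible
individuals receive $-\infty$. Pinning the non-product exchanges is the
package's resolution of how the achieved fluxes are obtained: it encodes
"same carbon input and biomass output" as hard constraints and leaves the
product flux as the one degree of freedom the fitness actually measures.

**Mutation operator.** Expression events bound what a mutation may do:

* *Constrain* (down-regulated): the bound magnitude may be tightened no
  further than (larger-magnitude reference flux)/(fold change). Initial
  mutations draw uniformly between the baseline flux magnitude and this
  limit; on reversible reactions both bounds move symmetrically toward
  zero.
* *Force* (up-regulated): the flux minimum is raised to at least
  (smaller-magnitude reference flux) × (fold change), never beyond the
  FVA maximum under the base exchange constraints; forcing is disallowed
  when the FVA interval straddles zero (no clear flux direction). The
  larger/smaller assignment of the two flanking reference fluxes makes
  constraint limits permissive and force minima conservative; both feed
  through `mutation_limits()` where the assignment is explicit.

Subsequent mutations perturb the existing bound by a Laplace(0, *b*) draw
with $b = 0.01\,|B|$ (and $b = 0.001$ at $B = 0$), clipped to the allowed
interval — a multiplicative-scale local search.

**Search scheme.** Generational loop with population 50, tournament
selection of size 2, elitism 1, and per-individual mutation probability
0.3 per generation (all configurable). The published description of this
style of algorithm leaves the population mechanics open; these defaults
are ordinary GA practice, documented here as this package's choice rather
than anyone else's. The generation budget defaults to 150 000; the
bundled fixtures are deliberately easy enough that captures typically
occur within tens of generations, and tests cap runs at 5 000.

**Multiple solutions.** When an individual reaches fitness ≥ 6 it is
frozen as a solution; its *key reaction* — the mutation whose restoration
to original bounds costs the most fitness, ties broken lexicographically —
is reset across the population and blocked from future mutation. This
forces later captures to explain the constrained product flux through
different reactions.

## Solution refinement and target tables

Captured solutions pass through four deterministic steps:

1. **Pruning:** mutations are reverted in ascending-contribution order
   (ties by id) and a reversion is kept when fitness stays ≥ 6, looping to
   a fixed point. Ascending order maximises removals; the loop order is
   deterministic so refined solutions are reproducible.
2. **Micro-optimisation:** coordinate-wise hill climb with steps of 1% of
   each bound's magnitude, at most 20 sweeps, accepting only
   improvements — fitness is non-decreasing by construction.
3. **Key-set extraction:** walking the contribution ranking, bounds are
   cumulatively restored while a *revised* fitness — the same score with
   the product target replaced by the unconstrained optimum — is
   recomputed; the walk stops at revised fitness ≥ 3.5. The returned
   prefix is the minimal set whose restoration recovers near-optimal
   production.
4. **Percent increase:** for each key reaction, two product-maximising
   solves (bounds restored vs. retained) give
   $100 \times (\text{restored} - \text{mutated})/\text{mutated}$. The
   *mutated* (constrained) flux is the denominator: the quantity reported
   is the improvement an engineer would gain over the current strain,
   and with a constrained flux of 0.12 against an unconstrained optimum
   of 0.3159 it evaluates to ≈163%, the scale on which such tables are
   read.

Aggregation across runs reports, per reaction: the intervention direction
(the opposite of the in-silico mutation — a constrained reaction is an
up-regulation target), the number of distinct runs containing it, and the
highest percent increase, sorted by (frequency, percent increase) with a
prominence flag at ≥ 50%.

## Synthetic fixtures: what they emulate and what they don't

`make_toy_model()` builds a ~19-reaction, 12-metabolite network: glucose
and xylose converted to pyruvate units; biomass consuming pyruvate and
phosphate; citrate synthesis with a CO₂-releasing overhead; a citrate
exporter; respiration and two overflow routes as carbon sinks; exchanges
for both phosphate pools, both sugars, citrate, CO₂ and O₂. The biomass
stoichiometry is *derived* from the planted target fluxes, so the
unconstrained product optimum equals the stored ground truth exactly and
the unconstrained:constrained ratio is ≈2.6 — the regime where a
constraint-explaining evolution is informative. Expression tables plant a
6-fold down-regulation on the bottleneck (the exporter, optionally also
the synthesis step), decoy events on reactions that cannot move the
product optimum, one sub-threshold event, and seeded jitter plus
unassociated decoy transcripts.

What passing tests on these fixtures demonstrates: the LP/FVA machinery,
the mapping rules, the EA's ability to recover a planted bottleneck among
eligible decoys, and the refinement arithmetic — all against hand-derivable
ground truth. What they do not demonstrate: behaviour on genome-scale
networks (thousands of reactions, extensive alternate optima), real
transcriptome noise structure, or kinetic parameters fitted to a real
fermentation. The fixtures are scaled so the full test suite and the
acceptance script run in minutes on one CPU (EA runs of ≤5 000
generations, dynamic simulations of 96 h at Δt = 0.02/0.01 h, 8–20 seeded
runs), sizes chosen as honest desk-scale representatives of the method.

## Degenerate inputs and edge rules

* A reaction with no association is never silenced and is not eligible
  for mutation (`NA` reaction-level expression, not zero).
* Zero expression at both timepoints: fold change undefined, reported
  not-significant with a reason.
* Empty eligible set: `evolve_bounds()` refuses to run.
* A mutated product flux of zero makes the percent increase undefined;
  the reaction is reported `NA` and excluded from ranking.
* Percent-increase ties and contribution ties break lexicographically by
  reaction id throughout, so every ranking is a deterministic function of
  the inputs and the seed.

## Known limitations

* The simplex is dense and single-threaded; fine for desk-scale models,
  not for genome-scale work.
* No SBML/JSON model import; the tabular dialect is the only format.
* Kinetic parameters are taken as given; no fitting to time-series data
  is shipped.
* The EA explores one mutation per individual per generation; highly
  epistatic multi-reaction bottlenecks may need larger budgets than the
  fixture defaults.
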