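---
title: "Thermodynamically consistent calibration of kinetic reaction models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamically consistent calibration of kinetic reaction models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermocal)
```

## The model

An open biochemical reaction system has $N$ species $X_1,\dots,X_N$ coupled
by $M$ reactions. In an ideal, well-stirred mixture at constant temperature
and volume, concentrations evolve by the reaction-rate equations

$$\frac{dx_n}{dt} \;=\; \sum_{m} \bar S_{nm}\,\phi_m(\mathbf x),
\qquad \bar S_{nm} = \nu'_{nm} - \nu_{nm},$$

with generalized mass-action net fluxes

$$\phi_m \;=\; \Big(\,r_{2m-1} \prod_n x_n^{\nu_{nm}}
 \;-\; r_{2m} \prod_n x_n^{\nu'_{nm}}\Big)\, f_m(\mathbf x, \boldsymbol\pi),$$

where $r_{2m-1}, r_{2m}$ are the forward and reverse rate constants and
$f_m > 0$ is a modulation factor ($f_m \equiv 1$ for plain mass action;
a rational function for reversible Michaelis–Menten-type mechanisms — every
reversible rate law in an ideal mixture can be written this way). Openness
is modelled by clamped species (held concentrations, implicit mass
exchange), null-species exchange reactions, irreversible reactions, and
partially modeled reactions with incomplete stoichiometry.

A **closed** system relaxes to a unique positive equilibrium at which every
reversible reaction is individually balanced (detailed balance), not merely
stationary in aggregate. Writing $z_m = \log(r_{2m-1}/r_{2m})$ and letting
$\mathbf b$ range over $\mathrm{null}(\bar{\mathbf S})$ of the closed
stoichiometry matrix, detailed balance forces the **Wegscheider
conditions** $\mathbf b^\top \mathbf z = 0$: around every reaction cycle the
product of equilibrium constants is one. It suffices to impose them for the
$M_2 = M_0 - \operatorname{rank}\bar{\mathbf S}$ basis cycles, and on the
log scale they are *linear* in the parameters. The entropy production rate
of driving the closed system so that net fluxes equal a cycle vector
$\mathbf b$ is

$$\sigma(\mathbf b) \;=\; A\,V\,k_B \sum_m b_m
  \log\!\frac{J^+_m}{J^-_m} \;=\; A\,V\,k_B\; \mathbf b^\top \mathbf z,$$

because the state-dependent terms cancel over the cycle ($\bar{\mathbf
S}\mathbf b = 0$). The second law requires $\sigma \ge 0$ with equality only
at equilibrium, so a parameter set giving $\sigma(\mathbf b) \ne 0$ for any
cycle is physically impossible; a *negative* value violates the second law
outright. The same cancellation yields a dynamic audit: along any
trajectory, $\sum_m b_m \log(J^+_m(t)/J^-_m(t))$ equals the cycle's
Wegscheider residual at every time point, arbitrarily far from equilibrium.

Crucially, the rate constants of an *open* system's reversible reactions
are constrained exactly as in the closed subsystem one obtains by pruning,
because rate constants do not depend on whether some concentrations happen
to be held fixed. Reactions pruned away are *not* constrained.

## Pruning to the closed subsystem

`prune_to_closed()` applies four ordered steps: drop null-exchange,
irreversible and partially modeled reactions; lift clamping on species in
the remaining reversible reactions (a flag flip — initial values are
untouched); keep only thermodynamically independent reactions; drop species
left without reactions. Independence has no algorithmic test in general;
the package uses the standard practical criterion — elementary
(single-step) reactions are independent — implemented as a heuristic:
reversible, total stoichiometry at most 2 on each side, no modulation
factor. Annotations can override it per reaction in either direction, and
can declare reactions partially modeled or thermodynamically dependent
(coupled reactions are outside the method's scope; see Limitations). Every
dropped reaction records exactly one exclusion reason, so audits are
traceable.

## Exact cycle analysis

The cycle count is a discrete structural invariant, so `cycle_basis()`
computes $\operatorname{rank}\bar{\mathbf S}$ and a null-space basis in
exact rational arithmetic (fraction-valued Gauss–Jordan elimination;
numerators and denominators of these small integer matrices remain far
below the exact-double range). Floating-point rank estimation is only used
later, for the real-valued constraint matrix. The basis is canonical —
reduced-row-echelon free columns, cleared to primitive integer vectors with
positive leading entry — so identical inputs give identical bases;
feasibility verdicts are invariant under change of basis, which the test
suite checks against randomized integer recombinations and against a
brute-force enumeration oracle on small networks.

## The constraint system and its parameterization

All constraints are linear in $\boldsymbol\kappa = \log \mathbf k$:
Wegscheider rows ($+b_m$ on the forward, $-b_m$ on the reverse
log-parameter of each cycle member) stacked above user constraints —
measured equilibrium constants ($\kappa_{2m-1}-\kappa_{2m} = \log R_m$),
Haldane relations entered as explicit coefficient rows, individually
measured parameters ($e_j^\top \boldsymbol\kappa = \log k^{\text{meas}}$),
and ties that share one value across reactions (the idiom for expanding a
validated model: fix the old parameters, estimate only the new ones).
Parameters whose *value* is exactly zero — reverse rates of irreversible
reactions, artificial rate slots of reactions that carry a raw
non-decomposable rate law, and anything the user pins to zero — have no
logarithm; they are eliminated from the system before the log transform
rather than represented by $-\infty$, and a row that needs one of them with
a nonzero coefficient is reported as contradictory.

`feasibility_check()` classifies the system by rank: inconsistent rows mean
the constraints must be reformulated; full column rank means the solution
is unique and no optimization is needed; otherwise the solution set is an
affine manifold of dimension $d = J_{\text{eff}} - \operatorname{rank}
\mathcal A$. `reparameterization()` writes it as $\boldsymbol\kappa =
\boldsymbol\kappa_0 + \mathbf B\mathbf v$ with $\boldsymbol\kappa_0$ the
constrained least-squares point closest to a reference (by Moore–Penrose
projection) and $\mathbf B$ an orthonormal SVD null-space basis with a
fixed sign convention. The reference defaults to the model's current
values: for recalibrating a published model those values already fit
reasonably, so the feasible point nearest to them is a good anchor; for a
de-novo model the reference is simply the user's initial guess. The choice
of $\mathbf B$ only rotates/scales the search axes, and the optimizer is
robust to that (checked by optimizing under different bases).

## Cost and optimization

The fit cost is unweighted least squares over experiments, observed species
and observation times — the maximum-likelihood criterion under i.i.d.
Gaussian observation error — with optional per-point weights for data
spanning decades. The reduced cost $C_0(\mathbf v) =
C(\boldsymbol\kappa_0 + \mathbf B \mathbf v)$ makes the search
unconstrained *and* lower-dimensional: every evaluation simulates a
feasible model, and the search space shrinks from $J$ to $d$ dimensions.

$C_0$ is non-convex with many local minima, so the reference optimizer is
simulated annealing: Gaussian proposals in $\mathbf v$, Metropolis
acceptance, geometric cooling (default 0.995 per iteration), proposal
standard deviation annealed as $\sqrt{T/T_0}$ times the base scale
(default 0.1) so the search explores while hot and refines while cold, and
restarts (default 5) that re-heat from the best point. Failed integrations
return an infinite-cost sentinel rather than an error, so the chain simply
rejects ill-conditioned regions. The optimizer sits behind a plain
`function(v) -> cost` interface and is replaceable; every run is
reproducible from its seed. With `no_thermo = TRUE` the Wegscheider block
is omitted — the classical unconstrained "collective fitting" comparator —
and the result is still audited against the true cycle basis so its
infeasibility is flagged.

## Simulation

`simulate_network()` integrates the stiff reaction-rate ODEs with
`deSolve::lsoda` (adaptive, stiffness-switching) at `rtol = 1e-8`,
`atol = 1e-12`; signalling models mix time scales across many orders of
magnitude, so a stiff-capable integrator is the safe default. Clamped
species are enforced by zeroing their right-hand-side rows, never
integrated, so they are constant to machine precision. Negative excursions
are not clipped: below `-1e-8` (configurable) the run fails, because silent
clipping distorts the cost surface; solver noise above that threshold is
truncated to zero on output. `integrated_response()` accumulates a species'
trapezoidal time-integral on the solver grid — the cumulative-activity
summary used, e.g., for ERK-PP dose–response characterisation — with the
window an explicit argument since no canonical window exists.

## Synthetic fixtures and what they show

The generator exists so that every stage is testable offline.
`make_triangle()` is the minimal cyclic network ($M_2 = 1$); its infeasible
variants reach stationary states that carry a persistent circulating flux —
the qualitative failure mode the audit exists to catch.
`make_random_network()` builds a connected reversible ring backbone (so
cycles can exist) plus random uni/bimolecular reactions, then applies
clamping, irreversibility and optional exchange reactions so each pruning
rule can fire; structure and rates are reproducible from the seed.
`sample_feasible_params()` draws $\mathbf v \sim \mathcal N(0, s^2 I)$
through the reparameterization, guaranteeing feasibility by construction,
and `generate_data()` adds i.i.d. Gaussian noise at the observation points
— exactly the observation model whose likelihood the least-squares cost
maximises, so self-fit costs are $\chi^2$ with one degree of freedom per
point (checked in expectation across seeds). Noisy values are floored at
zero, with the raw draw retained.

What passing these tests does *not* show: real signalling topologies are
far larger and sparser in observations (often one observed species), real
measurement error is correlated and often multiplicative, and real models
mix rate laws beyond mass action. The fixtures validate the algebra, the
audit, and the estimation loop under the stated noise model — not
biological verisimilitude.

The recovery study conditions are fixed once: a 6-reaction, 4-species
network with one clamped species and one irreversible reaction, a feasible
ground truth drawn at scale 0.4 in $\mathbf v$, two initial-condition
experiments observed at 6 time points each, noise $\sigma = 0.05$, starting
models offset by $\mathcal N(0, 0.3)$ in log-parameters (order-of-magnitude
prior knowledge typical for rate constants), annealing at 250 iterations
and 2 restarts. These desk-scale sizes keep the full suite and the
acceptance script fast while exercising every pipeline stage; they are the
package's chosen study conditions, stated here so results are interpretable.

## Numerical choices

* Exact rational arithmetic for rank/null space of the integer
  stoichiometry; floats only enter with real-valued user constraints.
* Rank tolerance for the real constraint matrix: singular values below
  $10^{-10}\sigma_{\max}$ count as zero.
* "Condition satisfied" tolerance on the log-residual scale: $10^{-9}$
  (published parameter files carry roughly six significant digits, so a
  stated threshold is required for any satisfied/violated count).
* Infeasibility reporting: a small conflicting row set found greedily by
  drop-one tests — usable diagnostics, not exact irreducible subsystems.
* Ties in SBML decomposition are broken by parameter order; the
  decomposition itself is randomized numeric probing at fixed internal
  seed (constant law/candidate ratio means plain mass action, an
  everywhere-positive ratio means a generalized law whose modulation
  factor is the quotient), with a documented diagnostic — never silent
  acceptance — when no split exists.

## Interfaces and shape

Tabular things — species, reactions, parameters, trajectories, experiment
data, audit reports — are tibbles in and out, so calls compose with the
pipe; networks, constraint systems, reparameterizations and calibration
results are S3 objects (their content is matrix algebra, not a table) with
`tidy()`, `glance()` and `autoplot()` methods. SBML input/output is
implemented directly over `xml2` for the core constructs kinetic ODE models
use (Level 2/3 read, Level 3 Version 2 write); events, assignment rules
beyond clamping, algebraic rules and multi-model files are out of scope.
The thin command-line wrapper (`inst/cli/thermocal.R`) exposes `prune`,
`audit`, `simulate`, `calibrate` over a YAML run configuration with
precedence command line > file > defaults, writes a manifest (model hash,
seed, package version) for reproducibility, and uses distinct exit codes
for I/O errors, infeasible constraints and integration failures.

## Limitations

* Thermodynamically *coupled* reactions are excluded by construction (the
  independence step); handling them is an open problem in non-equilibrium
  thermodynamics, not a missing feature here.
* Ideal mixtures only; no activity coefficients, no ion/pH/temperature
  dependence of parameters (though such dependencies expressed as
  log-linear relations could be supplied as extra constraint rows).
* Point estimation only: no Bayesian posterior, no identifiability or
  profile-likelihood analysis. With few observed species, overfitting
  remains possible — the constraints shrink the search space (variance)
  without adding bias, but they do not substitute for data.
* The audit of a *specific* published large-scale model requires that
  model's SBML file and its annotation/tie lists, which are not
  redistributable inside the package; `inst/scripts/reproduce_audit.R`
  runs the analysis when they are supplied.
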