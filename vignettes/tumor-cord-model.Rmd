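---
title: "The tumor-cord electro-chemotherapy model: methods and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The tumor-cord electro-chemotherapy model: methods and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorcord)
```

## The physical model and its assumptions

A tumor cord is the annular sleeve of tissue around a single capillary,
used as the representative unit of vascularized tumor tissue.  The domain
is axisymmetric: radius from the (time-varying) vessel wall $r_v$ to the
cord radius $R_{cord} = 200\,\mu m$, axial coordinate along the vessel up
to $L_{cord} = 400\,\mu m$.  Three drug pools are tracked, all in $\mu M$:

* $C_1$ — extracellular (interstitial) concentration, transported by
  diffusion ($D$) and, when the vessel constricts, by the radial tissue
  velocity $u_r$;
* $C_2$ — free intracellular concentration, exchanged with $C_1$ across
  the cell membrane at rate $\alpha k_1$ ($\alpha$: membrane area per
  tissue volume, $k_1$: membrane permeability);
* $C_3$ — intracellular drug bound to a finite pool of binding sites
  $C_0 = 2600\,\mu M$, with association rate $k_2$ and dissociation rate
  $k_{-2}$.

Intracellular pools have no spatial operator: cells do not exchange drug
laterally, so any radial or axial structure imprinted on $C_2$ relaxes
only through the membrane.  The volume fractions $\delta_1 = 0.0588$
(extracellular) and $\delta_2 = 0.941$ (intracellular) weight the
capacities.  At the wall a Robin condition
$D\,\partial C_1/\partial n = k_v (C_v - C_1)$ couples the tissue to the
bloodstream concentration $C_v(z,t)$, which obeys a one-dimensional
advection–exchange equation with the inlet pinned to the pharmacokinetic
profile.  All concentrations start at zero: the simulation begins at the
moment of injection.

Two inlet profiles are provided.  The mono-exponential bolus (MPK,
$50\,\mu M \cdot e^{-0.005 t}$) front-loads the dose; the one-short
tri-exponential infusion (TPK) ramps over $\tau' = 180$ s and decays on
three time scales.  Both integrate to the same exposure,
$\mathrm{AUC} \approx 2.78\ \mu M\,h$, so the campaign compares delivery
*kinetics* at constant total dose.

Electroporation enters through three laws, all driven by the field
magnitude $E$ (uniform at this scale) and the time $t_p$ since the last
session:

* a sigmoidal effective conductivity $\sigma(E)$ centred midway between
  the reversible and irreversible thresholds, from which the degrees of
  electroporation $DOE$ and $DIE$ are normalized;
* the transient degree $DOE_R = DOE\,[(1-DIE)e^{-t_p/\tau_i} + DIE]$
  ($\tau_i = 100$ s), which linearly interpolates the membrane and wall
  permeabilities between their resting and permeabilized bounds
  ($k_1$: $10^{-9}$–$10^{-6}$ m/s; $k_v$: $2.8$–$4.4 \times 10^{-6}$ m/s);
* a double-exponential vasoconstriction $\hat r(E, t_p)$ with floor
  $\hat r_{min} = 0.25$ and decay $\tau_r = 330$ s, whose time derivative
  sets the wall velocity and, via a linear interpolation to the fixed
  outer boundary, the radial tissue velocity.

The tissue and vessel wall have separate electrical parameter sets (the
wall's irreversible threshold is 175 kV/m against the tissue's 70 kV/m);
the wall column drives $k_v$ and the hydraulic permeability $k_{vc}$, the
tissue column drives $k_1$.  Blood flow loses volume through the wall
following the closed-form porous-tube solution; the decay coefficient is
implemented as $\vartheta^* = \sqrt{16\mu k_{vc}/r_v^3}$ — the square
root is required for the coefficient to carry units of 1/m, and the
printed expanded form of the leakage flow is retained alongside its
hyperbolic simplification as a mutual identity check.

### The vessel exchange rate

The bloodstream equation needs a volumetric exchange rate (1/s) while the
wall permeability $k_v$ is a velocity (m/s).  The package uses
$2 k_v / r_v$: the wall area per vessel volume is
$2\pi r_v/(\pi r_v^2) = 2/r_v$, and with this factor the drug leaving the
bloodstream exactly balances the Robin flux entering the tissue.  Any
other factor would create or destroy drug at the interface.
`advance_vessel_concentration()` takes the rate explicitly, so the
coupling is transparent and testable in isolation.

## Numerical scheme

* **Space**: a conservative finite-volume discretization on a structured
  $(r, z)$ grid with exact cylindrical cell volumes.  Interior fluxes
  telescope, so with a sealed wall total drug mass is conserved to solver
  tolerance (the suite checks a drift below $10^{-6}$ relative over 1000
  steps).  The Robin flux enters the wall-adjacent cells as a boundary
  face flux.  Advection by $u_r$ is first-order upwind on the sign of the
  velocity.
* **Time**: backward Euler for every field.  The scheme is
  unconditionally stable, positivity-preserving for this system
  (the $C_1$ matrix is an M-matrix; the pointwise $C_2$, $C_3$ updates
  have positive numerators and denominators), and its fixed points are
  the exact algebraic steady states — which is why the binding
  equilibrium test converges to $C_3 = C_0/(K_d + 1)$ with
  $K_d = k_{-2}/k_2 \approx 15.56\,\mu M$ regardless of step size.
* **Coupling**: within each step the fields are swept Gauss–Seidel style
  in the order $C_1 \to C_2 \to C_3 \to C_v$, each update under-relaxed
  with $\omega = 0.8$, until the maximum relative change falls below
  $10^{-6}$ (configurable).  Each $C_1$ solve is a direct sparse LU
  solve; the factorization is cached and reused while the geometry,
  permeabilities and step size are unchanged, which makes the no-field
  runs cheap.  Failure to converge within `max_outer` sweeps raises an
  error carrying the simulation time.
* **Scale factors** $S_L, S_T, S_C$ are applied as a uniform scaling of
  the assembled linear system, for conditioning only; with a direct
  solver the converged fields are invariant to them (asserted to
  $10^{-9}$ relative in the suite).
* **Saturation of $C_3$**: the implicit update
  $C_3^{n+1} = (C_3^n/\Delta t + k_2 C_2 C_0)/(1/\Delta t + k_2 C_2 + k_{-2})$
  is algebraically bounded by $C_0$, so the binding-site cap needs no
  clipping.

### Geometry updates and remeshing

Vasoconstriction is applied only when a field is on ($E > 0$): the
double-exponential law as printed decays to $\hat r_{min}$ even at
$E = 0$, which would constrict an untreated vessel, so the dynamics are
gated on the field and on the first session having started.  While
geometry updates are active, the radial grid is rebuilt on
$[\hat r\, r_{v0}, R_{cord}]$, fields are linearly interpolated column by
column, and the geometry-dependent properties are refreshed under two
conservation rules: the total intracellular volume and membrane area are
fixed, so $\delta_2$ and $\alpha$ dilute with the cord volume, the inert
solid fraction is preserved, $\delta_1$ takes up the remainder and the
effective diffusivity scales as $D = D_0\,\delta_1/\delta_{1,0}$.
Following the stated cost-saving rule, updates are applied only while
$\hat r \ge 0.9$ (relative reduction of at most 10%); below that the
geometry is frozen at its last applied state.  A `"delta"` mode
(re-mesh on changes larger than 10% since the last remesh) is available
as a configuration switch.  With the default vasoconstriction
coefficient, $\hat r(t_p{=}0) < 0.9$ already at 46 kV/m, so under the
campaign settings the geometry effectively stays at its initial state and
the moving-mesh machinery is exercised by direct unit tests at small
fields.

### Step sizes and problem scales

Three bundled problem sizes are used throughout: `smoke`
(13 × 5 nodes, 30 s steps, 1 h horizon) for interactive checks, `desk`
(31 × 13, 10 s, 24 h) for the full treatment and the acceptance script,
and `full` (61 × 25, 5 s) for convergence checks.  The reported
uniformity metrics change by less than 1% between `desk` and a grid four
times finer in each direction, and the suite asserts that the
refinement-to-refinement differences shrink monotonically.  A uniform
step of 5–10 s resolves the fastest transient of interest
($\tau_i = 100$ s) comfortably; no sub-stepping is used.

## The Boolean inference engine

The engine consumes only concentration snapshots.  For each grid point
and consecutive reporting interval it forms: the directions (increase `I`
/ decrease `D`) of $C_2/C_1$, $C_3/C_1$ and $C_3/C_2$; the reaction state
(`AS` if $C_3$ rose, `DIS` if it fell, `SATURATED` if it reached $C_0$,
which excludes association and reroutes to the no-association branch);
the membrane state at the interval end (`IN`, `EX` or `EQ` from
$C_2/C_1$ vs 1); and the direction of $C_1$.  Ties follow the non-strict
convention of the propositions — "remains equal" counts as an increase —
with a relative tie tolerance of $10^{-9}$ (configurable; shared with the
solver configuration).  Ratios whose denominator falls below
$10^{-12}\,\mu M$ are flagged `UNDEFINED` rather than classified, which
is how the all-zero initial interval is handled.

Five propositions carry the mechanism orderings
($P_8$: IN ≥ AS, $P_9$: EX ≤ DIS, $P_{10}$: EX ≥ ECT−,
$P_{11}$: IN ≤ ECT+, $P_{12}$: association exists), tied to the
observable directions by exclusive disjunctions ($C_1$ rises iff exactly
one of $P_{10}, P_{11}$; $C_2$ rises iff exactly one of $P_8, P_9$; $C_3$
rises iff $P_{12}$).  Contraposing the direction implications yields, per
scenario, a conjunction of three clauses; the reaction and membrane
states pin variables (association fixes $P_{12}$ true and removes the
dissociation arm; an absent mechanism cannot impose over a present one).
The classifier evaluates the pruned statement by exhaustive enumeration
(at most $2^4$ assignments) and reports the surviving relation, a
tautology, or a contradiction.  **The classifier always returns the
enumerated truth set**, rendered back into ordering strings.

`verify_rtm_table()` rebuilds every cell of the 8 × 2 × 3 scenario table
this way and compares it with the published simplified statements.  In
five of the eight direction scenarios the two agree exactly, cell by
cell, tautologies and contradictions included.  In the remaining three
rows the published derivation applies a resolution step and then drops
the clauses it resolved; resolution is an entailment, not an equivalence,
so those published statements are strict widenings of the enumerated
truth sets.  The verifier therefore reports both relations — equivalence
and entailment — and the suite asserts equivalence where the published
algebra kept all clauses and entailment everywhere.  The widened rows are
exactly the ones whose direction patterns are constrained by the ratio
identity $C_3/C_1 = (C_3/C_2)(C_2/C_1)$ (for example, $C_3/C_1$ cannot
rise while both factors fall), which is why several of their cells
enumerate to contradictions.  On simulated trajectories those patterns
arise only through ties, so the practical classifications are unaffected.

The $C_1$-direction refinements ("if $C_1$ increases, the statement
collapses to IN ≥ AS", and so on) are applied exactly where the scenario
table prints them, and each is verified by enumeration to imply its
unrefined statement.  The direction of $C_1$ is additionally emitted as
its own layer (the marker overlay in `plot_rtm_map()`).  The refinement
constraint is *not* imposed as a hard admissibility filter on other
cells: the Boolean abstraction renders negations as strict inequalities,
so a hard filter would misclassify the measure-zero equality cases that
real fields do visit.

An alternative interval semantics (`membrane_at = "both"`) requires the
membrane state to agree at both endpoints and tags disagreements as
`TRANSITION` ("A to B"), mirroring how mid-interval mechanism switches
are annotated in contour maps.

## What the simulations do and do not show

The campaign (18 scenarios: $E \in \{0, 46, 70\}$ kV/m,
$\lambda_{inl} \in \{10^{-4}, 10^{-3}, 10^{-2}\}$ m/s, two PK profiles)
emulates a 24 h treatment with six evenly spaced electroporation sessions
(0, 4, …, 20 h; the session count and total time are fixed by the study
design, the even spacing is this package's neutral choice and is
configurable).  The model is a continuum idealization: no cell-death or
resistance dynamics, no interstitial pressure field, no pulse-level
electroporation physics (the pulse-train microstructure is carried as
metadata but does not enter any equation), and a single straight
capillary rather than a vascular network.  Conclusions about spatial
uniformity therefore concern the cord scale, not whole-tumor
heterogeneity.

Against the reference values reported for this model family, the
package's grid-converged runs reproduce every $C_2/C_1$-based uniformity
range we test to within a few percent (e.g. 0.0134 vs 0.013 at 24 h for
the no-field infusion case), together with the qualitative regimes
(internalization throughout for the infusion, externalization after half
an hour for the bolus) and their time orderings.  The $C_3$-based ranges
and the reverse-diffusion crossing window do **not** match the reference
values under the printed parameter set: the discrepancies are
mesh-converged and traceable to the early-time radial imprint on the
intracellular pools and to the wall concentration equilibrating with the
bloodstream on a ~100 s time scale, both structural consequences of the
equations as printed.  The acceptance suite reports these quantities
honestly rather than fitting them; the corresponding checks are expected
to fail until the upstream model variant is clarified.

## Degenerate inputs and edge behaviour

Empty electroporation schedules yield an infinite time-since-session and
baseline permeabilities.  A sealed wall ($k_v = 0$) decouples the vessel;
leakage with zero hydraulic permeability short-circuits to zero flow
before the porous-tube amplitude (which would divide by
$\vartheta^* = 0$) is evaluated.  Axial velocities are floored at zero
with a warning if leakage exceeds inflow.  Negative concentrations after
remesh interpolation are clipped at zero.  All-zero snapshots classify as
`UNDEFINED` rather than erroring, and constant trajectories classify
under the tie conventions.
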