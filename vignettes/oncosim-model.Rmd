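---
title: "The oncosim tumor model: assumptions, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The oncosim tumor model: assumptions, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

oncosim is a discrete-entity, discrete-event simulator of solid (prostate)
tumor growth and response to fractionated external-beam radiotherapy. This
vignette is the package's own account of the science it implements: the
cytokinetic model and its assumptions, the radiobiology, the mesh mechanics,
the numerical choices that were genuinely open, and what the included tests
do and do not establish.

## The cytokinetic model

Tumor tissue is a mixture of five cell categories:

* **stem cells** — unlimited mitotic capacity; they alone sustain the tumor;
* **LIMP cells** (limited mitotic potential, a.k.a. committed or restricted
  progenitors) — perform `N_LIMP` mitoses, then differentiate terminally;
* **differentiated (DIFF) cells** — no mitotic capacity;
* **apoptotic** and **necrotic cells** — dead pools awaiting clearance.

Cycling cells (stem and LIMP) traverse G1, S, G2 and M. Mitosis lasts 1 h;
the rest of the cycle is split as `T_G1 = T_S = 0.41 (T_c - 1)`,
`T_G2 = 0.18 (T_c - 1)`. A stem division is symmetric (two stem daughters)
with probability `P_sym`, otherwise asymmetric (one stem + one LIMP daughter
with a full reserve of `N_LIMP` mitoses). A LIMP(k) division yields two
LIMP(k-1) daughters; LIMP(1) divisions yield two DIFF cells.

Immediately after mitosis, each newborn pair is routed together: with
probability `P_sleep` both daughters enter the hypoxic dormant phase G0,
otherwise both re-enter G1 (the cycle-versus-dormancy decision is taken once,
at M-exit — there is no mid-cycle exit). Cells in the cycle are assumed
adequately oxygenated until the next mitosis completes.

Spontaneous apoptosis removes a fraction `R_A` of all living stem and LIMP
cells (cycling and dormant) per hour. Differentiated cells die at `R_ADiff`
(apoptosis) and `R_NDiff` (necrosis) per hour. Dead cells disappear from the
tumor once necrosis/apoptosis has completed and the debris has been cleared,
after `T_N` / `T_A` hours.

### Dormancy semantics

`T_G0` is the *mean* dormant residence: each hour a fraction `1/T_G0` of the
dormant pool leaves G0, and of the leavers a fraction `P_G0toG1` re-enters G1
while the remainder dies through necrosis (starvation). `P_G0toG1` is
dimensionless (a routing fraction), not a per-hour rate. Two observations
pin this interpretation down. First, the analytic free-growth condition
(below) contains the factor `P_G0toG1 / (T_G0 R_A + 1)`, which is exactly the
probability that a G0 entrant facing a competing exit hazard `1/T_G0` and an
apoptosis hazard `R_A` eventually re-enters the cycle. Second, under the
alternative reading (a per-hour exit fraction of 0.5–1), the dormant pool
would be a 1–2 hour transit holding well under 0.1 % of the tumor, which is
irreconcilable with the G0 fractions of several percent that the reference
virtual tumors exhibit; the exponential-residence reading reproduces them.

### The free-growth condition

Whether a parameter set can sustain growth is screened analytically before
simulating. The expected number of stem-fated daughters per stem mitosis
that survive to their own mitosis is

    LHS = (1 + P_sym) * [ (1 - P_sleep) + P_sleep * P_G0toG1 / (T_G0 R_A + 1) ]
          * exp(-R_A * T_c)

`(1 + P_sym)` is the expected number of stem daughters per division
(`2 P_sym + (1 - P_sym)`); the bracket is the probability that a daughter
survives the dormancy detour; the exponential is survival over one cycle.
LHS < 0.9 means free growth cannot be sustained; LHS > 1.1 ensures it; the
band in between is resolved by simulation. `free_growth_lhs()` also exposes
an alternative parenthesization (`parse = "literal"`) for comparison; the
0.9/1.1 thresholds are applied to the default parse.

## Radiobiology

Cell kill follows the linear-quadratic model,
`S(D) = exp(-(alpha D + beta D^2))`, with a uniform dose across the tumor.
Radiosensitivity is phase specific: the S phase is the most radioresistant
proliferating phase and hypoxic G0 cells are more resistant still, derived
from the proliferating-phase pair `(alpha_p, beta_p)` through the oxygen
enhancement ratio:

    alpha_G0 = alpha_p / OER        beta_G0 = beta_p / OER^2
    alpha_s  = 0.6 alpha_p + 0.4 alpha_G0
    beta_s   = 0.6 beta_p  + 0.4 beta_G0

Lethally hit cycling cells are not removed at the instant of irradiation:
they are *marked* (at the instant of administration) and enter a rudimentary
cycle that ends in necrotic death after two further mitoses (mitotic
catastrophe). Hit cells skip dormancy; hit dormant cells keep their mark and
join the rudimentary cycle when they re-enter. Assumptions where the
underlying biology is not specified, documented here as design choices:
differentiated cells are irradiated with the G0 (most radioresistant,
non-cycling) sensitivities and transfer to the necrotic pool one hour after
the fraction; hit cells remain subject to spontaneous apoptosis and are not
re-marked by later fractions; `cell_kill_factor` multiplies the stem-cell
kill probability (default 1, since no reference value is available).

## Mesh and morphology

A cubic mesh of geometrical cells (GCs, edge 1 or 2 mm) is superimposed on
the anatomy; each occupied GC holds a compartment vector of its biological
cells (nominally `NBC = cell_density * voxel_edge^3`, with
`cell_density = 1e6 /mm^3`). Every hour two scans run: the first applies the
cytokinetic and radiobiological rules within each GC; the second applies the
morphological rules that keep density roughly uniform while the tumor
expands or shrinks:

* a GC above `(1 + margin) NBC` unloads its excess over NBC to occupied
  26-neighbors with free space, fullest-capacity receiver first (seeded
  random tie-breaks); if excess remains, a chain of GC contents is shifted
  one step outward along a random direction and the freed adjacent GC takes
  the excess (differential expansion);
* a GC below `(1 - margin) NBC` pushes its contents to neighbors with free
  space; if it empties, a chain is shifted toward the vacuum, along the
  direction (of six randomly sampled) whose outermost occupied GC has the
  most tumor 6-neighbors (differential shrinkage);
* isolated GCs (all six face-neighbors empty) drift one GC at a time toward
  the tumor center of mass along the coordinate axis with the smallest
  non-zero offset, and fully enclosed empty GCs are refilled — iterated to a
  fixpoint so the tumor stays cohesive.

Axes whose offset to the center of mass rounds to zero are excluded from the
axis-selection minimum; the literal minimum would pick a direction along
which the GC cannot actually move. Cells moved between GCs are drawn
proportionally from all subclasses of the source. The scan visits GCs in
lexicographic order from a random per-step origin offset, avoiding
directional drift. If a chain reaches the lattice boundary the run aborts
with an explicit error; the user re-runs with larger dimensions.

Newly occupied growth-front GCs legitimately hold less than the band minimum
until growth fills them; the occupancy band is otherwise restored by each
scan wherever a receiver with free space exists.

## Numerical choices

**Hourly clock, age-structured delay lines.** The discrete time unit is
1 h (the duration of mitosis). Each cycling class is stored as a delay line
with one bin per hour of its cycle, so phase residence times are exact and
cohorts transition synchronously, as in a register-based bookkeeping, but
without the averaging bias that merging new entrants into a single per-phase
register would introduce. This matters because the reference tumors are
near-critical: the expected stem multiplication per generation is 1.004 to
1.015, so a distortion of cycle time by even a few percent swings the
doubling time by far more than the tolerance of any comparison.

**Phase bins.** The real-valued phase durations are mapped to integer hour
bins by a largest-remainder partition that preserves the total `T_c` exactly
(31 h becomes 12/12/6/1). Rounding each phase up independently would
lengthen the cycle by ~6 % and, at near-critical growth, bias the doubling
time far outside tolerance.

**Deterministic fractional flows.** Rates such as `R_A` are applied as
linear per-hour fractions (`count * R * dt`), matching their definition as
"fraction of cells per unit time"; with dt = 1 h this differs from the
exponential form only at O(R^2). Counts are real numbers by default (GC
populations are ~1e6); a Monte-Carlo mode draws every flow binomially on
integer counts for small-population work, and the deterministic flows are
its expectation (verified by a convergence test).

**Initialization.** Free-growth composition is obtained by the equilibrium
bootstrap: 10 GCs are seeded with 100 stem cells each (times in phase drawn
randomly, different streams per GC to avoid artificial synchronization),
evolved until every composition fraction varies by less than 1 % (relative)
over a sliding 30-day window, with a 3000-day budget; the growth rate is an
OLS fit of log total cells over the final window, and the doubling time is
`ln 2 / (24 rate)`. Seeds start cycling; the dormant pool populates
dynamically (a `g0_seed_fraction` switch seeds G0 directly). Meshes are
populated from the converged compartment profile itself — the equilibrium
eigenvector — which makes subsequent free growth monotone from the first
hour (the stated purpose of the bootstrap); a `"uniform"` profile
(phase occupancy proportional to duration, flat ages) is retained for
comparison. Each GC's initial load carries a seeded +/-5 % jitter so that
neighboring GCs do not cross the occupancy band synchronously; without it
the whole tumor overloads in the same hour and the avalanche of expansion
events distorts the shape.

**Calibration.** `calibrate_alpha()` solves
`reduction(alpha) = observed reduction` by bracketing root finding
(`stats::uniroot`), with `beta = alpha / 3` (the prostate alpha/beta
convention) and a residual tolerance of 0.1 percentage points. The runner is
the lattice-free engine by default: volume reduction of a homogeneous tumor
is composition-driven, and the well-mixed limit is orders of magnitude
faster than the full mesh; a lattice run can confirm the fit afterwards.
The runner is deterministic, so the root find is well posed.

**Sensitivity analysis.** One-factor-at-a-time indices perturb a parameter
by +/-5 % (falling back to +/-2.5 % when the perturbed run is biologically
unrealistic, e.g. a non-convergent bootstrap) and normalize the output
change by the magnitude of the input change, so a positive correlation gives
`SI+ > 0` and `SI- < 0`. Integer parameters (`N_LIMP`) are perturbed to the
nearest distinct integer and normalized by the change actually applied.
Baseline and perturbed runs share the seed (common random numbers). When a
parameter sits at its range boundary (e.g. `P_G0toG1 = 1`), the infeasible
side is reported as `NA` and the ranking uses the feasible side.

## The synthetic data generator

No clinical images or treatment plans ship with the package.
`generate_fixture()` emulates them: ellipsoidal voxel masks in place of
MRI-derived tumor outlines, weekday fractionation schedules (daily fractions
with weekend pauses; the default study schedule is 35 x 2 Gy, a standard
70 Gy course), and parameter files prefilled from the reference virtual
tumors. These fixtures reproduce the *structure* of patient data — geometry,
schedule, parameter ranges — but none of its heterogeneity: no
intra-tumoral oxygenation gradients, no segmentation noise, no organ
deformation. Tests passing on these fixtures therefore establish the
correctness of the mechanics and the internal consistency of the model, not
clinical validity on real images.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen once:
equilibrium bootstraps use 10 GCs x 100 seed stem cells; mesh properties use
3-6 mm spheres (tens to hundreds of GCs) over 10-100 simulated days;
treatment runs use the lattice-free mode over a 119-day horizon with the
35-fraction schedule. The mechanics are size-independent — larger masks and
longer horizons only cost time.

## Known limitations

* Oxygen and nutrient transport are not modeled explicitly; dormancy and
  the OER stand in for hypoxia, with `P_sleep` and `P_G0toG1` constant in
  homogeneous runs.
* Uniform dose across the tumor; no dose-volume heterogeneity and no repair
  or repopulation corrections beyond what the automaton produces.
* The mechanical interaction with surrounding anatomy is reduced to the
  cohesion rules; there is no biomechanical (finite-element) coupling, so
  shape preservation is statistical, not mechanical.
* Per-region (proliferating vs necrotic) parameterization is carried
  through the data structures, but the shipped studies are homogeneous.
* The Monte-Carlo mode requires counts below 2^31 per compartment.
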