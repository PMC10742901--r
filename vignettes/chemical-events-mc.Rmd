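---
title: "A chemical-events Monte Carlo model of radiation-induced MAA polymerisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A chemical-events Monte Carlo model of radiation-induced MAA polymerisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polymc)
```

## The model

polymc simulates the growth of poly(methacrylic acid) in an irradiated
aqueous solution with a coarse-grained, event-driven Monte Carlo method.
The resolution is deliberately coarse: one bead is one whole MAA monomer,
represented as an oriented cuboid, and all of the radical chemistry --
initiation, propagation, chain transfer, termination -- is subsumed into
two *effective events* acting on whole structures:

* **activation (combination)**: a radical activates a structure, which
  bonds to a neighbouring structure and grows;
* **breakdown**: a radical severs a bond, splitting a structure in two.

Radicals appear at uniformly random locations in the box, mimicking the
spatially random energy deposition of gamma irradiation.  When a radical
appears within the capture radius of a bead, a dimensionless deposited
energy $U$ is drawn and the event outcome is decided from two
probability laws whose coefficients depend on the size $n$ (in monomers)
of the activated polymer:

$$P_{\mathrm{act}}(U) = X(1-F) + X\,F\,\operatorname{erf}(G\,U), \qquad
  P_{\mathrm{brk}}(U) = X(1-F) + X\,F\,\operatorname{erf}(G\,U^2).$$

Both laws rise monotonically from a floor $X(1-F)$ at $U = 0$ to an
asymptote $X$.  The $(X, F, G)$ coefficients per size class (1, 2, 3, 4,
5, 6--10, 11--15, $\ge$16) come from a quantum-chemistry-based fitting
for MAA oligomers under a 20 cGy/min gamma dose rate and are consumed as
given; they ship as a plain CSV (`event_params()`).  Two structural
consequences are worth noting: monomers ($X = 1$, $F = 0$) always
activate, making free monomers the growth feedstock, and a lone monomer
can never break, so `p_brk()` requires $n \ge 2$.

Because the dose-rate dependence is already folded into those fitted
coefficients, the radical generation step itself carries no additional
physics: by default every Monte Carlo step proposes exactly one radical
location (`p_radical = 1`).

### The Monte Carlo cycle

Each step of `mc_step()`:

1. draws a uniform random location in the box;
2. finds the nearest bead within the capture radius (no bead: no event);
3. draws $U \sim \mathrm{Exp}(U_{\mathrm{mean}})$ and decides
   *combination* (probability $P_{\mathrm{act}}$), else *breakdown*
   (probability $P_{\mathrm{brk}}$, only for $n \ge 2$), else nothing;
4. applies the topology operator.  Combination bonds the activated bead
   to the nearest bead of *another* polymer within the capture radius;
   breakdown cuts one bond incident to the activated bead, chosen
   uniformly;
5. applies a random rigid rotation--translation to the affected
   structure (or, with no event, to one uniformly chosen molecule, so
   the system keeps relaxing);
6. checks feasibility -- every moved vertex inside the box, no overlap
   between any non-bonded bead pair -- and reverts the *entire* step if
   the check fails.  The step counter advances either way.

### Combination scenarios

The way two structures join depends on where the radical strikes:

* a **terminal** activation bead extends a chain (`extend`) -- this also
  covers a whole structure attaching as a single branch;
* an **internal** activation bead either attaches its polymer as a
  branch, splitting into two branches at the activation point
  (`branch`), or performs a **segment swap** (`swap`): one incident bond
  is cut and only the fragment carrying the activation bead joins the
  partner, leaving the remainder behind as a new polymer.

The dispatch is deterministic from topology where the description is
unambiguous (terminal beads always extend); the genuinely ambiguous
internal case picks `branch` or `swap` with equal probability.  Joining
two beads of the same polymer would create a cycle and is rejected, so
every polymer remains a tree throughout.

Geometry is enforced at the junction: the new bond is created at the
configured bond length, and where a junction gains three consecutive
beads the bond angle is set to the tetrahedral 109.5 degrees, with the
azimuth drawn at random.  When the activation bead retains more than one
prior neighbour, the angle is enforced against one of them (drawn at
random); the feasibility check governs the rest.

## Parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `box_edge` | 50 | nm | reference box; 40 nm is the smallest edge at which box-size effects are negligible, and sub-30 nm boxes are chemically meaningless (kept available for unit-scale work, with warnings) |
| `n_molecules` | 5875 | -- | reference concentration for the 50 nm box |
| `bead_half_extents` | (0.30, 0.225, 0.20) | nm | approximates the molecular envelope of one MAA monomer; the source model does not state bead dimensions |
| `bond_length` | 0.5 | nm | bonded beads stay in contact (slightly interpenetrating, and exempt from the collision predicate), while second neighbours at the 109.5 degree angle (centre distance 0.82 nm) still clear each other |
| `bond_angle` | 109.5 | degrees | tetrahedral carbon backbone |
| `capture_radius` | 1.2 | nm | twice the longest bead edge; the source model says only "within a certain distance" |
| `U_mean` | 1.0 | -- | $U$ is dimensionless and its distribution is not specified at the source; an exponential deposit is the simplest physically motivated choice and `U_mean` is the model's main calibration knob |
| `p_radical` | 1.0 | -- | dose-rate dependence is folded into the fitted $(X,F,G)$ |
| `theta_I0` | 10 | monomer nm^2 | rotation cap $\theta_{max} = \pi/(1 + I/I_0)$: bulky structures rotate less |
| `d_0`, `N_0` | 2, 10 | nm, beads | translation cap $d_{max} = \min(6 L_{edge}, d_0/\sqrt{1 + N/N_0})$; the hard $6 L_{edge}$ ceiling is never exceeded |
| `contact_tol` | 1e-9 | nm | GJK distances below this count as contact/collision |

The move-scaling constants deserve a note: the source model states only
that moves were "based on" the moment of inertia.  We use the scalar
moment of inertia about the centre of mass with unit monomer masses and
inverse scaling for both the angle and the displacement, the physically
sensible reading (large objects diffuse less), with the constants above
exposed in `sim_config()`.

## What the initial-state generator emulates

`init_box()` builds the pre-irradiation solution: the configured number
of molecules split into monomers, dimers and trimers in equal thirds by
molecule count (remainder to monomers), placed by rejection sampling --
uniform position, uniform random orientation (normalised 4-vector of
Gaussians), accepted only when inside the box and collision free against
everything already placed.  Multimers are built with exact bond lengths
and exact 109.5 degree angles, beads oriented long-axis along the bond.
At the default concentration this corresponds to roughly one percent
volume occupancy, so packing succeeds in a handful of attempts per
molecule.

What it does **not** emulate: explicit water (the solvent is implicit in
the fitted coefficients), oxygen and other scavengers, diffusion-limited
kinetics, spatially correlated radiolysis tracks, pH/charge effects, and
disproportionation termination.  Tests passing on this generator say the
*engine* honours its contracts (conservation, tree topology, collision
freedom, reproducibility); they do not certify chemical accuracy for
real systems, which hinges on the fitted coefficients and on `U_mean`.

## Definitions used by the analyses

* **polymer length**: total bead count of a polymer.  (A defensible
  alternative would be a maximal-walk count; total mass is the reading
  we adopt.)
* **backbone length**: number of beads on the longest simple path
  through the bond tree -- the tree diameter in vertices, the standard
  backbone proxy for acyclic coarse-grained polymers.  Computed by
  double breadth-first search; ties are broken arbitrarily since only
  the length is reported.
* **growth statistics**: means are taken over polymers of size at least
  2; free monomers are counted separately.  A frame with no polymerised
  material reports the means as `NA`.
* **Jaccard similarity**: the compared sets are voxel-occupancy
  patterns -- 1 nm voxels (configurable) marked occupied when they
  contain at least one bead of a polymer of size at least 2.  This is
  the reading consistent with comparing growth *patterns*; an
  alternative strategy compares the multiset of polymer sizes instead
  (`strategy = "sizes"`).  Two empty patterns count as identical.  The
  flattened comparison series includes self-comparisons, so $n$ boxes
  yield $n^2$ entries (70 boxes: 4900).
* **subcube deviation**: the box is divided into cubes (10 nm cells
  give the 125-cell grid on the default box), beads are counted per
  cube, and for each pair of boxes the absolute count differences are
  averaged over corresponding cubes.  We flag this as an
  *interpretation*: it is one natural formalisation of comparing
  per-cube counts across boxes, not a formula stated by the source.

### Similarity decay in replicate ensembles

For replicates started from **one shared initial box** under different
random streams, the similarity matrix at step 0 is exactly all ones and
decays towards the random-overlap floor as trajectories diverge.  With
independently packed initial boxes there is no decay to observe: the
patterns are uncorrelated from the start and the index sits at the floor
throughout.  The decay is fast at unit-test scale -- a 15 nm box loses
most pattern memory within a few thousand steps because every step moves
a molecule by up to ~2 nm -- so recorded snapshots must be spaced
closely enough (we use 500 steps) for the early records to fall inside
the transient.  This is a measurement-design constraint, not a tuning:
measuring any decay requires sampling before it completes.

## Numerical choices

* **GJK**: native implementation over cuboid support functions (support
  point = vertex maximising the dot product with the search direction),
  with a closest-point simplex reduction; termination at 1e-10 nm or 64
  iterations; degenerate (zero-volume) inputs are rejected.  Touching
  bodies report distance 0 and count as colliding.
* **Collision predicate**: GJK distance below `contact_tol` for pairs
  at bond-graph distance greater than 1; bonded neighbours are in
  contact by construction and exempt.
* **Broad phase**: circumsphere prescreen per pair; the all-pairs box
  validation uses a uniform cell grid, defined to be an optimisation
  only -- correctness is fixed by the all-pairs predicate.
* **Boundaries**: a move placing any vertex outside the box is
  infeasible and reverted; there are no periodic images.  Bounds checks
  use the exact support extents of the oriented cuboid with a 1e-9 nm
  slack against floating-point jitter.
* **Orientations**: unit quaternions, renormalised after every
  composition to prevent drift; rotations pivot at the centre of mass
  of the moved structure.
* **Identifiers**: bead ids are stable for the whole run; a breakdown
  assigns a fresh polymer id to the detached component (the side not
  carrying the activated bead).

## Reproducibility

All randomness -- including the C++ packing kernel -- flows through R's
default Mersenne-Twister (MT19937) stream, so a `sim_config()` seed
fully determines every coordinate, event and statistic of a run,
bit-exactly within one platform/build.  Ensemble replicate $i$ runs at
seed `base_seed + i`.  The number of random draws consumed by a step
depends on the branch taken (an accepted combination consumes one
outcome draw, a rejected one two), which is part of the deterministic
contract, not a violation of it.

## Verification scale

The test suite verifies the engine at desk scale: 10--15 nm boxes at the
reference concentration (a 15 nm box holds 159 molecules), runs of 1e5
steps, ensembles of 20 replicates, 200 random cuboid pairs against a
dense-sampling distance oracle, 1e5 randomised topology operations, and
1000 random trees against an exhaustive longest-path search.  The
reference-scale campaign (70 boxes of 5875 molecules, 6e7 steps each)
is the package's documented target for cluster use; its headline growth
levels (mean backbone around 35 monomers, mean polymer length around 50)
are not recomputed at desk scale, where the same engine reaches a
smaller combination/breakdown equilibrium.  Desk-scale runs still show
the qualitative signature: growth from the initial mix (mean length 2.5)
to a fluctuating plateau with the mean backbone strictly below the mean
polymer length once branching appears.  Matching the full-scale levels
is a calibration exercise over `U_mean` and `capture_radius` at full box
size and step count.

## Known limitations

* Chemistry beyond the two effective events (secondary reactions,
  disproportionation, scavenging) is absent by design.
* Polymers are strict trees; cross-linked (cyclic) networks cannot
  form, so the late gel regime of real dosimeters is out of reach.
* The per-step cost grows with structure size through the collision
  check, and the engine is serial; reference-scale campaigns are long.
* `U` is an internal dimensionless energy with a chosen distribution;
  absolute dose calibration is only as good as the fitted coefficients.

## A worked example

```{r, eval = FALSE}
library(polymc)

cfg <- sim_config(box_edge = 15, n_molecules = 159, steps = 1e5,
                  seed = 7, snapshot_interval = 500)
run <- run_box(cfg)
glance(run)
autoplot(run)

shared <- init_box(cfg, seed = 7)
ens <- run_ensemble(cfg, n_boxes = 20, box = shared)
sim_early <- ensemble_similarity(ens, step = 500)
sim_late  <- ensemble_similarity(ens, step = 1e5)
glance(sim_early)$mean_jaccard - glance(sim_late)$mean_jaccard # > 0
```
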