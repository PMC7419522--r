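---
title: "Modelling aerosol deposition in airway trees with absorbing Markov chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling aerosol deposition in airway trees with absorbing Markov chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aerodep)
```

## The model and its assumptions

`aerodep` treats each airway segment of a dichotomously bifurcating tree as
one state of a discrete Markov chain. A particle in a segment is either
suspended (transient state) or deposited on the wall (an absorbing capture
state, one per segment); particles leaving a terminal bronchiole enter a
single absorbing escape state standing for alveolar delivery. The chain
makes one transition per airway generation; there is no notion of position
*within* a segment — every segment is entered with the cross-sectionally
uniform particle distribution its deposition formulas assume. That is the
central approximation: capture correlations between consecutive segments
(a particle that hugged the wall in the parent also starts near the wall in
the daughter) are deliberately averaged away, which is defensible because
consecutive segments are near-randomly reoriented in 3D.

Per-segment capture combines three mechanisms, assumed independent:

* **Gravitational sedimentation.** For Poiseuille flow in a cylinder at
  elevation $\theta$ from the horizontal, the settling parameter
  $\kappa = \tfrac34 (v_s/\bar U)(L/D)\lvert\cos\theta\rvert$ compares the
  settling time across the lumen with the transit time;
  $p_s = \tfrac2\pi\!\left[2\kappa\sqrt{1-\kappa^{2/3}}
  - \kappa^{1/3}\sqrt{1-\kappa^{2/3}} + \arcsin\kappa^{1/3}\right]$.
  A tube parallel to gravity ($\theta = -\pi/2$) has $\kappa = 0$ and
  exactly zero sedimentation. The closed form assumes
  $d_p \ll d_s = \sqrt{72 Q \mu / (\lvert\sin\theta\rvert \rho_p g \pi D^2)}$;
  the package warns when $d_p > 0.1\,d_s$.
* **Inertial impaction.** $p_i = 1.606\,\mathrm{Stk} + 0.0023$ with
  $\mathrm{Stk} = U_0 \rho_p d_p^2 C_c / (18 \mu D)$. The linear law is the
  small-Stk limb of the sigmoidal impaction curve; it is validated below
  $\mathrm{Stk} = 0.15$ and the package warns above that. Within the
  physiological flow range (0.0001–1 L/s) and for particles under 10 µm,
  encountered Stokes numbers stay below the bound.
* **Brownian diffusion.** A four-exponential expression in
  $\Delta = \frac{k_B T C_c}{3\pi\mu d_p}\,\frac{L}{\bar U}\,\frac{1}{D^2}$,
  with $p_d = 1$ for $\Delta \ge 0.16853$.

The segment escape probability is the independence product
$p_e = (1-p_s)(1-p_i)(1-p_d)$. Flow partitions at every bifurcation
inversely to the daughter subtrees' input resistances, built recursively
from per-segment Poiseuille resistances $R = 128\mu L/(\pi D^4)$ with
daughters in parallel; a terminal subtree's resistance is just the terminal
segment's own (no peripheral compliance). Partitioning is laminar and
linear — no inertial or bifurcation-angle corrections — so flow fractions
are a pure property of geometry, and rescaling the inlet flow rescales
every local flow proportionally.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| particle diameter $d_p$ | — | m | the dominant control on deposition |
| particle density $\rho_p$ | 1000 | kg/m³ | unit density, the aerosol convention |
| air viscosity $\mu$ | 1.9e-5 | Pa·s | dry air at 37 °C |
| air density $\rho$ | 1.14 | kg/m³ | dry air at 37 °C (enters only Re) |
| temperature $T$ | 310.15 | K | body temperature |
| mean free path $\lambda$ | 7.0e-8 | m | Cunningham correction at 37 °C |
| slip coefficients | 1.257, 0.4, 1.1 | — | standard Knudsen-regime values |
| $g$, $k_B$ | 9.80665, 1.380649e-23 | SI | standard values, overridable |
| admissible flow range | [1e-7, 1e-3] | m³/s | physiological 0.0001–1 L/s |
| voxel edge | 0.005 | m | planar-scintigraphy-scale resolution |

The Cunningham factor
$C_c = 1 + (2\lambda/d_p)(1.257 + 0.4\,e^{-1.1 d_p/2\lambda})$ and the
Stokes settling velocity $v_s = \rho_p g d_p^2 C_c/(18\mu)$ (buoyancy
neglected — air/water density ratio ~1e-3) are the package's choices; both
are standard and both are exposed for override. The single-tube optimum
flow for micron particles is insensitive to them: in the small-$\kappa$,
small-Stk regime the capture minimum sits where
$1.70\,\kappa \approx 1.606\,\mathrm{Stk}$, i.e. at
$Q^* \approx A\sqrt{0.75\,gL/0.945}$ — geometry alone. For the benchmark
bronchus (6.3 cm × 1.35 cm) that is ~0.1 L/s.

## The synthetic tree generator

No public morphometric reconstruction ships with the package, so study
conditions are defined by `generate_airway_tree()`: a full binary tree with
an adult-trachea-scale root (L = 0.12 m, D = 0.018 m) descending along
gravity, per-generation length and diameter ratios of 0.78 (major daughter)
and 0.70 (minor), branch half-angles uniform on 20–50° with uniform
azimuth, and a random left/right assignment of the major branch. These are
morphometrically plausible human values: diameters halve roughly every two
generations, daughters are unequal, and branch directions decorrelate from
gravity within a few generations. The generator is seeded and restores the
caller's RNG state.

What it does *not* emulate: lobar anatomy, intra-segment curvature, the
extrathoracic airway, airway wall motion during the breath, and regional
compliance differences. Tests passing on these trees therefore demonstrate
the *model machinery* — conservation, oracle equivalences, policy
orderings, rotation symmetries — on realistic scales, not agreement with
any individual lung. Escape probabilities for a specific patient geometry
require reading that geometry in through `read_airway_tree()`.

## Numerical choices and conventions

* $\kappa$ is clipped to $[0,1]$ before the sedimentation formula
  ($\kappa \ge 1$ means settling beats transit: certain capture, $p_s$ set
  to exactly 1); $\cos\theta$ magnitudes below 1e-12 are zeroed so that
  axis-parallel tubes give exactly $p_s = 0$ rather than a 1-ulp residue.
* $Q = 0$ follows the infinite-residence convention: $p_s = p_d = 1$,
  $p_i = 0.0023$.
* The diffusion threshold is applied exactly as stated even though the
  series evaluates to ≈0.93 just below $\Delta = 0.16853$, leaving a small
  jump to 1. The discontinuity sits at flows far below the physiological
  range for the particle sizes of interest.
* The capture-minimizing flow is found by a 200-point log-spaced grid seed
  followed by bounded scalar minimization in $\log_{10} Q$ (relative
  tolerance 1e-4 in $Q$); boundary minima are legal. A consequence of the
  printed kernels worth knowing: even for a 0.35 µm nanoparticle the
  combined single-tube capture has a *very shallow* interior minimum
  (~3e-4 absolute rise from ~0.16 L/s to 1 L/s) because the linear
  impaction slope eventually exceeds the decaying sedimentation/diffusion
  tails. On a log axis the curve looks monotone; strictly it is not, and
  one acceptance-style check of strict monotonicity documents this by
  failing.
* Absorption is solved exactly: the transient block of the chain is
  strictly triangular in the breadth-first ordering, so one sparse linear
  solve yields reach probabilities, per-segment capture, and per-terminal
  escape with no time-stepping error. Path enumeration of
  $P_e = (Q_n/Q_0)\prod_k p_{e,k}$ is implemented independently and agrees
  to 1e-10 — the module's standing cross-check, alongside a seeded
  Monte-Carlo walker simulation.
* Equal daughter resistances split flow exactly 0.5/0.5 (forced by the
  inverse-resistance formula).
* Rotation is applied about the coordinate origin; since deposition depends
  only on segment directions relative to gravity, the origin choice is
  immaterial. Rotations about the gravity axis change no gravity angle and
  therefore no probability.
* Voxelization assigns voxels by a center-in-cylinder test and then
  renormalizes within each segment so its voxels sum exactly to its capture
  probability — the raw voxel-to-segment volume ratio under-fills segments
  thinner than the 5 mm grid. A segment containing no voxel center (common
  in the periphery) deposits its whole mass in the voxel holding its
  midpoint; a voxel center inside two segments belongs to the deeper
  generation, deterministically. Escape mass is spread uniformly over a
  3×3×3 voxel cube at each terminal's distal end; overlapping cubes add.
  Probability is conserved to 1e-9 through voxelization and projection.

## Flow policies

The optimal waveform is built generation-locally: each segment's
capture-minimizing local flow (searched over the inlet range scaled by the
segment's flow fraction) is converted to an inlet-equivalent
$Q_0^* = Q^*_{\text{seg}}/f_{\text{seg}}$, clipped, and averaged
*arithmetically* within its generation (the geometric mean is a defensible
alternative; arithmetic was chosen as the convention for reporting inlet
flows, and the policy comparisons are insensitive to the choice). Step
durations are the mean residence times $L_k/\bar U_k$ of each generation at
that step's flows, with time zero at particle release into the trachea.
Policy evaluation steps a particle cohort one generation per step,
rescaling all flows to the step's inlet flow; a constant policy reproduces
the absorbing-chain solution exactly. Generation-local optimization is a
scope decision, not an oversight: joint optimization over all segments of
an asymmetric tree is a different (and much harder) problem.

Typical behavior on the default 12-generation synthetic tree: for 3.5 µm
particles the optimal ramp-up policy beats every constant policy (slow in
the vertical impaction-prone trachea, faster in the periphery); for
0.35 µm particles the optimum converges to the constant maximum flow
within 1%, since impaction never penalizes nanoparticles.

## Problem sizes used by the tests

The shipped suite exercises trees of 3–12 generations (7–4095 segments),
Monte-Carlo oracles at 1e5 samples, and 20-tree randomized equivalence
sweeps; the whole suite solves in well under a minute on a laptop-class
core. These sizes were chosen as the smallest that make the stochastic
oracle bounds (3 standard errors) meaningful and the policy orderings
unambiguous.

## Known limitations

* Per-segment probabilities assume developed Poiseuille flow; the first
  generations at high flow are inertia-dominated in reality, and
  resistance-based partitioning ignores the tendency of fast flow to favor
  aligned daughters.
* No exhalation phase, no time-resolved intra-breath concentration, no
  airway compliance or dimension changes during the breath.
* The upper airway (mouth, pharynx, larynx) is outside the model; optimal
  policies apply to the central and lower airways only.
* For particles above ~10 µm the linear impaction law under-predicts
  saturation; a sigmoidal law would be needed.

```{r example}
tr <- generate_airway_tree(8, seed = 1)
fit <- deposition(tr, particle(3.5e-6), q0 = 5e-4)
fit
```
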