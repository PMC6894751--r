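---
title: "Models and methods in vertexGBE"
author: "vertexGBE authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in vertexGBE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertexGBE)
```

# Scope

`vertexGBE` couples two things that are usually kept apart: a vertex-model
simulator of *Drosophila* germband extension (GBE) in which cell
rearrangement proceeds through higher-order vertices that resolve
stochastically, and the quantification suite used on tracked-cell data
(shape metrics, strain-rate decomposition, neighbour-exchange detection).
Because the simulator exports its trajectories in the same tracked-cell
schema that the synthetic generators produce, every analysis runs
identically on simulated tissues and on synthetic ground-truth data.

# The mechanical model

## Energy and dynamics

Cells are polygons on a periodic rectangular box (a torus: no boundary
artefacts, V − E + F = 0 throughout). The energy is the standard
vertex-model functional

$$E = \sum_c \tfrac{K}{2}(A_c - A_0)^2 \;+\; \sum_e \Lambda_e \ell_e \;+\;
  \sum_c \tfrac{\Gamma}{2} L_c^2,$$

with area elasticity $K = 1$, preferred area $A_0 = 1$ (all quantities in
dimensionless model units; one model length unit is exported as 3.4 µm and
one time unit as 1 minute), line tension $\Lambda = 0.05$ and perimeter
contractility $\Gamma = 0.04$ for the wild-type tissue. Vertices follow
overdamped gradient descent with unit friction and step `dt = 0.01` min;
with no topology events a step never increases the energy (checked to
1e-10 in the tests).

## Planar polarisation

Each cell carries one of four stripe identities repeating along the
anteroposterior (AP) axis, one column of the brick-staggered hexagonal
lattice per stripe. Interfaces between cells of different stripe identity
— the vertical, dorsoventrally (DV-) oriented junctions — receive a
supplementary cable tension `lambdaCable`. The lattice orientation was
chosen deliberately: with vertical boundary junctions, the pair of cells
that gains contact in a T1 lies within a single column (same stripe), so
the newly formed AP-oriented junction is cable-free and stable, making
swaps productive rather than reversible. The default `lambdaCable = 0.4`
($8\Lambda$) is the smallest value we found at which boundary junctions
become locally unstable and collapse within a 30-minute run; at the naive
$2\Lambda$ the polarised tension merely shortens all boundary junctions
uniformly to about 90% of their length and no rearrangement ever occurs.

## Box degrees of freedom

On a torus, convergence–extension requires the box itself to deform.
Two mechanisms move the box, both documented as this package's design
choices:

* **DV relaxation** (`boxRelaxStep`): the DV box length is a slow degree
  of freedom relaxing down the energy gradient,
  $\dot L_y/L_y = -\mu\,\sigma_{yy}$ with mobility `boxFriction = 0.1`/min.
  This is gradient descent (energy non-increasing) and supplies the DV
  convergence that lets polarised junctions actually shorten; with both
  box lengths frozen no junction can reach the merge threshold, whatever
  the cable tension, because uniform DV shortening is geometrically
  forbidden.
* **The posterior pull** (`applyPosteriorPull`): each step, a probe strain
  $E_x$ (default $10^{-3}$) maps the x-coordinates of the posterior region
  (the posterior-most two cell columns) as $x \to x + E_x x$; the AP
  stiffness is estimated as $C_{xx} = \Delta\sigma_{xx}/E_x$ from the
  change in the tissue stress tensor; the configuration is reverted
  exactly (stored positions are restored, so probe-and-revert is the
  bitwise identity); and the true strain
  $E^{\text{post}} = \sigma^{\text{post}}/C_{xx}$ is applied with the box
  length updated consistently. The stress schedule is a plateau
  ($\sigma_0 = 4\times10^{-4}$ for 15 min) followed by a linear ramp to
  zero at 30 min. $\sigma_0$ was calibrated once so the wild-type preset
  extends at ≈ 0.025/min initially (target band 0.02–0.03/min), and not
  revisited.

The tissue stress is the virial (Batchelor) expression — area-weighted
cell pressures plus line-tension dyads over the box area — and is
validated in the tests against a finite-difference derivative of the
energy with respect to an affine box strain.

## Rearrangement through higher-order vertices

Instead of instantaneous T1 swaps, junctions shorter than
`lMerge = 0.2` collapse into a single vertex: rank 4 (protorosette) when
two rank-3 vertices merge, rank 5+ (rosette) when a junction merges into
an already-collapsed vertex. Collapses that would create a two-sided cell
or fold a neighbour inside out are skipped. A rank-4 vertex resolves with
probability $1 - e^{-p_4\,dt}$ per step, reconnecting the cell pair that
was *not* adjacent before the collapse (completing the T1) with a new
junction of length `lNew = 0.3`; a rank-$r\geq5$ vertex resolves at rate
$p_{5+}$ by detaching a single cell (yielding ranks $r-1$ and 3), chosen
among admissible detachments as the one that lowers the energy most (ties
broken uniformly at random from the run's seeded RNG; draws are consumed
in ascending vertex order, so runs are reproducible). The exponential
rate-to-probability convention makes the behaviour invariant to `dt`
refinement.

`lMerge` had to sit inside the range the passive dynamics actually reach:
the junction-length floor under full DV stress relaxation is ≈ 0.19, so
the conventional "10% of a cell side" threshold is never crossed; 0.2
(about one third of the unit-area hexagon side) is reachable while
`lNew = 1.5 lMerge` keeps resolved junctions from re-collapsing
immediately.

## Presets and initial conditions

* `WT`: $p_4 = 1$/min, $p_{5+} = 0.1$/min.
* `sdk`: $p_4 = 0.1$/min, $p_{5+} = 0$/min (rosettes never resolve).
* `sdk_soft`: as `sdk` with $\Gamma = 0.01$ (reduced shear modulus).

The initial condition is a 14 × 20 tiling of regular unit-area hexagons
with a Gaussian vertex jitter of 0.05 model units (seeded from the run
seed). The jitter is a modelling necessity as much as realism: a
perfectly regular lattice shortens all its polarised junctions in
lock-step and no individual junction ever crosses the threshold first.

Under these conditions the wild type resolves its protorosettes quickly
(tens of unresolved rank-4+ vertices at 30 min) while the `sdk` preset
accumulates a few hundred, and rosettes in `sdk` are monotone
non-decreasing — the "stuck rosette" phenotype.

# Tracked-cell data and synthetic generators

`EmbryoTracks` holds per-frame cells (stable id, µm centroid, polygon
outline, type, temporal links) and interfaces (immortal id, incident
pair, endpoints, links) with the axis frame and a 30-s default cadence;
`readTracks`/`writeTracks` round-trip it through `cells.csv`,
`interfaces.csv` and `header.json`. Validation enforces simple outlines,
centroid–outline consistency (1e-6 µm), interface referential integrity
and temporal links.

Two generators create ground truth: `generateAffineFlowTracks` advects a
hexagonal lattice (2-µm sides, cell area ≈ 10.4 µm², in the range of
germband apical areas) by $x_{t+1} = (I + G\,\Delta t)x_t$, with optional
whole-cell Gaussian jitter — jitter moves outline and centroid together so
that centroid tracks are noisy but shapes stay exact, keeping the
recovery tests interpretable. `generateScriptedT1Lattice` shortens chosen
vertical junctions linearly to zero, optionally holds a four-way
configuration, and regrows the orthogonal (or, for reversions, the same)
junction; all outlines and interface endpoints are rebuilt from one
canonical vertex table so geometry and topology stay consistent.

What the generators do *not* emulate: segmentation noise on outlines,
pixelated contours, cells entering/leaving the field, curvature of the
embryo surface, or cell divisions. Passing the recovery tests therefore
shows correctness of the estimators on their stated input model, not
robustness to every artefact of real movies.

# Shape metrics

Cell shapes are summarised by the best-fit ellipse constrained to the
polygon's exact area and centroid, minimising the mismatch (symmetric
difference) area. The search is initialised from the polygon's second
moments and refined by Nelder–Mead over (log aspect, orientation); the
mismatch is evaluated by Sutherland–Hodgman clipping of the outline
against a 128-gon ellipse approximation. Because the optimiser never
returns a worse point than its initialisation, the refined fit is always
at least as good as the moment ellipse. From the fit:
anisotropy $=\ln(a/b)$; orientation folded into [0°, 90°] to AP; axial
shape elongation $=(\text{orientation}/45 - 1)\times\ln(a/b)$ (negative =
AP-elongated, positive = DV-elongated, zero for isotropic or 45°-oriented
cells); AP/DV cell lengths as the ellipse widths along the axes.
Interfaces are AP-oriented below 45° and DV-oriented above; exactly 45°
classifies as DV (a deterministic tie-break on a measure-zero case).
Heat maps bin (cell, frame) samples into 1-min × 3-µm cells over a
30 × 20 grid, with DV location measured as distance from the midline so
the two embryo halves pool by mirroring.

# Strain-rate decomposition

Domains are a focal cell plus one corona of interface neighbours,
followed over a 5-frame (2-minute) window. The tissue strain rate is the
symmetric part of the velocity gradient fitted by least squares to
centroid displacements: velocities are regressed on mid-interval
positions (centred on the domain mean) and the fitted gradient $G'$ is
corrected for the finite frame interval as
$G = (I - G'\Delta t/2)^{-1}G'$, which inverts the per-frame advection
map exactly — clean affine flows and rigid rotations are recovered to
machine precision, and mid-interval positions decorrelate the centroid
jitter from the velocity noise so jitter adds variance rather than bias. The cell-shape
strain rate fits, for each member cell and consecutive frame pair, the
linear map best carrying the centroid-aligned outline onto its successor,
averaged over the window and area-weighted across cells. When vertex
counts match, boundary points correspond by identity; only on a mismatch
are outlines resampled to 64 points by arc length (resampling does not
commute exactly with affine maps, so resampling only when forced keeps
the affine-recovery identity exact). Intercalation is the exact tensor
difference tissue − shape. Rates are projected onto the embryonic axes as
$\hat e^T S \hat e$; movies are synchronised at the first frame whose
median AP tissue strain rate strictly exceeds 0.01/min; genotype averages
carry an indicative confidence ribbon of half-width
$1.96\sqrt{\bar v/N}$ with $\bar v$ the mean of within-embryo variances
and $N$ the total samples at that time point (the pooled variance is
exported so alternative normalisations can be computed); and the
intercalation/tissue contribution is summarised per domain as
$\ln(i_{AP}/t_{AP})$, excluding non-positive components.

# Neighbour-exchange analysis

Connectivity changes of cell quartets identify T1 swaps. Interface
identity is made immortal: four-way frames are assigned to the most
recently connected pair (leading four-way frames to the first owner
seen), and interior ownership bouts shorter than 5 frames (2.5 min at
30-s cadence) are reversed, shortest bout first and earliest on ties,
iterating until none remain — the procedure is idempotent, and a
brute-force re-implementation of the written rules is used as an oracle
in the tests. One event is emitted per surviving ownership change, timed
at the gaining pair's first physical contact. Candidate quartets come
from first-contact events; the losing diagonal is preferentially the
common-neighbour pair that disconnects at the gain. Quartets whose two
diagonals are simultaneously connected somewhere in the tissue are
skipped by default (in dense rearranged tissue four cells can legitimately
meet at two separate junctions; `onBothDiagonals = "error"` restores the
strict behaviour).

Angular statistics: pre-swap orientation of the losing interface 5 min
before the gain (events too close to the track boundaries are excluded,
not errors); the lost–gained angle corrected for rigid rotation of the
quartet by subtracting the rotation of the gaining pair's
centroid–centroid line (90° for the idealised hexagonal quartet); the
shortening-interface–to–gaining-centroid-line angle over a 15-min
lookback (0° for the idealised quartet); and productive T1 counting —
cumulative DV-oriented minus AP-oriented gains, classified by the gaining
centroid line against 45°, normalised by the number of DV-oriented
interfaces per frame. For cross-genotype comparison on simulator exports
we summarise the normalised curve by its time average: stuck rosettes in
the `sdk` tissue remove vertex-model interfaces outright (a pixel tracker
would keep tiny interfaces), which deflates the late-time denominator and
can flip the final-frame value on its own.

The resolution phase of a swap is the contiguous interval, straddling the
gain, during which the immortal interface length (zero while a four-way
vertex persists) stays below 0.75 µm after smoothing with a normalised
5-frame Hanning window (the window length matches the 5-frame granularity
used elsewhere and is exposed as a parameter); phases touching the series
boundaries are discarded.

# Numerical choices and limitations

* Problem sizes in the test-suite: recovery tests run on 10 × 10 lattices
  over 21 frames; cross-genotype comparisons use five seeds per preset of
  the full 280-cell, 30-minute simulation; detector–oracle equivalence
  uses 1,000 random ownership series.
* The simulator's tissue is small (280 cells) and periodic; exported
  quartets can span the seam, and centroid tracks are unwrapped
  continuously so trajectories stay smooth across it.
* The ellipse mismatch is evaluated against a 128-gon, so mismatch areas
  carry an O(4e-4) relative discretisation error; the area constraint
  itself is exact.
* `sdk_soft` reproduces the reduced-shear-modulus variant mechanically;
  we make no claim that its strain-rate curve matches embryo data, only
  the qualitative orderings tested.
* No cell division, extrusion, 3D mechanics, explicit myosin dynamics or
  parameter fitting to embryos.

# A short worked run

```{r, eval = FALSE}
sim <- simulateGBE(gbePreset("WT", seed = 1))
sim
tracks <- simulationTracks(sim)
events <- detectT1Events(tracks)
productive <- countProductiveT1s(events, tracks)
mean(productive$normalized, na.rm = TRUE)
```
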