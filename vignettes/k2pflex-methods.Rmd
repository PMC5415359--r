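---
title: "Methods: quantifying K2P channel mechanogating from trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying K2P channel mechanogating from trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(k2pflex)
```

## The scientific problem

Mechanosensitive two-pore domain (K2P) potassium channels such as TREK-2
are gated by forces transmitted through the lipid bilayer ("force from
lipid").  Crystallography shows two principal conformations — a *down*
state with open lateral fenestrations and an *up* state in which the lower
transmembrane helices have moved and the fenestrations are sealed — and
simulation work shows that membrane stretch drives the down-to-up switch.
Analysing such trajectories requires a small set of recurring
measurements:

* **State metrics.** C&alpha; RMSD of the TM helices (M1–M4) against the
  down and up references, and three inter-residue distances that resolve
  the transition into its elementary steps: the *fenestration* distance
  (G324 on M4 to P198 on M2 of the adjacent chain), the *zipper* (W326 on
  M4 to R237 on M3 of the same chain) and the *expansion* (M322 on M4 to
  G212 on M2).  On stretch the fenestration contracts and closes while
  zipper and expansion grow, and unzipping always precedes expansion and
  closure; the two chains move independently.
* **Membrane geometry.** Cross-sectional area of the protein as a
  function of depth (the down-to-up switch expands the cytoplasmic half
  by roughly 4–5 nm²), bilayer thickness from the head-group phosphates
  (about 36 &Aring; for unstretched POPC, about 31 &Aring; when stretched),
  and area per lipid from the box dimensions.
* **Lateral pressure profile.** The depth-resolved stress anisotropy
  P<sub>L</sub>(z) = P<sub>&par;</sub>(z) − P<sub>&perp;</sub>(z), with
  P = −&sigma; and P<sub>&par;</sub> = (P<sub>xx</sub>+P<sub>yy</sub>)/2,
  computed from a z-binned local stress tensor
  (Hardy/Irving–Kirkwood–Noll) on a 0.1 nm grid.
* **Occupancy analyses.** K⁺ occupancy of the selectivity-filter sites
  S0–S4, pore hydration and transient dewetting of the inner cavity, and
  lipid–protein contact series (a lipid tail is "bound" when it comes
  within 4 &Aring; of the target residue).

The package implements each of these as a tested operation and, because
raw channel trajectories are rarely redistributable, ships synthetic-data
generators that produce every input class with recorded ground truth.

## The local stress model

For each z-bin *b* of width *h* the stress tensor is

$$\sigma(b) = -\frac{1}{V_b}\Big[\sum_{i \in b} m_i\, v_i \otimes v_i
  + \sum_{(i,j)} w_b(i,j)\; r_{ij} \otimes f_{ij}\Big],$$

where the virial of each interacting pair is distributed along the
straight minimum-image segment between the two particles, and
*w<sub>b</sub>* is the fraction of that segment inside bin *b* (a top-hat
bond function along the Irving–Kirkwood contour).  Contributions wrap
periodically, and the weights satisfy an exact partition of unity, which
makes two strong invariants testable:

* &Sigma;<sub>b</sub> w<sub>b</sub> = 1 to 10⁻¹² for arbitrary segments,
  including ones crossing the periodic boundary;
* the volume-weighted sum of the bin tensors equals the whole-box
  virial-plus-kinetic stress to 10⁻⁶ relative accuracy (in practice it is
  exact to floating-point rounding).

Units are internal kJ/mol, nm, ps and amu, with the single conversion
factor 16.6054 from kJ/mol/nm³ to bar recorded in the output metadata —
the dominant failure mode in pressure-profile code is a silent unit
error, so the convention is explicit everywhere.  When velocities are
absent the kinetic term may be substituted by the ideal thermal term
&rho;(z)·k<sub>B</sub>T·**I** at a user-supplied temperature; the
substitution is flagged in the output.  Forces are *consumed*, not
computed: the package evaluates forces only for its built-in synthetic
potentials (harmonic pair, truncated Lennard-Jones), which exist so the
stress machinery can be checked against closed forms (an ideal gas must
reproduce &rho;kT·**I** in every bin; a stretched harmonic pair has a
known virial allocated across bins in exact segment proportions).

The surface tension is reported as &gamma; = −&Sigma;<sub>b</sub>
P<sub>L</sub>(b)·h (midpoint rule).  With binned, piecewise-constant data
the midpoint rule is the natural quadrature: it makes the single-bin case
exact (&gamma; = −c·h for one bin with P<sub>L</sub> = c) and keeps
&gamma; consistent with the partition-of-unity bookkeeping.

Only z-resolved (1-D) profiles are produced; the 3-D field is binned
along z and averaged over xy, because every observable of interest here
is z-resolved.  Protein-embedded profiles need many-body force
decompositions beyond pairwise tables and are out of scope.

## Cross-sectional area

The area at height *z* is the area of the union of disks obtained by
slicing the selected atoms' van der Waals spheres with the plane at *z*.
It is computed by cutting the plane into y-scanlines spaced `raster`
apart: on each scanline the union of x-intervals is computed exactly, so
only the y direction is discretised.  The scheme is deterministic,
monotone under atom addition, converges as the raster shrinks, and is
testable against the closed-form circle (&pi;r²) and two-circle lens
areas; at the default raster of 0.25 &Aring; both closed forms are
reproduced within 1 %.  Defaults: slice thickness 1 &Aring;, raster
0.25 &Aring;, Bondi-style radii (recorded in the output metadata; unknown
elements default to 1.7 &Aring;).  The z-origin is the bilayer midplane
(mean phosphate z) when lipids are present, else the selection's
z-centroid, and is always recorded; "cytoplasmic half" means z < 0 after
recentring.

## Synthetic data: what it emulates and what it does not

The generators define the study conditions; their defaults are fixed,
documented here, and not tuned per analysis.

**Reference pair and transitions.**  `make_reference_pair()` builds a
C2-symmetric, two-chain C&alpha;-only bundle of ideal helices (M1–M4 per
chain, author numbering compatible with TREK-2).  The six residues
defining the gating distances are *pinned*: each mobile key atom is
placed at `partner + d · unit-vector` with a state-independent direction,
so the fenestration/zipper/expansion distances equal the declared
reference values exactly (defaults: down 14/8/7 &Aring;, up 6/14/13
&Aring; — values chosen once as field-plausible several-&Aring;
separations with the directions of change seen on stretch).  In the up
state the cytoplasmic halves of the helices are splayed radially outward;
the default splay (8 &Aring;, tapered over 10 &Aring; below the hinge at
z = 0) is chosen so the pair realises the ~4–5 nm² lower-half
cross-sectional expansion predicted by comparison of the down and up
crystal forms, with the upper (filter) half left unchanged.  C&alpha;
beads carry a 4 &Aring; envelope radius so the sparse C&alpha; trace
approximates a space-filling helix cross-section.

`make_transition_trajectory()` moves each chain's key atoms along their
fixed pair directions with sigmoidal steps centred at the planted event
times (zipper at *unzip*, expansion at *expand*, fenestration at
*close*; per chain the generator enforces unzip &le; expand &le; close),
while the remaining atoms interpolate between the reference frames.
Because the key-atom motion is collinear with the pair vector, each
distance series is an *exact* sigmoid plus exactly N(0, noise_sd) noise —
parameter recovery is therefore well-posed, and the event detector can be
held to "&plusmn;1 frame noiseless, &ge;95/100 correct orderings at 10 %
relative noise".  The default sigmoid width is 2 ps, well below the
event spacing.

**Bilayers.**  Coarse pseudo-lipids (one phosphate-like head bead plus
tail beads, no chemistry) in two leaflets.  Defaults are the unstretched
POPC conditions: thickness 36 &Aring; and area per lipid 64 &Aring;²; the
stretched stand-in uses 31 &Aring;.  Head-bead jitter is i.i.d. Gaussian,
which makes the thickness estimator's standard error exact and lets the
recovery tests use 3-SE bounds.

**Pore traces.**  Ions are placed at the centres of scheduled S0–S4
sites; waters uniformly fill a cavity cylinder except during planted
dewetting intervals.  Every downstream quantity (site probabilities,
density integrals, dewetting intervals) is reproducible from the
recorded ground truth *exactly*, so the occupancy tests assert equality,
not tolerance.

What the generators do **not** emulate: force-field realism, protein
side chains, water structure, lipid chemistry, membrane undulations, or
any actual dynamics (positions are constructed, not integrated).
Passing tests therefore demonstrate the *correctness of the
measurement machinery* under known conditions — not that a particular
real trajectory shows a particular biology.  In particular, the
direction of the stretch-induced S0/S1 occupancy shift is a property of
real trajectories and is deliberately not asserted anywhere.

## Event detection

For each chain and metric the smoothed series (moving average, default
window 5 ns of frames) must cross the midpoint between the down and up
reference values and stay across for a dwell time (default 10 ns).  The
event time is the first frame of the first qualifying crossing; chains
are reported independently, and `order_ok` requires all three events with
unzip &le; expand &le; close.  The defaults suit the 100-ns-scale
simulations the distances come from; the synthetic tests pass
correspondingly smaller windows.  Undetected events are reported as `NA`
rather than errors, because real series may legitimately never cross.

## Other numerical and design choices

* **Distances** default to C&alpha;, with a minimum-heavy-atom mode
  because fenestration closure is sterically a heavy-atom notion;
  C&alpha; is the default since it is computable from C&alpha;-only
  models.  The adjacent-chain mapping for the fenestration is explicit
  configuration (`A -> B`, `B -> A`), never inferred.
* **Superposition** is the Kabsch algorithm via a 3&times;3 SVD with the
  proper-rotation correction (det = +1); selections are matched 1:1 by
  (chain, resid, atom name) and collinear selections are rejected.  RMSD
  is computed on the dimer by default; per-chain series are obtained by
  passing a chain-restricted selection.
* **Classification margin** defaults to 0.5 &Aring;: a frame is labelled
  by the nearer reference only when the RMSD gap exceeds the margin,
  small relative to the several-&Aring; down/up separation.
* **Residue numbering** is always PDB author numbering; analyses that
  need a residue absent from a model raise an error naming it (gap
  policy for composite/incomplete models), rather than silently
  renumbering.
* **Boxes** are orthorhombic only; triclinic input is rejected with a
  clear message, since every analysis here is z-slab-based.
* **Altlocs** keep the highest-occupancy conformer, ties resolved to the
  first encountered.
* **Run configuration** is a single YAML file with every default shipped
  as a versioned file (`inst/extdata/default_config.yaml`), so each
  number in an output is traceable; the report command writes a manifest
  with the package version, config hash and per-file checksums, and
  reruns are bit-identical.
* **TM helix ranges** for RMSD ship as an explicit versioned table
  (`inst/extdata/tm_ranges.yaml`) because no authoritative source lists
  them; the unavoidable choice is made explicit and overridable.

## Problem sizes used by the tests and acceptance script

The suites size their simulations for tight statistical control at
desk scale: ideal-gas stress uses 250 particles in a 2&times;2&times;0.5 nm
box (5 z-bins at the 0.1 nm default grid) over 2000 resampled frames,
which keeps the per-bin 3-SE checks sharp while the number of
simultaneous comparisons stays small; conservation sweeps 100 random
small systems; event recovery uses 100 seeded 200-frame transitions;
bilayer recovery uses 50 frames of 100 lipids per leaflet with 1 &Aring;
jitter.  The quaternion-grid superposition oracle evaluates ~6&times;10⁴
grid rotations per system via the trace identity
&Vert;PR − Q&Vert;² = &Vert;P&Vert;² + &Vert;Q&Vert;² − 2·tr(R&#7488;P&#7488;Q),
so it stays brute-force yet fast.

## Known limitations

* XTC trajectories cannot be read (no XTC reader exists for R); DCD and
  the documented plain-text XYZ-with-box dialect are supported.
* The pressure module requires pair-force tables; it does not recompute
  forces for arbitrary force fields, and many-body decompositions are
  out of scope.
* The synthetic reference pair is a geometric stand-in, not a TREK-2
  model: its absolute cross-sectional areas are smaller than a real
  channel's, and only the *change* between states is calibrated.
* No free-energy landscapes, Markov-state models, permeation counting or
  conductance estimation; the F244 side-chain reorientation has no
  defined metric and is not measured.
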