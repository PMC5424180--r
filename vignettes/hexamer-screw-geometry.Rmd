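---
title: "Screw-axis geometry of hexameric motor ATPase rings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screw-axis geometry of hexameric motor ATPase rings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexscrew)
```

## The model

Hexameric motor ATPases of the PilB/PilT/GspE family (type IV pilus and type
II secretion motors) are not six equivalent rigid chains. The rigid body is
the *packing unit*: the second N-terminal domain (N2D) of one chain packed
against the C-terminal domain (CTD) of the ring-adjacent chain, with a
flexible linker handing each chain's own CTD to the next unit — six beads on
a string. `hexscrew` treats the hexamer as six packing units related by
rigid-body *screws* and derives everything else from that decomposition.

A screw is a rotation by a twist angle about an axis combined with a rise
along it. For a junction between consecutive units the package superposes
unit *k* onto unit *k+1* over C-alpha atoms matched by (domain role, residue
number), takes the optimal rotation/translation (Kabsch, SVD with the proper
rotation constraint) and decomposes it about the oriented ring axis.
Nucleotide-grasping (*closed*) interfaces wrap downwards — negative rise —
while nucleotide-exchanging (*open*) interfaces have a large positive rise.
A closed ring of six units is only possible when the six rises sum to zero;
with four closed interfaces near −12 Å / 65° and two open near +24 Å / 76°
the rises cancel but the twists sum to 412°, and that 52° excess over a full
turn is taken up as out-of-plane pucker of the ring. `build_ledger()` does
exactly this accounting: net rise, net (magnitude) twist, the residual of
the composed six-screw cycle from the identity, the open/closed pattern
string, and the pucker decomposition.

Sign convention, printed in every report: the ring axis is oriented towards
the N2D face, and a positive angle is counterclockwise for an observer on
the N2D side looking down the axis.

## Open/closed classification

An interface is closed when its rise is negative (`rise_threshold_A = 0`).
The rise separates the two populations by tens of Angstroms in these
motors, so it is the robust discriminant; buried surface area is consulted
only when the rise falls within `epsilon_A` (default 1 Å) of the threshold,
with a warning. Nucleotide labels come solely from ligand assignment: a
hetero group (waters excluded) is assigned to the one junction whose two
flanking units both lie within the heavy-atom cutoff (4.0 Å), ties resolved
by the smallest summed minimum distance. Named expected contacts (e.g. the
T327–T411 backbone pairing of closed interfaces) are validation checks that
warn when absent; they never feed into classification.

## Pucker: reference axis and shape classes

Out-of-plane deviations are measured for the six unit centroids along the
*mean interface-screw rotation axis* — the ring's helical symmetry axis —
rather than along the best-fit-plane normal. The reason is geometric: a
one-node (m = 1) deviation pattern around a near-regular hexagon is exactly
a plane tilt, so a fitted plane absorbs it and would report a boat-shaped
ring as planar. The screw axis is indifferent to per-unit axial offsets, so
deviations measured along it retain all modes. (`ring_axis()` itself remains
the total-least-squares plane normal, oriented towards the N2Ds; it defines
the viewing frame, not the pucker reference.)

The six signed deviations are decomposed into discrete Fourier modes and
classified by dominant variance share: one-node (m = 1) is the boat family
(with "twist-boat" when the two-node share exceeds half of it), two-node
(m = 2) is the saddle, alternating (m = 3) and mixtures fall to "other",
and rings with RMS deviation under `planar_tol = 0.25` Å are planar. The
amplitude reported is the RMS deviation; the synthetic generator normalises
its named shape vectors to unit RMS so a constructed amplitude is recovered
identically.

## Rotation inference and the direction of the motor

`infer_rotation()` aligns state B onto state A over all matched C-alphas and
measures the signed in-plane rotation of the sub-pore axis. When the pore
module has located the two sub-pores explicitly, their centers are tracked;
otherwise the orientation of the elongated pore is read from the two-fold
(m = 2) phase of the unit-centroid radii, which is exact for an elongation of
any amplitude and degrades gracefully: below 0.3 Å of modulation there is no
sub-pore axis to speak of, and the (near-zero) mean angular displacement of
unit centroids is reported instead.

Correspondence between states: when the two states carry the same chain
labels the label-preserving correspondence is used — the physical chains are
the same molecules before and after the catalytic step. Only label-free
comparisons fall back to a search over the six cyclic shifts, scored first
by open/closed pattern agreement and then by alignment RMSD; states whose
closed counts differ under every shift are rejected as incomparable.
Thrusting units — the ones the step pushes along the axis — are the units
both of whose flanking interfaces change state with at least one going
closed to open; marker residues (defaults: the conserved pore glutamate at
400 and the catalytic glutamate at 395 of the extension motor) are tracked
as total/axial/tangential C-alpha displacements.

`pilt_mode_inference()` implements the standard single-state device for
retraction motors: compare the hexamer with its own copy advanced by one
packing unit along the *chain-winding sense* (the direction the N2D-to-CTD
handoff travels around the ring) and report the signed ring-axis component
of the alignment rotation. For a perfect C6 ring this is exactly the 60°
slot angle with zero residual. Because an enantiomeric open/closed
arrangement winds the opposite spatial way, the same catalytic step yields
the opposite pore rotation — the geometric fact that distinguishes
extension from retraction motors — and in this package that flip emerges
from the winding attribute rather than from any flag.

## Pore profiling

`pore_profile()` slices the assembly along the oriented axis; at each slice
the in-plane center maximising the clearance to all van der Waals surfaces
is found by Nelder-Mead local search started from the axis and from the
previous slice's optimum. Slices whose surrounding atoms cover less than
75% of twelve angular bins are flagged open (off the end of the molecule)
and excluded from the min/max summary. Both surface-based and
center-to-atom-center radii are emitted, since published pore widths do not
always state their basis. `subpore_detect()` projects an axial slab onto the
ring plane, computes the 2D clearance field on a 0.5 Å grid and extracts up
to two maxima by a watershed in descending clearance: two maxima are
distinct sub-pores when the saddle between them drops below 80% of the
smaller maximum (`saddle_frac = 0.8`). The grid resolution bounds the
accuracy of detected diameters at about one grid step.

## Morphing

`interpolate_states()` is a Cartesian linear morph on matched atoms after a
global C-alpha alignment, so reported motions are internal rather than
whole-body. Endpoints are exact; intermediate frames accept the usual
bond-geometry distortion of Cartesian interpolation, which is the fidelity
of the standard visualisation-grade morphs this mirrors. The default frame
count is 21.

## The synthetic generator

`synth_spec()` encodes the study conditions as defaults: pattern CCOCCO,
closed interfaces at −12 Å / 65°, open at +24 Å / 76° (rises summing to
zero), ring radius 30 Å, a 4 Å two-fold radial elongation orienting the two
sub-pores through the antipodal minority interfaces, ADP pseudo-ligands at
closed interfaces, a one-slot clockwise catalytic step (−60°) and a 13 Å
axial marker thrust on the thrusting units. Pseudo-residues carry standard
backbone atom names, the N2D blob sits on the positive-axis side, and the
template's all-atom centroid is exactly at the origin so unit centroids
coincide with their construction positions.

Two-state pairs are built on the six angular slots with a uniform 60° unit
orientation step, so the two states differ only by per-unit translations
(period-3 radial/axial patterns, an m = 2 elongation phase shift, and the
antipodal marker thrust). These symmetry classes keep the cross-covariance
of the two coordinate sets symmetric, which makes the global C-alpha
alignment *exactly* the identity rotation — the constructed sub-pore
rotation and the marker displacements (corrected for the alignment's mean
shift, which the ground-truth record includes) are therefore recovered to
machine precision, and the recovery tests can assert 1e-3 tolerances
without slack. Ring closure for arbitrary screw parameters is available via
an equal redistribution of the residual over the six interfaces, after
which the corrected parameters are re-recorded as the ground truth.

What the generator does not emulate: real side-chain packing, sequence
realism, crystallographic disorder, or genuinely helical (non-coaxial)
interface axes. Green synthetic tests therefore demonstrate the correctness
of the geometry pipeline, not the crystallographic robustness of any
particular structure; the integration tier that runs the same measurements
on deposited PDB entries exists for that purpose and requires those files
to be present locally.

## Numerical choices

* Altloc policy: highest occupancy wins, ties towards altloc "A".
* Kabsch degeneracy: collinear or coincident inputs are rejected by a rank
  check on the centered coordinates (second singular value below 1e-8 of
  the first).
* Screw decomposition near the identity (< 0.1°) returns the ring axis and
  center with a pure-translation flag; at 180° the axis sign is tie-broken
  towards the ring axis. Twists are reported as magnitudes in (0°, 180°]
  with the handedness stored separately (and a signed twist derived), since
  published values print unsigned twists but signed rises.
* The per-interface rise is reported both along the common ring axis
  (`rise_A`, with the transform expressed about the ring center) and along
  the screw's own axis (`local_rise_A`); for coaxial assemblies the two
  coincide.
* SASA: Shrake-Rupley with a deterministic Fibonacci sphere rotated by a
  seed-derived rotation; 960 points and a 1.4 Å probe by default; element
  radii from a fixed Chothia-style table shared with the pore module.
* Polar contacts: N/O–N/O pairs within 3.5 Å; heavy-atom cutoff 4.0 Å for
  ligand assignment and optional nonpolar contacts. No hydrogens, no
  donor/acceptor angle criteria.

Test problem sizes were chosen at desk scale — twelve-residue pseudo-domains
(about 700 atoms per hexamer), 120–2000 sphere sample points, 0.25–0.5 Å
grids — which keeps the full suite under a minute while leaving every
tolerance at the precision the constructions guarantee.

## Limitations

* The hexamer-from-crystal-packing path applies deposited REMARK 350
  operators only; structures whose biological ring needs other symmetry
  operators must be expanded upstream, and the applied operator count is
  recorded in the report metadata.
* Cross-protein RMSD comparisons require an explicit user-supplied residue
  map; no sequence alignment is performed.
* The open/closed rule presumes the bimodal rise distribution of this motor
  family; rings with genuinely intermediate interfaces will trigger the
  tie-break warning rather than a third class.
* Sub-pore tracking presumes a C2-elongated (two-sub-pore) ring; C6 rings
  have no sub-pore axis and report near-zero rotation by construction.
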