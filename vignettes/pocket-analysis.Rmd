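---
title: "Dual-probe pocket analysis of nanoparticle monolayers: model and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-probe pocket analysis of nanoparticle monolayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A monolayer-protected nanoparticle presents a rough, dynamic surface in
which transient cavities host small-molecule guests. `shellpockets`
defines a pocket volumetrically: space that a water-sized spherical probe
(radius 1.4 Å) can reach but a larger probe (radius 3 Å) cannot. On each
frame the region enclosed by the solvent-excluded surface (SES) is
computed for both probes on a voxel grid; the difference region is
labelled into 26-connected components; components smaller than 100 Å³
(about the molecular volume of the salicylate guest, or three bulk
waters) are discarded. Surviving components are pockets, sorted by
volume (ties broken by lexicographic centre) with ids assigned from 0.

Each pocket carries its centre (the unweighted mean of its voxel
centres — the cavity region itself, not its wall atoms), a depth (the
distance of that centre from the mass-weighted centre of the
`role = "core"` atoms, reported in nm), a wall-atom set, a fragment
fingerprint, and optionally an occupancy flag. The deep/shallow split
uses a strict threshold: deep means depth < 1.3 nm, and a pocket exactly
at the threshold is shallow.

## SES on a voxel grid

The SES region is computed in three steps, all driven by the analytic
clearance field $c(v) = \min_i (|v - x_i| - r_i)$ evaluated exactly per
atom at every voxel centre (and capped above at a configurable value,
default 6 Å, which bounds each atom's sweep without affecting any
decision near surfaces):

1. voxels with $c(v) \le 0$ are the van der Waals voxelisation (a voxel
   belongs to a sphere iff its centre does);
2. voxels with $c(v) > r_\text{probe}$ are free probe centres; only the
   free component connected to the grid boundary is kept. This is the
   *accessibility* step: a probe position sealed inside a closed cavity
   cannot be reached by rolling in from bulk solvent, so it must not
   excavate the cavity. Without it, a hollow shell whose interior
   happens to admit the large probe would spuriously register its whole
   interior as a pocket, and sealed voids would depend discontinuously
   on probe size.
3. a voxel $v$ is outside the SES iff $|u - v| < c(u)$ for some
   accessible free voxel $u$. Because the clearance field is
   1-Lipschitz, a probe centred anywhere in the ball of radius
   $c(u) - r_\text{probe}$ around $u$ is collision-free, so this
   criterion is sound (it never excavates space the rolling probe could
   not reach) and it makes two properties exact by construction: the
   vdW region is always contained in the SES, and the SES of the small
   probe is contained in the SES of the large probe voxel-for-voxel.
   The test is an additively weighted (power) distance transform,
   computed with the separable lower-envelope algorithm in C++; ties
   (probe exactly tangent) count as inside, with a 1e-9 tolerance in
   voxel-squared units absorbing floating-point rounding of exact
   tangencies.

The residual discretisation error is sub-voxel: a band of at most a few
hundredths of an angstrom at the surface may be classified inside. For a
lattice-aligned isolated sphere the SES equals the vdW voxelisation
exactly at all tested spacings; for generic placements the difference is
confined to the one-voxel surface shell. All validation against the
brute-force oracle therefore excludes that shell, and the volume filter
(100 Å³) makes pocket-level null results exact: an isolated atom and a
sealed hollow shell yield zero pockets at every tested spacing.

Defaults: spacing 0.5 Å, grid padding `probe_big + 2` Å (so the grid rim
is bulk solvent), connectivity 26 (avoids fragmenting thin necks at
0.5 Å spacing; 6/18 available). Hydrogens are included in the
rasterisation when present (a heavy-atom-only flag exists); solvent and
free ions never contribute to the surface, and analyte atoms do not
contribute to the receptor surface either — otherwise a bound guest
would fill, and thereby erase, the very pocket it occupies.

## Wall atoms, fingerprints, occupancy

An atom forms a pocket's wall when its sphere surface comes within
`wall_contact_margin + spacing` of a pocket voxel centre; the margin
defaults to the small-probe radius (an atom is a wall atom if the
water-sized probe inside the pocket can essentially touch it). Wall sets
include core atoms, but fingerprints are defined over ligand fragments
only: each coating ligand is partitioned into contiguous Inner, Central
and Outer blocks by the fragment map, and a fragment instance — a
(ligand, class) pair — is counted once if at least one of its atoms is a
wall atom. The fingerprint is therefore insensitive to wall-atom
multiplicity within a fragment. Pockets sharing a triple are degenerate
members of one fingerprint class; `aggregate_fingerprints()` ranks
classes by count with lexicographic tie-breaks.

Occupancy uses a geometric criterion the source data do not fix
numerically, so it is config-exposed: an analyte molecule is inside a
pocket when at least 50% of its heavy atoms lie within the pocket voxel
region dilated by the small-probe radius. The dilation admits guests
seated against the wall, where voxels are excluded by vdW overlap. An
analyte is assigned to at most one pocket (most heavy atoms inside; ties
to the lower pocket id).

## Monolayer statistics

- Pockets per frame: mean and *population* standard deviation across
  frames (the choice of population vs sample sd is documented here
  because the convention is otherwise invisible); frames with zero
  pockets count as zero.
- Volume classes below 150 / 150–300 / above 300 Å³ and deep/shallow
  fractions; both are partitions of the detected pockets.
- The "median maximum distance" between pocket centres is computed as
  the per-frame maximum over centre pairs, median across frames; a
  pooled variant is exposed because the per-frame reading is one of two
  defensible conventions.
- Dihedrals along a declared heavy-atom chain use the standard atan2
  torsion (signs matching `bio3d::torsion.xyz`, which the tests use as
  an oracle); a dihedral is trans iff |φ| ≥ 120°, with exactly ±120°
  counting as trans (a 1e-7 degree tolerance absorbs float fuzz).
- Hydrogen bonds use the common MD convention, donor–acceptor distance
  ≤ 3.5 Å and donor–H···acceptor angle ≥ 135°, both config-exposed
  since the source data state percentages but not criteria. The
  "maximum possible" denominator is the number of donor hydrogens, and
  a hydrogen engaged with several acceptors counts once, so the
  percentage cannot exceed 100.
- `delta_g_from_ratio(k1, k2, T)` returns RT·ln(k1/k2) in kJ/mol with
  R = 8.314462618 J/(mol·K) and a default T of 298.15 K (no temperature
  is stated for the printed estimates; 25 °C is assumed once and not
  revisited).

## Synthetic fixtures and the oracle

No trajectories are distributed with the problem, so the package
generates its own test systems, seeded and deterministic:

- `make_cup_fixture()`: a bead shell (bead radius 1.5 Å, centre spacing
  about 0.9 bead radii — dense enough that the inter-bead grooves admit
  neither probe) of inner radius 4.5 Å minus a 45° polar cap. The mouth
  clearance (~2.7 Å) admits the 1.4 Å probe and blocks the 3 Å probe,
  so the cavity is the single expected pocket; with aperture 0° the
  shell is sealed and must yield none. Parameter combinations whose
  bead spacing exceeds the bead diameter error out as leaky.
- `make_coated_np_fixture()`: a smooth spherical core (single gold
  sphere, radius 8 Å) carrying 80 radial bead chains split 2/1/4 into
  Inner/Central/Outer blocks. The outer block is an "umbrella" — a tip
  bead plus a perpendicular ring — whose overlapping canopies seal the
  outer surface the way crowded glycol termini do; without this, the
  groove network between isolated terminal beads percolates into one
  spurious all-ligand pocket at any chain density we tried. Splayed
  groups are regular rings of chains diverged around a pole (the
  "flower-opening" motif), enclosing a conical void; background chains
  hugging the ring are pushed just outside it (guard angle 8°). The
  construction guarantees: the tight brush has no pockets; each splayed
  group is recovered as exactly one pocket centred on its axis whose
  wall-ligand set contains the group. Wall sets may additionally include
  the ring of background chains immediately behind the palisade gaps —
  an unavoidable consequence of the wall-contact margin, not a detection
  error. Frames beyond the first are jittered copies (σ = 0.15 Å by
  default), emulating thermal breathing, not dynamics.

The brute-force oracle shares no code with the engine: free probe
centres are enumerated on a dense lattice (clearance evaluated
analytically in R), bulk accessibility is established with an igraph
component search, and a point is outside the SES iff an accessible free
centre lies within the probe radius (plus half a lattice step — the
midpoint allowance that keeps the estimate unbiased under refinement;
without it the coverage converges only linearly and the cup volume
drifts ~12% between 0.5 and 0.25 Å lattices, with it ~0.3%).
`oracle_pocket_volume()` integrates the dual-probe difference region on
the lattice and labels 6-connected components. Cross-validation targets:
≥ 99% voxel agreement off the surface shell (measured ~99.999%), cup
pocket volume within 15% (measured ~3.5%).

## What passing tests do and do not show

The fixtures exercise the geometry the method must get right — cavity
detection, probe bridging, sealing, wall assignment, fingerprint
counting — at bead resolution and desk scale (hundreds of beads, single
or few frames; grids of order 10⁶ voxels; oracle lattices at 0.2–0.25 Å).
They do not emulate force-field dynamics, solvent structure, or the
microsecond ensembles behind published per-frame statistics
(pockets-per-frame means, occupancy percentages, fragment-occurrence
ranges of real nanoparticles); those depend on trajectories that are not
redistributable and are out of this package's acceptance surface.
Numbers the package reports on fixtures (e.g. 2 pockets/frame, ~250 Å³
wedge volumes) characterise the constructions, not any real monolayer.

## Known limitations

- Trajectories must be pre-imaged; no periodic-boundary handling.
- XTC trajectories are not readable (PDB/GRO/XYZ topologies; DCD,
  multi-model PDB, multi-frame XYZ trajectories are).
- No bond perception: fragment maps and donor/acceptor selections must
  name atoms explicitly; donor hydrogens are resolved by a 1.25 Å
  distance search within the frame.
- No pocket tracking across frames (each snapshot is analysed
  independently) and no mouth/aperture descriptors.
- The SES is volumetric only; no triangulated surface or surface areas.
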