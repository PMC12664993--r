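---
title: "Conformational gating metrics for pentameric ligand-gated ion channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational gating metrics for pentameric ligand-gated ion channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pentagate)
```

## The analysis problem

Pentameric ligand-gated ion channels (pLGICs) convert ligand binding into
ion flux through a cascade of quaternary rearrangements. Two global
coordinates are conventionally used to track progress along the gating
pathway: the **ECD twist**, a rotation of each subunit's extracellular
β-sandwich relative to the transmembrane helix bundle, and the
**β-expansion**, a separation of the β1 and β10 strands that straddle the
ECD–TMD interface. Prokaryotic channels such as DeCLIC add a large
periplasmic N-terminal domain (NTD) of two jelly-roll lobes (NTD1, NTD2)
whose rigid-body excursions, and whose calcium-binding sites, are of
direct mechanistic interest.

`pentagate` computes these quantities from static models (PDB/mmCIF) and
molecular-dynamics trajectories, together with a sphere-probe pore radius
profile and a geometric characterization of bound-cation coordination and
residence. A synthetic pentamer generator with exactly known ground truth
backs every metric with a construction oracle, so the whole pipeline is
testable without downloading any deposited data.

## Residue scheme

All selections use *author* residue numbering through a `domain_scheme`.
The defaults follow the DeCLIC convention:

| role        | residues | used for                                   |
|-------------|----------|--------------------------------------------|
| `tmd_align` | 328–639  | trajectory superposition (Cα)              |
| `ecd_twist` | 328–513  | ECD block of the twist dihedral            |
| `tmd_twist` | 515–636  | TMD block of the twist dihedral            |
| `beta1`     | 340–345  | β-expansion, principal strand              |
| `beta10`    | 511–515  | β-expansion, complementary strand          |
| `ntd_track` | 35–195   | whole-NTD COM tracking                     |

Residue 514 and 637–639 belong to the alignment range but to neither
twist block; the scheme reproduces this arithmetic verbatim rather than
"repairing" it, so results are comparable with prior work using the same
blocks. NTD1/NTD2 lobe ranges have no universally agreed definition and
are therefore configuration-mandatory; the synthetic generator uses
35–195 (NTD1) and 196–325 (NTD2) as its own convention. Missing residues
inside a range (disordered loops are routinely unbuilt in deposited
models) reduce a reported *coverage fraction* instead of failing; below a
floor of 0.8 the selection is flagged and a warning raised.

## The twist dihedral

For subunit *i*, the twist is the dihedral angle through four Cα centers
of mass:

\[
\theta_i \;=\; \operatorname{dihedral}\big(
\mathrm{COM}^{\mathrm{ECD}}_{i},\;
\mathrm{COM}^{\mathrm{ECD}}_{\mathrm{all}},\;
\mathrm{COM}^{\mathrm{TMD}}_{\mathrm{all}},\;
\mathrm{COM}^{\mathrm{TMD}}_{i}\big)
\]

"All subunits" includes subunit *i* itself — the middle two points are
full-pentamer centroids lying on the symmetry axis. The sign convention
is IUPAC (clockwise rotation viewed along the central axis from the ECD
toward the TMD is positive), fixed once and globally; the closed channel
sits near −26°. Because a dihedral is invariant under rigid motion, no
alignment is needed before computing twist or expansion — a property the
test suite asserts numerically to 10⁻⁹. Centers of mass over Cα atoms use
uniform weights (all Cα share a mass); mass weighting is available for
mixed-atom sets.

Degenerate configurations (the two axis points coinciding, or an outer
point colinear with them) have no defined dihedral and raise an error
rather than returning an arbitrary value.

## Lobe tracking and alignment

Trajectories are first superposed frame-by-frame on the reference's
`tmd_align` Cα atoms with a Kabsch least-squares fit (base `svd`, with
the determinant correction so only proper rotations occur). When the TMD
is internally rigid this removes any global rigid contamination exactly,
which is why lobe displacement is measured in the aligned frame: a lobe
COM displacement is then genuine internal motion, not whole-channel
drift. Displacement is referenced to each replicate's first frame (the
"initial pose"), not to the experimental model, and "COM RMSD" of a
single point reduces to that displacement magnitude.

The pore axis is estimated once per system as the smallest-variance
principal direction of the ring-like `tmd_twist` Cα selection, signed so
that +z points toward the periplasmic NTD; lobe traces report (radial, z)
about this fixed axis so positions from different frames and replicates
share one frame of reference.

## Sphere-probe pore profile

At each axial sample z the pore radius is the largest sphere centered in
the perpendicular plane that touches no atom:

\[
r(z) \;=\; \max_{c \,\in\, \text{plane}(z)} \;\min_i\;
\big(\lVert c - x_i\rVert - r^{\mathrm{vdw}}_i\big)
\]

The maximization is seeded by a coarse in-plane grid around the axis and
refined with Nelder–Mead; a per-slice 2-D search is appropriate because
the channel is axis-aligned after superposition and only per-z radii are
reported. Tests hold the optimizer to within 0.05 Å of an exhaustive
0.05 Å grid search on toy pores, and to closed-form values
(ring radius − vdW radius) on ideal cylinders. Radii use a Bondi-type
vdW table keyed by element (carbon 1.70 Å, oxygen 1.52 Å, …), recorded in
the configuration so profiles are bit-reproducible; hydrogens are
excluded by default since MD frames may or may not carry them. Samples
with no confining atoms are capped (default 10 Å) and flagged rather
than reported as spurious large radii. Prime positions (2′, 9′, 16′ on
the pore-lining M2 helix) are annotated at the axial coordinate of the
five corresponding Cα atoms' COM when the user supplies a `prime_map`;
no default map is invented because the prime-to-residue assignment is a
modeling decision.

## Cation sites

A coordination shell is every O (optionally N) heavy atom within a cutoff
of the ion, classified as side-chain O, backbone carbonyl O (protein atom
literally named "O"), or water O. The default cutoff of 3.5 Å is a
deliberately generous upper bound over typical printed Ca²⁺–O distances
(≤ 3.1 Å); the per-site distance bounds are *assertions about results*,
never detection parameters. Contacts sort deterministically by
(distance, chain, residue, atom name) so equidistant atoms cannot
reorder between runs.

Four shipped site definitions describe the archetypal periplasmic sites
as (residue, partner-class) requirement lists — Site 1: Asp76/Asp123/
Asp124 side chains plus Pro77/Asp123/Tyr129 carbonyls; Site 2:
Asp124/Gly126/Gly128 carbonyls; Site 3: Glu347 side chain plus
Pro434/Phe436/Leu477 carbonyls; Site 4: Glu480 side chain plus
Gln476/Gly478 carbonyls. An ion takes the best-matching label whose
matched fraction clears the definition's threshold (default 0.5, chosen
so the loosely coordinated Sites 2 and 4 still classify); exact ties are
reported with a tie flag, anything else is `unassigned`. Classification
here is purely geometric — it cannot distinguish a weakly bound cation
from a water molecule.

Residence is the fraction of frames an ion stays within a threshold
(default 5 Å) of its first-frame pose, measured in the TMD-aligned frame
so channel drift does not masquerade as unbinding. The summary reports
per-ion bound fraction, bound-at-end, and maximum displacement;
"chains bound at end per site" is the headline statistic.

## The synthetic generator

`build_pentamer()` constructs a C5-symmetric pseudo-atom pentamer — one
Cα per residue in four stacked blocks per chain, plus coordinating O
shells and Ca ions — engineered so that each metric returns its
construction parameter *exactly* at zero noise:

* the per-chain ECD Cα COM is placed at azimuth `twist_deg` relative to
  the TMD COM (filler residues absorb the bookkeeping for the β strands
  that straddle block boundaries), so `ecd_twist()` recovers `twist_deg`
  to 10⁻⁶ over the constructed grid −40°…+10°;
* β1 and β10 cluster centroids sit exactly `beta_sep` apart (grid
  8…20 Å);
* TMD rings of 20 carbon atoms realize the requested probe radii
  (atom-center radius = probe radius + 1.70 Å), with the inner ring at
  1.5 Å by default, mirroring a closed inner gate;
* each ion archetype's shell is placed at exact design distances
  (Site 1 ≤ 2.6 Å; Site 2 2.6–3.1 Å; Site 3 ≤ 2.7 Å; Site 4
  2.5–3.0 Å).

`build_trajectory()` replays scripted rigid events (lobe translations,
whole-ring ECD rotations, β10 shifts, ion escapes) cumulatively from
their onset frame, optionally contaminating every frame with a random
global rigid sway that alignment must remove, plus isotropic Gaussian
noise. The same spec, script and seed reproduce output bit-identically.

What the generator deliberately does **not** emulate: side-chain
packing, force-field physics, correlated (non-rigid) internal modes,
solvent and membrane, experimental coordinate error structure, or
realistic coordination geometry beyond exact distances. Passing the
recovery suite therefore demonstrates that the *measurement pipeline* is
correct and self-consistent — not that any biological conclusion about
real trajectories follows; those require the deposited data.

## Default study conditions

The acceptance script (`scripts/acceptance.R`) rebuilds two synthetic
conditions end to end, four replicates of 20 frames each with 0.1 Å
noise and random sway: a calcium-bound condition whose scripted ground
truth spans a 7° twist range, a 4 Å expansion range, lobe excursions up
to 13 Å (NTD1) and 7 Å (NTD2) with all ions resident, and a calcium-free
condition spanning 12°, 6 Å, 25 Å and 15 Å with one chain's Site-1 and
Site-3 ions escaping (leaving four of five chains bound). These problem
sizes keep the whole run under a minute while giving every reported
quantity a non-trivial pooled sample (400 frame×chain observations per
metric per condition); the recovery grids and the 0.05 Å brute-force
pore oracle run alongside. Pooling is over all chains, frames and
replicates per condition — the single-number-per-condition convention —
with per-replicate summaries emitted in parallel since the alternative
reading (worst-case replicate) is also defensible.

## Numerical and design notes

* Superposition requires ≥ 3 points and equal-cardinality ordered
  correspondence; mirrored optima are excluded by construction.
* The twist dihedral under the IUPAC convention is reversal-symmetric
  (reading the four COMs in reverse gives the same angle); mirroring
  flips the sign. Both are asserted as properties.
* Alternate locations: only blank/"A" altlocs are kept on reading.
* Chain order is taken from file order unless overridden; every
  per-subunit output row carries its chain id, so ordering never changes
  results.
* Ions are identified as hetero records with cation elements and named
  `"chain:residue"`; hydrogens never count toward coordination.
* `summarize_metrics()` drops non-finite values (flagged
  coverage-failure chains) before pooling and errors on an empty pool.

## Limitations

The pore probe reports per-slice in-plane radii; a strongly tilted or
branched channel would need full 3-D tunnel tracing. Axis estimation
assumes an intact five-fold TMD ring. Site classification is geometric
only. NTD2 tracking on real structures requires the user to supply a
lobe range. None of the headline trajectory statistics computed on
synthetic conditions constitute re-measurements of experimental systems.
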