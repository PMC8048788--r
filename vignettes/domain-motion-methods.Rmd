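---
title: "Quantifying clam-shell domain motions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying clam-shell domain motions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clamshell)
```

## The model

`clamshell` treats a conformational change between two structures of the
same (or homologous) protein as a rigid-body motion of one subdomain
relative to another, localised at hinges. The working assumptions are:

* each subdomain is internally (close to) rigid, so its internal RMSD
  between conformations is at the level of coordinate error;
* the motion of the mobile subdomain is well approximated by a single
  rigid transform, which by Chasles' theorem is a rotation about a
  unique axis plus a translation along it (a screw);
* hinges are short stretches whose Cα atoms barely move between
  conformations while the regions they connect move substantially.

The analysis is deliberately anchored: all displacements are measured
after superposing the mobile structure on the reference's *anchor*
subdomain (subdomain 2), because that is the frame in which "how far
did subdomain 1 swing" is a meaningful question. A global all-Cα fit is
reported alongside, since published pairwise comparison tables are
conventionally computed that way; for a genuinely rigid pair the two
agree, and their divergence is itself evidence of domain motion.

### Superposition

`kabsch_fit()` is an unweighted least-squares rigid fit via SVD of the
covariance of the centred coordinate sets, with the determinant-sign
correction that forbids reflections. There is no iterative outlier
rejection or distance weighting: external superposition programs apply
undocumented weighting heuristics, and a plainly specified estimator is
reproducible where an emulated heuristic is not. The test suite checks
the fit against an independent closed-form quaternion (Horn) solver;
the two agree to better than 1e-6 Å RMSD on random noisy instances.

Degenerate inputs are refused rather than guessed at: fewer than three
pairs, or point sets whose second singular value is below 1e-8
(collinear), raise errors, because the rotation is then
under-determined.

### Screw decomposition

For a fitted transform $x \mapsto Rx + t$, the rotation angle comes
from $\cos\theta = (\mathrm{tr}\,R - 1)/2$, the axis direction $u$ from
the eigenvector of $R$ with eigenvalue 1 (sign fixed by the right-hand
rule via the skew-symmetric part of $R$), the axial translation is
$u \cdot t$, and a point on the axis solves the rank-2 system
$(I - R)\,c = t - (u \cdot t)u$ by pseudo-inverse, projected onto the
plane through the origin normal to $u$. Below 0.1° the axis location is
numerically meaningless — the system is nearly rank-0 — so the result
is flagged `axis_defined = FALSE` and only the angle is reported.
Reconstruction (`screw_transform()`) reproduces arbitrary random
transforms on probe points to ≤ 1e-6 Å, which is the invariant the
tests assert.

The *opening* screw is the residual subdomain-1 fit taken in the
direction reference → mobile after anchoring, so that for an
open-versus-closed comparison the reported angle and axis describe how
the mobile lobe opens, with the sign convention matching the generator's
ground truth.

### Hinge detection

Published hinge assignments are typically made by visual inspection of
overlays. The package formalises that judgement so it is reproducible
and tunable. The displacement profile is smoothed with a centred moving
mean of width `window` (default 5 residues — about one helical turn,
enough to suppress single-residue noise without erasing a four-residue
hinge loop). A hinge call is a maximal run of residues with smoothed
displacement below `t_low` (default 1.5 Å, roughly the coordinate-error
floor of medium-resolution crystal structures) that lies in
subdomain 1 or within `window` residues of the subdomain boundary and
has a residue exceeding `t_high` (default 3.0 Å, unambiguously "moving")
within `window` positions of the run. The score is the maximum flanking
displacement over the mean in-run displacement (floored at 0.2 Å so
near-zero hinges do not produce infinite scores).

These defaults imply a detection limit worth stating plainly: a hinge
is only callable when the displacement field climbs from below 1.5 Å to
above 3.0 Å within five residues of the quiet run. A chain leaves a
hinge at a finite pace — for α-helical geometry the perpendicular
distance from the axis grows by at most ~1.5 Å per residue — so the
displacement gradient near a hinge is at most about
$2\sin(\theta/2) \times 1.5$ Å/residue. For opening angles below
roughly 10–12° that gradient cannot bridge the 1.5 Å band within the
window, and the detector (correctly, by its own definition) stays
silent even though the screw decomposition still recovers the angle to
a fraction of a degree. Small openings are therefore quantified by the
screw axis, not by hinge calls; the acceptance script reports the
measured localization rate over a 5–40° grid so this limit is visible
rather than hidden.

### Interactions

The contact detectors are distance-only. At the resolutions of typical
crystal structures there are no reliable hydrogen positions, so a
donor–acceptor angle term would be fitted to noise; the cost is a known
tendency to over-call polar contacts, and hydrogen bonds are not
distinguished from general electrostatic contacts. Cutoffs: 3.4 Å for
N/O/S polar pairs, 3.9 Å for apolar carbon pairs (the conventional
LigPlot-style threshold), 2.8 Å for metal inner-sphere coordination —
all overridable per call. Apolar carbons are taken from a per-residue
table of side-chain carbons not bonded to N or O in standard topology
(so Ser Cβ is polar-adjacent and excluded, Met Cε counts as apolar);
for non-standard residues every carbon except the backbone carbonyl is
accepted, which is the permissive choice. Water bridges are found by
breadth-first search through the water-oxygen contact graph, bounded at
three waters, reporting the shortest bridge (fewest waters, then total
path length) per residue pair. Bidentate carboxylate–metal geometry
falls out naturally as two records within the cutoff; no angle
screening is applied.

## Residue bookkeeping

Author residue numbering is the canonical key throughout, because that
is how residues are referred to in the literature the analyses are read
against; label-sequence numbering is ignored. Correspondence between
two structures is over residues with a Cα present in both — residues
observed in only one structure are excluded from fits, and the pair
counts carried on every result make that bookkeeping auditable.
Number-matching is the default; for homologues with different
numbering, global sequence alignment (BLOSUM62, gap open 10,
extension 0.5 — ordinary protein-alignment defaults, and a recognised
source of small pair-count differences) pairs aligned non-gap
positions. Alternate locations resolve to the highest-occupancy
conformer with ties broken by the first altloc identifier, a
deterministic and idempotent rule; `keep_all` retains conformers for
distance queries. Multi-copy crystal forms default to chain A, the
first copy, overridable per call — in practice inter-copy spread is
small compared to open/closed differences.

## The synthetic generator

`generate_clamshell()` emulates the statistical structure the analyses
rely on and nothing more: two internally rigid pseudo-helical Cα lobes
(rise 1.5 Å, radius 2.3 Å, 100°/residue — α-helix-like so files
visualise sanely), joined by a short loop lying on the opening axis,
with lobe 1 rotated by a known angle about a known axis to produce the
open partner, an optional zinc-like heteroatom near the interface that
rotates with lobe 1, and independent i.i.d. Gaussian coordinate noise
on both models. Default sizes (80 + 80 residues, 4-residue hinge) give
subdomains large enough for stable fits while keeping a full
1000-replicate calibration under a minute. Noise levels of 0–0.5 Å
bracket the coordinate uncertainty of good-to-moderate crystal
structures; opening angles of 5–40° bracket sub-detectable to
ACE2-scale openings.

What it does *not* emulate — side chains, sequence variation,
crystal-packing differences, correlated (non-isotropic) coordinate
error, partial disorder, and internal subdomain flexibility. Passing
the synthetic suite therefore demonstrates that the estimators are
correct for rigid motions under isotropic noise; it does not certify
behaviour on structures whose subdomains deform internally, where the
single-screw summary is an approximation whose residual RMSD
(`residual_rmsd` on the opening screw) should be inspected.

Every displacement in the generator's ground truth follows the closed
form $2r\sin(\theta/2)$ for a point at perpendicular distance $r$ from
the axis, which is also the analytic check used throughout the tests,
including for the metal.

## Determinism and problem sizes

Generation is deterministic given the spec and seed (the generator
saves and restores the caller's RNG state). The test suite and the
acceptance script run entirely on synthetic data: 100 random
superposition instances against the quaternion oracle, 50 screw
round-trips, and a 4 × 3 × 20 angle/noise/replicate recovery grid —
sizes chosen so the whole suite completes in well under a minute while
the Monte-Carlo rates are stable to a few percent. The acceptance
script derives every seed from its `--seed` argument, so its JSON
output is exactly reproducible.

## Known limitations

* Hinge calls have the small-angle detection limit derived above;
  report opening angles from the screw decomposition, not from the
  presence of hinge calls.
* The single-screw model summarises subdomain 1 as one rigid body; for
  proteins whose mobile subdomain itself flexes (e.g. a
  semi-independent lid), per-region fits of the displacement profile
  are the finer-grained view.
* Distance-only contact detection over-calls polar interactions
  relative to geometry-aware definitions, and classifies contacts of
  polar residues' apolar carbons as hydrophobic, which occasionally
  disagrees with hand-curated schematic figures.
* Sequence-alignment correspondence uses fixed standard alignment
  parameters; pair counts for distant homologues shift by a few
  residues under other reasonable choices.
* No crystallographic symmetry expansion is performed: analyses of
  symmetry-related interfaces expect both chains present in the input
  file.
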