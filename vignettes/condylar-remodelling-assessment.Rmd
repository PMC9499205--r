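---
title: "Assessing condylar remodelling on the mandibular ramus: models, parameters and design choices"
author: "ramus3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing condylar remodelling on the mandibular ramus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After orthognathic surgery (a bilateral sagittal split osteotomy with
maxillary repositioning), the mandibular condyle may remodel or resorb over
the following years. Quantifying that change from pre- and postoperative
CBCT requires superimposing the two scans on an anatomical region assumed
stable, then measuring how far the condylar surface has moved and how much
condylar volume has been lost. Two rigid registration families compete for
the superimposition step: surface-based registration (iterative closest
point on the reconstructed bone surface) and voxel-based registration
(maximisation of a grey-value similarity, here normalised mutual
information). Both are driven by a masked reference structure — the coronoid
process plus the ramal band between the mandibular notch and the posterior
border — and both inherit the observer's variability in placing the
landmarks and the mask. `ramus3d` implements the full assessment chain and a
ground-truthed synthetic phantom so that the accuracy and reliability of the
two engines can be compared under controlled, repeatable conditions.

## The synthetic phantom

Real patient scans are not distributable, so the cohort generator builds a
parametric hemimandible ramus as a smooth implicit solid: a super-elliptic
ramal blade (half-extents 14 x 3.5 x 18 mm) with a Gaussian depression in
its upper border forming the mandibular notch, a condylar head ellipsoid on
a cylindrical neck, a tapered coronoid process, and a gonial bulge at the
posterior-inferior angle. The union of these primitives is extracted by
marching tetrahedra on a 0.9 mm grid, which guarantees a watertight,
consistently oriented triangulation. The shape was designed so that every
cephalometric landmark used by the analysis is a *unique extremum* of the
mesh — the C-point is the most caudal point of the notch arc, the gonion the
extreme point of the angle in the posterior-inferior direction — and can
therefore be verified by brute-force vertex scans. A small bounded random
jitter (4 % relative, truncated at 2 sd) varies the shape across a cohort;
every case is a pure function of its parameters and seed.

What the phantom does *not* emulate: full-skull anatomy (the Frankfurt
landmarks Or/Po are placed on auxiliary reference geometry at the level of
the condylar apex), dental occlusion, cortical/trabecular intensity
structure, and CBCT physics (scatter, beam hardening). Intensities follow a
two-level model — background 0, bone 800 on an HU-like scale, optional
Gaussian noise — because CBCT grey values are not calibrated and only the
separability of bone from background at the standard threshold (226)
matters for the pipeline. Passing tests on this phantom therefore
demonstrate the correctness of the geometry, registration and statistics
chain, not robustness to scanner artefacts.

Volumes are voxelized at 0.30 mm isotropic spacing by default, the standard
high-resolution CBCT protocol; the experiment pipeline uses 0.6 mm to keep
cohort runs in the minutes range, a pure resolution choice that the engines
do not otherwise depend on.

## Remodelling and observers

Condylar resorption is modelled as an inward displacement of the affected
vertices along their outward normals, with full magnitude on the affected
core of the target region (the `affectedFraction` of faces closest to the
region centre) and a compactly supported quartic falloff that reaches
exactly zero at `falloff` mm — so remodelling is strictly local, volume
never increases, and the mesh topology is untouched. The cohort default
(magnitude 1 mm, falloff 3 mm, 70 % of the condyle affected) concentrates
the loss on the condylar head, the clinically typical pattern. The field is
deterministic; the generator's `seed` argument is reserved for stochastic
remodelling textures.

Observer variability enters in three places, mirroring how a human works:
the manual landmarks are displaced *tangentially* on the bone surface (a
two-component Gaussian in the local tangent plane whose total RMS equals
the configured scale, then re-projected onto the mesh), the derived
landmarks are recomputed from the perturbed manual ones, and the
reference-structure boundaries are jittered by the same scale. Landmarks on
the postoperative scan receive an independent perturbation of the same
scale before the closed-form landmark pre-alignment, so the registration
engines always start from a realistic, imperfect initialisation.

## Planes and regions

The cutting-plane construction follows the standard cephalometric recipe:
Frankfurt plane by least squares through the four Or/Po points; C-plane
through the C-point parallel to Frankfurt; ramus plane through Con, Cor and
Go; posterior ramus plane through RP and Con perpendicular to the ramus
plane; anterior ramus plane through Cor parallel to it; inferior ramus
plane through RI parallel to the C-plane. Two wrinkles deserve note.
First, the published recipe's intermediate-plane counts (three vertical,
six horizontal) would tile 4 x 7 = 28 cells, while the region count it
reports is 20; the package's default grid therefore uses four vertical
bands and five horizontal bands (treating the horizontal count as inclusive
of its two bounding planes), and a `grid = "literal"` mode provides the
4 x 7 reading with empty cells dropped. Second, the landmark definitions
"most posterior / most inferior point *on the ramus*" are evaluated on the
mesh section restricted below the C-plane, since the condylar head may
protrude further posteriorly than the posterior border itself. The
under-specified "first vertical plane" that defines RI is taken to be the
first intermediate plane parallel to the posterior ramus plane.

Faces above the C-plane must split into a posterior (condyle) and an
anterior (coronoid) component. Because the two processes meet the plane
exactly at the notch saddle, a strict component count is numerically
fragile: the split is computed on a core band slightly above the plane
(where the separation is unambiguous) and grown back to the plane through
face adjacency; grazing face-islands below 1 % of the above-plane area are
returned to the ramal grid. Faces below are binned by the cell containing
their centroid, with the outermost bands open outward so every face gets a
label. Region volumes use exact plane clipping: the solid is clipped
sequentially, each cut capped by centroid-fan triangulation of the chained
boundary loops, which keeps the solid combinatorially closed and makes the
signed-tetrahedron volume exact even for non-convex sections. Cells
therefore tile the ramal part exactly (conservation holds to float
precision), and each cell is bounded only by *interior* planes so that the
sum of the twenty cells equals the whole ramal part below the C-plane.

## Registration engines

**Surface engine.** Masked point-to-surface ICP: a moving vertex belongs to
the reference region if its closest point on the full fixed surface lies on
a reference face within the 2 mm capture range (this stops near-boundary
vertices from biasing the fit); correspondences against the reference
submesh feed a closed-form rigid update (SVD of the cross-covariance with
determinant correction), iterated until the mean residual changes by less
than 1e-6 mm or 200 iterations. Up to 1500 moving vertices are used
(deterministic uniform subsample). No outlier trimming by default; a trim
fraction is exposed.

**Voxel engine.** Normalised mutual information
(H(F) + H(M)) / H(F, M) over a 32 x 32 joint histogram accumulated with
partial-volume (trilinear-weight) binning of the fixed ROI voxels against
the moving volume, maximised over the six rigid degrees of freedom by a
deterministic regular-step gradient ascent (central differences, step
halving from 2 mm to 0.01 mm at the rotation lever arm of 30 mm) inside a
three-level mean-pooled multi-resolution pyramid. Rotations are
parameterised about the ROI centroid. The engine is seed-free and
deterministic.

**Insufficient information.** An ROI below 500 voxels, a constant-intensity
image under the ROI, an ROI falling mostly outside the moving volume, or
initial joint/moving-marginal entropies below 0.5 bits raise a typed
`insufficientInformation` condition rather than a silent misregistration.
The entropy bars differ from a classical "joint entropy >= 1 bit" rule for
a reason specific to the two-level intensity model: a perfectly aligned,
perfectly informative ROI sits at almost exactly 1 bit of joint entropy
(half background, half bone), indistinguishable by that statistic from an
ROI whose bone has resorbed away. What does collapse in the failure case is
the moving-image marginal under the ROI, so both the joint and the moving
entropies are checked against a 0.5-bit bar. With intensity noise the
histograms widen and the bars are generous; the failure demonstration
therefore uses noiseless volumes.

## Statistics

Reliability uses ICC(1,1) — one-way random effects, single measures — with
exact F-based 95 % confidence bounds, computed from explicit between- and
within-subject mean squares; the estimate may be negative, and an
all-identical input returns 1 with a flagged degenerate interval. MAD is
the mean absolute inter-observer difference and SD the sample standard
deviation of those absolute differences, matching the usual "MAD (SD)"
presentation (the SD of signed differences is a config alternative).
Method comparisons use the classical two-sided paired t on ramus-paired,
observer-averaged values; per-region p-values are reported uncorrected at
the 0.05 level, with a Holm option off by default. ICC classification
offers both the conventional scale (0.5 / 0.75 / 0.9) and a published-range
usage in which 0.82 already counts as excellent; both labels are emitted
rather than hiding the discrepancy.

## Problem sizes and numerical choices

The package's standard problem sizes, chosen to keep a full cohort study in
the minutes range on a single core: phantom meshes of roughly 30-35 k
triangles (0.9 mm extraction grid), experiment volumes at 0.6 mm spacing,
cohorts of 20 rami with two simulated observers, 20-case transform-recovery
sweeps, and 2000-replicate calibration loops. Degenerate inputs are handled
explicitly: planes coinciding with a mesh vertex layer (a real occurrence,
since the implicit field is symmetric across the sagittal mid-plane) are
handled by including on-plane vertices in section curves and cancelling
duplicate in-plane cap edges; zero-magnitude resorption and zero observer
scale are exact identities; empty clips return volume zero. Decimation
bounds the *cumulative* surface deviation: every removed vertex is tracked
on its nearest surviving face and re-checked whenever that face changes, so
the decimated surface stays within the 0.0375 mm tolerance of the original
at all tracked points, not merely per collapse.

A deliberate omission: no stage-level cache keyed by content hashes. At
these problem sizes every stage re-runs in seconds, and a cache is a second
source of truth that can silently break the pure-function-of-seed
reproducibility contract that the tests rely on.

## Known limitations

Phantom realism is the main one: two-level intensities flatter the voxel
engine's histogram statistics relative to clinical CBCT, and the stylised
geometry lacks the thin cortical shells where real segmentations struggle.
The segmentation stand-in is plain threshold-connected growth, not a
reproduction of any commercial bone-segmentation wizard, whose exact
algorithm is proprietary; likewise no parity with any commercial
registration tool's numeric output is claimed. Percent-volume changes are
reported signed, with absolute values used in reliability summaries —
whether published volumetric reliability figures summarise signed or
absolute changes is ambiguous, so both are available.
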