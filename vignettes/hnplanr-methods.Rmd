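---
title: "Desk-scale automated head-and-neck IMRT planning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Desk-scale automated head-and-neck IMRT planning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hnplanr)
```

# What this package models

`hnplanr` reconstructs, at desk scale, the moving parts of an automated
head-and-neck IMRT planning platform: template-plan automation (isocenter,
gantry layout, collimator jaws), beam's-eye-view (BEV) anatomical
projections on the fluence-map grid, fluence-map prediction with six
parotid/target tradeoff profiles, forward dose computation with
prescription normalization, dose-volume and conformity/heterogeneity
endpoints, gamma-index QA, and the paired commissioning statistics used to
compare automated plans against reference plans.

Everything runs on synthetic phantoms. No clinical data, no trained model
weights and no commercial treatment-planning system are involved; where the
clinical platform calls a GPU fluence model or a certified dose algorithm,
this package substitutes documented, testable stand-ins behind the same
interfaces. The goal is a faithful, fully checkable implementation of the
*workflow and its mathematics*, not clinical dosimetry.

# The synthetic phantom

`phantom_spec()` + `generate_phantom()` build a bilateral head-and-neck
phantom: a CT-like HU volume and the ten structures routinely modelled for
this site (primary PTV and CTV, brainstem, cord+5 mm, both parotids, oral
cavity, larynx, pharynx, mandible), plus BODY and lung/shoulder landmarks
used by the jaw-fitting heuristic.

Design choices:

* **Solids are ellipsoids, elliptic cylinders and slabs**, not anatomical
  meshes. Every structure therefore has a closed-form volume, and the test
  suite checks voxel-counted volumes against these analytic references
  (within 10%; in practice the default 2.5 mm grid is within ~4%).
* **Coordinates** follow the common DICOM patient convention: x to the
  patient's left, y posterior, z superior, in mm; `origin_mm` is the centre
  of voxel (1,1,1). One convention everywhere avoids silent axis flips
  between modules.
* **Default grid**: 80 x 80 x 96 voxels at 2.5 mm (240 x 240 x 240 mm),
  large enough to hold shoulders and brainstem. The prescription defaults
  to 44 Gy on the primary PTV, with an optional 70 Gy boost volume.
  Craniocaudal coverage is a free choice of the generator; the default
  spans vertex-of-shoulder to mid-skull as the planning CT for this site
  would.
* **PTV-parotid overlap** is a dial (`overlap_fraction` in [0, 0.5]): the
  parotid centre is moved medially by bisection until the requested
  fraction of its volume lies inside the PTV. This is the knob that makes
  parotid-sparing tradeoffs visible downstream.
* **HU values** are assigned per tissue class (air -1000, soft tissue ~40,
  lung ~-700, bone ~700) with seeded Gaussian noise (sd 8 HU). Identical
  spec + seed gives a bit-identical phantom.

What the phantom deliberately does **not** emulate: realistic organ shapes,
heterogeneity textures, dental artefacts, or inter-patient anatomical
variability beyond simple size/offset/asymmetry parameters. Tests passing
on these phantoms validate the geometry, integrals and statistics of the
pipeline - they say nothing about segmentation quality or clinical plan
quality on real anatomy.

# Template automation

* **Isocenter** (`place_isocenter()`): centroid of the highest-prescription
  PTV (the boost when present). If that point is more than 25 mm from the
  primary PTV's centroid, the primary centroid is used instead - beam
  divergence should stay close to the conditions a fluence model was built
  for. Each coordinate is then rounded to the nearest 5 mm *relative to the
  CT origin* (the reference for the rounding is otherwise ambiguous; both
  the reference and the 5 mm step are arguments). Centroid means the
  unweighted mean of mask voxel centres.
* **Gantry layout** (`place_beams()`): nine beams from 180 degrees in
  40-degree steps, advancing counterclockwise. Counterclockwise is
  interpreted as *decreasing* IEC gantry angle (180, 140, ..., 220), which
  reproduces the conventional evenly spaced layout for this site; a
  `direction` flag provides the opposite reading since the convention is
  genuinely ambiguous.
* **Jaws** (`fit_jaws()`): per beam, the bounding box of the PTV's
  divergent BEV projection plus a margin (default 7 mm). If a shoulder
  landmark projects into the field, the inferior jaw edge is raised to the
  landmark's most-superior projected extent plus a clearance (default
  5 mm) - the automated version of a planner balancing beam entrance
  through the shoulders against target coverage - but never so far that
  less than `min_coverage` (default 98%) of the projected PTV points stay
  in the field. The margin, clearance and coverage floor are package
  defaults, exposed as arguments; the balancing rule itself is one concrete
  instantiation of a qualitative clinical heuristic.

# BEV projections

Each beam gets a 12-channel anatomical input on the fluence grid (128 x 128
pixels of 2.5 mm in the isocenter plane, centred on the beam axis):
interface projections for all ten structures and intra-structure
projections for PTV and CTV.

Both are line integrals of CT-derived density along the divergent ray
through each pixel:

* **intra**: integrate only over voxels inside the structure mask;
* **interface**: integrate from the first body-entry point to the last
  structure-exit point (zero if the ray misses the structure).

Choices worth knowing:

* Density comes from a two-segment HU-to-relative-electron-density table
  (0 at -1000 HU to 1 at 0 HU, then 1 + HU/1950, clamped at zero). The
  aggregation operator along the ray is a *sum* (physical line integral);
  this is a modelling choice - the original preprocessing is unpublished -
  and any monotone rescaling is acceptable to the predictor interface.
* Voxel traversal is exact incremental grid stepping (Siddon-style), in
  compiled code, rather than ray sampling: it is testable against analytic
  chords and against brute-force voxel column sums (the suite requires
  agreement to 1e-6 relative on axis-aligned cases).
* Channels are max-normalized to [0, 1] per channel; all-zero channels stay
  zero. SAD defaults to 1000 mm.

# Fluence prediction and the six tradeoff profiles

`predict_fluence()` dispatches to a registered predictor; the package ships
one, `baseline_conformal()`, a deterministic conformal baseline that stands
in for a trained model so that the whole pipeline is exercisable and the
predictor *contract* (nonnegativity, grid conformity, determinism, jaw-clip
compliance, profile responsiveness) is testable against any future plug-in.

The six profiles pair a parotid-sparing preference (both / left-only /
right-only) with a PTV-vs-OAR priority, labelled BP, BO, LP, LO, RP, RO.
In the baseline they act as parameterizations: the aperture is the
thresholded PTV interface channel (threshold 0.05 of the normalized
channel); spared parotids attenuate the aperture over their BEV shadow by a
factor w (0.7 for *P profiles, 0.4 for *O; a single-parotid profile applies
w squared to its parotid and leaves the other unspared); edges are
feathered with a 1-pixel Gaussian; jaw clipping zeroes everything outside
the beam's rectangle. All four numbers are package defaults with no
clinical provenance, exposed via `params`.

The directional consequences - LP lowers left-parotid median dose relative
to BP; *O profiles lower parotid doses while raising target heterogeneity
and hot spots relative to *P - are asserted by the test suite on phantoms
with parotid-PTV overlap, mirroring the designed tradeoff pattern of the
clinical profiles.

# Dose engine and normalization

`compute_dose()` is a deliberately simple forward engine, clearly labelled
as such: each fluence pixel deposits primary dose along its divergent ray
as `fluence * exp(-mu * radiological_depth) * (SAD/r)^2`, with the
radiological depth computed by the same ray tracer used for projections
(one traversal implementation, doubly tested); a 3D Gaussian convolution
then models lateral scatter, and dose is clipped to BODY plus a small
buildup margin. Defaults: mu = 0.005 per mm water-equivalent and scatter
sigma = 4 mm, chosen to give plausible head-and-neck depth falloff;
deposition is gated on density >= 0.1 so dose stays out of air. The engine
is linear in fluence, additive over beams, and bit-reproducible - those are
the properties downstream analysis relies on, and the ones the tests pin
(including a closed-form check of the central-axis depth profile within
2%).

`normalize_to_prescription()` rescales a plan by one scalar so the
prescription covers exactly 95% of the PTV: D95% is read off the sorted
voxel doses by linear interpolation (the continuous inverse of the
cumulative DVH), so the post-condition V(rx)/V(PTV) = 95% holds to within
one voxel's DVH step. `rescale_prescription()` pools plans prescribed at
50 Gy with the 44 Gy cohort by plain multiplication with 44/50.
`total_mu_proxy()` is `calibration * sum over beams of max(fluence)` - a
relative monitor-unit proxy (peak fluence drives beam-on time), documented
as not being a clinical MU calculation.

# Endpoints

`dvh()` computes voxel-counted cumulative DVHs on a uniform axis (default
0.1 Gy bins). The endpoint set mirrors a standard commissioning table:
conformity index CI = V(prescription isodose) / V(PTV), with the isodose
volume counted over BODY by convention (a `within` argument provides the
PTV-only variant); heterogeneity index HI = (D2% - D98%) / rx, reported
x100 to match the conventional magnitude scale (a uniform target scores 0),
with the raw fraction attached as an attribute; D_x% by interpolated
inversion of the sorted voxel doses (type-7 quantiles); D_cc by converting
absolute volume to a percentage of the structure first; Dmedian = D50%.
Asking for more cc than the structure holds is an error, not an
extrapolation.

# Gamma QA

`gamma_index()` implements the standard dose-difference /
distance-to-agreement composite: for every evaluated point above the
low-dose threshold, gamma is the minimum over the reference neighbourhood
of `sqrt((dd/dose_crit)^2 + (dr/dist_crit)^2)`, with sub-pixel bilinear
(2D) or trilinear (3D) interpolation of the reference on a search lattice.
Defaults follow portal-dosimetry convention: global normalization to the
reference maximum, 10% threshold, search radius three times the distance
criterion, search step `dist/10` in 2D (`dist/2` in 3D, where exhaustive
search grows cubically). Gamma = 1 passes, with a 1e-9 tolerance at the
boundary so an exact-boundary case (uniform 3% offset under a 3% criterion)
reads 100% rather than falling to float rounding. `field_pass_report()`
implements the two-tier workflow: fields failing 3%/2 mm at the pass
threshold (default 95%) are re-evaluated at 2%/4 mm, and mean +/- SD of the
passing rate is reported. `portal_plane()` synthesizes a planar "portal"
dose by running one beam through a homogeneous water slab and extracting
the isocenter plane - a stand-in for a portal imager used to exercise the
QA chain.

Numerical note: the search lattice depends on the criteria through the
radius and step defaults. Criterion-monotonicity (tightening either
criterion never lowers any gamma) holds exactly on a *shared, nested*
lattice, and that is how the property is tested; across different default
lattices, sub-step artefacts of either sign can appear.

# Commissioning statistics

`paired_wilcoxon()` is the package's own two-sided paired signed-rank test:
zero differences dropped, midranks for ties, exact p by enumeration of all
2^n sign assignments for n <= 12 and the tie-corrected,
continuity-corrected normal approximation above. The base-R implementation
serves as an independent cross-check in the tests, never as the
implementation. All-zero differences return p = 1 with a warning (the
comparison is degenerate, not significant).

`build_report()` reproduces the commissioning comparison layout: cases are
grouped by the parotid tradeoff of their reference plan
(`assign_group()`: bilateral if the two parotid median doses differ by at
most tau, default 3 Gy, else the lower-dose side; tau is a parameter
because the clinical grouping criterion is qualitative); each group's
reference plans are compared against that group's *P profile (p1), its *O
profile (p2), and *P against *O (p3); every endpoint row is summarized as
median (IQR, type-7 quantiles) and flagged by Bonferroni at alpha = 0.05
with family size m = the number of endpoints in a comparison column
(12 here; m is configurable since the clinical family definition is not
recoverable). `dvh_bands()` aggregates DVHs across cases as pointwise
median and 25-75 percentile envelopes on a common resampled dose axis.

`simulate_commissioning_cohort()` generates the synthetic cohort: clinical
endpoint values drawn around typical bilateral head-and-neck magnitudes
(the endpoint location/spread table is in
`hnplanr:::clinical_endpoint_baseline()`), case laterality imposed on the
parotid medians so all three groups are populated, and per-profile effects
in the designed directions (*P tightens conformity and costs parotid dose;
*O spares OARs and costs homogeneity, hot spots and pharynx/cord dose).
Pairing noise is a fraction of each endpoint's spread (default 0.5) so one
dial behaves sensibly across endpoints whose scales differ by three orders
of magnitude. An `ai_shift` argument plants known constant shifts on chosen
endpoints; the test suite uses it for effect-recovery checks (the report
must flag exactly the planted endpoint and nothing else).

# Problem sizes and determinism

The default phantom (2.5 mm grid) runs the full pipeline - template,
9 x 12 projections, prediction, dose, normalization, endpoints - in a few
seconds per profile on one CPU. The test suite mostly uses an anatomically
complete 5 mm phantom; projection and gamma oracles run on small grids
(<= 32^3 voxels, 5 x 5 dose planes) where brute force is exact and cheap.
The acceptance script spans three profiles at full resolution plus the
statistics suite. Every stochastic step (phantom noise, cohort generation)
is seed-controlled; manifest-driven workflow reruns and written reports are
byte-identical (timestamps are deliberately absent from outputs).

# Known limitations

* The dose engine has no buildup region, no heterogeneity correction beyond
  density scaling, no MLC transmission or leaf sequencing; absolute HI and
  hot-spot magnitudes are engine artefacts and only comparisons *within*
  the engine are meaningful.
* The baseline predictor is conformal geometry, not a learned model; it
  reproduces tradeoff directions, not clinical fluence texture.
* Interface projections assume the body is convex along rays for the
  "equals full chord" limiting case; strongly concave bodies would insert
  air gaps into the integral.
* NRRD support covers the raw-encoded subset the package writes; DICOM-RT
  ingest is not implemented (the NIfTI/NRRD + JSON-manifest path carries
  the same information for synthetic work).
* Single-ray-per-pixel deposition has knife-edge behaviour at voxel-face
  tangencies; grids with commensurate transverse spacings can resolve
  exactly-degenerate corner crossings arbitrarily (the engine is still
  deterministic; the effect only matters when comparing two beams whose
  rays graze the same corners from opposite sides).
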