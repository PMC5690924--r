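---
title: "Evaluating lung SBRT plans: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating lung SBRT plans: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbrteval)
```

This vignette explains the dosimetric model the package implements, the
choices that were genuinely open during its design, and what the synthetic
phantom validation does and does not establish about real treatment plans.

## The evaluation model

A treatment plan is a non-negative scalar dose field on a regular 3D voxel
grid plus a set of boolean structure masks sharing that geometry and a
prescription (total dose Rx, fraction count n). Every quantity the package
reports is a function of these three ingredients; nothing depends on how
the dose was computed. The clinical series this package is built around
used a Monte Carlo dose engine on a 2 mm isotropic grid, which is why 2 mm
is the default grid everywhere, but the evaluation layer is agnostic to the
engine.

All metrics are computed **after DVH normalization**: the dose field is
rescaled by a single factor so that the dose received by 95% of the PTV
equals the prescription (`normalize_to_coverage()`). This mirrors the
common clinical convention "at least 95% of the PTV receives 100% of the
prescription" and matters because the spillage metrics are defined relative
to Rx. The applied scale factor is retained in the result's attributes so a
surprising normalization is visible.

### DVH representation

The cumulative DVH is voxel-exact: the sorted vector of all voxel doses
inside the structure. No histogram binning enters any query, so bin width
is not a hidden parameter.

- `volume_at_dose(curve, L)` counts voxels with dose >= L (inclusive,
  matching the "20 Gy or more" reading of V20).
- `dose_at_volume(curve, v)` returns the largest dose D such that at least
  v receives D, interpolating linearly between adjacent sorted voxel doses;
  as v tends to 0 it tends to the maximum voxel dose. "Dose to < X cc" of a
  structure is read as this query at exactly X cc — the minimum dose
  received by the hottest X cc, the standard protocol interpretation.
- Reported maximum doses are voxel maxima. Whether a planning system
  interpolates a finer grid for its "maximum point dose" is system-specific
  and not modelled; on a 2 mm grid the difference is small against the
  metric bands.

Degenerate inputs are handled explicitly rather than silently: an empty
structure raises a validation error (it almost always means a missing
contour); a cord smaller than 0.35 cc or a lung smaller than 1000 cc falls
back to the maximum / minimum dose with a warning; a rib structure smaller
than a query volume reports that query as missing.

### Geometry

Margin expansion (`expand_mask()`) is exact binary dilation with an
anisotropic ellipsoidal structuring element: voxel j is in the expansion
iff some occupied voxel i satisfies ||(i - j) * spacing|| <= margin. This
is mathematically the Euclidean distance transform thresholded at the
margin, evaluated via FFT convolution; because the convolution values are
integer counts, thresholding at 0.5 is immune to FFT round-off, and the
result is verified in the tests against a brute-force distance predicate.
Distances are voxel-centre to voxel-centre throughout; sub-voxel surface
precision is deliberately not attempted, since the 2 mm grid dominates the
error budget and a single convention keeps all metrics consistent.

The D2cm exclusion region is the complement of the 20 mm expansion of the
PTV — voxels at exactly 20 mm belong to the expansion — with no outer
bound, and no restriction to a body contour (the air outside the patient
carries negligible dose in any realistic plan, and the embedded fixtures
carry no body contour to restrict to). When the grid extends less than
20 mm beyond the PTV the shell is truncated and a warning is recorded.

### Compliance classification

R100% and V20 use fixed bands (1.2–1.5 and 10–15%). The R50% and D2cm
bands vary with PTV volume; the package interpolates the lower and upper
bounds linearly in volume between anchor rows of a JSON criteria table
(clamped outside the anchored range), and the default table ships in
`inst/extdata/`.

Two choices here were genuinely open:

- **Boundary rule.** A value at or below the lower bound is per-protocol;
  above the lower bound up to and including the upper bound is minor;
  beyond the upper bound is major. This strict-lower / inclusive-upper rule
  is the unique one consistent with every deviation flag in the embedded
  reference cohort — for example an R50% of 4.2 against a 4.2–5.2 band is
  unflagged there, while a D2cm exactly at its 61.9 upper bound is flagged
  as minor.
- **Anchor table.** The protocol's own volume table is not part of the
  packaged data; what is available are the twenty printed (PTV volume,
  band) pairs of the reference cohort. Those pairs are used directly as
  interpolation anchors. They are not perfectly monotone in volume (the
  published bounds are rounded to 0.1, which produces a local inversion
  around 26–27 cc), so fitting a monotone curve through them would have to
  miss some printed bounds by more than the rounding unit; interpolating
  the printed pairs exactly reproduces every published band at the printed
  volumes, at the cost of inheriting that small non-monotonicity between
  anchors. One duplicated volume (20.1 cc, printed with two D2cm lower
  bounds differing by 0.1) is stored as the mean of the two bounds. The
  criteria file is user-replaceable for sites that have the protocol's own
  table.

OAR limits are single thresholds ("greater than X Gy"), so exceedance is
reported as a deviation without a minor/major split, and a value exactly at
the limit is compliant. A plan is *fully compliant* when none of the four
spillage metrics deviates and no OAR limit is exceeded.

### Radiobiology and cohort analysis

BED uses the standard linear-quadratic closed form
`n d (1 + d / (alpha/beta))` with equal dose per fraction `d = D/n` and
alpha/beta = 3 Gy for ribs. Cohort rib BED applies each patient's own
fractionation to the rib dose metric itself; with the embedded cohort (3
fractions for patients 1–5, 5 for patients 6–20) this reproduces the
published cohort means of 249 Gy (maximum rib dose) and 173 Gy (rib D1cc)
after integer rounding. The protocol comparator values those means are
displayed against (165 and 112 Gy) are stored as constants
(`rtog_reference_bed()`): applying the same closed form to the protocol's
stated 4-fraction rib limits gives 173.3 and 117.3 Gy instead, so the
comparators' derivation is not reproducible and the package does not
pretend to recompute them.

Summary rows use the sample (n − 1) standard deviation; both conventions
round to the published values for this cohort size, so the choice is by
convention only. The distance–dose association uses the Spearman rank
correlation (the published claim is qualitative and monotone, and rib dose
saturates near the target, so a rank statistic is the honest choice)
together with mean doses in the three qualitative distance bands (< 2 cm,
2–5 cm, > 5 cm).

## The synthetic phantom

`make_phantom()` builds a fully synthetic plan: an ellipsoidal PTV at the
grid centre, an ITV obtained by shrinking it by the 5 mm setup margin, a
large lung ellipsoid, a spinal-cord cylinder, and a rib shell whose inner
radius is the target isocenter-to-rib distance. The dose is

\[
D(\mathbf{x}) = \mathrm{Rx} \cdot f(r_\mathrm{eff}), \qquad
f(r) = \begin{cases} 1 & r \le r_{100} \\
\dfrac{1}{1 + \left((r - r_{100})/g_{50}\right)^2} & r > r_{100}
\end{cases}
\]

where \(r_\mathrm{eff}\) is the ellipsoid-normalised radius,
\(r_{100}\) = `r100_scale` × the PTV radius is the prescription-isodose
radius, and \(g_{50}\) is the distance from the prescription isodose to the
half-prescription isodose. The sigmoid's heavy (Lorentzian) tail was chosen
over a Gaussian one deliberately: photon dose in low-density lung falls off
slowly at 2 cm from the target because of scatter, and a Gaussian tail is
far steeper there than clinical profiles, which both misrepresents the
plans being emulated and makes the D2cm oracle comparison hypersensitive to
the half-voxel discretization of the target surface.

For spherical targets every spillage metric has a closed form — volume
ratios are cube ratios of isodose radii, so R100 = `r100_scale`³ and the
half-prescription radius follows from R50 by a cube root
(`solve_profile_for_targets()`), and the analytic D2cm is the profile
evaluated at the PTV radius plus 20 mm. These are the oracles the test
suite holds the measurement pipeline to: at 1 mm spacing the sphere oracle
agrees within 3% on the volume ratios and 2 percentage points on D2cm; over
a seeded 20-plan cohort at the default 2 mm spacing, recovery errors stay
within 0.05 (R100), 0.2 (R50) and 3 percentage points (D2cm). Because every
PTV voxel receives exactly Rx, coverage normalization of a noiseless
phantom is the identity (scale 1), which the tests also pin down.

Default generator conditions mirror the reference cohort: 2 mm isotropic
grid, PTV volumes spanning 11.1–163 cc, prescriptions of 50 Gy / 5
fractions (54 Gy / 3 available via the config), and conformity targets
drawn from 1.05–1.35. Optional multiplicative Gaussian noise (seeded, off
by default) emulates Monte Carlo statistical noise for robustness checks.

**What the phantom does not emulate.** There are no beams, no multileaf
collimator, no tissue heterogeneity and no dose-calculation physics; the
dose is radially monotone by construction, while real plans have hot spots
inside the target, anisotropic falloff shaped by beam geometry, and rib
doses produced by beam entrance rather than pure radial distance. Passing
the phantom suites therefore demonstrates that the *measurement* pipeline
(DVH queries, mask geometry, classification arithmetic) is correct, not
that any clinical plan meets or fails the protocol. The per-patient values
of the embedded reference cohort are inputs transcribed from the published
tables, not quantities this package can recompute — reproducing them would
require the original clinical dose grids.

## Problem sizes and numerical notes

The default phantom grid is 70³ voxels (140 mm cube at 2 mm); the sphere
oracle in the acceptance tests runs one 96³ plan at 1 mm; the brute-force
geometry oracles run on grids up to ~20³, where exhaustive distance scans
are exact and fast. Band interpolation uses `stats::approx` with rule-2
clamping; DVH interpolation is linear between adjacent sorted voxel doses;
ties at classification boundaries follow the rules stated above. The
portable plan format stores doses as IEEE-754 doubles and masks as bytes in
column-major order, so a write/read round trip is bit-exact and repeated
writes are byte-identical.

## Known limitations

- DICOM-RT files are not parsed; plans enter through the portable format
  (the contour rasterization step a DICOM importer needs is available as
  `rasterize_contours()`).
- Contour rasterization is voxel-centre inclusion with the even-odd rule;
  partial voxels are not fractionally weighted, so very small structures on
  coarse grids are volume-noisy — the standard behaviour of clinical DVH
  engines, but worth remembering below ~1 cc.
- D2cm is evaluated over the whole grid, air included, with no outer bound
  on the exclusion region.
- The criteria table's volume dependence is linear between anchors; a site
  whose protocol table differs should supply its own criteria JSON.
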