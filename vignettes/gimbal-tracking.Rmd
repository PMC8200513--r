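---
title: "Modelling gimbal pan/tilt tumour tracking: beam geometry, phase weights and 4D dose accumulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gimbal pan/tilt tumour tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gimbaltrack)
library(dplyr)
```

## The problem

A gimbal-mounted linac (the Vero type) tracks a moving tumour during
irradiation by panning and tilting its head about a pivot 96 cm upstream of
the isocenter, up to ±2.4° per axis — equivalently, any point within ±4.2 cm
in the plane through isocenter perpendicular to the beam. Treatment planning
systems, however, compute dose on a *single* respiratory phase and know
nothing about this pan/tilt motion. On another breathing phase the
source-to-target distance and the tissue traversed by the beam both change,
so the dose an organ at risk (OAR) actually receives can differ from what
the plan predicts.

`gimbaltrack` models that motion *as geometry the planning system can
ingest*: for each static beam it computes the gantry, ring and collimator
angles, and the per-beam isocenter, that reproduce the panned/tilted beam's
path on another phase (the **rotation method**). Around that core it
provides the simpler whole-plan **translation** baseline, breathing-trace
**phase weighting**, deformation-field **dose accumulation** with
D0.03cc-style OAR constraint checks, and a fully **synthetic** test bed
(cylindrical phantom + toy dose engine) so the pipeline can be exercised end
to end without clinical data.

## The rotation method

The machine's gantry angle $G$ and ring angle $R$ parameterize the pivot
position on a sphere of radius $d = 96$ cm centred at the isocenter:

$$\mathbf{u}(G, R) = (\sin G \cos(-R),\; \sin G \sin(-R),\; \cos G),
\qquad P = \mathrm{iso} + d\,\mathbf{u}(G_1, R_1).$$

When the fiducial centroid moves by $\Delta$ between the reference and
target phases, the tracked beam's axis is the line from the fixed pivot $P$
through the displaced target $T = \mathrm{iso} + \Delta$. Writing
$\boldsymbol\rho = P - T = d\,\mathbf{u} - \Delta$, the transformed angles
are the spherical coordinates of $\boldsymbol\rho$,

$$G_2 = \operatorname{atan2}\!\big(\sqrt{\rho_x^2 + \rho_y^2},\; \rho_z\big),
\qquad R_2 = -\operatorname{atan2}(\rho_y,\; \rho_x) \bmod 360,$$

and the transformed isocenter sits on the new axis at the pivot distance:
$\mathrm{iso}_2 = P - d\,\boldsymbol\rho/\lVert\boldsymbol\rho\rVert$. The
per-beam isocenter shift is what encodes the changed beam path length; it
differs for every beam in a plan. Because the machine's collimator cannot
physically rotate, the plan-level collimator angle is adjusted instead to
keep the beam's-eye view (BEV) of the aperture fixed:

$$C_2 = \begin{cases}
(R_2 - R_1) \bmod 360 & G_2 < 90 \text{ or } G_2 > 270\\
-(R_2 - R_1) \bmod 360 & 90 < G_2 < 270\\
0 & G_1 = 90 \qquad\quad (180 \text{ for } G_1 = 270).
\end{cases}$$

Two conventions deserve explicit mention.

**Hemisphere chart.** The two-argument arctangent always yields
$G_2 \in [0, 180]$; a beam whose original gantry lies in $(180, 360)$
re-expresses in this canonical chart with its ring shifted by about 180°.
This matches the published worked example (original gantry 192 → new gantry
168.5, ring 17 → 194.5). The direction is identical — only the chart
changes. At *exactly* zero displacement `rotate_plan()` short-circuits and
returns each beam unchanged with collimator 0, so the identity is exact
rather than chart-flipped.

**Fiducial-term reading.** The printed algebra for $\boldsymbol\rho$
carries fiducial terms equivalent to $d\,\mathbf{u} + 2\Delta$, which is
inconsistent with the fixed-pivot construction and misses the worked
example's new isocenters by up to 3.5 cm under every axis convention we
tried. The geometrically consistent reading
$\boldsymbol\rho = d\,\mathbf{u} - \Delta$ reproduces all seven beams to
better than 0.1 cm and 0.1°, and is therefore the package's primary
implementation; the other reading remains available as
`rho_vector(..., reading = "printed")` for comparison, and the residuals of
both are visible in `table2_check()`.

**Axis convention.** The worked example states its displacement in clinical
directions ("left / inferior / posterior") without naming the frame axes.
`calibrate_axis_convention()` fits all 48 signed permutations of those
directions onto $(x, y, z)$ against the example's 42 printed outputs; the
winner — left → $-x$, posterior → $+y$, inferior → $+z$ — wins by an order
of magnitude in residual sum of squares, is hard-coded in
`displacement_from_clinical()`, and is pinned by a regression test.

An independent check, `geometric_oracle()`, rebuilds the transform by
explicit 3-D construction (pivot point, displaced target, line between
them) instead of the closed-form algebra, and additionally verifies that
the displaced target lies on the new axis to numerical precision.

```{r}
plan <- table2_plan()
iso <- c(plan$iso_x[1], plan$iso_y[1], plan$iso_z[1])
tracked <- rotate_plan(
  plan,
  fid_ref = fiducial_state(iso, "BH_exhale"),
  fid_phase = fiducial_state(
    iso + displacement_from_clinical(left = 0.46, inferior = 1.09,
                                     posterior = 0.99), "0%"))
report_table2(tracked)
table2_check()$pass
```

`check_gimbal_limits()` converts the displacement into equivalent pan/tilt
angles ($\tan\theta = $ transverse excursion / 96 cm) and warns — it never
errors — when the ±2.4° per-axis or ±4.2 cm in-plane range is exceeded.

## Breathing-trace phase weights

For two-phase dose accumulation each phase is weighted by the fraction of
breathing time the patient spends in it. `detect_cycles()` segments the
trace into cycles between successive inhalation maxima (local maxima with
topographic prominence ≥ 20% of the amplitude interquartile range and
spacing ≥ `min_period`, default 1.5 s — robust defaults for RPM-like traces,
both configurable), discarding partial cycles at the ends. Within each cycle
the halfway amplitude $(\max + \min)/2$ splits time into inhale (above) and
exhale (at or below); crossings are located by linear interpolation between
samples, which removes sampling-rate bias, and samples exactly at halfway
count as exhale so ties are deterministic.

`phase_weights()` averages the per-cycle inhale fractions (the literal
"average over all complete cycles"); the pooled-time ratio
$\sum t_{in} / \sum (t_{in} + t_{ex})$ is available via
`method = "pooled"` — on regular traces the two differ negligibly, and the
per-cycle mean is the default because it matches the stated procedure. The
weights are invariant under affine amplitude rescaling and time shifts, and
reflecting the trace swaps them.

```{r}
glance(phase_weights(make_trace(trace_spec(asymmetry = 2, seed = 1))))
```

## Dose accumulation and OAR constraints

Per-phase dose grids are pulled back to the reference anatomy with supplied
deformation vector fields. The field convention is *reference-to-phase*
(the value at reference point $x$ is the trilinear sample of the phase dose
at $x + u(x)$): one resampling, no field inversion, and the convention is
written into every NRRD header (`dvf_direction:=reference_to_phase`) so it
cannot silently flip. Dose mapping is plain trilinear interpolation of dose
values — no energy/mass (Jacobian) weighting, matching how planning systems
deform dose. Samples outside the phase grid score 0 cGy, but the fraction
of such voxels is recorded on the result and a configurable threshold
(default 1%) raises a warning, because silent zeros could fake OAR sparing.

`accumulate_dose()` forms $\sum_i w_i D_i$ (weights must sum to 1 within
$10^{-9}$); grids must agree in origin/spacing within $10^{-6}$ cm or an
error demands explicit resampling. `dose_at_volume()` implements the
near-maximum DVH metric (default D0.03cc): voxel doses inside the mask —
a voxel belongs to an ROI if its *center* is inside, with no
partial-volume weighting — are sorted descending and the cutoff volume is
located with partial-voxel linear interpolation, so ties contribute
pro-rata and the metric tends to the maximum voxel dose as the volume
shrinks. `run_method()` dispatches the five standard scenarios
(`Original_BH`, `Inhale_trans`, `Inhale_rot`, `Sum_2Phases`,
`Sum_10Phases`); the ten-phase sum always uses equal weights 0.1 because
equal-duration phase binning makes the weighting inherent.

## What the synthetic module emulates — and what it does not

`make_phantom()` builds a water-like cylindrical body (axis along $z$, the
superior–inferior direction) with a cylindrical target, an adjacent OAR
cylinder and three fiducial markers at fixed offsets around the target; the
grid uses even voxel counts so voxel centers sit at half-voxel offsets and
never exactly on a cylinder boundary (keeping voxelized volumes unbiased).
`make_trace()` produces $a(t) = A\cos^{2p}(\pi t / T) + \varepsilon$: $p=1$
is time-symmetric, larger $p$ sharpens the inhale peaks the way real traces
do; the default $p = 2$ gives an exhale fraction near 0.64, inside the
0.56–0.74 band reported for patients. `make_phase_series()` samples that
waveform at ten equal-duration phase centers (0% = full inhale, 50% =
exhale = reference) and attaches rigid constant-vector deformation fields
(a smooth edge-tapered variant exercises the interpolation paths).

The toy dose engine is deliberately *not* a commissioned dose calculation:
per beam, dose $\propto$ weight × inverse-square × $e^{-\mu\,\mathrm{depth}}$
($\mu$ = 0.02/cm by default) inside the divergent cone projected from a
source placed at the pivot distance, zero outside, summed over beams. It
exists so that rotation-vs-translation differences are *demonstrable* —
the two methods centre the target equally well (both BEV-recenter it to
< 0.05 cm) but route the beams through different tissue, which is exactly
the effect that matters clinically. Passing tests on this phantom therefore
show the geometry and accumulation machinery are correct; they say nothing
about heterogeneity, scatter, MLC transmission, breathing irregularity or
baseline drift, none of which are modelled. Patient-specific published dose
values require clinical CT data and are out of scope by design.

```{r, eval = FALSE}
res <- simulate_tracking(demo_config(seed = 1))
res$report
res$rot_trans_oar_diff   # max |rotation - translation| inside the OAR, cGy
```

## Numerical choices and problem sizes

* Units are cm and degrees throughout; radians appear only inside
  trigonometric calls. Angles are normalized to `[0, 360)` and rounded only
  at presentation (0.1° / 0.01 cm in reports).
* A transformed gantry landing exactly on 90° or 270° (outside the
  original-gantry special cases) takes the $-(R_2 - R_1)$ collimator
  branch, by continuity with the adjacent open interval.
* Multiple fiducial markers reduce to their centroid; per-marker pairing is
  available and only changes the error contract.
* The default demonstration grid is 0.4 cm (phantom analyses that check
  voxelized volumes use 0.2 cm); the unit-test pipeline runs a 0.8 cm grid
  with 4 phases. These sizes keep the full synthetic pipeline around ten
  seconds while leaving every check's tolerance unchanged.
* All randomness (trace noise, test sweeps) flows from explicit seeds;
  generators restore the caller's RNG state.

## Known limitations

* The per-beam isocenter anchors on the reference fiducial centroid (the
  printed algebra's convention); plans whose fiducial centroid is far from
  the planning isocenter should be interpreted with care.
* The ring values produced by the hemisphere chart can exceed a physical
  ring's travel range; like the worked example's printed values, they are a
  planning-system modelling convention, not deliverable machine positions.
* DICOM RT import/export is not implemented; the JSON plan schema is
  canonical, and NRRD/NIfTI carry the grids.
* Tracking latency, the 4D correlation model and servo dynamics are not
  modelled: the transform maps static per-phase geometry.
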