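---
title: "Methods: optical and impedance-based thrombus volumetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optical and impedance-based thrombus volumetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thrombovol)
```

# The measurement problem

Platelet aggregates (thrombi) form on a collagen-coated surface when whole
blood is perfused through a microfluidic channel at arteriolar shear
(`shear_rate()`: 6Q/wh², 1500 s⁻¹ at the default 500 × 100 µm cross-section
and 75 µl/min). Two independent routes quantify the aggregate volume at the
end of a 300 s perfusion:

* **Optical thresholding (OT)** — a confocal z-stack of the fluorescently
  labeled aggregates is binarized plane by plane at an intensity threshold;
  the surviving pixel areas, stacked as slabs of thickness Δz, integrate to
  a volume, `V_OT = Δz · Σᵢ Aᵢ(Thr)`.
* **Impedance inversion (IM)** — two coplanar u-shaped microelectrodes under
  the channel measure an impedance magnitude at 150 kHz. Platelet membranes
  insulate at that frequency, so a growing aggregate displaces conductive
  blood and raises |Z|. The aggregate's 3-D shape is modeled as a height
  field proportional to the 2-D fluorescence image, and the single unknown —
  the µm-per-intensity-level scale factor k — is fitted so the simulated
  impedance of that solid matches the measurement. The fitted height field
  then gives `V_IM = f² · Σ min(k·I(x,y), h)` and a watertight surface mesh.

Between t = 0 and t = 300 s, the relative impedance rise ΔZ(%) classifies
the blood's adhesion/aggregation behavior in real time and reveals abrupt
detachment (embolization) events.

# Automatic threshold selection

`threshold_curves()` evaluates `V_OT` and the maximum aggregate height
`H_max` at every threshold from 0 to the stack maximum. Lowering the
threshold reveals taller structure until the height curve saturates at the
stack height; past that point the additional "volume" is background noise,
so the volume curve turns its elbow. The method is usually described graphically, by pointing at the two
curves; this package makes the rule explicit and parameter-free
(`select_optimal_threshold()`):

> the optimal threshold is the **largest** threshold at which the height
> curve attains its maximum over thresholds ≥ 1.

Threshold 0 is excluded because every pixel trivially survives there. The
height at a threshold is defined as `i_max · Δz` with `i_max` the 0-based
index of the topmost plane containing a surviving pixel, because the bottom
(focal) plane sits at height zero; the stack as a whole spans
`(N − 1) · Δz` (`stack_height()`). Note an intentional asymmetry carried
over from the method's definitions: the volume integral sums N slabs of
thickness Δz while the stack height counts N − 1 gaps; both are implemented
exactly as defined, and the one-slab difference is far below the method's
uncertainty.

The selection rule relies on the acquisition including at least one plane
above the aggregate tips. In that top plane only background noise survives,
so the height-curve plateau extends up to (approximately) the maximum
background intensity — which is exactly where background stops contaminating
the volume. The synthetic renderer therefore pads stacks with
`pad_planes = 2` empty planes, mirroring the acquisition convention of
imaging up to the first plane past the tips.

## Uncertainty of the optical volume

`volume_uncertainty()` propagates the threshold-identification error through
the volume curve: `u(V) = |dV/dThr| · u(Thr)`. The curves are stepwise with
a worst-case step of about 3 threshold units, and treating the
identification error as uniform over ±δThr gives `u(Thr) = δThr/√3` with
δThr = 3. The derivative is a central finite difference on the integer
threshold grid (one-sided at the ends). On realistic noisy stacks this lands
at a relative uncertainty on the order of 15%, which is also what the
sensitivity analysis (`sensitivity_analysis()`, ±10 threshold units) shows:
a single threshold unit moves the volume by roughly 10–15%.

# The forward conduction model

`build_field()` + `forward_impedance()` discretize the channel with a
finite-volume (resistor-network) scheme: the potential satisfies
∇·(σ∇φ) = 0 with Dirichlet potentials ±V/2 on the two electrode footprints
(applied through half-cell face conductances on the bottom wall) and
zero-flux conditions elsewhere; face conductances use the harmonic mean of
the adjacent cell conductivities, so the 2 × 1 × 1 two-resistor case is
exact. The system is symmetric positive definite and solved with a
supernodal sparse Cholesky factorization. |Z| = V/I is purely resistive: at
150 kHz the measured magnitude is conduction-dominated and no reactive
components are modeled.

Design choices worth making explicit:

* **Two-phase medium.** Blood at σ_blood (default 0.59 S/m, the value
  recoverable from the baseline impedance via the cell constant,
  `estimate_blood_conductivity()`) and thrombus at σ_blood/8
  (`thrombus_conductivity()`). The one-eighth ratio is an effective-medium
  value: an aggregate is platelets plus conductive interstitial plasma.
* **Partial-volume mixing (default).** A voxel cut by the aggregate surface
  gets the volume-fraction mixture `φσ_t + (1−φ)σ_b`. This makes |Z|(k)
  continuous and strictly increasing in k. A strictly binary field
  (`partial_volume = FALSE`, a voxel is thrombus iff its center lies below
  the local height) is available, but it turns |Z|(k) into a staircase whose
  plateaus are ~10% wide in k at the default grid — too coarse for the
  inversion tolerances below.
* **Grid.** Lateral cells of 10 µm over the 280 × 280 µm electrode window;
  the channel is extended one window-width up- and downstream with
  geometrically growing cells (the current decays quickly away from coplanar
  electrodes); vertically a 14-layer graded mesh, 2 µm near the electrode
  wall coarsening to the roof. This lands at ~16k unknowns, a deliberate
  balance: one solve takes well under a second, which is what makes
  bisection inversions and cohort simulations practical, while vertical
  refinement (the direction that matters for height sensitivity) is
  converged to <0.5% in the cell constant.
* **Electrode arm geometry.** Only the window size (280 µm) and track widths
  (30/20 µm) are fixed by the device; arm positions are free configuration.
  The defaults place both U's and their gaps inside the central 169 × 169 µm
  region a 512 px camera at 0.33 µm/px images, so the electrical measurement
  is most sensitive exactly where heights can be read off the image. With
  the arms pushed to the window rim instead, the forward sensitivity at
  realistic coverage collapses to ~1% ΔZ, physically inconsistent with the
  10–65% rises the device observes.
* **Known limitation: lateral grid convergence.** The current density is
  singular at coplanar electrode edges, so the absolute cell constant
  converges slowly (and non-monotonically) under lateral refinement —
  measured drift ~5% per halving, versus 0.4% for vertical halving. This
  does not propagate into the volume estimates because calibration
  (baseline) and inversion always run on one and the same grid, so the
  geometry factor cancels; it would matter only if the solver's absolute
  impedance were compared against a physical meter.

# Scale-factor inversion

`invert_scale_factor()` exploits the strict monotonicity of |Z|(k) and uses
plain bisection on k ∈ [0, k_max], with `k_max = h / max(image)` (the
brightest pixel reaching the roof). Newton iterations would need solver
derivatives for little gain. Two stopping criteria must both hold: relative
impedance mismatch ≤ 10⁻³ **and** relative bracket width ≤ 10⁻⁴. The second
matters because |Z|(k) can be shallow: an impedance criterion alone would
accept a wide range of k. Noiseless round trips then recover k to better
than 0.1%.

Edge cases are signaled as typed conditions rather than silently clamped: a
measurement below the thrombus-free baseline (beyond a 2% tolerance) has no
physical solution under this model and usually means detachment or an
artifact; a measurement above |Z|(k_max) means an occlusive aggregate beyond
the height-field model's range. Saturated image pixels (level 255) break the
intensity–height linearity and are reported as a saturation fraction.

The fitted `V_IM` carries the method's 10% uncertainty class;
`compare_volumes()` tests each (V_OT, V_IM) pair for metrological
compatibility at `|ΔV| ≤ 2·√((0.15·V_OT)² + (0.10·V_IM)²)` — coverage
factor 2 over the two standard uncertainties, a conventional choice the
compatibility statement itself does not fix.

`reconstruct_3d()` exports the fitted solid as a watertight stepped surface
whose tiles carry block-mean heights; because means are preserved, the
enclosed mesh volume equals `V_IM` to floating point, which the
divergence-theorem integrator `mesh_volume()` verifies.

# Real-time classification and event detection

`delta_z()` references the trace to its initial value; `classify_trace()`
assigns group 1–4 from the final ΔZ at 300 s (<10, [10,20), [20,40),
≥40%). The group definitions also quote 10%-crossing times (within 240, 180,
120 s for groups 2–4); since the final-ΔZ bands partition the axis while
crossing-time windows overlap, the final value is the primary key and the
crossing bound a consistency flag. Traces that violate their group's bound
(e.g. 35% final but crossing only at 250 s) are flagged, not rejected: the
group definitions do not cover that case, so the package declines to guess.
Band edges are half-open: exactly 10.0% is group 2. `predict_group()` runs
the same logic forward in time: a 10% crossing by 120/180/240 s predicts
group 4/3/2; without a crossing the candidate set narrows with time and
groups 1 vs 2 separate only at 300 s.

`detect_detachment()` finds maximal intervals [t₁, t₂] of at most
`max_window` (default 10 s) over which ΔZ falls quasi-monotonically (per-step
rises up to 0.2 points tolerated) by at least `min_drop` (default 5 points),
with the additional requirement that the boundary steps are genuine falls.
Without the boundary condition, a sharp drop flanked by a flat signal would
smear into a family of sliding windows; with it, the event endpoints are the
drop's own. Both thresholds are configuration, not physiology: a canonical
detachment event spanning 286–292 s is recovered with exactly those
endpoints at the defaults, but the thresholds themselves are tunable per
assay.

# What the synthetic fixtures emulate — and what they do not

`make_thrombus_field()` scatters non-overlapping pyramids, frusta and domes
(the shapes aggregates assume under flow) with exact analytic volumes;
placement is largest-first with a bounded size back-off on crowded fields.
`render_zstack()` emulates the confocal acquisition: 512 × 512 8-bit planes
at 0.33 µm/px, Δz = 0.5 µm, object intensity 200 with Gaussian signal noise
(sd 5), background mean 8 / sd 5 — background parameters chosen so the
threshold elbow exists but is non-trivial (the optimal threshold comes out a
small intensity, a few times the background mean). `make_trace()` produces
logistic ΔZ archetypes pinned exactly to each group's mean final rise
(7.55 / 16.55 / 31.15 / 65.46%) and mean crossing time (—, 213.83, 159.32,
72.37 s); the logistic is the simplest saturating three-parameter family
that can hit both anchors, with the steepness fixed at 0.04 s⁻¹ and the
midpoint solved by root finding.

`make_paired_cohort()` ties everything together for the two-route
comparison: per experiment a uniform platelet adhesion carpet of 0.8–1.5 µm
(about one platelet monolayer) underlies 2–6 aggregates of 80–200 px base
and 10–28 µm height, the stack is rendered with intensity noise sd 5, and
the "measured" impedance is the forward solve at k_true = 0.12 µm/level with
2% multiplicative noise. The carpet is not cosmetic: isolated aggregates let
current detour around them laterally, making |Z|(k) strongly concave and the
inversion ill-conditioned (2% measurement noise would blow up to ~30% in k),
whereas a laterally continuous layer couples the impedance tightly to the
height scale. With the carpet the forward rise lands at 10–40% above
baseline — the band characteristic of regular-to-strong aggregation, the
behaviors for which end-point volume comparison is meaningful — and 2% impedance
noise propagates to roughly 5–8% in V_IM, consistent with the method's 10%
uncertainty class.

Not simulated: optical blur and the microscope PSF (the thresholding method
operates on intensities, and unvalidated blur would add free parameters, not
realism), photobleaching, hematocrit-dependent conductivity, electrode
double-layer effects, platelet adhesion kinetics in time, and deforming or
moving aggregates during a solve. Passing tests therefore demonstrate the
correctness and conditioning of the estimators under the stated noise model,
not robustness to optical artifacts absent from it.

# Problem sizes and numerical conventions

The validation suite runs the full-size pipeline where it matters — 512 px
stacks and the default solver grid for the paired cohort (n = 22) and for
the noise-propagation study (20 draws) — and reduced geometries (16–128 px
images, a 7-layer coarse grid) for property checks where size adds nothing.
Oracle comparisons use grids of ≤ 10³ voxels where a dense nodal solve is
exact and cheap. Intensities are integer 8-bit throughout; wider inputs are
rescaled to [0, 255] with a warning. Coordinates are (row, col) 0-based in
documentation of heights (bottom plane = index 0); physically x runs along
columns and y along rows, and images sit centered in the electrode window.
All generators are seed-deterministic, and every source of randomness in the
cohort flows from the single seed handed to `make_paired_cohort()`.
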