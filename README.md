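# thrombovol

Thrombus volumetry for microfluidic flow-chamber experiments, by two
independent routes:

* **Optical thresholding (OT).** A confocal z-stack of fluorescently labeled
  platelet aggregates is binarized plane by plane; the threshold is selected
  automatically at the saturation point of the maximum-height curve — the
  elbow of the volume curve — removing the operator's subjective choice. The
  volume is the slab sum `V_OT = Δz · Σᵢ Aᵢ(Thr)` with
  `Aᵢ = #{pixels ≥ Thr} · f²`, and the threshold-identification uncertainty
  propagates as `u(V_OT) = |∂V/∂Thr| · δThr/√3`.
* **Impedance inversion (IM).** Coplanar u-shaped microelectrodes under the
  channel measure |Z| at 150 kHz; platelet membranes insulate there, so a
  growing aggregate raises the impedance. The aggregate is modeled as a
  height field proportional to the 2-D fluorescence image, `h = k · I(x,y)`,
  and the scale factor k is fitted by bisection until a finite-volume
  conduction model of the channel reproduces the measurement:
  `V_IM = f² · Σ min(k·I, h_channel)`, plus a watertight 3-D surface mesh.

Around the two volume estimates, the package classifies perfusion traces
ΔZ(%) into four adhesion/aggregation behaviors (final rise <10, 10–20,
20–40, ≥40% with 10%-crossing consistency bounds), predicts the group in
real time, detects abrupt detachment events, and ships a synthetic-fixture
generator (z-stacks, projection images, impedance traces) with exact ground
truth, so the whole toolchain is testable without any experimental data.

It is written for researchers running platelet-function / thrombosis assays
in microfluidic chambers who want reproducible volume quantification and an
electrical, label-light readout validated against the optical standard.

## Worked example

```r
library(thrombovol)

# a synthetic experiment: three aggregates on a 1 um adhesion monolayer
field <- make_thrombus_field(n_thrombi = 3, base_range = c(60, 120),
                             height_range = c(10, 25), seed = 7,
                             dim = c(256, 256))
field
#> <thrombus_field> 256 x 256 px, 3 components, analytic volume 21280.0 um^3

hmap  <- field$height + 1
stack <- render_zstack(hmap, seed = 8)          # noisy confocal z-stack
fit   <- ot_volumetry(stack)                    # optical route
fit
#> <ot_volume> V_OT = 29027.0 um^3 (u = 0.0%) at threshold 29; H_zstack = 23.5 um (48 planes)
attr(stack, "truth")$volume_rendered
#> [1] 29024

# impedance route: simulate a measurement and invert it
image      <- render_projection_image(hmap, k_true = 0.12)
grid       <- solver_grid()
z_measured <- forward_impedance(build_field(image, 0.12, grid = grid)) * 1.01
inv        <- invert_scale_factor(image, z_measured, grid = grid)
inv
#> <fuseit_fit> k* = 0.12914 um/level, V_IM = 30385.5 um^3 (u = 10%), residual 7.5e-06 after 16 iterations

# perfusion-trace classification and event detection
classify_trace(delta_z(make_trace(3, seed = 9)))
#> # A tibble: 1 x 5
#>   group final_delta_z crossing_time_10pct consistent truncated
#>   <int>         <dbl>               <dbl> <lgl>      <lgl>
#> 1     3          30.5                160. TRUE       FALSE

detect_detachment(delta_z(make_trace(3, noise_sd = 0, seed = 2,
  events = data.frame(t1 = 286, t2 = 292, drop = 8))))
#> # A tibble: 1 x 3
#>      t1    t2  drop
#>   <dbl> <dbl> <dbl>
#> 1   286   292  7.91
```

Reading the numbers: the automatic threshold (29) sits just above the
background noise, and `V_OT` reproduces the rendered ground-truth voxel
volume to 0.01%. The inversion recovers the height scale from the perturbed
measurement with a residual of 8·10⁻⁶ in impedance; the 1% measurement error
maps into a ~7% volume difference, inside the method's 10% uncertainty
class, and the two routes are metrologically compatible under
`compare_volumes()`. The group-3 trace ends at a 30.5% rise with a 10%
crossing near 160 s, and the injected detachment event is recovered with its
exact endpoints.

`autoplot()` methods draw the threshold-selection curves (`ot_volumetry`),
ΔZ traces with group bands and event markers (`delta_z`), and the
V_OT–V_IM scatter (`compare_volumes`); `tidy()`/`glance()` give tibble
summaries of every fitted object.

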