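---
title: "Measuring longitudinal tissue motion with a tilted image sensor"
author: "stripescope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring longitudinal tissue motion with a tilted image sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stripescope)
```

## The measurement principle

Active motion compensation for intravital microscopy needs a fast, compact
sensor for the longitudinal (Z) motion of living tissue driven by
respiration and heartbeat. The system modelled here is a wide-field
fluorescence relay — lens I facing the specimen, lens II facing the camera —
whose image sensor is tilted 45° to the optical axis. Because the sensor
plane is not parallel to the image plane, only their intersection line is in
focus: the camera sees a narrow sharp *stripe*, and the column of that
stripe encodes the specimen's axial position. Tracking the stripe column
frame by frame therefore measures Z motion with a single ordinary camera.

## The paraxial model

The relay is modelled with ray-transfer (ABCD) matrices: the product of
propagation over the specimen distance $x_1$, thin lens I (focal length
$F_1$), propagation over the lens separation $d$, thin lens II ($F_2$), and
propagation over the image distance $x_2$. The imaging condition is $B = 0$,
which makes $x_2$ a rational-linear (Möbius) function of $x_1$; at that
point $A$ is the transverse magnification. The tilted sensor, referenced to
the back focal point of lens II and tilted by $\theta$, maps the image
distance to the stripe column

$$c \;=\; \left(\frac{x_2 - F_2}{\cos\theta} + \frac{W}{2}\right)\frac{N_c}{W},$$

with $W$ the sensor width and $N_c$ its column count. Only $\theta = 45°$ is
validated against the laboratory prototype; the implementation substitutes
$\cos\theta$ so other tilts can be explored.

At the telecentric (4f) separation $d = F_1 + F_2$ the Möbius map degenerates
to an affine one: the magnification is the constant $-F_2/F_1$ and the
depth-to-column map is exactly linear with slope

$$\frac{dc}{dx_1} = -\left(\frac{F_2}{F_1}\right)^2 \frac{N_c}{W\cos\theta}.$$

```{r model}
cfg <- optical_config()           # prototype: 45/18 mm, d = 63 mm, 1280 cols
sensitivity(cfg, 45)              # about -201 columns per mm
c(specimen_from_column(cfg, 1280), specimen_from_column(cfg, 0))
```

For the prototype this gives a sensitivity of about −201 /mm, a visible
specimen range of 41.8–48.2 mm (6.4 mm span) and a single-column resolution
of 6.4/1280 = 0.005 mm. Away from the telecentric separation the model stays
exact but the response becomes progressively nonlinear
(`optics_sweep()` quantifies this as the maximum deviation from a fitted
line, which grows monotonically with $d - F_1 - F_2$).

Because all maps involved are rational-linear, the inverse
(`specimen_from_column()`) is computed in closed form rather than by root
bracketing; round-trip accuracy is at machine precision and is enforced by a
property test.

## What the synthetic renderer emulates — and what it does not

No public recordings exist for this kind of sensor, so the package renders
its own frames. A rendered frame is the sum of the three components observed
in bench captures:

* a **periodic texture** (cosine grating along columns) standing in for the
  microscopic specimen texture, at full contrast at the stripe column;
* **defocus attenuation** away from the stripe: the grating amplitude is
  multiplied by the modulation-transfer factor
  $\exp(-2\pi^2\sigma^2/p^2)$ of a Gaussian blur whose width $\sigma$ grows
  linearly with column distance (the defocus law of the real optics is not
  documented; linear growth is the simplest monotone choice);
* a **smooth baseline** (low-order 2-D polynomial or broad Gaussian) plus
  additive Gaussian noise (Poisson shot noise is available but off by
  default; the sensor's true noise model is not documented).

Default parameters, chosen once to mirror the bench observations: texture
period 8 px, which places the grating's spectral radius at
$1280/8 = 160$ px — mid-way through the 20–300 px annulus where stripe
energy concentrates in real captures; texture contrast 80 grey levels over a
gentle baseline (offset 100, 10 grey-level ramp), reflecting how strongly
the in-focus fluctuation dominates; read noise of 2 grey levels, typical for
an 8-bit CMOS chip; blur growth 0.05 px of sigma per px of defocus distance,
giving a stripe of roughly ±30 px visible width. The default in-focus
plateau half-width is 0, keeping the defocus envelope strictly peaked so the
per-row amplitude maximum is unique.

The renderer deliberately does **not** emulate: real tissue texture
statistics (the grating is a stand-in with the right spectral placement, not
pig-heart or rat-liver texture), the magnification change with depth
(the estimator never uses magnification), photobleaching, or readout
artefacts. Passing tests therefore demonstrate the correctness of the
*algorithmic chain* under controlled conditions, not performance on real
tissue.

Rendering is deterministic given the scene seed; sequence frames use
`seed + frame_index`.

## Baseline removal: annular Gaussian bandpass

Illumination drift lives near the spectral origin (radius ≲ 20 px of the
centred spectrum), the stripe between radii of roughly 20 and 300 px. The
filter multiplies the centred 2-D spectrum by the annular transmission

$$T(r) = G_\mathrm{hi}(r)\,\bigl(1 - G_\mathrm{lo}(r)\bigr),$$

where $G_\mathrm{lo}$ is a Gaussian of width $r_\mathrm{low}(1+\rho)$
blocking the DC/baseline core and $G_\mathrm{hi}$ is flat out to
$r_\mathrm{high}$ before falling off with width $r_\mathrm{high}\rho$
(roll-off fraction $\rho = 0.1$ by default). The exact edge profile of the
original ImageJ-generated mask is not documented, so the tests pin down
band-interior and band-exterior behaviour (DC ≤ 1%, radius 160 ≥ 99%) rather
than an edge shape. Transmission follows the standard convention (1 = pass);
the mask is point-symmetric so filtered real images stay real. FFTs run on
the native frame shape without padding — masks are smooth, so wraparound
effects are confined to a thin border near the image edges.

## Stripe localization

Per frame: bandpass filter → subtract each row's baseline (arithmetic mean
by default; the filtered rows are near zero-mean, and a median option
exists) → take each row's peak of **absolute** value (the filtered stripe
oscillates symmetrically about zero, so a signed maximum would bias toward
bright half-cycles; ties break to the lowest column) → average the surviving
per-row peak columns. Fractional-pixel precision emerges from averaging
integer per-row peaks; no sub-pixel refinement of individual rows is
applied.

A quality gate discards rows whose peak amplitude is below 10 grey levels
(far below any in-focus texture contrast, far above the filtered noise
floor) and declares a frame invalid when fewer than 50 rows survive —
inert on frames that contain a stripe, but it cleanly rejects blank frames
instead of reporting a random column. Invalid frames propagate as missing
values, never silently interpolated; only the frequency analysis
interpolates, and says so.

## Calibration and trace analysis

Calibration regresses stripe column on stage displacement,
$y = ax + b$, by ordinary least squares — the same direction as the bench
protocol, so $a$ and $b$ are directly comparable to reported values;
displacement is then recovered analytically as $(y-b)/a$. Reported
uncertainties are one standard error (the convention of the quoted ± values
is not documented; the choice is labelled in the output). The *maximum
indication error* is the worst absolute difference between recovered and
true displacement over the calibration table itself.
`simulate_calibration_run()` reproduces the staircase protocol — stripe
starts near the right sensor edge, the stage steps 0.5 mm at a time, 13
steps spanning 6 mm — rendering and estimating each step.

Trace analysis defines **amplitude** as the peak-to-peak span between the
1% and 99% quantiles (robust to single-frame outliers; `robust_quantile = 0`
gives strict max − min), matching the arithmetic that converts a 290 px
span at slope magnitude 211.46 /mm into 1.37 mm. The **dominant frequency**
is the largest non-DC periodogram peak after mean subtraction, reported with
its resolution (frame rate / n); no window is applied by default because
physiological traces are short, with a Hann option for longer records.

## Numerical choices and problem sizes

* Lengths are mm internally; grey values are unbounded floats internally and
  clipped to 8 bits only when writing image files.
* Columns and frame indices are 0-based; column $c$ is continuous with
  pixel $k$ spanning $[k, k+1)$.
* Degenerate optics (Möbius pole, unreachable column) raise errors;
  per-point degeneracy inside `optics_sweep()` yields flagged `NA` rows.
* Analytic and finite-difference sensitivities must agree to 0.1%; the
  acceptance script asserts this before reporting.
* Tests and the example workflows render 64-row × 1280-column frames: the
  full column geometry (which the bandpass radii refer to) at a row count
  that keeps a 300-frame end-to-end pipeline run to seconds. Row count does
  not enter any reported quantity; 64 rows still average enough per-row
  peaks for sub-pixel estimates.

## Known limitations

* Paraxial thin-lens optics only: no aberrations, pupils, or diffraction.
* Only the 45° tilt is validated against hardware.
* The linear calibration is the only supported model, matching the
  validated instrument; strongly non-telecentric configurations would need
  a nonlinear calibration that is deliberately out of scope.
* Synthetic noise and texture are idealized; performance figures obtained
  on rendered frames (indication error, tracking error) characterize the
  algorithm, not the physical prototype.
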