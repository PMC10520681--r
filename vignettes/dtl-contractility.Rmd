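---
title: "Energy-balance force inversion and force-length analysis for magnetically preloaded muscular thin films"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-balance force inversion and force-length analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtlforce)
```

## The measurement problem

A muscular thin film (MTF) is a soft cantilever — here a
magnetoresponsive hydrogel sheet, 20 mm x 10 mm x 200 µm, half of it
clamped — carrying a cardiac cell layer on its top surface. When the
cells contract, the film bends upward; filming the film from the side at
240 fps and tracking its deflection reports the tissue's force. Stacked
permanent magnets under the chamber pull the nanoparticle-laden gel
downward, pre-stretching the cell layer before each electrically paced
twitch. Sweeping the magnet distance sweeps the *preload*, and the
preload dependence of the peak active force — the force–length (FL)
relation, the in-vitro analogue of the Frank–Starling dependence probed
in vivo by pressure–volume loops — quantifies contractility: a positive
inotrope steepens it.

`dtlforce` implements the full analysis chain, plus a synthetic-
experiment generator that stands in for the physical rig so every stage
is testable without recordings.

## The beam model

All quantities are SI. The model assumptions, in brief:

* the bent film is a clamped beam with the parabolic profile
  $w(x) = W x^2/L_0^2$ and *constant curvature* equal to the mean
  curvature, $c = 2W/L_0^2$ (downward positive);
* deformations are small ($|W|/L_0 \le 0.3$ hard limit, warnings above
  0.1), kinetic energy is negligible (quasi-static), the drag
  coefficient is uniform along the beam, gravity and buoyancy cancel in
  the reference position.

The instantaneous power balance equates the rate of change of bending
strain energy, $\bar E I c \dot c L_0$ with
$\bar E = E/(1-\nu^2)$, $I = b h^3/12$, to the power injected by the
magnetic body load $p_m$ (N/m, uniform), the drag
$p_d = -k_d \dot w$ with $k_d = 3\mu\pi(3b+2L_0)/(5L_0)$, and the cell
layer, whose length change is $\Delta L = W h/L_0$ (strain
$\varepsilon = Wh/L_0^2$). Substituting the parabolic profile,
integrating, and dividing by $\dot W$ yields the inversion implemented
in `cell_force()`:

$$
F_{cell} \;=\; -\frac{\bar E b h^2}{3 L_0^2}\,W
\;+\; \frac{L_0^2}{3h}\,p_m \;-\; \frac{k_d L_0^2}{5h}\,\dot W .
$$

The printed rendering of this formula in the source literature is
typographically ambiguous in its drag and magnetic coefficients; the
derivation from the (unambiguous) power balance is treated as
authoritative, and the package's acceptance suite checks `cell_force()`
against an independent numeric quadrature of the three power integrals
to better than $10^{-10}$ relative on 1000 random states.

Dividing the power balance by $\dot W$ also gives the forward dynamics:
a first-order linear ODE in $W$ with relaxation time
$\tau = k_d L_0^4/(20\,\bar E I)$ (44 ms for the default beam in water).
`simulate_deflection()` integrates it with an exact exponential step and
stores the instantaneous ODE rate as `Wdot`, so simulation followed by
inversion round-trips to machine precision.

```{r}
beam <- beam_spec(L0 = 10e-3, b = 10e-3, h = 200e-6, E = 12e3)
beam
cell_force(W = -1e-3, Wdot = 0, p_m = 0, beam)   # 1 mm upward bend
```

## Magnet calibration and the two inversion conventions

Cell-free recordings give the static deflection $W_m(d)$ versus magnet
distance $d$; `build_calibration()` converts them to force densities and
fits a monotone log–log interpolant. Two static inversions are exposed:

* `energy_consistent` (default): $p_m = \bar E b h^3 W_m / L_0^4$, the
  value at which `cell_force()` returns exactly zero on the same static
  cell-free state. The pipeline is then internally consistent:
  cell-free data invert to zero force.
* `uniform_load`: $p_m = 2 W_m E b h^3 / (3(1-\nu^2) L_0^4)$, the
  classical uniformly loaded cantilever formula
  $W = qL_0^4/(8\bar E I)$.

The two differ by the constant factor 2/3 — the constant-curvature
shape is stiffer than the true quartic deflection shape of a uniformly
loaded cantilever — and feeding the `uniform_load` value into
`cell_force()` leaves a residual $-\bar E b h^2 W_m/(9L_0^2)$ instead of
zero. Which convention the original platform software used is not
documented; both are shipped, and `energy_consistent` is the default
because a cell-free control must invert to zero force.

The semi-analytic magnet model (`axial_field()`, closed-form axial field
of a cuboid stack; `force_density_model()`, superparamagnetic body force
$\propto B\,\mathrm{d}B/\mathrm{d}d$) replaces finite-element
simulation. Its far field follows the $d^{-3}$ dipole law — in the
distance to the *stack centre*; face-referenced distances only approach
it asymptotically — and the force density falls as $d^{-7}$, making the
magnets negligible a couple of centimetres away. The link between
distance and force density is calibrated, never assumed, in the real
workflow; the parametric model exists to generate realistic synthetic
calibrations and is flagged as a modelling choice.

## The synthetic experiment

`run_protocol()` emulates the stated experimental conditions: 0.5 Hz
pacing with a 5 ms monophasic stimulus, a 500 ms preload hold released
at the moment of stimulation, 240 fps sampling, and preload levels given
as force densities (or magnet distances through a calibration). The
twitch is a double-exponential transient (rise 40 ms, decay 150 ms — a
typical paced cardiac twitch at room temperature; the source work does
not specify a waveform and only the peak's preload dependence matters
downstream) whose peak obeys

$$ F_{peak} = F_0\,(1 + s_{FL}\,\varepsilon_{pre}/\varepsilon_{ref}), $$

with $\varepsilon_{ref} = 10^{-3}$ a documented normalization that keeps
the FL gain $s_{FL}$ unitless. Defaults: $F_0 = 10\,\mu N$ (sub-millimetre
twitch deflections on a 12 kPa gel, in the range reported for engineered
cardiac films), $s_{FL} = 1$ for untreated tissue and 3 for an
inotrope-like condition, preload strains 0–$10^{-3}$ (tip preloads up to
1 mm, a tenth of the free length). Measurement noise is additive
Gaussian on the tip deflection, default 3 µm — about 40 dB below the
RMS deflection of a default protocol — plus 2 % per-pixel intensity
noise in rendered video.

What the generator does *not* emulate: spontaneous (unpaced) beats,
calcium dynamics, non-uniform magnet loading, out-of-plane motion,
photobleaching or illumination drift, and hydrogel degradation. A green
recovery test therefore establishes that the *analysis chain* is
unbiased and consistent under the stated world, not that the physical
rig meets any accuracy figure.

`render_video()` draws the film as an anti-aliased grayscale silhouette
(1-px linear edge ramp; the undeflected midline sits on a half-integer
row so the resting film covers whole pixel rows). Frames are plain
matrices, streamable through a provider closure, and serializable as
PGM sequences — chosen because it is a standard Netpbm format
read/written in base R without an image library.

## Tracking

Per frame: Otsu binarization (fixed threshold available), retention of
the largest connected component touching the clamp region, one midline
point per column, and a least-squares quadratic in physical units whose
$2a_2$ is the curvature and whose value at the furthest detected column
is the tip. Numerical choices worth recording:

* the **midline**, not a single edge, is tracked (halves rasterization
  bias, symmetric under intensity noise); it is computed as the
  intensity-weighted centroid of the column's band plus a 2-px apron,
  which is analytically exact for the symmetric trapezoidal silhouette
  profile — on noiseless rendered video the tracker recovers curvature
  to machine precision and the tip to < 0.1 px;
* the **tip** is read at the furthest detected column rather than
  extrapolated to the nominal free length (robust to partial occlusion;
  the fitted-vs-measured tip difference is kept as a quality flag);
* columns with interrupted foreground runs are skipped; frames are
  declared lost rather than guessed when fewer than 10 usable columns
  remain, and a recording fails if more than 5 % of frames are lost;
* the reference (zero-deflection) tip row is the median over a rest
  window, not a single frame, so reference noise does not bias every
  subsequent sample.

The small-angle check $\alpha = \mathrm{atan}(W/L)$ is reported per
frame with an $\alpha$-vs-$W$ linearity diagnostic ($R^2 > 0.999$ for
$|W|/L_0 \le 0.1$).

## Velocity estimation and the release transient

$\dot W$ comes from Savitzky–Golay differentiation (7 frames by
default). Two details matter and are easy to get wrong:

* the magnet release is a known discontinuity in the forcing; the
  derivative is therefore estimated *per segment* between actuation
  steps (`breaks`), never across them;
* the local fit is **cubic**, not quadratic: a quadratic SG derivative
  carries an $O(f''')$ bias that, on the exponential release transient,
  is proportional to the preload and masquerades as a false positive FL
  slope of order 1 %-point per unit relative preload. The cubic fit
  removes this bias class at a modest variance cost.

## Contractility readouts

`active_force()` references each twitch to its stimulus onset (median of
the *unsmoothed* inverted force over a 120 ms pre-stimulus window lying
inside the hold — a smoothed value would straddle the release step),
blanks 50 ms after the stimulus where the differentiated velocity is
unreliable, and samples the peak from an 80 ms-smoothed trace at the
per-recording median argmax lag. This fixed-lag, two-pass estimator
avoids the "maximum of noise" upward bias of a plain windowed maximum,
which would otherwise grow with the local noise level and leak into the
FL slope.

Stress is reported normalized: the absolute stress scale needs a
cell-layer thickness the assay does not measure, and it cancels in the
ratio to the peak baseline (no-preload) force, whose own maximum is
exactly 1 by construction. `build_loops()` averages the
$(\varepsilon, \hat\sigma)$ trajectory over one pacing cycle starting at
the hold onset — preload stretch, release, twitch, return — and reports
the shoelace area as a work surrogate; the loops are elliptical, unlike
the quadrilateral in-vivo pressure–volume loops shaped by valve events.

`fl_relation()` plots the percentage increase in average peak active
force against the *relative preload* — preload strain normalized to the
largest tested level, a definition this package fixes because the source
phrase is not defined there; the raw strain is also emitted. A weighted
least-squares line (delta-method variances; the pinned zero-baseline
point receives the smallest non-degenerate companion weight) gives the
contractility index, with a bootstrap over twitches (default 1000
resamples, seeded) for its confidence interval. `compare_conditions()`
bootstraps the slope difference of two conditions and issues a
`steeper` / `shallower` / `not distinguishable` verdict; resampling is
over twitches within each preload level, and percentages average over
twitches within a run (whether the original figures averaged over runs
or cantilevers is not stated).

```{r, warning = FALSE}
protocol <- twitch_protocol(
  preload_pm = preload_pm_for_strain(seq(0, 1e-3, length.out = 5), beam),
  n_twitches = 4L)
res <- run_dtl_experiment(protocol, twitch_model(s_FL = 1), beam,
                          seed = 1, n_boot = 200)
res$fl
```

## Degenerate inputs and guard rails

Poisson ratios $\ge 1$, non-positive geometry, thickness above half the
free length, deflections beyond $0.3 L_0$, non-uniform time bases, too
coarse ODE steps ($dt > \tau/10$), empty masks, sub-10-column midlines,
collinear fit designs, repeated calibration distances, non-monotone
cell-free sweeps, missing baselines and fewer than three preload levels
all raise typed errors; marginal regimes ($h/L_0 > 0.1$,
$|W|/L_0 > 0.1$, out-of-range calibration distances) warn and proceed.

## Known limitations

Geometrically nonlinear (large-deflection) bending, 3D plate effects,
non-uniform magnetic loading along the beam, afterload manipulation and
in-vivo pressure–volume processing are out of scope. The measured
relaxation of the physical platform (up to 410 ms with magnets close)
exceeds the water-viscosity prediction of this model; whether an
effective viscosity was used upstream is unknown, so `mu` is exposed as
an effective-viscosity knob with water as the default. The FL slope is
reported per *relative* preload; comparisons between experiments are
meaningful only on a common preload grid, which
`compare_conditions()` enforces by intersecting grids when they differ.
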