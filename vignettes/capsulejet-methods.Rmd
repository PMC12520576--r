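---
title: "Controlled breakup of a compound alginate jet: models, generator and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Controlled breakup of a compound alginate jet: models, generator and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capsulejet)
```

## The system

A three-way co-extrusion injector produces a compound liquid jet — a cell
suspension core, a sorbitol barrier layer and a 2% alginate sheath — from a
nozzle of radius $R = 95\,\mu m$ at a total flow rate $Q = 165$ mL/h. The jet
fragments into droplets by the Plateau–Rayleigh instability; the droplets
gel into core–shell hydrogel capsules in a calcium bath. Two actuators
control the breakup: a piezo element that shakes the injector at frequency
$f$ (mode selection), and a DC potential $U$ on a ring electrode (charge
effects). `capsulejet` implements the physics of this system, a synthetic
generator of ground-truthed high-speed movies of the breakup, the
video-analysis chain used to measure it, and the population statistics of
the resulting droplet and capsule radii.

## Jet physics

**Kinematics.** The jet velocity is $v_{jet} = Q/(\pi R^2) \approx 1.6$ m/s.
Jetting requires a Weber number $We = \rho v_{jet}^2 (2R)/\gamma \gtrsim 1$;
the Ohnesorge number $Oh = \mu/\sqrt{\rho\gamma R}$ measures viscous damping
of the instability (0.012 for pure sorbitol, 13.8 for pure alginate at zero
shear).

**Dispersion relation.** We use the long-wave viscous relation for the
growth rate $\omega$ of an axisymmetric perturbation of wavenumber $k$ on a
cylinder of radius $R$:

$$\omega^2 + 3\nu k^2 \omega
  = \frac{\gamma}{2\rho R^3}(kR)^2\left(1-(kR)^2\right),$$

with $\nu = \mu/\rho$, solved in closed form as the positive quadratic root
(`weber_growth_rate()`), and defined as 0 for $kR \ge 1$ rather than
extended to complex roots. Its maximiser has the analytic form
$kR^* = 1/\sqrt{2 + 3\sqrt2\,Oh}$, which `fastest_growing_mode()` also
verifies numerically (to $10^{-6}$ relative) — this dual route is a
permanent self-check. We chose this relation over the full Bessel-function
dispersion because it reproduces the measured sorbitol optimum
($kR^*\approx0.70$, droplet radius $\approx180\,\mu m$) while remaining
analytically testable. For pure alginate at its zero-shear viscosity the
relation predicts a fastest-mode droplet radius near $315\,\mu m$; reported
figures for this system quote $272\,\mu m$, a discrepancy we attribute to an
unstated rheological choice upstream and deliberately do not tune away: the
sorbitol limit is the tested anchor, and the alginate limit is used only
qualitatively (as the lower edge of the forcing band).

**Forced breakup.** Forcing at frequency $f$ imprints the wavenumber
$k = 2\pi f / v_{jet}$. One droplet per period and volume conservation give
the *targeted radius*

$$R_{th} = \left(\frac{3 R_{jet}^2 v_{jet}}{4 f}\right)^{1/3},$$

(`targeted_radius()`, with the exact inverse `frequency_for_radius()`).
Converting the usable band of dimensionless wavenumbers
($kR \in [0.185, 0.7]$, the two pure-fluid optima) to frequencies yields the
500–1900 Hz actuation band.

**Bead kinematics.** After breakup the droplets remain connected by thin
filaments (beads-on-a-string). The filament tension decelerates beads from
$v_{jet}$ toward $v_d = v_{jet} - 2\gamma/(\rho R_{jet} v_{jet})
\approx 0.84$ m/s (`schneider_bead_velocity()`); the retarding force itself
is $F = 2\pi R r_f \gamma$ (`capillary_force()`).

**Electric effects.** The electric Bond number $\Gamma = \varepsilon_0 U^2 /
(R_{jet}\gamma)$ compares electric and capillary stress. Whipping of a
cylinder of radius $r$ sets in at $U_c(r) = \sqrt{\Gamma_c r \gamma /
\varepsilon_0}$, i.e. thresholds scale as $\sqrt r$. The absolute scale
involves an electrode-geometry factor that the dimensionless argument does
not capture, so $\Gamma_c$ is a calibration constant; its default is set
once so that the jet threshold is 7000 V at $R = 95\,\mu m$,
$\gamma = 59.8$ mN/m. The connecting filament, thinner than the jet by a
configurable factor (default 10), then whips near
$7000/\sqrt{10} \approx 2214$ V; the observed threshold of 2500 V
corresponds to a ratio of about 7.8, within the "approximately ten times
thinner" description. Filament whipping breaks the string early, removing
both the capillary deceleration and the coalescence it causes — the central
mechanism the package's generator reproduces.

**Phase classification.** `classify_phase_point()` partitions the
$(kR, \Gamma)$ plane into monomodal Plateau–Rayleigh (I), bimodal (II, where
the second harmonic $2k$ is still inside the excitable band), filament
whipping and jet whipping. The band cutoffs default to the growth-rate
iso-level of 850 m$^{-1}$ expressed as $kR$ limits at $\Gamma = 0$ and shift
linearly toward higher wavenumbers with charge (`kr_shift`, default
0.15/unit $\Gamma$ — charge destabilises shorter wavelengths). All
boundaries are half-open with ties going to the lower region, so every grid
point receives exactly one label. Note that on the $\Gamma$ scale computed
from $\varepsilon_0 U^2/(R\gamma)$ the calibrated thresholds sit near 7.6
and 76, not at order unity; the order-unity statement absorbs the same
geometry factor as $\Gamma_c$.

**Encapsulation statistics.** With cells only in the core flow, the count
per capsule is Poisson with mean $\lambda = c \cdot \frac43\pi r^3 \cdot
Q_{CS}/Q$ (`expected_cells_per_capsule()`): 500,000 cells/mL in 200 µm
capsules at a 45/165 flow fraction gives $\lambda \approx 4.57$, i.e. 3–6
cells per capsule. `coalescence_radius()` and `core_shell_geometry()` are
the volume-conservation relations for merged drops ($n^{1/3}R_0$) and the
core/shell split (core radius $= R\,(Q_{inner}/Q)^{1/3}$).

## The synthetic generator

No raw experimental videos accompany the study, so every analysis stage is
exercised against a seeded generator (`scene_config()`,
`simulate_scene()`) whose defaults are the experimental acquisition
conditions: 12,000 frames/s, 8.5 µm/pixel, 2000 frames, 294×1000 px frames
with the nozzle 6 mm upstream of the field of view, piezo amplitude 4 µm.

**Effective fluid.** The compound jet is neither pure sorbitol nor pure
alginate, and a two-fluid dispersion relation is out of scope. The
generator's default fluid keeps the alginate interfacial tension
(59.8 mN/m) with an effective viscosity of 30 mPa·s, chosen once so that
the fragmentation length of the forced jet lands a few millimetres from the
nozzle — equivalently, spatial growth rates of order $10^3$ m$^{-1}$,
the magnitude the phase-diagram cutoff (850 m$^{-1}$) implies for the real
system. It was not revisited after testing.

**Breakup model.** Wavelengths are $v_{jet}/f$ with 3% multiplicative
jitter under forcing; in free breakup they are drawn from the unstable band
with probability proportional to $\omega(k)\,e^{\,g(\omega/\omega^*-1)}$
— growth rate times the exponential amplification accumulated over the
transit to the breakup point (mode competition), with $g$ the same
log-amplification gain as below. The amplification factor is needed for a
well-defined modal wavelength at $2\pi/k^*$: with the linear weight alone
the wavelength density is so flat near its peak that its sample mode is not
statistically stable.

Each wavelength $\lambda$ forms a bead of radius $(3R_{jet}^2\lambda/4)^{1/3}$
(so the noiseless forced train reproduces $R_{th}$ exactly, and total bead
volume per unit time equals $Q$ identically). The breakup point is placed by
the spatial growth model $L_{frag} = g\,v_{jet}/\omega(k)$ with gain $g = 7
\approx \ln(\text{jet radius}/\text{seed perturbation})$; only relative
comparisons of $L_{frag}$ across $(f, U)$ are claimed. Beads detach at the
jittered jet velocity (5% SD per bead, standing in for pump fluctuations,
whose magnitude is not reported), decelerate exponentially toward their
capillary-retarded velocity with a 1.5 ms time constant (the reported data
constrain only the endpoints; the exponential is the simplest profile
matching both), and their trailing filament pinches after three time
constants, freezing the velocity — this instant is the bead's breakup time
$T_b$. Contacting beads merge with exact volume conservation and an event
log. Satellites are Bernoulli draws (default probability 0.1, radius
fraction 0.3) whose volume is carved out of their primary; nonlinear
satellite dynamics are out of scope. Above the filament whipping threshold
the filament breaks immediately: no deceleration, no merging, and a small
transverse deflection (100 µm scale) replaces them.

**Rendering.** Transmission imaging: background grey 220, jet and beads 30,
drawn before a 1 px Gaussian blur and additive Gaussian noise (SD 5 grey
levels). The unbroken jet carries a sinusoidal envelope growing as
$e^{g(x/L_{frag}-1)}$ (capped at 70% of the radius so the thinnest neck
stays resolvable at this pixel pitch). Filaments are rendered at grey 150:
at one-pixel width they absorb far less light than the jet, so they are
visible in kymographs but sit above the binarization threshold — matching
the experimental situation in which the jet-end detector sees through them.
Frames are stored 8-bit; identical configuration and seed give byte-identical
stacks (one master seed, deterministic sub-streams per stage).

**What the generator does not emulate.** No free-surface hydrodynamics
(bead oscillations after pinch-off, filament thinning dynamics), no optical
point-spread function beyond Gaussian blur, no core–shell contrast inside
drops, no out-of-focus drops. Passing tests therefore demonstrate that the
analysis chain recovers known kinematics and size distributions under
realistic sampling, noise and overlap conditions — not that it is robust to
every optical artefact of a real bench.

## Video analysis

All pixel-to-physical conversions are exact multiplications by the pixel
pitch. Binarization defaults to a per-frame Otsu threshold (the reported
description says only "binarization"); a fixed threshold is available for
reproducibility. Otsu always returns a split, so frames whose threshold is
not at least 5 robust SDs below the background median are treated as empty.

**Axis correction** (`align_jet_axis()`): principal axis of the
time-averaged binarized mask via second moments; frames are rotated back by
bilinear interpolation, and rotations below 0.1° are skipped (interpolation
blur would exceed the correction).

**Fragmentation length** (`fragmentation_length()`): per frame, the
foreground count along the transverse axis gives an axial profile whose
first zero is the jet end — computed on the binarized mask rather than raw
intensity so that illumination gradients cannot shift the zero. Local
maxima of the jet-end series (prominence ≥ 3 px, minimum separation 2
frames, ties to the earlier frame) are breakup events; their mean plus the
nozzle offset is $L_{frag}$. Because the tip advances by one frame of
advection (~16 px) between samples, the sampled peak underestimates the
true maximum by half that advance on average; the estimator adds half the
median ramp slope back. A 2000-frame acquisition at kilohertz forcing
yields well over the 100 events the protocol requires.

**Droplet sizing** (`detect_droplets()`): a 1500 µm ROI positioned 1.5 mm
downstream of $L_{frag}$ (shape oscillations damped out) is processed with
a Canny detector (Sobel gradients, non-maximum suppression, hysteresis with
quantile thresholds — the reported pipeline names the filter but not its
parameters, so all are exposed) and a circular Hough transform over a
physics-informed radius window, $R_{th} \pm 50\%$ by default. Voting is
gradient-directed (each edge pixel votes along its gradient line); each
accumulator peak is refined by alternating centroid/mean-radius estimation
on its supporting edge pixels, and the final radius is read off the radial
intensity profile of the raw ROI (parabolic fit to the steepest ascent),
which is free of edge-digitisation bias (measured bias ~0.01 px on
synthetic disks); candidates whose
refined radius drifts out of the window or whose perimeter support falls
below 50% are rejected, and detections within half a radius are
deduplicated keeping the higher support. An in-focus score (mean gradient
on the circle relative to the frame's 95th-percentile gradient) implements
the "only in-focus droplets" criterion, which the reported description
leaves unspecified.

**Kymographs and tracking** (`build_kymograph()`, `detect_beads()`,
`track_beads()`): the kymograph is the per-frame transverse-minimum
projection; beads appear as dark traces of slope $v_d$. Tracking links
per-frame bead centroids by nearest neighbour with a gate of 1.5 expected
per-frame advections, computes central-difference velocities over the
actual sample times, spacing to the downstream neighbour, and aligns each
track on its end time so kinematic curves are functions of $t - T_b \le 0$.
A track that disappears while its predicted position coincides with a
detection claimed by another track is terminated as a coalescence; on
seeded scenes these terminations match the generator's event log within
±1. Beads cut by the frame border are excluded before linking (their
centroids are biased). If per-frame advection exceeds the median bead
spacing, linking is refused as undersampled.

**Capsule segmentation** (`segment_capsules()`): the reported pipeline
used a learned segmenter; this package replaces it with a classical one
(dark-rim threshold, hole filling, connected components, optional
distance-map watershed for touching rims, border exclusion) that preserves
the measured quantity — the equivalent-circle radius $\sqrt{A/\pi}$.
On synthetic micrographs (2.32 µm/pixel) recovered radii are within 2 px.

## Population statistics

`fit_mixture()` fits 1–3 component Gaussian mixtures to raw radii by
maximum likelihood (EM via mclust, deterministic model-based
initialisation), selecting the count by BIC under `"auto"` — the reported
analysis adjusted bimodal/trimodal histograms per condition by eye;
likelihood on raw radii is the binning-free standard. `selectivity()` is
the exact counting statistic $S = \#\{|r - R_{th}| \le 0.1 R_{th}\}/N$ with
an inclusive band (the reported definition does not state inclusivity;
inclusive chosen) and $R_{th}$ always from the volume-conservation formula,
never from the fitted mode. `label_modes()` assigns satellite/primary/
doublet/triplet by nearest volume-conserving anchor with midpoint
boundaries and a satellite cutoff at $0.7R_0$ (no reported threshold;
satellites in this system are several-fold smaller, so the cutoff is not
delicate). `shrinkage_ratio()` measures the ~15% gelation contraction with
a seeded bootstrap interval. `assemble_sweep()` collates per-$(f,U)$ runs
into the tidy table behind dispersion/selectivity maps, and `sweep_runs()`
drives whole simulate–analyse grids with per-point seeds, continuing past
per-point failures.

## Numerical choices and problem sizes

Growth rates are clamped to 0 for $kR \ge 1$. The closed-form/numerical
agreement for $kR^*$ is asserted at $10^{-6}$ relative; the Poisson pmf is
tabulated to `n_max` with an explicit tail remainder summing to 1 within
$10^{-9}$; truth CSVs round-trip numerics at $10^{-9}$ relative. Image
processing uses a separable shift-and-add Gaussian blur and a histogram
Otsu so that multi-thousand-frame stacks stay CPU-cheap; EBImage provides
rotation, hole filling, labelling and watershed. The test suite exercises
one full 2000-frame acquisition end-to-end and otherwise uses 40–300 frame
scenes; statistical recovery tests use the study's own sample size
(N = 1625) where the reported value is tied to it, and 12–60 seeded
replicates elsewhere. These sizes are the package's choices for a
fast-but-sensitive default suite; all generators scale to arbitrary length.

## Known limitations

Single-phase effective fluid (no two-fluid dispersion relation, no
shear-thinning rheology); whipping is represented by its threshold and a
schematic deflection, not an electrohydrodynamic trajectory; the spatial
growth model is the linear $\sigma = g/L_{frag}$ approximation with a fixed
default gain, so absolute growth rates carry that constant; the capsule
segmenter is classical and will undersplit heavily overlapping capsules
that a learned model might separate.
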