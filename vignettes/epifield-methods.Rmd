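---
title: "Simulating seizure spread on cortical surfaces and its SEEG signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating seizure spread on cortical surfaces and its SEEG signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Stereo-EEG (SEEG) depth electrodes record seizures through a handful of
contacts, each integrating the local field potentials of nearby cortex.  A
common electrographic onset pattern — sustained theta–alpha oscillations
whose amplitude grows gradually over several seconds (the TAA pattern) —
is often read as evidence of a gradual, Hopf-like transition of the
underlying tissue.  This package implements an alternative account: each
cortical point switches *abruptly* into the seizing state, a slow
recruitment front (millimetres per second) sweeps across the folded
cortical sheet, and the gradual sensor-level ramp arises purely from the
spatial averaging performed by the SEEG lead field.  The package provides
the complete chain needed to study this mechanism quantitatively on
synthetic geometry: surface meshes, the Epileptor neural-field model,
a dipole forward model, onset and velocity quantification, and an
identifiability experiment over candidate geometries.

## The model

The dynamics on the surface $\Omega$ are the Epileptor field equations:
five state variables per point, comprising a fast discharge-generating
subsystem $(u_1, u_2)$, an intermediate oscillatory subsystem
$(q_1, q_2)$, and a slow permittivity variable $v$ that guides the tissue
into and out of the seizure.  All equations share the global time constant
$\tau_s = 5.88$ (model time in milliseconds), the slow variable evolves on
$\tau_s \tau_0$ with $\tau_0 = 2\times 10^4$, and the intermediate
recovery on $\tau_s \tau_2$ with $\tau_2 = 100$.  Space enters through
three convolution terms: thresholded activity $S(u, \theta) = H(u -
\theta)$ (with $S(\theta,\theta)=1$) is smoothed by the Laplacian kernel

$$ w(x, y) = \frac{1}{2\pi b^2} \, e^{-d_g(x, y)/b}, \qquad b = 1\ \mathrm{mm}, $$

where $d_g$ is the geodesic distance along the surface.  The
$\gamma_{11}$-weighted term recruits the fast subsystem of neighbouring
tissue (setting the slow front speed), the $\gamma_{22}$ term couples the
intermediate oscillators (producing fast travelling waves through
recruited tissue), and the $\gamma_{12}$ term feeds a low-pass memory
variable $g$ that modulates the intermediate subsystem.  The memory
integral is implemented as an auxiliary state:
$\dot g = a_{12} u_1 + \gamma_{12}(w * S(u_1, \theta_{12})) - g/(\tau_s\tau_{12})$.

Excitability is a spatial field $u_0(x)$: an epileptogenic disc
(diameter 5 mm) is set supercritical ($u_0 = -1.8$) so that it seizes
autonomously, and the surround is set to $u_0 = -2.3$, where it is stable
but recruitable.  Every simulation starts from the healthy equilibrium of
the *unconnected* node at the surround excitability (epileptogenic
vertices included, which then drift into seizure on their own), uses
deterministic Heun integration with $\Delta t = 0.2$ ms, and receives no
input from outside the patch; kernel rows are not renormalised near the
patch boundary, which is the discrete analogue of surrounding the patch
with unexcitable tissue.

### The memory time constant

One parameter, $\tau_{12}$, is not fixed by the published parameter set,
and the package's choice deserves a full account because the model's
behaviour depends on it strongly through the equilibrium of the
intermediate subsystem, $q_1^\ast$ (the memory term contributes $0.002\,
g^\ast = 0.002\, \tau_s \tau_{12} a_{12} u_1^\ast$ to the $q_1$
nullcline).

* With large $\tau_{12}$ (e.g. 100), $q_1^\ast \approx -1.9$.  The frozen
  fast subsystem is then monostable at the surround excitability,
  contradicting the intended bistable-surround operating point, and no
  monostable/bistable boundary exists in $[-3.5, -2.5]$ at all.
* With small $\tau_{12}$ (e.g. 4.5), the boundary lands at $-3.02$, but
  $q_1^\ast \approx -0.71$ sits only $0.21$ below the intermediate
  coupling threshold $\theta_{22} = -0.5$.  A $q_1$-activation wave then
  detaches from the recruitment front and ignites the whole sheet within
  seconds, abolishing the staggered sensor onsets that are the point of
  the model.
* The default, $\tau_{12} = 17$, makes the memory term contribute
  $0.6\,u_1^\ast$ with a $\tau_s\tau_{12} \approx 100$ ms decay — the
  scaling of the original Epileptor's memory integral — and gives
  $q_1^\ast \approx -1.13$: deep enough that quiescent tissue ignores
  distant oscillations, shallow enough that the surround's frozen fast
  subsystem is bistable, as intended.  On the sine surrogate the
  detected bipolar onsets then follow the contact order with Spearman
  correlation $0.98$.

Two single-node landmarks characterise the resulting model.  Bisection
of the regime classifier recovers the critical excitability
$u_0^{crit} = -2.06$.  The monostable/bistable boundary of the frozen
fast subsystem computes to $-2.97$ rather than the $-3.025$ one might
expect: at $u_0 = -3.025$ the frozen values are exactly $u_1^\ast = -2$,
$v^\ast = 4.1$ *independently of* $\tau_{12}$, and a dense sweep of
initial conditions finds no coexisting limit cycle of the $(u_1, u_2)$
subsystem at $v = 4.1$ for any frozen $q_1$ — under these equations the
cycle fold lies near $v \approx 4.05$.  The boundary therefore cannot be
moved to $-3.025$ by any admissible $\tau_{12}$, and the package reports
the honestly computed value.

### Onset frequency

The TAA rhythm in the sensor signals reflects the discharge rate at
seizure onset.  In this implementation the instantaneous rate of the
first discharges of an uncoupled supercritical node depends on the memory
configuration: with the deep-memory variant ($\tau_{12} = 100$) the first
inter-discharge intervals correspond to 7.6–9 Hz, matching the theta–alpha
band, but that variant is excluded by the bistable-surround requirement
above.  With the default $\tau_{12} = 17$ the first discharges run faster
(≈ 30 Hz) and the power-spectral peak of $s = q_1 - u_1$ over the two
seconds after onset is dominated by the slow intermediate relaxation
(1–3 Hz).  The onset-frequency diagnostic
(`onset_oscillation_frequency()`) reports both the spectral peak and the
initial discharge rates so this trade-off is visible rather than hidden;
it is the one published landmark the chosen working point does not
reproduce.

## From sources to sensors

Each vertex acts as a current dipole oriented along the outward surface
normal, with moment proportional to its quadrature area $A_v$ (one third
of its incident triangle area) and the source activity $s = q_1 - u_1$.
The unit-free lead field

$$ G_{sv} = A_v\, \frac{n_v \cdot (x_s - x_v)}{|x_s - x_v|^3} $$

is precomputed per contact; bipolar channels are differences of
neighbouring contacts.  Conductivity prefactors are omitted, so all
amplitude comparisons are relative — matching the practice of comparing
normalised envelopes.  The spatial selectivity of a channel is summarised
by the cortical area accounting for 50 % of its accumulated absolute
gain: on a 100 × 100 mm sheet with a standard 9-contact electrode
(3.5 mm pitch, 1.47 mm standoff) monopolar contacts draw 50 % of their
gain from tens of cm², bipolar pairs from well under 1 cm².

## Quantification

Onsets are detected per bipolar channel as the first time the amplitude
envelope exceeds 20 % of its maximum over the analysis window.  The
envelope is the rectified signal after a 3rd-order 0.2 Hz Butterworth
high-pass, smoothed by a 3rd-order 0.6 Hz low-pass; both stages run
forward and backward (zero phase), with odd-extension padding at the ends
(roughly two cutoff periods) because at such low cutoffs unpadded
filtering leaks multi-second startup transients from the signals' large
DC offsets.  Onsets are shifted so the earliest is zero; undetected
channels are flagged, never zero-filled.

Two velocities are estimated.  The *spread* velocity uses recruitment
times ($u_1 \ge -0.8$) at two midline probes on a 40 × 20 mm sweep sheet
with a 10 mm epileptogenic strip; sweeping $\gamma_{11}$ gives a strictly
increasing velocity map that `calibrate_gamma11()` inverts by monotone
interpolation.  Because the discrete kernel quadrature depends on the
mesh, published coupling gains do not transfer across discretizations —
$\gamma_{11}$ is always recalibrated against a target velocity rather
than copied.  The *fast-wave* velocity aligns the $q_1$ series of 30
uniformly spaced vertices on the shortest inner-to-outer-contact path by
trial time shifts $d_g / u$ over a 50–1000 mm/s grid (200 points, linear
interpolation, windows cropped to common support) and takes the speed
maximising the mean pairwise correlation.  A maximum at a grid edge is
flagged as saturated — shortly after full recruitment the waves in this
implementation synchronise quickly, so late analysis windows tend to
saturate high while pairwise lags just after recruitment correspond to
80–250 mm/s.

## Synthetic data and what it can show

All inputs are generated in code.  The flat surrogate is an
exactly-(l + 2m) × 2m = 58 × 30 mm triangulated sheet (cell diagonals
alternate in a checkerboard so both diagonal directions exist in the edge
graph) with the electrode 1.47 mm above it; the sine surrogate folds the
same footprint with $z = A\sin(2\pi x/l)$, $A = 7.89$ mm, the electrode
threading the folds at $z = 0$; the gyral surrogate is a seeded
band-limited random height field (default 4 mm amplitude, 25 mm
wavelength) standing in for a patient-specific patch.  Default mesh
resolution is 0.4 mm; the simulation studies shipped in `analysis/` and
the tests run at 0.8–1.2 mm with durations of 10–40 s, sizes chosen so
each study completes in minutes while keeping several vertices per kernel
decay length.  A synthetic "observed" recording is produced by running
the full chain on a named surrogate and adding seeded Gaussian noise of a
stated fraction of the peak bipolar amplitude.

The identifiability experiment scores candidate geometries against such
a reference: per candidate, the propagation velocity implied by the
reference onsets *on that candidate's geometry* calibrates its
$\gamma_{11}$, the candidate is simulated and projected, and onset-time
RMSE/MAE plus envelope-mean correlation are tabulated.  Mesh resolution
matters: at 1.0–1.2 mm edges the generating sine surface wins clearly
(onset-RMSE margin ~10 % and envelope correlation ≈ 0.98 versus ≈ 0 for
the wrong geometries), while at 1.3 mm the folds are no longer resolved
against the 1 mm kernel and the ranking collapses — 1.2 mm is the
coarsest resolution at which the experiment is meaningful.  The
generating surface ranking best by RMSE demonstrates that the sensor
data carry geometric information; it does not show that real SEEG identifies real
cortical geometry, since the synthetic reference shares the model family,
the electrode geometry is exact, and observation noise is mild and
Gaussian.  Similarly, passing tests on grid meshes say nothing about
FreeSurfer-quality clinical meshes, electrode bending, or non-dipolar
sources.

## Numerical choices

Heun integration at $\Delta t = 0.2$ ms (refining the step from 0.1 to
0.05 ms changes probe traces by under 1 % RMS; at the default 0.2 ms the
discharge timing shifts by a few percent, immaterial for envelope-scale
quantities); kernel truncated at $6b$ (missing < 2 % of the planar kernel
mass) with area-weighted quadrature — the discrete kernel mass at an
interior vertex measures 0.96–1.00; Heaviside evaluated inclusively at
threshold; divergence guard at $|u_1| > 50$; geodesics by Dijkstra on the
mesh graph augmented with second-ring Euclidean chords (worst-case
directional bias ~3 %, against 21 % for the bare edge graph; exact
polyhedral geodesics remain unnecessary against $b = 1$ mm), while
path sampling for the wave estimator stays on the bare edge graph so the
path is vertex-dense; bisections to
$10^{-3}$ in $u_0$; regime classification discards the first half of a
60 s run and calls oscillation at peak-to-peak $> 10^{-3}$; the frozen
fast subsystem is probed from a fixed list of seven initial conditions
(30 s each).  Selectivity curves interpolate linearly between bracketing
cumulative points, treating the first (largest-gain) vertex as
indivisible.  All generators and workflows are deterministic given their
seeds.

## Known limitations

The monostable/bistable boundary and the uncoupled onset-frequency
landmarks cannot both be matched by any single memory configuration (see
above); the working point favours the field phenomenology.  Fast-wave
speed estimates can saturate at the grid edge for late analysis windows,
when the waves have synchronized.  Because the dominant sensor-band
activity of this working point travels as short-wavelength discharge
waves (a few mm at the sensors' scale), bipolar amplitudes follow the
incoherent combination of the gain lobes rather than the coherent
homogeneous-source proxy; the proxy remains exact for spatially uniform
sources, which is how it is tested.  The sine surrogate's
printed mesh area is not an invariant of this construction (the height
field stretches the footprint by an amount that depends on the exact
parametrisation, so only its planform is pinned).  Long-range
(connectome) coupling, stochastic integration, volume-conductor head
models and clinical data handling are out of scope.
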