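---
title: "Shaped-pulse SIFTER: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shaped-pulse SIFTER: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chirpsifter)
```

# Scope

`chirpsifter` models broadband pulsed dipolar EPR with linearly chirped
WURST pulses, with the single-frequency technique for refocusing (SIFTER)
as the central experiment. It covers four layers:

1. **Pulse arithmetic** — WURST envelopes, linear chirps, critical
   adiabaticity, time bandwidth products, flip angles, and resonator
   transfer-function compensation.
2. **Spin dynamics** — Bloch-vector propagation of non-interacting
   S = 1/2 ensembles through pulse sequences, with B1-inhomogeneity
   averaging and echo phase/amplitude analysis.
3. **Sequence design** — an exact linear solver for the pulse-length
   ratios that refocus the offset-dependent phase roll of chirped pulses
   over arbitrary coherence pathways.
4. **Dipolar data** — orientation-selective 2D-SIFTER simulation for rigid
   nitroxide pairs, synthetic data generation, and the processing chain
   down to a distance distribution by Tikhonov inversion.

# The pulse model

A chirp pulse is `S(t) = w1(t) * exp(i*phi(t))` on `t` in `[-tp/2, tp/2]`,
with the WURST envelope `w1(t) = w1_max * (1 - |sin(pi*t/tp)|^n)` and a
linear instantaneous-frequency sweep of width `SW` so that
`phi(t) = s*pi*(SW/tp)*t^2` (sweep sign `s = +-1`, phase zero at the pulse
center). Two dimensionless numbers control a chirp:

* the **critical adiabaticity** `Qcrit = w1_max^2 * tp / (2*pi*SW)`, which
  sets the effective flip angle `beta = acos(2*exp(-pi*Qcrit/2) - 1)`. A
  pi/2 pulse needs `Qcrit = 2*ln(2)/pi ~ 0.44`; the flip angle approaches
  pi asymptotically, so pi pulses are specified by a Qcrit value
  (default 5) rather than an exact angle;
* the **time bandwidth product** `TBP = tp*SW`, which controls the
  smoothness of the excitation profile (values below ~30 give visible
  distortions) and, as the Bloch simulations show, the slope of the echo
  phase against Qcrit.

Interfaces use MHz and ns; everything internal is rad/s and s. The
conversion pitfall — `w1` in angular frequency against `SW` in linear
frequency inside Qcrit — is pinned by a unit test
(`qcrit(18.7, 100, 500) ~ 0.44`).

Waveform sampling defaults to
`dt = min(tp/1000, 1/(16*(SW + nu1)))`: at least 1000 samples per pulse and
16 per period of the fastest frequency present. The propagator refuses
per-step rotations above pi/4, and `sample_waveform()` refuses grids whose
band-edge phase advance exceeds pi/8, naming the largest admissible `dt`.

Resonator compensation divides the sampled amplitude by the normalized
nutation response at each sample's instantaneous frequency and rescales to
the original peak (amplitude-only, as in standard transfer-function
correction; the sweep itself is not warped — pre-warping the frequency axis
is a possible extension that is deliberately not applied by default). A
response floor (default 0.05 of the maximum) guards against unbounded
boosts where the profile has no sensitivity.

# Bloch simulation conventions

Spins are propagated by exact axis–angle rotation about the effective field
`(w1*cos(phi), w1*sin(phi), Omega)`; rotations preserve the norm to machine
precision, which is why the propagator is a rotation rather than a
finite-difference integrator (an ODE integration of the same piecewise
field is used as an independent oracle in the tests). There is no
relaxation. The default ensemble is 1000 spins uniformly covering -100 to
+100 MHz.

Sign conventions, pinned by tests: `M_xy = Mx + i*My`, free precession
advances the phase as `exp(+i*Omega*t)`, and a rectangular `(pi/2)x` pulse
takes `+z` to `-y`. With these choices the rectangular Hahn echo with both
pulses along x forms along `+y` (`phi0 = +pi/2`), the standard reference
for the chirp-echo phase discussion. Note the three statements are not
independent: any convention that puts the x,x Hahn echo on `+y` must send
`+z` to `-y` under `(pi/2)x`.

Echo analysis: the echo time is the magnitude maximum of the detected
transient with 3-point parabolic refinement (tests assert it falls within
one sample of the coherence-order bookkeeping prediction); `phi0` is the
phase of the spin nearest zero offset at that time; `delta_phi` is the
unwrapped per-offset phase minus `phi0` (zero-order correction only);
`phi_p` is the quadratic coefficient of `delta_phi` over the central 60 %
of the sweep width. The echo amplitude equals the fidelity: transients are
normalized to the spin count and the B1 weight sum, so 1 means all spins
aligned in phase.

B1 inhomogeneity is a half-Gaussian distribution of relative scales with
width `sigma`, peak at 1 (most of a resonator sees the full field, the
ends see less): 21 scales on `[1 - 4*sigma, 1]`, weights
`exp(-(1-s)^2/(2*sigma^2))` renormalized. The grid and truncation are
package choices; the reference behavior is reproduced with `sigma = 0.05`.
Averaging is performed on the end-state magnetization, which is exact
because detection is linear in `M` (a test asserts equality with the
per-scale average).

Because no phase cycling is modeled (out of scope), every coherence
pathway survives into the detected transient. Where a quantitative echo
amplitude must isolate one pathway — e.g. comparing the 2:3:1:4 sequence,
whose passive-third-pulse pathway carries half the magnetization, against
the standard 2:2:2:1 SIFTER — the package's tests read the echo amplitude
above the off-echo pedestal (median |transient| more than 40 ns from the
echo), which is what an experimental phase cycle removes. Under that
measurement the simulated amplitude ratio is 0.5 within a few percent, as
the acceptance suite verifies.

# The refocusing-ratio solver

For equal sweep widths, a coherence pathway with orders `(o-_i, o+_i)`
around pulse `i` refocuses the chirp phase roll when
`sum_i s_i * tp_i * (o-_i - o+_i) = 0`. Each pathway is one homogeneous
linear equation; fixed lengths and equalities add rows. The solver reduces
the system by exact rational Gaussian elimination (numerators/denominators
kept as integers), so residuals of returned solutions are exactly zero.

Two SIFTER design conditions are encoded as auxiliary bookkeeping
pathways:

* **dispersion matching** (`dispersion_matching_pathway()`): the echo of
  pulses 1 and 2 must have the frequency dispersion of the third pulse's
  passage, `-s1*t1 + 2*s2*t2 - s3*t3 = 0`. Together with the regular
  pathway this is what makes the classic 2:2:2:1 sequence work;
* **dispersion-free solid echo** (`solid_echo_pathway()`): pulses 1 and 3
  must refocus the dipolar coupling without offset dispersion,
  `-s1*t1 + 2*s3*t3 = 0` (the 2:1 first-to-third relation for up sweeps).

With the regular pathway plus both conditions and all up sweeps the
solution is the unique ray 4:3:2:1; dropping the dispersion-matching
condition under up–down–up–down sweeps opens a two-parameter family that
contains 2:3:1:4.

**Ranking.** Solution families are enumerated as primitive positive
integer vectors with coefficients up to 12 and ranked by
`normalized_total`: the total length after scaling the shortest pi-role
pulse to 1, because the shortest pi pulse needs the highest amplitude and
therefore sets the absolute time unit of the whole sequence. That metric
alone is unbounded (trading ever-longer pi pulses for ever-shorter pi/2
pulses always "wins"), so when roles are declared a feasibility floor
applies: the shortest pi/2 pulse must be at least `min_pi2_frac`
(default 1/3) of the shortest pi pulse, reflecting that a pi/2 pulse much
shorter than the amplitude-limited pi pulses cannot keep an adequate time
bandwidth product (guideline TBP >= 30 against a typical shortest-pi TBP
of ~100). Under these defaults the top-ranked solution of the
up–down–up–down family is 2:3:1:4. Both the metric and the floor are
declared package choices; other rankings are possible and the full
enumerated family is always returned.

# Sequence templates and timing

Templates (`make_variant()`): the 2:1 two-pulse echo, the 2:2:1 and 2:2:2
refocused echoes, the 2:2:2:1 standard SIFTER, the 2:2:6:3 dual-pathway
variant (up–down–down–down), the 2:3:1:4 dispersion-free-solid-echo
variant (up–down–up–down), the asymmetric 2:2:2:2:3:2 six-pulse SIFTER,
and SIDRE references obtained by omitting the second pi/2 pulse. The
2:2:2 template intentionally does **not** refocus the parabolic phase
roll — it is the equal-pi-TBP reference whose `phi0` is flat in Qcrit
while a quadratic offset phase remains.

Delays are **center-to-center**, which makes the bookkeeping echo times
exact for linear chirps; edge-to-edge is the common lab convention, so the
difference matters when reproducing instrument timings. One consequence:
with symmetric center-to-center delays, the two coherence pathways of the
2:2:6:3 sequence refocus at the same nominal time, and the two distinct
echoes appear when the sequence is timed with equal edge-to-edge gaps (as
an instrument would); the dual-echo test does exactly that.

2D schedules define `dt` as the increment of the **dipolar time axis** per
point. The recommended mode increases tau2 while decreasing tau1 (tau1 <=
tau2 avoids echo crossings and receiver-gate overlap); the six-pulse rule
decreases tau1 while tau2, tau3, tau4 each grow by a third of that
decrement, so all pi-pulse refocusing conditions hold at every point
(pulse lengths never change during a schedule). Six-pulse sweep directions
default to all-up (zero residual); they are not pinned by any reference
and remain configurable.

# The rigid-pair dipolar model

A conformer is a distance `r` plus ZYZ Euler angles of each nitroxide
frame relative to the inter-spin frame (z along the inter-spin vector).
For each orientation of the field (deterministic golden-spiral grid,
default 2000 points, equal weights — seeds never touch the quadrature),
each spin contributes `(1 - lambda) + lambda*cos(2*pi*nu_dd*t)` with
`nu_dd = (D/r^3)*(1 - 3*cos^2(theta))`, `D = 52.04 MHz nm^3`, into the
offset bin given by its own first-order resonance
`(g(n) - g_iso)/g_iso * nu_mw + mI*A(n)` (three 14N projections, weight
1/3 each). Defaults: g = (2.0086, 2.0066, 2.0026), A = (14, 14, 95) MHz —
typical literature nitroxide values, not fitted to any sample — at
9.6 GHz. Exchange coupling is fixed at zero. Unresolved proton hyperfine
structure is a Gaussian blur of the offset axis (default 8 MHz FWHM; the
mechanism is standard, the width is a package default).

Two subtleties of the first-order stick spectrum matter for the
edge-to-center dispersion measurement (`sifter_dispersion_ratio()`): the
exact zero-offset bin of a collinear pair is dominated by near-magic-angle
orientations (the mI = 0 contour with `g(n) = g_iso` lies near
`cos^2(theta) = 1/3` for typical nitroxide g values), and hyperfine
broadening leaks inner orientations into the outermost bins. The
measurement therefore uses the unbroadened spectrum, reads the center at
the spectrum maximum (the mI = 0 perpendicular ridge, theta ~ 90 deg) and
the edges at the support extremes, and localizes peak frequencies on an
8x zero-filled magnitude FT so positions are not quantized to the raw
1/(n*dt) resolution. For a collinear pair at 3.5 nm with 4 us of dipolar
evolution this yields a ratio within about 1 % of the ideal factor 2.

# The synthetic data generator

`synth_dataset()` emulates a measured 2D data set as
`ideal 2D signal x envelope x background + noise`:

* envelope: Gaussian in the dipolar time, width 3000 ns, peaking at
  `tau1 = tau2` where the dynamic decoupling of the four-pulse sequence is
  optimal — the shape a SIDRE reference trace exhibits;
* background: intermolecular exponential `exp(-k*|t|)`, default
  `k = 2e-4 /ns`;
* modulation depth `lambda = 0.5` (reduced from the ideal 1, as incomplete
  excitation causes in practice);
* white Gaussian noise, default 1 % of the signal maximum, from a local
  RNG stream under the given seed (the session RNG state is restored);
* optionally a per-offset sensitivity shape emulating non-uniform
  excitation/detection across the band, which the profile-correction
  round trip then has to recover.

The companion SIDRE trace carries the same envelope and background without
modulation, with independent noise. What the generator does **not**
emulate: relaxation-driven envelope shapes beyond the Gaussian, nuclear
modulation (ESEEM), orientation-dependent relaxation, pathway-leakage
artifacts, and any analytically derived SIFTER background model — passing
the round-trip tests therefore shows the pipeline is self-consistent, not
that the background model is faithful to every measured data set.

# Processing choices

* Echo FT: zero-order phase chosen to maximize the integrated real
  spectrum (the criterion is a package choice); echoes centered within
  10 % of the record edge are refused as truncated.
* Excitation-profile correction: the profile is traced by following one
  spectral point through field-stepped spectra; division is floored at
  0.05 sensitivity to avoid amplifying noise outside the excited band.
* Background: division by the SIDRE trace, then by a log-linear
  exponential fit over the last 60 % of the dipolar axis (window
  configurable; a fitted growing background only warns, since noise can
  produce one on short traces).
* 2D FT: per column — background correction, normalization, re-weighting
  by the pre-correction intensity, magnitude FT with no zero filling or
  apodization; columns whose t = 0 intensity is below 5 % of the maximum
  are excluded (at the spectral edges no reliable exponential can be
  fitted). A squared/normalized heatmap mode eases visual inspection.
* Tikhonov inversion: the modulation depth is absorbed linearly by
  solving `F - 1 = (K - 1) Pw` for `Pw >= 0` (Lawson–Hanson NNLS on the
  stacked system with a second-difference penalty); the integral of `Pw`
  is the modulation depth and `P = Pw/integral` the density. `alpha`
  defaults to the L-curve corner (maximum discrete curvature over a
  logarithmic grid, 1e-3 to ~30); GCV is available. All of these are
  declared defaults — no reference prescribes the window or the alpha
  rule.

# Problem sizes and determinism

The test and acceptance workloads use offset ensembles of 301–401 spins
(the figure-level properties are stable beyond ~200 points over the
+-100 MHz box; the user-facing default stays at the canonical 1000),
Qcrit grids of 7–28 points, 2000-orientation sphere grids, 4 us dipolar
axes at 16 ns steps, and 10 noise seeds for the end-to-end recovery. All
randomness is seeded; sphere quadrature and solver enumeration are fully
deterministic.

# Known limitations

* No relaxation, instantaneous diffusion or ESEEM in the Bloch model;
  fidelities are upper bounds on real echo amplitudes.
* Single-quantum coherence bookkeeping (|o| <= 1 by default); DQC-style
  pathways would need the configurable order bound and new amplitudes.
* The dipolar simulation treats pulses as ideal for the spin pair
  (no partial dipolar refocusing during long chirps), so very short
  distances/fast oscillations are outside its validity.
* The SIFTER background is an empirical envelope-times-exponential model;
  quantitative background physics is explicitly out of scope.
* Amplitude-only resonator compensation; no AWG quantization or amplifier
  nonlinearity.
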