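# chirpsifter

Shaped-pulse design, Bloch-vector simulation and data processing for
broadband pulsed dipolar EPR, centered on the single-frequency technique
for refocusing (SIFTER).

## The problem

Nitroxide spin labels span far more bandwidth (~200 MHz at X-band) than a
rectangular microwave pulse can excite, so single-frequency dipolar
experiments such as SIFTER need frequency-swept (chirped) pulses. Chirps
bring their own physics: a WURST pulse

    S(t) = w1(t) * exp(i*phi(t)),   w1(t) = w1_max * (1 - |sin(pi*t/tp)|^n)

sweeping a width `SW` in a time `tp` tips each offset at a different
moment, imprinting a parabolic phase roll that later pulses must refocus.
Its flip angle is set by the critical adiabaticity

    Qcrit = w1_max^2 * tp / (2*pi*SW),     beta = acos(2*exp(-pi*Qcrit/2) - 1)

(`Qcrit ~ 0.44` for a pi/2 pulse), and the echo phase acquires
Qcrit-dependent shifts (`phi0`, `delta_phi`) that interfere destructively
under B1 inhomogeneity and oscillate the SIFTER echo amplitude during
calibration. Pulse-length ratios that refocus a coherence pathway solve

    sum_i  s_i * tp_i * (o-_i - o+_i)  =  0

over the sweep signs `s_i` and coherence orders around each pulse — the
2:1 two-pulse echo, the 2:2:1 refocused echo, the 2:2:2:1 four-pulse
SIFTER, 4:3:2:1, 2:3:1:4, 2:2:6:3 and the 2:2:2:2:3:2 six-pulse SIFTER all
arise as solutions under different side conditions.

The package is for spectroscopists designing or analyzing such
experiments: it constructs and resonator-corrects the waveforms, solves
the refocusing condition exactly over arbitrary pathways, simulates the
spin dynamics (including B1 averaging and echo phase analysis), simulates
orientation-selective 2D-SIFTER data of rigid nitroxide pairs, and
processes 2D data (echo FT, excitation-profile correction, SIDRE +
exponential background division, 2D dipolar FT, Tikhonov inversion) down
to a distance distribution.

## Worked example

```r
library(chirpsifter)

# a chirped pi/2 pulse: 100 ns over 500 MHz needs ~18.7 MHz of drive
qcrit_for_flip(pi / 2)
#> [1] 0.4412712
nu1_for_qcrit(qcrit_for_flip(pi / 2), tp = 100, sw = 500)
#> [1] 18.73906

# pulse-length ratios refocusing the SIFTER pathway for up-down-up-down
# sweeps with a dispersion-free solid echo (pulses 1 and 3)
solve_ratios(4, c(1, -1, 1, -1),
             list(pathway("0,1;1,-1;-1,-1;-1,1"), solid_echo_pathway(4)),
             roles = c("pi/2", "pi", "pi/2", "pi"))
#> refocusing ratios: 4 pulses, signs (+-+-), 2 pathway(s)
#>   24 solution(s)
#>     2:3:1:4   (normalized total 3.33)
#>     6:8:3:11   (normalized total 3.5)
#>     ...

# simulate the standard 2:2:2:1 SIFTER echo at a calibrated pi-pulse Qcrit
s <- make_sifter_2221(tp_unit = 100, sw = 500, tau1 = 500, q_pi = 3.1)
run_sequence(s, ensemble = spin_ensemble(seq(-100, 100, length.out = 401)))
#> echo record: echo at 2000 ns, amplitude 0.9675, phi0 = -0.2468 rad

# synthetic 2D data set for a rigid pair at 3.5 nm, inverted back
ds <- synth_dataset(rigid_pair(3.5), times = seq(0, 4000, by = 16),
                    offsets = seq(-130, 100, by = 2), seed = 1)
bc <- background_correct(ds$times, colSums(ds$signal), ds$sidre)
tikhonov_distance(ds$times, bc$corrected, r = seq(2, 6, by = 0.05))
#> distance distribution: peak at 3.5 nm, alpha = 0.00157, modulation depth 0.463
```

Reading the numbers: the first block is the pi/2 amplitude calibration;
the solver block lists the exact integer ratio families (2:3:1:4 ranks
first under the package's shortest-sequence metric); the echo forms at
the bookkeeping time 2000 ns (= tau2 after the last pulse center) with
96.75 % of the spins in phase; and the pipeline recovers the input 3.5 nm
distance with close to the generated modulation depth (0.5, here 0.463
after noise and background division).

A command-line front end for the same operations (echo simulation, ratio
solving, synthetic data, processing) is in
`inst/cli/chirpsifter-cli.R`.

## Layout

- `R/pulse_shapes.R` — WURST/chirp arithmetic, waveform sampling,
  resonator correction
- `R/sequences.R` — sequence templates, timing, 2D schedules
- `R/bloch_sim.R`, `src/bloch_core.cpp` — ensemble propagation and echo
  analysis
- `R/ratio_solver.R` — exact pathway/ratio solver
- `R/dipolar_sifter.R` — rigid-pair 2D-SIFTER simulation and synthetic
  data
- `R/processing_2d.R` — echo FT, profile correction, background division,
  2D FT, Tikhonov inversion
- `vignettes/chirped-sifter-methods.Rmd` — models, conventions and design
  choices
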