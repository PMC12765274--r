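# WURST chirp pulses: construction, sampling, adiabaticity and flip-angle
# arithmetic, and resonator transfer-function correction.

#' Create a WURST chirp pulse
#'
#' A linearly chirped pulse with a WURST (wideband, uniform rate, smooth
#' truncation) amplitude envelope, `1 - |sin(pi*t/tp)|^n`, swept over a
#' width `sw` during `tp`. The pulse time coordinate runs over
#' `[-tp/2, +tp/2]` and the phase is zero at the pulse center.
#'
#' The peak nutation amplitude can be given directly (`nu1`, MHz) or derived
#' from a target critical adiabaticity (`qcrit`) or a nominal flip angle
#' (`flip`, rad, via the adiabatic flip-angle relation).
#'
#' @param tp pulse length (ns).
#' @param sw sweep width (MHz, linear frequency).
#' @param n WURST steepness index (dimensionless, >= 1).
#' @param nu1 peak nutation amplitude (MHz). Exactly one of `nu1`, `qcrit`,
#'   `flip` must be given.
#' @param qcrit critical adiabaticity used to set the amplitude.
#' @param flip nominal flip angle (rad) used to set the amplitude.
#' @param sweep sweep direction, `+1` (up) or `-1` (down).
#' @param carrier_offset center of the sweep relative to the frame carrier
#'   (MHz).
#' @param phi_start phase offset at the pulse center (rad).
#' @param role nominal flip-angle tag, `"pi/2"` or `"pi"`.
#' @return an object of class `chirp_pulse`.
#' @examples
#' p <- chirp_pulse(tp = 100, sw = 500, n = 16, qcrit = 0.4413, role = "pi/2")
#' qcrit(p$nu1, 100, 500)
#' @export
chirp_pulse <- function(tp, sw, n = 16, nu1 = NULL, qcrit = NULL, flip = NULL,
                        sweep = +1L, carrier_offset = 0, phi_start = 0,
                        role = c("pi", "pi/2")) {
  role <- match.arg(role)
  if (!is.numeric(tp) || length(tp) != 1L || tp <= 0)
    stop("'tp' must be a single positive pulse length in ns")
  if (!is.numeric(sw) || length(sw) != 1L || sw <= 0)
    stop("'sw' must be a single positive sweep width in MHz")
  if (n < 1) stop("WURST index 'n' must be >= 1")
  if (!sweep %in% c(-1, 1)) stop("'sweep' must be +1 (up) or -1 (down)")
  given <- c(nu1 = !is.null(nu1), qcrit = !is.null(qcrit), flip = !is.null(flip))
  if (sum(given) != 1L)
    stop("give exactly one of 'nu1', 'qcrit', 'flip'")
  if (!is.null(flip)) qcrit <- qcrit_for_flip(flip)
  if (!is.null(qcrit)) nu1 <- nu1_for_qcrit(qcrit, tp, sw)
  if (nu1 < 0) stop("peak amplitude must be >= 0")
  structure(
    list(tp = tp, sw = sw, n = n, nu1 = nu1, sweep = as.integer(sweep),
         carrier_offset = carrier_offset, phi_start = phi_start, role = role),
    class = "chirp_pulse")
}

#' @export
print.chirp_pulse <- function(x, ...) {
  cat(sprintf(
    "WURST chirp pulse (%s): tp = %g ns, SW = %g MHz (%s sweep), n = %g\n",
    x$role, x$tp, x$sw, if (x$sweep > 0) "up" else "down", x$n))
  cat(sprintf("  nu1 = %.4g MHz, Qcrit = %.4g, TBP = %.4g\n",
              x$nu1, qcrit(x$nu1, x$tp, x$sw),
              time_bandwidth_product(x$tp, x$sw)))
  invisible(x)
}

.check_pulse_time <- function(pulse, t) {
  tol <- 1e-9 * pulse$tp
  if (any(t < -pulse$tp / 2 - tol | t > pulse$tp / 2 + tol))
    stop(sprintf("sample time outside pulse support [-%g, %g] ns",
                 pulse$tp / 2, pulse$tp / 2))
}

#' WURST amplitude envelope
#'
#' Fraction of the peak amplitude at time `t` (ns, relative to the pulse
#' center): `1 - |sin(pi*t/tp)|^n`.
#'
#' @param pulse a [chirp_pulse()].
#' @param t time (ns) in `[-tp/2, +tp/2]`.
#' @return amplitude fraction in `[0, 1]`.
#' @export
wurst_envelope <- function(pulse, t) {
  .check_pulse_time(pulse, t)
  1 - abs(sin(pi * t / pulse$tp))^pulse$n
}

#' Instantaneous frequency offset of a linear chirp
#'
#' Offset of the instantaneous frequency from the frame carrier at time `t`
#' (ns): `s * (SW/tp) * t + carrier_offset`, in MHz.
#'
#' @inheritParams wurst_envelope
#' @return frequency offset (MHz, linear).
#' @export
instantaneous_frequency <- function(pulse, t) {
  .check_pulse_time(pulse, t)
  pulse$sweep * (pulse$sw / pulse$tp) * t + pulse$carrier_offset
}

#' Phase function of a linear chirp
#'
#' Integral of the instantaneous frequency offset, with the phase-zero
#' convention at the pulse center: `phi(t) = s*pi*(SW/tp)*t^2 +
#' 2*pi*carrier_offset*t + phi_start` (radians; `t` in ns).
#'
#' @inheritParams wurst_envelope
#' @return phase (rad).
#' @export
phase_function <- function(pulse, t) {
  .check_pulse_time(pulse, t)
  t_s <- ns_to_s(t)
  sw_hz <- mhz_to_hz(pulse$sw)
  tp_s <- ns_to_s(pulse$tp)
  pulse$sweep * pi * (sw_hz / tp_s) * t_s^2 +
    2 * pi * mhz_to_hz(pulse$carrier_offset) * t_s + pulse$phi_start
}

#' Critical adiabaticity of a chirp pulse
#'
#' `Qcrit = omega1^2 * tp / (2*pi*SW)` with `omega1` the peak nutation
#' amplitude in angular frequency. Arguments are taken in the interface
#' units (MHz nutation frequency, ns, MHz sweep width) and converted
#' internally, so `qcrit(18.7, 100, 500)` is approximately 0.44.
#'
#' @param nu1 peak nutation amplitude (MHz).
#' @param tp pulse length (ns).
#' @param sw sweep width (MHz).
#' @return dimensionless critical adiabaticity.
#' @export
qcrit <- function(nu1, tp, sw) {
  if (any(nu1 <= 0) || any(tp <= 0) || any(sw <= 0))
    stop("'nu1', 'tp' and 'sw' must all be positive")
  omega1 <- mhz_to_radsec(nu1)
  omega1^2 * ns_to_s(tp) / (mhz_to_hz(sw) * 2 * pi)
}

#' Peak amplitude for a target critical adiabaticity
#'
#' Inverse of [qcrit()] in its first argument.
#'
#' @param q target critical adiabaticity (> 0).
#' @inheritParams qcrit
#' @return peak nutation amplitude (MHz).
#' @export
nu1_for_qcrit <- function(q, tp, sw) {
  if (any(q <= 0) || any(tp <= 0) || any(sw <= 0))
    stop("'q', 'tp' and 'sw' must all be positive")
  radsec_to_mhz(sqrt(q * mhz_to_hz(sw) * 2 * pi / ns_to_s(tp)))
}

#' Time bandwidth product
#'
#' `TBP = tp * SW` in consistent units; 100 ns at 500 MHz gives 50. Values
#' below about 30 give distorted excitation profiles.
#'
#' @inheritParams qcrit
#' @return dimensionless time bandwidth product.
#' @export
time_bandwidth_product <- function(tp, sw) {
  if (any(tp <= 0) || any(sw <= 0)) stop("'tp' and 'sw' must be positive")
  tp * sw / 1000
}

#' Effective flip angle of an adiabatic chirp pulse
#'
#' `beta = acos(2*exp(-pi*Q/2) - 1)`: zero at `Q = 0`, monotone increasing,
#' asymptotically approaching `pi`. A chirped pi/2 pulse corresponds to
#' `Q = 2*ln(2)/pi`, approximately 0.44.
#'
#' @param q critical adiabaticity (>= 0).
#' @return flip angle (rad).
#' @export
flip_angle <- function(q) {
  if (any(q < 0)) stop("'q' must be >= 0")
  acos(2 * exp(-pi * q / 2) - 1)
}

#' Critical adiabaticity for a target flip angle
#'
#' Exact inverse of [flip_angle()]: `Q = -(2/pi) * log((cos(beta) + 1)/2)`.
#'
#' @param beta flip angle (rad), `0 <= beta < pi`. A flip of exactly `pi`
#'   is only reached asymptotically and signals an error.
#' @return critical adiabaticity.
#' @export
qcrit_for_flip <- function(beta) {
  if (any(beta < 0) || any(beta >= pi))
    stop("flip angle must be in [0, pi); beta = pi is unreachable (Qcrit -> Inf)")
  -(2 / pi) * log((cos(beta) + 1) / 2)
}

#' Default waveform sample spacing
#'
#' `dt = min(tp/1000, 1/(16*(SW + nu1)))`: at least 1000 samples per pulse
#' and at least 16 samples per period of the fastest oscillation.
#'
#' @param pulse a [chirp_pulse()].
#' @return sample spacing (ns).
#' @export
default_dt <- function(pulse) {
  min(pulse$tp / 1000, 1e3 / (16 * (pulse$sw + pulse$nu1)))
}

#' Sample a chirp pulse into a complex waveform
#'
#' Evaluates `S(t) = omega1(t) * exp(i*phi(t))` on a uniform grid spanning
#' exactly `[-tp/2, +tp/2]`. Amplitudes are stored in angular frequency
#' (rad/s). The grid must resolve the phase: the per-step phase advance at
#' the band edge may not exceed pi/8.
#'
#' @param pulse a [chirp_pulse()].
#' @param dt sample spacing (ns); default [default_dt()].
#' @return an object of class `waveform` with fields `times` (ns),
#'   `envelope` (complex, rad/s), `dt` (ns).
#' @export
sample_waveform <- function(pulse, dt = NULL) {
  if (is.null(dt)) dt <- default_dt(pulse)
  # largest instantaneous |dphi/dt|: band edge of the sweep plus carrier
  wmax <- 2 * pi * mhz_to_hz(pulse$sw / 2 + abs(pulse$carrier_offset))
  dt_max <- s_to_ns((pi / 8) / wmax)
  if (dt > dt_max)
    stop(sprintf(
      "waveform under-sampled: dt = %g ns advances the band-edge phase by more than pi/8; use dt <= %g ns",
      dt, dt_max))
  nstep <- max(2L, ceiling(pulse$tp / dt))
  times <- seq(-pulse$tp / 2, pulse$tp / 2, length.out = nstep + 1L)
  amp <- mhz_to_radsec(pulse$nu1) * wurst_envelope(pulse, times)
  env <- amp * exp(1i * phase_function(pulse, times))
  structure(list(times = times, envelope = env, dt = times[2] - times[1]),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("waveform: %d samples, dt = %g ns, span [%g, %g] ns, peak nu1 = %.4g MHz\n",
              length(x$times), x$dt, min(x$times), max(x$times),
              radsec_to_mhz(max(Mod(x$envelope)))))
  invisible(x)
}

#' Resonator nutation profile
#'
#' Normalized nutation amplitude versus frequency offset, as recorded by a
#' Rabi nutation experiment across the band. The response is rescaled to a
#' maximum of 1.
#'
#' @param freqs frequency grid (MHz), strictly increasing. Offsets are
#'   relative to the frame carrier.
#' @param response nutation amplitude per frequency (arbitrary units,
#'   positive on the band).
#' @return an object of class `resonator_profile`.
#' @export
resonator_profile <- function(freqs, response) {
  if (length(freqs) != length(response))
    stop("'freqs' and 'response' must have equal length")
  if (any(diff(freqs) <= 0)) stop("'freqs' must be strictly increasing")
  if (any(response <= 0)) stop("profile response must be positive on the band")
  structure(list(freqs = freqs, response = response / max(response)),
            class = "resonator_profile")
}

#' Read a resonator profile from two-column delimited text
#'
#' Columns: frequency offset (MHz), nutation amplitude. Lines starting with
#' `#` are comments.
#'
#' @param path file path.
#' @return a [resonator_profile()].
#' @export
read_resonator_profile <- function(path) {
  tab <- utils::read.table(path, comment.char = "#")
  resonator_profile(tab[[1]], tab[[2]])
}

#' Correct a waveform amplitude for the resonator transfer function
#'
#' Divides the amplitude of each waveform sample by the normalized resonator
#' response at that sample's instantaneous frequency, then rescales so the
#' maximum amplitude equals the pulse's peak amplitude. The phase is left
#' unchanged (amplitude-only compensation; the frequency sweep is not
#' warped).
#'
#' @param wf a [sample_waveform()] result.
#' @param pulse the [chirp_pulse()] that generated `wf`.
#' @param profile a [resonator_profile()] covering the swept band.
#' @param floor minimum tolerated normalized response inside the band
#'   (default 0.05); lower responses would demand an unbounded amplitude
#'   boost and signal an error.
#' @return a corrected `waveform`.
#' @export
apply_transfer_correction <- function(wf, pulse, profile, floor = 0.05) {
  f <- instantaneous_frequency(pulse, wf$times)
  band <- range(f)
  if (band[1] < min(profile$freqs) || band[2] > max(profile$freqs))
    stop(sprintf("resonator profile [%g, %g] MHz does not cover the swept band [%g, %g] MHz",
                 min(profile$freqs), max(profile$freqs), band[1], band[2]))
  resp <- stats::approx(profile$freqs, profile$response, xout = f)$y
  if (any(resp < floor))
    stop(sprintf("resonator response drops below the %g floor inside the band; correction would boost the amplitude unboundedly", floor))
  env <- wf$envelope / resp
  peak <- max(Mod(env))
  if (peak > 0) env <- env * (mhz_to_radsec(pulse$nu1) / peak)
  structure(list(times = wf$times, envelope = env, dt = wf$dt),
            class = "waveform")
}

#' Export a waveform as delimited text
#'
#' Three columns: time (ns), real and imaginary nutation amplitude (MHz),
#' suitable for AWG-style consumption.
#'
#' @param wf a `waveform`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(wf, path) {
  tab <- data.frame(time_ns = wf$times,
                    re_mhz = radsec_to_mhz(Re(wf$envelope)),
                    im_mhz = radsec_to_mhz(Im(wf$envelope)))
  utils::write.table(format(tab, digits = 12), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
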