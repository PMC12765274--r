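# Bloch-vector simulation of chirp echoes.
#
# Independent S = 1/2 spins are propagated by exact axis-angle rotation
# about the effective field; B1 inhomogeneity is handled by repeating the
# simulation at scaled amplitudes and averaging the transients with the
# distribution weights. Relaxation is not modeled. Sign conventions:
# M_xy = Mx + i*My, free precession advances the phase by +Omega*t, and a
# rectangular (pi/2)x pulse takes +z to -y, so the rectangular Hahn echo
# with both pulses along x forms along +y (phi0 = +pi/2).

#' Create a spin ensemble
#'
#' Independent spins at the given frequency offsets, all starting at
#' equilibrium `(0, 0, 1)`. The default emulates the standard simulation
#' protocol for broadband chirp echoes: 1000 spins uniformly covering -100
#' to +100 MHz, no relaxation.
#'
#' @param offsets frequency offsets (MHz).
#' @return object of class `spin_ensemble` with fields `offsets` (rad/s)
#'   and `M` (3 x nspins matrix).
#' @export
spin_ensemble <- function(offsets = seq(-100, 100, length.out = 1000)) {
  n <- length(offsets)
  structure(list(offsets = mhz_to_radsec(offsets), offsets_mhz = offsets,
                 M = rbind(0, 0, rep(1, n))),
            class = "spin_ensemble")
}

#' Half-Gaussian B1 scale distribution
#'
#' Relative B1 scales peaking at 1 and truncated below, as found across a
#' microwave resonator where most of the sample sits at full field and the
#' edges see less. Scales cover `[1 - trunc*sigma, 1]` with weights
#' proportional to `exp(-(1-scale)^2 / (2*sigma^2))`, normalized to sum 1.
#' `sigma = 0` degenerates to a single scale of 1.
#'
#' @param sigma relative width of the half-Gaussian (dimensionless).
#' @param npts number of grid points (default 21).
#' @param trunc truncation in units of sigma (default 4).
#' @return object of class `b1_distribution` with `scales`, `weights`.
#' @export
b1_distribution <- function(sigma, npts = 21L, trunc = 4) {
  if (sigma < 0) stop("'sigma' must be >= 0")
  if (sigma == 0)
    return(structure(list(sigma = 0, scales = 1, weights = 1),
                     class = "b1_distribution"))
  scales <- seq(max(1 - trunc * sigma, 1e-3), 1, length.out = npts)
  w <- exp(-(1 - scales)^2 / (2 * sigma^2))
  structure(list(sigma = sigma, scales = scales, weights = w / sum(w)),
            class = "b1_distribution")
}

#' Propagate an ensemble through a piecewise-constant field
#'
#' Low-level propagator: each time step rotates every spin about its
#' effective field `(scale*wx, scale*wy, offset)` by `|field|*dt`. Errors
#' if any per-step rotation angle exceeds pi/4 (under-sampled drive).
#'
#' @param ens a [spin_ensemble()].
#' @param wx,wy in-phase/quadrature drive per step (rad/s).
#' @param dt step duration (ns).
#' @param scale B1 scale factor.
#' @return the updated ensemble.
#' @export
propagate_piecewise <- function(ens, wx, wy, dt, scale = 1) {
  dt_s <- ns_to_s(dt)
  maxfield <- sqrt(max(scale^2 * (wx^2 + wy^2)) + max(ens$offsets^2))
  if (maxfield * dt_s > pi / 4)
    stop(sprintf(
      "under-sampled propagation: per-step rotation angle %.3g rad exceeds pi/4; reduce dt",
      maxfield * dt_s))
  ens$M <- .bloch_propagate_cpp(ens$M, ens$offsets, wx, wy, dt_s, scale)
  ens
}

#' Propagate an ensemble through a sampled pulse
#'
#' Applies a [sample_waveform()] result (optionally phase-shifted, e.g.
#' `pi/2` for a y pulse) with the drive taken piecewise-constant at the
#' midpoints between waveform samples.
#'
#' @param ens a [spin_ensemble()].
#' @param wf a `waveform`.
#' @param scale B1 scale factor (dimensionless).
#' @param phase pulse phase (rad; 0 = x, pi/2 = y).
#' @return the updated ensemble.
#' @export
propagate_pulse <- function(ens, wf, scale = 1, phase = 0) {
  env <- wf$envelope * exp(1i * phase)
  mid <- (env[-1] + env[-length(env)]) / 2
  propagate_piecewise(ens, Re(mid), Im(mid), wf$dt, scale)
}

#' Free evolution of an ensemble
#'
#' Analytic z-rotation of every spin by `Omega * tau`; `Mz` is unchanged.
#'
#' @param ens a [spin_ensemble()].
#' @param tau delay (ns, >= 0).
#' @return the updated ensemble.
#' @export
propagate_delay <- function(ens, tau) {
  if (tau < 0) stop("'tau' must be >= 0")
  if (tau == 0) return(ens)
  th <- ens$offsets * ns_to_s(tau)
  c_ <- cos(th); s_ <- sin(th)
  mx <- ens$M[1, ]; my <- ens$M[2, ]
  ens$M[1, ] <- mx * c_ - my * s_
  ens$M[2, ] <- mx * s_ + my * c_
  ens
}

.unwrap <- function(phi) {
  d <- diff(phi)
  jumps <- cumsum(c(0, round(d / (2 * pi))))
  phi - 2 * pi * jumps
}

# 3-point parabolic refinement of a discrete maximum
.parabolic_peak <- function(x, y, i) {
  if (i <= 1L || i >= length(x)) return(list(x = x[i], y = y[i]))
  d <- (y[i - 1] - 2 * y[i] + y[i + 1])
  if (d >= 0) return(list(x = x[i], y = y[i]))
  delta <- 0.5 * (y[i - 1] - y[i + 1]) / d
  list(x = x[i] + delta * (x[i + 1] - x[i]),
       y = y[i] - 0.25 * (y[i - 1] - y[i + 1]) * delta)
}

# Propagate a full sequence once per B1 scale; returns the weight-averaged
# transverse magnetization per spin at the END of the last pulse, the
# absolute end time, and timing metadata. Averaging M before detection is
# exact because the detected transient is linear in M.
.propagate_sequence <- function(seq, ensemble, b1, dt_wave = NULL) {
  np <- length(seq$pulses)
  tp <- vapply(seq$pulses, `[[`, numeric(1), "tp")
  wfs <- lapply(seq$pulses, sample_waveform, dt = dt_wave)
  gaps <- seq$delays - (tp[-np] + tp[-1]) / 2
  timing <- sequence_timing(seq)

  mxy <- rep(0 + 0i, ncol(ensemble$M))
  mz <- rep(0, ncol(ensemble$M))
  for (k in seq_along(b1$scales)) {
    ens <- ensemble
    for (i in seq_len(np)) {
      ens <- propagate_pulse(ens, wfs[[i]], scale = b1$scales[k],
                             phase = seq$phases[i])
      if (i < np) ens <- propagate_delay(ens, gaps[i])
    }
    mxy <- mxy + b1$weights[k] * complex(real = ens$M[1, ],
                                         imaginary = ens$M[2, ])
    mz <- mz + b1$weights[k] * ens$M[3, ]
  }
  wsum <- sum(b1$weights)
  list(mxy = mxy / wsum, mz = mz / wsum, t_end = timing$table$end[np],
       echo_nom = timing$echo_time, offsets = ensemble$offsets)
}

#' Simulate a pulse sequence and detect the echo
#'
#' Propagates the ensemble through all pulses (sampled per the waveform
#' contract) and inter-pulse free evolutions, then samples the complex
#' transient `mean_i (Mx + i My)_i` in a detection window after the last
#' pulse. With a [b1_distribution()], the simulation is repeated per scale
#' and the transients averaged with the distribution weights (normalized to
#' the number of spins and the weight sum, so a fidelity of 1 means all
#' spins aligned in phase).
#'
#' The echo time is located at the transient magnitude maximum with 3-point
#' parabolic refinement. `phi0` is read from the spin closest to zero
#' offset; `delta_phi` is the unwrapped per-offset phase minus `phi0`;
#' `phi_p` is the quadratic coefficient of `delta_phi` against offset
#' (rad/(rad/s)^2) over the central 60 % of the sweep width.
#'
#' @param seq a `pulse_sequence`.
#' @param ensemble a [spin_ensemble()]; default the standard 1000-spin
#'   protocol.
#' @param b1 a [b1_distribution()] or `NULL` (ideal B1).
#' @param detection optional list: either `times` (absolute, ns, relative to
#'   the first pulse center) or `half` (window half-width, ns) and `dt`
#'   (sampling, ns) around the nominal echo time.
#' @param dt_wave waveform oversampling (ns); default per pulse.
#' @return an object of class `echo_record`: `times`, `transient` (complex),
#'   `echo_time`, `echo_amp`, `fidelity`, `phi0`, `offsets` (MHz),
#'   `delta_phi`, `per_offset_amp`, `phi_p`, `mz`.
#' @export
run_sequence <- function(seq, ensemble = NULL, b1 = NULL, detection = NULL,
                         dt_wave = NULL) {
  if (is.null(ensemble)) ensemble <- spin_ensemble()
  if (is.null(b1)) b1 <- b1_distribution(0)
  st <- .propagate_sequence(seq, ensemble, b1, dt_wave)

  times <- detection$times
  if (is.null(times)) {
    if (is.na(st$echo_nom))
      stop("sequence declares no pathway; give detection times")
    half <- detection$half %||% max(10, min(0.9 * (st$echo_nom - st$t_end), 60))
    dtd <- detection$dt %||% (1e3 / (4 * seq$sw))
    if (st$echo_nom - half < st$t_end) half <- st$echo_nom - st$t_end
    times <- seq(st$echo_nom - half, st$echo_nom + half, by = dtd)
  }
  if (min(times) < st$t_end - 1e-9)
    stop("detection window starts before the end of the last pulse")

  ph <- outer(st$offsets, ns_to_s(times - st$t_end))
  transient <- as.vector(crossprod(st$mxy, exp(1i * ph))) / length(st$mxy)

  amp <- Mod(transient)
  imax <- which.max(amp)
  if (length(amp) >= 3L && (imax == 1L || imax == length(amp)))
    stop("no echo maximum inside the detection window")
  pk <- .parabolic_peak(times, amp, imax)

  mxy_echo <- st$mxy * exp(1i * st$offsets * ns_to_s(pk$x - st$t_end))
  i0 <- which.min(abs(st$offsets))
  phi0 <- Arg(mxy_echo[i0])
  ord <- order(st$offsets)
  phases <- rep(NA_real_, length(mxy_echo))
  phases[ord] <- .unwrap(Arg(mxy_echo[ord]))
  delta_phi <- phases - phases[i0]

  core <- abs(ensemble$offsets_mhz) <= 0.3 * seq$sw
  phi_p <- NA_real_
  if (sum(core) > 5) {
    fit <- stats::lm(delta_phi[core] ~ stats::poly(st$offsets[core], 2,
                                                   raw = TRUE))
    phi_p <- unname(stats::coef(fit)[3])
  }

  structure(list(times = times, transient = transient, echo_time = pk$x,
                 echo_amp = pk$y, fidelity = pk$y, phi0 = phi0,
                 offsets = ensemble$offsets_mhz, delta_phi = delta_phi,
                 per_offset_amp = Mod(mxy_echo), phi_p = phi_p, mz = st$mz,
                 nominal_echo_time = st$echo_nom),
            class = "echo_record")
}

#' @export
print.echo_record <- function(x, ...) {
  cat(sprintf("echo record: echo at %.4g ns, amplitude %.4g, phi0 = %.4g rad\n",
              x$echo_time, x$echo_amp, x$phi0))
  invisible(x)
}

#' Export an echo transient as delimited text
#'
#' Three columns (time ns, real, imaginary) plus a structured-text sidecar
#' `<path>.meta` with the echo time, phi0 and fidelity.
#'
#' @param rec an `echo_record`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_echo_record <- function(rec, path) {
  utils::write.table(
    data.frame(time_ns = rec$times, re = Re(rec$transient),
               im = Im(rec$transient)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(sprintf("echo_time: %.12g", rec$echo_time),
               sprintf("phi0: %.12g", rec$phi0),
               sprintf("fidelity: %.12g", rec$fidelity)),
             paste0(path, ".meta"))
  invisible(path)
}

#' Phase of the on-resonance spin at a given time
#'
#' Propagates the sequence and returns the phase of the spin closest to zero
#' offset at the absolute time `t` (ns from the first pulse center), which
#' must fall after the last pulse. Used e.g. to read the two-pulse echo
#' phase at the position of the third pulse of a SIFTER sequence.
#'
#' @inheritParams run_sequence
#' @param t evaluation time (ns).
#' @return phase (rad).
#' @export
phi0_at <- function(seq, t, ensemble = NULL, b1 = NULL, dt_wave = NULL) {
  if (is.null(ensemble)) ensemble <- spin_ensemble()
  if (is.null(b1)) b1 <- b1_distribution(0)
  st <- .propagate_sequence(seq, ensemble, b1, dt_wave)
  if (t < st$t_end)
    stop("evaluation time falls before the end of the last pulse")
  i0 <- which.min(abs(st$offsets))
  Arg(st$mxy[i0] * exp(1i * st$offsets[i0] * ns_to_s(t - st$t_end)))
}

#' Echo phase phi0 versus critical adiabaticity
#'
#' Sweeps the shared Qcrit of the pi pulses of a template, extracts the
#' center-of-chirp echo phase, unwraps it over the grid, and fits a line
#' over `Q` in `[4, 10]` (below that, incomplete coherence inversion makes
#' the dependence nonlinear).
#'
#' @param name template name (see [make_variant()]).
#' @param q_grid Qcrit values (increasing grid in `[0.5, 20]`).
#' @param tp_unit,sw,tau1 sequence parameters (ns, MHz, ns).
#' @param ensemble,b1,dt_wave passed to [run_sequence()].
#' @param ... further arguments to [make_variant()].
#' @return list with `q`, `phi0` (unwrapped, rad), `slope` (rad per unit Q),
#'   `fit_window`.
#' @export
phi0_vs_qcrit <- function(name, q_grid, tp_unit, sw, tau1, ensemble = NULL,
                          b1 = NULL, dt_wave = NULL, ...) {
  phi <- vapply(q_grid, function(q) {
    s <- make_variant(name, tp_unit = tp_unit, sw = sw, tau1 = tau1,
                      q_pi = q, ...)
    run_sequence(s, ensemble = ensemble, b1 = b1, dt_wave = dt_wave)$phi0
  }, numeric(1))
  phi_u <- .unwrap(phi)
  if (any(abs(diff(phi_u)) > 0.9 * pi))
    stop("phi0 advances by more than ~pi between grid points; refine the Q grid")
  win <- q_grid >= 4 & q_grid <= 10
  slope <- if (sum(win) >= 2)
    unname(stats::coef(stats::lm(phi_u[win] ~ q_grid[win]))[2]) else NA_real_
  list(q = q_grid, phi0 = phi_u, slope = slope, fit_window = c(4, 10))
}

#' Echo amplitude versus critical adiabaticity
#'
#' Absolute echo amplitude as a function of the shared Qcrit of the pi
#' pulses (the pi/2 amplitude stays pinned to the adiabatic pi/2 flip),
#' optionally under a half-Gaussian B1 distribution.
#'
#' @inheritParams phi0_vs_qcrit
#' @return data frame with columns `q`, `echo`.
#' @export
echo_vs_qcrit <- function(name, q_grid, tp_unit, sw, tau1, ensemble = NULL,
                          b1 = NULL, dt_wave = NULL, ...) {
  echo <- vapply(q_grid, function(q) {
    s <- make_variant(name, tp_unit = tp_unit, sw = sw, tau1 = tau1,
                      q_pi = q, ...)
    run_sequence(s, ensemble = ensemble, b1 = b1, dt_wave = dt_wave)$echo_amp
  }, numeric(1))
  data.frame(q = q_grid, echo = echo)
}

#' Echo amplitude sweep for a Carr-Purcell chirp train
#'
#' Like [echo_vs_qcrit()] but for [make_cp_train()] sequences with a given
#' number of pi pulses.
#'
#' @param n_pi number of refocusing pi pulses.
#' @param q_grid Qcrit values.
#' @param tp_unit,sw,tau train parameters (ns, MHz, ns).
#' @inheritParams phi0_vs_qcrit
#' @return data frame with columns `q`, `echo`.
#' @export
echo_vs_qcrit_cp <- function(n_pi, q_grid, tp_unit, sw, tau, ensemble = NULL,
                             b1 = NULL, dt_wave = NULL) {
  echo <- vapply(q_grid, function(q) {
    s <- make_cp_train(n_pi, tp_unit, sw, tau, q_pi = q)
    run_sequence(s, ensemble = ensemble, b1 = b1, dt_wave = dt_wave)$echo_amp
  }, numeric(1))
  data.frame(q = q_grid, echo = echo)
}

#' Carr-Purcell chirp echo train with a terminal short pulse
#'
#' A pi/2 pulse followed by `n_pi` refocusing pi pulses with the length
#' pattern `(2, 2, ..., 2, 1) * tp_unit` (all but the last pulse twice the
#' last), all up sweeps, which refocuses the parabolic phase roll for the
#' alternating coherence pathway. Delays are `tau, 2*tau, ..., 2*tau`
#' between centers with the echo `tau` after the last pulse.
#'
#' @param n_pi number of pi pulses (>= 1).
#' @param tp_unit length of the terminal pulse (ns).
#' @param sw sweep width (MHz).
#' @param tau base delay (ns).
#' @param q_pi shared pi-pulse adiabaticity.
#' @param n WURST index.
#' @return a `pulse_sequence`.
#' @export
make_cp_train <- function(n_pi, tp_unit, sw, tau, q_pi = 5, n = 16) {
  stopifnot(n_pi >= 1)
  npulse <- n_pi + 1L
  ratios <- c(rep(2, npulse - 1L), 1)
  roles <- c("pi/2", rep("pi", n_pi))
  o <- integer(npulse + 1L)
  o[2] <- 1L
  for (i in seq_len(n_pi)) o[i + 2L] <- -o[i + 1L]
  pw <- paste(sprintf("%d,%d", o[-length(o)], o[-1]), collapse = ";")
  delays <- if (n_pi == 1L) tau else c(tau, rep(2 * tau, n_pi - 1L))
  chirp_sequence(ratios, roles, rep(1, npulse), rep(0, npulse), delays,
                 tp_unit, sw, q_pi = q_pi, n = n, pathway = pw,
                 name = sprintf("cp_%dpi", n_pi))
}

#' SIFTER pi-pulse amplitude sweep
#'
#' Emulates the SIFTER amplitude calibration: the shared Qcrit of the two pi
#' pulses is swept (keeping them at equal Qcrit, i.e. an amplitude ratio of
#' `1:sqrt(2)` for the 2:1 length pair of the standard sequence) while the
#' pi/2 amplitudes stay at the adiabatic pi/2 value. Returns the SIFTER echo
#' amplitude together with the phase `phi0` of the two-pulse echo evaluated
#' at the position of the (pi/2)y pulse: the SIFTER echo is maximal where
#' that phase crosses half-integer multiples of pi and minimal at integer
#' multiples.
#'
#' @param q_grid Qcrit values of the pi pulses.
#' @param tp_unit,sw,tau1,tau2 sequence parameters of [make_sifter_2221()].
#' @param ensemble,b1,dt_wave passed to [run_sequence()].
#' @return data frame with columns `q`, `echo`, `phi0_third` (unwrapped).
#' @export
sifter_amplitude_sweep <- function(q_grid, tp_unit, sw, tau1, tau2 = tau1,
                                   ensemble = NULL, b1 = NULL,
                                   dt_wave = NULL) {
  echo <- numeric(length(q_grid))
  phi3 <- numeric(length(q_grid))
  for (j in seq_along(q_grid)) {
    s <- make_sifter_2221(tp_unit, sw, tau1 = tau1, tau2 = tau2,
                          q_pi = q_grid[j])
    echo[j] <- run_sequence(s, ensemble = ensemble, b1 = b1,
                            dt_wave = dt_wave)$echo_amp
    sub <- chirp_sequence(s$ratios[1:2], s$roles[1:2], s$signs[1:2],
                          s$phases[1:2], s$delays[1], tp_unit, sw,
                          q_pi = q_grid[j], n = s$n, pathway = "0,1;1,-1",
                          name = "sifter_12")
    # third-pulse center sits tau1 after the second pulse center
    phi3[j] <- phi0_at(sub, t = 2 * s$taus[["tau1"]], ensemble = ensemble,
                       b1 = b1, dt_wave = dt_wave)
  }
  data.frame(q = q_grid, echo = echo, phi0_third = .unwrap(phi3))
}

#' Classify interior extrema of a sampled curve
#'
#' @param x,y curve samples.
#' @return data frame with columns `x`, `y`, `type` (`"max"`/`"min"`) for
#'   every interior local extremum, with parabolic x refinement.
#' @export
find_extrema <- function(x, y) {
  idx <- which(diff(sign(diff(y))) != 0) + 1L
  if (length(idx) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), type = character(0)))
  type <- ifelse(y[idx] > y[idx - 1L] & y[idx] > y[idx + 1L], "max", "min")
  out <- data.frame(x = x[idx], y = y[idx], type = type,
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(out))) {
    i <- idx[r]
    sgn <- if (out$type[r] == "max") 1 else -1
    pk <- .parabolic_peak(x, sgn * y, i)
    out$x[r] <- pk$x; out$y[r] <- sgn * pk$y
  }
  out
}
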