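# Processing of (2D-)SIFTER echo data: echo Fourier transform,
# excitation-profile post-correction, SIDRE + exponential background
# division, 2D dipolar FT, and Tikhonov inversion to a distance
# distribution.

#' Fourier transform of an echo transient
#'
#' Re-centers the record on the echo, Fourier transforms it, and applies the
#' zero-order phase that maximizes the integrated real part of the spectrum.
#' The offset axis is returned in MHz relative to the carrier.
#'
#' @param times uniform time grid (ns).
#' @param signal complex transient.
#' @param center echo center (ns); located at the magnitude maximum when
#'   `NULL`. An echo center within 10 % of the record edge signals a
#'   truncation error.
#' @return list with `offsets` (MHz), `spectrum` (complex, phased), `phase`
#'   (applied zero-order phase, rad), `center` (ns).
#' @export
echo_ft <- function(times, signal, center = NULL) {
  n <- length(times)
  if (n < 4L || length(signal) != n) stop("need a uniform transient of length >= 4")
  dt <- diff(times)
  if (any(abs(dt - dt[1]) > 1e-6 * dt[1])) stop("time grid must be uniform")
  dt <- dt[1]
  if (is.null(center)) center <- times[which.max(Mod(signal))]
  span <- times[n] - times[1]
  if (center - times[1] < 0.1 * span || times[n] - center < 0.1 * span)
    stop("echo center lies within 10 % of the record edge; transient is truncated")
  # FT with the time origin at the echo center
  freqs <- (seq_len(n) - 1L) / (n * dt)          # cycles per ns
  freqs <- ifelse(freqs >= 1 / (2 * dt), freqs - 1 / dt, freqs) * 1e3  # MHz
  spec <- stats::fft(signal) * dt
  spec <- spec * exp(2i * pi * (freqs / 1e3) * (center - times[1]))
  ord <- order(freqs)
  freqs <- freqs[ord]; spec <- spec[ord]
  phase <- Arg(sum(spec))
  list(offsets = freqs, spectrum = spec * exp(-1i * phase), phase = phase,
       center = center)
}

#' Excitation/detection profile from field-stepped spectra
#'
#' Shifting the field moves the spectrum through the fixed excitation and
#' detection band of the shaped pulses. Following one chosen spectral point
#' across the steps maps out the combined sensitivity: for step `j` the
#' point originally at `track` appears at `track + shift_j` with intensity
#' proportional to the sensitivity there.
#'
#' @param offsets offset grid of the spectra (MHz).
#' @param spectra matrix, one row per field step.
#' @param shifts field shifts (MHz), one per row; at least 5 steps.
#' @param track offset (MHz) of the tracked spectral feature at zero shift.
#' @return object of class `excitation_profile`: `offsets` (MHz) and
#'   `sensitivity` (max 1).
#' @export
excitation_profile_from_field_steps <- function(offsets, spectra, shifts,
                                                track = 0) {
  if (length(shifts) < 5L) stop("need at least 5 field steps across the band")
  if (nrow(spectra) != length(shifts))
    stop("one spectrum row per field shift is required")
  pos <- track + shifts
  if (any(pos < min(offsets)) || any(pos > max(offsets)))
    stop("tracked point leaves the recorded band for some field steps")
  val <- vapply(seq_along(shifts), function(j)
    stats::approx(offsets, spectra[j, ], xout = pos[j])$y, numeric(1))
  if (any(!is.finite(val)) || max(val) <= 0)
    stop("tracked feature not visible in all field steps")
  ord <- order(pos)
  structure(list(offsets = pos[ord], sensitivity = (val / max(val))[ord]),
            class = "excitation_profile")
}

#' Divide a spectrum by an excitation profile
#'
#' @param offsets spectrum offset grid (MHz).
#' @param spectrum spectral intensities.
#' @param profile an [excitation_profile_from_field_steps()] result.
#' @param floor smallest sensitivity divided by (default 0.05) to avoid
#'   blowing up noise outside the excited band.
#' @return corrected spectrum values.
#' @export
correct_excitation <- function(offsets, spectrum, profile, floor = 0.05) {
  sens <- stats::approx(profile$offsets, profile$sensitivity, xout = offsets,
                        rule = 2)$y
  spectrum / pmax(sens, floor)
}

#' SIDRE and exponential background correction of a SIFTER trace
#'
#' Divides the trace by the SIDRE reference (which carries the relaxation
#' envelope but no dipolar modulation), then by an exponential background
#' fitted log-linearly over a tail window of the dipolar axis. The result
#' approximates the dipolar form factor.
#'
#' @param times dipolar time axis (ns).
#' @param trace SIFTER column (real).
#' @param sidre SIDRE trace on the same axis (strictly positive).
#' @param fit_frac fraction of the axis (largest `|t|`) used for the
#'   exponential fit (default 0.6).
#' @param k fixed background rate (1/ns); fitted when `NULL`.
#' @return list with `corrected`, `k`, `amp` (fitted amplitude), and
#'   `precorrection_intensity` (trace value nearest `t = 0`).
#' @export
background_correct <- function(times, trace, sidre, fit_frac = 0.6, k = NULL) {
  if (length(sidre) == 1L) sidre <- rep(sidre, length(trace))
  if (any(sidre <= 0)) stop("SIDRE trace must be strictly positive")
  v <- trace / sidre
  i0 <- which.min(abs(times))
  amp <- 1
  if (is.null(k)) {
    at <- abs(times)
    win <- at >= stats::quantile(at, 1 - fit_frac)
    ok <- win & v > 0
    if (sum(ok) < 3L) stop("too few positive samples in the background window")
    fit <- stats::lm(log(v[ok]) ~ at[ok])
    k <- -unname(stats::coef(fit)[2])
    amp <- exp(unname(stats::coef(fit)[1]))
    if (k < 0)
      warning("fitted background grows with time; check the fit window")
  }
  list(corrected = v / (amp * exp(-k * abs(times))), k = k, amp = amp,
       precorrection_intensity = trace[i0])
}

#' 2D dipolar Fourier transform of a SIFTER data set
#'
#' Per offset column: SIDRE + exponential background correction,
#' normalization, re-weighting by the pre-correction intensity, and a
#' magnitude FT along the dipolar time axis without zero filling or
#' apodization. Columns whose `t = 0` intensity falls below `snr_floor`
#' times the maximum column are excluded (at the spectral edges the SNR is
#' too poor to fit a background).
#'
#' @param dataset a `sifter2d` (with a `sidre` trace, unless `sidre` given).
#' @param sidre optional SIDRE trace overriding `dataset$sidre`.
#' @param snr_floor relative `t = 0` intensity below which a column is
#'   excluded (default 0.05).
#' @param fit_frac,k passed to [background_correct()].
#' @param squared square each normalized dipolar spectrum (heatmap mode).
#' @return list with `offsets` (MHz, included columns), `nu` (dipolar
#'   frequency axis, MHz, signed), `spec` (offsets x frequencies magnitude
#'   matrix), `nu_folded`/`spec_folded` (|nu| axis), `excluded` (offsets of
#'   skipped columns).
#' @export
dipolar_ft_2d <- function(dataset, sidre = NULL, snr_floor = 0.05,
                          fit_frac = 0.6, k = NULL, squared = FALSE) {
  sid <- sidre %||% dataset$sidre
  if (is.null(sid)) stop("a SIDRE trace is required for background correction")
  times <- dataset$times
  i0 <- which.min(abs(times))
  t0int <- abs(dataset$signal[, i0])
  keep <- t0int >= snr_floor * max(t0int)
  n <- length(times)
  dt <- times[2] - times[1]
  freqs <- (seq_len(n) - 1L) / (n * dt)
  freqs <- ifelse(freqs >= 1 / (2 * dt), freqs - 1 / dt, freqs) * 1e3
  ord <- order(freqs)
  spec <- matrix(0, sum(keep), n)
  rows <- which(keep)
  for (r in seq_along(rows)) {
    bc <- background_correct(times, dataset$signal[rows[r], ], sid,
                             fit_frac = fit_frac, k = k)
    v <- bc$corrected / max(abs(bc$corrected)) * bc$precorrection_intensity
    m <- Mod(stats::fft(v))[ord]
    if (squared) {
      m <- m / max(m)
      m <- m^2
    }
    spec[r, ] <- m
  }
  nu <- freqs[ord]
  pos <- nu >= 0
  list(offsets = dataset$offsets[keep], nu = nu, spec = spec,
       nu_folded = nu[pos], spec_folded = spec[, pos, drop = FALSE],
       excluded = dataset$offsets[!keep])
}

#' Dominant nonzero dipolar frequency of a spectrum
#'
#' Largest magnitude peak away from the zero-frequency bin.
#'
#' @param nu frequency axis (MHz).
#' @param spec magnitude spectrum.
#' @param nu_min smallest |frequency| considered (default: 1.5 grid steps,
#'   excluding the DC bin).
#' @return |frequency| (MHz) of the dominant peak.
#' @export
dominant_dipolar_frequency <- function(nu, spec, nu_min = NULL) {
  step <- min(diff(sort(unique(nu))))
  if (is.null(nu_min)) nu_min <- 1.5 * step
  sel <- abs(nu) >= nu_min
  i <- which(sel)[which.max(spec[sel])]
  # parabolic refinement on the magnitude spectrum
  pk <- .parabolic_peak(nu, spec, i)
  abs(pk$x)
}

#' Tikhonov inversion of a dipolar form factor
#'
#' Non-negative Tikhonov regularization of the Fredholm problem
#' `F(t) = (1 - lambda) + lambda * int K(t, r) P(r) dr` with the powder
#' dipolar kernel of [dipolar_kernel()] and a second-difference smoothness
#' penalty. The modulation depth is absorbed into the linear problem by
#' solving `F - 1 = (K - 1) Pw` for `Pw >= 0`, whose integral is the
#' modulation depth. The regularization parameter is chosen at the L-curve
#' corner (maximum curvature) by default.
#'
#' @param times dipolar times (ns) of the form factor (must include t = 0
#'   or start near it; `F` is renormalized to `F(0) = 1`).
#' @param formfactor background-corrected trace.
#' @param r distance grid (nm).
#' @param alpha regularization parameter, or `"lcurve"` / `"gcv"` for
#'   automatic selection over `alpha_grid`.
#' @param alpha_grid candidate regularization parameters.
#' @param D dipolar constant (MHz nm^3).
#' @return object of class `distance_distribution`: `r` (nm), `p`
#'   (probability density, integrates to 1), `alpha`, `mod_depth`,
#'   `fit` (fitted form factor).
#' @export
tikhonov_distance <- function(times, formfactor, r = seq(1.5, 6, by = 0.05),
                              alpha = "lcurve",
                              alpha_grid = 10^seq(-3, 1.5, length.out = 24),
                              D = 52.04) {
  i0 <- which.min(abs(times))
  F0 <- formfactor / formfactor[i0]
  K <- dipolar_kernel(times, r, D = D)
  A <- K - 1
  y <- F0 - 1
  nr <- length(r)
  L <- diff(diag(nr), differences = 2)
  solve_alpha <- function(a) {
    M <- rbind(A, a * L)
    rhs <- c(y, rep(0, nrow(L)))
    fit <- pracma::lsqnonneg(M, rhs)
    pw <- fit$x
    list(pw = pw, resid = sqrt(sum((A %*% pw - y)^2)),
         smooth = sqrt(sum((L %*% pw)^2)))
  }
  if (is.character(alpha)) {
    method <- match.arg(alpha, c("lcurve", "gcv"))
    sols <- lapply(alpha_grid, solve_alpha)
    resid <- vapply(sols, `[[`, numeric(1), "resid")
    smooth <- vapply(sols, `[[`, numeric(1), "smooth")
    if (method == "lcurve") {
      lx <- log(pmax(resid, 1e-12)); ly <- log(pmax(smooth, 1e-12))
      # discrete curvature of the L-curve
      n <- length(lx)
      kappa <- rep(-Inf, n)
      for (i in 2:(n - 1)) {
        x1 <- lx[i] - lx[i - 1]; y1 <- ly[i] - ly[i - 1]
        x2 <- lx[i + 1] - lx[i]; y2 <- ly[i + 1] - ly[i]
        cross <- x1 * y2 - y1 * x2
        denom <- (sqrt(x1^2 + y1^2) * sqrt(x2^2 + y2^2) *
                    sqrt((x1 + x2)^2 + (y1 + y2)^2))
        if (denom > 0) kappa[i] <- cross / denom
      }
      best <- which.max(kappa)
    } else {
      # generalized cross-validation with an effective-df proxy
      gcv <- vapply(seq_along(alpha_grid), function(i) {
        df <- sum(sols[[i]]$pw > 1e-12)
        (resid[i]^2) / max(1e-9, (length(y) - df))^2
      }, numeric(1))
      best <- which.min(gcv)
    }
    alpha <- alpha_grid[best]
    sol <- sols[[best]]
  } else {
    sol <- solve_alpha(alpha)
  }
  dr <- mean(diff(r))
  depth <- sum(sol$pw)
  if (depth <= 0) stop("inversion degenerated: all-zero distribution at every alpha")
  p <- sol$pw / (depth * dr)
  structure(list(r = r, p = p, alpha = alpha, mod_depth = depth,
                 fit = as.vector(1 + A %*% sol$pw)),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf("distance distribution: peak at %.3g nm, alpha = %.3g, modulation depth %.3g\n",
              x$r[which.max(x$p)], x$alpha, x$mod_depth))
  invisible(x)
}

#' Write a distance distribution as two-column delimited text
#'
#' @param x a `distance_distribution`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_distance_distribution <- function(x, path) {
  utils::write.table(data.frame(r_nm = x$r, p = x$p), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
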