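test_that("WURST envelope matches its closed form and rejects out-of-support times", {
  p <- chirp_pulse(tp = 100, sw = 500, n = 16, nu1 = 20)
  expect_identical(wurst_envelope(p, 0), 1)
  expect_equal(wurst_envelope(p, c(-50, 50)), c(0, 0))
  expect_equal(wurst_envelope(p, 25), 1 - 2^-8)   # n = 16 at tp/4
  expect_error(wurst_envelope(p, 51), "support")
})

test_that("instantaneous frequency is the linear chirp and the phase its integral", {
  p <- chirp_pulse(tp = 100, sw = 500, n = 16, nu1 = 20)
  expect_identical(instantaneous_frequency(p, 0), 0)
  expect_equal(instantaneous_frequency(p, 50), 250)    # +SW/2 at the edge
  # slope of the angular frequency over the full pulse is 2*pi*SW/tp
  slope <- diff(mhz_to_radsec(instantaneous_frequency(p, c(-50, 50)))) /
    ns_to_s(100)
  expect_equal(slope, 2 * pi * mhz_to_hz(500) / ns_to_s(100))
  # numeric cumulative integration of the offset reproduces the phase
  tt <- seq(-50, 50, length.out = 1e4 + 1)   # odd count: exact center point
  dw <- mhz_to_radsec(instantaneous_frequency(p, tt))
  phi_num <- cumsum(c(0, (dw[-1] + dw[-(1e4 + 1)]) / 2 * ns_to_s(diff(tt))))
  phi_num <- phi_num - phi_num[which.min(abs(tt))]    # zero at center
  expect_lt(max(abs(phi_num - phase_function(p, tt))) /
              max(abs(phase_function(p, tt))), 1e-9)
  # symmetric in t, constant for zero-width sweep limit
  expect_equal(phase_function(p, 30), phase_function(p, -30))
  pd <- chirp_pulse(tp = 100, sw = 500, n = 16, nu1 = 20, sweep = -1)
  expect_equal(phase_function(pd, 30), -phase_function(p, 30))
})

test_that("critical adiabaticity carries the 2*pi convention of the flip-angle relation", {
  # the classic gotcha: omega1 in rad/s against SW in Hz
  expect_equal(round(qcrit(18.7, 100, 500), 2), 0.44)
  expect_equal(qcrit(2 * 18.7, 100, 500), 4 * qcrit(18.7, 100, 500))
  # inverting for the amplitude: Q = 0.4413 at 100 ns / 500 MHz -> ~18.7 MHz
  expect_equal(nu1_for_qcrit(0.4413, 100, 500), 18.7, tolerance = 3e-3)
  expect_equal(qcrit(nu1_for_qcrit(3.7, 100, 500), 100, 500), 3.7,
               tolerance = 1e-12)
  expect_error(qcrit(-1, 100, 500), "positive")
})

test_that("time bandwidth product is tp*SW and scale-invariant", {
  expect_identical(time_bandwidth_product(100, 500), 50)
  expect_identical(time_bandwidth_product(200, 500), 100)
  expect_equal(time_bandwidth_product(100 * 3, 500 / 3),
               time_bandwidth_product(100, 500))
})

test_that("adiabatic flip angle is monotone with the exact inverse", {
  expect_identical(flip_angle(0), 0)
  expect_equal(flip_angle(2 * log(2) / pi), pi / 2)
  expect_lt(abs(flip_angle(10) - pi), 0.01)
  q <- seq(0, 20, length.out = 1000)
  expect_true(all(diff(flip_angle(q)) > 0))
  b <- seq(0.1, 3.0, by = 0.1)
  expect_equal(flip_angle(qcrit_for_flip(b)), b, tolerance = 1e-12)
  expect_identical(qcrit_for_flip(0), 0)
  expect_error(qcrit_for_flip(pi), "unreachable")
})

test_that("sampled waveforms honor the analytic envelope and phase", {
  p <- chirp_pulse(tp = 100, sw = 500, n = 16, qcrit = 5)
  wf <- sample_waveform(p)
  expect_equal(range(wf$times), c(-50, 50))
  i0 <- which.min(abs(wf$times))
  expect_equal(Mod(wf$envelope[i0]), mhz_to_radsec(p$nu1), tolerance = 1e-6)
  expect_equal(Mod(wf$envelope[c(1, length(wf$times))]), c(0, 0))
  # unwrapped argument matches the closed-form phase
  mid <- abs(wf$times) < 45    # away from zero-amplitude endpoints
  arg <- Arg(wf$envelope[mid])
  arg <- arg + 2 * pi * cumsum(c(0, round(-diff(arg) / (2 * pi))))
  ref <- phase_function(p, wf$times[mid])
  expect_lt(max(abs((arg - arg[1]) - (ref - ref[1]))), 1e-9)
  # zero amplitude -> all-zero envelope
  p0 <- chirp_pulse(tp = 100, sw = 500, n = 16, nu1 = 0)
  expect_true(all(sample_waveform(p0, dt = 0.1)$envelope == 0))
  # under-sampling names the minimal dt
  expect_error(sample_waveform(p, dt = 2), "dt <=")
  # down sweep is the complex conjugate chirp with identical magnitude
  pd <- chirp_pulse(tp = 100, sw = 500, n = 16, qcrit = 5, sweep = -1)
  wd <- sample_waveform(pd, dt = wf$dt)
  expect_equal(wd$envelope, Conj(wf$envelope), tolerance = 1e-12)
})

test_that("resonator transfer correction boosts weak-response regions, capped by a floor", {
  p <- chirp_pulse(tp = 100, sw = 400, n = 16, qcrit = 5)
  wf <- sample_waveform(p)
  flat <- resonator_profile(seq(-300, 300, by = 10), rep(1, 61))
  expect_equal(apply_transfer_correction(wf, p, flat)$envelope, wf$envelope,
               tolerance = 1e-12)
  # response falling to 0.5 at the low band edge: the amplitude there is
  # boosted by 1/response relative to the band center before rescaling
  fr <- seq(-300, 300, by = 10)
  resp <- pmin(1, 1 + fr / 400)     # 0.5 at -200 MHz (the band edge), 1 at 0
  prof <- resonator_profile(fr, resp)
  corr <- apply_transfer_correction(wf, p, prof)
  ft <- instantaneous_frequency(p, wf$times)
  i_edge <- which.min(abs(ft + 190))
  i_mid <- which.min(abs(wf$times))
  resp_t <- stats::approx(fr, resp, xout = ft)$y
  gain <- Mod(corr$envelope) / pmax(Mod(wf$envelope), 1e-12)
  expect_equal(gain[i_edge] / gain[i_mid], resp_t[i_mid] / resp_t[i_edge],
               tolerance = 1e-9)
  expect_equal(stats::approx(fr, resp, xout = -200)$y, 0.5)  # x2 at the edge
  expect_equal(max(Mod(corr$envelope)), mhz_to_radsec(p$nu1),
               tolerance = 1e-9)
  # phase untouched
  expect_equal(Arg(corr$envelope[i_mid]), Arg(wf$envelope[i_mid]))
  # floor guard and coverage guard
  deep <- resonator_profile(fr, pmax(0.04, pmin(1, 1 + fr / 150)))
  expect_error(apply_transfer_correction(wf, p, deep), "floor")
  narrow <- resonator_profile(seq(-100, 100, by = 10), rep(1, 21))
  expect_error(apply_transfer_correction(wf, p, narrow), "cover")
  # corrected pulse seen through the resonator has a flatter effective
  # amplitude across the band than the uncorrected pulse
  core <- wurst_envelope(p, wf$times) > 0.99
  flatness <- function(env) {
    eff <- Mod(env)[core] * resp_t[core]
    diff(range(eff)) / max(eff)
  }
  expect_lt(flatness(corr$envelope), flatness(wf$envelope))
})

test_that("resonator profiles and waveforms round-trip through text files", {
  tmp <- tempfile()
  writeLines(c("# comment", "-100 0.5", "0 1.0", "100 0.8"), tmp)
  prof <- read_resonator_profile(tmp)
  expect_equal(prof$response, c(0.5, 1, 0.8))
  expect_error(resonator_profile(c(0, 0), c(1, 1)), "increasing")
  p <- chirp_pulse(tp = 50, sw = 200, n = 16, qcrit = 1)
  wf <- sample_waveform(p)
  out <- tempfile()
  write_waveform(wf, out)
  tab <- utils::read.table(out, header = TRUE)
  expect_equal(nrow(tab), length(wf$times))
  expect_equal(max(sqrt(tab$re_mhz^2 + tab$im_mhz^2)), p$nu1,
               tolerance = 1e-6)
})
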