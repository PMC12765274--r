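test_that("echo FT recovers a known spectrum and obeys the shift theorem", {
  offs <- seq(-100, 100, by = 2)
  true_spec <- exp(-(offs - 10)^2 / 600) + 0.6 * exp(-(offs + 40)^2 / 200)
  tt <- seq(-200, 200, by = 0.5)
  sig <- colSums(true_spec * exp(2i * pi * (offs / 1e3) %o% tt))
  ft <- echo_ft(tt, sig, center = 0)
  rec <- stats::approx(ft$offsets, Re(ft$spectrum), xout = offs)$y
  sc <- sum(rec * true_spec) / sum(rec^2)
  expect_lt(sqrt(mean((rec * sc - true_spec)^2)) / max(true_spec), 0.01)
  # pure cosine transient: single symmetric bin pair
  sig1 <- cos(2 * pi * 0.02 * tt)            # 20 MHz
  ft1 <- echo_ft(tt, sig1, center = 0)
  pk <- ft1$offsets[order(Mod(ft1$spectrum), decreasing = TRUE)[1:2]]
  expect_equal(sort(abs(pk)), c(20, 20), tolerance = 0.5)
  # a time-shifted echo without re-centering shows a linear phase ramp
  # (small shift so the ramp stays unwrapped across the band)
  shift <- 2
  ftsh <- echo_ft(tt, sig, center = shift)
  ph <- Arg(ftsh$spectrum / ft$spectrum)
  band <- abs(ft$offsets) < 60 & Mod(ft$spectrum) > 0.1 * max(Mod(ft$spectrum))
  slope <- unname(stats::coef(stats::lm(ph[band] ~ ft$offsets[band]))[2])
  expect_equal(abs(slope), 2 * pi * shift / 1e3, tolerance = 0.05)
  # truncation guard
  expect_error(echo_ft(tt, sig, center = 190), "10 %")
  # Parseval consistency: spectrum = fft * dt, so
  # sum |S|^2 * df equals sum |s|^2 * dt (df in cycles/ns)
  dt <- 0.5; df_ns <- 1 / (length(tt) * dt)
  expect_equal(sum(Mod(ft$spectrum)^2) * df_ns, sum(Mod(sig)^2) * dt,
               tolerance = 1e-10)
})

test_that("field-stepped spectra recover an imposed sensitivity profile", {
  offs <- seq(-120, 120, by = 2)
  spec <- exp(-(offs + 5)^2 / 800)
  sens <- 1 - 0.5 * ((offs - 10) / 130)^2
  shifts <- seq(-60, 60, by = 12)
  steps <- synth_field_step_spectra(offs, spec, sens, shifts)
  prof <- excitation_profile_from_field_steps(offs, steps, shifts, track = 0)
  ref <- stats::approx(offs, sens / max(sens), xout = prof$offsets)$y
  expect_lt(sqrt(mean((prof$sensitivity - ref)^2)), 0.02)
  # flat sensitivity gives a flat profile
  flatsteps <- synth_field_step_spectra(offs, spec, rep(1, length(offs)), shifts)
  flat <- excitation_profile_from_field_steps(offs, flatsteps, shifts, 0)
  expect_lt(diff(range(flat$sensitivity)), 1e-9)
  # dividing the observed spectrum by the profile restores the true shape
  obs <- spec * sens
  corr <- correct_excitation(offs, obs, prof)
  sc <- sum(corr * spec) / sum(corr^2)
  expect_lt(sqrt(mean((corr * sc - spec)^2)) / max(spec), 0.02)
  expect_error(excitation_profile_from_field_steps(offs, steps[1:3, ],
                                                   shifts[1:3], 0), "5")
  expect_error(excitation_profile_from_field_steps(offs, steps, shifts,
                                                   track = 100), "band")
})

test_that("SIDRE and exponential division recover the form factor", {
  times <- seq(0, 3000, by = 25)
  K <- dipolar_kernel(times, 3.4)
  form <- 0.5 + 0.5 * K[, 1]
  env <- exp(-(times / 2500)^2)
  k_true <- 3e-4
  trace <- form * env * exp(-k_true * times)
  # known building blocks: exact recovery
  bc <- background_correct(times, trace, env, k = k_true)
  expect_equal(bc$corrected, form, tolerance = 1e-12)
  # fitted exponential: close recovery
  bc2 <- background_correct(times, trace, env)
  expect_equal(bc2$k, k_true, tolerance = 0.25)
  expect_lt(max(abs(bc2$corrected / bc2$corrected[1] - form / form[1])), 0.05)
  # identity when sidre = 1 and k = 0
  id <- background_correct(times, form, 1, k = 0)
  expect_equal(id$corrected, form)
  # modulation-free trace flattens to ~1
  flat <- background_correct(times, env * exp(-k_true * times), env)
  expect_lt(max(abs(flat$corrected - 1)), 0.02)
  expect_error(background_correct(times, trace, c(-1, rep(1, length(times) - 1))),
               "positive")
  expect_warning(background_correct(times, exp(2e-4 * times), 1), "grows")
})

test_that("the 2D dipolar FT localizes single frequencies and applies the SNR floor", {
  times <- seq(0, 4000, by = 16)
  offsets <- c(-10, 0, 10)
  nu0 <- 2.5
  sig <- rbind(0.02 * (0.4 + 0.6 * cos(2 * pi * nu0 * times / 1e3)),
               1.00 * (0.4 + 0.6 * cos(2 * pi * nu0 * times / 1e3)),
               0.50 * (0.4 + 0.6 * cos(2 * pi * 1.0 * times / 1e3)))
  ds <- structure(list(offsets = offsets, times = times, signal = sig,
                       sidre = rep(1, length(times)), meta = list()),
                  class = "sifter2d")
  ft <- dipolar_ft_2d(ds, k = 0)
  expect_equal(ft$excluded, -10)              # below the 5 % floor
  expect_equal(ft$offsets, c(0, 10))
  expect_equal(dominant_dipolar_frequency(ft$nu, ft$spec[1, ]), nu0,
               tolerance = 0.05)
  expect_equal(dominant_dipolar_frequency(ft$nu, ft$spec[2, ]), 1.0,
               tolerance = 0.05)
  # spectrum symmetric in +-nu for these real traces
  possel <- ft$nu > 0
  negsel <- ft$nu < 0
  expect_equal(ft$spec[1, possel],
               rev(ft$spec[1, negsel])[seq_len(sum(possel))],
               tolerance = 1e-9)
  sq <- dipolar_ft_2d(ds, k = 0, squared = TRUE)
  expect_equal(max(sq$spec[1, ]), 1)
})

test_that("Tikhonov inversion recovers distances and degenerates smoothly", {
  times <- seq(0, 4000, by = 16)
  rgrid <- seq(2, 6, by = 0.05)
  K <- dipolar_kernel(times, 3.5)
  V <- 0.6 + 0.4 * K[, 1]
  dd <- tikhonov_distance(times, V, r = rgrid)
  expect_equal(dd$r[which.max(dd$p)], 3.5, tolerance = 0.051)
  expect_equal(dd$mod_depth, 0.4, tolerance = 0.02)
  expect_true(all(dd$p >= 0))
  expect_equal(sum(dd$p) * 0.05, 1, tolerance = 1e-9)
  # huge alpha: curvature-free (near-affine) density
  dd_inf <- tikhonov_distance(times, V, r = rgrid, alpha = 1e5)
  curv <- diff(dd_inf$p, differences = 2)
  expect_lt(max(abs(curv)) / max(dd_inf$p), 1e-3)
  # two Gaussians 0.7 nm apart at SNR 50 resolve into two modes
  r0 <- seq(2, 6, by = 0.02)
  p0 <- stats::dnorm(r0, 3.2, 0.08) + stats::dnorm(r0, 3.9, 0.08)
  p0 <- p0 / sum(p0)
  V2 <- 0.6 + 0.4 * as.vector(dipolar_kernel(times, r0) %*% p0)
  set.seed(11)
  V2 <- V2 + stats::rnorm(length(V2), sd = 0.4 / 50)
  dd2 <- tikhonov_distance(times, V2, r = rgrid)
  pk <- which(diff(sign(diff(dd2$p))) == -2) + 1
  pk <- pk[dd2$p[pk] > 0.1 * max(dd2$p)]
  expect_equal(length(pk), 2)
  expect_equal(dd2$r[pk], c(3.2, 3.9), tolerance = 0.08)
  # distributions export as two-column text
  tmp <- tempfile()
  write_distance_distribution(dd, tmp)
  tab <- utils::read.table(tmp, header = TRUE)
  expect_equal(tab$r_nm, dd$r)
})
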