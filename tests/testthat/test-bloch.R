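test_that("axis-angle propagation reproduces textbook rotations", {
  # on-resonance rectangular pi pulse inverts z
  ens <- spin_ensemble(0)
  w1 <- mhz_to_radsec(25)                      # pi in 20 ns
  out <- propagate_piecewise(ens, rep(w1, 200), rep(0, 200), dt = 0.1)
  expect_equal(out$M[, 1], c(0, 0, -1), tolerance = 1e-9)
  # our convention: (pi/2)x takes +z to -y
  out90 <- propagate_piecewise(ens, rep(w1, 100), rep(0, 100), dt = 0.1)
  expect_equal(out90$M[, 1], c(0, -1, 0), tolerance = 1e-9)
  # zero-amplitude drive is free evolution
  e1 <- propagate_piecewise(spin_ensemble(10), rep(0, 50), rep(0, 50),
                            dt = 0.5)
  e2 <- propagate_delay(spin_ensemble(10), 25)
  expect_equal(e1$M, e2$M, tolerance = 1e-12)
  # 10 MHz offset for 25 ns is a quarter turn about z; Mz untouched
  e3 <- spin_ensemble(10)
  e3$M[, 1] <- c(1, 0, 0)
  e3 <- propagate_delay(e3, 25)
  expect_equal(e3$M[, 1], c(0, 1, 0), tolerance = 1e-9)
  e4 <- propagate_delay(spin_ensemble(10), 1234.5)
  expect_equal(e4$M[3, 1], 1)
  expect_error(propagate_delay(e4, -1), ">= 0")
})

test_that("per-step rotations exceeding pi/4 are rejected as under-sampled", {
  ens <- spin_ensemble(0)
  expect_error(propagate_piecewise(ens, mhz_to_radsec(100), 0, dt = 5),
               "under-sampled")
})

test_that("norms are conserved to 1e-10 through a full chirp sequence", {
  s <- make_sifter_2221(100, 500, tau1 = 500)
  ens <- ens_coarse(101)
  for (i in seq_along(s$pulses)) {
    ens <- propagate_pulse(ens, sample_waveform(s$pulses[[i]]),
                           phase = s$phases[i])
    ens <- propagate_delay(ens, 300)
  }
  expect_lt(max(abs(sqrt(colSums(ens$M^2)) - 1)), 1e-10)
})

test_that("axis-angle propagation agrees with direct ODE integration of the Bloch equations", {
  # 5 spins, a random piecewise-constant drive, dM/dt = B x M
  set.seed(42)
  offsets <- c(-40, -11, 0, 7, 33)
  nseg <- 24
  wx <- mhz_to_radsec(stats::runif(nseg, -15, 15))
  wy <- mhz_to_radsec(stats::runif(nseg, -15, 15))
  seg <- 1                                      # ns per segment
  ens <- propagate_piecewise(spin_ensemble(offsets), wx, wy, dt = seg)
  ode_one <- function(om) {
    field <- function(t) {
      k <- pmin(nseg, floor(t / ns_to_s(seg)) + 1)
      c(wx[k], wy[k], om)
    }
    rhs <- function(t, y, parms) {
      B <- field(t)
      list(c(B[2] * y[3] - B[3] * y[2],
             B[3] * y[1] - B[1] * y[3],
             B[1] * y[2] - B[2] * y[1]))
    }
    tends <- ns_to_s(seg) * (0:nseg)
    y <- c(0, 0, 1)
    # integrate segment by segment so the discontinuous field is exact
    for (k in seq_len(nseg)) {
      sol <- deSolve::ode(y, c(tends[k], tends[k + 1]), rhs, NULL,
                          method = "lsoda", rtol = 1e-11, atol = 1e-12)
      y <- as.numeric(sol[2, 2:4])
    }
    y
  }
  Mref <- vapply(mhz_to_radsec(offsets), ode_one, numeric(3))
  expect_lt(max(abs(ens$M - Mref)), 1e-6)
})

test_that("a chirped pi/2 at the critical adiabaticity excites fully", {
  p <- chirp_pulse(100, 500, n = 16, qcrit = 2 * log(2) / pi, role = "pi/2")
  out <- propagate_pulse(spin_ensemble(0), sample_waveform(p))
  mxy <- sqrt(sum(out$M[1:2, 1]^2))
  expect_lt(abs(mxy - sin(flip_angle(2 * log(2) / pi))), 0.02)
})

test_that("B1 averaging is linear and degenerates to the single-scale case", {
  s <- make_variant("hahn_21", tp_unit = 100, sw = 500, tau1 = 400, q_pi = 5)
  ens <- ens_coarse(101)
  r0 <- run_sequence(s, ensemble = ens, b1 = b1_distribution(0))
  r00 <- run_sequence(s, ensemble = ens, b1 = NULL)
  expect_identical(r0$transient, r00$transient)
  b1 <- b1_distribution(0.05, npts = 5)
  ravg <- run_sequence(s, ensemble = ens, b1 = b1,
                       detection = list(times = r0$times))
  parts <- lapply(b1$scales, function(sc) {
    bb <- b1_distribution(0); bb$scales <- sc
    run_sequence(s, ensemble = ens, b1 = bb,
                 detection = list(times = r0$times))$transient
  })
  manual <- Reduce(`+`, Map(`*`, parts, b1$weights)) / sum(b1$weights)
  expect_equal(ravg$transient, manual, tolerance = 1e-12)
})

test_that("the rectangular Hahn echo forms along +y", {
  # offsets well inside the pulse bandwidth so the refocusing is clean
  ens <- spin_ensemble(seq(-2, 2, length.out = 101))
  w90 <- mhz_to_radsec(25)
  ens <- propagate_piecewise(ens, rep(w90, 50), rep(0, 50), dt = 0.2)  # pi/2
  ens <- propagate_delay(ens, 300)
  ens <- propagate_piecewise(ens, rep(w90, 100), rep(0, 100), dt = 0.2) # pi
  ens <- propagate_delay(ens, 300)
  mxy <- mean(complex(real = ens$M[1, ], imaginary = ens$M[2, ]))
  expect_equal(Arg(mxy), pi / 2, tolerance = 1e-3)
  expect_gt(Mod(mxy), 0.98)
})

test_that("chirp echoes refocus at the bookkeeping time with high fidelity", {
  s <- make_variant("hahn_21", tp_unit = 100, sw = 500, tau1 = 400, q_pi = 5)
  rec <- run_sequence(s, ensemble = ens_coarse())
  dt_det <- rec$times[2] - rec$times[1]
  expect_lt(abs(rec$echo_time - rec$nominal_echo_time), dt_det)
  # fidelity above 0.9 over the central 60 % of the sweep width
  core <- abs(rec$offsets) <= 0.3 * s$sw
  expect_gt(min(rec$per_offset_amp[core]), 0.9)
  expect_lte(rec$fidelity, 1)
})

test_that("the ABSTRUSE echo refocuses the offset-dependent phase", {
  # generous sweep width so the observed band sits in the flat core
  s <- make_variant("abstruse_221", tp_unit = 100, sw = 800, tau1 = 400,
                    q_pi = 10)
  rec <- run_sequence(s, ensemble = ens_fine(),
                      detection = list(dt = 0.125, half = 30))
  expect_lt(max(abs(rec$delta_phi)), 5 * pi / 180)
})

test_that("delta_phi is set by the sweep width, not the pulse length", {
  ens <- ens_fine(201)
  g <- function(u, sw) run_sequence(
    make_variant("hahn_21", tp_unit = u, sw = sw, tau1 = 3.2 * u, q_pi = 10),
    ensemble = ens, detection = list(dt = 0.25))
  a <- g(100, 500); b <- g(200, 500); c2 <- g(100, 250)
  core <- abs(a$offsets) <= 75
  expect_lt(max(abs(a$delta_phi[core] - b$delta_phi[core])), 0.15)
  expect_gt(max(abs(a$delta_phi[core] - c2$delta_phi[core])), 1)
})

test_that("echo records export to delimited text with a sidecar", {
  s <- make_variant("hahn_21", tp_unit = 50, sw = 400, tau1 = 300, q_pi = 5)
  rec <- run_sequence(s, ensemble = ens_coarse(51))
  tmp <- tempfile()
  write_echo_record(rec, tmp)
  tab <- utils::read.table(tmp, header = TRUE)
  expect_equal(nrow(tab), length(rec$times))
  meta <- readLines(paste0(tmp, ".meta"))
  expect_true(any(grepl("^phi0:", meta)))
})
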