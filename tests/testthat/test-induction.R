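# EMF synthesis: single-particle closed-form checks, superposition,
# pulse trains, counter-flow noise and SNR.

test_that("stationary centered particle peaks at n * Phi0 * omega", {
  tr <- single_particle_emf(30e-9, speed = 0, coil = PICKUP,
                            duration = 0.1, dt = 1e-4)
  m0 <- particle_moment(30e-9, H_DRIVE, iron)
  expected <- PICKUP$turns * dipole_flux_center(m0, PICKUP$radius) *
    2 * pi * 50
  expect_rel_equal(max(abs(tr$v)), expected, 1e-3)
})

test_that("unmagnetized particles induce nothing", {
  tr <- single_particle_emf(30e-9, speed = 0.7, coil = PICKUP,
                            drive = drive_field(0, 50), duration = 0.5,
                            dt = 1e-4)
  expect_true(all(tr$v == 0))
})

test_that("analytic EMF matches a finite-difference derivative of the flux", {
  dt <- 1 / (200 * 50)
  tr <- single_particle_emf(30e-9, speed = 0.7, coil = PICKUP,
                            duration = 1, dt = dt)
  # rebuild the modulated flux independently and difference it
  m0 <- particle_moment(30e-9, H_DRIVE, iron)
  x <- advect(-0.35, 0.7, tr$t)
  phi <- dipole_flux_axial(m0, PICKUP$radius, x) * cos(2 * pi * 50 * tr$t)
  n <- length(phi)
  v_fd <- -PICKUP$turns * (phi[3:n] - phi[1:(n - 2)]) / (2 * dt)
  dev <- max(abs(tr$v[2:(n - 1)] - v_fd)) / max(abs(tr$v))
  expect_lt(dev, 1e-3)
})

test_that("flux returns to zero over whole drive cycles with a distant particle", {
  dt <- 1e-4
  tr <- single_particle_emf(30e-9, speed = 0.7, coil = PICKUP,
                            duration = 1, dt = dt)
  # 1 s = 50 whole drive cycles; particle starts and ends 0.35 m out
  integral <- sum(tr$v[-1]) * dt
  expect_lt(abs(integral), 1e-3 * max(abs(tr$v)) * dt * length(tr$t))
})

test_that("ensembles superpose exactly and the two engines agree", {
  ens1 <- particle_ensemble(30e-9, 0, 0.7, 1, -0.35)
  ens2 <- particle_ensemble(rep(30e-9, 2), c(0, 0), rep(0.7, 2),
                            c(1, 1), rep(-0.35, 2))
  tr1 <- ensemble_emf(ens1, PICKUP, duration = 1, dt = 1e-4)
  tr2 <- ensemble_emf(ens2, PICKUP, duration = 1, dt = 1e-4)
  expect_identical(tr2$v, 2 * tr1$v)          # exact co-located doubling
  trr <- ensemble_emf(ens2, PICKUP, duration = 1, dt = 1e-4, engine = "r")
  expect_equal(tr2$v, trr$v, tolerance = 1e-12)
  # empty ensemble: a zero trace, not an error
  ens0 <- particle_ensemble(numeric(0), numeric(0), numeric(0),
                            numeric(0), numeric(0))
  tr0 <- ensemble_emf(ens0, PICKUP, duration = 0.1, dt = 1e-4)
  expect_true(all(tr0$v == 0))
})

test_that("burst peaks are linear in particles per pulse through the origin", {
  counts <- c(250, 500, 1000)
  peaks <- vapply(counts, function(n) {
    tr <- pulse_train_emf(n, pulse_rate = 1, n_pulses = 1, coil = PICKUP,
                          seed = 21, duration = 1.2)
    max(trace_envelope(tr))
  }, numeric(1))
  fit <- summary(lm(peaks ~ counts))
  expect_gt(fit$r.squared, 0.999)
  # doubling the count doubles the burst peak
  expect_rel_equal(peaks[3], 2 * peaks[2], 0.01)
  # zero particles: zero trace
  tr0 <- pulse_train_emf(0, pulse_rate = 1, n_pulses = 2, coil = PICKUP,
                         seed = 21, duration = 1)
  expect_true(all(tr0$v == 0))
})

test_that("a pulse train shows one envelope burst per pulse", {
  tr <- pulse_train_emf(200, pulse_rate = 1, n_pulses = 5, coil = PICKUP,
                        seed = 4)
  bursts <- find_bursts(tr)
  expect_equal(nrow(bursts), 5)
  # bursts arrive one transit time after each 1 Hz emission
  expect_equal(diff(bursts$t), rep(1, 4), tolerance = 0.05)
})

test_that("time-reversing a trajectory negates the motion-induced EMF", {
  dur <- 1
  f <- single_particle_emf(30e-9, 0.7, PICKUP, duration = dur, dt = 1e-3,
                           start = -0.35, carrier = "baseband")
  b <- single_particle_emf(30e-9, 0.7, PICKUP, duration = dur, dt = 1e-3,
                           start = -0.35 + 0.7 * dur, direction = -1,
                           carrier = "baseband")
  expect_lt(max(abs(b$v + rev(f$v))), 1e-9 * max(abs(f$v)))
})

test_that("venous traces are reproducible and vanish without motion", {
  a <- venous_noise_emf(500, coil = PICKUP, duration = 2, dt = 1e-3,
                        seed = 8, start = 0.1, carrier = "baseband")
  b <- venous_noise_emf(500, coil = PICKUP, duration = 2, dt = 1e-3,
                        seed = 8, start = 0.1, carrier = "baseband")
  expect_identical(a$v, b$v)
  still <- venous_noise_emf(500, speed = 0, coil = PICKUP, duration = 2,
                            dt = 1e-3, seed = 8, carrier = "baseband")
  expect_true(all(still$v == 0))
})

test_that("snr matches its definition and scales inversely with noise", {
  tr <- single_particle_emf(30e-9, speed = 0, coil = PICKUP,
                            duration = 0.2, dt = 1e-4)
  self <- snr(tr, tr)
  expect_rel_equal(self, max(abs(trace_envelope(tr))) / sqrt(mean(tr$v^2)),
                   1e-12)
  # a pure sinusoid: envelope ~ amplitude, so peak/RMS ~ sqrt(2)
  expect_rel_equal(self, sqrt(2), 0.01)
  noisy <- tr
  noisy$v <- tr$v * 10
  expect_rel_equal(snr(tr, noisy), self / 10, 1e-12)
  silent <- tr
  silent$v <- tr$v * 0
  expect_warning(expect_identical(snr(tr, silent), Inf), "zero RMS")
  coarse <- single_particle_emf(30e-9, 0, PICKUP, duration = 0.2, dt = 5e-4)
  expect_error(snr(tr, coarse), "sampling step")
})

test_that("arterial bursts stand two orders of magnitude above venous noise", {
  res <- counterflow_snr(seed = 1)
  expect_gt(res$snr, 100)
  # with the full AC carrier both streams share the drive tone and the
  # ratio collapses - the separation lives in the baseband component
  res_ac <- counterflow_snr(seed = 1, carrier = "ac")
  expect_lt(res_ac$snr, res$snr)
})

test_that("sampling must resolve the drive carrier", {
  expect_error(single_particle_emf(30e-9, 0.7, PICKUP, duration = 1,
                                   dt = 0.01), "aliasing")
})

test_that("traces carry complete, uniform metadata", {
  tr <- venous_noise_emf(100, coil = PICKUP, duration = 1, dt = 1e-3,
                         seed = 3, start = 0.05, carrier = "baseband")
  expect_equal(unique(round(diff(tr$t), 12)), 1e-3)
  meta <- trace_meta(tr)
  expect_equal(meta$n_particles, 100)
  expect_equal(meta$seed, 3L)
  expect_equal(meta$carrier, "baseband")
  expect_true(all(is.finite(tr$v)))
})
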