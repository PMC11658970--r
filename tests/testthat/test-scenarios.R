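# Seeded scenario generation: determinism, schedule structure, invariants.

test_that("pulsed generation produces the configured bursts deterministically", {
  cfg <- scenario_config(seed = 11, mode = "pulsed", n_particles = 1000,
                         duration = 3, pulse_rate = 1,
                         emission_window = 0.05)
  ens <- generate_pulse_ensemble(cfg)
  expect_equal(nrow(ens), 3000)
  # three disjoint emission clusters inside their windows
  for (k in 0:2) {
    in_window <- ens$t_emit >= k & ens$t_emit <= k + 0.05
    expect_equal(sum(in_window), 1000)
  }
  ens2 <- generate_pulse_ensemble(cfg)
  expect_identical(as.data.frame(ens), as.data.frame(ens2))
  ens3 <- generate_pulse_ensemble(modifyList(cfg, list(seed = 12L)))
  expect_false(identical(ens$t_emit, ens3$t_emit))
})

test_that("pulsed generation handles empty and overlapping configurations", {
  cfg0 <- scenario_config(seed = 1, mode = "pulsed", n_particles = 0,
                          duration = 3)
  expect_equal(nrow(generate_pulse_ensemble(cfg0)), 0)
  cfg_overlap <- scenario_config(seed = 1, mode = "pulsed",
                                 n_particles = 5, duration = 2,
                                 pulse_rate = 1, emission_window = 1.5)
  expect_warning(generate_pulse_ensemble(cfg_overlap), "overlap")
  expect_error(generate_pulse_ensemble(
    scenario_config(seed = 1, mode = "continuous", n_particles = 5)),
    "pulsed")
})

test_that("continuous generation covers the window at the configured rate", {
  cfg <- scenario_config(seed = 5, mode = "continuous", n_particles = 10000,
                         speed = 0.07, duration = 10, direction = -1,
                         start = 0.35)
  ens <- generate_counterflow_ensemble(cfg)
  expect_equal(nrow(ens), 10000)
  expect_true(all(ens$direction == -1))
  # mean inter-emission gap ~ duration / n
  expect_rel_equal(mean(diff(ens$t_emit)), 10 / 10000, 0.05)
  # exact count scaling
  cfg10 <- modifyList(cfg, list(n_particles = 1000))
  expect_equal(nrow(generate_counterflow_ensemble(cfg10)) * 10, nrow(ens))
  # empty window
  cfg0 <- scenario_config(seed = 5, mode = "continuous", n_particles = 100,
                          duration = 0)
  expect_equal(nrow(generate_counterflow_ensemble(cfg0)), 0)
})

test_that("lead-in pre-fills the stream without changing the emission rate", {
  base <- scenario_config(seed = 9, mode = "continuous", n_particles = 2000,
                          speed = 0.07, duration = 4, direction = -1,
                          start = 0.35)
  pre <- modifyList(base, list(lead_in = 8))
  e0 <- generate_counterflow_ensemble(base)
  e1 <- generate_counterflow_ensemble(pre)
  # rate preserved: total = n * (1 + lead_in / duration)
  expect_equal(nrow(e1), 2000 * (1 + 8 / 4))
  filled <- e1[e1$t_emit == 0, ]
  expect_gt(nrow(filled), 0)
  # pre-filled particles are already advanced downstream of the emitter
  expect_true(all(filled$x0 <= 0.35 + 1e-12))
  expect_true(any(filled$x0 < 0))
  expect_true(all(e1$t_emit >= 0))
  expect_identical(e0$t_emit, generate_counterflow_ensemble(base)$t_emit)
})

test_that("generation is isolated from the global RNG stream", {
  set.seed(777)
  before <- .Random.seed
  invisible(generate_pulse_ensemble(
    scenario_config(seed = 3, mode = "pulsed", n_particles = 50,
                    duration = 2)))
  expect_identical(.Random.seed, before)
})

test_that("generated ensembles satisfy the container invariants", {
  for (seed in 1:5) {
    cfg <- scenario_config(seed = seed, mode = "pulsed",
                           n_particles = 200, duration = 2)
    ens <- generate_pulse_ensemble(cfg)
    expect_false(is.unsorted(ens$t_emit))
    expect_true(all(ens$t_emit >= 0))
    expect_true(all(ens$speed >= 0))
    cfgc <- scenario_config(seed = seed, mode = "continuous",
                            n_particles = 500, duration = 2, lead_in = 1)
    ensc <- generate_counterflow_ensemble(cfgc)
    expect_false(is.unsorted(ensc$t_emit))
    expect_true(all(ensc$speed >= 0))
  }
})

test_that("presets load from the shipped configs and derive consistently", {
  art <- scenario_preset("arterial_pulses", seed = 2)
  expect_equal(art$n_particles, 1000)
  expect_equal(art$speed, 0.7)
  expect_equal(art$pulse_rate, 1)
  ven <- scenario_preset("venous_counterflow", seed = 2)
  expect_equal(ven$n_particles, 10000)
  expect_equal(ven$speed, 0.07)
  expect_equal(ven$direction, -1)
  single <- scenario_preset("single_arterial", seed = 2)
  expect_equal(single$n_particles, 1)
  # the derived venous rule: 10x the count at a tenth the speed, reversed
  derived <- venous_from_arterial(art)
  expect_equal(derived$n_particles, 10 * art$n_particles)
  expect_equal(derived$speed, art$speed / 10)
  expect_equal(derived$direction, -art$direction)
})
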