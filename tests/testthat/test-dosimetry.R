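# Detection limits, dose conversion and safety classification.

test_that("stroke volume and regional pulse volumes follow the physiology", {
  p <- physiology_params()
  expect_equal(stroke_volume(p), 5000 / 70)          # 71.43 mL
  expect_equal(stroke_volume(physiology_params(heart_rate = 100)), 50)
  expect_equal(stroke_volume(physiology_params(cardiac_output = 10)),
               2 * stroke_volume(p))
  expect_rel_equal(pulse_volume(p, "forearm"), 1.64, 0.01)
  expect_rel_equal(pulse_volume(p, "leg"), 4.64, 0.01)
  expect_equal(pulse_volume(physiology_params(forearm_fraction = 0),
                            "forearm"), 0)
  expect_error(pulse_volume(p, "torso"))
})

test_that("required counts follow the inverse-volume law", {
  vm <- voltmeter_spec("test", 1e-10)
  c5 <- required_particle_count(5e-9, vm, coil = PICKUP)
  c100 <- required_particle_count(100e-9, vm, coil = PICKUP)
  # d^-3: the 5 nm / 100 nm ratio is 8000 up to ceiling rounding
  expect_lt(abs(c5 / c100 - 8000), 8000 * 1e-4 + 1)
  # independently derived scale: ~5.5e6 30-nm particles at 1e-10 V with the
  # 2000-turn pickup (n mu0 m / 2R * 2 pi f with m ~ 2.3e-18 A m^2)
  c30 <- required_particle_count(30e-9, vm, coil = PICKUP)
  expect_rel_equal(c30, 5.5e6, 0.15)
  # halving the sensitivity halves the count (to ceiling rounding)
  c30_half <- required_particle_count(30e-9, voltmeter_spec("t", 5e-11),
                                      coil = PICKUP)
  expect_lt(abs(c30_half - c30 / 2), 1.1)
  # count * d^3 is diameter-independent
  ds <- c(5e-9, 30e-9, 50e-9, 100e-9)
  prod <- vapply(ds, function(d)
    required_particle_count(d, vm, coil = PICKUP) * d^3, numeric(1))
  # constant up to ceiling rounding of the smallest count (~1e5)
  expect_lt(diff(range(prod)) / mean(prod), 1e-4)
  expect_error(
    required_particle_count(30e-9, vm, coil = PICKUP,
                            drive = drive_field(0, 50)), "undetectable")
})

test_that("mass and concentration conversion is exact and consistent", {
  z <- particles_to_mass_concentration(0, 30e-9, volume_ml = 1.5)
  expect_equal(z$mass_ug, 0)
  expect_equal(z$conc_ug_ml, 0)
  # hand value: 2e6 * 5180 kg/m^3 * (pi/6)(30 nm)^3 = 1.4646e-13 kg
  mc <- particles_to_mass_concentration(2e6, 30e-9, volume_ml = 1.5)
  expect_rel_equal(mc$mass_ug, 1.4646e-4, 1e-4)
  expect_rel_equal(mc$conc_ug_ml, 9.764e-5, 1e-3)
  # linear in count, cubic in diameter
  mc2 <- particles_to_mass_concentration(4e6, 30e-9, volume_ml = 1.5)
  expect_equal(mc2$mass_ug, 2 * mc$mass_ug)
  mc3 <- particles_to_mass_concentration(2e6, 60e-9, volume_ml = 1.5)
  expect_equal(mc3$mass_ug, 8 * mc$mass_ug)
})

test_that("safety classification is three-way with closed safe boundaries", {
  expect_equal(classify_safety(c(0, 10, 10.1, 100, 101)),
               c("safe", "safe", "potentially_toxic", "potentially_toxic",
                 "toxic"))
  expect_error(classify_safety(1, safe_max = 100, toxic_min = 10),
               "safe_max")
  expect_error(classify_safety(-1), "conc")
})

test_that("sensitivity sweep reproduces the single-pair computation", {
  plan <- sensitivity_sweep(30e-9, 1e-10, coil = PICKUP)
  expect_equal(nrow(plan), 1)
  expect_equal(plan$count,
               required_particle_count(30e-9, voltmeter_spec("x", 1e-10),
                                       coil = PICKUP))
  mc <- particles_to_mass_concentration(plan$count, 30e-9,
                                        volume_ml = attr(plan, "volume_ml"))
  expect_equal(plan$mass_ug, mc$mass_ug)
})

test_that("sweep rows are monotone in size and sensitivity", {
  ds <- c(5e-9, 30e-9, 50e-9, 100e-9)
  ss <- c(1e-12, 1e-8, 1e-6)
  plan <- sensitivity_sweep(ds, ss)
  for (s in ss) {
    rows <- plan[plan$sensitivity_v == s, ]
    expect_true(all(diff(rows$count) < 0))    # bigger particles, fewer needed
  }
  for (d in ds) {
    rows <- plan[plan$diameter_nm == d * 1e9, ]
    expect_true(all(diff(rows$count) > 0))    # looser voltmeter, more needed
  }
  # mass per detection is diameter-independent at fixed sensitivity
  # (up to ceiling rounding of the smallest counts)
  for (s in ss) {
    rows <- plan[plan$sensitivity_v == s, ]
    expect_lt(diff(range(rows$mass_ug)) / mean(rows$mass_ug), 1e-4)
  }
})

test_that("the voltmeter ladder spans safe through toxic at default settings", {
  plan <- sensitivity_sweep(c(5e-9, 30e-9), c(1e-12, 1e-6))
  squid <- plan[plan$sensitivity_v == 1e-12, ]
  expect_true(all(squid$safety == "safe"))
  coarse <- plan[plan$sensitivity_v == 1e-6, ]
  expect_true(all(coarse$safety %in% c("potentially_toxic", "toxic")))
})

test_that("equal mass gives volume-ratio concentrations across regions", {
  p <- physiology_params()
  plan_f <- sensitivity_sweep(30e-9, 1e-8, region = "forearm")
  plan_l <- sensitivity_sweep(30e-9, 1e-8, region = "leg")
  expect_equal(plan_f$mass_ug, plan_l$mass_ug)
  expect_rel_equal(plan_l$conc_ug_ml / plan_f$conc_ug_ml,
                   pulse_volume(p, "forearm") / pulse_volume(p, "leg"),
                   1e-9)
})
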