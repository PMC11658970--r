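# shared fixtures: materials, coils, and the drive-field operating point

iron <- mnp_material("iron_oxide")
cobalt <- mnp_material("cobalt_ferrite")

H_DRIVE <- oe_to_am(2299.1)          # mains-solenoid field strength, A/m
PICKUP <- coil_spec(0.05, 2000)      # pickup used for flow simulations
DRIVE40 <- coil_spec(0.05, 40, 0.10, drive_ac_voltage(220, 50),
                     role = "drive")

# coarse loops are enough for qualitative loop-shape checks
quick_loop <- function(mat, H_max = 2e5, n_steps = 300L, ...) {
  ja_loop(mat, H_max = H_max, n_steps = n_steps, ...)
}

# cobalt ferrite's interdomain coupling field alpha * Ms ~ 3.4e7 A/m dwarfs
# the 2e5 A/m sweep used for iron oxide: reversing its magnetization needs a
# field of that order, so loop-shape checks sweep to 5e7 A/m (and may use a
# coarser marcher substep, still well below the a and k scales)
loop_fixture <- function(mat, ...) {
  if (mat$name == "cobalt_ferrite")
    quick_loop(mat, H_max = 5e7, he_step = 2.5e4, ...)
  else
    quick_loop(mat, ...)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected), tol * abs(expected))
}
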