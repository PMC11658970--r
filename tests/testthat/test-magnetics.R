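# Magnetization models: Langevin kernel, anhysteretic solve, scalar
# Jiles-Atherton integration, and per-particle moments.

test_that("Langevin function matches exact values, limits and symmetry", {
  expect_identical(langevin(0), 0)
  # coth(1) - 1 = (e^2 + 1)/(e^2 - 1) - 1, evaluated independently
  expect_equal(langevin(1), 0.313035285499331, tolerance = 1e-12)
  expect_gte(langevin(1e6), 0.999999)
  x <- c(1e-6, 1e-4, 0.01, 0.5, 1, 3, 10, 100)
  expect_equal(langevin(-x), -langevin(x), tolerance = 1e-12)
  # series/analytic switchover is continuous
  expect_equal(langevin(1.0000001e-4), langevin(0.9999999e-4),
               tolerance = 1e-6)
  # derivative consistent with central differences
  h <- 1e-6
  num <- (langevin(x + h) - langevin(x - h)) / (2 * h)
  expect_equal(langevin_deriv(x), num, tolerance = 1e-6)
  expect_equal(langevin_deriv(0), 1 / 3)
})

test_that("anhysteretic magnetization solves the self-consistent equation", {
  expect_identical(anhysteretic_magnetization(0, iron), 0)

  # independent check: dense scan of the residual f(M) = M - Ms L((H+aM)/a)
  # brackets the root without using the solver
  H <- H_DRIVE
  M_grid <- seq(-iron$Ms, iron$Ms, length.out = 200001)
  f <- M_grid - iron$Ms * langevin((H + iron$alpha * M_grid) / iron$a)
  i <- which(f[-1] * f[-length(f)] <= 0)[1]
  M_scan <- M_grid[i] - f[i] * (M_grid[i + 1] - M_grid[i]) / (f[i + 1] - f[i])
  M_solved <- anhysteretic_magnetization(H, iron)
  expect_rel_equal(M_solved, M_scan, 1e-8)
  expect_rel_equal(M_solved, 1.86e5, 0.005)

  # odd symmetry across a field sweep
  Hs <- c(1e3, 1e4, 1e5, 5e5)
  expect_equal(anhysteretic_magnetization(-Hs, iron),
               -anhysteretic_magnetization(Hs, iron), tolerance = 1e-10)

  # residual of the returned solution is at solver tolerance
  resid <- M_solved - iron$Ms *
    langevin((H + iron$alpha * M_solved) / iron$a)
  expect_lt(abs(resid), 1e-8 * iron$Ms)

  # strongly coupled mean field has no unique solution
  expect_error(anhysteretic_magnetization(1e4, cobalt), "multivalued")
})

test_that("fully reversible limit (c = 1) reproduces the anhysteretic curve", {
  mat <- mnp_material("iron_oxide", c = 1)
  loop <- quick_loop(mat)
  M_an <- anhysteretic_magnetization(loop$H, mat)
  expect_lt(max(abs(loop$M - M_an)), 1e-3 * mat$Ms)
  # loop area ~ 0: descending and ascending branches coincide
  desc <- loop[loop$branch == "descending" & loop$cycle == 2, ]
  asc <- loop[loop$branch == "ascending" & loop$cycle == 2, ]
  on_asc <- approx(asc$H, asc$M, xout = desc$H)$y
  expect_lt(max(abs(desc$M - on_asc), na.rm = TRUE), 1e-3 * mat$Ms)
})

test_that("computed loops satisfy bounds, closure and odd symmetry", {
  for (mat in list(iron, cobalt)) {
    loop <- loop_fixture(mat)
    expect_true(all(abs(loop$M) <= mat$Ms * (1 + 1e-12)))
    expect_lt(loop_closure_error(loop), 0.01)
    # odd symmetry of the saturated loop: M(-H) descending = -M(H) ascending
    desc <- loop[loop$branch == "descending" & loop$cycle == 2, ]
    asc <- loop[loop$branch == "ascending" & loop$cycle == 2, ]
    M_desc_at <- approx(desc$H, desc$M, xout = -asc$H)$y
    expect_lt(max(abs(M_desc_at + asc$M), na.rm = TRUE), 0.01 * mat$Ms)
  }
})

test_that("iron oxide shows no practical hysteresis; cobalt ferrite does", {
  fe_loop <- loop_fixture(iron)
  co_loop <- loop_fixture(cobalt)
  rem_fe <- remanence(fe_loop) / iron$Ms
  rem_co <- remanence(co_loop) / cobalt$Ms
  hc_fe <- coercivity(fe_loop)
  hc_co <- coercivity(co_loop)
  expect_lt(rem_fe, 0.05)            # superparamagnetic-like
  expect_gt(rem_co, 5 * rem_fe)      # pronounced remanence
  expect_gt(hc_co, 5 * hc_fe)        # high coercivity
})

test_that("classic dM/dH formulation agrees when stable and fails loudly when not", {
  M_he <- initial_magnetization(H_DRIVE, iron)
  M_cl <- initial_magnetization(H_DRIVE, iron, formulation = "classic")
  expect_lt(abs(M_he - M_cl), 0.03 * iron$Ms)
  expect_error(ja_loop(cobalt, H_max = 2e5, n_steps = 150,
                       formulation = "classic"), "H =")
})

test_that("integration converges under step halving", {
  m1 <- initial_magnetization(H_DRIVE, iron, he_step = 2000)
  m2 <- initial_magnetization(H_DRIVE, iron, he_step = 1000)
  expect_rel_equal(m1, m2, 1e-4)
})

test_that("single-particle moments hit the reported scale and scale as d^3", {
  m5 <- particle_moment(5e-9, H_DRIVE, iron, unit = "emu")
  m30 <- particle_moment(30e-9, H_DRIVE, iron, unit = "emu")
  m100 <- particle_moment(100e-9, H_DRIVE, iron, unit = "emu")
  expect_rel_equal(m5, 1.15e-17, 0.15)
  expect_rel_equal(m30, 2.3e-15, 0.15)
  expect_rel_equal(m100, 9.19e-14, 0.15)
  # exact volume scaling at equal field and material
  expect_equal(m100 / m5, 8000, tolerance = 1e-12)
  # saturation cap: Ms * V for d = 100 nm is 1.50796e-13 emu (hand value)
  expect_lte(m100, 1.50797e-13)
  expect_error(particle_moment(250e-9, H_DRIVE, iron), "diameter")
  expect_error(particle_moment(0, H_DRIVE, iron), "diameter")
})

test_that("unit conversions round-trip and match the CGS definitions", {
  x <- c(1e-6, 1, 2299.1, 1e7)
  expect_equal(am_to_oe(oe_to_am(x)), x, tolerance = 1e-12)
  expect_equal(emu_to_am2(am2_to_emu(x)), x, tolerance = 1e-12)
  expect_equal(oe_to_am(1), 1e3 / (4 * pi), tolerance = 1e-15)
  expect_equal(am2_to_emu(1), 1e3)
})

test_that("M-H curves export to CSV in either field unit", {
  loop <- quick_loop(iron, n_steps = 120)
  f <- tempfile(fileext = ".csv")
  write_mh_csv(loop, f, field_unit = "Oe")
  df <- read.csv(f)
  expect_named(df, c("H_Oe", "M", "branch", "cycle"))
  expect_equal(max(df$H_Oe), am_to_oe(2e5), tolerance = 1e-9)
  unlink(f)
})

test_that("ja_loop validates its inputs", {
  expect_error(ja_loop(iron, H_max = -1), "H_max")
  expect_error(ja_loop(iron, H_max = 1e5, n_steps = 50), "n_steps")
})
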