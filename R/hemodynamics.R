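#' Carreau viscosity parameters
#'
#' The Carreau model interpolates between a zero-shear plateau `eta0` and an
#' infinite-shear plateau `eta_inf`:
#' `eta(g) = eta_inf + (eta0 - eta_inf) * (1 + (lambda g)^2)^((n - 1)/2)`.
#' Defaults are the standard whole-blood fit (shear-thinning, n < 1).
#'
#' @param eta0 zero-shear viscosity, Pa s (default 0.056).
#' @param eta_inf infinite-shear viscosity, Pa s (default 0.0035).
#'   Must satisfy `eta0 > eta_inf > 0`.
#' @param lambda relaxation time constant, s (default 3.313).
#' @param n_index power-law index in (0, 1\] (default 0.3568).
#' @return an object of class `carreau_params`.
#' @export
#' @examples
#' blood <- carreau_params()
#' carreau_viscosity(c(0, 1, 1e4), blood)
carreau_params <- function(eta0 = 0.056, eta_inf = 0.0035,
                           lambda = 3.313, n_index = 0.3568) {
  check_num(eta0, "eta0", min = 0, strict_min = TRUE)
  check_num(eta_inf, "eta_inf", min = 0, strict_min = TRUE)
  if (eta0 <= eta_inf) stop_bad("eta0", "must exceed eta_inf")
  check_num(lambda, "lambda", min = 0, strict_min = TRUE)
  check_num(n_index, "n_index", min = 0, max = 1, strict_min = TRUE)
  structure(list(eta0 = eta0, eta_inf = eta_inf, lambda = lambda,
                 n_index = n_index),
            class = "carreau_params")
}

#' Carreau shear-thinning viscosity
#'
#' @param shear_rate shear rate, 1/s (>= 0; vectorized).
#' @param p a [carreau_params()] object.
#' @return dynamic viscosity, Pa s; non-increasing in shear rate and bounded
#'   in \[`eta_inf`, `eta0`\].
#' @export
carreau_viscosity <- function(shear_rate, p = carreau_params()) {
  stopifnot(inherits(p, "carreau_params"))
  if (any(shear_rate < 0)) stop_bad("shear_rate", "must be >= 0")
  p$eta_inf + (p$eta0 - p$eta_inf) *
    (1 + (p$lambda * shear_rate)^2)^((p$n_index - 1) / 2)
}

# d eta / d gamma, used by the vectorized Newton solver
carreau_viscosity_deriv <- function(g, p) {
  (p$eta0 - p$eta_inf) * (p$n_index - 1) * p$lambda^2 * g *
    (1 + (p$lambda * g)^2)^((p$n_index - 3) / 2)
}

#' Cylindrical vessel specification
#'
#' @param radius vessel radius, m (> 0; default 2 mm, forearm-artery scale —
#'   the vessel caliber is a model choice, not a measured input).
#' @param length vessel segment length, m (> 0).
#' @param mean_velocity mean (bulk) inlet velocity, m/s (>= 0;
#'   default 7.1 cm/s).
#' @return an object of class `vessel_spec`.
#' @export
vessel_spec <- function(radius = 2e-3, length = 0.1, mean_velocity = 0.071) {
  check_num(radius, "radius", min = 0, strict_min = TRUE)
  check_num(length, "length", min = 0, strict_min = TRUE)
  check_num(mean_velocity, "mean_velocity", min = 0)
  structure(list(radius = radius, length = length,
                 mean_velocity = mean_velocity),
            class = "vessel_spec")
}

# shear rate at wall stress tau for Carreau fluid: solve eta(g) * g = tau.
# Vectorized bisection on [tau/eta0, tau/eta_inf]; the map g -> eta(g) g is
# strictly increasing so the bracket is tight and convergence monotone.
carreau_shear_from_stress <- function(tau, p, iters = 80L) {
  lo <- tau / p$eta0
  hi <- tau / p$eta_inf
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    f <- carreau_viscosity(mid, p) * mid - tau
    up <- f < 0
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  (lo + hi) / 2
}

#' Steady laminar velocity profile with Carreau viscosity
#'
#' Solves fully developed pressure-driven flow in a straight tube for a
#' Carreau fluid. For a given axial pressure gradient `G` the shear stress is
#' `tau(r) = G r / 2`; the local shear rate follows by inverting
#' `eta(g) g = tau` (monotone, solved by vectorized bisection) and the axial
#' velocity by integrating the shear rate inward from the no-slip wall.
#' The pressure gradient is then adjusted (bracketed root search) until the
#' area-averaged velocity matches `vessel$mean_velocity` to a relative
#' tolerance of 1e-6. In the Newtonian limit (`eta0 = eta_inf`) the result
#' is the Poiseuille parabola with centerline velocity twice the mean;
#' shear-thinning blood gives a flatter profile (centerline/mean < 2).
#'
#' @param vessel a [vessel_spec()].
#' @param p a [carreau_params()] object.
#' @param n_radial number of radial samples returned (>= 16; default 64).
#' @param n_internal internal quadrature grid (default 4097 nodes).
#' @return a data.frame with columns `r` (m) and `u` (m/s), with the solved
#'   pressure gradient (Pa/m) and achieved mean velocity as attributes.
#' @export
#' @examples
#' prof <- velocity_profile(vessel_spec(), carreau_params(), n_radial = 32)
#' max(prof$u) / attr(prof, "mean_velocity")   # < 2: blunted profile
velocity_profile <- function(vessel, p = carreau_params(), n_radial = 64L,
                             n_internal = 4097L) {
  stopifnot(inherits(vessel, "vessel_spec"), inherits(p, "carreau_params"))
  if (n_radial < 16L) stop_bad("n_radial", "must be >= 16")
  R <- vessel$radius
  vbar <- vessel$mean_velocity
  if (vbar == 0) {
    r <- seq(0, R, length.out = n_radial)
    out <- data.frame(r = r, u = rep(0, n_radial))
    return(structure(out, pressure_gradient = 0, mean_velocity = 0,
                     class = c("velocity_profile", "data.frame")))
  }
  r <- seq(0, R, length.out = n_internal)

  mean_for_G <- function(G, return_profile = FALSE) {
    gam <- carreau_shear_from_stress(G * r / 2, p)
    U <- pracma::cumtrapz(r, gam)        # int_0^r gamma dr'
    u <- as.numeric(U[length(U)] - U)    # u(r) = int_r^R gamma dr'
    mean_u <- 2 / R^2 * pracma::trapz(r, u * r)
    if (return_profile) list(u = u, mean_u = mean_u) else mean_u
  }

  # mean velocity is increasing in G and bounded by the Newtonian solutions
  # at eta_inf and eta0, giving a rigorous bracket
  G_lo <- 8 * p$eta_inf * vbar / R^2
  G_hi <- 8 * p$eta0 * vbar / R^2
  root <- uniroot(function(G) mean_for_G(G) - vbar,
                  lower = G_lo * 0.999, upper = G_hi * 1.001,
                  tol = G_lo * 1e-10, maxiter = 200L)
  G <- root$root
  sol <- mean_for_G(G, return_profile = TRUE)
  if (abs(sol$mean_u - vbar) > 1e-6 * vbar)
    stop("velocity-profile solver did not reach the inlet mean velocity ",
         sprintf("(relative error %.2e)", abs(sol$mean_u - vbar) / vbar),
         call. = FALSE)

  r_out <- seq(0, R, length.out = n_radial)
  u_out <- stats::spline(r, sol$u, xout = r_out)$y
  u_out[n_radial] <- 0   # enforce no-slip at the sampled wall node
  out <- data.frame(r = r_out, u = u_out)
  structure(out, pressure_gradient = G, mean_velocity = sol$mean_u,
            class = c("velocity_profile", "data.frame"))
}

#' Kinematic particle advection along the vessel axis
#'
#' Straight-line motion at a constant assigned speed, the transport model
#' used for the induced-voltage synthesis (forces on the particles are
#' neglected; position is all the EMF math needs). Optionally a particle may
#' instead be assigned the local profile velocity at a sampled radial
#' position via [sample_profile_speed()].
#'
#' @param start starting axial position, m.
#' @param speed particle speed, m/s (>= 0).
#' @param t time or vector of times, s (>= 0).
#' @param direction +1 (with the x-axis) or -1 (counter-flow).
#' @return axial position(s) at `t`, m.
#' @export
#' @examples
#' advect(0, 0.7, 0.1)   # 0.07 m downstream
advect <- function(start, speed, t, direction = 1) {
  check_num(speed, "speed", min = 0)
  if (any(t < 0)) stop_bad("t", "must be >= 0")
  if (!direction %in% c(-1, 1)) stop_bad("direction", "must be +1 or -1")
  start + direction * speed * t
}

#' Sample a particle speed from a velocity profile
#'
#' Draws a radial position uniform in the tube cross-section (density
#' proportional to r) and returns the profile velocity there.
#'
#' @param profile a [velocity_profile()] result.
#' @param n number of speeds to draw.
#' @return numeric vector of speeds, m/s.
#' @export
sample_profile_speed <- function(profile, n = 1L) {
  stopifnot(inherits(profile, "velocity_profile"))
  R <- max(profile$r)
  rr <- R * sqrt(runif(n))
  approx(profile$r, profile$u, xout = rr)$y
}
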