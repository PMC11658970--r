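#' Coil geometry and electrical drive
#'
#' Describes a circular coil by radius, turn count and winding height, plus
#' an optional electrical drive. Drive coils are powered by an AC voltage
#' (mains) or an AC current; search coils are passive pickups.
#'
#' @param radius coil radius R, m (> 0).
#' @param turns number of turns n (>= 1).
#' @param height winding height h, m (>= 0; > 0 required for solenoid field
#'   calculations).
#' @param drive `NULL` for a passive coil, or a list from
#'   [drive_ac_voltage()] / [drive_ac_current()].
#' @param role `"search"` (default) or `"drive"`.
#' @return an object of class `coil_spec`.
#' @export
#' @examples
#' # the mains-powered drive coil: 5 cm radius, 10 cm height
#' drv <- coil_spec(0.05, 40, 0.10, drive_ac_voltage(220, 50), role = "drive")
#' # the pickup used for particle signals: 5 cm radius, 2000 turns
#' pick <- coil_spec(0.05, 2000)
coil_spec <- function(radius, turns, height = 0,
                      drive = NULL, role = c("search", "drive")) {
  role <- match.arg(role)
  check_num(radius, "radius", min = 0, strict_min = TRUE)
  check_num(turns, "turns", min = 1)
  check_num(height, "height", min = 0)
  if (!is.null(drive)) {
    if (!is.list(drive) || is.null(drive$type))
      stop_bad("drive", "must come from drive_ac_voltage()/drive_ac_current()")
    check_num(drive$value, "drive$value", min = 0)
    check_num(drive$freq, "drive$freq", min = 0, strict_min = TRUE)
  }
  structure(list(radius = radius, turns = turns, height = height,
                 drive = drive, role = role),
            class = "coil_spec")
}

#' @rdname coil_spec
#' @param volts RMS drive voltage, V (mains convention: 220 V RMS).
#' @param freq drive frequency, Hz.
#' @export
drive_ac_voltage <- function(volts, freq) {
  list(type = "voltage", value = volts, freq = freq)
}

#' @rdname coil_spec
#' @param amps drive current, A.
#' @export
drive_ac_current <- function(amps, freq) {
  list(type = "current", value = amps, freq = freq)
}

#' @export
print.coil_spec <- function(x, ...) {
  drv <- if (is.null(x$drive)) "passive" else
    sprintf("%s %.4g %s @ %g Hz", x$drive$type, x$drive$value,
            if (x$drive$type == "voltage") "V" else "A", x$drive$freq)
  cat(sprintf("<coil_spec: %s, R = %.3g m, n = %g, h = %.3g m, %s>\n",
              x$role, x$radius, x$turns, x$height, drv))
  invisible(x)
}

# Copper resistivity at 20 C, Ohm m
RHO_COPPER <- 1.68e-8

# Wire cross-section calibrated so the default mains-driven coil (220 V,
# 50 Hz, R = 5 cm, h = 10 cm) produces a 2299.1 Oe field; this is a model
# calibration (the wire gauge is a free design parameter), corresponding to
# ~0.44 mm^2, between AWG 20 and 21.
WIRE_AREA_DEFAULT <- 4.389191e-7

#' Field of a voltage-driven solenoid
#'
#' A solenoid wound from wire of cross-section `A_w` and resistivity `rho`
#' draws `I = V / (rho * n * 2 pi R / A_w)` and produces `H = n I / h`.
#' The turn count cancels: `H = V A_w / (rho * 2 pi R * h)`, so for a fixed
#' geometry and mains drive the achievable field is set by the wire gauge
#' alone. The drive voltage is interpreted as RMS; the returned field carries
#' the same convention (use `sqrt(2) * H` for the instantaneous amplitude if
#' needed).
#'
#' @param coil a [coil_spec()] with an AC-voltage drive and `height > 0`.
#' @param wire_area wire cross-section, m^2 (> 0). Default is the calibrated
#'   `WIRE_AREA_DEFAULT` (~0.44 mm^2).
#' @param resistivity wire resistivity, Ohm m (default copper at 20 C).
#' @param unit `"Am"` (default) or `"Oe"`.
#' @return field strength H in the requested unit.
#' @export
#' @examples
#' drv <- coil_spec(0.05, 40, 0.10, drive_ac_voltage(220, 50), role = "drive")
#' solenoid_field(drv, unit = "Oe")   # 2299.1 Oe, independent of turns
solenoid_field <- function(coil, wire_area = WIRE_AREA_DEFAULT,
                           resistivity = RHO_COPPER,
                           unit = c("Am", "Oe")) {
  stopifnot(inherits(coil, "coil_spec"))
  unit <- match.arg(unit)
  if (is.null(coil$drive) || coil$drive$type != "voltage")
    stop_bad("drive", "must be an AC voltage drive for solenoid_field()")
  if (coil$height <= 0) stop_bad("height", "must be > 0 for a solenoid")
  check_num(wire_area, "wire_area", min = 0, strict_min = TRUE)
  check_num(resistivity, "resistivity", min = 0, strict_min = TRUE)
  H <- coil$drive$value * wire_area /
    (resistivity * 2 * pi * coil$radius * coil$height)
  if (unit == "Oe") am_to_oe(H) else H
}

#' Wire cross-section needed for a target solenoid field
#'
#' Inverts [solenoid_field()] for the wire gauge: the cross-section that
#' makes the given voltage-driven coil reach `H_target`.
#'
#' @inheritParams solenoid_field
#' @param H_target target field, A/m.
#' @return wire cross-section, m^2.
#' @export
calibrate_wire_area <- function(coil, H_target, resistivity = RHO_COPPER) {
  stopifnot(inherits(coil, "coil_spec"))
  check_num(H_target, "H_target", min = 0)
  H_target * resistivity * 2 * pi * coil$radius * coil$height /
    coil$drive$value
}

#' Flux of a centered axial dipole through a circular coil
#'
#' For a point dipole of moment `m` at the center of a coil of radius `R`,
#' aligned with the coil axis, the flux threading one turn is
#' `Phi0 = mu0 m / (2 R)` — the closed form of the dipole far-field surface
#' integral over the plane outside the loop.
#'
#' @param m magnetic moment, A m^2 (>= 0; vectorized).
#' @param R coil radius, m (> 0).
#' @return flux per turn, Wb. Linear in `m`, inversely proportional to `R`.
#' @export
#' @examples
#' dipole_flux_center(1, 0.05)   # 1.2566e-5 Wb
dipole_flux_center <- function(m, R) {
  check_num(R, "R", min = 0, strict_min = TRUE)
  if (any(m < 0)) stop_bad("m", "must be >= 0")
  MU0 * m / (2 * R)
}

#' Flux of an on-axis axial dipole through a circular coil
#'
#' Extends [dipole_flux_center()] off-center along the coil axis:
#' `Phi(z) = mu0 m R^2 / (2 (R^2 + z^2)^(3/2))`, which reduces to the
#' centered value at `z = 0` and decays as `1/|z|^3` in the far field.
#'
#' @inheritParams dipole_flux_center
#' @param z axial offset of the dipole from the coil plane, m (vectorized).
#' @return flux per turn, Wb.
#' @export
dipole_flux_axial <- function(m, R, z) {
  check_num(R, "R", min = 0, strict_min = TRUE)
  MU0 * m * R^2 / (2 * (R^2 + z^2)^(3 / 2))
}

#' Biot-Savart quadrature oracle for the dipole flux
#'
#' Integrates the exact point-dipole field over the coil disk by tensor
#' quadrature (Gauss-Legendre radially, trapezoid in angle) and returns the
#' flux through one turn. For a dipole exactly in the coil plane the disk
#' integrand is singular at the dipole, so the flux is instead computed over
#' the exterior of the loop (where the paper-and-pencil closed form also
#' lives) and negated — the dipole's net flux through the full plane is zero.
#'
#' Intended as an independent numerical check of [dipole_flux_center()] and
#' [dipole_flux_axial()]; it shares no code with the closed forms.
#'
#' @param m magnetic moment, A m^2.
#' @param R coil radius, m (> 0).
#' @param z axial position of the dipole, m.
#' @param theta angle between the dipole moment and the coil axis, rad.
#' @param resolution radial quadrature order (default 96); the angular grid
#'   uses `2 * resolution` points.
#' @param check_convergence if `TRUE` (default), re-evaluates at 1.5x the
#'   resolution and errors if the two estimates differ by more than
#'   `conv_tol` relatively.
#' @param conv_tol relative convergence tolerance (default 1e-6).
#' @return flux per turn, Wb.
#' @export
flux_numeric_oracle <- function(m, R, z = 0, theta = 0, resolution = 96L,
                                check_convergence = TRUE, conv_tol = 1e-6) {
  check_num(R, "R", min = 0, strict_min = TRUE)
  check_num(m, "m", min = 0)
  eval_at <- function(nr) {
    nphi <- 2L * nr
    phi <- seq(0, 2 * pi, length.out = nphi + 1L)[-1L]
    wphi <- rep(2 * pi / nphi, nphi)
    mx <- m * cos(theta); my <- m * sin(theta)
    if (abs(z) < 1e-9 * R) {
      # dipole in the coil plane: integrate B_x over the exterior annulus
      # s in (R, Inf), mapped by s = R / u with u in (0, 1)
      gl <- pracma::gaussLegendre(nr, 0, 1)
      u <- gl$x; wu <- gl$w
      total <- 0
      for (i in seq_along(u)) {
        s <- R / u[i]
        # area element s ds dphi with s = R/u: s ds = (R^2 / u^3) du
        py <- s * cos(phi); pz <- s * sin(phi)
        rx <- -z; ry <- py; rz <- pz
        rr <- sqrt(rx^2 + ry^2 + rz^2)
        mdotr <- (mx * rx + my * ry) / rr
        Bx <- MU0 / (4 * pi) * (3 * mdotr * rx / rr - mx) / rr^3
        total <- total + wu[i] * (R^2 / u[i]^3) * sum(Bx * wphi)
      }
      # net dipole flux through the full plane is zero, so
      # disk flux = -exterior flux
      return(-total)
    }
    gl <- pracma::gaussLegendre(nr, 0, R)
    s <- gl$x; ws <- gl$w
    total <- 0
    for (i in seq_along(s)) {
      py <- s[i] * cos(phi); pz <- s[i] * sin(phi)
      rx <- -z; ry <- py; rz <- pz
      rr <- sqrt(rx^2 + ry^2 + rz^2)
      mdotr <- (mx * rx + my * ry) / rr
      Bx <- MU0 / (4 * pi) * (3 * mdotr * rx / rr - mx) / rr^3
      total <- total + ws[i] * s[i] * sum(Bx * wphi)
    }
    total
  }
  val <- eval_at(as.integer(resolution))
  if (check_convergence) {
    val2 <- eval_at(as.integer(ceiling(resolution * 1.5)))
    ref <- max(abs(val2), MU0 * m / (2 * R) * 1e-9, 1e-300)
    if (abs(val - val2) > conv_tol * ref)
      stop("flux quadrature not converged; increase `resolution` ",
           sprintf("(rel. change %.2e)", abs(val - val2) / ref),
           call. = FALSE)
    val <- val2
  }
  val
}

#' Distance from a particle to the coil center
#'
#' Two readings of the particle-to-coil distance are provided. The
#' `"paper_literal"` mode evaluates `sqrt(x^2 + (R + y)^2 + z^2)`, i.e. the
#' distance to a point on the winding displaced by the coil radius in y —
#' the form used by the reference 3D particle model. The `"euclidean"` mode
#' is the plain distance to the coil center, `sqrt(x^2 + y^2 + z^2)`.
#' The EMF synthesis defaults to the euclidean reading (see
#' [single_particle_emf()]); the literal mode is retained for reproduction.
#'
#' @param x,y,z particle coordinates, m (coil axis = x, center at origin).
#' @param R coil radius, m.
#' @param mode `"paper_literal"` (default) or `"euclidean"`.
#' @return distance, m (vectorized over coordinates).
#' @export
#' @examples
#' distance_to_center(0, 0, 0, R = 0.05)                      # 0.05
#' distance_to_center(0, 0, 0, R = 0.05, mode = "euclidean")  # 0
distance_to_center <- function(x, y, z, R,
                               mode = c("paper_literal", "euclidean")) {
  mode <- match.arg(mode)
  if (mode == "paper_literal") sqrt(x^2 + (R + y)^2 + z^2)
  else sqrt(x^2 + y^2 + z^2)
}
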