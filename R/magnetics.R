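#' Langevin function
#'
#' `L(x) = coth(x) - 1/x`, the anhysteretic magnetization kernel of
#' superparamagnetism: a dilute ensemble of thermally fluctuating moments in
#' field `x = mu0 m H / kB T` magnetizes to `Ms L(x)`. The removable
#' singularity at 0 is handled by the series `x/3 - x^3/45` for |x| < 1e-4.
#'
#' @param x numeric vector (dimensionless reduced field).
#' @return `L(x)`, in (-1, 1); odd; `L(x) -> 1` as `x -> Inf`.
#' @export
#' @examples
#' langevin(0)    # 0
#' langevin(1)    # 0.3130353
langevin <- function(x) {
  out <- x
  small <- abs(x) < 1e-4
  out[small] <- x[small] / 3 - x[small]^3 / 45
  xl <- x[!small]
  out[!small] <- 1 / tanh(xl) - 1 / xl
  out
}

#' Derivative of the Langevin function
#'
#' `L'(x) = 1/x^2 - 1/sinh(x)^2`, with the series `1/3 - x^2/15` near zero
#' and the `1/x^2` tail used beyond the range where `sinh` overflows.
#'
#' @param x numeric vector.
#' @return `L'(x)`, in (0, 1/3].
#' @export
langevin_deriv <- function(x) {
  out <- x
  ax <- abs(x)
  small <- ax < 1e-4
  big <- ax > 350            # sinh(x)^2 overflows; csch^2 term < 1e-300
  mid <- !small & !big
  out[small] <- 1 / 3 - x[small]^2 / 15
  out[big] <- 1 / x[big]^2
  out[mid] <- 1 / x[mid]^2 - 1 / sinh(x[mid])^2
  out
}

#' Anhysteretic magnetization
#'
#' Solves the self-consistent anhysteretic equation
#' `M_an = Ms * L((H + alpha * M_an) / a)` by bracketed root finding to a
#' relative tolerance of 1e-10. For materials with `alpha * Ms / (3 a) < 1`
#' (e.g. the iron-oxide preset) the solution is unique; if the mean-field
#' coupling makes the equation multivalued the call fails, since no single
#' anhysteretic value exists.
#'
#' @param H applied field, A/m (vectorized).
#' @param mat a [material_properties()] object.
#' @param tol relative tolerance of the root (default 1e-10).
#' @return anhysteretic magnetization, A/m. Odd in `H`, bounded by `Ms`.
#' @export
#' @examples
#' fe <- mnp_material("iron_oxide")
#' anhysteretic_magnetization(oe_to_am(2299.1), fe)  # ~1.86e5 A/m
anhysteretic_magnetization <- function(H, mat, tol = 1e-10) {
  stopifnot(inherits(mat, "material_properties"))
  if (mat$alpha * mat$Ms / (3 * mat$a) >= 1)
    stop("anhysteretic equation is multivalued for this material ",
         "(alpha * Ms / (3 a) >= 1); no unique solution", call. = FALSE)
  vapply(H, function(h) {
    if (h == 0) return(0)
    f <- function(M) M - mat$Ms * langevin((h + mat$alpha * M) / mat$a)
    # unique root in (-Ms, Ms): f(-Ms) <= 0 <= f(Ms) and f' > 0
    r <- uniroot(f, lower = -mat$Ms, upper = mat$Ms,
                 tol = tol * max(abs(h), mat$a), maxiter = 200L)
    # Newton polish to push below the requested relative tolerance
    M <- r$root
    for (i in 1:5) {
      x <- (h + mat$alpha * M) / mat$a
      fp <- 1 - mat$Ms * langevin_deriv(x) * mat$alpha / mat$a
      step <- (M - mat$Ms * langevin(x)) / fp
      M <- M - step
      if (abs(step) <= tol * max(abs(M), 1)) break
    }
    M
  }, numeric(1))
}

# ---------------------------------------------------------------------------
# Scalar Jiles-Atherton integration.
#
# Default ("effective_field") variant: the irreversible component is driven
# by the effective field He = H + alpha * M,
#     dM_irr/dHe = delta_M * (M_an(He) - M_irr) / (k * delta),
#     M          = c * M_an(He) + (1 - c) * M_irr,
# where delta = sign(dHe) and delta_M clamps the unphysical regime where the
# pinning term would push M_irr away from M_an against the sweep direction.
# Because M is an explicit function of (He, M_irr), the integrator marches in
# He-space and recovers H = He - alpha * M. Whenever alpha * dM/dHe > 1
# (strong mean-field coupling, e.g. the cobalt-ferrite preset) H is not
# monotone in He: the physical quasi-static response is a Barkhausen-like
# avalanche, which the marcher resolves naturally by continuing in He until H
# again reaches the requested waypoint. Waypoints are landed exactly by
# bisecting the final substep.
#
# "classic" variant: the textbook explicit ODE in H,
#     dM/dH = [(1-c) (M_an - M_irr) / (delta k - alpha (M_an - M_irr))
#              + c dM_an/dHe] / [1 - alpha c dM_an/dHe],
# integrated by fixed-step RK4 (the denominator closes the reversible
# He-feedback quasi-statically). Either denominator changes sign for
# strongly coupled materials; that raises an integration-failure error
# reporting the offending H.
# ---------------------------------------------------------------------------

ja_state_m <- function(mat, He, Mirr) {
  man <- mat$Ms * langevin(He / mat$a)
  mat$c * man + (1 - mat$c) * Mirr
}

# single RK4 substep of size h (signed) in He-space; returns new Mirr
ja_substep_he <- function(mat, He, Mirr, h) {
  if (mat$c >= 1 || mat$k == 0) {
    # fully reversible or pin-free: M_irr tracks M_an exactly
    return(mat$Ms * langevin((He + h) / mat$a))
  }
  delta <- sign(h)
  f <- function(He_, Mirr_) {
    d <- mat$Ms * langevin(He_ / mat$a) - Mirr_
    if (delta * d < 0) 0 else d / (mat$k * delta)
  }
  k1 <- f(He, Mirr)
  k2 <- f(He + h / 2, Mirr + h * k1 / 2)
  k3 <- f(He + h / 2, Mirr + h * k2 / 2)
  k4 <- f(He + h, Mirr + h * k3)
  Mirr + h * (k1 + 2 * k2 + 2 * k3 + k4) / 6
}

# March the state from its current (He, Mirr) until H = He - alpha*M reaches
# `target`, moving He in direction `dir`. Lands on the target exactly (to
# `tol`) by shrinking the last substep. Returns the updated state.
ja_march_to <- function(mat, state, target, dir, he_step, tol,
                        max_substeps = 5e6L) {
  He <- state$He; Mirr <- state$Mirr
  Hval <- He - mat$alpha * ja_state_m(mat, He, Mirr)
  n <- 0L
  while (dir * (Hval - target) < -tol) {
    # predictor: local susceptibility g = dM/dHe gives dH/dHe = 1 - alpha*g,
    # so a step of rem / (1 - alpha*g) lands near the waypoint; capped by
    # he_step for resolution and stability in the avalanche regime
    rem <- dir * (target - Hval)
    man <- mat$Ms * langevin(He / mat$a)
    g <- mat$c * mat$Ms / mat$a * langevin_deriv(He / mat$a)
    if (mat$c < 1 && mat$k > 0 && dir * (man - Mirr) > 0)
      g <- g + (1 - mat$c) * abs(man - Mirr) / mat$k
    h <- dir * min(he_step, max(rem / max(1 - mat$alpha * g, 0.05), tol))
    He2 <- He + h
    Mirr2 <- ja_substep_he(mat, He, Mirr, h)
    H2 <- He2 - mat$alpha * ja_state_m(mat, He2, Mirr2)
    if (dir * (H2 - target) > tol) {
      # overshoot: bisect the substep size to land on the waypoint
      lo <- 0; hi <- 1
      for (i in 1:60) {
        mid <- (lo + hi) / 2
        Mm <- ja_substep_he(mat, He, Mirr, h * mid)
        Hm <- (He + h * mid) - mat$alpha * ja_state_m(mat, He + h * mid, Mm)
        if (dir * (Hm - target) >= 0) hi <- mid else lo <- mid
        if ((hi - lo) * he_step < tol) break
      }
      He2 <- He + h * hi
      Mirr2 <- ja_substep_he(mat, He, Mirr, h * hi)
      H2 <- He2 - mat$alpha * ja_state_m(mat, He2, Mirr2)
    }
    He <- He2; Mirr <- Mirr2; Hval <- H2
    n <- n + 1L
    if (n > max_substeps)
      stop("Jiles-Atherton marcher exceeded the substep budget at H = ",
           signif(Hval, 6), " A/m", call. = FALSE)
  }
  list(He = He, Mirr = Mirr)
}

# integrate along a vector of H waypoints (piecewise monotone), returning M
# at each waypoint. he_step defaults to min(a, k>0) / 40: fine enough to
# resolve both the anhysteretic slope and the pinning relaxation scale.
ja_integrate_he <- function(mat, waypoints, he_step = NULL) {
  if (is.null(he_step)) {
    scales <- c(mat$a, if (mat$k > 0) mat$k)
    he_step <- min(scales) / 40
  }
  tol <- he_step * 1e-6 + 1e-9
  state <- list(He = 0, Mirr = 0)
  M <- numeric(length(waypoints))
  Hcur <- 0
  for (i in seq_along(waypoints)) {
    tgt <- waypoints[i]
    dir <- if (tgt >= Hcur) 1 else -1
    state <- ja_march_to(mat, state, tgt, dir, he_step, tol)
    M[i] <- ja_state_m(mat, state$He, state$Mirr)
    Hcur <- tgt
  }
  M
}

# classic explicit ODE in H (RK4, fixed step per waypoint spacing)
ja_integrate_classic <- function(mat, waypoints) {
  M <- numeric(length(waypoints))
  Mcur <- 0; Hcur <- 0
  dMdH <- function(H, M, delta) {
    He <- H + mat$alpha * M
    man <- mat$Ms * langevin(He / mat$a)
    mirr <- if (mat$c < 1) (M - mat$c * man) / (1 - mat$c) else man
    d <- man - mirr
    den_irr <- delta * mat$k - mat$alpha * d
    dman <- mat$Ms / mat$a * langevin_deriv(He / mat$a)
    den_rev <- 1 - mat$alpha * mat$c * dman
    if (delta * den_irr <= 1e-9 * max(mat$k, 1) || den_rev <= 1e-9)
      stop("Jiles-Atherton denominator vanished at H = ", signif(H, 6),
           " A/m (classic formulation); use the effective-field variant",
           call. = FALSE)
    irr <- d / den_irr
    if (delta * d < 0) irr <- 0   # clamp unphysical negative susceptibility
    ((1 - mat$c) * irr + mat$c * dman) / den_rev
  }
  for (i in seq_along(waypoints)) {
    h <- waypoints[i] - Hcur
    if (h != 0) {
      delta <- sign(h)
      k1 <- dMdH(Hcur, Mcur, delta)
      k2 <- dMdH(Hcur + h / 2, Mcur + h * k1 / 2, delta)
      k3 <- dMdH(Hcur + h / 2, Mcur + h * k2 / 2, delta)
      k4 <- dMdH(Hcur + h, Mcur + h * k3, delta)
      Mcur <- Mcur + h * (k1 + 2 * k2 + 2 * k3 + k4) / 6
    }
    Hcur <- waypoints[i]
    M[i] <- Mcur
  }
  M
}

#' Jiles-Atherton magnetization loop
#'
#' Integrates the scalar Jiles-Atherton model from the demagnetized state
#' (H = 0, M = 0) up the initial magnetization curve to `H_max`, then through
#' `cycles` full field cycles `+H_max -> -H_max -> +H_max`, and returns the
#' sampled M-H curve with branch labels. With the default material presets
#' the iron-oxide loop is effectively anhysteretic (superparamagnetic-like)
#' while cobalt ferrite develops a wide square loop.
#'
#' The default formulation drives the irreversible magnetization with the
#' effective field `He = H + alpha * M` and is robust for strongly coupled
#' materials (mean-field avalanches are resolved quasi-statically); the
#' `"classic"` explicit `dM/dH` form is available for comparison but fails
#' with an informative error when its denominator vanishes.
#'
#' @param mat a [material_properties()] object.
#' @param H_max field amplitude of the loop, A/m. Must be > 0.
#' @param n_steps samples per branch (>= 100; default 1000).
#' @param cycles number of full field cycles after the initial curve
#'   (default 2, so loop closure can be checked on the final cycle).
#' @param formulation `"effective_field"` (default) or `"classic"`.
#' @param he_step substep size of the effective-field marcher, A/m; default
#'   `min(a, k)/40`.
#' @return an object of class `mh_curve`: a data.frame with columns `H`,
#'   `M` (A/m), `branch` (`"initial"`, `"descending"`, `"ascending"`) and
#'   `cycle`, with the generating material attached as an attribute.
#' @seealso [remanence()], [coercivity()], [initial_magnetization()],
#'   [write_mh_csv()]
#' @export
#' @examples
#' fe <- mnp_material("iron_oxide")
#' loop <- ja_loop(fe, H_max = 2e5, n_steps = 200)
#' remanence(loop) / fe$Ms        # ~0.01: no practical hysteresis
ja_loop <- function(mat, H_max, n_steps = 1000L, cycles = 2L,
                    formulation = c("effective_field", "classic"),
                    he_step = NULL) {
  stopifnot(inherits(mat, "material_properties"))
  check_num(H_max, "H_max", min = 0, strict_min = TRUE)
  if (n_steps < 100L) stop_bad("n_steps", "must be >= 100")
  if (cycles < 1L) stop_bad("cycles", "must be >= 1")
  formulation <- match.arg(formulation)

  up0 <- seq(0, H_max, length.out = n_steps)
  down <- seq(H_max, -H_max, length.out = 2L * n_steps)[-1]
  up <- seq(-H_max, H_max, length.out = 2L * n_steps)[-1]
  waypoints <- up0
  branch <- rep("initial", length(up0))
  cycle <- rep(0L, length(up0))
  for (cy in seq_len(cycles)) {
    waypoints <- c(waypoints, down, up)
    branch <- c(branch, rep("descending", length(down)),
                rep("ascending", length(up)))
    cycle <- c(cycle, rep(cy, length(down) + length(up)))
  }

  M <- switch(formulation,
    effective_field = ja_integrate_he(mat, waypoints, he_step = he_step),
    classic = ja_integrate_classic(mat, waypoints))

  out <- data.frame(H = waypoints, M = M, branch = branch, cycle = cycle,
                    stringsAsFactors = FALSE)
  structure(out, class = c("mh_curve", "data.frame"),
            material = mat, formulation = formulation, H_max = H_max)
}

#' Initial-curve magnetization at a single field
#'
#' Magnetization reached at field `H` along the initial (virgin)
#' magnetization curve, i.e. integrating the Jiles-Atherton model from the
#' demagnetized state. This is the magnetization state relevant for particles
#' magnetized from rest by the drive coil.
#'
#' @inheritParams ja_loop
#' @param H applied field, A/m (scalar, >= 0 — use odd symmetry for
#'   negative fields).
#' @return magnetization M(H), A/m.
#' @export
.ja_memo <- new.env(parent = emptyenv())

initial_magnetization <- function(H, mat, n_steps = 1000L,
                                  formulation = c("effective_field",
                                                  "classic"),
                                  he_step = NULL) {
  stopifnot(inherits(mat, "material_properties"))
  check_num(H, "H", min = 0)
  formulation <- match.arg(formulation)
  if (H == 0) return(0)
  key <- paste(c(unlist(mat[c("Ms", "a", "k", "c", "alpha")]), H, n_steps,
                 formulation, he_step %||% -1), collapse = "|")
  hit <- .ja_memo[[key]]
  if (!is.null(hit)) return(hit)
  waypoints <- seq(0, H, length.out = max(n_steps, 100L))
  M <- switch(formulation,
    effective_field = ja_integrate_he(mat, waypoints, he_step = he_step),
    classic = ja_integrate_classic(mat, waypoints))
  .ja_memo[[key]] <- tail(M, 1L)
  .ja_memo[[key]]
}

#' Magnetic moment of a single spherical nanoparticle
#'
#' Multiplies the initial-curve magnetization at field `H` by the particle
#' volume `(pi/6) d^3`. Because magnetization is an intensive quantity in
#' this model, the moment scales exactly with `d^3` at fixed field and is
#' capped by the saturation moment `Ms * V`.
#'
#' @param diameter particle diameter, m; must be in (0, 200e-9].
#' @param H applied field, A/m (>= 0); the particle is taken to be
#'   magnetized from rest along the initial curve.
#' @param mat a [material_properties()] object (default iron oxide).
#' @param unit `"Am2"` (SI, default) or `"emu"` (1 A m^2 = 1e3 emu).
#' @param ... passed to [initial_magnetization()] (`n_steps`,
#'   `formulation`, `he_step`).
#' @return magnetic moment in the requested unit.
#' @export
#' @examples
#' fe <- mnp_material("iron_oxide")
#' particle_moment(30e-9, oe_to_am(2299.1), fe, unit = "emu")  # ~2.5e-15 emu
particle_moment <- function(diameter, H, mat = mnp_material("iron_oxide"),
                            unit = c("Am2", "emu"), ...) {
  unit <- match.arg(unit)
  check_num(diameter, "diameter", min = 0, max = 200e-9, strict_min = TRUE)
  check_num(H, "H", min = 0)
  M <- min(initial_magnetization(H, mat, ...), mat$Ms)
  vol <- pi / 6 * diameter^3
  m <- M * vol
  if (unit == "emu") am2_to_emu(m) else m
}

# linear interpolation of a zero crossing y(x) = 0 on a branch; robust to
# flat (saturated) stretches, returns the crossing nearest the sweep start
zero_crossing <- function(x, y) {
  s <- sign(y)
  idx <- which(s[-1] * s[-length(s)] < 0 | y[-1] == 0)
  if (length(idx) == 0L) return(NA_real_)
  i <- idx[1L]
  x[i] + (0 - y[i]) * (x[i + 1L] - x[i]) / (y[i + 1L] - y[i])
}

#' Remanence and coercivity of a computed loop
#'
#' `remanence()` returns |M| at H = 0 and `coercivity()` the |H| at M = 0,
#' both read off the final descending branch of an [ja_loop()] result by
#' linear interpolation.
#'
#' @param curve an `mh_curve` from [ja_loop()].
#' @return a scalar in A/m (`NA` if the branch does not cross zero).
#' @export
remanence <- function(curve) {
  stopifnot(inherits(curve, "mh_curve"))
  seg <- curve[curve$branch == "descending" & curve$cycle == max(curve$cycle), ]
  abs(approx(rev(seg$H), rev(seg$M), xout = 0, ties = "ordered")$y)
}

#' @rdname remanence
#' @export
coercivity <- function(curve) {
  stopifnot(inherits(curve, "mh_curve"))
  seg <- curve[curve$branch == "descending" & curve$cycle == max(curve$cycle), ]
  abs(zero_crossing(seg$H, seg$M))
}

#' Loop-closure error of a computed loop
#'
#' Maximum |M| difference between the last and the preceding cycle, as a
#' fraction of Ms. Values below 0.01 indicate a closed (stationary) loop.
#'
#' @param curve an `mh_curve` from [ja_loop()] with `cycles >= 2`.
#' @return closure error as a fraction of Ms.
#' @export
loop_closure_error <- function(curve) {
  stopifnot(inherits(curve, "mh_curve"))
  mat <- attr(curve, "material")
  last <- max(curve$cycle)
  if (last < 2L) stop("need cycles >= 2 to assess closure", call. = FALSE)
  a <- curve$M[curve$cycle == last]
  b <- curve$M[curve$cycle == last - 1L]
  max(abs(a - b)) / mat$Ms
}

#' Export an M-H curve as CSV
#'
#' Writes a 2-column CSV (plus branch labels) with the field in A/m or Oe.
#'
#' @param curve an `mh_curve` from [ja_loop()].
#' @param path output file path.
#' @param field_unit `"Am"` (default) or `"Oe"`.
#' @return `path`, invisibly.
#' @export
write_mh_csv <- function(curve, path, field_unit = c("Am", "Oe")) {
  stopifnot(inherits(curve, "mh_curve"))
  field_unit <- match.arg(field_unit)
  H <- if (field_unit == "Oe") am_to_oe(curve$H) else curve$H
  df <- data.frame(H = H, M = curve$M, branch = curve$branch,
                   cycle = curve$cycle)
  names(df)[1] <- if (field_unit == "Oe") "H_Oe" else "H_Am"
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.mh_curve <- function(x, ...) {
  mat <- attr(x, "material")
  cat(sprintf("<mh_curve: %s, H_max = %.4g A/m, %d samples, %s formulation>\n",
              mat$name, attr(x, "H_max"), nrow(x), attr(x, "formulation")))
  invisible(x)
}

#' @export
plot.mh_curve <- function(x, ...) {
  mat <- attr(x, "material")
  graphics::plot(x$H, x$M, type = "l", xlab = "H (A/m)", ylab = "M (A/m)",
                 main = sprintf("M-H curve: %s", mat$name), ...)
  graphics::abline(h = 0, v = 0, col = "grey70", lty = 3)
  invisible(x)
}
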