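#' Physiological circulation parameters
#'
#' Defaults are textbook resting values: cardiac output 5 L/min, heart rate
#' 70 bpm (stroke volume 71.4 mL) and regional flow fractions of 2.3%
#' (forearm) and 6.5% (leg).
#'
#' @param cardiac_output L/min (> 0).
#' @param heart_rate beats per minute (> 0).
#' @param forearm_fraction,leg_fraction fraction of cardiac output reaching
#'   the region, in \[0, 1).
#' @return an object of class `physiology_params`.
#' @export
physiology_params <- function(cardiac_output = 5, heart_rate = 70,
                              forearm_fraction = 0.023,
                              leg_fraction = 0.065) {
  check_num(cardiac_output, "cardiac_output", min = 0, strict_min = TRUE)
  check_num(heart_rate, "heart_rate", min = 0, strict_min = TRUE)
  check_num(forearm_fraction, "forearm_fraction", min = 0, max = 1)
  check_num(leg_fraction, "leg_fraction", min = 0, max = 1)
  if (forearm_fraction >= 1 || leg_fraction >= 1)
    stop_bad("fractions", "must be < 1")
  structure(list(cardiac_output = cardiac_output, heart_rate = heart_rate,
                 forearm_fraction = forearm_fraction,
                 leg_fraction = leg_fraction),
            class = "physiology_params")
}

#' Stroke volume
#'
#' Blood ejected per heartbeat: cardiac output divided by heart rate.
#'
#' @param p a [physiology_params()].
#' @return stroke volume, mL.
#' @export
#' @examples
#' stroke_volume(physiology_params())   # 71.4 mL
stroke_volume <- function(p = physiology_params()) {
  stopifnot(inherits(p, "physiology_params"))
  p$cardiac_output * 1e3 / p$heart_rate
}

#' Blood volume per arterial pulse reaching a limb region
#'
#' Stroke volume times the regional flow fraction: ~1.6 mL per pulse in the
#' forearm and ~4.6 mL in the leg at default physiology.
#'
#' @param p a [physiology_params()].
#' @param region `"forearm"` or `"leg"`.
#' @return pulse volume, mL.
#' @export
pulse_volume <- function(p = physiology_params(),
                         region = c("forearm", "leg")) {
  region <- match.arg(region)
  sv <- stroke_volume(p)
  frac <- switch(region, forearm = p$forearm_fraction, leg = p$leg_fraction)
  sv * frac
}

#' Voltmeter specification and presets
#'
#' A voltmeter is characterized by the minimum induced voltage it resolves.
#' The presets span the instrument ladder from a SQUID magnetometer readout
#' (1e-12 V) through a laboratory nanovoltmeter (1e-8 V) to a benchtop
#' 6.5-digit multimeter (1e-6 V).
#'
#' @param name instrument label.
#' @param sensitivity minimum detectable voltage, V (> 0).
#' @return a `voltmeter_spec`; `voltmeter_presets()` returns a named list of
#'   the three standard instruments.
#' @export
voltmeter_spec <- function(name, sensitivity) {
  check_num(sensitivity, "sensitivity", min = 0, strict_min = TRUE)
  structure(list(name = name, sensitivity = sensitivity),
            class = "voltmeter_spec")
}

#' @rdname voltmeter_spec
#' @export
voltmeter_presets <- function() {
  list(squid = voltmeter_spec("SQUID", 1e-12),
       nanovoltmeter = voltmeter_spec("nanovoltmeter", 1e-8),
       benchtop_dmm = voltmeter_spec("benchtop DMM", 1e-6))
}

# dosimetry defaults to the mains-powered 40-turn coil geometry; the
# 2000-turn pickup of the flow simulations can be passed explicitly.
dosimetry_coil_default <- function() coil_spec(0.05, 40, 0.10)

#' Peak EMF induced by one centered particle
#'
#' For a particle resting at the coil center under the AC drive the flux is
#' `Phi0 cos(w t)`, so the peak induced voltage is `n Phi0 w` with
#' `Phi0 = mu0 m / (2 R)`. This is the per-particle signal quantum used for
#' detection-limit analysis. An RMS metric (`peak / sqrt(2)`) is available.
#'
#' @param diameter particle diameter, m.
#' @param coil the pickup [coil_spec()] (default: 40 turns, R = 5 cm).
#' @param drive a [drive_field()].
#' @param material a [material_properties()].
#' @param metric `"peak"` (default) or `"rms"`.
#' @return EMF per particle, V.
#' @export
per_particle_emf <- function(diameter, coil = dosimetry_coil_default(),
                             drive = drive_field(),
                             material = mnp_material("iron_oxide"),
                             metric = c("peak", "rms")) {
  metric <- match.arg(metric)
  m0 <- particle_moment(diameter, drive$H_amplitude, material)
  v <- coil$turns * dipole_flux_center(m0, coil$radius) * 2 * pi * drive$freq
  if (metric == "rms") v / sqrt(2) else v
}

#' Particles required for a detectable signal
#'
#' Number of co-located particles whose summed peak EMF reaches the
#' voltmeter sensitivity: `ceil(sensitivity / per-particle EMF)`. Because
#' the per-particle moment scales with `d^3`, the required count scales with
#' `d^-3`: an 8000-fold drop from 5 nm to 100 nm diameter.
#'
#' @param diameter particle diameter, m.
#' @param voltmeter a [voltmeter_spec()].
#' @inheritParams per_particle_emf
#' @return required particle count (integer-valued numeric, >= 1).
#' @export
#' @examples
#' required_particle_count(30e-9, voltmeter_spec("10 pV", 1e-10),
#'                         coil = coil_spec(0.05, 2000))   # ~5e6
required_particle_count <- function(diameter, voltmeter,
                                    coil = dosimetry_coil_default(),
                                    drive = drive_field(),
                                    material = mnp_material("iron_oxide"),
                                    metric = c("peak", "rms")) {
  stopifnot(inherits(voltmeter, "voltmeter_spec"))
  v1 <- per_particle_emf(diameter, coil, drive, material, metric)
  if (v1 <= 0)
    stop("per-particle EMF is zero (unmagnetized particle); ",
         "signal is undetectable at any count", call. = FALSE)
  ceiling(voltmeter$sensitivity / v1)
}

# magnetite mineral density, kg/m^3; a model default, not a measured input
DENSITY_MAGNETITE <- 5180

#' Convert a particle count to mass and concentration
#'
#' Total mineral mass `count * density * (pi/6) d^3` and its concentration
#' in a stated blood volume.
#'
#' @param count particle count (>= 0).
#' @param diameter particle diameter, m.
#' @param density particle mineral density, kg/m^3 (default magnetite,
#'   5180).
#' @param volume_ml reference blood volume, mL (> 0).
#' @return list with `mass_ug` (micrograms) and `conc_ug_ml` (micrograms
#'   per mL).
#' @export
particles_to_mass_concentration <- function(count, diameter,
                                            density = DENSITY_MAGNETITE,
                                            volume_ml) {
  check_num(count, "count", min = 0)
  check_num(diameter, "diameter", min = 0, strict_min = TRUE)
  check_num(density, "density", min = 0, strict_min = TRUE)
  check_num(volume_ml, "volume_ml", min = 0, strict_min = TRUE)
  mass_kg <- count * density * pi / 6 * diameter^3
  mass_ug <- mass_kg * 1e9
  list(mass_ug = mass_ug, conc_ug_ml = mass_ug / volume_ml)
}

#' Safety classification of a nanoparticle concentration
#'
#' Three-way classification against configurable thresholds. The defaults
#' (safe below 10 ug/mL, toxic above 100 ug/mL, potentially toxic between)
#' are placeholder working values for iron-oxide formulations — dose safety
#' is formulation-specific and the thresholds should be set per application.
#' Boundaries classify on the safe side (closed lower intervals).
#'
#' @param conc_ug_ml concentration, ug/mL (vectorized).
#' @param safe_max upper edge of the safe range, ug/mL.
#' @param toxic_min lower edge of the toxic range, ug/mL; must exceed
#'   `safe_max`.
#' @return character vector: `"safe"`, `"potentially_toxic"` or `"toxic"`.
#' @export
classify_safety <- function(conc_ug_ml, safe_max = 10, toxic_min = 100) {
  check_num(safe_max, "safe_max", min = 0)
  check_num(toxic_min, "toxic_min", min = 0)
  if (safe_max >= toxic_min)
    stop_bad("safe_max", "must be below toxic_min")
  if (any(conc_ug_ml < 0)) stop_bad("conc_ug_ml", "must be >= 0")
  out <- ifelse(conc_ug_ml <= safe_max, "safe",
                ifelse(conc_ug_ml <= toxic_min, "potentially_toxic",
                       "toxic"))
  as.character(out)
}

#' Detection-limit sweep across sizes and sensitivities
#'
#' Full cross-product of particle diameters and voltmeter sensitivities:
#' for each pair, the required particle count, the corresponding mineral
#' mass, its concentration in the regional arterial pulse volume, and the
#' safety class. This is the package's dose-planning table.
#'
#' @param diameters particle diameters, m (non-empty).
#' @param sensitivities voltmeter sensitivities, V (non-empty), or a list of
#'   [voltmeter_spec()] objects.
#' @param coil the pickup [coil_spec()].
#' @param drive a [drive_field()].
#' @param physiology a [physiology_params()].
#' @param region `"forearm"` or `"leg"`.
#' @param material a [material_properties()].
#' @param density particle density, kg/m^3.
#' @param safe_max,toxic_min safety thresholds, ug/mL.
#' @param metric `"peak"` or `"rms"` detection metric.
#' @return a data.frame of class `detection_plan` with one row per
#'   (diameter, sensitivity) pair: `diameter_nm`, `sensitivity_v`, `count`,
#'   `mass_ug`, `conc_ug_ml`, `safety`.
#' @export
#' @examples
#' plan <- sensitivity_sweep(c(5e-9, 100e-9), c(1e-12, 1e-6))
#' subset(plan, sensitivity_v == 1e-12)$safety   # "safe" "safe"
sensitivity_sweep <- function(diameters,
                              sensitivities = c(1e-12, 1e-8, 1e-6),
                              coil = dosimetry_coil_default(),
                              drive = drive_field(),
                              physiology = physiology_params(),
                              region = c("forearm", "leg"),
                              material = mnp_material("iron_oxide"),
                              density = DENSITY_MAGNETITE,
                              safe_max = 10, toxic_min = 100,
                              metric = c("peak", "rms")) {
  region <- match.arg(region)
  metric <- match.arg(metric)
  if (length(diameters) == 0L) stop_bad("diameters", "must be non-empty")
  if (is.list(sensitivities))
    sensitivities <- vapply(sensitivities, `[[`, numeric(1), "sensitivity")
  if (length(sensitivities) == 0L)
    stop_bad("sensitivities", "must be non-empty")
  vol <- pulse_volume(physiology, region)
  grid <- expand.grid(diameter = diameters, sensitivity = sensitivities,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    d <- grid$diameter[i]; s <- grid$sensitivity[i]
    cnt <- required_particle_count(d, voltmeter_spec("sweep", s), coil,
                                   drive, material, metric)
    mc <- particles_to_mass_concentration(cnt, d, density, vol)
    data.frame(diameter_nm = d * 1e9, sensitivity_v = s, count = cnt,
               mass_ug = mc$mass_ug, conc_ug_ml = mc$conc_ug_ml,
               safety = classify_safety(mc$conc_ug_ml, safe_max, toxic_min),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("detection_plan", "data.frame"),
            region = region, volume_ml = vol, coil = coil,
            material = material$name)
}
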