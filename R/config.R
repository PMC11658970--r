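#' Default run configuration
#'
#' The run configuration bundles every model input the pipeline commands
#' need: material, coils, vessel, Carreau rheology, scenario, voltmeter
#' ladder, physiology, seed and unit preferences. Values printed in the
#' configuration are the model defaults; everything can be overridden from
#' a yaml file via [read_run_config()].
#'
#' @return a named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    material = "iron_oxide",
    drive_coil = list(radius = 0.05, turns = 40, height = 0.10,
                      volts = 220, freq = 50),
    pickup_coil = list(radius = 0.05, turns = 2000),
    wire_area = WIRE_AREA_DEFAULT,
    vessel = list(radius = 2e-3, length = 0.1, mean_velocity = 0.071),
    carreau = list(eta0 = 0.056, eta_inf = 0.0035, lambda = 3.313,
                   n_index = 0.3568),
    scenario = "arterial_pulses",
    voltmeters = list(squid = 1e-12, nanovoltmeter = 1e-8,
                      benchtop_dmm = 1e-6),
    physiology = list(cardiac_output = 5, heart_rate = 70,
                      forearm_fraction = 0.023, leg_fraction = 0.065),
    dosimetry = list(diameters = c(5e-9, 30e-9, 50e-9, 100e-9),
                     density = DENSITY_MAGNETITE,
                     safe_max = 10, toxic_min = 100, region = "forearm"),
    units = list(field = "Oe", moment = "emu")
  ), class = "run_config")
}

#' Read and validate a run configuration
#'
#' Reads a yaml configuration, overlays it on [default_run_config()] and
#' validates every field, failing with a message naming the offending key.
#' Custom materials may be given as a `material:` mapping with the fields of
#' [material_properties()] instead of a preset name.
#'
#' @param path yaml file path, or `NULL` for pure defaults.
#' @return a validated `run_config` list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop_bad("config", sprintf("file '%s' does not exist", path))
    user <- yaml::read_yaml(path)
    if (!is.list(user)) stop_bad("config", "must be a yaml mapping")
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0)
      stop_bad(unknown[1], "is not a recognized configuration key")
    cfg <- structure(modifyList(unclass(cfg), user), class = "run_config")
  }
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  check_num(cfg$seed, "seed")
  # constructors carry the detailed invariants; building them validates
  config_material(cfg)
  cfg_coil_drive(cfg)
  cfg_coil_pickup(cfg)
  check_num(cfg$wire_area, "wire_area", min = 0, strict_min = TRUE)
  do.call(vessel_spec, cfg$vessel)
  do.call(carreau_params, cfg$carreau)
  if (!cfg$scenario %in% c("single_arterial", "arterial_pulses",
                           "venous_counterflow"))
    stop_bad("scenario", "must name a built-in scenario preset")
  for (nm in names(cfg$voltmeters))
    check_num(cfg$voltmeters[[nm]], paste0("voltmeters$", nm),
              min = 0, strict_min = TRUE)
  do.call(physiology_params, cfg$physiology)
  with(cfg$dosimetry, {
    if (length(diameters) < 1) stop_bad("dosimetry$diameters", "is empty")
    check_num(density, "dosimetry$density", min = 0, strict_min = TRUE)
    if (safe_max >= toxic_min)
      stop_bad("dosimetry$safe_max", "must be below dosimetry$toxic_min")
    if (!region %in% c("forearm", "leg"))
      stop_bad("dosimetry$region", "must be 'forearm' or 'leg'")
  })
  if (!cfg$units$field %in% c("Oe", "Am"))
    stop_bad("units$field", "must be 'Oe' or 'Am'")
  cfg
}

config_material <- function(cfg) {
  m <- cfg$material
  if (is.character(m)) return(mnp_material(m))
  do.call(material_properties, m)
}

cfg_coil_drive <- function(cfg) {
  d <- cfg$drive_coil
  coil_spec(d$radius, d$turns, d$height,
            drive_ac_voltage(d$volts, d$freq), role = "drive")
}

cfg_coil_pickup <- function(cfg) {
  p <- cfg$pickup_coil
  coil_spec(p$radius, p$turns)
}

#' Write a voltage trace as CSV with a JSON metadata sidecar
#'
#' The CSV holds the two columns `t`, `v`; the sidecar
#' (`<path>.meta.json`) records coil, drive, particle count, seed and
#' conventions so the trace can be regenerated exactly.
#'
#' @param trace a [voltage_trace].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "voltage_trace"))
  write.csv(data.frame(t = trace$t, v = trace$v), path, row.names = FALSE)
  meta <- trace_meta(trace)
  meta$coil <- unclass(meta$coil)
  meta$drive <- unclass(meta$drive)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Run a pipeline command
#'
#' Config-driven front door tying the modules together; the thin shell
#' script under `inst/cli/` forwards to this function. Each command writes
#' its CSV/JSON artifacts into `outdir` together with a `manifest.json`
#' (config echo, seed, package version) sufficient to regenerate every file.
#' On error, partially written artifacts are removed.
#'
#' Commands:
#' * `mhcurve` — Jiles-Atherton loop of the configured material, as CSV.
#' * `single-particle` — EMF trace of the single-particle scenario.
#' * `pulse-train` — arterial pulse-train EMF trace.
#' * `noise` — venous counter-flow EMF trace.
#' * `snr` — arterial-vs-venous separation summary (JSON).
#' * `detection-limits` — required counts per size and sensitivity (CSV).
#' * `dose-plan` — full [sensitivity_sweep()] table (CSV) + JSON summary.
#'
#' @param command one of the commands above.
#' @param config a `run_config` list or a yaml path (`NULL` = defaults).
#' @param outdir output directory (created if missing).
#' @param seed optional integer overriding the configured seed.
#' @param plot if `TRUE`, also writes a PNG plot per time-series/curve.
#' @param verbose print per-stage progress messages.
#' @return invisibly, a character vector of the files written.
#' @export
run_pipeline <- function(command = c("mhcurve", "single-particle",
                                     "pulse-train", "noise", "snr",
                                     "detection-limits", "dose-plan"),
                         config = NULL, outdir = ".", seed = NULL,
                         plot = FALSE, verbose = FALSE) {
  command <- match.arg(command)
  cfg <- if (inherits(config, "run_config")) validate_run_config(config)
         else read_run_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)

  mat <- config_material(cfg)
  drive_coil <- cfg_coil_drive(cfg)
  pickup <- cfg_coil_pickup(cfg)
  drv <- drive_from_solenoid(drive_coil, wire_area = cfg$wire_area)
  written <- character(0)
  emit <- function(fname) {
    f <- file.path(outdir, fname)
    written <<- c(written, f)
    f
  }

  run <- function() {
    switch(command,
      "mhcurve" = {
        say("integrating Jiles-Atherton loop for ", mat$name)
        loop <- ja_loop(mat, H_max = 2e5, n_steps = 1000L)
        write_mh_csv(loop, emit("mhcurve.csv"),
                     field_unit = if (cfg$units$field == "Oe") "Oe" else "Am")
        if (plot) {
          grDevices::png(emit("mhcurve.png"), 800, 600)
          plot(loop); grDevices::dev.off()
        }
      },
      "single-particle" = {
        sc <- scenario_preset("single_arterial", seed = cfg$seed)
        tr <- single_particle_emf(sc$diameter, sc$speed, pickup, drv,
                                  duration = 1, material = mat)
        write_trace_csv(tr, emit("single_particle.csv"))
        if (plot) {
          grDevices::png(emit("single_particle.png"), 800, 600)
          plot(tr); grDevices::dev.off()
        }
      },
      "pulse-train" = {
        sc <- scenario_preset("arterial_pulses", seed = cfg$seed)
        say("synthesizing ", sc$n_particles, " particles/pulse")
        ens <- generate_pulse_ensemble(sc)
        tr <- ensemble_emf(ens, pickup, drv, duration = sc$duration,
                           material = mat)
        write_trace_csv(tr, emit("pulse_train.csv"))
        if (plot) {
          grDevices::png(emit("pulse_train.png"), 800, 600)
          plot(tr); grDevices::dev.off()
        }
      },
      "noise" = {
        sc <- scenario_preset("venous_counterflow", seed = cfg$seed)
        ens <- generate_counterflow_ensemble(sc)
        tr <- ensemble_emf(ens, pickup, drv, duration = sc$duration,
                           material = mat)
        write_trace_csv(tr, emit("venous_noise.csv"))
      },
      "snr" = {
        res <- counterflow_snr(seed = cfg$seed, coil = pickup, drive = drv)
        jsonlite::write_json(
          list(snr = res$snr, seed = cfg$seed,
               signal_peak_v = max(abs(trace_envelope(res$signal))),
               noise_rms_v = sqrt(mean(res$noise$v^2)),
               carrier = "baseband"),
          emit("snr.json"), auto_unbox = TRUE, digits = NA)
      },
      "detection-limits" = {
        rows <- expand.grid(diameter = cfg$dosimetry$diameters,
                            sensitivity = unlist(cfg$voltmeters),
                            KEEP.OUT.ATTRS = FALSE)
        rows$count <- mapply(function(d, s)
          required_particle_count(d, voltmeter_spec("cfg", s),
                                  coil = drive_coil, drive = drv,
                                  material = mat),
          rows$diameter, rows$sensitivity)
        rows$diameter <- rows$diameter * 1e9
        names(rows)[1] <- "diameter_nm"
        write.csv(rows, emit("detection_limits.csv"), row.names = FALSE)
      },
      "dose-plan" = {
        plan <- sensitivity_sweep(
          cfg$dosimetry$diameters, unlist(cfg$voltmeters),
          coil = drive_coil, drive = drv,
          physiology = do.call(physiology_params, cfg$physiology),
          region = cfg$dosimetry$region, material = mat,
          density = cfg$dosimetry$density,
          safe_max = cfg$dosimetry$safe_max,
          toxic_min = cfg$dosimetry$toxic_min)
        write.csv(as.data.frame(plan), emit("dose_plan.csv"),
                  row.names = FALSE)
        jsonlite::write_json(
          list(region = attr(plan, "region"),
               pulse_volume_ml = attr(plan, "volume_ml"),
               n_rows = nrow(plan),
               classes = as.list(table(plan$safety))),
          emit("dose_plan.json"), auto_unbox = TRUE, digits = NA)
      })
    manifest <- list(command = command, seed = cfg$seed,
                     package_version = as.character(packageVersion("searchcoil")),
                     config = unclass(cfg))
    jsonlite::write_json(manifest, emit("manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  tryCatch(run(), error = function(e) {
    # do not leave partial artifacts behind
    existing <- written[file.exists(written)]
    sidecars <- paste0(existing, ".meta.json")
    unlink(c(existing, sidecars[file.exists(sidecars)]))
    stop(e)
  })
  say("wrote ", length(written), " file(s) to ", outdir)
  invisible(written)
}
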