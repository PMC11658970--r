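#' Magnetic material properties
#'
#' Bundle of the five scalar Jiles-Atherton parameters plus bulk electrical
#' properties for a magnetic material. The Jiles-Atherton parameters are:
#' `Ms` the saturation magnetization (A/m), `a` the domain-wall density
#' parameter (A/m, sets the width of the anhysteretic sigmoid), `k` the
#' pinning-loss parameter (A/m, sets hysteresis dissipation), `c` the
#' magnetization reversibility (0 = fully hysteretic, 1 = fully reversible)
#' and `alpha` the dimensionless interdomain coupling entering the effective
#' field He = H + alpha * M.
#'
#' @param name label for the material.
#' @param sigma electrical conductivity, S/m.
#' @param eps_r relative permittivity (dimensionless).
#' @param Ms saturation magnetization, A/m. Must be > 0.
#' @param a domain-wall density parameter, A/m. Must be > 0.
#' @param k pinning-loss parameter, A/m. Must be >= 0.
#' @param c magnetization reversibility in \[0, 1\].
#' @param alpha interdomain coupling (dimensionless).
#' @return an object of class `material_properties`.
#' @seealso [mnp_material()] for the built-in presets.
#' @export
#' @examples
#' m <- material_properties("demo", sigma = 0.1, eps_r = 1,
#'                          Ms = 3e5, a = 1e5, k = 5e5, c = 0.9, alpha = 0.4)
#' m$Ms
material_properties <- function(name, sigma, eps_r, Ms, a, k, c, alpha) {
  if (!is.character(name) || length(name) != 1L)
    stop_bad("name", "must be a single string")
  check_num(sigma, "sigma", min = 0)
  check_num(eps_r, "eps_r", min = 0, strict_min = TRUE)
  check_num(Ms, "Ms", min = 0, strict_min = TRUE)
  check_num(a, "a", min = 0, strict_min = TRUE)
  check_num(k, "k", min = 0)
  check_num(c, "c", min = 0, max = 1)
  check_num(alpha, "alpha")
  structure(list(name = name, sigma = sigma, eps_r = eps_r, Ms = Ms,
                 a = a, k = k, c = c, alpha = alpha),
            class = "material_properties")
}

#' Built-in nanoparticle material presets
#'
#' Two presets cover the canonical contrast in nanoparticle magnetics:
#' `"iron_oxide"` behaves superparamagnetically (negligible remanence and
#' coercivity at these parameters) while `"cobalt_ferrite"` is strongly
#' hysteretic. Values can be overridden per call; user-defined materials can
#' also be supplied through the run configuration (see [read_run_config()]).
#'
#' @param name `"iron_oxide"` or `"cobalt_ferrite"`.
#' @param ... named overrides passed to [material_properties()].
#' @return a [material_properties()] object.
#' @export
#' @examples
#' mnp_material("iron_oxide")$Ms     # 2.88e5 A/m
#' mnp_material("cobalt_ferrite")$alpha
mnp_material <- function(name = c("iron_oxide", "cobalt_ferrite"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    iron_oxide = list(name = "iron_oxide", sigma = 0.13, eps_r = 1,
                      Ms = 2.88e5, a = 1.00e5, k = 5.00e5, c = 0.95,
                      alpha = 0.5),
    cobalt_ferrite = list(name = "cobalt_ferrite", sigma = 5.20e6, eps_r = 1,
                          Ms = 2.40e7, a = 1.00e5, k = 2.00e5, c = 0.4,
                          alpha = 1.4))
  do.call(material_properties, modifyList(base, list(...)))
}

#' @export
print.material_properties <- function(x, ...) {
  cat(sprintf("<material_properties: %s>\n", x$name))
  cat(sprintf("  Ms = %.4g A/m, a = %.4g A/m, k = %.4g A/m, c = %.3g, alpha = %.3g\n",
              x$Ms, x$a, x$k, x$c, x$alpha))
  cat(sprintf("  sigma = %.4g S/m, eps_r = %.3g\n", x$sigma, x$eps_r))
  invisible(x)
}
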