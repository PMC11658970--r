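# Vacuum permeability, T m / A. Kept at the classical defined value; the
# 2019 SI redefinition differs by < 1e-9 relative, far below model accuracy.
MU0 <- 4e-7 * pi

#' Unit conversions used throughout the package
#'
#' The magnetics literature mixes SI and CGS units: applied fields are often
#' quoted in oersted (Oe) and particle moments in emu. Internally everything
#' is SI (A/m, A m^2); these helpers convert at the interface only.
#'
#' Conversions: 1 Oe = 1e3/(4 pi) A/m; 1 A m^2 = 1e3 emu.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @examples
#' oe_to_am(2299.1)       # drive-field strength in A/m
#' am2_to_emu(2.3e-18)    # a 30 nm particle moment in emu
#' @name units
NULL

#' @rdname units
#' @export
oe_to_am <- function(x) x * 1e3 / (4 * pi)

#' @rdname units
#' @export
am_to_oe <- function(x) x * (4 * pi) / 1e3

#' @rdname units
#' @export
am2_to_emu <- function(x) x * 1e3

#' @rdname units
#' @export
emu_to_am2 <- function(x) x * 1e-3

# internal: scalar validation helpers shared by the S3 constructors
stop_bad <- function(key, msg) {
  stop(sprintf("invalid configuration: '%s' %s", key, msg), call. = FALSE)
}

check_num <- function(x, key, min = -Inf, max = Inf, strict_min = FALSE,
                      len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x) || any(!is.finite(x)))
    stop_bad(key, "must be a finite number")
  if (strict_min && any(x <= min)) stop_bad(key, sprintf("must be > %g", min))
  if (!strict_min && any(x < min)) stop_bad(key, sprintf("must be >= %g", min))
  if (any(x > max)) stop_bad(key, sprintf("must be <= %g", max))
  invisible(x)
}
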