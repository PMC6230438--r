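#' Parameters of one half-center
#'
#' A half-center is one of the two mutually exclusive integrating populations
#' of a limb's rhythm generator. While active, its state integrates
#' \eqn{\dot x = x_0 + g u + r_{leak} x} from 0 up to the switching threshold
#' of 1, so \code{x0} sets the background excitability and \code{g} scales the
#' descending drive \code{u}.
#'
#' @param x0 Background offset rate (state-units per second). May be negative;
#'   the fitted flexor-side offset is -0.0007.
#' @param g Input gain (state-units per second per unit of drive).
#' @return An object of class \code{half_center_params}.
#' @examples
#' half_center_params(x0 = 2.4256, g = 0.4882)
#' @export
half_center_params <- function(x0, g) {
  stopifnot(is.numeric(x0), length(x0) == 1L, is.finite(x0),
            is.numeric(g),  length(g)  == 1L, is.finite(g))
  structure(list(x0 = as.numeric(x0), g = as.numeric(g)),
            class = "half_center_params")
}

#' @export
print.half_center_params <- function(x, ...) {
  cat(sprintf("<half_center_params> x0 = %g, g = %g\n", x$x0, x$g))
  invisible(x)
}

#' Parameters of a single-limb rhythm generator
#'
#' Two reciprocal half-centers sharing one leak rate. Only one half-center is
#' active at a time; its state runs from 0 to the threshold (fixed at 1), at
#' which point activity switches to the antagonist. The leak rate must be
#' non-positive: each half-center is a leaky integrator with weak negative
#' state feedback.
#'
#' @param hc1,hc2 \code{\link{half_center_params}} for the two half-centers
#'   (index 1 and 2). With the default fitted values, phase 1 is the strongly
#'   speed-modulated, stance-like phase and phase 2 the weakly modulated,
#'   swing-like phase; the indices themselves carry no anatomical commitment
#'   (see the package vignette).
#' @param r_leak Leak rate in 1/s; must be \code{<= 0}. \code{r_leak = 0}
#'   gives pure (non-leaky) integrators.
#' @return An object of class \code{limb_cpg_params} with elements
#'   \code{hc1}, \code{hc2}, \code{r_leak} and \code{threshold} (always 1).
#' @seealso \code{\link{cpg_params_default}} for the fitted cat-walking values.
#' @examples
#' p <- limb_cpg_params(half_center_params(0, 1), half_center_params(0, 1), -0.01)
#' @export
limb_cpg_params <- function(hc1, hc2, r_leak = 0) {
  stopifnot(inherits(hc1, "half_center_params"),
            inherits(hc2, "half_center_params"),
            is.numeric(r_leak), length(r_leak) == 1L, is.finite(r_leak))
  if (r_leak > 0)
    stop("r_leak must be <= 0 (leaky, not self-exciting, integration)")
  structure(list(hc1 = hc1, hc2 = hc2,
                 r_leak = as.numeric(r_leak), threshold = 1),
            class = "limb_cpg_params")
}

#' @export
print.limb_cpg_params <- function(x, ...) {
  cat("<limb_cpg_params>\n")
  cat(sprintf("  hc1: x0 = %g, g = %g\n", x$hc1$x0, x$hc1$g))
  cat(sprintf("  hc2: x0 = %g, g = %g\n", x$hc2$x0, x$hc2$g))
  cat(sprintf("  r_leak = %g /s, threshold = %g\n", x$r_leak, x$threshold))
  invisible(x)
}

#' Fitted single-limb CPG parameters for cat walking
#'
#' The reference parameter set obtained by error-driven fitting of the
#' half-center model to phase-duration measurements of cat overground walking:
#' x01 = -0.0007, x02 = 2.4256, g1 = 0.6203, g2 = 0.4882, r_leak = -0.0094.
#' Shipped as a JSON fixture under \code{inst/extdata}.
#'
#' @return A \code{\link{limb_cpg_params}} object.
#' @examples
#' cpg_params_default()
#' @export
cpg_params_default <- function() {
  path <- system.file("extdata", "table_a1.json", package = "cpgrhythm",
                      mustWork = TRUE)
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  limb_cpg_params(half_center_params(v$x01, v$g1),
                  half_center_params(v$x02, v$g2),
                  r_leak = v$r_leak)
}

#' Empirical speed maps for cat walking
#'
#' The two printed empirical relations used throughout the package:
#' the affine regression from forward speed to CPG drive,
#' \eqn{u = (V + 0.1272)/0.2357}, and the phenomenological power law for step
#' cycle duration, \eqn{T_c = 0.5445\, V^{-0.5925}} (V in m/s, Tc in s),
#' together with the near-constant swing duration (0.25 s).
#'
#' @param u_offset,u_scale Affine map constants (m/s and m/s per drive unit).
#' @param emp_coeff,emp_exp Power-law coefficient and exponent.
#' @param swing_const Swing-phase duration treated as constant (s).
#' @return An object of class \code{speed_maps}.
#' @examples
#' speed_maps()
#' @export
speed_maps <- function(u_offset = NULL, u_scale = NULL,
                       emp_coeff = NULL, emp_exp = NULL,
                       swing_const = NULL) {
  path <- system.file("extdata", "speed_maps.json", package = "cpgrhythm",
                      mustWork = TRUE)
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- list(
    u_offset    = if (is.null(u_offset)) d$u_offset else u_offset,
    u_scale     = if (is.null(u_scale)) d$u_scale else u_scale,
    emp_coeff   = if (is.null(emp_coeff)) d$emp_coeff else emp_coeff,
    emp_exp     = if (is.null(emp_exp)) d$emp_exp else emp_exp,
    swing_const = if (is.null(swing_const)) d$swing_const else swing_const)
  stopifnot(m$u_scale > 0, m$emp_coeff > 0, m$emp_exp < 0)
  structure(m, class = "speed_maps")
}

#' @export
print.speed_maps <- function(x, ...) {
  cat("<speed_maps>\n")
  cat(sprintf("  drive map: u = (V + %g) / %g\n", x$u_offset, x$u_scale))
  cat(sprintf("  empirical: Tc = %g * V^%g s\n", x$emp_coeff, x$emp_exp))
  cat(sprintf("  swing duration: %g s (constant)\n", x$swing_const))
  invisible(x)
}
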