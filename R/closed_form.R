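# Closed-form phase and cycle durations for the single-limb half-center model.
#
# Within one phase the active state obeys the linear ODE
#   xdot = x0 + g*u + r_leak * x,   x(0) = 0,
# and the phase ends at the upward crossing of the threshold x = 1. For
# r_leak = r != 0 the solution is x(t) = ((x0 + g u)/r) (e^{rt} - 1); solving
# x(t) = 1 gives the exact phase duration, and a first-order Taylor expansion
# in rt gives the simpler reciprocal-rate form 1/(x0 + g u).

# minimal admissible drive for a positive effective rate (Taylor regime)
.u_min_rate <- function(hc) {
  if (hc$g > 0) -hc$x0 / hc$g
  else if (hc$g < 0) -Inf   # rate decreases with u; boundary is an upper limit
  else Inf
}

# minimal admissible drive to overcome the leak (exact regime, r <= 0)
.u_min_leak <- function(hc, r_leak) {
  if (hc$g > 0) (-r_leak - hc$x0) / hc$g
  else if (hc$g < 0) -Inf
  else Inf
}

#' Phase duration, Taylor (reciprocal-rate) approximation
#'
#' Duration of one locomotor phase under the non-leaky approximation: the
#' active state ramps at the constant effective rate \eqn{x_0 + g u} from 0 to
#' the threshold 1, so the phase lasts \eqn{1 / (x_0 + g u)} seconds.
#'
#' @param hc A \code{\link{half_center_params}} object.
#' @param u Drive magnitude (dimensionless input units).
#' @param phase Optional phase index used to label error messages.
#' @return Phase duration in seconds.
#' @section Errors: if \eqn{x_0 + g u \le 0} the state never rises and the
#'   phase never terminates; a condition of class
#'   \code{cpg_nonpositive_rate_error} is signalled carrying the minimal
#'   admissible drive (\code{u_min}).
#' @examples
#' phase_duration_taylor(half_center_params(2.4256, 0.4882), u = 4.7824)
#' @export
phase_duration_taylor <- function(hc, u, phase = NULL) {
  stopifnot(inherits(hc, "half_center_params"),
            is.numeric(u), length(u) == 1L, is.finite(u))
  rate <- hc$x0 + hc$g * u
  if (rate <= 0)
    stop_nonpositive_rate(rate, .u_min_rate(hc), phase)
  1 / rate
}

#' Phase duration, exact leaky-integrator solution
#'
#' Duration of one locomotor phase from the exact solution of the leaky
#' integrator: \eqn{t = (1/r)\,\log(1 + r/(x_0 + g u))} with
#' \eqn{r = r_{leak}}. For \code{r_leak = 0} this reduces continuously to the
#' Taylor value \eqn{1/(x_0 + g u)}, which is returned directly. With
#' \code{r_leak < 0} the exact duration is always at least the Taylor value,
#' because the leak slows the approach to threshold.
#'
#' @inheritParams phase_duration_taylor
#' @param r_leak Leak rate (1/s), \code{<= 0}.
#' @return Phase duration in seconds.
#' @section Errors: \code{cpg_nonpositive_rate_error} if the effective rate is
#'   non-positive; \code{cpg_saturation_error} if the rate is positive but not
#'   greater than \eqn{|r_{leak}|}, in which case the state saturates at an
#'   asymptote below threshold. Both carry the minimal admissible drive.
#' @examples
#' phase_duration_exact(half_center_params(2.4256, 0.4882), r_leak = -0.0094,
#'                      u = 4.7824)
#' @export
phase_duration_exact <- function(hc, r_leak, u, phase = NULL) {
  stopifnot(inherits(hc, "half_center_params"),
            is.numeric(r_leak), length(r_leak) == 1L, is.finite(r_leak),
            r_leak <= 0,
            is.numeric(u), length(u) == 1L, is.finite(u))
  rate <- hc$x0 + hc$g * u
  if (rate <= 0)
    stop_nonpositive_rate(rate, .u_min_rate(hc), phase)
  if (r_leak == 0)
    return(1 / rate)
  if (rate <= -r_leak)   # asymptote rate/(-r) <= 1: never reaches threshold
    stop_saturation(rate, r_leak, .u_min_leak(hc, r_leak), phase)
  log1p(r_leak / rate) / r_leak
}

#' Coefficients of the rational form for cycle duration
#'
#' Expanding the sum of the two reciprocal-rate phase durations puts the cycle
#' duration into the rational form
#' \deqn{T_c(u) = \frac{a + b u}{\tilde a + \tilde b u + \tilde c u^2}}
#' with \eqn{a = x_{01}+x_{02}}, \eqn{b = g_1+g_2},
#' \eqn{\tilde a = x_{01}x_{02}}, \eqn{\tilde b = x_{01}g_2 + x_{02}g_1},
#' \eqn{\tilde c = g_1 g_2}. Pure bookkeeping: the five constants are fixed by
#' the half-center parameters.
#'
#' @param params A \code{\link{limb_cpg_params}} object.
#' @return A list of class \code{rational_form_coefficients} with elements
#'   \code{a}, \code{b}, \code{a_t}, \code{b_t}, \code{c_t}.
#' @examples
#' rational_coefficients(cpg_params_default())
#' @export
rational_coefficients <- function(params) {
  stopifnot(inherits(params, "limb_cpg_params"))
  x01 <- params$hc1$x0; g1 <- params$hc1$g
  x02 <- params$hc2$x0; g2 <- params$hc2$g
  structure(list(a = x01 + x02, b = g1 + g2,
                 a_t = x01 * x02, b_t = x01 * g2 + x02 * g1, c_t = g1 * g2),
            class = "rational_form_coefficients")
}

#' @export
print.rational_form_coefficients <- function(x, ...) {
  cat(sprintf("<rational_form_coefficients> Tc(u) = (%g + %g u) / (%g + %g u + %g u^2)\n",
              x$a, x$b, x$a_t, x$b_t, x$c_t))
  invisible(x)
}

#' Evaluate the rational form for cycle duration
#'
#' @param coefs A \code{\link{rational_coefficients}} result.
#' @param u Drive magnitude (vectorised).
#' @return Cycle duration(s) in seconds.
#' @export
rational_cycle_duration <- function(coefs, u) {
  stopifnot(inherits(coefs, "rational_form_coefficients"), is.numeric(u))
  (coefs$a + coefs$b * u) / (coefs$a_t + coefs$b_t * u + coefs$c_t * u^2)
}

#' Full step-cycle duration of the single-limb oscillator
#'
#' The cycle duration is the sum of the two alternating phase durations,
#' \eqn{T_c = \tau_1 + \tau_2}, computed either from the exact leaky solution
#' (\code{method = "exact"}) or from the reciprocal-rate Taylor approximation
#' (\code{method = "taylor"}). The Taylor form is algebraically identical to
#' the rational form returned by \code{\link{rational_coefficients}}.
#'
#' @param params A \code{\link{limb_cpg_params}} object.
#' @param u Drive magnitude.
#' @param method \code{"taylor"} or \code{"exact"}.
#' @return An object of class \code{cycle_solution}: list with \code{tau1},
#'   \code{tau2}, \code{Tc} (seconds), plus the \code{u} and \code{method}
#'   used.
#' @section Errors: phase admissibility errors from the phase-duration
#'   functions propagate, labelled with the offending phase index.
#' @examples
#' cycle_duration(cpg_params_default(), u = 4.7824, method = "taylor")
#' @export
cycle_duration <- function(params, u, method = c("exact", "taylor")) {
  stopifnot(inherits(params, "limb_cpg_params"))
  method <- match.arg(method)
  if (method == "taylor") {
    tau1 <- phase_duration_taylor(params$hc1, u, phase = 1L)
    tau2 <- phase_duration_taylor(params$hc2, u, phase = 2L)
  } else {
    tau1 <- phase_duration_exact(params$hc1, params$r_leak, u, phase = 1L)
    tau2 <- phase_duration_exact(params$hc2, params$r_leak, u, phase = 2L)
  }
  structure(list(tau1 = tau1, tau2 = tau2, Tc = tau1 + tau2,
                 u = u, method = method),
            class = "cycle_solution")
}

#' @export
print.cycle_solution <- function(x, ...) {
  cat(sprintf("<cycle_solution> u = %g (%s): tau1 = %.4f s, tau2 = %.4f s, Tc = %.4f s\n",
              x$u, x$method, x$tau1, x$tau2, x$Tc))
  invisible(x)
}
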