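# Empirical reference relations for cat walking and the validation of the
# analytical cycle duration against the phenomenological power law.

#' Map forward speed to CPG drive
#'
#' Affine regression from overground forward speed V (m/s) to the
#' dimensionless drive u: \eqn{u = (V + u_{offset}) / u_{scale}}.
#'
#' @param V Forward speed in m/s (vectorised).
#' @param maps A \code{\link{speed_maps}} object.
#' @return Drive value(s) u.
#' @examples
#' input_from_speed(1.0)  # ~4.78
#' @export
input_from_speed <- function(V, maps = speed_maps()) {
  stopifnot(inherits(maps, "speed_maps"), is.numeric(V))
  (V + maps$u_offset) / maps$u_scale
}

#' Inverse map: drive to forward speed
#'
#' Exact inverse of \code{\link{input_from_speed}}.
#'
#' @param u Drive value(s).
#' @inheritParams input_from_speed
#' @return Forward speed(s) in m/s.
#' @export
speed_from_input <- function(u, maps = speed_maps()) {
  stopifnot(inherits(maps, "speed_maps"), is.numeric(u))
  u * maps$u_scale - maps$u_offset
}

#' Phenomenological cycle duration at a given speed
#'
#' The power law fitted to cat overground walking:
#' \eqn{T_c = 0.5445\,V^{-0.5925}} s with V in m/s (defaults; the constants
#' live in the \code{speed_maps} object).
#'
#' @inheritParams input_from_speed
#' @return Cycle duration(s) in seconds.
#' @examples
#' empirical_cycle_duration(1.0)  # 0.5445 s
#' @export
empirical_cycle_duration <- function(V, maps = speed_maps()) {
  stopifnot(inherits(maps, "speed_maps"), is.numeric(V))
  if (any(V <= 0))
    stop("V must be > 0: the power law diverges at zero speed")
  maps$emp_coeff * V^maps$emp_exp
}

#' Empirical swing and stance durations at a given speed
#'
#' Swing duration is treated as speed-independent (~0.25 s in walking cats);
#' stance is the remainder of the empirical cycle. Valid only while the cycle
#' is longer than the constant swing, i.e. within the walking range.
#'
#' @param V Forward speed in m/s (scalar).
#' @inheritParams input_from_speed
#' @return Named numeric vector \code{c(swing =, stance =)} in seconds.
#' @export
empirical_phase_durations <- function(V, maps = speed_maps()) {
  stopifnot(length(V) == 1L)
  Tc <- empirical_cycle_duration(V, maps)
  if (Tc <= maps$swing_const)
    stop(sprintf(paste0("cycle duration %.4g s does not exceed the constant ",
                        "swing %.4g s: V = %.4g m/s is outside the walking ",
                        "model's range (running gait)"),
                 Tc, maps$swing_const, V))
  c(swing = maps$swing_const, stance = Tc - maps$swing_const)
}

#' Validate analytical cycle durations against the empirical power law
#'
#' Over a grid of forward speeds, computes the analytical cycle duration
#' (drive mapped through the speed regression, then the closed-form solution)
#' and the phenomenological power-law duration, and summarises their agreement
#' as a squared correlation.
#'
#' Two R-squared flavours are reported: \code{r_squared} is the squared
#' Pearson correlation of the two duration vectors (scale-free, the form used
#' when one curve is regressed on the other), and \code{r_squared_identity}
#' is the coefficient of determination about the identity line
#' \eqn{1 - \sum(T_a - T_e)^2 / \sum(T_e - \bar T_e)^2}, which additionally
#' penalises any systematic offset.
#'
#' @param params A \code{\link{limb_cpg_params}} object.
#' @param maps A \code{\link{speed_maps}} object.
#' @param V_grid Speeds in m/s; default 0.1 to 2.0 in steps of 0.05, spanning
#'   the walking range. Needs at least 2 points.
#' @param method Closed-form flavour for the analytical curve; the exact
#'   leaky solution by default.
#' @return An object of class \code{cpg_validation}: list with \code{grid}
#'   (data.frame \code{V_mps}, \code{u}, \code{Tc_analytic_s},
#'   \code{Tc_empirical_s}), \code{r_squared}, \code{r_squared_identity} and
#'   \code{method}.
#' @examples
#' v <- validate_speed_law()
#' v$r_squared
#' @export
validate_speed_law <- function(params = cpg_params_default(),
                               maps = speed_maps(),
                               V_grid = seq(0.1, 2.0, by = 0.05),
                               method = c("exact", "taylor")) {
  stopifnot(inherits(params, "limb_cpg_params"), is.numeric(V_grid))
  method <- match.arg(method)
  if (length(V_grid) < 2L)
    stop("V_grid needs at least 2 points: correlation is undefined otherwise")
  u <- input_from_speed(V_grid, maps)
  Ta <- vapply(u, function(ui) cycle_duration(params, ui, method)$Tc,
               numeric(1))
  Te <- empirical_cycle_duration(V_grid, maps)
  r2 <- stats::cor(Ta, Te)^2
  r2_id <- 1 - sum((Ta - Te)^2) / sum((Te - mean(Te))^2)
  structure(list(
    grid = data.frame(V_mps = V_grid, u = u,
                      Tc_analytic_s = Ta, Tc_empirical_s = Te),
    r_squared = r2, r_squared_identity = r2_id, method = method),
    class = "cpg_validation")
}

#' @export
print.cpg_validation <- function(x, ...) {
  cat(sprintf("<cpg_validation> %d speeds (%g-%g m/s), %s solution\n",
              nrow(x$grid), min(x$grid$V_mps), max(x$grid$V_mps), x$method))
  cat(sprintf("  R^2 (Pearson^2)      = %.4f\n", x$r_squared))
  cat(sprintf("  R^2 (identity line)  = %.4f\n", x$r_squared_identity))
  invisible(x)
}
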