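# Two-limb differential-drive steering: a per-cycle heading change generated
# by an interlimb speed difference, gamma = Tc * (V_R - V_L) / W.

#' Steering configuration
#'
#' @param W Interlimb step width in metres (~0.15 m in the cat).
#' @param params Single-limb CPG parameters used for the cycle duration.
#' @param maps Speed maps used to convert limb speed to drive.
#' @param method Closed-form flavour for Tc.
#' @param angle_unit Reporting unit for angles in serialised output;
#'   internally everything is radians.
#' @param turn_first If \code{TRUE} (default) the heading is updated before
#'   the position advances at each step, so the per-step heading change is
#'   exactly the angle between consecutive step vectors; \code{FALSE}
#'   translates first (sensitivity-check variant).
#' @return An object of class \code{steering_config}.
#' @examples
#' steering_config()
#' @export
steering_config <- function(W = 0.15, params = cpg_params_default(),
                            maps = speed_maps(),
                            method = c("exact", "taylor"),
                            angle_unit = c("rad", "deg"),
                            turn_first = TRUE) {
  stopifnot(is.numeric(W), length(W) == 1L, W > 0,
            inherits(params, "limb_cpg_params"),
            inherits(maps, "speed_maps"),
            isTRUE(turn_first) || isFALSE(turn_first))
  structure(list(W = W, params = params, maps = maps,
                 method = match.arg(method),
                 angle_unit = match.arg(angle_unit),
                 turn_first = turn_first),
            class = "steering_config")
}

#' @export
print.steering_config <- function(x, ...) {
  cat(sprintf("<steering_config> W = %g m, Tc method = %s, angles in %s\n",
              x$W, x$method, x$angle_unit))
  invisible(x)
}

# Tc evaluated at the mean of the two limb speeds; errors gain speed context
.step_cycle_duration <- function(V_R, V_L, cfg) {
  V_mean <- (V_R + V_L) / 2
  if (V_mean <= 0)
    stop(sprintf("mean limb speed must be > 0, got %.4g m/s", V_mean))
  u <- input_from_speed(V_mean, cfg$maps)
  tryCatch(
    cycle_duration(cfg$params, u, cfg$method)$Tc,
    cpg_error = function(e) {
      e$message <- sprintf("mean speed %.4g m/s inadmissible: %s",
                           V_mean, conditionMessage(e))
      stop(e)
    })
}

#' Per-cycle heading change from an interlimb speed difference
#'
#' \eqn{\gamma = T_c (V_R - V_L) / W} radians per step cycle, with \eqn{T_c}
#' computed from the mean of the two limb speeds (mapped to drive through the
#' speed regression). Positive \eqn{\gamma} is a turn toward the slower, left
#' limb when \eqn{V_R > V_L}; \eqn{\gamma} is exactly antisymmetric and linear
#' in the speed differential.
#'
#' @param V_R,V_L Right and left limb speeds in m/s for one step cycle.
#' @param cfg A \code{\link{steering_config}}.
#' @return Heading change in radians per cycle.
#' @examples
#' heading_change(1.075, 0.925)  # ~0.55 rad toward the left
#' @export
heading_change <- function(V_R, V_L, cfg = steering_config()) {
  stopifnot(inherits(cfg, "steering_config"),
            is.numeric(V_R), length(V_R) == 1L,
            is.numeric(V_L), length(V_L) == 1L)
  if ((V_R + V_L) / 2 <= 0)
    stop("mean limb speed must be > 0")
  Tc <- .step_cycle_duration(V_R, V_L, cfg)
  Tc * (V_R - V_L) / cfg$W
}

#' Heading-change surface over mean speed and speed differential
#'
#' Evaluates \code{\link{heading_change}} on the grid of mean speeds and
#' interlimb speed differentials (\eqn{V_{R,L} = \bar V \pm \partial V / 2}).
#' Inadmissible cells become \code{NA} with a warning rather than aborting
#' the whole surface.
#'
#' @param mean_speeds Mean limb speeds (m/s), rows of the surface.
#' @param dV Interlimb speed differentials \eqn{V_R - V_L} (m/s), columns.
#' @param cfg A \code{\link{steering_config}}.
#' @return A matrix of heading changes (rad/cycle) with \code{mean_speeds} as
#'   rownames and \code{dV} as colnames, class \code{heading_surface}.
#' @examples
#' heading_surface(c(0.5, 1, 2), seq(-0.3, 0.3, by = 0.1))
#' @export
heading_surface <- function(mean_speeds, dV, cfg = steering_config()) {
  stopifnot(is.numeric(mean_speeds), is.numeric(dV),
            inherits(cfg, "steering_config"))
  G <- matrix(NA_real_, length(mean_speeds), length(dV),
              dimnames = list(signif(mean_speeds, 8), signif(dV, 8)))
  n_bad <- 0L
  for (i in seq_along(mean_speeds)) for (j in seq_along(dV)) {
    g <- tryCatch(
      heading_change(mean_speeds[i] + dV[j] / 2, mean_speeds[i] - dV[j] / 2,
                     cfg),
      error = function(e) { n_bad <<- n_bad + 1L; NA_real_ })
    G[i, j] <- g
  }
  if (n_bad > 0L)
    warning(sprintf("%d inadmissible grid cell(s) set to NA", n_bad))
  class(G) <- c("heading_surface", class(G))
  G
}

#' Simulate a planar walking path from per-step limb-speed commands
#'
#' For each step the heading change is computed from the limb speeds, the
#' heading accumulates, and the body advances one stride
#' (mean speed x cycle duration) along the heading. With
#' \code{cfg$turn_first} (default) the turn precedes the translation.
#'
#' @param V_R,V_L Numeric vectors of per-step right/left limb speeds (m/s),
#'   equal length.
#' @param cfg A \code{\link{steering_config}}.
#' @param initial_heading Starting heading in radians (0 = along +x,
#'   counter-clockwise positive).
#' @return A data.frame of class \code{walk_path}, one row per step:
#'   \code{step}, \code{V_R}, \code{V_L}, \code{Tc_s}, \code{gamma_rad},
#'   \code{heading_rad} (cumulative, after the step's turn), \code{x_m},
#'   \code{y_m} (position after the step), \code{stride_m}.
#' @examples
#' p <- simulate_walk_path(rep(1, 5), rep(1, 5))
#' sum(p$stride_m)  # straight-path length
#' @export
simulate_walk_path <- function(V_R, V_L, cfg = steering_config(),
                               initial_heading = 0) {
  stopifnot(is.numeric(V_R), is.numeric(V_L), length(V_R) == length(V_L),
            length(V_R) >= 1L, inherits(cfg, "steering_config"),
            is.numeric(initial_heading), length(initial_heading) == 1L)
  n <- length(V_R)
  out <- data.frame(step = seq_len(n), V_R = V_R, V_L = V_L,
                    Tc_s = NA_real_, gamma_rad = NA_real_,
                    heading_rad = NA_real_, x_m = NA_real_, y_m = NA_real_,
                    stride_m = NA_real_)
  heading <- initial_heading
  pos <- c(0, 0)
  for (k in seq_len(n)) {
    res <- tryCatch(
      list(Tc = .step_cycle_duration(V_R[k], V_L[k], cfg)),
      error = function(e) {
        e$message <- sprintf("step %d: %s", k, conditionMessage(e))
        stop(e)
      })
    Tc <- res$Tc
    gamma <- Tc * (V_R[k] - V_L[k]) / cfg$W
    stride <- (V_R[k] + V_L[k]) / 2 * Tc
    if (cfg$turn_first) {
      heading <- heading + gamma
      pos <- pos + stride * c(cos(heading), sin(heading))
    } else {
      pos <- pos + stride * c(cos(heading), sin(heading))
      heading <- heading + gamma
    }
    out$Tc_s[k] <- Tc; out$gamma_rad[k] <- gamma
    out$heading_rad[k] <- heading
    out$x_m[k] <- pos[1]; out$y_m[k] <- pos[2]
    out$stride_m[k] <- stride
  }
  class(out) <- c("walk_path", class(out))
  out
}

#' Default steering scenario: increasing speed differential over five steps
#'
#' Builds the per-step limb-speed schedule used for the trajectory examples:
#' at a fixed mean speed, the interlimb differential ramps linearly from 0 to
#' \code{dV_max} over the steps. Defaults ship in the
#' \code{fig4_scenario.json} fixture (mean speeds 0.5, 1 and 2 m/s, five
#' steps, ramp to 0.3 m/s).
#'
#' @param mean_speed Mean limb speed in m/s.
#' @param n_steps Number of steps (default from the fixture).
#' @param dV_max Final interlimb speed differential (m/s).
#' @return A data.frame with columns \code{V_R}, \code{V_L}.
#' @examples
#' steering_scenario(1.0)
#' @export
steering_scenario <- function(mean_speed, n_steps = NULL, dV_max = NULL) {
  path <- system.file("extdata", "fig4_scenario.json", package = "cpgrhythm",
                      mustWork = TRUE)
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(n_steps)) n_steps <- d$n_steps
  if (is.null(dV_max)) dV_max <- d$dV_max
  stopifnot(mean_speed > 0, n_steps >= 1)
  dV <- seq(0, dV_max, length.out = n_steps)
  data.frame(V_R = mean_speed + dV / 2, V_L = mean_speed - dV / 2)
}
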