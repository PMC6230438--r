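# Event-detecting time-domain simulation of the two-state half-center system.
#
# Only one state integrates at a time; on the upward crossing of the threshold
# (1) the finishing state is reset to 0 and the antagonist takes over from 0.
# The inactive state is clamped at 0, so each phase integrates from 0 to 1.

#' Piecewise-constant drive signal
#'
#' @param u Drive value(s). A scalar gives a constant drive; a vector gives a
#'   piecewise-constant schedule with change points at \code{start}.
#' @param start Segment start times (s), strictly increasing, first must be 0.
#' @return An object of class \code{input_signal}.
#' @examples
#' input_signal(4.78)                       # constant drive
#' input_signal(c(3, 6), start = c(0, 1))   # step change at t = 1 s
#' @export
input_signal <- function(u, start = 0) {
  stopifnot(is.numeric(u), length(u) >= 1L, all(is.finite(u)),
            is.numeric(start), length(start) == length(u),
            all(is.finite(start)))
  if (start[1] != 0)
    stop("first segment must start at t = 0")
  if (length(start) > 1L && any(diff(start) <= 0))
    stop("segment start times must be strictly increasing")
  structure(list(start = as.numeric(start), u = as.numeric(u)),
            class = "input_signal")
}

#' @export
print.input_signal <- function(x, ...) {
  cat(sprintf("<input_signal> %d segment(s): u = %s at t = %s s\n",
              length(x$u), paste(signif(x$u, 6), collapse = ", "),
              paste(signif(x$start, 6), collapse = ", ")))
  invisible(x)
}

# analytic time for the active state to go from x to the threshold 1 at
# constant drive; Inf if unreachable
.time_to_threshold <- function(x, rate, r) {
  if (r == 0) {
    if (rate <= 0) return(Inf)
    return((1 - x) / rate)
  }
  # x(t) = (x + rate/r) e^{rt} - rate/r ; solve x(t) = 1
  if (rate + r <= 0) return(Inf)          # asymptote -rate/r <= 1
  log((1 + rate / r) / (x + rate / r)) / r
}

# exact propagation of the active state over h at constant drive
.propagate <- function(x, rate, r, h) {
  if (r == 0) x + rate * h
  else (x + rate / r) * exp(r * h) - rate / r
}

#' Simulate the two-state oscillator with threshold resetting
#'
#' Integrates the active half-center state
#' \eqn{\dot x = x_0 + g u + r_{leak} x} through time, locating each upward
#' threshold crossing, resetting the finishing state to 0, and handing
#' activity to the antagonist. Supports piecewise-constant drive schedules.
#'
#' Two steppers are available. \code{"exact"} (default) uses the closed-form
#' exponential update within each step and solves the local closed form for
#' the crossing time, so the only error is floating-point roundoff; it is the
#' oracle-grade engine. \code{"euler"} is a plain first-order scheme with the
#' crossing located by linear interpolation inside the bracketing step; its
#' phase-duration error shrinks linearly with \code{dt} and is used to
#' exercise convergence behaviour.
#'
#' @param params A \code{\link{limb_cpg_params}} object.
#' @param input An \code{\link{input_signal}}, or a bare numeric scalar taken
#'   as a constant drive.
#' @param t_end Simulation end time (s), \code{> 0}.
#' @param initial_active Index (1 or 2) of the initially active state; both
#'   states start at 0.
#' @param dt Sampling/integration step (s); default 1e-4, well below the
#'   shortest phase (~0.1 s) in the modelled speed range.
#' @param stepper \code{"exact"} or \code{"euler"}.
#' @return A list of class \code{cpg_simulation} with elements
#'   \describe{
#'     \item{trajectory}{data.frame \code{time}, \code{x1}, \code{x2},
#'       \code{active}; the inactive state is 0 at every sample.}
#'     \item{events}{data.frame \code{time}, \code{ending_state},
#'       \code{duration}, \code{cycle_index}, one row per phase transition.}
#'   }
#' @section Errors: if the active state cannot reach threshold (non-positive
#'   effective rate, or leak saturation), a \code{cpg_stalled_error} is
#'   signalled carrying the stall time and the active state index.
#' @examples
#' sim <- simulate_cpg(cpg_params_default(), 4.7824, t_end = 2)
#' head(sim$events)
#' @export
simulate_cpg <- function(params, input, t_end, initial_active = 1L,
                         dt = 1e-4, stepper = c("exact", "euler")) {
  stopifnot(inherits(params, "limb_cpg_params"),
            is.numeric(t_end), length(t_end) == 1L, t_end > 0,
            is.numeric(dt), length(dt) == 1L, dt > 0,
            initial_active %in% c(1L, 2L))
  stepper <- match.arg(stepper)
  if (is.numeric(input)) input <- input_signal(input)
  stopifnot(inherits(input, "input_signal"))

  r <- params$r_leak
  hcs <- list(params$hc1, params$hc2)
  seg_start <- input$start
  seg_u <- input$u
  n_seg <- length(seg_u)
  seg_end <- c(seg_start[-1], Inf)

  n <- max(1L, ceiling(t_end / dt - 1e-9))
  times <- seq(0, by = dt, length.out = n + 1L)
  times[n + 1L] <- min(times[n + 1L], t_end)
  x1v <- numeric(n + 1L); x2v <- numeric(n + 1L)
  actv <- integer(n + 1L)

  ev_time <- numeric(0); ev_state <- integer(0); ev_dur <- numeric(0)

  active <- as.integer(initial_active)
  x <- 0
  t_cur <- 0
  phase_start <- 0
  seg_i <- 1L
  actv[1L] <- active

  check_stall <- function(x, rate, t) {
    if (stepper == "euler") {
      if (rate + r * x <= 0) stop_stalled(t, active)
    } else {
      if (rate <= 0 || (r < 0 && rate + r <= 0)) stop_stalled(t, active)
    }
  }

  for (i in seq_len(n)) {
    t_next <- times[i + 1L]
    # advance from t_cur to t_next, splitting at segment boundaries and events
    while (t_cur < t_next - 1e-15) {
      while (seg_i < n_seg && seg_start[seg_i + 1L] <= t_cur + 1e-15)
        seg_i <- seg_i + 1L
      sub_end <- min(t_next, seg_end[seg_i])
      h <- sub_end - t_cur
      hc <- hcs[[active]]
      rate <- hc$x0 + hc$g * seg_u[seg_i]
      check_stall(x, rate, t_cur)
      if (stepper == "exact") {
        t_hit <- .time_to_threshold(x, rate, r)
        if (t_hit <= h) {
          t_cur <- t_cur + t_hit
          ev_time <- c(ev_time, t_cur)
          ev_state <- c(ev_state, active)
          ev_dur <- c(ev_dur, t_cur - phase_start)
          phase_start <- t_cur
          x <- 0
          active <- if (active == 1L) 2L else 1L
        } else {
          x <- .propagate(x, rate, r, h)
          t_cur <- sub_end
        }
      } else {
        x_new <- x + h * (rate + r * x)
        if (x_new >= 1) {
          frac <- (1 - x) / (x_new - x)
          t_cur <- t_cur + h * frac
          ev_time <- c(ev_time, t_cur)
          ev_state <- c(ev_state, active)
          ev_dur <- c(ev_dur, t_cur - phase_start)
          phase_start <- t_cur
          x <- 0
          active <- if (active == 1L) 2L else 1L
        } else {
          x <- x_new
          t_cur <- sub_end
        }
      }
    }
    if (active == 1L) { x1v[i + 1L] <- x; x2v[i + 1L] <- 0 }
    else              { x2v[i + 1L] <- x; x1v[i + 1L] <- 0 }
    actv[i + 1L] <- active
  }

  k <- seq_along(ev_time)
  structure(list(
    trajectory = data.frame(time = times, x1 = x1v, x2 = x2v, active = actv),
    events = data.frame(time = ev_time, ending_state = ev_state,
                        duration = ev_dur, cycle_index = (k + 1L) %/% 2L),
    params = params, input = input, dt = dt, stepper = stepper),
    class = "cpg_simulation")
}

#' @export
print.cpg_simulation <- function(x, ...) {
  cat(sprintf("<cpg_simulation> %s stepper, dt = %g s, %d samples, %d phase events\n",
              x$stepper, x$dt, nrow(x$trajectory), nrow(x$events)))
  invisible(x)
}

#' Aggregate phase events into full step cycles
#'
#' Pairs consecutive phase durations into cycles (\eqn{T_c = \tau_1 + \tau_2});
#' a trailing unpaired phase is discarded. Events must alternate between the
#' two states.
#'
#' @param events The \code{events} data.frame from \code{\link{simulate_cpg}},
#'   or a \code{cpg_simulation} object.
#' @return A data.frame with columns \code{tau1}, \code{tau2}, \code{Tc}
#'   (durations of the two phases of each cycle, in event order, and their
#'   sum), one row per complete cycle. Fewer than two events yields an empty
#'   result with a warning.
#' @examples
#' sim <- simulate_cpg(cpg_params_default(), 4.7824, t_end = 2)
#' measure_cycles(sim)
#' @export
measure_cycles <- function(events) {
  if (inherits(events, "cpg_simulation")) events <- events$events
  stopifnot(is.data.frame(events),
            all(c("ending_state", "duration") %in% names(events)))
  n <- nrow(events)
  empty <- data.frame(tau1 = numeric(0), tau2 = numeric(0), Tc = numeric(0))
  if (n < 2L) {
    warning("fewer than 2 phase events: no complete cycle")
    return(empty)
  }
  if (any(diff(events$ending_state) == 0))
    stop("phase events do not alternate between states")
  n_cyc <- n %/% 2L
  i1 <- seq(1L, by = 2L, length.out = n_cyc)
  d <- events$duration
  data.frame(tau1 = d[i1], tau2 = d[i1 + 1L], Tc = d[i1] + d[i1 + 1L])
}
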