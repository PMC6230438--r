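# Structured error conditions. All inherit from "cpg_error" so callers can
# catch model-domain failures separately from programming errors.

cpg_error <- function(class, message, ...) {
  structure(
    class = c(class, "cpg_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
}

# Effective integration rate x0 + g*u is non-positive: the state never rises,
# so there is no threshold crossing at all.
stop_nonpositive_rate <- function(rate, u_min, phase = NULL) {
  lab <- if (is.null(phase)) "" else sprintf(" in phase %d", phase)
  msg <- sprintf(
    paste0("no threshold crossing%s: effective rate x0 + g*u = %.6g <= 0; ",
           "minimal admissible input u > %.6g"),
    lab, rate, u_min)
  stop(cpg_error("cpg_nonpositive_rate_error", msg,
                 rate = rate, u_min = u_min, phase = phase))
}

# Rate is positive but too small to overcome the leak: the leaky state
# saturates at an asymptote below the threshold of 1.
stop_saturation <- function(rate, r_leak, u_min, phase = NULL) {
  lab <- if (is.null(phase)) "" else sprintf(" in phase %d", phase)
  msg <- sprintf(
    paste0("no threshold crossing%s: state saturates below threshold ",
           "(x0 + g*u = %.6g <= |r_leak| = %.6g); ",
           "minimal admissible input u > %.6g"),
    lab, rate, abs(r_leak), u_min)
  stop(cpg_error("cpg_saturation_error", msg,
                 rate = rate, r_leak = r_leak, u_min = u_min, phase = phase))
}

# Simulator counterpart: the active state's derivative dropped to zero or
# below before reaching threshold during time-domain integration.
stop_stalled <- function(time, active) {
  msg <- sprintf(
    "stalled oscillator: active state %d cannot reach threshold (t = %.6g s)",
    active, time)
  stop(cpg_error("cpg_stalled_error", msg, time = time, active = active))
}
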