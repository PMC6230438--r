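# Shared fixtures: the fitted reference parameters come from the packaged
# JSON fixture, never hard-coded in tests.

ref_params <- function() cpg_params_default()
ref_maps <- function() speed_maps()

# random admissible parameter/drive draws for property tests; admissibility
# requires both effective rates to exceed |r_leak|
draw_admissible <- function(n, seed = 421L) {
  set.seed(seed)
  draws <- vector("list", n)
  i <- 0L
  while (i < n) {
    p <- limb_cpg_params(
      half_center_params(stats::runif(1, -0.5, 3), stats::runif(1, 0.05, 1)),
      half_center_params(stats::runif(1, -0.5, 3), stats::runif(1, 0.05, 1)),
      r_leak = -stats::runif(1, 0, 0.05))
    u <- stats::runif(1, 0.5, 10)
    ok <- (p$hc1$x0 + p$hc1$g * u > -p$r_leak + 0.05) &&
          (p$hc2$x0 + p$hc2$g * u > -p$r_leak + 0.05)
    if (ok) { i <- i + 1L; draws[[i]] <- list(params = p, u = u) }
  }
  draws
}
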