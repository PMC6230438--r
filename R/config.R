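# Configuration, serialization and command dispatch binding the computational
# layers into a reproducible command-line tool. Outputs are RFC-4180 CSV with
# "." decimals plus JSON sidecars; floats are written with 9 significant
# digits so identical configs give byte-identical artifacts.

.known_keys <- list(
  params = c("x01", "x02", "g1", "g2", "r_leak"),
  maps = c("u_offset", "u_scale", "emp_coeff", "emp_exp", "swing_const"),
  top = c("params", "maps", "simulate", "validate", "steer", "surface",
          "out_dir", "seed", "verbosity"),
  simulate = c("u", "u_start", "t_end", "dt", "initial_active", "stepper"),
  validate = c("V_min", "V_max", "V_step", "method"),
  steer = c("mean_speed", "n_steps", "dV_max", "W", "initial_heading"),
  surface = c("mean_speeds", "dV", "W"))

.check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), c(allowed, "comment"))
  if (length(bad))
    stop(sprintf("unknown config key(s) in %s: %s",
                 where, paste(bad, collapse = ", ")))
}

#' Load and resolve a run configuration
#'
#' Merges, in increasing precedence: package defaults (the fitted parameter
#' fixture and printed speed-map constants), an optional JSON or YAML config
#' file, and an optional list of flag-style overrides. A fully defaulted
#' configuration (no file, no overrides) is valid. Unknown keys and values
#' violating model invariants are rejected with field-precise messages.
#'
#' @param path Optional path to a JSON (\code{.json}) or YAML
#'   (\code{.yml}/\code{.yaml}) config file.
#' @param overrides Optional named list overriding file/default values; nested
#'   as in the file schema (e.g. \code{list(steer = list(W = 0.2))}).
#' @return A list of class \code{run_config} with elements \code{params}
#'   (\code{limb_cpg_params}), \code{maps} (\code{speed_maps}), the per-command
#'   blocks \code{simulate}, \code{validate}, \code{steer}, \code{surface},
#'   \code{out_dir}, \code{seed} and \code{verbosity}, plus \code{resolved} —
#'   the flat list of every resolved value, logged by \code{run_command}.
#' @examples
#' cfg <- load_config()
#' cfg$validate$V_step
#' @export
load_config <- function(path = NULL, overrides = list()) {
  file_cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    file_cfg <- switch(ext,
      json = jsonlite::read_json(path, simplifyVector = TRUE),
      yml = ,
      yaml = {
        if (!requireNamespace("yaml", quietly = TRUE))
          stop("YAML config requires the 'yaml' package")
        yaml::read_yaml(path)
      },
      stop("config file must be .json, .yml or .yaml: ", path))
    if (is.null(file_cfg)) file_cfg <- list()
  }
  .check_keys(file_cfg, .known_keys$top, "config file")
  .check_keys(overrides, .known_keys$top, "overrides")

  merge2 <- function(base, over, keys, where) {
    .check_keys(over, keys, where)
    for (k in names(over)) if (!identical(k, "comment")) base[[k]] <- over[[k]]
    base
  }
  pdef <- jsonlite::read_json(
    system.file("extdata", "table_a1.json", package = "cpgrhythm",
                mustWork = TRUE), simplifyVector = TRUE)
  mdef <- jsonlite::read_json(
    system.file("extdata", "speed_maps.json", package = "cpgrhythm",
                mustWork = TRUE), simplifyVector = TRUE)
  sdef <- jsonlite::read_json(
    system.file("extdata", "fig4_scenario.json", package = "cpgrhythm",
                mustWork = TRUE), simplifyVector = TRUE)

  p <- merge2(merge2(pdef, file_cfg$params, .known_keys$params,
                     "config file params"),
              overrides$params, .known_keys$params, "override params")
  m <- merge2(merge2(mdef, file_cfg$maps, .known_keys$maps,
                     "config file maps"),
              overrides$maps, .known_keys$maps, "override maps")

  block <- function(name, defaults) {
    merge2(merge2(defaults, file_cfg[[name]], .known_keys[[name]],
                  paste("config file", name)),
           overrides[[name]], .known_keys[[name]], paste("override", name))
  }
  sim_blk <- block("simulate", list(u = 4.7824, u_start = 0, t_end = 5,
                                    dt = 1e-4, initial_active = 1,
                                    stepper = "exact"))
  val_blk <- block("validate", list(V_min = 0.1, V_max = 2.0, V_step = 0.05,
                                    method = "exact"))
  steer_blk <- block("steer", list(mean_speed = 1.0, n_steps = sdef$n_steps,
                                   dV_max = sdef$dV_max, W = sdef$W,
                                   initial_heading = 0))
  surf_blk <- block("surface", list(mean_speeds = round(seq(0.3, 2.0, by = 0.1), 10),
                                    dV = round(seq(-0.3, 0.3, by = 0.05), 10),
                                    W = sdef$W))

  if (p$r_leak > 0)
    stop("invalid config: params.r_leak must be <= 0, got ", p$r_leak)
  if (m$u_scale <= 0)
    stop("invalid config: maps.u_scale must be > 0, got ", m$u_scale)

  params <- limb_cpg_params(half_center_params(p$x01, p$g1),
                            half_center_params(p$x02, p$g2), p$r_leak)
  maps <- speed_maps(u_offset = m$u_offset, u_scale = m$u_scale,
                     emp_coeff = m$emp_coeff, emp_exp = m$emp_exp,
                     swing_const = m$swing_const)

  top <- function(name, default) {
    v <- default
    if (!is.null(file_cfg[[name]])) v <- file_cfg[[name]]
    if (!is.null(overrides[[name]])) v <- overrides[[name]]
    v
  }
  structure(list(
    params = params, maps = maps,
    simulate = sim_blk, validate = val_blk, steer = steer_blk,
    surface = surf_blk,
    out_dir = top("out_dir", "."),
    seed = top("seed", NULL),
    verbosity = top("verbosity", "info"),
    resolved = list(params = p, maps = m, simulate = sim_blk,
                    validate = val_blk, steer = steer_blk,
                    surface = surf_blk)),
    class = "run_config")
}

# fixed float formatting: 9 significant digits, plain "." decimal
.fmt <- function(x) {
  if (is.numeric(x)) {
    out <- formatC(x, digits = 9, format = "g")
    out[is.na(x)] <- "NA"
    trimws(out)
  } else as.character(x)
}

#' Write a data.frame as deterministic CSV
#'
#' RFC-4180 CSV with a header row and all numeric columns formatted at 9
#' significant digits, so identical inputs give byte-identical files.
#'
#' @param df A data.frame.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_csv_fixed <- function(df, path) {
  out <- as.data.frame(lapply(df, .fmt), stringsAsFactors = FALSE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.write_sidecar <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 9, pretty = TRUE)
  invisible(path)
}

.log_info <- function(cfg, ...) {
  if (!identical(cfg$verbosity, "quiet"))
    message(sprintf(...))
}

#' Run a tool command and write its artifacts
#'
#' Dispatches one of the tool's commands against a resolved configuration and
#' writes its CSV/JSON artifacts into \code{cfg$out_dir}. The fully resolved
#' configuration is logged and recorded in each JSON sidecar; the model is
#' deterministic, so identical configurations produce identical artifacts.
#'
#' Commands: \describe{
#'   \item{cycle}{print/return Taylor and exact cycle durations at one speed
#'     (\code{extra$speed}, default 1 m/s); no files written.}
#'   \item{simulate}{time-domain run; writes \code{trajectory.csv} and
#'     \code{events.csv}.}
#'   \item{validate}{speed-grid validation; writes \code{validation.csv} and
#'     \code{validation.json} (with both R-squared flavours).}
#'   \item{steer}{walking-path simulation from the steer block's scenario;
#'     writes \code{walk_path.csv} and \code{walk_path.json}.}
#'   \item{surface}{heading-change surface; writes \code{heading_surface.csv}
#'     (axis header row/column) and \code{heading_surface.json}.}
#'   \item{scenario-fig4}{paths for all fixture mean speeds; writes one
#'     \code{walk_path_<speed>.csv} each plus a shared sidecar.}
#' }
#'
#' @param cfg A \code{\link{load_config}} result.
#' @param command One of the commands above.
#' @param extra Optional command-specific list (e.g. \code{list(speed = 1)}).
#' @return The computed object, invisibly; artifact files as side effects.
#' @export
run_command <- function(cfg, command, extra = list()) {
  stopifnot(inherits(cfg, "run_config"))
  command <- match.arg(command, c("cycle", "simulate", "validate", "steer",
                                  "surface", "scenario-fig4"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  .log_info(cfg, "command '%s'; resolved config: %s", command,
            jsonlite::toJSON(cfg$resolved, auto_unbox = TRUE, digits = 9))
  fp <- function(name) file.path(cfg$out_dir, name)

  if (command == "cycle") {
    V <- if (!is.null(extra$speed)) extra$speed else 1.0
    u <- input_from_speed(V, cfg$maps)
    tay <- cycle_duration(cfg$params, u, "taylor")
    exa <- cycle_duration(cfg$params, u, "exact")
    .log_info(cfg, "V = %g m/s -> u = %.6g; Tc taylor = %.6g s, exact = %.6g s",
              V, u, tay$Tc, exa$Tc)
    return(invisible(list(speed = V, u = u, taylor = tay, exact = exa)))
  }

  if (command == "simulate") {
    b <- cfg$simulate
    sim <- simulate_cpg(cfg$params,
                        input_signal(b$u, start = b$u_start),
                        t_end = b$t_end, initial_active = b$initial_active,
                        dt = b$dt, stepper = b$stepper)
    write_csv_fixed(sim$trajectory, fp("trajectory.csv"))
    write_csv_fixed(sim$events, fp("events.csv"))
    return(invisible(sim))
  }

  if (command == "validate") {
    b <- cfg$validate
    v <- validate_speed_law(cfg$params, cfg$maps,
                            V_grid = seq(b$V_min, b$V_max, by = b$V_step),
                            method = b$method)
    write_csv_fixed(v$grid, fp("validation.csv"))
    .write_sidecar(list(r_squared = v$r_squared,
                        r_squared_identity = v$r_squared_identity,
                        method = v$method,
                        grid_spec = b, params = cfg$resolved$params,
                        maps = cfg$resolved$maps),
                   fp("validation.json"))
    return(invisible(v))
  }

  scfg <- steering_config(W = cfg$steer$W, params = cfg$params,
                          maps = cfg$maps)

  if (command == "steer") {
    b <- cfg$steer
    sc <- steering_scenario(b$mean_speed, b$n_steps, b$dV_max)
    path <- simulate_walk_path(sc$V_R, sc$V_L, scfg,
                               initial_heading = b$initial_heading)
    write_csv_fixed(path, fp("walk_path.csv"))
    .write_sidecar(list(scenario = b, params = cfg$resolved$params,
                        maps = cfg$resolved$maps), fp("walk_path.json"))
    return(invisible(path))
  }

  if (command == "surface") {
    b <- cfg$surface
    scfg$W <- b$W
    G <- heading_surface(b$mean_speeds, b$dV, scfg)
    df <- data.frame(mean_speed_mps = as.numeric(rownames(G)),
                     as.data.frame(unclass(G)), check.names = FALSE)
    names(df) <- c("mean_speed_mps", paste0("dV_", colnames(G)))
    write_csv_fixed(df, fp("heading_surface.csv"))
    .write_sidecar(list(mean_speeds = b$mean_speeds, dV = b$dV, W = b$W,
                        params = cfg$resolved$params,
                        maps = cfg$resolved$maps),
                   fp("heading_surface.json"))
    return(invisible(G))
  }

  # scenario-fig4
  d <- jsonlite::read_json(
    system.file("extdata", "fig4_scenario.json", package = "cpgrhythm",
                mustWork = TRUE), simplifyVector = TRUE)
  paths <- lapply(d$mean_speeds, function(v) {
    sc <- steering_scenario(v, d$n_steps, d$dV_max)
    p <- simulate_walk_path(sc$V_R, sc$V_L, scfg)
    write_csv_fixed(p, fp(sprintf("walk_path_%s.csv", .fmt(v))))
    p
  })
  .write_sidecar(list(scenario = d, params = cfg$resolved$params,
                      maps = cfg$resolved$maps), fp("scenario_fig4.json"))
  invisible(paths)
}
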