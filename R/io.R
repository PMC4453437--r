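# Persistence: run containers (native RDS serialization), CSV score/
# trajectory exporters, YAML configuration round-trip.

.run_container_version <- 1L
.run_required <- c("config", "maps", "occupancy", "stats", "W")

#' Save / load a simulation run
#'
#' The run container is serialized with R's native format and carries a
#' format version plus the full configuration (including the seed), so a
#' saved run can be reproduced exactly from its own echo.
#'
#' @param run a `grid3d_run`.
#' @param path file path.
#' @return `load_run` returns the `grid3d_run`; `save_run` its path,
#'   invisibly.
#' @export
save_run <- function(run, path) {
  stopifnot(inherits(run, "grid3d_run"))
  saveRDS(list(version = .run_container_version, run = run), path)
  invisible(path)
}

#' @rdname save_run
#' @export
load_run <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$version))
    stop("not a gridcell3d run container: ", path)
  if (obj$version > .run_container_version)
    stop(sprintf("run container version %d is newer than supported (%d)",
                 obj$version, .run_container_version))
  run <- obj$run
  missing <- setdiff(.run_required, names(run))
  if (length(missing))
    stop("corrupted run container: missing ", paste(missing, collapse = ", "))
  run
}

#' Write per-unit grid scores to CSV
#'
#' @param scores data.frame from [analyze_run()].
#' @param path file path.
#' @export
write_scores_csv <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}

#' Write a trajectory to CSV (columns t, x, y, z)
#'
#' @param traj matrix from [simulate_path()].
#' @param path file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(data.frame(t = seq_len(nrow(traj)) - 1L,
                              x = traj[, 1], y = traj[, 2], z = traj[, 3]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Configuration round-trip through YAML
#'
#' `write_sim_config` stores every parameter of a [run_config()] (or bare
#' [sim_config()]); `read_sim_config` rebuilds it, injecting defaults for
#' missing fields (reported via a message) and rejecting unknown ones.
#'
#' @param rc a [run_config()] or [sim_config()].
#' @param path YAML file path.
#' @return the configuration object (read) or the path (write, invisibly).
#' @export
write_sim_config <- function(rc, path) {
  if (inherits(rc, "sim_config")) rc <- list(cfg = unclass(rc))
  else if (inherits(rc, "run_config")) {
    rc <- unclass(rc); rc$cfg <- unclass(rc$cfg)
  } else stop("rc must be a sim_config or run_config")
  rc$cfg$v_step <- NULL                      # derived; recomputed on read
  yaml::write_yaml(rc, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$cfg)) stop("config file has no 'cfg' block: ", path)
  known <- names(formals(sim_config))
  extra <- setdiff(names(obj$cfg), known)
  if (length(extra))
    stop("unknown config fields: ", paste(extra, collapse = ", "))
  missing <- setdiff(setdiff(known, c("b2")), names(obj$cfg))
  if (length(missing))
    message("config fields missing, defaults injected: ",
            paste(missing, collapse = ", "))
  obj$cfg$box_scale <- as.numeric(obj$cfg$box_scale %||% c(1, 1, 1))
  cfg <- do.call(sim_config, obj$cfg)
  run_fields <- intersect(names(obj), c("n_steps", "checkpoints", "map_res",
                                        "no_collaterals", "heterogeneous_b1",
                                        "seed"))
  if ("n_steps" %in% run_fields) {
    args <- obj[run_fields]
    args$cfg <- cfg
    do.call(run_config, args)
  } else cfg
}
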