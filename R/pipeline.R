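# End-to-end pipeline driving the command-line interface (inst/cli/gmews.R).
# Exit-code convention: 0 success, 2 validation, 3 identifiability,
# 4 numerical failure.

# small stable hash (polynomial rolling hash over the serialized object)
# for manifests; deterministic across sessions
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 0
  for (b in bytes) h <- (h * 131 + b + 1) %% 2147483647
  sprintf("%08x", h)
}

write_manifest <- function(out_dir, cfg, seed) {
  manifest <- list(
    package = "gmews",
    version = as.character(utils::packageVersion("gmews")),
    seed = seed,
    config_hash = config_hash(cfg[setdiff(names(cfg), "out_dir")]))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

sim_config_for <- function(system, seed, overrides = list()) {
  builder <- switch(system,
                    allee = allee_config,
                    fishery = fishery_config,
                    food_chain = ,
                    foodchain = food_chain_config,
                    gm_validation_error(sprintf("unknown system '%s'", system)))
  cfg <- do.call(builder, c(list(seed = seed), overrides))
  cfg
}

run_simulator <- function(system, cfg) {
  switch(system,
         allee = simulate_allee(cfg),
         fishery = simulate_fishery(cfg),
         food_chain = ,
         foodchain = simulate_food_chain(cfg))
}

demo_model_for <- function(system) {
  switch(system,
         allee = allee_model(),
         fishery = fishery_model(),
         food_chain = ,
         foodchain = food_chain_model())
}

demo_smoothing_for <- function(system) {
  # the sparse 15-point population record is used raw; the two noisy
  # densely observed scenarios are smoothed
  switch(system, allee = NULL, fishery = 5L, food_chain = 5L, foodchain = 5L)
}

demo_floor_for <- function(system) {
  # slowly drifting free variables (the food-chain predator, the fishery
  # planktivore) need chord baselines comfortably above the noise amplitude
  switch(system, food_chain = 0.03, foodchain = 0.03, fishery = 0.02,
         default_spacing_floor)
}

write_warning_csv <- function(report, path) {
  df <- as.data.frame(report)
  df$trend_statistic <- report$trend_statistic
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_jacobian_csv <- function(series, path) {
  rows <- lapply(series$jacobians, function(j) {
    entries <- as.vector(t(j$matrix))
    names(entries) <- paste0("J_", outer(rownames(j$matrix), colnames(j$matrix),
                                         paste, sep = "_"))
    ev <- j$eigenvalues
    evs <- c(rbind(Re(ev), Im(ev)))
    names(evs) <- paste0(rep(c("re_lambda", "im_lambda"), length(ev)),
                         rep(seq_along(ev), each = 2))
    c(time = j$time, entries, evs)
  })
  df <- as.data.frame(do.call(rbind, rows))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run one pipeline step (the engine behind the command-line tool)
#'
#' @param cfg a list describing the run: `subcommand` (`"simulate"`,
#'   `"estimate"`, `"detect"`, `"baseline"` or `"demo"`), `out_dir`, and
#'   per-subcommand fields: `system` and `overrides` (simulate/demo);
#'   `model` (path or [gm_model()]) and `observations` (path or
#'   [gm_observations()]) plus optional `smoothing`, `tau_crit`, `rho`,
#'   `iota_min` (estimate/detect); `observations`, `channel`,
#'   `statistic`, `window`, `detrending` (baseline); `seed` everywhere
#'   randomness is involved.
#' @return invisibly, a list with `status` (0 on success) and the paths of
#'   the artifacts written. Errors of the package's condition classes
#'   carry the documented exit codes for the CLI wrapper.
#' @export
run_pipeline <- function(cfg) {
  sub <- cfg$subcommand %||% gm_validation_error("no subcommand given")
  out_dir <- cfg$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- cfg$seed %||% 1L
  artifacts <- character()

  get_model <- function() {
    m <- cfg$model %||% gm_validation_error("a model (file or object) is required")
    if (is.character(m)) read_model(m) else m
  }
  get_obs <- function(model) {
    o <- cfg$observations %||% gm_validation_error("observations (file or object) are required")
    if (is.character(o)) read_observations(o, state_names = model$variables) else o
  }

  if (sub == "simulate" || sub == "demo") {
    system <- cfg$system %||% gm_validation_error("simulate/demo need a system name")
    sim_cfg <- sim_config_for(system, seed, cfg$overrides %||% list())
    sim <- run_simulator(system, sim_cfg)
    dense_path <- file.path(out_dir, "trajectory.csv")
    write.csv(sim$dense, dense_path, row.names = FALSE, quote = FALSE)
    obs_path <- file.path(out_dir, "observations.csv")
    write_observations(sim$observations, obs_path)
    truth_path <- file.path(out_dir, "ground_truth.json")
    jsonlite::write_json(
      list(system = sim$system, seed = sim$seed,
           true_bifurcation = sim$true_bifurcation[c("parameter", "value", "time")],
           collapse_time = sim$collapse_time,
           onset_time = sim$onset_time),
      truth_path, auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null")
    artifacts <- c(dense_path, obs_path, truth_path)
    if (sub == "demo") {
      model <- demo_model_for(system)
      fit <- gm_ews(model, sim$observations,
                    smoothing = cfg$smoothing %||% demo_smoothing_for(system),
                    floor = cfg$floor %||% demo_floor_for(system),
                    tau_crit = cfg$tau_crit %||% 0.6, rho = cfg$rho %||% 0.5,
                    iota_min = cfg$iota_min %||% 1e-3)
      warn_path <- file.path(out_dir, "warning.csv")
      write_warning_csv(fit$report, warn_path)
      summary_path <- file.path(out_dir, "summary.txt")
      s_lines <- utils::capture.output({print(fit); print(sim)})
      writeLines(s_lines, summary_path)
      artifacts <- c(artifacts, warn_path, summary_path)
      tb_time <- sim$true_bifurcation$time
      if (!fit$report$warning) {
        message("demo: no warning was raised on this realization")
      } else if (is.finite(tb_time) && fit$report$warning_time >= tb_time) {
        message("demo: warning came after the fast-subsystem bifurcation")
      } else {
        message(sprintf("demo: warning at t = %g precedes the bifurcation at t = %g",
                        fit$report$warning_time, tb_time))
      }
    }
  } else if (sub == "estimate") {
    model <- get_model()
    obs <- get_obs(model)
    series <- estimate_jacobian_series(model, obs,
                                       smoothing = cfg$smoothing %||% NULL)
    jac_path <- file.path(out_dir, "jacobians.csv")
    write_jacobian_csv(series, jac_path)
    artifacts <- jac_path
  } else if (sub == "detect") {
    model <- get_model()
    obs <- get_obs(model)
    fit <- gm_ews(model, obs, smoothing = cfg$smoothing %||% NULL,
                  tau_crit = cfg$tau_crit %||% 0.6, rho = cfg$rho %||% 0.5,
                  iota_min = cfg$iota_min %||% 1e-3)
    warn_path <- file.path(out_dir, "warning.csv")
    write_warning_csv(fit$report, warn_path)
    summary_path <- file.path(out_dir, "summary.txt")
    writeLines(utils::capture.output(print(fit)), summary_path)
    artifacts <- c(warn_path, summary_path)
  } else if (sub == "baseline") {
    obs <- {
      o <- cfg$observations %||% gm_validation_error("baseline needs observations")
      if (is.character(o)) read_observations(o) else o
    }
    channel <- cfg$channel %||% names(obs$states)[1]
    series <- obs$states[[channel]] %||% obs$rates[[channel]]
    if (is.null(series)) {
      gm_validation_error(sprintf("channel '%s' not found in observations", channel))
    }
    bl <- rolling_baseline(series, statistic = cfg$statistic %||% "variance",
                           window = cfg$window %||% 5L,
                           detrending = cfg$detrending %||% "none",
                           times = obs$times)
    bl_path <- file.path(out_dir, "baseline.csv")
    write.csv(data.frame(time = bl$end_times, value = bl$values),
              bl_path, row.names = FALSE, quote = FALSE)
    artifacts <- bl_path
  } else {
    gm_validation_error(sprintf("unknown subcommand '%s'", sub))
  }
  write_manifest(out_dir, cfg, seed)
  invisible(list(status = 0L, artifacts = c(artifacts,
                                            file.path(out_dir, "manifest.json"))))
}

#' Map a package condition to the CLI exit code
#'
#' @param e a condition object.
#' @return 2 for validation/usage errors, 3 for identifiability errors,
#'   4 for numerical errors, 1 otherwise.
#' @keywords internal
#' @export
exit_code_for <- function(e) {
  if (inherits(e, "gm_identifiability_error")) return(3L)
  if (inherits(e, "gm_numerical_error") || inherits(e, "gm_degenerate_spacing")) return(4L)
  if (inherits(e, "gm_validation_error") || inherits(e, "gm_usage_error")) return(2L)
  1L
}
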