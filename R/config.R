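#' Load and validate a simulation configuration
#'
#' Reads a YAML configuration with sections `engine`, `model` and
#' (optionally) `sweep`, validates it strictly - unknown keys anywhere are
#' rejected, enumerations are checked against their allowed values,
#' tolerances must be positive - and materializes all defaults. The
#' returned object fully determines a simulation: [build_problem()] turns
#' it into a problem, `$engine` is a ready [mr_config()].
#'
#' @param path YAML file path.
#' @return List of class `mr_run_config` with elements `engine`
#'   ([mr_config()]), `reltol`, `abstol_factor`, `model` (name +
#'   overrides), `sweep` (or NULL) and `raw` (the normalized
#'   configuration, round-trippable through [write_config()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path)
  raw <- yaml::read_yaml(path)
  validate_config(raw)
}

#' @rdname load_config
#' @param config a configuration list (as parsed from YAML).
#' @export
validate_config <- function(config) {
  check_keys(config, c("engine", "model", "sweep"), "top level")

  eng <- config$engine
  if (is.null(eng)) eng <- list()
  check_keys(eng, c("strategy", "communication", "mode", "t_end", "reltol",
                    "abstol_factor", "keep_trace", "safety", "facmin",
                    "facmax"), "engine")
  eng$strategy <- check_enum(eng$strategy, c("slow-first", "fast-first"),
                             "engine.strategy")
  eng$communication <- check_enum(eng$communication,
                                  c("asynchronous", "synchronous"),
                                  "engine.communication")
  eng$mode <- check_enum(eng$mode, c("multirate", "singlerate"),
                         "engine.mode")
  eng$t_end <- check_pos(eng$t_end %||% 2, "engine.t_end")
  eng$reltol <- check_pos(eng$reltol %||% 1e-6, "engine.reltol")
  eng$abstol_factor <- check_pos(eng$abstol_factor %||% 1e-3,
                                 "engine.abstol_factor")
  eng$keep_trace <- isTRUE(eng$keep_trace %||% FALSE)
  eng$safety <- check_pos(eng$safety %||% 0.9, "engine.safety")
  eng$facmin <- check_pos(eng$facmin %||% 0.2, "engine.facmin")
  eng$facmax <- check_pos(eng$facmax %||% 2, "engine.facmax")

  mod <- config$model
  if (is.null(mod)) mod <- list()
  check_keys(mod, c("name", "synthetic", "electrical", "biochemical",
                    "protocol"), "model")
  mod$name <- check_enum(mod$name, c("synthetic", "TC-slow", "TC-fast"),
                         "model.name")
  for (sec in c("synthetic", "electrical", "biochemical", "protocol"))
    if (is.null(mod[[sec]])) mod[[sec]] <- list()

  sw <- config$sweep
  if (!is.null(sw)) {
    check_keys(sw, c("tolerances", "t_eval"), "sweep")
    sw$tolerances <- as.numeric(unlist(sw$tolerances %||% c(1e-5, 1e-6, 1e-7)))
    if (any(sw$tolerances <= 0)) stop("config key sweep.tolerances must be positive")
    sw$t_eval <- check_pos(sw$t_eval %||% 2, "sweep.t_eval")
  }

  raw <- list(engine = eng, model = mod)
  if (!is.null(sw)) raw$sweep <- sw
  structure(list(
    engine = mr_config(eng$strategy, eng$communication, eng$mode,
                       t_end = eng$t_end,
                       controller = controller_settings(eng$safety,
                                                        eng$facmin,
                                                        eng$facmax),
                       keep_trace = eng$keep_trace),
    reltol = eng$reltol, abstol_factor = eng$abstol_factor,
    model = mod, sweep = sw, raw = raw),
    class = "mr_run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_keys <- function(x, allowed, where) {
  if (is.null(x)) return(invisible(NULL))
  if (!is.list(x)) stop(sprintf("config section '%s' must be a mapping", where))
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown config key%s in %s: %s (allowed: %s)",
                 if (length(bad) > 1) "s" else "", where,
                 paste(bad, collapse = ", "), paste(allowed, collapse = ", ")))
  invisible(NULL)
}

check_enum <- function(value, allowed, key) {
  if (is.null(value)) return(allowed[1L])
  if (!is.character(value) || length(value) != 1L || !(value %in% allowed))
    stop(sprintf("config key %s must be one of: %s (got '%s')",
                 key, paste(allowed, collapse = ", "), value))
  value
}

check_pos <- function(value, key) {
  value <- suppressWarnings(as.numeric(value))
  if (length(value) != 1L || is.na(value) || value <= 0)
    stop(sprintf("config key %s must be a positive number", key))
  value
}

#' Write a configuration back to YAML
#'
#' Writes the normalized configuration of an `mr_run_config`;
#' `load_config(write_config(cfg, f))` reproduces the configuration
#' exactly.
#'
#' @param config an `mr_run_config` from [load_config()] /
#'   [validate_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "mr_run_config"))
  yaml::write_yaml(config$raw, path)
  invisible(path)
}

#' Build the configured problem
#'
#' @param config an `mr_run_config`.
#' @return An `mr_problem` ([make_synthetic_problem()] or
#'   [make_testcase()]).
#' @export
build_problem <- function(config) {
  stopifnot(inherits(config, "mr_run_config"))
  mod <- config$model
  if (mod$name == "synthetic") {
    do.call(make_synthetic_problem, mod$synthetic)
  } else {
    make_testcase(mod$name,
                  elec = do.call(electrical_params, mod$electrical),
                  bioch = do.call(biochemical_params, mod$biochemical),
                  protocol = mod$protocol,
                  t_end = config$engine$t_end)
  }
}

#' Run a configured simulation and write its outputs
#'
#' One engine run driven by an `mr_run_config`: builds the problem and
#' components, runs [mr_run()], and writes per-component trajectory CSVs,
#' a counters CSV, optionally the step trace, and a JSON manifest
#' recording the configuration snapshot, package version, counters and
#' every output file. All floating-point output uses 17 significant
#' digits, so a rerun from the manifest's configuration reproduces the
#' files bit for bit.
#'
#' @param config an `mr_run_config`.
#' @param out_dir output directory (created if missing).
#' @return The manifest list, invisibly; side effect: files in `out_dir`.
#' @export
run_simulation <- function(config, out_dir) {
  stopifnot(inherits(config, "mr_run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  problem <- build_problem(config)
  comps <- problem_components(problem, reltol = config$reltol,
                              abstol_factor = config$abstol_factor)
  res <- mr_run(comps, config$engine)
  files <- character(0)
  for (id in names(res$trajectories)) {
    tr <- res$trajectories[[id]]
    f <- file.path(out_dir, paste0("trajectory_", id, ".csv"))
    write_csv17(data.frame(time = tr$times, tr$states), f)
    files <- c(files, f)
  }
  f <- file.path(out_dir, "counters.csv")
  write_csv17(res$counters, f)
  files <- c(files, f)
  if (!is.null(res$trace)) {
    f <- file.path(out_dir, "trace.csv")
    write_csv17(res$trace, f)
    files <- c(files, f)
  }
  manifest <- list(
    package = "multirate",
    version = as.character(utils::packageVersion("multirate")),
    config = config$raw,
    status = res$status,
    message = res$message,
    macros = res$macros,
    switches = res$switches,
    counters = res$counters,
    outputs = basename(files))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(manifest, list(result = res)))
}

# CSV writer with full (17 significant digit) float precision
write_csv17 <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2))
    if (is.double(df2[[j]])) df2[[j]] <- sprintf("%.17g", df2[[j]])
  utils::write.csv(df2, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
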