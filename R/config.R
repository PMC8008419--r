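# Run configuration: a YAML or JSON file naming a built-in problem (or a
# user R file supplying a problem and simulator), the optimisation settings,
# and output locations. Unknown keys are rejected loudly so typos never
# silently fall back to defaults.

.config_keys <- c("problem", "seed", "init_size", "iterations", "n_per_eval",
                  "quantile_level", "reference_point", "output_dir",
                  "checkpoint", "pso", "gp", "fixed", "benchmark", "verbose")

.user_error <- function(...) {
  stop(structure(class = c("ssdopt_user_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Read and validate a run configuration file
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration.
#' @return A validated named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) .user_error("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A configuration list (as read from file).
#' @export
validate_run_config <- function(cfg) {
  if (!is.list(cfg)) .user_error("config must be a mapping")
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown) > 0)
    .user_error("unknown config key(s): ", paste(unknown, collapse = ", "),
                "; allowed: ", paste(.config_keys, collapse = ", "))
  if (is.null(cfg$problem)) .user_error("config needs a 'problem' entry")
  if (is.character(cfg$problem)) cfg$problem <- list(name = cfg$problem)
  if (is.null(cfg$problem$name) && is.null(cfg$problem$source))
    .user_error("'problem' needs a 'name' (built-in) or 'source' (R file)")
  unknown_p <- setdiff(names(cfg$problem),
                       c("name", "source", "params", "ranges",
                         "type2_bound", "type1_bound"))
  if (length(unknown_p) > 0)
    .user_error("unknown 'problem' key(s): ", paste(unknown_p, collapse = ", "))
  for (key in c("seed", "init_size", "iterations", "n_per_eval")) {
    if (!is.null(cfg[[key]]) &&
        (!is.numeric(cfg[[key]]) || cfg[[key]] < 0 ||
         cfg[[key]] != floor(cfg[[key]])))
      .user_error("'", key, "' must be a nonnegative integer")
  }
  if (!is.null(cfg$quantile_level) &&
      (cfg$quantile_level <= 0.5 || cfg$quantile_level >= 1))
    .user_error("'quantile_level' must lie in (0.5, 1)")
  rng <- cfg$problem$ranges
  if (!is.list(rng)) rng <- NULL
  for (nm in names(rng)) {
    r <- unlist(rng[[nm]])
    if (length(r) != 2 || !is.numeric(r) || r[2] <= r[1])
      .user_error("range for '", nm, "' must be two increasing numbers")
  }
  structure(cfg, class = c("run_config", "list"))
}

# build (problem, simulator) from a validated config
build_problem <- function(cfg) {
  pc <- cfg$problem
  ref <- if (!is.null(cfg$reference_point)) unlist(cfg$reference_point) else NULL
  if (!is.null(pc$source)) {
    env <- new.env()
    sys.source(pc$source, envir = env)
    if (!exists("problem", env) || !exists("simulator", env))
      .user_error("user problem file must define objects 'problem' and 'simulator'")
    return(list(problem = get("problem", env), simulator = get("simulator", env)))
  }
  name <- tolower(pc$name)
  pars <- pc$params %||% list()
  rng <- pc$ranges %||% list()
  if (name %in% c("cluster", "cluster_rct")) {
    params <- do.call(cluster_params, pars)
    prob <- cluster_problem(params,
                            k_range = unlist(rng$k %||% c(10, 100)),
                            n_range = unlist(rng$n %||% c(100, 500)),
                            ref_point = ref)
    list(problem = prob, simulator = cluster_simulator(params), params = params)
  } else if (name %in% c("multilevel", "pace", "multilevel_two_endpoint")) {
    params <- do.call(multilevel_params, pars)
    prob <- pace_problem(params,
                         type2_bound = pc$type2_bound %||% 0.1,
                         type1_bound = pc$type1_bound %||% 0.2,
                         ref_point = ref)
    list(problem = prob, simulator = multilevel_simulator(params),
         params = params)
  } else {
    .user_error("unknown built-in problem '", pc$name,
                "'; available: cluster, multilevel")
  }
}

build_control <- function(cfg, output_dir = NULL) {
  pso_args <- cfg$pso %||% list()
  gp_args <- cfg$gp %||% list()
  ckpt <- cfg$checkpoint %||%
    if (!is.null(output_dir)) file.path(output_dir, "checkpoint.json") else NULL
  ctl <- ego_control(
    iterations = cfg$iterations %||% 30,
    init_size = cfg$init_size,
    n_per_eval = cfg$n_per_eval %||% 100,
    quantile_level = cfg$quantile_level %||% 0.9,
    seed = cfg$seed %||% 1,
    pso = do.call(pso_control, pso_args),
    gp = do.call(gp_control, gp_args),
    checkpoint = ckpt,
    verbose = isTRUE(cfg$verbose))
  ctl$config <- unclass(cfg)  # embedded so checkpoints are self-describing
  ctl
}
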