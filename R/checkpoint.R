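# Run-state checkpointing: everything needed to resume a run (evaluation
# archive, log, substream counter, GP hyperparameters, configuration) as
# plain JSON, written after every evaluation when a checkpoint path is set.

.maybe_checkpoint <- function(arch, problem, control, stream, models,
                              iteration = 0L) {
  if (is.null(control$checkpoint)) return(invisible(NULL))
  state <- list(
    problem = problem$name,
    config = control$config,
    iteration = iteration,
    control = control[c("iterations", "init_size", "n_per_eval",
                        "quantile_level", "seed")],
    stream = stream_state(stream),
    archive = list(
      X = unname(as.matrix(arch$X)),
      design_names = problem$space$names,
      successes = unname(as.matrix(arch$succ)),
      n_samples = unname(as.matrix(arch$nsamp))
    ),
    models = if (is.null(models)) NULL else lapply(models, gp_state),
    log = arch$log
  )
  jsonlite::write_json(state, control$checkpoint, auto_unbox = TRUE,
                       digits = NA, null = "null", dataframe = "columns")
  invisible(control$checkpoint)
}

#' Read an EGO checkpoint file
#'
#' @param path Path to a checkpoint JSON written during a run.
#' @return A list with the archived evaluations, log, substream state, and
#'   configuration needed to rebuild and resume the run.
#' @export
read_checkpoint <- function(path) {
  state <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x, ncol) {
    m <- if (is.matrix(x)) x else matrix(unlist(x), ncol = ncol, byrow = TRUE)
    matrix(as.numeric(m), nrow = nrow(m), ncol = ncol(m))
  }
  D <- length(state$archive$design_names)
  state$archive$X <- as_mat(state$archive$X, D)
  colnames(state$archive$X) <- state$archive$design_names
  C <- length(state$archive$successes) / nrow(state$archive$X)
  state$archive$successes <- as_mat(state$archive$successes, C)
  state$archive$n_samples <- as_mat(state$archive$n_samples, C)
  state$log <- tibble::as_tibble(state$log)
  state
}

# rebuild an ego_run from a checkpoint plus the (non-serialisable) problem
# and simulator, so the loop can continue where it stopped
.run_from_checkpoint <- function(state, problem, sim, control) {
  structure(
    list(problem = problem, sim = sim, control = control,
         log = state$log,
         archive = list(X = state$archive$X,
                        successes = state$archive$successes,
                        n_samples = state$archive$n_samples),
         models = NULL,
         approx = NULL,
         iterations_done = state$iteration,
         stream = state$stream),
    class = "ego_run"
  )
}
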