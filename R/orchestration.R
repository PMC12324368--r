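#' Pipeline configuration
#'
#' Validates and assembles the configuration for an end-to-end run:
#' task simulation, neural simulation, trial selection, encoding-model
#' classification, and population decoding. Every stochastic stage
#' receives a sub-seed derived deterministically from the root seed, so a
#' run is bit-reproducible from `(config, seed)`.
#'
#' @param seed Root integer seed.
#' @param n_trials Trials per session.
#' @param task A [task_config()].
#' @param agent An [agent_params()].
#' @param population A [population_config()].
#' @param stages Character vector of stages to run, a subset of
#'   `c("task", "neurons", "select", "encode", "decode")`.
#' @param n_shuffle Permutation count for tuning classification.
#' @param out_dir Optional directory for CSV/JSON outputs.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_trials = 250L,
                            task = task_config(),
                            agent = agent_params(),
                            population = population_config(),
                            stages = c("task", "neurons", "select",
                                       "encode", "decode"),
                            n_shuffle = 200L, out_dir = NULL) {
  allowed <- c("task", "neurons", "select", "encode", "decode")
  bad <- setdiff(stages, allowed)
  if (length(bad)) {
    stop("unknown stages: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  stopifnot(inherits(task, "task_config"), inherits(agent, "agent_params"),
            inherits(population, "population_config"), n_trials > 0)
  structure(list(seed = as.integer(seed), n_trials = as.integer(n_trials),
                 task = task, agent = agent, population = population,
                 stages = stages, n_shuffle = as.integer(n_shuffle),
                 out_dir = out_dir),
            class = "pipeline_config")
}

stage_seed <- function(root, stage) {
  # deterministic sub-seed per stage, kept within 32-bit integer range
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(root) * 7919 + h * 104729) %% 2147483647)
}

#' Run the simulation-and-analysis pipeline for one session
#'
#' Chains the stages enabled in the configuration: task simulation,
#' population spike simulation, engaged-trial selection (via a fitted
#' GLM-HMM when requested), rate-tensor preprocessing, encoding-model
#' classification, and evidence-axis / PC1 decoding. Returns all stage
#' outputs plus a manifest of sub-seeds and wall-clock times.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_run` with elements per completed
#'   stage (`trials`, `spikes`, `selection`, `tensor_hz`, `tensor_z`,
#'   `encoding`, `labels`, `axes`, `projections`) and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- list()
  manifest <- list(seed = config$seed, stages = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- expr
    manifest$stages[[name]] <<- list(
      seed = stage_seed(config$seed, name),
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
    out
  }
  if ("task" %in% config$stages) {
    res$trials <- t_stage("task", simulate_session(
      config$task, config$agent, config$n_trials,
      seed = stage_seed(config$seed, "task")))
  }
  if ("neurons" %in% config$stages) {
    neurons <- make_population(config$population,
                               seed = stage_seed(config$seed, "population"))
    res$neurons <- neurons
    res$spikes <- t_stage("neurons", simulate_population(
      res$trials, neurons, seed = stage_seed(config$seed, "neurons")))
  }
  if ("select" %in% config$stages) {
    res$selection <- t_stage("select", select_trials(res$trials))
  }
  if (any(c("encode", "decode") %in% config$stages)) {
    res$tensor_hz <- position_bin(res$spikes)
    res$tensor_z <- zscore_tensor(res$tensor_hz)
  }
  if ("encode" %in% config$stages) {
    keep <- if (!is.null(res$selection)) res$selection$included else
      rep(TRUE, nrow(res$trials))
    fit_off <- t_stage("encode", fit_encoding_model(
      structure(unclass(res$tensor_hz)[, keep, , drop = FALSE],
                class = "rate_tensor"),
      res$trials[keep, , drop = FALSE], include_laser = FALSE))
    res$encoding <- fit_off
    res$labels <- classify_tuning(
      fit_off, n_shuffle = config$n_shuffle,
      seed = stage_seed(config$seed, "classify"))
  }
  if ("decode" %in% config$stages) {
    keep <- if (!is.null(res$selection)) res$selection$included else
      rep(TRUE, nrow(res$trials))
    tens <- structure(unclass(res$tensor_z)[, keep, , drop = FALSE],
                      class = "rate_tensor")
    tr <- res$trials[keep, , drop = FALSE]
    folds <- make_folds(tr, seed = stage_seed(config$seed, "folds"))
    res$axes <- t_stage("decode", fit_evidence_axes(tens, tr, folds))
    res$projections <- project_axes(tens, res$axes, tr)
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(res$trials)) {
      write_trials_csv(res$trials, file.path(config$out_dir, "trials.csv"))
    }
    if (!is.null(res$labels)) {
      utils::write.csv(res$labels, file.path(config$out_dir, "labels.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(config$out_dir,
                                             "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res$manifest <- manifest
  class(res) <- "pipeline_run"
  res
}
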