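#' Simulate and analyse one opponent-rule session end to end
#'
#' Runs the full chain for one recording session under inhibition of one
#' striatal pathway: task simulation, Poisson population simulation with
#' the pathway's opponent laser rule, engaged-trial selection, rate-tensor
#' preprocessing, evidence-decoding axes over the requested positions,
#' cross-validated projections, and the PC1 control axis. Returns the
#' session-level quantities used by the laser-shift analyses.
#'
#' The default population is built so that the opponent laser perturbation
#' lies in the evidence-difference mode and is orthogonal to the shared
#' position-dynamics mode: evidence neurons come in matched ipsi/contra
#' pairs, position-gain deviations are zero-mean, and baselines are high
#' enough that inhibition never clips rates at zero. Under this
#' construction the evidence-axis projection shifts with the laser while
#' the PC1 projection does not.
#'
#' @param pathway `"indirect"`, `"direct"` or `"no_opsin"`.
#' @param n_trials Trials to simulate (default 190).
#' @param pop A [population_config()]; its `pathway` is overridden.
#' @param agent An [agent_params()]; pathway-appropriate laser weight by
#'   default (indirect biases ipsilaterally, direct contralaterally).
#' @param positions Position bins for the evidence axes (default: the
#'   second half of the cue region, where laser shifts are quantified).
#' @param seed Integer seed for the session.
#' @return A list: `shift` (evidence-axis laser shift), `pc1_shift`,
#'   `pc1_p` (per-session laser term p-value on the PC1 projection),
#'   `behavior_bias` (% ipsilateral laser bias), `proj_df` (per-trial
#'   projection records for pooled mixed-effects tests), and `n_trials`.
#' @export
simulate_opponent_session <- function(pathway = c("indirect", "direct",
                                                  "no_opsin"),
                                      n_trials = 190,
                                      pop = NULL, agent = NULL,
                                      positions = NULL, seed = 1L) {
  pathway <- match.arg(pathway)
  if (is.null(pop)) {
    pop <- population_config(n_evidence = 16L, n_choice = 8L,
                             n_outcome = 4L, n_untuned = 32L,
                             pathway = pathway, baseline_hz = 25,
                             evidence_gain_hz = 0.6, laser_effect_hz = 2,
                             position_gain_hz = 0, position_gain_sd = 6)
  } else {
    pop$pathway <- pathway
  }
  if (is.null(agent)) {
    lw <- switch(pathway, indirect = 1, direct = -1, no_opsin = 0)
    agent <- agent_params(laser_weight = lw)
  }
  if (is.null(positions)) {
    # second half of the cue region, sampled at 10-cm resolution
    pb <- position_bins()
    positions <- which(pb$lo >= 100 & pb$lo < 200)[c(TRUE, FALSE)]
  }
  set.seed(seed)
  trials <- simulate_session(task_config(), agent, n_trials,
                             seed = seed)
  neurons <- make_population(pop)
  spikes <- simulate_population(trials, neurons)
  # engaged, non-early, non-warm-up trials (generator ground truth)
  keep <- trials$state == 1 & !trials$early_turn &
    trials$maze_type != "warmup"
  trials_k <- trials[keep, , drop = FALSE]
  tensor_z <- zscore_tensor(position_bin(spikes))
  tensor_k <- structure(unclass(tensor_z)[, keep, , drop = FALSE],
                        class = "rate_tensor",
                        positions = attr(tensor_z, "positions"))
  folds <- make_folds(trials_k, min_trials = 40)
  axes <- fit_evidence_axes(tensor_k, trials_k, folds,
                            positions = positions)
  proj <- project_axes(tensor_k, axes, trials_k)
  shift <- projection_laser_shift(proj)
  pc1 <- fit_pc1(tensor_k, trials_k, folds)
  proj_pc1 <- project_axes(tensor_k, pc1, trials_k)
  ev_norm <- trials_k$final_evidence /
    max(abs(trials_k$final_evidence), 1)
  ev01 <- (ev_norm + 1) / 2 # normalised to [0, 1]
  mean_over <- function(p) rowMeans(p$values, na.rm = TRUE)
  proj_df <- tibble(
    activity = mean_over(proj),
    activity_pc1 = mean_over(proj_pc1),
    evidence = ev01,
    laser = as.numeric(trials_k$laser)
  )
  pc1_fit <- mixed_effects_laser_test(
    dplyr::mutate(proj_df, activity = .data$activity_pc1, neuron = 1),
    covariate = "evidence", group = "neuron")
  pc1_row <- pc1_fit[pc1_fit$term == "laser", ]
  bias <- tryCatch(laser_bias(trials_k), error = function(e) NA_real_)
  list(shift = shift,
       pc1_shift = pc1_row$estimate, pc1_p = pc1_row$p,
       behavior_bias = bias, proj_df = proj_df,
       n_trials = nrow(trials_k))
}

#' Multi-session opponent-rule laser-shift study
#'
#' Simulates `n_sessions` sessions under one pathway rule and pools them:
#' the evidence-axis laser shift is tested with the mixed-effects model
#' `projection ~ 1 + evidence + laser + (1 + evidence + laser | session)`,
#' and the PC1 laser shift is summarised by the per-session p-values.
#'
#' @param pathway Pathway rule.
#' @param n_sessions Number of sessions (replicates).
#' @param seed Root seed; session `i` uses `seed + i`.
#' @param ... Passed to [simulate_opponent_session()].
#' @return A list: `sessions` (tibble of per-session shift, PC1 p,
#'   behavioural bias), `laser_effect` (mixed-effects laser row for the
#'   evidence projection), `pc1_nonsig_fraction`.
#' @export
opponent_shift_study <- function(pathway, n_sessions = 12, seed = 1L, ...) {
  runs <- lapply(seq_len(n_sessions), function(i) {
    # sessions failing trial-count QC are re-drawn with a shifted seed
    for (attempt in 0:5) {
      out <- tryCatch(
        simulate_opponent_session(pathway, seed = seed + i + 10000L * attempt,
                                  ...),
        error = function(e) NULL)
      if (!is.null(out)) return(out)
    }
    stop("could not simulate a QC-passing session", call. = FALSE)
  })
  sessions <- purrr::map_dfr(seq_along(runs), function(i) {
    tibble(session = i, neural_shift = runs[[i]]$shift,
           pc1_shift = runs[[i]]$pc1_shift, pc1_p = runs[[i]]$pc1_p,
           behavior_bias = runs[[i]]$behavior_bias,
           n_trials = runs[[i]]$n_trials)
  })
  pooled <- purrr::map_dfr(seq_along(runs), function(i) {
    dplyr::mutate(runs[[i]]$proj_df, session = i)
  })
  me <- mixed_effects_laser_test(pooled, covariate = "evidence",
                                 group = "session")
  list(sessions = sessions,
       laser_effect = me[me$term == "laser", ],
       pc1_nonsig_fraction = mean(sessions$pc1_p > 0.05, na.rm = TRUE))
}
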