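# Shared small fixtures, built once per test run.

# A modest session with neural data, reused by encoding/decoding tests.
fixture_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      trials <- simulate_session(task_config(), agent_params(), 170,
                                 seed = 101)
      trials <- trials[trials$maze_type != "warmup", , drop = FALSE]
      trials <- trials[seq_len(150), , drop = FALSE]
      pop <- population_config(n_evidence = 16L, n_choice = 8L,
                               n_outcome = 4L, n_untuned = 12L)
      neurons <- make_population(pop, seed = 102)
      spikes <- simulate_population(trials, neurons, seed = 103)
      tensor_hz <- position_bin(spikes)
      cache <<- list(trials = trials, neurons = neurons, spikes = spikes,
                     tensor_hz = tensor_hz,
                     tensor_z = zscore_tensor(tensor_hz))
    }
    cache
  }
})

# A minimal trial table with hand-set fields for behavioural unit tests.
toy_trials <- function(evidence, choice = NULL, laser = NULL,
                       rewarded = NULL, correct = NULL) {
  n <- length(evidence)
  if (is.null(choice)) choice <- ifelse(evidence >= 0, "right", "left")
  if (is.null(rewarded)) rewarded <- ifelse(evidence >= 0, "right", "left")
  if (is.null(correct)) correct <- choice == rewarded
  if (is.null(laser)) laser <- rep(FALSE, n)
  tibble::tibble(
    trial = seq_len(n), maze_type = "main",
    rewarded_side = rewarded, choice = choice, correct = correct,
    laser = laser, state = 1L,
    n_left = pmax(0, -evidence), n_right = pmax(0, evidence),
    final_evidence = evidence, tie = evidence == 0,
    speed = 40, early_turn = FALSE
  )
}
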