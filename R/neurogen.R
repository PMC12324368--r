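#' Configure a synthetic neural population
#'
#' Describes a population of evidence-, choice-, outcome-tuned and untuned
#' neurons recorded under inhibition of one striatal pathway. Laser effects
#' on evidence-tuned neurons follow the pathway-specific opponent rule:
#' indirect-pathway inhibition excites contralateral-preferring and
#' inhibits ipsilateral-preferring evidence neurons; direct-pathway
#' inhibition excites ipsilateral-preferring evidence neurons and leaves
#' contralateral-preferring ones unchanged; a no-opsin population has no
#' laser effect anywhere. Effect magnitudes are free generator parameters
#' (the analyses estimate them back).
#'
#' @param n_evidence,n_choice,n_outcome,n_untuned Neuron counts per tuning
#'   class; evidence and choice classes are split evenly between
#'   ipsilateral and contralateral preference.
#' @param pathway `"indirect"`, `"direct"` or `"no_opsin"`.
#' @param baseline_hz Mean baseline rate in Hz (per-neuron baselines are
#'   jittered around this).
#' @param evidence_gain_hz Rate change per unit signed evidence at full
#'   ramp, in Hz.
#' @param choice_step_hz Rate step for a preferred-side choice, in Hz.
#' @param outcome_step_hz Rate step after a rewarded previous trial, in Hz.
#' @param laser_effect_hz Magnitude of the additive laser effect on
#'   evidence-tuned neurons, in Hz (sign set by the pathway rule).
#' @param laser_rule Optional function `(pathway, tuning_class, side_pref)
#'   -> signed Hz` overriding the default opponent rule.
#' @param evidence_ramp_cm Distance over which evidence coding ramps to
#'   full strength from the start of the cue region (default 200, i.e.
#'   linear across the whole cue region; smaller values give evidence
#'   coding that saturates earlier).
#' @param position_gain_hz,position_gain_sd Mean and SD of the per-neuron
#'   position-locked rate component (Hz at maze entry, decaying linearly
#'   to zero at the maze end). This shared progression-of-position
#'   dynamic is what the population's first principal component captures;
#'   set the mean to 0 to remove it.
#' @param time_step Spike-count bin width in seconds (default 0.010).
#' @return A list of class `population_config`.
#' @export
population_config <- function(n_evidence = 40L, n_choice = 20L,
                              n_outcome = 10L, n_untuned = 30L,
                              pathway = c("indirect", "direct", "no_opsin"),
                              baseline_hz = 10, evidence_gain_hz = 1.5,
                              choice_step_hz = 6, outcome_step_hz = 4,
                              laser_effect_hz = 4, laser_rule = NULL,
                              evidence_ramp_cm = 200,
                              position_gain_hz = 3, position_gain_sd = 1.5,
                              time_step = 0.010) {
  pathway <- match.arg(pathway)
  stopifnot(n_evidence >= 0, n_choice >= 0, n_outcome >= 0, n_untuned >= 0,
            baseline_hz >= 0, time_step > 0)
  structure(list(
    n_evidence = as.integer(n_evidence), n_choice = as.integer(n_choice),
    n_outcome = as.integer(n_outcome), n_untuned = as.integer(n_untuned),
    pathway = pathway, baseline_hz = baseline_hz,
    evidence_gain_hz = evidence_gain_hz, choice_step_hz = choice_step_hz,
    outcome_step_hz = outcome_step_hz, laser_effect_hz = laser_effect_hz,
    laser_rule = laser_rule, evidence_ramp_cm = evidence_ramp_cm,
    position_gain_hz = position_gain_hz,
    position_gain_sd = position_gain_sd, time_step = time_step
  ), class = "population_config")
}

default_laser_rule <- function(pathway, tuning_class, side_pref, magnitude) {
  if (pathway == "no_opsin" || tuning_class != "evidence") return(0)
  if (pathway == "indirect") {
    if (side_pref == "contra") magnitude else -magnitude
  } else { # direct
    if (side_pref == "ipsi") magnitude else 0
  }
}

#' Build the neuron roster for a population
#'
#' Draws per-neuron tuning parameters (baseline, gain, laser effect) from a
#' [population_config()]. Baselines are jittered log-normally around the
#' configured mean so the z-scoring stage is exercised. With
#' `paired_evidence = TRUE` (the default) evidence neurons are generated
#' as matched ipsilateral/contralateral pairs sharing the same baseline
#' and position gain, so the opponent laser perturbation (excite one
#' preference, inhibit the other) lies in the evidence-difference mode of
#' the population and is orthogonal, by construction, to the shared
#' position-dynamics mode that PC1 captures.
#'
#' @param pop A [population_config()].
#' @param seed Optional integer seed.
#' @param paired_evidence Match baseline and position gain within
#'   ipsi/contra evidence-neuron pairs (default TRUE).
#' @return A tibble of class `neuron_table` with one row per neuron:
#'   `neuron`, `tuning_class`, `side_pref`, `baseline`, `pos_gain`,
#'   `gain`, `laser_effect`.
#' @export
make_population <- function(pop, seed = NULL, paired_evidence = TRUE) {
  stopifnot(inherits(pop, "population_config"))
  if (!is.null(seed)) set.seed(seed)
  half <- function(n) c(rep("ipsi", ceiling(n / 2)), rep("contra", floor(n / 2)))
  specs <- dplyr::bind_rows(
    tibble(tuning_class = "evidence", side_pref = half(pop$n_evidence),
           gain = pop$evidence_gain_hz),
    tibble(tuning_class = "choice", side_pref = half(pop$n_choice),
           gain = pop$choice_step_hz),
    tibble(tuning_class = "outcome",
           side_pref = rep("none", pop$n_outcome), gain = pop$outcome_step_hz),
    tibble(tuning_class = "untuned",
           side_pref = rep("none", pop$n_untuned), gain = 0)
  )
  rule <- pop$laser_rule %||% function(p, tc, sp) {
    default_laser_rule(p, tc, sp, pop$laser_effect_hz)
  }
  out <- specs |>
    dplyr::mutate(
      neuron = dplyr::row_number(),
      baseline = pop$baseline_hz * exp(rnorm(dplyr::n(), 0, 0.25)),
      pos_gain = rnorm(dplyr::n(), pop$position_gain_hz,
                       pop$position_gain_sd),
      ramp_cm = pop$evidence_ramp_cm,
      laser_effect = purrr::map2_dbl(.data$tuning_class, .data$side_pref,
                                     ~ rule(pop$pathway, .x, .y)),
      .before = 1
    )
  if (paired_evidence && pop$n_evidence >= 2) {
    ev <- which(out$tuning_class == "evidence")
    ipsi <- ev[out$side_pref[ev] == "ipsi"]
    contra <- ev[out$side_pref[ev] == "contra"]
    n_pair <- min(length(ipsi), length(contra))
    out$baseline[contra[seq_len(n_pair)]] <-
      out$baseline[ipsi[seq_len(n_pair)]]
    out$pos_gain[contra[seq_len(n_pair)]] <-
      out$pos_gain[ipsi[seq_len(n_pair)]]
  }
  structure(out, class = c("neuron_table", class(out)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Position ramps: evidence tuning rises linearly over ramp_cm from cue
# onset and is sustained through the delay; choice tuning rises late.
evidence_ramp <- function(position, ramp_cm = 200) {
  clamp(position / ramp_cm, 0, 1)
}
choice_ramp <- function(position) clamp((position - 150) / 100, 0, 1)

#' Ground-truth firing rate of one synthetic neuron
#'
#' Evidence-class neurons change rate gradedly with the signed cumulative
#' evidence (#ipsi - #contra), scaled by a ramp that grows across the cue
#' region and is sustained through the delay; their preference holds on
#' both correct and incorrect trials. Choice-class neurons step with the
#' selected choice only (independent of evidence given choice), rising
#' toward the delay region, so their apparent evidence preference reverses
#' on incorrect trials. Outcome-class neurons step with the previous
#' trial's outcome; untuned neurons sit at baseline. The additive laser
#' effect applies while `laser_active` is TRUE, and rates are floored at 0.
#'
#' @param neuron One row of a [make_population()] table (list or
#'   single-row data frame).
#' @param position Numeric vector of maze positions (cm).
#' @param cum_evidence Signed cumulative evidence at each `position`.
#' @param choice Trial choice, `"left"` or `"right"` (ipsi = right).
#' @param prev_correct Logical, previous trial rewarded.
#' @param laser_active Logical vector (or scalar): laser on at `position`.
#' @return Numeric vector of rates in Hz, same length as `position`.
#' @export
ground_truth_rate <- function(neuron, position, cum_evidence = 0,
                              choice = "right", prev_correct = TRUE,
                              laser_active = FALSE) {
  tc <- neuron$tuning_class
  pref_sign <- switch(as.character(neuron$side_pref),
                      ipsi = 1, contra = -1, none = 0)
  chose_pref <- (choice == "right" && neuron$side_pref == "ipsi") ||
    (choice == "left" && neuron$side_pref == "contra")
  rate <- switch(as.character(tc),
    evidence = neuron$baseline + neuron$gain * pref_sign * cum_evidence *
      evidence_ramp(position, neuron$ramp_cm %||% 200),
    choice = neuron$baseline +
      neuron$gain * as.numeric(chose_pref) * choice_ramp(position),
    outcome = neuron$baseline +
      neuron$gain * as.numeric(prev_correct) + 0 * position,
    untuned = neuron$baseline + 0 * position,
    stop("unknown tuning class: ", tc, call. = FALSE)
  )
  rate <- rate + neuron$pos_gain * (1 - (position + 30) / 330)
  rate <- rate + neuron$laser_effect * as.numeric(laser_active)
  pmax(rate, 0)
}

# Ground-truth rates for the whole population at once (neurons x time),
# identical to ground_truth_rate() row by row but built from outer
# products for speed.
population_rate_matrix <- function(neurons, position, cum_evidence, choice,
                                   prev_correct, laser_active) {
  pref_sign <- ifelse(neurons$side_pref == "ipsi", 1,
                      ifelse(neurons$side_pref == "contra", -1, 0))
  chose_pref <- (choice == "right" & neurons$side_pref == "ipsi") |
    (choice == "left" & neurons$side_pref == "contra")
  ev_coef <- ifelse(neurons$tuning_class == "evidence",
                    neurons$gain * pref_sign, 0)
  ch_coef <- ifelse(neurons$tuning_class == "choice",
                    neurons$gain * as.numeric(chose_pref), 0)
  out_coef <- ifelse(neurons$tuning_class == "outcome",
                     neurons$gain * as.numeric(prev_correct), 0)
  ramp_cm <- if ("ramp_cm" %in% names(neurons)) neurons$ramp_cm[1] else 200
  rate <- outer(neurons$baseline + out_coef, rep(1, length(position))) +
    outer(neurons$pos_gain, 1 - (position + 30) / 330) +
    outer(ev_coef, cum_evidence * evidence_ramp(position, ramp_cm)) +
    outer(ch_coef, choice_ramp(position)) +
    outer(neurons$laser_effect, as.numeric(laser_active))
  pmax(rate, 0)
}

#' Simulate Poisson spike trains for a population across a session
#'
#' For each trial, the agent traverses -30 to 300 cm at the trial's speed;
#' spikes are emitted as Poisson counts in `time_step` bins around each
#' neuron's ground-truth rate, which depends on position, the trial's
#' cumulative evidence, choice, previous outcome, and (on laser trials,
#' within the cue region only) the neuron's laser effect.
#'
#' @param trials A trial table from [simulate_session()].
#' @param neurons A [make_population()] table.
#' @param time_step Bin width in seconds (default 0.010).
#' @param seed Optional integer seed.
#' @return A list of class `spike_data`: `counts` (per trial, a neurons x
#'   time-bins integer matrix), `position` (per trial, position at each
#'   time bin), `laser_on` (per trial, logical per time bin), `neurons`,
#'   `time_step`.
#' @export
simulate_population <- function(trials, neurons, time_step = 0.010,
                                seed = NULL) {
  stopifnot(nrow(trials) > 0, nrow(neurons) > 0)
  if (!is.null(seed)) set.seed(seed)
  prev_correct <- dplyr::lag(trials$correct, default = TRUE)
  n_neur <- nrow(neurons)
  counts <- position <- laser_on <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    speed <- if ("speed" %in% names(trials)) trials$speed[i] else 40
    if (is.na(speed) || speed <= 0) stop("zero-duration trial", call. = FALSE)
    duration <- 330 / speed
    n_bins <- floor(duration / time_step)
    if (n_bins < 1) stop("zero-duration trial", call. = FALSE)
    pos <- -30 + speed * (seq_len(n_bins) - 0.5) * time_step
    ev_bins <- trials$cum_evidence[[i]]
    bin_idx <- clamp(floor((pos + 30) / POSITION_BIN_WIDTH) + 1, 1,
                     N_POSITION_BINS)
    cum_ev <- ev_bins[bin_idx]
    las <- trials$laser[i] & pos >= 0 & pos < 200
    rate <- population_rate_matrix(neurons, pos, cum_ev, trials$choice[i],
                                   prev_correct[i], las)
    counts[[i]] <- matrix(rpois(n_neur * n_bins, rate * time_step),
                          n_neur, n_bins)
    position[[i]] <- pos
    laser_on[[i]] <- las
  }
  structure(list(counts = counts, position = position, laser_on = laser_on,
                 neurons = neurons, time_step = time_step),
            class = "spike_data")
}

#' Simulate off-task laser sweeps
#'
#' Outside the maze, each laser sweep spans -3 s to +6 s around laser
#' onset, with 3 s of continuous illumination (0-3 s) followed by a laser
#' off interval. Neurons fire at baseline off laser and at
#' baseline + laser effect during illumination, with Poisson emission.
#'
#' @param neurons A [make_population()] table.
#' @param n_sweeps Number of sweeps, between 30 and 40.
#' @param time_step Bin width in seconds (default 0.010).
#' @param seed Optional integer seed.
#' @return A list of class `off_task_sweeps`: `counts` (neurons x sweeps x
#'   time-bins array), `time` (bin centres in s, spanning \[-3, 6\]),
#'   `laser_interval = c(0, 3)`, `time_step`, `neurons`.
#' @export
simulate_off_task <- function(neurons, n_sweeps = 35L, time_step = 0.010,
                              seed = NULL) {
  stopifnot(n_sweeps >= 30, n_sweeps <= 40)
  if (!is.null(seed)) set.seed(seed)
  tm <- seq(-3 + time_step / 2, 6 - time_step / 2, by = time_step)
  n_t <- length(tm)
  n_neur <- nrow(neurons)
  rate <- outer(neurons$baseline, rep(1, n_t)) +
    outer(neurons$laser_effect, as.numeric(tm >= 0 & tm < 3))
  rate <- pmax(rate, 0)
  lam <- array(0, dim = c(n_neur, n_sweeps, n_t))
  for (s in seq_len(n_sweeps)) lam[, s, ] <- rate * time_step
  counts <- array(rpois(length(lam), lam), dim = dim(lam))
  structure(list(counts = counts, time = tm, laser_interval = c(0, 3),
                 time_step = time_step, neurons = neurons),
            class = "off_task_sweeps")
}
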