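#' Task configuration for the accumulation-of-evidence T-maze
#'
#' Bundles the geometry and scheduling parameters of the virtual T-maze
#' task: a start region (-30-0 cm), a cue region (0-200 cm) in which
#' transient visual cues appear on both walls, and a delay region
#' (200-300 cm) without cues. On main-maze trials the mean cue rates on the
#' majority (rewarded-rate) and minority side are drawn from one of two
#' rate pairs, 8.0:1.6 per metre (~50% of trials) or 7.3:2.3 per metre
#' (~32% of trials); the remaining trials arise from warm-up and easy-block
#' scheduling rules rather than fixed quotas. Same-side cues are separated
#' by a refractory window. The laser is delivered on a random subset of
#' main-maze trials, only while the agent is inside the cue region.
#'
#' @param cue_rate_pairs List of `c(majority, minority)` rates in cues per
#'   metre for main-maze trials.
#' @param cue_rate_weights Mixture weights for the rate pairs (renormalised).
#' @param refractory Minimum same-side cue spacing in cm (default 12).
#' @param laser_fraction Probability of laser delivery on a main-maze trial;
#'   must lie in \[0.10, 0.20\] unless `allow_any_laser_fraction = TRUE`.
#' @param warmup_n Maximum number of warm-up trials at session start
#'   (default 10); warm-up also ends once warm-up accuracy exceeds
#'   `warmup_accuracy`.
#' @param warmup_accuracy Warm-up exit accuracy threshold in % (default 85).
#' @param easy_accuracy Running-accuracy threshold in % that triggers an
#'   easy block (default 55).
#' @param easy_window Running-accuracy window in trials (default 40).
#' @param easy_block_length Length of an easy block in trials (default 10).
#' @param error_window_sigma Half-Gaussian sigma (trials) for the
#'   side-specific error fractions used by the debiasing controller
#'   (default 20, over the most recent 40 same-side-rewarded trials).
#' @param empirical_sigma Half-Gaussian sigma (trials) for the empirical
#'   right-rewarded fraction (default 60).
#' @param sqrt_cap Bounds applied to `sqrt(eR)` and `sqrt(eL)` before the
#'   softmax (default `c(0.15, 0.85)`).
#' @param allow_any_laser_fraction Set `TRUE` to bypass the laser-fraction
#'   range check (for null simulations with `laser_fraction = 0`).
#' @return A list of class `task_config`.
#' @export
task_config <- function(cue_rate_pairs = list(c(8.0, 1.6), c(7.3, 2.3)),
                        cue_rate_weights = c(0.50, 0.32),
                        refractory = 12,
                        laser_fraction = 0.15,
                        warmup_n = 10L,
                        warmup_accuracy = 85,
                        easy_accuracy = 55,
                        easy_window = 40L,
                        easy_block_length = 10L,
                        error_window_sigma = 20,
                        empirical_sigma = 60,
                        sqrt_cap = c(0.15, 0.85),
                        allow_any_laser_fraction = FALSE) {
  stopifnot(length(cue_rate_pairs) == length(cue_rate_weights),
            all(cue_rate_weights >= 0), sum(cue_rate_weights) > 0,
            refractory > 0, refractory < 200)
  if (!allow_any_laser_fraction &&
      (laser_fraction < 0.10 || laser_fraction > 0.20)) {
    stop("`laser_fraction` must lie in [0.10, 0.20]; ",
         "set `allow_any_laser_fraction = TRUE` to override.", call. = FALSE)
  }
  structure(list(
    cue_rate_pairs = cue_rate_pairs,
    cue_rate_weights = cue_rate_weights / sum(cue_rate_weights),
    refractory = refractory,
    laser_fraction = laser_fraction,
    warmup_n = as.integer(warmup_n),
    warmup_accuracy = warmup_accuracy,
    easy_accuracy = easy_accuracy,
    easy_window = as.integer(easy_window),
    easy_block_length = as.integer(easy_block_length),
    error_window_sigma = error_window_sigma,
    empirical_sigma = empirical_sigma,
    sqrt_cap = sqrt_cap
  ), class = "task_config")
}

#' Generate one trial's visual cues by a spatial Poisson process
#'
#' Draws cue positions independently on each maze side from a homogeneous
#' spatial Poisson process over the cue region, then enforces the same-side
#' refractory window by sequential rejection: positions are sorted and any
#' cue closer than `refractory` cm to the previously kept cue on the same
#' side is deleted.
#'
#' @param rate_left,rate_right Cue rates in cues per metre (>= 0).
#' @param region_length Cue-region length in cm (default 200).
#' @param refractory Minimum same-side spacing in cm (default 12); must be
#'   smaller than `region_length`.
#' @return A list with sorted numeric vectors `left` and `right` of cue
#'   positions in cm within `[0, region_length)`.
#' @export
generate_cues <- function(rate_left, rate_right, region_length = 200,
                          refractory = 12) {
  if (rate_left < 0 || rate_right < 0) {
    stop("cue rates must be non-negative", call. = FALSE)
  }
  if (region_length <= 0 || refractory >= region_length) {
    stop("need 0 < refractory < region_length", call. = FALSE)
  }
  draw_side <- function(rate_per_m) {
    n <- rpois(1, rate_per_m * region_length / 100)
    pos <- sort(runif(n, 0, region_length))
    if (length(pos) < 2L || refractory <= 0) return(pos)
    keep <- logical(length(pos))
    last <- -Inf
    for (i in seq_along(pos)) {
      if (pos[i] - last >= refractory) {
        keep[i] <- TRUE
        last <- pos[i]
      }
    }
    pos[keep]
  }
  list(left = draw_side(rate_left), right = draw_side(rate_right))
}

#' Debiased probability of drawing a right-rewarded trial
#'
#' Closed-loop side-debiasing: `eR` and `eL` are recency-weighted error
#' fractions on recent right- and left-rewarded trials. Their square roots
#' are clamped into `cap` and passed through a softmax,
#' `PR = exp(cR) / (exp(cR) + exp(cL))`, so that a side with more recent
#' errors is drawn more often. The caps bound `PR` within
#' `[logistic(-diff(cap)), logistic(diff(cap))]`, discouraging long
#' single-side sequences.
#'
#' @param eR,eL Weighted error fractions in \[0, 1\].
#' @param cap Clamp bounds for the square-rooted error fractions
#'   (default `c(0.15, 0.85)`).
#' @return Probability of drawing a right-rewarded trial, in (0, 1).
#' @export
debias_probability <- function(eR, eL, cap = c(0.15, 0.85)) {
  stopifnot(eR >= 0, eR <= 1, eL >= 0, eL <= 1)
  cR <- clamp(sqrt(eR), cap[1], cap[2])
  cL <- clamp(sqrt(eL), cap[1], cap[2])
  exp(cR) / (exp(cR) + exp(cL))
}

#' Draw the rewarded side under the pseudo-random debiasing prescription
#'
#' Because the empirical fraction of right-rewarded draws can deviate from
#' the target `PR` over short histories, the draw probability is pulled
#' back: when the empirical right fraction exceeds `PR`, right is drawn
#' with probability `0.5 * PR`; otherwise with `0.5 * (1 + PR)`.
#'
#' @param PR Target probability of a right-rewarded draw.
#' @param empirical_right Recency-weighted empirical right fraction.
#' @return `"left"` or `"right"`.
#' @export
draw_rewarded_side <- function(PR, empirical_right) {
  stopifnot(PR >= 0, PR <= 1, empirical_right >= 0, empirical_right <= 1)
  p_right <- if (empirical_right > PR) 0.5 * PR else 0.5 * (1 + PR)
  if (runif(1) < p_right) "right" else "left"
}

#' Parameters of the multi-state GLM-HMM behavioural agent
#'
#' The agent occupies one of `K` latent states with fixed transition
#' probabilities; in state `k` its choice is Bernoulli with
#' `P(right) = logistic(w_k . u)` where the covariates `u` are, in order:
#' delta cues (#right - #left), previous choice (-1/+1), previous rewarded
#' choice (-1/+1, 0 if unrewarded), laser (0/1), and a constant bias.
#' The defaults give a 3-state agent with one "engaged" state (high
#' evidence weight, laser-sensitive) and two oppositely biased,
#' evidence-insensitive states, all highly persistent.
#'
#' @param weights K x 5 matrix of per-state GLM weights (columns
#'   `dcues`, `prev_choice`, `prev_rewarded`, `laser`, `bias`).
#' @param transitions K x K row-stochastic transition matrix.
#' @param initial Initial state distribution (simplex vector of length K).
#' @param laser_weight Convenience override of the engaged-state laser
#'   weight in the default parameter set (ignored when `weights` is given).
#' @return A list of class `agent_params`.
#' @export
agent_params <- function(weights = NULL, transitions = NULL, initial = NULL,
                         laser_weight = 1.0) {
  if (is.null(weights)) {
    weights <- rbind(
      engaged = c(dcues = 0.5, prev_choice = 0.1, prev_rewarded = 0.1,
                  laser = laser_weight, bias = 0),
      right_biased = c(0.06, 0.2, 0.1, 0, 2.5),
      left_biased = c(0.06, 0.2, 0.1, 0, -2.5)
    )
  }
  weights <- as.matrix(weights)
  K <- nrow(weights)
  if (is.null(transitions)) {
    if (K == 3) {
      # persistent states; disengaged states return mostly to engaged,
      # giving ~2/3 engaged-state occupancy at stationarity
      transitions <- rbind(c(0.98, 0.01, 0.01),
                           c(0.04, 0.955, 0.005),
                           c(0.04, 0.005, 0.955))
    } else {
      transitions <- matrix(0.01, K, K)
      diag(transitions) <- 0
      diag(transitions) <- 1 - rowSums(transitions)
    }
  }
  if (is.null(initial)) initial <- c(1, rep(0, K - 1))
  if (!all(is.finite(weights))) stop("agent weights must be finite", call. = FALSE)
  stopifnot(nrow(transitions) == K, ncol(transitions) == K,
            all(abs(rowSums(transitions) - 1) < 1e-8),
            length(initial) == K, abs(sum(initial) - 1) < 1e-8)
  colnames(weights) <- c("dcues", "prev_choice", "prev_rewarded", "laser", "bias")
  structure(list(weights = weights, transitions = transitions,
                 initial = initial, n_states = K),
            class = "agent_params")
}

#' Advance the behavioural agent by one trial
#'
#' Draws a Bernoulli choice from the current state's GLM and the next
#' latent state from the transition matrix row.
#'
#' @param agent An [agent_params()] object.
#' @param state Current latent state (1-based integer).
#' @param inputs Covariate vector in the order
#'   `(dcues, prev_choice, prev_rewarded, laser, bias)`.
#' @return A list with `choice` (`"left"`/`"right"`), `p_right`, and
#'   `next_state`.
#' @export
agent_step <- function(agent, state, inputs) {
  stopifnot(inherits(agent, "agent_params"),
            state >= 1, state <= agent$n_states,
            length(inputs) == ncol(agent$weights))
  p_right <- logistic(sum(agent$weights[state, ] * inputs))
  choice <- if (runif(1) < p_right) "right" else "left"
  next_state <- sample.int(agent$n_states, 1, prob = agent$transitions[state, ])
  list(choice = choice, p_right = p_right, next_state = next_state)
}

#' One integration step of the view-angle dynamics
#'
#' The view angle Theta follows
#' `dTheta/dt = sign(omega) * min(exp(1.4 * |omega|^1.2) - 1, pi/2 - |Theta|)`,
#' an exponential transfer that suppresses small ball displacements and
#' saturates so that `|Theta|` never exceeds pi/2. The alternative
#' constant-grouping reading `exp(1.4) * |omega|^1.2 - 1` is available via
#' `grouping = "outside"`.
#'
#' @param theta Current view angle in radians, `|theta| <= pi/2`.
#' @param omega Displacement angle in radians.
#' @param dt Time step in seconds (> 0).
#' @param grouping Where the constants attach in the exponential
#'   (`"inside"`, the default, or `"outside"`).
#' @return Updated view angle in radians.
#' @export
view_angle_step <- function(theta, omega, dt, grouping = c("inside", "outside")) {
  grouping <- match.arg(grouping)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  stopifnot(abs(theta) <= pi / 2 + 1e-12)
  growth <- switch(grouping,
    inside = exp(1.4 * abs(omega)^1.2) - 1,
    outside = exp(1.4) * abs(omega)^1.2 - 1
  )
  rate <- sign(omega) * min(growth, pi / 2 - abs(theta))
  clamp(theta + rate * dt, -pi / 2, pi / 2)
}

# Recency-weighted error fraction on one side's rewarded trials.
# rewarded/correct are full history vectors, most recent last.
side_error_fraction <- function(rewarded_side, correct, side, sigma,
                                window = 40L) {
  idx <- which(rewarded_side == side)
  if (length(idx) == 0L) return(0.5)
  idx <- utils::tail(idx, window)
  err <- rev(!correct[idx]) # most recent first
  sum(half_gaussian_weights(length(err), sigma) * err)
}

empirical_right_fraction <- function(rewarded_side, sigma) {
  if (length(rewarded_side) == 0L) return(0.5)
  r <- rev(rewarded_side == "right")
  r <- r[seq_len(min(length(r), ceiling(4 * sigma)))]
  sum(half_gaussian_weights(length(r), sigma) * r)
}

# Simulate a coarse view-angle trajectory over the 66 position bins.
# Early-turn trials inject a large displacement angle mid-maze.
simulate_view_angle <- function(choice, speed, early_turn) {
  pb <- position_bins()
  dt <- POSITION_BIN_WIDTH / speed
  theta <- numeric(N_POSITION_BINS)
  th <- 0
  turn_sign <- if (choice == "right") -1 else 1
  for (b in seq_len(N_POSITION_BINS)) {
    drift <- if (pb$centre[b] > 290) turn_sign * 0.8 else 0
    omega <- drift + rnorm(1, 0, 0.05)
    if (early_turn && pb$centre[b] > 150 && pb$centre[b] < 250) {
      omega <- omega + turn_sign * 1.2
    }
    th <- view_angle_step(th, omega, dt)
    theta[b] <- th
  }
  theta
}

#' Simulate a full behavioural session
#'
#' Runs the closed-loop task: a warm-up prefix (up to `warmup_n` trials,
#' exited early once warm-up accuracy exceeds the threshold), main-maze
#' trials with spatial-Poisson cues and debiased majority-side draws, and
#' 10-trial easy blocks triggered whenever running 40-trial accuracy drops
#' below 55%. The rewarded side is the side with the greater realised cue
#' count (ties are randomly rewarded and flagged). Laser is delivered only
#' on main-maze trials, at the configured fraction, and only within the cue
#' region. Choices come from the multi-state GLM-HMM agent. Evidence is
#' expressed in the laser-hemisphere frame: ipsilateral = right.
#'
#' @param config A [task_config()].
#' @param agent An [agent_params()].
#' @param n_trials Number of trials to simulate.
#' @param seed Integer seed; the session is bit-reproducible given
#'   `(config, agent, n_trials, seed)`.
#' @param kinematics Simulate per-trial view-angle trajectories and
#'   early-turn errors (default TRUE).
#' @param early_turn_rate Probability of an early-turn motor error on a
#'   non-warm-up trial (default 0.05).
#' @param speed_mean,speed_sdlog Mean running speed (cm/s) and log-normal
#'   per-trial jitter used for trajectory timing.
#' @return A tibble of class `trial_table`, one row per trial, with cue
#'   positions, rewarded side, choice, outcome, laser flag, latent state,
#'   final signed evidence (#ipsi - #contra), per-bin cumulative evidence
#'   (`cum_evidence`, list of 66), view-angle trajectory and early-turn
#'   flag.
#' @export
simulate_session <- function(config, agent, n_trials, seed = NULL,
                             kinematics = TRUE, early_turn_rate = 0.05,
                             speed_mean = 40, speed_sdlog = 0.1) {
  stopifnot(inherits(config, "task_config"), inherits(agent, "agent_params"))
  if (n_trials < config$warmup_n) {
    stop("n_trials must be at least the warm-up length", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  rows <- vector("list", n_trials)
  state <- sample.int(agent$n_states, 1, prob = agent$initial)
  prev_choice <- 0; prev_rewarded <- 0
  rewarded_hist <- character(0); correct_hist <- logical(0)
  in_warmup <- TRUE; n_warm <- 0L; n_warm_correct <- 0L
  easy_left <- 0L
  main_correct <- logical(0)

  for (i in seq_len(n_trials)) {
    if (in_warmup && n_warm >= config$warmup_n &&
        (100 * n_warm_correct / n_warm > config$warmup_accuracy ||
         n_warm >= 3L * config$warmup_n)) {
      in_warmup <- FALSE
    }
    maze_type <- if (in_warmup) {
      "warmup"
    } else if (easy_left > 0L) {
      easy_left <- easy_left - 1L
      "easy"
    } else "main"

    # debiased majority-side draw
    eR <- side_error_fraction(rewarded_hist, correct_hist, "right",
                              config$error_window_sigma)
    eL <- side_error_fraction(rewarded_hist, correct_hist, "left",
                              config$error_window_sigma)
    PR <- debias_probability(eR, eL, config$sqrt_cap)
    emp <- empirical_right_fraction(rewarded_hist, config$empirical_sigma)
    majority_side <- draw_rewarded_side(PR, emp)

    if (maze_type == "main") {
      pair <- config$cue_rate_pairs[[
        sample.int(length(config$cue_rate_pairs), 1,
                   prob = config$cue_rate_weights)]]
    } else {
      pair <- c(8.0, 0) # guided trials: cues on the majority side only
    }
    rates <- if (majority_side == "right") {
      c(left = pair[2], right = pair[1])
    } else {
      c(left = pair[1], right = pair[2])
    }
    cues <- generate_cues(rates[["left"]], rates[["right"]],
                          refractory = config$refractory)
    n_left <- length(cues$left); n_right <- length(cues$right)
    tie <- n_left == n_right
    rewarded_side <- if (tie) {
      if (runif(1) < 0.5) "right" else "left"
    } else if (n_right > n_left) "right" else "left"

    laser <- maze_type == "main" && runif(1) < config$laser_fraction

    inputs <- c(n_right - n_left, prev_choice, prev_rewarded,
                as.numeric(laser), 1)
    if (maze_type != "main") {
      # guided trials: strong pull toward the cued (majority) side
      guided <- 4 * (if (majority_side == "right") 1 else -1)
      p_right <- logistic(sum(agent$weights[state, ] * inputs) + guided)
      choice <- if (runif(1) < p_right) "right" else "left"
      next_state <- sample.int(agent$n_states, 1,
                               prob = agent$transitions[state, ])
      step <- list(choice = choice, next_state = next_state)
    } else {
      step <- agent_step(agent, state, inputs)
    }
    choice <- step$choice
    correct <- choice == rewarded_side

    early_turn <- kinematics && maze_type == "main" &&
      runif(1) < early_turn_rate
    speed <- speed_mean * exp(rnorm(1, 0, speed_sdlog))
    theta <- if (kinematics) {
      simulate_view_angle(choice, speed, early_turn)
    } else NULL

    rows[[i]] <- tibble(
      trial = i, maze_type = maze_type,
      rewarded_side = rewarded_side, choice = choice,
      correct = correct, laser = laser, state = state,
      n_left = n_left, n_right = n_right,
      final_evidence = n_right - n_left, tie = tie,
      speed = speed, early_turn = early_turn,
      cues_left = list(cues$left), cues_right = list(cues$right),
      cum_evidence = list(cumulative_evidence(cues$right, cues$left)),
      view_angle = list(theta)
    )

    # bookkeeping
    if (in_warmup) {
      n_warm <- n_warm + 1L
      n_warm_correct <- n_warm_correct + as.integer(correct)
    } else {
      main_correct <- c(main_correct, correct)
      if (easy_left == 0L && maze_type == "main" &&
          length(main_correct) >= config$easy_window) {
        acc <- 100 * mean(utils::tail(main_correct, config$easy_window))
        if (acc < config$easy_accuracy) easy_left <- config$easy_block_length
      }
    }
    rewarded_hist <- c(rewarded_hist, rewarded_side)
    correct_hist <- c(correct_hist, correct)
    prev_choice <- if (choice == "right") 1 else -1
    prev_rewarded <- if (!correct) 0 else prev_choice
    state <- step$next_state
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("trial_table", class(out))
  out
}

#' Write / read a trial table as CSV
#'
#' Cue positions and per-bin cumulative evidence are stored as
#' semicolon-joined numbers so the file stays a flat, diffable CSV.
#'
#' @param trials A trial table from [simulate_session()].
#' @param path Output file path.
#' @return `path`, invisibly (`write_trials_csv`); a `trial_table` tibble
#'   (`read_trials_csv`).
#' @export
write_trials_csv <- function(trials, path) {
  flat <- trials |>
    dplyr::mutate(
      dplyr::across(dplyr::any_of(c("cues_left", "cues_right",
                                    "cum_evidence", "view_angle")),
                    ~ vapply(.x, function(v) {
                      if (is.null(v)) "" else paste(signif(v, 8), collapse = ";")
                    }, character(1))))
  utils::write.csv(flat, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  split_col <- function(s) {
    lapply(s, function(x) {
      if (is.na(x) || x == "") numeric(0) else as.numeric(strsplit(x, ";")[[1]])
    })
  }
  out <- as_tibble(raw)
  for (col in intersect(c("cues_left", "cues_right", "cum_evidence",
                          "view_angle"), names(out))) {
    out[[col]] <- split_col(out[[col]])
  }
  class(out) <- c("trial_table", class(out))
  out
}
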