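#' Smooth spike counts with a causal half-Gaussian filter
#'
#' Spike counts in 10-ms bins are smoothed with a causal half-Gaussian
#' kernel (400 ms standard deviation by default), so the smoothed value at
#' time `t` depends only on spikes at or before `t`.
#'
#' @param counts Numeric vector of per-bin counts, or a neurons x time
#'   matrix.
#' @param sd Kernel standard deviation in seconds (default 0.4).
#' @param time_step Bin width in seconds (default 0.010).
#' @return Smoothed counts, same shape as `counts`.
#' @export
smooth_spikes <- function(counts, sd = 0.4, time_step = 0.010) {
  stopifnot(all(counts >= 0, na.rm = TRUE))
  half_gaussian_smooth(counts, sd = sd, dt = time_step)
}

#' Bin smoothed spike trains by maze position
#'
#' Converts smoothed spike trains to a position-binned rate tensor over the
#' 66 5-cm bins spanning -30 to 300 cm (half-open `[lo, hi)` bins). Within
#' each (trial, bin) the smoothed counts over the occupied time points are
#' averaged and converted to Hz by dividing by the bin width in time
#' (`mode = "rate"`, the default, which is occupancy-invariant for a
#' constant-rate neuron). The literal recipe of dividing the mean count by
#' the occupied duration is available as `mode = "literal"`. Occupancy
#' durations are retained as an attribute; never-occupied bins are `NA`.
#'
#' @param spikes A `spike_data` object from [simulate_population()].
#' @param sd Smoothing kernel standard deviation in seconds.
#' @param mode Hz conversion convention, `"rate"` or `"literal"`.
#' @return A 3-D array of class `rate_tensor` (neurons x trials x 66) with
#'   attributes `units = "Hz"`, `occupancy` (trials x 66, seconds) and
#'   `positions`.
#' @export
position_bin <- function(spikes, sd = 0.4, mode = c("rate", "literal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spikes, "spike_data"))
  n_neur <- nrow(spikes$neurons)
  n_trials <- length(spikes$counts)
  out <- array(NA_real_, dim = c(n_neur, n_trials, N_POSITION_BINS))
  occ <- matrix(0, n_trials, N_POSITION_BINS)
  dt <- spikes$time_step
  for (i in seq_len(n_trials)) {
    sm <- smooth_spikes(spikes$counts[[i]], sd = sd, time_step = dt)
    if (is.null(dim(sm))) sm <- matrix(sm, nrow = 1)
    bin_idx <- floor((spikes$position[[i]] + 30) / POSITION_BIN_WIDTH) + 1
    ok <- bin_idx >= 1 & bin_idx <= N_POSITION_BINS
    f <- factor(bin_idx[ok], levels = seq_len(N_POSITION_BINS))
    n_per_bin <- tabulate(f, N_POSITION_BINS)
    occ[i, ] <- n_per_bin * dt
    sums <- t(rowsum(t(sm[, ok, drop = FALSE]), f))
    means <- sweep(sums, 2, pmax(n_per_bin, 1), "/")
    means[, n_per_bin == 0] <- NA_real_
    out[, i, ] <- switch(mode,
      rate = means / dt,
      literal = sweep(means, 2, ifelse(n_per_bin > 0, n_per_bin * dt, NA), "/")
    )
  }
  structure(out, units = "Hz", occupancy = occ,
            positions = position_bins()$lo, class = "rate_tensor")
}

#' Z-score a rate tensor
#'
#' On-task: each neuron's rates are centred and scaled by its mean and
#' standard deviation across all trials and position bins. Off-task sweep
#' arrays subtract the baseline-period (-3-0 s) mean and divide by the
#' supplied on-task standard deviation. Neurons with zero variance are
#' flagged (attribute `excluded`) and set to `NA` rather than propagating
#' non-finite values.
#'
#' @param tensor A `rate_tensor` (neurons x trials x bins), or for
#'   `mode = "off_task"` an `off_task_sweeps` object.
#' @param mode `"on_task"` or `"off_task"`.
#' @param on_task_sd Per-neuron on-task standard deviations (required for
#'   off-task mode).
#' @return The z-scored array with `units = "zscore"`, per-neuron `mean`
#'   and `sd` attributes, and an `excluded` logical attribute.
#' @export
zscore_tensor <- function(tensor, mode = c("on_task", "off_task"),
                          on_task_sd = NULL) {
  mode <- match.arg(mode)
  if (mode == "on_task") {
    x <- unclass(tensor)
    mu <- apply(x, 1, mean, na.rm = TRUE)
    sdev <- apply(x, 1, sd, na.rm = TRUE)
    excluded <- !is.finite(sdev) | sdev == 0
    z <- sweep(sweep(x, 1, mu, "-"), 1, ifelse(excluded, 1, sdev), "/")
    z[excluded, , ] <- NA_real_
    structure(z, units = "zscore", mean = mu, sd = sdev,
              excluded = excluded, occupancy = attr(tensor, "occupancy"),
              positions = attr(tensor, "positions"), class = "rate_tensor")
  } else {
    stopifnot(inherits(tensor, "off_task_sweeps"), !is.null(on_task_sd))
    x <- tensor$counts / tensor$time_step # Hz
    sm <- x
    for (s in seq_len(dim(x)[2])) {
      sm[, s, ] <- half_gaussian_smooth(x[, s, ], sd = 0.4,
                                        dt = tensor$time_step)
    }
    base <- apply(sm[, , tensor$time < 0, drop = FALSE], 1, mean)
    excluded <- !is.finite(on_task_sd) | on_task_sd == 0
    z <- sweep(sweep(sm, 1, base, "-"), 1,
               ifelse(excluded, 1, on_task_sd), "/")
    z[excluded, , ] <- NA_real_
    structure(list(z = z, time = tensor$time,
                   laser_interval = tensor$laser_interval,
                   excluded = excluded),
              class = "off_task_z")
  }
}

# Vectorised per-position OLS across all neurons: Y is trials x neurons.
# Returns list(coef, t) each variables x neurons.
ols_t <- function(X, Y) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  B <- qr.coef(qrX, Y)
  resid <- Y - X %*% B
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / df
  XtX_inv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot),
                                 drop = FALSE]
  se <- sqrt(outer(diag(XtX_inv), sigma2))
  list(coef = B, t = B / se, df = df)
}

#' Fit the per-neuron linear encoding model
#'
#' At each position bin, each neuron's trial-by-trial position-binned
#' firing rate (Hz) is regressed by ordinary least squares on: previous
#' trial outcome (incorrect -1 / correct +1), the signed cumulative
#' evidence up to that position (#ipsi - #contra cues), the current choice
#' (contra -1 / ipsi +1), and optionally the laser (off -1 / on +1).
#' Coefficients and t-statistics (coefficient / standard error) are
#' returned per neuron x variable x position. With
#' `include_laser = FALSE` only laser-off trials are used (the
#' classification configuration). The first trial of a session (undefined
#' previous outcome) and tied-evidence trials are dropped.
#'
#' @param tensor A `rate_tensor` in Hz (neurons x trials x 66).
#' @param trials The matching trial table.
#' @param include_laser Include the laser regressor and laser-on trials.
#' @param positions Position-bin indices to fit (default: cue + delay).
#' @return A list of class `encoding_fit` with arrays `coef` and `t`
#'   (variables x neurons x positions), the retained trial subset, the
#'   design pieces, and fitting metadata.
#' @export
fit_encoding_model <- function(tensor, trials, include_laser = TRUE,
                               positions = cue_delay_bins()) {
  stopifnot(dim(tensor)[2] == nrow(trials))
  keep <- !is.na(dplyr::lag(trials$correct)) & !isTRUE_vec(trials$tie)
  if (!include_laser) keep <- keep & !trials$laser
  trials_used <- trials[keep, , drop = FALSE]
  # previous outcome lags over the full session, then subsets
  prev_out_full <- ifelse(dplyr::lag(trials$correct), 1, -1)
  des <- list(
    prev_outcome = prev_out_full[keep],
    choice = ifelse(trials_used$choice == "right", 1, -1),
    laser = if (include_laser) ifelse(trials_used$laser, 1, -1) else NULL,
    evidence = do.call(rbind, trials_used$cum_evidence)
  )
  des$X <- cbind(intercept = 1, prev_outcome = des$prev_outcome,
                 choice = des$choice, laser = des$laser)
  vars <- c("prev_outcome", "evidence", "choice",
            if (include_laser) "laser")
  n_trial_min <- ncol(des$X) + 1 + 10
  if (nrow(des$X) < n_trial_min) {
    stop("need at least 10 more trials than regressors", call. = FALSE)
  }
  Y_all <- unclass(tensor)[, keep, , drop = FALSE]
  n_neur <- dim(Y_all)[1]
  cf <- tt <- array(NA_real_, dim = c(length(vars), n_neur,
                                      length(positions)),
                    dimnames = list(vars, NULL, NULL))
  for (pi in seq_along(positions)) {
    p <- positions[pi]
    X <- cbind(des$X[, "intercept", drop = FALSE],
               prev_outcome = des$X[, "prev_outcome"],
               evidence = des$evidence[, p],
               choice = des$X[, "choice"],
               laser = if (include_laser) des$X[, "laser"] else NULL)
    Y <- t(matrix(Y_all[, , p], nrow = n_neur))
    ok <- stats::complete.cases(Y) # unoccupied bins dropped pairwise
    fit <- ols_t(X[ok, , drop = FALSE], Y[ok, , drop = FALSE])
    cf[, , pi] <- fit$coef[vars, , drop = FALSE]
    tt[, , pi] <- fit$t[vars, , drop = FALSE]
  }
  structure(list(coef = cf, t = tt, variables = vars,
                 positions = positions, include_laser = include_laser,
                 trials = trials_used, tensor_index = which(keep),
                 design = des, tensor = Y_all),
            class = "encoding_fit")
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else x

#' Classify neurons as evidence-, choice- or non-decision-tuned
#'
#' Permutation-null tuning classification with per-neuron family-wise
#' control: the trial rows of the full prediction matrix are jointly
#' reordered (responses fixed; one permutation per shuffle applied at all
#' positions), the encoding model is refit, and the maximum and minimum
#' t-statistics over cue and delay positions are recorded per variable.
#' A neuron is significantly tuned to a variable if its real maximum
#' t-statistic exceeds the 95th percentile of the null maxima or its real
#' minimum falls below the 5th percentile of the null minima. A neuron is
#' `evidence`-tuned if the evidence coefficient is significant anywhere in
#' the cue or delay region, `choice`-tuned if choice but not evidence is
#' significant, otherwise `untuned`. Side preference is the sign of the
#' mean relevant coefficient over cue and delay positions (positive =
#' ipsilateral).
#'
#' @param fit An `encoding_fit` from [fit_encoding_model()] (typically on
#'   laser-off trials).
#' @param n_shuffle Number of design-row permutations (default 200; fewer
#'   than 100 triggers a warning).
#' @param seed Optional integer seed.
#' @return A tibble of class `tuning_labels`, one row per neuron:
#'   significance flags per variable, `tuning_class`, `side_pref`, and
#'   mean cue+delay coefficients. Null max/min arrays are attached as the
#'   `nulls` attribute.
#' @export
classify_tuning <- function(fit, n_shuffle = 200, seed = NULL) {
  stopifnot(inherits(fit, "encoding_fit"))
  if (n_shuffle < 100) {
    warning("n_shuffle < 100: null quantiles will be coarse")
  }
  if (!is.null(seed)) set.seed(seed)
  vars <- fit$variables
  n_neur <- dim(fit$t)[2]
  n_pos <- dim(fit$t)[3]
  n_tr <- nrow(fit$trials)
  ev <- fit$design$evidence
  prev_col <- fit$design$prev_outcome
  choice_col <- fit$design$choice
  laser_col <- fit$design$laser
  null_max <- null_min <- array(NA_real_,
                                dim = c(n_shuffle, length(vars), n_neur))
  for (s in seq_len(n_shuffle)) {
    perm <- sample.int(n_tr)
    tmax <- matrix(-Inf, length(vars), n_neur)
    tmin <- matrix(Inf, length(vars), n_neur)
    for (pi in seq_len(n_pos)) {
      p <- fit$positions[pi]
      X <- cbind(intercept = 1,
                 prev_outcome = prev_col[perm],
                 evidence = ev[perm, p],
                 choice = choice_col[perm],
                 laser = if (fit$include_laser) laser_col[perm] else NULL)
      Y <- t(matrix(fit$tensor[, , p], nrow = n_neur))
      ok <- stats::complete.cases(Y)
      f <- ols_t(X[ok, , drop = FALSE], Y[ok, , drop = FALSE])
      tmax <- pmax(tmax, f$t[vars, , drop = FALSE])
      tmin <- pmin(tmin, f$t[vars, , drop = FALSE])
    }
    null_max[s, , ] <- tmax
    null_min[s, , ] <- tmin
  }
  real_max <- apply(fit$t, c(1, 2), max, na.rm = TRUE)
  real_min <- apply(fit$t, c(1, 2), min, na.rm = TRUE)
  sig <- matrix(FALSE, length(vars), n_neur,
                dimnames = list(vars, NULL))
  # finite-sample percentile: the ceiling(0.95 (S+1))-th order statistic,
  # so that exceeding it has probability at most 5% under the null
  k_hi <- min(n_shuffle, ceiling(0.95 * (n_shuffle + 1)))
  k_lo <- max(1L, floor(0.05 * (n_shuffle + 1)))
  for (v in seq_along(vars)) {
    hi <- apply(null_max[, v, , drop = FALSE], 3,
                function(x) sort(x)[k_hi])
    lo <- apply(null_min[, v, , drop = FALSE], 3,
                function(x) sort(x)[k_lo])
    sig[v, ] <- real_max[v, ] > hi | real_min[v, ] < lo
  }
  mean_coef <- apply(fit$coef, c(1, 2), mean, na.rm = TRUE)
  labels <- tibble(
    neuron = seq_len(n_neur),
    evidence_sig = sig["evidence", ],
    choice_sig = sig["choice", ],
    prev_outcome_sig = sig["prev_outcome", ],
    laser_sig = if (fit$include_laser) sig["laser", ] else NA,
    mean_coef_evidence = mean_coef["evidence", ],
    mean_coef_choice = mean_coef["choice", ],
    mean_coef_laser = if (fit$include_laser) mean_coef["laser", ] else NA_real_,
    tuning_class = dplyr::case_when(
      evidence_sig ~ "evidence",
      choice_sig ~ "choice",
      TRUE ~ "untuned"
    ),
    side_pref = dplyr::case_when(
      tuning_class == "evidence" & mean_coef_evidence >= 0 ~ "ipsi",
      tuning_class == "evidence" ~ "contra",
      tuning_class == "choice" & mean_coef_choice >= 0 ~ "ipsi",
      tuning_class == "choice" ~ "contra",
      TRUE ~ "none"
    )
  )
  structure(labels, nulls = list(max = null_max, min = null_min),
            class = c("tuning_labels", class(labels)))
}

#' Evidence tuning curves
#'
#' Averages z-scored activity over the cue and delay regions across trials
#' grouped by sensory-evidence bin (see [bin_evidence()]), optionally split
#' by correctness and/or laser condition. SEM is computed across neurons
#' when more than one neuron is included, otherwise across trials.
#'
#' @param tensor A z-scored `rate_tensor`.
#' @param trials The matching trial table.
#' @param neurons Integer indices of the neurons to pool.
#' @param split `"none"` or `"correct_vs_incorrect"`.
#' @param laser_split Also split by laser condition.
#' @param positions Position bins to average (default cue + delay).
#' @return A tibble with `evidence_bin`, optional `correct`/`laser`
#'   columns, `mean`, `sem`, `n_trials`.
#' @export
tuning_curve <- function(tensor, trials, neurons = NULL,
                         split = c("none", "correct_vs_incorrect"),
                         laser_split = FALSE,
                         positions = cue_delay_bins()) {
  split <- match.arg(split)
  stopifnot(dim(tensor)[2] == nrow(trials))
  if (is.null(neurons)) neurons <- seq_len(dim(tensor)[1])
  if (length(neurons) == 0L) stop("empty neuron subset", call. = FALSE)
  bins <- bin_evidence(trials)
  x <- unclass(tensor)[neurons, , positions, drop = FALSE]
  per_trial <- apply(x, c(1, 2), mean, na.rm = TRUE) # neurons x trials
  df <- tibble(
    trial = rep(seq_len(nrow(trials)), each = length(neurons)),
    neuron = rep(neurons, times = nrow(trials)),
    activity = as.vector(per_trial),
    evidence_bin = rep(bins, each = length(neurons)),
    correct = rep(trials$correct, each = length(neurons)),
    laser = rep(trials$laser, each = length(neurons))
  ) |>
    dplyr::filter(.data$evidence_bin != "excluded")
  grp <- c("evidence_bin",
           if (split == "correct_vs_incorrect") "correct",
           if (laser_split) "laser")
  per_neuron <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "neuron")))) |>
    dplyr::summarise(activity = mean(.data$activity, na.rm = TRUE),
                     n_trials = dplyr::n(), .groups = "drop")
  out <- per_neuron |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      mean = mean(.data$activity, na.rm = TRUE),
      sem = if (dplyr::n() > 1) {
        sd(.data$activity, na.rm = TRUE) / sqrt(dplyr::n())
      } else NA_real_,
      n_trials = sum(.data$n_trials), n_neurons = dplyr::n(),
      .groups = "drop")
  out
}

#' Per-neuron laser-modulation tests
#'
#' On-task: cue-region mean activity per trial is compared between laser-on
#' and laser-off trials with an unpaired two-tailed Mann-Whitney U test.
#' Off-task: per-sweep baseline (-3-0 s) and laser-period (0-3 s) means
#' are compared with a two-tailed paired Wilcoxon signed-rank test. A
#' neuron with p < 0.05 is labelled excited or inhibited by the sign of
#' its mean on-minus-off difference, otherwise `ns`.
#'
#' @param data A `rate_tensor` plus `trials` (on-task), or an
#'   `off_task_z` / `off_task_sweeps` object.
#' @param trials Trial table (on-task context only).
#' @param context `"on_task"` or `"off_task"`.
#' @return A tibble with `neuron`, `p`, `diff` (mean on - off) and
#'   `direction`.
#' @export
laser_modulation_test <- function(data, trials = NULL,
                                  context = c("on_task", "off_task")) {
  context <- match.arg(context)
  if (context == "on_task") {
    stopifnot(!is.null(trials), dim(data)[2] == nrow(trials))
    cue_mean <- apply(unclass(data)[, , cue_region_bins(), drop = FALSE],
                      c(1, 2), mean, na.rm = TRUE)
    on <- trials$laser
    res <- purrr::map_dfr(seq_len(nrow(cue_mean)), function(j) {
      a <- cue_mean[j, on]; b <- cue_mean[j, !on]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (length(a) < 5 || length(b) < 5) {
        warning("fewer than 5 trials in a laser condition; neuron ", j,
                " marked ns")
        return(tibble(neuron = j, p = NA_real_, diff = NA_real_,
                      direction = "ns"))
      }
      p <- suppressWarnings(wilcox.test(a, b)$p.value)
      d <- mean(a) - mean(b)
      tibble(neuron = j, p = p, diff = d,
             direction = ifelse(p < 0.05, ifelse(d > 0, "excited",
                                                 "inhibited"), "ns"))
    })
    return(res)
  }
  # off-task
  z <- if (inherits(data, "off_task_z")) data$z else {
    data$counts / data$time_step
  }
  tm <- if (inherits(data, "off_task_z")) data$time else data$time
  base_idx <- tm < 0
  las_idx <- tm >= 0 & tm < 3
  purrr::map_dfr(seq_len(dim(z)[1]), function(j) {
    base <- apply(z[j, , base_idx, drop = FALSE], 2, mean)
    las <- apply(z[j, , las_idx, drop = FALSE], 2, mean)
    if (length(base) < 5) {
      warning("fewer than 5 sweeps; neuron ", j, " marked ns")
      return(tibble(neuron = j, p = NA_real_, diff = NA_real_,
                    direction = "ns"))
    }
    p <- suppressWarnings(wilcox.test(las, base, paired = TRUE)$p.value)
    if (is.na(p)) p <- 1 # identical paired values
    d <- mean(las) - mean(base)
    tibble(neuron = j, p = p, diff = d,
           direction = ifelse(p < 0.05, ifelse(d > 0, "excited",
                                               "inhibited"), "ns"))
  })
}

#' Two-proportion z-test (pooled variance, two-sided)
#'
#' @param k1,n1 Successes and total in group 1.
#' @param k2,n2 Successes and total in group 2.
#' @return A tibble with `p1`, `p2`, `z`, `p`.
#' @export
compare_proportions <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0)
  if (k1 > n1 || k2 > n2) stop("k must not exceed n", call. = FALSE)
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  tibble(p1 = p1, p2 = p2, z = z, p = 2 * pnorm(-abs(z)))
}

#' Linear mixed-effects test of laser modulation
#'
#' Fits, by maximum likelihood,
#' `activity ~ 1 + covariate + laser + (1 + covariate + laser | group)`
#' where the covariate is the final evidence normalised to \[0, 1\] per
#' session, or the choice coded 0/1, and laser is coded 0/1. The grouping
#' unit is the individual neuron (single-neuron activity) or the session
#' (population projections). The p-value of the laser fixed effect (t-test
#' on its coefficient) decides whether activity is shifted by the laser.
#' Singular random-effects fits fall back to uncorrelated, then
#' intercept-only random effects with a warning; a single grouping unit
#' reduces to ordinary regression.
#'
#' @param df Long-format tibble with columns `activity`, `laser` (0/1),
#'   the covariate column, and the grouping column.
#' @param covariate `"evidence"` (normalised to \[0,1\]) or `"choice"`
#'   (0/1).
#' @param group Grouping column name (default `"neuron"`).
#' @return A tibble of fixed effects (`term`, `estimate`, `se`, `t`, `p`)
#'   with the fitted model in the `model` attribute.
#' @export
mixed_effects_laser_test <- function(df, covariate = c("evidence", "choice"),
                                     group = "neuron") {
  covariate <- match.arg(covariate)
  stopifnot(all(c("activity", "laser", covariate, group) %in% names(df)))
  df <- as.data.frame(df)
  df$.grp <- factor(df[[group]])
  df$.cov <- df[[covariate]]
  if (nlevels(df$.grp) < 2L) {
    fit <- stats::lm(activity ~ 1 + .cov + laser, data = df)
    sm <- summary(fit)$coefficients
    out <- tibble(term = c("(Intercept)", covariate, "laser"),
                  estimate = sm[, 1], se = sm[, 2], t = sm[, 3], p = sm[, 4])
    return(structure(out, model = fit))
  }
  forms <- c(
    "activity ~ 1 + .cov + laser + (1 + .cov + laser | .grp)",
    "activity ~ 1 + .cov + laser + (1 + .cov + laser || .grp)",
    "activity ~ 1 + .cov + laser + (1 | .grp)"
  )
  fit <- NULL
  for (fml in forms) {
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(stats::as.formula(fml), data = df, REML = FALSE)
    ))
    if (!lme4::isSingular(fit, tol = 1e-5)) break
    if (fml != forms[length(forms)]) {
      warning("singular random-effects fit; simplifying covariance")
    }
  }
  sm <- summary(fit)$coefficients
  out <- tibble(term = sub("^\\.cov$", covariate, rownames(sm)),
                estimate = sm[, "Estimate"], se = sm[, "Std. Error"],
                t = sm[, "t value"], p = sm[, "Pr(>|t|)"])
  structure(out, model = fit)
}
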