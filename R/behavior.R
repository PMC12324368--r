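#' Bin trials by sensory-evidence level
#'
#' Trials with greater ipsilateral (delta cues > 0) or contralateral
#' (delta cues < 0) evidence are each split into three equal-count bins by
#' absolute evidence, giving low, intermediate and high evidence levels
#' per side. Binning uses all trials (laser on and off, correct and
#' incorrect). Tied trials (delta = 0) are labelled `"excluded"`.
#' Equal-count splitting ranks trials by absolute evidence with stable
#' order by trial index; remainder trials go to the lowest-evidence bins.
#'
#' @param trials A trial table with a `final_evidence` column
#'   (#ipsi - #contra).
#' @return An ordered factor per trial with levels `contra_3` (high
#'   contralateral) through `ipsi_3` (high ipsilateral), plus
#'   `"excluded"` for tied trials.
#' @export
bin_evidence <- function(trials) {
  ev <- trials$final_evidence
  if (all(ev == 0)) stop("all trials are tied; cannot bin", call. = FALSE)
  if (sum(ev != 0) < 6) stop("need at least 6 non-tied trials", call. = FALSE)
  lv <- c(paste0("contra_", 3:1), paste0("ipsi_", 1:3))
  out <- rep("excluded", length(ev))
  for (side in c("ipsi", "contra")) {
    idx <- if (side == "ipsi") which(ev > 0) else which(ev < 0)
    if (length(idx) == 0L) next
    ord <- idx[order(abs(ev[idx]), idx)] # stable by trial index
    n <- length(ord)
    base <- n %/% 3L
    sizes <- rep(base, 3)
    rem <- n - 3L * base
    if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    lab <- rep(1:3, times = sizes)
    out[ord] <- paste0(side, "_", lab)
  }
  factor(out, levels = c(lv, "excluded"), ordered = FALSE)
}

#' Psychometric curve: percent ipsilateral choices per evidence bin
#'
#' @param trials A trial table (ipsi = right).
#' @param bins Optional evidence bins from [bin_evidence()]; computed from
#'   `trials` when omitted.
#' @param by_laser Compute the curve separately for laser on and off
#'   trials (default TRUE).
#' @return A tibble of class `psychometric_curve` with `evidence_bin`,
#'   optional `laser`, `pct_ipsi`, `n`. Bins empty under a condition are
#'   kept with `pct_ipsi = NA`.
#' @export
psychometric <- function(trials, bins = NULL, by_laser = TRUE) {
  if (is.null(bins)) bins <- bin_evidence(trials)
  df <- tibble(
    evidence_bin = bins,
    ipsi_choice = trials$choice == "right",
    laser = trials$laser
  ) |>
    dplyr::filter(.data$evidence_bin != "excluded")
  grid <- tidyr::expand_grid(
    evidence_bin = factor(setdiff(levels(bins), "excluded"),
                          levels = levels(bins)),
    laser = if (by_laser) c(FALSE, TRUE) else NA
  )
  agg <- df |>
    dplyr::group_by(.data$evidence_bin,
                    laser = if (by_laser) .data$laser else NA) |>
    dplyr::summarise(pct_ipsi = 100 * mean(.data$ipsi_choice),
                     n = dplyr::n(), .groups = "drop")
  out <- grid |>
    dplyr::left_join(agg, by = c("evidence_bin", "laser")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  class(out) <- c("psychometric_curve", class(out))
  out
}

#' Laser-induced ipsilateral choice bias
#'
#' The accuracy difference between ipsilateral-rewarded and
#' contralateral-rewarded trials is computed separately for laser-on and
#' laser-off trials, and the laser bias is their difference
#' (on - off, percentage points; positive = laser-induced ipsilateral
#' bias). Tied trials are excluded. Flipping the ipsi/contra frame flips
#' the sign.
#'
#' @param trials A trial table (ipsi = right).
#' @param flip_frame Treat left as ipsilateral (default FALSE).
#' @return Laser bias in percentage points.
#' @export
laser_bias <- function(trials, flip_frame = FALSE) {
  df <- trials[!isTRUE_vec(trials$tie), , drop = FALSE]
  if (!any(df$laser)) stop("no laser-on trials", call. = FALSE)
  ipsi_side <- if (flip_frame) "left" else "right"
  acc_diff <- function(d) {
    100 * (mean(d$correct[d$rewarded_side == ipsi_side]) -
             mean(d$correct[d$rewarded_side != ipsi_side]))
  }
  acc_diff(df[df$laser, ]) - acc_diff(df[!df$laser, ])
}

# ---------------------------------------------------------------------------
# GLM-HMM

#' Assemble the GLM-HMM design from a trial table
#'
#' Covariates, in order: a constant bias, the difference in cue counts
#' (#right - #left) z-scored within session, previous choice (left -1 /
#' right +1, 0 on the first trial), previous rewarded choice (left
#' rewarded -1 / right rewarded +1 / unrewarded 0), and laser (off 0 /
#' on 1). The response is the binary choice (right = 1). Warm-up trials
#' are dropped.
#'
#' @param trials A trial table; a `session` column separates sessions
#'   (single session assumed when absent).
#' @return A tibble with `session`, `y`, and the five covariate columns.
#' @export
glmhmm_design <- function(trials) {
  if (!"session" %in% names(trials)) trials$session <- 1L
  trials |>
    dplyr::filter(.data$maze_type != "warmup") |>
    dplyr::group_by(.data$session) |>
    dplyr::mutate(
      y = as.integer(.data$choice == "right"),
      bias = 1,
      dcues = as.numeric(scale(.data$final_evidence)),
      prev_choice = dplyr::lag(ifelse(.data$choice == "right", 1, -1),
                               default = 0),
      prev_rewarded = dplyr::lag(
        ifelse(.data$correct, ifelse(.data$choice == "right", 1, -1), 0),
        default = 0),
      laser_cov = as.numeric(.data$laser)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(session = "session", y = "y", bias = "bias",
                  dcues = "dcues", prev_choice = "prev_choice",
                  prev_rewarded = "prev_rewarded", laser = "laser_cov")
}

glmhmm_covariates <- c("bias", "dcues", "prev_choice", "prev_rewarded",
                       "laser")

split_sessions <- function(df) {
  lapply(split(df, df$session), function(d) {
    list(X = as.matrix(d[, glmhmm_covariates]), y = d$y)
  })
}

# Weighted penalised Bernoulli-GLM M-step: Newton iterations warm-started
# at w0, with an optional Gaussian (ridge) prior on the weights.
irls_logistic <- function(X, y, w, w0, prior_prec = 0, max_iter = 25,
                          tol = 1e-9) {
  beta <- w0
  D <- ncol(X)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- logistic(eta)
    grad <- drop(crossprod(X, w * (y - mu))) - prior_prec * beta
    hess <- crossprod(X, X * (w * mu * (1 - mu))) +
      diag(prior_prec + 1e-10, D)
    step <- solve(hess, grad)
    beta <- beta + step
    if (!all(is.finite(beta))) {
      beta <- w0
      break
    }
    if (max(abs(step)) < tol) break
  }
  beta
}

# Scaled forward-backward for one session.
# Returns gamma (T x K), xi_sum (K x K), loglik.
forward_backward <- function(p_emit, trans, init) {
  Tt <- nrow(p_emit); K <- ncol(p_emit)
  alpha <- matrix(0, Tt, K); beta <- matrix(0, Tt, K)
  cnorm <- numeric(Tt)
  a <- init * p_emit[1, ]
  cnorm[1] <- sum(a)
  alpha[1, ] <- a / cnorm[1]
  if (Tt > 1) {
    for (t in 2:Tt) {
      a <- drop(crossprod(trans, alpha[t - 1, ])) * p_emit[t, ]
      cnorm[t] <- sum(a)
      alpha[t, ] <- a / cnorm[t]
    }
  }
  beta[Tt, ] <- 1
  if (Tt > 1) {
    for (t in (Tt - 1):1) {
      b <- drop(trans %*% (p_emit[t + 1, ] * beta[t + 1, ]))
      beta[t, ] <- b / cnorm[t + 1]
    }
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi_sum <- matrix(0, K, K)
  if (Tt > 1) {
    for (t in 1:(Tt - 1)) {
      xi <- (alpha[t, ] %o% (p_emit[t + 1, ] * beta[t + 1, ])) * trans
      xi_sum <- xi_sum + xi / cnorm[t + 1]
    }
  }
  list(gamma = gamma, xi_sum = xi_sum, loglik = sum(log(cnorm)))
}

emission_probs <- function(X, y, weights) {
  # weights: K x D; returns T x K Bernoulli likelihoods
  eta <- X %*% t(weights)
  mu <- logistic(eta)
  p <- ifelse(rep(y == 1, ncol(mu)), mu, 1 - mu)
  matrix(pmin(pmax(p, 1e-12), 1), nrow = nrow(X))
}

# Scaled forward-backward run jointly over a batch of equal-length
# sessions: p_emit is S x T x K. Returns gamma (S x T x K), the summed
# transition statistics, initial-state statistics, and per-session
# log-likelihoods.
forward_backward_batch <- function(p_emit, trans, init) {
  dm <- dim(p_emit)
  S <- dm[1]; Tt <- dm[2]; K <- dm[3]
  alpha <- array(0, dm)
  cnorm <- matrix(0, S, Tt)
  E_t <- matrix(p_emit[, 1, ], S, K)
  a <- sweep(E_t, 2, init, "*")
  cnorm[, 1] <- rowSums(a)
  alpha[, 1, ] <- a / cnorm[, 1]
  if (Tt > 1) {
    for (t in 2:Tt) {
      E_t <- matrix(p_emit[, t, ], S, K)
      a <- (matrix(alpha[, t - 1, ], S, K) %*% trans) * E_t
      cnorm[, t] <- rowSums(a)
      alpha[, t, ] <- a / cnorm[, t]
    }
  }
  gamma <- array(0, dm)
  xi_sum <- matrix(0, K, K)
  beta_t <- matrix(1, S, K)
  gamma[, Tt, ] <- matrix(alpha[, Tt, ], S, K)
  if (Tt > 1) {
    for (t in (Tt - 1):1) {
      E_next <- matrix(p_emit[, t + 1, ], S, K)
      eb <- (E_next * beta_t) / cnorm[, t + 1]
      a_t <- matrix(alpha[, t, ], S, K)
      xi_sum <- xi_sum + trans * crossprod(a_t, eb)
      beta_t <- eb %*% t(trans)
      g <- a_t * beta_t
      gamma[, t, ] <- g / rowSums(g)
    }
  }
  list(gamma = gamma, xi_sum = xi_sum,
       g1 = colSums(matrix(gamma[, 1, ], S, K)),
       loglik = rowSums(log(cnorm)))
}

# E-step over sessions of arbitrary lengths, batched by length.
# Returns gamma rows aligned with rbind(sessions$X).
estep_sessions <- function(sessions, weights, trans, init_dist) {
  lens <- vapply(sessions, function(s) length(s$y), integer(1))
  K <- nrow(weights)
  gamma_list <- vector("list", length(sessions))
  xi_tot <- matrix(0, K, K)
  g1 <- numeric(K)
  ll <- 0
  for (L in unique(lens)) {
    idx <- which(lens == L)
    p_emit <- array(0, c(length(idx), L, K))
    for (j in seq_along(idx)) {
      s <- sessions[[idx[j]]]
      p_emit[j, , ] <- emission_probs(s$X, s$y, weights)
    }
    fb <- forward_backward_batch(p_emit, trans, init_dist)
    for (j in seq_along(idx)) {
      gamma_list[[idx[j]]] <- matrix(fb$gamma[j, , ], L, K)
    }
    xi_tot <- xi_tot + fb$xi_sum
    g1 <- g1 + fb$g1
    ll <- ll + sum(fb$loglik)
  }
  list(gamma_all = do.call(rbind, gamma_list), xi_tot = xi_tot,
       g1 = g1, loglik = ll)
}

#' Fit a Bernoulli GLM-HMM to multi-session choice data
#'
#' Expectation-maximisation for a hidden Markov model whose per-state
#' emission is a Bernoulli GLM mapping task covariates onto choice
#' probability. The E-step runs scaled forward-backward per session; the
#' M-step refits each state's weights by IRLS-weighted logistic regression
#' and updates transitions and the initial distribution in closed form.
#' The model is fit `n_inits` times from different initialisations
#' (transitions from a Dirichlet favouring self-transitions, concentration
#' 10 on / 1 off the diagonal; weights from the 1-state fit plus small
#' Gaussian jitter) and the best fit by training log-likelihood is
#' returned.
#'
#' @param df Design tibble from [glmhmm_design()] (or compatible).
#' @param K Number of latent states.
#' @param n_inits Number of random initialisations (default 20).
#' @param max_iter Maximum EM iterations per fit (default 300).
#' @param tol Relative objective convergence tolerance (default 1e-6).
#' @param prior_sd Standard deviation of the Gaussian prior on GLM
#'   weights (MAP-EM; default 2). `Inf` disables the prior, giving plain
#'   maximum likelihood.
#' @param seed Optional integer seed.
#' @return An object of class `glmhmm`: per-state `weights` (K x 5),
#'   `transitions`, `initial`, `loglik` (data log-likelihood),
#'   `objective_trace` (penalised objective, non-decreasing across EM
#'   iterations), and a convergence flag.
#' @export
fit_glmhmm <- function(df, K, n_inits = 20, max_iter = 300, tol = 1e-6,
                       prior_sd = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  prior_prec <- if (is.finite(prior_sd)) 1 / prior_sd^2 else 0
  sessions <- split_sessions(df)
  D <- length(glmhmm_covariates)
  X_all <- do.call(rbind, lapply(sessions, `[[`, "X"))
  y_all <- unlist(lapply(sessions, `[[`, "y"))
  w1 <- suppressWarnings(
    glm.fit(X_all, y_all, family = binomial())$coefficients
  )
  if (prior_prec > 0) {
    w1 <- irls_logistic(X_all, y_all, rep(1, length(y_all)), w1,
                        prior_prec = prior_prec)
  }
  if (K == 1) {
    ll <- sum(log(emission_probs(X_all, y_all, matrix(w1, 1))))
    return(structure(list(
      weights = matrix(w1, 1, D, dimnames = list(NULL, glmhmm_covariates)),
      transitions = matrix(1, 1, 1), initial = 1, K = 1L,
      loglik = ll, ll_trace = ll,
      objective_trace = ll - prior_prec * sum(w1^2) / 2,
      prior_sd = prior_sd, converged = TRUE
    ), class = "glmhmm"))
  }
  best <- NULL
  for (init in seq_len(n_inits)) {
    weights <- matrix(rep(w1, each = K), K, D) +
      matrix(rnorm(K * D, 0, 0.2), K, D)
    trans <- t(vapply(seq_len(K), function(k) {
      a <- rep(1, K); a[k] <- 10
      g <- rgamma(K, a)
      g / sum(g)
    }, numeric(K)))
    init_dist <- rep(1 / K, K)
    obj_prev <- -Inf
    ll_trace <- obj_trace <- numeric(0)
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      es <- estep_sessions(sessions, weights, trans, init_dist)
      ll <- es$loglik
      obj <- ll - prior_prec * sum(weights^2) / 2
      ll_trace <- c(ll_trace, ll)
      obj_trace <- c(obj_trace, obj)
      if (is.finite(obj_prev) && abs(obj - obj_prev) < tol * abs(obj_prev)) {
        converged <- TRUE
        break
      }
      obj_prev <- obj
      for (k in seq_len(K)) {
        weights[k, ] <- irls_logistic(X_all, y_all, es$gamma_all[, k],
                                      weights[k, ],
                                      prior_prec = prior_prec)
      }
      trans <- es$xi_tot / pmax(rowSums(es$xi_tot), 1e-12)
      init_dist <- es$g1 / sum(es$g1)
    }
    obj_final <- obj_trace[length(obj_trace)]
    if (is.null(best) || obj_final > best$objective) {
      dimnames(weights) <- list(NULL, glmhmm_covariates)
      best <- list(weights = weights, transitions = trans,
                   initial = init_dist, K = as.integer(K),
                   loglik = ll_trace[length(ll_trace)],
                   objective = obj_final,
                   ll_trace = ll_trace, objective_trace = obj_trace,
                   prior_sd = prior_sd, converged = converged)
    }
  }
  if (!best$converged) {
    warning("GLM-HMM EM did not converge within max_iter iterations")
  }
  structure(best, class = "glmhmm")
}

#' Log-likelihood of held-out data under a fitted GLM-HMM
#'
#' @param model A `glmhmm` object.
#' @param df A design tibble from [glmhmm_design()].
#' @return Total log-likelihood (nats) over the sessions in `df`.
#' @export
loglik_glmhmm <- function(model, df) {
  sessions <- split_sessions(df)
  sum(vapply(sessions, function(s) {
    p_emit <- emission_probs(s$X, s$y, model$weights)
    forward_backward(p_emit, model$transitions, model$initial)$loglik
  }, numeric(1)))
}

#' Cross-validated model comparison in bits per session
#'
#' Sessions are split into `folds` held-out sets (balanced across mice
#' when a `mouse` column is present). For each fold and each number of
#' states `K`, the model is fit on the training sessions and its held-out
#' log-likelihood is expressed relative to the 1-state model in bits per
#' session: `(LL_K - LL_1) / (log(2) * n_test_sessions)`.
#'
#' @param df Design tibble from [glmhmm_design()]; optionally with a
#'   `mouse` column for balanced folds.
#' @param K_values Numbers of states to compare (default 1:5).
#' @param folds Number of session-level folds (default 5).
#' @param n_inits Initialisations per fit (default 5; raise for final
#'   fits).
#' @param seed Optional integer seed.
#' @param ... Passed to [fit_glmhmm()].
#' @return A tibble with `fold`, `K`, `bits_per_session`, plus a summary
#'   attribute `summary` (mean and SEM across folds per K).
#' @export
cv_bits_per_session <- function(df, K_values = 1:5, folds = 5, n_inits = 5,
                                seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sess <- unique(df$session)
  if (length(sess) < folds) stop("fewer sessions than folds", call. = FALSE)
  if ("mouse" %in% names(df)) {
    mouse_of <- df |>
      dplyr::distinct(.data$session, .data$mouse)
    fold_id <- integer(length(sess))
    names(fold_id) <- as.character(sess)
    for (m in unique(mouse_of$mouse)) {
      ms <- sample(mouse_of$session[mouse_of$mouse == m])
      fold_id[as.character(ms)] <- (seq_along(ms) - 1L) %% folds + 1L
    }
  } else {
    fold_id <- setNames((sample(length(sess)) - 1L) %% folds + 1L,
                        as.character(sess))
  }
  res <- purrr::map_dfr(seq_len(folds), function(f) {
    test_sess <- sess[fold_id[as.character(sess)] == f]
    train <- df[!df$session %in% test_sess, , drop = FALSE]
    test <- df[df$session %in% test_sess, , drop = FALSE]
    lls <- vapply(K_values, function(K) {
      m <- fit_glmhmm(train, K, n_inits = n_inits, ...)
      loglik_glmhmm(m, test)
    }, numeric(1))
    ll1 <- lls[K_values == 1]
    if (length(ll1) == 0) {
      m1 <- fit_glmhmm(train, 1, n_inits = 1, ...)
      ll1 <- loglik_glmhmm(m1, test)
    }
    tibble(fold = f, K = K_values,
           bits_per_session = (lls - ll1) / (log(2) * length(test_sess)))
  })
  summ <- res |>
    dplyr::group_by(.data$K) |>
    dplyr::summarise(mean_bits = mean(.data$bits_per_session),
                     sem_bits = sd(.data$bits_per_session) / sqrt(folds),
                     .groups = "drop")
  structure(res, summary = summ)
}

#' Posterior state probabilities and hard state assignments
#'
#' Forward-backward smoothed posteriors given the inputs and choices; each
#' trial is assigned to the state with maximum posterior probability.
#'
#' @param model A fitted `glmhmm`.
#' @param df Design tibble from [glmhmm_design()].
#' @return A tibble with `session`, `trial_in_session`, per-state
#'   posterior columns `p_state_k`, and `state` (argmax).
#' @export
assign_states <- function(model, df) {
  sessions <- split_sessions(df)
  purrr::map_dfr(names(sessions), function(sid) {
    s <- sessions[[sid]]
    p_emit <- emission_probs(s$X, s$y, model$weights)
    fb <- forward_backward(p_emit, model$transitions, model$initial)
    g <- fb$gamma
    colnames(g) <- paste0("p_state_", seq_len(ncol(g)))
    dplyr::bind_cols(
      tibble(session = sid, trial_in_session = seq_len(nrow(g))),
      as_tibble(g),
      tibble(state = max.col(g))
    )
  })
}

#' Identify the engaged state of a fitted GLM-HMM
#'
#' The task-engaged state is the one with the largest absolute weight on
#' sensory evidence (delta cues).
#'
#' @param model A fitted `glmhmm`.
#' @return Integer state index.
#' @export
engaged_state <- function(model) {
  which.max(abs(model$weights[, "dcues"]))
}

#' Simulate choice data from a known GLM-HMM (recovery harness)
#'
#' Generates sessions of covariates and choices from a given `glmhmm`
#' model: evidence is drawn standard-normal (already on the normalised
#' scale), the rewarded side is the sign of the evidence, history
#' covariates are assembled from the generated choices, and the laser is
#' Bernoulli. Used to test parameter recovery.
#'
#' @param model A `glmhmm` object (ground truth).
#' @param n_sessions,n_trials Sessions and trials per session.
#' @param laser_fraction Probability of laser on each trial.
#' @param seed Optional integer seed.
#' @return A design tibble as from [glmhmm_design()], with an extra
#'   `true_state` column.
#' @export
simulate_glmhmm_sessions <- function(model, n_sessions, n_trials,
                                     laser_fraction = 0.15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- model$K
  purrr::map_dfr(seq_len(n_sessions), function(sid) {
    dcues <- rnorm(n_trials)
    laser <- as.numeric(runif(n_trials) < laser_fraction)
    y <- integer(n_trials); st <- integer(n_trials)
    prev_choice <- 0; prev_rewarded <- 0
    state <- sample.int(K, 1, prob = model$initial)
    for (t in seq_len(n_trials)) {
      u <- c(1, dcues[t], prev_choice, prev_rewarded, laser[t])
      p <- logistic(sum(model$weights[state, ] * u))
      y[t] <- as.integer(runif(1) < p)
      st[t] <- state
      chc <- if (y[t] == 1) 1 else -1
      correct <- (dcues[t] > 0) == (y[t] == 1)
      prev_choice <- chc
      prev_rewarded <- if (correct) chc else 0
      state <- sample.int(K, 1, prob = model$transitions[state, ])
    }
    tibble(session = sid, y = y, bias = 1, dcues = dcues,
           prev_choice = dplyr::lag(ifelse(y == 1, 1, -1), default = 0),
           prev_rewarded = dplyr::lag(
             ifelse((dcues > 0) == (y == 1), ifelse(y == 1, 1, -1), 0),
             default = 0),
           laser = laser, true_state = st)
  })
}

#' Match estimated states to ground-truth states
#'
#' Finds the state permutation minimising the total Euclidean distance
#' between estimated and true weight vectors (exhaustive over the K!
#' permutations, equivalent to the optimal assignment for the small K
#' used here).
#'
#' @param fit,truth `glmhmm` objects with equal K.
#' @return Integer permutation `perm` such that `fit` state `perm[k]`
#'   corresponds to `truth` state `k`.
#' @export
match_states <- function(fit, truth) {
  K <- truth$K
  stopifnot(fit$K == K)
  perms <- permutations_of(K)
  costs <- vapply(perms, function(p) {
    sum((fit$weights[p, , drop = FALSE] - truth$weights)^2)
  }, numeric(1))
  perms[[which.min(costs)]]
}

permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in permutations_of(n - 1L)) {
      rest <- setdiff(seq_len(n), i)
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

#' Trial and session selection for neural analyses
#'
#' Builds the per-trial inclusion mask: trials must be in the task-engaged
#' state, not early-turn motor errors (absolute view angle reaching 90
#' degrees before 290 cm), and not warm-up trials. Session-level quality
#' control requires at least `min_off` included laser-off trials and
#' `min_on` laser-on trials (and, for population analyses, more than
#' `min_neurons` simultaneously recorded neurons, checked when
#' `n_neurons` is supplied).
#'
#' @param trials A trial table.
#' @param posterior State assignments from [assign_states()] aligned with
#'   the non-warm-up trials of `trials`, or NULL to skip the engagement
#'   filter.
#' @param engaged Integer engaged-state index (see [engaged_state()]).
#' @param n_neurons Number of simultaneously recorded neurons (> 1 Hz),
#'   for the population QC check; NA to skip.
#' @param min_off,min_on,min_neurons QC thresholds (defaults 50, 10, 50).
#' @return A tibble of per-trial flags (`engaged`, `early_turn`,
#'   `warmup`, `included`) with a `qc` attribute summarising session QC.
#' @export
select_trials <- function(trials, posterior = NULL, engaged = 1L,
                          n_neurons = NA, min_off = 50L, min_on = 10L,
                          min_neurons = 50L) {
  warmup <- trials$maze_type == "warmup"
  if (!is.null(posterior)) {
    eng <- rep(FALSE, nrow(trials))
    eng[!warmup] <- posterior$state == engaged
  } else {
    eng <- !warmup
  }
  if ("view_angle" %in% names(trials) &&
      !all(vapply(trials$view_angle, is.null, logical(1)))) {
    pb <- position_bins()
    early <- vapply(trials$view_angle, function(th) {
      if (is.null(th)) return(NA)
      any(abs(th[pb$centre < 290]) >= pi / 2 - 1e-9)
    }, logical(1))
  } else if ("early_turn" %in% names(trials)) {
    early <- trials$early_turn
  } else {
    stop("no kinematics available for early-turn filtering", call. = FALSE)
  }
  included <- eng & !early & !warmup
  n_off <- sum(included & !trials$laser)
  n_on <- sum(included & trials$laser)
  qc <- tibble(
    n_laser_off = n_off, n_laser_on = n_on, n_neurons = n_neurons,
    pass_trials = n_off >= min_off && n_on >= min_on,
    pass_population = n_off >= min_off && n_on >= min_on &&
      (!is.na(n_neurons) && n_neurons > min_neurons)
  )
  structure(tibble(trial = trials$trial, engaged = eng, early_turn = early,
                   warmup = warmup, included = included),
            qc = qc)
}
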