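#' Parameters of the generative hypothesis models
#'
#' Four generative models link evidence-tuned neurons, choice-tuned
#' neurons, the laser, and action. In all models the ipsilateral- and
#' contralateral-preferring evidence neurons fire at
#' `ei = a*e + b*l + gamma` and `ec = -a*e - b*l + gamma`, where `e` is
#' the final signed evidence (h1ii uses the attended evidence `e'`) and
#' `l` indicates laser. The models differ in how the 10 + 10 choice-tuned
#' neurons are driven:
#' \describe{
#'   \item{h1i}{choice neurons read the evidence-neuron difference through
#'     `Bernoulli(sigma(ei - ec))`, each lapsing to a fair coin with
#'     probability `PL = 0.5`; action = majority vote.}
#'   \item{h1ii}{a fraction `d = 0.3` of cues goes unattended (independent
#'     Bernoulli thinning per cue); choice neurons read the evidence
#'     difference without lapses; note the printed laser effect is
#'     `b = +2` for this model.}
#'   \item{h2}{the action is drawn first from `sigma(ei - ec)` with
#'     behavioural lapse `PA = 0.1`; choice neurons then read the action
#'     with lapse `PL = 0.1`.}
#'   \item{h3}{on each trial the choice population reads either the
#'     evidence neurons (probability `W = 0.5`) or a shared alternative
#'     decision draw `D ~ Bernoulli(0.5)`, each neuron still lapsing with
#'     `PL = 0.5`; action = majority vote with behavioural lapse
#'     `PA = 0.1`.}
#' }
#' The logistic readout is `sigma(x) = 1 / (1 + exp(-0.75 x))`.
#'
#' @param which One of `"h1i"`, `"h1ii"`, `"h2"`, `"h3"`.
#' @param a Evidence gain (default 1).
#' @param b Laser effect on the evidence neurons (default -2; +2 for
#'   h1ii, as printed for that model).
#' @param gamma Baseline rate (default 10).
#' @param slope Logistic slope (default 0.75).
#' @param PL Choice-neuron lapse probability (0.5 in h1i/h3, 0.1 in h2,
#'   0 in h1ii).
#' @param PA Behavioural lapse probability (0.1; h2 and h3 only).
#' @param W Probability of evidence readout (0.5; h3 only).
#' @param d Unattended cue fraction (0.3; h1ii only).
#' @param n_choice_neurons Choice neurons per side (default 10).
#' @param n_repeats Simulated repeats per input trial (default 4).
#' @return A list of class `hypothesis_params`.
#' @export
hypothesis_params <- function(which = c("h1i", "h1ii", "h2", "h3"),
                              a = 1, b = NULL, gamma = 10, slope = 0.75,
                              PL = NULL, PA = 0.1, W = 0.5, d = 0.3,
                              n_choice_neurons = 10L, n_repeats = 4L) {
  which <- match.arg(which)
  b <- b %||% if (which == "h1ii") 2 else -2
  PL <- PL %||% switch(which, h1i = 0.5, h1ii = 0, h2 = 0.1, h3 = 0.5)
  stopifnot(PL >= 0, PL <= 1, PA >= 0, PA <= 1, W >= 0, W <= 1,
            d >= 0, d <= 1, n_choice_neurons >= 1)
  structure(list(which = which, a = a, b = b, gamma = gamma, slope = slope,
                 PL = PL, PA = PA, W = W, d = d,
                 n_choice_neurons = as.integer(n_choice_neurons),
                 n_repeats = as.integer(n_repeats)),
            class = "hypothesis_params")
}

hyp_sigma <- function(x, slope = 0.75) 1 / (1 + exp(-slope * x))

#' Cue statistics for hypothesis simulations
#'
#' Generates base trials with the task's cue statistics (spatial Poisson
#' draws from the two main-maze rate pairs, balanced majority side) and a
#' laser flag, without simulating an agent. Used as the trial source for
#' the hypothesis models when no experimental trial table is supplied.
#'
#' @param n_trials Number of base trials (default 9000).
#' @param laser_fraction Fraction of laser-on trials (default 0.15).
#' @param seed Optional integer seed.
#' @return A tibble with `n_left`, `n_right`, `final_evidence`
#'   (#ipsi - #contra, ipsi = right), `laser`, and cue-position list
#'   columns.
#' @export
hypothesis_trials <- function(n_trials = 9000, laser_fraction = 0.15,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- task_config()
  pair_idx <- sample.int(length(cfg$cue_rate_pairs), n_trials, replace = TRUE,
                         prob = cfg$cue_rate_weights)
  majority_right <- runif(n_trials) < 0.5
  laser <- runif(n_trials) < laser_fraction
  n_left <- n_right <- integer(n_trials)
  cues_left <- cues_right <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    pair <- cfg$cue_rate_pairs[[pair_idx[i]]]
    rates <- if (majority_right[i]) c(pair[2], pair[1]) else c(pair[1], pair[2])
    cues <- generate_cues(rates[1], rates[2], refractory = cfg$refractory)
    n_left[i] <- length(cues$left); n_right[i] <- length(cues$right)
    cues_left[[i]] <- cues$left; cues_right[[i]] <- cues$right
  }
  tibble(n_left = n_left, n_right = n_right,
         final_evidence = n_right - n_left, laser = laser,
         cues_left = cues_left, cues_right = cues_right)
}

#' Simulate one generative hypothesis model
#'
#' Implements the four models exactly as specified (see
#' [hypothesis_params()]). Each input trial is simulated `n_repeats`
#' times with fresh randomness. In h1i, h2 and h3 the evidence-neuron
#' rates satisfy `ei + ec = 2*gamma` identically (the laser terms
#' cancel in the sum). Ties in the choice-population majority vote are
#' broken by a fair coin.
#'
#' @param which Hypothesis tag (`"h1i"`, `"h1ii"`, `"h2"`, `"h3"`).
#' @param trials Trial source: a tibble with `final_evidence` and `laser`
#'   (and cue counts for h1ii); defaults to [hypothesis_trials()].
#' @param params A [hypothesis_params()]; defaults for `which`.
#' @param seed Optional integer seed.
#' @return A tibble of class `hypothesis_sim`, one row per simulated
#'   trial: `e`, `e_att` (h1ii), `laser`, `ei`, `ec`, choice-neuron
#'   active counts `ci_sum`/`cc_sum` (out of `n_choice_neurons`), the
#'   alternative-decision draw `D` and `readout_was_evidence` flag (h3),
#'   and the action `A` (1 = ipsilateral). The parameter set is attached
#'   as the `params` attribute.
#' @export
simulate_hypothesis <- function(which = c("h1i", "h1ii", "h2", "h3"),
                                trials = NULL, params = NULL, seed = NULL) {
  which <- match.arg(which)
  params <- params %||% hypothesis_params(which)
  stopifnot(params$which == which)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(trials)) trials <- hypothesis_trials()
  R <- params$n_repeats
  n <- nrow(trials) * R
  e <- rep(trials$final_evidence, each = R)
  l <- rep(as.numeric(trials$laser), each = R)
  nc <- params$n_choice_neurons
  a <- params$a; b <- params$b; g <- params$gamma; sl <- params$slope

  e_att <- NA_real_
  n_presented <- NA_integer_
  n_attended <- NA_integer_
  if (which == "h1ii") {
    nl <- rep(trials$n_left, each = R)
    nr <- rep(trials$n_right, each = R)
    # independent Bernoulli(1 - d) retention per cue, fresh per repeat
    nl_att <- rbinom(n, nl, 1 - params$d)
    nr_att <- rbinom(n, nr, 1 - params$d)
    e_att <- nr_att - nl_att
    n_presented <- nl + nr
    n_attended <- nl_att + nr_att
    e_used <- e_att
  } else {
    e_used <- e
  }
  ei <- a * e_used + b * l + g
  ec <- -a * e_used - b * l + g
  de <- ei - ec
  p_ev <- hyp_sigma(de, sl)

  D <- NA_integer_
  w_sel <- NA_real_
  readout_was_evidence <- NA
  if (which %in% c("h1i", "h1ii")) {
    if (which == "h1i") {
      lapse_i <- matrix(runif(n * nc) < params$PL, n, nc)
      lapse_c <- matrix(runif(n * nc) < params$PL, n, nc)
      ci <- matrix(rbinom(n * nc, 1, rep(p_ev, nc)), n, nc)
      cc <- matrix(rbinom(n * nc, 1, rep(1 - p_ev, nc)), n, nc)
      coin_i <- matrix(rbinom(n * nc, 1, 0.5), n, nc)
      coin_c <- matrix(rbinom(n * nc, 1, 0.5), n, nc)
      ci[lapse_i] <- coin_i[lapse_i]
      cc[lapse_c] <- coin_c[lapse_c]
    } else {
      ci <- matrix(rbinom(n * nc, 1, rep(p_ev, nc)), n, nc)
      cc <- matrix(rbinom(n * nc, 1, rep(1 - p_ev, nc)), n, nc)
    }
    mi <- rowMeans(ci); mc <- rowMeans(cc)
    A <- ifelse(mi > mc, 1L, ifelse(mi < mc, 0L, rbinom(n, 1, 0.5)))
  } else if (which == "h2") {
    A <- ifelse(runif(n) > params$PA,
                rbinom(n, 1, p_ev), rbinom(n, 1, 0.5))
    lapse_i <- matrix(runif(n * nc) < params$PL, n, nc)
    lapse_c <- matrix(runif(n * nc) < params$PL, n, nc)
    ci <- matrix(rep(A, nc), n, nc)
    cc <- matrix(rep(1L - A, nc), n, nc)
    coin_i <- matrix(rbinom(n * nc, 1, 0.5), n, nc)
    coin_c <- matrix(rbinom(n * nc, 1, 0.5), n, nc)
    ci[lapse_i] <- coin_i[lapse_i]
    cc[lapse_c] <- coin_c[lapse_c]
  } else { # h3
    w_sel <- runif(n)
    readout_was_evidence <- w_sel < params$W
    D <- rbinom(n, 1, 0.5)
    lapse <- matrix(runif(n * nc) < params$PL, n, nc)
    lapse_c <- matrix(runif(n * nc) < params$PL, n, nc)
    ci <- matrix(0L, n, nc); cc <- matrix(0L, n, nc)
    ev_rows <- which(readout_was_evidence)
    alt_rows <- which(!readout_was_evidence)
    if (length(ev_rows)) {
      ci[ev_rows, ] <- matrix(rbinom(length(ev_rows) * nc, 1,
                                     rep(p_ev[ev_rows], nc)),
                              length(ev_rows), nc)
      cc[ev_rows, ] <- matrix(rbinom(length(ev_rows) * nc, 1,
                                     rep(1 - p_ev[ev_rows], nc)),
                              length(ev_rows), nc)
    }
    if (length(alt_rows)) {
      ci[alt_rows, ] <- matrix(rep(D[alt_rows], nc), length(alt_rows), nc)
      cc[alt_rows, ] <- matrix(rep(1L - D[alt_rows], nc),
                               length(alt_rows), nc)
    }
    coin <- matrix(rbinom(n * nc, 1, 0.5), n, nc)
    coin_c <- matrix(rbinom(n * nc, 1, 0.5), n, nc)
    # as printed: evidence branch reads out when p > PL, the alternative
    # branch reads out D when p < PL; the coin covers the remainder
    ev_row <- matrix(readout_was_evidence, n, nc)
    sel_i <- ifelse(ev_row, lapse, !lapse)
    sel_c <- ifelse(ev_row, lapse_c, !lapse_c)
    ci[sel_i] <- coin[sel_i]
    cc[sel_c] <- coin_c[sel_c]
    mi <- rowMeans(ci); mc <- rowMeans(cc)
    vote <- ifelse(mi > mc, 1L, ifelse(mi < mc, 0L, rbinom(n, 1, 0.5)))
    A <- ifelse(runif(n) > params$PA, vote, rbinom(n, 1, 0.5))
  }
  out <- tibble(
    base_trial = rep(seq_len(nrow(trials)), each = R),
    rep = rep(seq_len(R), times = nrow(trials)),
    e = e, e_att = e_att, laser = l == 1,
    ei = ei, ec = ec,
    ci_sum = rowSums(ci), cc_sum = rowSums(cc),
    D = D, w_sel = w_sel, readout_was_evidence = readout_was_evidence,
    n_presented = n_presented, n_attended = n_attended,
    A = as.integer(A)
  )
  attr(out, "params") <- params
  class(out) <- c("hypothesis_sim", class(out))
  out
}

#' Fit a lapse-logistic psychometric function to simulated choices
#'
#' Maximum-likelihood fit of
#' `P(ipsi | e) = lambda_lo + (1 - lambda_lo - lambda_hi) *
#' logistic(beta0 + beta1 * e)`.
#'
#' @param sim A `hypothesis_sim` tibble (or any tibble with `e` and `A`).
#' @param laser Restrict to laser-on (`TRUE`), laser-off (`FALSE`), or
#'   all trials (`NULL`, default uses laser-off).
#' @param n_boot Bootstrap resamples for standard errors (default 0:
#'   no bootstrap).
#' @param seed Optional integer seed for the bootstrap.
#' @return A tibble of class `lapse_fit` with `lambda_lo`, `lambda_hi`,
#'   `total_lapse`, `beta0`, `beta1`, `loglik`, and (with bootstrap)
#'   `*_se` columns.
#' @export
psychometric_from_sim <- function(sim, laser = FALSE, n_boot = 0,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  df <- if (is.null(laser)) sim else sim[sim$laser == laser, , drop = FALSE]
  fit_once <- function(e, A) {
    nll <- function(par) {
      llo <- logistic(par[1]); lhi <- logistic(par[2])
      p <- llo + (1 - llo - lhi) * logistic(par[3] + par[4] * e)
      p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
      -sum(ifelse(A == 1, log(p), log(1 - p)))
    }
    o <- optim(c(-3, -3, 0, 1), nll, method = "BFGS",
               control = list(maxit = 500))
    if (o$convergence != 0) {
      o <- optim(o$par, nll, method = "Nelder-Mead",
                 control = list(maxit = 2000))
    }
    if (o$convergence != 0) {
      stop("lapse-logistic fit did not converge; value = ", o$value,
           call. = FALSE)
    }
    c(lambda_lo = logistic(o$par[1]), lambda_hi = logistic(o$par[2]),
      beta0 = o$par[3], beta1 = o$par[4], loglik = -o$value)
  }
  est <- fit_once(df$e, df$A)
  out <- tibble(lambda_lo = est["lambda_lo"], lambda_hi = est["lambda_hi"],
                total_lapse = est["lambda_lo"] + est["lambda_hi"],
                beta0 = est["beta0"], beta1 = est["beta1"],
                loglik = est["loglik"])
  if (n_boot > 0) {
    bs <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(nrow(df), replace = TRUE)
      est_b <- fit_once(df$e[idx], df$A[idx])
      c(est_b["lambda_lo"] + est_b["lambda_hi"], est_b["beta1"])
    }, numeric(2))
    out$total_lapse_se <- sd(bs[1, ])
    out$beta1_se <- sd(bs[2, ])
  }
  class(out) <- c("lapse_fit", class(out))
  out
}

#' Recover hypothesis-model parameters from simulated data
#'
#' Estimators for the printed parameters of each generative model:
#' \describe{
#'   \item{h2}{`PA_hat` is the total lapse of the laser-off psychometric
#'     fit; `PL_hat` is twice the empirical probability that an
#'     ipsilateral-preferring choice neuron is silent on
#'     ipsilateral-action trials.}
#'   \item{h1i}{`PL_hat` from a maximum-likelihood fit of the mixture
#'     response `E[c] = (1 - PL) * sigma(s * de) + PL / 2` to pooled
#'     choice-neuron outputs across evidence-neuron differences `de`.}
#'   \item{h1ii}{`d_hat` is the mean per-trial fraction of presented cues
#'     missing from the attended set.}
#'   \item{h3}{`W_hat` is the empirical fraction of trials with evidence
#'     readout.}
#' }
#' Bootstrap confidence intervals resample trials.
#'
#' @param sim A `hypothesis_sim` from the matching hypothesis.
#' @param n_boot Bootstrap resamples (default 200).
#' @param seed Optional integer seed.
#' @return A tibble with `parameter`, `estimate`, `se`, `ci_lo`, `ci_hi`,
#'   `truth`.
#' @export
recover_parameters <- function(sim, n_boot = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params <- attr(sim, "params")
  which <- params$which
  if (nrow(sim) < 1000) {
    warning("fewer than 1000 trials; estimates will have wide intervals")
  }
  nc <- params$n_choice_neurons
  estimators <- switch(which,
    h2 = list(
      PA = function(d) {
        psychometric_from_sim(d, laser = FALSE)$total_lapse
      },
      PL = function(d) {
        ipsi_act <- d$A == 1
        2 * (1 - sum(d$ci_sum[ipsi_act]) / (nc * sum(ipsi_act)))
      }
    ),
    h1i = list(
      PL = function(d) fit_choice_mixture(d$ei - d$ec, d$ci_sum, nc)["PL"]
    ),
    h1ii = list(
      d = function(d) {
        keep <- d$n_presented > 0
        mean(1 - d$n_attended[keep] / d$n_presented[keep])
      }
    ),
    h3 = list(
      W = function(d) mean(d$readout_was_evidence)
    )
  )
  truths <- list(PA = params$PA, PL = params$PL, d = params$d, W = params$W)
  purrr::map_dfr(names(estimators), function(nm) {
    f <- estimators[[nm]]
    est <- unname(f(sim))
    bs <- vapply(seq_len(n_boot), function(i) {
      unname(f(sim[sample.int(nrow(sim), replace = TRUE), , drop = FALSE]))
    }, numeric(1))
    tibble(parameter = nm, estimate = est, se = sd(bs),
           ci_lo = unname(quantile(bs, 0.025)),
           ci_hi = unname(quantile(bs, 0.975)),
           truth = truths[[nm]])
  })
}

# ML fit of E[c] = (1 - PL) * sigma(s * de) + PL/2 to binomial counts.
fit_choice_mixture <- function(de, ci_sum, nc) {
  nll <- function(par) {
    PL <- logistic(par[1]); s <- exp(par[2])
    p <- (1 - PL) * hyp_sigma(de, s) + PL / 2
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    -sum(ci_sum * log(p) + (nc - ci_sum) * log(1 - p))
  }
  o <- optim(c(0, log(0.75)), nll, method = "BFGS",
             control = list(maxit = 500))
  c(PL = logistic(o$par[1]), slope = exp(o$par[2]))
}

#' Tuning curves of the simulated evidence and choice populations
#'
#' Mean evidence-neuron rates and choice-neuron activation per
#' final-evidence level, split by laser and by correctness (tied trials
#' are dropped from the correctness split).
#'
#' @param sim A `hypothesis_sim` tibble.
#' @param by Split variable: `"laser"` (default) or `"correct"`.
#' @return A tibble with `e`, the split column, `ei`, `ec`, `ci_mean`,
#'   `cc_mean`, `n`.
#' @export
tuning_curves_from_sim <- function(sim, by = c("laser", "correct")) {
  by <- match.arg(by)
  nc <- attr(sim, "params")$n_choice_neurons
  df <- sim |>
    dplyr::mutate(correct = dplyr::case_when(
      .data$e > 0 & .data$A == 1 ~ TRUE,
      .data$e < 0 & .data$A == 0 ~ TRUE,
      .data$e == 0 ~ NA,
      TRUE ~ FALSE))
  if (by == "correct") df <- dplyr::filter(df, !is.na(.data$correct))
  df |>
    dplyr::group_by(e = .data$e, !!rlang::sym(by) := .data[[by]]) |>
    dplyr::summarise(ei = mean(.data$ei), ec = mean(.data$ec),
                     ci_mean = mean(.data$ci_sum) / nc,
                     cc_mean = mean(.data$cc_sum) / nc,
                     n = dplyr::n(), .groups = "drop")
}
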