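test_that("evidence binning splits each side into equal-count thirds", {
  tr <- toy_trials(c(-3, -2, -1, 1, 2, 3))
  b <- bin_evidence(tr)
  expect_equal(as.character(b),
               c("contra_3", "contra_2", "contra_1",
                 "ipsi_1", "ipsi_2", "ipsi_3"))
  # tied trials are excluded
  tr0 <- toy_trials(c(0, -1, -2, -3, 1, 2, 3))
  expect_equal(as.character(bin_evidence(tr0))[1], "excluded")
  # 7 trials on a side -> bin sizes 3, 2, 2 with the remainder low
  tr7 <- toy_trials(c(1, 1, 2, 3, 4, 5, 6, -1, -2, -3, -4, -5, -6))
  b7 <- bin_evidence(tr7)
  expect_equal(as.integer(table(b7[1:7])[c("ipsi_1", "ipsi_2", "ipsi_3")]),
               c(3L, 2L, 2L))
  expect_error(bin_evidence(toy_trials(rep(0, 10))), "tied")
})

test_that("psychometric curves count ipsilateral choices per bin", {
  ev <- rep(c(-3, -2, -1, 1, 2, 3), each = 10)
  # an all-ipsi chooser sits at 100% in every bin
  tr <- toy_trials(ev, choice = rep("right", 60))
  pc <- psychometric(tr, by_laser = FALSE)
  expect_true(all(pc$pct_ipsi == 100))
  # a deterministic evidence-follower is above 50% on ipsi bins only
  tr2 <- toy_trials(ev)
  pc2 <- psychometric(tr2, by_laser = FALSE)
  ipsi_bins <- grepl("ipsi", pc2$evidence_bin)
  expect_true(all(pc2$pct_ipsi[ipsi_bins] > 50))
  expect_true(all(pc2$pct_ipsi[!ipsi_bins] < 50))
})

test_that("a laser-sensitive agent shifts the on-curve toward ipsi", {
  set.seed(21)
  ag <- agent_params(weights = rbind(c(0.5, 0, 0, 2, 0)),
                     transitions = matrix(1, 1, 1), initial = 1)
  n <- 4000
  ev <- round(rnorm(n, 0, 4))
  laser <- runif(n) < 0.5
  choice <- vapply(seq_len(n), function(i) {
    agent_step(ag, 1, c(ev[i], 0, 0, laser[i], 1))$choice
  }, character(1))
  tr <- toy_trials(ev, choice = choice, laser = laser)
  pc <- psychometric(tr)
  wide <- tidyr::pivot_wider(pc, id_cols = "evidence_bin",
                             names_from = "laser",
                             values_from = "pct_ipsi")
  expect_true(all(wide$`TRUE` > wide$`FALSE`))
})

test_that("laser bias is signed, antisymmetric, and null without opsin", {
  set.seed(22)
  n <- 6000
  ev <- sample(c(-4, -2, 2, 4), n, replace = TRUE)
  laser <- runif(n) < 0.3
  # laser pushes choices to the right (ipsi)
  p_right <- plogis(0.8 * ev + 2 * laser)
  choice <- ifelse(runif(n) < p_right, "right", "left")
  tr <- toy_trials(ev, choice = choice, laser = laser)
  b <- laser_bias(tr)
  expect_gt(b, 0)
  expect_equal(laser_bias(tr, flip_frame = TRUE), -b)
  # laser-independent agent: bias centred on zero
  choice0 <- ifelse(runif(n) < plogis(0.8 * ev), "right", "left")
  tr0 <- toy_trials(ev, choice = choice0, laser = laser)
  expect_lt(abs(laser_bias(tr0)), 5)
  expect_error(laser_bias(toy_trials(c(1, -1))), "laser")
})

test_that("a 1-state GLM-HMM reduces to the direct logistic fit", {
  set.seed(23)
  truth <- structure(list(
    weights = matrix(c(0.3, 1.5, 0.2, 0.1, 0.5), 1),
    transitions = matrix(1, 1, 1), initial = 1, K = 1L), class = "glmhmm")
  df <- simulate_glmhmm_sessions(truth, 4, 250, seed = 24)
  fit <- fit_glmhmm(df, K = 1, prior_sd = Inf)
  X <- as.matrix(df[, c("bias", "dcues", "prev_choice", "prev_rewarded",
                        "laser")])
  ref <- suppressWarnings(
    glm.fit(X, df$y, family = binomial())$coefficients)
  expect_equal(unname(fit$weights[1, ]), unname(ref), tolerance = 1e-6)
})

test_that("EM objective is non-decreasing and posteriors normalise", {
  set.seed(25)
  truth <- structure(list(
    weights = rbind(c(0, 3, 0.2, 0.2, 1), c(1, 0.2, 0.3, 0.1, 0.3)),
    transitions = rbind(c(0.95, 0.05), c(0.05, 0.95)),
    initial = c(0.5, 0.5), K = 2L), class = "glmhmm")
  df <- simulate_glmhmm_sessions(truth, 6, 200, seed = 26)
  fit <- suppressWarnings(fit_glmhmm(df, K = 2, n_inits = 3, seed = 27))
  expect_true(all(diff(fit$objective_trace) > -1e-6 * abs(fit$objective)))
  post <- assign_states(fit, df)
  sums <- post$p_state_1 + post$p_state_2
  expect_true(all(abs(sums - 1) < 1e-10))
  expect_true(all(abs(rowSums(fit$transitions) - 1) < 1e-10))
  # K = 1 posterior is trivially 1
  fit1 <- fit_glmhmm(df, K = 1)
  expect_true(all(assign_states(fit1, df)$p_state_1 == 1))
})

test_that("held-out likelihood is invariant to trial order given fixed covariates", {
  set.seed(28)
  truth <- structure(list(
    weights = matrix(c(0.2, 1.5, 0, 0, 0.5), 1),
    transitions = matrix(1, 1, 1), initial = 1, K = 1L), class = "glmhmm")
  df <- simulate_glmhmm_sessions(truth, 2, 100, seed = 29)
  m <- fit_glmhmm(df, K = 1)
  # a 1-state likelihood is a sum over trials: permuting rows while
  # holding the (already-computed) history covariates fixed leaves it
  # unchanged
  df_perm <- df[sample(nrow(df)), , drop = FALSE]
  expect_equal(loglik_glmhmm(m, df_perm), loglik_glmhmm(m, df),
               tolerance = 1e-10)
})

test_that("the engaged state is identified by its evidence weight", {
  m <- structure(list(weights = rbind(c(2, 0.1, 0, 0, 0),
                                      c(0, 2.5, 0, 0, 1),
                                      c(-2, 0.3, 0, 0, 0)),
                      K = 3L), class = "glmhmm")
  colnames(m$weights) <- c("bias", "dcues", "prev_choice",
                           "prev_rewarded", "laser")
  expect_equal(engaged_state(m), 2L)
})

test_that("trial selection applies engagement, early-turn and warm-up filters", {
  tr <- toy_trials(c(2, -2, 3, -3, 2, -2))
  tr$maze_type <- c("warmup", rep("main", 5))
  tr$early_turn <- c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  post <- tibble::tibble(state = c(1L, 1L, 2L, 1L, 1L))
  sel <- select_trials(tr, posterior = post, engaged = 1L,
                       min_off = 2, min_on = 0)
  expect_equal(sel$included, c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE))
  qc <- attr(sel, "qc")
  expect_true(qc$pass_trials)
  # a view angle past 90 degrees before 290 cm is an early turn
  tr2 <- toy_trials(c(2, -2))
  tr2$view_angle <- list(rep(0, 66),
                         c(rep(0, 50), rep(pi / 2, 16)))
  sel2 <- select_trials(tr2, min_off = 1, min_on = 0)
  expect_equal(sel2$early_turn, c(FALSE, TRUE))
  # session QC thresholds: 49 included laser-off trials fail
  tr3 <- toy_trials(rep(c(2, -2), 30))
  tr3$laser <- c(rep(TRUE, 11), rep(FALSE, 49))
  sel3 <- select_trials(tr3)
  expect_false(attr(sel3, "qc")$pass_trials)
})
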