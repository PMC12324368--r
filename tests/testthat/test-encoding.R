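test_that("causal half-Gaussian smoothing is causal and mass-preserving", {
  expect_equal(smooth_spikes(rep(0, 100)), rep(0, 100))
  # a single spike produces zero output before it and a decaying
  # half-Gaussian profile after it
  x <- rep(0, 400); x[200] <- 1
  y <- smooth_spikes(x)
  expect_true(all(abs(y[1:199]) < 1e-12)) # zero up to FFT round-off
  k <- exp(-((0:160) * 0.01)^2 / (2 * 0.4^2))
  k <- k / sum(k)
  expect_equal(y[200:360], k[1:161], tolerance = 1e-6)
  # constant input maps to the same constant (kernel sums to one and the
  # edge is renormalised)
  expect_equal(smooth_spikes(rep(3, 200)), rep(3, 200), tolerance = 1e-9)
})

test_that("position binning is occupancy-invariant for constant rates", {
  trials <- toy_trials(rep(c(2, -2), 30))
  trials$cum_evidence <- replicate(60, rep(0, 66), simplify = FALSE)
  trials$speed <- rep(c(25, 60), 30) # strongly different traversal speeds
  neurons <- tibble::tibble(neuron = 1, tuning_class = "untuned",
                            side_pref = "none", baseline = 20, gain = 0,
                            pos_gain = 0, laser_effect = 0)
  sp <- simulate_population(trials, neurons, seed = 31)
  tens <- position_bin(sp)
  expect_equal(dim(tens), c(1, 60, 66))
  slow <- apply(unclass(tens)[1, trials$speed == 25, ], 2, mean)
  fast <- apply(unclass(tens)[1, trials$speed == 60, ], 2, mean)
  # same Hz in every bin regardless of traversal speed (bound ~3 SE of a
  # per-bin mean difference under Poisson noise at this rate)
  expect_lt(max(abs(slow - fast), na.rm = TRUE), 5)
  expect_lt(abs(mean(slow, na.rm = TRUE) - 20), 1)
  # occupancy durations are retained and scale with 1/speed
  occ <- attr(tens, "occupancy")
  expect_gt(mean(occ[trials$speed == 25, 10]),
            mean(occ[trials$speed == 60, 10]))
})

test_that("z-scoring normalises per neuron and flags constant neurons", {
  fx <- fixture_session()
  z <- fx$tensor_z
  m <- apply(unclass(z), 1, mean, na.rm = TRUE)
  s <- apply(unclass(z), 1, sd, na.rm = TRUE)
  expect_true(all(abs(m) < 1e-10))
  expect_true(all(abs(s - 1) < 1e-10))
  # constant neuron: flagged, not NaN-propagated
  const <- structure(array(5, dim = c(1, 4, 66)), class = "rate_tensor")
  zc <- zscore_tensor(const)
  expect_true(attr(zc, "excluded")[1])
  expect_true(all(is.na(unclass(zc))))
})

test_that("encoding model recovers an exact linear response", {
  fx <- fixture_session()
  tr <- fx$trials
  ev <- do.call(rbind, tr$cum_evidence)
  n_tr <- nrow(tr)
  # response constructed as 2 * evidence with no noise
  tens <- array(NA_real_, dim = c(2, n_tr, 66))
  tens[1, , ] <- 2 * ev
  tens[2, , ] <- outer(ifelse(tr$choice == "right", 1, -1), rep(1, 66))
  tens <- structure(tens, class = "rate_tensor")
  fit <- fit_encoding_model(tens, tr, include_laser = TRUE)
  ok_pos <- which(apply(fit$coef["evidence", 1, , drop = FALSE], 3,
                        function(x) !is.na(x)))
  expect_lt(max(abs(fit$coef["evidence", 1, ok_pos] - 2)), 1e-8)
  expect_lt(max(abs(fit$coef["choice", 1, ok_pos])), 1e-8)
  expect_lt(max(abs(fit$coef["choice", 2, ok_pos] - 1)), 1e-8)
})

test_that("OLS coefficients and t-statistics match the normal equations", {
  set.seed(32)
  for (i in 1:20) {
    n <- 40; p <- 4
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    Y <- matrix(rnorm(n * 3), n)
    fit <- optoshift:::ols_t(X, Y)
    B_ref <- solve(t(X) %*% X) %*% t(X) %*% Y
    expect_lt(max(abs(fit$coef - B_ref)), 1e-8)
    for (j in 1:3) {
      res <- Y[, j] - X %*% B_ref[, j]
      s2 <- sum(res^2) / (n - p)
      se <- sqrt(diag(solve(t(X) %*% X)) * s2)
      expect_lt(max(abs(fit$t[, j] - B_ref[, j] / se)), 1e-8)
    }
  }
  # rank-deficient designs are refused with the offending column named
  Xbad <- cbind(a = rep(1, 10), b = 1:10, c = 1:10)
  expect_error(optoshift:::ols_t(Xbad, matrix(rnorm(10))), "collinear")
})

test_that("the laser coefficient halves the on-minus-off difference", {
  set.seed(33)
  # random choices and outcomes so no design column is degenerate
  ev <- rep(c(3, -3), 40)
  tr <- toy_trials(ev,
                   choice = sample(c("left", "right"), 80, replace = TRUE),
                   laser = rep(c(TRUE, FALSE, FALSE, FALSE), 20))
  tr$cum_evidence <- lapply(tr$final_evidence, function(e) {
    cumsum(rep(e / 66, 66))
  })
  tr$correct <- tr$choice == tr$rewarded_side
  delta <- 4
  n_tr <- nrow(tr)
  tens <- array(rnorm(n_tr * 66, sd = 1e-8), dim = c(1, n_tr, 66))
  tens[1, , ] <- tens[1, , ] + delta * tr$laser
  tens <- structure(tens, class = "rate_tensor")
  fit <- fit_encoding_model(tens, tr, include_laser = TRUE)
  # with a +/-1 coding an additive on-off effect of delta appears as
  # a coefficient of delta / 2
  expect_equal(mean(fit$coef["laser", 1, ]), delta / 2, tolerance = 1e-6)
})

test_that("classification finds strong tuning with the right preference", {
  fx <- fixture_session()
  fit <- fit_encoding_model(fx$tensor_hz, fx$trials, include_laser = FALSE)
  labels <- classify_tuning(fit, n_shuffle = 100, seed = 34)
  truth <- fx$neurons
  ev <- truth$tuning_class == "evidence"
  # strong evidence neurons are found with the correct side preference
  expect_gte(mean(labels$tuning_class[ev] == "evidence"), 0.85)
  found <- ev & labels$tuning_class == "evidence"
  expect_true(all(labels$side_pref[found] == truth$side_pref[found]))
  # evidence significance dominates choice significance in the labels
  both <- labels$evidence_sig & labels$choice_sig
  expect_true(all(labels$tuning_class[both] == "evidence"))
})

test_that("tuning curves are graded for evidence cells and flip for choice cells", {
  fx <- fixture_session()
  truth <- fx$neurons
  ipsi_ev <- which(truth$tuning_class == "evidence" &
                     truth$side_pref == "ipsi")
  curve <- tuning_curve(fx$tensor_z, fx$trials, neurons = ipsi_ev)
  vals <- curve$mean[order(curve$evidence_bin)]
  # increasing in expectation from high-contra to high-ipsi evidence
  expect_gt(vals[6], vals[1])
  expect_gt(cor(seq_len(6), vals), 0.8)
  # untuned population: flat around zero
  unt <- which(truth$tuning_class == "untuned")
  c0 <- tuning_curve(fx$tensor_z, fx$trials, neurons = unt)
  expect_lt(max(abs(c0$mean)), 0.35)
  # choice neurons: slope sign flips between correct and incorrect trials
  ch <- which(truth$tuning_class == "choice" & truth$side_pref == "ipsi")
  cc <- tuning_curve(fx$tensor_z, fx$trials, neurons = ch,
                     split = "correct_vs_incorrect")
  slope <- function(d) {
    d <- d[order(d$evidence_bin), ]
    cor(seq_len(nrow(d)), d$mean)
  }
  s_cor <- slope(cc[cc$correct == TRUE, ])
  s_err <- slope(cc[cc$correct == FALSE, ])
  expect_gt(s_cor, 0)
  expect_lt(s_err, 0)
})

test_that("laser modulation tests calibrate and detect", {
  set.seed(35)
  # identical distributions: close to the nominal false-positive rate
  n_rep <- 400
  p_null <- replicate(n_rep, {
    a <- rnorm(30); b <- rnorm(30)
    suppressWarnings(wilcox.test(a, b)$p.value)
  })
  expect_lt(mean(p_null < 0.05), 0.09)
  # +5 Hz on a 10 Hz baseline with 100 trials: detected and excited
  trials <- toy_trials(rep(c(2, -2), 50),
                       laser = rep(c(TRUE, FALSE), 50))
  trials$cum_evidence <- replicate(100, rep(0, 66), simplify = FALSE)
  neurons <- tibble::tibble(neuron = 1, tuning_class = "untuned",
                            side_pref = "none", baseline = 10, gain = 0,
                            pos_gain = 0, laser_effect = 5)
  sp <- simulate_population(trials, neurons, seed = 36)
  tens <- position_bin(sp)
  res <- laser_modulation_test(tens, trials, context = "on_task")
  expect_equal(res$direction, "excited")
  expect_lt(res$p, 0.05)
  # off-task paired test
  ot <- simulate_off_task(neurons, n_sweeps = 40, seed = 37)
  res2 <- laser_modulation_test(ot, context = "off_task")
  expect_equal(res2$direction, "excited")
})

test_that("two-proportion z-tests match their closed form", {
  r <- compare_proportions(10, 100, 10, 100)
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)
  # reported neuron-count comparison is significant
  r2 <- compare_proportions(117, 1698, 78, 1698)
  expect_lt(r2$p, 0.01)
  expect_gt(r2$z, 0)
  # direction agrees with the exact binomial comparison on small counts
  r3 <- compare_proportions(9, 10, 2, 10)
  expect_gt(r3$z, 0)
  expect_lt(r3$p, 0.05)
  expect_error(compare_proportions(11, 10, 2, 10), "exceed")
})

test_that("mixed-effects laser test recovers an additive shift", {
  set.seed(38)
  n_neur <- 60; n_tr <- 60
  delta <- 0.3
  df <- tidyr::expand_grid(neuron = seq_len(n_neur),
                           trial = seq_len(n_tr)) |>
    dplyr::mutate(
      evidence = runif(dplyr::n()),
      laser = rep(rbinom(n_tr, 1, 0.3), times = n_neur),
      activity = rnorm(n_neur)[neuron] + 0.5 * evidence +
        delta * laser + rnorm(dplyr::n(), 0, 0.5))
  res <- suppressWarnings(mixed_effects_laser_test(df, "evidence"))
  las <- res[res$term == "laser", ]
  expect_lt(abs(las$estimate - delta), 3 * las$se)
  expect_lt(las$p, 0.01)
  # single grouping unit reduces to ordinary regression
  df1 <- df[df$neuron == 1, ]
  res1 <- mixed_effects_laser_test(df1, "evidence")
  ref <- summary(lm(activity ~ evidence + laser, data = df1))$coefficients
  expect_equal(unname(res1$estimate), unname(ref[, 1]), tolerance = 1e-8)
})
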