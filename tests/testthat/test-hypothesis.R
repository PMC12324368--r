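test_that("evidence-neuron equations hold exactly", {
  tr <- hypothesis_trials(300, seed = 51)
  for (h in c("h1i", "h2", "h3")) {
    sim <- simulate_hypothesis(h, tr, seed = 52)
    # laser terms cancel in the sum: ei + ec = 2 * gamma identically
    expect_true(all(sim$ei + sim$ec == 20))
    off0 <- sim$e == 0 & !sim$laser
    if (any(off0)) expect_true(all(sim$ei[off0] == 10))
    # laser shifts ei by b at matched evidence
    p <- attr(sim, "params")
    for (e_val in unique(sim$e[abs(sim$e) <= 2])) {
      on <- sim$e == e_val & sim$laser
      off <- sim$e == e_val & !sim$laser
      if (any(on) && any(off)) {
        expect_equal(mean(sim$ei[on]) - mean(sim$ei[off]), p$b)
      }
    }
  }
  # h1ii uses attended evidence and the printed positive laser effect
  s2 <- simulate_hypothesis("h1ii", tr, seed = 53)
  expect_equal(attr(s2, "params")$b, 2)
  expect_true(all(s2$ei == 1 * s2$e_att + 2 * s2$laser + 10))
  expect_true(all(s2$n_attended <= s2$n_presented))
})

test_that("each input trial is repeated n_repeats times", {
  tr <- hypothesis_trials(50, seed = 54)
  sim <- simulate_hypothesis("h2", tr, seed = 55)
  expect_equal(nrow(sim), 200)
  expect_equal(as.integer(table(sim$base_trial)), rep(4L, 50))
  # repeats share the trial's evidence but have fresh randomness
  expect_true(all(tapply(sim$e, sim$base_trial, function(x) {
    length(unique(x)) == 1
  })))
})

test_that("without laser effect the action is symmetric at zero evidence", {
  tr <- hypothesis_trials(3000, seed = 56)
  for (h in c("h1i", "h2", "h3")) {
    p <- hypothesis_params(h, b = 0)
    sim <- simulate_hypothesis(h, tr, params = p, seed = 57)
    at0 <- sim$e == 0
    n0 <- sum(at0)
    expect_gt(n0, 100)
    expect_lt(abs(mean(sim$A[at0]) - 0.5), 3 * sqrt(0.25 / n0))
  }
})

test_that("b = 0 makes laser-on and laser-off choices indistinguishable", {
  tr <- hypothesis_trials(6000, seed = 58)
  p <- hypothesis_params("h2", b = 0)
  sim <- simulate_hypothesis("h2", tr, params = p, seed = 59)
  # KS test on per-evidence-level choice frequencies
  tab <- sim |>
    dplyr::group_by(.data$e, .data$laser) |>
    dplyr::summarise(p_ipsi = mean(.data$A), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::filter(.data$n >= 25)
  wide <- tidyr::pivot_wider(tab, id_cols = "e", names_from = "laser",
                             values_from = "p_ipsi") |>
    stats::na.omit()
  ks <- suppressWarnings(stats::ks.test(wide$`TRUE`, wide$`FALSE`))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulated tuning curves show the models' signatures", {
  tr <- hypothesis_trials(8000, seed = 60)
  s2 <- simulate_hypothesis("h2", tr, seed = 61)
  tc <- tuning_curves_from_sim(s2, by = "laser")
  # evidence neurons: exactly linear, slope +1 (ipsi), laser offset -2
  off <- tc[!tc$laser, ]
  on <- tc[tc$laser, ]
  expect_equal(off$ei, off$e + 10)
  shared <- intersect(on$e, off$e)
  expect_equal(on$ei[match(shared, on$e)] -
                 off$ei[match(shared, off$e)], rep(-2, length(shared)))
  # choice-neuron population mean is monotone in evidence on correct trials
  for (h in c("h1i", "h2", "h3")) {
    sim <- simulate_hypothesis(h, tr, seed = 62)
    cc <- tuning_curves_from_sim(sim, by = "correct")
    cor_t <- cc[cc$correct & cc$n > 200, ]
    # monotone rise (h2 saturates into plateaus, so a linear association
    # plus an end-to-end increase is the robust check)
    expect_gt(cor(cor_t$e, cor_t$ci_mean), 0.8)
    expect_gt(cor_t$ci_mean[which.max(cor_t$e)],
              cor_t$ci_mean[which.min(cor_t$e)])
  }
  # h1i incorrect-trial choice curves lose amplitude; h2 maintains it
  amp <- function(sim) {
    cc <- tuning_curves_from_sim(sim, by = "correct")
    cc <- cc[cc$n > 50 & abs(cc$e) <= 6, ]
    sapply(split(cc, cc$correct), function(d) diff(range(d$ci_mean)))
  }
  s1 <- simulate_hypothesis("h1i", tr, seed = 63)
  a1 <- amp(s1)
  a2 <- amp(s2)
  expect_lt(a1[["FALSE"]], 0.6 * a1[["TRUE"]])
  expect_gt(a2[["FALSE"]], 0.8 * a2[["TRUE"]])
})

test_that("the lapse-logistic psychometric fit recovers its parameters", {
  tr <- hypothesis_trials(8000, seed = 64)
  s2 <- simulate_hypothesis("h2", tr, seed = 65)
  fit <- psychometric_from_sim(s2, laser = FALSE)
  # total lapse recovers PA; slope recovers 2 * a * 0.75
  expect_lt(abs(fit$total_lapse - 0.1), 0.03)
  expect_lt(abs(fit$beta1 - 1.5), 0.15)
  # PA = 0 drives the fitted lapses to zero
  s0 <- simulate_hypothesis("h2", tr,
                            params = hypothesis_params("h2", PA = 0),
                            seed = 66)
  fit0 <- psychometric_from_sim(s0, laser = FALSE)
  expect_lt(fit0$total_lapse, 0.02)
  # laser shifts the on-trials curve toward ipsilateral (b = -2 raises
  # ei - ec ... with b = -2 the difference 2ae + 2bl falls, so the shift
  # is toward contralateral: P(ipsi) drops at matched evidence)
  fit_on <- psychometric_from_sim(s2, laser = TRUE)
  p_at <- function(f, e) {
    f$lambda_lo + (1 - f$lambda_lo - f$lambda_hi) *
      plogis(f$beta0 + f$beta1 * e)
  }
  expect_lt(p_at(fit_on, 0), p_at(fit, 0))
})

test_that("parameter recovery estimators are consistent near truth", {
  tr <- hypothesis_trials(4000, seed = 67)
  s2 <- simulate_hypothesis("h2", tr, seed = 68)
  r2 <- recover_parameters(s2, n_boot = 60, seed = 69)
  expect_lt(abs(r2$estimate[r2$parameter == "PA"] - 0.1),
            3 * r2$se[r2$parameter == "PA"])
  expect_lt(abs(r2$estimate[r2$parameter == "PL"] - 0.1),
            3 * r2$se[r2$parameter == "PL"])
  s3 <- simulate_hypothesis("h3", tr, seed = 70)
  r3 <- recover_parameters(s3, n_boot = 60, seed = 71)
  expect_lt(abs(r3$estimate - 0.5), 3 * r3$se)
  expect_warning(
    recover_parameters(simulate_hypothesis("h2", tr[1:100, ], seed = 72),
                       n_boot = 10),
    "wide")
})
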