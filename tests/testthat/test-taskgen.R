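test_that("cue generation follows the spatial Poisson statistics", {
  set.seed(1)
  # empty process on a zero-rate side
  cues <- generate_cues(0, 8)
  expect_length(cues$left, 0)
  # Monte-Carlo mean for 8 cues/m over 2 m without refractory thinning
  set.seed(2)
  counts <- replicate(20000, length(generate_cues(8, 0, refractory = 1e-9)$left))
  sem <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 16), 3 * sem + 1e-9)
  expect_error(generate_cues(-1, 2), "non-negative")
  expect_error(generate_cues(2, 2, region_length = 10, refractory = 12),
               "refractory")
})

test_that("the 12-cm refractory window holds on every draw", {
  set.seed(3)
  for (i in 1:500) {
    cues <- generate_cues(8, 2.3, refractory = 12)
    for (side in cues) {
      if (length(side) > 1) expect_gte(min(diff(side)), 12)
    }
    expect_true(!is.unsorted(cues$left) && !is.unsorted(cues$right))
    expect_true(all(unlist(cues) >= 0 & unlist(cues) < 200))
  }
})

test_that("debias probability is the clamped softmax with bounded range", {
  # symmetric errors give an unbiased draw
  expect_equal(debias_probability(0.3, 0.3), 0.5)
  # caps: sqrt(e) clamped to [0.15, 0.85] gives PR = logistic(0.7)
  expect_equal(debias_probability(1, 0), 1 / (1 + exp(-0.7)),
               tolerance = 1e-12)
  # any history stays within the cap-implied bounds
  set.seed(4)
  for (i in 1:200) {
    pr <- debias_probability(runif(1), runif(1))
    expect_gte(pr, 1 / (1 + exp(0.7)) - 1e-12)
    expect_lte(pr, 1 / (1 + exp(-0.7)) + 1e-12)
  }
})

test_that("rewarded-side draws follow the pseudo-random prescription", {
  set.seed(5)
  n <- 20000
  # empirical fraction above PR halves the right-draw probability
  draws <- replicate(n, draw_rewarded_side(0.5, 0.7))
  p_hat <- mean(draws == "right")
  expect_lt(abs(p_hat - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  draws <- replicate(n, draw_rewarded_side(0.5, 0.3))
  p_hat <- mean(draws == "right")
  expect_lt(abs(p_hat - 0.75), 3 * sqrt(0.75 * 0.25 / n))
})

test_that("agent steps draw Bernoulli choices and Markov transitions", {
  ag <- agent_params(weights = matrix(0, 1, 5),
                     transitions = matrix(1, 1, 1), initial = 1)
  set.seed(6)
  p <- replicate(4000, agent_step(ag, 1, c(5, 1, 1, 1, 1))$choice)
  expect_lt(abs(mean(p == "right") - 0.5), 3 * sqrt(0.25 / 4000))
  # degenerate transition row keeps the state
  ag2 <- agent_params(weights = matrix(0, 3, 5),
                      transitions = rbind(c(0, 1, 0), c(0, 1, 0),
                                          c(0, 1, 0)),
                      initial = c(1, 0, 0))
  expect_equal(agent_step(ag2, 1, rep(0, 5))$next_state, 2L)
  expect_error(agent_params(weights = matrix(Inf, 1, 5),
                            transitions = matrix(1, 1, 1), initial = 1),
               "finite")
})

test_that("engaged-agent accuracy rises with the evidence level", {
  set.seed(7)
  ag <- agent_params()
  dcues <- rep(c(1, 4, 8, 12), each = 600)
  correct <- vapply(dcues, function(d) {
    s <- agent_step(ag, 1, c(d, 0, 0, 0, 1))
    s$choice == "right"
  }, logical(1))
  acc <- tapply(correct, dcues, mean)
  expect_true(all(diff(acc) > -0.02)) # monotone up to Monte-Carlo noise
  expect_gt(acc[["12"]], acc[["1"]])
})

test_that("view-angle dynamics follow the saturating exponential rule", {
  # no displacement, no rotation
  expect_equal(view_angle_step(0.3, 0, dt = 0.1), 0.3)
  # at the clamp the angle cannot grow further
  expect_lte(view_angle_step(pi / 2, 2, dt = 0.1), pi / 2)
  # large displacement activates the clamp argument exactly
  th <- 0.2; om <- 3
  expected <- th + (pi / 2 - th) * 0.01
  expect_equal(view_angle_step(th, om, dt = 0.01), expected,
               tolerance = 1e-12)
  expect_error(view_angle_step(0, 1, dt = 0), "positive")
  # alternative constant grouping is exposed
  expect_lt(view_angle_step(0, 0.1, 0.01, grouping = "outside"),
            view_angle_step(0, 0.1, 0.01, grouping = "inside") + 1)
})

test_that("simulated sessions respect maze-type and laser structure", {
  tr <- simulate_session(task_config(), agent_params(), 400, seed = 11)
  expect_true(all(tr$correct == (tr$choice == tr$rewarded_side)))
  # laser only on main-maze trials; warm-up trials never lasered
  expect_true(all(!tr$laser[tr$maze_type != "main"]))
  # warm-up is a prefix
  w <- which(tr$maze_type == "warmup")
  expect_equal(w, seq_along(w))
  # final evidence equals the last cumulative-evidence bin
  expect_equal(vapply(tr$cum_evidence, function(x) x[66], numeric(1)),
               as.numeric(tr$final_evidence))
  # evidence fields consistent with the cue sets
  expect_equal(tr$final_evidence,
               lengths(tr$cues_right) - lengths(tr$cues_left))
})

test_that("sessions are bit-reproducible for a fixed seed", {
  a <- simulate_session(task_config(), agent_params(), 60, seed = 12)
  b <- simulate_session(task_config(), agent_params(), 60, seed = 12)
  expect_identical(a, b)
})

test_that("realized laser rate matches the configured fraction", {
  tr <- simulate_session(task_config(laser_fraction = 0.15),
                         agent_params(), 2500, seed = 13,
                         kinematics = FALSE)
  main <- tr$maze_type == "main"
  n <- sum(main)
  expect_lt(abs(mean(tr$laser[main]) - 0.15),
            3 * sqrt(0.15 * 0.85 / n))
})

test_that("debiasing pulls rewarded-side draws against a biased agent", {
  # an always-right chooser errs only on left-rewarded trials, so the
  # controller draws left-rewarded trials more often
  ag <- agent_params(weights = rbind(c(0, 0, 0, 0, 50)),
                     transitions = matrix(1, 1, 1), initial = 1)
  tr <- simulate_session(task_config(), ag, 400, seed = 14,
                         kinematics = FALSE)
  main <- tr[tr$maze_type == "main", ]
  expect_lt(mean(main$rewarded_side == "right"), 0.5)
})

test_that("with debiasing at equilibrium a symmetric agent sees balanced sides", {
  tr <- simulate_session(task_config(), agent_params(), 3000, seed = 15,
                         kinematics = FALSE)
  main <- tr[tr$maze_type == "main", ]
  p <- mean(main$rewarded_side == "right")
  # centred on 0.5 (the controller regulates around balance)
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / nrow(main)) + 0.02)
})

test_that("trial tables round-trip through CSV", {
  tr <- simulate_session(task_config(), agent_params(), 40, seed = 16)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials_csv(tr, path)
  back <- read_trials_csv(path)
  expect_equal(back$final_evidence, tr$final_evidence)
  expect_equal(back$choice, tr$choice)
  expect_equal(unlist(back$cues_left), unlist(tr$cues_left),
               tolerance = 1e-6)
})
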