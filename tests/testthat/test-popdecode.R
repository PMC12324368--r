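test_that("folds partition laser-off trials with matched evidence", {
  tr <- toy_trials(round(rnorm(100, 0, 4)))
  folds <- make_folds(tr, seed = 41)
  expect_equal(sort(as.integer(table(folds$outer))), rep(20L, 5))
  expect_setequal(folds$trial_idx, seq_len(100))
  # evidence distributions matched across folds
  ev <- tr$final_evidence
  fold_means <- tapply(ev, folds$outer, mean)
  expect_lt(max(abs(fold_means - mean(ev))), 0.5 * sd(ev))
  # inner folds partition each outer training set
  for (f in 1:5) {
    expect_length(folds$inner[[f]], sum(folds$outer != f))
    expect_setequal(unique(folds$inner[[f]]), 1:5)
  }
  expect_error(make_folds(toy_trials(1:10)), "laser-off")
})

test_that("projections equal explicit dot products on a toy case", {
  tr <- toy_trials(rep(c(2, -2), 30))
  tr$laser[1:6] <- TRUE
  folds <- make_folds(tr, min_trials = 40, seed = 42)
  n_pos <- 3
  axes <- list(axes = array(0, dim = c(n_pos, 5, 3)),
               positions = 10:12, folds = folds)
  w <- c(0.6, 0.8, 0)
  for (p in 1:n_pos) for (f in 1:5) axes$axes[p, f, ] <- w
  x <- array(rnorm(3 * 60 * 66), dim = c(3, 60, 66))
  tens <- structure(x, class = "rate_tensor")
  proj <- project_axes(tens, axes, tr, center = FALSE)
  for (p in 1:n_pos) {
    expect_equal(proj$values[, p],
                 drop(t(x[, , 10 + p - 1]) %*% w), tolerance = 1e-12)
  }
  # centring subtracts the laser-off positional mean
  projc <- project_axes(tens, axes, tr, center = TRUE)
  expect_lt(max(abs(colMeans(projc$values[!tr$laser, ]))), 1e-12)
  # neuron-axis mismatch is an error
  bad <- structure(array(0, dim = c(4, 60, 66)), class = "rate_tensor")
  expect_error(project_axes(bad, axes, tr), "neuron")
})

test_that("position smoothing of projections is causal", {
  vals <- matrix(0, 4, 30)
  vals[, 16:30] <- 1
  sm <- half_gaussian_smooth(vals, sd = 10, dt = 5)
  expect_true(all(abs(sm[, 1:15]) < 1e-12)) # zero up to FFT round-off
  expect_true(all(sm[, 16:30] > 0))
})

test_that("evidence axes find a planted signal with unit norm", {
  set.seed(43)
  n_tr <- 80; n_neur <- 12
  ev <- round(rnorm(n_tr, 0, 4))
  tr <- toy_trials(ev)
  tr$cum_evidence <- lapply(ev, function(e) {
    c(rep(0, 6), seq(0, e, length.out = 40), rep(e, 20))
  })
  x <- array(rnorm(n_neur * n_tr * 66), dim = c(n_neur, n_tr, 66))
  ev_mat <- do.call(rbind, tr$cum_evidence)
  x[1, , ] <- ev_mat + rnorm(length(ev_mat), 0, 0.05) # neuron 1 carries it
  tens <- structure(x, class = "rate_tensor")
  folds <- make_folds(tr, min_trials = 40, seed = 44)
  pos <- c(30, 40)
  ax <- fit_evidence_axes(tens, tr, folds, positions = pos)
  nrm <- apply(ax$axes, c(1, 2), function(w) sum(w^2))
  expect_lt(max(abs(nrm - 1)), 1e-10)
  # at least 95% of the axis mass on the planted neuron
  expect_true(all(ax$axes[, , 1]^2 >= 0.95))
  expect_true(all(ax$summary$r_heldout > 0.9))
})

test_that("larger penalties give sparser axes and match a proximal oracle", {
  set.seed(45)
  n <- 60; p <- 8
  X <- matrix(rnorm(n * p), n)
  y <- X[, 1] * 0.8 + rnorm(n, 0, 0.3)
  grid <- lambda_grid_default()
  lp <- optoshift:::lasso_path(X, y, grid)
  nz <- colSums(as.matrix(coef(lp$fit)[-1, , drop = FALSE]) != 0)
  lam_fit <- grid[lp$order] # decreasing
  # the grid-maximum penalty gives a sparser axis than the minimum
  expect_lte(nz[1], nz[length(nz)])
  expect_equal(unname(nz[length(nz)]), 8L) # unregularised endpoint is dense
  # glmnet solution minimises the lasso objective (proximal-gradient
  # oracle) at an exact grid value
  lam <- sort(grid)[11]
  obj <- function(b0, b) {
    sum((y - b0 - X %*% b)^2) / (2 * n) + lam * sum(abs(b))
  }
  cf <- as.numeric(coef(lp$fit, s = lam, exact = FALSE))
  # proximal gradient descent from zero
  b <- rep(0, p); b0 <- mean(y)
  step <- 1 / (2 * max(eigen(crossprod(X) / n)$values))
  for (it in 1:20000) {
    r <- y - b0 - X %*% b
    b <- b + step * drop(crossprod(X, r)) / n
    b <- sign(b) * pmax(abs(b) - step * lam, 0)
    b0 <- mean(y - X %*% b)
  }
  expect_lt(abs(obj(cf[1], cf[-1]) - obj(b0, b)), 1e-6)
})

test_that("PC1 matches the spectral oracle and aligns signs", {
  fx <- fixture_session()
  folds <- make_folds(fx$trials, seed = 46)
  pc1 <- fit_pc1(fx$tensor_z, fx$trials, folds)
  # oracle: top eigenvector of the covariance of the column-centred
  # trial-averaged matrix
  x <- unclass(fx$tensor_z)
  train <- folds$trial_idx[folds$outer != 1]
  M <- apply(x[, train, optoshift:::cue_region_bins()], c(1, 3), mean)
  M <- sweep(M, 2, colMeans(M))
  eig <- eigen(M %*% t(M))
  cosine <- abs(sum(pc1$axis_matrix[1, ] * eig$vectors[, 1]))
  expect_gte(cosine, 0.999)
  # fold axes pairwise positively correlated after alignment
  cors <- cor(t(pc1$axis_matrix))
  expect_true(all(cors > 0))
  # unit norm
  expect_lt(max(abs(rowSums(pc1$axis_matrix^2) - 1)), 1e-10)
  # rank-1 data: the planted direction is recovered exactly up to sign
  w_true <- rnorm(8); w_true <- w_true / sqrt(sum(w_true^2))
  prof <- seq(1, -1, length.out = 40)
  x1 <- array(0, dim = c(8, 50, 66))
  for (tr_i in 1:50) {
    x1[, tr_i, optoshift:::cue_region_bins()] <- outer(w_true, prof)
  }
  t1 <- structure(x1, class = "rate_tensor")
  tt <- toy_trials(round(rnorm(50, 0, 3)))
  f1 <- make_folds(tt, min_trials = 40, seed = 47)
  p1 <- fit_pc1(t1, tt, f1)
  expect_gte(abs(sum(p1$axis_matrix[1, ] * w_true)), 1 - 1e-6)
})

test_that("no trial is projected onto an axis trained on it", {
  # audit: held-out discipline of project_axes for laser-off trials
  tr <- toy_trials(rep(c(3, -3, 2, -2), 15))
  folds <- make_folds(tr, min_trials = 40, seed = 48)
  n_neur <- 5
  axes <- list(axes = array(0, dim = c(1, 5, n_neur)),
               positions = 20, folds = folds)
  for (f in 1:5) axes$axes[1, f, ] <- as.numeric(seq_len(n_neur) == f)
  x <- array(0, dim = c(n_neur, 60, 66))
  for (f in 1:5) {
    held <- folds$trial_idx[folds$outer == f]
    x[f, held, 20] <- 1 # marker visible only through fold f's axis
  }
  tens <- structure(x, class = "rate_tensor")
  proj <- project_axes(tens, axes, tr, center = FALSE)
  # every laser-off trial must see exactly its held-out fold's marker
  expect_true(all(proj$values[, 1] == 1))
})

test_that("session-level shift-bias correlation behaves", {
  set.seed(49)
  n <- 12
  shift <- rnorm(n)
  sess <- tibble::tibble(neural_shift = shift,
                         behavior_bias = 10 * shift + rnorm(n, 0, 0.5))
  r <- shift_vs_bias(sess)
  expect_gt(r$r, 0.9)
  expect_lt(r$p, 0.01)
  # constant bias: flagged undefined
  sess2 <- tibble::tibble(neural_shift = shift, behavior_bias = 1)
  expect_true(is.na(shift_vs_bias(sess2)$r))
  expect_error(shift_vs_bias(sess[1:2, ]), "3 sessions")
})
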