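#' Evidence-stratified cross-validation folds
#'
#' Laser-off trials are pseudo-randomly distributed over `k` disjoint
#' folds such that each fold samples a similar distribution of evidence
#' values: trials are sorted by final evidence and dealt round-robin with
#' within-block shuffling. Inner folds are built identically from each
#' outer training set (for nested cross-validation).
#'
#' @param trials A trial table.
#' @param k Number of folds (default 5).
#' @param min_trials Minimum number of laser-off trials (default 50).
#' @param seed Optional integer seed.
#' @return A list of class `fold_assignment`: `trial_idx` (row indices of
#'   the laser-off trials in `trials`), `outer` (fold id per laser-off
#'   trial), and `inner` (per outer fold, inner fold ids over its training
#'   trials).
#' @export
make_folds <- function(trials, k = 5, min_trials = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  off_idx <- which(!trials$laser)
  if (length(off_idx) < min_trials) {
    stop("need at least ", min_trials, " laser-off trials", call. = FALSE)
  }
  deal <- function(values) {
    n <- length(values)
    ord <- order(values, runif(n)) # random tie-break within evidence level
    fold <- integer(n)
    pos <- 0L
    while (pos < n) {
      block <- ord[(pos + 1L):min(pos + k, n)]
      fold[block] <- sample(seq_len(k))[seq_along(block)]
      pos <- pos + k
    }
    fold
  }
  ev <- trials$final_evidence[off_idx]
  outer <- deal(ev)
  inner <- lapply(seq_len(k), function(f) {
    train <- which(outer != f)
    setNames(deal(ev[train]), train)
  })
  structure(list(trial_idx = off_idx, outer = outer, inner = inner, k = k),
            class = "fold_assignment")
}

#' Default lasso regularisation grid
#'
#' Fifteen penalty values: 0 (ordinary least squares) plus fourteen
#' logarithmically spaced points between 1e-4 and 1.
#'
#' @return Numeric vector of length 15, increasing.
#' @export
lambda_grid_default <- function() {
  c(0, exp(seq(log(1e-4), log(1), length.out = 14)))
}

lasso_path <- function(X, y, lambdas) {
  # glmnet wants a decreasing lambda sequence
  ord <- order(lambdas, decreasing = TRUE)
  fit <- glmnet::glmnet(X, y, alpha = 1, lambda = lambdas[ord],
                        standardize = FALSE, intercept = TRUE,
                        thresh = 1e-8)
  list(fit = fit, order = ord)
}

#' Fit per-position evidence-decoding axes with nested cross-validation
#'
#' For each maze position and each outer fold, a lasso (L1) linear
#' regression maps z-scored population activity onto the cumulative
#' evidence at that position (normalised to \[-1, 1\] by the session
#' maximum absolute evidence). The penalty is chosen per (position, fold)
#' by an inner 5-fold cross-validation over the 15-value grid, scoring by
#' Pearson correlation between actual and predicted evidence on the inner
#' test folds (tie-break: the largest penalty within 1e-6 of the best
#' mean correlation). The final model is refit on the full outer training
#' set and its weight vector is normalised to unit Euclidean norm.
#'
#' @param tensor A z-scored `rate_tensor` (neurons x trials x 66).
#' @param trials The matching trial table.
#' @param folds A `fold_assignment` from [make_folds()].
#' @param lambda_grid Penalty grid (default [lambda_grid_default()]).
#' @param positions Position-bin indices to decode (default the 60 cue +
#'   delay bins).
#' @return A list of class `evidence_axes`: `axes` (positions x folds x
#'   neurons array of unit vectors; NA where every penalty produced an
#'   all-zero vector), `intercepts`, and a per-(position, fold) summary
#'   tibble with the chosen `lambda` and held-out Pearson `r`.
#' @export
fit_evidence_axes <- function(tensor, trials, folds,
                              lambda_grid = lambda_grid_default(),
                              positions = cue_delay_bins()) {
  stopifnot(inherits(folds, "fold_assignment"))
  x <- unclass(tensor)
  n_neur <- dim(x)[1]
  off_idx <- folds$trial_idx
  ev_mat <- do.call(rbind, trials$cum_evidence)[off_idx, , drop = FALSE]
  ev_scale <- max(abs(ev_mat))
  if (ev_scale == 0) stop("no evidence variation", call. = FALSE)
  ev_mat <- ev_mat / ev_scale
  k <- folds$k
  axes <- array(NA_real_, dim = c(length(positions), k, n_neur))
  intercepts <- matrix(NA_real_, length(positions), k)
  summary_rows <- vector("list", length(positions) * k)
  ri <- 0L
  for (pi in seq_along(positions)) {
    p <- positions[pi]
    Xp <- t(x[, off_idx, p]) # trials x neurons
    yp <- ev_mat[, p]
    ok_all <- stats::complete.cases(Xp)
    for (f in seq_len(k)) {
      train <- which(folds$outer != f)
      test <- which(folds$outer == f)
      inner_id <- folds$inner[[f]]
      # inner CV over the lambda grid
      r_sum <- matrix(NA_real_, 5, length(lambda_grid))
      for (g in seq_len(5)) {
        tr_in <- train[inner_id != g]
        te_in <- train[inner_id == g]
        tr_in <- tr_in[ok_all[tr_in]]; te_in <- te_in[ok_all[te_in]]
        if (length(tr_in) < 5 || length(te_in) < 3) next
        lp <- lasso_path(Xp[tr_in, , drop = FALSE], yp[tr_in], lambda_grid)
        pred <- predict(lp$fit, Xp[te_in, , drop = FALSE])
        r_sum[g, lp$order] <- suppressWarnings(
          apply(pred, 2, function(pr) {
            if (sd(pr) == 0 || sd(yp[te_in]) == 0) NA_real_
            else cor(pr, yp[te_in])
          }))
      }
      mean_r <- colMeans(r_sum, na.rm = TRUE)
      mean_r[is.nan(mean_r)] <- -Inf
      best_r <- max(mean_r)
      lam <- if (is.finite(best_r)) {
        max(lambda_grid[mean_r >= best_r - 1e-6])
      } else lambda_grid[length(lambda_grid)]
      # final fit on the full outer training set
      tr <- train[ok_all[train]]; te <- test[ok_all[test]]
      lp <- lasso_path(Xp[tr, , drop = FALSE], yp[tr], lambda_grid)
      w <- as.numeric(coef(lp$fit, s = lam, exact = FALSE))[-1]
      b0 <- as.numeric(coef(lp$fit, s = lam, exact = FALSE))[1]
      nrm <- sqrt(sum(w^2))
      r_test <- if (length(te) >= 3) {
        pred <- drop(Xp[te, , drop = FALSE] %*% w) + b0
        if (sd(pred) == 0) NA_real_ else cor(pred, yp[te])
      } else NA_real_
      if (nrm > 0) {
        axes[pi, f, ] <- w / nrm
        intercepts[pi, f] <- b0
      }
      ri <- ri + 1L
      summary_rows[[ri]] <- tibble(
        position = p, fold = f, lambda = lam, r_heldout = r_test,
        n_nonzero = sum(w != 0), flagged = nrm == 0)
    }
  }
  structure(list(axes = axes, intercepts = intercepts,
                 positions = positions, folds = folds,
                 ev_scale = ev_scale,
                 summary = dplyr::bind_rows(summary_rows)),
            class = "evidence_axes")
}

#' Project population activity onto decoding axes
#'
#' Laser-off trials are projected only onto the axis of the outer fold
#' that held them out (strict cross-validation); laser-on trials, which
#' never contribute to training, are projected onto all five fold axes and
#' averaged. The per-position mean over laser-off trials is subtracted,
#' and the trajectories may be smoothed with a causal half-Gaussian filter
#' (SD 10 cm).
#'
#' @param tensor The z-scored `rate_tensor` used for fitting.
#' @param axes An `evidence_axes` (or `pc1_axes`) object.
#' @param trials The matching trial table.
#' @param smooth Apply causal smoothing along position (default FALSE).
#' @param smooth_sd Smoothing SD in cm (default 10).
#' @param center Subtract the laser-off positional mean (default TRUE).
#' @return A list of class `projection_set`: `values` (trials x positions
#'   matrix), `positions`, `off_mean`, provenance flags, and the trial
#'   table rows.
#' @export
project_axes <- function(tensor, axes, trials, smooth = FALSE,
                         smooth_sd = 10, center = TRUE) {
  x <- unclass(tensor)
  n_neur <- dim(x)[1]
  folds <- axes$folds
  if (dim(axes$axes)[3] != n_neur) {
    stop("axes and tensor disagree on the neuron axis", call. = FALSE)
  }
  n_trials <- dim(x)[2]
  n_pos <- length(axes$positions)
  vals <- matrix(NA_real_, n_trials, n_pos)
  fold_of <- rep(NA_integer_, n_trials)
  fold_of[folds$trial_idx] <- folds$outer
  for (pi in seq_len(n_pos)) {
    p <- axes$positions[pi]
    W <- axes$axes[pi, , ] # folds x neurons
    act <- t(x[, , p]) # trials x neurons
    for (f in seq_len(folds$k)) {
      held <- which(fold_of == f)
      if (length(held) && !all(is.na(W[f, ]))) {
        vals[held, pi] <- act[held, , drop = FALSE] %*% W[f, ]
      }
    }
    on_tr <- which(is.na(fold_of)) # laser-on (and any unassigned) trials
    if (length(on_tr)) {
      Wok <- W[!apply(is.na(W), 1, any), , drop = FALSE]
      if (nrow(Wok)) {
        vals[on_tr, pi] <- rowMeans(act[on_tr, , drop = FALSE] %*% t(Wok))
      }
    }
  }
  off_mean <- colMeans(vals[!trials$laser, , drop = FALSE], na.rm = TRUE)
  if (center) vals <- sweep(vals, 2, off_mean)
  if (smooth) {
    vals <- half_gaussian_smooth(vals, sd = smooth_sd,
                                 dt = POSITION_BIN_WIDTH)
  }
  structure(list(values = vals, positions = axes$positions,
                 off_mean = off_mean, smoothed = smooth,
                 centered = center, trials = trials),
            class = "projection_set")
}

#' Held-out decoding performance versus a label-shuffled baseline
#'
#' Per-position Pearson correlation between cross-validated projections
#' and the true (normalised) cumulative evidence on held-out laser-off
#' trials, compared with the mean correlation over label-shuffled refits
#' (the trial-to-evidence pairing is permuted and the whole nested
#' cross-validation pipeline is rerun).
#'
#' @param tensor A z-scored `rate_tensor`.
#' @param trials The matching trial table.
#' @param folds A `fold_assignment`.
#' @param lambda_grid Penalty grid.
#' @param positions Position bins to decode.
#' @param n_label_shuffles Number of shuffled refits (default 10).
#' @param seed Optional integer seed.
#' @return A tibble with `position`, `r_data`, `r_shuffled` (mean over
#'   shuffles; NA where undefined).
#' @export
decoding_performance <- function(tensor, trials, folds,
                                 lambda_grid = lambda_grid_default(),
                                 positions = cue_delay_bins(),
                                 n_label_shuffles = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  perf <- function(tr) {
    ax <- fit_evidence_axes(tensor, tr, folds, lambda_grid, positions)
    ax$summary |>
      dplyr::group_by(.data$position) |>
      dplyr::summarise(r = mean(.data$r_heldout, na.rm = TRUE),
                       .groups = "drop")
  }
  real <- perf(trials) |> dplyr::rename(r_data = "r")
  off_idx <- folds$trial_idx
  shuf <- purrr::map_dfr(seq_len(n_label_shuffles), function(s) {
    tr2 <- trials
    perm <- sample(off_idx)
    tr2$cum_evidence[off_idx] <- trials$cum_evidence[perm]
    tr2$final_evidence[off_idx] <- trials$final_evidence[perm]
    perf(tr2) |> dplyr::mutate(shuffle = s)
  }) |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(r_shuffled = mean(.data$r, na.rm = TRUE),
                     .groups = "drop")
  dplyr::left_join(real, shuf, by = "position")
}

#' Fit cross-validated first principal component axes
#'
#' For each outer training fold, the trial-averaged z-scored firing rates
#' across the 40 cue-region bins (laser-off training trials only) form a
#' neurons x positions matrix; after column centring, the first principal
#' axis over the neuron dimension is extracted and unit-normalised. Fold
#' axes are sign-aligned within the session to the first fold (flipped if
#' negatively correlated); the across-session convention flips all axes if
#' the trial-averaged PC1 projection increases from the beginning to the
#' end of the cue region.
#'
#' @param tensor A z-scored `rate_tensor`.
#' @param trials The matching trial table.
#' @param folds A `fold_assignment`.
#' @return A list of class `pc1_axes` compatible with [project_axes()]:
#'   `axes` (positions x folds x neurons; the same axis replicated across
#'   the cue-region positions), `axis_matrix` (folds x neurons), and the
#'   fold assignment.
#' @export
fit_pc1 <- function(tensor, trials, folds) {
  x <- unclass(tensor)
  cue_bins <- cue_region_bins()
  if (length(cue_bins) < 2) stop("need at least 2 positions", call. = FALSE)
  n_neur <- dim(x)[1]
  k <- folds$k
  W <- matrix(NA_real_, k, n_neur)
  for (f in seq_len(k)) {
    train_trials <- folds$trial_idx[folds$outer != f]
    M <- apply(x[, train_trials, cue_bins, drop = FALSE], c(1, 3), mean,
               na.rm = TRUE) # neurons x 40
    M <- sweep(M, 2, colMeans(M)) # centre each position column
    sv <- svd(M, nu = 1, nv = 0)
    w <- sv$u[, 1]
    W[f, ] <- w / sqrt(sum(w^2))
  }
  # within-session alignment to fold 1
  for (f in seq_len(k)[-1]) {
    if (cor(W[f, ], W[1, ]) < 0) W[f, ] <- -W[f, ]
  }
  # across-session convention: trial-averaged projection must not increase
  avg_act <- apply(x[, folds$trial_idx, cue_bins, drop = FALSE], c(1, 3),
                   mean, na.rm = TRUE)
  proj_prof <- drop(crossprod(avg_act, colMeans(W))) # per cue position
  n_edge <- max(1L, length(cue_bins) %/% 5L)
  if (mean(utils::tail(proj_prof, n_edge)) >
      mean(utils::head(proj_prof, n_edge))) {
    W <- -W
  }
  axes <- array(NA_real_, dim = c(length(cue_bins), k, n_neur))
  for (pi in seq_along(cue_bins)) axes[pi, , ] <- W
  structure(list(axes = axes, axis_matrix = W, positions = cue_bins,
                 folds = folds),
            class = c("pc1_axes"))
}

#' Decode maze position from PC1-projected activity
#'
#' Pools laser-off (trial, cue-region position) observations and fits a
#' 5-fold cross-validated linear regression of position on the PC1
#' projection; performance is the Pearson correlation between actual and
#' predicted positions, compared with the mean over position-shuffled
#' refits.
#'
#' @param projections A `projection_set` from [project_axes()] on PC1
#'   axes.
#' @param folds The `fold_assignment` used for fitting.
#' @param n_shuffles Number of position-shuffled refits (default 10).
#' @param seed Optional integer seed.
#' @return A tibble with one row: `r_data` and `r_shuffled`.
#' @export
pc1_position_decoding <- function(projections, folds, n_shuffles = 10,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  off_idx <- folds$trial_idx
  vals <- projections$values
  if (isTRUE(projections$centered)) {
    # position decoding needs the positional mean back
    vals <- sweep(vals, 2, projections$off_mean, "+")
  }
  vals <- vals[off_idx, , drop = FALSE]
  pos <- position_bins()$centre[projections$positions]
  long_x <- as.vector(vals)
  long_y <- rep(pos, each = length(off_idx))
  long_trial <- rep(seq_along(off_idx), times = length(pos))
  ok <- is.finite(long_x)
  cvr <- function(yv) {
    fold_of <- folds$outer[long_trial]
    preds <- rep(NA_real_, length(long_x))
    for (f in seq_len(folds$k)) {
      tr <- ok & fold_of != f
      te <- ok & fold_of == f
      if (sum(tr) < 3 || sum(te) < 3) next
      b <- stats::coef(stats::lm.fit(cbind(1, long_x[tr]), yv[tr]))
      preds[te] <- b[1] + b[2] * long_x[te]
    }
    sel <- is.finite(preds)
    if (sum(sel) < 3 || sd(preds[sel]) == 0) return(NA_real_)
    cor(preds[sel], yv[sel])
  }
  r_data <- cvr(long_y)
  r_shuf <- mean(vapply(seq_len(n_shuffles), function(s) {
    cvr(sample(long_y))
  }, numeric(1)), na.rm = TRUE)
  tibble(r_data = r_data, r_shuffled = r_shuf)
}

#' Session-level laser shift of the evidence projection
#'
#' The neural shift is the mean unsmoothed evidence-axis projection on
#' laser-on minus laser-off trials, averaged over the second half of the
#' cue region (100-200 cm).
#'
#' @param projections A `projection_set` (uncentred or centred; the
#'   difference is unaffected by centring).
#' @return Neural shift in projection units.
#' @export
projection_laser_shift <- function(projections) {
  pb <- position_bins()
  sel <- pb$lo[projections$positions] >= 100 &
    pb$lo[projections$positions] < 200
  on_mean <- mean(projections$values[projections$trials$laser, sel],
                  na.rm = TRUE)
  off_mean <- mean(projections$values[!projections$trials$laser, sel],
                   na.rm = TRUE)
  on_mean - off_mean
}

#' Correlate per-session neural shifts with behavioural laser bias
#'
#' Pearson correlation, across sessions, between the laser-induced shift
#' of the evidence-axis projection (see [projection_laser_shift()]) and
#' the behavioural ipsilateral laser bias (see [laser_bias()]).
#'
#' @param sessions A tibble with columns `neural_shift` and
#'   `behavior_bias`, one row per session (at least 3).
#' @return A tibble with `r`, `p`, `n`; degenerate inputs (constant
#'   columns) are flagged with NA.
#' @export
shift_vs_bias <- function(sessions) {
  stopifnot(all(c("neural_shift", "behavior_bias") %in% names(sessions)))
  if (nrow(sessions) < 3) stop("need at least 3 sessions", call. = FALSE)
  if (sd(sessions$neural_shift) == 0 || sd(sessions$behavior_bias) == 0) {
    return(tibble(r = NA_real_, p = NA_real_, n = nrow(sessions)))
  }
  ct <- cor.test(sessions$neural_shift, sessions$behavior_bias)
  tibble(r = unname(ct$estimate), p = ct$p.value, n = nrow(sessions))
}
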