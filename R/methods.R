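#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted GLM-HMM
#'
#' @param x A `glmhmm` object.
#' @param ... Unused.
#' @return A tibble with one row per state x covariate: `state`, `term`,
#'   `estimate`.
#' @export
tidy.glmhmm <- function(x, ...) {
  tibble(
    state = rep(seq_len(x$K), times = ncol(x$weights)),
    term = rep(colnames(x$weights), each = x$K),
    estimate = as.vector(x$weights)
  ) |>
    dplyr::arrange(.data$state, match(.data$term, colnames(x$weights)))
}

#' One-row summary of a fitted GLM-HMM
#'
#' @param x A `glmhmm` object.
#' @param ... Unused.
#' @return A tibble with `K`, `loglik`, `n_em_iterations`, `converged`,
#'   and the mean self-transition probability.
#' @export
glance.glmhmm <- function(x, ...) {
  tibble(K = x$K, loglik = x$loglik,
         n_em_iterations = length(x$ll_trace),
         converged = x$converged,
         mean_self_transition = mean(diag(x$transitions)))
}

#' @export
print.glmhmm <- function(x, ...) {
  cat("Bernoulli GLM-HMM:", x$K, "state(s), log-likelihood",
      format(x$loglik, digits = 8), "\n")
  cat("State weights:\n")
  print(round(x$weights, 3))
  cat("Transition matrix:\n")
  print(round(x$transitions, 3))
  invisible(x)
}

#' Tidy tuning-classification labels
#'
#' @param x A `tuning_labels` tibble.
#' @param ... Unused.
#' @return Per-class counts: `tuning_class`, `side_pref`, `n`, `fraction`.
#' @export
tidy.tuning_labels <- function(x, ...) {
  x |>
    dplyr::count(.data$tuning_class, .data$side_pref, name = "n") |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))
}

#' Tidy a hypothesis-model recovery table
#'
#' @param x Output of [recover_parameters()] is already tidy; this method
#'   standardises column naming for composition with broom-style tools.
#' @param ... Unused.
#' @export
tidy.lapse_fit <- function(x, ...) {
  tidyr::pivot_longer(
    as_tibble(x)[, c("lambda_lo", "lambda_hi", "beta0", "beta1")],
    dplyr::everything(), names_to = "term", values_to = "estimate")
}

#' @export
print.trial_table <- function(x, ...) {
  if (all(c("maze_type", "laser") %in% names(x))) {
    cat("Trial table:", nrow(x), "trials |",
        sum(x$maze_type == "main"), "main,",
        sum(x$maze_type == "warmup"), "warm-up,",
        sum(x$maze_type == "easy"), "easy |",
        sum(x$laser), "laser-on\n")
  }
  NextMethod()
}

#' @export
print.rate_tensor <- function(x, ...) {
  d <- dim(x)
  cat("Rate tensor:", d[1], "neurons x", d[2], "trials x", d[3],
      "position bins [", attr(x, "units"), "]\n")
  invisible(x)
}

#' @export
print.evidence_axes <- function(x, ...) {
  cat("Evidence-decoding axes:", length(x$positions), "positions x",
      dim(x$axes)[2], "folds x", dim(x$axes)[3], "neurons\n")
  cat("Median held-out r:",
      round(stats::median(x$summary$r_heldout, na.rm = TRUE), 3), "\n")
  invisible(x)
}
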