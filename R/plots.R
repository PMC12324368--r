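#' Plot a psychometric curve
#'
#' Percent ipsilateral choices per evidence bin, with laser-on and
#' laser-off curves overlaid when present.
#'
#' @param x A `psychometric_curve` from [psychometric()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psychometric_curve <- function(x, ...) {
  df <- dplyr::filter(x, !is.na(.data$pct_ipsi))
  has_laser <- !all(is.na(df$laser))
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$evidence_bin, y = .data$pct_ipsi,
    group = if (has_laser) .data$laser else 1)) +
    ggplot2::geom_hline(yintercept = 50, linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Evidence bin (contra -> ipsi)",
                  y = "% ipsilateral choices") +
    ggplot2::theme_classic()
  if (has_laser) {
    p <- p + ggplot2::aes(colour = .data$laser) +
      ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                              `TRUE` = "orange"),
                                   name = "laser")
  }
  p
}

#' @rdname autoplot.psychometric_curve
#' @param object A `psychometric_curve`.
#' @export
plot_psychometric <- function(object, ...) autoplot.psychometric_curve(object, ...)

#' Plot per-state GLM-HMM weights
#'
#' @param x A fitted `glmhmm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.glmhmm <- function(x, ...) {
  tidy(x) |>
    dplyr::mutate(term = factor(.data$term, levels = colnames(x$weights)),
                  state = factor(.data$state)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$term, y = .data$estimate,
                                 colour = .data$state,
                                 group = .data$state)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "GLM weight") +
    ggplot2::theme_classic()
}

#' Plot evidence tuning curves
#'
#' @param curve Output of [tuning_curve()].
#' @return A ggplot object.
#' @export
plot_tuning_curve <- function(curve) {
  aes_args <- ggplot2::aes(x = .data$evidence_bin, y = .data$mean, group = 1)
  p <- ggplot2::ggplot(curve, aes_args)
  if ("laser" %in% names(curve)) {
    p <- ggplot2::ggplot(curve, ggplot2::aes(
      x = .data$evidence_bin, y = .data$mean,
      colour = .data$laser, group = .data$laser))
  } else if ("correct" %in% names(curve)) {
    p <- ggplot2::ggplot(curve, ggplot2::aes(
      x = .data$evidence_bin, y = .data$mean,
      colour = .data$correct, group = .data$correct))
  }
  p +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem)) +
    ggplot2::labs(x = "Evidence bin (contra -> ipsi)",
                  y = "Normalised activity (z)") +
    ggplot2::theme_classic()
}

#' Plot trial-averaged evidence-axis trajectories by evidence bin
#'
#' @param projections A `projection_set` from [project_axes()].
#' @param by_laser Overlay laser-on vs laser-off means (default FALSE:
#'   split by final-evidence bin on laser-off trials).
#' @return A ggplot object.
#' @export
plot_projection <- function(projections, by_laser = FALSE) {
  pos_cm <- position_bins()$centre[projections$positions]
  trials <- projections$trials
  if (by_laser) {
    df <- purrr::map_dfr(c(FALSE, TRUE), function(on) {
      sel <- trials$laser == on
      tibble(position = pos_cm,
             mean = colMeans(projections$values[sel, , drop = FALSE],
                             na.rm = TRUE),
             laser = on)
    })
    return(ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$mean,
                                            colour = .data$laser)) +
             ggplot2::geom_line() +
             ggplot2::labs(x = "Position (cm)",
                           y = "Evidence-axis projection (a.u.)") +
             ggplot2::theme_classic())
  }
  bins <- bin_evidence(trials)
  df <- purrr::map_dfr(setdiff(levels(bins), "excluded"), function(bl) {
    sel <- bins == bl & !trials$laser
    if (!any(sel)) return(NULL)
    tibble(position = pos_cm,
           mean = colMeans(projections$values[sel, , drop = FALSE],
                           na.rm = TRUE),
           evidence_bin = bl)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$mean,
                                   colour = .data$evidence_bin)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Position (cm)",
                  y = "Evidence-axis projection (a.u.)",
                  colour = "final evidence") +
    ggplot2::theme_classic()
}

#' Plot cross-validated model comparison in bits per session
#'
#' @param cv Output of [cv_bits_per_session()].
#' @return A ggplot object.
#' @export
plot_cv_bits <- function(cv) {
  summ <- attr(cv, "summary")
  ggplot2::ggplot(summ, ggplot2::aes(.data$K, .data$mean_bits)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_bits - .data$sem_bits,
      ymax = .data$mean_bits + .data$sem_bits)) +
    ggplot2::labs(x = "Number of states",
                  y = "Test log-likelihood (bits/session)") +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
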