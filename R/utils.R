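#' @importFrom stats rpois rbinom runif rnorm quantile sd cor coef predict
#' @importFrom stats glm.fit binomial optim pnorm wilcox.test cor.test
#' @importFrom stats prcomp approx rlnorm na.omit setNames wilcox.test
#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# Maze geometry: start -30-0 cm, cue 0-200 cm, delay 200-300 cm, 5-cm bins.
POSITION_BIN_WIDTH <- 5
POSITION_EDGES <- seq(-30, 300, by = 5)
N_POSITION_BINS <- 66L

#' Position-bin metadata for the 66-bin maze discretisation
#'
#' The maze stem spans -30 to 300 cm and is discretised into 66 half-open
#' 5-cm bins `[lo, lo + 5)`. Bins 1-6 cover the start region (-30-0 cm),
#' bins 7-46 the cue region (0-200 cm) and bins 47-66 the delay region
#' (200-300 cm).
#'
#' @return A tibble with one row per position bin: `bin`, `lo`, `hi`,
#'   `centre` (cm) and `region` (start/cue/delay).
#' @export
position_bins <- function() {
  lo <- POSITION_EDGES[-length(POSITION_EDGES)]
  tibble(
    bin = seq_along(lo),
    lo = lo,
    hi = lo + POSITION_BIN_WIDTH,
    centre = lo + POSITION_BIN_WIDTH / 2,
    region = dplyr::case_when(lo < 0 ~ "start", lo < 200 ~ "cue", TRUE ~ "delay")
  )
}

cue_region_bins <- function() which(position_bins()$region == "cue")
cue_delay_bins <- function() which(position_bins()$region %in% c("cue", "delay"))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

logistic <- function(x) 1 / (1 + exp(-x))

#' Causal half-Gaussian smoothing
#'
#' Convolves a signal with a truncated, renormalised half-Gaussian kernel
#' supported on the past only, so the output at sample `t` depends only on
#' samples at or before `t`. Near the start of the signal the kernel is
#' renormalised over the available samples, so a constant input maps to the
#' same constant everywhere.
#'
#' @param x Numeric vector, or a matrix smoothed along rows (columns = time).
#' @param sd Kernel standard deviation in the same units as `dt`.
#' @param dt Sample spacing.
#' @param truncate Kernel support in standard deviations (default 4).
#' @return Smoothed object of the same shape as `x`.
#' @export
half_gaussian_smooth <- function(x, sd, dt, truncate = 4) {
  L <- max(1L, ceiling(truncate * sd / dt))
  k <- exp(-((0:L) * dt)^2 / (2 * sd^2))
  k <- k / sum(k)
  cum_k <- cumsum(k)
  smooth_cols <- function(m) {
    # causal convolution per column (FFT with zero padding), then
    # renormalise the early edge over the available kernel mass
    n <- nrow(m)
    if (n == 0L) return(m)
    N <- stats::nextn(n + L + 1L, 2)
    kf <- stats::fft(c(k, rep(0, N - length(k))))
    mf <- stats::mvfft(rbind(m, matrix(0, N - n, ncol(m))))
    y <- Re(stats::mvfft(mf * kf, inverse = TRUE)) / N
    y <- y[seq_len(n), , drop = FALSE]
    edge <- seq_len(min(L, n))
    y[edge, ] <- y[edge, , drop = FALSE] / cum_k[edge]
    y
  }
  if (is.matrix(x)) {
    t(smooth_cols(t(x)))
  } else {
    drop(smooth_cols(matrix(x, ncol = 1)))
  }
}

#' Half-Gaussian recency weights
#'
#' Weights `g(i) = exp(-i^2 / (2 sigma^2))` for lags `i = 0, 1, ...`
#' (most recent first), normalised to sum to one.
#'
#' @param n Number of weights (history length).
#' @param sigma Standard deviation in trials.
#' @return Numeric vector of length `n` summing to 1.
#' @export
half_gaussian_weights <- function(n, sigma) {
  if (n == 0L) return(numeric(0))
  w <- exp(-((seq_len(n) - 1)^2) / (2 * sigma^2))
  w / sum(w)
}

# Cumulative signed evidence (#ipsi - #contra) at each of the 66 bins.
# A cue at position x contributes to every bin whose upper edge exceeds x.
cumulative_evidence <- function(cues_ipsi, cues_contra) {
  hi <- POSITION_EDGES[-1]
  vapply(hi, function(h) sum(cues_ipsi < h) - sum(cues_contra < h), numeric(1))
}
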