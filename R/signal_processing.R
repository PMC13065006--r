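#' Time series container
#'
#' Light wrapper pairing sampled values with their sampling rate. `values`
#' may be a numeric vector (scalar series) or an n-by-3 matrix (3D series).
#' Gaps are not representable: upstream code must supply complete series.
#'
#' @param values numeric vector or n-by-3 numeric matrix.
#' @param rate sampling rate in Hz (> 0).
#' @return object of class `ts_series`.
#' @export
ts_series <- function(values, rate) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a single positive number (Hz)")
  if (is.matrix(values)) {
    if (ncol(values) != 3L) stop("matrix series must have 3 columns (x, y, z)")
  } else {
    values <- as.numeric(values)
  }
  if (anyNA(values)) stop("series contains missing samples; resolve gaps upstream")
  structure(list(values = values, rate = rate), class = "ts_series")
}

n_samples <- function(series) {
  if (is.matrix(series$values)) nrow(series$values) else length(series$values)
}

as_ts_series <- function(x, rate) {
  if (inherits(x, "ts_series")) x else ts_series(x, rate)
}

#' Zero-lag Butterworth low-pass filter
#'
#' Forward-backward (zero phase) Butterworth low-pass filtering with 1 s
#' signal-reflection padding at both ends to suppress edge transients.
#' By convention `order` names the effective order after both passes, as is
#' usual in biomechanics when a "4th order zero-lag" filter is reported: the
#' designed order per pass is `order / 2`. Set `order_convention =
#' "per_pass"` to design at `order` in each direction instead.
#'
#' @param series `ts_series` (scalar or 3-column).
#' @param cutoff cut-off frequency in Hz, strictly below Nyquist.
#' @param order even filter order (default 4).
#' @param order_convention `"effective"` (default: design order = order/2 per
#'   pass) or `"per_pass"`.
#' @return filtered `ts_series`, same length and shape.
#' @export
butterworth_lowpass <- function(series, cutoff, order = 4L,
                                order_convention = c("effective", "per_pass")) {
  order_convention <- match.arg(order_convention)
  rate <- series$rate
  nyq <- rate / 2
  if (cutoff <= 0 || cutoff >= nyq)
    stop("cutoff must lie strictly inside (0, Nyquist = ", nyq, " Hz)")
  if (order %% 2 != 0) stop("order must be even")
  design_order <- if (order_convention == "effective") order / 2 else order
  bf <- signal::butter(design_order, cutoff / nyq, type = "low")
  pad <- min(round(rate), n_samples(series) - 1L)  # 1 s reflection padding
  filt1 <- function(x) {
    n <- length(x)
    # mirror (even) reflection: continuous at the boundary and free of the
    # DC pedestal that point reflection adds when an end lies off-centre of
    # a local oscillation
    head_pad <- x[seq(pad + 1L, 2L, by = -1L)]
    tail_pad <- x[seq(n - 1L, n - pad, by = -1L)]
    xp <- c(head_pad, x, tail_pad)
    y <- signal::filter(bf, xp)
    y <- rev(as.numeric(signal::filter(bf, rev(as.numeric(y)))))
    y[seq(pad + 1L, pad + n)]
  }
  v <- series$values
  out <- if (is.matrix(v)) apply(v, 2L, filt1) else filt1(v)
  ts_series(out, rate)
}

#' Select a low-pass cut-off by residual analysis
#'
#' Winter-style residual analysis: for each candidate cut-off the RMS
#' residual between the raw and zero-lag filtered series is computed; a
#' straight line is fitted to the residuals of the noise-dominated tail
#' (candidates in the upper half of the supplied range) and extrapolated to
#' 0 Hz, giving a noise estimate (the intercept). The selected cut-off is
#' the smallest candidate whose residual does not exceed that intercept.
#'
#' @param series `ts_series` (scalar; 3D series are reduced by the vector
#'   norm of the residual).
#' @param candidate_cutoffs ascending candidate cut-offs in Hz, all strictly
#'   inside (0, Nyquist); at least 4 are required for the tail line fit.
#' @param order filter order passed to [butterworth_lowpass()].
#' @return selected cut-off (Hz), with attributes `residuals` and `noise_rms`.
#' @export
residual_analysis_cutoff <- function(series, candidate_cutoffs, order = 4L) {
  fc <- as.numeric(candidate_cutoffs)
  if (length(fc) < 4L) stop("need at least 4 candidate cutoffs for the tail line fit")
  if (is.unsorted(fc, strictly = TRUE)) stop("candidate cutoffs must be strictly ascending")
  nyq <- series$rate / 2
  if (fc[1] <= 0 || fc[length(fc)] >= nyq)
    stop("candidates must lie strictly inside (0, Nyquist)")
  rms1 <- function(x) sqrt(mean(x^2))
  # residuals are measured away from the ends, where the zero-lag filter's
  # boundary transients would otherwise dominate the noise estimate
  n <- n_samples(series)
  edge <- min(round(series$rate), floor((n - 8L) / 2))
  keep <- seq.int(edge + 1L, n - edge)
  res <- vapply(fc, function(f) {
    d <- series$values - butterworth_lowpass(series, f, order = order)$values
    if (is.matrix(d)) rms1(sqrt(rowSums(d[keep, , drop = FALSE]^2)))
    else rms1(d[keep])
  }, numeric(1))
  tail_idx <- which(fc >= (fc[1] + fc[length(fc)]) / 2)
  if (length(tail_idx) < 2L) tail_idx <- seq(length(fc) - 1L, length(fc))
  fit <- stats::lm.fit(cbind(1, fc[tail_idx]), res[tail_idx])
  noise <- max(fit$coefficients[1], 0)
  # tolerance of 1% of the worst-candidate residual absorbs the gradual
  # roll-off of a finite-order filter when the signal is (nearly) noiseless
  ok <- which(res <= noise + 0.01 * res[1L])
  sel <- if (length(ok)) fc[min(ok)] else fc[length(fc)]
  structure(sel, residuals = res, noise_rms = noise)
}

#' Differentiate a sampled series
#'
#' Central differences on interior samples, one-sided differences at the two
#' ends; exact for linear signals. Output has the same length as the input.
#'
#' @param series `ts_series`.
#' @return `ts_series` of derivatives (input units per second).
#' @export
differentiate <- function(series) {
  n <- n_samples(series)
  if (n < 3L) stop("differentiate needs at least 3 samples")
  dt <- 1 / series$rate
  d1 <- function(x) {
    dx <- numeric(length(x))
    dx[1] <- (x[2] - x[1]) / dt
    dx[length(x)] <- (x[length(x)] - x[length(x) - 1L]) / dt
    i <- 2:(length(x) - 1L)
    dx[i] <- (x[i + 1L] - x[i - 1L]) / (2 * dt)
    dx
  }
  v <- series$values
  out <- if (is.matrix(v)) apply(v, 2L, d1) else d1(v)
  ts_series(out, series$rate)
}

#' Locate strict interior extrema and peak prominences
#'
#' Finds strict local minima and maxima of a scalar series (plateaus are
#' resolved to their first sample) and computes the topographic prominence
#' of each maximum: its height above the higher of the two bounding saddle
#' levels (series minima towards the nearest higher peak on each side, the
#' series end counting as an open boundary).
#'
#' @param series `ts_series` (scalar) or numeric vector.
#' @return list with integer vectors `minima`, `maxima` and numeric
#'   `prominences` (aligned with `maxima`).
#' @export
find_local_extrema <- function(series) {
  x <- if (inherits(series, "ts_series")) series$values else as.numeric(series)
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples")
  # run-length compress plateaus; keep first index of each run
  r <- rle(x)
  k <- length(r$values)
  first_idx <- cumsum(c(1L, r$lengths[-k]))
  v <- r$values
  minima <- integer(0); maxima <- integer(0)
  if (k >= 3L) {
    i <- 2:(k - 1L)
    is_max <- v[i] > v[i - 1L] & v[i] > v[i + 1L]
    is_min <- v[i] < v[i - 1L] & v[i] < v[i + 1L]
    maxima <- first_idx[i][is_max]
    minima <- first_idx[i][is_min]
  }
  prominences <- vapply(maxima, function(p) {
    h <- x[p]
    left <- x[seq_len(p - 1L)]
    right <- x[seq.int(p + 1L, n)]
    higher_l <- which(left >= h)
    higher_r <- which(right >= h)
    saddle_l <- if (length(higher_l)) min(left[seq.int(max(higher_l), p - 1L)]) else min(left)
    saddle_r <- if (length(higher_r)) min(right[seq_len(min(higher_r))]) else min(right)
    h - max(saddle_l, saddle_r)
  }, numeric(1))
  list(minima = minima, maxima = maxima, prominences = prominences)
}

#' Index of the most prominent maximum
#'
#' Ties are broken to the earliest index.
#' @param series scalar `ts_series` or numeric vector.
#' @return integer sample index.
#' @export
most_prominent_peak <- function(series) {
  ex <- find_local_extrema(series)
  if (!length(ex$maxima)) stop("series has no interior maxima")
  ex$maxima[which.max(ex$prominences)]
}
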