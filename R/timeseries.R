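#' Construct a scan time-series object
#'
#' @param values `n_rois` x `n_volumes` matrix, one row per ROI.
#' @param tr Repetition time in seconds (sampling interval of volumes).
#' @return Object of class `scan_timeseries`.
#' @export
scan_timeseries <- function(values, tr = 2.0) {
  assert_that(is.matrix(values) && is.numeric(values),
              "`values` must be a numeric matrix (ROIs x volumes)")
  assert_that(all(is.finite(values)), "time series must contain no missing values")
  assert_that(is_number(tr) && tr > 0, "`tr` must be a positive number")
  structure(list(values = values, tr = as.numeric(tr)),
            class = "scan_timeseries")
}

#' @export
print.scan_timeseries <- function(x, ...) {
  cat("<scan_timeseries> ", nrow(x$values), " ROIs x ", ncol(x$values),
      " volumes, TR = ", x$tr, " s\n", sep = "")
  invisible(x)
}

as_ts_matrix <- function(ts) {
  if (inherits(ts, "scan_timeseries")) ts$values else ts
}

#' Remove linear and quadratic temporal trends
#'
#' Per ROI, subtracts the least-squares fit of a degree-2 polynomial in
#' time, leaving each series orthogonal to the span of
#' \{1, t, t^2\}.  Idempotent (orthogonal projection).
#'
#' @param ts A [scan_timeseries()] (or plain ROI x volume matrix).
#' @return Detrended object of the same type.
#' @export
detrend_timeseries <- function(ts) {
  m <- as_ts_matrix(ts)
  nv <- ncol(m)
  assert_that(nv >= 4, "detrending needs at least 4 volumes")
  t_idx <- seq_len(nv)
  basis <- cbind(1, t_idx, t_idx^2)
  q <- qr.Q(qr(basis))
  out <- m - (m %*% q) %*% t(q)
  if (inherits(ts, "scan_timeseries")) scan_timeseries(out, ts$tr) else out
}

#' Ideal band-pass filter of ROI time series
#'
#' Frequency-domain mask retaining discrete Fourier components with
#' `low_hz <= f <= high_hz` (inclusive band edges).  The DC component is
#' always outside the band, so each filtered series has zero mean.  The
#' defaults, 0.005-0.1 Hz, cover the slow spontaneous fluctuations that
#' carry resting-state functional connectivity.
#'
#' @param ts A [scan_timeseries()].
#' @param low_hz,high_hz Pass-band edges in Hz.
#' @return Filtered [scan_timeseries()].
#' @export
bandpass_timeseries <- function(ts, low_hz = 0.005, high_hz = 0.1) {
  assert_that(inherits(ts, "scan_timeseries"),
              "`ts` must be a scan_timeseries (the TR is needed)")
  m <- ts$values
  nv <- ncol(m)
  assert_that(nv >= 8, "band-pass needs at least 8 volumes")
  nyquist <- 1 / (2 * ts$tr)
  assert_that(is_number(low_hz) && is_number(high_hz) &&
                0 <= low_hz && low_hz < high_hz,
              "need 0 <= low_hz < high_hz")
  assert_that(high_hz <= nyquist,
              "high_hz exceeds the Nyquist frequency ", nyquist, " Hz")
  freqs <- (seq_len(nv) - 1) / (nv * ts$tr)
  freqs <- pmin(freqs, 1 / ts$tr - freqs)  # fold to [0, Nyquist]
  keep <- freqs >= low_hz & freqs <= high_hz & freqs > 0
  assert_that(any(keep),
              "pass band contains no resolvable frequency at this n_volumes/TR")
  ft <- t(apply(m, 1, stats::fft))
  ft[, !keep] <- 0
  out <- t(apply(ft, 1, function(row) Re(stats::fft(row, inverse = TRUE)))) / nv
  scan_timeseries(out, ts$tr)
}

#' Pairwise Pearson correlation matrix of ROI time series
#'
#' @param ts A [scan_timeseries()] or ROI x volume matrix.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(ts) {
  m <- as_ts_matrix(ts)
  v <- apply(m, 1, var)
  if (any(v == 0)) {
    abort("zero-variance time series for ROI(s): ",
          paste(which(v == 0), collapse = ", "))
  }
  r <- cor(t(m))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

#' Build a Fisher-z connectome from ROI time series
#'
#' Convenience chain: optional detrending, optional band-pass, Pearson
#' correlation, Fisher z, canonical vectorization.
#'
#' @param ts A [scan_timeseries()].
#' @param detrend Remove linear/quadratic trends first (default TRUE).
#' @param bandpass Apply the 0.005-0.1 Hz ideal band-pass (default TRUE).
#' @param low_hz,high_hz Pass-band edges.
#' @return A [connectome()].
#' @export
build_connectome <- function(ts, detrend = TRUE, bandpass = TRUE,
                             low_hz = 0.005, high_hz = 0.1) {
  assert_that(inherits(ts, "scan_timeseries"), "`ts` must be a scan_timeseries")
  if (detrend) ts <- detrend_timeseries(ts)
  if (bandpass) ts <- bandpass_timeseries(ts, low_hz, high_hz)
  vectorize_connectome(correlation_matrix(ts), fisher = TRUE)
}
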