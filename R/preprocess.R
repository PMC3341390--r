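#' Remove per-region linear trends
#'
#' Subtracts the least-squares line (intercept + slope) from every
#' regional time series, removing scanner drift before filtering.
#' Constant columns come back as all zeros.
#'
#' @param ts T x N time-series matrix.
#' @return detrended matrix of the same shape.
#' @export
detrend_linear <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) stop("need at least 3 timepoints")
  x <- cbind(1, seq_len(nrow(ts)))
  res <- ts - x %*% qr.coef(qr(x), ts)
  dimnames(res) <- dimnames(ts)
  res
}

#' Regress out nuisance signals
#'
#' Ordinary least squares of every regional time series on the nuisance
#' predictors (conventionally nine: white-matter mean, CSF mean, global
#' signal, six motion parameters) plus an intercept, returning the
#' residuals. Residuals are orthogonal to every retained predictor.
#' Collinear predictor columns are dropped with a warning and recorded in
#' the `"dropped_predictors"` attribute.
#'
#' @param ts T x N time-series matrix.
#' @param nuisance T x P predictor matrix (no intercept column).
#' @return residual matrix, T x N.
#' @export
regress_nuisance <- function(ts, nuisance) {
  ts <- as.matrix(ts)
  nuisance <- as.matrix(nuisance)
  if (nrow(ts) != nrow(nuisance))
    stop("time series and nuisance set must have the same number of rows")
  if (is.null(colnames(nuisance)))
    colnames(nuisance) <- paste0("nuis", seq_len(ncol(nuisance)))
  x <- cbind(`(intercept)` = 1, nuisance)
  qx <- qr(x)
  dropped <- character(0)
  if (qx$rank < ncol(x)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    dropped <- colnames(x)[setdiff(seq_len(ncol(x)), keep)]
    warning("dropping collinear predictor(s): ",
            paste(dropped, collapse = ", "))
    qx <- qr(x[, keep, drop = FALSE])
  }
  res <- qr.resid(qx, ts)
  dimnames(res) <- dimnames(ts)
  attr(res, "dropped_predictors") <- dropped
  res
}

#' Temporal band-pass filter
#'
#' Zero-phase band-pass implemented as an ideal frequency-domain (DFT)
#' filter: each regional series is demeaned, transformed, components with
#' frequency outside `[low_hz, high_hz]` are zeroed (including DC), and
#' the series is inverse-transformed. The conventional resting-state band
#' is 0.01-0.08 Hz, retaining slow spontaneous BOLD fluctuations while
#' rejecting drift and high-frequency physiological noise.
#'
#' @param ts T x N time-series matrix.
#' @param low_hz,high_hz passband edges in Hz; `0 < low < high < Nyquist`.
#' @param tr_seconds repetition time (sampling interval) in seconds.
#' @return filtered matrix of the same shape.
#' @export
bandpass_filter <- function(ts, low_hz = 0.01, high_hz = 0.08,
                            tr_seconds = 2) {
  ts <- as.matrix(ts)
  nt <- nrow(ts)
  nyquist <- 1 / (2 * tr_seconds)
  if (low_hz <= 0 || low_hz >= high_hz) stop("need 0 < low_hz < high_hz")
  if (high_hz >= nyquist) stop("high_hz must be below the Nyquist frequency")
  centred <- sweep(ts, 2, colMeans(ts))
  freq <- seq_len(nt) - 1
  freq <- pmin(freq, nt - freq) / (nt * tr_seconds)  # two-sided bins
  keep <- freq >= low_hz & freq <= high_hz
  f <- stats::mvfft(centred)
  f[!keep, ] <- 0
  out <- Re(stats::mvfft(f, inverse = TRUE)) / nt
  dimnames(out) <- dimnames(ts)
  out
}

#' Full temporal preprocessing pipeline
#'
#' Linear detrend, optional nuisance regression, band-pass filter, in that
#' order.
#'
#' @inheritParams bandpass_filter
#' @param nuisance optional T x P nuisance matrix for [regress_nuisance()].
#' @param detrend,bandpass logical switches for the respective stages.
#' @return preprocessed T x N matrix.
#' @export
preprocess_roi <- function(ts, nuisance = NULL, low_hz = 0.01,
                           high_hz = 0.08, tr_seconds = 2,
                           detrend = TRUE, bandpass = TRUE) {
  out <- as.matrix(ts)
  if (detrend) out <- detrend_linear(out)
  if (!is.null(nuisance)) out <- regress_nuisance(out, nuisance)
  if (bandpass) out <- bandpass_filter(out, low_hz, high_hz, tr_seconds)
  out
}
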