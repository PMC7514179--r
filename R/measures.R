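## Per-PM outcome measures: sample entropy of the (filtered, detrended)
## principal positions, sample entropy of the filtered principal
## accelerations, and control-tightness statistics on the filtered PA
## (zero-crossing count N and inter-crossing timing SD sigma).
##
## Processing order: PP -> 7 Hz low-pass -> 501-point moving-average detrend
## -> SaEn; PA (central difference of the unfiltered PP) -> 7 Hz low-pass ->
## SaEn / N / sigma. Filtering precedes detrending so the long moving
## average never smears filter transients.

#' Sample-entropy parameters
#'
#' Typical postural-sway settings: embedding dimension m = 2, tolerance
#' r = 0.2 x SD of the series, embedding lag tau = 12 samples (100 ms at
#' 120 Hz, a physiologically meaningful correction timescale).
#'
#' @param m embedding dimension (>= 1).
#' @param r_coeff tolerance as a multiple of the series SD (> 0).
#' @param tau embedding lag in samples (>= 1).
#' @param rate sampling rate the lag refers to (Hz).
#' @return list of class \code{EntropyParams}.
#' @export
entropyParams <- function(m = 2L, r_coeff = 0.2, tau = 12L, rate = 120) {
  stopifnot(m >= 1L, r_coeff > 0, tau >= 1L, rate > 0)
  structure(list(m = as.integer(m), r_coeff = r_coeff, tau = as.integer(tau),
                 rate = rate), class = "EntropyParams")
}

#' Moving-average detrend with nearest-available edge rule
#'
#' Subtracts a centered moving average of odd length \code{window}. For the
#' first and last (window-1)/2 points, where the centered average is
#' undefined, the subtracted value is the nearest fully-defined average
#' (i.e., the first/last valid one).
#'
#' @param x numeric series, longer than \code{window}.
#' @param window odd window length in samples (default 501, about 4 s at
#'   120 Hz).
#' @return the detrended series.
#' @export
movingAverageDetrend <- function(x, window = 501L) {
  if (window %% 2L == 0L) stop("window must be odd (centered average)")
  n <- length(x)
  if (n <= window) stop("series must be longer than the window")
  if (window == 1L) return(x - x)
  ma <- stats::filter(x, rep(1 / window, window), sides = 2)
  ma <- as.numeric(ma)
  half <- (window - 1L) %/% 2L
  ma[seq_len(half)] <- ma[half + 1L]
  ma[(n - half + 1L):n] <- ma[n - half]
  x - ma
}

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward application of a Butterworth design (default 6th order,
#' 7 Hz cutoff at 120 Hz), so crossing times and entropy templates are not
#' phase-shifted; the net magnitude response is the squared single-pass
#' response. \code{zero_phase = FALSE} gives the single forward pass.
#'
#' @param x numeric series.
#' @param cutoff cutoff frequency (Hz), below Nyquist.
#' @param order filter order (default 6).
#' @param rate sampling rate (Hz).
#' @param zero_phase forward-backward (default TRUE).
#' @return the filtered series.
#' @export
butterworthLowpass <- function(x, cutoff = 7, order = 6L, rate = 120,
                               zero_phase = TRUE) {
  if (cutoff <= 0 || cutoff >= rate / 2)
    stop("cutoff must lie in (0, rate/2)")
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  # odd-reflection padding long enough for the start-up transient of the
  # zero-initial-condition filter to decay below numerical noise
  n <- length(x)
  L <- min(n - 1L, as.integer(ceiling(25 * rate / cutoff)))
  left <- 2 * x[1L] - x[(L + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - L)]
  xp <- c(left, x, right)
  out <- if (zero_phase) signal::filtfilt(bf, xp)
         else signal::filter(bf, xp)
  as.numeric(out)[(L + 1L):(L + n)]
}

#' Fraction of spectral power below a frequency limit
#'
#' Periodogram-based check that the signal content lives at low frequencies
#' (excluding DC).
#'
#' @param x numeric series (length >= 256).
#' @param rate sampling rate (Hz).
#' @param f_limit frequency limit (Hz).
#' @return fraction of non-DC power at frequencies <= \code{f_limit}.
#' @export
powerFraction <- function(x, rate, f_limit) {
  n <- length(x)
  if (n < 256L) stop("series too short for a stable spectrum (need >= 256)")
  X <- stats::fft(x - mean(x))
  nf <- n %/% 2L
  P <- Mod(X[2L:(nf + 1L)])^2
  f <- (1L:nf) * rate / n
  sum(P[f <= f_limit]) / sum(P)
}

#' Sample entropy with lagged embedding
#'
#' SaEn = -ln(A/B) where B counts template pairs (i < j) of the lag-tau
#' embedded series matching within Chebyshev tolerance r at dimension m and
#' A the same at dimension m+1, both over the common index range,
#' self-matches excluded. r = r_coeff x SD of the series as passed in, so
#' the measure is invariant to affine scaling.
#'
#' @param x numeric series (after any filtering/detrending).
#' @param params an [entropyParams()].
#' @return SaEn in nats; \code{Inf} (with a warning) when no m+1 matches
#'   exist; \code{NA} for degenerate inputs is never returned silently —
#'   constant series raise an error.
#' @export
sampleEntropy <- function(x, params = entropyParams()) {
  m <- params$m; tau <- params$tau
  n <- length(x)
  if (n < (m + 1L) * tau + 10L)
    stop("series too short for the requested embedding")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("sample entropy undefined for a constant series (r = 0)")
  r <- params$r_coeff * s
  cnt <- .sampenCounts(as.numeric(x), m, tau, r)
  A <- cnt[1L]; B <- cnt[2L]
  if (B == 0) {
    warning("no template matches at dimension m; sample entropy undefined")
    return(NA_real_)
  }
  if (A == 0) {
    warning("no template matches at dimension m+1; returning Inf sentinel")
    return(Inf)
  }
  -log(A / B)
}

#' Count zero crossings
#'
#' Sign changes between consecutive samples, with exact zeros inheriting the
#' preceding nonzero sign (leading zeros take the following sign), so a run
#' of zeros contributes at most one crossing.
#'
#' @param x numeric series (length >= 2).
#' @return integer crossing count (0 with a warning for an all-zero series).
#' @export
zeroCrossings <- function(x) {
  if (length(x) < 2L) stop("need at least 2 samples")
  s <- sign(x)
  if (all(s == 0)) {
    warning("all-zero series: no crossings")
    return(0L)
  }
  nz <- s != 0
  # zeros inherit the previous nonzero sign; leading zeros the next sign
  filled <- s
  idx <- which(nz)
  filled <- s[idx][cumsum(nz)]
  filled <- c(rep(s[idx[1L]], idx[1L] - 1L), filled)
  sum(diff(filled) != 0)
}

## Sample indices just after each sign change (same zero-handling rule).
.crossingIndices <- function(x) {
  s <- sign(x)
  nz <- s != 0
  if (!any(nz)) return(integer(0))
  idx <- which(nz)
  filled <- c(rep(s[idx[1L]], idx[1L] - 1L), s[idx][cumsum(nz)])
  which(diff(filled) != 0) + 1L
}

#' Timing variability of zero crossings
#'
#' Standard deviation (n-1 denominator) of the times between successive
#' zero crossings; crossing time = index of the sample after the sign
#' change divided by the sampling rate.
#'
#' @param x numeric series.
#' @param rate sampling rate (Hz).
#' @return SD of inter-crossing intervals in seconds; \code{NA} (sentinel)
#'   when fewer than 3 crossings exist.
#' @export
intercrossingSD <- function(x, rate) {
  ci <- .crossingIndices(x)
  if (length(ci) < 3L) {
    warning("fewer than 3 zero crossings: timing SD undefined")
    return(NA_real_)
  }
  stats::sd(diff(ci / rate))
}

#' Compute the per-trial, per-PM measure table
#'
#' For every trial and retained PM: SaEn of the low-passed, detrended PP;
#' SaEn, zero-crossing count N and inter-crossing timing SD sigma of the
#' low-passed PA (PA computed by central differences of the unfiltered PP).
#' Undefined measures become \code{NA} sentinels without aborting the
#' table; \code{filter_pa = FALSE} exposes the unfiltered-PA variant.
#'
#' @param scores list of [PMScores-class] (one per trial).
#' @param retained integer indices of retained PMs.
#' @param params an [entropyParams()].
#' @param cutoff,order low-pass settings (Hz / filter order).
#' @param detrend_window detrend window in samples (odd).
#' @param filter_pa low-pass the PA before N/sigma/SaEn (default TRUE).
#' @return long data.frame: subject_id, group, condition, pm, saen_pp,
#'   saen_pa, n, sigma.
#' @export
computeMeasures <- function(scores, retained, params = entropyParams(),
                            cutoff = 7, order = 6L, detrend_window = 501L,
                            filter_pa = TRUE) {
  rows <- lapply(scores, function(sc) {
    m <- trialMeta(sc)
    rate <- sampleRate(sc)
    pp <- principalPositions(sc)
    pa <- principalAccelerations(sc)
    do.call(rbind, lapply(retained, function(k) {
      pp_f <- tryCatch(
        movingAverageDetrend(
          butterworthLowpass(pp[, k], cutoff = cutoff, order = order,
                             rate = rate),
          window = detrend_window),
        error = function(e) NULL)
      pa_f <- if (filter_pa)
        butterworthLowpass(pa[, k], cutoff = cutoff, order = order,
                           rate = rate)
      else pa[, k]
      quiet <- function(expr) suppressWarnings(
        tryCatch(expr, error = function(e) NA_real_))
      data.frame(
        subject_id = m$subject_id, group = m$group, condition = m$condition,
        pm = k,
        saen_pp = if (is.null(pp_f)) NA_real_
                  else quiet(sampleEntropy(pp_f, params)),
        saen_pa = quiet(sampleEntropy(pa_f, params)),
        n = quiet(as.numeric(zeroCrossings(pa_f))),
        sigma = quiet(intercrossingSD(pa_f, rate)),
        stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
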