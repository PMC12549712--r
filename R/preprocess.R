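# Signal chain from raw dual-wavelength intensity to the model-ready tensor.

# Zero-phase filtering with odd-symmetric (reflected) edge padding; plain
# filtfilt rings badly at the boundaries for low cutoffs. `np` should cover
# the filter's settle time (a few periods of the cutoff frequency).
.filtfilt_pad <- function(bf, x, np) {
  n <- length(x)
  np <- max(1L, min(n - 1L, as.integer(np)))
  left <- 2 * x[1] - x[(np + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - np)]
  y <- signal::filtfilt(bf, c(left, x, right))
  y[(np + 1):(np + n)]
}

#' Temporal derivative distribution repair (TDDR) motion correction
#'
#' Robust iterative Tukey-biweight reweighting of the signal's temporal
#' derivative: the low-frequency derivative is re-estimated with weights that
#' shrink abrupt outlying derivative samples (motion spikes, baseline shifts)
#' towards the robust trend, and the signal is reintegrated. Two tuning
#' parameters: `sd_threshold` sets the initial outlier mask in robust-SD
#' units, and `amplification` blends the corrected and original derivatives
#' for samples that are only mildly down-weighted (hard outliers are always
#' fully corrected). A signal whose second differences are uniformly small
#' relative to its first differences is band-limited far below Nyquist and
#' cannot contain abrupt artifacts; such series are returned unchanged so
#' clean haemodynamics are never distorted.
#'
#' @param series Numeric vector (one channel, one wavelength).
#' @param sd_threshold Initial outlier mask threshold in robust SD units.
#' @param amplification Blend weight in `[0, 1]` applied to the correction of
#'   mildly down-weighted samples (0 = leave them alone, 1 = full Tukey
#'   correction). Default 0.5.
#' @param sampling_hz Sampling rate; used to split off the high-frequency
#'   component (cardiac band), which is passed through untouched.
#' @return Corrected series, same length.
#' @export
tddr_correct <- function(series, sd_threshold = 3.0, amplification = 0.5,
                         sampling_hz = 100) {
  # iterate the repair to a fixed point so reapplication is a near no-op
  cur <- .tddr_pass(series, sd_threshold, amplification, sampling_hz)
  mag <- max(abs(cur - series))
  if (mag == 0) return(cur)
  for (i in 1:12) {
    nxt <- .tddr_pass(cur, sd_threshold, amplification, sampling_hz)
    if (max(abs(nxt - cur)) < 5e-3 * mag) return(nxt)
    cur <- nxt
  }
  cur
}

.tddr_pass <- function(series, sd_threshold, amplification, sampling_hz) {
  n <- length(series)
  if (n < 3L) return(series)
  if (!all(is.finite(series))) stop("tddr_correct: series must be finite")
  if (stats::sd(series) == 0) return(series)

  d1 <- diff(series)
  d2 <- diff(series, differences = 2)
  m1 <- max(abs(d1)); m2 <- max(abs(d2))
  if (m1 == 0 || m2 / m1 < 0.1) return(series)  # smooth, artifact-free

  # split off the cardiac/high-frequency part; correct the slow component
  if (sampling_hz > 2) {
    fc <- min(0.5, 0.4 * sampling_hz / 2)
    bf <- signal::butter(2, fc / (sampling_hz / 2), type = "low")
    low <- .filtfilt_pad(bf, series, 3 * sampling_hz / fc)
  } else low <- series
  high <- series - low

  d <- diff(low)
  med <- stats::median(d)
  s0 <- 1.4826 * stats::median(abs(d - med))
  if (s0 <= .Machine$double.eps * max(abs(d), 1)) return(series)
  # initial outlier mask in robust-SD units; the full-repair mask is only
  # triggered by strong outliers (2x threshold, beyond chance for Gaussian
  # noise) and dilated so whole transients (onset plus decay) are repaired,
  # while mild outliers get the smooth Tukey-weighted correction only
  z0 <- abs(d - med) / s0
  hard <- z0 > 2 * sd_threshold
  # the zero-phase split is least reliable at the boundaries; do not let the
  # edge region seed a repair
  guard <- min(length(d) %/% 4L, max(2L, round(sampling_hz)))
  hard[seq_len(guard)] <- FALSE
  hard[(length(d) - guard + 1L):length(d)] <- FALSE
  if (any(hard)) {
    # hysteresis: grow each triggered region while the (smoothed) derivative
    # stays elevated, so a transient's whole decay is repaired with its onset
    nd <- length(d)
    ks <- max(1L, round(0.5 * sampling_hz))
    zs <- as.numeric(stats::filter(z0, rep(1 / ks, ks), sides = 2))
    zs[!is.finite(zs)] <- z0[!is.finite(zs)]
    pad <- max(1L, round(0.25 * sampling_hz))
    for (i in which(hard)) {
      j <- i
      while (j < nd && zs[j + 1] > 1) j <- j + 1
      k <- i
      while (k > 1 && zs[k - 1] > 1) k <- k - 1
      hard[max(1, k - pad):min(nd, j + pad)] <- TRUE
    }
  }
  w <- as.numeric(z0 <= sd_threshold & !hard)

  mu <- med
  for (iter in 1:50) {
    mu_new <- sum(w * d) / max(sum(w), 1e-12)
    r <- d - mu_new
    s <- 1.4826 * stats::median(abs(r))
    if (s <= .Machine$double.eps * max(abs(d), 1)) break
    z <- r / (4.685 * s)
    w <- ifelse(abs(z) < 1, (1 - z^2)^2, 0)
    if (abs(mu_new - mu) < 1e-12 * (abs(mu) + 1e-12)) { mu <- mu_new; break }
    mu <- mu_new
  }
  r <- d - mu
  corrected <- mu + w * r
  # only derivative samples flagged by the initial outlier mask are touched,
  # and those only by the partial (amplification-weighted) correction, so
  # clean physiology passes through and reapplication is nearly a no-op;
  # masked runs are repaired by linear interpolation of the slow component
  # across the run, anchored just outside it, which removes the excursion
  # and restores the exit level
  d_new <- ifelse(z0 > sd_threshold,
                  (1 - amplification) * d + amplification * corrected, d)
  rr <- rle(hard)
  ends <- cumsum(rr$lengths); starts <- ends - rr$lengths + 1L
  for (k in seq_along(rr$values)) {
    if (!rr$values[k]) next
    s0 <- starts[k]; s1 <- ends[k] + 1L       # sample-index range of the run
    a0 <- low[max(1L, s0 - 1L)]; a1 <- low[min(n, s1 + 1L)]
    d_new[s0:(s1 - 1L)] <- (a1 - a0) / (s1 - s0 + 2L)
  }
  low_new <- cumsum(c(low[1], d_new))
  # a sharp transient also leaks into the high-frequency component; silence
  # it inside the artifact mask (clean physiology there is unrecoverable)
  ms <- c(hard, FALSE) | c(FALSE, hard)
  high[ms] <- 0
  low_new + high
}

# ---- small Haar DWT (no wavelet package available; periodised transform) ----

.haar_dwt <- function(x) {
  n <- length(x)
  J <- floor(log2(n))
  n2 <- 2^J
  head <- x[seq_len(n2)]
  details <- vector("list", J)
  a <- head
  for (j in seq_len(J)) {
    even <- a[seq(2, length(a), 2)]; odd <- a[seq(1, length(a), 2)]
    details[[j]] <- (odd - even) / sqrt(2)
    a <- (odd + even) / sqrt(2)
  }
  list(approx = a, details = details, tail = if (n2 < n) x[(n2 + 1):n] else numeric(0))
}

.haar_idwt <- function(w) {
  a <- w$approx
  for (j in rev(seq_along(w$details))) {
    dtl <- w$details[[j]]
    odd <- (a + dtl) / sqrt(2); even <- (a - dtl) / sqrt(2)
    out <- numeric(2 * length(a))
    out[seq(1, length(out), 2)] <- odd
    out[seq(2, length(out), 2)] <- even
    a <- out
  }
  c(a, w$tail)
}

#' Hybrid spline interpolation / wavelet shrinkage motion correction
#'
#' Addresses complex (non-spike) artifacts: segments flagged as motion are
#' detrended by subtracting a smoothing-spline fit of the segment (re-levelled
#' so the segment reconnects to its neighbours), then residual structure within
#' the flagged segments is shrunk by soft universal-threshold Haar wavelet
#' denoising. Samples outside flagged segments are left untouched, so clean
#' series pass through essentially unchanged. Segments may be supplied or
#' detected internally from robust derivative outliers.
#'
#' @param series Numeric vector.
#' @param segments Optional logical vector flagging motion samples; if `NULL`,
#'   segments are detected from robust z-scores of the derivative
#'   (`|z| > detect_threshold`, dilated by `pad_s` seconds).
#' @param sampling_hz Sampling rate (Hz).
#' @param detect_threshold Robust z threshold for internal detection.
#' @param pad_s Dilation of detected segments, seconds.
#' @return Corrected series.
#' @export
spline_wavelet_correct <- function(series, segments = NULL, sampling_hz = 100,
                                   detect_threshold = 5, pad_s = 1) {
  n <- length(series)
  if (n < 8L) { warning("series shorter than one wavelet support; passthrough"); return(series) }
  if (all(series == 0)) return(series)
  if (is.null(segments)) {
    # band-limited series far below Nyquist carry no abrupt artifacts
    d2 <- diff(series, differences = 2)
    if (max(abs(diff(series))) == 0 ||
        max(abs(d2)) / max(abs(diff(series))) < 0.1) return(series)
    d <- diff(series)
    s <- 1.4826 * stats::median(abs(d - stats::median(d)))
    if (s <= .Machine$double.eps * max(abs(d), 1)) return(series)
    flag <- c(FALSE, abs(d - stats::median(d)) / s > detect_threshold)
    pad <- max(1L, round(pad_s * sampling_hz))
    idx <- which(flag)
    if (length(idx) == 0) return(series)
    segments <- rep(FALSE, n)
    for (i in idx) segments[max(1, i - pad):min(n, i + pad)] <- TRUE
  }
  if (!any(segments)) return(series)
  out <- series
  rr <- rle(segments)
  ends <- cumsum(rr$lengths); starts <- ends - rr$lengths + 1L
  for (k in seq_along(rr$values)) {
    if (!rr$values[k]) next
    i0 <- starts[k]; i1 <- ends[k]
    seg <- out[i0:i1]
    m <- length(seg)
    if (m >= 8) {
      sp <- stats::smooth.spline(seq_len(m), seg, spar = 0.6)
      fitv <- stats::fitted(sp)
      resid <- seg - fitv
      # wavelet shrinkage of the residual inside the segment
      w <- .haar_dwt(resid)
      sigma <- stats::median(abs(w$details[[1]])) / 0.6745
      thr <- sigma * sqrt(2 * log(max(m, 2)))
      w$details <- lapply(w$details, function(dd) sign(dd) * pmax(abs(dd) - thr, 0))
      resid <- .haar_idwt(w)
      # remove the within-segment excursion but keep the entry level, then
      # re-level everything after the segment so the series stays continuous
      # (this is what turns a step artifact back into a flat baseline)
      corrected <- fitv[1] + resid
      shift <- seg[m] - corrected[m]
      out[i0:i1] <- corrected
    } else {
      level <- if (i0 > 1) out[i0 - 1] else seg[1]
      shift <- seg[m] - level
      out[i0:i1] <- level
    }
    if (i1 < n) out[(i1 + 1):n] <- out[(i1 + 1):n] - shift
  }
  out
}

#' Scalp coupling index
#'
#' Zero-lag Pearson correlation of the two wavelengths' intensity series after
#' band-pass filtering to the cardiac band and scaling to unit variance. High
#' values indicate the optode is well coupled to the scalp (both wavelengths
#' see the same cardiac pulsation).
#'
#' @param intensity_w1,intensity_w2 Intensity series of the two wavelengths.
#' @param sampling_hz Sampling rate (Hz).
#' @param cardiac_band Band in Hz, default `c(0.5, 2.5)`.
#' @return Score in `[-1, 1]`; degenerate (zero-variance) series give 0 with
#'   attribute `degenerate = TRUE`. If the sampling rate cannot resolve the
#'   cardiac band, returns `NA` with attribute `unresolved = TRUE`.
#' @export
scalp_coupling_index <- function(intensity_w1, intensity_w2, sampling_hz,
                                 cardiac_band = c(0.5, 2.5)) {
  stopifnot(length(intensity_w1) == length(intensity_w2))
  nyq <- sampling_hz / 2
  if (cardiac_band[1] >= nyq * 0.95)
    return(structure(NA_real_, unresolved = TRUE))
  hi <- min(cardiac_band[2], 0.95 * nyq)
  bf <- signal::butter(3, c(cardiac_band[1], hi) / nyq, type = "pass")
  np <- 3 * sampling_hz / cardiac_band[1]
  x <- .filtfilt_pad(bf, intensity_w1 - mean(intensity_w1, na.rm = TRUE), np)
  y <- .filtfilt_pad(bf, intensity_w2 - mean(intensity_w2, na.rm = TRUE), np)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0)
    return(structure(0, degenerate = TRUE))
  as.numeric(stats::cor(x / sx, y / sy))
}

#' Composite signal quality index
#'
#' A 1-5 rating combining (i) cardiac-band spectral prominence, (ii) the
#' flatline/saturation fraction and (iii) the spike rate, each mapped to a
#' `[0, 1]` sub-score and combined as a weighted sum:
#' `score = 1 + 4 * (0.45 s_cardiac + 0.35 s_flat + 0.20 s_spike)`, so a
#' flatline fails on its own while spikes and weak cardiac content degrade
#' the score gradually. The score is monotone
#' (non-increasing) in flatline fraction and spike rate and non-decreasing in
#' cardiac prominence; clean channels with a cardiac component score above the
#' 2.5 exclusion threshold, flatlined channels below it.
#'
#' @param intensity Raw intensity series of one channel (either wavelength).
#' @param sampling_hz Sampling rate (Hz).
#' @param cardiac_band Cardiac band in Hz.
#' @return Numeric score in `[1, 5]`, with sub-scores as attributes.
#' @export
signal_quality_index <- function(intensity, sampling_hz,
                                 cardiac_band = c(0.5, 2.5)) {
  x <- intensity[is.finite(intensity)]
  n <- length(x)
  if (n < 16) return(structure(1, cardiac = 0, flat = 0, spike = 0))
  # flatline fraction: runs of (near-)identical consecutive values
  tol <- 1e-12 * max(abs(x), 1)
  flat_frac <- mean(abs(diff(x)) <= tol)
  s_flat <- 1 - flat_frac
  # cardiac prominence: spectral peak in the cardiac band relative to the
  # median in-band density (>> 1 for a genuine pulsation, O(10) for white
  # noise, 0 for a flatline)
  nyq <- sampling_hz / 2
  if (cardiac_band[1] < 0.95 * nyq && stats::sd(x) > tol) {
    xd <- x - mean(x)
    p <- Mod(stats::fft(xd))^2
    freqs <- (seq_len(n) - 1) / n * sampling_hz
    inband <- freqs >= cardiac_band[1] & freqs <= min(cardiac_band[2], nyq)
    medp <- stats::median(p[inband])
    ratio <- if (medp > 0) max(p[inband]) / medp else 0
    s_card <- min(1, ratio / 50)
  } else if (stats::sd(x) <= tol) s_card <- 0
  else s_card <- 0.6  # band unresolvable at this rate: neutral
  # spike rate: robust derivative outliers per minute
  d <- diff(x)
  s <- 1.4826 * stats::median(abs(d - stats::median(d)))
  spikes <- if (s > tol) sum(abs(d - stats::median(d)) > 6 * s) else 0
  rate_min <- spikes / (n / sampling_hz) * 60
  s_spike <- 1 / (1 + 0.25 * rate_min)
  # weighted additive combination: a flatline fails on its own, while spikes
  # and weak cardiac content degrade the score without instant exclusion
  score <- 1 + 4 * (0.45 * s_card + 0.35 * s_flat + 0.20 * s_spike)
  structure(score, cardiac = s_card, flat = s_flat, spike = s_spike)
}

#' Zero-phase low-pass Butterworth filter
#'
#' 4th-order Butterworth applied forward and backward (`filtfilt`), so the
#' effective magnitude response is the square of the single-pass response and
#' the phase is zero; DC gain is exactly 1.
#'
#' @param series Numeric vector.
#' @param cutoff_hz Cutoff frequency, default 0.1 Hz.
#' @param sampling_hz Sampling rate (Hz).
#' @param order Filter order (default 4).
#' @return Filtered series.
#' @export
butter_lowpass <- function(series, cutoff_hz = 0.1, sampling_hz, order = 4) {
  nyq <- sampling_hz / 2
  if (cutoff_hz >= nyq) stop("butter_lowpass: cutoff must be below Nyquist")
  if (stats::sd(series) == 0) return(series)  # constant: DC gain 1
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  mu <- mean(series)
  .filtfilt_pad(bf, series - mu, 3 * sampling_hz / cutoff_hz) + mu
}

#' Baseline correction by pre-task mean subtraction
#'
#' Subtracts the mean of the first 10 s (the pre-task window) from the whole
#' series.
#'
#' @param series Numeric vector.
#' @param design A [block_design()] with `pre_task_s >= window_s`.
#' @param window_s Baseline window length in seconds (default 10).
#' @return Corrected series.
#' @export
baseline_correct <- function(series, design, window_s = 10) {
  stopifnot(inherits(design, "block_design"))
  if (design$pre_task_s < window_s)
    stop("baseline_correct: design has no ", window_s, " s pre-task window")
  k <- round(window_s * design$sampling_hz)
  series - mean(series[seq_len(k)], na.rm = TRUE)
}

#' Savitzky-Golay smoothing
#'
#' Standard SG convolution (polynomial order 3, window 5 by default); edges are
#' handled by least-squares polynomial fits on the truncated windows, so exact
#' polynomials up to the filter order are reproduced everywhere.
#'
#' @param series Numeric vector.
#' @param polyorder Polynomial order (default 3).
#' @param window Odd window length > `polyorder` (default 5).
#' @return Smoothed series.
#' @export
savgol_smooth <- function(series, polyorder = 3, window = 5) {
  if (window %% 2 == 0 || window <= polyorder)
    stop("savgol_smooth: window must be odd and greater than polyorder")
  if (length(series) < window) return(series)
  as.numeric(signal::sgolayfilt(series, p = polyorder, n = window))
}

#' Channel-wise Z-score standardisation
#'
#' Standardises each (subject, channel) time series to mean 0, SD 1. Constant
#' channels are returned as zeros and flagged rather than divided by zero.
#'
#' @param x Numeric vector, matrix (channels x time) or array
#'   (subjects x channels x time).
#' @return Same shape, standardised; attribute `constant_channels` flags any
#'   zero-variance series.
#' @export
zscore_channels <- function(x) {
  z1 <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) return(structure(rep(0, length(v)), constant = TRUE))
    (v - mean(v)) / s
  }
  if (is.null(dim(x))) {
    out <- z1(x); flag <- isTRUE(attr(out, "constant"))
    attributes(out) <- NULL
    return(structure(out, constant_channels = flag))
  }
  const <- NULL
  if (length(dim(x)) == 2L) {
    out <- x
    for (i in seq_len(nrow(x))) {
      z <- z1(x[i, ]); if (isTRUE(attr(z, "constant"))) const <- c(const, i)
      out[i, ] <- z
    }
  } else if (length(dim(x)) == 3L) {
    out <- x
    for (s in seq_len(dim(x)[1])) for (i in seq_len(dim(x)[2])) {
      z <- z1(x[s, i, ]); if (isTRUE(attr(z, "constant"))) const <- rbind(const, c(s, i))
      out[s, i, ] <- z
    }
  } else stop("zscore_channels: unsupported shape")
  structure(out, constant_channels = const)
}

#' Interquartile-range outlier winsorisation
#'
#' Samples outside `[Q1 - k*IQR, Q3 + k*IQR]` (quartiles per channel across
#' time) are flagged and clipped to the fence. A zero IQR (constant channel)
#' yields no flags.
#'
#' @param x Numeric vector or matrix (channels x time).
#' @param k Fence multiplier (default 1.5).
#' @return List with `x` (winsorised) and `mask` (logical flags, same shape).
#' @export
iqr_outlier_clip <- function(x, k = 1.5) {
  clip1 <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
    iqr <- q[2] - q[1]
    if (iqr == 0) return(list(x = v, mask = rep(FALSE, length(v))))
    lo <- q[1] - k * iqr; hi <- q[2] + k * iqr
    mask <- !is.na(v) & (v < lo | v > hi)
    v[!is.na(v) & v < lo] <- lo
    v[!is.na(v) & v > hi] <- hi
    list(x = v, mask = mask)
  }
  if (is.null(dim(x))) return(clip1(x))
  out <- x; mask <- matrix(FALSE, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) {
    r <- clip1(x[i, ]); out[i, ] <- r$x; mask[i, ] <- r$mask
  }
  list(x = out, mask = mask)
}

#' Multiple imputation of missing samples by chained ridge regression
#'
#' Missing samples in a channels x time matrix are filled by regressing each
#' incomplete channel on the complete channels (ridge penalty), adding
#' residual-scale Gaussian noise, repeating `m` times, and averaging the
#' imputations. Channels with >= 50% missing are excluded (set entirely to
#' `NA`) instead of imputed. Deterministic under `seed`.
#'
#' @param x Matrix channels x time with `NA` for missing samples.
#' @param mask Optional logical matrix marking entries to (re-)impute;
#'   defaults to `is.na(x)`.
#' @param m Number of imputations (default 5).
#' @param ridge Ridge penalty (default 1e-3).
#' @param seed Integer seed.
#' @return List with `x` (imputed matrix), `mask`, `excluded` (channel
#'   indices) and `imputation_sd` (across-imputation SD averaged over entries).
#' @export
impute_missing <- function(x, mask = NULL, m = 5, ridge = 1e-3, seed = 1) {
  if (is.null(mask)) mask <- is.na(x)
  mask <- mask | is.na(x)  # an all-NA (excluded) channel must never be a donor
  if (!any(mask)) return(list(x = x, mask = mask, excluded = integer(0), imputation_sd = 0))
  set.seed(as.integer(seed))
  nch <- nrow(x)
  frac <- rowMeans(mask)
  excluded <- which(frac >= 0.5)
  donors <- which(frac == 0)
  out <- x
  sds <- c()
  for (i in setdiff(which(frac > 0), excluded)) {
    obs <- !mask[i, ]
    if (length(donors) == 0) {  # fall back to within-channel interpolation
      out[i, ] <- stats::approx(which(obs), x[i, obs], xout = seq_len(ncol(x)), rule = 2)$y
      next
    }
    X <- t(x[donors, , drop = FALSE])          # time x donors
    Xo <- X[obs, , drop = FALSE]; yo <- x[i, obs]
    Xm <- X[!obs, , drop = FALSE]
    mu <- colMeans(Xo); Xoc <- sweep(Xo, 2, mu); ymu <- mean(yo)
    A <- crossprod(Xoc) + ridge * sum(obs) * diag(ncol(Xoc))
    beta <- solve(A, crossprod(Xoc, yo - ymu))
    fit_obs <- Xoc %*% beta + ymu
    res_sd <- stats::sd(yo - fit_obs)
    pred <- sweep(Xm, 2, mu) %*% beta + ymu
    draws <- matrix(rep(pred, m), ncol = m) +
      matrix(stats::rnorm(length(pred) * m, 0, res_sd), ncol = m)
    out[i, !obs] <- rowMeans(draws)
    sds <- c(sds, mean(apply(draws, 1, stats::sd)))
  }
  if (length(excluded)) out[excluded, ] <- NA_real_
  list(x = out, mask = mask, excluded = excluded,
       imputation_sd = if (length(sds)) mean(sds) else 0)
}
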