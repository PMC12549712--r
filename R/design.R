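#' Block-design description of an fNIRS session
#'
#' Encodes the task paradigm used throughout the package: a pre-task window
#' followed by `n_cycles` repetitions of rest / task / rest, with any remaining
#' time spent at rest. The default is the 840 s pegboard paradigm: 10 s
#' pre-task, then seven cycles of 30 s rest, 30 s task, 50 s rest, leaving a
#' 60 s residual rest at the end of the session. `total_s` is authoritative:
#' the cycles must fit inside it, and the session length in samples is
#' `total_s * sampling_hz`.
#'
#' @param pre_task_s Pre-task (blank screen) duration in seconds.
#' @param rest_before_s Rest duration before each task phase, seconds.
#' @param task_s Task phase duration, seconds.
#' @param rest_after_s Rest duration after each task phase, seconds.
#' @param n_cycles Number of task-rest cycles.
#' @param total_s Total session duration in seconds.
#' @param sampling_hz Sampling rate in Hz; `total_s * sampling_hz` must be a
#'   whole number of samples.
#' @return An object of class `block_design`.
#' @examples
#' d <- block_design()
#' d$n_samples    # 84000 at the default 100 Hz
#' @export
block_design <- function(pre_task_s = 10, rest_before_s = 30, task_s = 30,
                         rest_after_s = 50, n_cycles = 7, total_s = 840,
                         sampling_hz = 100) {
  for (v in c(pre_task_s, rest_before_s, task_s, rest_after_s, total_s, sampling_hz))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("block_design: all durations and rates must be single non-negative numbers")
  if (task_s <= 0 || sampling_hz <= 0 || total_s <= 0)
    stop("block_design: task_s, total_s and sampling_hz must be positive")
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 1L) stop("block_design: n_cycles must be >= 1")
  cycle_s <- rest_before_s + task_s + rest_after_s
  residual_s <- total_s - pre_task_s - n_cycles * cycle_s
  if (residual_s < 0)
    stop("block_design: pre_task_s + n_cycles * cycle does not fit in total_s")
  n_samples <- total_s * sampling_hz
  if (abs(n_samples - round(n_samples)) > 1e-9)
    stop("block_design: total_s * sampling_hz must be an integer number of samples")
  structure(list(
    pre_task_s = pre_task_s, rest_before_s = rest_before_s, task_s = task_s,
    rest_after_s = rest_after_s, n_cycles = n_cycles, total_s = total_s,
    sampling_hz = sampling_hz, cycle_s = cycle_s, residual_s = residual_s,
    n_samples = as.integer(round(n_samples))
  ), class = "block_design")
}

#' @export
print.block_design <- function(x, ...) {
  cat(sprintf(
    "Block design: %gs pre-task + %d x (%g rest / %g task / %g rest) + %gs residual rest = %gs @ %g Hz (%d samples)\n",
    x$pre_task_s, x$n_cycles, x$rest_before_s, x$task_s, x$rest_after_s,
    x$residual_s, x$total_s, x$sampling_hz, x$n_samples))
  invisible(x)
}

#' Task indicator (boxcar) for a block design
#'
#' @param design A [block_design()].
#' @return Numeric vector of length `design$n_samples`, 1 during task phases.
#' @export
task_boxcar <- function(design) {
  stopifnot(inherits(design, "block_design"))
  fs <- design$sampling_hz
  x <- numeric(design$n_samples)
  for (k in seq_len(design$n_cycles)) {
    on_s <- design$pre_task_s + (k - 1) * design$cycle_s + design$rest_before_s
    i0 <- floor(on_s * fs) + 1L
    i1 <- min(floor((on_s + design$task_s) * fs), design$n_samples)
    if (i0 <= i1) x[i0:i1] <- 1
  }
  x
}

#' Phase labels for every sample of a block design
#'
#' @param design A [block_design()].
#' @return Character vector (`"pre"`, `"rest1"`, `"task"`, `"rest2"`,
#'   `"residual"`) of length `design$n_samples`.
#' @export
design_phases <- function(design) {
  stopifnot(inherits(design, "block_design"))
  fs <- design$sampling_hz
  ph <- rep("residual", design$n_samples)
  seg <- function(from_s, to_s) {
    i0 <- floor(from_s * fs) + 1L
    i1 <- min(floor(to_s * fs), design$n_samples)
    if (i0 <= i1) i0:i1 else integer(0)
  }
  ph[seg(0, design$pre_task_s)] <- "pre"
  for (k in seq_len(design$n_cycles)) {
    c0 <- design$pre_task_s + (k - 1) * design$cycle_s
    ph[seg(c0, c0 + design$rest_before_s)] <- "rest1"
    ph[seg(c0 + design$rest_before_s, c0 + design$rest_before_s + design$task_s)] <- "task"
    ph[seg(c0 + design$rest_before_s + design$task_s, c0 + design$cycle_s)] <- "rest2"
  }
  ph
}

#' Prefrontal 22-channel montage with anatomical regions
#'
#' The fixed montage used by the staging study design: 22 channels over the
#' prefrontal cortex, partitioned into left/right/medial frontal polar cortex
#' (L-FPC, R-FPC, mFPC), left/right dorsolateral prefrontal cortex (L-DLPFC,
#' R-DLPFC) and Brodmann area 8 (BA8), with 3 cm source-detector separation.
#'
#' @param source_detector_distance_cm Optode separation in cm.
#' @return A `channel_layout`: data frame with columns `channel` and `region`,
#'   ordered CH01..CH22, with the separation stored as an attribute.
#' @export
channel_layout <- function(source_detector_distance_cm = 3) {
  regions <- list(
    "L-FPC"   = c("CH01", "CH05", "CH06", "CH10"),
    "R-FPC"   = c("CH04", "CH08", "CH09", "CH13"),
    "mFPC"    = c("CH02", "CH03", "CH07", "CH11", "CH12", "CH16"),
    "L-DLPFC" = c("CH14", "CH15", "CH19"),
    "R-DLPFC" = c("CH17", "CH18", "CH22"),
    "BA8"     = c("CH20", "CH21")
  )
  channel <- sprintf("CH%02d", 1:22)
  region <- character(22)
  for (r in names(regions)) region[match(regions[[r]], channel)] <- r
  out <- data.frame(channel = channel, region = region, stringsAsFactors = FALSE)
  attr(out, "source_detector_distance_cm") <- source_detector_distance_cm
  attr(out, "region_levels") <- names(regions)
  class(out) <- c("channel_layout", "data.frame")
  out
}

#' @export
print.channel_layout <- function(x, ...) {
  cat(sprintf("22-channel prefrontal layout (%g cm separation)\n",
              attr(x, "source_detector_distance_cm")))
  for (r in attr(x, "region_levels"))
    cat(sprintf("  %-8s %s\n", r, paste(x$channel[x$region == r], collapse = " ")))
  invisible(x)
}

#' Canonical double-gamma haemodynamic response kernel
#'
#' Difference of two gamma densities with the main (positive) lobe peaking at
#' `peak_s` and the (negative) undershoot near `undershoot_s`, scaled so the
#' peak value is exactly 1. The positive-lobe scale is calibrated numerically
#' so that the peak of the combined kernel (not just of the first gamma) lands
#' on `peak_s`.
#'
#' @param peak_s Time of the main response peak, seconds (default 5.5, i.e.
#'   within the physiological 5-6 s range).
#' @param undershoot_s Time of the undershoot minimum, seconds.
#' @param sampling_hz Sampling rate of the kernel.
#' @param duration_s Kernel support in seconds.
#' @param undershoot_ratio Amplitude of the undershoot gamma relative to the
#'   main lobe before normalisation.
#' @return Numeric kernel of length `duration_s * sampling_hz + 1` with
#'   `max(kernel) == 1`; time axis attached as attribute `t`.
#' @export
fnirs_hrf <- function(peak_s = 5.5, undershoot_s = 15, sampling_hz = 100,
                      duration_s = 30, undershoot_ratio = 1 / 6) {
  if (!(peak_s > 0 && undershoot_s > peak_s))
    stop("fnirs_hrf: need 0 < peak_s < undershoot_s")
  if (sampling_hz <= 0 || duration_s <= 0)
    stop("fnirs_hrf: sampling_hz and duration_s must be positive")
  t <- seq(0, duration_s, by = 1 / sampling_hz)
  shape1 <- 6; shape2 <- 16
  scale2 <- undershoot_s / (shape2 - 1)
  scale1 <- peak_s / (shape1 - 1)
  kern <- function(s1) {
    dgamma(t, shape = shape1, scale = s1) -
      undershoot_ratio * dgamma(t, shape = shape2, scale = scale2)
  }
  # superposition shifts both extrema away from the gamma modes; re-centre
  # each by fixed-point iteration on its scale
  for (i in 1:8) {
    k <- kern(scale1)
    tmax <- t[which.max(k)]
    tmin <- t[which.min(k)]
    ok_peak <- abs(tmax - peak_s) < 0.25 / sampling_hz
    ok_under <- abs(tmin - undershoot_s) < max(0.25 / sampling_hz, 0.05)
    if (ok_peak && ok_under) break
    if (!ok_peak) scale1 <- scale1 * peak_s / tmax
    if (!ok_under) scale2 <- scale2 * undershoot_s / tmin
  }
  k <- kern(scale1)
  k <- k / max(k)
  attr(k, "t") <- t
  k
}
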