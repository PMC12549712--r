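#' Group-dependent task-evoked activation profile
#'
#' Describes, per class (HC, HY1, HY2) and anatomical region, the task-evoked
#' HbO amplitude, the response latency shift, and between-subject variability.
#' The defaults encode the physiological picture the classifier is meant to
#' exploit: H&Y stage 1 shows frontal-polar *hyper*activation (a compensatory
#' mechanism in early disease), while stage 2 shows an attenuated and delayed
#' response relative to healthy controls. Dorsolateral and BA8 channels carry
#' a weaker version of the same effect.
#'
#' @param fpc_amplitude_uM Named vector of frontal-polar HbO amplitudes (uM)
#'   per class, default `c(HC = 0.5, HY1 = 0.8, HY2 = 0.3)`.
#' @param nonfpc_fraction Fraction of the FPC amplitude carried by the
#'   non-frontal-polar regions (L/R-DLPFC, BA8); a single number, or a named
#'   per-class vector (a class-dependent spatial extent models compensatory
#'   recruitment of additional prefrontal territory).
#' @param latency_s Named vector of response latency shifts in seconds.
#' @param variability Between-subject amplitude coefficient of variation.
#' @param hbr_ratio HbR evoked amplitude as a fraction of HbO (typically
#'   negative; default -1/3).
#' @param channel_gain Optional multiplier per channel applied on top of the
#'   region amplitude; lets discriminative signal be confined to chosen
#'   channels. Either a named vector (CH01..CH22, shared by all classes) or
#'   a classes x channels matrix (rownames HC/HY1/HY2) for class-dependent
#'   spatial patterns such as lateralised compensation. Default: all 1.
#' @param task `"pegboard"` (full amplitudes) or `"gait_imagery"` (the pilot
#'   task; amplitudes scaled by `gait_fraction`).
#' @param gait_fraction Amplitude scale of the gait-imagery task relative to
#'   the pegboard task (default 0.6; the pilot task is assumed weaker).
#' @return An object of class `effect_profile`: list with an `amplitude`
#'   matrix (class x region, uM), `latency_s`, `variability`, `hbr_ratio`,
#'   `channel_gain`.
#' @export
group_effect_profile <- function(fpc_amplitude_uM = c(HC = 0.5, HY1 = 0.8, HY2 = 0.3),
                                 nonfpc_fraction = 0.4,
                                 latency_s = c(HC = 0, HY1 = 0, HY2 = 2),
                                 variability = 0.15,
                                 hbr_ratio = -1 / 3,
                                 channel_gain = NULL,
                                 task = c("pegboard", "gait_imagery"),
                                 gait_fraction = 0.6) {
  task <- match.arg(task)
  classes <- c("HC", "HY1", "HY2")
  if (!all(classes %in% names(fpc_amplitude_uM)))
    stop("group_effect_profile: fpc_amplitude_uM must name HC, HY1 and HY2")
  if (!all(is.finite(fpc_amplitude_uM))) stop("amplitudes must be finite")
  if (variability < 0) stop("variability must be >= 0")
  regions <- attr(channel_layout(), "region_levels")
  if (length(nonfpc_fraction) == 1L)
    nonfpc_fraction <- stats::setNames(rep(nonfpc_fraction, 3), classes)
  if (!all(classes %in% names(nonfpc_fraction)))
    stop("group_effect_profile: per-class nonfpc_fraction must name all classes")
  amp <- matrix(0, 3, length(regions), dimnames = list(classes, regions))
  for (cl in classes) {
    a <- fpc_amplitude_uM[[cl]] * if (task == "gait_imagery") gait_fraction else 1
    amp[cl, c("L-FPC", "R-FPC", "mFPC")] <- a
    amp[cl, c("L-DLPFC", "R-DLPFC", "BA8")] <- a * nonfpc_fraction[[cl]]
  }
  ch <- sprintf("CH%02d", 1:22)
  gain <- matrix(1, 3, 22, dimnames = list(classes, ch))
  if (!is.null(channel_gain)) {
    if (is.matrix(channel_gain)) {
      if (!all(classes %in% rownames(channel_gain)) ||
          !all(colnames(channel_gain) %in% ch))
        stop("channel_gain matrix needs class rownames and CHxx colnames")
      gain[rownames(channel_gain), colnames(channel_gain)] <- channel_gain
    } else {
      if (is.null(names(channel_gain)) || !all(names(channel_gain) %in% ch))
        stop("channel_gain must be named with channel ids CH01..CH22")
      gain[, names(channel_gain)] <- rep(channel_gain, each = 3)
    }
  }
  structure(list(amplitude = amp, latency_s = latency_s[classes],
                 variability = variability, hbr_ratio = hbr_ratio,
                 channel_gain = gain, task = task),
            class = "effect_profile")
}

#' Physiological and instrumental noise profile
#'
#' Amplitudes of the standard fNIRS nuisance components, in concentration
#' units (uM) unless noted: cardiac (~1.1 Hz), respiratory (~0.25 Hz) and
#' Mayer-wave (~0.1 Hz) oscillations, random-walk drift, white sensor noise,
#' motion-spike transients (added in optical-density space as exponential
#' decays), occasional flatlined channels and missing samples. `scale`
#' multiplies every amplitude/rate at once (`scale = 0` gives a noiseless,
#' artifact-free recording).
#'
#' @param cardiac_hz,cardiac_amp Cardiac frequency (Hz) and amplitude (uM).
#' @param resp_hz,resp_amp Respiratory component.
#' @param mayer_hz,mayer_amp Mayer-wave component.
#' @param white_sd White noise standard deviation (uM).
#' @param drift_scale Random-walk drift scale (uM per sqrt(second)).
#' @param motion_rate_per_min Motion spike rate (events/minute).
#' @param motion_amp Motion spike amplitude in OD units.
#' @param motion_tau_s Exponential decay constant of motion transients (s).
#' @param bad_channel_prob Probability a channel is flatlined (poor coupling).
#' @param missing_prob Per-sample probability of a missing (dropped) sample.
#' @param scale Global multiplier applied to every amplitude, rate and
#'   probability above.
#' @return An object of class `noise_profile`.
#' @export
noise_profile <- function(cardiac_hz = 1.1, cardiac_amp = 0.08,
                          resp_hz = 0.25, resp_amp = 0.05,
                          mayer_hz = 0.1, mayer_amp = 0.06,
                          white_sd = 0.05, drift_scale = 0.01,
                          motion_rate_per_min = 0.5, motion_amp = 0.05,
                          motion_tau_s = 1.5,
                          bad_channel_prob = 0.02, missing_prob = 0.001,
                          scale = 1) {
  vals <- list(cardiac_hz = cardiac_hz, cardiac_amp = cardiac_amp * scale,
               resp_hz = resp_hz, resp_amp = resp_amp * scale,
               mayer_hz = mayer_hz, mayer_amp = mayer_amp * scale,
               white_sd = white_sd * scale, drift_scale = drift_scale * scale,
               motion_rate_per_min = motion_rate_per_min * scale,
               motion_amp = motion_amp * scale, motion_tau_s = motion_tau_s,
               bad_channel_prob = bad_channel_prob * scale,
               missing_prob = missing_prob * scale)
  if (any(unlist(vals) < 0)) stop("noise_profile: rates and amplitudes must be >= 0")
  structure(vals, class = "noise_profile")
}

# Block response: task boxcar (optionally delayed) convolved with the HRF,
# normalised so a sustained block plateaus at 1.
.block_response <- function(design, hrf, latency_s = 0) {
  box <- task_boxcar(design)
  shift <- round(latency_s * design$sampling_hz)
  if (shift > 0) box <- c(numeric(shift), box[seq_len(length(box) - shift)])
  full <- stats::convolve(box, rev(hrf), type = "open")
  r <- full[seq_along(box)]
  r / max(cumsum(hrf))
}

#' Simulate one subject's dual-wavelength optical recording
#'
#' Builds per-channel HbO/HbR concentration series as the block response
#' (task boxcar convolved with the double-gamma HRF) scaled by the subject's
#' class- and region-specific amplitude, adds physiological noise, and
#' forward-projects to strictly positive dual-wavelength light intensity via
#' the same modified Beer-Lambert model the preprocessing chain inverts.
#' Motion transients are applied in optical-density space; flatlined channels
#' and missing samples are injected per the noise profile. Fully deterministic
#' given `seed`.
#'
#' @param label Class label: `"HC"`, `"HY1"` or `"HY2"`.
#' @param design A [block_design()].
#' @param layout A [channel_layout()].
#' @param effects A [group_effect_profile()].
#' @param noise A [noise_profile()].
#' @param seed Integer seed.
#' @param subject_id Optional id string.
#' @param dpf,baseline_intensity Beer-Lambert forward parameters (DPF 6.0;
#'   baseline intensity 1 arbitrary unit per wavelength).
#' @return An object of class `fnirs_subject`: list with `intensity`
#'   (channels x time x 2), `wavelengths_nm`, `sampling_hz`, `layout`,
#'   `design`, `label`, and a `ground_truth` list (injected per-channel
#'   amplitudes, latency, bad channels, missing mask) for test oracles only.
#' @export
simulate_subject <- function(label, design = block_design(),
                             layout = channel_layout(),
                             effects = group_effect_profile(),
                             noise = noise_profile(), seed = 1,
                             subject_id = NULL, dpf = 6.0,
                             baseline_intensity = 1.0) {
  label <- match.arg(label, c("HC", "HY1", "HY2"))
  stopifnot(inherits(design, "block_design"), inherits(layout, "channel_layout"),
            inherits(effects, "effect_profile"), inherits(noise, "noise_profile"))
  set.seed(as.integer(seed))
  fs <- design$sampling_hz
  n <- design$n_samples
  nch <- nrow(layout)
  dist_cm <- attr(layout, "source_detector_distance_cm")
  tt <- seq_len(n) / fs

  hrf <- fnirs_hrf(sampling_hz = fs)
  resp <- .block_response(design, hrf, effects$latency_s[[label]])

  base_amp <- effects$amplitude[label, layout$region] *
    effects$channel_gain[label, layout$channel]
  subj_mult <- max(0, 1 + effects$variability * rnorm(1))
  ch_mult <- pmax(0, 1 + (effects$variability / 2) * rnorm(nch))
  amp <- base_amp * subj_mult * ch_mult

  osc <- function(f, a) {
    if (a <= 0 || f >= 0.45 * fs) return(matrix(0, nch, n))  # skip above Nyquist margin
    ph <- runif(nch, 0, 2 * pi)
    aj <- a * (0.8 + 0.4 * runif(nch))
    t(vapply(seq_len(nch), function(i) aj[i] * sin(2 * pi * f * tt + ph[i]),
             numeric(n)))
  }
  wdrift <- function(sd_white) {
    w <- if (sd_white > 0) matrix(rnorm(nch * n, 0, sd_white), nch, n) else matrix(0, nch, n)
    d <- if (noise$drift_scale > 0)
      t(apply(matrix(rnorm(nch * n, 0, noise$drift_scale / sqrt(fs)), nch, n), 1, cumsum))
    else matrix(0, nch, n)
    w + d
  }
  # the pulsatile components ride on blood volume, hence are shared (in
  # phase) between chromophores; sensor white noise and drift are not
  osc_all <- osc(noise$cardiac_hz, noise$cardiac_amp) +
    osc(noise$resp_hz, noise$resp_amp) +
    osc(noise$mayer_hz, noise$mayer_amp)

  evoked <- outer(amp, resp)                       # channels x time, uM
  hbo <- evoked + wdrift(noise$white_sd) + osc_all
  hbr <- effects$hbr_ratio * evoked + 0.4 * (wdrift(noise$white_sd) + osc_all)

  # motion transients, shared event times across channels (head movement)
  motion <- matrix(0, nch, n)
  n_events <- if (noise$motion_rate_per_min > 0)
    rpois(1, noise$motion_rate_per_min * design$total_s / 60) else 0L
  if (n_events > 0) {
    times <- sort(sample.int(n - 1L, n_events, replace = FALSE))
    decay <- exp(-(0:ceiling(5 * noise$motion_tau_s * fs)) / (noise$motion_tau_s * fs))
    for (ev in times) {
      a_ch <- noise$motion_amp * (0.5 + rexp(nch)) * sample(c(-1, 1), nch, replace = TRUE)
      idx <- ev:min(n, ev + length(decay) - 1L)
      motion[, idx] <- motion[, idx] + outer(a_ch, decay[seq_along(idx)])
    }
  }

  bad <- runif(nch) < noise$bad_channel_prob
  intensity <- array(NA_real_, c(nch, n, 2),
                     dimnames = list(layout$channel, NULL, c("w695", "w830")))
  for (i in seq_len(nch)) {
    od <- .hemo_to_od(hbo[i, ], hbr[i, ], dpf = dpf, distance_cm = dist_cm)
    od <- od + motion[i, ]
    intensity[i, , 1] <- baseline_intensity * 10^(-od[, 1])
    intensity[i, , 2] <- baseline_intensity * 10^(-od[, 2])
    if (bad[i]) {  # flatlined optode: no physiology, tiny instrument jitter
      flat <- baseline_intensity * (1 + 1e-4 * rnorm(n))
      intensity[i, , 1] <- flat
      intensity[i, , 2] <- baseline_intensity * (1 + 1e-4 * rnorm(n))
    }
  }
  missing <- matrix(runif(nch * n) < noise$missing_prob, nch, n)
  if (any(missing)) for (w in 1:2) { tmp <- intensity[, , w]; tmp[missing] <- NA_real_; intensity[, , w] <- tmp }

  structure(list(
    subject_id = if (is.null(subject_id)) sprintf("S_%s_%d", label, seed) else subject_id,
    label = label,
    intensity = intensity,
    wavelengths_nm = c(695, 830),
    sampling_hz = fs,
    layout = layout,
    design = design,
    dpf = dpf,
    ground_truth = list(amplitude_uM = stats::setNames(amp, layout$channel),
                        latency_s = effects$latency_s[[label]],
                        bad_channels = layout$channel[bad],
                        missing = missing,
                        hbo = hbo, hbr = hbr)
  ), class = "fnirs_subject")
}

#' @export
print.fnirs_subject <- function(x, ...) {
  cat(sprintf("fNIRS subject %s [%s]: %d channels x %d samples @ %g Hz, 2 wavelengths\n",
              x$subject_id, x$label, dim(x$intensity)[1], dim(x$intensity)[2],
              x$sampling_hz))
  invisible(x)
}

#' Simulate a balanced multi-subject cohort
#'
#' Generates `n_per_class` subjects for each of HC, HY1 and HY2 under a shared
#' design, layout, effect and noise profile. The gait-imagery task uses the
#' same block design with a weaker effect profile. Per-subject seeds are drawn
#' reproducibly from the master seed, so cohorts are bit-identical across runs.
#'
#' @param n_per_class Subjects per class (>= 1).
#' @param task `"pegboard"` or `"gait_imagery"`.
#' @param design,layout,noise See [simulate_subject()].
#' @param effects Effect profile; default is [group_effect_profile()] for the
#'   chosen task.
#' @param seed Master seed.
#' @return An object of class `fnirs_cohort`: list of `fnirs_subject`s plus
#'   `labels` (factor HC/HY1/HY2), `design`, `layout`, `task`.
#' @export
simulate_cohort <- function(n_per_class, task = c("pegboard", "gait_imagery"),
                            design = block_design(), layout = channel_layout(),
                            effects = NULL, noise = noise_profile(), seed = 1) {
  task <- match.arg(task)
  n_per_class <- as.integer(n_per_class)
  if (n_per_class < 1L) stop("simulate_cohort: n_per_class must be >= 1")
  if (is.null(effects)) effects <- group_effect_profile(task = task)
  classes <- c("HC", "HY1", "HY2")
  labels <- factor(rep(classes, each = n_per_class), levels = classes)
  n <- length(labels)
  set.seed(as.integer(seed))
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    subjects[[i]] <- simulate_subject(
      as.character(labels[i]), design = design, layout = layout,
      effects = effects, noise = noise, seed = subject_seeds[i],
      subject_id = sprintf("S%03d", i))
  }
  structure(list(subjects = subjects, labels = labels, design = design,
                 layout = layout, task = task, seed = seed),
            class = "fnirs_cohort")
}

#' @export
print.fnirs_cohort <- function(x, ...) {
  cat(sprintf("fNIRS cohort: %d subjects (%s), task %s, %d channels, %g s @ %g Hz\n",
              length(x$subjects), paste(table(x$labels), collapse = "/"),
              x$task, nrow(x$layout), x$design$total_s, x$design$sampling_hz))
  invisible(x)
}

#' Write / read a cohort in the flat CSV dialect
#'
#' One CSV per subject with 44 intensity columns (`CH01_w695` ... `CH22_w830`),
#' a `labels.csv` (subject_id, label) and a `meta.json` holding the design and
#' sampling information. Missing samples are empty fields.
#'
#' @param cohort An `fnirs_cohort`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort_csv` returns `dir` invisibly; `read_cohort_csv`
#'   returns an `fnirs_cohort` (without ground-truth fields).
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fnirs_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- cohort$design
  meta <- list(pre_task_s = d$pre_task_s, rest_before_s = d$rest_before_s,
               task_s = d$task_s, rest_after_s = d$rest_after_s,
               n_cycles = d$n_cycles, total_s = d$total_s,
               sampling_hz = d$sampling_hz, task = cohort$task,
               wavelengths_nm = c(695, 830))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  ids <- vapply(cohort$subjects, `[[`, "", "subject_id")
  utils::write.csv(data.frame(subject_id = ids, label = as.character(cohort$labels)),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  for (s in cohort$subjects) {
    m <- cbind(t(s$intensity[, , 1]), t(s$intensity[, , 2]))
    colnames(m) <- c(paste0(s$layout$channel, "_w695"), paste0(s$layout$channel, "_w830"))
    utils::write.csv(m, file.path(dir, paste0(s$subject_id, ".csv")), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  design <- block_design(meta$pre_task_s, meta$rest_before_s, meta$task_s,
                         meta$rest_after_s, meta$n_cycles, meta$total_s,
                         meta$sampling_hz)
  layout <- channel_layout()
  lab <- utils::read.csv(file.path(dir, "labels.csv"), stringsAsFactors = FALSE)
  subjects <- vector("list", nrow(lab))
  for (i in seq_len(nrow(lab))) {
    m <- as.matrix(utils::read.csv(file.path(dir, paste0(lab$subject_id[i], ".csv"))))
    nch <- nrow(layout)
    intensity <- array(NA_real_, c(nch, nrow(m), 2),
                       dimnames = list(layout$channel, NULL, c("w695", "w830")))
    intensity[, , 1] <- t(m[, seq_len(nch), drop = FALSE])
    intensity[, , 2] <- t(m[, nch + seq_len(nch), drop = FALSE])
    subjects[[i]] <- structure(list(
      subject_id = lab$subject_id[i], label = lab$label[i], intensity = intensity,
      wavelengths_nm = meta$wavelengths_nm, sampling_hz = design$sampling_hz,
      layout = layout, design = design, dpf = 6.0, ground_truth = NULL),
      class = "fnirs_subject")
  }
  structure(list(subjects = subjects,
                 labels = factor(lab$label, levels = c("HC", "HY1", "HY2")),
                 design = design, layout = layout, task = meta$task, seed = NA),
            class = "fnirs_cohort")
}
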