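# From a simulated or imported cohort to the N x 22 x T model-ready tensor.

# Quality gating of one subject from raw intensity. Returns per-channel scores.
.channel_quality <- function(subject, sqi_threshold = 2.5, sci_threshold = 0.5) {
  nch <- dim(subject$intensity)[1]
  sci <- sqi <- numeric(nch)
  for (i in seq_len(nch)) {
    w1 <- subject$intensity[i, , 1]; w2 <- subject$intensity[i, , 2]
    w1[!is.finite(w1)] <- mean(w1, na.rm = TRUE)
    w2[!is.finite(w2)] <- mean(w2, na.rm = TRUE)
    s <- scalp_coupling_index(w1, w2, subject$sampling_hz)
    sci[i] <- if (is.na(s)) NA_real_ else as.numeric(s)
    sqi[i] <- as.numeric(signal_quality_index(w1, subject$sampling_hz))
  }
  resolved <- !is.na(sci)
  excluded <- (sqi < sqi_threshold) | (resolved & sci < sci_threshold)
  data.frame(channel = subject$layout$channel, sqi = sqi, sci = sci,
             excluded = excluded,
             reason = ifelse(!excluded, "",
                             ifelse(sqi < sqi_threshold & (!resolved | sci >= sci_threshold),
                                    "sqi", ifelse(sqi >= sqi_threshold, "sci", "sqi+sci"))))
}

# Block-mean decimation of a channels x time matrix to target_hz.
.decimate <- function(x, sampling_hz, target_hz) {
  fac <- sampling_hz / target_hz
  if (abs(fac - round(fac)) > 1e-9)
    stop("decimation requires an integer rate ratio")
  fac <- as.integer(round(fac))
  if (fac == 1L) return(x)
  nt <- floor(ncol(x) / fac)
  grp <- rep(seq_len(nt), each = fac)
  t(vapply(seq_len(nrow(x)), function(i)
    as.numeric(tapply(x[i, seq_len(nt * fac)], grp, mean)), numeric(nt)))
}

#' Run the full preprocessing chain and assemble the dataset tensor
#'
#' Applies, per subject: optical-density conversion (pre-task reference
#' window), TDDR, hybrid spline/wavelet correction, SQI/SCI channel quality
#' gating, zero-phase Butterworth low-pass (0.1 Hz), modified Beer-Lambert
#' inversion, pre-task baseline correction, Savitzky-Golay smoothing, optional
#' block-mean decimation to `target_hz`, IQR winsorisation, chained-ridge
#' multiple imputation of missing samples and channel-wise Z-scoring; then
#' stacks subjects into an `N x channels x time` array. Channels failing
#' quality gating are excluded from all computation (including imputation
#' regressors) and re-filled after normalisation with the cross-subject
#' channel mean so the model input width stays fixed; the exclusion mask is
#' kept alongside the data. Subjects failing more than 50% of channels are
#' dropped with a provenance entry.
#'
#' @param cohort An `fnirs_cohort`.
#' @param chromophore `"hbo"`, `"hbr"` or `"hbt"`.
#' @param target_hz Output sampling rate (`NULL` keeps the native rate); must
#'   divide the native rate.
#' @param zscore Apply the final Z-score step (default `TRUE`).
#' @param quality_gate Apply SQI/SCI channel exclusion (default `TRUE`).
#' @param tddr,motion_hybrid,lowpass,savgol,iqr Logical toggles for the
#'   corresponding steps (all `TRUE` by default).
#' @param sqi_threshold,sci_threshold Exclusion thresholds (2.5 and 0.5).
#' @param seed Seed for the imputation draws.
#' @return An object of class `fnirs_dataset`: list with `data`
#'   (N x channels x time), `labels`, `channel_ids`, `excluded`
#'   (N x channels logical), `provenance` (character), `sampling_hz`,
#'   `design`, `layout`, `subject_ids`.
#' @export
build_dataset <- function(cohort, chromophore = c("hbo", "hbr", "hbt"),
                          target_hz = NULL, zscore = TRUE, quality_gate = TRUE,
                          tddr = TRUE, motion_hybrid = TRUE, lowpass = TRUE,
                          savgol = TRUE, iqr = TRUE,
                          sqi_threshold = 2.5, sci_threshold = 0.5, seed = 1) {
  stopifnot(inherits(cohort, "fnirs_cohort"))
  chromophore <- match.arg(chromophore)
  design <- cohort$design
  fs <- design$sampling_hz
  out_hz <- if (is.null(target_hz)) fs else target_hz
  nt_out <- as.integer(round(design$total_s * out_hz))
  nsub <- length(cohort$subjects)
  nch <- nrow(cohort$layout)
  prov <- c("od")
  if (tddr) prov <- c(prov, "tddr")
  if (motion_hybrid) prov <- c(prov, "motion_hybrid")
  if (quality_gate) prov <- c(prov, "quality")
  if (lowpass) prov <- c(prov, "butter")
  prov <- c(prov, "mbll", "baseline")
  if (savgol) prov <- c(prov, "savgol")
  if (out_hz != fs) prov <- c(prov, sprintf("decimate_%ghz", out_hz))
  if (iqr) prov <- c(prov, "iqr")
  prov <- c(prov, "impute")
  if (zscore) prov <- c(prov, "zscore")

  data <- array(NA_real_, c(nsub, nch, nt_out))
  excluded <- matrix(FALSE, nsub, nch)
  keep <- rep(TRUE, nsub)
  notes <- character(0)
  ref <- seq_len(round(design$pre_task_s * fs))

  for (s in seq_len(nsub)) {
    subj <- cohort$subjects[[s]]
    miss <- !is.finite(subj$intensity[, , 1]) | !is.finite(subj$intensity[, , 2])

    qual <- if (quality_gate)
      .channel_quality(subj, sqi_threshold, sci_threshold)
    else data.frame(excluded = rep(FALSE, nch))
    excl <- qual$excluded
    if (mean(excl) > 0.5) {
      keep[s] <- FALSE
      notes <- c(notes, sprintf("dropped %s: %d/%d channels failed quality",
                                subj$subject_id, sum(excl), nch))
      next
    }
    excluded[s, ] <- excl

    od <- intensity_to_od(subj$intensity, reference_window = ref)
    # bridge missing samples so the filters stay defined; re-imputed later
    for (i in seq_len(nch)) for (w in 1:2) {
      v <- od[i, , w]
      if (anyNA(v)) {
        ok <- which(is.finite(v))
        if (length(ok) < 2) { v[] <- 0 } else
          v <- stats::approx(ok, v[ok], xout = seq_along(v), rule = 2)$y
        od[i, , w] <- v
      }
    }
    for (i in which(!excl)) for (w in 1:2) {
      v <- od[i, , w]
      if (tddr) v <- tddr_correct(v, sampling_hz = fs)
      if (motion_hybrid) v <- spline_wavelet_correct(v, sampling_hz = fs)
      if (lowpass) v <- butter_lowpass(v, 0.1, fs)
      od[i, , w] <- v
    }
    conc <- beer_lambert_invert(od, dpf = subj$dpf,
                                distance_cm = attr(subj$layout, "source_detector_distance_cm"))
    x <- conc[, , chromophore]
    for (i in which(!excl)) {
      v <- baseline_correct(x[i, ], design)
      if (savgol) v <- savgol_smooth(v)
      x[i, ] <- v
    }
    if (out_hz != fs) x <- .decimate(x, fs, out_hz)
    miss_out <- if (out_hz != fs) {
      fac <- as.integer(round(fs / out_hz))
      nt <- floor(ncol(miss) / fac)
      m <- matrix(FALSE, nch, ncol(x))
      for (i in seq_len(nch)) m[i, seq_len(nt)] <-
          tapply(miss[i, seq_len(nt * fac)], rep(seq_len(nt), each = fac), any)
      m
    } else miss
    x[excl, ] <- NA_real_  # excluded channels carry no signal downstream
    if (iqr) {
      r <- iqr_outlier_clip(x[!excl, , drop = FALSE])
      x[!excl, ] <- r$x
    }
    if (any(miss_out[!excl, ])) {
      m2 <- miss_out; m2[excl, ] <- FALSE
      r <- impute_missing(x, mask = m2, seed = seed + s)
      x <- r$x
      x[union(which(excl), r$excluded), ] <- NA_real_
      excluded[s, r$excluded] <- TRUE
    }
    if (zscore) {
      z <- zscore_channels(x[!excl, , drop = FALSE])
      attr(z, "constant_channels") <- NULL
      x[!excl, ] <- z
    }
    data[s, , ] <- x[, seq_len(nt_out)]
  }

  data <- data[keep, , , drop = FALSE]
  excluded <- excluded[keep, , drop = FALSE]
  labels <- cohort$labels[keep]
  # fixed input width: refill excluded channels with the cross-subject mean
  for (i in seq_len(nch)) {
    bad <- excluded[, i] | apply(data[, i, , drop = FALSE], 1, function(v) anyNA(v))
    if (any(bad)) {
      fill <- if (all(bad)) rep(0, dim(data)[3]) else
        apply(data[!bad, i, , drop = FALSE], 3, mean)
      for (s in which(bad)) data[s, i, ] <- fill
      excluded[bad, i] <- TRUE
    }
  }
  structure(list(data = data, labels = labels,
                 channel_ids = cohort$layout$channel,
                 excluded = excluded, provenance = prov,
                 notes = notes, sampling_hz = out_hz, design = design,
                 layout = cohort$layout,
                 subject_ids = vapply(cohort$subjects[keep], `[[`, "", "subject_id"),
                 chromophore = chromophore, zscored = zscore),
            class = "fnirs_dataset")
}

#' @export
print.fnirs_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("fNIRS dataset: %d x %d x %d (%s, %g Hz)%s\n", d[1], d[2], d[3],
              x$chromophore, x$sampling_hz,
              if (x$zscored) ", z-scored" else ""))
  cat("  labels:", paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                         collapse = " "), "\n")
  cat("  chain:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Subset a dataset by subject indices
#'
#' @param dataset An `fnirs_dataset`.
#' @param idx Integer subject indices.
#' @return An `fnirs_dataset` restricted to those subjects.
#' @export
dataset_subset <- function(dataset, idx) {
  stopifnot(inherits(dataset, "fnirs_dataset"))
  out <- dataset
  out$data <- dataset$data[idx, , , drop = FALSE]
  out$labels <- dataset$labels[idx]
  out$excluded <- dataset$excluded[idx, , drop = FALSE]
  out$subject_ids <- dataset$subject_ids[idx]
  out
}
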