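zero_noise <- function() noise_profile(scale = 0)
fixed_effects <- function() group_effect_profile(variability = 0)

test_that("a default-design subject has 84,000 samples per channel", {
  s <- fixture("subject_100hz", function()
    simulate_subject("HC", design = block_design(), noise = zero_noise(),
                     effects = fixed_effects(), seed = 3))
  expect_equal(dim(s$intensity), c(22, 84000, 2))
})

test_that("zero amplitudes and zero noise give constant baseline intensity", {
  eff <- group_effect_profile(fpc_amplitude_uM = c(HC = 0, HY1 = 0, HY2 = 0),
                              variability = 0)
  s <- simulate_subject("HC", design = block_design(sampling_hz = 2),
                        effects = eff, noise = zero_noise(), seed = 1)
  expect_true(all(abs(s$intensity - 1.0) < 1e-12))
})

test_that("identical seeds give bit-identical recordings", {
  d <- block_design(sampling_hz = 2)
  a <- simulate_subject("HY1", design = d, seed = 7)
  b <- simulate_subject("HY1", design = d, seed = 7)
  expect_identical(a$intensity, b$intensity)
  expect_false(identical(
    a$intensity, simulate_subject("HY1", design = d, seed = 8)$intensity))
})

test_that("noiseless block-mean difference equals amplitude times the HRF gain", {
  d <- block_design(sampling_hz = 2)
  s <- simulate_subject("HY1", design = d, noise = zero_noise(),
                        effects = fixed_effects(), seed = 1)
  # independent oracle: direct O(n k) convolution of the boxcar with the
  # kernel (the generator itself goes through an FFT convolution)
  k <- fnirs_hrf(sampling_hz = 2)
  box <- task_boxcar(d)
  n <- length(box)
  conv <- numeric(n)
  for (t in seq_len(n)) {
    jmax <- min(t, length(k))
    conv[t] <- sum(box[t - seq_len(jmax) + 1] * k[seq_len(jmax)])
  }
  conv <- conv / max(cumsum(k))
  task <- box == 1
  gain <- mean(conv[task]) - mean(conv[!task])
  for (ch in c(1, 4, 14)) {
    amp <- unname(s$ground_truth$amplitude_uM[ch])
    hbo <- s$ground_truth$hbo[ch, ]
    measured <- mean(hbo[task]) - mean(hbo[!task])
    expect_equal(measured, amp * gain, tolerance = 1e-9)
  }
})

test_that("forward projection inverts exactly through the Beer-Lambert model", {
  d <- block_design(sampling_hz = 2)
  s <- simulate_subject("HY2", design = d, noise = zero_noise(),
                        effects = fixed_effects(), seed = 5)
  od <- intensity_to_od(s$intensity,
                        reference_window = seq_len(10 * d$sampling_hz))
  conc <- beer_lambert_invert(od)
  expect_lt(max(abs(conc[, , "hbo"] - s$ground_truth$hbo)), 1e-6)
  expect_lt(max(abs(conc[, , "hbr"] - s$ground_truth$hbr)), 1e-6)
})

test_that("cohorts are balanced, sized and deterministic", {
  d <- block_design(sampling_hz = 1)
  co <- simulate_cohort(3, design = d, seed = 11)
  expect_equal(length(co$subjects), 9)
  expect_equal(as.numeric(table(co$labels)), c(3, 3, 3))
  co2 <- simulate_cohort(3, design = d, seed = 11)
  expect_identical(co$subjects[[5]]$intensity, co2$subjects[[5]]$intensity)
  expect_error(simulate_cohort(0), "n_per_class")
  expect_error(simulate_cohort(2, task = "tapping"), "arg")
})

test_that("class labels are recoverable from noiseless block means", {
  d <- block_design(sampling_hz = 1)
  co <- simulate_cohort(1, design = d, noise = zero_noise(),
                        effects = fixed_effects(), seed = 2)
  box <- task_boxcar(d) == 1
  diffs <- vapply(co$subjects, function(s) {
    m <- s$ground_truth$hbo[1, ]   # CH01, frontal polar
    mean(m[box]) - mean(m[!box])
  }, numeric(1))
  names(diffs) <- as.character(co$labels)
  # stage 1 hyperactivation > control > attenuated stage 2
  expect_gt(diffs[["HY1"]], diffs[["HC"]])
  expect_gt(diffs[["HC"]], diffs[["HY2"]])
})

test_that("gait-imagery task scales the effect profile down", {
  peg <- group_effect_profile(task = "pegboard")
  gait <- group_effect_profile(task = "gait_imagery")
  expect_equal(gait$amplitude, 0.6 * peg$amplitude)
})

test_that("the CSV dialect round-trips a cohort", {
  d <- block_design(sampling_hz = 1)
  co <- simulate_cohort(1, design = d, seed = 4)
  dir <- withr::local_tempdir()
  write_cohort_csv(co, dir)
  expect_true(file.exists(file.path(dir, "labels.csv")))
  back <- read_cohort_csv(dir)
  expect_equal(length(back$subjects), 3)
  expect_equal(back$labels, co$labels)
  expect_equal(back$subjects[[2]]$intensity, co$subjects[[2]]$intensity,
               tolerance = 1e-9)
  expect_equal(back$design$n_samples, d$n_samples)
})

test_that("class separation grows with the configured amplitude gap", {
  # a wider frontal-polar amplitude gap never hurts a simple block-mean
  # classifier (checked over a small seed grid at 1 Hz)
  d <- block_design(sampling_hz = 1)
  box <- task_boxcar(d) == 1
  acc_for <- function(gap_scale, seed) {
    amp <- c(HC = 0.5, HY1 = 0.5 + 0.4 * gap_scale, HY2 = max(0.5 - 0.35 * gap_scale, 0.05))
    eff <- group_effect_profile(fpc_amplitude_uM = amp, variability = 0.1)
    co <- simulate_cohort(4, design = d, effects = eff,
                          noise = noise_profile(scale = 0.5), seed = seed)
    feat <- vapply(co$subjects, function(s) {
      hbo <- s$ground_truth$hbo[c(1, 4, 5, 8), ]
      mean(hbo[, box]) - mean(hbo[, !box])
    }, numeric(1))
    centers <- tapply(feat, co$labels, mean)
    pred <- names(centers)[apply(abs(outer(feat, centers, "-")), 1, which.min)]
    mean(pred == as.character(co$labels))
  }
  for (seed in 1:3) {
    weak <- acc_for(0.3, seed)
    strong <- acc_for(1.0, seed)
    expect_gte(strong, weak)
  }
})
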