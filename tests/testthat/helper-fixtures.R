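# Shared fixtures, memoised across test files within a run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# The learnability condition: strong frontal-polar effect gap, 60 subjects,
# simulated at 10 Hz and decimated to 1 Hz sequences. Channel-wise
# standardisation is scale-invariant, so class structure is carried by
# effective SNR (wide amplitude ratio), response latency (delayed stage 2)
# and spatial extent (stage-1 compensatory recruitment of extra prefrontal
# territory) rather than raw amplitude.
high_snr_effects <- function(channel_gain = NULL) {
  group_effect_profile(fpc_amplitude_uM = c(HC = 0.4, HY1 = 1.0, HY2 = 0.15),
                       nonfpc_fraction = c(HC = 0.3, HY1 = 0.8, HY2 = 0.3),
                       latency_s = c(HC = 0, HY1 = 0, HY2 = 4),
                       variability = 0.10, channel_gain = channel_gain)
}

high_snr_dataset <- function() {
  fixture("high_snr_dataset", function() {
    cohort <- simulate_cohort(20, design = block_design(sampling_hz = 10),
                              effects = high_snr_effects(), seed = 2026)
    build_dataset(cohort, chromophore = "hbo", target_hz = 1, seed = 1)
  })
}

# A disjoint-seed cohort from the same conditions, used as the held-out test
# set for the learnability and robustness checks (45 subjects keeps the
# binomial noise of the accuracy estimate below ~6%).
high_snr_testset <- function() {
  fixture("high_snr_testset", function() {
    cohort <- simulate_cohort(15, design = block_design(sampling_hz = 10),
                              effects = high_snr_effects(), seed = 9001)
    build_dataset(cohort, chromophore = "hbo", target_hz = 1, seed = 1)
  })
}

# Compact hybrid spec used for the synthetic-cohort fits: the full-width
# model of the clinical protocol is unnecessary for 60 subjects and would
# dominate the suite's runtime.
small_atlas_spec <- function(epochs = 45, patience = 15) {
  model_spec("atlas", d_model = 16, n_heads = 2, n_transformer_layers = 1,
             lstm_hidden = 16, dropout = c(0.3, 0.4), learning_rate = 2e-3,
             epochs = epochs, batch_size = 8, patience = patience,
             input_channels = 22)
}

high_snr_fit <- function() {
  fixture("high_snr_fit", function() {
    ds <- high_snr_dataset()
    sp <- split_dataset(ds$labels, fractions = c(0.85, 0, 0.15), seed = 42)
    fit <- atlas_pd(ds$data[sp$train, , ], ds$labels[sp$train],
                    ds$data[sp$test, , ], ds$labels[sp$test],
                    spec = small_atlas_spec())
    list(fit = fit, split = sp, dataset = ds)
  })
}

# A tiny sequence-classification problem every architecture can solve in
# seconds: class k scales a sinusoid in the first channels.
toy_sequences <- function(n_per_class = 20, Tn = 50, channels = 4, seed = 1,
                          noise_sd = 0.5) {
  set.seed(seed)
  n <- 3 * n_per_class
  x <- array(stats::rnorm(n * channels * Tn, 0, noise_sd), c(n, channels, Tn))
  y <- factor(rep(c("HC", "HY1", "HY2"), each = n_per_class),
              levels = c("HC", "HY1", "HY2"))
  tt <- seq_len(Tn) / 10
  for (i in seq_len(n)) {
    a <- as.integer(y[i])
    x[i, 1, ] <- x[i, 1, ] + a * sin(2 * pi * tt)
    x[i, 2, ] <- x[i, 2, ] + 0.5 * a
  }
  list(x = x, y = y)
}

# A fixed-probability "model" so evaluation code can be tested against
# hand-computed metrics.
fixed_prob_model <- function(probs) {
  structure(list(probs = probs), class = "fixed_prob")
}

predict.fixed_prob <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  pr <- object$probs
  if (is.array(newdata) && length(dim(newdata)) == 3 && dim(newdata)[1] != nrow(pr))
    stop("fixture model: size mismatch")
  if (type == "class")
    factor(colnames(pr)[max.col(pr, ties.method = "first")], levels = colnames(pr))
  else pr
}
registerS3method("predict", "fixed_prob", predict.fixed_prob)
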