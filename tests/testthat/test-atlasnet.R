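# Architecture, training harness, splits and hyperparameter search.

test_that("model specs enforce their invariants", {
  expect_error(model_spec("atlas", d_model = 30, n_heads = 4), "divisible")
  expect_error(model_spec("atlas", dropout = c(0.3, 1.0)), "dropout")
  expect_error(model_spec("atlas", patience = 0), "patience")
  s <- model_spec("atlas")
  expect_equal(s$d_model, 128)
  expect_equal(s$n_heads, 4)
  expect_equal(s$n_transformer_layers, 2)
  expect_equal(s$learning_rate, 8e-4)
  sl <- model_spec("lstm")
  expect_equal(sl$lstm_hidden, c(128, 64))
  expect_equal(sl$learning_rate, 2e-3)
  expect_equal(sl$dropout, c(0.3, 0.4))
})

test_that("analytic gradients match central differences", {
  grad_check <- function(spec) {
    Tn <- 7; B <- 2
    set.seed(5)
    params <- atlaspd:::.net_init(spec, 11)
    state <- atlaspd:::.net_state_init(spec)
    x3 <- array(rnorm(Tn * B * spec$input_channels), c(Tn, B, spec$input_channels))
    y <- c(1L, 3L)
    r <- atlaspd:::.net_loss_grad(params, state, x3, y, spec, training = TRUE)
    leaves <- list()
    walk <- function(p, path) for (nm in names(p)) {
      if (is.list(p[[nm]])) walk(p[[nm]], c(path, nm))
      else leaves[[length(leaves) + 1]] <<- c(path, nm)
    }
    walk(params, character())
    get_leaf <- function(p, path) { for (nm in path) p <- p[[nm]]; p }
    set_leaf <- function(p, path, v) {
      if (length(path) == 1) { p[[path]] <- v; return(p) }
      p[[path[1]]] <- set_leaf(p[[path[1]]], path[-1], v)
      p
    }
    worst <- 0
    set.seed(99)
    for (lf in leaves) {
      g <- get_leaf(r$grads, lf)
      pv <- get_leaf(params, lf)
      for (ci in sample(length(pv), min(2, length(pv)))) {
        eps <- 1e-5
        up <- pv; up[ci] <- up[ci] + eps
        dn <- pv; dn[ci] <- dn[ci] - eps
        l1 <- atlaspd:::.net_loss_grad(set_leaf(params, lf, up), state, x3, y,
                                       spec, TRUE)$loss
        l2 <- atlaspd:::.net_loss_grad(set_leaf(params, lf, dn), state, x3, y,
                                       spec, TRUE)$loss
        gn <- (l1 - l2) / (2 * eps)
        worst <- max(worst, abs(gn - g[ci]) / max(1e-6, abs(gn) + abs(g[ci])))
      }
    }
    worst
  }
  sa <- model_spec("atlas", d_model = 8, n_heads = 2, n_transformer_layers = 2,
                   lstm_hidden = 6, dropout = c(0, 0), l2_lambda = 0,
                   batch_size = 2, input_channels = 3)
  expect_lt(grad_check(sa), 1e-4)
  sl <- model_spec("lstm", lstm_hidden = c(6, 5), dropout = c(0, 0),
                   l2_lambda = 0, batch_size = 2, input_channels = 3)
  expect_lt(grad_check(sl), 1e-4)
})

test_that("forward passes emit valid, deterministic probabilities", {
  spec <- model_spec("atlas", d_model = 8, n_heads = 2, n_transformer_layers = 1,
                     lstm_hidden = 6, input_channels = 4)
  params <- atlaspd:::.net_init(spec, 1)
  state <- atlaspd:::.net_state_init(spec)
  x <- array(rnorm(5 * 4 * 12), c(5, 4, 12))
  p1 <- atlaspd:::.net_predict(params, state, x, spec)$probs
  expect_equal(rowSums(p1), rep(1, 5), tolerance = 1e-6)
  p2 <- atlaspd:::.net_predict(params, state, x, spec)$probs
  expect_identical(p1, p2)
})

test_that("stacked LSTM parameter count matches the closed form", {
  spec <- model_spec("lstm", lstm_hidden = c(12, 7), input_channels = 5)
  params <- atlaspd:::.net_init(spec, 1)
  lstm_params <- function(din, h) 4 * ((din + h) * h + h)
  expected <- lstm_params(5, 12) + lstm_params(12, 7) + (7 * 3 + 3)
  expect_equal(atlaspd:::.count_params(params), expected)
})

test_that("both architectures learn a separable toy problem", {
  toy <- toy_sequences(seed = 1)
  sp <- split_dataset(toy$y, seed = 1)
  sa <- model_spec("atlas", d_model = 16, n_heads = 2, n_transformer_layers = 1,
                   lstm_hidden = 16, dropout = c(0, 0), learning_rate = 3e-3,
                   epochs = 60, batch_size = 14, patience = 60,
                   input_channels = 4, l2_lambda = 1e-4)
  fit <- atlas_pd(toy$x[sp$train, , ], toy$y[sp$train],
                  toy$x[sp$val, , ], toy$y[sp$val], spec = sa)
  expect_gt(mean(predict(fit, toy$x[sp$test, , ], type = "class") ==
                   toy$y[sp$test]), 0.8)
  pr <- predict(fit, toy$x[sp$test, , ])
  expect_equal(rowSums(pr), rep(1, length(sp$test)), tolerance = 1e-6)
  sl <- model_spec("lstm", lstm_hidden = c(16, 8), dropout = c(0, 0),
                   learning_rate = 1e-2, epochs = 100, batch_size = 14,
                   patience = 100, input_channels = 4, l2_lambda = 1e-4)
  fit2 <- lstm_net(toy$x[sp$train, , ], toy$y[sp$train],
                   toy$x[sp$val, , ], toy$y[sp$val], spec = sl)
  expect_gt(mean(predict(fit2, toy$x[sp$test, , ], type = "class") ==
                   toy$y[sp$test]), 0.8)
})

test_that("training is reproducible and checkpoints the best epoch", {
  toy <- toy_sequences(n_per_class = 8, Tn = 20, seed = 2)
  spec <- model_spec("atlas", d_model = 8, n_heads = 2, n_transformer_layers = 1,
                     lstm_hidden = 8, dropout = c(0.2, 0.2), learning_rate = 2e-3,
                     epochs = 10, batch_size = 8, patience = 10,
                     input_channels = 4)
  f1 <- atlas_pd(toy$x, toy$y, spec = spec, seed_shuffle = 42, seed_weights = 123)
  f2 <- atlas_pd(toy$x, toy$y, spec = spec, seed_shuffle = 42, seed_weights = 123)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  # checkpoint contract: stored model corresponds to the max validation accuracy
  expect_equal(f1$history$val_acc[f1$best_epoch], max(f1$history$val_acc))
  # with patience >= epochs and improving loss the full schedule runs
  expect_lte(nrow(f1$history), spec$epochs)
})

test_that("stratified splitting uses largest-remainder allocation", {
  y240 <- factor(rep(c("HC", "HY1", "HY2"), each = 80))
  sp <- split_dataset(y240, seed = 1)
  expect_equal(lengths(sp)[c("train", "val", "test")],
               c(train = 168, val = 36, test = 36))
  for (part in sp)
    expect_true(all(table(y240[part]) == length(part) / 3))  # internally balanced
  expect_equal(sort(unname(unlist(sp))), 1:240)  # disjoint and exhaustive
  # 6/4 class mix at (0.7, 0.15, 0.15): hand-enumerated largest remainder:
  # class A (6): quotas 4.2/0.9/0.9 -> 4/1/1; class B (4): 2.8/0.6/0.6 -> 3/1/0
  y10 <- factor(c(rep("A", 6), rep("B", 4)))
  sp10 <- split_dataset(y10, seed = 2)
  expect_equal(lengths(sp10), c(train = 7, val = 2, test = 1))
  expect_equal(as.numeric(table(y10[sp10$train])), c(4, 3))
  expect_equal(as.numeric(table(y10[sp10$val])), c(1, 1))
  expect_equal(as.numeric(table(y10[sp10$test])), c(1, 0))
  expect_identical(split_dataset(y240, seed = 9), split_dataset(y240, seed = 9))
  expect_error(split_dataset(factor(c("A", "A", "B"))), "at least")
})

test_that("stratified folds rotate remainders for near-equal sizes", {
  y <- factor(rep(c("HC", "HY1", "HY2"), each = 68))  # the 204-subject pool
  fold <- atlaspd:::.stratified_folds(y, 5, seed = 1)
  expect_equal(sort(as.numeric(table(fold))), c(40, 41, 41, 41, 41))
  for (k in 1:5)
    expect_true(all(abs(table(y[fold == k]) - 68 / 5) <= 1))
  expect_identical(atlaspd:::.stratified_folds(y, 5, 3),
                   atlaspd:::.stratified_folds(y, 5, 3))
})

test_that("Bayesian search improves on a known analytic objective", {
  # separable quadratic with optimum at lr = 1e-3, d_model = 256, 3 layers
  obj <- function(cfg) {
    -(log10(cfg$learning_rate) + 3)^2 - ((cfg$d_model - 256) / 200)^2 -
      (cfg$n_transformer_layers - 3)^2 / 4 - (cfg$dropout[1] - 0.3)^2
  }
  r <- bayes_search(search_space(), objective = obj, n_iter = 25, n_init = 8,
                    seed = 7)
  expect_true(all(diff(r$trace$incumbent) >= 0))
  # grid oracle for the achievable optimum over the space
  best_possible <- 0
  expect_gt(r$best_score, best_possible - 0.35)  # within the top of the domain
  expect_equal(nrow(r$trace), 25)
  # singleton space degenerates to one evaluation
  s1 <- search_space(transformer_layers = c(2, 2), attention_heads = c(4, 4),
                     learning_rate = c(1e-3, 1e-3), hidden_dims = c(64, 64),
                     dropout = c(0.3, 0.3))
  r1 <- bayes_search(s1, objective = obj, n_iter = 10, seed = 1)
  expect_equal(nrow(r1$trace), 1)
  expect_equal(r1$best$d_model, 64)
  expect_equal(r1$best$n_heads, 4)
})

test_that("sampled configurations respect head divisibility", {
  set.seed(3)
  for (i in 1:50) {
    cfg <- atlaspd:::.sample_config(search_space())
    expect_equal(cfg$d_model %% cfg$n_heads, 0)
    expect_gte(cfg$learning_rate, 1e-5)
    expect_lte(cfg$learning_rate, 1e-2)
  }
})
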