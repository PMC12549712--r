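#' Model specification for the deep classifiers
#'
#' Holds the architecture and training hyperparameters of the hybrid
#' attention Transformer-LSTM classifier (`arch = "atlas"`) and of the plain
#' stacked-LSTM baseline (`arch = "lstm"`). Defaults are the tuned values of
#' the staging study: 2 Transformer encoder layers, 4 attention heads,
#' `d_model` 128, learning rate 8e-4 (hybrid) / 2e-3 (LSTM), LSTM hidden
#' sizes `[128, 64]` for the plain LSTM, dropout `[0.3, 0.4]`, 120 epochs,
#' L2 weight decay 0.001, early-stopping patience 20.
#'
#' @param arch `"atlas"` (Transformer + LSTM hybrid) or `"lstm"`.
#' @param d_model Transformer width; must be divisible by `n_heads`.
#' @param n_heads Attention heads.
#' @param n_transformer_layers Encoder layers.
#' @param lstm_hidden Hidden widths: a single width for the hybrid's LSTM
#'   (defaults to `d_model`), or two widths for the stacked baseline.
#' @param dropout Two dropout rates in `[0, 1)` for the two dropout sites.
#' @param learning_rate Adam learning rate.
#' @param epochs Maximum training epochs.
#' @param l2_lambda L2 weight-decay coefficient.
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement); must be >= 1.
#' @param n_classes Number of classes (3).
#' @param input_channels Input channels (22).
#' @param ff_mult Feed-forward width multiplier (4 x d_model).
#' @param readout LSTM readout feeding the dense head: `"mean"` (temporal
#'   mean of the hidden states, the default — robust to the long trailing
#'   rest of the block design) or `"last"` (final hidden state).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(arch = c("atlas", "lstm"), d_model = 128, n_heads = 4,
                       n_transformer_layers = 2, lstm_hidden = NULL,
                       dropout = c(0.3, 0.4),
                       learning_rate = NULL, epochs = 120, l2_lambda = 0.001,
                       batch_size = 16, patience = 20, n_classes = 3,
                       input_channels = 22, ff_mult = 4,
                       readout = c("mean", "last")) {
  arch <- match.arg(arch)
  readout <- match.arg(readout)
  if (is.null(learning_rate)) learning_rate <- if (arch == "atlas") 8e-4 else 2e-3
  if (is.null(lstm_hidden)) lstm_hidden <- if (arch == "atlas") d_model else c(128, 64)
  if (arch == "atlas" && d_model %% n_heads != 0)
    stop("model_spec: d_model must be divisible by n_heads")
  if (any(dropout < 0 | dropout >= 1)) stop("model_spec: dropout must be in [0, 1)")
  if (length(dropout) != 2) stop("model_spec: two dropout rates expected")
  if (patience < 1) stop("model_spec: patience must be >= 1")
  for (v in c(d_model, n_heads, n_transformer_layers, lstm_hidden, epochs,
              batch_size, n_classes, input_channels))
    if (v < 1) stop("model_spec: counts must be >= 1")
  structure(list(arch = arch, d_model = d_model, n_heads = n_heads,
                 n_transformer_layers = n_transformer_layers,
                 lstm_hidden = lstm_hidden, dropout = dropout,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 l2_lambda = l2_lambda, batch_size = as.integer(batch_size),
                 patience = as.integer(patience), n_classes = as.integer(n_classes),
                 input_channels = as.integer(input_channels), ff_mult = ff_mult,
                 readout = readout),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  if (x$arch == "atlas")
    cat(sprintf("ATLAS spec: proj %d->%d, %d encoder layer(s) x %d heads, LSTM %d, dropout [%g, %g], lr %g\n",
                x$input_channels, x$d_model, x$n_transformer_layers, x$n_heads,
                x$lstm_hidden[1], x$dropout[1], x$dropout[2], x$learning_rate))
  else
    cat(sprintf("LSTM spec: %d -> %s, dropout [%g, %g], lr %g\n",
                x$input_channels, paste(x$lstm_hidden, collapse = " -> "),
                x$dropout[1], x$dropout[2], x$learning_rate))
  invisible(x)
}

# ---- network assembly -------------------------------------------------------

.net_init <- function(spec, seed) {
  set.seed(as.integer(seed))
  if (spec$arch == "atlas") {
    d <- spec$d_model
    list(proj = .init_linear(spec$input_channels, d),
         bn = .init_bn(d),
         enc = lapply(seq_len(spec$n_transformer_layers),
                      function(i) .init_encoder_layer(d, spec$ff_mult * d)),
         lstm = .init_lstm(d, spec$lstm_hidden[1]),
         out = .init_linear(spec$lstm_hidden[1], spec$n_classes))
  } else {
    h <- spec$lstm_hidden
    list(lstm1 = .init_lstm(spec$input_channels, h[1]),
         lstm2 = .init_lstm(h[1], h[2]),
         out = .init_linear(h[2], spec$n_classes))
  }
}

.net_state_init <- function(spec) {
  if (spec$arch == "atlas")
    list(bn = list(mean = rep(0, spec$d_model), var = rep(1, spec$d_model)))
  else list()
}

# LSTM readout: either the final hidden state or the temporal mean of all
# hidden states (the mean readout does not have to carry task information
# across the session's long trailing rest).
.lstm_readout <- function(lst, readout) {
  if (readout == "last") return(lst$h_last)
  Tn <- dim(lst$H)[1]; B <- dim(lst$H)[2]; h <- dim(lst$H)[3]
  matrix(colMeans(matrix(lst$H, Tn, B * h)), B, h)
}

# gradient of the readout w.r.t. the hidden-state sequence
.lstm_readout_bwd <- function(dh_read, Tn, readout) {
  if (readout == "last") return(list(dH = NULL, dh_last = dh_read))
  B <- nrow(dh_read); h <- ncol(dh_read)
  list(dH = array(rep(as.numeric(dh_read / Tn), each = Tn), c(Tn, B, h)),
       dh_last = NULL)
}

# x3: (T, B, C) array. Returns probs, penultimate features and full cache.
.net_fwd <- function(params, state, x3, spec, training) {
  Tn <- dim(x3)[1]; B <- dim(x3)[2]
  if (spec$arch == "atlas") {
    d <- spec$d_model
    x2 <- matrix(x3, Tn * B, dim(x3)[3])
    pr <- .linear_fwd(params$proj, x2)
    bn <- .bn_fwd(params$bn, pr, state$bn, training)
    state$bn <- bn$state
    pe <- .positional_encoding(Tn, d)
    y <- bn$y + pe[rep(seq_len(Tn), B), ]
    dr1 <- .dropout_fwd(y, spec$dropout[1], training)
    y <- dr1$y
    enc_caches <- vector("list", spec$n_transformer_layers)
    for (l in seq_len(spec$n_transformer_layers)) {
      caches_b <- vector("list", B)
      for (b in seq_len(B)) {
        rows <- (b - 1) * Tn + seq_len(Tn)
        e <- .encoder_fwd(params$enc[[l]], y[rows, , drop = FALSE],
                          spec$n_heads, spec$dropout[1], training)
        y[rows, ] <- e$y
        caches_b[[b]] <- e$cache
      }
      enc_caches[[l]] <- caches_b
    }
    lst <- .lstm_fwd(params$lstm, array(y, c(Tn, B, d)))
    h_read <- .lstm_readout(lst, spec$readout)
    dr2 <- .dropout_fwd(h_read, spec$dropout[2], training)
    logits <- .linear_fwd(params$out, dr2$y)
    probs <- .softmax_rows(logits)
    list(probs = probs, penultimate = h_read, state = state,
         cache = list(x2 = x2, pr = pr, bn = bn, dr1 = dr1,
                      enc = enc_caches, y_enc = y, lst = lst, dr2 = dr2,
                      Tn = Tn, B = B))
  } else {
    l1 <- .lstm_fwd(params$lstm1, x3)
    h1 <- dim(l1$H)[3]
    H1m <- matrix(l1$H, Tn * B, h1)
    dr1 <- .dropout_fwd(H1m, spec$dropout[1], training)
    l2 <- .lstm_fwd(params$lstm2, array(dr1$y, c(Tn, B, h1)))
    h_read <- .lstm_readout(l2, spec$readout)
    dr2 <- .dropout_fwd(h_read, spec$dropout[2], training)
    logits <- .linear_fwd(params$out, dr2$y)
    probs <- .softmax_rows(logits)
    list(probs = probs, penultimate = h_read, state = state,
         cache = list(l1 = l1, dr1 = dr1, l2 = l2, dr2 = dr2, Tn = Tn, B = B))
  }
}

# y_int: integer class labels in 1..K. Returns loss, grads.
.net_loss_grad <- function(params, state, x3, y_int, spec, training = TRUE) {
  fw <- .net_fwd(params, state, x3, spec, training)
  B <- nrow(fw$probs)
  p_true <- fw$probs[cbind(seq_len(B), y_int)]
  loss <- -mean(log(pmax(p_true, 1e-12))) + .l2_penalty(params, spec$l2_lambda)
  dlogits <- fw$probs
  dlogits[cbind(seq_len(B), y_int)] <- dlogits[cbind(seq_len(B), y_int)] - 1
  dlogits <- dlogits / B
  cache <- fw$cache
  grads <- list()
  if (spec$arch == "atlas") {
    bo <- .linear_bwd(params$out, cache$dr2$y, dlogits); grads$out <- bo$grads
    dh_read <- .dropout_bwd(bo$dx, cache$dr2$mask)
    ro <- .lstm_readout_bwd(dh_read, cache$Tn, spec$readout)
    bl <- .lstm_bwd(params$lstm, cache$lst$cache, dH = ro$dH,
                    dh_last = ro$dh_last)
    grads$lstm <- bl$grads
    Tn <- cache$Tn; B2 <- cache$B
    dy <- matrix(bl$dx3, Tn * B2, spec$d_model)
    grads$enc <- vector("list", spec$n_transformer_layers)
    for (l in rev(seq_len(spec$n_transformer_layers))) {
      gsum <- NULL
      for (b in seq_len(B2)) {
        rows <- (b - 1) * Tn + seq_len(Tn)
        eb <- .encoder_bwd(params$enc[[l]], cache$enc[[l]][[b]],
                           dy[rows, , drop = FALSE], spec$n_heads)
        dy[rows, ] <- eb$dx
        gsum <- if (is.null(gsum)) eb$grads else .tree_add(gsum, eb$grads)
      }
      grads$enc[[l]] <- gsum
    }
    dy <- .dropout_bwd(dy, cache$dr1$mask)
    bb <- .bn_bwd(params$bn, cache$bn$cache, dy); grads$bn <- bb$grads
    bp <- .linear_bwd(params$proj, cache$x2, bb$dx); grads$proj <- bp$grads
  } else {
    bo <- .linear_bwd(params$out, cache$dr2$y, dlogits); grads$out <- bo$grads
    dh_read <- .dropout_bwd(bo$dx, cache$dr2$mask)
    ro <- .lstm_readout_bwd(dh_read, cache$Tn, spec$readout)
    b2 <- .lstm_bwd(params$lstm2, cache$l2$cache, dH = ro$dH,
                    dh_last = ro$dh_last)
    grads$lstm2 <- b2$grads
    Tn <- cache$Tn; B2 <- cache$B
    h1 <- ncol(params$lstm1$Wh) / 4
    dH1 <- .dropout_bwd(matrix(b2$dx3, Tn * B2, h1), cache$dr1$mask)
    b1 <- .lstm_bwd(params$lstm1, cache$l1$cache, dH = array(dH1, c(Tn, B2, h1)))
    grads$lstm1 <- b1$grads
  }
  acc <- mean(max.col(fw$probs, ties.method = "first") == y_int)
  list(loss = loss, acc = acc, grads = grads, state = fw$state)
}

# N x C x T array -> (T, B, C) for a subset of subjects
.to_tbc <- function(x, idx) aperm(x[idx, , , drop = FALSE], c(3, 1, 2))

.net_predict <- function(params, state, x, spec, batch = 64) {
  n <- dim(x)[1]
  probs <- matrix(NA_real_, n, spec$n_classes)
  feats <- matrix(NA_real_, n, if (spec$arch == "atlas") spec$lstm_hidden[1]
                  else spec$lstm_hidden[2])
  for (start in seq(1, n, by = batch)) {
    idx <- start:min(start + batch - 1, n)
    fw <- .net_fwd(params, state, .to_tbc(x, idx), spec, training = FALSE)
    probs[idx, ] <- fw$probs
    feats[idx, ] <- fw$penultimate
  }
  list(probs = probs, penultimate = feats)
}

.count_params <- function(params) {
  s <- 0
  rec <- function(p) for (nm in names(p)) {
    if (is.list(p[[nm]])) rec(p[[nm]]) else s <<- s + length(p[[nm]])
  }
  rec(params)
  s
}

# ---- training harness -------------------------------------------------------

.fit_net <- function(x, y, spec, x_val, y_val, seed_weights, seed_shuffle,
                     verbose = FALSE) {
  classes <- levels(y)
  y_int <- as.integer(y); yv_int <- as.integer(y_val)
  params <- .net_init(spec, seed_weights)
  state <- .net_state_init(spec)
  opt <- .adam_new(params)
  set.seed(as.integer(seed_shuffle))
  n <- dim(x)[1]
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     train_acc = numeric(0), val_loss = numeric(0),
                     val_acc = numeric(0))
  best <- list(val_acc = -Inf, params = params, state = state, epoch = 0)
  best_val_loss <- Inf; stall <- 0
  for (epoch in seq_len(spec$epochs)) {
    ord <- sample.int(n)
    tl <- ta <- 0; nb <- 0
    for (start in seq(1, n, by = spec$batch_size)) {
      idx <- ord[start:min(start + spec$batch_size - 1, n)]
      r <- .net_loss_grad(params, state, .to_tbc(x, idx), y_int[idx], spec, TRUE)
      if (!is.finite(r$loss))
        stop("training diverged (non-finite loss) at epoch ", epoch,
             "; lower the learning rate")
      state <- r$state
      st <- .adam_step(params, r$grads, opt, spec$learning_rate, spec$l2_lambda)
      params <- st$params; opt <- st$state
      tl <- tl + r$loss; ta <- ta + r$acc; nb <- nb + 1
    }
    ev <- .net_eval(params, state, x_val, yv_int, spec)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tl / nb,
                                   train_acc = ta / nb, val_loss = ev$loss,
                                   val_acc = ev$acc))
    if (verbose) message(sprintf("epoch %3d  loss %.4f acc %.3f | val loss %.4f acc %.3f",
                                 epoch, tl / nb, ta / nb, ev$loss, ev$acc))
    if (ev$acc > best$val_acc) best <- list(val_acc = ev$acc, params = params,
                                            state = state, epoch = epoch)
    if (ev$loss < best_val_loss - 1e-6) { best_val_loss <- ev$loss; stall <- 0 }
    else stall <- stall + 1
    if (stall >= spec$patience) break
  }
  list(params = best$params, state = best$state, history = hist,
       best_epoch = best$epoch, classes = classes,
       n_params = .count_params(best$params))
}

.net_eval <- function(params, state, x, y_int, spec, batch = 64) {
  pr <- .net_predict(params, state, x, spec, batch)$probs
  p_true <- pr[cbind(seq_along(y_int), y_int)]
  list(loss = -mean(log(pmax(p_true, 1e-12))) + .l2_penalty(params, spec$l2_lambda),
       acc = mean(max.col(pr, ties.method = "first") == y_int))
}

.resolve_xy <- function(x, y) {
  if (inherits(x, "fnirs_dataset")) {
    if (is.null(y)) y <- x$labels
    x <- x$data
  }
  if (!is.array(x) || length(dim(x)) != 3)
    stop("x must be an N x channels x time array or an fnirs_dataset")
  y <- factor(y, levels = c("HC", "HY1", "HY2"))
  if (anyNA(y)) stop("labels must be HC / HY1 / HY2")
  list(x = x, y = y)
}

#' Fit the attention-based Transformer-LSTM classifier (ATLAS-PD)
#'
#' Trains the hybrid architecture — linear input projection (channels ->
#' `d_model`), batch normalisation, sinusoidal positional encoding,
#' `n_transformer_layers` Transformer encoder layers (multi-head
#' self-attention + position-wise feed-forward, post-norm residuals), a
#' single LSTM layer and a dense softmax head on the last hidden state — with
#' Adam, cross-entropy loss, L2 weight decay, dropout, early stopping on
#' validation loss (patience) and checkpointing on best validation accuracy.
#' All randomness flows from the two seeds (`seed_shuffle` for data order and
#' dropout, `seed_weights` for initialisation); repeated runs are identical.
#'
#' @param x `N x channels x time` array of preprocessed series, or an
#'   `fnirs_dataset`.
#' @param y Class labels (HC/HY1/HY2); taken from the dataset if omitted.
#' @param x_val,y_val Validation set; if omitted, a stratified 15% of the
#'   training data is held out.
#' @param spec A [model_spec()] with `arch = "atlas"`.
#' @param seed_shuffle,seed_weights Integer seeds (defaults 42 and 123).
#' @param verbose Print per-epoch progress.
#' @return An object of class `c("atlas_pd", "fnirs_classifier")` with
#'   methods `predict`, `print`, `summary` and `plot`. `predict` returns a
#'   row-stochastic probability matrix (columns HC, HY1, HY2).
#' @seealso [lstm_net()], [fit_baseline()], [evaluate_classifier()]
#' @export
atlas_pd <- function(x, y = NULL, x_val = NULL, y_val = NULL,
                     spec = NULL, seed_shuffle = 42, seed_weights = 123,
                     verbose = FALSE) {
  d <- .resolve_xy(x, y)
  if (is.null(spec)) spec <- model_spec("atlas", input_channels = dim(d$x)[2])
  stopifnot(inherits(spec, "model_spec"), spec$arch == "atlas")
  .fit_deep(d, x_val, y_val, spec, seed_shuffle, seed_weights, verbose,
            cls = "atlas_pd")
}

#' Fit the stacked-LSTM baseline classifier
#'
#' Two LSTM layers (hidden sizes 128 and 64 by default) followed by a dense
#' softmax classification layer, trained with the same harness as
#' [atlas_pd()] (Adam, dropout `[0.3, 0.4]`, L2 decay, early stopping,
#' best-validation-accuracy checkpointing).
#'
#' @inheritParams atlas_pd
#' @param spec A [model_spec()] with `arch = "lstm"`.
#' @return An object of class `c("lstm_net", "fnirs_classifier")`.
#' @export
lstm_net <- function(x, y = NULL, x_val = NULL, y_val = NULL,
                     spec = NULL, seed_shuffle = 42, seed_weights = 123,
                     verbose = FALSE) {
  d <- .resolve_xy(x, y)
  if (is.null(spec)) spec <- model_spec("lstm", input_channels = dim(d$x)[2])
  stopifnot(inherits(spec, "model_spec"), spec$arch == "lstm")
  .fit_deep(d, x_val, y_val, spec, seed_shuffle, seed_weights, verbose,
            cls = "lstm_net")
}

.fit_deep <- function(d, x_val, y_val, spec, seed_shuffle, seed_weights,
                      verbose, cls) {
  if (is.null(x_val)) {
    sp <- split_dataset(d$y, fractions = c(0.85, 0, 0.15), seed = seed_shuffle)
    x_tr <- d$x[sp$train, , , drop = FALSE]; y_tr <- d$y[sp$train]
    x_val <- d$x[sp$test, , , drop = FALSE]; y_val <- d$y[sp$test]
  } else {
    v <- .resolve_xy(x_val, y_val)
    x_tr <- d$x; y_tr <- d$y; x_val <- v$x; y_val <- v$y
  }
  fit <- .fit_net(x_tr, y_tr, spec, x_val, y_val, seed_weights, seed_shuffle,
                  verbose)
  structure(list(params = fit$params, state = fit$state, spec = spec,
                 history = fit$history, best_epoch = fit$best_epoch,
                 classes = fit$classes, n_params = fit$n_params,
                 seeds = c(shuffle = seed_shuffle, weights = seed_weights)),
            class = c(cls, "fnirs_classifier"))
}

#' @export
predict.fnirs_classifier <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "fnirs_dataset")) newdata <- newdata$data
  pr <- .net_predict(object$params, object$state, newdata, object$spec)$probs
  colnames(pr) <- object$classes
  if (type == "class") factor(object$classes[max.col(pr, ties.method = "first")],
                              levels = object$classes)
  else pr
}

# Penultimate-layer features (the representation fed to the softmax head).
.penultimate_features <- function(object, x) {
  if (inherits(x, "fnirs_dataset")) x <- x$data
  if (!inherits(object, "fnirs_classifier") || is.null(object$params))
    stop("penultimate features are available for atlas_pd / lstm_net fits only")
  .net_predict(object$params, object$state, x, object$spec)$penultimate
}

#' @export
print.fnirs_classifier <- function(x, ...) {
  cat(sprintf("%s fit: %d parameters, best epoch %d (val acc %.3f), %d epochs run\n",
              class(x)[1], x$n_params, x$best_epoch,
              max(x$history$val_acc), nrow(x$history)))
  invisible(x)
}

#' @export
summary.fnirs_classifier <- function(object, ...) {
  print(object)
  print(object$spec)
  h <- object$history
  cat(sprintf("final: train loss %.4f / acc %.3f; val loss %.4f / acc %.3f\n",
              h$train_loss[nrow(h)], h$train_acc[nrow(h)],
              h$val_loss[nrow(h)], h$val_acc[nrow(h)]))
  invisible(object)
}

#' @export
plot.fnirs_classifier <- function(x, ...) {
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch", ylab = "loss",
       main = "loss", ylim = range(c(h$train_loss, h$val_loss)))
  graphics::lines(h$epoch, h$val_loss, lty = 2)
  graphics::legend("topright", c("train", "val"), lty = 1:2, bty = "n")
  plot(h$epoch, h$train_acc, type = "l", xlab = "epoch", ylab = "accuracy",
       main = "accuracy", ylim = c(0, 1))
  graphics::lines(h$epoch, h$val_acc, lty = 2)
  graphics::abline(h = 1 / 3, col = "grey")
  invisible(x)
}

# ---- splits and folds -------------------------------------------------------

#' Stratified train/validation/test split
#'
#' Allocates each class across the three splits proportionally with
#' largest-remainder rounding (remainder ties resolved in split order), then
#' assigns shuffled within-class indices. Splits are disjoint and exhaustive;
#' a balanced 240-subject cohort at (0.70, 0.15, 0.15) yields 168/36/36 with
#' each split internally balanced.
#'
#' @param y Label factor, or an `fnirs_dataset`.
#' @param fractions Three fractions summing to 1.
#' @param seed Shuffle seed.
#' @param min_class Minimum members per class (default 3).
#' @return List with integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(y, fractions = c(0.70, 0.15, 0.15), seed = 42,
                          min_class = 3) {
  if (inherits(y, "fnirs_dataset")) y <- y$labels
  y <- as.factor(y)
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (length(fractions) != 3) stop("three fractions expected (train, val, test)")
  cnt <- table(y)
  if (any(cnt > 0 & cnt < min_class))
    stop("every class needs at least ", min_class, " members")
  set.seed(as.integer(seed))
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    n_c <- length(idx)
    quota <- n_c * fractions
    base <- floor(quota)
    rem <- n_c - sum(base)
    if (rem > 0) {
      extra <- order(-(quota - base), seq_along(quota))[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    take <- cumsum(base)
    out$train <- c(out$train, idx[seq_len(base[1])])
    if (base[2] > 0) out$val <- c(out$val, idx[(take[1] + 1):take[2]])
    if (base[3] > 0) out$test <- c(out$test, idx[(take[2] + 1):take[3]])
  }
  lapply(out, sort)
}

# Stratified k folds with rotating remainder assignment so fold sizes are as
# equal as possible overall (204 balanced samples / 5 folds -> 41/41/41/41/40).
.stratified_folds <- function(y, k, seed) {
  y <- as.factor(y)
  if (any(table(y) < k)) stop("every class needs at least k members")
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (ci in seq_along(levels(y))) {
    idx <- sample(which(y == levels(y)[ci]))
    n_c <- length(idx)
    base <- n_c %/% k; r <- n_c %% k
    sizes <- rep(base, k)
    if (r > 0) {
      extras <- ((ci - 1) * r + 0:(r - 1)) %% k + 1
      sizes[extras] <- sizes[extras] + 1
    }
    fold[idx] <- rep(seq_len(k), times = sizes)
  }
  fold
}

# ---- Bayesian hyperparameter search ----------------------------------------

#' Hyperparameter search space
#'
#' Ranges searched by [bayes_search()]: Transformer layers 1-5, attention
#' heads 1-12 (head/width divisibility enforced by rejection sampling),
#' learning rate 1e-5 to 1e-2 on a log scale, hidden dimension 64-512,
#' dropout 0.1-0.6.
#'
#' @param transformer_layers,attention_heads,hidden_dims Integer ranges
#'   `c(min, max)`.
#' @param learning_rate,dropout Continuous ranges.
#' @return An object of class `search_space`.
#' @export
search_space <- function(transformer_layers = c(1, 5), attention_heads = c(1, 12),
                         learning_rate = c(1e-5, 1e-2), hidden_dims = c(64, 512),
                         dropout = c(0.1, 0.6)) {
  structure(list(transformer_layers = transformer_layers,
                 attention_heads = attention_heads,
                 learning_rate = learning_rate, hidden_dims = hidden_dims,
                 dropout = dropout), class = "search_space")
}

.sample1 <- function(v) if (length(v) == 1L) v else sample(v, 1)

.sample_config <- function(space) {
  repeat {
    d <- round(stats::runif(1, space$hidden_dims[1], space$hidden_dims[2]))
    h <- .sample1(space$attention_heads[1]:space$attention_heads[2])
    d <- max(h, round(d / h) * h)  # snap width to a multiple of the head count
    if (d >= space$hidden_dims[1] && d <= space$hidden_dims[2]) break
  }
  list(n_transformer_layers = .sample1(space$transformer_layers[1]:space$transformer_layers[2]),
       n_heads = h,
       learning_rate = 10^stats::runif(1, log10(space$learning_rate[1]),
                                       log10(space$learning_rate[2])),
       d_model = d,
       dropout = stats::runif(2, space$dropout[1], space$dropout[2]))
}

.encode_config <- function(cfg, space) {
  c((cfg$n_transformer_layers - space$transformer_layers[1]) /
      max(diff(space$transformer_layers), 1),
    (cfg$n_heads - space$attention_heads[1]) / max(diff(space$attention_heads), 1),
    (log10(cfg$learning_rate) - log10(space$learning_rate[1])) /
      (log10(space$learning_rate[2]) - log10(space$learning_rate[1])),
    (cfg$d_model - space$hidden_dims[1]) / max(diff(space$hidden_dims), 1),
    (cfg$dropout - space$dropout[1]) / max(diff(space$dropout), 1e-12))
}

.space_degenerate <- function(space)
  all(vapply(space, function(r) diff(range(r)) == 0, logical(1)))

#' Bayesian optimisation of classifier hyperparameters
#'
#' Gaussian-process surrogate (RBF kernel via \pkg{kernlab}) with Expected
#' Improvement acquisition over the [search_space()]; the objective defaults
#' to mean stratified k-fold cross-validated validation accuracy of an
#' `atlas_pd` fit, and a custom `objective(config)` can be supplied instead
#' (used to test the optimiser against analytic functions). If the surrogate
#' fit fails the iteration falls back to random sampling and the trace flags
#' it.
#'
#' @param space A [search_space()].
#' @param objective Optional function taking a config list and returning a
#'   scalar score to maximise.
#' @param x,y Training data for the default cross-validation objective.
#' @param n_iter Total evaluations (default 50).
#' @param n_init Random initial design points.
#' @param folds Cross-validation folds for the default objective.
#' @param cv_epochs Training epochs per fold for the default objective.
#' @param seed Seed.
#' @return List with `best` (config), `best_score`, and `trace` (data frame
#'   with per-iteration score, incumbent score and fallback flag).
#' @export
bayes_search <- function(space = search_space(), objective = NULL, x = NULL,
                         y = NULL, n_iter = 50, n_init = 10, folds = 5,
                         cv_epochs = 15, seed = 1) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (is.null(objective)) {
    if (is.null(x)) stop("either an objective or data must be supplied")
    objective <- function(cfg) .cv_objective(cfg, x, y, folds, cv_epochs, seed)
  }
  set.seed(as.integer(seed))
  if (.space_degenerate(space)) {
    cfg <- .sample_config(space)
    sc <- objective(cfg)
    return(list(best = cfg, best_score = sc,
                trace = data.frame(iter = 1, score = sc, incumbent = sc,
                                   fallback = FALSE)))
  }
  configs <- list(); scores <- numeric(0); fallback <- logical(0)
  n_init <- min(n_init, n_iter)
  for (i in seq_len(n_init)) {
    configs[[i]] <- .sample_config(space)
    scores[i] <- objective(configs[[i]])
    fallback[i] <- FALSE
  }
  while (length(scores) < n_iter) {
    X <- t(vapply(configs, .encode_config, numeric(6), space = space))
    fb <- FALSE
    cand <- NULL
    if (stats::sd(scores) > 1e-12) {
      gp <- tryCatch(kernlab::gausspr(X, scores, variance.model = TRUE,
                                      kpar = "automatic", var = 1e-4),
                     error = function(e) NULL)
      if (!is.null(gp)) {
        pool <- replicate(300, .sample_config(space), simplify = FALSE)
        Xp <- t(vapply(pool, .encode_config, numeric(6), space = space))
        mu <- as.numeric(kernlab::predict(gp, Xp))
        sdv <- pmax(as.numeric(kernlab::predict(gp, Xp, type = "sdeviation")), 1e-9)
        best_sc <- max(scores)
        z <- (mu - best_sc - 0.01) / sdv
        ei <- (mu - best_sc - 0.01) * stats::pnorm(z) + sdv * stats::dnorm(z)
        cand <- pool[[which.max(ei)]]
      }
    }
    if (is.null(cand)) { cand <- .sample_config(space); fb <- TRUE }
    configs[[length(configs) + 1]] <- cand
    scores[length(scores) + 1] <- objective(cand)
    fallback[length(fallback) + 1] <- fb
  }
  best_i <- which.max(scores)
  list(best = configs[[best_i]], best_score = scores[best_i],
       trace = data.frame(iter = seq_along(scores), score = scores,
                          incumbent = cummax(scores), fallback = fallback))
}

.cv_objective <- function(cfg, x, y, folds, cv_epochs, seed) {
  d <- .resolve_xy(x, y)
  fold <- .stratified_folds(d$y, folds, seed)
  accs <- numeric(folds)
  for (k in seq_len(folds)) {
    tr <- which(fold != k); va <- which(fold == k)
    spec <- model_spec("atlas", d_model = cfg$d_model, n_heads = cfg$n_heads,
                       n_transformer_layers = cfg$n_transformer_layers,
                       dropout = cfg$dropout, learning_rate = cfg$learning_rate,
                       epochs = cv_epochs, patience = cv_epochs,
                       input_channels = dim(d$x)[2])
    fit <- atlas_pd(d$x[tr, , , drop = FALSE], d$y[tr],
                    d$x[va, , , drop = FALSE], d$y[va], spec = spec,
                    seed_shuffle = seed, seed_weights = seed + 1)
    accs[k] <- max(fit$history$val_acc)
  }
  mean(accs)
}
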