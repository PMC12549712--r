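# Interpretability: permutation channel importance, anatomical aggregation,
# and t-SNE embedding of penultimate-layer features.

#' Permutation importance of each input channel
#'
#' For each channel, shuffles that channel's whole series across subjects
#' (within-channel, across-subject permutation), repeats `repeats` times, and
#' records the mean drop in test accuracy relative to the unpermuted input.
#' Raw drops are min-max normalised to `[0, 1]` (an all-equal degenerate case
#' returns zeros with a flag) and channels are ranked in descending order
#' with stable ties broken by channel id.
#'
#' @param model A fitted deep classifier (tensor input).
#' @param x Test tensor `N x C x T` or `fnirs_dataset` (N >= 2).
#' @param y True labels.
#' @param repeats Permutations per channel (default 10).
#' @param seed Seed.
#' @param channel_ids Channel names (default CH01..).
#' @return An object of class `importance_report`: data frame `channels`
#'   (channel, raw, normalized, rank), `clean_accuracy`, `repeats`, `seed`,
#'   `degenerate` flag.
#' @export
permutation_importance <- function(model, x, y, repeats = 10, seed = 1,
                                   channel_ids = NULL) {
  if (inherits(x, "fnirs_dataset")) {
    if (is.null(channel_ids)) channel_ids <- x$channel_ids
    x <- x$data
  }
  n <- dim(x)[1]; nch <- dim(x)[2]
  if (n < 2) stop("permutation_importance: need at least 2 test subjects")
  if (is.null(channel_ids)) channel_ids <- sprintf("CH%02d", seq_len(nch))
  classes <- c("HC", "HY1", "HY2")
  y <- factor(y, levels = classes)
  clean <- mean(predict(model, x, type = "class") == y)
  set.seed(as.integer(seed))
  raw <- numeric(nch)
  for (i in seq_len(nch)) {
    drops <- numeric(repeats)
    for (r in seq_len(repeats)) {
      perm <- sample.int(n)
      xp <- x
      xp[, i, ] <- x[perm, i, ]
      drops[r] <- clean - mean(predict(model, xp, type = "class") == y)
    }
    raw[i] <- mean(drops)
  }
  rng <- range(raw)
  degenerate <- diff(rng) <= .Machine$double.eps * max(abs(rng), 1)
  norm <- if (degenerate) rep(0, nch) else (raw - rng[1]) / diff(rng)
  ord <- order(-norm, channel_ids)
  rank <- integer(nch); rank[ord] <- seq_len(nch)
  structure(list(channels = data.frame(channel = channel_ids, raw = raw,
                                       normalized = norm, rank = rank,
                                       stringsAsFactors = FALSE),
                 clean_accuracy = clean, repeats = repeats, seed = seed,
                 degenerate = degenerate),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat(sprintf("Permutation importance (repeats=%d, clean accuracy %.3f)%s\n",
              x$repeats, x$clean_accuracy,
              if (x$degenerate) " [degenerate: all drops equal]" else ""))
  ch <- x$channels[order(x$channels$rank), ]
  print(utils::head(transform(ch, raw = round(raw, 4),
                              normalized = round(normalized, 3)), 10),
        row.names = FALSE)
  invisible(x)
}

#' Aggregate channel importance by anatomical region
#'
#' Region score = arithmetic mean of the member channels' normalised
#' importance; region order follows the layout.
#'
#' @param report An `importance_report`.
#' @param layout A [channel_layout()].
#' @return Data frame (region, mean_importance, n_channels), sorted by the
#'   layout's region order, with the descending ranking in column `rank`.
#' @export
aggregate_by_region <- function(report, layout = channel_layout()) {
  stopifnot(inherits(report, "importance_report"))
  ch <- report$channels
  if (!all(ch$channel %in% layout$channel))
    stop("aggregate_by_region: report contains channels missing from the layout")
  regions <- attr(layout, "region_levels")
  mi <- vapply(regions, function(r) {
    members <- layout$channel[layout$region == r]
    mean(ch$normalized[match(members, ch$channel)])
  }, numeric(1))
  out <- data.frame(region = regions, mean_importance = mi,
                    n_channels = as.integer(table(layout$region)[regions]),
                    stringsAsFactors = FALSE)
  out$rank <- rank(-out$mean_importance, ties.method = "first")
  out
}

# ---- exact t-SNE (small n) --------------------------------------------------

.tsne_p_matrix <- function(d2, perplexity) {
  n <- nrow(d2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      H <- log(sw) + beta * sum(di * w) / sw
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

.tsne <- function(x, dims = 2, perplexity = 30, max_iter = 500, seed = 1,
                  lr = 100) {
  n <- nrow(x)
  if (perplexity >= n / 3) stop("perplexity too large for the sample count")
  d2 <- as.matrix(stats::dist(x))^2
  P <- .tsne_p_matrix(d2, perplexity)
  set.seed(as.integer(seed))
  Y <- matrix(stats::rnorm(n * dims, 0, 1e-4), n, dims)
  inc <- matrix(0, n, dims)
  momentum <- 0.5
  P4 <- P * 4  # early exaggeration
  for (iter in seq_len(max_iter)) {
    Pi <- if (iter <= 100) P4 else P
    if (iter == 250) momentum <- 0.8
    dy2 <- as.matrix(stats::dist(Y))^2
    W <- 1 / (1 + dy2); diag(W) <- 0
    Q <- pmax(W / sum(W), 1e-12)
    L <- (Pi - Q) * W
    G <- 4 * (diag(rowSums(L)) - L) %*% Y
    inc <- momentum * inc - lr * G
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' t-SNE embedding of a model's penultimate-layer features
#'
#' Extracts the representation feeding the softmax head of a deep fit (the
#' LSTM's last hidden state) and embeds it with exact t-SNE (perplexity 30 or
#' 50; 2-d or 3-d), deterministically under `seed`.
#'
#' @param model A fitted `atlas_pd` or `lstm_net`.
#' @param x Input tensor or `fnirs_dataset`.
#' @param y Optional labels carried through for colouring.
#' @param perplexity t-SNE perplexity (must be < n/3).
#' @param dims 2 or 3.
#' @param seed Seed.
#' @param max_iter Gradient-descent iterations.
#' @return An object of class `embedding_result`: data frame `coords`
#'   (sample, label, Y1..Ydims) plus the settings.
#' @export
embed_features <- function(model, x, y = NULL, perplexity = 30, dims = 2,
                           seed = 1, max_iter = 500) {
  if (!dims %in% 2:3) stop("dims must be 2 or 3")
  if (inherits(x, "fnirs_dataset")) { if (is.null(y)) y <- x$labels }
  feats <- .penultimate_features(model, x)
  Y <- .tsne(feats, dims = dims, perplexity = perplexity, max_iter = max_iter,
             seed = seed)
  coords <- data.frame(sample = seq_len(nrow(Y)),
                       label = if (is.null(y)) NA else as.character(y))
  for (j in seq_len(dims)) coords[[paste0("Y", j)]] <- Y[, j]
  structure(list(coords = coords, perplexity = perplexity, dims = dims,
                 seed = seed),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("t-SNE embedding: %d samples, %d-d, perplexity %g\n",
              nrow(x$coords), x$dims, x$perplexity))
  invisible(x)
}

#' @export
plot.embedding_result <- function(x, ...) {
  lab <- factor(x$coords$label)
  plot(x$coords$Y1, x$coords$Y2, col = as.integer(lab), pch = 19,
       xlab = "t-SNE 1", ylab = "t-SNE 2")
  graphics::legend("topright", levels(lab), col = seq_along(levels(lab)),
                   pch = 19, bty = "n")
  invisible(x)
}
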