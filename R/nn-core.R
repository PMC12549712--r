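# Internal neural-network engine: linear / batch-norm / layer-norm /
# multi-head self-attention / feed-forward / LSTM layers with hand-derived
# backpropagation, trained with Adam. Matrix-op based so BLAS does the work.
# Naming convention: parameter matrices whose names start with "W" receive L2
# weight decay; biases (b*) and normalisation parameters (gamma/beta) do not.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.softmax_rows <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

.init_linear <- function(din, dout) {
  sd <- sqrt(2 / (din + dout))
  list(W = matrix(stats::rnorm(din * dout, 0, sd), din, dout),
       b = matrix(0, 1, dout))
}

.linear_fwd <- function(p, x) sweep(x %*% p$W, 2, p$b, "+")

.linear_bwd <- function(p, x, dy) {
  list(dx = dy %*% t(p$W),
       grads = list(W = crossprod(x, dy), b = matrix(colSums(dy), 1)))
}

# ---- batch norm over rows (features in columns) ----

.init_bn <- function(d) list(gamma = matrix(1, 1, d), beta = matrix(0, 1, d))

.bn_fwd <- function(p, x, state, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(sweep(x, 2, mu)^2)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else { mu <- state$mean; v <- state$var }
  xc <- sweep(x, 2, mu)
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv, "*")
  y <- sweep(sweep(xhat, 2, as.numeric(p$gamma), "*"), 2, as.numeric(p$beta), "+")
  list(y = y, cache = list(xc = xc, inv = inv, xhat = xhat), state = state)
}

.bn_bwd <- function(p, cache, dy) {
  n <- nrow(dy)
  dgamma <- matrix(colSums(dy * cache$xhat), 1)
  dbeta <- matrix(colSums(dy), 1)
  dxhat <- sweep(dy, 2, as.numeric(p$gamma), "*")
  # dX = inv/n * (n*dxhat - colSums(dxhat) - xhat * colSums(dxhat*xhat))
  t1 <- n * dxhat
  t2 <- matrix(colSums(dxhat), n, ncol(dy), byrow = TRUE)
  t3 <- cache$xhat * matrix(colSums(dxhat * cache$xhat), n, ncol(dy), byrow = TRUE)
  dx <- sweep(t1 - t2 - t3, 2, cache$inv / n, "*")
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# ---- layer norm per row ----

.init_ln <- function(d) list(gamma = matrix(1, 1, d), beta = matrix(0, 1, d))

.ln_fwd <- function(p, x, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(sweep(xhat, 2, as.numeric(p$gamma), "*"), 2, as.numeric(p$beta), "+")
  list(y = y, cache = list(xhat = xhat, inv = inv))
}

.ln_bwd <- function(p, cache, dy) {
  d <- ncol(dy)
  dgamma <- matrix(colSums(dy * cache$xhat), 1)
  dbeta <- matrix(colSums(dy), 1)
  dxhat <- sweep(dy, 2, as.numeric(p$gamma), "*")
  rs1 <- rowSums(dxhat)
  rs2 <- rowSums(dxhat * cache$xhat)
  dx <- cache$inv * (dxhat - rs1 / d - cache$xhat * rs2 / d)
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

.dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- matrix(stats::rbinom(length(x), 1, 1 - rate), nrow(x), ncol(x)) / (1 - rate)
  list(y = x * mask, mask = mask)
}

.dropout_bwd <- function(dy, mask) if (is.null(mask)) dy else dy * mask

# ---- multi-head self-attention (one sequence, T x d) ----

.init_mha <- function(d) {
  c(stats::setNames(lapply(1:4, function(i) .init_linear(d, d)$W),
                    c("Wq", "Wk", "Wv", "Wo")),
    list(bq = matrix(0, 1, d), bk = matrix(0, 1, d),
         bv = matrix(0, 1, d), bo = matrix(0, 1, d)))
}

.mha_fwd <- function(p, x, n_heads) {
  d <- ncol(x); dh <- d / n_heads
  Q <- sweep(x %*% p$Wq, 2, p$bq, "+")
  K <- sweep(x %*% p$Wk, 2, p$bk, "+")
  V <- sweep(x %*% p$Wv, 2, p$bv, "+")
  Cc <- matrix(0, nrow(x), d)
  A <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(dh)
    A[[h]] <- .softmax_rows(S)
    Cc[, idx] <- A[[h]] %*% V[, idx, drop = FALSE]
  }
  y <- sweep(Cc %*% p$Wo, 2, p$bo, "+")
  list(y = y, cache = list(x = x, Q = Q, K = K, V = V, A = A, Cc = Cc))
}

.mha_bwd <- function(p, cache, dy, n_heads) {
  x <- cache$x; d <- ncol(x); dh <- d / n_heads
  dWo <- crossprod(cache$Cc, dy)
  dbo <- matrix(colSums(dy), 1)
  dC <- dy %*% t(p$Wo)
  dQ <- dK <- dV <- matrix(0, nrow(x), d)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    Ah <- cache$A[[h]]
    dCh <- dC[, idx, drop = FALSE]
    dAh <- tcrossprod(dCh, cache$V[, idx, drop = FALSE])
    dV[, idx] <- crossprod(Ah, dCh)
    dS <- Ah * (dAh - rowSums(dAh * Ah))
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE] / sqrt(dh)
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE]) / sqrt(dh)
  }
  dx <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  list(dx = dx,
       grads = list(Wq = crossprod(x, dQ), Wk = crossprod(x, dK),
                    Wv = crossprod(x, dV), Wo = dWo,
                    bq = matrix(colSums(dQ), 1), bk = matrix(colSums(dK), 1),
                    bv = matrix(colSums(dV), 1), bo = dbo))
}

# ---- transformer encoder layer (post-norm residual blocks) ----

.init_encoder_layer <- function(d, d_ff) {
  list(attn = .init_mha(d), ln1 = .init_ln(d),
       ff1 = .init_linear(d, d_ff), ff2 = .init_linear(d_ff, d),
       ln2 = .init_ln(d))
}

.encoder_fwd <- function(p, x, n_heads, dropout, training) {
  a <- .mha_fwd(p$attn, x, n_heads)
  da <- .dropout_fwd(a$y, dropout, training)
  l1 <- .ln_fwd(p$ln1, x + da$y)
  h <- .linear_fwd(p$ff1, l1$y)
  hr <- pmax(h, 0)
  f <- .linear_fwd(p$ff2, hr)
  df <- .dropout_fwd(f, dropout, training)
  l2 <- .ln_fwd(p$ln2, l1$y + df$y)
  list(y = l2$y, cache = list(a = a, da = da, l1 = l1, h = h, hr = hr,
                              f = f, df = df, l2 = l2, x = x))
}

.encoder_bwd <- function(p, cache, dy, n_heads) {
  g <- list()
  b2 <- .ln_bwd(p$ln2, cache$l2$cache, dy); g$ln2 <- b2$grads
  dff <- .dropout_bwd(b2$dx, cache$df$mask)
  bf2 <- .linear_bwd(p$ff2, cache$hr, dff); g$ff2 <- bf2$grads
  dh <- bf2$dx * (cache$h > 0)
  bf1 <- .linear_bwd(p$ff1, cache$l1$y, dh); g$ff1 <- bf1$grads
  dl1y <- b2$dx + bf1$dx
  b1 <- .ln_bwd(p$ln1, cache$l1$cache, dl1y); g$ln1 <- b1$grads
  datt <- .dropout_bwd(b1$dx, cache$da$mask)
  ba <- .mha_bwd(p$attn, cache$a$cache, datt, n_heads); g$attn <- ba$grads
  list(dx = b1$dx + ba$dx, grads = g)
}

# ---- LSTM layer over a (T, B, din) array ----

.init_lstm <- function(din, h) {
  sd <- sqrt(1 / h)
  p <- list(Wx = matrix(stats::rnorm(din * 4 * h, 0, sqrt(2 / (din + 4 * h))), din, 4 * h),
            Wh = matrix(stats::rnorm(h * 4 * h, 0, sd), h, 4 * h),
            b = matrix(0, 1, 4 * h))
  p$b[1, (h + 1):(2 * h)] <- 1  # forget-gate bias
  p
}

# x3: array (T, B, din). Returns all hidden states as (T, B, h) plus caches.
.lstm_fwd <- function(p, x3) {
  Tn <- dim(x3)[1]; B <- dim(x3)[2]; din <- dim(x3)[3]
  h <- ncol(p$Wh)/4
  x2 <- matrix(x3, Tn * B, din)
  xw <- sweep(x2 %*% p$Wx, 2, p$b, "+")   # (T*B) x 4h
  H <- array(0, c(Tn, B, h))
  ii <- ff <- gg <- oo <- cc <- tc <- array(0, c(Tn, B, h))
  hprev_all <- matrix(0, Tn * B, h)
  hh <- matrix(0, B, h); cs <- matrix(0, B, h)
  i_idx <- 1:h; f_idx <- (h + 1):(2 * h); g_idx <- (2 * h + 1):(3 * h); o_idx <- (3 * h + 1):(4 * h)
  for (t in seq_len(Tn)) {
    rows <- t + (0:(B - 1)) * Tn
    hprev_all[rows, ] <- hh
    G <- xw[rows, , drop = FALSE] + hh %*% p$Wh
    i_g <- .sigmoid(G[, i_idx, drop = FALSE]); f_g <- .sigmoid(G[, f_idx, drop = FALSE])
    g_g <- tanh(G[, g_idx, drop = FALSE]);     o_g <- .sigmoid(G[, o_idx, drop = FALSE])
    cs <- f_g * cs + i_g * g_g
    tch <- tanh(cs)
    hh <- o_g * tch
    H[t, , ] <- hh
    ii[t, , ] <- i_g; ff[t, , ] <- f_g; gg[t, , ] <- g_g; oo[t, , ] <- o_g
    cc[t, , ] <- cs; tc[t, , ] <- tch
  }
  list(H = H, h_last = hh,
       cache = list(x2 = x2, hprev_all = hprev_all, i = ii, f = ff, g = gg,
                    o = oo, c = cc, tc = tc, Tn = Tn, B = B, h = h))
}

# dH: either array (T, B, h) of upstream gradients for every step, or NULL;
# dh_last: (B x h) gradient on the final hidden state.
.lstm_bwd <- function(p, cache, dH = NULL, dh_last = NULL) {
  Tn <- cache$Tn; B <- cache$B; h <- cache$h
  dG_all <- matrix(0, Tn * B, 4 * h)
  dh <- if (is.null(dh_last)) matrix(0, B, h) else dh_last
  dc <- matrix(0, B, h)
  i_idx <- 1:h; f_idx <- (h + 1):(2 * h); g_idx <- (2 * h + 1):(3 * h); o_idx <- (3 * h + 1):(4 * h)
  for (t in rev(seq_len(Tn))) {
    if (!is.null(dH)) dh <- dh + matrix(dH[t, , ], B, h)
    i_g <- matrix(cache$i[t, , ], B, h); f_g <- matrix(cache$f[t, , ], B, h)
    g_g <- matrix(cache$g[t, , ], B, h); o_g <- matrix(cache$o[t, , ], B, h)
    tch <- matrix(cache$tc[t, , ], B, h)
    c_prev <- if (t > 1) matrix(cache$c[t - 1, , ], B, h) else matrix(0, B, h)
    do_ <- dh * tch
    dc <- dc + dh * o_g * (1 - tch^2)
    di <- dc * g_g; df <- dc * c_prev; dg <- dc * i_g
    dG <- cbind(di * i_g * (1 - i_g), df * f_g * (1 - f_g),
                dg * (1 - g_g^2), do_ * o_g * (1 - o_g))
    rows <- t + (0:(B - 1)) * Tn
    dG_all[rows, ] <- dG
    dh <- dG %*% t(p$Wh)
    dc <- dc * f_g
  }
  dx2 <- dG_all %*% t(p$Wx)
  list(dx3 = array(dx2, c(Tn, B, nrow(p$Wx))),
       grads = list(Wx = crossprod(cache$x2, dG_all),
                    Wh = crossprod(cache$hprev_all, dG_all),
                    b = matrix(colSums(dG_all), 1)))
}

# ---- sinusoidal positional encoding ----

.positional_encoding <- function(Tn, d) {
  pos <- seq_len(Tn) - 1
  pe <- matrix(0, Tn, d)
  for (k in seq_len(ceiling(d / 2))) {
    freq <- 1 / 10000^((2 * (k - 1)) / d)
    pe[, 2 * k - 1] <- sin(pos * freq)
    if (2 * k <= d) pe[, 2 * k] <- cos(pos * freq)
  }
  pe
}

# ---- parameter-tree helpers (Adam, cloning, decay) ----

.tree_walk <- function(params, grads, f) {
  # apply f(name, p, g) to every numeric leaf; returns modified params tree
  rec <- function(p, g) {
    if (is.numeric(p)) stop("unreachable")
    out <- p
    for (nm in names(p)) {
      if (is.list(p[[nm]])) out[[nm]] <- rec(p[[nm]], g[[nm]])
      else out[[nm]] <- f(nm, p[[nm]], g[[nm]])
    }
    out
  }
  rec(params, grads)
}

.tree_zeros <- function(params) {
  rec <- function(p) {
    out <- p
    for (nm in names(p)) {
      if (is.list(p[[nm]])) out[[nm]] <- rec(p[[nm]])
      else out[[nm]] <- p[[nm]] * 0
    }
    out
  }
  rec(params)
}

.adam_new <- function(params) list(m = .tree_zeros(params), v = .tree_zeros(params), t = 0)

.adam_step <- function(params, grads, state, lr, l2 = 0,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8, clip = 5) {
  # global-norm gradient clipping for stability
  sq <- 0
  acc <- function(p, g) for (nm in names(p)) {
    if (is.list(p[[nm]])) acc(p[[nm]], g[[nm]]) else sq <<- sq + sum(g[[nm]]^2)
  }
  acc(params, grads)
  gnorm <- sqrt(sq)
  scale <- if (is.finite(gnorm) && gnorm > clip) clip / gnorm else 1
  state$t <- state$t + 1
  t <- state$t
  upd <- function(pp, gg, mm, vv, path_decay) {
    rec <- function(p, g, m, v) {
      for (nm in names(p)) {
        if (is.list(p[[nm]])) {
          r <- rec(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
          p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
        } else {
          gr <- g[[nm]] * scale
          if (l2 > 0 && startsWith(nm, "W")) gr <- gr + 2 * l2 * p[[nm]]
          m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * gr
          v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * gr^2
          mh <- m[[nm]] / (1 - beta1^t)
          vh <- v[[nm]] / (1 - beta2^t)
          p[[nm]] <- p[[nm]] - lr * mh / (sqrt(vh) + eps)
        }
      }
      list(p = p, m = m, v = v)
    }
    rec(pp, gg, mm, vv)
  }
  r <- upd(params, grads, state$m, state$v)
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}

.tree_add <- function(a, b) {
  for (nm in names(a)) {
    if (is.list(a[[nm]])) a[[nm]] <- .tree_add(a[[nm]], b[[nm]])
    else a[[nm]] <- a[[nm]] + b[[nm]]
  }
  a
}

.l2_penalty <- function(params, l2) {
  if (l2 <= 0) return(0)
  s <- 0
  rec <- function(p) for (nm in names(p)) {
    if (is.list(p[[nm]])) rec(p[[nm]])
    else if (startsWith(nm, "W")) s <<- s + sum(p[[nm]]^2)
  }
  rec(params)
  l2 * s
}
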