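# Minimal feed-forward conv-net engine on BLAS matrix products.
#
# Feature maps are dense arrays with dims (N, H, W, C), column-major, so
# matrix(x, ncol = C) flattens (sample, row, col) into rows without
# copying semantics getting in the way. Convolutions are evaluated with
# im2col plus one GEMM, which keeps the whole training loop inside BLAS. Everything is deterministic given the
# seed and thread count.

conv_out_dim <- function(n, k, s) (n - k) %/% s + 1L

# Forward convolution via im2col (compiled kernel) plus one GEMM. W has
# dims (kh, kw, Cin, Cout); pad is c(ph, pw); stride c(sh, sw). The column
# matrix is cached for the backward pass so the input is traversed once.
conv_fwd <- function(x, W, b, stride = c(1L, 1L), pad = c(0L, 0L),
                     keep_cache = TRUE) {
  d <- dim(W)
  kh <- d[1]; kw <- d[2]; cin <- d[3]; cout <- d[4]
  dx <- dim(x)
  col <- im2col_nhwc(x, as.integer(dx), kh, kw, stride[1], stride[2],
                     pad[1], pad[2])
  h2 <- conv_out_dim(dx[2] + 2L * pad[1], kh, stride[1])
  w2 <- conv_out_dim(dx[3] + 2L * pad[2], kw, stride[2])
  out <- col %*% matrix(W, kh * kw * cin, cout)
  out <- out + rep(b, each = nrow(col))
  out <- array(out, c(dx[1], h2, w2, cout))
  if (keep_cache) {
    list(out = out, col = col, in_dim = dx)
  } else {
    list(out = out)
  }
}

# Backward convolution from the cached column matrix.
conv_bwd <- function(dy, col, W, stride, pad, input_dim) {
  d <- dim(W)
  kh <- d[1]; kw <- d[2]; cin <- d[3]; cout <- d[4]
  cout_rows <- dim(dy)[1] * dim(dy)[2] * dim(dy)[3]
  dy_mat <- matrix(dy, cout_rows, cout)
  dW <- array(crossprod(col, dy_mat), dim(W))
  db <- colSums(dy_mat)
  dcol <- dy_mat %*% t(matrix(W, kh * kw * cin, cout))
  dx <- col2im_nhwc(dcol, as.integer(input_dim), kh, kw, stride[1],
                    stride[2], pad[1], pad[2])
  list(dW = dW, db = db, dx = dx)
}

# Non-overlapping average pooling and its adjoint. Trailing rows/cols
# that do not fill a cell are dropped; the backward pass restores them as
# zeros.
pool_fwd <- function(x, ph, pw) {
  d <- dim(x)
  h2 <- d[2] %/% ph; w2 <- d[3] %/% pw
  xc <- x[, seq_len(h2 * ph), seq_len(w2 * pw), , drop = FALSE]
  dim(xc) <- c(d[1], ph, h2, pw, w2, d[4])
  out <- array(0, c(d[1], h2, w2, d[4]))
  for (r in seq_len(ph)) {
    for (s2 in seq_len(pw)) {
      sl <- xc[, r, , s2, , , drop = FALSE]
      dim(sl) <- c(d[1], h2, w2, d[4])
      out <- out + sl
    }
  }
  out / (ph * pw)
}

pool_bwd <- function(dy, ph, pw, input_dim) {
  d <- dim(dy)
  g <- dy / (ph * pw)
  dxr <- array(0, c(d[1], ph, d[2], pw, d[3], d[4]))
  for (r in seq_len(ph)) {
    for (s2 in seq_len(pw)) {
      dxr[, r, , s2, , ] <- g
    }
  }
  dim(dxr) <- c(d[1], ph * d[2], pw * d[3], d[4])
  if (ph * d[2] == input_dim[2] && pw * d[3] == input_dim[3]) return(dxr)
  dx <- array(0, input_dim)
  dx[, seq_len(ph * d[2]), seq_len(pw * d[3]), ] <- dxr
  dx
}

relu_fwd <- function(x) {
  x[x < 0] <- 0
  x
}

relu_bwd <- function(dy, out) {
  dy[out <= 0] <- 0
  dy
}

# Global average pooling: (N, H, W, C) -> (N, C).
gap_fwd <- function(x) {
  d <- dim(x)
  xm <- array(x, c(d[1], d[2] * d[3], d[4]))
  out <- matrix(0, d[1], d[4])
  for (c in seq_len(d[4])) out[, c] <- rowMeans(xm[, , c, drop = FALSE])
  out
}

gap_bwd <- function(dy, input_dim) {
  n <- input_dim[1]; h <- input_dim[2]; w <- input_dim[3]; c <- input_dim[4]
  scale <- 1 / (h * w)
  array(rep(dy * scale, each = 1), c(n, 1, 1, c))[, rep(1, h), rep(1, w), ,
                                                  drop = FALSE]
}

concat_c <- function(xs) {
  d <- dim(xs[[1]])
  cs <- vapply(xs, function(x) dim(x)[4], 1L)
  array(unlist(xs, use.names = FALSE), c(d[1], d[2], d[3], sum(cs)))
}

split_c <- function(dy, cs) {
  out <- vector("list", length(cs))
  at <- 0L
  for (i in seq_along(cs)) {
    out[[i]] <- dy[, , , (at + 1L):(at + cs[i]), drop = FALSE]
    at <- at + cs[i]
  }
  out
}

# PyTorch-style uniform initialization bounded by 1/sqrt(fan_in).
init_uniform <- function(dims, fan_in) {
  bound <- 1 / sqrt(fan_in)
  array(stats::runif(prod(dims), -bound, bound), dims)
}

init_conv <- function(kh, kw, cin, cout) {
  list(W = init_uniform(c(kh, kw, cin, cout), kh * kw * cin),
       b = numeric(cout))
}

init_dense <- function(fin, fout = 1L) {
  list(W = init_uniform(c(fin, fout), fin), b = numeric(fout))
}

# ---------------------------------------------------------------------------
# Architectures. All families share a strided "spectral stem": a 32 x 1
# axial convolution (stride 16) whose filters are long enough to act as
# learned band-pass filters on the RF carrier, followed by rectification
# and average pooling across the entire lateral axis. Pooling raw RF
# would cancel the carrier and destroy the spectral information; pooling
# rectified band energies is the standard incoherent estimate. Lateral
# structure is deliberately pooled away: it reflects machine-specific
# beam geometry rather than tissue.

nn_init_params <- function(spec) {
  h <- spec$input_shape[1]; w <- spec$input_shape[2]
  stem_k <- c(32L, 1L); stem_s <- c(16L, 1L)
  if (h < stem_k[1] || w < stem_k[2]) {
    stop("input shape smaller than the receptive field", call. = FALSE)
  }
  c0 <- spec$base_channels
  params <- list(stem = init_conv(stem_k[1], stem_k[2], 1L, c0))
  h2 <- conv_out_dim(h, stem_k[1], stem_s[1])
  w2 <- conv_out_dim(w, stem_k[2], stem_s[2])
  if (spec$family == "dense_style") {
    cin <- c0
    for (bk in seq_len(spec$n_blocks)) {
      params[[paste0("block", bk)]] <- init_conv(3L, 3L, cin, c0)
      cin <- cin + c0
    }
    params$head <- init_dense(cin)
  } else if (spec$family == "residual_style") {
    for (bk in seq_len(spec$n_blocks)) {
      params[[paste0("block", bk, "a")]] <- init_conv(3L, 3L, c0, c0)
      params[[paste0("block", bk, "b")]] <- init_conv(3L, 3L, c0, c0)
    }
    params$head <- init_dense(c0)
  } else if (spec$family == "linear_baseline") {
    params <- list(head = init_dense(h * w))
  } else {
    stop("unknown family: ", spec$family, call. = FALSE)
  }
  attr(params, "stem_dims") <- c(h2, w2)
  params
}

# Forward pass to logits. `x` has dims (N, H, W, 1). With keep_cache the
# intermediate activations needed by nn_backward are returned.
nn_forward <- function(params, x, spec, keep_cache = FALSE) {
  cache <- list(x_dim = dim(x))
  if (spec$family == "linear_baseline") {
    flat <- matrix(x, nrow = dim(x)[1])
    logits <- drop(flat %*% params$head$W) + params$head$b
    cache$flat <- if (keep_cache) flat else NULL
    return(list(logits = logits, cache = cache))
  }
  st <- conv_fwd(x, params$stem$W, params$stem$b, stride = c(16L, 1L),
                 pad = c(0L, 0L), keep_cache = keep_cache)
  a0 <- relu_fwd(st$out)
  d0 <- dim(a0)
  # average away the lateral axis entirely: lateral speckle texture is
  # machine-specific (beam geometry), while rectified axial band energy
  # transfers across machines
  pool <- c(min(2L, d0[2]), d0[3])
  a <- pool_fwd(a0, pool[1], pool[2])
  cache$stem <- if (keep_cache) {
    list(col = st$col, out = a0, pool = pool, pre_pool_dim = d0)
  } else NULL
  if (spec$family == "dense_style") {
    feats <- list(a)
    for (bk in seq_len(spec$n_blocks)) {
      inb <- concat_c(feats)
      p <- params[[paste0("block", bk)]]
      cv <- conv_fwd(inb, p$W, p$b, stride = c(1L, 1L), pad = c(1L, 1L),
                     keep_cache = keep_cache)
      ab <- relu_fwd(cv$out)
      if (keep_cache) {
        cache[[paste0("block", bk)]] <-
          list(col = cv$col, out = ab, in_dim = dim(inb))
      }
      feats[[bk + 1L]] <- ab
    }
    top <- concat_c(feats)
    cache$feat_channels <- vapply(feats, function(f) dim(f)[4], 1L)
  } else {
    h <- a
    for (bk in seq_len(spec$n_blocks)) {
      pa <- params[[paste0("block", bk, "a")]]
      pb <- params[[paste0("block", bk, "b")]]
      c1 <- conv_fwd(h, pa$W, pa$b, stride = c(1L, 1L), pad = c(1L, 1L),
                     keep_cache = keep_cache)
      t1 <- relu_fwd(c1$out)
      c2 <- conv_fwd(t1, pb$W, pb$b, stride = c(1L, 1L), pad = c(1L, 1L),
                     keep_cache = keep_cache)
      hn <- relu_fwd(h + c2$out)
      if (keep_cache) {
        cache[[paste0("block", bk)]] <-
          list(col1 = c1$col, t1 = t1, col2 = c2$col,
               h_dim = dim(h), out = hn)
      }
      h <- hn
    }
    top <- h
  }
  g <- gap_fwd(top)
  logits <- drop(g %*% params$head$W) + params$head$b
  if (keep_cache) {
    cache$top_dim <- dim(top)
    cache$gap <- g
  }
  list(logits = logits, cache = cache)
}

# Backward pass from dlogits; returns gradients with the params layout.
nn_backward <- function(params, spec, cache, dlogits) {
  grads <- list()
  if (spec$family == "linear_baseline") {
    grads$head <- list(W = crossprod(cache$flat, matrix(dlogits)),
                       b = sum(dlogits))
    return(grads)
  }
  g <- cache$gap
  grads$head <- list(W = crossprod(g, matrix(dlogits)), b = sum(dlogits))
  dgap <- matrix(dlogits) %*% t(params$head$W)
  dtop <- gap_bwd(dgap, cache$top_dim)
  if (spec$family == "dense_style") {
    dfeats <- split_c(dtop, cache$feat_channels)
    for (bk in rev(seq_len(spec$n_blocks))) {
      cc <- cache[[paste0("block", bk)]]
      day <- relu_bwd(dfeats[[bk + 1L]], cc$out)
      p <- params[[paste0("block", bk)]]
      bw <- conv_bwd(day, cc$col, p$W, stride = c(1L, 1L),
                     pad = c(1L, 1L), input_dim = cc$in_dim)
      grads[[paste0("block", bk)]] <- list(W = bw$dW, b = bw$db)
      dins <- split_c(bw$dx, cache$feat_channels[seq_len(bk)])
      for (i in seq_len(bk)) dfeats[[i]] <- dfeats[[i]] + dins[[i]]
    }
    dstem <- dfeats[[1L]]
  } else {
    dh <- dtop
    for (bk in rev(seq_len(spec$n_blocks))) {
      cc <- cache[[paste0("block", bk)]]
      dsum <- relu_bwd(dh, cc$out)
      pb <- params[[paste0("block", bk, "b")]]
      pa <- params[[paste0("block", bk, "a")]]
      bw2 <- conv_bwd(dsum, cc$col2, pb$W, stride = c(1L, 1L),
                      pad = c(1L, 1L), input_dim = dim(cc$t1))
      grads[[paste0("block", bk, "b")]] <- list(W = bw2$dW, b = bw2$db)
      dt1 <- relu_bwd(bw2$dx, cc$t1)
      bw1 <- conv_bwd(dt1, cc$col1, pa$W, stride = c(1L, 1L),
                      pad = c(1L, 1L), input_dim = cc$h_dim)
      grads[[paste0("block", bk, "a")]] <- list(W = bw1$dW, b = bw1$db)
      dh <- dsum + bw1$dx
    }
    dstem <- dh
  }
  dstem <- pool_bwd(dstem, cache$stem$pool[1], cache$stem$pool[2],
                    cache$stem$pre_pool_dim)
  dstem <- relu_bwd(dstem, cache$stem$out)
  bw <- conv_bwd(dstem, cache$stem$col, params$stem$W,
                 stride = c(16L, 1L), pad = c(0L, 0L),
                 input_dim = cache$x_dim)
  grads$stem <- list(W = bw$dW, b = bw$db)
  grads
}

# Numerically stable per-sample binary cross-entropy from logits.
bce_from_logits <- function(logits, y) {
  pmax(logits, 0) - logits * y + log1p(exp(-abs(logits)))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# ---------------------------------------------------------------------------
# Adam optimizer over the nested parameter list.

adam_init <- function(params) {
  zero_like <- function(p) lapply(p, function(a) {
    if (is.null(dim(a))) numeric(length(a)) else array(0, dim(a))
  })
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (layer in names(params)) {
    for (slot in names(params[[layer]])) {
      g <- grads[[layer]][[slot]]
      m <- beta1 * state$m[[layer]][[slot]] + (1 - beta1) * g
      v <- beta2 * state$v[[layer]][[slot]] + (1 - beta2) * g^2
      state$m[[layer]][[slot]] <- m
      state$v[[layer]][[slot]] <- v
      params[[layer]][[slot]] <- params[[layer]][[slot]] -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  list(params = params, state = state)
}

# Forward in evaluation batches; returns logits for all rows of X (n,h,w).
nn_predict_logits <- function(params, spec, X, batch_size = 512L) {
  n <- dim(X)[1]
  out <- numeric(n)
  at <- 1L
  while (at <= n) {
    idx <- at:min(n, at + batch_size - 1L)
    xb <- array(X[idx, , , drop = FALSE],
                c(length(idx), dim(X)[2], dim(X)[3], 1L))
    out[idx] <- nn_forward(params, xb, spec)$logits
    at <- at + batch_size
  }
  out
}

# One optimization epoch over `idx` (already shuffled); returns updated
# params/state and the mean batch loss.
nn_epoch <- function(params, state, spec, X, y, idx, lr, batch_size,
                     augment_probability) {
  losses <- numeric(0)
  at <- 1L
  while (at <= length(idx)) {
    bi <- idx[at:min(length(idx), at + batch_size - 1L)]
    xb <- X[bi, , , drop = FALSE]
    if (augment_probability > 0) {
      xb <- augment_flip(xb, augment_probability)
    }
    xb <- array(xb, c(length(bi), dim(X)[2], dim(X)[3], 1L))
    fw <- nn_forward(params, xb, spec, keep_cache = TRUE)
    yb <- y[bi]
    losses <- c(losses, mean(bce_from_logits(fw$logits, yb)))
    dlogits <- (sigmoid(fw$logits) - yb) / length(bi)
    grads <- nn_backward(params, spec, fw$cache, dlogits)
    upd <- adam_step(params, grads, state, lr)
    params <- upd$params
    state <- upd$state
    at <- at + batch_size
  }
  list(params = params, state = state, loss = mean(losses))
}
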