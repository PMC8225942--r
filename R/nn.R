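# Minimal convolutional-network primitives used by the multi-task U-Net.
# Activations are stored as (H*W*N) x C matrices: within one image, pixels in
# column-major order; images stacked along rows. Convolutions are evaluated
# as sums of 9 shifted matrix products against per-offset weight matrices,
# which keeps every heavy operation inside BLAS.

.icgflow_idx_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .icgflow_idx_cache)) {
    assign(key, builder(), envir = .icgflow_idx_cache)
  }
  get(key, envir = .icgflow_idx_cache)
}

# 3x3 "same" convolution gather indices: rows x 9 integer matrix giving, for
# each of the 9 offsets, the source row feeding each output pixel;
# out-of-frame sources point at the sentinel row `rows + 1` (implicit zero).
conv3_idx <- function(H, W, N) {
  cache_get(sprintf("c3_%d_%d_%d", H, W, N), function() {
    sentinel <- H * W * N + 1L
    r <- rep(seq_len(H), W); cc <- rep(seq_len(W), each = H)
    out <- matrix(0L, H * W * N, 9L)
    k <- 1L
    for (dc in -1:1) for (dr in -1:1) {
      rr <- r + dr; c2 <- cc + dc
      ok <- rr >= 1L & rr <= H & c2 >= 1L & c2 <= W
      lin <- ifelse(ok, (c2 - 1L) * H + rr, NA_integer_)
      full <- as.vector(outer(lin, (seq_len(N) - 1L) * H * W, "+"))
      full[is.na(full)] <- sentinel
      out[, k] <- as.integer(full)
      k <- k + 1L
    }
    out
  })
}

# 2x2 max-pool gather indices (H, W even): 4 source rows per output pixel.
pool_idx <- function(H, W, N) {
  cache_get(sprintf("p2_%d_%d_%d", H, W, N), function() {
    h2 <- H %/% 2L; w2 <- W %/% 2L
    r2 <- rep(seq_len(h2), w2); c2 <- rep(seq_len(w2), each = h2)
    out <- vector("list", 4L)
    k <- 1L
    for (dc in 0:1) for (dr in 0:1) {
      rs <- 2L * r2 - 1L + dr; cs <- 2L * c2 - 1L + dc
      lin <- (cs - 1L) * H + rs
      out[[k]] <- as.integer(as.vector(outer(lin, (seq_len(N) - 1L) * H * W, "+")))
      k <- k + 1L
    }
    out
  })
}

# 2x2 stride-2 up-convolution scatter indices: each input pixel writes a
# 2x2 block in the (2H x 2W) output.
up_idx <- function(H, W, N) {
  cache_get(sprintf("u2_%d_%d_%d", H, W, N), function() {
    r <- rep(seq_len(H), W); cc <- rep(seq_len(W), each = H)
    H2 <- 2L * H
    out <- vector("list", 4L)
    k <- 1L
    for (dc in 0:1) for (dr in 0:1) {
      ro <- 2L * r - 1L + dr; co <- 2L * cc - 1L + dc
      lin <- (co - 1L) * H2 + ro
      out[[k]] <- as.integer(as.vector(outer(lin, (seq_len(N) - 1L) * 4L * H * W, "+")))
      k <- k + 1L
    }
    out
  })
}

# Weight rows are ordered offset-fast within channel (matching the im2col
# column layout produced by conv3_cols).
conv3_init <- function(c_in, c_out) {
  sd <- sqrt(2 / (9 * c_in))
  list(W = matrix(stats::rnorm(9 * c_in * c_out, 0, sd), 9 * c_in, c_out),
       b = numeric(c_out))
}

conv1_init <- function(c_in, c_out) {
  sd <- sqrt(2 / c_in)
  list(W = matrix(stats::rnorm(c_in * c_out, 0, sd), c_in, c_out),
       b = numeric(c_out))
}

up_init <- function(c_in, c_out) {
  sd <- sqrt(2 / c_in)
  list(W = lapply(1:4, function(k) matrix(stats::rnorm(c_in * c_out, 0, sd),
                                          c_in, c_out)),
       b = numeric(c_out))
}

# Forward / backward of the 3x3 convolution; the fused im2col + GEMM kernels
# live in src/conv.cpp. Weight rows follow the im2col column layout
# (offset-fast within channel).
conv3_fw <- function(x, par, idx) {
  cpp_conv3_fw(x, idx, par$W, par$b)
}

conv3_bw <- function(dout, x, par, idx) {
  g <- cpp_conv3_bw(dout, x, idx, par$W)
  list(dx = g$dx, grad = list(W = g$dW, b = as.numeric(g$db)))
}

relu_fw <- function(x) { x[x < 0] <- 0; x }
relu_bw <- function(dout, act) { dout[act <= 0] <- 0; dout }

pool_fw <- function(x, idx) {
  m <- x[idx[[1]], , drop = FALSE]
  arg <- matrix(idx[[1]], nrow(m), ncol(m))
  for (k in 2:4) {
    a <- x[idx[[k]], , drop = FALSE]
    upd <- a > m
    m[upd] <- a[upd]
    arg[upd] <- matrix(idx[[k]], nrow(m), ncol(m))[upd]
  }
  list(out = m, arg = arg)
}

pool_bw <- function(dout, arg, n_in) {
  dx <- matrix(0, n_in, ncol(dout))
  dx[cbind(as.vector(arg), rep(seq_len(ncol(dout)), each = nrow(dout)))] <-
    as.vector(dout)
  dx
}

up_fw <- function(x, par, idx) {
  out <- matrix(par$b, 4L * nrow(x), length(par$b), byrow = TRUE)
  for (k in 1:4) out[idx[[k]], ] <- out[idx[[k]], , drop = FALSE] +
      x %*% par$W[[k]]
  out
}

up_bw <- function(dout, x, par, idx) {
  dW <- vector("list", 4L)
  dx <- matrix(0, nrow(x), ncol(x))
  for (k in 1:4) {
    dk <- dout[idx[[k]], , drop = FALSE]
    dW[[k]] <- crossprod(x, dk)
    dx <- dx + dk %*% t(par$W[[k]])
  }
  list(dx = dx, grad = list(W = dW, b = colSums(dout)))
}

conv1_fw <- function(x, par) {
  sweep(x %*% par$W, 2, par$b, "+")
}

conv1_bw <- function(dout, x, par) {
  list(dx = dout %*% t(par$W),
       grad = list(W = crossprod(x, dout), b = colSums(dout)))
}

softmax2 <- function(z) {
  m <- pmax(z[, 1], z[, 2])
  e1 <- exp(z[, 1] - m); e2 <- exp(z[, 2] - m)
  s <- e1 + e2
  cbind(e1 / s, e2 / s)
}

# Adam update, walking a nested parameter list. State is a mirrored list of
# first/second moment estimates.
adam_init <- function(params) {
  walk <- function(p) {
    if (is.list(p)) lapply(p, walk) else p * 0
  }
  list(m = walk(params), v = walk(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      res <- mapply(upd, p, g, m, v, SIMPLIFY = FALSE)
      list(p = lapply(res, `[[`, "p"), m = lapply(res, `[[`, "m"),
           v = lapply(res, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mh <- m / (1 - beta1^t); vh <- v / (1 - beta2^t)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
    }
  }
  res <- upd(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = t))
}
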