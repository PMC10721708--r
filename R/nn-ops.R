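# Primitive differentiable operations for the two-pathway network.
#
# Array layout everywhere: (H, W, T, C, N) — spatial dims first so a frame
# is an ordinary matrix, channels fourth, batch last.  Convolutions run
# through the compiled im2col kernels; everything else is vectorized R.
# Each *_f returns list(y, cache); each *_b consumes (cache, dy).

conv_pad <- function(w) as.integer(dim(w)[1:3] %/% 2L)

conv_f <- function(x, w, b, stride = c(1L, 1L, 1L), keep_col = TRUE) {
  stopifnot(dim(x)[4] == dim(w)[4])
  res <- .cpp_conv3d_forward(x, dim(x), w, dim(w), b,
                             as.integer(stride), conv_pad(w), keep_col)
  list(y = res$y, cache = list(col = res$col, dimx = dim(x), w = w,
                               stride = as.integer(stride)))
}

conv_b <- function(cache, dy) {
  g <- .cpp_conv3d_backward(cache$col, cache$dimx, cache$w, dim(cache$w),
                            dy, cache$stride, conv_pad(cache$w))
  list(dx = g$dx, dw = g$dw, db = g$db)
}

relu_f <- function(x) {
  y <- x
  y[y < 0] <- 0
  list(y = y, cache = x > 0)
}

relu_b <- function(cache, dy) dy * cache

# 2x2 spatial average pooling, stride 2; an odd trailing row/column is
# dropped.
avgpool2_f <- function(x) {
  d <- dim(x)
  H2 <- d[1] %/% 2L
  W2 <- d[2] %/% 2L
  ro <- seq.int(1L, 2L * H2, 2L)
  co <- seq.int(1L, 2L * W2, 2L)
  y <- (x[ro, co, , , , drop = FALSE] + x[ro + 1L, co, , , , drop = FALSE] +
        x[ro, co + 1L, , , , drop = FALSE] +
        x[ro + 1L, co + 1L, , , , drop = FALSE]) / 4
  list(y = y, cache = d)
}

avgpool2_b <- function(cache, dy) {
  d <- cache
  H2 <- d[1] %/% 2L
  W2 <- d[2] %/% 2L
  ro <- seq.int(1L, 2L * H2, 2L)
  co <- seq.int(1L, 2L * W2, 2L)
  dx <- array(0, dim = d)
  q <- dy / 4
  dx[ro, co, , , ] <- q
  dx[ro + 1L, co, , , ] <- dx[ro + 1L, co, , , , drop = FALSE] + q
  dx[ro, co + 1L, , , ] <- dx[ro, co + 1L, , , , drop = FALSE] + q
  dx[ro + 1L, co + 1L, , , ] <- dx[ro + 1L, co + 1L, , , , drop = FALSE] + q
  dx
}

# Global average pooling over (H, W, T): (H,W,T,C,N) -> C x N matrix.
gap_f <- function(x) {
  d <- dim(x)
  m <- x
  dim(m) <- c(prod(d[1:3]), d[4], d[5])
  list(y = colMeans(m), cache = d)
}

gap_b <- function(cache, dy) {
  d <- cache
  HWT <- prod(d[1:3])
  dx <- rep(as.vector(dy) / HWT, each = HWT)
  dim(dx) <- d
  dx
}

linear_f <- function(x, w, b) {
  list(y = w %*% x + b, cache = list(x = x, w = w))
}

linear_b <- function(cache, dy) {
  list(dx = crossprod(cache$w, dy), dw = tcrossprod(dy, cache$x),
       db = rowSums(dy))
}

# Inverted dropout on a C x N feature matrix.
dropout_f <- function(x, p, training) {
  if (!training || p <= 0) return(list(y = x, cache = NULL))
  mask <- matrix((runif(length(x)) >= p) / (1 - p), nrow(x), ncol(x))
  list(y = x * mask, cache = mask)
}

dropout_b <- function(cache, dy) if (is.null(cache)) dy else dy * cache

# Channel-wise concatenation of two (H,W,T,C,N) arrays.
concat_f <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  y <- array(0, dim = c(da[1:3], da[4] + db[4], da[5]))
  y[, , , seq_len(da[4]), ] <- a
  y[, , , da[4] + seq_len(db[4]), ] <- b
  list(y = y, cache = c(da[4], db[4]))
}

concat_b <- function(cache, dy) {
  C1 <- cache[1]
  C2 <- cache[2]
  list(da = dy[, , , seq_len(C1), , drop = FALSE],
       db = dy[, , , C1 + seq_len(C2), , drop = FALSE])
}

# Softmax + cross-entropy on K x N logits; labels are integers in 1..K.
softmax_ce <- function(logits, labels) {
  z <- sweep(logits, 2, apply(logits, 2, max), "-")
  ez <- exp(z)
  p <- sweep(ez, 2, colSums(ez), "/")
  N <- ncol(p)
  idx <- cbind(labels, seq_len(N))
  loss <- -mean(log(pmax(p[cbind(labels, seq_len(N))], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits / N
  list(loss = loss, probs = p, dlogits = dlogits)
}
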