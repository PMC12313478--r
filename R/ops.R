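# Differentiable primitives. Feature maps are numeric arrays with dims
# (C, H, W, N); token stacks are (N*L, d) matrices, sample-major rows.
# Channel-wise broadcasting exploits R's recycling along the first
# (fastest-varying) dimension.

ad_add <- function(a, b) {
  a <- nd(a); b <- nd(b)
  ad_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  a <- nd(a); b <- nd(b)
  ad_node(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  a <- nd(a); b <- nd(b)
  av <- a$value; bv <- b$value
  ad_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ad_scale <- function(a, s) {
  a <- nd(a)
  ad_node(a$value * s, list(a), function(g) list(g * s))
}

ad_mul_const <- function(a, k) {
  a <- nd(a)
  ad_node(a$value * k, list(a), function(g) list(g * k))
}

ad_neg <- function(a) ad_scale(a, -1)

# Gate (1,H,W,N) multiplying every channel of x (C,H,W,N).
ad_mul_gate <- function(x, gate) {
  x <- nd(x); gate <- nd(gate)
  dx <- dim(x$value); C <- dx[1]
  gv <- gate$value
  gb <- array(rep(gv, each = C), dim = dx)
  xv <- x$value
  ad_node(xv * gb, list(x, gate), function(g) {
    dgate <- colSums(array(g * xv, dim = c(C, prod(dx[-1]))))
    dim(dgate) <- dim(gv)
    list(g * gb, dgate)
  })
}

ad_matmul <- function(a, b) {
  a <- nd(a); b <- nd(b)
  av <- a$value; bv <- b$value
  ad_node(av %*% bv, list(a, b),
          function(g) list(g %*% t(bv), t(av) %*% g))
}

# X (R, din) %*% W (din, dout) + b (dout)
ad_linear <- function(x, w, b = NULL) {
  x <- nd(x); w <- nd(w)
  xv <- x$value; wv <- w$value
  out <- xv %*% wv
  if (is.null(b)) {
    return(ad_node(out, list(x, w), function(g) list(g %*% t(wv), t(xv) %*% g)))
  }
  b <- nd(b)
  out <- sweep(out, 2L, b$value, "+")
  ad_node(out, list(x, w, b),
          function(g) list(g %*% t(wv), t(xv) %*% g, colSums(g)))
}

# out = M %*% X with a constant mixing matrix M (masked means, groupings).
ad_const_matmul <- function(M, x) {
  x <- nd(x)
  ad_node(M %*% x$value, list(x), function(g) list(t(M) %*% g))
}

ad_relu <- function(a) {
  a <- nd(a)
  m <- a$value > 0
  ad_node(a$value * m, list(a), function(g) list(g * m))
}

ad_leaky_relu <- function(a, slope = 0.2) {
  a <- nd(a)
  v <- a$value
  m <- ifelse(v > 0, 1, slope)
  ad_node(v * m, list(a), function(g) list(g * m))
}

ad_sigmoid <- function(a) {
  a <- nd(a)
  s <- 1 / (1 + exp(-a$value))
  ad_node(s, list(a), function(g) list(g * s * (1 - s)))
}

ad_log <- function(a, eps = 1e-12) {
  a <- nd(a)
  v <- pmax(a$value, eps)
  ad_node(log(v), list(a), function(g) list(g / v))
}

ad_mean <- function(a) {
  a <- nd(a)
  n <- length(a$value)
  d <- dim(a$value)
  ad_node(sum(a$value) / n, list(a), function(g) {
    gx <- rep(g / n, n)
    if (!is.null(d)) dim(gx) <- d
    list(gx)
  })
}

ad_sum <- function(a) {
  a <- nd(a)
  d <- dim(a$value)
  ad_node(sum(a$value), list(a), function(g) {
    gx <- rep(g, length(a$value))
    if (!is.null(d)) dim(gx) <- d
    list(gx)
  })
}

# Sum over the class/channel axis: (K,H,W,N) -> (1,H,W,N).
ad_sum_ch <- function(a) {
  a <- nd(a)
  d <- dim(a$value); K <- d[1]
  s <- colSums(array(a$value, dim = c(K, prod(d[-1]))))
  dim(s) <- c(1L, d[-1])
  ad_node(s, list(a), function(g) {
    list(array(rep(g, each = K), dim = d))
  })
}

ad_concat_ch <- function(a, b) {
  a <- nd(a); b <- nd(b)
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(all(da[-1] == db[-1]))
  out <- array(0, dim = c(da[1] + db[1], da[2], da[3], da[4]))
  out[seq_len(da[1]), , , ] <- a$value
  out[da[1] + seq_len(db[1]), , , ] <- b$value
  ad_node(out, list(a, b), function(g) {
    list(g[seq_len(da[1]), , , , drop = FALSE],
         g[da[1] + seq_len(db[1]), , , , drop = FALSE])
  })
}

# ---- convolution / pooling / resampling ------------------------------------

# x: (Cin,H,W,N); w: matrix (Cout, Cin*k*k); b: numeric (Cout).
ad_conv2d <- function(x, w, b, k, pad = (k - 1L) %/% 2L, stride = 1L) {
  x <- nd(x); w <- nd(w); b <- nd(b)
  d <- dim(x$value)
  C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  cols <- cpp_im2col(as.numeric(x$value), C, H, W, N, k, pad, stride)
  wv <- w$value
  out <- wv %*% cols + b$value
  Cout <- nrow(wv)
  dim(out) <- c(Cout, Ho, Wo, N)
  ad_node(out, list(x, w, b), function(g) {
    gm <- matrix(g, nrow = Cout)
    dx <- cpp_col2im(crossprod(wv, gm), C, H, W, N, k, pad, stride)
    dim(dx) <- d
    list(dx, tcrossprod(gm, cols), rowSums(gm))
  })
}

ad_maxpool <- function(x, k = 2L, stride = k, pad = 0L) {
  x <- nd(x)
  d <- dim(x$value)
  r <- cpp_maxpool(as.numeric(x$value), d[1], d[2], d[3], d[4], k, pad, stride)
  Ho <- (d[2] + 2L * pad - k) %/% stride + 1L
  Wo <- (d[3] + 2L * pad - k) %/% stride + 1L
  out <- r$out
  dim(out) <- c(d[1], Ho, Wo, d[4])
  idx <- r$idx
  ad_node(out, list(x), function(g) {
    dx <- cpp_maxpool_bwd(as.numeric(g), idx, prod(d))
    dim(dx) <- d
    list(dx)
  })
}

# Nearest-neighbour 2x upsampling.
ad_upsample2 <- function(x) {
  x <- nd(x)
  d <- dim(x$value)
  ih <- rep(seq_len(d[2]), each = 2L)
  iw <- rep(seq_len(d[3]), each = 2L)
  out <- x$value[, ih, iw, , drop = FALSE]
  ad_node(out, list(x), function(g) {
    o1 <- seq(1L, 2L * d[2], by = 2L); o2 <- o1 + 1L
    e1 <- seq(1L, 2L * d[3], by = 2L); e2 <- e1 + 1L
    dh <- g[, o1, , , drop = FALSE] + g[, o2, , , drop = FALSE]
    dx <- dh[, , e1, , drop = FALSE] + dh[, , e2, , drop = FALSE]
    list(dx)
  })
}

ad_patchify <- function(x, p) {
  x <- nd(x)
  d <- dim(x$value)
  tok <- cpp_patchify(as.numeric(x$value), d[1], d[2], d[3], d[4], p)
  ad_node(tok, list(x), function(g) {
    dx <- cpp_patchify_bwd(g, d[1], d[2], d[3], d[4], p)
    dim(dx) <- d
    list(dx)
  })
}

ad_unpatchify <- function(tok, C, H, W, p) {
  tok <- nd(tok)
  N <- nrow(tok$value) %/% ((H %/% p) * (W %/% p))
  out <- cpp_unpatchify(tok$value, C, H, W, N, p)
  dim(out) <- c(C, H, W, N)
  ad_node(out, list(tok), function(g) {
    list(cpp_unpatchify_bwd(as.numeric(g), C, H, W, N, p))
  })
}

# ---- normalization ----------------------------------------------------------

# Channel batch norm over (H,W,N); `bnst` is an environment holding running
# moments, updated as a side effect in training mode.
ad_batchnorm <- function(x, gamma, beta, bnst, train = TRUE,
                         eps = 1e-5, momentum = 0.9) {
  x <- nd(x); gamma <- nd(gamma); beta <- nd(beta)
  d <- dim(x$value); C <- d[1]; M <- prod(d[-1])
  xm <- array(x$value, dim = c(C, M))
  if (train) {
    mu <- rowMeans(xm)
    va <- rowMeans(xm * xm) - mu * mu
    bnst$rm <- momentum * bnst$rm + (1 - momentum) * mu
    bnst$rv <- momentum * bnst$rv + (1 - momentum) * va
  } else {
    mu <- bnst$rm
    va <- bnst$rv
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- (x$value - mu) * inv          # recycling along channel axis
  out <- gamma$value * xhat + beta$value
  gval <- gamma$value
  ad_node(out, list(x, gamma, beta), function(g) {
    gm <- array(g, dim = c(C, M))
    xh <- array(xhat, dim = c(C, M))
    dgamma <- rowSums(gm * xh)
    dbeta <- rowSums(gm)
    if (train) {
      dxh <- gval * g
      dxhm <- array(dxh, dim = c(C, M))
      s1 <- rowSums(dxhm)
      s2 <- rowSums(dxhm * xh)
      dx <- inv * (dxh - s1 / M - xhat * (s2 / M))
    } else {
      dx <- gval * inv * g
    }
    dim(dx) <- d
    list(dx, dgamma, dbeta)
  })
}

# Row-wise layer norm for token matrices (R, dmodel).
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- nd(x); gamma <- nd(gamma); beta <- nd(beta)
  xv <- x$value
  dmod <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  gmat <- matrix(gamma$value, nrow(xv), dmod, byrow = TRUE)
  out <- xhat * gmat + matrix(beta$value, nrow(xv), dmod, byrow = TRUE)
  ad_node(out, list(x, gamma, beta), function(g) {
    dgamma <- colSums(g * xhat)
    dbeta <- colSums(g)
    dxh <- g * gmat
    m1 <- rowMeans(dxh)
    m2 <- rowMeans(dxh * xhat)
    dx <- inv * (dxh - m1 - xhat * m2)
    list(dx, dgamma, dbeta)
  })
}

# ---- attention / embeddings -------------------------------------------------

ad_attention <- function(q, k, v, L, nheads, mask = NULL) {
  q <- nd(q); k <- nd(k); v <- nd(v)
  qv <- q$value; kv <- k$value; vv <- v$value
  if (is.null(mask)) mask <- rep(1, nrow(qv))
  out <- cpp_attn_fwd(qv, kv, vv, L, nheads, mask)
  ad_node(out, list(q, k, v), function(g) {
    r <- cpp_attn_bwd(qv, kv, vv, L, nheads, mask, g)
    list(r$dQ, r$dK, r$dV)
  })
}

# ids: integer matrix (L, N), 1-based rows of `table` (V, d).
ad_embedding <- function(ids, table) {
  table <- nd(table)
  idvec <- as.integer(ids)
  out <- table$value[idvec, , drop = FALSE]
  V <- nrow(table$value); dmod <- ncol(table$value)
  ad_node(out, list(table), function(g) {
    rs <- rowsum(g, group = idvec)
    dt <- matrix(0, V, dmod)
    dt[as.integer(rownames(rs)), ] <- rs
    list(dt)
  })
}

# Add a per-position embedding (L, d) to every sample block of tok (N*L, d).
ad_add_pos <- function(tok, pos) {
  tok <- nd(tok); pos <- nd(pos)
  L <- nrow(pos$value)
  N <- nrow(tok$value) %/% L
  grp <- rep(seq_len(L), times = N)
  out <- tok$value + pos$value[grp, , drop = FALSE]
  ad_node(out, list(tok, pos), function(g) {
    list(g, rowsum(g, group = grp))
  })
}

# Broadcast per-sample channel vectors (N, C) to a map (C, h, w, N).
ad_broadcast_hw <- function(x, h, w) {
  x <- nd(x)
  N <- nrow(x$value); C <- ncol(x$value)
  out <- array(0, dim = c(C, h, w, N))
  for (n in seq_len(N)) out[, , , n] <- matrix(x$value[n, ], C, h * w)
  ad_node(out, list(x), function(g) {
    dxm <- array(g, dim = c(C, h * w, N))
    dx <- t(apply(dxm, c(1, 3), sum))
    dim(dx) <- c(N, C)
    list(dx)
  })
}

# Global average pool (C,H,W,N) -> (N, C).
ad_gap <- function(x) {
  x <- nd(x)
  d <- dim(x$value)
  M <- d[2] * d[3]
  xm <- array(x$value, dim = c(d[1], M, d[4]))
  out <- t(colMeans(aperm(xm, c(2, 1, 3))))    # (N, C)
  dim(out) <- c(d[4], d[1])
  ad_node(out, list(x), function(g) {
    dx <- array(0, dim = d)
    for (n in seq_len(d[4])) dx[, , , n] <- matrix(g[n, ] / M, d[1], M)
    list(dx)
  })
}

# Softmax over the class axis of (K,H,W,N).
ad_softmax_ch <- function(x) {
  x <- nd(x)
  d <- dim(x$value); K <- d[1]; M <- prod(d[-1])
  xm <- array(x$value, dim = c(K, M))
  mx <- apply(xm, 2, max)
  ex <- exp(sweep(xm, 2L, mx))
  p <- sweep(ex, 2L, colSums(ex), "/")
  pv <- array(p, dim = d)
  ad_node(pv, list(x), function(g) {
    gm <- array(g, dim = c(K, M))
    dot <- colSums(gm * p)
    dx <- p * sweep(gm, 2L, dot)
    dim(dx) <- d
    list(dx)
  })
}

# Apply a spatial pixel permutation (index vector over H*W) to (K,H,W,N).
ad_pixperm <- function(x, perm, H, W) {
  x <- nd(x)
  d <- dim(x$value)
  xm <- array(x$value, dim = c(d[1], H * W, d[4]))
  out <- xm[, perm, , drop = FALSE]
  dim(out) <- d
  ad_node(out, list(x), function(g) {
    inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
    gm <- array(g, dim = c(d[1], H * W, d[4]))
    dx <- gm[, inv, , drop = FALSE]
    dim(dx) <- d
    list(dx)
  })
}

# Channel-axis max: (C,H,W,N) -> (1,H,W,N), with argmax routing in the vjp.
ad_max_ch <- function(x) {
  x <- nd(x)
  d <- dim(x$value); K <- d[1]; M <- prod(d[-1])
  xm <- array(x$value, dim = c(K, M))
  am <- max.col(t(xm), ties.method = "first")
  v <- xm[cbind(am, seq_len(M))]
  out <- array(v, dim = c(1L, d[-1]))
  ad_node(out, list(x), function(g) {
    dx <- matrix(0, K, M)
    dx[cbind(am, seq_len(M))] <- as.numeric(g)
    dim(dx) <- d
    list(dx)
  })
}

# Spatial max pool over all pixels: (C,H,W,N) -> (N, C).
ad_max_sp <- function(x) {
  x <- nd(x)
  d <- dim(x$value); M <- d[2] * d[3]
  xm <- array(x$value, dim = c(d[1], M, d[4]))
  out <- matrix(0, d[4], d[1])
  am <- matrix(0L, d[4], d[1])
  for (n in seq_len(d[4])) {
    sl <- xm[, , n, drop = FALSE]
    dim(sl) <- c(d[1], M)
    am[n, ] <- max.col(sl, ties.method = "first")
    out[n, ] <- sl[cbind(seq_len(d[1]), am[n, ])]
  }
  ad_node(out, list(x), function(g) {
    dx <- array(0, dim = d)
    dxm <- array(dx, dim = c(d[1], M, d[4]))
    for (n in seq_len(d[4])) {
      dxm[cbind(seq_len(d[1]), am[n, ], n)] <- g[n, ]
    }
    dim(dxm) <- d
    list(dxm)
  })
}

# Multiply x (C,H,W,N) by per-sample channel gains (N, C).
ad_mul_chvec <- function(x, gain) {
  x <- nd(x); gain <- nd(gain)
  d <- dim(x$value); M <- d[2] * d[3]
  gb <- array(0, dim = d)
  for (n in seq_len(d[4])) gb[, , , n] <- matrix(gain$value[n, ], d[1], M)
  xv <- x$value
  ad_node(xv * gb, list(x, gain), function(g) {
    dgain <- matrix(0, d[4], d[1])
    gx <- array(g * xv, dim = c(d[1], M, d[4]))
    for (n in seq_len(d[4])) dgain[n, ] <- rowSums(gx[, , n, drop = FALSE])
    list(g * gb, dgain)
  })
}
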