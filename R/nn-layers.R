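# Minimal trainable-layer library with explicit reverse-mode gradients.
# Each layer is a mutable environment holding parameters (arrays), their
# gradient accumulators (prefixed "g"), and a forward cache. Layers operate
# on channels-last (B,H,W,C) tensors. Gradient correctness is covered by
# finite-difference checks in the test suite.

new_layer <- function(class, params = character()) {
  e <- new.env(parent = emptyenv())
  e$param_names <- params
  class(e) <- c(class, "hmc_layer")
  e
}

# ---- 2-D convolution (kernel-offset decomposition: one (B*Ho*Wo, Cin) x
# (Cin, Cout) product per kernel tap; stride via index sequences) ----

conv_new <- function(in_ch, out_ch, k, stride = 1L, pad = (k - 1L) %/% 2L,
                     bias = TRUE) {
  m <- new_layer("hmc_conv", if (bias) c("W", "b") else "W")
  m$in_ch <- in_ch; m$out_ch <- out_ch; m$k <- k
  m$stride <- stride; m$pad <- pad; m$has_bias <- bias
  sd <- sqrt(2 / (k * k * in_ch))          # He initialization
  m$W <- rand_norm(c(k, k, in_ch, out_ch), sd)
  if (bias) m$b <- numeric(out_ch)
  m
}

conv_fwd <- function(m, x) {
  d <- dim(x); B <- d[1]; H <- d[2]; W <- d[3]
  k <- m$k; s <- m$stride; p <- m$pad
  Hp <- H + 2 * p; Wp <- W + 2 * p
  if (p > 0) {
    xp <- array(0, c(B, Hp, Wp, m$in_ch))
    xp[, (p + 1):(p + H), (p + 1):(p + W), ] <- x
  } else xp <- x
  Ho <- (Hp - k) %/% s + 1L; Wo <- (Wp - k) %/% s + 1L
  n <- B * Ho * Wo
  out <- if (m$has_bias) matrix(m$b, n, m$out_ch, byrow = TRUE) else
    matrix(0, n, m$out_ch)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    hs <- seq.int(i, by = s, length.out = Ho)
    ws <- seq.int(j, by = s, length.out = Wo)
    sl <- xp[, hs, ws, , drop = FALSE]
    dim(sl) <- c(n, m$in_ch)
    out <- out + sl %*% matrix(m$W[i, j, , ], m$in_ch, m$out_ch)
  }
  dim(out) <- c(B, Ho, Wo, m$out_ch)
  m$cache <- list(xp = xp, H = H, W = W, Ho = Ho, Wo = Wo)
  out
}

conv_bwd <- function(m, dy) {
  cc <- m$cache
  d <- dim(dy); B <- d[1]; Ho <- cc$Ho; Wo <- cc$Wo
  k <- m$k; s <- m$stride; p <- m$pad
  n <- B * Ho * Wo
  dym <- dy; dim(dym) <- c(n, m$out_ch)
  if (m$has_bias) m$gb <- m$gb + colSums(dym)
  dxp <- array(0, dim(cc$xp))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    hs <- seq.int(i, by = s, length.out = Ho)
    ws <- seq.int(j, by = s, length.out = Wo)
    sl <- cc$xp[, hs, ws, , drop = FALSE]
    dim(sl) <- c(n, m$in_ch)
    m$gW[i, j, , ] <- m$gW[i, j, , ] + crossprod(sl, dym)
    dsl <- dym %*% t(matrix(m$W[i, j, , ], m$in_ch, m$out_ch))
    dim(dsl) <- c(B, Ho, Wo, m$in_ch)
    dxp[, hs, ws, ] <- dxp[, hs, ws, , drop = FALSE] + dsl
  }
  if (p > 0) dxp[, (p + 1):(p + cc$H), (p + 1):(p + cc$W), , drop = FALSE] else dxp
}

# ---- batch normalization ----

bn_new <- function(ch, momentum = 0.1, eps = 1e-5) {
  m <- new_layer("hmc_bn", c("gamma", "beta"))
  m$ch <- ch; m$momentum <- momentum; m$eps <- eps
  m$gamma <- rep(1, ch); m$beta <- numeric(ch)
  m$run_mean <- numeric(ch); m$run_var <- rep(1, ch)
  m
}

bn_fwd <- function(m, x, training) {
  d <- dim(x); n <- prod(d[1:3])
  xm <- x; dim(xm) <- c(n, m$ch)
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu)
    v <- colMeans(xc * xc)
    m$run_mean <- (1 - m$momentum) * m$run_mean + m$momentum * mu
    m$run_var <- (1 - m$momentum) * m$run_var + m$momentum * v * n / max(n - 1, 1)
  } else {
    mu <- m$run_mean; v <- m$run_var
    xc <- sweep(xm, 2, mu)
  }
  istd <- 1 / sqrt(v + m$eps)
  xhat <- sweep(xc, 2, istd, `*`)
  y <- sweep(sweep(xhat, 2, m$gamma, `*`), 2, m$beta, `+`)
  m$cache <- list(xhat = xhat, istd = istd, n = n, training = training)
  dim(y) <- d
  y
}

bn_bwd <- function(m, dy) {
  cc <- m$cache
  d <- dim(dy); n <- cc$n
  dym <- dy; dim(dym) <- c(n, m$ch)
  m$gbeta <- m$gbeta + colSums(dym)
  m$ggamma <- m$ggamma + colSums(dym * cc$xhat)
  dxhat <- sweep(dym, 2, m$gamma, `*`)
  if (cc$training) {
    s1 <- colMeans(dxhat)
    s2 <- colMeans(dxhat * cc$xhat)
    dxm <- sweep(dxhat, 2, s1) - sweep(cc$xhat, 2, s2, `*`)
    dxm <- sweep(dxm, 2, cc$istd, `*`)
  } else {
    dxm <- sweep(dxhat, 2, cc$istd, `*`)
  }
  dim(dxm) <- d
  dxm
}

# ---- max pooling (k x k window, stride s, zero-order padding) ----

maxpool_new <- function(k = 3L, stride = 2L, pad = 1L) {
  m <- new_layer("hmc_maxpool")
  m$k <- k; m$stride <- stride; m$pad <- pad
  m
}

maxpool_fwd <- function(m, x) {
  d <- dim(x); B <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  k <- m$k; s <- m$stride; p <- m$pad
  Hp <- H + 2 * p; Wp <- W + 2 * p
  xp <- array(-Inf, c(B, Hp, Wp, C))
  xp[, (p + 1):(p + H), (p + 1):(p + W), ] <- x
  Ho <- (Hp - k) %/% s + 1L; Wo <- (Wp - k) %/% s + 1L
  cur <- array(-Inf, c(B, Ho, Wo, C))
  arg <- array(0L, c(B, Ho, Wo, C))
  idx <- 0L
  for (i in seq_len(k)) for (j in seq_len(k)) {
    idx <- idx + 1L
    hs <- seq.int(i, by = s, length.out = Ho)
    ws <- seq.int(j, by = s, length.out = Wo)
    sl <- xp[, hs, ws, , drop = FALSE]
    upd <- sl > cur
    cur[upd] <- sl[upd]
    arg[upd] <- idx
  }
  m$cache <- list(arg = arg, H = H, W = W, Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo,
                  B = B, C = C)
  cur
}

maxpool_bwd <- function(m, dy) {
  cc <- m$cache
  k <- m$k; s <- m$stride; p <- m$pad
  dxp <- array(0, c(cc$B, cc$Hp, cc$Wp, cc$C))
  idx <- 0L
  for (i in seq_len(k)) for (j in seq_len(k)) {
    idx <- idx + 1L
    hs <- seq.int(i, by = s, length.out = cc$Ho)
    ws <- seq.int(j, by = s, length.out = cc$Wo)
    contrib <- dy * (cc$arg == idx)
    dxp[, hs, ws, ] <- dxp[, hs, ws, , drop = FALSE] + contrib
  }
  dxp[, (p + 1):(p + cc$H), (p + 1):(p + cc$W), , drop = FALSE]
}

# ---- fully connected ----

linear_new <- function(in_f, out_f) {
  m <- new_layer("hmc_linear", c("W", "b"))
  m$W <- matrix(stats::rnorm(in_f * out_f, sd = sqrt(2 / in_f)), in_f, out_f)
  m$b <- numeric(out_f)
  m
}

linear_fwd <- function(m, x) {
  m$cache <- list(x = x)
  sweep(x %*% m$W, 2, m$b, `+`)
}

linear_bwd <- function(m, dy) {
  m$gW <- m$gW + crossprod(m$cache$x, dy)
  m$gb <- m$gb + colSums(dy)
  dy %*% t(m$W)
}

# ---- global average pooling: (B,H,W,C) -> (B,C) ----

gap_fwd <- function(x) {
  d <- dim(x)
  xr <- x; dim(xr) <- c(d[1], d[2] * d[3], d[4])
  xr <- aperm(xr, c(2, 1, 3))
  dim(xr) <- c(d[2] * d[3], d[1] * d[4])
  y <- colMeans(xr)
  dim(y) <- c(d[1], d[4])
  attr(y, "hw") <- d[2:3]
  y
}

gap_bwd <- function(dy, hw, B, C) {
  n <- hw[1] * hw[2]
  dx <- matrix(rep(as.vector(dy) / n, each = n), n, B * C)
  dim(dx) <- c(n, B, C)
  dx <- aperm(dx, c(2, 1, 3))
  dim(dx) <- c(B, hw[1], hw[2], C)
  dx
}

# ---- parameter bookkeeping ----

zero_grads_layer <- function(m) {
  for (p in m$param_names) {
    g <- paste0("g", p)
    m[[g]] <- m[[p]] * 0
  }
  invisible(m)
}
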