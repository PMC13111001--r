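# Independent oracles and small fixture builders used across the suite.
# Each oracle re-derives the quantity with explicit loops / first
# principles, sharing no code path with the implementation it checks.

# brute-force gamma-gated attention: nested loops over positions/channels
attend_oracle <- function(X, Y, p) {
  d <- dim(X); B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  N <- H * W; dk <- p$d_k
  out <- array(0, d)
  hh <- rep(seq_len(H), W); ww <- rep(seq_len(W), each = H)  # h fastest
  for (b in seq_len(B)) {
    Q <- matrix(0, N, dk); K <- matrix(0, N, dk); V <- matrix(0, N, C)
    for (i in seq_len(N)) {
      for (a in seq_len(dk)) {
        sq <- p$bq[a]; sk <- p$bk[a]
        for (cc in seq_len(C)) {
          sq <- sq + X[b, cc, hh[i], ww[i]] * p$Wq[cc, a]
          sk <- sk + Y[b, cc, hh[i], ww[i]] * p$Wk[cc, a]
        }
        Q[i, a] <- sq; K[i, a] <- sk
      }
      for (a in seq_len(C)) {
        sv <- p$bv[a]
        for (cc in seq_len(C)) sv <- sv + Y[b, cc, hh[i], ww[i]] * p$Wv[cc, a]
        V[i, a] <- sv
      }
    }
    E <- matrix(0, N, N)
    for (i in seq_len(N)) for (j in seq_len(N))
      E[i, j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
    A <- matrix(0, N, N)
    for (i in seq_len(N)) {
      ex <- exp(E[i, ] - max(E[i, ]))
      A[i, ] <- ex / sum(ex)
    }
    for (i in seq_len(N)) for (cc in seq_len(C)) {
      o <- sum(A[i, ] * V[, cc])
      out[b, cc, hh[i], ww[i]] <- p$gamma * o + X[b, cc, hh[i], ww[i]]
    }
  }
  out
}

# per-pixel bilinear resize with half-pixel centers, coded directly
bilerp_oracle <- function(x, oh, ow) {
  hi <- nrow(x); wi <- ncol(x)
  out <- matrix(0, oh, ow)
  for (i in seq_len(oh)) for (j in seq_len(ow)) {
    sy <- min(max((i - 0.5) * hi / oh - 0.5, 0), hi - 1)
    sx <- min(max((j - 0.5) * wi / ow - 0.5, 0), wi - 1)
    y0 <- floor(sy); x0 <- floor(sx)
    fy <- sy - y0; fx <- sx - x0
    y1 <- min(y0 + 1, hi - 1); x1 <- min(x0 + 1, wi - 1)
    out[i, j] <- (1 - fy) * (1 - fx) * x[y0 + 1, x0 + 1] +
      (1 - fy) * fx * x[y0 + 1, x1 + 1] +
      fy * (1 - fx) * x[y1 + 1, x0 + 1] +
      fy * fx * x[y1 + 1, x1 + 1]
  }
  out
}

# literal Grad-CAM++ from A (h,w,K) and G (h,w,K): explicit pixel loops
gradcampp_oracle <- function(A, G, input_size, use_relu_g = TRUE) {
  K <- dim(A)[3]
  cam <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_len(K)) {
    Ak <- A[, , k]; Gk <- G[, , k]
    sumA <- sum(Ak)
    w <- 0
    for (i in seq_len(nrow(Ak))) for (j in seq_len(ncol(Ak))) {
      den <- 2 * Gk[i, j]^2 + sumA * Gk[i, j]^3
      aij <- if (den == 0) 0 else Gk[i, j]^2 / den
      w <- w + aij * (if (use_relu_g) max(Gk[i, j], 0) else 1)
    }
    cam <- cam + w * Ak
  }
  cam <- pmax(cam, 0)
  cam <- bilerp_oracle(cam, input_size, input_size)
  rng <- range(cam)
  if (rng[2] - rng[1] <= 1e-9 * max(abs(rng), 1e-12)) return(cam * 0)
  (cam - rng[1]) / (rng[2] - rng[1])
}

# micro network configuration: tiny enough for exhaustive numeric checks
micro_config <- function(input_size = 32L)
  backbone_config(stage_channels = c(8L, 8L, 16L, 16L, 16L),
                  input_size = input_size, width_divisor = 1L)

micro_batch <- function(B = 2L, size = 32L, seed = 99L) {
  set.seed(seed)
  array(stats::rnorm(B * 3 * size * size, sd = 0.5), c(B, 3L, size, size))
}

# write a tiny PGM (binary P5 or ascii P2) for reader tests
write_pgm_fixture <- function(mat255, path, ascii = FALSE) {
  h <- nrow(mat255); w <- ncol(mat255)
  if (ascii) {
    lines <- c("P2", "# fixture", paste(w, h), "255",
               apply(mat255, 1, paste, collapse = " "))
    writeLines(lines, path)
  } else {
    con <- file(path, "wb")
    writeChar(sprintf("P5\n%d %d\n255\n", w, h), con, eos = NULL)
    writeBin(as.raw(as.integer(t(mat255))), con)
    close(con)
  }
  path
}
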