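# gamma-gated query/key/value attention shared by the hierarchical
# self-attention (HA1, HA2) and multi-scale cross-attention (CA23, CA34)
# blocks. Queries come from the feature map X, keys/values from Y; the
# output is gamma * O + X, with gamma a learnable scalar initialized to 0 so
# every attention block is the identity at construction.

#' Construct attention parameters
#'
#' Builds the 1x1-projection weights and the gamma gate for an attention
#' block over feature maps with `C` channels. Queries and keys are projected
#' to `C/8` channels (so `C` must be divisible by 8), values keep `C`
#' channels. All projections carry a bias initialized to 0; `gamma` starts
#' at exactly 0, which makes the block the identity mapping.
#'
#' @param C channel count of the attended feature maps; must be divisible by 8.
#' @param seed optional integer seed for the weight initialization.
#' @return an object of class `hmc_attention_params` with elements `Wq`,
#'   `bq`, `Wk`, `bk`, `Wv`, `bv` (matrices/vectors), `gamma` (scalar 0),
#'   `C`, and `d_k = C/8`.
#' @examples
#' p <- attention_params(8, seed = 1)
#' p$gamma  # 0
#' @export
attention_params <- function(C, seed = NULL) {
  if (C %% 8 != 0 || C < 8)
    hmc_stop(sprintf("attention requires C divisible by 8 (got C = %d)", C),
             "hmcnet_config_error")
  if (!is.null(seed)) set.seed(seed)
  d_k <- C %/% 8L
  sd <- sqrt(2 / C)
  p <- list(
    Wq = matrix(stats::rnorm(C * d_k, sd = sd), C, d_k), bq = numeric(d_k),
    Wk = matrix(stats::rnorm(C * d_k, sd = sd), C, d_k), bk = numeric(d_k),
    Wv = matrix(stats::rnorm(C * C, sd = sd), C, C), bv = numeric(C),
    gamma = 0, C = C, d_k = d_k
  )
  class(p) <- "hmc_attention_params"
  p
}

#' Scaled row softmax of attention energies
#'
#' Converts an energy array into row-stochastic attention weights:
#' `softmax(E / sqrt(d_k))` over the last index, so each query position
#' holds a probability distribution over key positions.
#'
#' @param E energy array of shape `(B, N, N)` (or an `N x N` matrix, treated
#'   as batch size 1).
#' @param d_k key dimensionality used for the `1/sqrt(d_k)` scaling.
#' @return array of the same shape; every row sums to 1.
#' @export
attention_weights <- function(E, d_k) {
  check_finite(E, "attention energies")
  was_mat <- is.matrix(E)
  if (was_mat) E <- array(E, c(1L, dim(E)))
  d <- dim(E)
  A <- array(0, d)
  for (b in seq_len(d[1]))
    A[b, , ] <- softmax_rows(matrix(E[b, , ], d[2], d[3]) / sqrt(d_k))
  if (was_mat) A <- matrix(A[1, , ], d[2], d[3])
  A
}

#' Apply gamma-gated attention between two feature maps
#'
#' Computes single-head attention with queries projected from `X` and
#' keys/values projected from `Y` (for self-attention pass the same map
#' twice), and returns `gamma * O + X`. Energies are scaled by
#' `1/sqrt(d_k)` before the row softmax. With freshly constructed
#' parameters (`gamma = 0`) the output equals `X` exactly.
#'
#' @param X query feature map, array `(B, C, H, W)`.
#' @param Y key/value feature map, same shape as `X`.
#' @param params an [attention_params()] object with matching `C`.
#' @param return_trace if `TRUE`, attach the intermediate `Q`, `K`, `V`,
#'   energies `E`, attention weights `A` and weighted values `O` as the
#'   `"trace"` attribute of the result.
#' @param max_positions guard against quadratic memory blow-up: an error is
#'   raised when `H * W` exceeds this cap instead of silently approximating.
#' @return array `(B, C, H, W)`; optionally with a `"trace"` attribute.
#' @export
attend <- function(X, Y, params, return_trace = FALSE, max_positions = 8192L) {
  dx <- dim(X); dy <- dim(Y)
  if (length(dx) != 4 || length(dy) != 4 || !all(dx == dy))
    hmc_stop(sprintf(
      "attend: X and Y must share shape (B,C,H,W); got (%s) vs (%s)",
      paste(dx, collapse = ","), paste(dy, collapse = ",")),
      "hmcnet_dim_error")
  C <- dx[2]
  if (C != params$C)
    hmc_stop(sprintf("attend: params built for C = %d but maps have C = %d",
                     params$C, C), "hmcnet_config_error")
  N <- dx[3] * dx[4]
  if (N > max_positions)
    hmc_stop(sprintf(
      "attend: %d spatial positions exceed max_positions = %d (energy matrix would be %d x %d)",
      N, max_positions, N, N), "hmcnet_config_error")
  B <- dx[1]
  out <- X
  if (return_trace) {
    trQ <- array(0, c(B, params$d_k, dx[3], dx[4])); trK <- trQ
    trV <- array(0, dx)
    trE <- array(0, c(B, N, N)); trA <- trE
    trO <- array(0, dx)
  }
  for (b in seq_len(B)) {
    Xb <- matrix(aperm(array(X[b, , , ], dx[2:4]), c(2, 3, 1)), N, C)
    Yb <- matrix(aperm(array(Y[b, , , ], dx[2:4]), c(2, 3, 1)), N, C)
    Q <- sweep(Xb %*% params$Wq, 2, params$bq, `+`)
    K <- sweep(Yb %*% params$Wk, 2, params$bk, `+`)
    V <- sweep(Yb %*% params$Wv, 2, params$bv, `+`)
    E <- tcrossprod(Q, K)
    A <- softmax_rows(E / sqrt(params$d_k))
    O <- A %*% V
    Outb <- params$gamma * O + Xb
    out[b, , , ] <- aperm(array(Outb, c(dx[3], dx[4], C)), c(3, 1, 2))
    if (return_trace) {
      trQ[b, , , ] <- aperm(array(Q, c(dx[3], dx[4], params$d_k)), c(3, 1, 2))
      trK[b, , , ] <- aperm(array(K, c(dx[3], dx[4], params$d_k)), c(3, 1, 2))
      trV[b, , , ] <- aperm(array(V, c(dx[3], dx[4], C)), c(3, 1, 2))
      trE[b, , ] <- E
      trA[b, , ] <- A
      trO[b, , , ] <- aperm(array(O, c(dx[3], dx[4], C)), c(3, 1, 2))
    }
  }
  if (return_trace)
    attr(out, "trace") <- list(Q = trQ, K = trK, V = trV, E = trE, A = trA, O = trO)
  out
}

#' Match channels and resample a feature map
#'
#' The adapter that aligns a shallower stage with a deeper one before
#' cross-attention: a 1x1 convolution maps the channel count, then bilinear
#' resampling (half-pixel centers, constants preserved exactly) changes the
#' spatial size.
#'
#' @param F feature map `(B, C, H, W)`.
#' @param target_channels output channel count.
#' @param target_hw integer vector `(H', W')`.
#' @param weights `C x target_channels` matrix of 1x1-convolution weights.
#' @param bias optional length-`target_channels` bias (default zeros).
#' @return feature map `(B, target_channels, H', W')`.
#' @export
channel_match_resample <- function(F, target_channels, target_hw, weights,
                                   bias = NULL) {
  d <- dim(F)
  if (length(d) != 4)
    hmc_stop("channel_match_resample: F must be (B,C,H,W)", "hmcnet_dim_error")
  if (any(target_hw <= 0))
    hmc_stop("channel_match_resample: target_hw must be positive",
             "hmcnet_config_error")
  if (nrow(weights) != d[2] || ncol(weights) != target_channels)
    hmc_stop(sprintf(
      "channel_match_resample: weights must be %d x %d, got %d x %d",
      d[2], target_channels, nrow(weights), ncol(weights)), "hmcnet_dim_error")
  if (is.null(bias)) bias <- numeric(target_channels)
  x <- bchw_to_bhwc(F)
  xm <- x; dim(xm) <- c(prod(d[c(1, 3, 4)]), d[2])
  ym <- sweep(xm %*% weights, 2, bias, `+`)
  dim(ym) <- c(d[1], d[3], d[4], target_channels)
  ym <- resize_bilinear_bhwc(ym, target_hw[1], target_hw[2])
  bhwc_to_bchw(ym)
}

# ---- internal trainable attention layer (channels-last tensors) ----

attn_new <- function(C) {
  if (C %% 8 != 0)
    hmc_stop(sprintf("attention requires C divisible by 8 (got %d)", C),
             "hmcnet_config_error")
  m <- new_layer("hmc_attn", c("Wq", "bq", "Wk", "bk", "Wv", "bv", "gamma"))
  d_k <- C %/% 8L
  sd <- sqrt(2 / C)
  m$C <- C; m$d_k <- d_k
  m$Wq <- matrix(stats::rnorm(C * d_k, sd = sd), C, d_k); m$bq <- numeric(d_k)
  m$Wk <- matrix(stats::rnorm(C * d_k, sd = sd), C, d_k); m$bk <- numeric(d_k)
  m$Wv <- matrix(stats::rnorm(C * C, sd = sd), C, C); m$bv <- numeric(C)
  m$gamma <- 0
  m
}

attn_fwd <- function(m, X, Y) {
  d <- dim(X)
  B <- d[1]; N <- d[2] * d[3]; C <- d[4]
  out <- X
  cache <- vector("list", B)
  for (b in seq_len(B)) {
    Xb <- matrix(X[b, , , ], N, C)
    Yb <- matrix(Y[b, , , ], N, C)
    Q <- sweep(Xb %*% m$Wq, 2, m$bq, `+`)
    K <- sweep(Yb %*% m$Wk, 2, m$bk, `+`)
    V <- sweep(Yb %*% m$Wv, 2, m$bv, `+`)
    A <- softmax_rows(tcrossprod(Q, K) / sqrt(m$d_k))
    O <- A %*% V
    out[b, , , ] <- m$gamma * O + Xb
    cache[[b]] <- list(Xb = Xb, Yb = Yb, Q = Q, K = K, V = V, A = A, O = O)
  }
  m$cache <- list(per_b = cache, d = d, N = N)
  out
}

attn_bwd <- function(m, dOut) {
  cc <- m$cache
  d <- cc$d; B <- d[1]; N <- cc$N; C <- d[4]
  dX <- dOut           # residual path
  dY <- array(0, d)
  sq <- sqrt(m$d_k)
  for (b in seq_len(B)) {
    cb <- cc$per_b[[b]]
    dOb <- matrix(dOut[b, , , ], N, C)
    m$ggamma <- m$ggamma + sum(dOb * cb$O)
    dO <- m$gamma * dOb
    dA <- tcrossprod(dO, cb$V)
    dV <- crossprod(cb$A, dO)
    dS <- cb$A * (dA - rowSums(dA * cb$A))
    dE <- dS / sq
    dQ <- dE %*% cb$K
    dK <- crossprod(dE, cb$Q)
    m$gWq <- m$gWq + crossprod(cb$Xb, dQ); m$gbq <- m$gbq + colSums(dQ)
    m$gWk <- m$gWk + crossprod(cb$Yb, dK); m$gbk <- m$gbk + colSums(dK)
    m$gWv <- m$gWv + crossprod(cb$Yb, dV); m$gbv <- m$gbv + colSums(dV)
    dX[b, , , ] <- dX[b, , , ] + array(dQ %*% t(m$Wq), d[2:4])
    dY[b, , , ] <- array(dK %*% t(m$Wk) + dV %*% t(m$Wv), d[2:4])
  }
  list(dX = dX, dY = dY)
}

# adapter: 1x1 conv + bilinear resize to a target spatial size
adapter_new <- function(in_ch, out_ch) {
  m <- new_layer("hmc_adapter", c("W", "b"))
  m$in_ch <- in_ch; m$out_ch <- out_ch
  m$W <- matrix(stats::rnorm(in_ch * out_ch, sd = sqrt(2 / in_ch)), in_ch, out_ch)
  m$b <- numeric(out_ch)
  m
}

adapter_fwd <- function(m, x, out_h, out_w) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(prod(d[1:3]), d[4])
  y <- sweep(xm %*% m$W, 2, m$b, `+`)
  dim(y) <- c(d[1:3], m$out_ch)
  m$cache <- list(xm = xm, d = d, out_h = out_h, out_w = out_w)
  resize_bilinear_bhwc(y, out_h, out_w)
}

adapter_bwd <- function(m, dy) {
  cc <- m$cache
  d <- cc$d
  dyl <- resize_bilinear_bhwc_bwd(dy, d[2], d[3])
  dym <- dyl; dim(dym) <- c(prod(d[1:3]), m$out_ch)
  m$gW <- m$gW + crossprod(cc$xm, dym)
  m$gb <- m$gb + colSums(dym)
  dx <- dym %*% t(m$W)
  dim(dx) <- d
  dx
}
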