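# Internal tensor helpers. Activations travel through the network in
# channels-last layout (B, H, W, C) so that kernel-offset slices reshape
# directly into (B*H*W, C) matrices for BLAS; the public FeatureMap
# convention is channels-first (B, C, H, W) and is converted at the API
# boundary.

#' @keywords internal
hmc_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "hmcnet_error")))
}

#' @keywords internal
bchw_to_bhwc <- function(x) aperm(x, c(1, 3, 4, 2))

#' @keywords internal
bhwc_to_bchw <- function(x) aperm(x, c(1, 4, 2, 3))

#' Row-wise numerically stable softmax
#' @keywords internal
softmax_rows <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  mx <- apply(m, 1L, max)
  e <- exp(m - mx)
  e / rowSums(e)
}

#' Bilinear interpolation matrix (half-pixel centers, no corner alignment)
#'
#' Returns an `n_out x n_in` row-stochastic matrix `M` such that `M %*% v`
#' resamples a length-`n_in` signal to `n_out` samples. Rows sum to 1, so
#' constants are preserved exactly.
#' @keywords internal
interp_matrix <- function(n_out, n_in) {
  M <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    s <- (i - 0.5) * n_in / n_out - 0.5
    s <- min(max(s, 0), n_in - 1)
    lo <- floor(s)
    f <- s - lo
    M[i, lo + 1] <- M[i, lo + 1] + (1 - f)
    hi <- min(lo + 1, n_in - 1)
    M[i, hi + 1] <- M[i, hi + 1] + f
  }
  M
}

#' Nearest-neighbour index map for mask resampling
#' @keywords internal
nn_index <- function(n_out, n_in) {
  i <- seq_len(n_out)
  pmin(pmax(floor((i - 0.5) * n_in / n_out) + 1, 1), n_in)
}

#' Bilinear resize of a 2-D matrix
#' @keywords internal
resize_bilinear_2d <- function(x, out_h, out_w) {
  if (nrow(x) != out_h) x <- interp_matrix(out_h, nrow(x)) %*% x
  if (ncol(x) != out_w) x <- x %*% t(interp_matrix(out_w, ncol(x)))
  x
}

# Apply a matrix along dimension `d` (2 = H, 3 = W) of a (B,H,W,C) tensor.
#' @keywords internal
apply_dim <- function(x, M, d) {
  dm <- dim(x)
  perm <- c(d, setdiff(1:4, d))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  dim(xp) <- c(dp[1], prod(dp[-1]))
  yp <- M %*% xp
  dim(yp) <- c(nrow(M), dp[-1])
  aperm(yp, order(perm))
}

#' Bilinear resize of a (B,H,W,C) tensor; returns the tensor and keeps the
#' operation linear so the adjoint is the transposed matrices.
#' @keywords internal
resize_bilinear_bhwc <- function(x, out_h, out_w) {
  d <- dim(x)
  if (d[2] != out_h) x <- apply_dim(x, interp_matrix(out_h, d[2]), 2L)
  if (dim(x)[3] != out_w) x <- apply_dim(x, interp_matrix(out_w, dim(x)[3]), 3L)
  x
}

#' Adjoint of resize_bilinear_bhwc (gradient wrt the input)
#' @keywords internal
resize_bilinear_bhwc_bwd <- function(dy, in_h, in_w) {
  d <- dim(dy)
  if (d[2] != in_h) dy <- apply_dim(dy, t(interp_matrix(d[2], in_h)), 2L)
  if (dim(dy)[3] != in_w) dy <- apply_dim(dy, t(interp_matrix(dim(dy)[3], in_w)), 3L)
  dy
}

#' @keywords internal
rand_norm <- function(dims, sd) array(stats::rnorm(prod(dims), sd = sd), dim = dims)

#' @keywords internal
check_finite <- function(x, what) {
  if (!all(is.finite(x))) hmc_stop(paste0("non-finite values in ", what), "hmcnet_numeric_error")
  invisible(x)
}
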