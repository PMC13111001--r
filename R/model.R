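# Five-stage bottleneck residual backbone with gamma-gated attention:
# hierarchical self-attention HA1/HA2 after stages 1 and 2, multi-scale
# cross-attention CA23/CA34 fusing stage 2->3 and stage 3->4. The module
# registry (`model$mods`) is a flat named list; parameter names are shared
# across variants so the baseline's parameter set is a strict subset of
# every attention variant's.

#' Backbone configuration
#'
#' @param stage_channels five stage widths (stem and stages 1-4). Every
#'   width at which an attention block is attached must be divisible by 8.
#'   The default reproduces the standard 50-layer bottleneck network
#'   (64, 256, 512, 1024, 2048).
#' @param input_size square input resolution in pixels.
#' @param num_classes number of output classes.
#' @param width_divisor divides all stage widths; `width_divisor = 8` with
#'   `input_size = 64` is the "tiny" preset used throughout the tests so the
#'   whole pipeline trains on one CPU in minutes.
#' @return a `hmc_config` list.
#' @export
backbone_config <- function(stage_channels = c(64L, 256L, 512L, 1024L, 2048L),
                            input_size = 224L, num_classes = 3L,
                            width_divisor = 1L) {
  if (length(stage_channels) != 5)
    hmc_stop("stage_channels must have length 5", "hmcnet_config_error")
  ch <- as.integer(stage_channels / width_divisor)
  if (any(ch < 1))
    hmc_stop("width_divisor leaves a stage with < 1 channel", "hmcnet_config_error")
  structure(list(stage_channels = ch, input_size = as.integer(input_size),
                 num_classes = as.integer(num_classes)),
            class = "hmc_config")
}

#' Tiny test-scale configuration (64 px input, widths / 8)
#' @param input_size input resolution; 64 by default.
#' @return a `hmc_config` list.
#' @export
tiny_config <- function(input_size = 64L) {
  backbone_config(input_size = input_size, width_divisor = 8L)
}

VARIANTS <- c("hmc", "hierarchical_only", "multiscale_only", "baseline")

variant_flags <- function(variant) {
  variant <- match.arg(variant, VARIANTS)
  list(ha = variant %in% c("hmc", "hierarchical_only"),
       ca = variant %in% c("hmc", "multiscale_only"))
}

bottleneck_new <- function(in_ch, out_ch, stride) {
  mid <- out_ch %/% 4L
  b <- new.env(parent = emptyenv())
  b$conv1 <- conv_new(in_ch, mid, 1L, 1L, 0L, bias = FALSE)
  b$bn1 <- bn_new(mid)
  b$conv2 <- conv_new(mid, mid, 3L, stride, 1L, bias = FALSE)
  b$bn2 <- bn_new(mid)
  b$conv3 <- conv_new(mid, out_ch, 1L, 1L, 0L, bias = FALSE)
  b$bn3 <- bn_new(out_ch)
  if (in_ch != out_ch || stride != 1L) {
    b$down_conv <- conv_new(in_ch, out_ch, 1L, stride, 0L, bias = FALSE)
    b$down_bn <- bn_new(out_ch)
  }
  class(b) <- "hmc_block"
  b
}

block_layers <- function(b) {
  ls <- list(conv1 = b$conv1, bn1 = b$bn1, conv2 = b$conv2, bn2 = b$bn2,
             conv3 = b$conv3, bn3 = b$bn3)
  if (!is.null(b$down_conv)) ls <- c(ls, list(down_conv = b$down_conv,
                                              down_bn = b$down_bn))
  ls
}

block_fwd <- function(b, x, training) {
  h1 <- bn_fwd(b$bn1, conv_fwd(b$conv1, x), training)
  m1 <- h1 > 0; h1 <- h1 * m1
  h2 <- bn_fwd(b$bn2, conv_fwd(b$conv2, h1), training)
  m2 <- h2 > 0; h2 <- h2 * m2
  h3 <- bn_fwd(b$bn3, conv_fwd(b$conv3, h2), training)
  idn <- if (is.null(b$down_conv)) x else
    bn_fwd(b$down_bn, conv_fwd(b$down_conv, x), training)
  y <- h3 + idn
  m3 <- y > 0
  b$cache <- list(m1 = m1, m2 = m2, m3 = m3)
  y * m3
}

block_bwd <- function(b, dy) {
  cc <- b$cache
  dy <- dy * cc$m3
  d_idn <- if (is.null(b$down_conv)) dy else
    conv_bwd(b$down_conv, bn_bwd(b$down_bn, dy))
  dh <- conv_bwd(b$conv3, bn_bwd(b$bn3, dy))
  dh <- dh * cc$m2
  dh <- conv_bwd(b$conv2, bn_bwd(b$bn2, dh))
  dh <- dh * cc$m1
  dx <- conv_bwd(b$conv1, bn_bwd(b$bn1, dh))
  dx + d_idn
}

#' Build a model
#'
#' Assembles the residual backbone with the attention modules the `variant`
#' calls for. All weights are drawn fresh from `seed` (no pre-trained
#' layers); every attention gate `gamma` is exactly 0, so at initialization
#' each variant's logits coincide with the plain backbone's given shared
#' backbone weights.
#'
#' @param variant one of `"hmc"` (HA1+HA2+CA23+CA34), `"hierarchical_only"`,
#'   `"multiscale_only"`, `"baseline"`.
#' @param config a [backbone_config()].
#' @param seed integer seed for weight initialization.
#' @return a `hmc_model` environment.
#' @export
build_model <- function(variant = "hmc", config = backbone_config(),
                        seed = 1L) {
  flags <- variant_flags(variant)
  ch <- config$stage_channels
  if (flags$ha || flags$ca) {
    need8 <- ch[2:5]
    if (any(need8 %% 8 != 0))
      hmc_stop(sprintf(
        "attention stages need channels divisible by 8; got %s",
        paste(need8, collapse = ", ")), "hmcnet_config_error")
  }
  set.seed(seed)
  model <- new.env(parent = emptyenv())
  model$variant <- match.arg(variant, VARIANTS)
  model$config <- config
  model$seed <- as.integer(seed)
  mods <- list()
  # deterministic construction order: backbone first, then attention, so the
  # backbone draws identical weights for every variant under the same seed
  mods[["stem.conv"]] <- conv_new(3L, ch[1], 7L, 2L, 3L, bias = FALSE)
  mods[["stem.bn"]] <- bn_new(ch[1])
  model$stem_pool <- maxpool_new(3L, 2L, 1L)
  nblocks <- c(3L, 4L, 6L, 3L)
  in_ch <- ch[1]
  model$stages <- vector("list", 4)
  for (s in 1:4) {
    out_ch <- ch[s + 1]
    blocks <- vector("list", nblocks[s])
    for (i in seq_len(nblocks[s])) {
      stride <- if (s > 1 && i == 1) 2L else 1L
      blocks[[i]] <- bottleneck_new(in_ch, out_ch, stride)
      for (nm in names(block_layers(blocks[[i]])))
        mods[[sprintf("layer%d.b%d.%s", s, i, nm)]] <- block_layers(blocks[[i]])[[nm]]
      in_ch <- out_ch
    }
    model$stages[[s]] <- blocks
  }
  mods[["fc"]] <- linear_new(ch[5], config$num_classes)
  if (flags$ha) {
    mods[["ha1"]] <- attn_new(ch[2])
    mods[["ha2"]] <- attn_new(ch[3])
  }
  if (flags$ca) {
    mods[["ca23.match"]] <- adapter_new(ch[3], ch[4])
    mods[["ca23.attn"]] <- attn_new(ch[4])
    mods[["ca34.match"]] <- adapter_new(ch[4], ch[5])
    mods[["ca34.attn"]] <- attn_new(ch[5])
  }
  model$mods <- mods
  class(model) <- "hmc_model"
  model
}

check_input_batch <- function(model, batch) {
  d <- dim(batch)
  s <- model$config$input_size
  if (length(d) != 4 || d[2] != 3)
    hmc_stop(sprintf("input batch must be (B,3,H,W); got (%s)",
                     paste(d, collapse = ",")), "hmcnet_dim_error")
  if (d[3] != s || d[4] != s)
    hmc_stop(sprintf("stage stem expects %dx%d input, got %dx%d",
                     s, s, d[3], d[4]), "hmcnet_dim_error")
}

# Full forward pass on a channels-last tensor; stores the wiring cache
# needed for backward() and returns stage outputs for the explainers.
model_fwd_internal <- function(model, x, training = FALSE) {
  mods <- model$mods
  flags <- variant_flags(model$variant)
  h <- bn_fwd(mods$stem.bn, conv_fwd(mods$stem.conv, x), training)
  stem_mask <- h > 0
  h <- maxpool_fwd(model$stem_pool, h * stem_mask)
  x0 <- h
  run_stage <- function(s, inp) {
    for (b in model$stages[[s]]) inp <- block_fwd(b, inp, training)
    inp
  }
  x1 <- run_stage(1, x0)
  x1p <- if (flags$ha) attn_fwd(mods$ha1, x1, x1) else x1
  x2 <- run_stage(2, x1p)
  x2p <- if (flags$ha) attn_fwd(mods$ha2, x2, x2) else x2
  x3 <- run_stage(3, x2p)
  if (flags$ca) {
    d3 <- dim(x3)
    x2pp <- adapter_fwd(mods$ca23.match, x2p, d3[2], d3[3])
    x3p <- attn_fwd(mods$ca23.attn, x3, x2pp)
  } else x3p <- x3
  x4 <- run_stage(4, x3p)
  if (flags$ca) {
    d4 <- dim(x4)
    x3pp <- adapter_fwd(mods$ca34.match, x3p, d4[2], d4[3])
    x4p <- attn_fwd(mods$ca34.attn, x4, x3pp)
  } else x4p <- x4
  pooled <- gap_fwd(x4p)
  logits <- linear_fwd(mods$fc, pooled)
  model$cache <- list(stem_mask = stem_mask, hw4 = dim(x4p)[2:3],
                      B = dim(x)[1])
  model$stage_out <- list(x0 = x0, x1 = x1, x1p = x1p, x2 = x2, x2p = x2p,
                          x3 = x3, x3p = x3p, x4 = x4, x4p = x4p)
  logits
}

model_bwd_internal <- function(model, dlogits) {
  mods <- model$mods
  flags <- variant_flags(model$variant)
  cc <- model$cache
  C4 <- model$config$stage_channels[5]
  dpooled <- linear_bwd(mods$fc, dlogits)
  dx4p <- gap_bwd(dpooled, cc$hw4, cc$B, C4)
  if (flags$ca) {
    g <- attn_bwd(mods$ca34.attn, dx4p)
    dx4 <- g$dX
    dx3p_extra <- adapter_bwd(mods$ca34.match, g$dY)
  } else { dx4 <- dx4p; dx3p_extra <- 0 }
  back_stage <- function(s, dy) {
    for (b in rev(model$stages[[s]])) dy <- block_bwd(b, dy)
    dy
  }
  dx3p <- back_stage(4, dx4) + dx3p_extra
  if (flags$ca) {
    g <- attn_bwd(mods$ca23.attn, dx3p)
    dx3 <- g$dX
    dx2p_extra <- adapter_bwd(mods$ca23.match, g$dY)
  } else { dx3 <- dx3p; dx2p_extra <- 0 }
  dx2p <- back_stage(3, dx3) + dx2p_extra
  if (flags$ha) {
    g <- attn_bwd(mods$ha2, dx2p)
    dx2 <- g$dX + g$dY
  } else dx2 <- dx2p
  dx1p <- back_stage(2, dx2)
  if (flags$ha) {
    g <- attn_bwd(mods$ha1, dx1p)
    dx1 <- g$dX + g$dY
  } else dx1 <- dx1p
  dx0 <- back_stage(1, dx1)
  dh <- maxpool_bwd(model$stem_pool, dx0) * cc$stem_mask
  conv_bwd(mods$stem.conv, bn_bwd(mods$stem.bn, dh))
}

#' Forward pass: class logits
#'
#' @param model a [build_model()] result.
#' @param batch input array `(B, 3, H, W)` at the configured input size
#'   (values already normalized to `[-1, 1]` by [preprocess_image()]).
#' @param training if `TRUE`, batch statistics are used and cached for a
#'   subsequent backward pass; the default uses running statistics.
#' @return logit matrix `(B, num_classes)`.
#' @export
model_forward <- function(model, batch, training = FALSE) {
  check_input_batch(model, batch)
  model_fwd_internal(model, bchw_to_bhwc(batch), training)
}

#' Class probabilities via row softmax of the logits
#'
#' @inheritParams model_forward
#' @param images input array `(B, 3, H, W)` or a single `(3, H, W)` image.
#' @return matrix `(B, num_classes)` of probabilities; rows sum to 1.
#' @export
predict_proba <- function(model, images) {
  if (length(dim(images)) == 3) dim(images) <- c(1L, dim(images))
  softmax_rows(model_forward(model, images))
}

# ---- parameter plumbing ----

#' @keywords internal
param_refs <- function(model) {
  refs <- list()
  for (nm in names(model$mods)) {
    m <- model$mods[[nm]]
    for (p in m$param_names)
      refs[[paste(nm, p, sep = ".")]] <- list(env = m, field = p)
  }
  refs
}

#' Named list of all trainable parameters
#' @param model a `hmc_model`.
#' @return named list of numeric arrays.
#' @export
get_params <- function(model) {
  refs <- param_refs(model)
  lapply(refs, function(r) r$env[[r$field]])
}

#' Overwrite parameters by name
#'
#' Names absent from `params` are left untouched, so a baseline model's
#' parameters can be copied into any attention variant (shared-backbone
#' naming).
#' @param model a `hmc_model`.
#' @param params named list as returned by [get_params()].
#' @export
set_params <- function(model, params) {
  refs <- param_refs(model)
  for (nm in intersect(names(params), names(refs))) {
    r <- refs[[nm]]
    cur <- r$env[[r$field]]
    new <- params[[nm]]
    if (!identical(dim(cur), dim(new)) || length(cur) != length(new))
      hmc_stop(sprintf("parameter %s has incompatible shape", nm),
               "hmcnet_config_error")
    if (!is.null(dim(cur))) dim(new) <- dim(cur)
    r$env[[r$field]] <- new
  }
  invisible(model)
}

#' @keywords internal
zero_grads <- function(model) {
  for (m in model$mods) zero_grads_layer(m)
  invisible(model)
}

#' @keywords internal
get_grads <- function(model) {
  refs <- param_refs(model)
  lapply(refs, function(r) r$env[[paste0("g", r$field)]])
}

#' @export
print.hmc_model <- function(x, ...) {
  np <- sum(vapply(get_params(x), length, 1L))
  cat(sprintf("<hmc_model variant=%s input=%dpx channels=[%s] params=%d>\n",
              x$variant, x$config$input_size,
              paste(x$config$stage_channels, collapse = ","), np))
  invisible(x)
}
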