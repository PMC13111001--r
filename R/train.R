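# Training: Adam on softmax cross-entropy, on-the-fly augmentation of
# training samples only, patient-wise validation split, per-epoch history.

#' Training configuration
#'
#' @param lr Adam learning rate (the reference setting is 1e-4).
#' @param batch_size minibatch size (reference setting 32).
#' @param epochs number of passes over the training set.
#' @param seed integer seed governing shuffling and augmentation draws.
#' @param val_fraction fraction of training *patients* held out patient-wise
#'   for validation curves; 0 disables the split.
#' @param augment apply random augmentation to training samples
#'   (never to validation samples).
#' @param beta1,beta2,eps Adam moment parameters.
#' @param lr_decay_epochs epochs at whose start the learning rate is
#'   multiplied by `lr_decay_factor` (step decay); empty for a flat rate.
#' @param lr_decay_factor multiplicative decay factor.
#' @param verbose print one line per epoch.
#' @return a `hmc_train_config` list.
#' @export
train_config <- function(lr = 1e-4, batch_size = 32L, epochs = 50L,
                         seed = 1L, val_fraction = 0.1, augment = TRUE,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         lr_decay_epochs = integer(0), lr_decay_factor = 0.1,
                         verbose = FALSE) {
  if (lr < 0) hmc_stop("learning rate must be >= 0", "hmcnet_config_error")
  if (batch_size < 1) hmc_stop("batch_size must be >= 1", "hmcnet_config_error")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 val_fraction = val_fraction, augment = isTRUE(augment),
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 lr_decay_epochs = as.integer(lr_decay_epochs),
                 lr_decay_factor = lr_decay_factor,
                 verbose = isTRUE(verbose)),
            class = "hmc_train_config")
}

ce_loss_grad <- function(logits, labels) {
  # labels are 0-based class indices; returns mean CE and d loss / d logits
  B <- nrow(logits)
  p <- softmax_rows(logits)
  idx <- cbind(seq_len(B), labels + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dl <- p
  dl[idx] <- dl[idx] - 1
  list(loss = loss, dlogits = dl / B, probs = p)
}

adam_new <- function(cfg) {
  e <- new.env(parent = emptyenv())
  e$t <- 0L; e$m <- list(); e$v <- list(); e$cfg <- cfg
  e
}

adam_step <- function(opt, model) {
  cfg <- opt$cfg
  opt$t <- opt$t + 1L
  bc1 <- 1 - cfg$beta1^opt$t
  bc2 <- 1 - cfg$beta2^opt$t
  refs <- param_refs(model)
  for (nm in names(refs)) {
    r <- refs[[nm]]
    g <- r$env[[paste0("g", r$field)]]
    if (is.null(opt$m[[nm]])) { opt$m[[nm]] <- g * 0; opt$v[[nm]] <- g * 0 }
    opt$m[[nm]] <- cfg$beta1 * opt$m[[nm]] + (1 - cfg$beta1) * g
    opt$v[[nm]] <- cfg$beta2 * opt$v[[nm]] + (1 - cfg$beta2) * g * g
    upd <- (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + cfg$eps)
    r$env[[r$field]] <- r$env[[r$field]] - cfg$lr * upd
  }
  invisible(opt)
}

# assemble a (B,H,W,3) channels-last batch from dataset samples
make_batch <- function(dataset, idx, size, augmenting) {
  B <- length(idx)
  x <- array(0, c(B, size, size, 3L))
  for (i in seq_len(B)) {
    img <- dataset$images[[idx[i]]]
    if (augmenting) img <- augment_image(img)
    x[i, , , ] <- preprocess_internal(img, size)
  }
  x
}

dataset_check <- function(dataset) {
  if (is.null(dataset$images) || length(dataset$images) == 0)
    hmc_stop("dataset is empty", "hmcnet_input_error")
  if (!all(dataset$labels %in% 0:2))
    hmc_stop("labels must be in {0, 1, 2}", "hmcnet_input_error")
  if (is.null(dataset$patient_id))
    dataset$patient_id <- seq_along(dataset$images)
  dataset
}

#' Train a model
#'
#' Minimizes the softmax cross-entropy `L = -sum_c t_c log p_c` with Adam.
#' Augmentation (jitter, flip, rotation) is applied to training samples
#' only; an optional patient-wise validation split is held out for the
#' learning curves. Runs are reproducible for a fixed seed.
#'
#' @param model a [build_model()] result (modified in place and returned).
#' @param dataset a list with `images` (list of `[0,1]` grayscale matrices),
#'   `labels` (integer 0/1/2 for normal/benign/malignant) and optionally
#'   `patient_id`; see [phantom_dataset()].
#' @param tcfg a [train_config()].
#' @return the trained model, with the per-epoch history data frame
#'   (`epoch`, `train_loss`, `val_loss`, `train_acc`, `val_acc`) in
#'   `model$history`.
#' @export
train_model <- function(model, dataset, tcfg = train_config()) {
  dataset <- dataset_check(dataset)
  set.seed(tcfg$seed)
  n <- length(dataset$images)
  size <- model$config$input_size
  # patient-wise validation split
  val_idx <- integer(0)
  if (tcfg$val_fraction > 0) {
    pats <- unique(dataset$patient_id)
    nv <- max(1L, round(tcfg$val_fraction * length(pats)))
    if (nv < length(pats)) {
      vp <- sample(pats, nv)
      val_idx <- which(dataset$patient_id %in% vp)
    }
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  opt <- adam_new(tcfg)
  hist <- vector("list", tcfg$epochs)
  for (ep in seq_len(tcfg$epochs)) {
    if (ep %in% tcfg$lr_decay_epochs)
      opt$cfg$lr <- opt$cfg$lr * tcfg$lr_decay_factor
    ord <- sample(tr_idx)
    tl <- 0; tn <- 0; tcorr <- 0
    for (start in seq(1, length(ord), by = tcfg$batch_size)) {
      bi <- ord[start:min(start + tcfg$batch_size - 1L, length(ord))]
      xb <- make_batch(dataset, bi, size, tcfg$augment)
      yb <- dataset$labels[bi]
      logits <- model_fwd_internal(model, xb, training = length(bi) > 1)
      lg <- ce_loss_grad(logits, yb)
      if (!is.finite(lg$loss))
        hmc_stop(sprintf("non-finite loss at epoch %d", ep),
                 "hmcnet_numeric_error")
      zero_grads(model)
      model_bwd_internal(model, lg$dlogits)
      if (tcfg$lr > 0) adam_step(opt, model)
      tl <- tl + lg$loss * length(bi); tn <- tn + length(bi)
      tcorr <- tcorr + sum(max.col(lg$probs) - 1L == yb)
    }
    row <- data.frame(epoch = ep, train_loss = tl / tn,
                      val_loss = NA_real_, train_acc = tcorr / tn,
                      val_acc = NA_real_)
    if (length(val_idx) > 0) {
      ev <- evaluate_split(model, dataset, val_idx)
      row$val_loss <- ev$loss; row$val_acc <- ev$acc
    }
    if (tcfg$verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %.3f  val_acc %s", ep,
                      row$train_loss, row$train_acc,
                      ifelse(is.na(row$val_acc), "-", sprintf("%.3f", row$val_acc))))
    hist[[ep]] <- row
  }
  model$history <- do.call(rbind, hist)
  model
}

#' Evaluate a model on a subset of a dataset (no augmentation)
#'
#' @param model a trained model.
#' @param dataset see [train_model()].
#' @param idx indices to evaluate (default all).
#' @param batch_size evaluation batch size.
#' @return list with `loss`, `acc`, `pred` (0-based classes) and `probs`.
#' @export
evaluate_split <- function(model, dataset, idx = seq_along(dataset$images),
                           batch_size = 32L) {
  dataset <- dataset_check(dataset)
  size <- model$config$input_size
  loss <- 0; corr <- 0
  preds <- integer(length(idx))
  probs <- matrix(0, length(idx), model$config$num_classes)
  for (start in seq(1, length(idx), by = batch_size)) {
    sel <- start:min(start + batch_size - 1L, length(idx))
    bi <- idx[sel]
    xb <- make_batch(dataset, bi, size, FALSE)
    logits <- model_fwd_internal(model, xb, training = FALSE)
    lg <- ce_loss_grad(logits, dataset$labels[bi])
    loss <- loss + lg$loss * length(bi)
    preds[sel] <- max.col(lg$probs) - 1L
    probs[sel, ] <- lg$probs
    corr <- corr + sum(preds[sel] == dataset$labels[bi])
  }
  list(loss = loss / length(idx), acc = corr / length(idx),
       pred = preds, probs = probs)
}

#' Save / load model checkpoints
#'
#' Checkpoints carry a schema version, the backbone configuration, variant,
#' seed and all parameters plus batch-norm running statistics.
#'
#' @param model a `hmc_model`.
#' @param path file path.
#' @return `load_checkpoint` returns a reconstructed `hmc_model`.
#' @export
save_checkpoint <- function(model, path) {
  run_stats <- list()
  for (nm in names(model$mods)) {
    m <- model$mods[[nm]]
    if (inherits(m, "hmc_bn"))
      run_stats[[nm]] <- list(mean = m$run_mean, var = m$run_var)
  }
  obj <- list(schema = 1L, variant = model$variant,
              config = unclass(model$config), seed = model$seed,
              params = get_params(model), run_stats = run_stats,
              history = model$history)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$schema) || obj$schema != 1L)
    hmc_stop("unsupported checkpoint schema", "hmcnet_input_error")
  cfg <- structure(obj$config, class = "hmc_config")
  model <- build_model(obj$variant, cfg, obj$seed)
  set_params(model, obj$params)
  for (nm in names(obj$run_stats)) {
    model$mods[[nm]]$run_mean <- obj$run_stats[[nm]]$mean
    model$mods[[nm]]$run_var <- obj$run_stats[[nm]]$var
  }
  model$history <- obj$history
  model
}
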