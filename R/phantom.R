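# Synthetic mammographic phantom generator: three classes of [0,1]
# grayscale images with exact ground-truth lesion masks.
#   normal    - smooth low-frequency background texture only
#   benign    - background + one bright near-circular blob, smooth boundary
#   malignant - background + one irregular (angular-harmonic) blob with
#               radiating spicules and higher contrast
# Every sample is bit-reproducible from its own seed.

phantom_background <- function(size) {
  ng <- 6L
  g <- matrix(stats::runif(ng * ng, 0.20, 0.40), ng, ng)
  bg <- resize_bilinear_2d(g, size, size)
  bg + matrix(stats::rnorm(size * size, sd = 0.02), size, size)
}

phantom_lesion <- function(size, malignant) {
  cy <- stats::runif(1, 0.30 * size, 0.70 * size)
  cx <- stats::runif(1, 0.30 * size, 0.70 * size)
  r <- matrix(rep(seq_len(size), size), size, size)
  c_ <- matrix(rep(seq_len(size), each = size), size, size)
  dy <- r - cy; dx <- c_ - cx
  d <- sqrt(dy^2 + dx^2)
  theta <- atan2(dy, dx)
  if (malignant) {
    r0 <- stats::runif(1, 0.08, 0.14) * size
    amp <- stats::runif(1, 0.45, 0.60)
    # irregular outline: angular harmonics of orders 2..5
    a <- stats::runif(4, 0, 0.15); ph <- stats::runif(4, 0, 2 * pi)
    redge <- r0 * (1 + a[1] * cos(2 * theta + ph[1]) +
                     a[2] * cos(3 * theta + ph[2]) +
                     a[3] * cos(4 * theta + ph[3]) +
                     a[4] * cos(5 * theta + ph[4]))
    mask <- d <= redge
    # radiating spicules: rays wide enough to stay visible at 64 px
    nray <- sample(6:10, 1)
    angs <- stats::runif(nray, -pi, pi)
    rlen <- r0 * stats::runif(nray, 1.6, 2.4)
    halfw <- stats::runif(nray, 0.08, 0.15)
    for (i in seq_len(nray)) {
      da <- abs(atan2(sin(theta - angs[i]), cos(theta - angs[i])))
      mask <- mask | (da <= halfw[i] & d <= rlen[i])
    }
    add <- amp * exp(-(d / (0.9 * r0))^2)
    add[mask & d > r0] <- pmax(add[mask & d > r0], 0.5 * amp)
  } else {
    r0 <- stats::runif(1, 0.07, 0.12) * size
    amp <- stats::runif(1, 0.20, 0.32)
    ecc <- stats::runif(1, 0.9, 1.1)   # mild ellipticity
    dd <- sqrt((dy * ecc)^2 + (dx / ecc)^2)
    mask <- dd <= r0
    add <- amp * exp(-(dd / (0.8 * r0))^2)
  }
  list(add = add, mask = mask)
}

#' Generate one phantom sample
#'
#' @param label `"normal"`, `"benign"` or `"malignant"`.
#' @param size square image size in pixels.
#' @param seed integer seed; identical seeds give bit-identical samples.
#' @return list with `image` (`[0,1]` matrix), `mask` (0/1 matrix, empty for
#'   normal), `label`, `seed`.
#' @export
phantom_sample <- function(label, size = 224L, seed = 1L) {
  label <- match.arg(label, c("normal", "benign", "malignant"))
  set.seed(seed)
  img <- phantom_background(size)
  mask <- matrix(0L, size, size)
  if (label != "normal") {
    les <- phantom_lesion(size, label == "malignant")
    img <- img + les$add
    mask <- matrix(as.integer(les$mask), size, size)
  }
  list(image = pmin(pmax(img, 0), 1), mask = mask, label = label,
       seed = as.integer(seed))
}

#' Generate a seeded phantom set
#'
#' @param n number of samples.
#' @param class_mix named or positional proportions for
#'   (normal, benign, malignant); must sum to 1.
#' @param size image size in pixels.
#' @param seed master seed; per-sample seeds are drawn from it, so the whole
#'   sequence is bit-reproducible.
#' @return list of [phantom_sample()] results, in shuffled class order.
#' @export
generate_phantoms <- function(n, class_mix = c(1, 1, 1) / 3, size = 224L,
                              seed = 1L) {
  if (n < 1) hmc_stop("n must be >= 1", "hmcnet_input_error")
  if (length(class_mix) != 3 || any(class_mix < 0) ||
      abs(sum(class_mix) - 1) > 1e-8)
    hmc_stop("class_mix must be 3 nonnegative proportions summing to 1",
             "hmcnet_input_error")
  counts <- diff(c(0, round(cumsum(class_mix) * n)))
  labels <- rep(c("normal", "benign", "malignant"), counts)
  set.seed(seed)
  labels <- sample(labels)
  seeds <- sample.int(.Machine$integer.max, n)
  lapply(seq_len(n), function(i) phantom_sample(labels[i], size, seeds[i]))
}

#' Convert a phantom set into a training dataset
#'
#' Labels are coded 0/1/2 for normal/benign/malignant; consecutive samples
#' are paired into pseudo-patients (two images per patient, mirroring the
#' two-films-per-patient layout of screening data).
#'
#' @param phantoms result of [generate_phantoms()].
#' @return list with `images`, `labels`, `patient_id`, `masks`.
#' @export
phantom_dataset <- function(phantoms) {
  lab <- vapply(phantoms, function(p) p$label, "")
  list(images = lapply(phantoms, function(p) p$image),
       labels = match(lab, c("normal", "benign", "malignant")) - 1L,
       patient_id = (seq_along(phantoms) + 1L) %/% 2L,
       masks = lapply(phantoms, function(p) p$mask))
}

#' Write a phantom set to disk (PNG images + masks + CSV manifest)
#'
#' @param phantoms result of [generate_phantoms()].
#' @param dir output directory (created if missing).
#' @return the manifest data frame, invisibly.
#' @export
write_phantoms <- function(phantoms, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(phantoms), function(i) {
    p <- phantoms[[i]]
    id <- sprintf("phantom%04d", i)
    img_path <- file.path(dir, paste0(id, ".png"))
    png::writePNG(p$image, img_path)
    mask_path <- NA_character_
    if (p$label != "normal") {
      mask_path <- file.path(dir, paste0(id, "_mask.png"))
      png::writePNG(p$mask + 0, mask_path)
    }
    data.frame(id = id, label = p$label, seed = p$seed,
               image_path = img_path, mask_path = mask_path)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Boundary-pixel count of a binary mask (4-connectivity)
#' @param mask 0/1 matrix.
#' @return integer count of mask pixels with at least one background neighbor.
#' @export
mask_perimeter <- function(mask) {
  m <- mask > 0
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  inner <- pad[2:(h + 1), 2:(w + 1)] & pad[1:h, 2:(w + 1)] &
    pad[3:(h + 2), 2:(w + 1)] & pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  sum(m) - sum(inner)
}
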