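# Preprocessing and augmentation. Images are [0,1] grayscale matrices
# (rows = top-to-bottom). Preprocessing: bilinear resize to the network
# input size, replication into 3 identical channels, normalization with
# fixed mean/sd 0.5 into [-1, 1]. Augmentation (training folds only):
# brightness/contrast jitter of +-20%, horizontal flip with probability
# 0.5, rotation uniform in +-15 degrees with zero fill, applied in that
# order.

# channels-last (H,W,3) version used by the training loop
preprocess_internal <- function(image, size) {
  if (length(image) == 0)
    hmc_stop("empty image", "hmcnet_input_error")
  img <- resize_bilinear_2d(image, size, size)
  img <- (img - 0.5) / 0.5
  array(img, c(size, size, 3L))
}

#' Preprocess a grayscale image for the network
#'
#' @param image matrix with values in `[0, 1]`.
#' @param size target square resolution (default 224).
#' @return array `(3, size, size)`: three identical channels in `[-1, 1]`.
#' @export
preprocess_image <- function(image, size = 224L) {
  x <- preprocess_internal(image, size)
  aperm(x, c(3, 1, 2))
}

rotate_image <- function(image, angle_deg) {
  h <- nrow(image); w <- ncol(image)
  th <- angle_deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  r <- matrix(rep(seq_len(h), w), h, w)
  c_ <- matrix(rep(seq_len(w), each = h), h, w)
  # inverse map: rotate output coords by -angle around the center
  sy <- cy + cos(th) * (r - cy) - sin(th) * (c_ - cx)
  sx <- cx + sin(th) * (r - cy) + cos(th) * (c_ - cx)
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  val <- function(rr, cc) {
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    v <- numeric(length(rr))
    v[ok] <- image[cbind(rr[ok], cc[ok])]
    v
  }
  out <- (1 - fy) * (1 - fx) * val(y0, x0) +
    (1 - fy) * fx * val(y0, x0 + 1) +
    fy * (1 - fx) * val(y0 + 1, x0) +
    fy * fx * val(y0 + 1, x0 + 1)
  matrix(out, h, w)
}

#' Randomly augment a training image
#'
#' Draws brightness and contrast factors uniformly in `[0.8, 1.2]`, flips
#' horizontally with probability 0.5, and rotates by an angle uniform in
#' `[-15, 15]` degrees (bilinear, zero fill outside the frame). The draws
#' come from R's global RNG stream, so a fixed seed fixes the output.
#'
#' @param image `[0,1]` grayscale matrix.
#' @param seed optional integer; if given, seeds the RNG first.
#' @return augmented matrix, clipped to `[0, 1]`.
#' @export
augment_image <- function(image, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bright <- stats::runif(1, 0.8, 1.2)
  contrast <- stats::runif(1, 0.8, 1.2)
  do_flip <- stats::runif(1) < 0.5
  angle <- stats::runif(1, -15, 15)
  img <- image * bright
  img <- (img - mean(img)) * contrast + mean(img)
  img <- pmin(pmax(img, 0), 1)
  if (do_flip) img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
  if (abs(angle) > 1e-12) img <- rotate_image(img, angle)
  pmin(pmax(img, 0), 1)
}

#' Offline augmentation expansion
#'
#' Derives exactly `m` augmented variants from the given training images by
#' cycling through them and drawing fresh augmentation parameters for each
#' variant. The published fixed-count regime (hundreds of thousands of
#' variants) is a configuration value of this routine, not a constant.
#'
#' @param images list of `[0,1]` grayscale matrices (training fold only).
#' @param m total number of derived images to produce.
#' @param seed integer seed.
#' @return list of `m` augmented images; each element carries the index of
#'   its source image in the `source` attribute.
#' @export
expand_augmented <- function(images, m, seed = 1L) {
  if (length(images) == 0) hmc_stop("no images to augment", "hmcnet_input_error")
  if (m < 1) hmc_stop("m must be >= 1", "hmcnet_input_error")
  set.seed(seed)
  src <- rep(seq_along(images), length.out = m)
  out <- lapply(src, function(i) augment_image(images[[i]]))
  for (j in seq_len(m)) attr(out[[j]], "source") <- src[j]
  out
}

#' Patient-level k-fold split
#'
#' Partitions patients (not images) into `k` near-equal groups so that all
#' images of a patient land in exactly one test fold; group sizes differ by
#' at most one patient. The absence of train/test patient overlap is
#' asserted programmatically before returning.
#'
#' @param records a data frame or list with a `patient_id` element (one
#'   entry per image), or a bare vector of patient ids.
#' @param k number of folds (>= 2).
#' @param seed integer seed for the patient shuffle.
#' @return list of `k` folds, each `list(train, test, test_patients)` with
#'   `train`/`test` image indices.
#' @export
patient_kfold <- function(records, k = 5L, seed = 1L) {
  pid <- if (is.atomic(records)) records else records$patient_id
  if (is.null(pid)) hmc_stop("records carry no patient_id", "hmcnet_input_error")
  pats <- unique(pid)
  if (k < 2) hmc_stop("k must be >= 2", "hmcnet_input_error")
  if (k > length(pats))
    hmc_stop(sprintf("k = %d exceeds patient count %d", k, length(pats)),
             "hmcnet_input_error")
  set.seed(seed)
  shuffled <- sample(pats)
  # near-equal group sizes: the first (n %% k) groups get one extra patient
  base <- length(pats) %/% k; extra <- length(pats) %% k
  sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  groups <- split(shuffled, rep(seq_len(k), times = sizes))
  folds <- lapply(seq_len(k), function(i) {
    test_p <- groups[[i]]
    test <- which(pid %in% test_p)
    train <- setdiff(seq_along(pid), test)
    if (length(intersect(pid[train], pid[test])) > 0)
      hmc_stop("patient leakage between train and test", "hmcnet_internal_error")
    list(train = train, test = test, test_patients = test_p)
  })
  folds
}
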