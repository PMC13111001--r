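# MIAS parsing, PGM I/O, ROI masks, preprocessing, augmentation,
# patient-level splitting, and the phantom generator.

test_that("MIAS info lines parse into records with correct labels and ROIs", {
  info <- tempfile()
  writeLines(c(
    "mdb001 G CIRC B 535 425 197",
    "mdb002 G NORM",
    "mdb003 D MISC M 338 314 56",
    "mdb003 D CALC B 546 520 40",   # second abnormality, same image
    "mdb004 F NORM"
  ), info)
  recs <- read_mias(info)
  expect_equal(nrow(recs), 4L)
  r1 <- recs[recs$image_id == "mdb001", ]
  expect_equal(r1$abnormality, "CIRC")
  expect_equal(r1$severity, "benign")
  expect_equal(r1$rois[[1]][[1]]$center, c(535, 425))
  expect_equal(r1$rois[[1]][[1]]$radius, 197)
  expect_equal(recs$label, c("benign", "normal", "malignant", "normal"))
  # malignant > benign precedence, mask list keeps both discs
  r3 <- recs[recs$image_id == "mdb003", ]
  expect_length(r3$rois[[1]], 2L)
  # NORM records carry no ROI
  expect_length(recs$rois[[2]], 0L)
  # consecutive pairing: records 2i-1 and 2i share a patient
  expect_equal(recs$patient_id, c(1L, 1L, 2L, 2L))
  writeLines("mdb009 G CIRC X 1 2 3", info)
  expect_error(read_mias(info), "line 1", class = "hmcnet_parse_error")
})

test_that("a full-size annotation set yields 322 records over 161 patients", {
  info <- tempfile()
  set.seed(30)
  lines <- vapply(seq_len(322), function(i) {
    id <- sprintf("mdb%03d", i)
    if (i %% 3 == 0)
      sprintf("%s G %s %s %d %d %d", id, sample(c("CIRC", "SPIC", "MISC"), 1),
              sample(c("B", "M"), 1), sample(1024, 1) - 1, sample(1024, 1) - 1,
              sample(20:200, 1))
    else paste(id, "G NORM")
  }, "")
  writeLines(lines, info)
  recs <- read_mias(info)
  expect_equal(nrow(recs), 322L)
  expect_equal(length(unique(recs$patient_id)), 161L)
  expect_true(all(table(recs$patient_id) == 2L))
})

test_that("PGM reader handles binary and ASCII dialects and image checks", {
  set.seed(31)
  mat <- matrix(sample(0:255, 12 * 10, replace = TRUE), 12, 10)
  p5 <- write_pgm_fixture(mat, tempfile(fileext = ".pgm"))
  p2 <- write_pgm_fixture(mat, tempfile(fileext = ".pgm"), ascii = TRUE)
  expect_equal(read_pgm(p5), mat / 255, tolerance = 1e-12)
  expect_equal(read_pgm(p2), mat / 255, tolerance = 1e-12)
  # read_mias validates image presence when a directory is supplied
  dir <- tempfile(); dir.create(dir)
  write_pgm_fixture(mat, file.path(dir, "mdb001.pgm"))
  info <- tempfile()
  writeLines(c("mdb001 G NORM", "mdb002 G NORM"), info)
  expect_error(read_mias(info, dir), "mdb002",
               class = "hmcnet_consistency_error")
  writeLines("mdb001 G NORM", info)
  recs <- read_mias(info, dir)
  ds <- mias_dataset(recs)
  expect_equal(ds$images[[1]], mat / 255, tolerance = 1e-12)
  expect_equal(ds$labels, 0L)
})

test_that("ROI masks flip the y origin, clip at bounds, and fill discs", {
  rec <- list(rois = list(list(center = c(10, 20), radius = 0)))
  m <- roi_mask(rec, 64L)
  expect_equal(sum(m), 1L)
  expect_equal(m[64 - 20, 10 + 1], 1L)   # bottom-left origin -> row flip
  # corner center: clipped to at most a quarter disc (plus boundary pixels)
  rec <- list(rois = list(list(center = c(0, 0), radius = 10)))
  m <- roi_mask(rec, 64L)
  expect_lte(sum(m), ceiling(pi * 10^2 / 4) + 2 * 10 + 1)
  expect_equal(m[64, 1], 1L)
  # centered disc area within 2% of pi r^2
  rec <- list(rois = list(list(center = c(128, 128), radius = 50)))
  m <- roi_mask(rec, 256L)
  expect_lt(abs(sum(m) - pi * 50^2) / (pi * 50^2), 0.02)
  expect_error(roi_mask(list(rois = list()), 64L), class = "hmcnet_input_error")
})

test_that("preprocessing resizes, replicates channels, and maps to [-1, 1]", {
  img <- matrix(0.5, 10, 10)
  x <- preprocess_image(img, 8L)
  expect_equal(dim(x), c(3L, 8L, 8L))
  expect_equal(max(abs(x)), 0)           # 0.5 maps to 0
  set.seed(32)
  img <- matrix(runif(20 * 20), 20, 20)
  x <- preprocess_image(img, 16L)
  expect_equal(x[1, , ], x[2, , ])
  expect_equal(x[2, , ], x[3, , ])
  expect_true(all(x >= -1 & x <= 1))
  expect_equal(preprocess_image(matrix(1, 4, 4), 4L)[1, 1, 1], 1)
  expect_equal(preprocess_image(matrix(0, 4, 4), 4L)[1, 1, 1], -1)
  expect_error(preprocess_image(matrix(numeric(0), 0, 0), 8L),
               class = "hmcnet_input_error")
})

test_that("augmentation draws stay in the stated ranges and are seeded", {
  img <- matrix(runif(16 * 16), 16, 16)
  a1 <- augment_image(img, seed = 42)
  a2 <- augment_image(img, seed = 42)
  expect_identical(a1, a2)
  # double flip is the identity
  flipped <- img[, rev(seq_len(ncol(img)))]
  expect_identical(flipped[, rev(seq_len(ncol(flipped)))], img)
  # Monte-Carlo check of the stated parameter ranges
  set.seed(43)
  n <- 10000
  flips <- logical(n); angles <- numeric(n); brights <- numeric(n)
  for (i in seq_len(n)) {
    brights[i] <- stats::runif(1, 0.8, 1.2)
    stats::runif(1, 0.8, 1.2)
    flips[i] <- stats::runif(1) < 0.5
    angles[i] <- stats::runif(1, -15, 15)
  }
  expect_lt(abs(mean(flips) - 0.5), 0.02)
  expect_true(all(abs(angles) <= 15))
  expect_true(all(brights >= 0.8 & brights <= 1.2))
  # rotation keeps values in [0,1] and zero-fills corners
  rot <- hmcnet:::rotate_image(matrix(1, 32, 32), 15)
  expect_equal(rot[1, 1], 0)
  expect_true(all(rot >= 0 & rot <= 1 + 1e-12))
})

test_that("offline expansion yields exactly m derived images, reproducibly", {
  imgs <- lapply(1:3, function(i) matrix(runif(64), 8, 8))
  ex1 <- expand_augmented(imgs, 10, seed = 4)
  ex2 <- expand_augmented(imgs, 10, seed = 4)
  expect_length(ex1, 10L)
  expect_identical(ex1, ex2)
  expect_equal(vapply(ex1, attr, 0L, "source"),
               rep(1:3, length.out = 10))
  expect_error(expand_augmented(list(), 5), class = "hmcnet_input_error")
})

test_that("patient k-fold splits partition records without leakage", {
  pid <- rep(1:23, each = 2)
  folds <- patient_kfold(pid, k = 5, seed = 1)
  test_all <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_equal(test_all, seq_along(pid))           # complete, disjoint
  sizes <- vapply(folds, function(f) length(f$test_patients), 0L)
  expect_lte(max(sizes) - min(sizes), 1L)
  for (f in folds)
    expect_length(intersect(pid[f$train], pid[f$test]), 0L)
  # no patient in two different test folds
  tp <- unlist(lapply(folds, `[[`, "test_patients"))
  expect_equal(anyDuplicated(tp), 0L)
  expect_error(patient_kfold(pid, k = 24), class = "hmcnet_input_error")
})

test_that("phantoms are seeded, labelled, and masked consistently", {
  ph1 <- generate_phantoms(12, size = 48, seed = 9)
  ph2 <- generate_phantoms(12, size = 48, seed = 9)
  expect_identical(ph1, ph2)
  for (p in ph1) {
    expect_true(all(p$image >= 0 & p$image <= 1))
    if (p$label == "normal") expect_equal(sum(p$mask), 0L)
    else expect_gt(sum(p$mask), 0L)
  }
  labs <- vapply(ph1, `[[`, "", "label")
  expect_setequal(unique(labs), c("normal", "benign", "malignant"))
  ds <- phantom_dataset(ph1)
  expect_equal(sort(unique(ds$labels)), 0:2)
  expect_true(all(table(ds$patient_id) <= 2))
  # preprocessing composed with generation stays in [-1,1], 3 equal channels
  x <- preprocess_image(ds$images[[1]], 32L)
  expect_true(all(x >= -1 & x <= 1))
  expect_equal(x[1, , ], x[3, , ])
  expect_error(generate_phantoms(5, class_mix = c(0.5, 0.5, 0.5)),
               class = "hmcnet_input_error")
})

test_that("lesions are brighter inside the mask; malignant masks are more spiculated", {
  ph <- generate_phantoms(100, class_mix = c(0, 0.5, 0.5), size = 64,
                          seed = 10)
  labs <- vapply(ph, `[[`, "", "label")
  shape_idx <- function(p) mask_perimeter(p$mask)^2 / sum(p$mask)
  inside_gt <- vapply(ph, function(p)
    mean(p$image[p$mask == 1]) > mean(p$image[p$mask == 0]), TRUE)
  expect_true(all(inside_gt))
  ben <- vapply(ph[labs == "benign"], shape_idx, 0)
  mal <- vapply(ph[labs == "malignant"], shape_idx, 0)
  expect_gt(mean(mal), mean(ben))
})

test_that("phantom sets round-trip through the PNG + manifest writer", {
  dir <- tempfile()
  ph <- generate_phantoms(6, size = 32, seed = 11)
  manifest <- write_phantoms(ph, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(nrow(manifest), 6L)
  img <- png::readPNG(manifest$image_path[1])
  expect_equal(dim(img), c(32L, 32L))
  expect_equal(img, ph[[1]]$image, tolerance = 1 / 255)
  unlink(dir, recursive = TRUE)
})
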