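# MIAS-format I/O: the whitespace-delimited annotation file (one line per
# abnormality: image id, background tissue, abnormality class, severity,
# ROI center x y, radius; NORM lines carry no severity/ROI) and PGM images
# (binary P5 and ASCII P2 dialects). MIAS uses a bottom-left coordinate
# origin, so ROI rows are flipped when masks are rasterized.

#' Read a PGM image
#'
#' Supports the ASCII (`P2`) and binary (`P5`) dialects with maxval up to
#' 65535; pixel values are scaled to `[0, 1]`.
#'
#' @param path file path.
#' @return numeric matrix (rows = image rows, top to bottom).
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2))
  if (!magic %in% c("P2", "P5"))
    hmc_stop(sprintf("%s: not a PGM file (magic '%s')", path, magic),
             "hmcnet_parse_error")
  tokens <- character(0)
  # header: width, height, maxval; '#' starts a comment to end of line
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0 || ch == "")
        hmc_stop(sprintf("%s: truncated PGM header", path), "hmcnet_parse_error")
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1, useBytes = TRUE)
          if (length(ch) == 0 || ch == "" || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok)
      } else tok <- paste0(tok, ch)
    }
  }
  w <- as.integer(read_token()); h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  n <- w * h
  if (magic == "P5") {
    vals <- if (maxval < 256) as.integer(readBin(con, "raw", n)) else
      readBin(con, "integer", n, size = 2, signed = FALSE, endian = "big")
  } else {
    txt <- readChar(con, file.size(path), useBytes = TRUE)
    txt <- gsub("#[^\n]*", " ", txt)
    vals <- as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1]])[seq_len(n)]
  }
  if (length(vals) < n || anyNA(vals))
    hmc_stop(sprintf("%s: truncated PGM pixel data", path), "hmcnet_parse_error")
  matrix(vals / maxval, h, w, byrow = TRUE)
}

parse_mias_line <- function(line, lineno) {
  tok <- strsplit(trimws(line), "[[:space:]]+")[[1]]
  bad <- function() hmc_stop(
    sprintf("malformed MIAS info line %d: '%s'", lineno, line),
    "hmcnet_parse_error")
  if (length(tok) < 3) bad()
  rec <- list(image_id = tok[1], background = tok[2], abnormality = tok[3],
              severity = "none", roi = NULL)
  if (tok[3] == "NORM") {
    if (length(tok) > 3) bad()
    return(rec)
  }
  if (length(tok) < 4) bad()
  rec$severity <- switch(tok[4], B = "benign", M = "malignant", bad())
  if (length(tok) >= 7) {
    xyz <- suppressWarnings(as.numeric(tok[5:7]))
    if (anyNA(xyz)) bad()
    rec$roi <- list(center = xyz[1:2], radius = xyz[3])
  } else if (length(tok) != 4) bad()
  rec
}

#' Read MIAS-style records
#'
#' Parses the plain-text annotation file and (optionally) checks that the
#' corresponding PGM images exist. Images listed with several abnormalities
#' collapse into one record whose label follows the severity precedence
#' malignant > benign and whose ROI list keeps every disc. Patient ids are
#' assigned by consecutive pairing: records 2i-1 and 2i share patient i
#' (two films per patient, which reproduces 161 patients for the full
#' 322-image set).
#'
#' @param info_file path to the annotation text file.
#' @param image_dir optional directory of `<image_id>.pgm` files; when
#'   given, a missing image raises a consistency error and each record
#'   carries its image path.
#' @return data frame with columns `image_id`, `background`, `abnormality`,
#'   `severity`, `label`, `patient_id`, `path`, and a list-column `rois`
#'   (each element a list of `center`/`radius` pairs, or empty).
#' @export
read_mias <- function(info_file, image_dir = NULL) {
  lines <- readLines(info_file)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(seq_along(lines), function(i) parse_mias_line(lines[i], i))
  ids <- vapply(recs, function(r) r$image_id, "")
  uniq <- unique(ids)
  out <- lapply(uniq, function(id) {
    sub <- recs[ids == id]
    sev <- vapply(sub, function(r) r$severity, "")
    abn <- vapply(sub, function(r) r$abnormality, "")
    label <- if (all(abn == "NORM")) "normal" else
      if (any(sev == "malignant")) "malignant" else "benign"
    rois <- Filter(Negate(is.null), lapply(sub, function(r) r$roi))
    list(image_id = id, background = sub[[1]]$background,
         abnormality = paste(unique(abn), collapse = "+"),
         severity = if (label == "normal") "none" else label,
         label = label, rois = rois)
  })
  df <- data.frame(
    image_id = vapply(out, `[[`, "", "image_id"),
    background = vapply(out, `[[`, "", "background"),
    abnormality = vapply(out, `[[`, "", "abnormality"),
    severity = vapply(out, `[[`, "", "severity"),
    label = vapply(out, `[[`, "", "label"),
    stringsAsFactors = FALSE)
  df$patient_id <- (seq_len(nrow(df)) + 1L) %/% 2L
  df$rois <- I(lapply(out, `[[`, "rois"))
  df$path <- NA_character_
  if (!is.null(image_dir)) {
    paths <- file.path(image_dir, paste0(df$image_id, ".pgm"))
    missing <- !file.exists(paths)
    if (any(missing))
      hmc_stop(sprintf("info/image mismatch: no PGM for %s",
                       paste(df$image_id[missing], collapse = ", ")),
               "hmcnet_consistency_error")
    df$path <- paths
  }
  df
}

#' Rasterize the ROI disc(s) of a record into a binary mask
#'
#' MIAS coordinates place the origin at the bottom-left corner, so the
#' stated y is converted to an image row as `row = size - y` (1-based from
#' the top). The mask is the union of all discs of the record, clipped to
#' the image bounds; a pixel belongs to a disc when its Euclidean distance
#' from the center is at most the radius.
#'
#' @param record one row of [read_mias()] output (data frame of one row, or
#'   a list with a `rois` element).
#' @param image_size square image size in pixels (MIAS images are 1024).
#' @return 0/1 integer matrix `image_size x image_size`.
#' @export
roi_mask <- function(record, image_size = 1024L) {
  rois <- if (is.data.frame(record)) record$rois[[1]] else record$rois
  if (is.null(rois) || length(rois) == 0)
    hmc_stop("record has no ROI", "hmcnet_input_error")
  mask <- matrix(0L, image_size, image_size)
  r <- matrix(rep(seq_len(image_size), image_size), image_size, image_size)
  c_ <- matrix(rep(seq_len(image_size), each = image_size), image_size,
               image_size)
  for (roi in rois) {
    row0 <- image_size - roi$center[2]   # bottom-left origin -> top row
    col0 <- roi$center[1] + 1
    hit <- (r - row0)^2 + (c_ - col0)^2 <= roi$radius^2
    mask[hit] <- 1L
  }
  mask
}

#' Convert MIAS records + images into a training dataset
#'
#' @param records [read_mias()] output with image paths.
#' @return list with `images`, `labels` (0/1/2), `patient_id`, `records`.
#' @export
mias_dataset <- function(records) {
  if (anyNA(records$path))
    hmc_stop("records carry no image paths (read_mias without image_dir)",
             "hmcnet_input_error")
  list(images = lapply(records$path, read_pgm),
       labels = match(records$label, c("normal", "benign", "malignant")) - 1L,
       patient_id = records$patient_id,
       records = records)
}
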