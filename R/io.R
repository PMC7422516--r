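#' Read an RGB image
#'
#' Reads an 8-bit PNG or TIFF into an integer H x W x 3 array with values in
#' `[0, 255]`. Grayscale inputs are replicated to three channels; an alpha
#' channel, if present, is dropped. Files stored at more than 8 bits per
#' channel are accepted only when every sample is an exact multiple of the
#' 8-bit rescaling step (a lossless downcast); otherwise an error names the
#' bit depth.
#'
#' Pixel coordinates throughout the package are `(row, col)`, 0-based at the
#' top-left; crop windows are half-open.
#'
#' @param path Path to a PNG or TIFF file.
#' @return Integer array of dimension `c(H, W, 3)` with values in 0..255.
#' @export
read_image <- function(path) {
  arr <- read_pixels(path)
  bits <- attr(arr, "bits")
  if (!is.null(bits) && bits > 8L) {
    step <- (2^bits - 1) / 255
    if (any(arr %% step != 0)) {
      stop("'", path, "' is ", bits,
           "-bit per channel and cannot be losslessly downcast to 8-bit")
    }
    arr <- arr / step
    storage.mode(arr) <- "integer"
  }
  attr(arr, "bits") <- NULL
  d <- dim(arr)
  if (is.matrix(arr)) {
    arr <- array(rep(arr, 3L), dim = c(d[1L], d[2L], 3L))
  } else if (length(d) == 3L && d[3L] == 2L) {
    # grayscale + alpha
    arr <- array(rep(arr[, , 1L], 3L), dim = c(d[1L], d[2L], 3L))
  } else if (length(d) == 3L && d[3L] >= 3L) {
    arr <- arr[, , 1:3, drop = FALSE]
  } else {
    stop("unsupported channel layout in '", path, "'")
  }
  storage.mode(arr) <- "integer"
  arr
}

#' Read an instance label mask
#'
#' Reads a single-channel 8- or 16-bit PNG or TIFF label map
#' (0 = background, positive integer = nucleus id) and canonicalizes it:
#' positive labels are relabeled to `1..n` in order of first pixel occurrence
#' in a row-major scan.
#'
#' @param path Path to a single-channel PNG or TIFF file.
#' @return Integer matrix (H x W) with labels `0..n`.
#' @export
read_label_mask <- function(path) {
  arr <- read_pixels(path)
  if (!is.matrix(arr)) {
    d <- dim(arr)
    if (length(d) == 3L && d[3L] == 1L) {
      arr <- arr[, , 1L]
    } else {
      stop("label mask '", path, "' must be single-channel, got ",
           d[3L], " channels")
    }
  }
  if (any(arr < 0)) stop("label mask '", path, "' contains negative values")
  attr(arr, "bits") <- NULL
  canonicalize_mask(arr)
}

#' Write an instance label mask
#'
#' Writes a label mask losslessly. A `.tif`/`.tiff` path yields a 16-bit
#' single-channel TIFF (the package's default ground-truth encoding,
#' supporting up to 65535 instances); a `.png` path yields an 8-bit
#' single-channel PNG and requires at most 255 instances. Round trip through
#' [read_label_mask()] reproduces the canonical mask exactly.
#'
#' @param mask Integer label matrix.
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @return Invisibly, the canonicalized mask that was written.
#' @export
write_label_mask <- function(mask, path) {
  mask <- canonicalize_mask(mask)
  n <- n_instances(mask)
  if (n > 65535L) stop("mask has ", n, " instances; at most 65535 supported")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L,
                    compression = "none")
  } else if (ext == "png") {
    if (n > 255L) {
      stop("mask has ", n,
           " instances; PNG output is 8-bit (max 255), use a .tif path")
    }
    png::writePNG(mask / 255, path)
  } else {
    stop("unsupported mask extension '", ext, "'")
  }
  invisible(mask)
}

#' Write an RGB image
#'
#' @param image Integer H x W x 3 array with values in 0..255.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return Invisibly, `path`.
#' @export
write_image <- function(image, path) {
  validate_rgb_image(image)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(image / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(image / 255, path, bits.per.sample = 8L,
                    compression = "none")
  } else {
    stop("unsupported image extension '", ext, "'")
  }
  invisible(path)
}

#' Write a per-image metric report as CSV
#'
#' Writes one row per image with columns
#' `image_id, precision, recall, f1, adc, aji`, followed by an aggregate
#' `mean` row and, when at least two images are present, an `sd` row.
#'
#' @param report Data frame with the columns above; one row per image.
#' @param path Output CSV path.
#' @return Invisibly, the full table written (including aggregate rows).
#' @export
write_report <- function(report, path) {
  cols <- c("image_id", "precision", "recall", "f1", "adc", "aji")
  if (!is.data.frame(report) || nrow(report) == 0L) {
    stop("report must be a non-empty data frame")
  }
  if (!all(cols %in% names(report))) {
    stop("report must have columns: ", paste(cols, collapse = ", "))
  }
  report <- report[, cols]
  vals <- as.matrix(report[, -1L])
  if (any(vals < 0 | vals > 1)) stop("metric values must lie in [0, 1]")
  agg <- data.frame(image_id = "mean", t(colMeans(vals)))
  names(agg) <- cols
  out <- rbind(report, agg)
  if (nrow(report) >= 2L) {
    sdrow <- data.frame(image_id = "sd", t(apply(vals, 2L, stats::sd)))
    names(sdrow) <- cols
    out <- rbind(out, sdrow)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Canonicalize an instance label mask
#'
#' Relabels positive labels to `1..n` in order of first pixel occurrence in a
#' row-major scan (top-left to bottom-right, rows first). Idempotent.
#'
#' @param mask Numeric or integer label matrix with non-negative values.
#' @return Integer matrix with labels exactly `{0} U {1..n}`.
#' @export
canonicalize_mask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  m <- mask
  storage.mode(m) <- "integer"
  if (any(m < 0L)) stop("mask contains negative values")
  v <- as.vector(t(m))            # row-major scan order
  u <- unique(v[v > 0L])
  if (length(u) == 0L) return(m)
  map <- integer(max(u))
  map[u] <- seq_along(u)
  pos <- m > 0L
  m[pos] <- map[m[pos]]
  m
}

#' Number of instances in a canonical label mask
#' @param mask Integer label matrix.
#' @return Count of distinct positive labels.
#' @export
n_instances <- function(mask) {
  length(unique(mask[mask > 0L]))
}

#' Validate an RGB image array
#' @param image Candidate H x W x 3 array.
#' @return Invisibly `TRUE`; errors on violation.
#' @export
validate_rgb_image <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L) stop("image must be an H x W x 3 array")
  if (d[1L] < 1L || d[2L] < 1L) stop("image dimensions must be positive")
  if (any(image < 0 | image > 255)) stop("channel values must lie in [0, 255]")
  if (any(image != round(image))) stop("channel values must be integers")
  invisible(TRUE)
}

#' Validate an instance label mask
#' @param mask Candidate label matrix.
#' @return Invisibly `TRUE`; errors on violation.
#' @export
validate_label_mask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (any(mask < 0)) stop("mask values must be non-negative")
  if (any(mask != round(mask))) stop("mask values must be integers")
  labs <- sort(unique(mask[mask > 0]))
  if (length(labs) && !identical(as.integer(labs), seq_len(length(labs)))) {
    stop("mask is not canonical: labels must be exactly 1..n")
  }
  invisible(TRUE)
}

# -- internal readers ---------------------------------------------------------

# Decode a PNG/TIFF file to an integer array of raw sample values.
# PNG bit depth is taken from the IHDR chunk (readPNG normalizes to [0,1]);
# TIFF is read with as.is = TRUE so samples arrive as stored integers.
read_pixels <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    bits <- png_bit_depth(path)
    a <- png::readPNG(path)
    raw <- round(a * (2^bits - 1))
    downcast_to_8bit(raw, bits, path)
  } else if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path, info = TRUE)
    if (is.list(a)) a <- a[[1L]]
    bits <- attr(a, "bits.per.sample")
    if (is.null(bits)) bits <- 8L
    raw <- round(a * (2^bits - 1))
    attributes(raw) <- list(dim = dim(a))
    downcast_to_8bit(raw, bits, path)
  } else {
    stop("unsupported file extension '", ext, "' (PNG or TIFF expected)")
  }
}

png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  sig <- as.integer(hdr[1:8])
  if (!identical(sig, c(137L, 80L, 78L, 71L, 13L, 10L, 26L, 10L))) {
    stop("'", path, "' is not a PNG file")
  }
  as.integer(hdr[25L])  # IHDR bit depth byte
}

# Label masks keep 16-bit values as-is; image samples above 8 bits must
# downcast losslessly (every value a multiple of 257 for 16-bit data).
downcast_to_8bit <- function(raw, bits, path) {
  storage.mode(raw) <- "integer"
  if (bits <= 8L) return(raw)
  attr(raw, "bits") <- bits
  raw
}
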