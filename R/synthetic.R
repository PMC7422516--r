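#' Parameters for the synthetic H&E image generator
#'
#' Bundles the knobs of the seeded generator that emulates
#' hematoxylin-and-eosin stained tissue: elliptical nuclei with a
#' blue-purple color distribution distinct from the pink surrounding-tissue
#' and near-white background distributions, a global per-image stain shift
#' (emulating over-/under-staining), overlap control, and additive noise.
#'
#' Defaults describe an "easy regime" H&E patch: blue-purple nuclei
#' (hematoxylin), pink surrounding tissue (eosin), near-white background,
#' with per-channel color standard deviations small relative to the
#' between-class mean separations so the three color classes are learnable.
#'
#' @param height,width Image size in pixels.
#' @param n_nuclei Number of nuclei to place.
#' @param radius_range Length-2 vector, min/max semi-major axis in pixels
#'   (min must be >= 2).
#' @param eccentricity_range Length-2 vector in `[0, 1)`.
#' @param class_color_means List of three RGB mean vectors named
#'   `nuclei`, `tissue`, `background`.
#' @param class_color_stds List of three per-channel standard deviation
#'   vectors, same names.
#' @param stain_shift Length-3 vector added to all class means (global
#'   stain variation for this image).
#' @param noise_std Additive per-pixel Gaussian noise standard deviation.
#' @param overlap_allowed If `FALSE`, nuclei pixel sets are rejection-sampled
#'   to be pairwise disjoint (retry budget: 100 placements per nucleus).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(height = 256L, width = 256L, n_nuclei = 20L,
                         radius_range = c(6, 12),
                         eccentricity_range = c(0, 0.6),
                         class_color_means = list(
                           nuclei = c(100, 60, 150),
                           tissue = c(225, 150, 185),
                           background = c(244, 242, 244)),
                         class_color_stds = list(
                           nuclei = c(8, 8, 8),
                           tissue = c(10, 10, 10),
                           background = c(3, 3, 3)),
                         stain_shift = c(0, 0, 0),
                         noise_std = 2,
                         overlap_allowed = FALSE,
                         seed = 1L) {
  stopifnot(height >= 1, width >= 1, n_nuclei >= 0,
            length(radius_range) == 2, radius_range[1] >= 2,
            radius_range[1] <= radius_range[2],
            eccentricity_range[1] >= 0, eccentricity_range[2] < 1,
            noise_std >= 0,
            all(vapply(class_color_stds, function(s) all(s >= 0), TRUE)))
  p <- list(height = as.integer(height), width = as.integer(width),
            n_nuclei = as.integer(n_nuclei), radius_range = radius_range,
            eccentricity_range = eccentricity_range,
            class_color_means = class_color_means,
            class_color_stds = class_color_stds,
            stain_shift = stain_shift, noise_std = noise_std,
            overlap_allowed = isTRUE(overlap_allowed),
            seed = as.integer(seed))
  class(p) <- "synth_params"
  p
}

#' Generate one synthetic H&E-like image with ground truth
#'
#' Places `n_nuclei` filled rotated ellipses (radius and eccentricity drawn
#' from the stated ranges), fills a random blobby surrounding-tissue region,
#' and draws pixel colors per class from per-channel Gaussians centered at
#' `class mean + stain_shift`, clipped to `[0, 255]`. When overlaps are
#' disallowed, nucleus centers are rejection-sampled until pixel sets are
#' pairwise disjoint, with a budget of `100 * n_nuclei` placements.
#'
#' @param params A [synth_params()] object.
#' @return List with elements `image` (H x W x 3 integer array) and
#'   `mask` (canonical integer label matrix).
#' @export
generate_image <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  withr::with_seed(params$seed, generate_image_impl(params))
}

generate_image_impl <- function(p) {
  H <- p$height; W <- p$width
  mask <- matrix(0L, H, W)
  placed <- 0L
  attempts <- 0L
  budget <- 100L * max(1L, p$n_nuclei)
  while (placed < p$n_nuclei) {
    if (attempts >= budget) {
      stop("could only place ", placed, " of ", p$n_nuclei,
           " disjoint nuclei within the retry budget")
    }
    attempts <- attempts + 1L
    a <- stats::runif(1, p$radius_range[1], p$radius_range[2])
    e <- stats::runif(1, p$eccentricity_range[1], p$eccentricity_range[2])
    b <- a * sqrt(1 - e^2)
    th <- stats::runif(1, 0, pi)
    cy <- stats::runif(1, a + 1, H - a)
    cx <- stats::runif(1, a + 1, W - a)
    idx <- ellipse_pixels(H, W, cy, cx, a, b, th)
    if (length(idx) == 0L) next
    if (!p$overlap_allowed && any(mask[idx] > 0L)) next
    placed <- placed + 1L
    mask[idx] <- placed
  }

  # blobby surrounding-tissue region: union of random disks, minus nuclei
  cls <- matrix(3L, H, W)  # 1 nuclei, 2 tissue, 3 background
  n_blobs <- max(3L, as.integer(round(H * W / 8000)))
  for (i in seq_len(n_blobs)) {
    r <- stats::runif(1, min(H, W) / 10, min(H, W) / 4)
    cy <- stats::runif(1, 1, H)
    cx <- stats::runif(1, 1, W)
    cls[ellipse_pixels(H, W, cy, cx, r, r, 0)] <- 2L
  }
  cls[mask > 0L] <- 1L

  img <- array(0L, dim = c(H, W, 3L))
  mu <- do.call(rbind, p$class_color_means[c("nuclei", "tissue", "background")])
  sd_ <- do.call(rbind, p$class_color_stds[c("nuclei", "tissue", "background")])
  n_px <- H * W
  for (ch in 1:3) {
    v <- mu[cls, ch] + p$stain_shift[ch] +
      stats::rnorm(n_px, 0, sd_[cls, ch])
    if (p$noise_std > 0) v <- v + stats::rnorm(n_px, 0, p$noise_std)
    img[, , ch] <- as.integer(pmin(255, pmax(0, round(v))))
  }
  list(image = img, mask = canonicalize_mask(mask))
}

# Linear (column-major) indices of a filled rotated ellipse clipped to H x W.
ellipse_pixels <- function(H, W, cy, cx, a, b, theta) {
  r0 <- max(1L, as.integer(floor(cy - a)))
  r1 <- min(H, as.integer(ceiling(cy + a)))
  c0 <- max(1L, as.integer(floor(cx - a)))
  c1 <- min(W, as.integer(ceiling(cx + a)))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rows <- r0:r1; cols <- c0:c1
  dy <- rep(rows - cy, times = length(cols))
  dx <- rep(cols - cx, each = length(rows))
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  inside <- (u / a)^2 + (v / b)^2 <= 1
  rr <- rep(rows, times = length(cols))[inside]
  cc <- rep(cols, each = length(rows))[inside]
  (cc - 1L) * H + rr
}

#' Generate a dataset of synthetic images with a manifest
#'
#' Writes `n_images` image/mask pairs under `out_dir` plus a CSV manifest
#' listing image path, mask path, and the seed used. Image `i` uses seed
#' `params$seed + i`, so the dataset is reproducible file-by-file.
#'
#' @param params A [synth_params()] object (its `seed` is the base seed).
#' @param n_images Number of images (>= 1).
#' @param out_dir Output directory (created if missing).
#' @return The manifest data frame (columns `image`, `mask`, `seed`),
#'   invisibly.
#' @export
generate_dataset <- function(params, n_images, out_dir) {
  stopifnot(inherits(params, "synth_params"))
  if (n_images < 1L) stop("n_images must be >= 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create directory '", out_dir, "'")
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    p_i <- params
    p_i$seed <- params$seed + i
    sim <- generate_image(p_i)
    img_path <- file.path(out_dir, sprintf("image_%03d.png", i))
    mask_path <- file.path(out_dir, sprintf("mask_%03d.tif", i))
    write_image(sim$image, img_path)
    write_label_mask(sim$mask, mask_path)
    rows[[i]] <- data.frame(image = img_path, mask = mask_path,
                            seed = p_i$seed)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
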