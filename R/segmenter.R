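#' Construct a segmenter backend
#'
#' The pluggable instance-segmenter contract: a backend exposes
#' `segment(image)` returning a canonical label mask of the same shape as
#' the input. The wrapper validates every output (shape match, canonical
#' labels), so any backend that passes through it satisfies the pipeline's
#' invariants.
#'
#' @param name Backend name (appears in logs).
#' @param segment_fn Function `(H x W x 3 image) -> label matrix`.
#' @param deterministic Logical flag recorded on the backend.
#' @return Object of class `segmenter_backend`.
#' @export
segmenter_backend <- function(name, segment_fn, deterministic = TRUE) {
  force(segment_fn)
  backend <- list(
    name = name,
    deterministic = isTRUE(deterministic),
    segment = function(image) {
      out <- segment_fn(image)
      d <- dim(image)
      if (!is.matrix(out) || !identical(dim(out), d[1:2])) {
        stop("backend '", name, "' returned a mask of the wrong shape")
      }
      canonicalize_mask(out)
    })
  class(backend) <- "segmenter_backend"
  backend
}

#' Classical watershed baseline segmentation
#'
#' The desk-scale stand-in for a learned detector: (1) a nuclei-likelihood
#' map, by default the nuclei-class posterior from a 3-class Gaussian color
#' mixture ([fit_gmm_em()]; the nuclei class is the component with the
#' darkest mean color), falling back to inverted luminance when the mixture
#' cannot be fitted; (2) Otsu global threshold; (3) hole filling;
#' (4) distance transform; (5) watershed from distance-transform maxima
#' with neighborhood radius `expected_radius` (separates touching nuclei);
#' (6) instances smaller than `min_area` pixels discarded. Deterministic
#' given the seed.
#'
#' @param image H x W x 3 integer RGB array.
#' @param min_area Minimum instance area in pixels.
#' @param seed Integer seed (forwarded to the mixture fit).
#' @param expected_radius Expected nucleus radius in pixels; sets the
#'   local-maxima separation of the watershed markers.
#' @param stain_model Optional precomputed [class_gaussians()] (working
#'   space of `codec`): when supplied, the likelihood map comes from one
#'   E-step under this model instead of a fresh EM fit (used by the
#'   pipeline, which fits the color model once per image).
#' @param codec [color_codec()] used for the mixture.
#' @param em_max_iter,max_pixels Passed to [fit_gmm_em()] when fitting.
#' @param nuclei_max_luminance Hematoxylin-stained nuclei are dark; when the
#'   darkest mixture class's mean luminance exceeds this cutoff (default
#'   200 of 255) the image is treated as containing no nuclei.
#' @return Canonical label matrix.
#' @export
baseline_segment <- function(image, min_area = 30L, seed = 0L,
                             expected_radius = 8L, stain_model = NULL,
                             codec = color_codec(), em_max_iter = 100L,
                             max_pixels = 20000L,
                             nuclei_max_luminance = 200) {
  validate_rgb_image(image)
  d <- dim(image)
  no_nuclei <- FALSE
  lik <- tryCatch({
    if (is.null(stain_model)) {
      fit <- suppressWarnings(
        fit_gmm_em(image, K = 3L, codec = codec, max_iter = em_max_iter,
                   seed = seed, max_pixels = max_pixels))
      model <- fit$model
      post <- fit$posterior
    } else {
      model <- stain_model
      X <- codec$forward(image)
      R <- e_step(X, model$weights, model$means, model$covariances)$resp
      post <- array(R, dim = c(d[1L], d[2L], model$K))
    }
    mlum <- rowMeans(model_means_rgb(model, codec))
    k_nuc <- which.min(mlum)
    if (mlum[k_nuc] > nuclei_max_luminance) no_nuclei <- TRUE
    post[, , k_nuc]
  }, error = function(e) {
    lum <- (image[, , 1L] + image[, , 2L] + image[, , 3L]) / 3
    if (min(lum) > nuclei_max_luminance) no_nuclei <<- TRUE
    (255 - lum) / 255
  })
  if (no_nuclei) return(matrix(0L, d[1L], d[2L]))
  lik <- matrix(pmin(1, pmax(0, lik)), d[1L], d[2L])

  th <- tryCatch(EBImage::otsu(EBImage::Image(lik)), error = function(e) 0.5)
  bw <- lik > th
  if (!any(bw)) return(matrix(0L, d[1L], d[2L]))
  filled <- EBImage::fillHull(EBImage::Image(bw * 1))
  dm <- EBImage::distmap(filled)
  ws <- EBImage::watershed(dm, tolerance = 1, ext = as.integer(expected_radius))
  mask <- matrix(as.integer(EBImage::imageData(ws)), d[1L], d[2L])
  # drop small fragments
  sizes <- tabulate(mask[mask > 0L])
  small <- which(sizes < min_area)
  if (length(small)) mask[mask %in% small] <- 0L
  canonicalize_mask(mask)
}

# Class mean colors mapped back to RGB intensity space (rows = classes).
model_means_rgb <- function(model, codec) {
  if (codec$name == "rgb") return(model$means)
  out <- pmin(255, pmax(0, 256 * exp(-model$means) - 1))
  matrix(out, nrow(model$means), ncol(model$means))
}

#' Baseline segmenter backend
#'
#' Wraps [baseline_segment()] into the backend contract.
#'
#' @inheritParams baseline_segment
#' @return A [segmenter_backend()].
#' @export
baseline_segmenter <- function(min_area = 30L, seed = 0L,
                               expected_radius = 8L, stain_model = NULL,
                               codec = color_codec(), em_max_iter = 100L,
                               max_pixels = 20000L) {
  segmenter_backend(
    name = "baseline",
    segment_fn = function(image) {
      baseline_segment(image, min_area = min_area, seed = seed,
                       expected_radius = expected_radius,
                       stain_model = stain_model, codec = codec,
                       em_max_iter = em_max_iter, max_pixels = max_pixels)
    },
    deterministic = TRUE)
}

#' Flatten scored, possibly overlapping instance masks to a label map
#'
#' Adapter shim for detectors that emit overlapping soft masks: each pixel
#' claimed by several instances goes to the highest-scoring claimant
#' (ties: the larger instance, then the smaller index). Instances left with
#' no pixels are dropped.
#'
#' @param instances List of `list(pixels = <linear indices>, score = <real>)`.
#' @param shape Length-2 vector `(H, W)`.
#' @return Canonical label matrix.
#' @export
resolve_overlaps <- function(instances, shape) {
  out <- matrix(0L, shape[1L], shape[2L])
  if (!length(instances)) return(out)
  score <- vapply(instances, function(i) i$score, 1.0)
  size <- vapply(instances, function(i) length(i$pixels), 1L)
  # ascending priority: winner (max score, then max size, then min index)
  # is written last
  ord <- order(score, size, -seq_along(instances))
  for (i in ord) out[instances[[i]]$pixels] <- i
  canonicalize_mask(out)
}

#' Recorded Mask R-CNN adapter configuration
#'
#' The detector configuration used with an external Mask R-CNN backend:
#' anchor aspect ratios 1:1, 1:2 and 2:1; five anchor scales with box areas
#' 8^2 through 128^2; the top 1000 candidate proposals; a ResNet-101 FPN
#' backbone; SGD with learning rate 0.001 and momentum 0.9. The package
#' never trains or runs the network itself — the record round-trips through
#' the config file so an external detector plugs in with the exact setup.
#'
#' @return Named list of class `mask_rcnn_config`.
#' @export
mask_rcnn_config <- function() {
  structure(list(
    anchor_ratios = c("1:1", "1:2", "2:1"),
    anchor_scales = as.integer(c(8, 16, 32, 64, 128)^2),
    top_candidates = 1000L,
    backbone = "resnet101-fpn",
    learning_rate = 0.001,
    momentum = 0.9
  ), class = "mask_rcnn_config")
}
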