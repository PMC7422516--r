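#' Fusion parameters for multiple inference
#'
#' @param iou_threshold An augmented-variant instance joins a reference
#'   nucleus's matched set when their IoU is strictly greater than this
#'   (default 0.2).
#' @param vote_threshold A pixel survives the vote when it appears in
#'   strictly more than this fraction of the matched set (default 0.5, i.e.
#'   a strict pixel-level majority).
#' @return List of class `fusion_params`.
#' @export
fusion_params <- function(iou_threshold = 0.2, vote_threshold = 0.5) {
  stopifnot(iou_threshold >= 0, iou_threshold <= 1,
            vote_threshold >= 0, vote_threshold <= 1)
  structure(list(iou_threshold = iou_threshold,
                 vote_threshold = vote_threshold),
            class = "fusion_params")
}

#' Intersection over union of two pixel sets
#'
#' @param a,b Integer vectors of (linear) pixel indices.
#' @return `|a n b| / |a u b|`; 0 when both sets are empty.
#' @export
iou <- function(a, b) {
  a <- unique(a); b <- unique(b)
  inter <- sum(a %in% b)
  uni <- length(a) + length(b) - inter
  if (uni == 0L) return(0)
  inter / uni
}

#' Fuse the seven test-time-augmentation predictions of one image
#'
#' The multiple-inference post-processing step: each per-variant prediction
#' is mapped back to the original frame by the inverse transform; then, for
#' every nucleus of the original (identity) prediction, every instance from
#' the seven inverted masks with IoU above `iou_threshold` joins its
#' matched set (the reference nucleus matches itself at IoU 1, and several
#' instances from the same variant may all join); finally a pixel-level
#' majority vote keeps the pixels present in strictly more than
#' `vote_threshold` of the matched set. Nuclei detected only in augmented
#' variants are discarded — references come from the original prediction
#' alone. Pixels claimed by two fused nuclei go to the one with the higher
#' vote fraction (tie: the smaller original label). Empty survivors are
#' dropped and the output is canonicalized.
#'
#' @param predictions List of exactly 7 elements
#'   `list(transform = <name>, mask = <label matrix>)`, containing exactly
#'   one identity entry; each mask lives in its variant's frame.
#' @param params A [fusion_params()].
#' @return Canonical label matrix in the original frame.
#' @export
fuse <- function(predictions, params = fusion_params()) {
  if (length(predictions) != 7L) {
    stop("expected 7 predictions, got ", length(predictions))
  }
  tnames <- vapply(predictions, function(p) p$transform, "")
  id_at <- which(tnames == "identity")
  if (length(id_at) != 1L) {
    stop("predictions must contain exactly one identity-transform entry")
  }
  inv <- lapply(predictions, function(p) {
    canonicalize_mask(apply_transform(p$mask, inverse_transform(p$transform)))
  })
  d0 <- dim(inv[[id_at]])
  for (m in inv) {
    if (!identical(dim(m), d0)) {
      stop("mask shapes differ after transform inversion")
    }
  }
  ref <- inv[[id_at]]
  n_ref <- max(0L, max(ref))
  out <- matrix(0L, d0[1L], d0[2L])
  if (n_ref == 0L) return(out)

  # instance pixel sets of every inverted variant
  variant_sets <- lapply(inv, function(m) {
    labs <- seq_len(max(0L, max(m)))
    lapply(labs, function(l) which(m == l))
  })

  kept <- vector("list", n_ref)
  frac <- vector("list", n_ref)
  for (l in seq_len(n_ref)) {
    R <- which(ref == l)
    matched <- list()
    for (v in seq_along(variant_sets)) {
      for (s in variant_sets[[v]]) {
        if (iou(R, s) > params$iou_threshold) {
          matched[[length(matched) + 1L]] <- s
        }
      }
    }
    M <- length(matched)
    votes <- table(unlist(matched))
    px <- as.integer(names(votes))
    keep <- votes > params$vote_threshold * M
    kept[[l]] <- px[keep]
    frac[[l]] <- as.numeric(votes[keep]) / M
  }

  # conflicts: higher vote fraction wins, tie -> smaller original label;
  # write in ascending priority so the winner lands last
  claims <- data.frame(px = unlist(kept),
                       label = rep(seq_len(n_ref), lengths(kept)),
                       frac = unlist(frac))
  if (nrow(claims)) {
    ord <- order(claims$frac, -claims$label)
    out[claims$px[ord]] <- claims$label[ord]
  }
  canonicalize_mask(out)
}

#' Run full multiple inference on one (square) image
#'
#' Composes [tta_variants()], a segmenter backend on each variant, and
#' [fuse()]. Deterministic whenever the backend is.
#'
#' @param image Square H x H x 3 integer RGB array.
#' @param segmenter A segmenter backend (see [segmenter_backend()]).
#' @param params A [fusion_params()].
#' @return Canonical label matrix for `image`.
#' @export
run_multiple_inference <- function(image, segmenter,
                                   params = fusion_params()) {
  variants <- tta_variants(image)
  preds <- lapply(variants, function(v) {
    list(transform = v$transform, mask = segmenter$segment(v$data))
  })
  fuse(preds, params)
}
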