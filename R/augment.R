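#' The multiple-inference transform group
#'
#' The seven geometric transforms used for training augmentation and
#' test-time multiple inference: the identity, counter-clockwise rotations
#' by 90, 180 and 270 degrees, horizontal flip (columns mirrored), vertical
#' flip (rows mirrored), and the combined horizontal+vertical flip. Each has
#' an exact inverse in the set and none changes the image size, so label
#' values survive round trips exactly (nearest-neighbor semantics, no
#' interpolation). Note that `hvflip` coincides with `rot180` on a pixel
#' grid; the group nevertheless enumerates all seven names because the
#' inference protocol votes over seven variants.
#'
#' @format Character vector of the seven transform names, identity first.
#' @export
AUGMENT_TRANSFORMS <- c("identity", "rot90", "rot180", "rot270",
                        "hflip", "vflip", "hvflip")

#' Inverse of a transform
#' @param t Transform name, one of [AUGMENT_TRANSFORMS].
#' @return The name of the inverse transform.
#' @export
inverse_transform <- function(t) {
  switch(match.arg(t, AUGMENT_TRANSFORMS),
         identity = "identity",
         rot90 = "rot270",
         rot180 = "rot180",
         rot270 = "rot90",
         hflip = "hflip",
         vflip = "vflip",
         hvflip = "hvflip")
}

#' Apply a geometric transform to an image or label mask
#'
#' Rotations are counter-clockwise about the image center on the pixel grid.
#' Works on matrices (label masks) and H x W x C arrays (images), preserving
#' values exactly. Quarter rotations require square input in contexts that
#' must preserve shape; this function permits non-square input (the output
#' is then W x H) and shape enforcement happens at the call sites that
#' need it.
#'
#' @param x Matrix or 3-d array.
#' @param t Transform name, one of [AUGMENT_TRANSFORMS].
#' @return Transformed object of the same type.
#' @export
apply_transform <- function(x, t) {
  t <- match.arg(t, AUGMENT_TRANSFORMS)
  if (is.matrix(x)) return(transform_matrix(x, t))
  d <- dim(x)
  if (length(d) != 3L) stop("x must be a matrix or a 3-d array")
  ch <- lapply(seq_len(d[3L]), function(k) transform_matrix(x[, , k], t))
  out <- array(unlist(ch), dim = c(dim(ch[[1L]]), d[3L]))
  storage.mode(out) <- storage.mode(x)
  out
}

transform_matrix <- function(m, t) {
  switch(t,
         identity = m,
         rot90 = t(m)[ncol(m):1, , drop = FALSE],
         rot180 = m[nrow(m):1, ncol(m):1, drop = FALSE],
         rot270 = t(m)[, nrow(m):1, drop = FALSE],
         hflip = m[, ncol(m):1, drop = FALSE],
         vflip = m[nrow(m):1, , drop = FALSE],
         hvflip = m[nrow(m):1, ncol(m):1, drop = FALSE])
}

#' Generate the seven test-time-augmentation variants of an image
#'
#' Returns the ordered list of the seven variants used for multiple
#' inference: the untouched input first, then the three rotations and three
#' flips. The input must be square so quarter rotations preserve shape.
#'
#' @param x Square matrix or H x H x C array.
#' @return List of 7 elements, each `list(transform = <name>, data = <variant>)`.
#' @export
tta_variants <- function(x) {
  d <- dim(x)
  if (d[1L] != d[2L]) {
    stop("tta_variants requires square input, got ", d[1L], " x ", d[2L])
  }
  lapply(AUGMENT_TRANSFORMS, function(t) {
    list(transform = t, data = apply_transform(x, t))
  })
}
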