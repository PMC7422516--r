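#' Overlapping tile grid for large-image inference
#'
#' Computes square tile origins covering an image with overlap. Per axis of
#' length `D`, the offsets are `{0, D - tile}` plus their midpoint
#' `floor((D - tile) / 2)`, deduplicated and sorted; the tile set is the
#' Cartesian product of the two axis offset sets. For a 1000 x 1000 image
#' and 500-pixel tiles this yields the nine origins
#' (0,0), (0,250), (0,500), (250,0), (250,250), (250,500), (500,0),
#' (500,250), (500,500), so every nucleus cut by one tile seam is whole in
#' an overlapping neighbor.
#'
#' @param height,width Image dimensions.
#' @param tile Square tile side; must not exceed either dimension.
#' @return Data frame of tile specs with columns
#'   `index, row0, col0, height, width` (origins 0-based, windows half-open).
#' @export
make_tiles <- function(height, width, tile) {
  if (tile > height || tile > width) {
    stop("tile size ", tile, " exceeds image dimensions ",
         height, " x ", width)
  }
  offs <- function(D) unique(sort(c(0L, as.integer(D - tile),
                                    as.integer((D - tile) %/% 2L))))
  ro <- offs(height)
  co <- offs(width)
  grid <- expand.grid(col0 = co, row0 = ro)[, c("row0", "col0")]
  data.frame(index = seq_len(nrow(grid)), row0 = grid$row0, col0 = grid$col0,
             height = as.integer(tile), width = as.integer(tile))
}

#' Crop an image or label mask to a tile window
#'
#' Copies the half-open window `[row0, row0+h) x [col0, col0+w)` (0-based).
#' Mask crops are re-canonicalized, since instances may be cut away.
#'
#' @param x H x W x 3 image array or label matrix.
#' @param spec One tile spec: a list or single data frame row with
#'   `row0, col0, height, width`.
#' @return Cropped object of the same type.
#' @export
crop <- function(x, spec) {
  r0 <- spec$row0; c0 <- spec$col0; h <- spec$height; w <- spec$width
  d <- dim(x)
  if (r0 < 0 || c0 < 0 || r0 + h > d[1L] || c0 + w > d[2L]) {
    stop("tile window [", r0, ",", r0 + h, ") x [", c0, ",", c0 + w,
         ") outside image bounds ", d[1L], " x ", d[2L])
  }
  rows <- (r0 + 1L):(r0 + h)
  cols <- (c0 + 1L):(c0 + w)
  if (is.matrix(x)) {
    canonicalize_mask(x[rows, cols, drop = FALSE])
  } else {
    x[rows, cols, , drop = FALSE]
  }
}

#' Stitching parameters
#' @param merge_iou Two placed instances from different tiles are the same
#'   nucleus when their IoU reaches this threshold (default 0.5).
#' @param containment Alternatively, when the smaller instance's
#'   intersection-over-own-area reaches this threshold (default 0.8) — the
#'   seam-fragment case.
#' @return List of class `stitch_params`.
#' @export
stitch_params <- function(merge_iou = 0.5, containment = 0.8) {
  stopifnot(merge_iou >= 0, merge_iou <= 1, containment >= 0, containment <= 1)
  structure(list(merge_iou = merge_iou, containment = containment),
            class = "stitch_params")
}

#' Stitch per-tile instance masks into a full-image mask
#'
#' Places every tile instance at its absolute coordinates, then merges
#' instances from different tiles that are duplicates of the same nucleus:
#' any pair with IoU >= `merge_iou` or smaller-over-intersection containment
#' >= `containment` is unioned, transitively via union-find, so a nucleus
#' seen in three or more tiles collapses to one instance regardless of
#' pairwise order. Among unmerged conflicting claims to a pixel, the
#' instance whose centroid lies farther from its source-tile boundary wins
#' (a detection near a tile edge is more likely truncated). Output is
#' canonicalized.
#'
#' @param tile_masks List of label matrices, one per tile.
#' @param specs Tile specs as returned by [make_tiles()] (data frame or
#'   list of rows), aligned with `tile_masks`.
#' @param canvas Length-2 vector `(H, W)` of the output size.
#' @param params A [stitch_params()].
#' @return Canonical label matrix of size `canvas`.
#' @export
stitch_instances <- function(tile_masks, specs, canvas,
                             params = stitch_params()) {
  if (is.data.frame(specs)) {
    specs <- lapply(seq_len(nrow(specs)), function(i) as.list(specs[i, ]))
  }
  if (length(tile_masks) != length(specs)) {
    stop("tile_masks and specs have different lengths (",
         length(tile_masks), " vs ", length(specs), ")")
  }
  H <- canvas[1L]; W <- canvas[2L]
  for (s in specs) {
    if (s$row0 < 0 || s$col0 < 0 || s$row0 + s$height > H ||
        s$col0 + s$width > W) {
      stop("tile spec outside canvas")
    }
  }

  # collect absolute-coordinate instances
  pixels <- list(); tile_of <- integer(0); border_d <- numeric(0)
  for (t in seq_along(tile_masks)) {
    m <- tile_masks[[t]]
    s <- specs[[t]]
    labs <- sort(unique(m[m > 0L]))
    for (l in labs) {
      idx <- which(m == l)
      if (!length(idx)) next
      r <- (idx - 1L) %% nrow(m) + 1L
      c_ <- (idx - 1L) %/% nrow(m) + 1L
      abs_idx <- (c_ + s$col0 - 1L) * H + (r + s$row0)
      pixels[[length(pixels) + 1L]] <- abs_idx
      tile_of <- c(tile_of, t)
      # centroid distance to source-tile boundary (tile-local coords)
      cr <- mean(r); cc <- mean(c_)
      border_d <- c(border_d, min(cr - 0.5, s$height - cr + 0.5,
                                  cc - 0.5, s$width - cc + 0.5))
    }
  }
  n <- length(pixels)
  if (n == 0L) return(matrix(0L, H, W))

  # union duplicates across tiles
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  sizes <- lengths(pixels)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (tile_of[i] == tile_of[j]) next
      inter <- length(intersect_sorted(pixels[[i]], pixels[[j]]))
      if (inter == 0L) next
      iou_ij <- inter / (sizes[i] + sizes[j] - inter)
      cont <- inter / min(sizes[i], sizes[j])
      if (iou_ij >= params$merge_iou || cont >= params$containment) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(n), find, 1L)
  groups <- split(seq_len(n), root)

  gpix <- lapply(groups, function(g) sort(unique(unlist(pixels[g]))))
  gd <- vapply(groups, function(g) max(border_d[g]), 1.0)

  # contested pixels go to the group farther from its tile border
  # (tie: smaller group id); write losers first so the winner lands last
  ord <- order(gd, -seq_along(groups))
  out <- matrix(0L, H, W)
  for (g in ord) out[gpix[[g]]] <- g
  canonicalize_mask(out)
}

# Intersection of two sorted integer vectors.
intersect_sorted <- function(a, b) a[a %in% b]
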