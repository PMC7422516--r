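#' Dice coefficient of two pixel sets
#'
#' `D(X, Y) = 2 |X n Y| / (|X| + |Y|)`, the symmetric pixel-overlap
#' similarity between a predicted region and its ground truth.
#'
#' @param x,y Integer vectors of pixel indices; not both empty.
#' @return Value in `[0, 1]`.
#' @export
dice <- function(x, y) {
  x <- unique(x); y <- unique(y)
  if (length(x) == 0L && length(y) == 0L) {
    stop("dice is undefined for two empty sets")
  }
  2 * sum(x %in% y) / (length(x) + length(y))
}

#' Object-level matching of predicted and ground-truth instances
#'
#' Candidate pairs are all (ground truth, prediction) instance pairs whose
#' Dice coefficient strictly exceeds `dc_threshold` (default 0.2, the
#' true-positive criterion). Pairs are matched one-to-one greedily in
#' descending Dice order (ties broken by smaller ground-truth label, then
#' smaller prediction label). Matched pairs are true positives; unmatched
#' predictions are false positives; unmatched ground-truth instances are
#' false negatives.
#'
#' @param gt,pred Label matrices of the same shape.
#' @param dc_threshold Strict Dice threshold for a candidate pair.
#' @return Object of class `confusion_counts`: list with `TP`, `FP`, `FN`
#'   and `matched_pairs` (data frame `gt, pred, dice`).
#' @export
match_instances <- function(gt, pred, dc_threshold = 0.2) {
  if (!identical(dim(gt), dim(pred))) {
    stop("gt and pred have different shapes")
  }
  gt <- canonicalize_mask(gt)
  pred <- canonicalize_mask(pred)
  ov <- overlap_stats(gt, pred)
  ng <- ov$ng; np <- ov$np
  matched <- data.frame(gt = integer(0), pred = integer(0),
                        dice = numeric(0))
  if (ng > 0L && np > 0L) {
    D <- 2 * ov$inter / outer(ov$gsz, ov$psz, "+")
    cand <- which(D > dc_threshold, arr.ind = TRUE)
    if (nrow(cand)) {
      dc <- D[cand]
      ord <- order(-dc, cand[, 1L], cand[, 2L])
      used_g <- logical(ng); used_p <- logical(np)
      for (i in ord) {
        g <- cand[i, 1L]; p <- cand[i, 2L]
        if (used_g[g] || used_p[p]) next
        used_g[g] <- TRUE; used_p[p] <- TRUE
        matched <- rbind(matched,
                         data.frame(gt = g, pred = p, dice = D[g, p]))
      }
    }
  }
  structure(list(TP = nrow(matched),
                 FP = np - nrow(matched),
                 FN = ng - nrow(matched),
                 matched_pairs = matched),
            class = "confusion_counts")
}

#' Precision, recall and F1 from object-level confusion counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2 TP / (2 TP + FP + FN)`; each 0/0 case is defined as 0.
#'
#' @param c A `confusion_counts` object (or list with `TP`, `FP`, `FN`).
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(c) {
  safe <- function(num, den) if (den == 0) 0 else num / den
  c(precision = safe(c$TP, c$TP + c$FP),
    recall = safe(c$TP, c$TP + c$FN),
    f1 = safe(2 * c$TP, 2 * c$TP + c$FP + c$FN))
}

#' Average Dice coefficient over matched pairs
#'
#' The arithmetic mean of the Dice values of the true-positive
#' (matched ground truth, prediction) pairs; 0 when nothing matched.
#'
#' @param c A `confusion_counts` object.
#' @return Value in `[0, 1]`.
#' @export
adc <- function(c) {
  if (nrow(c$matched_pairs) == 0L) return(0)
  mean(c$matched_pairs$dice)
}

#' Aggregated Jaccard index
#'
#' For each ground-truth instance (ascending label), the prediction with
#' the highest Jaccard index (ties: smaller prediction label) is its best
#' match; the match's intersection and union pixels accumulate into the
#' aggregate numerator and denominator and the prediction is marked used.
#' A ground-truth instance with no overlapping prediction contributes its
#' own pixel count to the denominator. Finally every unused prediction's
#' pixel count is added to the denominator, penalizing spurious detections.
#' A prediction may be best match for several ground-truth instances but
#' enters the unused sum at most once.
#'
#' @param gt Label matrix with at least one instance.
#' @param pred Label matrix of the same shape (may be empty; yields 0).
#' @return Value in `[0, 1]`.
#' @export
aji <- function(gt, pred) {
  if (!identical(dim(gt), dim(pred))) {
    stop("gt and pred have different shapes")
  }
  gt <- canonicalize_mask(gt)
  pred <- canonicalize_mask(pred)
  ov <- overlap_stats(gt, pred)
  if (ov$ng == 0L) stop("aji requires at least one ground-truth instance")
  if (ov$np == 0L) return(0)
  J <- ov$inter / (outer(ov$gsz, ov$psz, "+") - ov$inter)
  C <- 0; U <- 0
  used <- logical(ov$np)
  for (g in seq_len(ov$ng)) {
    j <- which.max(J[g, ])  # ties -> smallest index
    if (J[g, j] > 0) {
      C <- C + ov$inter[g, j]
      U <- U + ov$gsz[g] + ov$psz[j] - ov$inter[g, j]
      used[j] <- TRUE
    } else {
      U <- U + ov$gsz[g]
    }
  }
  U <- U + sum(ov$psz[!used])
  C / U
}

#' Full per-image evaluation row
#'
#' Composes [match_instances()], [precision_recall_f1()], [adc()] and
#' [aji()] into one report row.
#'
#' @param gt,pred Label matrices of the same shape.
#' @param dc_threshold Dice threshold for object matching.
#' @return One-row data frame `precision, recall, f1, adc, aji`.
#' @export
evaluate_pair <- function(gt, pred, dc_threshold = 0.2) {
  cc <- match_instances(gt, pred, dc_threshold)
  prf <- precision_recall_f1(cc)
  a <- if (n_instances(gt) == 0L) 0 else aji(gt, pred)
  data.frame(precision = prf[["precision"]], recall = prf[["recall"]],
             f1 = prf[["f1"]], adc = adc(cc), aji = a)
}

# Instance sizes and the ng x np pixel-intersection matrix of two canonical
# masks, computed by integer-coding co-labeled pixels.
overlap_stats <- function(gt, pred) {
  ng <- max(0L, max(gt)); np <- max(0L, max(pred))
  gsz <- tabulate(gt[gt > 0L], nbins = ng)
  psz <- tabulate(pred[pred > 0L], nbins = np)
  inter <- matrix(0L, ng, np)
  if (ng > 0L && np > 0L) {
    sel <- gt > 0L & pred > 0L
    if (any(sel)) {
      code <- (gt[sel] - 1L) * np + pred[sel]
      cnt <- tabulate(code, nbins = ng * np)
      inter <- matrix(cnt, ng, np, byrow = TRUE)
    }
  }
  list(ng = ng, np = np, gsz = gsz, psz = psz, inter = inter)
}
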