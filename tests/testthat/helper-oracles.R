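# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use naive pixel-set code paths (which/intersect/union loops), not the
# package's matrix-based implementations.

# Random label mask: n rectangles written sequentially (later boxes may
# partly overwrite earlier ones), then canonicalized.
random_mask <- function(H = 32L, W = 32L, n = 5L, seed = 1L) {
  withr::with_seed(seed, {
    m <- matrix(0L, H, W)
    for (l in seq_len(n)) {
      h <- sample(2:min(8L, H - 1L), 1L)
      w <- sample(2:min(8L, W - 1L), 1L)
      r0 <- sample.int(H - h + 1L, 1L)
      c0 <- sample.int(W - w + 1L, 1L)
      m[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- l
    }
    canonicalize_mask(m)
  })
}

random_rgb_image <- function(H = 16L, W = 16L, seed = 1L) {
  withr::with_seed(seed, {
    array(sample(0:255, H * W * 3L, replace = TRUE), dim = c(H, W, 3L))
  })
}

instance_sets <- function(mask) {
  labs <- sort(unique(mask[mask > 0L]))
  lapply(labs, function(l) which(mask == l))
}

jacc_sets <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

# AJI following the published pseudocode directly on pixel sets.
oracle_aji <- function(gt, pred) {
  gsets <- instance_sets(gt)
  psets <- instance_sets(pred)
  if (!length(psets)) {
    return(0)
  }
  C <- 0; U <- 0; used <- rep(FALSE, length(psets))
  for (gs in gsets) {
    best <- 0; bj <- 0L
    for (j in seq_along(psets)) {
      ji <- jacc_sets(gs, psets[[j]])
      if (ji > best) { best <- ji; bj <- j }
    }
    if (best > 0) {
      C <- C + length(intersect(gs, psets[[bj]]))
      U <- U + length(union(gs, psets[[bj]]))
      used[bj] <- TRUE
    } else {
      U <- U + length(gs)
    }
  }
  U <- U + sum(vapply(psets[!used], length, 1L))
  C / U
}

dice_sets <- function(a, b) 2 * length(intersect(a, b)) / (length(a) + length(b))

# Greedy descending-Dice one-to-one matching on raw pixel sets.
oracle_match <- function(gt, pred, thr = 0.2) {
  gsets <- instance_sets(gt)
  psets <- instance_sets(pred)
  cand <- NULL
  for (g in seq_along(gsets)) {
    for (p in seq_along(psets)) {
      d <- dice_sets(gsets[[g]], psets[[p]])
      if (d > thr) cand <- rbind(cand, data.frame(g = g, p = p, d = d))
    }
  }
  TP <- 0L
  if (!is.null(cand)) {
    cand <- cand[order(-cand$d, cand$g, cand$p), ]
    ug <- c(); up <- c()
    for (i in seq_len(nrow(cand))) {
      if (cand$g[i] %in% ug || cand$p[i] %in% up) next
      ug <- c(ug, cand$g[i]); up <- c(up, cand$p[i]); TP <- TP + 1L
    }
  }
  list(TP = TP, FP = length(psets) - TP, FN = length(gsets) - TP)
}

# Exhaustive maximum-TP one-to-one matching over threshold-passing pairs.
oracle_max_tp <- function(gt, pred, thr = 0.2) {
  gsets <- instance_sets(gt)
  psets <- instance_sets(pred)
  ok <- matrix(FALSE, length(gsets), length(psets))
  for (g in seq_along(gsets)) {
    for (p in seq_along(psets)) {
      ok[g, p] <- dice_sets(gsets[[g]], psets[[p]]) > thr
    }
  }
  best <- 0L
  rec <- function(g, used) {
    if (g > nrow(ok)) return(0L)
    top <- rec(g + 1L, used)  # leave g unmatched
    for (p in seq_len(ncol(ok))) {
      if (ok[g, p] && !used[p]) {
        used2 <- used; used2[p] <- TRUE
        top <- max(top, 1L + rec(g + 1L, used2))
      }
    }
    top
  }
  if (nrow(ok) == 0L || ncol(ok) == 0L) return(0L)
  rec(1L, rep(FALSE, ncol(ok)))
}

# Strict-majority pixel tally over a list of pixel sets.
oracle_majority <- function(sets, vote_threshold = 0.5) {
  M <- length(sets)
  tal <- table(unlist(sets))
  as.integer(names(tal)[tal > vote_threshold * M])
}
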