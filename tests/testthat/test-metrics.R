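test_that("dice follows the formula and its conventions", {
  expect_equal(dice(1:4, 1:4), 1.0)
  expect_equal(dice(1:4, 5:8), 0.0)
  expect_equal(dice(1:4, 3:6), 0.5)  # 2 * 2 / (4 + 4)
  expect_equal(dice(1:3, 2:4), dice(2:4, 1:3))
  expect_error(dice(integer(0), integer(0)), "empty")
})

test_that("perfect predictions give a clean confusion matrix", {
  m <- random_mask(24L, 24L, 4L, seed = 2L)
  cc <- match_instances(m, m)
  expect_equal(cc$TP, n_instances(m))
  expect_equal(cc$FP, 0L)
  expect_equal(cc$FN, 0L)
  expect_true(all(cc$matched_pairs$dice == 1))
})

test_that("a pair at Dice exactly 0.2 is not a true positive", {
  gt <- matrix(0L, 4L, 4L); gt[1:5] <- 1L             # |gt| = 5
  pred <- matrix(0L, 4L, 4L); pred[c(1L, 6:9)] <- 1L  # |pred| = 5, inter = 1
  expect_equal(dice(which(gt == 1L), which(pred == 1L)), 0.2)
  cc <- match_instances(gt, pred)
  expect_equal(c(cc$TP, cc$FP, cc$FN), c(0L, 1L, 1L))
})

test_that("precision, recall and F1 apply the formulas with 0/0 -> 0", {
  prf <- precision_recall_f1(list(TP = 2L, FP = 1L, FN = 1L))
  expect_equal(as.numeric(prf), c(2 / 3, 2 / 3, 4 / 6))
  expect_equal(as.numeric(precision_recall_f1(list(TP = 0L, FP = 0L,
                                                   FN = 0L))),
               c(0, 0, 0))
  expect_equal(as.numeric(precision_recall_f1(list(TP = 5L, FP = 0L,
                                                   FN = 0L))),
               c(1, 1, 1))
})

test_that("ADC averages matched-pair Dice values", {
  cc <- structure(list(TP = 2L, FP = 0L, FN = 0L,
                       matched_pairs = data.frame(gt = 1:2, pred = 1:2,
                                                  dice = c(1.0, 0.5))),
                  class = "confusion_counts")
  expect_equal(adc(cc), 0.75)
  cc0 <- structure(list(TP = 0L, FP = 1L, FN = 1L,
                        matched_pairs = data.frame(gt = integer(0),
                                                   pred = integer(0),
                                                   dice = numeric(0))),
                   class = "confusion_counts")
  expect_equal(adc(cc0), 0)
})

test_that("aji boundary conventions hold", {
  m <- random_mask(16L, 16L, 3L, seed = 5L)
  expect_equal(aji(m, m), 1.0)
  expect_equal(aji(m, matrix(0L, 16L, 16L)), 0.0)
  expect_error(aji(matrix(0L, 4L, 4L), m[1:4, 1:4]), "ground-truth")
})

test_that("aji and match_instances agree with brute-force oracles on 200 cases", {
  for (case in 1:200) {
    gt <- random_mask(32L, 32L, sample(1:5, 1L), seed = case)
    pred <- random_mask(32L, 32L, sample(0:5, 1L), seed = case + 1000L)
    if (n_instances(pred) == 0L) {
      expect_equal(aji(gt, pred), 0)
    } else {
      expect_equal(aji(gt, pred), oracle_aji(gt, pred), tolerance = 1e-12)
    }
    cc <- match_instances(gt, pred)
    om <- oracle_match(gt, pred)
    expect_equal(cc$TP, om$TP)
    expect_equal(cc$FP, om$FP)
    expect_equal(cc$FN, om$FN)
  }
})

test_that("greedy matching attains the exhaustive maximum on a crafted case", {
  gt <- matrix(0L, 16L, 16L)
  gt[2:6, 2:6] <- 1L; gt[9:14, 9:14] <- 2L
  pred <- matrix(0L, 16L, 16L)
  pred[2:6, 2:5] <- 1L; pred[9:12, 9:14] <- 2L; pred[1:2, 12:16] <- 3L
  cc <- match_instances(gt, pred)
  expect_equal(cc$TP, oracle_max_tp(gt, pred))
  expect_equal(c(cc$TP, cc$FP, cc$FN), c(2L, 1L, 0L))
})

test_that("matching is invariant under label permutations", {
  gt <- random_mask(24L, 24L, 4L, seed = 3L)
  pred <- random_mask(24L, 24L, 4L, seed = 30L)
  base <- match_instances(gt, pred)
  perm <- c(3L, 1L, 4L, 2L)
  gt_p <- gt
  gt_p[gt > 0L] <- perm[gt[gt > 0L]]
  cc <- match_instances(gt, pred)
  cc_p <- match_instances(gt_p, pred)
  expect_equal(cc_p$TP, base$TP)
})

test_that("a spurious prediction never helps precision, F1 or AJI", {
  for (seed in 1:10) {
    gt <- random_mask(32L, 32L, 4L, seed = seed)
    pred <- random_mask(32L, 32L, 3L, seed = seed + 500L)
    # add a spurious instance in a background corner
    spur <- pred
    free <- which(gt == 0L & pred == 0L)
    spur[free[1:6]] <- n_instances(pred) + 1L
    before <- evaluate_pair(gt, pred)
    after <- evaluate_pair(gt, spur)
    expect_lte(after$precision, before$precision)
    expect_lte(after$f1, before$f1)
    expect_lte(after$aji, before$aji)
  }
})

test_that("evaluate_pair composes the individual metrics", {
  m <- random_mask(24L, 24L, 4L, seed = 8L)
  row <- evaluate_pair(m, m)
  expect_equal(as.numeric(row), c(1, 1, 1, 1, 1))

  empty <- matrix(0L, 24L, 24L)
  row0 <- evaluate_pair(m, empty)
  expect_equal(as.numeric(row0), c(0, 0, 0, 0, 0))

  gt <- random_mask(32L, 32L, 4L, seed = 9L)
  pred <- random_mask(32L, 32L, 4L, seed = 90L)
  row2 <- evaluate_pair(gt, pred)
  cc <- match_instances(gt, pred)
  prf <- precision_recall_f1(cc)
  expect_equal(row2$precision, prf[["precision"]])
  expect_equal(row2$recall, prf[["recall"]])
  expect_equal(row2$f1, prf[["f1"]])
  expect_equal(row2$adc, adc(cc))
  expect_equal(row2$aji, aji(gt, pred))
})
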