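test_that("codecs invert exactly on 8-bit images", {
  img <- random_rgb_image(8L, 8L, seed = 4L)
  for (nm in c("rgb", "optical_density")) {
    cd <- color_codec(nm)
    expect_identical(cd$backward(cd$forward(img), dim(img)[1:2]), img)
  }
})

test_that("single-component fit reduces to the pixel-cloud moments", {
  img <- random_rgb_image(16L, 16L, seed = 8L)
  cd <- color_codec("rgb")
  fit <- suppressWarnings(fit_gmm_em(img, K = 1L, codec = cd))
  X <- cd$forward(img)
  expect_equal(as.numeric(fit$model$means), colMeans(X), tolerance = 1e-8)
  Xc <- sweep(X, 2L, colMeans(X))
  ml_cov <- crossprod(Xc) / nrow(X)  # EM covariance is the ML estimate
  eps <- 1e-6 * mean(diag(stats::cov(X)))
  expect_equal(fit$model$covariances[[1L]], ml_cov + diag(eps, 3L),
               tolerance = 1e-6)
})

test_that("EM recovers planted three-class color means and is deterministic", {
  p <- synth_params(height = 96L, width = 96L, n_nuclei = 12L,
                    noise_std = 0.5, seed = 13L)
  sim <- generate_image(p)
  cd <- color_codec("rgb")
  fit <- fit_gmm_em(sim$image, K = 3L, codec = cd, seed = 1L)
  truth <- do.call(rbind, p$class_color_means)
  tm <- class_gaussians(rep(1 / 3, 3L), truth,
                        replicate(3L, diag(3L), simplify = FALSE))
  # optimal assignment: component k of the fit corresponds to truth perm[k]
  perm <- align_components(fit$model, tm)
  err <- abs(fit$model$means - truth[perm, ])
  expect_lt(max(err), 5)

  fit2 <- fit_gmm_em(sim$image, K = 3L, codec = cd, seed = 1L)
  expect_identical(fit$model, fit2$model)
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  for (seed in 1:20) {
    img <- random_rgb_image(24L, 24L, seed = seed)
    fit <- suppressWarnings(
      fit_gmm_em(img, K = 3L, codec = color_codec("rgb"), max_iter = 40L))
    expect_true(all(diff(fit$loglik) >= -1e-6 * abs(fit$loglik[-1L])))
  }
})

test_that("degenerate flat images are refused for K > 1", {
  flat <- array(128L, dim = c(8L, 8L, 3L))
  expect_error(fit_gmm_em(flat, K = 3L), "distinct colors")
})

test_that("posterior rows are a simplex", {
  img <- random_rgb_image(16L, 16L, seed = 6L)
  fit <- suppressWarnings(fit_gmm_em(img, K = 3L, codec = color_codec("rgb")))
  sums <- apply(fit$posterior, c(1L, 2L), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(fit$posterior >= 0 & fit$posterior <= 1))
})

test_that("one M-step from a hard or uniform posterior matches closed forms", {
  img <- random_rgb_image(12L, 12L, seed = 5L)
  cd <- color_codec("rgb")
  X <- cd$forward(img)
  n <- nrow(X)

  # one-hot posterior partitioning the pixels into 3 blocks
  grp <- rep(1:3, length.out = n)
  post <- array(0, dim = c(12L, 12L, 3L))
  for (k in 1:3) post[, , k] <- matrix(as.numeric(grp == k), 12L, 12L)
  model <- estimate_class_gaussians(img, post, cd)
  for (k in 1:3) {
    expect_equal(as.numeric(model$means[k, ]),
                 colMeans(X[grp == k, ]), tolerance = 1e-8)
  }

  # uniform posterior: every class mean is the global mean
  unif <- array(1 / 3, dim = c(12L, 12L, 3L))
  mu <- estimate_class_gaussians(img, unif, cd)$means
  for (k in 1:3) {
    expect_equal(as.numeric(mu[k, ]), colMeans(X), tolerance = 1e-8)
  }

  # starved class
  starved <- array(0, dim = c(12L, 12L, 3L))
  starved[, , 1L] <- 1
  expect_error(estimate_class_gaussians(img, starved, cd), "class 2")
})

test_that("feeding EM's final posterior back in reproduces its M-step", {
  p <- synth_params(height = 48L, width = 48L, n_nuclei = 5L, seed = 3L)
  img <- generate_image(p)$image
  cd <- color_codec("rgb")
  fit <- fit_gmm_em(img, K = 3L, codec = cd, tol = 1e-12, max_iter = 2000L)
  re <- estimate_class_gaussians(img, fit$posterior, cd)
  expect_equal(re$means, fit$model$means, tolerance = 1e-4)
  expect_equal(re$weights, fit$model$weights, tolerance = 1e-5)
})

test_that("component alignment matches the brute-force minimum", {
  mk <- function(M) class_gaussians(rep(1 / nrow(M), nrow(M)), M,
                                    replicate(nrow(M), diag(3L),
                                              simplify = FALSE))
  a <- mk(matrix(c(0, 0, 0, 10, 0, 0, 0, 10, 0), 3L, byrow = TRUE))
  expect_identical(align_components(a, a), 1:3)
  rev_a <- mk(a$means[3:1, ])
  expect_identical(align_components(a, rev_a), 3:1)

  for (seed in 1:10) {
    withr::with_seed(seed, {
      A <- mk(matrix(stats::rnorm(9, sd = 5), 3L))
      B <- mk(matrix(stats::rnorm(9, sd = 5), 3L))
    })
    all_p <- expand.grid(1:3, 1:3, 1:3)
    all_p <- all_p[apply(all_p, 1L, function(r) length(unique(r)) == 3L), ]
    costs <- apply(all_p, 1L, function(p) {
      sum(sqrt(rowSums((A$means - B$means[as.integer(p), ])^2)))
    })
    got <- align_components(A, B)
    expect_equal(sum(sqrt(rowSums((A$means - B$means[got, ])^2))),
                 min(costs), tolerance = 1e-12)
  }
})

test_that("identity transfer returns the input image", {
  p <- synth_params(height = 64L, width = 64L, n_nuclei = 6L, seed = 17L)
  img <- generate_image(p)$image
  fit <- fit_gmm_em(img, K = 3L)
  out <- normalize_colors(img, fit$model, fit$posterior, fit$model)
  frac_close <- mean(abs(out - img) <= 1)
  expect_gte(frac_close, 0.99)
})

test_that("K = 1 transfer with diagonal covariances is the per-channel affine map", {
  img <- random_rgb_image(16L, 16L, seed = 10L)
  cd <- color_codec("rgb")
  mu_in <- c(120, 100, 140); sd_in <- c(10, 20, 5)
  mu_t <- c(180, 90, 60); sd_t <- c(5, 10, 20)
  m_in <- class_gaussians(1, matrix(mu_in, 1L), list(diag(sd_in^2)))
  m_t <- class_gaussians(1, matrix(mu_t, 1L), list(diag(sd_t^2)))
  post <- array(1, dim = c(16L, 16L, 1L))
  out <- normalize_colors(img, m_in, post, m_t, cd)
  for (ch in 1:3) {
    want <- (sd_t[ch] / sd_in[ch]) * (img[, , ch] - mu_in[ch]) + mu_t[ch]
    want <- pmin(255, pmax(0, round(want)))
    expect_true(all(abs(out[, , ch] - want) <= 1))
  }
})

test_that("normalization removes a planted stain shift", {
  base <- synth_params(height = 96L, width = 96L, n_nuclei = 10L,
                       noise_std = 0.5, seed = 23L)
  shifted <- base
  shifted$stain_shift <- c(25, -15, 12)
  shifted$seed <- 24L
  tmpl_sim <- generate_image(base)
  in_sim <- generate_image(shifted)
  res <- normalize_image(in_sim$image, tmpl_sim$image, K = 3L)
  tmpl_nuc_mean <- vapply(1:3, function(ch) {
    mean(tmpl_sim$image[, , ch][tmpl_sim$mask > 0L])
  }, 1.0)
  out_nuc_mean <- vapply(1:3, function(ch) {
    mean(res$image[, , ch][in_sim$mask > 0L])
  }, 1.0)
  pre_nuc_mean <- vapply(1:3, function(ch) {
    mean(in_sim$image[, , ch][in_sim$mask > 0L])
  }, 1.0)
  expect_lt(max(abs(out_nuc_mean - tmpl_nuc_mean)), 5)
  # and the drift really was reduced relative to the un-normalized input
  expect_lt(max(abs(out_nuc_mean - tmpl_nuc_mean)),
            max(abs(pre_nuc_mean - tmpl_nuc_mean)))
})

test_that("transfer is invariant to component permutation", {
  p <- synth_params(height = 48L, width = 48L, n_nuclei = 5L, seed = 31L)
  img <- generate_image(p)$image
  fit <- fit_gmm_em(img, K = 3L)
  tm <- permute_components(fit$model, c(2L, 3L, 1L))  # arbitrary template
  out1 <- normalize_colors(img, fit$model, fit$posterior, tm)
  perm <- c(3L, 1L, 2L)
  model_p <- permute_components(fit$model, perm)
  post_p <- fit$posterior[, , perm]
  tm_p <- permute_components(tm, perm)
  out2 <- normalize_colors(img, model_p, post_p, tm_p)
  expect_identical(out1, out2)
})

test_that("normalization is idempotent up to quantization", {
  p <- synth_params(height = 64L, width = 64L, n_nuclei = 8L,
                    stain_shift = c(15, -10, 8), seed = 41L)
  tmpl <- generate_image(synth_params(height = 64L, width = 64L,
                                      n_nuclei = 8L, seed = 40L))$image
  img <- generate_image(p)$image
  once <- normalize_image(img, tmpl, K = 3L)$image
  twice <- normalize_image(once, tmpl, K = 3L)$image
  moved <- mean(abs(twice - once) > 2)
  expect_lte(moved, 0.01)
})
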