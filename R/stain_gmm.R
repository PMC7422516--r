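#' Color space codec for stain modeling
#'
#' Maps between 8-bit RGB images and the real-valued per-pixel color vectors
#' the Gaussian mixture is fitted in. Two spaces are supported:
#'
#' * `rgb` — raw channel intensities.
#' * `optical_density` (default) — `OD_c = -log((I_c + 1) / 256)` per
#'   channel. Stain absorption is approximately linear in optical density
#'   (Beer-Lambert), which makes the tissue-class color clusters closer to
#'   Gaussian; the `+1` offset keeps the map finite and exactly invertible
#'   on integers.
#'
#' @param name `"rgb"` or `"optical_density"`.
#' @return Object of class `color_codec` with `forward` (image -> N x 3
#'   matrix, pixels in column-major order) and `backward` (N x 3 matrix +
#'   dim -> image) mappings.
#' @export
color_codec <- function(name = c("optical_density", "rgb")) {
  name <- match.arg(name)
  if (name == "rgb") {
    fwd <- function(image) {
      d <- dim(image)
      matrix(as.numeric(image), d[1L] * d[2L], 3L)
    }
    bwd <- function(X, dims) {
      arr <- array(as.integer(pmin(255, pmax(0, round(X)))),
                   dim = c(dims, 3L))
      arr
    }
  } else {
    fwd <- function(image) {
      d <- dim(image)
      -log((matrix(as.numeric(image), d[1L] * d[2L], 3L) + 1) / 256)
    }
    bwd <- function(X, dims) {
      array(as.integer(pmin(255, pmax(0, round(256 * exp(-X) - 1)))),
            dim = c(dims, 3L))
    }
  }
  structure(list(name = name, forward = fwd, backward = bwd),
            class = "color_codec")
}

#' Per-tissue-class Gaussian color model
#'
#' Constructor for the mixture describing an image's pixel colors with one
#' multivariate Gaussian per tissue class (default K = 3: nuclei,
#' surrounding tissue, background).
#'
#' @param weights Length-K simplex vector.
#' @param means K x 3 matrix of class mean colors (codec working space).
#' @param covariances List of K symmetric positive-definite 3 x 3 matrices.
#' @return Object of class `class_gaussians`.
#' @export
class_gaussians <- function(weights, means, covariances) {
  K <- length(weights)
  stopifnot(abs(sum(weights) - 1) < 1e-9, all(weights >= 0),
            nrow(means) == K, length(covariances) == K)
  for (S in covariances) {
    stopifnot(isSymmetric(S, tol = 1e-8))
  }
  structure(list(K = K, weights = as.numeric(weights), means = means,
                 covariances = covariances),
            class = "class_gaussians")
}

#' @export
print.class_gaussians <- function(x, ...) {
  cat("Gaussian color model with", x$K, "classes\n")
  for (k in seq_len(x$K)) {
    cat(sprintf("  class %d: weight %.3f, mean (%s)\n", k, x$weights[k],
                paste(sprintf("%.2f", x$means[k, ]), collapse = ", ")))
  }
  invisible(x)
}

#' Fit a per-class Gaussian color model by expectation-maximization
#'
#' Classical EM on the image's pixel color cloud: the E-step computes
#' Gaussian responsibilities, the M-step re-estimates weights, means and
#' full covariances from responsibility-weighted pixels. Iteration stops
#' when the relative log-likelihood improvement falls below `tol` or after
#' `max_iter` iterations; non-convergence is reported with a warning, not an
#' error. Covariances are regularized by adding `eps * I` with
#' `eps = 1e-6` of the mean channel variance, which keeps whitening
#' well-posed on flat background regions.
#'
#' Initialization is deterministic: class means are placed at K evenly
#' spaced quantiles of the pixel luminance ordering, weights are uniform,
#' and every covariance starts at the global pixel covariance. The seed only
#' perturbs exact ties among initial means.
#'
#' @param image H x W x 3 integer RGB array.
#' @param K Number of classes (default 3).
#' @param codec A [color_codec()]; default optical density.
#' @param tol Relative log-likelihood stopping tolerance.
#' @param max_iter Maximum EM iterations.
#' @param seed Integer seed (tie-breaking only).
#' @param max_pixels Fit on at most this many pixels, chosen by a
#'   deterministic stride; the returned posterior always covers every pixel.
#'   Default `Inf` fits on the full cloud.
#' @return List with `model` (a [class_gaussians()]), `posterior`
#'   (H x W x K responsibility array), `loglik` (per-iteration trace over
#'   the fitted pixel set), `iterations`, and `converged`.
#' @export
fit_gmm_em <- function(image, K = 3L, codec = color_codec(), tol = 1e-6,
                       max_iter = 500L, seed = 0L, max_pixels = Inf) {
  validate_rgb_image(image)
  d <- dim(image)
  X_all <- codec$forward(image)
  n_all <- nrow(X_all)
  codes <- as.vector(image[, , 1L]) + 256 * as.vector(image[, , 2L]) +
    65536 * as.vector(image[, , 3L])
  if (length(unique(codes)) < K) {
    stop("image has fewer than K = ", K,
         " distinct colors; cannot fit a ", K, "-class mixture")
  }
  fit_idx <- if (is.finite(max_pixels) && n_all > max_pixels) {
    as.integer(round(seq(1L, n_all, length.out = max_pixels)))
  } else {
    seq_len(n_all)
  }
  X <- X_all[fit_idx, , drop = FALSE]
  n <- nrow(X)

  # deterministic quantile init along the luminance ordering
  lum <- rowMeans(matrix(as.numeric(image), n_all, 3L))[fit_idx]
  ord <- order(lum, seq_len(n))  # stable
  qpos <- as.integer(round((seq_len(K) - 0.5) / K * (n - 1))) + 1L
  mu <- X[ord[qpos], , drop = FALSE]
  if (anyDuplicated(mu)) {
    mu <- withr::with_seed(seed, mu + matrix(stats::rnorm(3L * K, 0, 1e-3),
                                             K, 3L))
  }
  gcov <- stats::cov(X)
  eps <- 1e-6 * mean(diag(gcov))
  if (eps <= 0) eps <- 1e-12
  covs <- replicate(K, gcov + diag(eps, 3L), simplify = FALSE)
  w <- rep(1 / K, K)

  ll_prev <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  R <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    es <- e_step(X, w, mu, covs)
    R <- es$resp
    trace <- c(trace, es$loglik)
    # M-step
    Nk <- colSums(R)
    w <- Nk / n
    mu <- crossprod(R, X) / Nk
    covs <- lapply(seq_len(K), function(k) {
      Xc <- sweep(X, 2L, mu[k, ])
      S <- crossprod(Xc * sqrt(R[, k])) / Nk[k]
      (S + t(S)) / 2 + diag(eps, 3L)
    })
    if (is.finite(ll_prev) &&
        (es$loglik - ll_prev) < tol * abs(ll_prev)) {
      converged <- TRUE
      break
    }
    ll_prev <- es$loglik
  }
  if (!converged) {
    warning("EM did not converge in ", max_iter,
            " iterations; returning last state")
  }
  model <- class_gaussians(w, mu, covs)
  post_full <- e_step(X_all, w, mu, covs)$resp
  posterior <- array(post_full, dim = c(d[1L], d[2L], K))
  list(model = model, posterior = posterior, loglik = trace,
       iterations = iter, converged = converged)
}

# E-step: responsibilities and observed-data log-likelihood.
e_step <- function(X, w, mu, covs) {
  K <- length(w)
  L <- vapply(seq_len(K), function(k) {
    log(w[k]) + ldmvnorm(X, mu[k, ], covs[[k]])
  }, numeric(nrow(X)))
  if (K == 1L) L <- matrix(L, ncol = 1L)
  m <- do.call(pmax, lapply(seq_len(K), function(k) L[, k]))
  lse <- m + log(rowSums(exp(L - m)))
  list(resp = exp(L - lse), loglik = sum(lse))
}

# Multivariate normal log-density via Cholesky.
ldmvnorm <- function(X, mu, Sigma) {
  R <- chol(Sigma)
  Xc <- sweep(X, 2L, mu)
  Y <- Xc %*% backsolve(R, diag(ncol(X)))
  quad <- rowSums(Y^2)
  -0.5 * (ncol(X) * log(2 * pi) + 2 * sum(log(diag(R))) + quad)
}

#' One M-step: class Gaussians from a given pixel posterior
#'
#' Computes exactly one responsibility-weighted parameter update: weights
#' are the mean responsibility per class, means the responsibility-weighted
#' color means, covariances the responsibility-weighted covariances plus the
#' regularization floor. This is the bridge that lets any posterior provider
#' (the built-in EM, or a plugged-in learned network) drive the color
#' transfer.
#'
#' @param image H x W x 3 integer RGB array.
#' @param posterior H x W x K responsibility array (rows sum to 1).
#' @param codec A [color_codec()].
#' @return A [class_gaussians()].
#' @export
estimate_class_gaussians <- function(image, posterior, codec = color_codec()) {
  validate_rgb_image(image)
  d <- dim(image)
  dp <- dim(posterior)
  if (length(dp) != 3L || dp[1L] != d[1L] || dp[2L] != d[2L]) {
    stop("posterior shape does not match image")
  }
  K <- dp[3L]
  X <- codec$forward(image)
  n <- nrow(X)
  R <- matrix(posterior, n, K)
  Nk <- colSums(R)
  low <- which(Nk < 10)
  if (length(low)) {
    stop("class ", low[1L], " has total responsibility ",
         format(Nk[low[1L]], digits = 4),
         " (< 10 pixels-equivalent); cannot estimate its Gaussian")
  }
  gcov <- stats::cov(X)
  eps <- 1e-6 * mean(diag(gcov))
  if (eps <= 0) eps <- 1e-12
  w <- Nk / n
  mu <- crossprod(R, X) / Nk
  covs <- lapply(seq_len(K), function(k) {
    Xc <- sweep(X, 2L, mu[k, ])
    S <- crossprod(Xc * sqrt(R[, k])) / Nk[k]
    (S + t(S)) / 2 + diag(eps, 3L)
  })
  class_gaussians(w, mu, covs)
}

#' Align mixture components between two color models
#'
#' EM component order is arbitrary; color transfer needs nuclei mapped to
#' nuclei. Returns the permutation `p` minimizing the total Euclidean
#' distance between matched means, i.e. component `k` of `a` corresponds to
#' component `p[k]` of `b`. Exhaustive over the K! permutations (refused for
#' K > 8).
#'
#' @param a,b Two [class_gaussians()] with equal K.
#' @return Integer permutation vector of length K.
#' @export
align_components <- function(a, b) {
  stopifnot(inherits(a, "class_gaussians"), inherits(b, "class_gaussians"))
  if (a$K != b$K) stop("models have different numbers of components")
  K <- a$K
  if (K > 8L) stop("K = ", K, " too large for exhaustive alignment (max 8)")
  P <- permutations(K)
  cost <- apply(P, 1L, function(p) {
    sum(sqrt(rowSums((a$means - b$means[p, , drop = FALSE])^2)))
  })
  p <- P[which.min(cost), ]
  as.integer(unname(p))
}

permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- permutations(n - 1L)
    cbind(i, matrix(seq_len(n)[-i][rest], nrow(rest)))
  }))
}

#' Reorder the components of a color model
#' @param model A [class_gaussians()].
#' @param perm Integer permutation: new component k is old component `perm[k]`.
#' @return A [class_gaussians()] with permuted components.
#' @export
permute_components <- function(model, perm) {
  class_gaussians(model$weights[perm],
                  model$means[perm, , drop = FALSE],
                  model$covariances[perm])
}

#' Transfer an image's per-class color distributions onto a template's
#'
#' Per pixel with working-space color `x` and class responsibilities
#' `g_k`, the output color is
#' `x' = sum_k g_k * (S_k (x - mu_k^in) + mu_k^tmpl)` with
#' `S_k = (Sigma_k^tmpl)^{1/2} (Sigma_k^in)^{-1/2}` using symmetric
#' (eigendecomposition) matrix square roots — a per-class
#' whitening-recoloring that moves each tissue class's Gaussian onto the
#' template's, blended by the posterior. Component correspondence between
#' the two models must already be established (see [align_components()]).
#'
#' @param input H x W x 3 integer RGB array.
#' @param input_model [class_gaussians()] fitted to `input`.
#' @param input_post H x W x K responsibility array for `input`.
#' @param template_model [class_gaussians()] of the template, with
#'   components ordered to correspond to `input_model`'s.
#' @param codec A [color_codec()] (must match the one used for fitting).
#' @return Normalized H x W x 3 integer RGB array.
#' @export
normalize_colors <- function(input, input_model, input_post, template_model,
                             codec = color_codec()) {
  validate_rgb_image(input)
  if (input_model$K != template_model$K) {
    stop("input and template models must have the same number of components")
  }
  d <- dim(input)
  K <- input_model$K
  X <- codec$forward(input)
  n <- nrow(X)
  G <- matrix(input_post, n, K)
  out <- matrix(0, n, 3L)
  for (k in seq_len(K)) {
    Sk <- sqrtm_sym(template_model$covariances[[k]]) %*%
      invsqrtm_sym(input_model$covariances[[k]])
    Xk <- sweep(X, 2L, input_model$means[k, ]) %*% t(Sk)
    Xk <- sweep(Xk, 2L, template_model$means[k, ], "+")
    out <- out + G[, k] * Xk
  }
  codec$backward(out, d[1:2])
}

# Symmetric matrix square root / inverse square root via eigendecomposition.
sqrtm_sym <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

invsqrtm_sym <- function(S, floor = 1e-12) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < floor) {
    stop("covariance eigenvalue ", format(min(e$values)),
         " below floor; matrix is numerically singular")
  }
  e$vectors %*% ((1 / sqrt(e$values)) * t(e$vectors))
}

#' Normalize an image's colors onto a template image
#'
#' Convenience wrapper over the full stage: fits the template and input
#' color models with [fit_gmm_em()], aligns mixture components by nearest
#' means, and applies [normalize_colors()].
#'
#' @param input,template H x W x 3 integer RGB arrays.
#' @param K Number of tissue classes.
#' @param codec A [color_codec()].
#' @param tol,max_iter,seed,max_pixels Passed to [fit_gmm_em()].
#' @return List with `image` (normalized RGB array), `input_model`,
#'   `template_model` (aligned to the input's component order), and
#'   `permutation`.
#' @export
normalize_image <- function(input, template, K = 3L, codec = color_codec(),
                            tol = 1e-6, max_iter = 500L, seed = 0L,
                            max_pixels = Inf) {
  fi <- fit_gmm_em(input, K = K, codec = codec, tol = tol,
                   max_iter = max_iter, seed = seed, max_pixels = max_pixels)
  ft <- fit_gmm_em(template, K = K, codec = codec, tol = tol,
                   max_iter = max_iter, seed = seed, max_pixels = max_pixels)
  perm <- align_components(fi$model, ft$model)
  tmpl <- permute_components(ft$model, perm)
  out <- normalize_colors(input, fi$model, fi$posterior, tmpl, codec)
  list(image = out, input_model = fi$model, template_model = tmpl,
       permutation = perm)
}
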