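test_that("the delta kernel encodes label agreement", {
  expect_equal(delta_kernel(c("a", "a", "b")),
               rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)), ignore_attr = TRUE)
  expect_equal(delta_kernel(rep("x", 4)), matrix(1, 4, 4), ignore_attr = TRUE)
  expect_equal(delta_kernel(letters[1:3]), diag(3), ignore_attr = TRUE)
  expect_error(delta_kernel(character(0)), class = "lcasonify_param_error")
})

test_that("kernel centering matches the hand computation and is idempotent", {
  expect_equal(center_kernel(diag(2)), rbind(c(0.5, -0.5), c(-0.5, 0.5)))
  expect_equal(center_kernel(matrix(1, 3, 3)), matrix(0, 3, 3))
  K <- withr::with_seed(1, {A <- matrix(rnorm(25), 5); A %*% t(A)})
  Kc <- center_kernel(K)
  expect_equal(center_kernel(Kc), Kc, tolerance = 1e-10)
  expect_lt(max(abs(rowSums(Kc))), 1e-8)
  expect_error(center_kernel(matrix(1, 2, 3)), class = "lcasonify_param_error")
})

test_that("the weighted Gaussian kernel follows the projected-distance formula", {
  X <- withr::with_seed(2, matrix(rnorm(40), 10, 4))
  expect_equal(weighted_gaussian_kernel(X, matrix(0, 4, 2)),
               matrix(1, 10, 10))
  K <- weighted_gaussian_kernel(matrix(c(0, 2), 2, 1), matrix(1, 1, 1))
  expect_equal(K[1, 2], exp(-2), tolerance = 1e-12)
  expect_error(weighted_gaussian_kernel(X, matrix(0, 3, 2)),
               class = "lcasonify_param_error")
})

test_that("alignment is 1 for proportional kernels and size-checked", {
  K <- withr::with_seed(3, {A <- matrix(rnorm(36), 6); A %*% t(A)})
  expect_equal(cka_alignment(K, K), 1, tolerance = 1e-12)
  expect_equal(cka_alignment(K, 3.7 * K), 1, tolerance = 1e-12)
  expect_error(cka_alignment(K, diag(5)), class = "lcasonify_param_error")
  expect_warning(z <- cka_alignment(matrix(1, 6, 6), K), "Zero-norm")
  expect_equal(z, 0)
})

test_that("a fixed-kernel alignment with permuted labels sits in the null", {
  X <- withr::with_seed(5, matrix(rnorm(200 * 6), 200, 6))
  labels <- rep(quadrants, 50)
  K <- weighted_gaussian_kernel(scale(X), diag(6) * 0.5)
  a_obs <- cka_alignment(K, delta_kernel(labels))
  null_a <- withr::with_seed(6, sapply(seq_len(500), function(i) {
    cka_alignment(K, delta_kernel(sample(labels)))
  }))
  expect_lt(a_obs, quantile(null_a, 0.95))
})

test_that("the CKA ascent improves alignment monotonically and is deterministic", {
  g <- gen_coupled_features(80, 10, 6, 0.3, label_sep = 2, seed = 12)
  f1 <- fit_cka(g$X, g$labels, d = 3, max_iter = 40)
  f2 <- fit_cka(g$X, g$labels, d = 3, max_iter = 40)
  expect_identical(f1$W, f2$W)
  expect_true(all(diff(f1$alignment_trace) >= 0))
  expect_gte(f1$alignment, f1$alignment_trace[1])
  expect_true(all(f1$alignment_trace >= 0 & f1$alignment_trace <= 1))
  expect_error(fit_cka(g$X, rep("a", 80)), class = "lcasonify_param_error")
})

test_that("relevance maps aggregate as documented", {
  W <- matrix(0, 5, 2); W[3, ] <- c(1, 2)
  expect_equal(feature_relevance(W), c(0, 0, 1, 0, 0))
  Wu <- diag(4)  # orthogonal equal-norm rows
  expect_equal(feature_relevance(Wu), rep(0.25, 4))
  expect_warning(u <- feature_relevance(matrix(0, 3, 2)), "Zero")
  expect_equal(u, rep(1 / 3, 3))

  idx <- pair_idx <- expand.grid(ch1 = c("C3", "C4", "Pz"), ch2 = c("C3", "C4", "Pz"),
                                 stringsAsFactors = FALSE)
  idx <- idx[idx$ch1 < idx$ch2, ]
  rel <- c(1, 0, 0)  # all mass on the (C3, C4) pair
  er <- electrode_relevance(rel, idx)
  expect_equal(sort(er$electrode[1:2]), c("C3", "C4"))
  eru <- electrode_relevance(rep(1 / 3, 3), idx)
  expect_true(all(abs(eru$relevance - 1) < 1e-12))  # complete-graph symmetry
  expect_error(electrode_relevance(rel, NULL), class = "lcasonify_param_error")
})

test_that("CCA reduces to known closed forms", {
  X <- withr::with_seed(21, matrix(rnorm(60 * 4), 60, 4))
  expect_equal(fit_cca(X, X, regularization = 0)$r, 1, tolerance = 1e-6)
  x <- rnorm(50); y <- 0.6 * x + rnorm(50)
  expect_equal(fit_cca(matrix(x), matrix(y), regularization = 0)$r,
               abs(cor(x, y)), tolerance = 1e-9)
  # invariance to invertible affine maps of either block
  Y <- withr::with_seed(22, matrix(rnorm(60 * 3), 60, 3))
  A <- matrix(c(2, 1, 0, 1, 3, 0, 0, 1, 1), 3, 3)
  r1 <- fit_cca(X, Y, regularization = 0)$r
  r2 <- fit_cca(X, Y %*% A + 5, regularization = 0)$r
  expect_equal(r1, r2, tolerance = 1e-6)
  # rank deficiency without regularization is surfaced with guidance
  Xd <- cbind(X, X[, 1])
  expect_error(fit_cca(Xd, Y, regularization = 0), "regularization")
  expect_s3_class(fit_cca(Xd, Y, regularization = 1e-3), "cca_fit")
})

test_that("unit-variance constraints hold for the canonical pair", {
  g <- gen_coupled_features(200, 6, 5, 0.7, seed = 31)
  f <- fit_cca(g$X, g$Y, regularization = 0)
  Xs <- scale(g$X); Ys <- scale(g$Y)
  expect_equal(as.numeric(var(Xs %*% f$alpha_x)), 1, tolerance = 1e-6)
  expect_equal(as.numeric(var(Ys %*% f$alpha_y)), 1, tolerance = 1e-6)
  expect_gt(f$alpha_x[which(abs(f$alpha_x) > 1e-12)[1]], 0)  # sign convention
})

test_that("the two-step pipeline is deterministic and validates inputs", {
  g <- gen_coupled_features(60, 8, 6, 0.5, label_sep = 1, seed = 41)
  f1 <- lca(g$X, g$Y, g$labels, d = 3, max_iter = 30)
  f2 <- lca(g$X, g$Y, g$labels, d = 3, max_iter = 30)
  expect_identical(f1$cca$alpha_x, f2$cca$alpha_x)
  expect_identical(f1$r, f2$r)
  expect_error(lca(g$X, g$Y[-1, ], g$labels), class = "lcasonify_param_error")
  expect_error(lca(g$X, g$Y, g$labels[-1]), class = "lcasonify_param_error")
  expect_error(lca(g$X, g$Y, NULL, two_step = TRUE), class = "lcasonify_param_error")

  f0 <- lca(g$X, g$Y, g$labels, two_step = FALSE)
  expect_null(f0$cka_x)
  expect_s3_class(f0$cca, "cca_fit")
})

test_that("tidy and glance methods return the documented shapes", {
  g <- gen_coupled_features(60, 8, 6, 0.5, label_sep = 1, seed = 43)
  f <- lca(g$X, g$Y, g$labels, d = 3, max_iter = 20)
  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 8L)
  expect_equal(sum(td$relevance), 1, tolerance = 1e-12)
  gl <- glance(f)
  expect_equal(nrow(gl), 1L)
  expect_true(all(c("r", "r_squared", "alignment_x") %in% names(gl)))
  expect_equal(nrow(glance(f$cca)), 1L)
  expect_equal(nrow(tidy(f$cka_x)), 8L)
})
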