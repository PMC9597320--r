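# KMO, PCA with supplementary variables, oblimin rotation, clustering.

test_that("KMO reproduces the equicorrelated closed form", {
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  # partial correlations of an equicorrelated triple are r/(1+r) = 1/3
  expect_equal(kmo(R), 0.75 / (0.75 + 1 / 3), tolerance = 1e-12)
  expect_equal(round(kmo(R), 4), 0.6923)
})

test_that("KMO is bounded and invariant to variable rescaling", {
  set.seed(51)
  X <- matrix(rnorm(200 * 6), 200, 6) %*% matrix(rnorm(36), 6, 6)
  k1 <- kmo(X)
  expect_gte(k1, 0); expect_lte(k1, 1)
  X2 <- sweep(X, 2, c(1, 10, 0.1, 5, 2, 100), `*`)
  expect_equal(kmo(X2), k1, tolerance = 1e-10)
  expect_error(kmo(X[, 1:2]), "at least 3")
})

test_that("PCA explained variance is conserved and collinearity is detected", {
  set.seed(52)
  x <- rnorm(50)
  X <- cbind(a = x, b = 2 * x + 3)        # perfectly correlated pair
  p <- pca_with_supplementary(X)
  expect_equal(p$explained_pct[1], 100, tolerance = 1e-8)
  X2 <- matrix(rnorm(50 * 5), 50, 5)
  p2 <- pca_with_supplementary(X2)
  expect_equal(sum(p2$explained_pct), 100, tolerance = 1e-8)
  expect_equal(unname(cor(p2$scores)), diag(5), tolerance = 1e-8)
})

test_that("scores reconstruct the standardized data with all components", {
  set.seed(53)
  X <- matrix(rnorm(40 * 6), 40, 6)
  p <- pca_with_supplementary(X)
  Xs <- scale(X)
  expect_equal(unname(p$scores %*% t(p$eigenvectors)), unname(Xs),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("a supplementary duplicate of an active variable loads like it", {
  set.seed(54)
  X <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, paste0("v", 1:4)))
  p <- pca_with_supplementary(X, x_supplementary = cbind(dup = X[, 2]))
  # structure correlation of active variable 2 with each component
  expect_equal(unname(p$supplementary_loadings["dup", ]),
               unname(cor(X[, 2], p$scores)[1, ]), tolerance = 1e-10)
  # and that equals cor of variable with scores by construction of loadings
  expect_equal(unname(p$supplementary_loadings["dup", ]),
               unname(cor(scale(X)[, 2], p$scores)[1, ]), tolerance = 1e-10)
})

test_that("constant active variables are dropped with a warning", {
  set.seed(55)
  X <- cbind(a = rnorm(30), b = rnorm(30), c = rep(1, 30))
  expect_warning(p <- pca_with_supplementary(X), "constant")
  expect_identical(p$dropped, "c")
  expect_identical(nrow(p$loadings_unrotated), 2L)
})

test_that("oblimin leaves perfect simple structure alone and normalizes contributions", {
  A <- rbind(c(0.9, 0), c(0.8, 0), c(0.7, 0),
             c(0, 0.9), c(0, 0.8), c(0, 0.6))
  r <- oblimin_rotation(A)
  expect_equal(abs(r$pattern), A, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(unname(colSums(r$contributions_pct)), c(100, 100), tolerance = 1e-8)
  expect_equal(r$criterion, 0, tolerance = 1e-10)
})

test_that("oblimin matches an independent optimizer on a fixed 8x3 problem", {
  A <- rbind(
    c(0.83,  0.08, -0.04), c(0.78, -0.05,  0.12), c(0.72,  0.14,  0.07),
    c(0.11,  0.81,  0.05), c(-0.07, 0.76,  0.14), c(0.15,  0.68, -0.09),
    c(0.04,  0.12,  0.79), c(-0.10, 0.06,  0.74))
  r <- oblimin_rotation(A)
  ref <- oblimin_reference(A)
  expect_equal(r$criterion, ref$criterion, tolerance = 1e-6)
  expect_equal(unname(r$pattern), unname(align_columns(ref$pattern, r$pattern)),
               tolerance = 1e-6)
  # criterion value recomputed by the independent transcription
  expect_equal(oblimin_crit_oracle(r$pattern), r$criterion, tolerance = 1e-10)
})

test_that("rotation preserves communalities (pattern Phi pattern')", {
  set.seed(56)
  A <- matrix(rnorm(24, 0, 0.5), 8, 3)
  r <- oblimin_rotation(A)
  h_before <- rowSums(A^2)
  h_after <- diag(r$pattern %*% r$factor_correlations %*% t(r$pattern))
  expect_equal(unname(h_after), unname(h_before), tolerance = 1e-8)
  # structure = pattern x factor correlations
  expect_equal(r$structure, r$pattern %*% r$factor_correlations,
               ignore_attr = TRUE)
})

test_that("hierarchical k-means recovers well-separated blobs deterministically", {
  set.seed(57)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
  X <- do.call(rbind, lapply(1:4, function(i)
    sweep(matrix(rnorm(10, 0, 0.3), 5, 2), 2, centers[i, ], `+`)))
  rownames(X) <- paste0("g", 1:20)
  truth <- rep(1:4, each = 5)
  cl <- hierarchical_kmeans(X, k = 4)
  expect_equal(adjusted_rand_index(cl$labels, truth), 1)
  expect_identical(sort(unique(unname(cl$labels))), 1:4)
  # determinism and input-order invariance
  cl2 <- hierarchical_kmeans(X, k = 4)
  expect_identical(cl$labels, cl2$labels)
  perm <- sample(20)
  cl3 <- hierarchical_kmeans(X[perm, ], k = 4)
  expect_equal(adjusted_rand_index(cl3$labels[rownames(X)], cl$labels), 1)
  # trivial and error cases
  expect_true(all(hierarchical_kmeans(X, k = 1)$labels == 1))
  expect_error(hierarchical_kmeans(X[1:3, ], k = 5), "exceeds")
})

test_that("auto-k selects the true blob count in nearly all seeds", {
  hits <- vapply(1:200, function(s) {
    set.seed(600 + s)
    centers <- rbind(c(0, 0), c(8, 0), c(0, 8), c(8, 8))
    X <- do.call(rbind, lapply(1:4, function(i)
      sweep(matrix(rnorm(8, 0, 0.5), 4, 2), 2, centers[i, ], `+`)))
    hierarchical_kmeans(X, k = "auto")$k == 4L
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("in-package ARI agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(58)
  for (i in 1:20) {
    a <- sample(1:4, 30, TRUE); b <- sample(1:3, 30, TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, c(2, 3, 4, 5, 1)), 1)
})
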