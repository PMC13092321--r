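test_that("fit_gaussian uses the 1/N convention", {
  g1 <- fit_gaussian(matrix(c(1, 2), 1, 2))
  expect_equal(g1$mean, c(1, 2))
  expect_equal(g1$covariance, matrix(0, 2, 2))
  g2 <- fit_gaussian(matrix(c(0, 0, 2, 0), 2, 2, byrow = TRUE))
  expect_equal(g2$mean, c(1, 0))
  expect_equal(g2$covariance, matrix(c(1, 0, 0, 0), 2, 2))
  g2u <- fit_gaussian(matrix(c(0, 0, 2, 0), 2, 2, byrow = TRUE),
                      unbiased = TRUE)
  expect_equal(g2u$covariance[1, 1], 2)
})

test_that("moment estimates converge to the sampling distribution", {
  S <- matrix(c(2, 0.5, 0.3, 0, 0.5, 1, 0.2, 0, 0.3, 0.2, 1.5, 0,
                0, 0, 0, 0.7), 4, 4)
  S <- (S + t(S)) / 2
  E <- sample_cloud(gaussian_cloud_spec(1:4, S, 100000, seed = 3))
  g <- fit_gaussian(E)
  expect_lt(max(abs(g$mean - 1:4)), 0.05)
  expect_lt(max(abs(g$covariance - S)), 0.05)
})

test_that("closed-form distances: identical, scalar and commuting cases", {
  S <- matrix(c(2, 0.3, 0.3, 1), 2, 2)
  g <- gaussian_summary(c(1, -1), S)
  expect_lt(abs(frechet_gaussian_distance(g, g)), 1e-8)
  gx <- gaussian_summary(0, matrix(1, 1, 1))
  gy <- gaussian_summary(3, matrix(4, 1, 1))
  expect_equal(as.numeric(frechet_gaussian_distance(gx, gy)), 10,
               tolerance = 1e-10)
  ga <- gaussian_summary(c(0, 0), diag(c(1, 4)))
  gb <- gaussian_summary(c(1, 1), diag(c(4, 1)))
  expect_equal(as.numeric(frechet_gaussian_distance(ga, gb)), 4,
               tolerance = 1e-10)
  expect_error(frechet_gaussian_distance(gx, ga), "mismatch")
})

test_that("symmetric-form trace agrees with the product-eigendecomposition route", {
  set.seed(7)
  for (r in 1:20) {
    A <- matrix(rnorm(64), 8); Sx <- crossprod(A) / 8 + diag(1e-3, 8)
    B <- matrix(rnorm(64), 8); Sy <- crossprod(B) / 8 + diag(1e-3, 8)
    sym <- protfid:::.trace_sqrt_cross(Sx, Sy)
    # independent route: eigendecompose the (diagonalizable) product Sy Sx
    ev <- eigen(Sy %*% Sx, only.values = TRUE)$values
    prod_route <- sum(sqrt(pmax(Re(ev), 0)))
    expect_lt(abs(sym - prod_route), 1e-6)
  }
})

test_that("joint PCA recovers rank structure and matches a spectral oracle", {
  set.seed(5)
  v <- rnorm(10)
  Z <- outer(rnorm(30), v) + 3        # rank-1 around an offset
  b1 <- fit_joint_pca(Z[1:15, ], Z[16:30, ], d = 1)
  tot <- sum(eigen(stats::cov(Z) * 29 / 30, symmetric = TRUE,
                   only.values = TRUE)$values)
  expect_gte(b1$explained_variance[1] / tot, 0.999)

  X <- matrix(rnorm(100 * 50), 100, 50)
  b <- fit_joint_pca(X[1:50, ], X[51:100, ], d = 4)
  oracle <- eigen(crossprod(sweep(X, 2, colMeans(X))) / 100,
                  symmetric = TRUE, only.values = TRUE)$values[1:4]
  expect_equal(b$explained_variance, oracle, tolerance = 1e-8)
  expect_error(fit_joint_pca(X[1:5, ], X[6:10, ], d = 11), "d must")
})

test_that("projection is the advertised affine map", {
  X <- matrix(rnorm(40), 10, 4)
  b <- fit_joint_pca(X[1:5, ], X[6:10, ], d = 2)
  expect_equal(as.numeric(project(matrix(b$center, 1), b)), c(0, 0),
               tolerance = 1e-12)
  # reconstruction on the span
  Y <- project(X, b)
  back <- sweep(unclass(Y) %*% b$components, 2, b$center, "+")
  Y2 <- project(back, b)
  expect_equal(unclass(Y2), unclass(Y), tolerance = 1e-8,
               ignore_attr = TRUE)
  # contraction
  norms_in <- sqrt(rowSums(sweep(X, 2, b$center)^2))
  expect_true(all(sqrt(rowSums(unclass(Y)^2)) <= norms_in + 1e-10))
})

test_that("full-rank projection leaves the distance unchanged", {
  A <- sample_cloud(gaussian_cloud_spec(rep(0, 4), diag(4), 300, seed = 1))
  B <- sample_cloud(gaussian_cloud_spec(rep(0.5, 4), diag(4) * 1.3, 300,
                                        seed = 2))
  direct <- frechet_gaussian_distance(fit_gaussian(A), fit_gaussian(B))
  via_pca <- compute_fid(A, B, d = 4)$value
  expect_equal(via_pca, as.numeric(direct), tolerance = 1e-6)
})

test_that("the end-to-end distance matches the analytic Gaussian value", {
  p <- 64
  mu2 <- c(3, rep(0, p - 1))
  S2 <- diag(p); S2[2, 2] <- 4   # analytic W2^2 = 9 + (2 - 1)^2 = 10
  A <- sample_cloud(gaussian_cloud_spec(rep(0, p), diag(p), 3000, seed = 11))
  B <- sample_cloud(gaussian_cloud_spec(mu2, S2, 3000, seed = 12))
  f <- compute_fid(A, B, d = 8)
  expect_lt(abs(f$value - 10) / 10, 0.1)
  expect_false(f$degenerate_warning)
  # symmetry of the whole pipeline
  expect_equal(compute_fid(B, A, d = 8)$value, f$value, tolerance = 1e-6)
  # identical inputs
  expect_lt(compute_fid(A, A, d = 8)$value, 1e-6)
})

test_that("near-degenerate pre-projection covariance raises the flag", {
  base <- sample_cloud(gaussian_cloud_spec(rep(0, 3), diag(3), 200, seed = 4))
  X <- cbind(unclass(base), unclass(base)[, 1] * 2)  # exactly collinear
  f <- compute_fid(embedding_matrix(X[1:100, ]), embedding_matrix(X[101:200, ]),
                   d = 3)
  expect_true(f$degenerate_warning)
})

test_that("undersized samples warn about rank deficiency", {
  A <- sample_cloud(gaussian_cloud_spec(rep(0, 8), diag(8), 6, seed = 1))
  B <- sample_cloud(gaussian_cloud_spec(rep(0, 8), diag(8), 50, seed = 2))
  expect_warning(compute_fid(A, B, d = 6), "rank-deficient")
})

test_that("distance estimates keep model ordering across sample sizes", {
  # three synthetic "models" at increasing true distance from the reference
  p <- 6
  shifts <- c(0.5, 1.5, 3)
  set.seed(123)
  ords <- replicate(20, {
    seed <- sample.int(1e6, 1)
    ref <- sample_cloud(gaussian_cloud_spec(rep(0, p), diag(p), 1000,
                                            seed = seed))
    vals <- sapply(c(50, 200, 1000), function(n) {
      sapply(seq_along(shifts), function(m) {
        ev <- sample_cloud(gaussian_cloud_spec(
          c(shifts[m], rep(0, p - 1)), diag(p), n,
          seed = seed + 17 * m + n))
        compute_fid(ref, ev, d = p)$value
      })
    })
    all(apply(vals, 2, function(v) identical(order(v), 1:3)))
  })
  expect_gte(mean(ords), 0.95)
})
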