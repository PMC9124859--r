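random_spd <- function(n) {
  a <- matrix(rnorm(n * n), n)
  crossprod(a) / n + diag(n)
}

test_that("noise covariance estimation matches its sampling and loading contracts", {
  set.seed(4)
  # unit-variance independent channels: C approaches the identity
  X <- matrix(rnorm(6 * 1e5), 6)
  C <- estimate_noise_covariance(list(X), loading = 0)
  expect_lt(max(abs(C$matrix - diag(6))), 0.05)
  # loading = 1 collapses to mean-variance times identity
  C1 <- estimate_noise_covariance(list(X), loading = 1)
  expect_equal(C1$matrix, mean(diag(stats::cov(t(X)))) * diag(6),
               tolerance = 1e-10)
  # duplicated channel: off-diagonal equals the shared variance
  Y <- rbind(X[1, ], X[1, ], X[2, ])
  Cd <- estimate_noise_covariance(list(Y), loading = 0)
  expect_equal(Cd$matrix[1, 2], Cd$matrix[1, 1], tolerance = 1e-10)
  expect_error(estimate_noise_covariance(list()), "empty")
  expect_warning(estimate_noise_covariance(matrix(rnorm(8), 4, 2)),
                 "rank deficient")
})

test_that("depth weights follow the leadfield column norms", {
  fw <- small_forward()
  W0 <- depth_weights(fw$leadfield, gamma = 0)
  expect_equal(W0$weights, rep(1, ncol(fw$leadfield$gain)))
  W1 <- depth_weights(fw$leadfield, gamma = 1)
  lf2 <- fw$leadfield; lf2$gain <- 2 * lf2$gain
  expect_equal(depth_weights(lf2, gamma = 1)$weights, 2 * W1$weights)
  zero <- fw$leadfield; zero$gain[, 3] <- 0
  expect_error(depth_weights(zero), "source 3")
})

test_that("the WMNE kernel equals the regularized normal-equation solution", {
  set.seed(12)
  for (rep in 1:20) {
    nE <- sample(4:10, 1); nS <- sample(nE:25, 1)
    L <- leadfield(matrix(rnorm(nE * nS), nE))
    C <- structure(list(matrix = random_spd(nE), loading = 0),
                   class = "noise_covariance")
    w <- runif(nS, 0.5, 2)
    W <- structure(list(weights = w, gamma = NA), class = "source_weighting")
    lam <- runif(1, 0.05, 2)
    K <- build_wmne_operator(L, C, W, lambda = lam)
    y <- rnorm(nE)
    xhat <- K$kernel %*% y
    # oracle: solve (L' C^-1 L + lam W^2) x = L' C^-1 y directly
    Ci <- solve(C$matrix)
    xo <- solve(crossprod(L$gain, Ci %*% L$gain) + lam * diag(w^2),
                crossprod(L$gain, Ci %*% y))
    expect_lt(max(abs(xhat - xo)), 1e-8)
  }
})

test_that("identity problem, shrinkage limit, and singularity handling behave", {
  L <- leadfield(diag(2))
  K0 <- build_wmne_operator(L, lambda = 0)
  expect_equal(K0$kernel, diag(2), tolerance = 1e-12)
  expect_equal(as.vector(K0$kernel %*% c(1, 0)), c(1, 0), tolerance = 1e-12)
  set.seed(3)
  Lr <- leadfield(matrix(rnorm(8 * 20), 8))
  k1 <- build_wmne_operator(Lr, lambda = 1)
  k6 <- build_wmne_operator(Lr, lambda = 1e6)
  expect_lt(norm(k6$kernel, "F"), 1e-4 * norm(k1$kernel, "F"))
  # monotone shrinkage of the solution norm in lambda
  y <- rnorm(8)
  norms <- sapply(c(0.01, 0.1, 1, 10), function(l)
    sum((build_wmne_operator(Lr, lambda = l)$kernel %*% y)^2))
  expect_true(all(diff(norms) < 0))
  # rank-deficient leadfield at lambda = 0
  Ld <- leadfield(matrix(rnorm(20), 4) %x% matrix(1, 2, 1))  # repeated rows
  expect_error(build_wmne_operator(leadfield(rbind(Ld$gain[1:4, ],
                                                   Ld$gain[1:4, ])),
                                   lambda = 0), "lambda > 0")
})

test_that("apply_inverse is linear and conserves labels and trials", {
  set.seed(6)
  K <- structure(list(kernel = matrix(rnorm(12 * 4), 12), lambda = 1,
                      gamma = 0, provenance = NULL),
                 class = "inverse_operator")
  e1 <- epoch_set(array(rnorm(3 * 4 * 50), c(3, 4, 50)), c("T1", "T2", "T4"),
                  160, letters[1:4])
  e2 <- epoch_set(array(rnorm(3 * 4 * 50), c(3, 4, 50)), c("T1", "T2", "T4"),
                  160, letters[1:4])
  s1 <- apply_inverse(K, e1); s2 <- apply_inverse(K, e2)
  mix <- e1; mix$epochs <- 2 * e1$epochs - 5 * e2$epochs
  smix <- apply_inverse(K, mix)
  expect_equal(smix$epochs, 2 * s1$epochs - 5 * s2$epochs, tolerance = 1e-10)
  expect_identical(s1$labels, e1$labels)
  expect_equal(dim(s1$epochs), c(3L, 12L, 50L))
  zero <- e1; zero$epochs[] <- 0
  expect_true(all(apply_inverse(K, zero)$epochs == 0))
  expect_error(apply_inverse(K, epoch_set(array(0, c(1, 5, 10)), "T1", 160,
                                          letters[1:5])), "montage mismatch")
})

test_that("a single active scout is localized to itself at high SNR", {
  fw <- small_forward()
  cfg <- sim_config(sensor_snr_db = 40, erd_depth = 0)
  vmap <- hemidiff:::scout_vertex_map(fw$scouts)
  set.seed(10)
  tr <- generate_source_activity("T1", cfg)
  target <- "C3"
  tr$activity[rownames(tr$activity) != target, ] <- 0
  y <- project_to_scalp(tr, fw$leadfield, vmap, cfg)
  ep <- epoch_set(array(y, c(1, dim(y))), "T1", cfg$fs, fw$montage$names)
  K <- build_wmne_operator(fw$leadfield, NULL, depth_weights(fw$leadfield),
                           lambda = NULL, snr_power = 100)
  src <- apply_inverse(K, ep)
  sc <- extract_scout_series(src, fw$scouts)
  pw <- apply(sc$series[1, , ], 1, function(v) mean(v^2))
  expect_identical(names(which.max(pw)), target)
})

test_that("inverse operators round-trip through their export format", {
  set.seed(2)
  K <- build_wmne_operator(leadfield(matrix(rnorm(6 * 10), 6)), lambda = 0.5)
  base <- file.path(withr::local_tempdir(), "kernel")
  write_inverse_operator(K, base)
  K2 <- read_inverse_operator(base)
  expect_equal(K2$kernel, K$kernel, tolerance = 1e-12)
  expect_equal(K2$lambda, K$lambda)
})
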