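test_that("Pearson correlation matrices match the definitional formula", {
  set.seed(71)
  X <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("x1", "x2", "x3")))
  Y <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("y1", "y2")))
  R <- pearson_matrix(X, Y)
  oracle <- function(a, b) {
    ca <- a - mean(a); cb <- b - mean(b)
    sum(ca * cb) / sqrt(sum(ca^2) * sum(cb^2))
  }
  for (i in 1:3) for (j in 1:2)
    expect_equal(R[i, j], oracle(X[, i], Y[, j]), tolerance = 1e-12)

  # identical and affine anti-correlated columns
  expect_equal(pearson_matrix(X, X)["x1", "x1"], 1)
  Y2 <- cbind(y = -2 * X[, 1] + 7)
  expect_equal(pearson_matrix(X, Y2)["x1", "y"], -1, tolerance = 1e-12)
  # constant columns are undefined, not zero
  Xc <- cbind(X, const = 5)
  expect_true(is.na(pearson_matrix(Xc, Y)["const", "y1"]))
  expect_error(pearson_matrix(X[1:2, ], Y[1:2, ]), "at least 3")
})

test_that("Euclidean distances honour the standardization flag", {
  M <- rbind(a = c(0, 0), b = c(3, 4))
  D <- euclidean_distance(M, standardize = FALSE)
  expect_equal(D["a", "b"], 5)
  expect_equal(diag(D), c(a = 0, b = 0))
  # identical rows at distance zero
  M0 <- rbind(a = c(1, 2), b = c(1, 2), c = c(4, 8))
  expect_equal(euclidean_distance(M0, standardize = FALSE)["a", "b"], 0)
  expect_equal(euclidean_distance(M0)["a", "b"], 0)
  # z-scoring changes distances exactly as recomputation predicts
  set.seed(72)
  M2 <- matrix(rnorm(20, sd = c(1, 100)), 10, 2)
  Dz <- euclidean_distance(M2)
  expect_equal(Dz, as.matrix(stats::dist(scale(M2))), tolerance = 1e-12,
               ignore_attr = TRUE)
  # zero-variance columns are excluded with a warning
  expect_warning(euclidean_distance(cbind(M2, k = 1)), "zero-variance")
})

test_that("the Mantel test is exact on self-comparison and seed-stable", {
  set.seed(73)
  D1 <- as.matrix(stats::dist(matrix(rnorm(24), 8)))
  m <- mantel_test(D1, D1, n_perm = 199, seed = 1)
  expect_equal(m$r, 1)
  expect_equal(m$p_value, 1 / 200)     # minimum attainable p
  # scale invariance of the statistic
  m2 <- mantel_test(D1, 3.7 * D1, n_perm = 99, seed = 1)
  expect_equal(m2$r, 1)
  # reproducibility under a fixed seed
  D2 <- as.matrix(stats::dist(matrix(rnorm(24), 8)))
  expect_identical(mantel_test(D1, D2, 199, seed = 9),
                   mantel_test(D1, D2, 199, seed = 9))
  expect_error(mantel_test(D1, D2[1:5, 1:5]), "differ in size")
  # the statistic agrees with vegan's implementation
  skip_if_not_installed("vegan")
  vg <- vegan::mantel(stats::as.dist(D1), stats::as.dist(D2),
                      permutations = 10)
  expect_equal(mantel_test(D1, D2, 9, seed = 2)$r, unname(vg$statistic),
               tolerance = 1e-12)
})

test_that("Mantel p-values are calibrated under the null", {
  # scaled-down type-I error check; the acceptance suite runs the full one
  set.seed(74)
  rej <- mean(vapply(1:200, function(i) {
    D1 <- as.matrix(stats::dist(matrix(stats::rnorm(24), 8)))
    D2 <- as.matrix(stats::dist(matrix(stats::rnorm(24), 8)))
    mantel_test(D1, D2, n_perm = 99, seed = i)$p_value <= 0.05
  }, logical(1)))
  expect_gte(rej, 0.01)
  expect_lte(rej, 0.10)
})

test_that("classical scaling recovers known configurations", {
  # collinear points: one positive eigenvalue, axis-1 reproduces D exactly
  pts <- cbind(c(0, 1, 3, 7), c(0, 2, 6, 14))
  D <- as.matrix(stats::dist(pts))
  o <- pcoa(D, k = 2)
  expect_equal(sum(o$eigenvalues > 1e-9), 1L)
  expect_equal(as.matrix(stats::dist(o$coordinates[, 1])), D,
               tolerance = 1e-9, ignore_attr = TRUE)

  # known 2-D configuration recovered up to rotation/reflection
  skip_if_not_installed("vegan")
  set.seed(75)
  X <- matrix(rnorm(24), 12, 2)
  o2 <- pcoa(as.matrix(stats::dist(X)), k = 2)
  pro <- vegan::procrustes(X, o2$coordinates, symmetric = FALSE)
  expect_lt(sqrt(mean(stats::residuals(pro)^2)), 1e-8)
  # re-embedded coordinates reproduce a Euclidean-embeddable D
  expect_equal(as.matrix(stats::dist(o2$coordinates)),
               as.matrix(stats::dist(X)), tolerance = 1e-9,
               ignore_attr = TRUE)

  # equidistant triple: two equal positive eigenvalues
  D3 <- matrix(1, 3, 3) - diag(3)
  o3 <- pcoa(D3, k = 2)
  pos <- o3$eigenvalues[o3$eigenvalues > 1e-12]
  expect_length(pos, 2L)
  expect_equal(pos[1], pos[2], tolerance = 1e-9)

  # deterministic axis orientation: largest-magnitude loading positive
  expect_true(all(apply(o2$coordinates, 2,
                        function(v) v[which.max(abs(v))] > 0)))
  expect_error(pcoa(D3, k = 3), "smaller")
})
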