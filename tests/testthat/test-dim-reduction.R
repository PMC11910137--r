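# Dimensionality reduction: oracle equivalences against dense eigen-solvers,
# the LDA dimensionality bound, identity of NONE, and centroid distances.

make_xy <- function(seed = 1, n = 30, p = 6, k = 3, sep = 2) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- factor(rep(seq_len(k), length.out = n))
  X + sep * matrix(rnorm(k * p), k, p)[as.integer(y), ]
}

test_that("PCA scores equal a brute-force covariance eigendecomposition", {
  set.seed(2)
  X <- matrix(rnorm(8 * 5), 8, 5)
  fit <- fit_dr(dr_spec("PCA", out_dim = 3), X)
  Z <- transform_dr(fit, X)
  ev <- eigen(stats::cov(X), symmetric = TRUE)
  Z_oracle <- scale(X, center = TRUE, scale = FALSE) %*% ev$vectors[, 1:3]
  expect_equal(abs(unname(Z)), abs(unname(Z_oracle)), tolerance = 1e-8)
})

test_that("LDA projection equals the generalized eigenproblem oracle", {
  X <- make_xy(seed = 3, n = 30, p = 5, k = 3)
  y <- factor(rep(1:3, length.out = 30))
  fit <- fit_dr(dr_spec("LDA", out_dim = 2), X, y)
  Z <- transform_dr(fit, X)
  # oracle: eigenvectors of Sw^-1 Sb, normalized so v' Sw v = 1
  p <- ncol(X); k <- nlevels(y); n <- nrow(X)
  mu <- colMeans(X)
  Sw <- matrix(0, p, p); Sb <- matrix(0, p, p)
  for (c in levels(y)) {
    Xi <- X[y == c, , drop = FALSE]
    Sw <- Sw + crossprod(scale(Xi, center = TRUE, scale = FALSE))
    d <- colMeans(Xi) - mu
    Sb <- Sb + nrow(Xi) * tcrossprod(d)
  }
  Sw <- Sw / (n - k)
  V <- Re(eigen(solve(Sw) %*% Sb)$vectors[, 1:2])
  for (j in 1:2) V[, j] <- V[, j] / sqrt(drop(t(V[, j]) %*% Sw %*% V[, j]))
  Z_oracle <- scale(X, center = mu, scale = FALSE) %*% V
  expect_equal(abs(unname(Z)), abs(unname(Z_oracle)), tolerance = 1e-8)
})

test_that("SUP_PCA equals the label-kernel covariance eigendecomposition", {
  X <- make_xy(seed = 4, n = 24, p = 6, k = 2)
  y <- factor(rep(1:2, length.out = 24))
  fit <- fit_dr(dr_spec("SUP_PCA", out_dim = 2), X, y)
  Z <- transform_dr(fit, X)
  # brute force: Q = Xc' H L H Xc with L = Y Y', H the centering matrix
  n <- nrow(X)
  H <- diag(n) - matrix(1 / n, n, n)
  Y <- model.matrix(~ y - 1)
  L <- tcrossprod(Y)
  Xc <- H %*% X
  Q <- t(Xc) %*% H %*% L %*% H %*% Xc
  V <- eigen((Q + t(Q)) / 2, symmetric = TRUE)$vectors[, 1:2]
  Z_oracle <- Xc %*% V
  expect_equal(abs(unname(Z)), abs(unname(Z_oracle)), tolerance = 1e-8)
})

test_that("SUP_PCA's top direction follows the class-mean difference", {
  set.seed(5)
  n <- 400
  mu_diff <- c(3, 0, 0, 0)
  X <- matrix(rnorm(n * 4, sd = 0.5), n, 4)
  y <- rep(c("a", "b"), each = n / 2)
  X[y == "b", 1] <- X[y == "b", 1] + mu_diff[1]
  fit <- fit_dr(dr_spec("SUP_PCA", out_dim = 1), X, y)
  v <- fit$proj[, 1]
  target <- mu_diff / sqrt(sum(mu_diff^2))
  angle <- acos(min(1, abs(sum(v * target)))) * 180 / pi
  expect_lt(angle, 5)
})

test_that("KPCA with a linear kernel reproduces PCA scores up to sign", {
  set.seed(6)
  X <- matrix(rnorm(20 * 6), 20, 6)
  Zk <- transform_dr(fit_dr(dr_spec("KPCA", out_dim = 3, kernel = "linear"), X), X)
  Zp <- transform_dr(fit_dr(dr_spec("PCA", out_dim = 3), X), X)
  expect_equal(abs(unname(Zk)), abs(unname(Zp)), tolerance = 1e-6)
})

test_that("NONE transforms identically and LDA enforces its class bound", {
  ds <- small_dataset()
  fit <- fit_dr(dr_spec("NONE"), ds)
  red <- transform_dr(fit, ds)
  expect_identical(red$features, ds$intensities)
  expect_identical(red$labels, ds$labels)
  # 4-class growth-stage task: 3 dims allowed, 4 rejected
  expect_s3_class(fit_dr(dr_spec("LDA", out_dim = 3), ds, "stage"), "fitted_dr")
  expect_error(fit_dr(dr_spec("LDA", out_dim = 4), ds, "stage"),
               "at most n_classes - 1 = 3")
})

test_that("every DR method yields out_dim finite columns on training data", {
  ds <- small_dataset(seed = 21L, n_strains = 4L, genus_partition = c(2L, 1L, 1L),
                      spectra = 8L, n_channels = 60L)
  for (m in dr_methods()) {
    d <- if (m == "LDA") 3L else 5L
    fit <- fit_dr(dr_spec(m, out_dim = d), ds, "strain")
    Z <- transform_dr(fit, ds)$features
    expect_equal(nrow(Z), nrow(ds$intensities))
    expect_equal(ncol(Z), if (m == "NONE") ncol(ds$intensities) else d)
    expect_true(all(is.finite(Z)), info = m)
  }
})

test_that("supervised methods demand labels; out_dim is capped by channels", {
  ds <- small_dataset()
  expect_error(fit_dr(dr_spec("LDA", out_dim = 2), ds), "supervised")
  expect_error(fit_dr(dr_spec("PCA", out_dim = 1000), ds), "exceeds")
})

test_that("transform_dr validates grids and dimensionality", {
  ds <- small_dataset()
  fit <- fit_dr(dr_spec("PCA", out_dim = 3), ds)
  other <- ds
  other$grid <- ds$grid + 1
  expect_error(transform_dr(fit, other), "grid")
  expect_error(transform_dr(fit, ds$intensities[, 1:10]), "dimensionality")
})

test_that("class_centroid_distance matches hand arithmetic", {
  red <- structure(list(features = matrix(c(0, 0, 3, 4), 2, byrow = TRUE),
                        labels = data.frame(strain = c("a", "b"))),
                   class = "scrs_features")
  expect_equal(class_centroid_distance(red, "strain", "a", "b"), 5)
  red$labels$strain <- c("a", "a")
  expect_equal(class_centroid_distance(red, "strain", "a", "a"), 0)
  expect_error(class_centroid_distance(red, "strain", "a", "zzz"), "not present")
})

test_that("deterministic refits give identical projections (fixed data)", {
  ds <- small_dataset(seed = 22L, n_strains = 4L, genus_partition = c(2L, 1L, 1L),
                      spectra = 6L, n_channels = 50L)
  for (m in c("PCA", "LDA", "SUP_PCA", "ISM_SDR")) {
    d <- if (m == "LDA") 3L else 4L
    f1 <- fit_dr(dr_spec(m, out_dim = d), ds, "strain")
    f2 <- fit_dr(dr_spec(m, out_dim = d), ds, "strain")
    expect_equal(fitted_params(f1), fitted_params(f2), info = m)
  }
})
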