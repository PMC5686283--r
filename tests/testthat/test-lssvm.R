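test_that("the RBF kernel uses the sigma-squared convention", {
  x <- c(1, 2); z <- c(1, 2)
  expect_equal(rbf_kernel(x, z, 1.5), 1)
  # ||x - z||^2 = sigma^2 gives exp(-1)
  expect_equal(rbf_kernel(c(0, 0), c(3, 4), 5), exp(-1), tolerance = 1e-12)
  withr::with_seed(2, {
    for (i in 1:10) {
      a <- rnorm(4); b <- rnorm(4)
      expect_equal(rbf_kernel(a, b, 2), rbf_kernel(b, a, 2),
                   tolerance = 1e-15)
    }
  })
  expect_error(rbf_kernel(1:2, 1:3, 1), "dimension")
  expect_error(rbf_kernel(1:2, 2:3, 0), "positive")
})

test_that("class costs reproduce the benchmark class sizes", {
  y <- c(rep(1, 44), rep(-1, 508))
  v <- class_costs(y)
  expect_equal(unique(v[y == 1]), 552 / 88, tolerance = 1e-12)   # 6.2727
  expect_equal(unique(v[y == -1]), 552 / 1016, tolerance = 1e-12) # 0.5433
  # balanced classes: all unit costs
  expect_equal(class_costs(rep(c(1, -1), 10)), rep(1, 20))
  v2 <- class_costs(y, ratio_multiplier = 2)
  expect_equal(unique(v2[y == 1]), 2 * 552 / 88)
  expect_equal(unique(v2[y == -1]), 552 / 1016)
  expect_error(class_costs(rep(1, 5)), "both classes")
})

test_that("normalization is learned on training data and invertible", {
  tr <- fit_normalization(matrix(c(1, 2, 3, 10, 20, 30), ncol = 2))
  z <- apply_normalization(tr, matrix(c(1, 2, 3, 10, 20, 30), ncol = 2))
  expect_equal(colMeans(z), c(0, 0), tolerance = 1e-12)
  expect_equal(apply(z, 2, sd), c(1, 1), tolerance = 1e-12)
  back <- invert_normalization(tr, z)
  expect_equal(back, matrix(c(1, 2, 3, 10, 20, 30), ncol = 2),
               tolerance = 1e-12)
  # constant column flagged and left finite
  x <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  tr2 <- fit_normalization(x)
  expect_identical(tr2$flagged, "b")
  expect_equal(apply_normalization(tr2, x)[, "b"], rep(0, 3))
})

test_that("a symmetric two-point problem has zero bias and equal weights", {
  X <- rbind(c(1, 0), c(-1, 0))
  m <- lssvm_fit(X, c(1, -1), sigma = 1, gamma = 1, costs = c(1, 1),
                 normalize = FALSE)
  expect_equal(m$b, 0, tolerance = 1e-10)
  expect_equal(m$a[1], m$a[2], tolerance = 1e-10)
  # exact score 0 at the midpoint maps to the majority class -1
  expect_equal(predict(m, rbind(c(0, 0))), -1)
})

test_that("the KKT system is solved to high precision", {
  withr::with_seed(10, {
    X <- matrix(rnorm(30 * 3), ncol = 3)
    y <- rep(c(1, -1), 15)
    m <- lssvm_fit(X, y, sigma = 2, gamma = 5, normalize = FALSE)
    expect_lt(lssvm_kkt_residual(m), 1e-8)
    # the stated equality conditions: y_i f(x_i) = 1 - e_i, e_i = a_i/(g v_i)
    f <- predict(m, X, type = "score")
    e <- m$a / (m$gamma * m$costs)
    expect_equal(y * f, 1 - e, tolerance = 1e-8)
  })
})

test_that("the dual solution matches an independent dense solve", {
  withr::with_seed(11, {
    X <- matrix(rnorm(120 * 4), ncol = 4)
    y <- sample(c(1, -1), 120, replace = TRUE, prob = c(0.2, 0.8))
    v <- class_costs(y)
    m <- lssvm_fit(X, y, sigma = 3, gamma = 2, costs = v, normalize = FALSE)
    # independent construction + generic solver
    K <- exp(-as.matrix(dist(X))^2 / 3^2)
    M <- rbind(c(0, y), cbind(y, (y %o% y) * K + diag(1 / (2 * v))))
    sol <- unname(qr.solve(M, c(0, rep(1, 120))))
    expect_equal(m$b, sol[1], tolerance = 1e-8)
    expect_equal(m$a, sol[-1], tolerance = 1e-8)
  })
})

test_that("large gamma separates separable blobs perfectly", {
  withr::with_seed(12, {
    X <- rbind(matrix(rnorm(40, 3), ncol = 2),
               matrix(rnorm(40, -3), ncol = 2))
    y <- c(rep(1, 20), rep(-1, 20))
    m <- lssvm_fit(X, y, sigma = 3, gamma = 1e6, normalize = TRUE)
    expect_equal(predict(m, X), y)
  })
})

test_that("training-point order does not change predictions", {
  withr::with_seed(13, {
    X <- matrix(rnorm(40 * 2), ncol = 2)
    y <- rep(c(1, -1), 20)
    m1 <- lssvm_fit(X, y, sigma = 1.5, gamma = 3, normalize = FALSE)
    p <- sample(40)
    m2 <- lssvm_fit(X[p, ], y[p], sigma = 1.5, gamma = 3, normalize = FALSE)
    Xt <- matrix(rnorm(10 * 2), ncol = 2)
    expect_equal(predict(m1, Xt, type = "score"),
                 predict(m2, Xt, type = "score"), tolerance = 1e-10)
  })
})

test_that("predictions are invariant to affine rescaling of raw inputs", {
  withr::with_seed(14, {
    X <- matrix(rnorm(60 * 3), ncol = 3)
    y <- rep(c(1, -1), 30)
    Xs <- sweep(sweep(X, 2, c(10, 0.1, 3), "*"), 2, c(-5, 2, 100), "+")
    m1 <- lssvm_fit(X, y, sigma = 2, gamma = 4)
    m2 <- lssvm_fit(Xs, y, sigma = 2, gamma = 4)
    Xt <- matrix(rnorm(8 * 3), ncol = 3)
    Xts <- sweep(sweep(Xt, 2, c(10, 0.1, 3), "*"), 2, c(-5, 2, 100), "+")
    expect_equal(predict(m1, Xt, type = "score"),
                 predict(m2, Xts, type = "score"), tolerance = 1e-8)
  })
})

test_that("gamma -> 0 collapses the support values", {
  withr::with_seed(15, {
    X <- matrix(rnorm(30 * 2), ncol = 2)
    y <- rep(c(1, -1), 15)
    m <- lssvm_fit(X, y, sigma = 2, gamma = 1e-8, normalize = FALSE)
    expect_lt(max(abs(m$a)), 1e-6)
  })
})

test_that("raising the positive cost never lowers training sensitivity", {
  withr::with_seed(16, {
    X <- rbind(matrix(rnorm(10 * 2, 0.8), ncol = 2),
               matrix(rnorm(80 * 2, -0.8), ncol = 2))
    y <- c(rep(1, 10), rep(-1, 80))
    sens <- vapply(c(0.25, 1, 4, 16), function(mult) {
      m <- lssvm_fit(X, y, sigma = 2, gamma = 1,
                     costs = class_costs(y, mult), normalize = FALSE)
      cm <- confusion(y, predict(m, X))
      metric_suite(cm)$sensitivity
    }, numeric(1))
    expect_true(all(diff(sens) >= 0))
  })
})
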