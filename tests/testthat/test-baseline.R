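test_that("PCA loadings are orthonormal and complete", {
  X <- withr::with_seed(1, matrix(rnorm(50 * 6), ncol = 6))
  p <- pca_fit(X)
  expect_equal(unname(crossprod(p$loadings)), diag(6), tolerance = 1e-10)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  # full reconstruction
  sc <- pca_apply(p, X)
  back <- sweep(sc %*% t(p$loadings), 2, p$center, "+")
  expect_equal(unname(back), unname(X), tolerance = 1e-10)
  # training scores are centered
  expect_equal(unname(colMeans(sc)), rep(0, 6), tolerance = 1e-10)
})

test_that("collinear data concentrates variance in one component", {
  t <- seq(0, 1, length.out = 100)
  X <- cbind(t, 3 * t) + withr::with_seed(2, matrix(rnorm(200, sd = 1e-4),
                                                    ncol = 2))
  p <- pca_fit(X)
  expect_gt(p$explained_variance[1] / sum(p$explained_variance), 0.999)
})

test_that("SMOTE output size, geometry, and determinism are exact", {
  X <- withr::with_seed(3, matrix(rnorm(44 * 3), ncol = 3))
  s <- smote(X, amount_pct = 100, k = 5, seed = 7)
  expect_equal(nrow(s), 44L)
  expect_equal(nrow(smote(X, 300, seed = 7)), 132L)
  # every synthetic row lies on a segment between two true minority rows
  on_some_segment <- function(pt) {
    for (j in seq_len(nrow(X) - 1)) {
      for (m in (j + 1):nrow(X)) {
        v <- X[m, ] - X[j, ]
        u <- sum((pt - X[j, ]) * v) / sum(v^2)
        if (u > -1e-9 && u < 1 + 1e-9 &&
            sqrt(sum((X[j, ] + u * v - pt)^2)) < 1e-8) return(TRUE)
      }
    }
    FALSE
  }
  expect_true(all(vapply(seq_len(nrow(s)), function(i) {
    on_some_segment(s[i, ])
  }, logical(1))))
  expect_identical(smote(X, 200, seed = 9), smote(X, 200, seed = 9))
  expect_warning(smote(X[1:4, ], 100, k = 5, seed = 1), "k = 3")
})

test_that("MMDC reduces to nearest mean under identity covariance", {
  withr::with_seed(4, {
    X <- rbind(matrix(rnorm(200, 2), ncol = 2),
               matrix(rnorm(200, -2), ncol = 2))
    y <- c(rep(1, 100), rep(-1, 100))
    m <- mmdc_fit(X, y)
    # spherical data: boundary is the perpendicular bisector
    pts <- matrix(rnorm(40, sd = 4), ncol = 2)
    d_pos <- sqrt(colSums((t(pts) - m$mu_pos)^2))
    d_neg <- sqrt(colSums((t(pts) - m$mu_neg)^2))
    agree <- mean((d_pos < d_neg) == (predict(m, pts) == 1))
    expect_gt(agree, 0.9)
    # a point at a class mean belongs to that class
    expect_equal(predict(m, rbind(m$mu_pos)), 1)
    expect_equal(predict(m, rbind(m$mu_neg)), -1)
  })
})

test_that("MMDC matches the closed-form linear discriminant boundary", {
  withr::with_seed(5, {
    # anisotropic shared covariance
    A <- matrix(c(2, 0.8, 0.8, 0.6), 2)
    X <- rbind(matrix(rnorm(400), ncol = 2) %*% A,
               sweep(matrix(rnorm(400), ncol = 2) %*% A, 2, c(-3, 1), "+"))
    y <- c(rep(1, 200), rep(-1, 200))
    m <- mmdc_fit(X, y, ridge = 0)
    # equal-covariance LDA: w = S^-1 (mu+ - mu-), threshold at midpoint
    w <- m$sigma_inv %*% (m$mu_pos - m$mu_neg)
    c0 <- as.numeric(t(w) %*% (m$mu_pos + m$mu_neg)) / 2
    pts <- matrix(rnorm(100, sd = 3), ncol = 2)
    lda_lab <- ifelse(as.numeric(pts %*% w) - c0 > 0, 1, -1)
    expect_equal(predict(m, pts), lda_lab)
  })
})

test_that("the baseline learner keeps SMOTE inside the training fold", {
  tbl <- toy_feature_table(8, 40, d = 5, effect = 3, seed = 6)
  learner <- mmdc_learner()
  grid <- tibble::tibble(pc_k = 2, smote_amount = 200)
  folds <- outer_folds(tbl$label, seed = 1)
  f <- folds[[1]]
  poisoned <- tbl
  poisoned[f$test, 3:7] <- 1e6
  fit_a <- protocol_fit_fold(tbl, f$train, subset = paste0("f", 1:5),
                             learner = learner, grid = grid,
                             n_inner_repeats = 1, seed = 3)
  fit_b <- protocol_fit_fold(poisoned, f$train, subset = paste0("f", 1:5),
                             learner = learner, grid = grid,
                             n_inner_repeats = 1, seed = 3)
  expect_identical(fit_a$model$mmdc$mu_pos, fit_b$model$mmdc$mu_pos)
  expect_identical(fit_a$model$mmdc$sigma, fit_b$model$mmdc$sigma)
})

test_that("the baseline scheme solves separable data under the protocol", {
  tbl <- toy_feature_table(8, 40, d = 4, effect = 4, seed = 7)
  ev <- run_protocol(tbl, subset = paste0("f", 1:4),
                     learner = mmdc_learner(),
                     grid = tibble::tibble(pc_k = c(2, 3),
                                           smote_amount = c(100, 200)),
                     n_outer_repeats = 2, n_inner_repeats = 1, seed = 11)
  expect_gt(mean(ev$metrics$g_mean), 0.9)
})
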