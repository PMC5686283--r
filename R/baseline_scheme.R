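# Baseline comparator: PCA dimensionality reduction, synthetic minority
# oversampling, and a minimum Mahalanobis distance classifier, run under
# the same nested protocol with {retained PCs, oversampling amount} as
# the tuned grid.

#' Fit a PCA transform on training data
#'
#' Eigendecomposition of the training covariance (via [stats::prcomp()]);
#' loadings are columnwise orthonormal and explained variance is
#' non-increasing. Inputs are expected z-scored upstream.
#'
#' @param x training matrix (n >= 2 rows).
#' @return An object of class `fhr_pca`: `loadings` (features x k),
#'   `center`, `explained_variance`.
#' @export
pca_fit <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop_fhr("need at least 2 rows for PCA")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  structure(
    list(loadings = p$rotation, center = p$center,
         explained_variance = p$sdev^2),
    class = "fhr_pca"
  )
}

#' Project data onto a fitted PCA
#'
#' @param transform an `fhr_pca`.
#' @param x matrix of rows to project.
#' @param k number of leading components to retain (default all).
#' @return Score matrix (n x k).
#' @export
pca_apply <- function(transform, x, k = ncol(transform$loadings)) {
  x <- as.matrix(x)
  k <- min(k, ncol(transform$loadings))
  sweep(x, 2, transform$center) %*% transform$loadings[, seq_len(k),
                                                       drop = FALSE]
}

#' Synthetic minority oversampling (SMOTE)
#'
#' For each minority point, `amount_pct / 100` times: pick a random one
#' of its `k` nearest minority neighbors (Euclidean) and emit
#' `point + u (neighbor - point)` with `u ~ Uniform(0, 1)`. The output
#' size is exactly `floor(amount_pct / 100) * nrow(x_min)`. When the
#' minority class is no larger than `k`, `k` is reduced with a warning.
#'
#' @param x_min minority-class matrix.
#' @param amount_pct oversampling amount, a multiple of 100.
#' @param k neighbor count.
#' @param seed RNG seed.
#' @return Matrix of synthetic minority rows.
#' @export
smote <- function(x_min, amount_pct = 100, k = 5, seed = 1) {
  x_min <- as.matrix(x_min)
  n <- nrow(x_min)
  if (n < 2L) stop_fhr("need at least 2 minority samples for SMOTE")
  if (amount_pct < 100) return(x_min[0, , drop = FALSE])
  if (n <= k) {
    rlang::warn(sprintf("minority size %d <= k = %d; using k = %d",
                        n, k, n - 1L))
    k <- n - 1L
  }
  dup <- floor(amount_pct / 100)
  d <- as.matrix(stats::dist(x_min))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  with_seed(seed, {
    out <- matrix(NA_real_, nrow = dup * n, ncol = ncol(x_min))
    row <- 0L
    for (i in seq_len(n)) {
      for (j in seq_len(dup)) {
        nb <- nn[i, sample.int(k, 1L)]
        u <- stats::runif(1)
        row <- row + 1L
        out[row, ] <- x_min[i, ] + u * (x_min[nb, ] - x_min[i, ])
      }
    }
    colnames(out) <- colnames(x_min)
    out
  })
}

#' Fit a minimum Mahalanobis distance classifier
#'
#' Class means and a pooled within-class covariance; prediction assigns
#' the class whose mean is nearer in Mahalanobis distance under the
#' pooled covariance (a linear boundary for the two-class case). A small
#' ridge `ridge * trace / dim` is added for invertibility.
#'
#' @param x score matrix (e.g. PCA scores).
#' @param y labels +1 / -1 (both classes present).
#' @param ridge relative ridge added to the pooled covariance.
#' @return An object of class `fhr_mmdc`.
#' @export
mmdc_fit <- function(x, y, ridge = 1e-6) {
  x <- as.matrix(x)
  if (!all(y %in% c(-1, 1)) || length(unique(y)) < 2L) {
    stop_fhr("both classes must be present")
  }
  mu_pos <- colMeans(x[y == 1, , drop = FALSE])
  mu_neg <- colMeans(x[y == -1, , drop = FALSE])
  center <- function(m, mu) sweep(m, 2, mu)
  sp <- crossprod(center(x[y == 1, , drop = FALSE], mu_pos)) +
    crossprod(center(x[y == -1, , drop = FALSE], mu_neg))
  sigma <- sp / (nrow(x) - 2)
  d <- ncol(x)
  sigma <- sigma + diag(ridge * sum(diag(sigma)) / d, d)
  sigma_inv <- tryCatch(solve(sigma), error = function(e) {
    stop_fhr("pooled covariance singular even after ridge",
             class = "fhrbench_numeric_error")
  })
  structure(
    list(mu_pos = mu_pos, mu_neg = mu_neg, sigma = sigma,
         sigma_inv = sigma_inv, ridge = ridge),
    class = "fhr_mmdc"
  )
}

#' Predict with a minimum Mahalanobis distance classifier
#'
#' @param object an `fhr_mmdc`.
#' @param newdata score matrix.
#' @param ... unused.
#' @return Vector of +1 / -1 labels; exact ties go to -1.
#' @export
predict.fhr_mmdc <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  maha <- function(mu) {
    dx <- sweep(newdata, 2, mu)
    rowSums((dx %*% object$sigma_inv) * dx)
  }
  d_pos <- maha(object$mu_pos)
  d_neg <- maha(object$mu_neg)
  ifelse(d_pos < d_neg, 1, -1)
}

#' PCA + SMOTE + MMDC learner for the protocol
#'
#' The baseline classification scheme: PCA fitted on the (normalized)
#' training fold, SMOTE applied to the minority class in PC space
#' (training rows only), and an MMDC on the augmented scores. Tuned over
#' `pc_k` (retained components) and `smote_amount` (percent).
#'
#' @param grid data frame with columns `pc_k`, `smote_amount`; `NULL`
#'   for the default grid (`pc_k` 2-54 capped, amounts 100-500%).
#' @param k_neighbors SMOTE neighbor count.
#' @return A learner object usable by [run_protocol()].
#' @export
mmdc_learner <- function(grid = NULL, k_neighbors = 5) {
  if (is.null(grid)) {
    grid <- expand.grid(pc_k = c(2, 3, 5, 10, 20, 54),
                        smote_amount = c(100, 200, 300, 400, 500))
  }
  list(
    name = "pca_smote_mmdc",
    grid = tibble::as_tibble(grid),
    fit = function(x, y, params, seed) {
      k <- min(params$pc_k, ncol(x), nrow(x) - 1L)
      pca <- pca_fit(x)
      sc <- pca_apply(pca, x, k = k)
      x_min <- sc[y == 1, , drop = FALSE]
      synth <- if (nrow(x_min) >= 2L && params$smote_amount >= 100) {
        smote(x_min, params$smote_amount,
              k = min(k_neighbors, nrow(x_min) - 1L), seed = seed)
      } else x_min[0, , drop = FALSE]
      sc_aug <- rbind(sc, synth)
      y_aug <- c(y, rep(1, nrow(synth)))
      model <- mmdc_fit(sc_aug, y_aug)
      list(pca = pca, k = k, mmdc = model)
    },
    predict = function(model, x) {
      predict(model$mmdc, pca_apply(model$pca, x, k = model$k))
    }
  )
}
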