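# Weighted least-squares support vector machine with RBF kernel, trained
# by solving the dual KKT linear system. Every training point is retained
# as a support vector; class imbalance is handled by per-sample error
# costs.

#' RBF kernel
#'
#' `K(x, z) = exp(-||x - z||^2 / sigma^2)` — note the `sigma^2`
#' denominator (no factor 2), matching the LS-SVM convention used by this
#' benchmark.
#'
#' @param x,z numeric vectors of equal length.
#' @param sigma kernel spread (> 0).
#' @return Kernel value in `(0, 1]`.
#' @export
rbf_kernel <- function(x, z, sigma) {
  if (length(x) != length(z)) stop_fhr("dimension mismatch")
  if (sigma <= 0) stop_fhr("`sigma` must be positive")
  exp(-sum((x - z)^2) / sigma^2)
}

# full kernel matrix between rows of A and rows of B
rbf_kernel_matrix <- function(A, B, sigma) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-d2 / sigma^2)
}

#' Per-sample class costs for imbalance compensation
#'
#' Baseline costs `N / (2 N_p)` for positives and `N / (2 N_N)` for
#' negatives, so a balanced problem gets unit costs; the positive-class
#' cost is additionally multiplied by `ratio_multiplier`, the tuned
#' imbalance factor.
#'
#' @param labels vector of +1 / -1 labels (both classes present).
#' @param ratio_multiplier multiplier on the positive-class cost.
#' @return Numeric cost per training sample.
#' @export
class_costs <- function(labels, ratio_multiplier = 1) {
  if (!all(labels %in% c(-1, 1))) stop_fhr("labels must be +1 or -1")
  n <- length(labels)
  np <- sum(labels == 1)
  nn <- sum(labels == -1)
  if (np == 0L || nn == 0L) stop_fhr("both classes must be present")
  ifelse(labels == 1, ratio_multiplier * n / (2 * np), n / (2 * nn))
}

#' Fit the per-feature z-score transform on training data
#'
#' @param x numeric matrix or data frame (training rows only).
#' @return List `center`, `scale`, `flagged` (features whose SD was zero;
#'   their scale is replaced by 1).
#' @export
fit_normalization <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop_fhr("need at least 2 rows to fit normalization")
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  flagged <- names(scale)[scale == 0 | !is.finite(scale)]
  scale[scale == 0 | !is.finite(scale)] <- 1
  list(center = center, scale = scale, flagged = flagged)
}

#' Apply a stored z-score transform
#'
#' @param transform result of [fit_normalization()].
#' @param x matrix or data frame to transform (training or test rows).
#' @return Transformed matrix.
#' @export
apply_normalization <- function(transform, x) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, transform$center), 2, transform$scale, "/")
}

#' Invert a stored z-score transform
#'
#' @inheritParams apply_normalization
#' @return Matrix on the original scale.
#' @export
invert_normalization <- function(transform, x) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, transform$scale, "*"), 2, transform$center, "+")
}

#' Fit a weighted least-squares SVM
#'
#' Solves the dual KKT system of the cost-weighted LS-SVM objective
#' `min 1/2 w'w + gamma/2 sum v_i e_i^2` s.t.
#' `y_i (w' phi(x_i) + b) = 1 - e_i`:
#' \deqn{\begin{bmatrix} 0 & y^T \\ y & \Omega + diag(1/(\gamma v)) \end{bmatrix}
#'       \begin{bmatrix} b \\ a \end{bmatrix} =
#'       \begin{bmatrix} 0 \\ 1 \end{bmatrix}}
#' with `Omega_ij = y_i y_j K(x_i, x_j)`. A dense solve is used, with a
#' least-squares fallback when the system is ill-conditioned (the
#' reciprocal condition estimate is kept on the model).
#'
#' Inputs are z-scored internally: the transform is learned here from the
#' training rows and stored on the model, and applied to any prediction
#' input, so raw feature tables can be passed straight in.
#'
#' @param x training feature matrix / data frame (raw scale).
#' @param y labels, +1 / -1.
#' @param sigma RBF spread (on the normalized scale).
#' @param gamma regularization weight (> 0).
#' @param costs per-sample costs; defaults to [class_costs()] of `y`.
#' @param normalize fit and store a z-score transform (set `FALSE` if `x`
#'   is already normalized upstream).
#' @return An object of class `fhr_lssvm`: support values `a`, bias `b`,
#'   kernel/regularization parameters, costs, the stored normalization
#'   and training inputs.
#' @export
lssvm_fit <- function(x, y, sigma, gamma, costs = NULL, normalize = TRUE) {
  x <- as.matrix(x)
  if (anyNA(x)) stop_fhr("missing values in training inputs")
  if (length(y) != nrow(x)) stop_fhr("x / y length mismatch")
  if (!all(y %in% c(-1, 1))) stop_fhr("labels must be +1 or -1")
  if (sigma <= 0 || gamma <= 0) stop_fhr("sigma and gamma must be positive")
  if (is.null(costs)) costs <- class_costs(y)
  if (any(costs <= 0)) stop_fhr("costs must be positive")
  transform <- if (normalize) fit_normalization(x) else NULL
  xn <- if (normalize) apply_normalization(transform, x) else x
  n <- nrow(xn)
  K <- rbf_kernel_matrix(xn, xn, sigma)
  Omega <- (y %o% y) * K
  M <- rbind(c(0, y), cbind(y, Omega + diag(1 / (gamma * costs), n)))
  rhs <- c(0, rep(1, n))
  rc <- rcond(M)
  sol <- if (rc > 1e-14) {
    solve(M, rhs)
  } else {
    qr.solve(qr(M, LAPACK = TRUE), rhs)
  }
  sol <- unname(sol)
  structure(
    list(a = sol[-1], b = sol[1], sigma = sigma, gamma = gamma,
         costs = costs, y = y, x = xn, transform = transform,
         rcond = rc),
    class = "fhr_lssvm"
  )
}

#' @export
print.fhr_lssvm <- function(x, ...) {
  cat(sprintf(
    "<fhr_lssvm>  n = %d, d = %d | sigma %.4g, gamma %.4g | bias %.4g\n",
    nrow(x$x), ncol(x$x), x$sigma, x$gamma, x$b))
  invisible(x)
}

#' Predict with a fitted LS-SVM
#'
#' Score = `sum_i a_i y_i K(x_i, x) + b` on the stored normalized scale;
#' label = sign(score) with the tie `score == 0` mapped to `-1`
#' (conservative toward the majority/normal class).
#'
#' @param object an `fhr_lssvm`.
#' @param newdata matrix / data frame of raw-scale rows.
#' @param type `"label"` or `"score"`.
#' @param ... unused.
#' @return Numeric vector of labels or scores.
#' @export
predict.fhr_lssvm <- function(object, newdata, type = c("label", "score"),
                              ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$x)) stop_fhr("dimension mismatch")
  xn <- if (!is.null(object$transform)) {
    apply_normalization(object$transform, newdata)
  } else newdata
  K <- rbf_kernel_matrix(xn, object$x, object$sigma)
  score <- as.numeric(K %*% (object$a * object$y)) + object$b
  if (type == "score") score else ifelse(score > 0, 1, -1)
}

#' KKT residual of a fitted LS-SVM
#'
#' Maximum absolute residual of the dual system at the stored solution;
#' a direct check that the stationarity/equality conditions hold.
#'
#' @param model an `fhr_lssvm`.
#' @return Scalar residual (should be ~1e-8 or below).
#' @export
lssvm_kkt_residual <- function(model) {
  n <- nrow(model$x)
  K <- rbf_kernel_matrix(model$x, model$x, model$sigma)
  Omega <- (model$y %o% model$y) * K
  M <- rbind(c(0, model$y),
             cbind(model$y, Omega + diag(1 / (model$gamma * model$costs), n)))
  max(abs(M %*% c(model$b, model$a) - c(0, rep(1, n))))
}

#' @export
tidy.fhr_lssvm <- function(x, ...) {
  tibble::tibble(
    sample = seq_along(x$a),
    label = x$y,
    support_value = x$a,
    cost = x$costs,
    error = x$a / (x$gamma * x$costs)
  )
}

#' @export
glance.fhr_lssvm <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$x), n_features = ncol(x$x),
    sigma = x$sigma, gamma = x$gamma, bias = x$b, rcond = x$rcond
  )
}
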