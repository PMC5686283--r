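# Confusion-matrix bookkeeping, imbalance-robust metrics, and the nested
# stratified cross-validation protocol (outer loop for performance
# estimation, inner loop for parameter tuning).

#' Confusion matrix of binary +1/-1 predictions
#'
#' @param y_true,y_pred equal-length vectors of +1 / -1 labels.
#' @return An object of class `fhr_confusion`: named list `tp`, `fn`,
#'   `fp`, `tn`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop_fhr("empty input")
  if (length(y_true) != length(y_pred)) stop_fhr("length mismatch")
  if (!all(c(y_true, y_pred) %in% c(-1, 1))) {
    stop_fhr("labels must be +1 or -1")
  }
  structure(
    list(tp = sum(y_true == 1 & y_pred == 1),
         fn = sum(y_true == 1 & y_pred == -1),
         fp = sum(y_true == -1 & y_pred == 1),
         tn = sum(y_true == -1 & y_pred == -1)),
    class = "fhr_confusion"
  )
}

#' Sum confusion matrices entrywise
#'
#' @param cms list of `fhr_confusion` objects.
#' @return An `fhr_confusion`.
#' @export
confusion_sum <- function(cms) {
  structure(
    list(tp = sum(vapply(cms, `[[`, 0, "tp")),
         fn = sum(vapply(cms, `[[`, 0, "fn")),
         fp = sum(vapply(cms, `[[`, 0, "fp")),
         tn = sum(vapply(cms, `[[`, 0, "tn"))),
    class = "fhr_confusion"
  )
}

#' @export
print.fhr_confusion <- function(x, ...) {
  cat(sprintf("<fhr_confusion>  TP %d  FN %d | FP %d  TN %d\n",
              x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Imbalance-robust metric suite of a confusion matrix
#'
#' Computes accuracy, sensitivity (TP rate / recall), specificity (TN
#' rate), precision (PPV), the balanced error rate, geometric mean,
#' F-measure, and Matthews correlation coefficient. Two BER variants are
#' reported: `ber` is the conventional
#' `1/2 (FN/(TP+FN) + FP/(TN+FP)) = 1 - (sens + spec)/2`, which drives
#' tuning; `ber_printed` pairs FP with (FN+TP) and FN with (FP+TN), a
#' variant that circulates in the benchmark literature and is kept for
#' comparability. Metrics with a zero denominator are returned as `NA`.
#'
#' @param cm an `fhr_confusion` (or list with `tp`, `fn`, `fp`, `tn`).
#' @return A named list of metrics; also `one_minus_ber`.
#' @export
metric_suite <- function(cm) {
  tp <- cm$tp; fn <- cm$fn; fp <- cm$fp; tn <- cm$tn
  total <- tp + fn + fp + tn
  if (total <= 0) stop_fhr("confusion matrix is empty")
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  ppv <- safe_div(tp, tp + fp)
  ber <- if (is.na(sens) || is.na(spec)) NA_real_ else
    0.5 * ((1 - sens) + (1 - spec))
  ber_printed <- if ((fn + tp) > 0 && (fp + tn) > 0) {
    0.5 * (fp / (fn + tp) + fn / (fp + tn))
  } else NA_real_
  g_mean <- if (is.na(sens) || is.na(spec)) NA_real_ else sqrt(sens * spec)
  f_measure <- if (is.na(sens) || is.na(ppv) || (sens + ppv) == 0) {
    NA_real_
  } else 2 * ppv * sens / (ppv + sens)
  mcc_den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mcc_den > 0) {
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(mcc_den)
  } else NA_real_
  list(accuracy = (tp + tn) / total,
       sensitivity = sens, specificity = spec, ppv = ppv,
       ber = ber, ber_printed = ber_printed,
       one_minus_ber = if (is.na(ber)) NA_real_ else 1 - ber,
       g_mean = g_mean, f_measure = f_measure, mcc = mcc)
}

# criterion accessor: value to MAXIMIZE
criterion_value <- function(metrics, criterion) {
  switch(criterion,
         ber = if (is.na(metrics$ber)) -Inf else -metrics$ber,
         gmean = if (is.na(metrics$g_mean)) -Inf else metrics$g_mean,
         fmeasure = if (is.na(metrics$f_measure)) -Inf else
           metrics$f_measure,
         mcc = if (is.na(metrics$mcc)) -Inf else metrics$mcc,
         stop_fhr("criterion must be ber, gmean, fmeasure, or mcc"))
}

#' Stratified outer folds for an imbalanced label vector
#'
#' One fold per abnormal (+1) record: each test set holds exactly one
#' abnormal plus an (almost) equal share of the normals — with 508
#' normals over 44 folds, 24 folds of 12 and 20 of 11. Every record is
#' tested exactly once; assignment is shuffled by `seed`.
#'
#' @param labels vector of +1 / -1 labels (>= 2 abnormal).
#' @param seed RNG seed.
#' @return List of folds, each a list with `train` and `test` index
#'   vectors.
#' @export
outer_folds <- function(labels, seed = 1) {
  pos <- which(labels == 1)
  neg <- which(labels == -1)
  k <- length(pos)
  if (k < 2L || length(neg) < k) {
    stop_fhr("degenerate class sizes for stratified folding")
  }
  with_seed(seed, {
    pos <- sample(pos)
    neg <- sample(neg)
    sizes <- rep(length(neg) %/% k, k)
    extra <- length(neg) %% k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    stops <- cumsum(sizes)
    starts <- stops - sizes + 1L
    lapply(seq_len(k), function(i) {
      test <- c(pos[i], neg[starts[i]:stops[i]])
      list(train = setdiff(seq_along(labels), test), test = test)
    })
  })
}

#' Inner-fold plan with non-repeating normal companions
#'
#' Builds `n_repeats` stratified fold assignments (one abnormal per
#' fold). Abnormals and normals are shuffled once by `seed`; in repeat
#' `r` the normal ordering is rotated by `r` times the maximal fold
#' share, so each abnormal's normal companions are disjoint across
#' repeats whenever that is feasible (`n_repeats * ceil(n_neg / k) <=
#' n_neg`). When infeasible the rotation still maximally decorrelates
#' the pairings and a warning is raised.
#'
#' @param labels +1 / -1 label vector.
#' @param n_repeats number of fold assignments.
#' @param seed RNG seed.
#' @return List of length `n_repeats`; each element a list of folds as
#'   in [outer_folds()].
#' @export
inner_fold_plan <- function(labels, n_repeats, seed = 1) {
  pos <- which(labels == 1)
  neg <- which(labels == -1)
  k <- length(pos)
  if (k < 2L || length(neg) < k) {
    stop_fhr("degenerate class sizes for stratified folding")
  }
  sizes <- rep(length(neg) %/% k, k)
  extra <- length(neg) %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  s_max <- max(sizes)
  if (n_repeats * s_max > length(neg)) {
    rlang::warn("companion-repeat constraint infeasible at this size")
  }
  stops <- cumsum(sizes)
  starts <- stops - sizes + 1L
  with_seed(seed, {
    pos <- sample(pos)
    neg <- sample(neg)
    lapply(seq_len(n_repeats) - 1L, function(r) {
      rot <- (r * s_max) %% length(neg)
      neg_r <- if (rot == 0L) neg
               else c(neg[-seq_len(rot)], neg[seq_len(rot)])
      lapply(seq_len(k), function(i) {
        test <- c(pos[i], neg_r[starts[i]:stops[i]])
        list(train = setdiff(seq_along(labels), test), test = test)
      })
    })
  })
}

#' Tune learner parameters by repeated inner cross-validation
#'
#' For each grid row, the tuning criterion is computed on the aggregated
#' confusion matrix of a stratified inner cross-validation (one fold per
#' abnormal training case), repeated `n_repeats` times with reshuffled
#' normals constrained so that no abnormal case is ever matched with the
#' same normal companions twice across the repeats; the mean over repeats
#' is the grid score. The best row is returned (argmin for `ber`,
#' argmax otherwise; ties go to the first row in grid order).
#'
#' @param x normalized training feature matrix.
#' @param y training labels +1 / -1.
#' @param grid data frame of parameter rows for the learner.
#' @param learner a learner object, e.g. [lssvm_learner()].
#' @param criterion `"ber"`, `"gmean"`, `"fmeasure"`, or `"mcc"`.
#' @param n_repeats inner repetitions.
#' @param seed RNG seed.
#' @return List `params` (the chosen grid row), `scores` (per-row mean
#'   criterion as maximized).
#' @export
inner_tune <- function(x, y, grid, learner, criterion = "gmean",
                       n_repeats = 5, seed = 1) {
  if (nrow(grid) == 0L) stop_fhr("empty tuning grid")
  x <- as.matrix(x)
  scores <- matrix(NA_real_, nrow = nrow(grid), ncol = n_repeats)
  plan <- inner_fold_plan(y, n_repeats, seed)
  for (rep_i in seq_len(n_repeats)) {
    folds <- plan[[rep_i]]
    for (g in seq_len(nrow(grid))) {
      cms <- lapply(folds, function(f) {
        model <- learner$fit(x[f$train, , drop = FALSE], y[f$train],
                             grid[g, , drop = FALSE],
                             seed = derive_seed(seed, 1000 + rep_i))
        confusion(y[f$test],
                  learner$predict(model, x[f$test, , drop = FALSE]))
      })
      scores[g, rep_i] <-
        criterion_value(metric_suite(confusion_sum(cms)), criterion)
    }
  }
  mean_scores <- rowMeans(scores)
  best <- which.max(mean_scores) # ties: first in grid order
  list(params = grid[best, , drop = FALSE], scores = mean_scores)
}

#' LS-SVM learner for the protocol
#'
#' Wraps [lssvm_fit()] for use inside the cross-validation protocol. The
#' kernel spread is parameterized relative to the median pairwise
#' distance of the training inputs (`sigma = sigma_rel * median dist`),
#' the usual scale-free heuristic. The default grid spans
#' `sigma_rel = 2^-3..2^6`, `gamma = 2^-6..2^10` (powers of 4), and
#' imbalance multipliers 0.25-4.
#'
#' @param grid data frame with columns `sigma_rel`, `gamma`, `ratio`;
#'   `NULL` for the default grid.
#' @return A learner object (list with `name`, `grid`, `fit`, `predict`).
#' @export
lssvm_learner <- function(grid = NULL) {
  if (is.null(grid)) {
    grid <- expand.grid(sigma_rel = 2^seq(-3, 6, by = 1.5),
                        gamma = 2^seq(-6, 10, by = 2),
                        ratio = c(0.25, 0.5, 1, 2, 4))
  }
  list(
    name = "lssvm",
    grid = tibble::as_tibble(grid),
    fit = function(x, y, params, seed) {
      med <- median_pairwise_dist(x)
      lssvm_fit(x, y,
                sigma = params$sigma_rel * max(med, 1e-8),
                gamma = params$gamma,
                costs = class_costs(y, params$ratio),
                normalize = FALSE)
    },
    predict = function(model, x) predict(model, x, type = "label")
  )
}

median_pairwise_dist <- function(x, max_n = 200L) {
  x <- as.matrix(x)
  if (nrow(x) > max_n) x <- x[seq_len(max_n), , drop = FALSE]
  stats::median(stats::dist(x))
}

#' Run the nested cross-validation protocol
#'
#' Per outer repetition: stratified outer folds (one abnormal per test
#' fold), and per fold — z-score normalization fitted on the training
#' rows only, feature-subset choice (the pinned benchmark subsets or
#' fully nested ranking on training data), inner tuning via
#' [inner_tune()], a final fit on the whole training fold, and prediction
#' of the held-out fold. Confusions are aggregated per repetition and the
#' metric suite is reported per repetition with mean and SD across
#' repetitions.
#'
#' @param features feature table (`record_id`, `label`, features).
#' @param subset number of features (3, 9, or all) or an explicit
#'   character vector of feature names.
#' @param learner learner object; [lssvm_learner()] by default.
#' @param grid tuning grid; defaults to the learner's grid.
#' @param criterion tuning criterion, also highlighted in the report.
#' @param n_outer_repeats outer repetitions (benchmark uses 15).
#' @param n_inner_repeats inner repetitions (benchmark uses 5).
#' @param feature_selection `"pinned"` (benchmark subsets, the default)
#'   or `"nested"` (rank on each outer training fold).
#' @param ranking_repeats leave-out repeats when `feature_selection =
#'   "nested"`.
#' @param seed master seed; per-repeat and per-fold seeds are derived
#'   deterministically.
#' @return An object of class `fhr_eval`; see [tidy.fhr_eval()] /
#'   [glance.fhr_eval()].
#' @export
run_protocol <- function(features, subset = 3, learner = lssvm_learner(),
                         grid = learner$grid, criterion = "gmean",
                         n_outer_repeats = 15, n_inner_repeats = 5,
                         feature_selection = c("pinned", "nested"),
                         ranking_repeats = 20, seed = 1) {
  check_feature_table(features)
  feature_selection <- match.arg(feature_selection)
  y <- features$label
  per_repeat <- vector("list", n_outer_repeats)
  chosen_params <- list()
  for (r in seq_len(n_outer_repeats)) {
    folds <- outer_folds(y, derive_seed(seed, r))
    cms <- lapply(seq_along(folds), function(fi) {
      f <- folds[[fi]]
      fit <- protocol_fit_fold(
        features, f$train, subset = subset, learner = learner,
        grid = grid, criterion = criterion,
        n_inner_repeats = n_inner_repeats,
        feature_selection = feature_selection,
        ranking_repeats = ranking_repeats,
        seed = derive_seed(seed, r * 1000 + fi))
      xt <- apply_normalization(
        fit$transform, as.matrix(features[f$test, fit$features]))
      confusion(y[f$test], learner$predict(fit$model, xt))
    })
    per_repeat[[r]] <- confusion_sum(cms)
    chosen_params[[r]] <- NULL
  }
  metrics <- dplyr::bind_rows(lapply(per_repeat, function(cm) {
    tibble::as_tibble(metric_suite(cm))
  }))
  metrics$repeat_id <- seq_len(n_outer_repeats)
  structure(
    list(per_repeat = per_repeat,
         aggregated = confusion_sum(per_repeat),
         metrics = metrics,
         criterion = criterion,
         subset = subset,
         learner = learner$name,
         n_outer_repeats = n_outer_repeats,
         n_inner_repeats = n_inner_repeats,
         seed = seed),
    class = "fhr_eval"
  )
}

#' Fit one outer training fold (normalization, subset, tuning, final fit)
#'
#' The per-fold training pipeline used by [run_protocol()], exposed so
#' the no-leakage contract can be verified directly: it sees only the
#' training rows it is given.
#'
#' @inheritParams run_protocol
#' @param train_idx row indices of the outer training fold.
#' @param seed fold seed.
#' @return List `model`, `transform`, `features` (selected names),
#'   `params` (tuned grid row).
#' @export
protocol_fit_fold <- function(features, train_idx, subset = 3,
                              learner = lssvm_learner(),
                              grid = learner$grid, criterion = "gmean",
                              n_inner_repeats = 5,
                              feature_selection = "pinned",
                              ranking_repeats = 20, seed = 1) {
  y <- features$label[train_idx]
  all_feats <- setdiff(names(features), c("record_id", "label"))
  sel <- if (is.character(subset)) {
    subset
  } else if (feature_selection == "pinned" &&
             all(paper_subset_ok(subset, all_feats))) {
    paper_subset(subset)
  } else if (as.integer(subset) >= length(all_feats)) {
    all_feats
  } else {
    rk <- rank_features(features[train_idx, ],
                        n_repeats = ranking_repeats,
                        seed = derive_seed(seed, 7))
    select_subset(rk, subset)
  }
  xtr_raw <- as.matrix(features[train_idx, sel])
  transform <- fit_normalization(xtr_raw)
  xtr <- apply_normalization(transform, xtr_raw)
  tuned <- inner_tune(xtr, y, grid, learner, criterion = criterion,
                      n_repeats = n_inner_repeats,
                      seed = derive_seed(seed, 11))
  model <- learner$fit(xtr, y, tuned$params,
                       seed = derive_seed(seed, 13))
  list(model = model, transform = transform, features = sel,
       params = tuned$params)
}

paper_subset_ok <- function(k, available) {
  if (!is.numeric(k)) return(FALSE)
  if (k >= length(available)) return(TRUE)
  sub <- tryCatch(paper_subset(k), error = function(e) NULL)
  !is.null(sub) && all(sub %in% available)
}

#' @export
print.fhr_eval <- function(x, ...) {
  cat(sprintf(
    "<fhr_eval>  %s | subset %s | criterion %s | %d x outer CV\n",
    x$learner, paste(x$subset, collapse = ","), x$criterion,
    x$n_outer_repeats))
  g <- glance(x)
  cat(sprintf(
    "  mean 1-BER %.4f | g-mean %.4f | F %.4f | MCC %.4f | sens %.4f | spec %.4f\n",
    g$one_minus_ber, g$g_mean, g$f_measure, g$mcc, g$sensitivity,
    g$specificity))
  invisible(x)
}

#' Per-repetition metrics of a protocol run
#'
#' @param x an `fhr_eval`.
#' @param ... unused.
#' @return Tibble with one row per outer repetition.
#' @export
tidy.fhr_eval <- function(x, ...) {
  dplyr::relocate(x$metrics, "repeat_id")
}

#' Mean metrics of a protocol run
#'
#' @param x an `fhr_eval`.
#' @param ... unused.
#' @return One-row tibble of metric means over repetitions (NA-removed).
#' @export
glance.fhr_eval <- function(x, ...) {
  m <- x$metrics[setdiff(names(x$metrics), "repeat_id")]
  out <- tibble::as_tibble(lapply(m, mean, na.rm = TRUE))
  out$n_outer_repeats <- x$n_outer_repeats
  out$criterion <- x$criterion
  out
}

#' Plot metric distributions across outer repetitions
#'
#' @param object an `fhr_eval`.
#' @param metrics which metric columns to show.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.fhr_eval <- function(object,
                              metrics = c("one_minus_ber", "g_mean",
                                          "f_measure", "mcc"), ...) {
  d <- tidyr::pivot_longer(tidy(object), dplyr::all_of(metrics),
                           names_to = "metric")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "value",
                  title = sprintf("Protocol metrics (%d repetitions)",
                                  object$n_outer_repeats)) +
    ggplot2::theme_minimal()
}
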