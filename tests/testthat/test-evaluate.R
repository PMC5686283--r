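test_that("confusion matrices tally and swap correctly", {
  y <- c(rep(1, 5), rep(-1, 7))
  cm <- confusion(y, y)
  expect_equal(unlist(cm[c("tp", "fn", "fp", "tn")]),
               c(tp = 5, fn = 0, fp = 0, tn = 7))
  cm_inv <- confusion(y, -y)
  expect_equal(cm_inv$fn, cm$tp)
  expect_equal(cm_inv$fp, cm$tn)
  expect_error(confusion(integer(0), integer(0)), "empty")
  expect_error(confusion(c(1, -1), c(1, -1, 1)), "length")
})

test_that("the all-negative classifier accuracy is the exact quotient", {
  cm <- list(tp = 0, fn = 44, fp = 0, tn = 508)
  m <- metric_suite(cm)
  expect_identical(m$accuracy, 508 / 552)
  expect_identical(m$sensitivity, 0)
  expect_identical(m$specificity, 1)
  expect_true(is.na(m$ppv)) # no positive predictions
  expect_equal(m$g_mean, 0)
})

test_that("a perfect classifier maxes every metric", {
  m <- metric_suite(list(tp = 10, fn = 0, fp = 0, tn = 90))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$g_mean, 1)
  expect_equal(m$mcc, 1)
  expect_equal(m$ber, 0)
  expect_equal(m$one_minus_ber, 1)
  expect_equal(m$f_measure, 1)
})

test_that("metric formulas match independent arithmetic", {
  tp <- 30; fn <- 14; fp <- 113; tn <- 395
  m <- metric_suite(list(tp = tp, fn = fn, fp = fp, tn = tn))
  expect_equal(m$mcc,
               (tp * tn - fp * fn) /
                 sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)),
               tolerance = 1e-14)
  expect_equal(m$g_mean, sqrt((tp / (tp + fn)) * (tn / (tn + fp))),
               tolerance = 1e-14)
  expect_equal(m$ber_printed, 0.5 * (fp / (fn + tp) + fn / (fp + tn)),
               tolerance = 1e-14)
  expect_equal(m$ber, 1 - (m$sensitivity + m$specificity) / 2,
               tolerance = 1e-14)
})

test_that("the suite matches recomputation on random confusion matrices", {
  withr::with_seed(55, {
    for (i in 1:1000) {
      cm <- as.list(setNames(rpois(4, lambda = sample(c(2, 20, 200), 4,
                                                      TRUE)),
                             c("tp", "fn", "fp", "tn")))
      if (sum(unlist(cm)) == 0) next
      m <- metric_suite(cm)
      with(cm, {
        expect_equal(m$accuracy, (tp + tn) / (tp + fn + fp + tn))
        if (tp + fn > 0) expect_equal(m$sensitivity, tp / (tp + fn))
        if (tn + fp > 0) expect_equal(m$specificity, tn / (tn + fp))
        if (tp + fp > 0) expect_equal(m$ppv, tp / (tp + fp))
        if (tp + fn > 0 && tn + fp > 0) {
          expect_equal(m$one_minus_ber,
                       (tp / (tp + fn) + tn / (tn + fp)) / 2)
        }
      })
    }
  })
})

test_that("outer folds reproduce the 1-abnormal + 12-or-11-normal rule", {
  labels <- c(rep(1, 44), rep(-1, 508))
  folds <- outer_folds(labels, seed = 3)
  expect_length(folds, 44L)
  n_norm <- vapply(folds, function(f) sum(labels[f$test] == -1), 0)
  n_abn <- vapply(folds, function(f) sum(labels[f$test] == 1), 0)
  expect_true(all(n_abn == 1))
  expect_equal(sum(n_norm == 12), 24L)
  expect_equal(sum(n_norm == 11), 20L)
  # the test sets partition the data
  all_test <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_identical(all_test, seq_along(labels))
  # train = complement
  f1 <- folds[[1]]
  expect_identical(sort(c(f1$train, f1$test)), seq_along(labels))
})

test_that("outer folds split evenly when possible and are seed-stable", {
  labels <- c(rep(1, 4), rep(-1, 20))
  folds <- outer_folds(labels, seed = 9)
  expect_length(folds, 4L)
  expect_true(all(vapply(folds, function(f) length(f$test), 0L) == 6L))
  expect_identical(outer_folds(labels, seed = 9), folds)
  expect_false(identical(outer_folds(labels, seed = 10), folds))
  expect_error(outer_folds(rep(-1, 10), 1), "degenerate")
})

test_that("inner tuning selects the separating configuration", {
  tbl <- toy_feature_table(8, 40, d = 2, effect = 4, seed = 21)
  x <- as.matrix(tbl[, c("f1", "f2")])
  y <- tbl$label
  learner <- lssvm_learner()
  # one absurd configuration, one sane one
  grid <- tibble::tibble(sigma_rel = c(1e-4, 1), gamma = c(1e-9, 1),
                         ratio = c(1, 1))
  sel <- inner_tune(scale(x), y, grid, learner, criterion = "gmean",
                    n_repeats = 2, seed = 4)
  expect_equal(sel$params$sigma_rel, 1)
  # a single-point grid returns that point
  sel1 <- inner_tune(scale(x), y, grid[2, ], learner, n_repeats = 1,
                     seed = 4)
  expect_equal(sel1$params, grid[2, ])
  # determinism
  sel2 <- inner_tune(scale(x), y, grid, learner, criterion = "gmean",
                     n_repeats = 2, seed = 4)
  expect_identical(sel$scores, sel2$scores)
})

test_that("no abnormal case repeats its normal companions across repeats", {
  for (case in list(c(6, 60), c(44, 508))) {
    y <- c(rep(1, case[1]), rep(-1, case[2]))
    plan <- inner_fold_plan(y, n_repeats = 5, seed = 17)
    seen <- list()
    for (r in 1:5) {
      for (f in plan[[r]]) {
        ab <- as.character(f$test[y[f$test] == 1][1])
        comp <- f$test[y[f$test] == -1]
        expect_false(any(comp %in% seen[[ab]]))
        seen[[ab]] <- c(seen[[ab]], comp)
      }
    }
    # every repeat is itself a partition
    for (r in 1:5) {
      expect_identical(sort(unlist(lapply(plan[[r]], `[[`, "test"))),
                       seq_along(y))
    }
  }
  expect_warning(inner_fold_plan(c(rep(1, 3), rep(-1, 9)), 5, 1),
                 "infeasible")
})

test_that("the full protocol is deterministic and leak-free", {
  tbl <- toy_feature_table(8, 40, d = 3, effect = 3, seed = 31)
  learner <- lssvm_learner()
  grid <- tibble::tibble(sigma_rel = 1, gamma = 1, ratio = 1)
  ev1 <- run_protocol(tbl, subset = names(tbl)[3:5], learner = learner,
                      grid = grid, n_outer_repeats = 1,
                      n_inner_repeats = 1, seed = 6)
  ev2 <- run_protocol(tbl, subset = names(tbl)[3:5], learner = learner,
                      grid = grid, n_outer_repeats = 1,
                      n_inner_repeats = 1, seed = 6)
  expect_identical(ev1$metrics, ev2$metrics)
  # aggregated = sum of per-repeat; totals = n records per repetition
  agg <- ev1$aggregated
  expect_equal(agg$tp + agg$fn + agg$fp + agg$tn, nrow(tbl))

  # poisoning the held-out rows must not change the trained fold model
  folds <- outer_folds(tbl$label, seed = fhrbench:::derive_seed(6, 1))
  f <- folds[[1]]
  poisoned <- tbl
  poisoned[f$test, 3:5] <- 1e6
  fit_a <- protocol_fit_fold(tbl, f$train, subset = names(tbl)[3:5],
                             learner = learner, grid = grid,
                             n_inner_repeats = 1, seed = 99)
  fit_b <- protocol_fit_fold(poisoned, f$train, subset = names(tbl)[3:5],
                             learner = learner, grid = grid,
                             n_inner_repeats = 1, seed = 99)
  expect_identical(fit_a$model$a, fit_b$model$a)
  expect_identical(fit_a$model$b, fit_b$model$b)
  expect_identical(fit_a$transform, fit_b$transform)
})

test_that("easy synthetic structure is recovered, permuted labels are not", {
  tbl <- toy_feature_table(10, 60, d = 3, effect = 3, seed = 41)
  learner <- lssvm_learner()
  grid <- tibble::tibble(sigma_rel = c(0.5, 1), gamma = c(1, 1),
                         ratio = c(1, 1))
  ev <- run_protocol(tbl, subset = paste0("f", 1:3), learner = learner,
                     grid = grid, n_outer_repeats = 3,
                     n_inner_repeats = 2, seed = 8)
  expect_gt(mean(ev$metrics$g_mean), 0.9)

  null_tbl <- tbl
  null_tbl$label <- withr::with_seed(5, sample(tbl$label))
  ev0 <- run_protocol(null_tbl, subset = paste0("f", 1:3),
                      learner = learner, grid = grid,
                      n_outer_repeats = 3, n_inner_repeats = 2, seed = 8)
  gm0 <- mean(ev0$metrics$g_mean, na.rm = TRUE)
  expect_lt(abs(gm0 - 0.5), 0.35)
})

test_that("report accessors expose per-repeat and mean metrics", {
  tbl <- toy_feature_table(6, 30, d = 3, effect = 3, seed = 51)
  learner <- lssvm_learner()
  grid <- tibble::tibble(sigma_rel = 1, gamma = 1, ratio = 1)
  ev <- run_protocol(tbl, subset = paste0("f", 1:3), learner = learner,
                     grid = grid, n_outer_repeats = 2,
                     n_inner_repeats = 1, seed = 2)
  td <- tidy(ev)
  expect_equal(nrow(td), 2L)
  expect_true(all(c("repeat_id", "g_mean", "ber", "ber_printed") %in%
                    names(td)))
  g <- glance(ev)
  expect_equal(g$g_mean, mean(td$g_mean))
  expect_s3_class(autoplot(ev), "ggplot")
})
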