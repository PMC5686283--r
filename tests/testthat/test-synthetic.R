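test_that("generation is a deterministic function of the seed", {
  cfg <- desk_config()
  a <- generate_record(1, cfg, seed = 3)
  b <- generate_record(1, cfg, seed = 3)
  expect_identical(a$record$fhr, b$record$fhr)
  expect_identical(a$truth$events, b$truth$events)
  expect_false(identical(a$record$fhr,
                         generate_record(1, cfg, seed = 4)$record$fhr))
  # generation does not disturb the caller's RNG stream
  withr::with_seed(1, {
    before <- runif(1)
  })
  withr::with_seed(1, {
    invisible(generate_record(1, cfg, seed = 3))
    after <- runif(1)
  })
  expect_identical(before, after)
})

test_that("a degenerate config yields a constant trace", {
  cfg <- generator_config(
    duration_s = 300, baseline_range = c(140, 140), baseline_drift_bpm = 0,
    variability_sd_bpm = 0, vlf_amp_bpm = 0, lf_amp_bpm = 0, mf_amp_bpm = 0,
    accel_rate = 0, decel_rate = 0, spike_rate = 0, gap_rate = 0
  )
  g <- generate_record(-1, cfg, seed = 1)
  expect_equal(g$record$fhr, rep(140, 1200))
})

test_that("event counts follow the configured Poisson rates", {
  cfg <- generator_config(duration_s = 1800, decel_rate = 0.5,
                          spike_rate = 0, gap_rate = 0,
                          decel_rate_ratio = 4)
  # abnormal decel rate = 0.5 * 4 = 2/min -> mean 60 per 30 min
  counts <- vapply(1:8, function(s) {
    generate_record(1, cfg, seed = s)$truth$n_decel
  }, numeric(1))
  expect_gt(mean(counts), 60 - 3 * sqrt(60))
  expect_lt(mean(counts), 60 + 3 * sqrt(60))
})

test_that("datasets carry the configured imbalance and pH consistency", {
  ds <- generate_dataset(20, 4, desk_config(), seed = 2)
  expect_equal(nrow(ds$meta), 24L)
  expect_equal(sum(ds$meta$label == 1), 4L)
  comp <- dataset_composition(ds$meta)
  expect_equal(comp$n_abnormal, 4L)
  expect_equal(comp$n_normal, 20L)
  # abnormal pH at or below the boundary, normal above
  expect_true(all(ds$meta$ph[ds$meta$label == 1] <= 7.05))
  expect_true(all(ds$meta$ph[ds$meta$label == -1] > 7.05))
})

test_that("the gap mixture exercises both interpolation and masking", {
  cfg <- generator_config(duration_s = 1800, gap_rate = 1.5,
                          long_gap_prob = 0.3, spike_rate = 0)
  found_short <- FALSE; found_long <- FALSE
  for (s in 1:5) {
    g <- generate_record(-1, cfg, seed = s)
    if (any(!g$truth$gaps$long)) found_short <- TRUE
    if (any(g$truth$gaps$long)) found_long <- TRUE
    cl <- preprocess_record(g$record)
    if (any(g$truth$gaps$long)) expect_gt(cl$long_gap_fraction, 0)
    if (any(!g$truth$gaps$long)) expect_gt(cl$noise_fraction, 0)
  }
  expect_true(found_short && found_long)
})

test_that("extracted SDNN responds monotonically to variability scale", {
  sdnn_at <- vapply(c(0.5, 1, 2, 4, 8), function(scale) {
    cfg <- desk_config(variability_sd_bpm = 2 * scale, gap_rate = 0,
                       spike_rate = 0, n_accel = 0, n_decel = 0)
    mean(vapply(1:3, function(s) {
      g <- generate_record(-1, cfg, seed = 100 + s)
      extract_features(g$record)$sdnn
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(sdnn_at) > 0))
})

test_that("class-separated generator knobs surface in the ranking", {
  rank_top <- function(cfg, seed_base, k) {
    vapply(1:4, function(s) {
      ds <- generate_dataset(16, 5, cfg, seed = seed_base + s)
      fm <- extract_dataset(ds$records)
      fm <- fm[, !vapply(fm, anyNA, logical(1))]
      rk <- rank_features(fm, n_repeats = 10, n_neg_out = 3, seed = s)
      paste(select_subset(rk, k), collapse = " ")
    }, character(1))
  }
  # classes differing only in narrowband LF/VLF power rank band-energy
  # features on top
  cfg_band <- desk_config(
    lf_ratio = 0.3, vlf_ratio = 3, lf_amp_bpm = 5, vlf_amp_bpm = 4,
    variability_ratio = 1, accel_rate_ratio = 1, decel_rate_ratio = 1,
    gap_rate = 0.15, spike_rate = 0.5, between_sd_log = 0
  )
  hits_band <- grepl("lf_|vlf", rank_top(cfg_band, 3000, 3))
  expect_gte(sum(hits_band), 3L)
  # classes differing only in variability scale rank beat-to-beat
  # variability / Poincare features on top
  cfg_var <- desk_config(
    variability_ratio = 0.5, lf_ratio = 1, vlf_ratio = 1,
    accel_rate_ratio = 1, decel_rate_ratio = 1,
    gap_rate = 0.15, spike_rate = 0.5, between_sd_log = 0
  )
  hits_var <- grepl("stv|sd1|sd2|sdnn|rmssd|delta|lti|iqr|mad",
                    rank_top(cfg_var, 4000, 3))
  expect_gte(sum(hits_var), 3L)
})
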