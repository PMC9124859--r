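test_that("sim_config validates its invariants", {
  expect_error(sim_config(fs = 160, epoch_s = 4.003), "integer sample count")
  expect_error(sim_config(erd_depth = 1.2), "erd_depth")
  expect_error(sim_config(trials_per_class = 0), "trials_per_class")
  cfg <- sim_config()
  expect_equal(cfg$n_samples, 640L)
  expect_setequal(names(cfg$class_templates), mi_classes())
})

test_that("source activity is deterministic, class-checked, and ERD-free at depth 0", {
  cfg <- sim_config(erd_depth = 0.8)
  expect_error(generate_source_activity("T9", cfg), "unknown motor-imagery class")
  set.seed(3); a1 <- generate_source_activity("T2", cfg)
  set.seed(3); a2 <- generate_source_activity("T2", cfg)
  expect_identical(a1$activity, a2$activity)
  expect_equal(dim(a1$activity), c(18L, 640L))
  expect_setequal(a1$active_rois, motor_scout_names()$left)
  # depth 0: active and inactive regions are draws from the same process
  cfg0 <- sim_config(erd_depth = 0)
  set.seed(5)
  pw <- replicate(40, {
    a <- generate_source_activity("T2", cfg0)
    c(mean(apply(a$activity[1:9, ], 1, oracle_band_power)),
      mean(apply(a$activity[10:18, ], 1, oracle_band_power)))
  })
  expect_equal(mean(pw[1, ]) / mean(pw[2, ]), 1, tolerance = 0.15)
})

test_that("mu-power suppression matches (1 - erd_depth)^2 within sampling error", {
  cfg <- sim_config(erd_depth = 0.8)
  set.seed(11)
  pw <- replicate(100, {
    a <- generate_source_activity("T2", cfg)   # left-hemisphere ERD
    c(mean(apply(a$activity[1:9, ], 1, oracle_band_power)),
      mean(apply(a$activity[10:18, ], 1, oracle_band_power)))
  })
  ratio <- mean(pw[1, ]) / mean(pw[2, ])
  expect_equal(ratio, (1 - 0.8)^2, tolerance = 0.3 * (1 - 0.8)^2 / (1 - 0.8)^2)
  expect_lt(abs(ratio - 0.04), 0.3 * 0.04 + 0.01)
})

test_that("contralateral mu-power ratio decreases monotonically in erd_depth", {
  set.seed(23)
  ratios <- sapply(c(0, 0.4, 0.8), function(d) {
    cfg <- sim_config(erd_depth = d)
    pw <- replicate(50, {
      a <- generate_source_activity("T2", cfg)
      c(mean(apply(a$activity[1:9, ], 1, oracle_band_power)),
        mean(apply(a$activity[10:18, ], 1, oracle_band_power)))
    })
    mean(pw[1, ]) / mean(pw[2, ])
  })
  expect_true(all(diff(ratios) < 0))
})

test_that("T4 suppresses beta but not mu", {
  cfg <- sim_config(erd_depth = 0.8)
  set.seed(31)
  pw <- replicate(50, {
    a <- generate_source_activity("T4", cfg)
    c(mean(apply(a$activity, 1, oracle_band_power, lo = 10, hi = 12)),
      mean(apply(a$activity, 1, oracle_band_power, lo = 18, hi = 25)))
  })
  cfg0 <- sim_config(erd_depth = 0)
  set.seed(31)
  pw0 <- replicate(50, {
    a <- generate_source_activity("T1", cfg0)
    c(mean(apply(a$activity, 1, oracle_band_power, lo = 10, hi = 12)),
      mean(apply(a$activity, 1, oracle_band_power, lo = 18, hi = 25)))
  })
  expect_equal(mean(pw[1, ]) / mean(pw0[1, ]), 1, tolerance = 0.2)  # mu intact
  expect_lt(mean(pw[2, ]) / mean(pw0[2, ]), 0.25)                    # beta cut
})

test_that("scalp projection is exactly linear and respects the noise floor", {
  fw <- small_forward()
  cfg <- sim_config(sensor_snr_db = Inf)   # noiseless: snr -> no noise added
  vmap <- hemidiff:::scout_vertex_map(fw$scouts)
  set.seed(2)
  tr <- generate_source_activity("T3", cfg)
  y1 <- project_to_scalp(tr, fw$leadfield, vmap, cfg)
  tr2 <- tr; tr2$activity <- 2 * tr$activity
  y2 <- project_to_scalp(tr2, fw$leadfield, vmap, cfg)
  expect_equal(y2, 2 * y1, tolerance = 1e-12)
  # single active vertex reproduces the leadfield column exactly
  one <- tr
  one$activity <- matrix(0, 18, cfg$n_samples,
                         dimnames = dimnames(tr$activity))
  one$activity[1, ] <- tr$activity[1, ]
  vone <- vmap
  for (nm in names(vone)) vone[[nm]] <- vone[[nm]][1]
  yv <- project_to_scalp(one, fw$leadfield, vone, cfg)
  v <- vone[[rownames(tr$activity)[1]]]
  expect_equal(yv, fw$leadfield$gain[, v, drop = FALSE] %*%
                 (one$activity[1, , drop = FALSE] * cfg$source_amp),
               tolerance = 1e-12, ignore_attr = TRUE)
  # zero activity: output is pure noise at the configured floor variance
  zero <- one
  zero$activity[] <- 0
  cfgf <- sim_config(noise_floor_var = 4e-12)
  set.seed(9)
  yz <- project_to_scalp(zero, fw$leadfield, vmap, cfgf)
  expect_equal(stats::var(as.vector(yz)), 4e-12, tolerance = 0.05)
  # dimension mismatch is rejected
  bad <- vmap; bad[[1]] <- c(bad[[1]], ncol(fw$leadfield$gain) + 1L)
  expect_error(project_to_scalp(tr, fw$leadfield, bad, cfg), "exceeds")
})

test_that("generated datasets have the documented shape, balance, and determinism", {
  ds <- small_dataset()
  expect_equal(dim(ds$epochs$epochs), c(8L, 64L, 640L))
  expect_equal(unname(table(as.character(ds$epochs$labels))), rep(2L, 4),
               ignore_attr = TRUE)
  ds2 <- generate_dataset(sim_config(trials_per_class = 2, seed = 42,
                                     baseline_s = 8), small_forward())
  expect_identical(ds$epochs$epochs, ds2$epochs$epochs)
  expect_identical(ds$epochs$labels, ds2$epochs$labels)
  # single trial per class
  ds1 <- generate_dataset(sim_config(trials_per_class = 1, seed = 1,
                                     baseline_s = 8), small_forward())
  expect_equal(dim(ds1$epochs$epochs)[1], 4L)
})

test_that("default dataset structure matches the emulated recordings", {
  cfg <- sim_config()
  expect_equal(cfg$trials_per_class * 4L, 84L)
  expect_equal(cfg$fs, 160)
  expect_equal(cfg$n_samples, 640L)
  expect_equal(cfg$n_channels, 64L)
})
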