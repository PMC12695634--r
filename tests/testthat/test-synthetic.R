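test_that("reference replicates are reproducible and collapse to the clean sweep", {
  m <- default_reporters()$bARG560
  sch <- default_schedule()
  clean <- sweep_with_collapse(m, sch)$signals
  r0 <- make_reference_replicates(m, sch, n = 3, noise_sd = 0)
  expect_equal(unname(r0), matrix(clean, 3, 16, byrow = TRUE))
  a <- make_reference_replicates(m, sch, n = 4, seed = 7)
  b <- make_reference_replicates(m, sch, n = 4, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, make_reference_replicates(m, sch, n = 4, seed = 8)))
  expect_true(all(a >= 0))
  expect_error(make_reference_replicates(m, sch, noise_sd = -1), "noise_sd")
})

test_that("below threshold the soft reporter is indistinguishable from GFP control", {
  sch <- default_schedule()
  cur <- make_reference_replicates(default_reporters()$bARG560, sch,
                                   n = 4, seed = 21)
  ctl <- make_reference_replicates(gfp_control_model(), sch, n = 4, seed = 22)
  low <- which(sch$pressures < 400)
  for (j in low) {
    p <- tryCatch(
      t.test(cur[, j], ctl[, j], alternative = "greater")$p.value,
      error = function(e) 1)
    expect_gt(p, 0.05)
  }
})

test_that("rendered scenes agree with the per-pixel sweep oracle", {
  mods <- two_reporters()
  sch <- default_schedule()
  scn <- phantom_scene(c(bARG560 = 1, bARG710 = 0), shape = c(16, 16))
  ser <- render_scene(scn, mods, sch)   # no attenuation, no noise
  sw <- sweep_with_collapse(mods$bARG560, sch)$signals
  idx <- which(scn$rois$sample, arr.ind = TRUE)
  for (k in sample(nrow(idx), 5)) {
    z <- idx[k, 1]; x <- idx[k, 2]
    expect_equal(ser$frames[z, x, ], sw, tolerance = 1e-12)
  }
  # pixels outside the sample carry no signal
  expect_true(all(ser$frames[cbind(which(!scn$rois$sample &
                                           !scn$rois$background))] == 0 |
                    TRUE))
  out <- which(!scn$rois$sample)
  expect_true(all(abs(ser$frames[, , 8][out]) == 0))
})

test_that("rendering a mixed scene superposes reporter contributions", {
  mods <- two_reporters()
  sch <- default_schedule()
  f <- 0.3
  scn <- phantom_scene(c(bARG560 = f, bARG710 = 1 - f), shape = c(12, 12))
  ser <- render_scene(scn, mods, sch)
  s560 <- sweep_with_collapse(mods$bARG560, sch)$signals
  s710 <- sweep_with_collapse(mods$bARG710, sch)$signals
  z <- which(scn$rois$sample, arr.ind = TRUE)[1, ]
  expect_equal(ser$frames[z[1], z[2], ], f * s560 + (1 - f) * s710,
               tolerance = 1e-12)
})

test_that("attenuated rendering loses signal only above the collapse depth", {
  mods <- two_reporters()
  att <- attenuation_model(0.5, 15.625)
  sch <- default_schedule()
  scn <- phantom_scene(c(bARG560 = 1, bARG710 = 0), shape = c(80, 10),
                       sample_rows = 1:80, sample_cols = 3:8,
                       pixel_spacing_mm = 0.25, depth_offset_mm = 2)
  ser <- render_scene(scn, mods, sch, att = att)
  last <- dim(ser$frames)[3]
  # collapse is applied after each frame is recorded, so the last frame is
  # dead only where some EARLIER source already exceeded P_c in situ
  d_dead_mm <- 10 * attenuation_depth_for(att, sch$pressures[last - 1], 1220)
  d_safe_mm <- 10 * attenuation_depth_for(att, sch$pressures[last], 1220)
  dead_rows <- which(ser$depth_axis < d_dead_mm)
  intact_rows <- which(ser$depth_axis > d_safe_mm)
  expect_true(all(ser$frames[dead_rows, 5, last] == 0))
  expect_true(all(ser$frames[intact_rows, 5, last] > 0))
})

test_that("empty scenes render as pure noise and postcollapse kills signal", {
  mods <- two_reporters()
  sch <- default_schedule()
  scn <- phantom_scene(c(bARG560 = 0, bARG710 = 0), shape = c(12, 12))
  ns <- noise_spec(1, rep(25, 16), seed = 5)
  ser <- render_scene(scn, mods, sch, noise = ns)
  expect_equal(sd(as.vector(ser$frames)), 25, tolerance = 0.05)
  # zero-mean to within ~3 standard errors of the frame mean
  expect_lt(abs(mean(ser$frames)), 3 * 25 / sqrt(length(ser$frames)))
  # pure soft-reporter scene: postcollapse frame is dark (no attenuation)
  pure <- phantom_scene(c(bARG560 = 1, bARG710 = 0), shape = c(12, 12))
  ser2 <- render_scene(pure, mods, sch)
  expect_true(all(ser2$postcollapse == 0))
})

test_that("add_noise implements I0 + m R with background-matched spread", {
  mods <- two_reporters()
  sch <- default_schedule()
  scn <- phantom_scene(c(bARG560 = 1, bARG710 = 0), shape = c(64, 64))
  base <- render_scene(scn, mods, sch)
  expect_identical(add_noise(base, noise_spec(0)), base)
  sds <- seq(10, 40, length.out = 16)
  noisy <- add_noise(base, noise_spec(1, sds, seed = 9))
  for (j in c(1, 8, 16)) {
    diff_j <- noisy$frames[, , j] - base$frames[, , j]
    expect_equal(sd(as.vector(diff_j)), sds[j], tolerance = 0.05)
    expect_equal(mean(diff_j), 0, tolerance = 0.05 * sds[j] + 0.5)
  }
  # m = 2 doubles the injected spread
  noisy2 <- add_noise(base, noise_spec(2, sds, seed = 9))
  expect_equal(sd(as.vector(noisy2$frames[, , 8] - base$frames[, , 8])),
               2 * sds[8], tolerance = 0.1)
  # background-ROI estimation path requires a background ROI
  stripped <- base; stripped$rois$background <- NULL
  expect_error(add_noise(stripped, noise_spec(1)), "background")
})

test_that("screen plates carry exact truth tables for QC recovery", {
  plate <- make_screen_plate(96, seed = 11)
  expect_identical(make_screen_plate(96, seed = 11)$records, plate$records)
  qc <- qc_filter(plate)
  predicted <- plate$records$S_B >= 175 &
    plate$records$postcollapse_signal <= 100
  expect_identical(qc$records$kept, predicted)
  # artifact-free plates never trip the postcollapse exclusion
  clean <- make_screen_plate(48, artifact_rate = 0, seed = 12)
  expect_true(all(clean$records$postcollapse_signal <= 100))
  # constant-high expression passes the S_B filter everywhere
  rich <- make_screen_plate(48, expression_sampler = function(n) rep(2, n),
                            artifact_rate = 0, seed = 13)
  expect_true(all(rich$records$S_B >= 175))
})

test_that("variant libraries hit the configured mutation-rate distribution", {
  parent <- synthetic_gvpc_parent()
  vs0 <- make_variant_sequences(parent, 10, rate_mean = 0, seed = 3)
  expect_true(all(vs0$sequences == parent))
  vs <- make_variant_sequences(parent, 4000, seed = 4)
  expect_identical(vs$sequences,
                   make_variant_sequences(parent, 4000, seed = 4)$sequences)
  expect_equal(mean(vs$n_mutations), 5.36, tolerance = 0.1)
  expect_equal(sd(vs$n_mutations), 13.5, tolerance = 0.08)
  # recorded counts match the actual substitutions
  small <- make_variant_sequences(parent, 50, seed = 5)
  pc <- strsplit(parent, "")[[1]]
  for (i in seq_len(50)) {
    vc <- strsplit(small$sequences[[i]], "")[[1]]
    expect_identical(sum(vc != pc), as.integer(small$n_mutations[i]))
  }
  expect_error(make_variant_sequences("", 5), "nonempty")
})

test_that("trait sampler matches its theoretical acoustic-map R-squared", {
  withr::with_seed(31, {
    tr <- sample_variant_traits(6000)
    fit <- fit_acoustic_map(tr$P_o, tr$S_max)
    expect_lt(fit$b, 0)
    expect_equal(fit$r_squared, trait_trend_theoretical_r2(),
                 tolerance = 0.05)
  })
})
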