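test_that("multiplexing matrix rows equal the model sweep for noiseless references", {
  mods <- two_reporters()
  sch <- default_schedule()
  refs <- lapply(names(mods), function(nm) {
    conc <- setNames(as.numeric(names(mods) == nm), names(mods))
    render_scene(phantom_scene(conc, shape = c(16, 16)), mods, sch)
  })
  names(refs) <- names(mods)
  M <- build_multiplex_matrix(refs)
  trimmed <- sch$pressures[sch$pressures <= 1200]
  expect_identical(ncol(M$M), length(trimmed))
  expect_true(all(schedule_pressures(M$schedule) <= 1200))
  for (nm in names(mods)) {
    sw <- sweep_with_collapse(mods[[nm]], sch)$signals[seq_along(trimmed)]
    expect_equal(unname(M$M[nm, ]), sw, tolerance = 1e-9)
  }
})

test_that("identical references produce a rank-deficient matrix warning", {
  mods <- two_reporters()
  sch <- default_schedule()
  ref <- render_scene(phantom_scene(c(bARG560 = 1, bARG710 = 0),
                                    shape = c(12, 12)), mods, sch)
  expect_warning(build_multiplex_matrix(list(a = ref, b = ref)),
                 "rank-deficient")
})

test_that("schedule mismatches and empty ROIs are rejected", {
  mods <- two_reporters()
  ref1 <- render_scene(phantom_scene(c(bARG560 = 1, bARG710 = 0),
                                     shape = c(12, 12)), mods,
                       default_schedule())
  ref2 <- render_scene(phantom_scene(c(bARG560 = 0, bARG710 = 1),
                                     shape = c(12, 12)), mods,
                       pressure_schedule(seq(300, 1800, length.out = 12), 1200))
  expect_error(build_multiplex_matrix(list(bARG560 = ref1, bARG710 = ref2)),
               "schedule")
  bad <- ref1; bad$rois$sample[] <- FALSE
  expect_error(build_multiplex_matrix(list(bARG560 = bad)), "ROI")
  M <- multiplex_matrix_from_models(mods)
  short <- render_scene(phantom_scene(c(bARG560 = 1, bARG710 = 0),
                                      shape = c(8, 8)), mods,
                        pressure_schedule(seq(200, 900, length.out = 5), 900))
  expect_error(unmix_pixelwise(short, M), "pressures")
})

test_that("pixel thresholding separates sample from background exactly", {
  mods <- two_reporters()
  sch <- default_schedule()
  scn <- phantom_scene(c(bARG560 = 1, bARG710 = 0), shape = c(20, 20))
  ser <- render_scene(scn, mods, sch)
  # in-sample peak is thousands of a.u., background exactly zero here
  expect_identical(threshold_pixels(ser, 100), scn$rois$sample)
  expect_true(all(threshold_pixels(ser, 0)))
  none <- threshold_pixels(ser, max(ser$frames) + 1)
  expect_false(any(none))
  cm <- unmix_pixelwise(ser, multiplex_matrix_from_models(mods, sch), none)
  expect_true(all(cm$C == 0))
  expect_true(all(is.na(cm$residual)))
})

test_that("NNLS solves the worked two-reporter examples", {
  M <- multiplex_matrix(matrix(c(1, 2, 4, 3, 2, 1), 2, byrow = TRUE),
                        c("r1", "r2"),
                        pressure_schedule(c(100, 200, 300), 300))
  A <- t(M$M)
  # exact nonnegative combination is recovered exactly
  fit <- gvmux:::nnls_solve(A, as.numeric(1 * M$M[1, ] + 2 * M$M[2, ]))
  expect_equal(fit$x, c(1, 2), tolerance = 1e-12)
  expect_equal(fit$resid, 0, tolerance = 1e-9)
  # active-set case pinned against the dense grid oracle
  b <- c(2.5, 1, -1)
  fit2 <- gvmux:::nnls_solve(A, b)
  oracle <- nnls_grid_oracle(A, b, step = 0.001, cmax = 1.5)
  expect_equal(fit2$x, c(0, 0.6071), tolerance = 1e-3)
  expect_equal(fit2$x, oracle$x, tolerance = 2e-3)
  expect_lte(fit2$resid, oracle$resid + 1e-6)
})

test_that("closed-form two-channel NNLS agrees with the active-set solver", {
  withr::with_seed(17, {
    for (i in 1:50) {
      A <- matrix(runif(16, 0, 10), 8, 2)
      b <- rnorm(8, sd = 5)
      mine <- gvmux:::nnls_solve(A, b)
      ref <- pracma::lsqnonneg(A, b)
      expect_equal(mine$x, ref$x, tolerance = 1e-8)
      expect_equal(mine$resid^2, ref$resid.norm, tolerance = 1e-8)
    }
  })
})

test_that("noiseless compositions of matrix rows are recovered to 1e-6", {
  mods <- two_reporters()
  M <- multiplex_matrix_from_models(mods)
  A <- t(M$M)
  withr::with_seed(23, {
    for (i in 1:200) {
      cc <- runif(2, 0, 3)
      fit <- gvmux:::nnls_solve(A, as.numeric(A %*% cc))
      expect_equal(fit$x, cc, tolerance = 1e-6)
    }
  })
})

test_that("a 1:1 noiseless mixture unmixes to equal channels", {
  mods <- two_reporters()
  sch <- default_schedule()
  scn <- phantom_scene(c(bARG560 = 0.5, bARG710 = 0.5), shape = c(16, 16))
  ser <- render_scene(scn, mods, sch)
  cm <- unmix_pixelwise(ser, multiplex_matrix_from_models(mods, sch))
  px <- which(cm$mask)
  ratio <- cm$C[, , 1][px] / cm$C[, , 2][px]
  expect_true(all(abs(ratio - 1) < 1e-6))
})

test_that("depth-corrected unmixing reduces exactly to flat unmixing at alpha 0", {
  mods <- two_reporters()
  sch <- default_schedule()
  scn <- phantom_scene(c(bARG560 = 0.6, bARG710 = 0.4), shape = c(20, 12))
  ser <- render_scene(scn, mods, sch,
                      noise = noise_spec(1, rep(20, 16), seed = 2))
  m2d <- build_m2d(mods, attenuation_model(0, 15.625), ser$depth_axis, sch)
  flat <- unmix_pixelwise(ser, multiplex_matrix_from_models(mods, sch))
  corr <- unmix_depth_corrected(ser, m2d)
  expect_equal(corr$C, flat$C, tolerance = 1e-12)
  expect_equal(corr$residual, flat$residual, tolerance = 1e-12)
})

test_that("M(d) rows vanish below the buckling depth and flag deep pixels", {
  mods <- two_reporters()
  att <- attenuation_model(0.5, 15.625)
  sch <- default_schedule()
  # depth at which even the strongest in-window source falls below both P_o:
  # responses there are at baseline (zero) for both reporters
  p_in_window <- max(sch$pressures[sch$pressures <= 1200])
  d_dead_mm <- 10 * attenuation_depth_for(att, p_in_window, 400)
  m2d <- build_m2d(mods, att, c(5, d_dead_mm + 5), sch)
  deep <- m2d$stack[[2]]
  expect_true(all(deep < control_detection_limit()))
  # at the 5-mm calibration depth the soft reporter responds strongly
  shallow <- m2d$stack[[1]]
  expect_gt(max(shallow), 10 * control_detection_limit())
  # depth alignment beyond half a row spacing is an error
  scn <- phantom_scene(c(bARG560 = 1, bARG710 = 0), shape = c(10, 10))
  ser <- render_scene(scn, mods, sch, att = att)
  m2d_bad <- build_m2d(mods, att, ser$depth_axis + 2, sch)
  expect_error(unmix_depth_corrected(ser, m2d_bad), "depth axis")
})

test_that("normalized difference is bounded, antisymmetric and flags sentinels", {
  C <- array(0, dim = c(2, 3, 2))
  C[1, 1, ] <- c(5, 0)    # pure channel 1
  C[1, 2, ] <- c(3, 3)    # balanced
  C[1, 3, ] <- c(0, 2)    # pure channel 2
  C[2, 1, ] <- c(4, 1)
  cmap <- gvmux:::new_coefficient_map(C, matrix(0, 2, 3), c("a", "b"),
                                      matrix(TRUE, 2, 3))
  ndc <- normalized_difference(cmap, "corrected")
  expect_equal(ndc$nd[1, 1], 1)
  expect_equal(ndc$nd[1, 2], 0)
  expect_equal(ndc$nd[1, 3], -1)
  expect_true(is.na(ndc$nd[2, 2]))  # both channels zero
  expect_true(all(abs(ndc$nd[!is.na(ndc$nd)]) <= 1))
  ndp <- normalized_difference(cmap, "as_printed")
  expect_equal(ndp$nd[1, 1], 1)
  expect_true(is.na(ndp$nd[1, 2]))  # zero radicand is undefined as printed
  expect_true(is.na(ndp$nd[1, 3]))  # negative radicand
  # swapping channels negates the corrected variant
  Cs <- C[, , 2:1]
  swapped <- gvmux:::new_coefficient_map(Cs, matrix(0, 2, 3), c("b", "a"),
                                         matrix(TRUE, 2, 3))
  nds <- normalized_difference(swapped, "corrected")
  expect_equal(nds$nd[!is.na(nds$nd)], -ndc$nd[!is.na(ndc$nd)])
  one <- gvmux:::new_coefficient_map(array(1, c(2, 2, 1)), matrix(0, 2, 2),
                                     "a", matrix(TRUE, 2, 2))
  expect_error(normalized_difference(one), "two channels")
})

test_that("channel means report pixel or replicate s.e.m. as appropriate", {
  C <- array(0, dim = c(4, 4, 2))
  C[, , 1] <- 3            # uniform channel
  cmap <- gvmux:::new_coefficient_map(C, matrix(0, 4, 4), c("a", "b"),
                                      matrix(TRUE, 4, 4))
  roi <- matrix(TRUE, 4, 4)
  cm <- channel_means(cmap, roi)
  expect_equal(cm$mean, c(3, 0))
  expect_equal(cm$sem, c(0, 0))
  expect_identical(cm$sem_basis, rep("pixels", 2))
  reps <- lapply(c(2.5, 3.5), function(v) {
    Ci <- C; Ci[, , 1] <- v
    gvmux:::new_coefficient_map(Ci, matrix(0, 4, 4), c("a", "b"), roi)
  })
  cmr <- channel_means(reps, roi)
  expect_equal(cmr$mean, c(3, 0))
  expect_identical(cmr$sem_basis, rep("replicates", 2))
  expect_equal(cmr$sem[1], sd(c(2.5, 3.5)) / sqrt(2))
  expect_error(channel_means(cmap, matrix(FALSE, 4, 4)), "nonempty")
})

test_that("mixture linearity is exact for noiseless mixtures", {
  expect_error(mixture_linearity(c(0.5, 0.5, 0.5), c(1, 2, 3)), "distinct")
  f <- c(0, 0.25, 0.5, 0.75, 1)
  exact <- mixture_linearity(f, f)
  expect_equal(exact$r_squared, 1)
  expect_equal(exact$slope, 1)
  mods <- two_reporters()
  sch <- default_schedule()
  M <- multiplex_matrix_from_models(mods, sch)
  ch <- vapply(f, function(fi) {
    scn <- phantom_scene(c(bARG560 = fi, bARG710 = 1 - fi), shape = c(12, 12))
    ser <- render_scene(scn, mods, sch)
    cm <- unmix_pixelwise(ser, M, scn$rois$sample)
    means <- channel_means(cm, scn$rois$sample)$mean
    means[1] / sum(means)
  }, 0)
  fit <- mixture_linearity(f, ch)
  expect_gte(fit$r_squared, 0.99)
})
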