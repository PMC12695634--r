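test_that("B-mode ROI automation finds the sample top edge per column", {
  bm <- make_test_bmode(Z = 40, X = 20, edge_row = 20)
  mask <- segment_roi_from_bmode(bm, band_rows = 8)
  tops <- apply(mask, 2, function(col) which(col)[1])
  expect_true(all(abs(tops - 20) <= 1))
  expect_true(all(colSums(mask) == 8))
  # blank image: empty mask with a warning
  expect_warning(empty <- segment_roi_from_bmode(matrix(7, 30, 10)),
                 "no edge")
  expect_false(any(empty))
  # edge at the first row is a legal boundary case
  top_edge <- make_test_bmode(Z = 30, X = 8, edge_row = 1)
  m2 <- segment_roi_from_bmode(top_edge, band_rows = 5, edge_offset = 0)
  expect_true(all(m2[1, ]))
})

test_that("rendered B-mode images drive ROI placement end to end", {
  mods <- two_reporters()
  scn <- phantom_scene(c(bARG560 = 1, bARG710 = 0), shape = c(40, 30),
                       sample_rows = 15:32, sample_cols = 4:27)
  ser <- render_scene(scn, mods, default_schedule())
  roi <- segment_roi_from_bmode(ser$bmode, band_rows = 10)
  tops <- apply(roi[, 4:27], 2, function(col) which(col)[1])
  expect_true(all(abs(tops - 15) <= 2))
})

test_that("QC filter reproduces the worked toy table and boundary rule", {
  toy <- data.frame(S_B = c(100, 175, 200, 300, 250),
                    postcollapse_signal = c(10, 10, 500, 10, 10))
  qc <- qc_filter(toy, s_b_min = 175, postcollapse_max = 100)
  expect_identical(which(qc$records$kept), c(2L, 4L, 5L))
  expect_identical(unname(qc$report["kept"]), 3L)
  expect_identical(unname(qc$report["low_expression"]), 1L)
  expect_identical(unname(qc$report["artifact"]), 1L)
  # S_B exactly at the threshold is kept
  expect_true(qc$records$kept[2])
  all_kept <- qc_filter(toy, s_b_min = 0, postcollapse_max = Inf)
  expect_true(all(all_kept$records$kept))
})

test_that("threshold estimation requires a real signal above control", {
  sch <- default_schedule()
  ctl_a <- make_reference_replicates(gfp_control_model(), sch, n = 4, seed = 1)
  ctl_b <- make_reference_replicates(gfp_control_model(), sch, n = 4, seed = 2)
  est <- estimate_po(ctl_a, ctl_b, sch)
  expect_false(est$detected)
  expect_true(is.na(est$P_o))
  expect_error(estimate_po(ctl_a[1, , drop = FALSE], ctl_b, sch), "replicates")
})

test_that("a noiseless curve crossing the limit at a grid point is returned exactly", {
  sch <- default_schedule()
  p <- sch$pressures
  ctl <- make_reference_replicates(gfp_control_model(), sch, n = 4, seed = 3)
  limit <- mean(ctl) + 2 * sd(ctl)
  # deterministic ramp that equals the detection limit exactly at p[6]
  ramp <- pmax(0, limit * (p - p[4]) / (p[6] - p[4]))
  curves <- rbind(ramp, ramp, ramp + 1e-9, ramp)
  est <- estimate_po(curves, ctl, sch)
  expect_true(est$detected)
  expect_equal(est$P_o, p[6], tolerance = 1e-6)
})

test_that("threshold estimates track a translation of the response curve", {
  sch <- default_schedule()
  base <- default_reporters()$bARG560
  shifted <- reporter_model("shifted", base$P_o + 150, base$S_max, base$P_c,
                            base$p_mid + 150, base$w)
  ctl <- make_reference_replicates(gfp_control_model(), sch, n = 8, seed = 4)
  cur_a <- make_reference_replicates(base, sch, n = 4, seed = 5)
  cur_b <- make_reference_replicates(shifted, sch, n = 4, seed = 5)
  a <- estimate_po(cur_a, ctl, sch)$P_o
  b <- estimate_po(cur_b, ctl, sch)$P_o
  expect_equal(b - a, 150, tolerance = 40)
})

test_that("yield estimation is windowed and ignores pressures above the cap", {
  sch <- default_schedule()
  p <- sch$pressures
  mono <- seq(10, 1500, length.out = length(p))
  est <- estimate_smax(mono, sch)
  expect_equal(est$at_pressure, max(p[p <= 1200]))
  expect_equal(est$S_max, mono[sum(p <= 1200)])
  # instrumented tail: poisoned out-of-window values change nothing
  poisoned <- mono
  poisoned[p > 1200] <- 1e9
  expect_equal(estimate_smax(poisoned, sch)$S_max, est$S_max)
  expect_error(estimate_smax(mono, sch, window_cap = 100), "window")
})

test_that("collapse pressure is recovered by 50%-survival interpolation", {
  m <- default_reporters()$bARG560
  grid <- seq(1100, 1350, by = 10)
  sw <- collapse_survival_sweep(m, grid)
  est <- estimate_pc(sw$max_pressure_kpa, sw$surviving_fraction)
  expect_equal(est$P_c, 1220, tolerance = 10)
  # graded collapse of width 30 kPa: midpoint recovered within 5 kPa
  soft <- reporter_model("soft", 560, 5900, 1220, 840, 58,
                         collapse_width = 30)
  sws <- collapse_survival_sweep(soft, grid)
  expect_equal(estimate_pc(sws$max_pressure_kpa,
                           sws$surviving_fraction)$P_c, 1220, tolerance = 5)
  expect_error(estimate_pc(grid, rep(1, length(grid))), "transition")
})

test_that("acoustic-map fitting recovers exact log trends and flags degeneracy", {
  P_o <- seq(500, 1100, length.out = 20)
  S <- 30000 - 4000 * log(P_o)
  fit <- fit_acoustic_map(P_o, S)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$b, -4000, tolerance = 1e-9)
  expect_warning(two <- fit_acoustic_map(c(500, 900), c(3000, 1200)),
                 "degenerate")
  expect_true(two$degenerate)
  expect_error(fit_acoustic_map(c(-5, 600, 700), c(1, 2, 3)), "P_o")
})

test_that("plate characterization recovers the generating parameters", {
  plate <- make_screen_plate(96, seed = 41)
  rec <- characterize_plate(plate, control_seed = 141)
  expect_identical(is.na(rec$P_o_hat) | rec$kept, rep(TRUE, nrow(rec)))
  kept <- rec[rec$kept & !is.na(rec$P_o_hat), ]
  expect_gt(nrow(kept), 60)
  grid_step <- diff(plate$schedule$pressures[1:2])
  expect_lte(median(abs(kept$P_o_hat - kept$true_P_o)), grid_step)
  expect_lte(median(abs(kept$S_max_hat - kept$true_S_max) / kept$true_S_max),
             0.05)
})

test_that("the library acoustic map reproduces the configured trend", {
  plate <- make_screen_plate(879, seed = 42)
  rec <- characterize_plate(plate, control_seed = 142)
  kept <- rec[rec$kept & !is.na(rec$P_o_hat), ]
  truth_fit <- fit_acoustic_map(kept$true_P_o, kept$true_S_max)
  expect_equal(truth_fit$r_squared, trait_trend_theoretical_r2(),
               tolerance = 0.05)
  meas_fit <- fit_acoustic_map(kept$P_o_hat, kept$S_max_hat)
  expect_lt(meas_fit$b, 0)
  # threshold-estimation error attenuates the measured correlation somewhat
  expect_gt(meas_fit$r_squared, 0.7)
})

test_that("region assignment honors polygon priority and outliers", {
  polys <- list(
    "1s" = cbind(P_o = c(700, 1000, 1000, 700), S_max = c(500, 500, 2000, 2000)),
    "2s" = cbind(P_o = c(950, 1200, 1200, 950), S_max = c(100, 100, 800, 800)))
  lab <- assign_regions(c(800, 975, 1100, 400), c(1000, 600, 300, 4000), polys)
  expect_identical(lab, c("1s", "1s", "2s", "outlier"))
  expect_identical(assign_regions(800, 1000, list()), "outlier")
  expect_error(assign_regions(800, 1000, list(bad = cbind(1, 2))), "polygon")
})

test_that("contrast-to-noise ratio follows its definition", {
  img <- matrix(0, 4, 5)
  img[1, ] <- 10                      # target strip
  img[3, ] <- c(6, 6, 2, 2, 4)        # background mean 4, s.d. 2
  target <- row(img) == 1
  bg <- row(img) == 3
  res <- compute_cnr(img, target, bg)
  expect_equal(res$cnr, 3)
  expect_equal(res$S_target, 10)
  expect_equal(res$sigma_background, 2)
  # identical region statistics: zero contrast
  img2 <- rbind(c(1, 5, 1, 5), 0, c(1, 5, 1, 5), 0)
  expect_equal(compute_cnr(img2, row(img2) == 1, row(img2) == 3)$cnr, 0)
  expect_error(compute_cnr(img, target, target), "disjoint")
  expect_error(compute_cnr(matrix(1, 2, 2), matrix(c(TRUE, FALSE, FALSE, FALSE), 2),
                           matrix(c(FALSE, TRUE, TRUE, TRUE), 2)), "s.d.")
})

test_that("fold change uses the amplitude decibel convention", {
  expect_equal(signal_fold_change_db(c(5, 5), c(5, 5)), c(0, 0))
  expect_equal(signal_fold_change_db(10, 1), 20)
  expect_equal(signal_fold_change_db(2, 1), 6.0206, tolerance = 1e-4)
  expect_equal(signal_fold_change_db(10, 1, convention = "power"), 10)
  expect_true(is.na(signal_fold_change_db(c(1, 0), c(1, 1))[2]))
})
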