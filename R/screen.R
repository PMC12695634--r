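#' Automated sample ROI placement from a B-mode image
#'
#' B-mode images of phantom wells carry a reliable high-contrast edge at the
#' top of each sample. Per lateral column, the first depth row whose
#' intensity exceeds an adaptive edge threshold (Otsu two-class split of the
#' image histogram) is taken as the sample top, and a fixed-depth band below
#' it is returned as the sample ROI. An image with no detectable edge (for
#' example all-constant) yields an empty mask with a warning.
#'
#' @param bmode numeric Z x X B-mode image.
#' @param band_rows depth of the ROI band below the detected edge, rows.
#' @param edge_offset rows skipped below the bright edge itself before the
#'   band starts (the edge is specular, not sample signal).
#' @return logical Z x X mask.
#' @export
segment_roi_from_bmode <- function(bmode, band_rows = 10, edge_offset = 1) {
  rng <- range(bmode)
  if (diff(rng) <= 0) {
    warning("no edge found in B-mode image; returning empty mask")
    return(matrix(FALSE, nrow(bmode), ncol(bmode)))
  }
  norm <- (bmode - rng[1L]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  Z <- nrow(bmode); X <- ncol(bmode)
  mask <- matrix(FALSE, Z, X)
  found <- FALSE
  for (x in seq_len(X)) {
    top <- which(norm[, x] > thr)[1L]
    if (is.na(top)) next
    found <- TRUE
    lo <- min(top + edge_offset, Z)
    mask[seq(lo, min(lo + band_rows - 1L, Z)), x] <- TRUE
  }
  if (!found) warning("no edge found in B-mode image; returning empty mask")
  mask
}

#' Quality-control filter for screening records
#'
#' A record is kept iff its B-mode intensity `S_B` is at least `s_b_min`
#' (sufficient gas-vesicle expression for reliable nonlinear readout;
#' boundary value kept) and its postcollapse nonlinear signal is at most
#' `postcollapse_max` (signals surviving the collapse pulse indicate an
#' artifact, e.g. a bubble reflection, not gas vesicles).
#'
#' @param records data.frame with columns `S_B` and `postcollapse_signal`
#'   (e.g. the `records` of a [make_screen_plate()]), or a `screen_plate`.
#' @param s_b_min B-mode expression threshold, a.u. (default 175).
#' @param postcollapse_max artifact exclusion cutoff, a.u.; defaults to the
#'   in vitro pixel threshold (100).
#' @return list with `records` (input plus logical `low_expression`,
#'   `artifact_excluded`, `kept`), `kept` (kept subset) and `report`
#'   (counts per exclusion reason).
#' @export
qc_filter <- function(records, s_b_min = 175, postcollapse_max = 100) {
  if (inherits(records, "screen_plate")) records <- records$records
  stopifnot(s_b_min >= 0, postcollapse_max >= 0)
  low <- records$S_B < s_b_min
  art <- records$postcollapse_signal > postcollapse_max
  records$low_expression <- low
  records$artifact_excluded <- art
  records$kept <- !low & !art
  list(records = records,
       kept = records[records$kept, , drop = FALSE],
       report = c(n = nrow(records),
                  low_expression = sum(low),
                  artifact = sum(art),
                  kept = sum(records$kept)))
}

# ---- parameter estimators ---------------------------------------------------

welch_greater_p <- function(a, b) {
  tryCatch(t.test(a, b, alternative = "greater", var.equal = FALSE)$p.value,
           error = function(e) 1)
}

#' Estimate the nonlinear signal threshold P_o
#'
#' At each scheduled pressure, in increasing order, sample replicates are
#' compared to GFP-control replicates with a one-sided Welch two-sample test
#' (sample greater than control) at `alpha`, uncorrected. The detection
#' pressure is the first significant grid point whose sample mean also
#' reaches the control-derived detection limit (pooled control mean plus two
#' control standard deviations); the consistency requirement guards against
#' spurious low-pressure significances of the uncorrected test on few
#' replicates. The returned threshold refines the detection point by
#' interpolating where the sample mean curve crosses the detection limit
#' between the detection point and its predecessor (or an earlier pair if
#' the mean curve crossed sooner). The interpolation is linear in
#' log-signal: below its midpoint a logistic response rises exponentially,
#' so the log-domain chord reproduces the noiseless crossing exactly,
#' whereas a plain linear chord is biased low by a fifth of the grid
#' spacing. Where the predecessor mean is nonpositive the interpolation
#' falls back to linear.
#'
#' @param curves replicates x pressures signal matrix of the sample.
#' @param control replicates x pressures matrix of the GFP control (same
#'   schedule).
#' @param schedule the shared [pressure_schedule()].
#' @param alpha significance level of the per-pressure test.
#' @return list with `P_o` (kPa, `NA` if not detected), `detected`,
#'   `detection_index` (grid index of the first significant pressure),
#'   `detection_limit` (a.u.).
#' @export
estimate_po <- function(curves, control, schedule = default_schedule(),
                        alpha = 0.05) {
  curves <- as.matrix(curves); control <- as.matrix(control)
  if (nrow(curves) < 2L || nrow(control) < 2L)
    stop("need at least 2 replicates for sample and control")
  p <- schedule_pressures(schedule)
  if (ncol(curves) != length(p) || ncol(control) != length(p))
    stop("curve columns must match the schedule")
  limit <- mean(control) + 2 * sd(control)
  m <- colMeans(curves)
  k <- NA_integer_
  for (j in seq_along(p)) {
    if (m[j] >= limit &&
        welch_greater_p(curves[, j], control[, j]) < alpha) { k <- j; break }
  }
  if (is.na(k))
    return(list(P_o = NA_real_, detected = FALSE,
                detection_index = NA_integer_, detection_limit = limit))
  j <- which(m[seq_len(k)] >= limit)[1L]
  if (j == 1L) {
    P_o <- p[1L]
  } else if (m[j - 1L] > 0 && limit > 0) {
    # exponential-phase crossing: interpolate the log-signal chord
    P_o <- p[j - 1L] + (log(limit) - log(m[j - 1L])) /
      (log(m[j]) - log(m[j - 1L])) * (p[j] - p[j - 1L])
  } else {
    P_o <- p[j - 1L] + (limit - m[j - 1L]) / (m[j] - m[j - 1L]) *
      (p[j] - p[j - 1L])
  }
  list(P_o = unname(P_o), detected = TRUE, detection_index = k,
       detection_limit = limit)
}

#' Estimate the maximum nonlinear yield S_max
#'
#' Maximum of the mean signal curve over scheduled pressures within the
#' nondestructive pressure window (at or below `window_cap`).
#'
#' @param curves replicates x pressures matrix (or a single curve vector).
#' @param schedule the [pressure_schedule()].
#' @param window_cap nondestructive upper limit, kPa.
#' @return list with `S_max` (a.u.) and `at_pressure` (kPa).
#' @export
estimate_smax <- function(curves, schedule = default_schedule(),
                          window_cap = schedule$window_cap) {
  p <- schedule_pressures(schedule)
  m <- if (is.matrix(curves)) colMeans(curves) else as.numeric(curves)
  if (length(m) != length(p)) stop("curve length must match the schedule")
  keep <- p <= window_cap
  if (!any(keep)) stop("no scheduled pressures within the window")
  i <- which(keep)[which.max(m[keep])]
  list(S_max = unname(m[i]), at_pressure = unname(p[i]))
}

#' Simulate a collapse-exposure sweep
#'
#' Surviving signal fraction of a reporter after exposure to increasing
#' maximum applied pressures: `1 - collapse_fraction(model, p)` per grid
#' pressure. This is the synthetic input to [estimate_pc()].
#'
#' @param model a [reporter_model()].
#' @param max_pressures grid of maximum applied pressures, kPa.
#' @return data.frame with `max_pressure_kpa`, `surviving_fraction`.
#' @export
collapse_survival_sweep <- function(model, max_pressures) {
  data.frame(max_pressure_kpa = max_pressures,
             surviving_fraction = 1 - collapse_fraction(model, max_pressures))
}

#' Estimate the collapse pressure P_c
#'
#' Linear interpolation of the pressure at which the surviving signal
#' fraction crosses 0.5. The sweep must cover the transition (fractions both
#' above and below 0.5).
#'
#' @param max_pressures increasing applied-pressure grid, kPa.
#' @param surviving_fraction surviving signal fraction at each grid point.
#' @return list with `P_c` (kPa).
#' @export
estimate_pc <- function(max_pressures, surviving_fraction) {
  stopifnot(length(max_pressures) == length(surviving_fraction))
  if (!any(surviving_fraction > 0.5) || !any(surviving_fraction < 0.5))
    stop("sweep does not cover the collapse transition")
  above <- which(surviving_fraction >= 0.5)
  i <- max(above[above < which(surviving_fraction < 0.5)[1L]])
  j <- i + 1L
  P_c <- max_pressures[i] +
    (0.5 - surviving_fraction[i]) /
    (surviving_fraction[j] - surviving_fraction[i]) *
    (max_pressures[j] - max_pressures[i])
  list(P_c = P_c)
}

#' Characterize every kept record of a screening plate
#'
#' Runs [estimate_po()] (against shared GFP-control replicates) and
#' [estimate_smax()] on each kept record's replicate curves.
#'
#' @param plate a [make_screen_plate()] result.
#' @param control control replicates x pressures matrix; generated from
#'   [gfp_control_model()] with the plate's noise if omitted. A screening
#'   plate dedicates a strip of GFP-control wells, so the default pools
#'   `n_control` replicates — a stable detection limit matters more for a
#'   whole library than for a single sample.
#' @param s_b_min,postcollapse_max QC thresholds, see [qc_filter()].
#' @param alpha significance level for threshold detection.
#' @param n_control generated control replicates when `control` is omitted.
#' @param control_seed seed for the generated control replicates.
#' @return data.frame: the QC-annotated records plus `P_o_hat` and
#'   `S_max_hat` (`NA` for excluded or undetected records).
#' @export
characterize_plate <- function(plate, control = NULL, s_b_min = 175,
                               postcollapse_max = 100, alpha = 0.05,
                               n_control = 16L, control_seed = 1L) {
  stopifnot(inherits(plate, "screen_plate"))
  qc <- qc_filter(plate$records, s_b_min, postcollapse_max)
  rec <- qc$records
  if (is.null(control))
    control <- make_reference_replicates(gfp_control_model(), plate$schedule,
                                         n = n_control,
                                         noise_sd = plate$noise_sd,
                                         seed = control_seed)
  rec$P_o_hat <- NA_real_
  rec$S_max_hat <- NA_real_
  for (i in which(rec$kept)) {
    cur <- plate$curves[[rec$variant_id[i]]]
    rec$P_o_hat[i] <- estimate_po(cur, control, plate$schedule, alpha)$P_o
    rec$S_max_hat[i] <- estimate_smax(cur, plate$schedule)$S_max
  }
  rec
}

# ---- acoustic map -----------------------------------------------------------

#' Fit the acoustic-map trend
#'
#' Least-squares fit of `S_max = a + b * ln(P_o)` over the kept variants of a
#' screening library; on mutagenesis libraries the slope is negative (shells
#' needing more force to buckle deform less once buckled).
#'
#' @param P_o thresholds, kPa (> 0).
#' @param S_max yields, a.u.
#' @return list with `a`, `b`, `r_squared`, `n`, `degenerate` (TRUE when
#'   only two points define the fit) and the `lm` fit object.
#' @export
fit_acoustic_map <- function(P_o, S_max) {
  ok <- complete.cases(P_o, S_max)
  P_o <- P_o[ok]; S_max <- S_max[ok]
  if (any(P_o <= 0)) stop("P_o must be > 0")
  if (length(P_o) < 2L) stop("need at least 2 points")
  degenerate <- length(P_o) == 2L
  if (degenerate) warning("only 2 points: fit is exact and degenerate")
  fit <- lm(S_max ~ log(P_o))
  list(a = unname(coef(fit)[1L]), b = unname(coef(fit)[2L]),
       r_squared = if (degenerate) 1 else summary(fit)$r.squared,
       n = length(P_o), degenerate = degenerate, fit = fit)
}

#' Assign acoustic-map points to named regions
#'
#' Point-in-polygon labelling of `(P_o, S_max)` points against user-supplied
#' region polygons (e.g. primary sink, secondary sink, bridge). Polygons are
#' tested in list order (priority order): the first polygon containing a
#' point wins, so a point on a shared edge takes the earlier region's label.
#' Points in no polygon are labelled `"outlier"`.
#'
#' @param P_o,S_max point coordinates.
#' @param polygons named list of two-column matrices (columns `P_o`, `S_max`)
#'   giving polygon vertices.
#' @return character vector of region labels.
#' @export
assign_regions <- function(P_o, S_max, polygons) {
  pts <- cbind(P_o, S_max)
  labels <- rep("outlier", nrow(pts))
  if (length(polygons) == 0L) return(labels)
  if (is.null(names(polygons)) || any(names(polygons) == ""))
    stop("polygons must be named")
  # iterate lowest priority first so earlier (higher priority) polygons
  # overwrite later ones
  for (nm in rev(names(polygons))) {
    bnd <- as.matrix(polygons[[nm]])
    if (ncol(bnd) != 2L || nrow(bnd) < 3L)
      stop("polygon '", nm, "' must be a >= 3 row, 2-column matrix")
    inside <- mgcv::in.out(bnd, pts)
    labels[inside] <- nm
  }
  labels
}

# ---- image-quality metrics --------------------------------------------------

#' Contrast-to-noise ratio of a target region
#'
#' `CNR = |S_target - S_background| / sigma_background` with `S` the region
#' mean signals and `sigma` the background standard deviation.
#'
#' @param image numeric matrix (one frame).
#' @param target_roi,background_roi disjoint nonempty logical masks.
#' @return list with `S_target`, `S_background`, `sigma_background`, `cnr`.
#' @export
compute_cnr <- function(image, target_roi, background_roi) {
  if (!any(target_roi) || !any(background_roi)) stop("ROIs must be nonempty")
  if (any(target_roi & background_roi)) stop("ROIs must be disjoint")
  s_t <- mean(image[target_roi])
  s_b <- mean(image[background_roi])
  sig <- sd(image[background_roi])
  if (!is.finite(sig) || sig == 0) stop("background s.d. is zero")
  list(S_target = s_t, S_background = s_b, sigma_background = sig,
       cnr = abs(s_t - s_b) / sig)
}

#' Per-pressure signal fold change in decibels
#'
#' `20 * log10(a / b)` per pressure under the amplitude convention (pressure
#' is an amplitude quantity); `10 * log10` available as the power convention.
#' Pressures where either curve is nonpositive yield `NA`.
#'
#' @param curve_a,curve_b signal curves on a shared schedule, a.u.
#' @param convention `"amplitude"` (20 log10) or `"power"` (10 log10).
#' @return numeric vector of dB values.
#' @export
signal_fold_change_db <- function(curve_a, curve_b,
                                  convention = c("amplitude", "power")) {
  convention <- match.arg(convention)
  if (length(curve_a) != length(curve_b))
    stop("curves must share one schedule")
  k <- if (convention == "amplitude") 20 else 10
  out <- rep(NA_real_, length(curve_a))
  ok <- curve_a > 0 & curve_b > 0
  out[ok] <- k * log10(curve_a[ok] / curve_b[ok])
  out
}
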