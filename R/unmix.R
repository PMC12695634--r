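#' Multiplexing matrix of reference spectra
#'
#' An `N x P` matrix whose row `r`, column `p` entry is the nonlinear signal
#' of reporter `r` at the `p`-th scheduled pressure. Columns above the
#' nondestructive window cap are never present: they are trimmed from the
#' tail of the series before the matrix is built.
#'
#' @param M numeric `N x P` matrix, entries >= 0.
#' @param reporters character vector of `N` reporter labels.
#' @param schedule [pressure_schedule()] of the `P` retained acquisitions.
#' @return object of class `multiplex_matrix`.
#' @export
multiplex_matrix <- function(M, reporters, schedule) {
  M <- as.matrix(M)
  if (any(M < 0)) stop("multiplexing matrix entries must be >= 0")
  if (nrow(M) < 1L) stop("need at least one reporter row")
  if (any(apply(M, 1L, function(r) all(r == 0))))
    stop("multiplexing matrix rows must not be all-zero")
  if (length(reporters) != nrow(M)) stop("one label per row required")
  if (length(schedule_pressures(schedule)) != ncol(M))
    stop("one schedule pressure per column required")
  dimnames(M) <- list(reporter = reporters,
                      pressure_kpa = format(round(schedule_pressures(schedule), 1),
                                            trim = TRUE))
  if (qr(M)$rank < nrow(M))
    warning("multiplexing matrix is rank-deficient; unmixing is ambiguous")
  structure(list(M = M, reporters = reporters,
                 schedule = if (inherits(schedule, "pressure_schedule"))
                   schedule else pressure_schedule(schedule)),
            class = "multiplex_matrix")
}

#' @export
print.multiplex_matrix <- function(x, ...) {
  cat(sprintf("<multiplex_matrix> %d reporters x %d pressures (<= %.0f kPa)\n",
              nrow(x$M), ncol(x$M), x$schedule$window_cap))
  print(round(x$M, 1))
  invisible(x)
}

trim_to_cap <- function(schedule, cap = schedule$window_cap) {
  p <- schedule_pressures(schedule)
  keep <- p <= cap
  if (!any(keep)) stop("no scheduled pressures at or below the window cap")
  list(keep = which(keep),
       schedule = pressure_schedule(p[keep], min(cap, max(p[keep]))))
}

#' Build the multiplexing matrix from reference acquisitions
#'
#' Each reference series images a pure population of one reporter; row `r`,
#' column `p` of `M` is the mean nonlinear signal over the reference's sample
#' ROI at scheduled pressure `p`. Acquisitions above the nondestructive
#' window cap (the collapse pressure of the most fragile reporter) are
#' removed from the tail of every series before the matrix is assembled.
#'
#' @param reference_series named list of `nl_image_series`, one per reporter;
#'   each must carry a `sample` ROI (or pass `rois`).
#' @param rois optional named list of logical masks overriding the series'
#'   own sample ROIs.
#' @param cap window cap, kPa; defaults to the shared schedule's cap.
#' @return a [multiplex_matrix()] with the tail-trimmed schedule.
#' @export
build_multiplex_matrix <- function(reference_series, rois = NULL, cap = NULL) {
  stopifnot(length(reference_series) >= 1L)
  if (is.null(names(reference_series)) || any(names(reference_series) == ""))
    stop("reference series must be named by reporter")
  sched <- reference_series[[1L]]$schedule
  for (s in reference_series)
    if (!isTRUE(all.equal(s$schedule$pressures, sched$pressures)))
      stop("all reference series must share one schedule")
  if (is.null(cap)) cap <- sched$window_cap
  tr <- trim_to_cap(sched, cap)
  rows <- lapply(names(reference_series), function(nm) {
    s <- reference_series[[nm]]
    roi <- if (!is.null(rois)) rois[[nm]] else s$rois$sample
    if (is.null(roi) || !any(roi)) stop("empty or missing sample ROI for ", nm)
    vapply(tr$keep, function(j) mean(s$frames[, , j][roi]), 0)
  })
  multiplex_matrix(pmax(do.call(rbind, rows), 0),
                   reporters = names(reference_series),
                   schedule = tr$schedule)
}

#' Multiplexing matrix straight from reporter models
#'
#' Noiseless matrix built from the forward model: each row is the
#' collapse-aware sweep of one reporter, evaluated at the in-situ pressure at
#' `reference_depth_mm` under the attenuation model (reference samples are
#' calibrated by hydrophone at a fixed depth). With `att = NULL` the
#' scheduled pressures are used directly.
#'
#' @param models named list of [reporter_model()]s.
#' @param schedule a [pressure_schedule()].
#' @param att optional [attenuation_model()].
#' @param reference_depth_mm calibration depth, mm (default 5).
#' @param cap window cap, kPa.
#' @return a [multiplex_matrix()].
#' @export
multiplex_matrix_from_models <- function(models, schedule = default_schedule(),
                                         att = NULL, reference_depth_mm = 5,
                                         cap = NULL) {
  if (is.null(names(models))) names(models) <- vapply(models, `[[`, "", "name")
  if (is.null(cap)) cap <- schedule$window_cap
  tr <- trim_to_cap(schedule, cap)
  p_src <- schedule_pressures(tr$schedule)
  p_eff <- if (is.null(att)) p_src else
    attenuated_pressure(att, p_src, reference_depth_mm / 10)
  rows <- lapply(models, function(m) {
    sweep_with_collapse(m, pressure_schedule(p_eff, max(p_eff)))$signals
  })
  multiplex_matrix(do.call(rbind, rows), names(models), tr$schedule)
}

#' Pixels with detectable nonlinear signal
#'
#' A pixel passes if its nonlinear signal surpasses `cutoff` at any acquired
#' pressure; pixels that never do are zeroed out of the coefficient map.
#' Default cutoffs are ~100 a.u. for in vitro samples and ~200 a.u. for
#' in vivo images.
#'
#' @param series an `nl_image_series`.
#' @param cutoff signal threshold, a.u. (>= 0).
#' @param mode `"invitro"` or `"invivo"`; sets the default cutoff.
#' @return logical Z x X mask.
#' @export
threshold_pixels <- function(series, cutoff = NULL,
                             mode = c("invitro", "invivo")) {
  mode <- match.arg(mode)
  if (is.null(cutoff)) cutoff <- if (mode == "invitro") 100 else 200
  if (cutoff < 0) stop("cutoff must be >= 0")
  apply(series$frames, c(1L, 2L), max) >= cutoff
}

# exact nonnegative least squares for min || A c - b ||, c >= 0
nnls_solve <- function(A, b) {
  n <- ncol(A)
  if (n == 2L) {
    # closed form: interior stationary point, else best single-column fit
    g <- crossprod(A)             # 2x2 Gram matrix
    h <- crossprod(A, b)
    det <- g[1L, 1L] * g[2L, 2L] - g[1L, 2L]^2
    if (det > .Machine$double.eps * g[1L, 1L] * g[2L, 2L]) {
      c_int <- c(g[2L, 2L] * h[1L] - g[1L, 2L] * h[2L],
                 g[1L, 1L] * h[2L] - g[1L, 2L] * h[1L]) / det
      if (all(c_int >= 0)) {
        r <- b - A %*% c_int
        return(list(x = c_int, resid = sqrt(sum(r^2))))
      }
    }
    # all-zero reference rows (e.g. sub-threshold depths) get coefficient 0
    c1 <- if (g[1L, 1L] > 0) max(h[1L] / g[1L, 1L], 0) else 0
    c2 <- if (g[2L, 2L] > 0) max(h[2L] / g[2L, 2L], 0) else 0
    r1 <- sum((b - A[, 1L] * c1)^2)
    r2 <- sum((b - A[, 2L] * c2)^2)
    if (r1 <= r2) list(x = c(c1, 0), resid = sqrt(r1))
    else list(x = c(0, c2), resid = sqrt(r2))
  } else {
    fit <- pracma::lsqnonneg(A, b)
    list(x = fit$x, resid = sqrt(fit$resid.norm))
  }
}

match_series_columns <- function(series, pressures, tol = 0.5) {
  sp <- series$schedule$pressures
  idx <- vapply(pressures, function(p) {
    j <- which.min(abs(sp - p))
    if (abs(sp[j] - p) > tol) NA_integer_ else j
  }, 0L)
  if (any(is.na(idx)))
    stop("series schedule does not contain the multiplexing-matrix pressures")
  idx
}

new_coefficient_map <- function(C, residual, reporters, mask) {
  dimnames(C)[[3L]] <- reporters
  structure(list(C = C, residual = residual, reporters = reporters,
                 mask = mask), class = "coefficient_map")
}

#' @export
print.coefficient_map <- function(x, ...) {
  d <- dim(x$C)
  cat(sprintf("<coefficient_map> %d x %d pixels x %d channels (%s); %d unmixed pixels\n",
              d[1L], d[2L], d[3L], paste(x$reporters, collapse = ", "),
              sum(x$mask)))
  invisible(x)
}

#' Pixelwise non-negative least-squares unmixing
#'
#' For each masked pixel, the pressure spectrum `lambda(z, x, .)` is
#' decomposed over the reference spectra by solving
#' `argmin_{c >= 0} || t(M) c - lambda ||_2` (Lawson-Hanson active-set
#' semantics). The coefficients form the per-reporter "acoustic channel"
#' images; pixels outside the mask are all-zero with residual flagged `NA`.
#' Frames above the window cap are ignored (the matrix never contains them).
#'
#' @param series an `nl_image_series`.
#' @param M a [multiplex_matrix()].
#' @param mask logical Z x X pixel mask; defaults to
#'   [threshold_pixels()] at the in vitro cutoff.
#' @param ... passed to [threshold_pixels()] when `mask` is `NULL`.
#' @return object of class `coefficient_map`: `C` (Z x X x N, >= 0),
#'   `residual` (Z x X fit residual norm, `NA` where masked out), `reporters`,
#'   `mask`.
#' @export
unmix_pixelwise <- function(series, M, mask = NULL, ...) {
  stopifnot(inherits(series, "nl_image_series"), inherits(M, "multiplex_matrix"))
  cols <- match_series_columns(series, schedule_pressures(M$schedule))
  if (is.null(mask)) mask <- threshold_pixels(series, ...)
  Z <- dim(series$frames)[1L]; X <- dim(series$frames)[2L]
  N <- nrow(M$M)
  A <- t(M$M)
  C <- array(0, dim = c(Z, X, N))
  residual <- matrix(NA_real_, Z, X)
  for (z in seq_len(Z)) for (x in seq_len(X)) {
    if (!mask[z, x]) next
    fit <- nnls_solve(A, series$frames[z, x, cols])
    C[z, x, ] <- fit$x
    residual[z, x] <- fit$resid
  }
  new_coefficient_map(C, residual, M$reporters, mask)
}

# ---- depth-corrected unmixing -----------------------------------------------

#' Depth-resolved multiplexing matrix M(d)
#'
#' With tissue attenuation, the in-situ pressure a pixel experiences depends
#' on its depth, so a single reference matrix acquired at one calibration
#' depth misrepresents the spectra elsewhere. `build_m2d` evaluates each
#' reporter's collapse-aware sweep at the attenuated in-situ pressures of
#' every depth, producing one multiplexing matrix per depth row.
#'
#' @param models named list of [reporter_model()]s.
#' @param att an [attenuation_model()].
#' @param depth_axis depths of the image rows, mm from the transducer face.
#' @param schedule source-amplitude [pressure_schedule()].
#' @param cap window cap on source amplitudes, kPa.
#' @return object of class `depth_multiplex_matrix`: `stack` (list of N x P
#'   matrices, one per depth), `depth_axis` (mm), `reporters`, `schedule`.
#' @export
build_m2d <- function(models, att, depth_axis, schedule = default_schedule(),
                      cap = NULL) {
  stopifnot(inherits(att, "attenuation_model"))
  if (length(depth_axis) > 1L && any(diff(depth_axis) <= 0))
    stop("depth_axis must be strictly increasing")
  if (is.null(names(models))) names(models) <- vapply(models, `[[`, "", "name")
  if (is.null(cap)) cap <- schedule$window_cap
  tr <- trim_to_cap(schedule, cap)
  p_src <- schedule_pressures(tr$schedule)
  stack <- lapply(depth_axis, function(d) {
    p_eff <- attenuated_pressure(att, p_src, d / 10)
    m <- do.call(rbind, lapply(models, function(mod)
      sweep_with_collapse(mod, pressure_schedule(p_eff, max(p_eff)))$signals))
    rownames(m) <- names(models)
    m
  })
  structure(list(stack = stack, depth_axis = depth_axis,
                 reporters = names(models), schedule = tr$schedule, att = att),
            class = "depth_multiplex_matrix")
}

#' @export
print.depth_multiplex_matrix <- function(x, ...) {
  cat(sprintf("<depth_multiplex_matrix> %d depths (%.1f-%.1f mm), %d reporters x %d pressures\n",
              length(x$depth_axis), min(x$depth_axis), max(x$depth_axis),
              length(x$reporters), ncol(x$stack[[1L]])))
  invisible(x)
}

#' Depth-corrected pixelwise unmixing
#'
#' Identical contract to [unmix_pixelwise()] but each image row is unmixed
#' against the multiplexing matrix of its own depth, `M(d)`. Rows are matched
#' to the nearest `M2d` depth; a mismatch beyond half a row spacing is an
#' error (explicit failure rather than silent interpolation). With zero
#' attenuation every `M(d)` is identical and the result reduces exactly to
#' flat unmixing.
#'
#' @param series an `nl_image_series` (must carry a depth axis).
#' @param m2d a [build_m2d()] result.
#' @param mask logical pixel mask; defaults to [threshold_pixels()].
#' @param ... passed to [threshold_pixels()] when `mask` is `NULL`.
#' @return a `coefficient_map`.
#' @export
unmix_depth_corrected <- function(series, m2d, mask = NULL, ...) {
  stopifnot(inherits(series, "nl_image_series"),
            inherits(m2d, "depth_multiplex_matrix"))
  cols <- match_series_columns(series, schedule_pressures(m2d$schedule))
  if (is.null(mask)) mask <- threshold_pixels(series, ...)
  half <- if (length(m2d$depth_axis) > 1L)
    min(diff(m2d$depth_axis)) / 2 else Inf
  row_idx <- vapply(series$depth_axis, function(d) {
    j <- which.min(abs(m2d$depth_axis - d))
    if (abs(m2d$depth_axis[j] - d) > half + 1e-9)
      stop("series depth axis does not align with M2d depth axis")
    j
  }, 0L)
  Z <- dim(series$frames)[1L]; X <- dim(series$frames)[2L]
  N <- length(m2d$reporters)
  C <- array(0, dim = c(Z, X, N))
  residual <- matrix(NA_real_, Z, X)
  for (z in seq_len(Z)) {
    A <- t(m2d$stack[[row_idx[z]]])
    for (x in seq_len(X)) {
      if (!mask[z, x]) next
      fit <- nnls_solve(A, series$frames[z, x, cols])
      C[z, x, ] <- fit$x
      residual[z, x] <- fit$resid
    }
  }
  new_coefficient_map(C, residual, m2d$reporters, mask)
}

# ---- channel summaries ------------------------------------------------------

#' Normalized difference between two acoustic channels
#'
#' Per-pixel bounded contrast between the two unmixed channels. The default
#' `corrected` variant is `(S1 - S2) / sqrt(S1^2 + S2^2)`, bounded in
#' `[-1, 1]` and antisymmetric under channel swap. The `as_printed` variant
#' uses the difference of squares under the radical, `sqrt(S1^2 - S2^2)`,
#' and returns `NA` wherever the radicand is not positive. Pixels with both
#' channels zero are `NA` in both variants.
#'
#' @param cmap a `coefficient_map` with exactly two channels.
#' @param variant `"corrected"` or `"as_printed"`.
#' @return object of class `nd_map`: `nd` (Z x X, `NA` where undefined) and
#'   `variant`.
#' @export
normalized_difference <- function(cmap, variant = c("corrected", "as_printed")) {
  variant <- match.arg(variant)
  stopifnot(inherits(cmap, "coefficient_map"))
  if (dim(cmap$C)[3L] != 2L)
    stop("normalized difference requires exactly two channels")
  s1 <- cmap$C[, , 1L]; s2 <- cmap$C[, , 2L]
  num <- s1 - s2
  if (variant == "corrected") {
    den <- sqrt(s1^2 + s2^2)
  } else {
    den <- s1^2 - s2^2
    den[den <= 0] <- NA_real_   # nonpositive radicand: undefined as printed
    den <- sqrt(den)
  }
  nd <- ifelse(s1 == 0 & s2 == 0, NA_real_, num / den)
  structure(list(nd = nd, variant = variant,
                 reporters = cmap$reporters), class = "nd_map")
}

#' @export
print.nd_map <- function(x, ...) {
  cat(sprintf("<nd_map> %s variant, %d defined pixels (range %.2f to %.2f)\n",
              x$variant, sum(!is.na(x$nd)),
              suppressWarnings(min(x$nd, na.rm = TRUE)),
              suppressWarnings(max(x$nd, na.rm = TRUE))))
  invisible(x)
}

#' Per-channel mean signal over an ROI
#'
#' Mean and standard error of each acoustic channel over the ROI pixels.
#' When a list of replicate coefficient maps is given, the s.e.m. is computed
#' across replicate ROI means (the between-sample error); otherwise across
#' pixels. The basis is reported in the output.
#'
#' @param cmap a `coefficient_map`, or a list of replicate maps.
#' @param roi logical Z x X mask (nonempty).
#' @return data.frame with `reporter`, `mean`, `sem`, `n`, `sem_basis`.
#' @export
channel_means <- function(cmap, roi) {
  if (inherits(cmap, "coefficient_map")) {
    if (!any(roi)) stop("ROI must be nonempty")
    N <- dim(cmap$C)[3L]
    out <- data.frame(
      reporter = cmap$reporters,
      mean = vapply(seq_len(N), function(k) mean(cmap$C[, , k][roi]), 0),
      sem = vapply(seq_len(N), function(k) {
        v <- cmap$C[, , k][roi]
        sd(v) / sqrt(length(v))
      }, 0),
      n = sum(roi), sem_basis = "pixels", stringsAsFactors = FALSE)
    return(out)
  }
  # replicate maps: sem across replicate ROI means
  per_rep <- lapply(cmap, function(cm) channel_means(cm, roi)$mean)
  mat <- do.call(rbind, per_rep)
  data.frame(reporter = cmap[[1L]]$reporters,
             mean = colMeans(mat),
             sem = apply(mat, 2L, sd) / sqrt(nrow(mat)),
             n = nrow(mat), sem_basis = "replicates",
             stringsAsFactors = FALSE)
}

#' Linearity of unmixed channel fraction against mixture composition
#'
#' Ordinary least-squares fit of the first-channel fraction
#' `S1 / (S1 + S2)` against the known volume fraction of the first reporter
#' across a mixture series.
#'
#' @param volume_fractions known volume fractions (>= 3 distinct values).
#' @param channel_fractions measured channel fractions, same length.
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
mixture_linearity <- function(volume_fractions, channel_fractions) {
  if (length(unique(volume_fractions)) < 3L)
    stop("need at least 3 distinct volume fractions")
  if (length(volume_fractions) != length(channel_fractions))
    stop("inputs must have equal length")
  fit <- lm(channel_fractions ~ volume_fractions)
  tss <- sum((channel_fractions - mean(channel_fractions))^2)
  r2 <- if (tss > 0) 1 - sum(residuals(fit)^2) / tss else 1
  list(slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       r_squared = r2)
}

#' Per-depth channel cross-talk of a pure-population scene
#'
#' For a scene containing only the `on` reporter, cross-talk at a depth row
#' is the mean off-channel coefficient divided by the mean on-channel
#' coefficient over that row's unmixed pixels. Rows whose on-channel mean is
#' below `min_on` (unidentifiable, e.g. below threshold) are `NA`.
#'
#' @param cmap a two-channel `coefficient_map`.
#' @param on name or index of the true (on) channel.
#' @param min_on minimum on-channel mean for a defined ratio.
#' @return numeric vector, one ratio per image row.
#' @export
channel_crosstalk <- function(cmap, on, min_on = 1e-6) {
  stopifnot(inherits(cmap, "coefficient_map"))
  if (is.character(on)) on <- match(on, cmap$reporters)
  off <- setdiff(seq_len(dim(cmap$C)[3L]), on)
  if (length(off) != 1L) stop("cross-talk is defined for two channels")
  Z <- dim(cmap$C)[1L]
  vapply(seq_len(Z), function(z) {
    sel <- cmap$mask[z, ]
    if (!any(sel)) return(NA_real_)
    on_mean <- mean(cmap$C[z, , on][sel])
    if (on_mean < min_on) return(NA_real_)
    mean(cmap$C[z, , off][sel]) / on_mean
  }, 0)
}
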