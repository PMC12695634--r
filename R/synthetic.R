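#' Noise specification for image series
#'
#' Additive zero-mean noise whose per-acquisition spread matches a background
#' region: the noisy series is `I(m) = I0 + m * R`, where `R` has mean 0 and a
#' per-frame standard deviation equal to that of the background region of the
#' original series (or an explicit per-pressure s.d. list).
#'
#' @param m dimensionless noise multiplier (>= 0).
#' @param background_sd_per_pressure optional numeric vector, one s.d. (a.u.)
#'   per pressure acquisition; if `NULL`, [add_noise()] measures it from the
#'   series' background ROI.
#' @param seed optional integer seed making the injected noise reproducible.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(m = 1, background_sd_per_pressure = NULL, seed = NULL) {
  if (!is.finite(m) || m < 0) stop("m must be >= 0")
  if (!is.null(background_sd_per_pressure) &&
      any(background_sd_per_pressure < 0))
    stop("background s.d. values must be >= 0")
  structure(list(m = m, background_sd_per_pressure = background_sd_per_pressure,
                 seed = seed), class = "noise_spec")
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Replicate reference curves for one reporter
#'
#' Emulates imaging replicate reference samples across the pressure domain:
#' each replicate is the collapse-aware sweep of the model plus i.i.d.
#' zero-mean Gaussian noise (s.d. `noise_sd`), clipped at zero since nonlinear
#' signal magnitudes are nonnegative.
#'
#' @param model a [reporter_model()].
#' @param schedule a [pressure_schedule()].
#' @param n number of replicates (>= 1).
#' @param noise_sd Gaussian noise s.d., a.u. (>= 0).
#' @param seed integer seed.
#' @return `n` x `P` matrix of signals (a.u.); columns named by pressure (kPa).
#' @export
make_reference_replicates <- function(model, schedule = default_schedule(),
                                      n = 4, noise_sd = default_noise_sd(),
                                      seed = NULL) {
  stopifnot(n >= 1)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  clean <- sweep_with_collapse(model, schedule)$signals
  p <- schedule_pressures(schedule)
  with_seed_if(seed, {
    noise <- matrix(rnorm(n * length(p), sd = noise_sd), nrow = n)
    curves <- pmax(sweep(noise, 2L, clean, `+`), 0)
    dimnames(curves) <- list(replicate = seq_len(n),
                             pressure_kpa = format(round(p, 1), trim = TRUE))
    curves
  })
}

# ---- scenes -----------------------------------------------------------------

#' A 2-D imaging scene
#'
#' Defines the spatial layout the renderer turns into a nonlinear image
#' series: per-reporter relative-concentration maps on a depth-by-lateral
#' pixel grid, plus named ROI masks. Row 1 is the shallowest depth, located
#' `depth_offset_mm` from the transducer face; depth increases with row index.
#'
#' @param concentration_maps named list of Z x X nonnegative matrices, one per
#'   reporter (names must match the reporter models passed to
#'   [render_scene()]).
#' @param rois named list of Z x X logical masks; a `sample` and a
#'   `background` mask are conventional.
#' @param pixel_spacing_mm pixel pitch, mm.
#' @param depth_offset_mm depth of the first row from the transducer face, mm.
#' @return object of class `scene`.
#' @export
scene <- function(concentration_maps, rois = list(),
                  pixel_spacing_mm = 0.1, depth_offset_mm = 3) {
  if (length(concentration_maps) < 1L) stop("need at least one concentration map")
  if (is.null(names(concentration_maps)) || any(names(concentration_maps) == ""))
    stop("concentration_maps must be named by reporter")
  dims <- dim(concentration_maps[[1L]])
  for (m in concentration_maps) {
    if (!identical(dim(m), dims)) stop("all concentration maps must share one shape")
    if (any(m < 0)) stop("concentrations must be >= 0")
  }
  for (r in rois)
    if (!identical(dim(r), dims) || !is.logical(r))
      stop("ROIs must be logical masks of the image shape")
  structure(list(concentration_maps = concentration_maps, rois = rois,
                 shape = dims, pixel_spacing_mm = pixel_spacing_mm,
                 depth_offset_mm = depth_offset_mm),
            class = "scene")
}

#' Depth axis of a scene, mm from the transducer face
#' @param x a `scene` or `nl_image_series`.
#' @return numeric vector, one depth per image row.
#' @export
depth_axis_mm <- function(x) {
  if (inherits(x, "nl_image_series")) return(x$depth_axis)
  x$depth_offset_mm + (seq_len(x$shape[1L]) - 1L) * x$pixel_spacing_mm
}

#' Rectangular phantom scene with a well-shaped sample region
#'
#' Convenience constructor: a `Z x X` grid whose central block (the sample
#' well) carries the given per-reporter concentrations; everything outside is
#' background. Used as the standard phantom in tests and demos.
#'
#' @param concentrations named numeric vector of relative concentrations, one
#'   per reporter (e.g. `c(bARG560 = 0.5, bARG710 = 0.5)`).
#' @param shape `c(Z, X)` image shape in pixels.
#' @param sample_rows,sample_cols integer ranges of the sample block.
#' @inheritParams scene
#' @export
phantom_scene <- function(concentrations, shape = c(48, 48),
                          sample_rows = NULL, sample_cols = NULL,
                          pixel_spacing_mm = 0.25, depth_offset_mm = 3) {
  Z <- shape[1L]; X <- shape[2L]
  if (is.null(sample_rows)) sample_rows <- seq(max(1L, round(Z * 0.25)), round(Z * 0.75))
  if (is.null(sample_cols)) sample_cols <- seq(max(1L, round(X * 0.25)), round(X * 0.75))
  sample_mask <- matrix(FALSE, Z, X)
  sample_mask[sample_rows, sample_cols] <- TRUE
  maps <- lapply(concentrations, function(ci) {
    m <- matrix(0, Z, X); m[sample_mask] <- ci; m
  })
  names(maps) <- names(concentrations)
  bg <- !sample_mask
  # keep a clear margin between the sample and the background reference strip
  bg[, seq(min(sample_cols), max(sample_cols))] <- FALSE
  scene(maps, rois = list(sample = sample_mask, background = bg),
        pixel_spacing_mm = pixel_spacing_mm, depth_offset_mm = depth_offset_mm)
}

#' Render a scene into a nonlinear image series
#'
#' Forward-simulates the acquisition: for each scheduled source amplitude, the
#' in-situ pressure at each depth row follows the attenuation model (or equals
#' the scheduled pressure when `att` is `NULL`), each reporter contributes
#' `concentration * signal_at(...)`, and irreversible collapse is tracked per
#' depth row and reporter along the sweep (collapse applied after the frame at
#' that pressure is recorded). Companion images are also produced: a B-mode
#' frame rendered as an affine function of total concentration with a bright
#' top edge on the sample ROI (a deliberately simple expression/edge proxy),
#' and a postcollapse nonlinear frame at maximum pressure after exposing every
#' pixel to the maximum scheduled pressure.
#'
#' @param scn a [scene()].
#' @param models list of [reporter_model()]s named like the scene's
#'   concentration maps.
#' @param schedule a [pressure_schedule()].
#' @param att an [attenuation_model()], or `NULL` for a lossless medium.
#' @param noise a [noise_spec()], or `NULL` for a noiseless rendering.
#' @param bmode_scale B-mode a.u. per unit total concentration.
#' @param bmode_edge_gain brightness multiplier of the top-edge highlight.
#' @return object of class `nl_image_series`: `frames` (Z x X x P array,
#'   a.u.), `schedule`, `bmode`, `postcollapse`, `depth_axis` (mm), `rois`,
#'   `meta`.
#' @export
render_scene <- function(scn, models, schedule = default_schedule(),
                         att = NULL, noise = NULL,
                         bmode_scale = 350, bmode_edge_gain = 2) {
  stopifnot(inherits(scn, "scene"))
  if (is.null(names(models))) names(models) <- vapply(models, `[[`, "", "name")
  if (!setequal(names(models), names(scn$concentration_maps)))
    stop("need exactly one concentration map per reporter model")
  models <- models[names(scn$concentration_maps)]
  Z <- scn$shape[1L]; X <- scn$shape[2L]
  p_src <- schedule_pressures(schedule)
  P <- length(p_src)
  depth_cm <- depth_axis_mm(scn) / 10
  insitu <- if (is.null(att)) {
    matrix(p_src, nrow = Z, ncol = P, byrow = TRUE)
  } else {
    outer(depth_cm, p_src, function(d, s) attenuated_pressure(att, s, d))
  }

  frames <- array(0, dim = c(Z, X, P))
  nrep <- length(models)
  cf <- matrix(0, nrow = Z, ncol = nrep)  # collapse state per depth row x reporter
  for (j in seq_len(P)) {
    for (r in seq_len(nrep)) {
      sig_row <- signal_at(models[[r]], insitu[, j], cf[, r])
      frames[, , j] <- frames[, , j] + scn$concentration_maps[[r]] * sig_row
    }
    for (r in seq_len(nrep))
      cf[, r] <- pmax(cf[, r], collapse_fraction(models[[r]], insitu[, j]))
  }

  # postcollapse: expose everything to the max scheduled pressure, then image
  p_max_insitu <- insitu[, P]
  cf_post <- cf
  for (r in seq_len(nrep))
    cf_post[, r] <- pmax(cf_post[, r], collapse_fraction(models[[r]], p_max_insitu))
  postcollapse <- matrix(0, Z, X)
  for (r in seq_len(nrep))
    postcollapse <- postcollapse +
      scn$concentration_maps[[r]] * signal_at(models[[r]], p_max_insitu, cf_post[, r])

  total_conc <- Reduce(`+`, scn$concentration_maps)
  bmode <- bmode_scale * total_conc
  if (!is.null(scn$rois$sample)) {
    peak <- max(bmode, bmode_scale)
    for (x in seq_len(X)) {
      top <- which(scn$rois$sample[, x])[1L]
      if (!is.na(top)) bmode[top, x] <- bmode_edge_gain * peak
    }
  }

  series <- structure(list(
    frames = frames, schedule = if (inherits(schedule, "pressure_schedule"))
      schedule else pressure_schedule(schedule),
    bmode = bmode, postcollapse = postcollapse,
    depth_axis = depth_axis_mm(scn), rois = scn$rois,
    meta = list(reporters = names(models),
                att = if (is.null(att)) NULL else unclass(att),
                noise_seed = if (is.null(noise)) NULL else noise$seed)),
    class = "nl_image_series")
  if (!is.null(noise)) series <- add_noise(series, noise)
  series
}

#' @export
print.nl_image_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<nl_image_series> %d x %d pixels, %d pressure acquisitions (%.0f-%.0f kPa)\n",
              d[1L], d[2L], d[3L], min(x$schedule$pressures),
              max(x$schedule$pressures)))
  invisible(x)
}

#' Inject background-matched noise into an image series
#'
#' Implements `I(m) = I0 + m * R` with `R` zero-mean Gaussian whose per-frame
#' s.d. matches the background region of `I0` at each pressure acquisition
#' (or an explicit s.d. list). The same noise (scaled by the s.d. of the last
#' frame) is applied to the postcollapse image. `m = 0` returns the input
#' unchanged. Frames are not clipped, preserving the additive model exactly.
#'
#' @param series an `nl_image_series`.
#' @param noise a [noise_spec()].
#' @return a new `nl_image_series`.
#' @export
add_noise <- function(series, noise) {
  stopifnot(inherits(series, "nl_image_series"), inherits(noise, "noise_spec"))
  if (noise$m == 0) return(series)
  P <- dim(series$frames)[3L]
  sds <- noise$background_sd_per_pressure
  if (is.null(sds)) {
    bg <- series$rois$background
    if (is.null(bg)) stop("need a background ROI or an explicit s.d. list")
    sds <- vapply(seq_len(P), function(j) sd(series$frames[, , j][bg]), 0)
    sds[!is.finite(sds) | sds == 0] <- default_noise_sd()
  }
  if (length(sds) != P) stop("s.d. list length must equal the number of frames")
  Z <- dim(series$frames)[1L]; X <- dim(series$frames)[2L]
  with_seed_if(noise$seed, {
    for (j in seq_len(P))
      series$frames[, , j] <- series$frames[, , j] +
        noise$m * matrix(rnorm(Z * X, sd = sds[j]), Z, X)
    series$postcollapse <- series$postcollapse +
      noise$m * matrix(rnorm(Z * X, sd = sds[P]), Z, X)
  })
  series$meta$noise_m <- noise$m
  series
}

# ---- screening plates -------------------------------------------------------

#' Trait sampler for mutagenesis-library variants
#'
#' Draws `(P_o, S_max)` pairs along a negative logarithmic acoustic-map trend
#' `S_max = a + b * ln(P_o)` with Gaussian scatter: stiffer shells buckle at
#' higher pressures but deform less, yielding less signal. `P_o` is
#' log-normal around the parent threshold and truncated to the usable sweep
#' range; `S_max` is floored a factor of ~3 above the detection limit so
#' every variant remains a valid (if faint) reporter.
#'
#' @param n number of variants to draw.
#' @param log_po_mean,log_po_sd mean and s.d. of `log(P_o)`.
#' @param map_a,map_b intercept (a.u.) and slope (a.u. per log-kPa, negative)
#'   of the acoustic-map trend.
#' @param scatter_sd s.d. (a.u.) of the trend scatter.
#' @param po_range truncation range for `P_o`, kPa.
#' @param smax_min floor for `S_max`, a.u.
#' @return data.frame with columns `P_o`, `S_max`.
#' @export
sample_variant_traits <- function(n, log_po_mean = log(860), log_po_sd = 0.10,
                                  map_a = 36000, map_b = -5150,
                                  scatter_sd = 152,
                                  po_range = c(420, 1150), smax_min = 150) {
  P_o <- pmin(pmax(rlnorm(n, log_po_mean, log_po_sd), po_range[1L]), po_range[2L])
  S_max <- pmax(map_a + map_b * log(P_o) + rnorm(n, sd = scatter_sd), smax_min)
  data.frame(P_o = P_o, S_max = S_max)
}

#' Theoretical acoustic-map R-squared of the trait sampler
#'
#' Variance decomposition of the generating model: the coefficient of
#' determination of `S_max` against `ln(P_o)` is
#' `b^2 Var(ln P_o) / (b^2 Var(ln P_o) + scatter_sd^2)` (truncation and the
#' yield floor perturb this only slightly at the default settings).
#'
#' @inheritParams sample_variant_traits
#' @export
trait_trend_theoretical_r2 <- function(log_po_sd = 0.10, map_b = -5150,
                                       scatter_sd = 152) {
  v <- (map_b * log_po_sd)^2
  v / (v + scatter_sd^2)
}

# solid-phase expression mostly saturates; a minority of wells fail to
# assemble enough gas vesicles and land well below the S_B filter
default_expression_sampler <- function(n, fail_rate = 0.12) {
  fail <- runif(n) < fail_rate
  ifelse(fail, rlnorm(n, meanlog = log(0.25), sdlog = 0.3),
         rlnorm(n, meanlog = 0, sdlog = 0.05))
}

variant_reporter_model <- function(P_o, S_max, w = 50,
                                   detection_limit = control_detection_limit()) {
  # fraction capped below 1/2 so the logistic midpoint stays above P_o
  p_mid <- P_o - w * qlogis(min(detection_limit / S_max, 0.45))
  reporter_model("variant", P_o = P_o, S_max = S_max, P_c = p_mid + 400,
                 p_mid = p_mid, w = w)
}

#' Generate a synthetic 96-well-format screening plate
#'
#' Emulates one arrayed mutagenesis-library acquisition: each variant carries
#' a sampled reporter model (via [sample_variant_traits()]), an expression
#' scale that multiplies its yield and sets its B-mode intensity `S_B`, an
#' artifact flag (with probability `artifact_rate`) that injects spurious
#' nonlinear signal surviving the collapse pulse, and `n_rep` noisy measured
#' curves. The generating truth is stored alongside each record so QC and
#' parameter-recovery tests can check exactly which records should fail which
#' rule.
#'
#' @param n_variants number of library variants (>= 1).
#' @param trait_sampler function of `n` returning a data.frame with `P_o`,
#'   `S_max` columns.
#' @param expression_sampler function of `n` returning positive expression
#'   scales (1 = nominal expression).
#' @param artifact_rate probability a record is confounded by an artifact.
#' @param schedule a [pressure_schedule()].
#' @param n_rep replicates per measured curve.
#' @param noise_sd measurement noise s.d., a.u.
#' @param sb_scale B-mode a.u. per unit expression.
#' @param seed integer seed.
#' @return object of class `screen_plate`: `records` (data.frame with
#'   `variant_id`, `S_B`, `postcollapse_signal`, truth columns `true_P_o`,
#'   `true_S_max` (windowed operational yield), `true_S_max_param`
#'   (asymptotic model yield), `true_expression`, `artifact`) and `curves`
#'   (list of `n_rep` x `P` matrices).
#' @export
make_screen_plate <- function(n_variants = 96,
                              trait_sampler = sample_variant_traits,
                              expression_sampler = default_expression_sampler,
                              artifact_rate = 0.02,
                              schedule = default_schedule(),
                              n_rep = 4, noise_sd = default_noise_sd(),
                              sb_scale = 350, seed = NULL) {
  stopifnot(n_variants >= 1, artifact_rate >= 0, artifact_rate <= 1)
  p <- schedule_pressures(schedule)
  with_seed_if(seed, {
    traits <- trait_sampler(n_variants)
    expr <- expression_sampler(n_variants)
    artifact <- runif(n_variants) < artifact_rate
    S_B <- pmax(sb_scale * expr + rnorm(n_variants, sd = 10), 0)
    postcollapse <- ifelse(artifact, runif(n_variants, 150, 600),
                           abs(rnorm(n_variants, sd = 10)))
    curves <- vector("list", n_variants)
    cap <- if (inherits(schedule, "pressure_schedule"))
      schedule$window_cap else max(p)
    true_smax_windowed <- numeric(n_variants)
    for (i in seq_len(n_variants)) {
      mod <- variant_reporter_model(traits$P_o[i], traits$S_max[i])
      clean <- sweep_with_collapse(mod, schedule)$signals * expr[i]
      # operational yield truth: the windowed maximum of the noiseless curve
      # (high-threshold variants cannot express their full yield within the
      # nondestructive window, exactly as in a real screen)
      true_smax_windowed[i] <- max(clean[p <= cap])
      if (artifact[i]) clean <- clean + postcollapse[i]
      cur <- pmax(sweep(matrix(rnorm(n_rep * length(p), sd = noise_sd),
                               nrow = n_rep), 2L, clean, `+`), 0)
      dimnames(cur) <- list(replicate = seq_len(n_rep),
                            pressure_kpa = format(round(p, 1), trim = TRUE))
      curves[[i]] <- cur
    }
    records <- data.frame(
      variant_id = sprintf("var%04d", seq_len(n_variants)),
      S_B = S_B, postcollapse_signal = postcollapse,
      true_P_o = traits$P_o, true_S_max = true_smax_windowed,
      true_S_max_param = traits$S_max,
      true_expression = expr, artifact = artifact,
      stringsAsFactors = FALSE)
    names(curves) <- records$variant_id
    structure(list(records = records, curves = curves,
                   schedule = if (inherits(schedule, "pressure_schedule"))
                     schedule else pressure_schedule(schedule),
                   noise_sd = noise_sd, n_rep = n_rep),
              class = "screen_plate")
  })
}

#' @export
print.screen_plate <- function(x, ...) {
  cat(sprintf("<screen_plate> %d variants, %d replicates, %d pressures\n",
              nrow(x$records), x$n_rep, length(x$schedule$pressures)))
  invisible(x)
}

# ---- variant sequences ------------------------------------------------------

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Synthetic GvpC-like parent sequence
#'
#' A deterministic synthetic stand-in for the GvpC scaffold protein: an
#' N-terminal segment followed by five 33-residue helical repeats rich in
#' E/A/R (GvpC-family repeats are highly charged alpha-helices) and a short
#' C-terminal tail. It is not the natural sequence; it only provides a
#' realistic length (~190 aa) and repeat structure for alignment-distance
#' analyses.
#'
#' @return single character string (amino acids).
#' @export
synthetic_gvpc_parent <- function() {
  repeat_unit <- "AELQAFRHEVAEKLAAESQARLAETQDRLARLS"
  paste0("MSIQKDLLS", strrep(repeat_unit, 5), "GSSWAEEVAELRAAFDSFAE")
}

#' Generate a mutagenized protein variant library
#'
#' Per-sequence mutation counts are drawn from a wide (gamma-mixed Poisson,
#' i.e. negative binomial) distribution matching an error-prone PCR library
#' pooled over a broad mutagen range; defaults give mean 5.36 and s.d. 13.5
#' mutations per sequence. Mutations are point substitutions at distinct
#' positions, each replaced by a uniformly drawn different residue.
#'
#' @param parent parent amino-acid sequence (single string).
#' @param n number of variants.
#' @param rate_mean mean mutations per sequence.
#' @param rate_sd s.d. of mutations per sequence (> `sqrt(rate_mean)` for
#'   overdispersion; equal-dispersion falls back to Poisson).
#' @param seed integer seed.
#' @return object of class `variant_set`: `sequences` (named character
#'   vector), `n_mutations` (true counts), `parent`.
#' @export
make_variant_sequences <- function(parent, n, rate_mean = 5.36,
                                   rate_sd = 13.5, seed = NULL) {
  if (!nzchar(parent)) stop("parent sequence must be nonempty")
  parent_chars <- strsplit(parent, "")[[1L]]
  if (!all(parent_chars %in% c(AA20, "X")))
    stop("parent contains non-amino-acid characters")
  L <- length(parent_chars)
  with_seed_if(seed, {
    if (rate_mean == 0) {
      k <- integer(n)
    } else if (rate_sd^2 > rate_mean) {
      size <- rate_mean^2 / (rate_sd^2 - rate_mean)
      k <- stats::rnbinom(n, size = size, mu = rate_mean)
    } else {
      k <- rpois(n, rate_mean)
    }
    k <- pmin(k, L)
    seqs <- character(n)
    for (i in seq_len(n)) {
      chars <- parent_chars
      if (k[i] > 0) {
        pos <- sample.int(L, k[i])
        for (j in pos)
          chars[j] <- sample(setdiff(AA20, chars[j]), 1L)
      }
      seqs[i] <- paste(chars, collapse = "")
    }
    names(seqs) <- sprintf("var%04d", seq_len(n))
    structure(list(sequences = seqs, n_mutations = k, parent = parent),
              class = "variant_set")
  })
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("<variant_set> %d variants of a %d-aa parent (mean %.2f mutations)\n",
              length(x$sequences), nchar(x$parent), mean(x$n_mutations)))
  invisible(x)
}
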