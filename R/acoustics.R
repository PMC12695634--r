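#' Parametric pressure-response model of an acoustic reporter
#'
#' A reporter is summarized by its nonlinear signal threshold `P_o` (the
#' lowest peak positive pressure at which nonlinear signal exceeds a
#' GFP-control detection limit), its maximum nonlinear yield `S_max` within
#' the nondestructive pressure window, and its irreversible collapse pressure
#' `P_c`. The noiseless response curve is a scaled logistic
#' `baseline + S_max * plogis((P - p_mid) / w)`, attenuated multiplicatively
#' by the collapsed fraction of the gas-vesicle population.
#'
#' @param name reporter label.
#' @param P_o nonlinear signal threshold, kPa.
#' @param S_max maximum nonlinear yield, arbitrary units (a.u.).
#' @param P_c irreversible collapse pressure, kPa.
#' @param p_mid logistic midpoint of the response curve, kPa.
#' @param w logistic width, kPa.
#' @param baseline signal floor of the non-buckling state, a.u.
#' @param collapse_width width of the collapse transition, kPa; `0` gives a
#'   hard step at `P_c`.
#' @return an object of class `reporter_model`.
#' @seealso [calibrate_reporter()] for solving `p_mid` and `w` from nominal
#'   `P_o`/`S_max`, [default_reporters()] for the built-in reporter set.
#' @export
reporter_model <- function(name, P_o, S_max, P_c, p_mid, w,
                           baseline = 0, collapse_width = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  vals <- c(P_o = P_o, S_max = S_max, P_c = P_c, p_mid = p_mid, w = w,
            baseline = baseline, collapse_width = collapse_width)
  if (any(!is.finite(vals)))
    stop("all reporter_model parameters must be finite")
  if (!(P_o < p_mid && p_mid < P_c))
    stop("reporter_model requires P_o < p_mid < P_c")
  if (S_max <= 0) stop("S_max must be > 0")
  if (w <= 0) stop("w must be > 0")
  if (baseline < 0) stop("baseline must be >= 0")
  if (collapse_width < 0) stop("collapse_width must be >= 0")
  structure(list(name = name, P_o = P_o, S_max = S_max, P_c = P_c,
                 p_mid = p_mid, w = w, baseline = baseline,
                 collapse_width = collapse_width),
            class = "reporter_model")
}

#' @export
print.reporter_model <- function(x, ...) {
  cat(sprintf(
    "<reporter_model> %s\n  P_o %.0f kPa | S_max %.0f a.u. | P_c %.0f kPa\n  logistic: midpoint %.1f kPa, width %.1f kPa; baseline %.1f; collapse width %.0f kPa\n",
    x$name, x$P_o, x$S_max, x$P_c, x$p_mid, x$w, x$baseline, x$collapse_width))
  invisible(x)
}

#' Calibrate the logistic response so nominal parameters are recoverable
#'
#' Solves `p_mid` and `w` in closed form on the logistic so that the noiseless
#' curve (i) crosses the threshold-estimator detection limit exactly at the
#' nominal `P_o`, and (ii) reaches the fraction `f_cap` of `S_max` at the
#' window cap. This makes the nominal threshold and yield well-posed targets
#' for the estimators in [estimate_po()] and [estimate_smax()].
#'
#' With `z(P) = (P - p_mid)/w` the two conditions are
#' `baseline + S_max * plogis(z(P_o)) = detection_limit` and
#' `plogis(z(cap)) = f_cap`, giving
#' `w = (cap - P_o) / (qlogis(f_cap) - qlogis((detection_limit - baseline)/S_max))`.
#'
#' @inheritParams reporter_model
#' @param detection_limit signal level (a.u.) the threshold estimator uses as
#'   its detection limit; defaults to [control_detection_limit()], the
#'   asymptotic control-mean-plus-two-s.d. level of the GFP-control
#'   replicates.
#' @param cap pressure (kPa) at which the curve reaches `f_cap * S_max`;
#'   defaults to the nondestructive window cap of 1,200 kPa.
#' @param f_cap saturation fraction reached at `cap` (strictly between the
#'   detection fraction and 1).
#' @return a calibrated [reporter_model()].
#' @export
calibrate_reporter <- function(name, P_o, S_max, P_c,
                               detection_limit = control_detection_limit(),
                               cap = 1200, f_cap = 0.998,
                               baseline = 0, collapse_width = 0) {
  f_o <- (detection_limit - baseline) / S_max
  if (!(f_o > 0 && f_o < f_cap && f_cap < 1))
    stop("need 0 < (detection_limit - baseline)/S_max < f_cap < 1")
  if (cap <= P_o) stop("cap must exceed P_o")
  w <- (cap - P_o) / (qlogis(f_cap) - qlogis(f_o))
  p_mid <- P_o - w * qlogis(f_o)
  reporter_model(name, P_o = P_o, S_max = S_max, P_c = P_c,
                 p_mid = p_mid, w = w, baseline = baseline,
                 collapse_width = collapse_width)
}

#' Built-in reporter models
#'
#' Calibrated defaults for the three reporters used throughout: the soft-shell
#' gvpC-deleted construct (threshold 560 kPa, yield 5,900 a.u., collapse
#' 1,220 kPa), the evolved stiff-shell GvpC(L154P) construct (threshold
#' 710 kPa) and the wild-type parent operon (threshold 820 kPa, yield
#' 1,000 a.u.). Collapse pressures of the stiffer reporters are above the
#' nondestructive window and are set at 1,500 and 1,700 kPa.
#'
#' @param detection_limit passed to [calibrate_reporter()].
#' @return named list of three `reporter_model` objects:
#'   `bARG560`, `bARG710`, `bARGSer`.
#' @export
default_reporters <- function(detection_limit = control_detection_limit()) {
  list(
    bARG560 = calibrate_reporter("bARG560", P_o = 560, S_max = 5900,
                                 P_c = 1220, detection_limit = detection_limit),
    bARG710 = calibrate_reporter("bARG710", P_o = 710, S_max = 5000,
                                 P_c = 1500, detection_limit = detection_limit),
    bARGSer = calibrate_reporter("bARGSer", P_o = 820, S_max = 1000,
                                 P_c = 1700, detection_limit = detection_limit)
  )
}

#' Default background noise level
#'
#' Standard deviation (a.u.) of the zero-mean Gaussian background used by the
#' generators; 30 a.u. puts the background peak around the tens of a.u.,
#' two orders of magnitude below in-sample peaks, consistent with the pixel
#' threshold of ~100 a.u. used for in vitro images.
#'
#' @return numeric scalar, a.u.
#' @export
default_noise_sd <- function() 30

#' Asymptotic detection limit derived from GFP-control replicates
#'
#' The threshold estimator's detection limit is the pooled control mean plus
#' two control standard deviations. Control curves are zero-mean Gaussian
#' noise of s.d. `noise_sd` clipped at zero (signal magnitudes), for which
#' the limit has the closed form
#' `noise_sd * (dnorm(0) + 2 * sqrt(1/2 - dnorm(0)^2))`, about
#' `1.566 * noise_sd`. Reporter calibration targets this level so that the
#' noiseless curve crosses the estimator's limit exactly at the nominal
#' threshold.
#'
#' @param noise_sd background noise s.d., a.u.
#' @return detection limit, a.u.
#' @export
control_detection_limit <- function(noise_sd = default_noise_sd()) {
  phi0 <- stats::dnorm(0)
  noise_sd * (phi0 + 2 * sqrt(0.5 - phi0^2))
}

#' Control (GFP) reporter stand-in
#'
#' GFP-expressing cells carry no gas vesicles and produce no pressure-dependent
#' nonlinear signal; their measured curves are background noise only. This is
#' modelled as a degenerate flat response with negligible yield.
#'
#' @return a `reporter_model` whose noiseless curve is ~0 everywhere.
#' @export
gfp_control_model <- function() {
  reporter_model("GFP", P_o = 500, S_max = 1e-6, P_c = 1e6,
                 p_mid = 1000, w = 200, baseline = 0)
}

# ---- pressure schedule ------------------------------------------------------

#' Pressure acquisition schedule
#'
#' @param pressures strictly increasing peak positive pressures, kPa.
#' @param window_cap nondestructive upper limit, kPa (at most `max(pressures)`).
#' @return an object of class `pressure_schedule`.
#' @export
pressure_schedule <- function(pressures, window_cap = 1200) {
  pressures <- as.numeric(pressures)
  if (length(pressures) < 1L || any(!is.finite(pressures)) || any(pressures <= 0))
    stop("pressures must be finite and > 0")
  if (any(diff(pressures) <= 0)) stop("pressures must be strictly increasing")
  if (window_cap > max(pressures)) stop("window_cap must be <= max(pressures)")
  structure(list(pressures = pressures, window_cap = window_cap),
            class = "pressure_schedule")
}

#' Default pressure sweep
#'
#' Sixteen evenly spaced peak positive pressures spanning 330 to 1,840 kPa
#' inclusive (about 100 kPa spacing), with a 1,200 kPa nondestructive window
#' cap set by the collapse pressure of the most fragile reporter.
#'
#' @param n number of acquisitions.
#' @export
default_schedule <- function(n = 16) {
  pressure_schedule(seq(330, 1840, length.out = n), window_cap = 1200)
}

#' @export
print.pressure_schedule <- function(x, ...) {
  cat(sprintf("<pressure_schedule> %d acquisitions, %.0f-%.0f kPa (cap %.0f kPa)\n",
              length(x$pressures), min(x$pressures), max(x$pressures),
              x$window_cap))
  invisible(x)
}

# ---- forward model ----------------------------------------------------------

#' Nonlinear signal of a reporter at one pressure
#'
#' Evaluates the noiseless response curve
#' `(1 - collapsed_fraction) * (baseline + S_max * plogis((P - p_mid)/w))`.
#' Vectorized over `pressure`.
#'
#' @param model a [reporter_model()].
#' @param pressure peak positive pressure(s), kPa, in situ at the sample.
#' @param collapsed_fraction fraction of the population already irreversibly
#'   collapsed, in `[0, 1]`.
#' @return nonlinear signal, a.u.
#' @export
signal_at <- function(model, pressure, collapsed_fraction = 0) {
  stopifnot(inherits(model, "reporter_model"))
  if (any(!is.finite(pressure))) stop("pressure must be finite")
  if (any(pressure <= 0)) stop("pressure must be > 0")
  if (any(collapsed_fraction < 0 | collapsed_fraction > 1))
    stop("collapsed_fraction must be in [0, 1]")
  (1 - collapsed_fraction) *
    (model$baseline + model$S_max * plogis((pressure - model$p_mid) / model$w))
}

#' Collapsed fraction induced by exposure to a pressure
#'
#' Hard step at `P_c` when `collapse_width == 0` (collapse iff the applied
#' pressure exceeds `P_c`), otherwise a logistic transition of the given width
#' centred on `P_c`.
#'
#' @inheritParams signal_at
#' @return collapsed fraction in `[0, 1]`.
#' @export
collapse_fraction <- function(model, pressure) {
  stopifnot(inherits(model, "reporter_model"))
  if (model$collapse_width == 0) {
    as.numeric(pressure > model$P_c)
  } else {
    plogis((pressure - model$P_c) / model$collapse_width)
  }
}

#' Sweep a reporter through a pressure schedule with irreversible collapse
#'
#' Acquires frames in schedule order. Collapse is applied after the frame at a
#' given pressure is recorded (a frame measures the state at transmit time),
#' and is irreversible: the collapsed fraction is the running maximum of the
#' collapse transition evaluated at every pressure applied so far.
#'
#' @param model a [reporter_model()].
#' @param schedule a [pressure_schedule()], or numeric pressures (kPa).
#' @param collapsed_fraction initial collapsed state in `[0, 1]`.
#' @return list with `signals` (a.u., one per scheduled pressure) and
#'   `collapsed_fraction` (final state after the sweep).
#' @export
sweep_with_collapse <- function(model, schedule, collapsed_fraction = 0) {
  p <- schedule_pressures(schedule)
  cf <- collapsed_fraction
  signals <- numeric(length(p))
  for (i in seq_along(p)) {
    signals[i] <- signal_at(model, p[i], cf)
    cf <- max(cf, collapse_fraction(model, p[i]))
  }
  list(signals = signals, collapsed_fraction = cf)
}

schedule_pressures <- function(schedule) {
  if (inherits(schedule, "pressure_schedule")) return(schedule$pressures)
  pressure_schedule(schedule)$pressures
}

# ---- attenuation ------------------------------------------------------------

#' Acoustic attenuation model
#'
#' Frequency-dependent amplitude attenuation `alpha` (dB cm^-1 MHz^-1) at
#' transmit frequency `freq` (MHz). Pressure is an amplitude quantity, so the
#' decibel convention is `20 * log10` throughout.
#'
#' @param alpha attenuation rate, dB cm^-1 MHz^-1 (>= 0). The biologically
#'   relevant soft-tissue default is 0.5.
#' @param freq transmit frequency, MHz (> 0); default 15.625 MHz, the
#'   cross-amplitude-modulation transmit frequency.
#' @return object of class `attenuation_model`.
#' @export
attenuation_model <- function(alpha = 0.5, freq = 15.625) {
  if (!is.finite(alpha) || alpha < 0) stop("alpha must be >= 0")
  if (!is.finite(freq) || freq <= 0) stop("freq must be > 0")
  structure(list(alpha = alpha, freq = freq, convention = "amplitude-dB"),
            class = "attenuation_model")
}

#' In-situ pressure after attenuation through tissue
#'
#' `source_amplitude * 10^(-alpha * freq * depth / 20)` (amplitude-dB
#' convention). Vectorized over `source_amplitude` and `depth`.
#'
#' @param att an [attenuation_model()].
#' @param source_amplitude source peak positive pressure(s), kPa.
#' @param depth depth(s) from the transducer face, cm (>= 0).
#' @return in-situ pressure, kPa.
#' @export
attenuated_pressure <- function(att, source_amplitude, depth) {
  stopifnot(inherits(att, "attenuation_model"))
  if (any(!is.finite(depth)) || any(depth < 0)) stop("depth must be >= 0")
  source_amplitude * 10^(-att$alpha * att$freq * depth / 20)
}

#' Depth at which a source amplitude attenuates to a target pressure
#'
#' Closed-form inverse of [attenuated_pressure()]; useful for locating where
#' an in-situ pressure first drops below a collapse or buckling threshold.
#'
#' @inheritParams attenuated_pressure
#' @param target in-situ pressure, kPa.
#' @return depth in cm (negative if the target exceeds the source amplitude).
#' @export
attenuation_depth_for <- function(att, source_amplitude, target) {
  stopifnot(inherits(att, "attenuation_model"))
  if (att$alpha == 0) stop("no finite depth in a lossless medium")
  20 * log10(source_amplitude / target) / (att$alpha * att$freq)
}

#' Build a depth-by-source-amplitude pressure field
#'
#' @param att an [attenuation_model()].
#' @param source_amplitudes source peak positive pressures, kPa.
#' @param depths strictly increasing depths from the transducer face, cm.
#' @return object of class `pressure_field` with `field` (depth x source
#'   amplitude matrix, kPa), `depths` and `source_amplitudes`.
#' @export
build_pressure_field <- function(att, source_amplitudes, depths) {
  if (length(source_amplitudes) < 1L || length(depths) < 1L)
    stop("source_amplitudes and depths must be nonempty")
  if (length(depths) > 1L && any(diff(depths) <= 0))
    stop("depths must be strictly increasing")
  field <- outer(depths, source_amplitudes,
                 function(d, s) attenuated_pressure(att, s, d))
  dimnames(field) <- list(depth_cm = format(depths, trim = TRUE),
                          source_kpa = format(source_amplitudes, trim = TRUE))
  structure(list(field = field, depths = depths,
                 source_amplitudes = source_amplitudes, att = att),
            class = "pressure_field")
}

#' @export
print.pressure_field <- function(x, ...) {
  cat(sprintf("<pressure_field> %d depths x %d source amplitudes (alpha %.2f dB/cm/MHz @ %.3f MHz)\n",
              length(x$depths), length(x$source_amplitudes),
              x$att$alpha, x$att$freq))
  invisible(x)
}
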