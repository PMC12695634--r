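#' @name gvmux-io
#' @title Readers and writers for pipeline artifacts
#' @description
#' All tabular artifacts are CSV with unit-suffixed headers (`pressure_kpa`,
#' `signal_au`, `depth_mm`); image series are multi-frame TIFF stacks with a
#' JSON sidecar carrying the schedule, depth axis, ROIs and the intensity
#' scaling needed to restore a.u. values from the normalized TIFF samples;
#' reporter/attenuation settings are flat YAML; sequences are FASTA.
NULL

#' Write / read a pressure schedule as CSV
#'
#' Columns `index`, `pressure_kpa`.
#' @param schedule a [pressure_schedule()].
#' @param path CSV file path.
#' @export
write_schedule_csv <- function(schedule, path) {
  p <- schedule_pressures(schedule)
  write.csv(data.frame(index = seq_along(p) - 1L, pressure_kpa = p),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @param window_cap nondestructive cap, kPa (not stored in the CSV).
#' @export
read_schedule_csv <- function(path, window_cap = 1200) {
  df <- read.csv(path)
  pressure_schedule(df$pressure_kpa, window_cap = min(window_cap,
                                                      max(df$pressure_kpa)))
}

#' Write / read reporter and attenuation settings as flat YAML
#'
#' @param models named list of [reporter_model()]s.
#' @param att optional [attenuation_model()].
#' @param path YAML file path.
#' @export
write_reporter_config <- function(models, path, att = NULL) {
  cfg <- list(reporters = lapply(models, function(m)
    m[c("name", "P_o", "S_max", "P_c", "p_mid", "w", "baseline",
        "collapse_width")]))
  if (!is.null(att)) cfg$attenuation <- list(alpha = att$alpha, freq = att$freq)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_reporter_config
#' @export
read_reporter_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  models <- lapply(cfg$reporters, function(r)
    reporter_model(r$name, r$P_o, r$S_max, r$P_c, r$p_mid, r$w,
                   baseline = r$baseline %||% 0,
                   collapse_width = r$collapse_width %||% 0))
  names(models) <- vapply(models, `[[`, "", "name")
  att <- if (!is.null(cfg$attenuation))
    attenuation_model(cfg$attenuation$alpha, cfg$attenuation$freq)
  list(models = models, att = att)
}

#' Write / read a nonlinear image series (TIFF stack + JSON sidecar)
#'
#' The TIFF holds the pressure frames followed by the B-mode and postcollapse
#' frames, normalized to `[0, 1]`; the sidecar (same path with `.json`
#' appended) records the affine intensity scaling, the schedule, the depth
#' axis and the ROI masks, so `read_image_series` restores the object.
#'
#' @param series an `nl_image_series`.
#' @param path TIFF file path (sidecar written next to it).
#' @export
write_image_series <- function(series, path) {
  P <- dim(series$frames)[3L]
  stack <- c(lapply(seq_len(P), function(j) series$frames[, , j]),
             list(series$bmode, series$postcollapse))
  lo <- min(vapply(stack, min, 0))
  hi <- max(vapply(stack, max, 0))
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF(lapply(stack, function(m) (m - lo) / scale),
                  path, bits.per.sample = 32L, reduce = FALSE)
  sidecar <- list(
    n_pressure_frames = P,
    intensity_offset_au = lo, intensity_scale_au = scale,
    schedule = list(pressures_kpa = series$schedule$pressures,
                    window_cap_kpa = series$schedule$window_cap),
    depth_axis_mm = series$depth_axis,
    rois = lapply(series$rois, which),
    meta = series$meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_image_series
#' @export
read_image_series <- function(path) {
  stack <- tiff::readTIFF(path, all = TRUE)
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  restore <- function(m) m * sc$intensity_scale_au + sc$intensity_offset_au
  P <- sc$n_pressure_frames
  Z <- nrow(stack[[1L]]); X <- ncol(stack[[1L]])
  frames <- array(0, dim = c(Z, X, P))
  for (j in seq_len(P)) frames[, , j] <- restore(stack[[j]])
  rois <- lapply(sc$rois, function(idx) {
    m <- matrix(FALSE, Z, X); m[idx] <- TRUE; m
  })
  structure(list(frames = frames,
                 schedule = pressure_schedule(sc$schedule$pressures_kpa,
                                              sc$schedule$window_cap_kpa),
                 bmode = restore(stack[[P + 1L]]),
                 postcollapse = restore(stack[[P + 2L]]),
                 depth_axis = sc$depth_axis_mm,
                 rois = rois,
                 meta = as.list(sc$meta)),
            class = "nl_image_series")
}

#' Write / read a multiplexing matrix as CSV
#'
#' Rows are reporters (first column `reporter`), remaining headers are
#' `p_<pressure>` in kPa.
#'
#' @param M a [multiplex_matrix()].
#' @param path CSV file path.
#' @export
write_multiplex_matrix <- function(M, path) {
  p <- schedule_pressures(M$schedule)
  df <- data.frame(reporter = M$reporters, M$M, check.names = FALSE)
  names(df)[-1L] <- paste0("p_", format(round(p, 1), trim = TRUE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_multiplex_matrix
#' @param window_cap cap associated with the stored schedule, kPa.
#' @export
read_multiplex_matrix <- function(path, window_cap = NULL) {
  df <- read.csv(path, check.names = FALSE)
  p <- as.numeric(sub("^p_", "", names(df)[-1L]))
  if (is.null(window_cap)) window_cap <- max(p)
  multiplex_matrix(as.matrix(df[, -1L, drop = FALSE]), df$reporter,
                   pressure_schedule(p, min(window_cap, max(p))))
}

#' Write a depth-resolved multiplexing matrix (one CSV per depth + index)
#'
#' @param m2d a [build_m2d()] result.
#' @param dir output directory (created if needed).
#' @export
write_m2d <- function(m2d, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("m_depth_%03d.csv", seq_along(m2d$depth_axis))
  for (i in seq_along(m2d$depth_axis)) {
    mm <- multiplex_matrix(m2d$stack[[i]], m2d$reporters, m2d$schedule)
    write_multiplex_matrix(mm, file.path(dir, files[i]))
  }
  write.csv(data.frame(depth_mm = m2d$depth_axis, file = files),
            file.path(dir, "index.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write a coefficient map (channel TIFF + CSV summary)
#'
#' @param cmap a `coefficient_map`.
#' @param path TIFF path for the channel stack; a `_summary.csv` with
#'   per-channel means over the unmixed pixels is written next to it.
#' @export
write_coefficient_map <- function(cmap, path) {
  N <- dim(cmap$C)[3L]
  hi <- max(cmap$C, 1e-12)
  tiff::writeTIFF(lapply(seq_len(N), function(k) cmap$C[, , k] / hi),
                  path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(reporters = cmap$reporters,
                            intensity_scale_au = hi,
                            unmixed_pixels = sum(cmap$mask)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  if (any(cmap$mask)) {
    sm <- channel_means(cmap, cmap$mask)
    write.csv(sm, sub("\\.tiff?$", "_summary.csv", path), row.names = FALSE)
  }
  invisible(path)
}

#' Write / read a screening plate as CSV
#'
#' One row per variant (`variant_id`, `S_B`, `postcollapse_signal`, truth
#' columns when present, then mean-curve columns `p_<kpa>`); replicate curves
#' go to a companion long-format CSV (`variant_id`, `replicate`,
#' `pressure_kpa`, `signal_au`).
#'
#' @param plate a `screen_plate`.
#' @param path main CSV path; the replicate CSV gets a `_curves` suffix.
#' @export
write_screen_plate <- function(plate, path) {
  p <- schedule_pressures(plate$schedule)
  means <- t(vapply(plate$curves, colMeans, numeric(length(p))))
  colnames(means) <- paste0("p_", format(round(p, 1), trim = TRUE))
  write.csv(cbind(plate$records, as.data.frame(means)), path,
            row.names = FALSE)
  long <- do.call(rbind, lapply(names(plate$curves), function(id) {
    cur <- plate$curves[[id]]
    data.frame(variant_id = id,
               replicate = rep(seq_len(nrow(cur)), times = ncol(cur)),
               pressure_kpa = rep(p, each = nrow(cur)),
               signal_au = as.vector(cur))
  }))
  write.csv(long, sub("\\.csv$", "_curves.csv", path), row.names = FALSE)
  invisible(path)
}

#' @rdname write_screen_plate
#' @param window_cap cap for the reconstructed schedule, kPa.
#' @export
read_screen_plate <- function(path, window_cap = 1200) {
  records <- read.csv(path, check.names = FALSE)
  records <- records[, !grepl("^p_", names(records)), drop = FALSE]
  long <- read.csv(sub("\\.csv$", "_curves.csv", path))
  p <- sort(unique(long$pressure_kpa))
  n_rep <- max(long$replicate)
  curves <- lapply(split(long, long$variant_id), function(d) {
    d <- d[order(d$pressure_kpa, d$replicate), ]
    matrix(d$signal_au, nrow = n_rep,
           dimnames = list(replicate = seq_len(n_rep),
                           pressure_kpa = format(round(p, 1), trim = TRUE)))
  })
  curves <- curves[records$variant_id]
  structure(list(records = records, curves = curves,
                 schedule = pressure_schedule(p, min(window_cap, max(p))),
                 noise_sd = NA_real_, n_rep = n_rep),
            class = "screen_plate")
}

#' FASTA output / input for variant sequence sets
#'
#' @param variants a `variant_set` or named character vector of sequences.
#' @param path FASTA file path.
#' @export
write_variants_fasta <- function(variants, path) {
  if (inherits(variants, "variant_set")) variants <- variants$sequences
  Biostrings::writeXStringSet(Biostrings::AAStringSet(variants), path)
  invisible(path)
}

#' @rdname write_variants_fasta
#' @export
read_fasta_sequences <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  setNames(as.character(s), names(s))
}
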